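---
title: "Ranking plant species as ecological engineers for unstable slopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking plant species as ecological engineers for unstable slopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slopetraits)
```

## The problem

Shallow landslides and severe erosion on steep, deforested slopes are often
driven by small degradation *hotspots*. Revegetating a hotspot with the right
species is a cheap and durable fix, but "right" is a multi-trait question:
roots must occupy the soil (abundance), resist tension and bending
(mechanics), and stay metabolically active and long-lived (physiology).
`slopetraits` implements a complete trait-measurement and score-synthesis
pipeline for comparing candidate species on these three properties, modelled
on a field campaign of nine pioneer species (herbs, shrubs, a creeper, a
liana and trees) on degraded slopes of the Salween valley, Yunnan.

The pipeline has four stages, each exposed as package functions and driven
by the numbered scripts under `analysis/`:

1. **simulate** (or load) per-root measurement records,
2. reduce them to **architectural**, **mechanical** and **soil** traits,
3. assign per-trait **1/2/3 scores** and synthesise them into property
   globals,
4. emit **placement** recommendations on a hotspot.

## Trait models

### Architecture

The *individual soil volume* (ISV) is the envelope a plant's roots occupy.
For radial root systems each slope sector (up, down) contributes a quarter
of an ellipsoid of revolution: horizontal semi-axes equal to the sector's
maximal radius $r$, vertical semi-axis the maximal rooting depth $z$, giving
$\tfrac{1}{3}\pi r^2 z$ per sector (the below-ground half-ellipsoid split
into up- and downslope halves). Species whose roots are organised linearly
along a horizontal stem (creepers, underground stems) use a quarter
*cylinder* per sector instead: length $L$ along the stem, elliptical
cross-section with semi-axes $r$ and $z$, volume $\tfrac{\pi}{4} r z L$.
Per-layer volumes are obtained by horizontal **slab slicing** of the solid
(an analytic integral, tested against Monte-Carlo volume integration to
0.5%); proportional allocation was the alternative convention and was
rejected because slicing is the only one that is exact for the stated
geometry. ISV is standardised by the collar diameter $D_c$ so individuals
of different sizes compare fairly.

The *root area ratio* (RAR) is the cumulated root cross-sectional area per
soil area crossing a plane; for roots crossing a layer perpendicularly this
equals cumulated root volume per soil volume, $\sum V_r /(A h)$, which is
how the package computes it from segment records (cylinder volumes where
volume was not measured directly). Roots split at 2 mm into fine and coarse
classes; the boundary diameter is assigned to the coarse class so the two
published class intervals stay disjoint. By default the reference area $A$
of a (sector, layer) cell is the footprint of the ISV solid at the top of
that layer; a fixed $A$ can be supplied instead (`system_rar()`).

### Mechanics

Tensile records are force-displacement curves. The **break** is the global
force maximum, accepted when the record afterwards drops by at least 30% of
the peak; a curve that ends still ascending has no detectable break and the
specimen is invalid. Then $T_{max} = F_{break}/CSA$ (circular section on the
mean of three diameter readings) and
$\varepsilon_{ult} = 100\,u_{break}/L_0$ with $L_0$ the initial gauge
length (raw displacement origin; no toe correction). Specimens are excluded
when they failed outside the middle third, slipped in the clamps, or have a
gauge shorter than 30 diameters. The strength-diameter relation
$T_{max} = \alpha D^{-\beta}$ is fitted by OLS on $(\log D, \log T_{max})$
— matching the logarithmic presentation conventional for these data and
making multiplicative scatter homoskedastic — with $\beta > 0$ meaning
strength decreasing with diameter; no invalid specimen ever enters a fit.

Bending records use the three-point central-load relation
$F = 48 E I \delta / L^3$: the stiffness $k$ is the best-$R^2$ linear slope
of the load-deflection curve within the 10-40% force band ("shortly after
the beginning of the test"), $E = k L^3/(48 I)$, and the second moment of
an elliptical section is $I = \pi w d^3/64$ (depth diameter $d$ in the
loading direction; $\pi d^4/64$ for circular sections). Rigidity $EI$ is
reported in kN mm². Tests below the span/depth threshold (default 10) are
invalid (shear contamination). The elastic-window bounds are configurable
(`mech_config()`) because "shortly after the beginning" is qualitative; the
best-$R^2$ sliding window makes the choice reproducible.

### Soil

Gravimetric water contents and dry bulk density follow the mass-ratio
definitions $w_i = 100 (m_i - m_d)/m_d$, $w_s = 100 (m_s - m_d)/m_d$
(percent of dry mass), $\rho_d = m_d/v$. Direct-shear records are converted
to stresses over the 60 mm × 60 mm box plan area (the 200/300/500 N
protocol loads map to normal stresses 55.56/83.33/138.89 kPa) and the
Mohr-Coulomb envelope $\tau = c + \sigma\tan\phi$ is fitted by OLS on
stresses, so $c$ and $\phi$ carry their conventional units directly. A
negative fitted intercept is reported with a warning rather than clipped:
clipping would silently bias site comparisons.

**Identifiability caveat.** The envelope's slope ($\phi$) is well
determined by a triplet design, but the intercept is not: with eight
triplets and 10% stress noise the intercept's standard error is ~3-5 kPa,
i.e. the same order as the cohesion of weakly cohesive slope soils (the
published hotspot value, 0.49 ± 0.92 kPa, has a standard error twice the
estimate). Parameter-recovery tests for $c$ are therefore meaningful only
in relative terms for cohesive operating points (the suite uses 40 kPa at
n = 200); at field-realistic cohesions only the *absolute* uncertainty is
controlled. This is a property of the measurement design, not of the code.

## Score synthesis

Each trait is scored 1 (poor), 2 (average), 3 (good). Scores combine
pairwise through a fixed rule table, **not** arithmetic:
(1,1)→1, (3,3)→3, (1,3)→2, (1,2)→1, (3,2)→3, plus (2,2)→2 and symmetry,
which the published scorecard's cells force (e.g. "2*2 = 2", "2*1 = 1")
though they are absent from the stated rule list. The operator is
idempotent and bounded but **non-associative** — (1,1,3) folds to 2 while
(1,3,1) folds to 1 — so sequences are left-folded in a declared order.

Two composites precede the mechanical fold: tension = fine-RAR ⊗ T$_{max}$
and bending = coarse-RAR ⊗ EI (strength and rigidity only matter in
proportion to how much root of that class is present). The three property
globals fold:

* abundance: (stems m⁻², ISV/D$_c$, RAR);
* mechanical: (tension, bending, ε$_{ult}$);
* physiological: (ε$_{ult}$, cellulose, nitrogen).

The physiological order deviates from the display order of the trait rows
(strain, nitrogen, cellulose): because the operator is non-associative the
two orders differ, and only (strain, cellulose, nitrogen) reproduces the
published globals for every species — the display order disagrees for
*F. tikoua* (2 vs 1) and *P. stricta* (2 vs 3). Fold orders are therefore
explicit, configurable arguments with these defaults.

How raw trait values map to 1/2/3 was never published, so `assign_scores()`
offers two modes: `"fixture"` returns the shipped published scorecard
verbatim (including its two diverging ε$_{ult}$ columns, kept unreconciled),
and `"tertile"` ranks species per trait — respecting polarity, ε$_{ult}$
being the only lower-better trait — and cuts the ranking into thirds, with
average-rank-then-lexicographic tie-breaking (deterministic, seedless).
Tertile scores on synthetic data are *not* claimed to match the published
assignments.

### Placement

Where on a hotspot should a species go? Roots biased upslope of the stem
have the best chance of crossing the potential shear plane when the plant
sits at the **top**; a downslope bias points to the **toe**; desirable
traits concentrated at depth (without a sector bias) reinforce the deep
shear zone in the **middle**; a shallow concentration suits **top or toe**
where the shear plane is shallowest. `recommend_position()` applies this
cascade to a per-species profile of sector/depth biases, each of which must
cite trait-level evidence; the shipped profiles encode the field
observations (e.g. *P. stricta*: more numerous, stronger roots upslope →
top).

```{r}
placement_table()[c("species", "position")]
```

## The synthetic-data generators

No raw field data were ever deposited, so the package ships a generator
for every record type, parameterised by nine species *archetypes*
(`default_archetypes()`) that encode the qualitative root-system
descriptions: taproots deep and densely branched for *P. stricta*, a tufted
shallow system for *C. anomala*, linear layouts for *A. americana* and
*F. tikoua* (whose strength *rises* with diameter: negative β), and so on.
Archetype numbers are plausible fixtures reproducing orderings (strongest
and least extensible fine roots for *P. stricta*, ε$_{ult}$ highest for
*F. tikoua*…), not estimates of the unpublished data; segment lengths and
branching counts are explicitly arbitrary, since no distributional
information about them was published.

Generator structure, chosen once:

* diameters are lognormal (positive, heavy-tailed, spanning 0.1 to >2 mm);
* tensile strength noise is multiplicative lognormal with log-mean zero,
  so log-log fitting is unbiased and residuals homoskedastic;
* tensile curves are three-phase — concave toe (stretching), linear
  elastic, shallower linear plastic to the break — then a sharp drop, so
  break detection and modulus extraction face realistic shapes;
* bending curves are linear at stiffness $48EI/L^3$ then soften;
* shear noise is homoskedastic Gaussian with sd = `noise_cv` × mean
  envelope stress; quadrat counts are Poisson.

All generators are deterministic given `generator_config(seed = …)`; with
`noise_cv = 0` every analysis routine recovers the generating truth to
machine precision (round-trip invariant). What passing tests on these data
do **not** show: recovery of the real field means and variances, realism of
branching geometry, clamp/slippage physics, or rate effects — the
generators emulate statistical structure, not a particular slope.

## Numerical choices and test scale

Degenerate inputs: zero depth or radius gives zero ISV; a curve with no
force drop is invalid rather than an error; an all-invalid specimen set
makes fitting fail loudly; missing segment volumes fall back to cylinder
geometry and error only when diameter or length is also absent; a linear
layout without a measured stem length is an error (never inferred).

Default problem sizes keep the full suite fast while leaving comfortable
statistical margins: Monte-Carlo geometry checks use 10⁶ points per cell of
a 5 × 5 extent grid (MC relative se ≈ 0.1%, against a 0.5% band);
power-law recovery uses 100 replicates of 200 specimens at 20% noise
(predicted per-replicate failure odds ≪ 1%, against a ≥95% requirement);
the pipeline demonstration uses 9 species × 3 plants × 60 tensile tests.

## Known limitations

* The score synthesis is exactly the published rule system; no weighting,
  AHP-style extensions, or uncertainty propagation into scores.
* The Mohr-Coulomb intercept is weakly identifiable at triplet-design
  sample sizes (see above); cohesion comparisons between weakly cohesive
  sites need many more specimens than the protocol's eight.
* Tertile scoring is one defensible mapping from trait values to 1/2/3;
  with nine species it forces three species per level per trait, which the
  published assignments do not always respect.
* No 3-D root reconstruction, topology, factor-of-safety or root-cohesion
  (Wu/Waldron) modelling: the package ends where the scorecard and
  placement map end.
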