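# slopetraits

Rank plant species as "ecological engineers" for fixing soil on unstable
slopes. The package is written for researchers and restoration managers who
need to compare candidate species — herbs, shrubs, creepers, lianas, trees —
by the root traits that matter for shallow-landslide and erosion control,
and to decide *where* on a degradation hotspot each species is most useful.
It implements the full chain from raw measurement records to a
multi-criteria scorecard, modelled on a field study of nine pioneer species
on degraded slopes of the Salween valley (Yunnan, China).

## What it computes

**Architectural traits.** Individual soil volume (ISV), the envelope a root
system occupies: quarter-ellipsoids of revolution per slope sector
(`(1/3)πr²z`; up- and downslope radii may differ) for radial systems,
quarter-cylinders (`(π/4)rzL`) for species whose roots hang off a
horizontal stem; partitioned into 10-cm depth layers by slab slicing and
standardised by collar diameter (ISV/Dc). Root area ratio (RAR) per depth
layer, slope sector and diameter class (fine < 2 mm ≤ coarse), computed as
cumulated root volume per soil volume, `RAR = ΣV_r/(A·h)`.

**Mechanical traits.** From tensile force–displacement records: maximal
tensile stress `T_max = F_break/CSA`, ultimate strain
`ε_ult = 100·u_break/L₀`, tensile modulus, with specimen-validity filtering
(middle-third failure, no clamp slippage, gauge ≥ 30 diameters, detectable
break) and the power law `T_max = α·D^−β` fitted by log–log OLS over valid
specimens. From three-point bending records: `I = πwd³/64`,
`E = kL³/(48I)`, rigidity `EI` (kN·mm²), with a span/depth validity
threshold.

**Soil traits.** Gravimetric water contents `w = 100(m−m_d)/m_d`, dry bulk
density `ρ_d = m_d/v`, and the Mohr-Coulomb envelope `τ = c + σ·tan φ`
fitted on stresses from direct-shear records (60-mm box, 200/300/500 N
loads → σ = 55.56/83.33/138.89 kPa).

**Score synthesis.** Each trait scores 1 (poor) / 2 (average) / 3 (good);
scores combine through a fixed, symmetric, *non-associative* rule table —
(1,1)→1, (3,3)→3, (1,3)→2, (1,2)→1, (3,2)→3, (2,2)→2 — folded in declared
orders into composite tension/bending scores and three property globals
(root abundance, mechanical resistance, physiological properties). The
shipped fixture reproduces the published nine-species scorecard exactly; a
tertile mode scores arbitrary trait tables. A rule cascade over depth and
slope-sector trait biases then recommends a hotspot position (top / middle
/ toe / top-or-toe).

**Synthetic data.** Because the study's raw field data were never
deposited, a generator module emulates every record type (root systems,
tensile/bending curves, shear tests, soil samples, quadrat counts) from
nine species archetypes, deterministically from a seed, with exact
noiseless round trips — so the whole pipeline is testable from a clean
checkout.

## Worked example

```r
library(slopetraits)

cards <- score_cards(reference_trait_scores())
subset(cards, species %in% c("P. stricta", "A. hispidus"))
#>       species composite_tension composite_bending global_abundance
#> 3 A. hispidus                 3                 1                2
#> 8  P. stricta                 3                 3                2
#>   global_mechanical global_physiological
#> 3                 1                    1
#> 8                 3                    3
```

*P. stricta* combines strong fine roots (tension composite 3) with rigid
coarse roots (bending composite 3) and short, recoverable strains, giving
the top global profile (2, 3, 3) — shared only by *A. codonocephala* —
while *A. hispidus*'s few thin roots leave it poor on both mechanics and
physiology. Placement follows from trait biases:

```r
recommend_position("up", "shallow",
                   evidence = "more numerous and stronger roots upslope")
#> [1] "top"
```

The numbered scripts under `analysis/` run the whole chain on a simulated
campaign (`01_simulate.R` … `05_scores.R`), writing stage tables under
`results/`; `run_pipeline(pipeline_config(seed = 1))` does the same in one
call and writes a JSON manifest with the seed and file checksums, so every
run is reproducible from its manifest alone.

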