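#!/usr/bin/env Rscript
# Architectural traits: individual soil volume (ISV), ISV standardised by
# collar diameter, and root area ratio by depth layer, slope sector and
# fine/coarse class, for every simulated plant.

library(slopetraits)

cfg <- pipeline_config(seed = 1, out_dir = "results")
camp <- simulate_campaign(cfg)

tab <- do.call(rbind, lapply(names(camp$systems), function(sp) {
  arch_traits(camp$systems[[sp]], layer_height = cfg$layer_height,
              fine_boundary = cfg$fine_boundary)
}))
dir.create("results", showWarnings = FALSE)
write.csv(tab, "results/arch_traits.csv", row.names = FALSE)

per_sp <- aggregate(cbind(isv_over_dc = isv_over_dc) ~ species,
                    data = unique(tab[c("species", "plant_id", "isv_over_dc")]),
                    FUN = mean)
cat("Mean ISV/Dc per species (m^3 cm^-1):\n")
print(per_sp[order(-per_sp$isv_over_dc), ], row.names = FALSE)
cat("\nDeep, wide root systems (climber/taproot archetypes) occupy the\n")
cat("largest standardised soil volumes; tufted shallow herbs the smallest.\n")
cat("Full per-layer table in results/arch_traits.csv\n")
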