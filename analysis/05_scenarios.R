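#!/usr/bin/env Rscript
# Step 5: perturbation scenarios on the reference census.
#
# Three textbook perturbations of the healthy reference state, evaluated
# as multiplicative modifiers on the census: localized lymphadenopathy
# (a small fraction of lymph-node mass enlarged by the cube-law volume
# factor), splenomegaly (spleen mass doubled), and obesity (adipose mass
# tripled with a tenfold adipose macrophage density).

library(immunecensus)

SEED <- 2023
densities <- utils::read.csv("results/densities.csv")
tissues <- utils::read.csv("results/synthetic_inputs/tissues.csv")

run <- function(name, modifiers) {
  sc <- apply_scenario(densities, modifiers, person = "male",
                       tissues = tissues, seed = SEED)
  message(sprintf("%s: grand total %+.1f%%", name,
                  100 * sc$grand_rel_change))
  chg <- sc$change[abs(sc$change$rel_change) > 1e-12, ]
  for (i in seq_len(nrow(chg))) {
    message(sprintf("  %s %+.1f%%", chg$tissue_id[i],
                    100 * chg$rel_change[i]))
  }
  transform(chg, scenario = name)
}

# diameter doubling of affected nodes: volume x 8; here 2% of lymph-node
# mass enlarged 11-fold (midpoint of the 8-15 factor range) -> +20% there
message(sprintf("cube law: diameter x2 -> volume x%d",
                volume_scale_from_diameter(2)))
out <- rbind(
  run("lymphadenopathy",
      data.frame(tissue_id = "lymph_nodes", cell_type = NA_character_,
                 factor = 11, fraction = 0.02)),
  run("splenomegaly",
      data.frame(tissue_id = "spleen", cell_type = NA_character_,
                 factor = 2, fraction = 1)),
  run("obesity",
      data.frame(tissue_id = c("adipose", "adipose"),
                 cell_type = c(NA_character_, "macrophage"),
                 factor = c(3, 10), fraction = c(1, 1))))

utils::write.csv(out, "results/scenarios.csv", row.names = FALSE)
message("wrote results/scenarios.csv")
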