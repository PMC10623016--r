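#!/usr/bin/env Rscript
# Step 2: evidence tables -> per-gram density table.
#
# Normalizes every literature record to cells/g, aggregates the
# multiplexed-imaging counts per patient and tissue, combines the two
# methods by inverse-variance weighting in log space, and fills the
# remaining (tissue, cell type) gaps by cross-species and tissue-group
# extrapolation (restricted cell types excepted). Writes the final
# density table and the extrapolation audit log.

library(immunecensus)

SEED <- 2023
indir <- "results/synthetic_inputs"

evidence <- read_density_evidence(file.path(indir, "evidence.csv"))
multiplex <- read_multiplex_counts(file.path(indir, "multiplex.csv"))
sizes <- read_size_records(file.path(indir, "sizes.csv"))
tissues <- utils::read.csv(file.path(indir, "tissues.csv"))

norm <- normalize_evidence(evidence, tissues, person = "male", seed = SEED)
human <- norm[norm$species == "human", ]
nonhuman <- norm[norm$species == "nonhuman", ]
message(sprintf("normalized %d human and %d non-human evidence groups",
                nrow(human), nrow(nonhuman)))

mx <- multiplex_density_table(multiplex, tissues)
message(sprintf("multiplex densities for %d (tissue, cell type) strata",
                nrow(mx)))

combined <- combine_methods(human, mx, tissues)
filled <- fill_missing_densities(combined, nonhuman, tissues)
n_extrap <- sum(filled$densities$method == "extrapolated")
message(sprintf("density table: %d pairs (%d extrapolated, %d flagged)",
                nrow(filled$densities), n_extrap,
                sum(filled$audit$discrepant)))

utils::write.csv(filled$densities, "results/densities.csv",
                 row.names = FALSE)
utils::write.csv(filled$audit, "results/extrapolation_audit.csv",
                 row.names = FALSE)
message("wrote results/densities.csv and results/extrapolation_audit.csv")
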