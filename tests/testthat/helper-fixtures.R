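# Shared fixture builders. Everything is generated in code; no files.

# Monte-Carlo sampler of a lognormal estimate: median v, shape ln(f).
rlognorm_est <- function(n, v, f) {
  v * exp(log(f) * stats::rnorm(n))
}

# A tiny density table covering three tissues and two cell types, exact.
tiny_density_table <- function() {
  data.frame(
    tissue_id = c("spleen", "spleen", "liver", "liver", "skin"),
    cell_type = c("T cell", "macrophage", "T cell", "macrophage", "T cell"),
    value = c(5e8, 4e7, 1e7, 2e7, 6e6),
    ferror = c(1.5, 2, 1.4, 1.6, 1.3),
    stringsAsFactors = FALSE
  )
}

# Minimal size-record table covering every census cell type.
tiny_size_records <- function() {
  base <- data.frame(
    cell_type = setdiff(cell_types(), "macrophage"),
    tissue = NA_character_,
    diameter_low_um = c(7.5, 7.5, 14, 8.5, 8.8, 9, 9, 12.6, 9.5, 15.3),
    diameter_high_um = NA_real_,
    volume_um3 = NA_real_,
    context = "tissue section",
    species = "human",
    source = "fixture",
    stringsAsFactors = FALSE
  )
  mac <- data.frame(
    cell_type = "macrophage",
    tissue = c("liver", "gi_tract", NA_character_),
    diameter_low_um = c(21, 15, 18),
    diameter_high_um = NA_real_,
    volume_um3 = NA_real_,
    context = "tissue section",
    species = "human",
    source = "fixture",
    stringsAsFactors = FALSE
  )
  rbind(base, mac)
}

# Long-format multiplex table from a matrix of per-sample totals.
multiplex_from_counts <- function(tissue, patient_ids, sample_ids, counts,
                                  cell_type = "T cell",
                                  field_area_um2 = 160000) {
  data.frame(sample_id = sample_ids, patient_id = patient_ids,
             tissue_id = tissue, cell_type = cell_type, count = counts,
             field_area_um2 = field_area_um2, stringsAsFactors = FALSE)
}
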