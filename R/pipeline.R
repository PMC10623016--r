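#' Run the full census pipeline on an input bundle
#'
#' The end-to-end path from raw evidence to the whole-body censuses:
#' 1. normalize literature evidence to per-gram densities (human and
#'    non-human kept separate);
#' 2. aggregate multiplexed-imaging counts to per-gram densities;
#' 3. combine literature and multiplex per pair by inverse-variance
#'    weighting in log space;
#' 4. fill gaps by cross-species / tissue-group extrapolation, honoring
#'    tissue restrictions;
#' 5. integrate densities with the reference person's organ masses into a
#'    count census with bootstrap margins;
#' 6. resolve representative cell masses and derive the mass census.
#'
#' Deconvolution tables in the bundle are never consumed here — they feed
#' [validate_deconvolution()] only, and the censuses are identical with or
#' without them.
#'
#' @param bundle A list with `evidence`, `sizes`, `tissues`, and
#'   optionally `multiplex` (see [generate_bundle()] for the shapes, and
#'   the `read_*` functions for file-based input).
#' @param person Reference person for the organ masses.
#' @param seed Seed controlling every bootstrap in the run.
#' @param n_draws Bootstrap draws for all margins.
#' @param multiplex_weight Weight multiplier for multiplex estimates in
#'   lymphatic tissues.
#' @param species_penalty ferror multiplier for non-human evidence.
#' @return A list: `densities` (final per-gram table), `audit`
#'   (extrapolation log), `counts` and `masses` (`census_table`s),
#'   `mass_table` (per-type representative masses), `multiplex`
#'   (the aggregated multiplex densities).
#' @export
run_census_pipeline <- function(bundle, person = "male", seed = 2023,
                                n_draws = 1000, multiplex_weight = 1,
                                species_penalty = 1.5) {
  tissues <- if (is.null(bundle$tissues)) tissue_table() else bundle$tissues
  norm <- normalize_evidence(bundle$evidence, tissues, person = person,
                             seed = seed)
  human <- norm[norm$species == "human", , drop = FALSE]
  nonhuman <- norm[norm$species == "nonhuman", , drop = FALSE]

  mx_table <- NULL
  if (!is.null(bundle$multiplex) && nrow(bundle$multiplex) > 0) {
    mx_table <- multiplex_density_table(bundle$multiplex, tissues)
  }
  combined <- combine_methods(human, mx_table, tissues, multiplex_weight)
  filled <- fill_missing_densities(combined, nonhuman, tissues,
                                   species_penalty = species_penalty)
  counts <- integrate_counts(filled$densities, person, tissues,
                             n_draws = n_draws, seed = seed)
  mass_table <- representative_mass_table(bundle$sizes, tissues,
                                          species_penalty = species_penalty)
  masses <- mass_census(counts, mass_table)
  list(densities = filled$densities, audit = filled$audit,
       counts = counts, masses = masses, mass_table = mass_table,
       multiplex = mx_table)
}

#' Validate the census against deconvolution-derived counts
#'
#' Anchors the bundle's deconvolution fractions to absolute per-tissue
#' group counts and contrasts them with the census counts rolled up to
#' the same groups. Validation only: the census is not altered.
#'
#' @param bundle A bundle with `fractions` and `anchors` tables.
#' @param counts The count `census_table` to validate.
#' @return The comparison table of [compare_to_reference()], plus a
#'   `granulocyte_bias` attribute (mean log10 ratio of the granulocyte
#'   group, the direction deconvolution is known to underestimate).
#' @export
validate_deconvolution <- function(bundle, counts) {
  deconv <- cluster_and_average(bundle$fractions, bundle$anchors)
  ref <- rollup_to_groups(
    data.frame(tissue_id = counts$entries$tissue_id,
               cell_type = counts$entries$cell_type,
               value = counts$entries$value,
               ferror = counts$entries$ferror,
               stringsAsFactors = FALSE))
  cmp <- compare_to_reference(deconv, ref)
  gran <- cmp$log10_ratio[cmp$group == "granulocyte"]
  attr(cmp, "granulocyte_bias") <- if (length(gran)) mean(gran) else NA_real_
  cmp
}

#' Coverage experiment over seeded synthetic replicates
#'
#' Regenerates a synthetic world and reruns the full pipeline `n_reps`
#' times with seeds `base_seed + 1 ... base_seed + n_reps`, recording
#' whether each replicate's bootstrap 95% CI for the grand total covers
#' the replicate's true grand total, and the signed log10 error of the
#' point estimate.
#'
#' @param n_reps Number of replicates.
#' @param base_seed Offset for the per-replicate seeds.
#' @param n_draws Bootstrap draws per replicate (margins only need the
#'   grand total here).
#' @param ... Overrides passed to [synth_config()].
#' @return A data.frame with one row per replicate: `seed`, `truth`,
#'   `estimate`, `ci_low`, `ci_high`, `covered`, `log10_error`.
#' @export
coverage_experiment <- function(n_reps = 100, base_seed = 1000,
                                n_draws = 1000, ...) {
  rows <- lapply(seq_len(n_reps), function(r) {
    cfg <- synth_config(seed = base_seed + r, ...)
    bundle <- generate_bundle(cfg)
    res <- run_census_pipeline(bundle, person = "male",
                               seed = base_seed + r, n_draws = n_draws)
    truth <- bundle$truth$male$grand_count
    g <- res$counts$grand
    data.frame(seed = base_seed + r, truth = truth,
               estimate = g[["value"]],
               ci_low = g[["ci_low"]], ci_high = g[["ci_high"]],
               covered = truth >= g[["ci_low"]] & truth <= g[["ci_high"]],
               log10_error = log10(g[["value"]] / truth))
  })
  do.call(rbind, rows)
}
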