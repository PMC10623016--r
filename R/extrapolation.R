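#' Cross-species extrapolation of a cell density
#'
#' When no human measurement exists for a (tissue, cell type) pair, rodent
#' or monkey densities for the same pair are pooled by geometric mean. A
#' species penalty inflates each record's ferror (default x1.5) so that
#' extrapolated values are always down-weighted against direct human
#' evidence in any later combination.
#'
#' @param records Data.frame of normalized non-human density records for
#'   one (tissue, cell type): columns `value`, `ferror`.
#' @param species_penalty Multiplier applied to each record's ferror.
#' @return A `lognormal_estimate`, or `NULL` (not-applicable sentinel)
#'   when no records exist.
#' @export
extrapolate_cross_species <- function(records, species_penalty = 1.5) {
  if (is.null(records) || nrow(records) == 0) return(NULL)
  geometric_pool(lognormal_estimate(records$value,
                                    records$ferror * species_penalty))
}

#' Tissue-group geometric-mean extrapolation
#'
#' Pools the human densities of the same cell type measured in other
#' tissues of the target's similarity group. The ferror reflects the
#' between-tissue log spread, floored (default 1.5) so a lucky agreement
#' between two tissues never produces an overconfident extrapolation.
#'
#' @param records Data.frame of normalized human density records of the
#'   cell type in same-group tissues: columns `value`, `ferror`.
#' @param floor_ferror Minimum ferror of the result.
#' @return A `lognormal_estimate`, or `NULL` when the group is empty.
#' @export
extrapolate_group_mean <- function(records, floor_ferror = 1.5) {
  if (is.null(records) || nrow(records) == 0) return(NULL)
  geometric_pool(lognormal_estimate(records$value, records$ferror),
                 floor_ferror = floor_ferror)
}

#' Combine the two extrapolation strategies
#'
#' The point value is the geometric mean of the cross-species and
#' group-mean extrapolations (or the single available one); the ferror is
#' the larger input ferror. Pairs whose two strategies disagree by more
#' than a factor of 2 are flagged — historically the two routes agree
#' within that factor, so a flag marks a pair worth manual review.
#'
#' @param a Cross-species result (`lognormal_estimate` or `NULL`).
#' @param b Group-mean result (`lognormal_estimate` or `NULL`).
#' @return `NULL` if both are `NULL`; else a `lognormal_estimate` with
#'   attribute `discrepant` (logical).
#' @export
combine_extrapolations <- function(a, b) {
  if (is.null(a) && is.null(b)) return(NULL)
  if (is.null(a) || is.null(b)) {
    out <- if (is.null(a)) b else a
    attr(out, "discrepant") <- FALSE
    return(out)
  }
  ratio <- max(a$value, b$value) / min(a$value, b$value)
  out <- lognormal_estimate(sqrt(a$value * b$value),
                            max(a$ferror, b$ferror))
  attr(out, "discrepant") <- ratio > 2
  out
}

#' Fill density gaps by extrapolation
#'
#' For every (tissue, cell type) pair of the tissue table with no direct
#' human estimate, attempts cross-species extrapolation (from non-human
#' records of the same pair) and tissue-group extrapolation (from human
#' estimates of the same cell type in same-group tissues), combining the
#' two. Tissue-restricted cell types (eosinophils, mast cells, basophils)
#' are never extrapolated outside their home tissues. Every filled pair is
#' assigned a correlation group keyed by its evidence source, so that
#' totals treat extrapolations sharing a source as perfectly correlated.
#'
#' @param direct Data.frame of direct human per-gram estimates:
#'   `tissue_id`, `cell_type`, `value`, `ferror`.
#' @param nonhuman Data.frame of normalized non-human records (same
#'   columns plus `species`), or `NULL`.
#' @param tissues Tissue table, see [tissue_table()].
#' @param restrictions Named list, see [restricted_tissues()].
#' @param species_penalty,floor_ferror Tuning of the two strategies.
#' @return A list: `densities` — `direct` plus filled rows (with columns
#'   `method` = `"extrapolated"` and `corr_group`); `audit` — one row per
#'   candidate gap with the strategy used, values and discrepancy flag.
#' @export
fill_missing_densities <- function(direct, nonhuman = NULL,
                                   tissues = tissue_table(),
                                   restrictions = restricted_tissues(),
                                   species_penalty = 1.5,
                                   floor_ferror = 1.5) {
  direct$method <- if (is.null(direct$method)) "literature" else direct$method
  direct$corr_group <- NA_character_
  grid <- expand.grid(tissue_id = tissues$tissue_id,
                      cell_type = cell_types(),
                      stringsAsFactors = FALSE)
  have <- paste(direct$tissue_id, direct$cell_type)
  gaps <- grid[!(paste(grid$tissue_id, grid$cell_type) %in% have), ]
  group_of <- stats::setNames(tissues$group, tissues$tissue_id)

  filled <- list(); audit <- list()
  for (i in seq_len(nrow(gaps))) {
    tis <- gaps$tissue_id[i]; ct <- gaps$cell_type[i]
    restr <- restrictions[[ct]]
    if (!is.null(restr) && !(tis %in% restr)) {
      audit[[length(audit) + 1]] <- data.frame(
        tissue_id = tis, cell_type = ct, strategy = "forbidden",
        value = 0, ferror = NA_real_, discrepant = FALSE,
        stringsAsFactors = FALSE)
      next
    }
    nh <- if (!is.null(nonhuman)) {
      nonhuman[nonhuman$tissue_id == tis & nonhuman$cell_type == ct, ,
               drop = FALSE]
    }
    a <- extrapolate_cross_species(nh, species_penalty)
    peers <- direct[direct$cell_type == ct &
                      group_of[direct$tissue_id] == group_of[[tis]] &
                      direct$method != "extrapolated" &
                      direct$value > 0, , drop = FALSE]
    b <- extrapolate_group_mean(peers, floor_ferror)
    comb <- combine_extrapolations(a, b)
    strategy <- if (is.null(comb)) "missing"
      else if (!is.null(a) && !is.null(b)) "combined"
      else if (!is.null(a)) "cross_species" else "group_geometric_mean"
    if (is.null(comb)) {
      audit[[length(audit) + 1]] <- data.frame(
        tissue_id = tis, cell_type = ct, strategy = strategy,
        value = 0, ferror = NA_real_, discrepant = FALSE,
        stringsAsFactors = FALSE)
      next
    }
    # correlated errors: extrapolations of the same cell type share their
    # evidence base, so they share a resampling deviate in totals
    cg <- paste0("extrap:", ct, ":",
                 if (strategy == "cross_species") tis
                 else group_of[[tis]])
    filled[[length(filled) + 1]] <- data.frame(
      tissue_id = tis, cell_type = ct, value = comb$value,
      ferror = comb$ferror, method = "extrapolated", corr_group = cg,
      stringsAsFactors = FALSE)
    audit[[length(audit) + 1]] <- data.frame(
      tissue_id = tis, cell_type = ct, strategy = strategy,
      value = comb$value, ferror = comb$ferror,
      discrepant = isTRUE(attr(comb, "discrepant")),
      stringsAsFactors = FALSE)
  }
  dens <- rbind(direct[c("tissue_id", "cell_type", "value", "ferror",
                         "method", "corr_group")],
                if (length(filled)) do.call(rbind, filled))
  rownames(dens) <- NULL
  list(densities = dens,
       audit = if (length(audit)) do.call(rbind, audit) else
         data.frame(tissue_id = character(0), cell_type = character(0),
                    strategy = character(0), value = numeric(0),
                    ferror = numeric(0), discrepant = logical(0)))
}
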