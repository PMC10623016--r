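#' Absolute cell number from a relative fraction and an anchor
#'
#' Converts a relative cell-type fraction from deconvolution (or any
#' compartment-fraction assay) into an absolute count using an anchor cell
#' type whose absolute number in the tissue is independently known:
#' `N_im = P_im * N_an / P_an`. Fractions are treated as exact; the
#' anchor's multiplicative error carries through unchanged.
#'
#' @param p_im Fraction of the cell type of interest, `>= 0`.
#' @param p_an Fraction of the anchor type, `> 0`.
#' @param n_an A `lognormal_estimate` of the anchor's absolute count.
#' @param sample_id Optional label used in error messages.
#' @return A `lognormal_estimate` of the absolute count; the zero sentinel
#'   when `p_im = 0`.
#' @export
absolute_from_fraction <- function(p_im, p_an, n_an, sample_id = NULL) {
  if (any(p_an <= 0)) {
    stop("anchor fraction is zero",
         if (!is.null(sample_id)) paste0(" in sample '", sample_id, "'"),
         ": cannot anchor absolute counts")
  }
  if (any(p_im < 0)) stop("`p_im` must be nonnegative")
  if (p_im == 0) return(zero_estimate())
  scale_estimate(n_an, p_im / p_an)
}

#' Read deconvolution fraction and anchor tables
#'
#' Fractions: long CSV with `sample_id`, `tissue_id`, `group`, `fraction`.
#' Anchors: CSV with `tissue_id`, `anchor_type`, `anchor_fraction_group`
#' (the group label whose fraction anchors the sample), `anchor_count`,
#' `anchor_ferror`.
#'
#' @param fractions_path,anchors_path CSV paths.
#' @return A list with data.frames `fractions` and `anchors`.
#' @export
read_fraction_tables <- function(fractions_path, anchors_path) {
  fr <- utils::read.csv(fractions_path, stringsAsFactors = FALSE)
  an <- utils::read.csv(anchors_path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "tissue_id", "group", "fraction") %in%
                  names(fr)),
            all(c("tissue_id", "anchor_fraction_group", "anchor_count",
                  "anchor_ferror") %in% names(an)))
  bad <- stats::aggregate(fraction ~ sample_id, fr, sum)
  if (any(bad$fraction > 1 + 1e-6)) {
    stop("fractions exceed 1 in samples: ",
         paste(bad$sample_id[bad$fraction > 1 + 1e-6], collapse = ", "))
  }
  list(fractions = fr, anchors = an)
}

#' Per-tissue absolute counts from fraction samples
#'
#' Samples declared as coming from the same tissue are grouped (no
#' unsupervised clustering — the tissue label is the cluster) and averaged:
#' each sample's fractions are anchored to absolute counts, and per
#' (tissue, group) the geometric mean across samples is taken. The ferror
#' combines the between-sample log-scale standard error with the anchor's
#' ferror in quadrature.
#'
#' @param fractions Long fraction table (see [read_fraction_tables()]).
#' @param anchors Anchor table, one row per tissue.
#' @return A data.frame `tissue_id`, `group`, `value`, `ferror`,
#'   `n_samples`. Groups observed at zero in every sample are dropped.
#' @export
cluster_and_average <- function(fractions, anchors) {
  out <- list()
  for (tis in unique(fractions$tissue_id)) {
    a <- anchors[anchors$tissue_id == tis, ]
    if (nrow(a) == 0) stop("no anchor for tissue ", tis)
    n_an <- lognormal_estimate(a$anchor_count[1], a$anchor_ferror[1])
    ft <- fractions[fractions$tissue_id == tis, ]
    for (grp in unique(ft$group)) {
      if (grp == a$anchor_fraction_group[1]) next
      counts <- numeric(0)
      for (sid in unique(ft$sample_id)) {
        fs <- ft[ft$sample_id == sid, ]
        p_an <- fs$fraction[fs$group == a$anchor_fraction_group[1]]
        p_im <- fs$fraction[fs$group == grp]
        if (length(p_an) == 0 || length(p_im) == 0) next
        est <- absolute_from_fraction(p_im, p_an, n_an, sample_id = sid)
        if (!is_zero_sentinel(est)) counts <- c(counts, est$value)
      }
      if (length(counts) == 0) next
      k <- length(counts)
      se_log <- if (k > 1) stats::sd(log(counts)) / sqrt(k) else 0
      f <- exp(sqrt(se_log^2 + log(n_an$ferror)^2))
      out[[length(out) + 1]] <- data.frame(
        tissue_id = tis, group = grp,
        value = exp(mean(log(counts))), ferror = f, n_samples = k,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) stop("no overlapping fraction/anchor data")
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Compare deconvolution-derived counts with reference estimates
#'
#' Validation only: deconvolution never enters the headline census. For
#' each overlapping (tissue, group) the log10 ratio
#' deconvolution/reference is reported with the combined ferror (errors
#' added in quadrature on the log scale) and an agreement flag — agreement
#' means the ratio is within the combined 95% interval,
#' `|ln ratio| <= 1.96 * s_combined`.
#'
#' @param deconv Data.frame from [cluster_and_average()].
#' @param reference Data.frame with `tissue_id`, `group`, `value`,
#'   `ferror` — e.g. census counts summed to the deconvolution groups.
#' @return A data.frame with `tissue_id`, `group`, `log10_ratio`,
#'   `combined_ferror`, `agree`.
#' @export
compare_to_reference <- function(deconv, reference) {
  m <- merge(deconv, reference, by = c("tissue_id", "group"),
             suffixes = c("_deconv", "_ref"))
  if (nrow(m) == 0) stop("no overlapping (tissue, group) keys to compare")
  s_comb <- sqrt(log(m$ferror_deconv)^2 + log(m$ferror_ref)^2)
  lr <- log(m$value_deconv / m$value_ref)
  data.frame(tissue_id = m$tissue_id, group = m$group,
             log10_ratio = lr / log(10),
             combined_ferror = exp(s_comb),
             agree = abs(lr) <= 1.96 * s_comb,
             stringsAsFactors = FALSE)
}

#' Census counts rolled up to deconvolution group labels
#'
#' Deconvolution resolves five immune groups (B, T, NK, granulocyte,
#' nongranulocyte myeloid); this maps census cell types onto those groups
#' so the two can be compared. Plasma cells roll into B.
#'
#' @param counts Data.frame with `tissue_id`, `cell_type`, `value`,
#'   `ferror` (census entries).
#' @return A data.frame `tissue_id`, `group`, `value`, `ferror` where the
#'   group value is the sum of member values and the ferror the largest
#'   member ferror (conservative roll-up for a validation contrast).
#' @export
rollup_to_groups <- function(counts) {
  map <- c("B cell" = "B", "plasma cell" = "B", "T cell" = "T",
           "NK cell" = "NK",
           "neutrophil" = "granulocyte", "eosinophil" = "granulocyte",
           "basophil" = "granulocyte", "mast cell" = "granulocyte",
           "macrophage" = "nongranulocyte-myeloid",
           "monocyte" = "nongranulocyte-myeloid",
           "dendritic cell" = "nongranulocyte-myeloid")
  counts$group <- unname(map[counts$cell_type])
  agg_v <- stats::aggregate(value ~ tissue_id + group, counts, sum)
  agg_f <- stats::aggregate(ferror ~ tissue_id + group, counts, max)
  out <- merge(agg_v, agg_f, by = c("tissue_id", "group"))
  out[out$value > 0, , drop = FALSE]
}
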