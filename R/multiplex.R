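#' Read a multiplexed-imaging cell table
#'
#' Long format, one row per sample x cell type: columns `sample_id`,
#' `patient_id`, `tissue_id`, `cell_type`, `count`, and optionally
#' `field_area_um2` (default 400 x 400 = 160,000 um^2, one imaging field).
#'
#' @param path CSV path.
#' @param field_area_um2 Default field area applied where the column is
#'   absent.
#' @return A data.frame of per-sample counts.
#' @export
read_multiplex_counts <- function(path, field_area_um2 = 160000) {
  mx <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "patient_id", "tissue_id", "cell_type", "count")
  miss <- setdiff(need, names(mx))
  if (length(miss)) stop("multiplex table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (is.null(mx$field_area_um2)) mx$field_area_um2 <- field_area_um2
  bad <- setdiff(unique(mx$cell_type), cell_types())
  if (length(bad)) stop("unknown cell types: ", paste(bad, collapse = ", "))
  mx
}

#' Quality-control filter on multiplexed samples
#'
#' Removes samples whose total cell count is an outlier within their tissue
#' stratum: z-score of the sample total against the stratum mean and
#' population SD exceeding 1.96 in absolute value. A single pass — removal
#' does not trigger re-screening. Strata with fewer than three samples pass
#' through with a warning, since a z-score over so few totals is
#' meaningless.
#'
#' @param mx Long-format multiplex table (see [read_multiplex_counts()]).
#' @param z_cut Absolute z-score threshold, default 1.96.
#' @return A list with data.frames `kept` and `removed` (the latter with a
#'   `z` column recording each removed sample's score).
#' @export
filter_outlier_samples <- function(mx, z_cut = 1.96) {
  totals <- stats::aggregate(count ~ sample_id + tissue_id, mx, sum)
  removed <- list()
  drop_ids <- character(0)
  for (tis in unique(totals$tissue_id)) {
    tt <- totals[totals$tissue_id == tis, ]
    if (nrow(tt) < 3) {
      warning("tissue '", tis, "' has fewer than 3 samples; ",
              "outlier screen skipped")
      next
    }
    mu <- mean(tt$count)
    sdev <- sqrt(mean((tt$count - mu)^2))  # population SD
    if (sdev == 0) next
    z <- (tt$count - mu) / sdev
    out <- abs(z) > z_cut
    if (any(out)) {
      removed[[tis]] <- data.frame(sample_id = tt$sample_id[out],
                                   tissue_id = tis,
                                   total = tt$count[out], z = z[out],
                                   stringsAsFactors = FALSE)
      drop_ids <- c(drop_ids, tt$sample_id[out])
    }
  }
  removed <- if (length(removed)) do.call(rbind, c(removed,
                                                   make.row.names = FALSE))
  else data.frame(sample_id = character(0), tissue_id = character(0),
                  total = numeric(0), z = numeric(0))
  list(kept = mx[!(mx$sample_id %in% drop_ids), , drop = FALSE],
       removed = removed)
}

#' Volumetric density of one cell type in one imaging field
#'
#' The imaging section has negligible physical thickness, so the effective
#' sampled slab is one cell diameter thick: `rho = n / (A * D)` (the
#' areal-count formula with `T = 0`).
#'
#' @param count Nonnegative cell count in the field.
#' @param field_area_um2 Field area in um^2.
#' @param diameter_um Representative cell diameter in um.
#' @return Density in cells/cm^3.
#' @examples
#' sample_density(160, 160000, 10)  # 1e8 cells/cm^3
#' @export
sample_density <- function(count, field_area_um2, diameter_um) {
  if (any(!is.finite(diameter_um) | diameter_um <= 0)) {
    stop("missing or nonpositive cell diameter: configure diameters for ",
         "every imaged cell type")
  }
  density_from_areal_count(count, field_area_um2 * 1e-8, 0,
                           diameter_um * 1e-4)
}

#' Patient-aggregated multiplex density for one tissue and cell type
#'
#' Sample densities are aggregated hierarchically: the geometric mean over
#' each patient's positive-density samples gives a per-patient density, and
#' the geometric mean across patients is the point estimate. The shape
#' parameter combines both levels of variation,
#' `s^2 = s_between^2 / k + mean(s_within^2) / n_bar`, with `k` patients
#' and `n_bar` the mean number of positive samples per patient. Samples
#' with a zero count are excluded from the geometric mean (no pseudo-count
#' floor); their share is reported as `zero_fraction`. The volumetric
#' result is converted to cells/g by the tissue's specific gravity.
#'
#' @param mx Long-format kept multiplex table.
#' @param tissue_id,cell_type The stratum to aggregate.
#' @param diameters_um Named diameters, see [default_diameters_um()].
#' @param specific_gravity Tissue g/cm^3 for the per-gram conversion.
#' @return A `lognormal_estimate` in cells/g with attributes `n_patients`,
#'   `zero_fraction`; the zero sentinel if every sample is zero.
#' @export
aggregate_patients <- function(mx, tissue_id, cell_type,
                               diameters_um = default_diameters_um(),
                               specific_gravity = 1.03) {
  rows <- mx[mx$tissue_id == tissue_id & mx$cell_type == cell_type, ]
  if (nrow(rows) == 0) stop("no samples for ", tissue_id, " / ", cell_type)
  d_um <- diameters_um[[cell_type]]
  rho <- sample_density(rows$count, rows$field_area_um2, d_um)
  dens <- volumetric_to_per_gram(rho, specific_gravity)
  pos <- dens > 0
  zero_fraction <- mean(!pos)
  if (!any(pos)) {
    out <- zero_estimate()
    attr(out, "n_patients") <- length(unique(rows$patient_id))
    attr(out, "zero_fraction") <- 1
    return(out)
  }
  ld <- log(dens[pos])
  pat <- rows$patient_id[pos]
  per_pat_mean <- tapply(ld, pat, mean)
  per_pat_var <- tapply(ld, pat, function(x)
    if (length(x) > 1) stats::var(x) else 0)
  n_per <- tapply(ld, pat, length)
  k <- length(per_pat_mean)
  s_between2 <- if (k > 1) stats::var(as.numeric(per_pat_mean)) else 0
  s2 <- s_between2 / k + mean(as.numeric(per_pat_var)) / mean(n_per)
  out <- lognormal_estimate(exp(mean(per_pat_mean)), exp(sqrt(s2)))
  attr(out, "n_patients") <- k
  attr(out, "zero_fraction") <- zero_fraction
  out
}

#' Multiplex density table across all tissues and cell types present
#'
#' Runs the QC filter then [aggregate_patients()] over every
#' (tissue, cell type) stratum, returning a normalized per-gram density
#' table compatible with the literature-evidence table.
#'
#' @param mx Long-format multiplex table.
#' @param tissues Tissue table (for specific gravities).
#' @param diameters_um Named diameters per cell type.
#' @return A data.frame with `tissue_id`, `cell_type`, `method`
#'   (`"multiplex"`), `value`, `ferror`, `n_patients`, `zero_fraction`.
#' @export
multiplex_density_table <- function(mx, tissues = tissue_table(),
                                    diameters_um = default_diameters_um()) {
  qc <- filter_outlier_samples(mx)
  kept <- qc$kept
  sg <- stats::setNames(tissues$specific_gravity, tissues$tissue_id)
  strata <- unique(kept[c("tissue_id", "cell_type")])
  rows <- lapply(seq_len(nrow(strata)), function(i) {
    tis <- strata$tissue_id[i]; ct <- strata$cell_type[i]
    est <- aggregate_patients(kept, tis, ct, diameters_um, sg[[tis]])
    if (is_zero_sentinel(est)) return(NULL)
    data.frame(tissue_id = tis, cell_type = ct, method = "multiplex",
               value = est$value, ferror = est$ferror,
               n_patients = attr(est, "n_patients"),
               zero_fraction = attr(est, "zero_fraction"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(tissue_id = character(0), cell_type = character(0),
                      method = character(0), value = numeric(0),
                      ferror = numeric(0), n_patients = integer(0),
                      zero_fraction = numeric(0))
  }
  rownames(out) <- NULL
  out
}
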