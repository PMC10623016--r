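#' Volumetric density from an areal histology count
#'
#' Converts a two-dimensional count per section area into a volumetric
#' density with the stereological thickness correction: a section of
#' thickness `T` captures every cell whose centre lies within `T + D` of
#' the section plane, `D` being the cell diameter, so
#' `rho = n / (A * (T + D))`. All lengths are in centimetres; convert
#' micrometre inputs with `um * 1e-4`.
#'
#' @param n Nonnegative cell count.
#' @param A_cm2 Section area in cm^2, positive.
#' @param T_cm Section thickness in cm, nonnegative (0 for an imaging beam
#'   of negligible thickness).
#' @param D_cm Cell diameter in cm, positive.
#' @return Density in cells/cm^3.
#' @examples
#' density_from_areal_count(1000, 0.01, 5e-4, 1e-3)  # 6.67e7 cells/cm^3
#' @export
density_from_areal_count <- function(n, A_cm2, T_cm, D_cm) {
  if (any(n < 0)) stop("`n` must be nonnegative")
  if (any(A_cm2 <= 0)) stop("`A_cm2` must be positive")
  if (any(T_cm < 0)) stop("`T_cm` must be nonnegative")
  if (any(D_cm <= 0)) stop("`D_cm` must be positive")
  n / (A_cm2 * (T_cm + D_cm))
}

#' Convert cells/cm^3 to cells/g via tissue specific gravity
#'
#' Dimensional conversion: dividing a volumetric density by the tissue's
#' specific gravity (g/cm^3) yields cells per gram. Generic soft tissue is
#' 1.03 g/mL; adipose 0.91 g/mL. The difference this choice makes is small
#' (a few percent) next to the density uncertainties themselves.
#'
#' @param rho Nonnegative volumetric density, cells/cm^3.
#' @param specific_gravity Tissue density in g/cm^3.
#' @return Density in cells/g.
#' @export
volumetric_to_per_gram <- function(rho, specific_gravity = 1.03) {
  if (any(rho < 0)) stop("`rho` must be nonnegative")
  rho / specific_gravity
}

#' Per-gram density from a relative abundance
#'
#' A cell type reported as a fraction of all nucleated cells is anchored to
#' a reference density of nucleated cells per gram; the two multiply, with
#' the fraction treated as exact unless it carries its own ferror.
#'
#' @param fraction Fraction in (0, 1], or a `lognormal_estimate` whose
#'   value is in (0, 1].
#' @param reference A `lognormal_estimate` of total nucleated cells/g.
#' @return A `lognormal_estimate` in cells/g.
#' @export
density_from_relative_abundance <- function(fraction, reference) {
  fv <- if (inherits(fraction, "lognormal_estimate")) fraction$value else
    fraction
  if (any(fv <= 0 | fv > 1)) stop("`fraction` must lie in (0, 1]")
  f <- if (inherits(fraction, "lognormal_estimate")) fraction else
    lognormal_estimate(fraction, 1)
  propagate_product(f, reference)
}

#' Per-gram density from a whole-organ total count
#'
#' @param total A `lognormal_estimate` of the total cells in the organ.
#' @param organ_mass_g Organ mass in grams, positive and treated as exact;
#'   the ferror of the total is preserved.
#' @return A `lognormal_estimate` in cells/g.
#' @export
density_from_total_count <- function(total, organ_mass_g) {
  if (any(!is.finite(organ_mass_g) | organ_mass_g <= 0)) {
    stop("`organ_mass_g` must be positive")
  }
  scale_estimate(total, 1 / organ_mass_g)
}

#' Mass-fraction-weighted density over tissue compartments
#'
#' Some tissues have compartment-resolved evidence (e.g. epithelium vs the
#' rest of the gut wall); the whole-tissue density is the arithmetic mean of
#' compartment densities weighted by compartment mass fractions. The
#' uncertainty of the weighted sum is propagated by bootstrap over the
#' compartments.
#'
#' @param fractions Numeric mass fractions summing to 1 (tolerance 1e-6).
#' @param densities A vectorized `lognormal_estimate` (or list), one per
#'   compartment, in cells/g. Exact zero compartments may be encoded as the
#'   zero sentinel.
#' @param n_draws,seed Passed to the internal bootstrap.
#' @return A `lognormal_estimate` in cells/g.
#' @export
compartment_weighted_density <- function(fractions, densities,
                                         n_draws = 1000, seed = 2023) {
  d <- as_estimate_vector(densities)
  if (length(fractions) != length(d$value)) {
    stop("`fractions` and `densities` lengths differ")
  }
  if (abs(sum(fractions) - 1) > 1e-6) {
    stop("compartment mass fractions must sum to 1")
  }
  scaled <- lognormal_estimate(
    ifelse(d$value == 0, 0, d$value * fractions), d$ferror)
  total <- bootstrap_sum(scaled, n_draws = n_draws, seed = seed)
  if (is_zero_sentinel(total)) return(total)
  lognormal_estimate(total$value, total$ferror)
}

#' Read a density-evidence table
#'
#' One row per piece of literature evidence for the density of a
#' (tissue, cell type) pair. Expected columns: `tissue_id`, `cell_type`,
#' `method` (histology/flow/total-count/...), `value`, `value_kind` in
#' `{per_gram, per_cm3, areal_count, fraction, total_count}`, `A_cm2`,
#' `T_um`, `D_um` (areal counts only), `error`, `error_kind`
#' (`ferror`, default, or `se`), `species` (human/rodent/monkey),
#' `compartment`, `compartment_fraction`, `ref_value`, `ref_ferror`
#' (fraction rows only: reference nucleated-cell density), `source`.
#' Missing optional columns are filled with defaults.
#'
#' @param path CSV file path.
#' @return A data.frame of evidence records.
#' @export
read_density_evidence <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tissue_id", "cell_type", "method", "value", "value_kind")
  miss <- setdiff(need, names(ev))
  if (length(miss)) stop("evidence table lacks columns: ",
                         paste(miss, collapse = ", "))
  defaults <- list(A_cm2 = NA_real_, T_um = NA_real_, D_um = NA_real_,
                   error = 1, error_kind = "ferror", species = "human",
                   compartment = NA_character_,
                   compartment_fraction = NA_real_,
                   ref_value = NA_real_, ref_ferror = NA_real_,
                   source = NA_character_)
  for (nm in names(defaults)) {
    if (is.null(ev[[nm]])) ev[[nm]] <- defaults[[nm]]
  }
  bad <- setdiff(unique(ev$cell_type), cell_types())
  if (length(bad)) stop("unknown cell types in evidence: ",
                        paste(bad, collapse = ", "))
  ev
}

# Turn one evidence row into a per-gram lognormal_estimate.
normalize_record <- function(row, sg) {
  err <- if (identical(row$error_kind, "se")) {
    # moment-match the reported mean+/-SE; note this shifts the point value
    fit_lognormal_from_normal(row$value, row$error)
  } else {
    lognormal_estimate(row$value, max(row$error, 1))
  }
  switch(row$value_kind,
    per_gram = err,
    per_cm3 = lognormal_estimate(volumetric_to_per_gram(err$value, sg),
                                 err$ferror),
    areal_count = {
      rho <- density_from_areal_count(err$value, row$A_cm2,
                                      row$T_um * 1e-4, row$D_um * 1e-4)
      lognormal_estimate(volumetric_to_per_gram(rho, sg), err$ferror)
    },
    fraction = {
      if (!is.finite(row$ref_value)) {
        stop("fraction record without ref_value for ", row$tissue_id)
      }
      density_from_relative_abundance(
        err, lognormal_estimate(row$ref_value,
                                max(row$ref_ferror, 1, na.rm = TRUE)))
    },
    total_count = {
      if (!is.finite(row$organ_mass_g)) {
        stop("total_count record needs an organ mass for ", row$tissue_id)
      }
      density_from_total_count(err, row$organ_mass_g)
    },
    stop("unknown value_kind: ", row$value_kind)
  )
}

#' Normalize an evidence table to per-gram density records
#'
#' Converts every evidence row to cells/g using the tissue's specific
#' gravity (and, for total counts, the reference person's organ mass), then
#' merges records of the same (tissue, cell type, species): compartment
#' records are first combined by mass-fraction weighting, then repeated
#' records are pooled by geometric mean with between-record spread folded
#' into the ferror. Human and non-human records are kept apart — non-human
#' evidence feeds cross-species extrapolation, not the direct estimates.
#'
#' @param evidence Data.frame from [read_density_evidence()].
#' @param tissues Tissue table, see [tissue_table()].
#' @param person Reference person supplying organ masses for total-count
#'   records.
#' @param seed Seed for the compartment-weighting bootstrap.
#' @return A data.frame with columns `tissue_id`, `cell_type`, `species`,
#'   `method`, `value` (cells/g), `ferror`, `n_records`.
#' @export
normalize_evidence <- function(evidence, tissues = tissue_table(),
                               person = "male", seed = 2023) {
  masses <- person_masses(person, tissues)
  sg <- stats::setNames(tissues$specific_gravity, tissues$tissue_id)
  unknown <- setdiff(unique(evidence$tissue_id), tissues$tissue_id)
  if (length(unknown)) stop("evidence names unknown tissues: ",
                            paste(unknown, collapse = ", "))
  evidence$organ_mass_g <- unname(masses[evidence$tissue_id])
  evidence$.species_class <- ifelse(evidence$species == "human",
                                    "human", "nonhuman")

  key <- interaction(evidence$tissue_id, evidence$cell_type,
                     evidence$.species_class, drop = TRUE)
  out <- lapply(split(evidence, key), function(rows) {
    ests <- lapply(seq_len(nrow(rows)), function(i)
      normalize_record(rows[i, ], sg[[rows$tissue_id[1]]]))
    # compartment-resolved rows first collapse to one whole-tissue record
    comp <- is.finite(rows$compartment_fraction)
    if (any(comp)) {
      fr <- rows$compartment_fraction[comp]
      whole <- compartment_weighted_density(
        fr, as_estimate_vector(ests[comp]), seed = seed)
      ests <- c(ests[!comp], list(whole))
    }
    pooled <- geometric_pool(as_estimate_vector(ests))
    data.frame(tissue_id = rows$tissue_id[1],
               cell_type = rows$cell_type[1],
               species = rows$.species_class[1],
               method = rows$method[1],
               value = pooled$value, ferror = pooled$ferror,
               n_records = nrow(rows), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
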