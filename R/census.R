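#' Combine literature and multiplex density estimates per pair
#'
#' Cross-method integration by inverse-variance weighting in log space.
#' Where both a literature-based and a multiplexed-imaging estimate exist
#' for a (tissue, cell type), they are pooled with weights `1/ln(f)^2`;
#' an optional weight multiplier can up-weight the multiplex method in
#' lymphatic-group tissues (default 1: its typically smaller ferror
#' already earns it the larger weight). Deconvolution-derived estimates
#' never enter — they are validation only.
#'
#' @param literature Data.frame `tissue_id`, `cell_type`, `value`,
#'   `ferror` (direct human literature estimates, cells/g).
#' @param multiplex Data.frame of the same shape from
#'   [multiplex_density_table()], or `NULL`.
#' @param tissues Tissue table (to identify lymphatic-group tissues).
#' @param multiplex_weight Weight multiplier for multiplex estimates in
#'   lymphatic tissues.
#' @return A data.frame `tissue_id`, `cell_type`, `value`, `ferror`,
#'   `method` (`literature`, `multiplex` or `combined`).
#' @export
combine_methods <- function(literature, multiplex = NULL,
                            tissues = tissue_table(),
                            multiplex_weight = 1) {
  if (is.null(multiplex) || nrow(multiplex) == 0) {
    literature$method <- "literature"
    return(literature[c("tissue_id", "cell_type", "value", "ferror",
                        "method")])
  }
  lymphatic <- tissues$tissue_id[tissues$group == "lymphatic"]
  key <- function(d) paste(d$tissue_id, d$cell_type)
  lit_k <- key(literature); mx_k <- key(multiplex)
  rows <- list()
  for (k in union(lit_k, mx_k)) {
    li <- literature[lit_k == k, , drop = FALSE]
    mi <- multiplex[mx_k == k, , drop = FALSE]
    if (nrow(li) && nrow(mi)) {
      w_mx <- if (mi$tissue_id[1] %in% lymphatic) multiplex_weight else 1
      est <- inverse_variance_combine(
        lognormal_estimate(c(li$value[1], mi$value[1]),
                           c(li$ferror[1], mi$ferror[1])),
        weight_multipliers = c(1, w_mx))
      rows[[k]] <- data.frame(tissue_id = li$tissue_id[1],
                              cell_type = li$cell_type[1],
                              value = est$value, ferror = est$ferror,
                              method = "combined",
                              stringsAsFactors = FALSE)
    } else if (nrow(li)) {
      rows[[k]] <- data.frame(li[1, c("tissue_id", "cell_type", "value",
                                      "ferror")],
                              method = "literature",
                              stringsAsFactors = FALSE)
    } else {
      rows[[k]] <- data.frame(mi[1, c("tissue_id", "cell_type", "value",
                                      "ferror")],
                              method = "multiplex",
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out
}

# Two-component lognormal bootstrap over census entries.
# Each entry i is sampled as value_i * exp(s1_i z[g1_i] + s2_i z[g2_i]):
# component 1 carries the density/count error (correlated within
# extrapolation groups), component 2 an error shared across entries (the
# per-type cell-mass error in the mass census; zero in the count census).
boot_entry_draws <- function(value, s1, g1, s2, g2, n_draws, seed) {
  n <- length(value)
  g1 <- as.character(g1); g2 <- as.character(g2)
  g1[is.na(g1)] <- paste0(".i1_", seq_len(n))[is.na(g1)]
  g2[is.na(g2)] <- paste0(".i2_", seq_len(n))[is.na(g2)]
  f1 <- factor(g1); f2 <- factor(g2)
  with_local_seed(seed, {
    z1 <- matrix(stats::rnorm(n_draws * nlevels(f1)), nrow = n_draws)
    z2 <- matrix(stats::rnorm(n_draws * nlevels(f2)), nrow = n_draws)
    lf <- sweep(z1[, as.integer(f1), drop = FALSE], 2, s1, `*`) +
      sweep(z2[, as.integer(f2), drop = FALSE], 2, s2, `*`)
    exp(sweep(lf, 2, log(pmax(value, .Machine$double.xmin)), `+`)) *
      rep(as.numeric(value > 0), each = n_draws)
  })
}

margin_from_draws <- function(point, draws_mat, idx) {
  total <- sum(point[idx])
  d <- if (length(idx) == 1) draws_mat[, idx] else
    rowSums(draws_mat[, idx, drop = FALSE])
  q <- stats::quantile(d, c(0.025, 0.975), names = FALSE)
  sd_log <- if (all(d > 0)) stats::sd(log(d)) else NA_real_
  c(value = total, ci_low = q[1], ci_high = q[2],
    ferror = if (is.na(sd_log)) NA_real_ else exp(sd_log))
}

build_census <- function(entries, unit, person, n_draws, seed) {
  draws <- boot_entry_draws(entries$value, entries$s1, entries$g1,
                            entries$s2, entries$g2, n_draws, seed)
  by_tissue <- do.call(rbind, lapply(split(seq_len(nrow(entries)),
                                           entries$tissue_id),
    function(idx) margin_from_draws(entries$value, draws, idx)))
  by_type <- do.call(rbind, lapply(split(seq_len(nrow(entries)),
                                         entries$cell_type),
    function(idx) margin_from_draws(entries$value, draws, idx)))
  grand <- margin_from_draws(entries$value, draws,
                             seq_len(nrow(entries)))
  structure(list(
    entries = entries,
    by_tissue = data.frame(tissue_id = rownames(by_tissue),
                           by_tissue, row.names = NULL),
    by_type = data.frame(cell_type = rownames(by_type),
                         by_type, row.names = NULL),
    grand = grand,
    draws = draws, unit = unit, person = person,
    n_draws = n_draws, seed = seed
  ), class = "census_table")
}

#' @export
print.census_table <- function(x, ...) {
  cat(sprintf("<census_table: %s, %s, %d entries>\n", x$unit, x$person,
              nrow(x$entries)))
  cat(sprintf("grand total %s %s (95%% CI %s - %s)\n",
              signif(x$grand[["value"]], 2), x$unit,
              signif(x$grand[["ci_low"]], 2),
              signif(x$grand[["ci_high"]], 2)))
  invisible(x)
}

#' Assemble a whole-body count census from per-gram densities
#'
#' Multiplies each (tissue, cell type) density by the reference person's
#' organ mass (an exact factor) and propagates the multiplicative errors
#' into tissue, cell-type and grand-total margins by bootstrap, honoring
#' the correlation groups attached to extrapolated densities. Pairs absent
#' from the density table count as zero.
#'
#' @param densities Data.frame `tissue_id`, `cell_type`, `value` (cells/g),
#'   `ferror`, optional `corr_group`, optional `method`.
#' @param person `"male"`, `"female"` or `"child"`.
#' @param tissues Tissue table with per-person organ masses.
#' @param n_draws,seed Bootstrap control (defaults 1000 draws, seed 2023).
#' @return A `census_table`: entries plus `by_tissue`, `by_type` and
#'   `grand` margins, each with point value, bootstrap 95% CI and fitted
#'   ferror. Margins equal the sums of their member point values.
#' @export
integrate_counts <- function(densities, person = "male",
                             tissues = tissue_table(),
                             n_draws = 1000, seed = 2023) {
  masses <- resolve_person_masses(person, tissues)
  missing_mass <- setdiff(unique(densities$tissue_id), names(masses))
  if (length(missing_mass)) {
    stop("no organ mass for tissue(s): ",
         paste(missing_mass, collapse = ", "))
  }
  entries <- data.frame(
    tissue_id = densities$tissue_id,
    cell_type = densities$cell_type,
    value = densities$value * unname(masses[densities$tissue_id]),
    s1 = log(densities$ferror),
    g1 = if (is.null(densities$corr_group)) NA_character_ else
      densities$corr_group,
    s2 = 0, g2 = NA_character_,
    method = if (is.null(densities$method)) "literature" else
      densities$method,
    stringsAsFactors = FALSE)
  entries$ferror <- exp(entries$s1)
  build_census(entries, unit = "cells", person = person,
               n_draws = n_draws, seed = seed)
}

# Person organ masses with the lymph-node linear body-mass interpolation.
resolve_person_masses <- function(person, tissues = tissue_table()) {
  masses <- person_masses(person, tissues)
  if (anyNA(masses)) {
    male <- person_masses("male", tissues)
    ratio <- reference_body_mass_kg()[[person]] /
      reference_body_mass_kg()[["male"]]
    na <- is.na(masses)
    masses[na] <- male[na] * ratio
  }
  masses
}

#' Convert a count census to a mass census
#'
#' Each count entry is multiplied by the representative per-cell mass of
#' its type (tissue-resolved for macrophages). The per-type mass error is
#' shared across every tissue entry of that type — a single size estimate
#' feeds them all — so the bootstrap samples it as one correlated
#' component on top of the count errors.
#'
#' @param counts A `census_table` in cells.
#' @param mass_table Data.frame from [representative_mass_table()].
#' @return A `census_table` in grams.
#' @export
mass_census <- function(counts, mass_table) {
  e <- counts$entries
  mass_of <- function(ct, tis) {
    m <- mass_table[mass_table$cell_type == ct &
                      (is.na(mass_table$tissue_id) |
                         mass_table$tissue_id == tis), , drop = FALSE]
    # prefer the tissue-resolved row where present
    if (any(!is.na(m$tissue_id))) m <- m[!is.na(m$tissue_id), , drop = FALSE]
    if (nrow(m) == 0) stop("no representative mass for cell type '", ct, "'")
    m[1, c("mass_g", "ferror")]
  }
  mm <- do.call(rbind, Map(mass_of, e$cell_type, e$tissue_id))
  entries <- data.frame(
    tissue_id = e$tissue_id, cell_type = e$cell_type,
    value = e$value * mm$mass_g,
    s1 = e$s1, g1 = e$g1,
    s2 = log(mm$ferror), g2 = paste0("mass:", e$cell_type),
    method = e$method, stringsAsFactors = FALSE)
  entries$ferror <- exp(sqrt(entries$s1^2 + entries$s2^2))
  build_census(entries, unit = "g", person = counts$person,
               n_draws = counts$n_draws, seed = counts$seed)
}

#' Scale the census to another reference person
#'
#' Densities are taken as independent of sex and age; only the organ
#' masses change. A missing lymph-node mass is interpolated linearly from
#' the reference male value by body-mass ratio.
#'
#' @param densities Per-gram density table as for [integrate_counts()].
#' @param person Target person.
#' @inheritParams integrate_counts
#' @return A `census_table` for the target person.
#' @export
scale_to_person <- function(densities, person, tissues = tissue_table(),
                            n_draws = 1000, seed = 2023) {
  integrate_counts(densities, person = person, tissues = tissues,
                   n_draws = n_draws, seed = seed)
}

#' Margin over an arbitrary subset of cell types
#'
#' Totals for cell-type families (lymphocytes, granulocytes, ...) with a
#' bootstrap CI consistent with the census's own draws.
#'
#' @param census A `census_table`.
#' @param cell_types Character vector of member cell types.
#' @return Named numeric: `value`, `ci_low`, `ci_high`, `ferror`.
#' @export
margin_subset <- function(census, cell_types) {
  idx <- which(census$entries$cell_type %in% cell_types)
  if (!length(idx)) stop("no entries for the requested cell types")
  margin_from_draws(census$entries$value, census$draws, idx)
}

#' Volume scaling of a sphere under diameter scaling
#'
#' The cube law behind lymph-node enlargement arithmetic: scaling a
#' node's diameter by `r` scales its volume (and, at constant density,
#' its cell content) by `r^3`. Diameter doubling gives a factor of 8.
#'
#' @param diameter_ratio Positive ratio of enlarged to normal diameter.
#' @return The volume factor `diameter_ratio^3`.
#' @export
volume_scale_from_diameter <- function(diameter_ratio) {
  if (any(diameter_ratio <= 0)) stop("diameter ratio must be positive")
  diameter_ratio^3
}

#' Evaluate a perturbation scenario on the census
#'
#' Scenarios are multiplicative perturbations of the healthy reference
#' state: lymphadenopathy (a fraction of lymph-node mass enlarged by a
#' volume factor), splenomegaly (spleen mass doubled), obesity (adipose
#' mass or macrophage density scaled). A modifier row either scales a
#' tissue's mass — `cell_type = NA`, optionally only for a mass `fraction`
#' of the tissue, giving an effective factor `1 + fraction*(factor-1)` —
#' or scales one (tissue, cell type) density.
#'
#' @param densities Per-gram density table.
#' @param modifiers Data.frame with `tissue_id`, `cell_type` (`NA` for a
#'   mass modifier), `factor`, `fraction` (default 1).
#' @param person,tissues,n_draws,seed As for [integrate_counts()].
#' @return A list: `census` (the perturbed `census_table`), `baseline`,
#'   and `change` — data.frame of tissue margins with the relative change
#'   of each.
#' @export
apply_scenario <- function(densities, modifiers, person = "male",
                           tissues = tissue_table(),
                           n_draws = 1000, seed = 2023) {
  if (is.null(modifiers$fraction)) modifiers$fraction <- 1
  unknown <- setdiff(modifiers$tissue_id, tissues$tissue_id)
  if (length(unknown)) stop("scenario names unknown tissue(s): ",
                            paste(unknown, collapse = ", "))
  base <- integrate_counts(densities, person, tissues, n_draws, seed)
  mod_tissues <- tissues
  dens <- densities
  col <- paste0("mass_", person, "_g")
  for (i in seq_len(nrow(modifiers))) {
    eff <- 1 + modifiers$fraction[i] * (modifiers$factor[i] - 1)
    if (is.na(modifiers$cell_type[i])) {
      j <- mod_tissues$tissue_id == modifiers$tissue_id[i]
      mod_tissues[[col]][j] <- mod_tissues[[col]][j] * eff
    } else {
      j <- dens$tissue_id == modifiers$tissue_id[i] &
        dens$cell_type == modifiers$cell_type[i]
      dens$value[j] <- dens$value[j] * eff
    }
  }
  pert <- integrate_counts(dens, person, mod_tissues, n_draws, seed)
  chg <- merge(base$by_tissue[c("tissue_id", "value")],
               pert$by_tissue[c("tissue_id", "value")],
               by = "tissue_id", suffixes = c("_base", "_scenario"))
  chg$rel_change <- chg$value_scenario / chg$value_base - 1
  list(census = pert, baseline = base, change = chg,
       grand_rel_change = pert$grand[["value"]] / base$grand[["value"]] - 1)
}

#' Cell-type summary rounded for reporting
#'
#' A per-type table of counts and masses with 95% CIs, rounded to one
#' significant digit the way headline census tables are printed; full
#' precision stays in the census objects.
#'
#' @param counts A `census_table` in cells.
#' @param masses The matching `census_table` in grams.
#' @return A data.frame, one row per cell type plus a total row.
#' @export
census_summary <- function(counts, masses) {
  ct <- counts$by_type; mt <- masses$by_type
  m <- merge(ct, mt, by = "cell_type", suffixes = c("_n", "_g"))
  m <- m[match(cell_types(), m$cell_type), ]
  tot <- data.frame(cell_type = "total",
                    value_n = counts$grand[["value"]],
                    ci_low_n = counts$grand[["ci_low"]],
                    ci_high_n = counts$grand[["ci_high"]],
                    ferror_n = counts$grand[["ferror"]],
                    value_g = masses$grand[["value"]],
                    ci_low_g = masses$grand[["ci_low"]],
                    ci_high_g = masses$grand[["ci_high"]],
                    ferror_g = masses$grand[["ferror"]])
  out <- rbind(m, tot)
  for (col in c("value_n", "ci_low_n", "ci_high_n",
                "value_g", "ci_low_g", "ci_high_g")) {
    out[[paste0(col, "_printed")]] <- signif(out[[col]], 1)
  }
  rownames(out) <- NULL
  out
}
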