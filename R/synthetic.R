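#' Configuration of the synthetic-data generator
#'
#' Controls a complete, internally consistent synthetic input bundle with
#' known ground truth: lognormal literature evidence around true per-gram
#' densities, Poisson multiplexed-imaging counts, deconvolution fraction
#' tables consistent with the true compositions, and literature-style cell
#' size records. The defaults are the study conditions: three evidence
#' records per observed pair with a typical multiplicative error of 1.6
#' (literature spread reaches an order of magnitude in places), five
#' patients with four imaging fields each per lymphoid tissue, and a 15%
#' chance that a pair has no direct human evidence (exercising
#' extrapolation).
#'
#' @param seed Integer seed; the bundle is deterministic per seed.
#' @param n_evidence Human evidence records per observed (tissue, cell
#'   type) pair.
#' @param evidence_ferror True multiplicative error of one literature
#'   record (1 = noiseless evidence, declared exact).
#' @param tissue_jitter_sd_log10 SD of the per-tissue log10 jitter around
#'   its group's density scale.
#' @param missing_pair_prob Probability a pair has no human evidence and
#'   must be extrapolated (non-human records are emitted for a subset).
#' @param n_patients,n_fields Multiplex patients per lymphoid tissue and
#'   fields per patient.
#' @param patient_sd_log Between-patient lognormal random effect on
#'   multiplex field intensities (0 disables; with
#'   `evidence_ferror = 1` counts are set to their exact expectations).
#' @param fraction_noise_sd_log Lognormal noise on deconvolution
#'   fractions.
#' @param n_size_records Size records per cell type.
#' @param size_sd_log SD of log diameter jitter across size records.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1,
                         n_evidence = 3,
                         evidence_ferror = 1.6,
                         tissue_jitter_sd_log10 = 0.15,
                         missing_pair_prob = 0.15,
                         n_patients = 5,
                         n_fields = 4,
                         patient_sd_log = 0.15,
                         fraction_noise_sd_log = 0.2,
                         n_size_records = 3,
                         size_sd_log = 0.08) {
  stopifnot(evidence_ferror >= 1, missing_pair_prob >= 0,
            missing_pair_prob <= 1, n_evidence >= 1)
  structure(as.list(environment()), class = "synth_config")
}

#' Preset emulating the published census's density structure
#'
#' Group-level density scales reproduce the qualitative ordering of the
#' real data: bone marrow and lymphatic tissue highest (~1e9 cells/g),
#' epithelial tissue roughly an order of magnitude lower, adipose and
#' muscle up to two orders below epithelium. Run end to end on the ICRP
#' male masses this preset yields a grand total of order 1.8e12 cells.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [synth_config()].
#' @return A `synth_config`.
#' @export
paper_like_preset <- function(seed = 1, ...) {
  synth_config(seed = seed, ...)
}

# Group-level total immune density scales (cells/g) behind the preset.
group_density_scales <- function() {
  c("bone marrow" = 6.3e8,
    "lymphatic" = 1.7e9,
    "blood" = 7e6,
    "barrier epithelial" = 3.5e7,
    "other epithelial" = 2.2e7,
    "striated muscle" = 2e5,
    "adipose" = 5e5,
    "other connective" = 2e6,
    "CNS" = 1.5e6,
    "extracellular fluids and matrix" = 2e5)
}

# Within-group immune composition (fraction of total immune density per
# cell type); restricted types are zeroed per tissue and the rest
# renormalized.
group_compositions <- function() {
  ct <- cell_types()
  comp <- list(
    "bone marrow" = c(0.02, 0.06, 0.01, 0.005, 0.77, 0.05, 0.003, 0.002,
                      0.02, 0.05, 0.01),
    "lymphatic" = c(0.50, 0.33, 0.015, 0.02, 0.03, 0.005, 0, 0.005,
                    0.04, 0.005, 0.05),
    "blood" = c(0.21, 0.05, 0.002, 0.05, 0.62, 0, 0.005, 0,
                0.003, 0.055, 0.005),
    "barrier epithelial" = c(0.25, 0.05, 0.06, 0.03, 0.04, 0.02, 0, 0.26,
                             0.22, 0.02, 0.06),
    "other epithelial" = c(0.16, 0.05, 0.01, 0.10, 0.01, 0, 0, 0,
                           0.60, 0.03, 0.04),
    "striated muscle" = c(0.25, 0.05, 0, 0.05, 0, 0, 0, 0,
                          0.55, 0.05, 0.05),
    "adipose" = c(0.20, 0.05, 0, 0.05, 0, 0, 0, 0, 0.65, 0.05, 0),
    "other connective" = c(0.15, 0.05, 0, 0, 0, 0, 0, 0.35,
                           0.40, 0, 0.05),
    "CNS" = c(0.05, 0, 0, 0, 0, 0, 0, 0, 0.92, 0.02, 0.01),
    "extracellular fluids and matrix" = c(0.30, 0.10, 0, 0, 0, 0, 0, 0,
                                          0.50, 0.10, 0))
  lapply(comp, function(x) stats::setNames(x / sum(x), ct))
}

# True representative diameters (um); macrophages by replenishment class.
true_diameters <- function() {
  list(base = c("T cell" = 7.5, "B cell" = 7.5, "plasma cell" = 14,
                "NK cell" = 8.5, "neutrophil" = 8.8, "eosinophil" = 9,
                "basophil" = 9, "mast cell" = 12.6, "monocyte" = 9.5,
                "dendritic cell" = 15.3),
       macrophage_replenished = 15,
       macrophage_resident = 21)
}

#' True per-gram density table of a synthetic world
#'
#' Constructs the ground-truth density for every (tissue, cell type):
#' group density scale x per-tissue lognormal jitter x within-group
#' composition, with tissue-restricted cell types zeroed outside their
#' home tissues and the remaining composition renormalized.
#'
#' @param cfg A `synth_config`.
#' @param tissues Tissue table.
#' @return A data.frame `tissue_id`, `cell_type`, `density` (cells/g).
#' @export
true_density_table <- function(cfg, tissues = tissue_table()) {
  scales <- group_density_scales()
  comps <- group_compositions()
  restr <- restricted_tissues()
  jit <- with_local_seed(cfg$seed * 7 + 1,
                         stats::rnorm(nrow(tissues), 0,
                                      cfg$tissue_jitter_sd_log10))
  rows <- list()
  for (i in seq_len(nrow(tissues))) {
    tis <- tissues$tissue_id[i]; grp <- tissues$group[i]
    total <- scales[[grp]] * 10^jit[i]
    comp <- comps[[grp]]
    for (ct in names(comp)) {
      allowed <- is.null(restr[[ct]]) || tis %in% restr[[ct]]
      if (!allowed) comp[[ct]] <- 0
    }
    comp <- comp / sum(comp)
    rows[[i]] <- data.frame(tissue_id = tis, cell_type = names(comp),
                            density = unname(total * comp),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# True per-cell masses in grams, macrophages resolved per tissue.
true_mass_table <- function(tissues = tissue_table()) {
  td <- true_diameters()
  mac <- macrophage_tissue_classes()
  rows <- data.frame(cell_type = names(td$base),
                     tissue_id = NA_character_,
                     mass_g = (pi / 6) * td$base^3 *
                       CELL_SPECIFIC_GRAVITY * 1e-12,
                     stringsAsFactors = FALSE)
  mac_d <- ifelse(mac$monocyte_replenished,
                  td$macrophage_replenished, td$macrophage_resident)
  rbind(rows,
        data.frame(cell_type = "macrophage", tissue_id = mac$tissue_id,
                   mass_g = (pi / 6) * mac_d^3 *
                     CELL_SPECIFIC_GRAVITY * 1e-12,
                   stringsAsFactors = FALSE))
}

# Ground-truth totals for one person from the true tables.
true_totals <- function(truth_densities, person = "male",
                        tissues = tissue_table(),
                        truth_masses = true_mass_table(tissues)) {
  masses <- resolve_person_masses(person, tissues)
  d <- truth_densities
  d$count <- d$density * unname(masses[d$tissue_id])
  key <- paste(d$cell_type, d$tissue_id)
  mt <- truth_masses
  mkey <- paste(mt$cell_type, mt$tissue_id)
  cell_mass <- ifelse(key %in% mkey,
                      stats::setNames(mt$mass_g, mkey)[key],
                      stats::setNames(mt$mass_g,
                                      mt$cell_type)[d$cell_type])
  d$mass <- d$count * cell_mass
  list(by_tissue = stats::aggregate(cbind(count, mass) ~ tissue_id, d, sum),
       by_type = stats::aggregate(cbind(count, mass) ~ cell_type, d, sum),
       grand_count = sum(d$count), grand_mass = sum(d$mass),
       entries = d)
}

#' Generate a complete synthetic input bundle with ground truth
#'
#' Emits every table the census pipeline reads, all drawn around a known
#' ground truth, deterministically per seed:
#' * literature evidence — per observed pair, `n_evidence` human records
#'   drawn lognormally around truth with the declared ferror, cycling
#'   through the per-gram / per-cm3 / areal-count dialects; pairs flagged
#'   missing get rodent/monkey records (for cross-species extrapolation)
#'   or nothing (group-mean extrapolation only);
#' * multiplexed imaging — for lymphoid tissues, Poisson field counts
#'   around truth x field volume with a between-patient lognormal effect;
#' * deconvolution fractions and anchors — per-sample group fractions
#'   consistent with the true immune composition plus lognormal noise,
#'   anchored on a non-immune population of known size;
#' * cell-size records — diameters jittered around the true size table,
#'   including blood-smear records inflated by the known smear bias.
#'
#' With `evidence_ferror = 1`, `patient_sd_log = 0` and
#' `fraction_noise_sd_log = 0` the bundle is noiseless: evidence equals
#' truth exactly, multiplex counts are set to their exact expectations,
#' and the pipeline reproduces the ground-truth totals to rounding error.
#'
#' @param cfg A `synth_config`.
#' @param tissues Tissue table (also returned in the bundle).
#' @return A list with `evidence`, `multiplex`, `fractions`, `anchors`,
#'   `sizes`, `tissues`, and `truth` (`densities`, `cell_masses`, and
#'   per-person totals for `male`, `female`, `child`).
#' @export
generate_bundle <- function(cfg, tissues = tissue_table()) {
  stopifnot(inherits(cfg, "synth_config"))
  truth <- true_density_table(cfg, tissues)
  tmass <- true_mass_table(tissues)
  noiseless <- cfg$evidence_ferror == 1
  sg <- stats::setNames(tissues$specific_gravity, tissues$tissue_id)
  lymphoid <- tissues$tissue_id[tissues$group == "lymphatic"]
  diam <- default_diameters_um()

  masses_male <- resolve_person_masses("male", tissues)

  with_local_seed(cfg$seed, {
    pos <- truth[truth$density > 0, ]
    miss <- stats::runif(nrow(pos)) < cfg$missing_pair_prob
    # density gaps afflict minor (tissue, cell type) pairs: any pair
    # carrying a substantial share of the body total has direct human
    # measurements, so extrapolation only ever fills small contributors
    contribution <- pos$density * unname(masses_male[pos$tissue_id])
    miss[contribution > 1e9] <- FALSE

    s_ev <- log(cfg$evidence_ferror)
    ev <- list()
    kinds <- c("per_gram", "per_cm3", "areal_count")
    for (i in seq_len(nrow(pos))) {
      tis <- pos$tissue_id[i]; ct <- pos$cell_type[i]
      d_true <- pos$density[i]
      if (!miss[i]) {
        for (j in seq_len(cfg$n_evidence)) {
          v_pg <- d_true * exp(stats::rnorm(1, 0, s_ev))
          kind <- kinds[(j - 1) %% length(kinds) + 1]
          row <- data.frame(tissue_id = tis, cell_type = ct,
                            method = if (j %% 2) "histology" else "flow",
                            value = v_pg, value_kind = "per_gram",
                            A_cm2 = NA_real_, T_um = NA_real_,
                            D_um = NA_real_,
                            error = cfg$evidence_ferror,
                            error_kind = "ferror", species = "human",
                            source = paste0("synthetic:", tis, ":", ct,
                                            ":", j),
                            stringsAsFactors = FALSE)
          if (kind == "per_cm3") {
            row$value <- v_pg * sg[[tis]]
            row$value_kind <- "per_cm3"
          } else if (kind == "areal_count") {
            row$value_kind <- "areal_count"
            row$A_cm2 <- 0.01; row$T_um <- 5; row$D_um <- 10
            row$value <- v_pg * sg[[tis]] * 0.01 * (5e-4 + 1e-3)
          }
          ev[[length(ev) + 1]] <- row
        }
      } else if (stats::runif(1) < 0.7) {
        # animal evidence only: density correct in order of magnitude
        n_nh <- 1 + (stats::runif(1) < 0.5)
        for (j in seq_len(n_nh)) {
          ev[[length(ev) + 1]] <- data.frame(
            tissue_id = tis, cell_type = ct, method = "histology",
            value = d_true * exp(stats::rnorm(1, 0, max(s_ev, 0.3))),
            value_kind = "per_gram", A_cm2 = NA_real_, T_um = NA_real_,
            D_um = NA_real_, error = max(cfg$evidence_ferror, 1.5),
            error_kind = "ferror",
            species = if (j %% 2) "rodent" else "monkey",
            source = paste0("synthetic-animal:", tis, ":", ct),
            stringsAsFactors = FALSE)
        }
      }
    }
    evidence <- do.call(rbind, c(ev, make.row.names = FALSE))

    # multiplexed imaging of the lymphoid organs
    mx <- list()
    field_area_um2 <- 160000
    for (tis in lymphoid) {
      tdens <- truth[truth$tissue_id == tis & truth$density > 0, ]
      for (p in seq_len(cfg$n_patients)) {
        eff <- if (cfg$patient_sd_log > 0)
          exp(stats::rnorm(1, 0, cfg$patient_sd_log)) else 1
        for (f in seq_len(cfg$n_fields)) {
          lam <- tdens$density * sg[[tis]] *
            (field_area_um2 * 1e-8) * (diam[tdens$cell_type] * 1e-4) * eff
          counts <- if (noiseless) lam else stats::rpois(length(lam), lam)
          mx[[length(mx) + 1]] <- data.frame(
            sample_id = sprintf("%s_p%02d_f%02d", tis, p, f),
            patient_id = sprintf("%s_p%02d", tis, p),
            tissue_id = tis, cell_type = tdens$cell_type,
            count = counts, field_area_um2 = field_area_um2,
            stringsAsFactors = FALSE)
        }
      }
    }
    multiplex <- do.call(rbind, c(mx, make.row.names = FALSE))

    # deconvolution fractions: immune groups as fractions of nucleated
    # cells, anchored on a non-immune population of known absolute size
    deconv_tissues <- intersect(c("spleen", "liver", "gi_tract", "lungs",
                                  "blood"), tissues$tissue_id)
    grp_counts <- rollup_to_groups(
      data.frame(tissue_id = truth$tissue_id, cell_type = truth$cell_type,
                 value = truth$density, ferror = 1))
    fr <- list(); an <- list()
    for (tis in deconv_tissues) {
      g <- grp_counts[grp_counts$tissue_id == tis, ]
      imm_total <- sum(g$value)
      nucleated <- imm_total * 3        # immune cells ~a third of nucleated
      anchor_frac_true <- 0.4
      an[[length(an) + 1]] <- data.frame(
        tissue_id = tis, anchor_type = "parenchymal",
        anchor_fraction_group = "anchor",
        anchor_count = anchor_frac_true * nucleated * masses_male[[tis]],
        anchor_ferror = 1.3, stringsAsFactors = FALSE)
      for (s in 1:3) {
        noise <- function() if (cfg$fraction_noise_sd_log > 0)
          exp(stats::rnorm(1, 0, cfg$fraction_noise_sd_log)) else 1
        fracs <- c(g$value / nucleated * replicate(nrow(g), noise()),
                   anchor_frac_true * noise())
        # fractions are compositional: renormalize if noise pushes past 1
        if (sum(fracs) > 1) fracs <- fracs / sum(fracs)
        fr[[length(fr) + 1]] <- data.frame(
          sample_id = sprintf("%s_s%d", tis, s), tissue_id = tis,
          group = c(g$group, "anchor"), fraction = fracs,
          stringsAsFactors = FALSE)
      }
    }
    fractions <- do.call(rbind, c(fr, make.row.names = FALSE))
    anchors <- do.call(rbind, c(an, make.row.names = FALSE))

    # cell-size records around the true mass table
    sz <- list()
    smear_types <- c("neutrophil", "basophil", "monocyte", "eosinophil")
    for (i in seq_len(nrow(tmass))) {
      ct <- tmass$cell_type[i]; tis <- tmass$tissue_id[i]
      d_true_um <- (6 * tmass$mass_g[i] /
                      (pi * CELL_SPECIFIC_GRAVITY * 1e-12))^(1 / 3)
      if (ct == "macrophage" && is.na(tis)) next
      n_rec <- if (ct == "macrophage") 2 else cfg$n_size_records
      for (j in seq_len(n_rec)) {
        smear <- ct %in% smear_types && j == 1
        d_obs <- d_true_um * exp(stats::rnorm(1, 0, cfg$size_sd_log)) *
          if (smear) (1 / 0.7)^(1 / 3) else 1
        sz[[length(sz) + 1]] <- data.frame(
          cell_type = ct, tissue = if (ct == "macrophage") tis else
            NA_character_,
          diameter_low_um = d_obs * 0.9, diameter_high_um = d_obs / 0.9,
          volume_um3 = NA_real_,
          context = if (smear) "blood smear" else "tissue section",
          species = "human",
          source = paste0("synthetic-size:", ct, ":", j),
          stringsAsFactors = FALSE)
      }
    }
    sizes <- do.call(rbind, c(sz, make.row.names = FALSE))

    list(evidence = evidence, multiplex = multiplex,
         fractions = fractions, anchors = anchors, sizes = sizes,
         tissues = tissues,
         truth = list(densities = truth, cell_masses = tmass,
                      male = true_totals(truth, "male", tissues, tmass),
                      female = true_totals(truth, "female", tissues, tmass),
                      child = true_totals(truth, "child", tissues, tmass)))
  })
}

#' Write a synthetic bundle to CSV files
#'
#' Serializes the bundle in the exact CSV dialects the pipeline readers
#' expect, plus the ground-truth density table for audit.
#'
#' @param bundle From [generate_bundle()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(evidence = file.path(dir, "evidence.csv"),
             multiplex = file.path(dir, "multiplex.csv"),
             fractions = file.path(dir, "fractions.csv"),
             anchors = file.path(dir, "anchors.csv"),
             sizes = file.path(dir, "sizes.csv"),
             tissues = file.path(dir, "tissues.csv"),
             truth_densities = file.path(dir, "truth_densities.csv"))
  utils::write.csv(bundle$evidence, paths["evidence"], row.names = FALSE)
  utils::write.csv(bundle$multiplex, paths["multiplex"], row.names = FALSE)
  utils::write.csv(bundle$fractions, paths["fractions"], row.names = FALSE)
  utils::write.csv(bundle$anchors, paths["anchors"], row.names = FALSE)
  utils::write.csv(bundle$sizes, paths["sizes"], row.names = FALSE)
  utils::write.csv(bundle$tissues, paths["tissues"], row.names = FALSE)
  utils::write.csv(bundle$truth$densities, paths["truth_densities"],
                   row.names = FALSE)
  invisible(paths)
}
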