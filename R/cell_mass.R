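#' Spherical cell volume from a diameter or diameter range
#'
#' Cells are modelled as spheres, `V = (pi/6) d^3`. Literature records
#' often give a diameter range; sizes are treated as lognormal, so the
#' representative diameter of a range is the geometric mean of its
#' endpoints.
#'
#' @param d_low_um Positive diameter in um (the single diameter, or the
#'   low end of a range).
#' @param d_high_um Optional high end of the range.
#' @return Volume in um^3.
#' @examples
#' volume_from_diameter(10)      # 523.6 um^3
#' volume_from_diameter(8, 18)   # geometric-mean diameter 12 -> 904.8
#' @export
volume_from_diameter <- function(d_low_um, d_high_um = NULL) {
  if (any(d_low_um <= 0)) stop("diameter must be positive")
  d <- if (is.null(d_high_um) || all(is.na(d_high_um))) d_low_um else {
    if (any(!is.na(d_high_um) & d_high_um < d_low_um)) {
      stop("diameter range has high < low")
    }
    ifelse(is.na(d_high_um), d_low_um, sqrt(d_low_um * d_high_um))
  }
  (pi / 6) * d^3
}

#' Correct blood-smear volumes for spreading
#'
#' Cells flattened on a blood smear read larger than in situ; smear-derived
#' volumes are shrunk by a factor of 0.7. Other measurement contexts pass
#' through unchanged.
#'
#' @param v_um3 Positive volume in um^3.
#' @param context Measurement context: `"blood smear"`, `"tissue section"`
#'   or `"suspension"`.
#' @param factor Smear correction factor, default 0.7.
#' @return Corrected volume in um^3.
#' @export
apply_smear_correction <- function(v_um3, context, factor = 0.7) {
  if (any(v_um3 <= 0)) stop("volume must be positive")
  ifelse(context == "blood smear", v_um3 * factor, v_um3)
}

# Per-record corrected volume in um^3 from a size-record data.frame.
record_volumes <- function(records) {
  v <- ifelse(is.finite(records$volume_um3), records$volume_um3,
              volume_from_diameter(records$diameter_low_um,
                                   records$diameter_high_um))
  apply_smear_correction(v, records$context)
}

#' Cell specific gravity, g/mL
#'
#' Single constant 1.07 g/mL for all immune cell types; the ~0.02 g/mL
#' variation between types is negligible next to volume uncertainty.
#' @export
CELL_SPECIFIC_GRAVITY <- 1.07

#' Representative cell mass from literature size records
#'
#' Corrected volumes are pooled assuming a lognormal size distribution:
#' geometric mean as the representative volume, log-space standard error
#' as its uncertainty; rodent records carry the species ferror penalty.
#' Mass = volume x 1.07 g/mL (1.07e-12 g/um^3).
#'
#' Macrophage sizes are strongly tissue-dependent. Resolution order for a
#' macrophage query with a `tissue` argument: records of that tissue;
#' else the aggregate over the tissue's monocyte-replenishment class; else
#' all macrophage records.
#'
#' @param records Size-record data.frame: `cell_type`, `tissue`,
#'   `diameter_low_um`, `diameter_high_um`, `volume_um3`, `context`,
#'   `species`, `source`.
#' @param cell_type The cell type to resolve.
#' @param tissue Optional tissue id (macrophages only).
#' @param mac_classes Data.frame from [macrophage_tissue_classes()].
#' @param species_penalty ferror multiplier on rodent/monkey records.
#' @return A `lognormal_estimate` in grams per cell.
#' @export
representative_mass <- function(records, cell_type, tissue = NULL,
                                mac_classes = macrophage_tissue_classes(),
                                species_penalty = 1.5) {
  rec <- records[records$cell_type == cell_type, , drop = FALSE]
  if (nrow(rec) == 0) {
    stop("no size records for cell type '", cell_type,
         "': the size table must cover every cell type in the census")
  }
  if (cell_type == "macrophage" && !is.null(tissue)) {
    tis_rec <- rec[!is.na(rec$tissue) & rec$tissue == tissue, , drop = FALSE]
    if (nrow(tis_rec) > 0) {
      rec <- tis_rec
    } else {
      cls <- mac_classes$monocyte_replenished[mac_classes$tissue_id == tissue]
      if (length(cls) == 1) {
        class_tissues <- mac_classes$tissue_id[
          mac_classes$monocyte_replenished == cls]
        cls_rec <- rec[!is.na(rec$tissue) & rec$tissue %in% class_tissues, ,
                       drop = FALSE]
        if (nrow(cls_rec) > 0) rec <- cls_rec
      }
    }
  }
  v <- record_volumes(rec)
  k <- length(v)
  se_log <- if (k > 1) stats::sd(log(v)) / sqrt(k) else 0
  penalty <- ifelse(rec$species != "human", log(species_penalty), 0)
  s <- sqrt(se_log^2 + mean(penalty)^2)
  lognormal_estimate(exp(mean(log(v))) * CELL_SPECIFIC_GRAVITY * 1e-12,
                     exp(s))
}

#' Read a cell-size record table
#'
#' @param path CSV with columns `cell_type`, `tissue`, `diameter_low_um`,
#'   `diameter_high_um`, `volume_um3`, `context`, `species`, `source`;
#'   exactly one of diameter / volume per row.
#' @return A data.frame of size records.
#' @export
read_size_records <- function(path) {
  sz <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_type", "context", "species")
  miss <- setdiff(need, names(sz))
  if (length(miss)) stop("size table lacks columns: ",
                         paste(miss, collapse = ", "))
  for (nm in c("tissue", "source")) {
    if (is.null(sz[[nm]])) sz[[nm]] <- NA_character_
  }
  for (nm in c("diameter_low_um", "diameter_high_um", "volume_um3")) {
    if (is.null(sz[[nm]])) sz[[nm]] <- NA_real_
  }
  has_d <- is.finite(sz$diameter_low_um)
  has_v <- is.finite(sz$volume_um3)
  if (any(has_d == has_v)) {
    stop("each size record needs exactly one of diameter or volume")
  }
  sz
}

#' Representative mass table for all cell types
#'
#' Resolves [representative_mass()] for every census cell type, and for
#' macrophages one row per tissue (falling back through the resolution
#' hierarchy where tissue-specific records are absent).
#'
#' @param records Size-record data.frame.
#' @param tissues Tissue table (for the macrophage per-tissue rows).
#' @param species_penalty ferror multiplier on non-human records.
#' @return A data.frame `cell_type`, `tissue_id` (`NA` for the
#'   tissue-independent types), `mass_g`, `ferror`.
#' @export
representative_mass_table <- function(records, tissues = tissue_table(),
                                      species_penalty = 1.5) {
  rows <- list()
  for (ct in cell_types()) {
    if (ct == "macrophage") {
      for (tis in tissues$tissue_id) {
        m <- representative_mass(records, ct, tissue = tis,
                                 species_penalty = species_penalty)
        rows[[length(rows) + 1]] <- data.frame(
          cell_type = ct, tissue_id = tis, mass_g = m$value,
          ferror = m$ferror, stringsAsFactors = FALSE)
      }
    } else {
      m <- representative_mass(records, ct,
                               species_penalty = species_penalty)
      rows[[length(rows) + 1]] <- data.frame(
        cell_type = ct, tissue_id = NA_character_, mass_g = m$value,
        ferror = m$ferror, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
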