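#' Published whole-body per-type totals
#'
#' The printed headline table of the published human immune-cell census:
#' per cell type, the total number of cells and total cellular mass in
#' the 73-kg reference male with 95% CIs, rounded to one significant
#' digit as printed, plus the grand-total row. Shipped for cross-checks
#' and for in-table consistency arithmetic (e.g. the macrophage share of
#' total immune-cell mass).
#'
#' @return A data.frame with columns `cell_type`, `total_number`,
#'   `number_ci_low`, `number_ci_high`, `total_mass_g`, `mass_ci_low_g`,
#'   `mass_ci_high_g`.
#' @export
published_cell_type_totals <- function() {
  utils::read.csv(system.file("extdata", "published_cell_type_totals.csv",
                              package = "immunecensus"),
                  stringsAsFactors = FALSE)
}

#' Share of one cell type in a printed totals table
#'
#' Computes a cell type's share of the table's own total, in percent —
#' internal consistency arithmetic on printed values (for example the
#' macrophage share of total immune-cell mass, ~50%).
#'
#' @param totals A table as from [published_cell_type_totals()].
#' @param cell_type The cell type of interest.
#' @param column `"total_mass_g"` or `"total_number"`.
#' @return The share in percent.
#' @export
cell_type_share <- function(totals = published_cell_type_totals(),
                            cell_type = "macrophage",
                            column = "total_mass_g") {
  num <- totals[[column]][totals$cell_type == cell_type]
  den <- totals[[column]][totals$cell_type == "total"]
  if (length(num) != 1 || length(den) != 1) {
    stop("table must contain '", cell_type, "' and a 'total' row")
  }
  100 * num / den
}
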