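#' The eleven immune cell types of the census
#'
#' Closed vocabulary of the major immune cell types tracked by the census,
#' split into the lymphoid and myeloid lineages. Three rare granulocyte
#' types are tissue-restricted: eosinophils (GI tract, bone marrow, spleen,
#' lymph nodes, thymus), mast cells (connective tissues, lamina propria of
#' barrier epithelia, minimal bone marrow presence) and basophils (bone
#' marrow and blood). Restricted types are never extrapolated outside their
#' home tissues.
#'
#' @return A data.frame with columns `cell_type`, `lineage`
#'   (`lymphoid`/`myeloid`) and `is_granulocyte`.
#' @export
cell_type_table <- function() {
  data.frame(
    cell_type = c("T cell", "B cell", "plasma cell", "NK cell",
                  "neutrophil", "eosinophil", "basophil", "mast cell",
                  "macrophage", "monocyte", "dendritic cell"),
    lineage = c(rep("lymphoid", 4), rep("myeloid", 7)),
    is_granulocyte = c(rep(FALSE, 4), TRUE, TRUE, TRUE, TRUE,
                       FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' @rdname cell_type_table
#' @export
cell_types <- function() cell_type_table()$cell_type

#' @rdname cell_type_table
#' @export
lymphocyte_types <- function() c("T cell", "B cell", "plasma cell", "NK cell")

#' @rdname cell_type_table
#' @export
granulocyte_types <- function() {
  ct <- cell_type_table()
  ct$cell_type[ct$is_granulocyte]
}

#' Tissue-restriction rules for rare granulocytes
#'
#' Maps each restricted cell type to the tissues where it has a meaningful
#' presence; for all other tissues its density is fixed at zero and never
#' extrapolated. Unlisted cell types are unrestricted. Editable: pass a
#' modified copy to [fill_missing_densities()].
#'
#' @return Named list of character vectors of tissue ids.
#' @export
restricted_tissues <- function() {
  list(
    "eosinophil" = c("gi_tract", "bone_marrow", "spleen", "lymph_nodes",
                     "thymus"),
    "mast cell" = c("gi_tract", "skin", "lungs", "other_connective",
                    "bone_marrow"),
    "basophil" = c("bone_marrow", "blood")
  )
}

#' Reference tissue table
#'
#' The tissues and organs the census covers, grouped by assumed similarity
#' of immune-cell presence, with specific gravity (1.03 g/mL generic,
#' 0.91 g/mL adipose) and ICRP-style reference organ masses for the three
#' reference persons (73-kg adult male, 60-kg adult female, 32-kg
#' 10-year-old child). Lymph-node mass is tabulated only for the male; for
#' other persons it is interpolated linearly by body-mass ratio at census
#' time (see [scale_to_person()]).
#'
#' Masses are working reference values in grams; callers with their own
#' anatomical table can supply a replacement data.frame with the same
#' columns (`tissue_id`, `group`, `specific_gravity`, `mass_male_g`,
#' `mass_female_g`, `mass_child_g`).
#'
#' @return A data.frame, one row per tissue.
#' @export
tissue_table <- function() {
  df <- read.csv(text = "
tissue_id,group,specific_gravity,mass_male_g,mass_female_g,mass_child_g
bone_marrow,bone marrow,1.03,1170,900,610
spleen,lymphatic,1.03,150,130,80
lymph_nodes,lymphatic,1.03,250,NA,NA
thymus,lymphatic,1.03,25,20,38
tonsils,lymphatic,1.03,3,3,3
blood,blood,1.03,5600,4100,2400
skin,barrier epithelial,1.03,3300,2300,1600
gi_tract,barrier epithelial,1.03,1200,1000,700
lungs,barrier epithelial,1.03,1200,950,640
liver,other epithelial,1.03,1800,1400,830
kidneys,other epithelial,1.03,310,275,180
pancreas,other epithelial,1.03,140,120,60
skeletal_muscle,striated muscle,1.03,29000,17500,9500
heart,striated muscle,1.03,330,250,220
adipose,adipose,0.91,18200,22500,8600
other_connective,other connective,1.03,3000,2400,1500
cns,CNS,1.03,1450,1300,1310
ecf_matrix,extracellular fluids and matrix,1.03,4000,3200,1800
", stringsAsFactors = FALSE, strip.white = TRUE)
  df
}

#' Organ masses of one reference person
#'
#' @param person One of `"male"`, `"female"`, `"child"`.
#' @param tissues A tissue table as from [tissue_table()].
#' @return Named numeric vector of organ masses in grams (lymph nodes may
#'   be `NA` for non-male persons; see [scale_to_person()]).
#' @export
person_masses <- function(person = c("male", "female", "child"),
                          tissues = tissue_table()) {
  person <- match.arg(person)
  col <- paste0("mass_", person, "_g")
  stats::setNames(tissues[[col]], tissues$tissue_id)
}

#' Reference-person body masses
#' @return Named numeric vector, kg: male 73, female 60, child 32.
#' @export
reference_body_mass_kg <- function() {
  c(male = 73, female = 60, child = 32)
}

#' Default representative cell diameters for imaging fields
#'
#' Effective section thickness per cell type when converting per-area
#' imaging counts to volumetric densities (cells span roughly 7.5 to
#' 17 um depending on type): lymphocytes 7.5 um, granulocytes and
#' monocytes 10-12 um, macrophages and dendritic cells 17 um.
#' Override by passing a modified copy where measured diameters exist.
#'
#' @return Named numeric vector of diameters in micrometres.
#' @export
default_diameters_um <- function() {
  c("T cell" = 7.5, "B cell" = 7.5, "plasma cell" = 10, "NK cell" = 7.5,
    "neutrophil" = 10, "eosinophil" = 10, "basophil" = 10,
    "mast cell" = 12, "macrophage" = 17, "monocyte" = 12,
    "dendritic cell" = 17)
}

#' Monocyte-replenishment classification of tissue macrophages
#'
#' Tissue macrophage size depends on niche; tissues are classed by whether
#' the macrophage pool is continuously replenished from blood monocytes
#' (e.g. gut, dermis) or self-maintained (e.g. microglia, Kupffer cells,
#' alveolar macrophages established prenatally).
#'
#' @return A data.frame with `tissue_id` and logical `monocyte_replenished`.
#' @export
macrophage_tissue_classes <- function() {
  t <- tissue_table()$tissue_id
  replenished <- c("gi_tract", "skin", "adipose", "other_connective",
                   "ecf_matrix", "pancreas", "kidneys", "heart",
                   "skeletal_muscle", "bone_marrow", "blood")
  data.frame(tissue_id = t,
             monocyte_replenished = t %in% replenished,
             stringsAsFactors = FALSE)
}
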