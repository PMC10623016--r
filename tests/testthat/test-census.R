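# Census assembly: method combination, integration, margins, scenarios.

test_that("method combination pools literature and multiplex per pair", {
  lit <- data.frame(tissue_id = c("spleen", "liver"),
                    cell_type = "T cell", value = c(1e7, 2e6),
                    ferror = c(3, 1.5), stringsAsFactors = FALSE)
  only_lit <- combine_methods(lit, NULL)
  expect_equal(only_lit$value, lit$value)
  expect_true(all(only_lit$method == "literature"))

  mx <- data.frame(tissue_id = "spleen", cell_type = "T cell",
                   value = 4e7, ferror = 1.3, stringsAsFactors = FALSE)
  comb <- combine_methods(lit, mx)
  sp <- comb[comb$tissue_id == "spleen", ]
  expect_equal(sp$method, "combined")
  # inverse-variance: the tighter multiplex estimate dominates
  w <- 1 / log(c(3, 1.3))^2
  expect_equal(w[2] / w[1], 17.5, tolerance = 0.02)
  expect_equal(sp$value, exp(sum(w * log(c(1e7, 4e7))) / sum(w)),
               tolerance = 1e-12)
  expect_gt(sp$value, 1e7); expect_lt(sp$value, 4e7)
  expect_gt(sp$value, 3e7)  # closer to the multiplex side
  # liver untouched, multiplex-only pairs pass through
  expect_equal(comb$value[comb$tissue_id == "liver"], 2e6)
  mx2 <- rbind(mx, data.frame(tissue_id = "thymus", cell_type = "T cell",
                              value = 5e8, ferror = 1.2))
  comb2 <- combine_methods(lit, mx2)
  expect_equal(comb2$method[comb2$tissue_id == "thymus"], "multiplex")

  # equal ferrors reduce to the geometric mean
  eq <- combine_methods(
    data.frame(tissue_id = "spleen", cell_type = "B cell",
               value = 1e7, ferror = 2, stringsAsFactors = FALSE),
    data.frame(tissue_id = "spleen", cell_type = "B cell",
               value = 4e7, ferror = 2, stringsAsFactors = FALSE))
  expect_equal(eq$value, 2e7, tolerance = 1e-12)
})

test_that("count integration multiplies density by organ mass with margins", {
  dens <- data.frame(tissue_id = "spleen", cell_type = "T cell",
                     value = 1e7, ferror = 1, stringsAsFactors = FALSE)
  tis <- tissue_table()
  cen <- integrate_counts(dens, "male", tis, n_draws = 500, seed = 1)
  expect_equal(cen$entries$value, 1e7 * 150)  # exact product
  expect_equal(cen$grand[["value"]], 1.5e9)
  expect_equal(cen$grand[["ci_low"]], 1.5e9)  # exact in, exact out

  expect_error(integrate_counts(
    data.frame(tissue_id = "nowhere", cell_type = "T cell", value = 1,
               ferror = 1), "male", tis), "nowhere")
})

test_that("margins conserve: tissue sum = type sum = grand total", {
  bundle <- generate_bundle(synth_config(seed = 4))
  res <- run_census_pipeline(bundle, seed = 4, n_draws = 500)
  for (cen in list(res$counts, res$masses)) {
    g <- cen$grand[["value"]]
    expect_equal(sum(cen$by_tissue$value), g, tolerance = 1e-9)
    expect_equal(sum(cen$by_type$value), g, tolerance = 1e-9)
    expect_equal(sum(cen$entries$value), g, tolerance = 1e-9)
    expect_true(all(cen$entries$value >= 0))
    # every margin equals the sum of its member point values
    for (tis in cen$by_tissue$tissue_id) {
      expect_equal(cen$by_tissue$value[cen$by_tissue$tissue_id == tis],
                   sum(cen$entries$value[cen$entries$tissue_id == tis]),
                   tolerance = 1e-9)
    }
  }
})

test_that("increasing a density or organ mass never shrinks a margin", {
  dens <- tiny_density_table()
  tis <- tissue_table()
  base <- integrate_counts(dens, "male", tis, n_draws = 500, seed = 2)
  up <- dens; up$value[1] <- up$value[1] * 2
  cen_up <- integrate_counts(up, "male", tis, n_draws = 500, seed = 2)
  expect_true(all(cen_up$by_tissue$value >= base$by_tissue$value))
  expect_true(all(cen_up$by_type$value >= base$by_type$value))
  expect_gt(cen_up$grand[["value"]], base$grand[["value"]])

  tis2 <- tis; tis2$mass_male_g[tis2$tissue_id == "liver"] <- 2 * 1800
  cen_m <- integrate_counts(dens, "male", tis2, n_draws = 500, seed = 2)
  expect_true(all(cen_m$by_tissue$value >= base$by_tissue$value))
  expect_gt(cen_m$grand[["value"]], base$grand[["value"]])
})

test_that("mass census multiplies counts by per-type masses, macrophages by tissue", {
  dens <- tiny_density_table()
  cen <- integrate_counts(dens, "male", n_draws = 500, seed = 3)
  mt <- representative_mass_table(tiny_size_records())
  mc <- mass_census(cen, mt)
  # 1e9-scale check: count x mass entry by entry
  liver_mac_count <- cen$entries$value[cen$entries$tissue_id == "liver" &
                                         cen$entries$cell_type == "macrophage"]
  liver_mac_mass <- mc$entries$value[mc$entries$tissue_id == "liver" &
                                       mc$entries$cell_type == "macrophage"]
  m_liver <- mt$mass_g[mt$cell_type == "macrophage" &
                         !is.na(mt$tissue_id) & mt$tissue_id == "liver"]
  expect_equal(liver_mac_mass, liver_mac_count * m_liver, tolerance = 1e-12)
  # spleen macrophages use the spleen-resolved (class) mass, not liver's
  spleen_mac_mass <- mc$entries$value[mc$entries$tissue_id == "spleen" &
                                        mc$entries$cell_type == "macrophage"]
  spleen_mac_count <- cen$entries$value[cen$entries$tissue_id == "spleen" &
                                          cen$entries$cell_type == "macrophage"]
  m_spleen <- mt$mass_g[mt$cell_type == "macrophage" &
                          !is.na(mt$tissue_id) & mt$tissue_id == "spleen"]
  expect_equal(spleen_mac_mass, spleen_mac_count * m_spleen,
               tolerance = 1e-12)
  # 5e8 T cells/g * 150 g * 236 pg/cell = ~17.7 g of spleen T cells
  t_mass <- mt$mass_g[mt$cell_type == "T cell" & is.na(mt$tissue_id)]
  expect_equal(mc$entries$value[mc$entries$tissue_id == "spleen" &
                                  mc$entries$cell_type == "T cell"],
               5e8 * 150 * t_mass, tolerance = 1e-12)
})

test_that("person scaling is linear in organ masses with lymph-node interpolation", {
  dens <- tiny_density_table()
  tis <- tissue_table()
  male <- integrate_counts(dens, "male", tis, n_draws = 500, seed = 6)
  male2 <- scale_to_person(dens, "male", tis, n_draws = 500, seed = 6)
  expect_identical(male$entries, male2$entries)

  child <- scale_to_person(dens, "child", tis, n_draws = 500, seed = 6)
  masses_c <- person_masses("child", tis)
  for (i in seq_len(nrow(child$entries))) {
    tid <- child$entries$tissue_id[i]
    expect_equal(child$entries$value[i] / male$entries$value[i],
                 masses_c[[tid]] / person_masses("male", tis)[[tid]],
                 tolerance = 1e-12)
  }
  # interpolated lymph-node mass: male value x body-mass ratio
  dens_ln <- data.frame(tissue_id = "lymph_nodes", cell_type = "T cell",
                        value = 5e8, ferror = 1.5, stringsAsFactors = FALSE)
  ln_child <- scale_to_person(dens_ln, "child", tis, n_draws = 500, seed = 6)
  expect_equal(ln_child$entries$value, 5e8 * 250 * 32 / 73,
               tolerance = 1e-12)

  # halving every organ mass halves every entry and margin
  tis_half <- tis
  for (col in c("mass_male_g")) tis_half[[col]] <- tis_half[[col]] / 2
  half <- integrate_counts(dens, "male", tis_half, n_draws = 500, seed = 6)
  expect_equal(half$entries$value, male$entries$value / 2, tolerance = 1e-12)
  expect_equal(half$grand[["value"]], male$grand[["value"]] / 2,
               tolerance = 1e-12)
})

test_that("scenario engine: cube law, fraction-weighted enlargement, identity", {
  expect_identical(volume_scale_from_diameter(2), 8)
  expect_equal(volume_scale_from_diameter(2.5), 15.625)

  dens <- tiny_density_table()
  dens <- rbind(dens, data.frame(tissue_id = "lymph_nodes",
                                 cell_type = "T cell", value = 5e8,
                                 ferror = 1.5, stringsAsFactors = FALSE))
  # 2% of lymph-node mass enlarged 11-fold: factor 1 + 0.02*10 = 1.20
  sc <- apply_scenario(dens,
                       data.frame(tissue_id = "lymph_nodes",
                                  cell_type = NA_character_,
                                  factor = 11, fraction = 0.02),
                       n_draws = 500, seed = 8)
  ln <- sc$change[sc$change$tissue_id == "lymph_nodes", ]
  expect_equal(ln$rel_change, 0.20, tolerance = 1e-12)
  others <- sc$change[sc$change$tissue_id != "lymph_nodes", ]
  expect_true(all(abs(others$rel_change) < 1e-12))

  # splenomegaly: doubling spleen mass doubles its margin
  sp <- apply_scenario(dens,
                       data.frame(tissue_id = "spleen",
                                  cell_type = NA_character_, factor = 2,
                                  fraction = 1),
                       n_draws = 500, seed = 8)
  expect_equal(sp$change$rel_change[sp$change$tissue_id == "spleen"], 1,
               tolerance = 1e-12)

  # density modifier touches only its (tissue, cell type)
  ob <- apply_scenario(dens,
                       data.frame(tissue_id = "liver",
                                  cell_type = "macrophage", factor = 10,
                                  fraction = 1),
                       n_draws = 500, seed = 8)
  liv <- ob$census$entries
  expect_equal(liv$value[liv$tissue_id == "liver" &
                           liv$cell_type == "macrophage"],
               10 * 2e7 * 1800, tolerance = 1e-12)
  expect_equal(liv$value[liv$tissue_id == "liver" &
                           liv$cell_type == "T cell"], 1e7 * 1800)

  # empty scenario is the identity
  id <- apply_scenario(dens, data.frame(tissue_id = character(0),
                                        cell_type = character(0),
                                        factor = numeric(0),
                                        fraction = numeric(0)),
                       n_draws = 500, seed = 8)
  expect_equal(id$grand_rel_change, 0)
  expect_error(apply_scenario(dens, data.frame(tissue_id = "nowhere",
                                               cell_type = NA,
                                               factor = 2, fraction = 1)),
               "unknown tissue")
})

test_that("subset margins and the report summary stay consistent", {
  bundle <- generate_bundle(synth_config(seed = 14))
  res <- run_census_pipeline(bundle, seed = 14, n_draws = 500)
  lymph <- margin_subset(res$counts, lymphocyte_types())
  gran <- margin_subset(res$counts, granulocyte_types())
  rest <- margin_subset(res$counts,
                        setdiff(cell_types(),
                                c(lymphocyte_types(), granulocyte_types())))
  expect_equal(lymph[["value"]] + gran[["value"]] + rest[["value"]],
               res$counts$grand[["value"]], tolerance = 1e-9)
  expect_lt(lymph[["ci_low"]], lymph[["value"]])
  expect_gt(lymph[["ci_high"]], lymph[["value"]])

  summ <- census_summary(res$counts, res$masses)
  expect_equal(nrow(summ), 12)
  expect_equal(summ$value_n[summ$cell_type == "total"],
               res$counts$grand[["value"]])
  # printed columns are rounded to one significant digit
  expect_equal(summ$value_n_printed, signif(summ$value_n, 1))
})
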