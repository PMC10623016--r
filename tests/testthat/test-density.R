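# Literature evidence -> per-gram densities.

test_that("areal-count stereology formula and unit handling", {
  expect_equal(density_from_areal_count(0, 1, 5e-4, 1e-3), 0)
  # 1000 cells over 0.01 cm^2, 5 um section, 10 um cells
  expect_equal(density_from_areal_count(1000, 0.01, 5e-4, 1e-3),
               1000 / (0.01 * 1.5e-3))
  expect_equal(density_from_areal_count(1000, 0.01, 5e-4, 1e-3),
               6.6667e7, tolerance = 1e-4)
  # zero-thickness imaging section
  expect_equal(density_from_areal_count(100, 1, 0, 1e-3), 1e5)
  expect_error(density_from_areal_count(10, 0, 1e-4, 1e-3), "A_cm2")
  expect_error(density_from_areal_count(10, 1, 1e-4, 0), "D_cm")

  # linear in n, inversely linear in A and (T + D)
  base <- density_from_areal_count(50, 0.5, 4e-4, 8e-4)
  expect_equal(density_from_areal_count(100, 0.5, 4e-4, 8e-4), 2 * base)
  expect_equal(density_from_areal_count(50, 1.0, 4e-4, 8e-4), base / 2)
  expect_equal(density_from_areal_count(50, 0.5, 8e-4, 1.6e-3), base / 2)
})

test_that("specific-gravity conversion divides, with the adipose exception", {
  expect_equal(volumetric_to_per_gram(1.03e6, 1.03), 1e6)
  expect_equal(volumetric_to_per_gram(0, 1.03), 0)
  expect_equal(volumetric_to_per_gram(9.1e5, 0.91), 1e6)
})

test_that("relative-abundance and total-count conversions propagate ferror", {
  ref <- lognormal_estimate(1e7, 1.3)
  ident <- density_from_relative_abundance(1, ref)
  expect_equal(ident$value, 1e7); expect_equal(ident$ferror, 1.3)

  d <- density_from_relative_abundance(0.05, lognormal_estimate(2e8, 2))
  expect_equal(d$value, 1e7); expect_equal(d$ferror, 2)
  expect_error(density_from_relative_abundance(1.5, ref), "fraction")
  expect_error(density_from_relative_abundance(0, ref), "fraction")

  t1 <- density_from_total_count(lognormal_estimate(7.3e11, 1.2), 73000)
  expect_equal(t1$value, 1e7); expect_equal(t1$ferror, 1.2)
  t2 <- density_from_total_count(lognormal_estimate(0.5e9, 1), 500)
  expect_equal(t2$value, 1e6); expect_equal(t2$ferror, 1)
  expect_error(density_from_total_count(lognormal_estimate(1e9, 2), 0),
               "positive")
  # round trip: integrating the density back over the mass recovers the total
  expect_equal(t1$value * 73000, 7.3e11)
})

test_that("compartment weighting averages by mass fraction and stays bounded", {
  one <- compartment_weighted_density(1, lognormal_estimate(3e6, 1.8),
                                      seed = 1)
  expect_equal(one$value, 3e6)

  half <- compartment_weighted_density(
    c(0.5, 0.5),
    lognormal_estimate(c(2e6, 0), c(1, Inf)), seed = 1)
  expect_equal(half$value, 1e6)

  epi <- compartment_weighted_density(
    c(0.1, 0.9), lognormal_estimate(c(1e8, 1e6), c(1.5, 1.5)), seed = 1)
  expect_equal(epi$value, 0.1 * 1e8 + 0.9 * 1e6)
  expect_equal(epi$value, 1.09e7)

  expect_error(compartment_weighted_density(
    c(0.5, 0.4), lognormal_estimate(c(1, 1), 1), seed = 1), "sum to 1")

  set.seed(9)
  for (i in 1:10) {
    k <- sample(2:4, 1)
    fr <- as.numeric(rmultinom(1, 100, rep(1, k))) / 100
    fr <- fr[fr > 0]
    v <- 10^runif(length(fr), 4, 8)
    est <- compartment_weighted_density(
      fr, lognormal_estimate(v, runif(length(fr), 1, 2)), seed = i)
    expect_gte(est$value, min(v) - 1e-9)
    expect_lte(est$value, max(v) + 1e-9)
  }
})

test_that("evidence normalization merges records by geometric mean with spread", {
  ev <- data.frame(
    tissue_id = "spleen", cell_type = "T cell", method = "histology",
    value = c(1e8, 4e8), value_kind = "per_gram",
    A_cm2 = NA_real_, T_um = NA_real_, D_um = NA_real_,
    error = 1.5, error_kind = "ferror", species = "human",
    compartment = NA_character_, compartment_fraction = NA_real_,
    ref_value = NA_real_, ref_ferror = NA_real_, source = "x",
    stringsAsFactors = FALSE)
  norm <- normalize_evidence(ev, seed = 1)
  expect_equal(nrow(norm), 1)
  expect_equal(norm$value, 2e8)  # geometric mean
  # ferror folds measurement error and between-record spread, shrunk by k
  s2_expected <- (log(1.5)^2 + var(log(c(1e8, 4e8)))) / 2
  expect_equal(norm$ferror, exp(sqrt(s2_expected)), tolerance = 1e-12)
  expect_gt(norm$ferror, 1)

  # per_cm3 and areal_count dialects land on the same per-gram value
  ev2 <- ev[1, ]
  ev2$value_kind <- "per_cm3"; ev2$value <- 1e8 * 1.03
  ev3 <- ev[1, ]
  ev3$value_kind <- "areal_count"
  ev3$A_cm2 <- 0.01; ev3$T_um <- 5; ev3$D_um <- 10
  ev3$value <- 1e8 * 1.03 * 0.01 * 1.5e-3
  both <- normalize_evidence(rbind(ev[1, ], ev2, ev3), seed = 1)
  expect_equal(both$value, 1e8, tolerance = 1e-12)
  expect_equal(both$n_records, 3)

  # nonhuman records are normalized but kept apart from human evidence
  ev4 <- rbind(ev, transform(ev[1, ], species = "rodent", value = 2e8))
  norm4 <- normalize_evidence(ev4, seed = 1)
  expect_setequal(norm4$species, c("human", "nonhuman"))
  expect_equal(norm4$value[norm4$species == "nonhuman"], 2e8)
})

test_that("se-kind errors are moment-matched during normalization", {
  ev <- data.frame(
    tissue_id = "liver", cell_type = "NK cell", method = "flow",
    value = 1e6, value_kind = "per_gram", A_cm2 = NA_real_,
    T_um = NA_real_, D_um = NA_real_, error = 5e5, error_kind = "se",
    species = "human", compartment = NA_character_,
    compartment_fraction = NA_real_, ref_value = NA_real_,
    ref_ferror = NA_real_, source = "x", stringsAsFactors = FALSE)
  norm <- normalize_evidence(ev, seed = 1)
  ref <- fit_lognormal_from_normal(1e6, 5e5)
  expect_equal(norm$value, ref$value, tolerance = 1e-12)
  expect_equal(norm$ferror, ref$ferror, tolerance = 1e-12)
})

test_that("normalized densities cover generator truth across seeded replicates", {
  # per-(tissue, cell type) 95% CI coverage of the known truth, pooled
  # over 200 light replicates of the evidence stage
  hits <- 0L; n <- 0L
  for (r in 1:200) {
    cfg <- synth_config(seed = 7000 + r, missing_pair_prob = 0)
    truth <- true_density_table(cfg)
    bundle <- generate_bundle(cfg)
    norm <- normalize_evidence(bundle$evidence, seed = r)
    m <- merge(norm[norm$species == "human", ], truth,
               by = c("tissue_id", "cell_type"))
    ci <- ci95(lognormal_estimate(m$value, m$ferror))
    hits <- hits + sum(m$density >= ci$low & m$density <= ci$high)
    n <- n + nrow(m)
  }
  expect_gt(n, 1000)
  expect_gte(hits / n, 0.90)
})
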