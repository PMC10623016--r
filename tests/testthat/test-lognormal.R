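# Core multiplicative-error arithmetic.

test_that("moment-matched lognormal fit reproduces normal mean and SD", {
  # zero uncertainty is the identity
  e0 <- fit_lognormal_from_normal(10, 0)
  expect_equal(e0$value, 10)
  expect_equal(e0$ferror, 1)

  # closed-form values for mean 100, se 50
  e <- fit_lognormal_from_normal(100, 50)
  s2 <- log(1 + 0.25)
  expect_equal(shape_param(e)^2, s2, tolerance = 1e-12)
  expect_equal(e$ferror, exp(sqrt(s2)), tolerance = 1e-12)
  expect_equal(e$value, 100 * exp(-s2 / 2), tolerance = 1e-12)
  expect_equal(e$value, 89.4427, tolerance = 1e-4)
  expect_equal(e$ferror, 1.6038, tolerance = 1e-4)

  # round trip: the fitted lognormal has the input moments
  for (case in list(c(10, 2), c(1e6, 3e5), c(5, 12))) {
    f <- fit_lognormal_from_normal(case[1], case[2])
    mom <- lognormal_moments(f)
    expect_equal(mom$mean, case[1], tolerance = 1e-12)
    expect_equal(mom$sd, case[2], tolerance = 1e-12)
  }

  expect_error(fit_lognormal_from_normal(5, -1), "nonnegative")
  expect_error(fit_lognormal_from_normal(-5, 1), "positive")
  expect_error(fit_lognormal_from_normal(1, 10), "ill-posed")
})

test_that("moment fit agrees with Monte-Carlo moments of the fitted lognormal", {
  e <- fit_lognormal_from_normal(100, 50)
  set.seed(42)
  draws <- rlognorm_est(2e5, e$value, e$ferror)
  expect_equal(mean(draws), 100, tolerance = 0.01)
  expect_equal(sd(draws), 50, tolerance = 0.03)
})

test_that("product propagation follows root-sum-of-squares of shapes", {
  a <- lognormal_estimate(2, 1.5)
  b <- lognormal_estimate(3, 1)
  p <- propagate_product(a, b)
  expect_equal(p$value, 6)
  expect_equal(p$ferror, 1.5)  # exact factor is identity

  q <- propagate_product(lognormal_estimate(1, 2), lognormal_estimate(1, 2))
  expect_equal(q$ferror, exp(sqrt(2 * log(2)^2)), tolerance = 1e-12)
  expect_equal(q$ferror, 2.6651, tolerance = 1e-4)

  big <- propagate_product(lognormal_estimate(1e6, 1.2),
                           lognormal_estimate(73, 1))
  expect_equal(big$value, 7.3e7)
  expect_equal(big$ferror, 1.2)
})

test_that("product propagation is commutative, associative, dominance-monotone", {
  set.seed(7)
  for (i in 1:20) {
    v <- runif(3, 0.1, 100); f <- runif(3, 1, 4)
    e <- lapply(1:3, function(j) lognormal_estimate(v[j], f[j]))
    ab <- propagate_product(e[[1]], e[[2]])
    ba <- propagate_product(e[[2]], e[[1]])
    expect_equal(ab$value, ba$value)
    expect_equal(ab$ferror, ba$ferror)
    abc1 <- propagate_product(ab, e[[3]])
    abc2 <- propagate_product(e[[1]], propagate_product(e[[2]], e[[3]]))
    expect_equal(abc1$ferror, abc2$ferror, tolerance = 1e-12)
    expect_gte(ab$ferror, max(f[1:2]) - 1e-12)
  }
})

test_that("propagated product matches a Monte-Carlo product of lognormals", {
  a <- lognormal_estimate(1, 2); b <- lognormal_estimate(1, 2)
  p <- propagate_product(a, b)
  set.seed(11)
  draws <- rlognorm_est(1e6, a$value, a$ferror) *
    rlognorm_est(1e6, b$value, b$ferror)
  mc <- quantile(draws, c(0.025, 0.975), names = FALSE)
  an <- ci95(p)
  expect_equal(an$low, mc[1], tolerance = 0.03)
  expect_equal(an$high, mc[2], tolerance = 0.03)
})

test_that("interval extraction matches the one-sigma and 95% definitions", {
  exact <- ci95(lognormal_estimate(1, 1))
  expect_equal(exact$low, 1); expect_equal(exact$high, 1)

  one_sigma <- ci68(lognormal_estimate(1, 2))
  expect_equal(one_sigma$low, 0.5)   # half to double the value
  expect_equal(one_sigma$high, 2)

  wide <- ci95(lognormal_estimate(100, 1.5))
  expect_equal(wide$low, 100 * 1.5^-1.96, tolerance = 1e-12)
  expect_equal(wide$high, 100 * 1.5^1.96, tolerance = 1e-12)
  expect_equal(wide$low, 45.17, tolerance = 1e-3)
  expect_equal(wide$high, 221.38, tolerance = 1e-3)
})

test_that("inverse-variance combination pools on the log scale", {
  # identity on a single estimate
  single <- inverse_variance_combine(lognormal_estimate(3, 1.7))
  expect_equal(single$value, 3)
  expect_equal(single$ferror, 1.7)

  # equal ferrors -> geometric mean, shrunk shape
  comb <- inverse_variance_combine(lognormal_estimate(c(1e6, 4e6), 2))
  expect_equal(comb$value, 2e6, tolerance = 1e-12)
  expect_equal(comb$ferror, exp(log(2) / sqrt(2)), tolerance = 1e-12)
  expect_equal(comb$ferror, 1.6325, tolerance = 1e-4)

  # grossly unequal precision: the tight estimate dominates
  skew <- inverse_variance_combine(
    lognormal_estimate(c(1e6, 1e8), c(1.1, 10)))
  w <- 1 / log(c(1.1, 10))^2
  expect_gt(w[1] / w[2], 500)  # log-weight ratio ~583
  expect_equal(skew$value, 1e6 * 100^(w[2] / sum(w)), tolerance = 1e-10)
  expect_lt(skew$value, 1.02e6)  # pinned to the tight estimate's side

  # exact estimates dominate absolutely; conflicting exacts error
  ex <- inverse_variance_combine(lognormal_estimate(c(5, 5, 9), c(1, 1, 3)))
  expect_equal(ex$value, 5); expect_equal(ex$ferror, 1)
  expect_error(
    inverse_variance_combine(lognormal_estimate(c(5, 6), c(1, 1))),
    "conflicting exact")
})

test_that("inverse-variance combination matches fixed-effect meta-analysis", {
  skip_if_not_installed("metafor")
  v <- c(1e6, 4e6, 2.5e7); f <- c(2, 1.5, 3)
  ours <- inverse_variance_combine(lognormal_estimate(v, f))
  fe <- metafor::rma(yi = log(v), vi = log(f)^2, method = "FE")
  expect_equal(log(ours$value), as.numeric(fe$beta), tolerance = 1e-10)
  expect_equal(log(ours$ferror), fe$se, tolerance = 1e-10)
})

test_that("combining k copies shrinks the shape by sqrt(k) and stays between extremes", {
  e <- lognormal_estimate(7e8, 2.3)
  for (k in c(2, 5, 10)) {
    copies <- lognormal_estimate(rep(e$value, k), rep(e$ferror, k))
    comb <- inverse_variance_combine(copies)
    expect_equal(comb$value, e$value)
    expect_equal(comb$ferror, exp(log(e$ferror) / sqrt(k)),
                 tolerance = 1e-12)
  }
  set.seed(3)
  for (i in 1:20) {
    v <- 10^runif(4, 3, 9); f <- runif(4, 1.05, 5)
    comb <- inverse_variance_combine(lognormal_estimate(v, f))
    expect_gte(comb$value, min(v)); expect_lte(comb$value, max(v))
  }
})

test_that("bootstrap sum reproduces a single input distribution", {
  e <- lognormal_estimate(5, 2)
  bs <- bootstrap_sum(e, n_draws = 1e5, seed = 99)
  expect_equal(bs$value, 5)
  ci <- attr(bs, "ci")
  expect_equal(ci[["p2.5"]], 5 * 2^-1.96, tolerance = 0.03)
  expect_equal(ci[["p97.5"]], 5 * 2^1.96, tolerance = 0.03)
  expect_equal(ci[["p50"]], 5, tolerance = 0.03)
})

test_that("bootstrap sum of independent estimates matches a brute-force oracle", {
  est <- lognormal_estimate(c(1e9, 1e9), 2)
  bs <- bootstrap_sum(est, n_draws = 1e6, seed = 7)
  expect_equal(bs$value, 2e9)
  set.seed(1234)  # independent oracle stream
  oracle <- rlognorm_est(1e6, 1e9, 2) + rlognorm_est(1e6, 1e9, 2)
  oq <- quantile(oracle, c(0.025, 0.975), names = FALSE)
  ci <- attr(bs, "ci")
  expect_equal(ci[["p2.5"]], oq[1], tolerance = 0.03)
  expect_equal(ci[["p97.5"]], oq[2], tolerance = 0.03)
})

test_that("a fully correlated group collapses to the scaled single lognormal", {
  est <- lognormal_estimate(c(1e9, 1e9), 2)
  grouped <- bootstrap_sum(est, groups = c("g", "g"), n_draws = 5000,
                           seed = 21)
  single <- bootstrap_sum(lognormal_estimate(2e9, 2), n_draws = 5000,
                          seed = 21)
  expect_identical(grouped$value, single$value)
  # same seed, one shared deviate: the same draws up to summation order
  expect_equal(attr(grouped, "ci"), attr(single, "ci"), tolerance = 1e-12)
  # and wider than the independent combination
  indep <- bootstrap_sum(est, n_draws = 5000, seed = 21)
  expect_gt(attr(grouped, "ci")[["p97.5"]], attr(indep, "ci")[["p97.5"]])
  expect_lt(attr(grouped, "ci")[["p2.5"]], attr(indep, "ci")[["p2.5"]])
})

test_that("bootstrap is seed-reproducible, leaves the RNG alone, and widens with ferror", {
  est <- lognormal_estimate(c(1e6, 3e6, 5e5), c(1.5, 2, 3))
  a <- bootstrap_sum(est, n_draws = 2000, seed = 5)
  b <- bootstrap_sum(est, n_draws = 2000, seed = 5)
  expect_identical(attr(a, "ci"), attr(b, "ci"))

  set.seed(1); before <- runif(5)
  set.seed(1); invisible(bootstrap_sum(est, n_draws = 500, seed = 5))
  after <- runif(5)
  expect_identical(before, after)

  wider <- lognormal_estimate(c(1e6, 3e6, 5e5), c(1.5, 2.6, 3))
  w <- bootstrap_sum(wider, n_draws = 2000, seed = 5)
  expect_gte(attr(w, "ci")[["p97.5"]] - attr(w, "ci")[["p2.5"]],
             attr(a, "ci")[["p97.5"]] - attr(a, "ci")[["p2.5"]])

  expect_error(bootstrap_sum(est, n_draws = 2000), "seed")
  expect_error(bootstrap_sum(list(), seed = 1))
  expect_error(bootstrap_sum(est, n_draws = 50, seed = 1), "100")
})

test_that("estimate construction enforces the invariants", {
  expect_error(lognormal_estimate(-1, 2), "positive")
  expect_error(lognormal_estimate(1, 0.5), "ferror")
  z <- zero_estimate()
  expect_true(is_zero_sentinel(z))
  expect_false(any(is_zero_sentinel(lognormal_estimate(1, 1))))
})
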