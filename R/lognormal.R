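#' Lognormal point estimates with a multiplicative error factor
#'
#' The package's universal uncertainty currency. An estimate is a positive
#' point value `value` together with a multiplicative error factor
#' `ferror >= 1`; the underlying model is a lognormal distribution with
#' median `value` and log-scale shape parameter `s = ln(ferror)`. An
#' `ferror` of 2 means one sigma spans half to double the point value.
#' `ferror = 1` marks an exact quantity.
#'
#' Vectors are supported: `value` and `ferror` are recycled to a common
#' length and all operations act elementwise.
#'
#' A zero-density sentinel (`value = 0`, `ferror = Inf`) is admitted to
#' represent "no cells observed, uncertainty unbounded"; it never enters
#' log-scale arithmetic (see [is_zero_sentinel()]).
#'
#' @param value Positive numeric vector (geometric-scale point estimate).
#' @param ferror Numeric vector `>= 1`, multiplicative error factor.
#' @return An object of class `lognormal_estimate`: a list with numeric
#'   fields `value` and `ferror`.
#' @examples
#' e <- lognormal_estimate(1e6, 2)
#' ci95(e)
#' @export
lognormal_estimate <- function(value, ferror = 1) {
  n <- max(length(value), length(ferror))
  value <- rep_len(as.numeric(value), n)
  ferror <- rep_len(as.numeric(ferror), n)
  zero <- value == 0 & is.infinite(ferror)
  if (any(!zero & (!is.finite(value) | value <= 0))) {
    stop("`value` must be positive and finite (or the zero sentinel 0/Inf)")
  }
  if (any(!zero & (is.na(ferror) | ferror < 1))) {
    stop("`ferror` must be >= 1")
  }
  structure(list(value = value, ferror = ferror),
            class = "lognormal_estimate")
}

#' Zero-density sentinel
#'
#' @return A `lognormal_estimate` with `value = 0`, `ferror = Inf`,
#'   flagging an all-zero observation rather than a measured density.
#' @export
zero_estimate <- function() lognormal_estimate(0, Inf)

#' @rdname zero_estimate
#' @param e A `lognormal_estimate`.
#' @export
is_zero_sentinel <- function(e) e$value == 0 & is.infinite(e$ferror)

#' @export
print.lognormal_estimate <- function(x, ...) {
  cat(sprintf("<lognormal_estimate[%d]>\n", length(x$value)))
  show <- utils::head(data.frame(value = x$value, ferror = x$ferror), 10)
  print(show, ...)
  invisible(x)
}

#' @export
length.lognormal_estimate <- function(x) length(x$value)

#' Log-scale shape parameter s = ln(ferror)
#' @param e A `lognormal_estimate`.
#' @return Numeric vector of shape parameters.
#' @export
shape_param <- function(e) log(e$ferror)

#' Fit a lognormal estimate to a normal mean and standard error
#'
#' Transforms a value reported as mean +/- SE into the multiplicative-error
#' representation by moment matching: the fitted lognormal has the same mean
#' and variance as the normal, giving `s^2 = ln(1 + (se/mean)^2)`. The point
#' value is the median of the fitted lognormal, `mean * exp(-s^2/2)`.
#'
#' @param mean Positive numeric, the reported mean.
#' @param se Nonnegative numeric, the reported standard error.
#' @param max_cv Largest admissible coefficient of variation `se/mean`;
#'   above this the normal is too wide for a meaningful lognormal fit.
#' @return A `lognormal_estimate`.
#' @examples
#' fit_lognormal_from_normal(100, 50)  # ferror ~ 1.60
#' @export
fit_lognormal_from_normal <- function(mean, se, max_cv = 3) {
  if (any(!is.finite(mean) | mean <= 0)) stop("`mean` must be positive")
  if (any(!is.finite(se) | se < 0)) stop("`se` must be nonnegative")
  cv <- se / mean
  if (any(cv > max_cv)) {
    stop("coefficient of variation se/mean exceeds ", max_cv,
         ": lognormal moment fit is ill-posed")
  }
  s2 <- log1p(cv^2)
  lognormal_estimate(mean * exp(-s2 / 2), exp(sqrt(s2)))
}

#' Mean and SD of the distribution behind an estimate
#'
#' Inverse of the moment-matching fit: returns the arithmetic mean and SD of
#' the lognormal with median `value` and shape `ln(ferror)`.
#'
#' @param e A `lognormal_estimate`.
#' @return A list with numeric `mean` and `sd`.
#' @export
lognormal_moments <- function(e) {
  s2 <- shape_param(e)^2
  m <- e$value * exp(s2 / 2)
  list(mean = m, sd = m * sqrt(expm1(s2)))
}

#' Propagate multiplicative error through a product
#'
#' The product of two lognormal variables is lognormal; point values
#' multiply and shape parameters add in quadrature:
#' `f_xy = exp(sqrt(ln(f_x)^2 + ln(f_y)^2))`. Multiplying by an exact
#' factor (`ferror = 1`) changes only the point value.
#'
#' @param a,b `lognormal_estimate` objects (recycled elementwise).
#' @return A `lognormal_estimate` for the product.
#' @export
propagate_product <- function(a, b) {
  lognormal_estimate(a$value * b$value,
                     exp(sqrt(shape_param(a)^2 + shape_param(b)^2)))
}

#' Multiply an estimate by an exact scalar
#' @param e A `lognormal_estimate`.
#' @param k Positive numeric factor, treated as exact.
#' @return A `lognormal_estimate`.
#' @export
scale_estimate <- function(e, k) lognormal_estimate(e$value * k, e$ferror)

#' 95% and one-sigma intervals of a lognormal estimate
#'
#' The central 95% interval is `value * ferror^{-1.96}` to
#' `value * ferror^{+1.96}`; the one-sigma interval is `value / ferror` to
#' `value * ferror`.
#'
#' @param e A `lognormal_estimate`.
#' @param z Normal quantile on the log scale; 1.96 for 95%.
#' @return A list with numeric vectors `low` and `high`.
#' @export
ci95 <- function(e, z = 1.96) {
  list(low = e$value * e$ferror^(-z), high = e$value * e$ferror^z)
}

#' @rdname ci95
#' @export
ci68 <- function(e) ci95(e, z = 1)

#' Inverse-variance combination of estimates in log space
#'
#' Fixed-effect pooling of several estimates of the same quantity: each log
#' value is weighted by `w_i = m_i / ln(f_i)^2` (inverse log-scale variance,
#' optionally scaled by a weight multiplier), giving
#' `ln(value) = sum(w_i ln(v_i)) / sum(w_i)` and combined shape
#' `s = sqrt(1 / sum(w_i))`. An exact estimate (`ferror = 1`) carries
#' infinite weight and dominates; two disagreeing exact estimates are an
#' inconsistency error.
#'
#' @param estimates A list of `lognormal_estimate` objects, or one
#'   vectorized `lognormal_estimate`.
#' @param weight_multipliers Optional positive multipliers `m_i`, default 1.
#' @return A single `lognormal_estimate` lying between the smallest and
#'   largest input value.
#' @export
inverse_variance_combine <- function(estimates, weight_multipliers = NULL) {
  e <- as_estimate_vector(estimates)
  k <- length(e$value)
  if (k == 0) stop("need at least one estimate")
  m <- if (is.null(weight_multipliers)) rep(1, k) else
    rep_len(as.numeric(weight_multipliers), k)
  if (any(m <= 0)) stop("weight multipliers must be positive")
  s <- shape_param(e)
  exact <- s == 0
  if (any(exact)) {
    v <- e$value[exact]
    if (max(v) / min(v) - 1 > 1e-9) {
      stop("conflicting exact estimates (ferror = 1) cannot be combined: ",
           paste(signif(unique(v), 6), collapse = ", "))
    }
    return(lognormal_estimate(v[1], 1))
  }
  w <- m / s^2
  lognormal_estimate(exp(sum(w * log(e$value)) / sum(w)),
                     exp(sqrt(1 / sum(w))))
}

# Accept either a list of estimates or a single vectorized estimate.
as_estimate_vector <- function(estimates) {
  if (inherits(estimates, "lognormal_estimate")) return(estimates)
  stopifnot(is.list(estimates), length(estimates) > 0)
  lognormal_estimate(
    unlist(lapply(estimates, function(e) e$value)),
    unlist(lapply(estimates, function(e) e$ferror))
  )
}

#' Bootstrap the sum of lognormal estimates with correlated error groups
#'
#' The sum of lognormals has no closed form; uncertainty on totals is
#' propagated by resampling. Each draw samples every member from its
#' lognormal (`v * f^z`, `z` standard normal), except that members sharing a
#' correlation group reuse one deviate per draw — errors inside a group are
#' treated as perfectly correlated, the conservative model for estimates
#' extrapolated from a common source. The point value of the total is the
#' sum of member point values; the interval comes from percentile spread.
#'
#' @param estimates A list of `lognormal_estimate` objects or one
#'   vectorized estimate (zero sentinels contribute 0 exactly).
#' @param groups Optional character/factor vector, one label per member;
#'   `NA` means independent. Members with the same label share a deviate.
#' @param n_draws Number of bootstrap draws (>= 100); default 1000.
#' @param seed Integer seed; required so every reported interval is
#'   reproducible. The caller's RNG state is left untouched.
#' @return A `lognormal_estimate` for the total, with attributes
#'   `ci` (named numeric: `p2.5`, `p50`, `p97.5`) and `draws_sd_log`
#'   (SD of log draws, from which the fitted ferror is derived).
#' @export
bootstrap_sum <- function(estimates, groups = NULL, n_draws = 1000, seed) {
  e <- as_estimate_vector(estimates)
  if (length(e$value) == 0) stop("`estimates` must be non-empty")
  if (missing(seed)) stop("`seed` is required: no implicit global randomness")
  if (n_draws < 100) stop("`n_draws` must be >= 100")

  zero <- is_zero_sentinel(e)
  v <- e$value[!zero]
  s <- shape_param(e)[!zero]
  point <- sum(e$value)
  if (length(v) == 0) {
    out <- zero_estimate()
    attr(out, "ci") <- c(p2.5 = 0, p50 = 0, p97.5 = 0)
    attr(out, "draws_sd_log") <- NA_real_
    return(out)
  }

  g <- if (is.null(groups)) rep(NA_character_, length(e$value)) else
    as.character(rep_len(groups, length(e$value)))
  g <- g[!zero]
  # each NA gets its own private group
  g[is.na(g)] <- paste0(".indep", seq_len(sum(is.na(g))))
  gf <- factor(g)

  draws <- with_local_seed(seed, {
    z <- matrix(stats::rnorm(n_draws * nlevels(gf)), nrow = n_draws)
    # draw matrix: n_draws x members, member j uses its group's deviate
    zs <- z[, as.integer(gf), drop = FALSE]
    exp(sweep(zs, 2, s, `*`) + rep(log(v), each = n_draws)) |>
      rowSums()
  })

  q <- stats::quantile(draws, c(0.025, 0.5, 0.975), names = FALSE)
  sd_log <- stats::sd(log(draws))
  out <- lognormal_estimate(point, exp(sd_log))
  attr(out, "ci") <- c(p2.5 = q[1], p50 = q[2], p97.5 = q[3])
  attr(out, "draws_sd_log") <- sd_log
  out
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Geometric mean combination with between-record spread
#'
#' Merges several records of the same quantity: the point value is the
#' geometric mean; the shape parameter combines the records' average
#' measurement error with the observed between-record log spread, both
#' shrunk by the record count, `s^2 = (mean(s_i^2) + var(ln v_i)) / k`.
#'
#' @param e A vectorized `lognormal_estimate` of the records.
#' @param floor_ferror Minimum ferror of the result (default 1, no floor).
#' @return A single `lognormal_estimate`.
#' @export
geometric_pool <- function(e, floor_ferror = 1) {
  e <- as_estimate_vector(e)
  k <- length(e$value)
  if (k == 0) stop("need at least one record")
  lv <- log(e$value)
  between <- if (k > 1) stats::var(lv) else 0
  s2 <- (mean(shape_param(e)^2) + between) / k
  lognormal_estimate(exp(mean(lv)), max(exp(sqrt(s2)), floor_ferror))
}
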