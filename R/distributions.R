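#' Distribution specifications
#'
#' Lightweight parameter objects for the three distribution families the
#' risk simulations use: lognormal (TEQ, cancer slope factor), normal
#' (exposure time, children's body weight) and uniform (the truncation
#' multiplier of the 2-D Monte-Carlo analysis). Truncated specs are sampled
#' by renormalized inverse-CDF transformation of uniform draws, which keeps
#' the distribution proper on its support (no atoms at the bounds) and makes
#' each draw a monotone function of the truncation bound under common random
#' numbers.
#'
#' @param meanlog,sdlog Log-scale mean and SD of a lognormal (`sdlog >= 0`).
#' @param upper Optional upper truncation bound on the natural scale.
#' @param mean,sd Mean and SD of a normal (`sd >= 0`).
#' @param lower Lower truncation bound (default `-Inf`; use 0 and 24 for
#'   exposure time in hours/day).
#' @param min,max Bounds of a uniform distribution (`min < max`).
#' @return An object of class `dist_spec` (subclass `lnorm_spec`,
#'   `norm_spec` or `unif_spec`).
#' @examples
#' et <- norm_spec(5.9, 2.6, lower = 0, upper = 24)
#' dist_mean(et)
#' dist_sample(lnorm_spec(0, 1), 3, seed = 1)
#' @name dist_spec
NULL

#' @rdname dist_spec
#' @export
lnorm_spec <- function(meanlog, sdlog, upper = Inf) {
  stopifnot(is.numeric(meanlog), length(meanlog) == 1, is.finite(meanlog))
  if (!is.numeric(sdlog) || length(sdlog) != 1 || is.na(sdlog) || sdlog < 0) {
    abort("`sdlog` must be a single non-negative number.")
  }
  if (!is.numeric(upper) || length(upper) != 1 || is.na(upper) || upper <= 0) {
    abort("`upper` must be a single positive number (Inf for no truncation).")
  }
  structure(
    list(meanlog = meanlog, sdlog = sdlog, upper = upper),
    class = c("lnorm_spec", "dist_spec")
  )
}

#' @rdname dist_spec
#' @export
norm_spec <- function(mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(is.numeric(mean), length(mean) == 1, is.finite(mean))
  if (!is.numeric(sd) || length(sd) != 1 || is.na(sd) || sd < 0) {
    abort("`sd` must be a single non-negative number.")
  }
  if (!(lower < upper)) abort("`lower` must be strictly less than `upper`.")
  if (mean < lower || mean > upper) {
    abort("`mean` must lie inside the truncation bounds.")
  }
  structure(
    list(mean = mean, sd = sd, lower = lower, upper = upper),
    class = c("norm_spec", "dist_spec")
  )
}

#' @rdname dist_spec
#' @export
unif_spec <- function(min, max) {
  if (!(is.numeric(min) && is.numeric(max) && min <= max)) {
    abort("`min` must be <= `max`.")
  }
  structure(list(min = min, max = max), class = c("unif_spec", "dist_spec"))
}

#' @export
print.dist_spec <- function(x, ...) {
  cat("<", class(x)[1], "> ", sep = "")
  cat(paste(names(x), signif(unlist(x), 6), sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

is_dist_spec <- function(x) inherits(x, "dist_spec")

#' Lognormal specs from reported summary statistics
#'
#' `lognormal_from_moments()` moment-matches a lognormal to a reported
#' arithmetic mean and SD: `sigma^2 = log(1 + sd^2/mean^2)`,
#' `mu = log(mean) - sigma^2/2`, so the spec's analytic mean and SD equal
#' the inputs exactly. `lognormal_from_gm_gsd()` parameterizes from a
#' geometric mean and geometric SD: `mu = log(gm)`, `sigma = log(gsd)`.
#' `fit_lognormal()` is the log-scale MLE for a raw positive series
#' (`mu = mean(log x)`, `sigma = sd(log x)`, n-1 convention). Use the
#' moment-matching path when only a published mean +/- SD is available and
#' the MLE path when the raw series is.
#'
#' @param mean,sd Arithmetic mean (> 0) and SD (>= 0).
#' @param gm,gsd Geometric mean (> 0) and geometric SD (>= 1).
#' @param x A strictly positive numeric vector, length >= 2.
#' @return A [lnorm_spec()].
#' @examples
#' s <- lognormal_from_moments(2.8, 2.8)
#' c(dist_mean(s), dist_sd(s))
#' lognormal_from_gm_gsd(3.14, 1.80)
#' @export
lognormal_from_moments <- function(mean, sd) {
  if (!is.numeric(mean) || length(mean) != 1 || is.na(mean) || mean <= 0) {
    abort("`mean` must be a single positive number.")
  }
  if (!is.numeric(sd) || length(sd) != 1 || is.na(sd) || sd < 0) {
    abort("`sd` must be a single non-negative number.")
  }
  sigma2 <- log(1 + (sd / mean)^2)
  lnorm_spec(meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
}

#' @rdname lognormal_from_moments
#' @export
lognormal_from_gm_gsd <- function(gm, gsd) {
  if (!is.numeric(gm) || length(gm) != 1 || is.na(gm) || gm <= 0) {
    abort("`gm` must be a single positive number.")
  }
  if (!is.numeric(gsd) || length(gsd) != 1 || is.na(gsd) || gsd < 1) {
    abort("`gsd` must be a single number >= 1.")
  }
  lnorm_spec(meanlog = log(gm), sdlog = log(gsd))
}

#' @rdname lognormal_from_moments
#' @export
fit_lognormal <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2 || any(x <= 0)) {
    abort("`x` must contain at least two strictly positive values.")
  }
  lx <- log(x)
  lnorm_spec(meanlog = mean(lx), sdlog = sd(lx))
}

#' Seeded sampling from a distribution spec
#'
#' Draws are reproducible for a fixed `seed` and never touch the caller's
#' RNG state. Truncated specs are sampled by inverse-CDF transformation of
#' uniforms restricted to the truncation probability interval, i.e. the
#' renormalized truncated distribution.
#'
#' @param spec A [dist_spec] object.
#' @param n Number of draws (`n >= 1`).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return A numeric vector of length `n`, always inside the spec's bounds.
#' @export
dist_sample <- function(spec, n, seed = NULL) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  n <- as.integer(n)
  u <- with_seed_or_not(seed, runif(n))
  dist_transform(spec, u)
}

# maps iid U(0,1) draws through the (truncated) quantile function
dist_transform <- function(spec, u) UseMethod("dist_transform")

#' @export
dist_transform.lnorm_spec <- function(spec, u) {
  if (spec$sdlog == 0) {
    return(rep(min(exp(spec$meanlog), spec$upper), length(u)))
  }
  pu <- if (is.finite(spec$upper)) {
    plnorm(spec$upper, spec$meanlog, spec$sdlog)
  } else {
    1
  }
  qlnorm(u * pu, spec$meanlog, spec$sdlog)
}

#' @export
dist_transform.norm_spec <- function(spec, u) {
  if (spec$sd == 0) return(rep(spec$mean, length(u)))
  plo <- pnorm(spec$lower, spec$mean, spec$sd)
  phi <- pnorm(spec$upper, spec$mean, spec$sd)
  qnorm(plo + u * (phi - plo), spec$mean, spec$sd)
}

#' @export
dist_transform.unif_spec <- function(spec, u) {
  spec$min + u * (spec$max - spec$min)
}

#' Quantiles and closed-form moments of distribution specs
#'
#' `dist_quantile()` inverts the (renormalized, if truncated) CDF.
#' `dist_mean()` and `dist_sd()` return analytic moments, including the
#' standard closed forms for truncated normal and upper-truncated lognormal
#' distributions. `dist_gm()`/`dist_gsd()` return the geometric mean and
#' geometric SD of lognormal specs (`exp(mu)`, `exp(sigma)` untruncated;
#' via the truncated-normal moments of `log X` when truncated).
#'
#' @inheritParams dist_sample
#' @param p Probabilities, all strictly inside (0, 1).
#' @return A numeric vector (`dist_quantile`) or scalar (moments).
#' @examples
#' dist_quantile(lnorm_spec(0, 1), 0.5) # exp(mu) = 1
#' dist_gsd(lognormal_from_gm_gsd(3.14, 1.8))
#' @export
dist_quantile <- function(spec, p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p <= 0) || any(p >= 1)) {
    abort("`p` must lie strictly inside (0, 1).")
  }
  dist_transform(spec, p)
}

#' @rdname dist_quantile
#' @export
dist_mean <- function(spec) UseMethod("dist_mean")

#' @rdname dist_quantile
#' @export
dist_sd <- function(spec) UseMethod("dist_sd")

#' @rdname dist_quantile
#' @export
dist_gm <- function(spec) UseMethod("dist_gm")

#' @rdname dist_quantile
#' @export
dist_gsd <- function(spec) UseMethod("dist_gsd")

# k-th raw moment of a lognormal upper-truncated at b:
# E[X^k | X <= b] = exp(k mu + k^2 s^2 / 2) * Phi((log b - mu - k s^2)/s) / Phi((log b - mu)/s)
lnorm_trunc_moment <- function(spec, k) {
  mu <- spec$meanlog
  s <- spec$sdlog
  full <- exp(k * mu + k^2 * s^2 / 2)
  if (!is.finite(spec$upper)) return(full)
  if (s == 0) return(min(exp(mu), spec$upper)^k)
  beta <- (log(spec$upper) - mu) / s
  full * pnorm(beta - k * s) / pnorm(beta)
}

#' @export
dist_mean.lnorm_spec <- function(spec) lnorm_trunc_moment(spec, 1)

#' @export
dist_sd.lnorm_spec <- function(spec) {
  sqrt(max(0, lnorm_trunc_moment(spec, 2) - lnorm_trunc_moment(spec, 1)^2))
}

# mean/var of a normal truncated to [a, b]
norm_trunc_mean_var <- function(mean, sd, lower, upper) {
  if (sd == 0) return(c(mean, 0))
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- pnorm(b) - pnorm(a)
  da <- dnorm(a)
  db <- dnorm(b)
  m <- mean + sd * (da - db) / z
  ata <- if (is.finite(a)) a * da else 0
  btb <- if (is.finite(b)) b * db else 0
  v <- sd^2 * (1 + (ata - btb) / z - ((da - db) / z)^2)
  c(m, max(0, v))
}

#' @export
dist_mean.norm_spec <- function(spec) {
  norm_trunc_mean_var(spec$mean, spec$sd, spec$lower, spec$upper)[1]
}

#' @export
dist_sd.norm_spec <- function(spec) {
  sqrt(norm_trunc_mean_var(spec$mean, spec$sd, spec$lower, spec$upper)[2])
}

#' @export
dist_mean.unif_spec <- function(spec) (spec$min + spec$max) / 2

#' @export
dist_sd.unif_spec <- function(spec) (spec$max - spec$min) / sqrt(12)

#' @export
dist_gm.lnorm_spec <- function(spec) {
  if (!is.finite(spec$upper) || spec$sdlog == 0) {
    return(min(exp(spec$meanlog), spec$upper))
  }
  # log X is normal truncated above at log(upper)
  mv <- norm_trunc_mean_var(spec$meanlog, spec$sdlog, -Inf, log(spec$upper))
  exp(mv[1])
}

#' @export
dist_gsd.lnorm_spec <- function(spec) {
  if (!is.finite(spec$upper) || spec$sdlog == 0) return(exp(spec$sdlog))
  mv <- norm_trunc_mean_var(spec$meanlog, spec$sdlog, -Inf, log(spec$upper))
  exp(sqrt(mv[2]))
}

#' Latin hypercube draws from a uniform spec
#'
#' Stratified sampling: the interval `[min, max]` is split into `n`
#' equal-width strata and exactly one draw lands in each, in randomized
#' order. Used for the outer (uncertainty) loop of [two_dim_mca()].
#'
#' @param spec A [unif_spec()].
#' @inheritParams dist_sample
#' @return A numeric vector of `n` stratified draws.
#' @export
lhs_uniform <- function(spec, n, seed = NULL) {
  if (!inherits(spec, "unif_spec")) abort("`spec` must be a unif_spec.")
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  n <- as.integer(n)
  u <- with_seed_or_not(seed, as.vector(lhs::randomLHS(n, 1)))
  spec$min + u * (spec$max - spec$min)
}
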