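#' Partial-correlation sensitivity analysis of a risk simulation
#'
#' For each stochastic input (TEQ, ET, CSF and, for children, BW) the
#' partial correlation with the simulated ILCR (or DI) is the Pearson
#' correlation between the residuals of that input and of the output after
#' linearly regressing both on the remaining inputs. Under the
#' multiplicative risk formula the expected signs are positive for TEQ,
#' ET and CSF and negative for BW. Inputs with no variation get an `NA`
#' coefficient with a warning. `transform` applies a common monotone
#' transform to all columns first: `"none"` (raw draws, the default),
#' `"rank"`, or `"log"` (requires positive draws; makes the output an
#' exact linear function of the inputs, so log-scale coefficients are
#' +/- 1 up to truncation effects, a useful internal consistency check).
#'
#' @param sim A `risk_sim` from [simulate_ilcr()] (or [simulate_di()]).
#' @param inputs Character vector of input column names in
#'   `tidy(sim)`; defaults to the stochasticity-relevant set present
#'   (`teq`, `et`, `csf`, `bw`).
#' @param transform One of `"none"`, `"rank"`, `"log"`.
#' @return A tibble of class `pah_sensitivity` with columns `variable`,
#'   `partial_correlation`, `transform`, `n`.
#' @examples
#' grp <- population_group("HZ", "adult", "total",
#'   ir = 16.5, et = norm_spec(3.4, 2.0, 0, 24), bw = 60.5, ed = 30
#' )
#' sim <- simulate_ilcr(lognormal_from_moments(2.8, 2.8), grp, n = 2000, seed = 1)
#' partial_correlations(sim)
#' @export
partial_correlations <- function(sim, inputs = NULL,
                                 transform = c("none", "rank", "log")) {
  transform <- match.arg(transform)
  if (!inherits(sim, "risk_sim")) abort("`sim` must be a risk_sim.")
  samples <- sim$samples
  # default input set: TEQ always, plus whichever of ET/CSF/BW the stratum
  # actually treats as stochastic (BW only for children with a bw spec)
  candidates <- intersect(c("teq", "et", "csf", "bw"), names(samples))
  if (is.null(inputs)) {
    g <- sim$group
    keep <- c(
      teq = TRUE,
      et = !is.null(g$et) && g$et$sd > 0,
      csf = !is.null(g$csf) && g$csf$sdlog > 0,
      bw = inherits(g$bw, "norm_spec")
    )
    inputs <- candidates[keep[candidates]]
  }
  missing_in <- setdiff(inputs, names(samples))
  if (length(missing_in) > 0) {
    abort(paste0(
      "Input column(s) not in the simulation: ",
      paste(missing_in, collapse = ", ")
    ))
  }
  n <- nrow(samples)
  if (n < length(inputs) + 3) {
    abort("Need at least 3 more iterations than inputs.")
  }

  y <- samples[[sim$type]]
  x <- as.data.frame(samples[inputs])
  if (transform == "rank") {
    y <- rank(y)
    x[] <- lapply(x, rank)
  } else if (transform == "log") {
    if (any(y <= 0) || any(vapply(x, function(v) any(v <= 0), logical(1)))) {
      abort("`transform = \"log\"` requires strictly positive draws.")
    }
    y <- log(y)
    x[] <- lapply(x, log)
  }

  est <- vapply(inputs, function(v) {
    xv <- x[[v]]
    if (sd(xv) == 0) {
      warn(paste0("Input `", v, "` is constant; partial correlation undefined."))
      return(NA_real_)
    }
    others <- setdiff(inputs, v)
    others <- others[vapply(x[others], function(z) sd(z) > 0, logical(1))]
    if (length(others) == 0) {
      return(cor(xv, y))
    }
    z <- as.matrix(x[others])
    rx <- resid(lm(xv ~ z))
    ry <- resid(lm(y ~ z))
    if (sd(ry) == 0) return(NA_real_)
    cor(rx, ry)
  }, numeric(1))

  out <- tibble::tibble(
    variable = inputs,
    partial_correlation = unname(est),
    transform = transform,
    n = n
  )
  class(out) <- c("pah_sensitivity", class(out))
  out
}

#' @export
autoplot.pah_sensitivity <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(
      x = stats::reorder(.data$variable, abs(.data$partial_correlation)),
      y = .data$partial_correlation
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "partial correlation with output",
      title = "Sensitivity of simulated risk to its inputs"
    ) +
    ggplot2::theme_minimal()
}

#' Two-dimensional Monte-Carlo uncertainty analysis of the CSF truncation
#'
#' The cancer-slope-factor distribution has no published maximum, so its
#' truncation bound is treated as uncertain: the bound is
#' `exp(log(GM) + k * log(GSD))` with the multiplier `k` drawn by Latin
#' hypercube sampling from `k_range` (default uniform on \[2, 4\]). The
#' outer loop draws `n_outer` values of `k` (uncertainty); for each, an
#' inner loop of `n_inner` iterations (variability) recomputes the 95th
#' percentile ILCR with the CSF truncated at that bound. All inner loops
#' share one seed substream (common random numbers), so the spread of the
#' outer values reflects truncation uncertainty alone; a collapsed
#' `k_range` therefore gives an exactly zero-width interval. The envelope
#' reports the 2.5th--97.5th percentile interval of the outer values.
#'
#' @inheritParams simulate_ilcr
#' @param k_range A [unif_spec()] for the truncation multiplier
#'   (default `unif_spec(2, 4)`); a degenerate range (`min == max`) is
#'   allowed.
#' @param n_outer Outer (uncertainty) iterations, >= 2 (default 100).
#' @param n_inner Inner (variability) iterations (default 10000).
#' @return An object of class `uncertainty_envelope`: the outer tibble of
#'   `(k, truncation bound, p95_ilcr)` plus the confidence interval.
#' @examples
#' grp <- population_group("HZ", "adult", "total",
#'   ir = 16.5, et = norm_spec(3.4, 2.0, 0, 24), bw = 60.5, ed = 30
#' )
#' env <- two_dim_mca(lognormal_from_moments(2.8, 2.8), grp,
#'   n_outer = 10, n_inner = 500, seed = 1
#' )
#' glance(env)
#' @export
two_dim_mca <- function(teq, group, k_range = unif_spec(2, 4),
                        n_outer = 100, n_inner = 10000, seed = NULL) {
  teq <- as_teq_spec(teq)
  if (!inherits(group, "population_group")) {
    abort("`group` must be a population_group.")
  }
  if (!inherits(k_range, "unif_spec")) abort("`k_range` must be a unif_spec.")
  stopifnot(n_outer >= 2, n_inner >= 2)

  ks <- lhs_uniform(k_range, n_outer, derive_seed(seed, "outer"))
  inner_seed <- derive_seed(seed, "inner")
  gm <- dist_gm(group$csf)
  gsd <- dist_gsd(group$csf)

  p95 <- vapply(ks, function(k) {
    bound <- exp(log(gm) + k * log(gsd))
    g <- group
    g$csf <- lnorm_spec(group$csf$meanlog, group$csf$sdlog, upper = bound)
    percentile_95(simulate_ilcr(teq, g, n = n_inner, seed = inner_seed))
  }, numeric(1))

  outer <- tibble::tibble(
    k = ks,
    csf_upper = exp(log(gm) + ks * log(gsd)),
    p95_ilcr = p95
  )
  structure(
    list(
      outer = outer,
      ci_lower = quantile(p95, 0.025, type = 7, names = FALSE),
      ci_upper = quantile(p95, 0.975, type = 7, names = FALSE),
      n_outer = as.integer(n_outer),
      n_inner = as.integer(n_inner),
      group = group,
      seed = seed
    ),
    class = "uncertainty_envelope"
  )
}

#' @export
print.uncertainty_envelope <- function(x, ...) {
  cat(sprintf(
    "<uncertainty_envelope> %d x %d iterations; 95%% CI of 95th ILCR: [%.3g, %.3g]\n",
    x$n_outer, x$n_inner, x$ci_lower, x$ci_upper
  ))
  invisible(x)
}

#' Tidiers for uncertainty envelopes
#'
#' `tidy()` returns the outer-loop table (truncation multiplier `k`, the
#' implied CSF upper bound, and the inner-loop 95th-percentile ILCR);
#' `glance()` returns the one-row confidence-interval summary.
#'
#' @param x An `uncertainty_envelope` from [two_dim_mca()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.uncertainty_envelope <- function(x, ...) x$outer

#' @rdname tidy.uncertainty_envelope
#' @export
glance.uncertainty_envelope <- function(x, ...) {
  tibble::tibble(
    city = x$group$city,
    age_group = x$group$age_group,
    gender = x$group$gender,
    ci_lower = x$ci_lower,
    ci_upper = x$ci_upper,
    ci_width = x$ci_upper - x$ci_lower,
    median_p95 = median(x$outer$p95_ilcr),
    n_outer = x$n_outer,
    n_inner = x$n_inner,
    seed = x$seed %||% NA_integer_
  )
}

#' @export
autoplot.uncertainty_envelope <- function(object, ...) {
  ggplot2::ggplot(object$outer, ggplot2::aes(x = .data$k, y = .data$p95_ilcr)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(
      yintercept = c(object$ci_lower, object$ci_upper), linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "CSF truncation multiplier k",
      y = "95th percentile ILCR",
      title = "Uncertainty in the 95th ILCR from the CSF truncation bound"
    ) +
    ggplot2::theme_minimal()
}
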