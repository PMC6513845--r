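#' Default cancer slope factor distribution
#'
#' The inhalation cancer slope factor for BaP-equivalent exposure is
#' modelled lognormal with geometric mean 3.14 (mg/kg-day)^-1 and geometric
#' SD 1.80.
#'
#' @return A [lnorm_spec()].
#' @export
csf_default <- function() lognormal_from_gm_gsd(3.14, 1.80)

#' Exposure-factor set for one population stratum
#'
#' Bundles everything the daily-intake and cancer-risk simulations need for
#' one city x age-group x gender stratum. Exposure time is a (truncated)
#' normal spec in hours/day; body weight is a point value for adults and
#' may be a normal spec for children; averaging time is in hours (supply
#' `at_years` to have the years -> hours conversion done explicitly).
#'
#' @param city,age_group,gender Stratum labels; `age_group` is `"adult"` or
#'   `"child"`, `gender` one of `"male"`, `"female"`, `"total"`.
#' @param ir Inhalation rate, m^3/day (> 0).
#' @param et Exposure time: a [norm_spec()] in hours/day, or a single
#'   number treated as a point value.
#' @param bw Body weight, kg: a positive number (required for adults) or,
#'   for children, optionally a [norm_spec()].
#' @param ed Exposure duration, years (> 0).
#' @param ef Exposure frequency, days/year (0 < ef <= 366).
#' @param at_hours Averaging time in hours; defaults to `at_years` years.
#' @param at_years Averaging time in years, converted as
#'   `years * 365 * 24`; ignored when `at_hours` is given.
#' @param cf Conversion factor, mg/pg (default 1e-9).
#' @param csf Cancer slope factor: a [lnorm_spec()] (default
#'   [csf_default()]) or a positive point value.
#' @return An object of class `population_group`.
#' @examples
#' grp <- population_group("HZ", "adult", "total",
#'   ir = 16.5, et = norm_spec(3.4, 2.0, 0, 24), bw = 60.5, ed = 30
#' )
#' grp$at_hours
#' @export
population_group <- function(city, age_group = c("adult", "child"),
                             gender = c("total", "male", "female"),
                             ir, et, bw, ed, ef = 365,
                             at_hours = NULL, at_years = 70,
                             cf = 1e-9, csf = csf_default()) {
  age_group <- match.arg(age_group)
  gender <- match.arg(gender)
  if (!is.numeric(ir) || ir <= 0) abort("`ir` must be a positive number (m^3/day).")
  if (is.numeric(et) && length(et) == 1) {
    if (et <= 0 || et > 24) abort("Exposure-time must lie in (0, 24] h/day.")
    et <- norm_spec(et, 0, lower = 0, upper = 24)
  }
  if (!inherits(et, "norm_spec")) abort("`et` must be a norm_spec or a point value.")
  if (et$mean <= 0 || et$mean > 24) abort("Exposure-time mean must lie in (0, 24] h/day.")
  if (inherits(bw, "norm_spec")) {
    if (age_group == "adult") {
      abort("Adults use a point body weight; only children may have a norm_spec `bw`.")
    }
    if (bw$mean <= 0) abort("Body-weight mean must be positive.")
    if (!is.finite(bw$lower) || bw$lower < 0) bw$lower <- 0
  } else if (!is.numeric(bw) || bw <= 0) {
    abort("`bw` must be a positive number (kg) or, for children, a norm_spec.")
  }
  if (!is.numeric(ed) || ed <= 0) abort("`ed` must be positive (years).")
  if (!is.numeric(ef) || ef <= 0 || ef > 366) abort("`ef` must lie in (0, 366] days/year.")
  at_hours <- at_hours %||% (at_years * 365 * 24)
  if (!is.numeric(at_hours) || at_hours <= 0) abort("Averaging time must be positive.")
  if (is.numeric(csf) && length(csf) == 1) {
    if (csf <= 0) abort("A point `csf` must be positive.")
    csf <- lnorm_spec(log(csf), 0)
  }
  if (!inherits(csf, "lnorm_spec")) abort("`csf` must be a lnorm_spec or a point value.")
  if (cf <= 0) abort("`cf` must be positive (mg/pg).")
  structure(
    list(
      city = city, age_group = age_group, gender = gender,
      ir = ir, et = et, bw = bw, ed = ed, ef = ef,
      at_hours = at_hours, cf = cf, csf = csf
    ),
    class = "population_group"
  )
}

#' @export
print.population_group <- function(x, ...) {
  cat(sprintf(
    "<population_group> %s %s %s | IR %.2g m3/d, ED %g y, EF %g d/y, AT %g h\n",
    x$city, x$age_group, x$gender, x$ir, x$ed, x$ef, x$at_hours
  ))
  invisible(x)
}

as_teq_spec <- function(teq) {
  if (is.numeric(teq) && length(teq) == 1 && teq > 0) {
    return(lnorm_spec(log(teq), 0))
  }
  if (!inherits(teq, "lnorm_spec")) {
    abort("`teq` must be a lnorm_spec (ng/m^3) or a positive point value.")
  }
  teq
}

new_risk_sim <- function(samples, type, group, seed) {
  x <- samples[[type]]
  structure(
    list(
      samples = samples,
      type = type,
      summary = tibble::tibble(
        n = nrow(samples),
        mean = mean(x),
        median = quantile(x, 0.5, type = 7, names = FALSE),
        q25 = quantile(x, 0.25, type = 7, names = FALSE),
        q75 = quantile(x, 0.75, type = 7, names = FALSE),
        iqr = quantile(x, 0.75, type = 7, names = FALSE) -
          quantile(x, 0.25, type = 7, names = FALSE),
        p95 = quantile(x, 0.95, type = 7, names = FALSE)
      ),
      group = group,
      n_iterations = nrow(samples),
      seed = seed
    ),
    class = "risk_sim"
  )
}

#' Monte-Carlo simulation of daily intake (DI)
#'
#' Per iteration, `DI = TEQ * IR * ET / 24` in ng/day, with TEQ (ng/m^3)
#' drawn from a lognormal spec and ET (hours/day) from the stratum's
#' (truncated) normal spec. TEQ, ET, CSF and BW use independent named seed
#' substreams, so the DI draws match the TEQ/ET draws of an ILCR simulation
#' run from the same master seed.
#'
#' @param teq TEQ distribution: a [lnorm_spec()] in ng/m^3 (e.g. from
#'   [fit_lognormal()] or [lognormal_from_moments()]) or a positive point
#'   value.
#' @param group A [population_group()].
#' @param n Number of iterations (default 10000).
#' @param seed Optional master integer seed.
#' @return A `risk_sim` object; see [tidy.risk_sim()], [glance.risk_sim()],
#'   [percentile_95()].
#' @examples
#' grp <- population_group("HZ", "adult", "total",
#'   ir = 16.5, et = norm_spec(3.4, 2.0, 0, 24), bw = 60.5, ed = 30
#' )
#' sim <- simulate_di(lognormal_from_moments(2.8, 2.8), grp, n = 1000, seed = 1)
#' glance(sim)
#' @export
simulate_di <- function(teq, group, n = 10000, seed = NULL) {
  teq <- as_teq_spec(teq)
  if (!inherits(group, "population_group")) {
    abort("`group` must be a population_group.")
  }
  stopifnot(n >= 1)
  n <- as.integer(n)
  teq_s <- dist_sample(teq, n, derive_seed(seed, "teq"))
  et_s <- dist_sample(group$et, n, derive_seed(seed, "et"))
  samples <- tibble::tibble(
    iteration = seq_len(n),
    teq = teq_s,
    et = et_s,
    di = teq_s * group$ir * et_s / 24
  )
  new_risk_sim(samples, "di", group, seed)
}

#' Monte-Carlo simulation of incremental lifetime cancer risk (ILCR)
#'
#' Per iteration,
#' `ILCR = (TEQ_pg * IR * CF * ED * ET * EF) * CSF / (BW * AT)`,
#' dimensionless: TEQ is carried in ng/m^3 throughout the package and
#' converted to pg/m^3 internally (x 1000), with the conversion factor CF
#' in mg/pg closing the unit chain
#' (pg/m^3 * m^3/d * mg/pg * y * h/d * d/y * (mg/kg-day)^-1 / (kg * h)).
#' TEQ and CSF are lognormal, ET truncated normal, and BW is drawn per
#' iteration only when the stratum supplies a body-weight spec (children);
#' adults use their point value. Each variable has its own seed substream.
#'
#' @inheritParams simulate_di
#' @return A `risk_sim` object whose samples retain the per-iteration
#'   `teq`, `et`, `csf` and `bw` draws alongside `ilcr`.
#' @examples
#' grp <- population_group("HZ", "adult", "total",
#'   ir = 16.5, et = norm_spec(3.4, 2.0, 0, 24), bw = 60.5, ed = 30
#' )
#' sim <- simulate_ilcr(lognormal_from_moments(2.8, 2.8), grp, n = 1000, seed = 1)
#' percentile_95(sim)
#' @export
simulate_ilcr <- function(teq, group, n = 10000, seed = NULL) {
  teq <- as_teq_spec(teq)
  if (!inherits(group, "population_group")) {
    abort("`group` must be a population_group.")
  }
  stopifnot(n >= 1)
  n <- as.integer(n)
  teq_s <- dist_sample(teq, n, derive_seed(seed, "teq"))
  et_s <- dist_sample(group$et, n, derive_seed(seed, "et"))
  csf_s <- dist_sample(group$csf, n, derive_seed(seed, "csf"))
  bw_s <- if (inherits(group$bw, "norm_spec")) {
    dist_sample(group$bw, n, derive_seed(seed, "bw"))
  } else {
    rep(group$bw, n)
  }
  teq_pg <- teq_s * 1000 # ng/m^3 -> pg/m^3
  ilcr <- (teq_pg * group$ir * group$cf * group$ed * et_s * group$ef) *
    csf_s / (bw_s * group$at_hours)
  samples <- tibble::tibble(
    iteration = seq_len(n),
    teq = teq_s, et = et_s, csf = csf_s, bw = bw_s,
    ilcr = ilcr
  )
  new_risk_sim(samples, "ilcr", group, seed)
}

#' @export
print.risk_sim <- function(x, ...) {
  cat(sprintf(
    "<risk_sim: %s> %d iterations (%s %s %s)\n", x$type, x$n_iterations,
    x$group$city, x$group$age_group, x$group$gender
  ))
  print(x$summary)
  invisible(x)
}

#' 95th percentile of a risk simulation
#'
#' The headline statistic of the ILCR analysis: the type-7 (linearly
#' interpolated order-statistic) sample quantile at p = 0.95 of the
#' simulated DI or ILCR values.
#'
#' @param result A `risk_sim` from [simulate_di()] or [simulate_ilcr()].
#' @return A single number.
#' @export
percentile_95 <- function(result) {
  if (!inherits(result, "risk_sim")) abort("`result` must be a risk_sim.")
  x <- result$samples[[result$type]]
  if (length(x) < 2) abort("Need at least two samples for a percentile.")
  quantile(x, 0.95, type = 7, names = FALSE)
}

risk_category_levels <- function() c("acceptable", "potential", "concern")

#' Classify ILCR values into regulatory risk bands
#'
#' ILCR below 1e-6 is an acceptable risk, between 1e-6 and 1e-4 a potential
#' risk, and above 1e-4 a public-health concern. The boundary values 1e-6
#' and 1e-4 belong to the "potential" band.
#'
#' @param ilcr_value Non-negative numeric vector of ILCR values.
#' @return A factor with ordered levels acceptable < potential < concern.
#' @examples
#' classify_risk(c(4.8e-7, 1e-5, 2e-4))
#' @export
classify_risk <- function(ilcr_value) {
  if (!is.numeric(ilcr_value) || any(is.na(ilcr_value)) || any(ilcr_value < 0)) {
    abort("`ilcr_value` must be non-negative.")
  }
  out <- ifelse(
    ilcr_value < 1e-6, "acceptable",
    ifelse(ilcr_value <= 1e-4, "potential", "concern")
  )
  factor(out, levels = risk_category_levels(), ordered = TRUE)
}

#' Tidiers for risk simulations
#'
#' `tidy()` returns the per-iteration sample table (input draws plus the
#' DI or ILCR output); `glance()` returns the one-row summary (mean,
#' median, quartiles, IQR, 95th percentile) with the stratum labels,
#' iteration count and seed.
#'
#' @param x A `risk_sim` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.risk_sim <- function(x, ...) x$samples

#' @rdname tidy.risk_sim
#' @export
glance.risk_sim <- function(x, ...) {
  tibble::tibble(
    city = x$group$city,
    age_group = x$group$age_group,
    gender = x$group$gender,
    type = x$type,
    x$summary,
    seed = x$seed %||% NA_integer_
  )
}

#' Cumulative-probability plot of a risk simulation
#'
#' The empirical cumulative distribution of the simulated DI (ng/day) or
#' ILCR values, on a log-10 x axis, with the median and 95th percentile
#' marked.
#'
#' @param object A `risk_sim` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.risk_sim <- function(object, ...) {
  lab <- if (object$type == "di") "daily intake (ng/day)" else "ILCR"
  ggplot2::ggplot(object$samples, ggplot2::aes(x = .data[[object$type]])) +
    ggplot2::stat_ecdf(linewidth = 0.6) +
    ggplot2::geom_vline(
      xintercept = c(object$summary$median, object$summary$p95),
      linetype = c("dashed", "dotted")
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = lab, y = "cumulative probability",
      title = sprintf(
        "%s %s %s (%d iterations)", object$group$city,
        object$group$age_group, object$group$gender, object$n_iterations
      )
    ) +
    ggplot2::theme_minimal()
}
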