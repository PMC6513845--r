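#' Run the full PAH risk-assessment pipeline
#'
#' Drives every stage end to end for each city and population stratum:
#' TEQ summaries (seasonal and annual mean +/- SD), diagnostic-ratio source
#' screening, seasonal and annual daily-intake medians with IQR, the 95th
#' percentile ILCR with its risk band, partial-correlation sensitivity
#' coefficients, and the two-dimensional Monte-Carlo uncertainty interval.
#' Everything derives deterministically from one master seed; rerunning
#' the same configuration reproduces every output byte for byte.
#'
#' `config` is a named list:
#' \describe{
#'   \item{table}{A congener table, a CSV path, or `NULL` to simulate from
#'     `profiles`.}
#'   \item{profiles}{List of [city_profile()]s used when `table` is `NULL`
#'     (default [default_city_profiles()]), with `n_days_per_season`
#'     (default 30).}
#'   \item{population}{Required: an exposure-factor tibble shaped like
#'     [default_exposure_config()], or a CSV path. The pipeline refuses to
#'     run without one.}
#'   \item{tefs, thresholds}{Optional TEF and ratio-threshold tables.}
#'   \item{bdl_policy}{Below-detection policy, see [resolve_bdl()].}
#'   \item{n_inner, n_outer}{Monte-Carlo sizes (defaults 10000 and 100;
#'     `n_inner >= 100`).}
#'   \item{transform}{Partial-correlation transform, see
#'     [partial_correlations()].}
#'   \item{seed}{Master integer seed (required for reproducible bundles).}
#'   \item{out_dir}{Optional directory; when set, all tables are written
#'     as CSV plus a `manifest.json` recording seed, config hash and
#'     package version.}
#' }
#'
#' @param config Named list as described above.
#' @return Invisibly, a named list of tibbles: `teq_seasonal`,
#'   `teq_annual`, `sources`, `di_summary`, `ilcr_summary`, `sensitivity`,
#'   `uncertainty`, plus `manifest`.
#' @examples
#' \donttest{
#' bundle <- run_pipeline(list(
#'   population = default_exposure_config(), seed = 1,
#'   profiles = default_city_profiles(), n_days_per_season = 10,
#'   n_inner = 200, n_outer = 5
#' ))
#' bundle$ilcr_summary
#' }
#' @export
run_pipeline <- function(config) {
  cfg <- validate_run_config(config)

  log_stage("synthetic_data/io", "assembling congener table")
  table <- if (!is.null(cfg$table)) {
    if (is.character(cfg$table)) read_congener_table(cfg$table) else congener_table(cfg$table)
  } else {
    purrr::map_dfr(
      cfg$profiles, generate_congener_table,
      n_days_per_season = cfg$n_days_per_season, seed = derive_seed(cfg$seed, "simulate")
    )
  }

  log_stage("teq_source", "TEQ and source screening")
  teq <- compute_teq(table, tefs = cfg$tefs, bdl_policy = cfg$bdl_policy)
  teq_seasonal <- summarize_teq(teq, by = "season")
  teq_annual <- summarize_teq(teq, by = "annual")
  sources <- classify_source(
    diagnostic_ratios(table, bdl_policy = cfg$bdl_policy),
    thresholds = cfg$thresholds
  )

  pop <- cfg$population
  groups <- purrr::pmap(pop, function(city, age_group, gender, et_mean, et_sd,
                                      ir, bw_mean, bw_sd, ed, ef, at_hours, cf, ...) {
    bw <- if (!is.na(bw_sd) && bw_sd > 0) {
      norm_spec(bw_mean, bw_sd, lower = 0)
    } else {
      bw_mean
    }
    population_group(
      city = city, age_group = age_group, gender = gender,
      ir = ir, et = norm_spec(et_mean, et_sd, lower = 0, upper = 24),
      bw = bw, ed = ed, ef = ef, at_hours = at_hours, cf = cf
    )
  })

  # seasonal + annual lognormal TEQ specs per city, log-scale MLE on samples
  teq_specs <- teq |>
    dplyr::group_by(.data$city, .data$season) |>
    dplyr::summarise(spec = list(fit_lognormal(.data$teq_ng_m3)), .groups = "drop") |>
    dplyr::mutate(season = as.character(.data$season)) |>
    dplyr::bind_rows(
      teq |>
        dplyr::group_by(.data$city) |>
        dplyr::summarise(spec = list(fit_lognormal(.data$teq_ng_m3)), .groups = "drop") |>
        dplyr::mutate(season = "annual")
    )

  log_stage("exposure_risk", sprintf(
    "DI/ILCR Monte Carlo (%d strata x %d iterations)", length(groups), cfg$n_inner
  ))
  di_summary <- purrr::map_dfr(groups, function(g) {
    specs <- teq_specs[teq_specs$city == g$city, ]
    purrr::map_dfr(seq_len(nrow(specs)), function(i) {
      sim <- simulate_di(
        specs$spec[[i]], g, n = cfg$n_inner,
        seed = derive_seed(cfg$seed, paste("di", g$city, g$age_group, g$gender, specs$season[i]))
      )
      dplyr::mutate(glance(sim), season = specs$season[i], .after = "gender")
    })
  })

  ilcr_sims <- purrr::map(groups, function(g) {
    spec <- teq_specs$spec[teq_specs$city == g$city & teq_specs$season == "annual"][[1]]
    simulate_ilcr(
      spec, g, n = cfg$n_inner,
      seed = derive_seed(cfg$seed, paste("ilcr", g$city, g$age_group, g$gender))
    )
  })
  ilcr_summary <- purrr::map_dfr(ilcr_sims, function(sim) {
    gl <- glance(sim)
    gl$risk_category <- as.character(classify_risk(gl$p95))
    gl
  })

  log_stage("sensitivity_uncertainty", "partial correlations and 2-D MCA")
  sensitivity <- purrr::map2_dfr(ilcr_sims, groups, function(sim, g) {
    pc <- partial_correlations(sim, transform = cfg$transform)
    tibble::tibble(
      city = g$city, age_group = g$age_group, gender = g$gender,
      tibble::as_tibble(pc)
    )
  })

  uncertainty <- purrr::map_dfr(groups, function(g) {
    spec <- teq_specs$spec[teq_specs$city == g$city & teq_specs$season == "annual"][[1]]
    env <- two_dim_mca(
      spec, g,
      n_outer = cfg$n_outer, n_inner = cfg$n_inner,
      seed = derive_seed(cfg$seed, paste("mca", g$city, g$age_group, g$gender))
    )
    glance(env)
  })

  manifest <- list(
    package = "pahrisk",
    version = as.character(packageVersion("pahrisk")),
    seed = cfg$seed,
    n_inner = cfg$n_inner,
    n_outer = cfg$n_outer,
    bdl_policy = cfg$bdl_policy,
    transform = cfg$transform,
    config_hash = {
      hashed <- cfg[setdiff(names(cfg), "out_dir")]
      rlang::hash(hashed[order(names(hashed))])
    }
  )

  bundle <- list(
    teq_seasonal = teq_seasonal,
    teq_annual = teq_annual,
    sources = sources,
    di_summary = di_summary,
    ilcr_summary = ilcr_summary,
    sensitivity = sensitivity,
    uncertainty = uncertainty,
    manifest = manifest
  )

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in setdiff(names(bundle), "manifest")) {
      readr::write_csv(bundle[[nm]], file.path(cfg$out_dir, paste0(nm, ".csv")),
        progress = FALSE
      )
    }
    jsonlite::write_json(
      manifest, file.path(cfg$out_dir, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE
    )
  }

  invisible(bundle)
}

validate_run_config <- function(config) {
  if (!is.list(config)) abort("`config` must be a named list.")
  if (is.null(config$population)) {
    abort(paste0(
      "run_pipeline: no population exposure-factor configuration supplied. ",
      "Pass `population = default_exposure_config()` explicitly (documented ",
      "synthetic placeholders) or your own table; exposure factors are never invented."
    ))
  }
  pop <- config$population
  if (is.character(pop)) {
    if (!file.exists(pop)) {
      abort(paste0("run_pipeline: population config file not found: ", pop))
    }
    pop <- readr::read_csv(pop, show_col_types = FALSE, progress = FALSE)
  }
  need <- c(
    "city", "age_group", "gender", "ir", "et_mean", "et_sd",
    "bw_mean", "bw_sd", "ed", "ef", "at_hours", "cf"
  )
  miss <- setdiff(need, names(pop))
  if (length(miss) > 0) {
    abort(paste0(
      "Population config is missing column(s): ", paste(miss, collapse = ", ")
    ))
  }
  if (is.character(config$table) && !file.exists(config$table)) {
    abort(paste0("run_pipeline: congener table file not found: ", config$table))
  }
  n_inner <- config$n_inner %||% 10000
  if (n_inner < 100) abort("`n_inner` must be at least 100.")
  seed <- config$seed
  if (!is.null(seed) && (!is.numeric(seed) || seed != as.integer(seed))) {
    abort("`seed` must be an integer.")
  }
  list(
    table = config$table,
    profiles = config$profiles %||% default_city_profiles(),
    n_days_per_season = config$n_days_per_season %||% 30,
    population = tibble::as_tibble(pop),
    tefs = config$tefs %||% default_tef_table(),
    thresholds = config$thresholds %||% default_ratio_thresholds(),
    bdl_policy = config$bdl_policy %||% "half_lod",
    n_inner = as.integer(n_inner),
    n_outer = as.integer(config$n_outer %||% 100),
    transform = config$transform %||% "none",
    seed = if (is.null(seed)) NULL else as.integer(seed),
    out_dir = config$out_dir
  )
}

log_stage <- function(stage, msg) {
  if (isTRUE(getOption("pahrisk.quiet", TRUE))) return(invisible())
  message(sprintf("[pahrisk:%s] %s", stage, msg))
}
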