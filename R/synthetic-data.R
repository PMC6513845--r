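#' City concentration profiles for the synthetic generator
#'
#' A `city_profile` describes how daily congener concentrations are
#' simulated for one city: a per-congener baseline geometric mean (ng/m^3),
#' a common geometric SD, multiplicative season factors (winter strictly
#' greatest), and a winter enrichment factor applied to the 4--6-ring
#' congeners only, which produces the cold-season dominance of
#' high-molecular-weight congeners seen in urban PM2.5 records.
#'
#' @param city City label.
#' @param congener_gm Named numeric vector of baseline geometric means for
#'   all 16 congeners (ng/m^3), all > 0.
#' @param gsd Geometric SD (> 1) shared by all congeners.
#' @param season_factors Named numeric vector over
#'   spring/summer/autumn/winter, all > 0, winter strictly greatest.
#' @param high_ring_winter_factor Extra multiplier (> 1) on 4--6-ring
#'   congener geometric means in winter.
#' @return An object of class `city_profile`.
#' @seealso [default_city_profiles()], [generate_congener_table()]
#' @export
city_profile <- function(city, congener_gm, gsd, season_factors,
                         high_ring_winter_factor = 1) {
  congeners <- pah_congeners()$congener
  if (!setequal(names(congener_gm), congeners)) {
    abort("`congener_gm` must be named with exactly the 16 congeners.")
  }
  congener_gm <- congener_gm[congeners]
  if (any(!is.finite(congener_gm)) || any(congener_gm <= 0)) {
    abort("All baseline geometric means must be positive.")
  }
  if (!is.numeric(gsd) || gsd <= 1) abort("`gsd` must exceed 1.")
  if (!setequal(names(season_factors), season_levels())) {
    abort("`season_factors` must be named spring/summer/autumn/winter.")
  }
  season_factors <- season_factors[season_levels()]
  if (any(season_factors <= 0)) abort("Season factors must be positive.")
  if (season_factors[["winter"]] <= max(season_factors[c("spring", "summer", "autumn")])) {
    abort("The winter factor must be strictly greatest.")
  }
  if (high_ring_winter_factor <= 0) {
    abort("`high_ring_winter_factor` must be positive.")
  }
  structure(
    list(
      city = city, congener_gm = congener_gm, gsd = gsd,
      season_factors = season_factors,
      high_ring_winter_factor = high_ring_winter_factor
    ),
    class = "city_profile"
  )
}

# Baseline composition (ng/m3 GMs): 4-6-ring congeners carry ~80% of the
# summed GM so that, with the winter high-ring enrichment, the winter
# high-ring mass share lands near 0.86 and winter/summer total ratios near 3.
base_congener_gm <- function() {
  c(
    Nap = 0.50, Acy = 0.10, Flu = 0.30, Ace = 0.15, Phe = 0.80, Ant = 0.15,
    Fle = 1.00, Pyr = 0.90, Chr = 0.70, BaA = 0.60, BbF = 1.20, BkF = 0.50,
    BaP = 0.90, DBA = 0.15, BghiP = 1.10, InP = 0.95
  )
}

#' Default synthetic city profiles
#'
#' Five city profiles (HZ, JH, LS, NB, ZS) sharing one seasonal structure
#' (winter 1.8, spring 1.05, autumn 1.0, summer 0.85; winter high-ring
#' enrichment 1.6; GSD 1.8) and differing only by a total-concentration
#' scale, calibrated so annual mean total concentrations span roughly
#' 7.5--18 ng/m^3 across cities. These constants are documented synthetic
#' stand-ins, not measured values.
#'
#' @return A named list of [city_profile()] objects.
#' @export
default_city_profiles <- function() {
  scales <- c(HZ = 1.08, JH = 1.10, LS = 1.02, NB = 0.82, ZS = 0.45)
  purrr::imap(as.list(scales), function(s, city) {
    city_profile(
      city = city,
      congener_gm = base_congener_gm() * s,
      gsd = 1.8,
      season_factors = c(spring = 1.05, summer = 0.85, autumn = 1.0, winter = 1.8),
      high_ring_winter_factor = 1.6
    )
  })
}

season_months <- function(season) {
  switch(season,
    spring = c(3L, 4L, 5L), summer = c(6L, 7L, 8L),
    autumn = c(9L, 10L, 11L), winter = c(12L, 1L, 2L)
  )
}

#' Simulate a congener concentration table
#'
#' Draws `n_days_per_season` sampling days per season for one city. Each
#' day carries all 16 congeners, sampled independently from lognormals
#' whose geometric means are the profile baseline scaled by the season
#' factor (and, for 4--6-ring congeners in winter, the winter enrichment
#' factor). Reproducible for a fixed seed.
#'
#' @param profile A [city_profile()].
#' @param n_days_per_season Sampling days simulated per season (>= 1).
#' @param seed Optional integer seed.
#' @param year Calendar year stamped on the simulated dates.
#' @return A validated congener table (see [congener_table()]).
#' @examples
#' tab <- generate_congener_table(default_city_profiles()$HZ,
#'   n_days_per_season = 3, seed = 1
#' )
#' dplyr::count(tab, season)
#' @export
generate_congener_table <- function(profile, n_days_per_season = 30,
                                    seed = NULL, year = 2015) {
  if (!inherits(profile, "city_profile")) {
    abort("`profile` must be a city_profile.")
  }
  stopifnot(n_days_per_season >= 1)
  n_days_per_season <- as.integer(n_days_per_season)
  congeners <- pah_congeners()
  high <- congeners$congener[congeners$ring_class == "high"]

  grid <- purrr::map_dfr(season_levels(), function(sn) {
    months <- season_months(sn)
    idx <- seq_len(n_days_per_season)
    tibble::tibble(
      season_label = sn,
      month = months[(idx - 1L) %% 3L + 1L],
      day = 1L + (9L + (idx - 1L) %/% 3L) %% 28L
    )
  })
  grid$date <- as.Date(sprintf("%d-%02d-%02d", year, grid$month, grid$day))
  grid$sample_id <- sprintf("%s-%s-%03d", profile$city, substr(grid$season_label, 1, 2),
    stats::ave(seq_len(nrow(grid)), grid$season_label, FUN = seq_along)
  )

  rows <- tidyr::expand_grid(grid, congener = congeners$congener)
  gm <- profile$congener_gm[rows$congener] *
    profile$season_factors[rows$season_label]
  enrich <- rows$season_label == "winter" & rows$congener %in% high
  gm[enrich] <- gm[enrich] * profile$high_ring_winter_factor

  conc <- with_seed_or_not(
    derive_seed(seed, paste0("congener-table-", profile$city)),
    rlnorm(nrow(rows), meanlog = log(gm), sdlog = log(profile$gsd))
  )

  congener_table(tibble::tibble(
    sample_id = rows$sample_id,
    city = profile$city,
    date = rows$date,
    congener = rows$congener,
    conc_ng_m3 = conc
  ))
}

#' Simulate an exposure-time and body-weight survey
#'
#' Draws questionnaire-style responses per population stratum: exposure
#' time (hours/day) from a normal distribution truncated to \[0, 24\] and
#' body weight (kg) from the stratum's point value (adults) or a positive
#' truncated normal (children).
#'
#' @param profile A survey profile tibble with one row per stratum and
#'   columns `city`, `age_group`, `gender`, `et_mean`, `et_sd`, `bw_mean`,
#'   `bw_sd` (`NA` or 0 for point body weight), `n_respondents`.
#' @param seed Optional integer seed.
#' @return A tibble with `city`, `age_group`, `gender`, `respondent_id`,
#'   `et_hours`, `bw_kg`.
#' @seealso [default_survey_profiles()]
#' @export
generate_exposure_survey <- function(profile, seed = NULL) {
  need <- c(
    "city", "age_group", "gender", "et_mean", "et_sd",
    "bw_mean", "bw_sd", "n_respondents"
  )
  if (!all(need %in% names(profile))) {
    abort(paste0(
      "Survey profile needs columns: ", paste(need, collapse = ", ")
    ))
  }
  if (any(profile$et_mean <= 0) || any(profile$et_mean >= 24)) {
    abort("Exposure-time means must lie in (0, 24) hours/day.")
  }
  if (any(profile$n_respondents < 1)) abort("`n_respondents` must be >= 1.")

  purrr::pmap_dfr(profile, function(city, age_group, gender, et_mean, et_sd,
                                    bw_mean, bw_sd, n_respondents, ...) {
    stratum <- paste("survey", city, age_group, gender, sep = "-")
    n <- as.integer(n_respondents)
    et <- dist_sample(
      norm_spec(et_mean, et_sd, lower = 0, upper = 24), n,
      seed = derive_seed(seed, paste0(stratum, "-et"))
    )
    bw <- if (is.na(bw_sd) || bw_sd == 0) {
      rep(bw_mean, n)
    } else {
      dist_sample(
        norm_spec(bw_mean, bw_sd, lower = 0), n,
        seed = derive_seed(seed, paste0(stratum, "-bw"))
      )
    }
    tibble::tibble(
      city = city, age_group = age_group, gender = gender,
      respondent_id = seq_len(n), et_hours = et, bw_kg = bw
    )
  })
}

#' Default synthetic exposure-factor configuration
#'
#' One row per city x age-group x gender with the full exposure-factor set
#' used by the daily-intake and cancer-risk simulations: inhalation rate
#' `ir` (m^3/day), outdoor exposure-time normal spec (`et_mean`, `et_sd`,
#' hours/day), body weight (`bw_mean` kg; `bw_sd` > 0 only for children),
#' exposure duration `ed` (years), exposure frequency `ef` (days/year),
#' averaging time `at_hours` (a 70-year lifetime in hours) and unit
#' conversion factor `cf` (mg/pg). Exposure-time means and SDs fall inside
#' typical urban survey ranges (adults roughly 2--6 h/day, children
#' 3--7 h/day). All values are documented synthetic placeholders: the
#' simulations require an explicit configuration and never invent one.
#'
#' @return A tibble, one row per stratum (5 cities x adult/child x
#'   male/female/total).
#' @export
default_exposure_config <- function() {
  et_adult <- tibble::tribble(
    ~city, ~et_mean, ~et_sd,
    "HZ", 3.4, 2.0,
    "JH", 5.9, 2.6,
    "LS", 4.8, 2.3,
    "NB", 2.1, 1.7,
    "ZS", 5.2, 2.4
  )
  et_child <- tibble::tribble(
    ~city, ~et_mean, ~et_sd,
    "HZ", 3.5, 1.5,
    "JH", 7.0, 4.1,
    "LS", 2.9, 0.7,
    "NB", 5.3, 2.0,
    "ZS", 3.0, 1.0
  )
  strata <- tidyr::expand_grid(
    city = et_adult$city,
    age_group = c("adult", "child"),
    gender = c("male", "female", "total")
  )
  strata |>
    dplyr::left_join(
      dplyr::bind_rows(
        dplyr::mutate(et_adult, age_group = "adult"),
        dplyr::mutate(et_child, age_group = "child")
      ),
      by = c("city", "age_group")
    ) |>
    dplyr::mutate(
      # mild male/female offset around the stratum mean
      et_mean = .data$et_mean +
        dplyr::case_when(
          .data$gender == "male" ~ 0.4,
          .data$gender == "female" ~ -0.4,
          TRUE ~ 0
        ),
      ir = dplyr::case_when(
        .data$age_group == "adult" & .data$gender == "male" ~ 18.0,
        .data$age_group == "adult" & .data$gender == "female" ~ 15.0,
        .data$age_group == "adult" ~ 16.5,
        .data$gender == "male" ~ 9.5,
        .data$gender == "female" ~ 9.0,
        TRUE ~ 9.25
      ),
      bw_mean = dplyr::case_when(
        .data$age_group == "adult" & .data$gender == "male" ~ 65.0,
        .data$age_group == "adult" & .data$gender == "female" ~ 56.5,
        .data$age_group == "adult" ~ 60.5,
        .data$gender == "male" ~ 35.0,
        .data$gender == "female" ~ 33.0,
        TRUE ~ 34.0
      ),
      bw_sd = dplyr::if_else(.data$age_group == "child", 6.0, 0),
      ed = dplyr::if_else(.data$age_group == "adult", 30, 10),
      ef = 365,
      at_hours = 70 * 365 * 24,
      cf = 1e-9
    )
}

#' @rdname generate_exposure_survey
#' @details `default_survey_profiles()` derives survey-simulation profiles
#'   from [default_exposure_config()] (1000 adult and 600 child respondents
#'   per city, matching typical questionnaire campaign sizes).
#' @export
default_survey_profiles <- function() {
  default_exposure_config() |>
    dplyr::filter(.data$gender != "total") |>
    dplyr::mutate(
      n_respondents = dplyr::if_else(.data$age_group == "adult", 500L, 300L)
    ) |>
    dplyr::select(
      "city", "age_group", "gender", "et_mean", "et_sd",
      "bw_mean", "bw_sd", "n_respondents"
    )
}
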