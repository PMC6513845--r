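#' Default toxic equivalency factor (TEF) table
#'
#' The Nisbet--LaGoy TEF scheme for the 16 priority congeners, expressing
#' each congener's carcinogenic potency relative to benzo\[a\]pyrene
#' (TEF(BaP) = 1 by definition). The dibenz\[a,h\]anthracene TEF is
#' scheme-ambiguous in the literature (1 or 5), so it is an explicit
#' argument rather than a hidden constant; the default is 1.
#'
#' @param dba_tef TEF for DBA (dibenz\[a,h\]anthracene); 1 by default, 5 in
#'   some uses of the scheme.
#' @return A tibble with columns `congener`, `tef`, `scheme`, `citation`.
#' @examples
#' default_tef_table()
#' @export
default_tef_table <- function(dba_tef = 1) {
  stopifnot(is.numeric(dba_tef), length(dba_tef) == 1, dba_tef > 0)
  tef <- c(
    Nap = 0.001, Acy = 0.001, Flu = 0.001, Ace = 0.001, Phe = 0.001,
    Ant = 0.01, Fle = 0.001, Pyr = 0.001, Chr = 0.01, BaA = 0.1,
    BbF = 0.1, BkF = 0.1, BaP = 1, DBA = dba_tef, BghiP = 0.01, InP = 0.1
  )
  tibble::tibble(
    congener = names(tef),
    tef = unname(tef),
    scheme = "Nisbet-LaGoy",
    citation = "Nisbet & LaGoy (1992) Regul Toxicol Pharmacol 16:290-300"
  )
}

validate_tef_table <- function(tefs) {
  if (!all(c("congener", "tef") %in% names(tefs))) {
    abort("TEF table needs columns `congener` and `tef`.")
  }
  tefs$congener <- canonicalize_congener(as.character(tefs$congener))
  if (any(!is.finite(tefs$tef)) || any(tefs$tef <= 0)) {
    abort("All TEF values must be positive.")
  }
  bap <- tefs$tef[tefs$congener == "BaP"]
  if (length(bap) != 1 || bap != 1) {
    abort("TEF(BaP) must be present and equal to 1.")
  }
  tefs
}

#' BaP-equivalent toxicity (TEQ) of congener mixtures
#'
#' The carcinogenic potency of a PAH mixture is expressed as the toxic
#' equivalent quotient of benzo\[a\]pyrene:
#' `TEQ = sum_i C_i * TEF_i` over the 16 congeners, in the concentration
#' units of the input (ng/m^3 here). Linear in the concentrations.
#'
#' @param table A congener table (see [congener_table()]).
#' @param tefs A TEF table; defaults to [default_tef_table()]. Every
#'   congener present in `table` must have a TEF.
#' @param bdl_policy Below-detection substitution policy, see
#'   [resolve_bdl()].
#' @return A tibble with one row per sample: `sample_id`, `city`, `date`,
#'   `season`, `teq_ng_m3`.
#' @examples
#' tab <- tibble::tibble(
#'   sample_id = "s1", city = "HZ", date = as.Date("2015-01-12"),
#'   congener = c("BaP", "BaA"), conc_ng_m3 = c(1, 10)
#' )
#' compute_teq(tab)
#' @export
compute_teq <- function(table, tefs = default_tef_table(),
                        bdl_policy = "half_lod") {
  table <- resolve_bdl(table, bdl_policy)
  tefs <- validate_tef_table(tibble::as_tibble(tefs))
  missing_tef <- setdiff(unique(table$congener), tefs$congener)
  if (length(missing_tef) > 0) {
    abort(paste0(
      "No TEF supplied for congener(s): ", paste(missing_tef, collapse = ", ")
    ))
  }
  table |>
    dplyr::left_join(tefs[c("congener", "tef")], by = "congener") |>
    dplyr::group_by(.data$sample_id, .data$city, .data$date, .data$season) |>
    dplyr::summarise(
      teq_ng_m3 = sum(.data$conc_ng_m3 * .data$tef),
      .groups = "drop"
    )
}

#' Group summaries of TEQ series
#'
#' Arithmetic mean and sample (n-1) SD of per-sample TEQ, per city and
#' season (`by = "season"`) or per city over the whole record
#' (`by = "annual"`).
#'
#' @param series A TEQ tibble from [compute_teq()].
#' @param by `"season"` or `"annual"`.
#' @return A tibble with `city`, (`season`,) `n`, `mean_teq`, `sd_teq`.
#' @export
summarize_teq <- function(series, by = c("season", "annual")) {
  by <- match.arg(by)
  groups <- if (by == "season") c("city", "season") else "city"
  series |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_teq = mean(.data$teq_ng_m3),
      sd_teq = if (dplyr::n() > 1) sd(.data$teq_ng_m3) else 0,
      .groups = "drop"
    )
}

#' Mass share of high-molecular-weight congeners
#'
#' Fraction of total 16-congener mass contributed by the 4--6-ring ("high")
#' congeners, per city and season or annually. Low- and high-ring shares
#' sum to one per group.
#'
#' @inheritParams compute_teq
#' @param by `"season"` or `"annual"`.
#' @return A tibble with `city`, (`season`,) `low_ring_share`,
#'   `high_ring_share`.
#' @export
ring_class_fractions <- function(table, by = c("season", "annual"),
                                 bdl_policy = "half_lod") {
  by <- match.arg(by)
  table <- resolve_bdl(table, bdl_policy)
  groups <- if (by == "season") c("city", "season") else "city"
  table |>
    dplyr::left_join(
      pah_congeners()[c("congener", "ring_class")],
      by = "congener"
    ) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::summarise(
      low_ring_share =
        sum(.data$conc_ng_m3[.data$ring_class == "low"]) / sum(.data$conc_ng_m3),
      high_ring_share =
        sum(.data$conc_ng_m3[.data$ring_class == "high"]) / sum(.data$conc_ng_m3),
      .groups = "drop"
    )
}

diagnostic_ratio_names <- function() {
  c("Fle/Pyr", "BaP/BghiP", "BaP/(BaP+Chr)")
}

#' Diagnostic source ratios of congener means
#'
#' Computes the three source-screening ratios Fle/Pyr, BaP/BghiP and
#' BaP/(BaP+Chr) on group-mean concentrations (one ratio per city, not the
#' mean of per-sample ratios). A zero denominator yields `NA` for that
#' ratio rather than an error.
#'
#' @inheritParams compute_teq
#' @return A tibble with columns `city`, `ratio`, `value`.
#' @export
diagnostic_ratios <- function(table, bdl_policy = "half_lod") {
  table <- resolve_bdl(table, bdl_policy)
  means <- table |>
    dplyr::group_by(.data$city, .data$congener) |>
    dplyr::summarise(m = mean(.data$conc_ng_m3), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "congener", values_from = "m", values_fill = 0)
  for (cg in pah_congeners()$congener) {
    if (!cg %in% names(means)) means[[cg]] <- 0
  }
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  means |>
    dplyr::transmute(
      city = .data$city,
      `Fle/Pyr` = safe_div(.data$Fle, .data$Pyr),
      `BaP/BghiP` = safe_div(.data$BaP, .data$BghiP),
      `BaP/(BaP+Chr)` = safe_div(.data$BaP, .data$BaP + .data$Chr)
    ) |>
    tidyr::pivot_longer(-"city", names_to = "ratio", values_to = "value")
}

#' Default diagnostic-ratio interval thresholds
#'
#' Literature-based half-open intervals `[lo, hi)` mapping each diagnostic
#' ratio to a dominant emission source. Editable: supply your own table of
#' the same shape to [classify_source()]. Intervals must not overlap within
#' a ratio.
#'
#' @return A tibble with `ratio`, `lo`, `hi`, `source_label`, `citation`.
#' @export
default_ratio_thresholds <- function() {
  tibble::tribble(
    ~ratio, ~lo, ~hi, ~source_label,
    "Fle/Pyr", 0, 1, "gasoline emission",
    "Fle/Pyr", 1, Inf, "coal combustion",
    "BaP/BghiP", 0, 0.6, "gasoline emission",
    "BaP/BghiP", 0.6, Inf, "coal combustion",
    "BaP/(BaP+Chr)", 0, 0.5, "diesel emission",
    "BaP/(BaP+Chr)", 0.5, Inf, "gasoline emission"
  ) |>
    dplyr::mutate(
      citation = "diagnostic-ratio source ranges, PAH source-apportionment literature"
    )
}

validate_ratio_thresholds <- function(thresholds) {
  need <- c("ratio", "lo", "hi", "source_label")
  if (!all(need %in% names(thresholds))) {
    abort(paste0(
      "Threshold table needs columns: ", paste(need, collapse = ", ")
    ))
  }
  if (any(thresholds$lo >= thresholds$hi)) abort("Each interval needs lo < hi.")
  split(thresholds, thresholds$ratio) |>
    purrr::walk(function(d) {
      d <- d[order(d$lo), ]
      if (nrow(d) > 1 && any(d$hi[-nrow(d)] > d$lo[-1])) {
        abort(paste0("Overlapping intervals for ratio ", d$ratio[1]))
      }
    })
  thresholds
}

#' Classify emission sources from diagnostic ratios
#'
#' Deterministic interval lookup of each ratio value in the threshold
#' table (membership `lo <= value < hi`), plus a per-city consensus label:
#' the majority vote over classified ratios, `"mixed"` on a tie, and
#' `"unclassified"` when a value falls outside all intervals (such values
#' do not vote).
#'
#' @param ratios A tibble from [diagnostic_ratios()].
#' @param thresholds A threshold table, see [default_ratio_thresholds()].
#' @return The `ratios` tibble with added columns `source` (per ratio) and
#'   `consensus` (per city, repeated).
#' @export
classify_source <- function(ratios, thresholds = default_ratio_thresholds()) {
  thresholds <- validate_ratio_thresholds(tibble::as_tibble(thresholds))
  lookup <- function(ratio, value) {
    if (is.na(value)) return(NA_character_)
    d <- thresholds[thresholds$ratio == ratio, ]
    hit <- which(d$lo <= value & value < d$hi)
    if (length(hit) == 1) d$source_label[hit] else "unclassified"
  }
  out <- ratios |>
    dplyr::mutate(
      source = purrr::map2_chr(.data$ratio, .data$value, lookup)
    )
  consensus <- out |>
    dplyr::group_by(.data$city) |>
    dplyr::summarise(
      consensus = majority_label(.data$source),
      .groups = "drop"
    )
  dplyr::left_join(out, consensus, by = "city")
}

# majority vote over classified labels; tie -> "mixed", none -> "unclassified"
majority_label <- function(labels) {
  labels <- labels[!is.na(labels) & labels != "unclassified"]
  if (length(labels) == 0) return("unclassified")
  tab <- sort(table(labels), decreasing = TRUE)
  if (length(tab) > 1 && tab[1] == tab[2]) "mixed" else names(tab)[1]
}
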