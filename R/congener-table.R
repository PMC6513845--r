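#' Validate and normalize a congener concentration table
#'
#' A congener table is tidy: one row per sample x congener, with columns
#' `sample_id`, `city`, `date`, `congener`, `conc_ng_m3`, and optionally
#' `season` (derived from `date` when absent), `below_detection` (logical,
#' default `FALSE`) and `lod_ng_m3` (detection limit, default `NA`).
#' Congener abbreviations are canonicalized through [congener_synonyms()];
#' unknown names, negative concentrations, duplicated (sample, congener)
#' pairs and season/date mismatches are rejected with the offending rows
#' named.
#'
#' @param df A data frame with the columns above.
#' @return A validated tibble with columns in canonical order.
#' @seealso [read_congener_table()], [resolve_bdl()]
#' @export
congener_table <- function(df) {
  required <- c("sample_id", "city", "date", "congener", "conc_ng_m3")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Congener table is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  out <- tibble::as_tibble(df)
  out$sample_id <- as.character(out$sample_id)
  out$city <- as.character(out$city)
  out$date <- as.Date(out$date)
  out$congener <- canonicalize_congener(as.character(out$congener))

  known <- pah_congeners()$congener
  bad <- which(!out$congener %in% known)
  if (length(bad) > 0) {
    abort(paste0(
      "Unknown congener name(s) in row(s) ",
      paste(utils::head(bad, 10), collapse = ", "), ": ",
      paste(unique(out$congener[bad]), collapse = ", ")
    ))
  }

  out$conc_ng_m3 <- as.numeric(out$conc_ng_m3)
  neg <- which(is.na(out$conc_ng_m3) | out$conc_ng_m3 < 0)
  if (length(neg) > 0) {
    abort(paste0(
      "Negative or missing concentration(s) in row(s): ",
      paste(utils::head(neg, 10), collapse = ", ")
    ))
  }

  if (!"below_detection" %in% names(out)) out$below_detection <- FALSE
  out$below_detection <- as.logical(out$below_detection)
  if (anyNA(out$below_detection)) {
    abort("`below_detection` must be logical or 0/1 with no missing values.")
  }
  if (!"lod_ng_m3" %in% names(out)) out$lod_ng_m3 <- NA_real_
  out$lod_ng_m3 <- as.numeric(out$lod_ng_m3)

  derived <- season_of(out$date)
  if (!"season" %in% names(out) || all(is.na(out$season))) {
    out$season <- derived
  } else {
    out$season <- factor(as.character(out$season), levels = season_levels())
    mismatch <- which(is.na(out$season) | out$season != derived)
    if (length(mismatch) > 0) {
      abort(paste0(
        "`season` disagrees with the date's month in row(s): ",
        paste(utils::head(mismatch, 10), collapse = ", ")
      ))
    }
  }

  dup <- duplicated(out[c("sample_id", "congener")])
  if (any(dup)) {
    abort(paste0(
      "Duplicated (sample_id, congener) pair(s) in row(s): ",
      paste(utils::head(which(dup), 10), collapse = ", ")
    ))
  }

  out[c(
    "sample_id", "city", "date", "season", "congener",
    "conc_ng_m3", "below_detection", "lod_ng_m3"
  )]
}

#' Read / write congener concentration tables as CSV
#'
#' The on-disk format is a plain CSV with columns `sample_id`, `city`,
#' `date` (ISO-8601), `congener`, `conc_ng_m3`, `below_detection` (0/1) and
#' `lod_ng_m3` (may be empty); `season` is recomputed from the date on read.
#' `read_congener_table(write_congener_table(x, path))` round-trips all
#' fields.
#'
#' @param path Path to a CSV file.
#' @return `read_congener_table()` returns a validated congener tibble.
#' @export
read_congener_table <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  congener_table(raw)
}

#' @rdname read_congener_table
#' @param table A congener table (see [congener_table()]).
#' @return `write_congener_table()` returns `path` invisibly.
#' @export
write_congener_table <- function(table, path) {
  table <- congener_table(table)
  out <- table
  out$season <- as.character(out$season)
  out$below_detection <- as.integer(out$below_detection)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Substitute below-detection concentrations
#'
#' Rows flagged `below_detection` get a substituted concentration according
#' to `policy`: `"half_lod"` (default) uses `lod_ng_m3 / 2` when a detection
#' limit is present and 0 otherwise; `"zero"` uses 0; `"lod_over_sqrt2"`
#' uses `lod_ng_m3 / sqrt(2)` (0 when no limit is present). Rows not flagged
#' are untouched. Analysis functions ([compute_teq()], [diagnostic_ratios()],
#' [ring_class_fractions()]) apply this internally; the reader keeps raw
#' values so that table I/O stays lossless.
#'
#' @param table A congener table.
#' @param policy One of `"half_lod"`, `"zero"`, `"lod_over_sqrt2"`.
#' @return The table with substituted `conc_ng_m3` for flagged rows.
#' @export
resolve_bdl <- function(table, policy = c("half_lod", "zero", "lod_over_sqrt2")) {
  policy <- match.arg(policy)
  table <- congener_table(table)
  flagged <- table$below_detection
  if (!any(flagged)) return(table)
  lod <- table$lod_ng_m3[flagged]
  sub <- switch(policy,
    half_lod = ifelse(is.na(lod), 0, lod / 2),
    zero = rep(0, sum(flagged)),
    lod_over_sqrt2 = ifelse(is.na(lod), 0, lod / sqrt(2))
  )
  table$conc_ng_m3[flagged] <- sub
  table
}
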