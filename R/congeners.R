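#' The 16 US-EPA priority PAH congeners
#'
#' Registry of the sixteen priority polycyclic aromatic hydrocarbons with
#' their aromatic ring counts and the low/high molecular-weight split used
#' throughout the package: 2--3-ring congeners are "low", 4--6-ring congeners
#' are "high". The abbreviations are the canonical congener dialect for all
#' package inputs; [congener_synonyms()] maps common alternatives onto them.
#'
#' @return A tibble with columns `congener`, `full_name`, `ring_count`
#'   (integer, 2--6) and `ring_class` (`"low"` or `"high"`).
#' @examples
#' pah_congeners()
#' @export
pah_congeners <- function() {
  tbl <- tibble::tibble(
    congener = c(
      "Nap", "Acy", "Flu", "Ace", "Phe", "Ant",
      "Fle", "Pyr", "Chr", "BaA", "BbF", "BkF",
      "BaP", "DBA", "BghiP", "InP"
    ),
    full_name = c(
      "naphthalene", "acenaphthylene", "fluorene", "acenaphthene",
      "phenanthrene", "anthracene", "fluoranthene", "pyrene",
      "chrysene", "benz[a]anthracene", "benzo[b]fluoranthene",
      "benzo[k]fluoranthene", "benzo[a]pyrene", "dibenz[a,h]anthracene",
      "benzo[g,h,i]perylene", "indeno[1,2,3-cd]pyrene"
    ),
    ring_count = c(2L, 3L, 3L, 3L, 3L, 3L, 4L, 4L, 4L, 4L, 5L, 5L, 5L, 5L, 6L, 6L)
  )
  tbl$ring_class <- ring_class_of(tbl$ring_count)
  tbl
}

# low = 2-3 rings, high = 4-6 rings; pure function of the ring count
ring_class_of <- function(ring_count) {
  ifelse(ring_count <= 3L, "low", "high")
}

#' Synonym map for congener abbreviations
#'
#' Import-side aliases for congener abbreviations seen in the literature
#' (e.g. `"Flt"` for fluoranthene, `"DahA"` for dibenz\[a,h\]anthracene).
#' Applied by [congener_table()] and [read_congener_table()] before
#' validation; output tables always use the canonical abbreviations.
#'
#' @return A named character vector mapping alias -> canonical abbreviation.
#' @export
congener_synonyms <- function() {
  c(
    Flt = "Fle", Fla = "Fle", Flua = "Fle",
    DahA = "DBA", DBahA = "DBA",
    IcdP = "InP", IP = "InP", IND = "InP",
    BgP = "BghiP", BPer = "BghiP"
  )
}

canonicalize_congener <- function(x) {
  syn <- congener_synonyms()
  hit <- x %in% names(syn)
  x[hit] <- unname(syn[x[hit]])
  x
}

season_levels <- function() c("spring", "summer", "autumn", "winter")

# month -> season lookup (Dec/Jan/Feb winter, Mar-May spring, ...)
month_season <- function() {
  c(
    "winter", "winter", "spring", "spring", "spring", "summer",
    "summer", "summer", "autumn", "autumn", "autumn", "winter"
  )
}

#' Map calendar dates to meteorological seasons
#'
#' Seasons are month-based: March--May spring, June--August summer,
#' September--November autumn, December--February winter. The four seasons
#' partition the twelve months.
#'
#' @param date A `Date` vector, or anything coercible via [as.Date()].
#' @return A factor with levels spring, summer, autumn, winter.
#' @examples
#' season_of(as.Date(c("2015-01-12", "2015-04-01", "2015-09-30")))
#' @export
season_of <- function(date) {
  date <- tryCatch(as.Date(date), error = function(e) {
    abort(paste0("`date` is not a valid calendar date: ", conditionMessage(e)))
  })
  if (anyNA(date)) abort("`date` contains values that are not valid calendar dates.")
  m <- as.integer(format(date, "%m"))
  factor(month_season()[m], levels = season_levels())
}
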