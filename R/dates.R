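#' Calendar-month date arithmetic with end-of-month clamping
#'
#' Advances a date by a whole number of calendar months. When the target
#' month is shorter than the starting day-of-month, the result is clamped to
#' the last day of the target month (2019-08-31 advanced 6 months is
#' 2020-02-29). This is the arithmetic used by the six-month gap rule; base
#' date sequences are not suitable because they let short months overflow
#' into the next month.
#'
#' @param dates a `Date` vector (`NA` allowed, propagated).
#' @param months integer number of calendar months to advance (may be
#'   negative).
#' @return a `Date` vector of the same length.
#' @examples
#' add_months_clamped(as.Date("2019-08-31"), 6)  # 2020-02-29
#' add_months_clamped(as.Date("2019-01-15"), 6)  # 2019-07-15
#' @export
add_months_clamped <- function(dates, months) {
  stopifnot(inherits(dates, "Date"), length(months) == 1L,
            is.finite(months), months == round(months))
  lt <- as.POSIXlt(dates)
  total <- lt$year * 12L + lt$mon + as.integer(months)
  year <- total %/% 12L
  mon <- total %% 12L
  last <- days_in_month(year + 1900L, mon + 1L)
  lt$year <- year
  lt$mon <- mon
  lt$mday <- pmin(lt$mday, last)
  as.Date(lt)
}

# Number of days in month `mon` (1-12) of `year`, Gregorian.
days_in_month <- function(year, mon) {
  base <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  leap <- (year %% 4L == 0L & year %% 100L != 0L) | year %% 400L == 0L
  ifelse(mon == 2L & leap, 29L, base[mon])
}

#' Does the surgery-to-chemotherapy gap exceed six calendar months?
#'
#' The audit uses the gap between breast cancer surgery (modified radical
#' mastectomy or breast-conserving surgery) and the palliative chemotherapy
#' claim as a surrogate for disease status when metastasis is not
#' documented: a gap of six months or less is read as indicative of
#' non-metastatic disease, while a gap of more than six months is compatible
#' with a palliative indication.
#'
#' @param surgery_date `Date` vector; `NA` where no surgery date is recorded.
#' @param chemo_date `Date` vector of the chemotherapy claim dates (no `NA`).
#' @return character vector with values `"yes"` (chemo date strictly later
#'   than the surgery date advanced six calendar months, end-of-month
#'   clamped), `"no"` (surgery date present but gap not exceeded; the exact
#'   six-month anniversary counts as "no"), or `"unknown"` (no surgery
#'   date).
#' @examples
#' gap_exceeds_six_months(as.Date("2019-01-15"), as.Date("2019-07-16"))  # yes
#' gap_exceeds_six_months(as.Date("2019-01-15"), as.Date("2019-07-15"))  # no
#' gap_exceeds_six_months(as.Date(NA), as.Date("2019-07-15"))            # unknown
#' @export
gap_exceeds_six_months <- function(surgery_date, chemo_date) {
  stopifnot(inherits(surgery_date, "Date"), inherits(chemo_date, "Date"))
  if (anyNA(chemo_date)) {
    stop("chemo_date must not contain missing values", call. = FALSE)
  }
  n <- max(length(surgery_date), length(chemo_date))
  surgery_date <- rep_len(surgery_date, n)
  chemo_date <- rep_len(chemo_date, n)
  bad <- !is.na(surgery_date) & surgery_date > chemo_date
  if (any(bad)) {
    stop("surgery_date after chemo_date (chronology violation) at position(s) ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  out <- rep("unknown", n)
  known <- !is.na(surgery_date)
  if (any(known)) {
    thr <- add_months_clamped(surgery_date[known], 6L)
    out[known] <- ifelse(chemo_date[known] > thr, "yes", "no")
  }
  out
}
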