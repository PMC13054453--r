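#' Complete a partial date
#'
#' Spontaneous reports often carry incomplete drug-start or event-onset dates.
#' A date with a missing day is completed to the middle of the month (day 15);
#' a date with only a year is completed to the middle of the year (July 2).
#' Dates missing the year entirely cannot be imputed and yield `NA`.
#'
#' All arguments are recycled to a common length, so the function can be used
#' on whole columns of a report table.
#'
#' @param year integer vector of years (`NA` = date absent).
#' @param month optional integer vector of months (1-12, `NA` = missing).
#' @param day optional integer vector of days (`NA` = missing).
#' @return a `Date` vector; `NA` where the year is missing.
#' @examples
#' impute_date(2020, 5, NA)   # 2020-05-15
#' impute_date(2020, NA, NA)  # 2020-07-02
#' impute_date(2020, 5, 10)   # unchanged
#' @export
impute_date <- function(year, month = NA_integer_, day = NA_integer_) {
  n <- max(length(year), length(month), length(day))
  year <- rep_len(as.integer(year), n)
  month <- rep_len(as.integer(month), n)
  day <- rep_len(as.integer(day), n)
  # day without month would be ambiguous; treat as month missing
  day[is.na(month)] <- NA_integer_
  month_i <- ifelse(is.na(month), 7L, month)
  day_i <- ifelse(is.na(month), 2L, ifelse(is.na(day), 15L, day))
  out <- as.Date(rep(NA_real_, n), origin = "1970-01-01")
  ok <- !is.na(year)
  if (any(ok)) {
    out[ok] <- as.Date(sprintf("%04d-%02d-%02d", year[ok], month_i[ok], day_i[ok]),
                       format = "%Y-%m-%d")
  }
  out
}

#' Time to onset in days from partial dates
#'
#' Computes onset minus start in calendar days after completing both partial
#' dates with [impute_date()]. Pairs where either date is missing are returned
#' as `NA` (such reports are ignored when summarising time to onset), and
#' pairs whose completed difference is negative are also set to `NA`: a
#' negative interval after imputation is an artefact of date completion, not
#' evidence that the event preceded the drug. A same-day start and onset
#' (0 days) is retained.
#'
#' @param start_year,start_month,start_day drug start date components.
#' @param onset_year,onset_month,onset_day event onset date components.
#' @return numeric vector of days (>= 0) or `NA`.
#' @export
compute_tto <- function(start_year, start_month = NA_integer_, start_day = NA_integer_,
                        onset_year, onset_month = NA_integer_, onset_day = NA_integer_) {
  start <- impute_date(start_year, start_month, start_day)
  onset <- impute_date(onset_year, onset_month, onset_day)
  tto <- as.numeric(onset - start)
  tto[!is.na(tto) & tto < 0] <- NA_real_
  tto
}

# Age bands used for stratification and for the generator's strata.
# Unknown age is kept as its own stratum rather than dropped.
.default_age_breaks <- c(0, 18, 45, 65, 75, Inf)
.default_age_labels <- c("<18", "18-44", "45-64", "65-74", ">=75")

#' Assign age bands
#'
#' Cuts age in years into the bands `<18`, `18-44`, `45-64`, `65-74`, `>=75`,
#' with missing ages mapped to the band `"unknown"`. These are the strata
#' used by the Mantel-Haenszel adjusted analysis (crossed with sex).
#'
#' @param age_years numeric vector of ages; `NA` allowed.
#' @return factor with the band labels plus `"unknown"`.
#' @export
age_band <- function(age_years) {
  b <- cut(age_years, breaks = .default_age_breaks,
           labels = .default_age_labels, right = FALSE)
  b <- factor(ifelse(is.na(b), "unknown", as.character(b)),
              levels = c(.default_age_labels, "unknown"))
  b
}
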