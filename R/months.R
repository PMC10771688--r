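#' Map calendar dates to study month indices
#'
#' The study timeline is an integer month index \code{1..n_months} anchored at
#' a configurable origin month (default \code{"2020-03"}, the month the safer
#' supply guidance was released). Two binning schemes are supported:
#' \code{"calendar"} bins by calendar month, while \code{"mid16"} bins records
#' from the 16th of one month through the 15th of the next into the earlier
#' month, the alternative measurement window used in sensitivity analyses.
#'
#' @param dates a \code{Date} vector (or anything coercible via
#'   \code{as.Date}).
#' @param origin origin month as a \code{"YYYY-MM"} string; that month has
#'   index 1.
#' @param scheme month-binning scheme, \code{"calendar"} or \code{"mid16"}.
#' @return integer vector of month indices (may be < 1 for historical dates).
#' @export
#' @examples
#' month_index(as.Date(c("2020-03-27", "2020-05-01")))
month_index <- function(dates, origin = "2020-03", scheme = c("calendar", "mid16")) {
  scheme <- match.arg(scheme)
  d <- as.Date(dates)
  if (scheme == "mid16") d <- d - 15L
  # date -> (year, month) by integer arithmetic on days-since-epoch; avoids
  # per-element format()/POSIXlt work on large claim files
  z <- as.integer(unclass(d)) + 719468L
  era <- (z - (z < 0L) * 146096L) %/% 146097L
  doe <- z - era * 146097L
  yoe <- (doe - doe %/% 1460L + doe %/% 36524L - doe %/% 146096L) %/% 365L
  doy <- doe - (365L * yoe + yoe %/% 4L - yoe %/% 100L)
  mp <- (5L * doy + 2L) %/% 153L
  m <- mp + 3L - 12L * (mp >= 10L)
  y <- yoe + era * 400L + (mp >= 10L)
  oy <- as.integer(substr(origin, 1L, 4L))
  om <- as.integer(substr(origin, 6L, 7L))
  (y - oy) * 12L + (m - om) + 1L
}

#' Label a study month index as "YYYY-MM"
#'
#' @param index integer month index (1 = origin month).
#' @param origin origin month as \code{"YYYY-MM"}.
#' @return character vector of month labels.
#' @export
month_label <- function(index, origin = "2020-03") {
  oy <- as.integer(substr(origin, 1L, 4L))
  om <- as.integer(substr(origin, 6L, 7L))
  k <- om + as.integer(index) - 1L
  y <- oy + (k - 1L) %/% 12L
  m <- (k - 1L) %% 12L + 1L
  sprintf("%04d-%02d", y, m)
}

#' Last calendar day of a study month
#'
#' @inheritParams month_label
#' @return a \code{Date} vector of month-end dates.
#' @export
month_end_date <- function(index, origin = "2020-03") {
  first_next <- as.Date(paste0(month_label(as.integer(index) + 1L, origin), "-01"))
  first_next - 1L
}

#' First calendar day of a study month
#'
#' @inheritParams month_label
#' @return a \code{Date} vector of month-start dates.
#' @export
month_start_date <- function(index, origin = "2020-03") {
  as.Date(paste0(month_label(index, origin), "-01"))
}
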