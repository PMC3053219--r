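#' Imprecise calendar dates
#'
#' Follow-up documentation frequently records dates at reduced precision
#' ("Oct. 2008", "2007") when the exact day of an event is unknown. The
#' package represents such dates as ISO 8601 truncated strings: `"YYYY"`,
#' `"YYYY-MM"` or `"YYYY-MM-DD"`. Precision is carried by the string length,
#' so the representation is unambiguous and sorts chronologically.
#'
#' @param year integer calendar year.
#' @param month optional integer month (1-12); required when `day` is given.
#' @param day optional integer day of month (1-31); the full date must be a
#'   valid calendar date.
#' @return character vector of ISO truncated date strings.
#' @examples
#' imprecise_date(2008, 10)          # "2008-10"
#' imprecise_date(1992, 6, 3)        # "1992-06-03"
#' resolve_date(c("2007", "2008-10", "1992-06-03"))
#' @seealso [resolve_date()], [date_precision()]
#' @export
imprecise_date <- function(year, month = NA, day = NA) {
  n <- max(length(year), length(month), length(day))
  year <- rep_len(as.integer(year), n)
  month <- rep_len(as.integer(month), n)
  day <- rep_len(as.integer(day), n)
  if (any(!is.na(day) & is.na(month)))
    stop("a day component requires a month component", call. = FALSE)
  out <- ifelse(is.na(month), sprintf("%04d", year),
         ifelse(is.na(day), sprintf("%04d-%02d", year, month),
                sprintf("%04d-%02d-%02d", year, month, day)))
  out[is.na(year)] <- NA_character_
  validate_imprecise(out)
  out
}

#' Precision of an imprecise date string
#'
#' @param x character vector of ISO truncated dates.
#' @return character vector with values `"year"`, `"month"` or `"day"`
#'   (`NA` for missing input).
#' @export
date_precision <- function(x) {
  validate_imprecise(x)
  p <- rep(NA_character_, length(x))
  p[!is.na(x) & nchar(x) == 4L] <- "year"
  p[!is.na(x) & nchar(x) == 7L] <- "month"
  p[!is.na(x) & nchar(x) == 10L] <- "day"
  p
}

# stop() with the offending values if any non-NA entry is not a valid
# truncated ISO date; resolving must never silently produce nonsense.
validate_imprecise <- function(x) {
  x <- as.character(x)
  ok <- is.na(x) | grepl("^\\d{4}(-\\d{2}(-\\d{2})?)?$", x)
  if (any(!ok))
    stop("not an ISO truncated date (YYYY, YYYY-MM or YYYY-MM-DD): ",
         paste(unique(x[!ok]), collapse = ", "), call. = FALSE)
  full <- !is.na(x) & nchar(x) == 10L
  if (any(full)) {
    d <- as.Date(x[full], format = "%Y-%m-%d")
    if (anyNA(d))
      stop("invalid calendar date: ",
           paste(unique(x[full][is.na(d)]), collapse = ", "), call. = FALSE)
  }
  mo <- !is.na(x) & nchar(x) >= 7L
  if (any(mo)) {
    m <- as.integer(substr(x[mo], 6, 7))
    if (any(m < 1L | m > 12L))
      stop("invalid month in: ",
           paste(unique(x[mo][m < 1L | m > 12L]), collapse = ", "),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Resolve an imprecise date to a single calendar date
#'
#' Imprecise dates are resolved by the midpoint convention: month precision
#' resolves to the 15th of the month, year precision to July 1 of the year.
#' The midpoint minimizes the maximum resolution error and is symmetric, so
#' durations computed from resolved dates are not systematically biased in
#' either direction. Resolution is deterministic: the same input always
#' yields the same date.
#'
#' @param x character vector of ISO truncated dates (`"YYYY"`, `"YYYY-MM"`,
#'   `"YYYY-MM-DD"`), or `Date` input which is returned unchanged.
#' @return `Date` vector.
#' @examples
#' resolve_date("1992-06-03")  # 1992-06-03
#' resolve_date("2008-10")     # 2008-10-15
#' resolve_date("2007")        # 2007-07-01
#' @export
resolve_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  validate_imprecise(x)
  out <- rep(as.Date(NA), length(x))
  yr <- !is.na(x) & nchar(x) == 4L
  mo <- !is.na(x) & nchar(x) == 7L
  dy <- !is.na(x) & nchar(x) == 10L
  if (any(yr)) out[yr] <- as.Date(paste0(x[yr], "-07-01"))
  if (any(mo)) out[mo] <- as.Date(paste0(x[mo], "-15"))
  if (any(dy)) out[dy] <- as.Date(x[dy])
  out
}

# Duration in years between two Date vectors, using the 365.25-day year.
years_between <- function(from, to) {
  as.numeric(to - from) / 365.25
}
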