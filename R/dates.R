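#' Parse registry dates with explicit precision
#'
#' Registry exports mix full dates, month-only dates and bare years, in both
#' ISO and European day-first notations. Each mapping config lists the date
#' dialects its registry uses; parsing records the precision of what was
#' actually present so that downstream pre-registration classification can
#' treat coarse dates conservatively. Month-precision dates floor to the first
#' of the month, year-precision to January 1.
#'
#' Supported format keys: `"ymd"` (2011-04-05), `"dmy_dot"` (05.04.2011),
#' `"dmy_slash"` (05/04/2011), `"ym"` (2011-04), `"my_dot"` (04.2011),
#' `"my_slash"` (04/2011), `"y"` (2011).
#'
#' @param x Character vector of raw date strings.
#' @param formats Character vector of format keys, tried in order.
#' @return A tibble with columns `date` (Date, `NA` where unparseable) and
#'   `precision` (`"day"`, `"month"`, `"year"`, or `NA`).
#' @examples
#' parse_registry_date(c("2011-04-05", "2011-04", "garbage"),
#'                     c("ymd", "ym"))
#' @export
parse_registry_date <- function(x, formats = c("ymd", "ym", "y")) {
  x <- stringr::str_trim(as.character(x))
  n <- length(x)
  date <- rep(as.Date(NA), n)
  precision <- rep(NA_character_, n)
  todo <- !is.na(x) & nzchar(x)

  specs <- list(
    ymd       = list(rx = "^(\\d{4})-(\\d{1,2})-(\\d{1,2})$", ord = c(1, 2, 3), prec = "day"),
    dmy_dot   = list(rx = "^(\\d{1,2})\\.(\\d{1,2})\\.(\\d{4})$", ord = c(3, 2, 1), prec = "day"),
    dmy_slash = list(rx = "^(\\d{1,2})/(\\d{1,2})/(\\d{4})$", ord = c(3, 2, 1), prec = "day"),
    ym        = list(rx = "^(\\d{4})-(\\d{1,2})$", ord = c(1, 2, NA), prec = "month"),
    my_dot    = list(rx = "^(\\d{1,2})\\.(\\d{4})$", ord = c(2, 1, NA), prec = "month"),
    my_slash  = list(rx = "^(\\d{1,2})/(\\d{4})$", ord = c(2, 1, NA), prec = "month"),
    y         = list(rx = "^(\\d{4})$", ord = c(1, NA, NA), prec = "year")
  )
  unknown <- setdiff(formats, names(specs))
  if (length(unknown) > 0) {
    stop("unknown date format key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  for (key in formats) {
    if (!any(todo)) break
    sp <- specs[[key]]
    m <- stringr::str_match(x, sp$rx)
    hit <- todo & !is.na(m[, 1])
    if (!any(hit)) next
    pick <- function(slot) {
      if (is.na(sp$ord[slot])) rep("1", sum(hit)) else m[hit, sp$ord[slot] + 1]
    }
    cand <- suppressWarnings(as.Date(
      paste(pick(1), pick(2), pick(3), sep = "-"), format = "%Y-%m-%d"))
    ok <- !is.na(cand)
    idx <- which(hit)[ok]
    date[idx] <- cand[ok]
    precision[idx] <- sp$prec
    todo[idx] <- FALSE
  }
  tibble(date = date, precision = precision)
}

precision_rank <- function(p) {
  unname(c(day = 3L, month = 2L, year = 1L)[p])
}

# Floor a date to the given precision ("day" = identity).
floor_to_precision <- function(d, precision) {
  out <- d
  m <- !is.na(precision) & precision == "month"
  y <- !is.na(precision) & precision == "year"
  out[m] <- lubridate::floor_date(d[m], "month")
  out[y] <- lubridate::floor_date(d[y], "year")
  out
}
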