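#' Classify pre-registration status
#'
#' A trial counts as pre-registered when its (earliest) registration date is
#' on or before its start date; registration exactly at study start counts as
#' pre-registered. When either date carries only month or year precision the
#' comparison is made at the coarser of the two precisions, so that e.g. a
#' month-precision registration in the same month as a day-precision start is
#' conservatively classed as pre-registered. Trials missing either date are
#' `"unknown"`.
#'
#' @param trials Tibble with `registration_date`, `start_date` and (optional)
#'   `registration_date_precision`, `start_date_precision` columns; missing
#'   precision columns are treated as day precision.
#' @return `trials` with a `preregistered` column
#'   (`"pre"`/`"retro"`/`"unknown"`).
#' @export
classify_preregistration <- function(trials) {
  assert_columns(trials, c("registration_date", "start_date"), "trials")
  rp <- if ("registration_date_precision" %in% names(trials)) {
    trials$registration_date_precision
  } else rep("day", nrow(trials))
  sp <- if ("start_date_precision" %in% names(trials)) {
    trials$start_date_precision
  } else rep("day", nrow(trials))
  rp[is.na(rp)] <- "day"
  sp[is.na(sp)] <- "day"
  coarser <- ifelse(precision_rank(rp) <= precision_rank(sp), rp, sp)
  reg <- floor_to_precision(trials$registration_date, coarser)
  sta <- floor_to_precision(trials$start_date, coarser)
  status <- dplyr::case_when(
    is.na(reg) | is.na(sta) ~ "unknown",
    reg <= sta ~ "pre",
    TRUE ~ "retro"
  )
  dplyr::mutate(trials, preregistered = status)
}

#' Load a structural-context table
#'
#' The context lists German Universities of Excellence with their funding
#' windows and KKS (Koordinierungszentrum für Klinische Studien) sites with
#' their opening years, as diacritic-folded, case-insensitive regular
#' expression patterns to be matched against sponsor names. The packaged
#' default was compiled from public lists of the excellence initiative
#' funding lines and the KKS network; it is an editable data file, not code.
#'
#' @param path CSV with columns `entity`, `pattern`, `window_start`,
#'   `window_end`, `kind` (`"uoe"` or `"kks"`); defaults to the packaged
#'   context.
#' @return A validated tibble.
#' @export
load_structural_context <- function(path = NULL) {
  path <- path %||% system.file("extdata", "structural_context.csv",
                                package = "ctrquality")
  ctx <- readr::read_csv(path, col_types = readr::cols(
    entity = readr::col_character(),
    pattern = readr::col_character(),
    window_start = readr::col_date(),
    window_end = readr::col_date(),
    kind = readr::col_character()
  ), progress = FALSE, show_col_types = FALSE)
  if (!all(ctx$kind %in% c("uoe", "kks"))) {
    stop("context 'kind' must be 'uoe' or 'kks'", call. = FALSE)
  }
  bad <- !is.na(ctx$window_end) & ctx$window_start > ctx$window_end
  if (any(bad)) stop("context window_start after window_end", call. = FALSE)
  yr <- lubridate::year(ctx$window_start)
  if (any(yr < 1990 | yr > 2100)) {
    stop("context window years out of plausible range", call. = FALSE)
  }
  ctx
}

match_any_pattern <- function(sponsor_folded, patterns) {
  hit <- rep(FALSE, length(sponsor_folded))
  for (p in patterns) {
    hit <- hit | stringr::str_detect(
      sponsor_folded, stringr::regex(p, ignore_case = TRUE))
  }
  hit & !is.na(sponsor_folded)
}

#' Derive structural analysis flags for trials
#'
#' Adds the per-trial flags used as regression predictors:
#' * `university_sponsor` — any sponsor name contains "universit"
#'   (case-insensitive; captures German and English university and university
#'   medical center names).
#' * `uoe_active` — a University-of-Excellence pattern matches a sponsor AND
#'   the trial start date falls inside that university's funding window
#'   (closed interval, boundaries inclusive).
#' * `kks_active` — a KKS city pattern matches a sponsor AND the trial start
#'   year is at or after the KKS opening year (inclusive).
#' * `observational` — study type is observational.
#'
#' Trials with a missing start date get `uoe_active = kks_active = FALSE`
#' with a warning: the temporal window cannot be evaluated. This is a
#' location-based proxy; it flags trials a KKS could have supported, not
#' documented cooperation.
#'
#' @param trials Unified-trial tibble with `sponsor_names`, `start_date`,
#'   `study_type`.
#' @param context Context tibble from [load_structural_context()].
#' @return `trials` with the four flag columns appended.
#' @export
detect_structural_factors <- function(trials,
                                      context = load_structural_context()) {
  assert_columns(trials, c("sponsor_names", "start_date", "study_type"),
                 "trials")
  sponsor <- fold_ascii(trials$sponsor_names)
  start <- trials$start_date
  start_year <- lubridate::year(start)

  uni <- stringr::str_detect(sponsor, stringr::fixed("universit")) &
    !is.na(sponsor)

  uoe <- rep(FALSE, nrow(trials))
  for (i in which(context$kind == "uoe")) {
    m <- match_any_pattern(sponsor, context$pattern[i])
    inside <- !is.na(start) & start >= context$window_start[i] &
      (is.na(context$window_end[i]) | start <= context$window_end[i])
    uoe <- uoe | (m & inside)
  }
  kks <- rep(FALSE, nrow(trials))
  for (i in which(context$kind == "kks")) {
    m <- match_any_pattern(sponsor, context$pattern[i])
    open_year <- lubridate::year(context$window_start[i])
    after <- !is.na(start_year) & start_year >= open_year
    kks <- kks | (m & after)
  }
  if (any(is.na(start))) {
    warning(sprintf(
      "%d trial(s) have no start date; uoe_active/kks_active set to FALSE",
      sum(is.na(start))), call. = FALSE)
  }
  dplyr::mutate(trials,
                university_sponsor = uni,
                uoe_active = uoe,
                kks_active = kks,
                observational = !is.na(.data$study_type) &
                  .data$study_type == "observational")
}

#' Classify all per-trial analysis flags in one step
#'
#' Convenience wrapper: [classify_preregistration()] followed by
#' [detect_structural_factors()], plus `registration_year` and `start_year`
#' helper columns.
#'
#' @inheritParams detect_structural_factors
#' @return Flagged trial tibble.
#' @export
classify_trials <- function(trials, context = load_structural_context()) {
  trials |>
    classify_preregistration() |>
    detect_structural_factors(context) |>
    dplyr::mutate(
      registration_year = lubridate::year(.data$registration_date),
      start_year = lubridate::year(.data$start_date))
}
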