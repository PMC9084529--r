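#' Column-mapping configuration for a registry export dialect
#'
#' Export schemas drift across registry snapshot versions, so the mapping from
#' source columns to the harmonized record model ships as an editable YAML
#' config per dialect rather than hard-coded headers. The packaged configs
#' target the export shapes in use around early 2021.
#'
#' @param dialect One of `"AACT"`, `"DRKS"`, `"ICTRP"`, or a path to a custom
#'   mapping YAML file.
#' @return A list with the dialect's delimiter, registry label, field map,
#'   date-format keys and mandatory columns.
#' @examples
#' m <- registry_mapping("AACT")
#' m$fields$record_id
#' @export
registry_mapping <- function(dialect) {
  if (file.exists(dialect)) {
    path <- dialect
  } else {
    path <- system.file("extdata", "mappings",
                        paste0(tolower(dialect), ".yaml"),
                        package = "ctrquality")
    if (!nzchar(path)) {
      stop("unknown dialect '", dialect,
           "' (expected AACT, DRKS, ICTRP, or a mapping file path)",
           call. = FALSE)
    }
  }
  cfg <- yaml::read_yaml(path)
  stopifnot(!is.null(cfg$fields$record_id))
  cfg
}

#' Read a registry export file into raw records
#'
#' Parses one of the three supported export dialects (AACT pipe-delimited,
#' DRKS CSV, ICTRP CSV with quoted fields) without altering any values beyond
#' delimiter/quote parsing: one raw record per data row, all columns read as
#' text.
#'
#' @param path Path to the export file.
#' @param dialect `"AACT"`, `"DRKS"` or `"ICTRP"` (or a mapping file path).
#' @return A tibble of raw records, all columns character, with a
#'   `source_dialect` column prepended and the mapping attached as attribute
#'   `"mapping"`.
#' @seealso [harmonize_records()]
#' @export
read_registry_export <- function(path, dialect) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  mapping <- registry_mapping(dialect)
  raw <- readr::read_delim(
    path, delim = mapping$delimiter, quote = "\"",
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), trim_ws = FALSE, progress = FALSE,
    show_col_types = FALSE
  )
  missing <- setdiff(unlist(mapping$mandatory), names(raw))
  if (length(missing) > 0) {
    stop(sprintf("%s export is missing mandatory column(s): %s",
                 mapping$dialect, paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  out <- dplyr::mutate(raw, source_dialect = mapping$dialect, .before = 1)
  attr(out, "mapping") <- mapping
  out
}

# Documented synonym table from registry study-type strings to the harmonized
# enum. Matching is case-insensitive on the folded string; bracketed
# qualifiers such as "Observational [Patient Registry]" are resolved by their
# base type. Unrecognized non-empty values map to "other"; empty to NA.
study_type_synonyms <- function() {
  c(
    "interventional"                        = "interventional",
    "interventional clinical trial of medicinal product" = "interventional",
    "intervention"                          = "interventional",
    "observational"                         = "observational",
    "observational [patient registry]"      = "observational",
    "observational study"                   = "observational",
    "non-interventional"                    = "observational",
    "post marketing"                        = "post_marketing",
    "post-marketing"                        = "post_marketing",
    "post marketing surveillance"           = "post_marketing",
    "pms"                                   = "post_marketing",
    "expanded access"                       = "expanded_access",
    "diagnostic test"                       = "diagnostic_test",
    "diagnosis"                             = "diagnostic_test",
    "other"                                 = "other"
  )
}

map_study_type <- function(x) {
  syn <- study_type_synonyms()
  key <- stringr::str_squish(tolower(x))
  out <- unname(syn[key])
  # fall back to the base type before a bracketed qualifier
  base <- stringr::str_squish(stringr::str_remove(key, "\\[.*\\]$"))
  out[is.na(out)] <- unname(syn[base[is.na(out)]])
  out[is.na(out) & !is.na(key) & nzchar(key)] <- "other"
  out[!is.na(key) & !nzchar(key)] <- NA_character_
  out
}

harmonized_columns <- function() {
  c("record_id", "registry", "title",
    "registration_date", "registration_date_precision",
    "start_date", "start_date_precision",
    "study_type", "sample_size",
    "secondary_ids", "sponsor_names", "contact_emails",
    "recruiting_countries")
}

#' Harmonize raw registry records into the common trial-record model
#'
#' Maps dialect columns onto the harmonized schema, parses dates with explicit
#' precision (month-only dates floor to the 1st, year-only to Jan 1), maps
#' study types through a documented synonym table, and coerces sample sizes to
#' non-negative integers. Harmonization never invents data: every non-null
#' output field traces to a source column or a documented default.
#'
#' Records with a missing or empty primary ID are rejected; the rejects, with
#' reason codes, are attached as attribute `"rejected"`. Unparseable dates
#' become `NA` with a warning naming the count.
#'
#' @param raw Tibble from [read_registry_export()].
#' @param mapping Mapping config; defaults to the one attached to `raw`.
#' @return A tibble of harmonized trial records (one row per accepted record)
#'   with columns `record_id`, `registry`, `title`, `registration_date`,
#'   `registration_date_precision`, `start_date`, `start_date_precision`,
#'   `study_type`, `sample_size`, and ";"-joined multi-value columns
#'   `secondary_ids`, `sponsor_names`, `contact_emails`,
#'   `recruiting_countries`.
#' @export
harmonize_records <- function(raw, mapping = attr(raw, "mapping")) {
  if (is.null(mapping)) {
    stop("no mapping supplied or attached to the raw records", call. = FALSE)
  }
  fld <- mapping$fields
  grab <- function(field) {
    col <- fld[[field]]
    if (is.null(col) || !col %in% names(raw)) {
      rep(NA_character_, nrow(raw))
    } else {
      v <- raw[[col]]
      ifelse(!is.na(v) & nzchar(stringr::str_trim(v)), v, NA_character_)
    }
  }

  registry <- if (!is.null(mapping$registry_from)) {
    src <- grab_registry_source(raw, mapping)
    paste0(mapping$registry_prefix %||% "", src)
  } else {
    rep(mapping$registry, nrow(raw))
  }

  reg <- parse_registry_date(grab("registration_date"), mapping$date_formats)
  sta <- parse_registry_date(grab("start_date"), mapping$date_formats)
  n_bad <- sum(!is.na(grab("registration_date")) & is.na(reg$date)) +
    sum(!is.na(grab("start_date")) & is.na(sta$date))
  if (n_bad > 0) {
    warning(sprintf("%d date value(s) could not be parsed and were set to NA",
                    n_bad), call. = FALSE)
  }

  size_raw <- suppressWarnings(as.numeric(grab("sample_size")))
  size <- ifelse(!is.na(size_raw) & size_raw >= 0, as.integer(round(size_raw)),
                 NA_integer_)

  clean_multi <- function(x) {
    vapply(x, function(v) {
      if (is.na(v)) NA_character_ else join_multi(split_multi(v))
    }, character(1), USE.NAMES = FALSE)
  }

  out <- tibble(
    record_id = stringr::str_trim(grab("record_id")),
    registry = registry,
    title = grab("title"),
    registration_date = reg$date,
    registration_date_precision = reg$precision,
    start_date = sta$date,
    start_date_precision = sta$precision,
    study_type = map_study_type(grab("study_type")),
    sample_size = size,
    secondary_ids = clean_multi(grab("secondary_ids")),
    sponsor_names = clean_multi(grab("sponsor_names")),
    contact_emails = clean_multi(grab("contact_emails")),
    recruiting_countries = clean_multi(grab("recruiting_countries"))
  )

  bad_id <- is.na(out$record_id) | !nzchar(out$record_id)
  rejected <- tibble(row = which(bad_id), reason = "missing_record_id")
  out <- out[!bad_id, , drop = FALSE]
  attr(out, "rejected") <- rejected
  out
}

grab_registry_source <- function(raw, mapping) {
  col <- mapping$registry_from
  if (!col %in% names(raw)) {
    stop("registry source column '", col, "' not present in export",
         call. = FALSE)
  }
  v <- stringr::str_trim(raw[[col]])
  ifelse(nzchar(v), v, "unknown")
}

#' Read and harmonize a registry export in one step
#'
#' @inheritParams read_registry_export
#' @return A harmonized trial-record tibble (see [harmonize_records()]).
#' @export
ingest_registry_export <- function(path, dialect) {
  harmonize_records(read_registry_export(path, dialect))
}

#' Write / read the harmonized interchange file
#'
#' Two equivalent on-disk forms are supported: a CSV with the documented
#' column order, and a line-delimited JSON file (one record object per line,
#' same field order). Both round-trip field-identically.
#'
#' @param records Harmonized trial-record tibble.
#' @param path Output (input) file path.
#' @param format `"csv"` or `"jsonl"`; inferred from the file extension when
#'   omitted.
#' @return `write_harmonized()` returns `path` invisibly; `read_harmonized()`
#'   returns the record tibble.
#' @export
write_harmonized <- function(records, path, format = NULL) {
  assert_columns(records, harmonized_columns(), "harmonized records")
  format <- format %||% infer_format(path)
  records <- records[, harmonized_columns()]
  if (format == "csv") {
    readr::write_csv(records, path, na = "", progress = FALSE)
  } else {
    df <- dplyr::mutate(records,
                        registration_date = as.character(.data$registration_date),
                        start_date = as.character(.data$start_date))
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    jsonlite::stream_out(df, con, na = "null", verbose = FALSE)
  }
  invisible(path)
}

#' @rdname write_harmonized
#' @export
read_harmonized <- function(path, format = NULL) {
  format <- format %||% infer_format(path)
  if (format == "csv") {
    out <- readr::read_csv(
      path,
      col_types = readr::cols(
        registration_date = readr::col_date(),
        start_date = readr::col_date(),
        sample_size = readr::col_integer(),
        .default = readr::col_character()
      ),
      na = "", progress = FALSE, show_col_types = FALSE
    )
  } else {
    con <- file(path, open = "r", encoding = "UTF-8")
    on.exit(close(con))
    out <- as_tibble(jsonlite::stream_in(con, verbose = FALSE))
    out$registration_date <- as.Date(out$registration_date)
    out$start_date <- as.Date(out$start_date)
    out$sample_size <- as.integer(out$sample_size)
    for (col in setdiff(harmonized_columns(),
                        c("registration_date", "start_date", "sample_size"))) {
      out[[col]] <- as.character(out[[col]])
    }
  }
  out[, harmonized_columns()]
}

infer_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jsonl", "ndjson", "json")) "jsonl" else "csv"
}
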