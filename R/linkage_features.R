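# Pairwise comparison features for the duplicate-match classifier.
# Predictors follow the record-linkage setup: shared IDs, title similarity,
# registration/start date gaps, sample-size ratio, shared contact e-mail.

normalize_title <- function(x) {
  x <- fold_ascii(x)
  x <- stringr::str_replace_all(x, "[^a-z0-9]+", " ")
  stringr::str_squish(x)
}

# Token-set similarity: sort the unique tokens of each title, re-join, and
# compute a normalized Levenshtein similarity. Robust to word order and small
# typographical perturbations.
#' Normalized token-set title similarity
#'
#' Case-folded, diacritic-folded, punctuation-stripped titles are reduced to
#' their sorted unique token sets; similarity is `1 - d/L` where `d` is the
#' Levenshtein distance between the re-joined token strings and `L` the longer
#' length. Identical token sets score 1, disjoint strings near 0.
#'
#' @param a,b Character vectors of titles (recycled to common length).
#' @return Numeric vector in `[0, 1]`; `NA` where either title is missing.
#' @export
title_similarity <- function(a, b) {
  norm <- function(x) {
    vapply(normalize_title(x), function(t) {
      if (is.na(t)) return(NA_character_)
      paste(sort(unique(strsplit(t, " ", fixed = TRUE)[[1]])), collapse = " ")
    }, character(1), USE.NAMES = FALSE)
  }
  ta <- norm(a)
  tb <- norm(b)
  out <- rep(NA_real_, length(ta))
  ok <- !is.na(ta) & !is.na(tb)
  if (any(ok)) {
    d <- mapply(function(x, y) adist(x, y)[1, 1], ta[ok], tb[ok])
    L <- pmax(nchar(ta[ok]), nchar(tb[ok]), 1L)
    out[ok] <- pmax(0, 1 - d / L)
  }
  out
}

normalize_id <- function(x) toupper(gsub("\\s+", "", x))

record_id_sets <- function(records) {
  purrr::map2(records$record_id, records$secondary_ids, function(p, s) {
    normalize_id(c(p, split_multi(if (is.na(s)) "" else s)))
  })
}

record_email_sets <- function(records) {
  purrr::map(records$contact_emails, function(e) {
    tolower(split_multi(if (is.na(e)) "" else e))
  })
}

#' Compute pairwise match features for candidate record pairs
#'
#' @param records Harmonized trial-record tibble.
#' @param pairs Tibble with columns `id1`, `id2` holding `record_id` values.
#' @return `pairs` with feature columns: `id_overlap` (any shared primary or
#'   secondary ID), `title_similarity`, `reg_gap_days`, `start_gap_days`
#'   (absolute day gaps, `NA` when either date is missing),
#'   `sample_size_ratio` (min/max, `NA` unless both sizes are positive), and
#'   `shared_contact` (any common e-mail, case-folded).
#' @export
pair_features <- function(records, pairs) {
  assert_columns(records, c("record_id", "title", "registration_date",
                            "start_date", "sample_size", "secondary_ids",
                            "contact_emails"), "records")
  idx <- match(pairs$id1, records$record_id)
  jdx <- match(pairs$id2, records$record_id)
  if (anyNA(idx) || anyNA(jdx)) {
    stop("pairs reference record_ids not present in records", call. = FALSE)
  }
  ids <- record_id_sets(records)
  emails <- record_email_sets(records)

  overlap <- function(sets_i, sets_j) {
    mapply(function(a, b) length(intersect(a, b)) > 0, sets_i, sets_j)
  }
  gap <- function(d1, d2) abs(as.integer(d1 - d2))
  n1 <- records$sample_size[idx]
  n2 <- records$sample_size[jdx]
  ratio <- ifelse(!is.na(n1) & !is.na(n2) & n1 > 0 & n2 > 0,
                  pmin(n1, n2) / pmax(n1, n2), NA_real_)

  dplyr::mutate(
    pairs,
    id_overlap = overlap(ids[idx], ids[jdx]),
    title_similarity = title_similarity(records$title[idx],
                                        records$title[jdx]),
    reg_gap_days = gap(records$registration_date[idx],
                       records$registration_date[jdx]),
    start_gap_days = gap(records$start_date[idx], records$start_date[jdx]),
    sample_size_ratio = ratio,
    shared_contact = overlap(emails[idx], emails[jdx])
  )
}

matcher_feature_names <- function() {
  c("id_overlap", "title_similarity", "reg_gap_days", "start_gap_days",
    "sample_size_ratio", "shared_contact")
}

# Encode features for the forest: logical -> 0/1, NA -> -1 plus missingness
# indicators (forests split on the indicator rather than an imputed value).
encode_features <- function(features) {
  x <- features[, matcher_feature_names()]
  x$id_overlap <- as.numeric(x$id_overlap)
  x$shared_contact <- as.numeric(x$shared_contact)
  for (col in c("reg_gap_days", "start_gap_days", "sample_size_ratio",
                "title_similarity")) {
    miss <- is.na(x[[col]])
    x[[paste0(col, "_missing")]] <- as.numeric(miss)
    x[[col]] <- ifelse(miss, -1, as.numeric(x[[col]]))
  }
  as.data.frame(x)
}
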