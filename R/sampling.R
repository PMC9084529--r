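excludable_study_types <- function() {
  c("post_marketing", "expanded_access", "diagnostic_test", "other")
}

#' Exclude trials by study type
#'
#' Removes post-marketing, expanded-access, diagnostic-test and other-type
#' studies — record types that typically reference other records or material
#' and cannot be rated on their own — keeping interventional and
#' observational trials.
#'
#' @param trials Trial tibble with a populated `study_type` column.
#' @return A list: `trials` (filtered tibble) and `tally` (tibble of
#'   `reason`, `n`, plus attribute-free `remaining` count column on one row
#'   via `attr(, "remaining")`). Conservation holds: input rows = remaining +
#'   sum of tally.
#' @export
exclude_by_study_type <- function(trials) {
  assert_columns(trials, "study_type", "trials")
  drop <- trials$study_type %in% excludable_study_types()
  tally <- trials[drop, , drop = FALSE] |>
    dplyr::count(reason = .data$study_type, name = "n") |>
    dplyr::arrange(.data$reason)
  kept <- trials[!drop, , drop = FALSE]
  list(trials = kept, tally = tally, remaining = nrow(kept))
}

# Largest-remainder (Hamilton) allocation of n across strata of given sizes,
# proportional to size, capped at stratum size with overflow redistributed.
largest_remainder_allocation <- function(sizes, n) {
  stopifnot(n <= sum(sizes))
  alloc <- rep(0L, length(sizes))
  open <- sizes > 0
  remaining <- n
  while (remaining > 0) {
    quota <- remaining * sizes[open] / sum(sizes[open])
    base <- pmin(floor(quota), sizes[open] - alloc[open])
    add <- as.integer(base)
    left <- remaining - sum(add)
    if (left > 0) {
      frac <- quota - floor(quota)
      room <- sizes[open] - alloc[open] - add
      ord <- order(-frac, seq_along(frac))
      for (i in ord) {
        if (left == 0) break
        if (room[i] > 0) {
          add[i] <- add[i] + 1L
          left <- left - 1L
        }
      }
    }
    alloc[open] <- alloc[open] + add
    remaining <- n - sum(alloc)
    open <- sizes > alloc
    if (remaining > 0 && !any(open)) {
      stop("allocation failed: no capacity left", call. = FALSE)
    }
    # loop continues only when caps truncated some strata
  }
  alloc
}

#' Draw a stratified random sample of trials
#'
#' Proportional allocation across the non-empty strata with largest-remainder
#' rounding; empty strata are skipped and their share redistributed. Sampling
#' is reproducible by `seed` and leaves the caller's RNG state untouched.
#'
#' @param trials Trial tibble.
#' @param n Total sample size (must not exceed the number of trials).
#' @param strata Character vector of stratification column names (default:
#'   start year, University-of-Excellence activity, KKS availability).
#' @param seed Integer seed.
#' @return Sampled tibble; the per-stratum allocation report is attached as
#'   attribute `"allocation"` (columns: stratum values, `size`, `allocated`).
#' @export
stratified_sample <- function(trials, n,
                              strata = c("start_year", "uoe_active",
                                         "kks_active"),
                              seed = 1L) {
  assert_columns(trials, strata, "trials")
  if (n > nrow(trials)) {
    stop("requested sample size exceeds the population", call. = FALSE)
  }
  key <- do.call(paste, c(lapply(strata, function(s) {
    v <- trials[[s]]
    ifelse(is.na(v), "<NA>", as.character(v))
  }), sep = "\r"))
  sizes_tbl <- tibble(stratum = key) |>
    dplyr::count(.data$stratum, name = "size") |>
    dplyr::arrange(.data$stratum)
  alloc <- largest_remainder_allocation(sizes_tbl$size, n)
  sizes_tbl$allocated <- alloc

  idx <- with_local_seed(seed, {
    unlist(purrr::map2(sizes_tbl$stratum, sizes_tbl$allocated, function(s, k) {
      members <- which(key == s)
      if (k == 0) integer(0)
      else sort(members[sample.int(length(members), k)])
    }))
  })
  out <- trials[sort(idx), , drop = FALSE]

  report <- tidyr::separate(sizes_tbl, "stratum", into = strata,
                            sep = "\r", convert = FALSE)
  attr(out, "allocation") <- report
  out
}

manual_exclusion_reasons <- function() {
  c("extension", "multi_part", "patient_registry", "follow_up", "sub_study")
}

#' Apply manual exclusion labels to a sample
#'
#' Manual inspection of a sample can reveal records that cannot be rated as a
#' single trial: extension studies, multi-part trials, patient registry
#' studies, follow-up studies, and records containing sub-studies. Labels are
#' a judgment input, not computed from record text.
#'
#' @param sample Sampled trial tibble with `trial_id`.
#' @param labels Tibble `trial_id`, `reason`; reasons must come from
#'   `extension`, `multi_part`, `patient_registry`, `follow_up`, `sub_study`.
#'   Trials absent from `labels` are kept.
#' @return A list: `trials` (analysis set), `tally` (per-reason counts),
#'   `remaining`.
#' @export
apply_manual_exclusions <- function(sample, labels) {
  assert_columns(sample, "trial_id", "sample")
  if (nrow(labels) > 0) {
    assert_columns(labels, c("trial_id", "reason"), "labels")
    bad <- setdiff(unique(labels$reason), manual_exclusion_reasons())
    if (length(bad) > 0) {
      stop("unknown manual exclusion reason(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    orphan <- setdiff(labels$trial_id, sample$trial_id)
    if (length(orphan) > 0) {
      stop("labels reference trials outside the sample: ",
           paste(head(orphan, 5), collapse = ", "), call. = FALSE)
    }
  }
  drop <- sample$trial_id %in% labels$trial_id
  tally <- labels[labels$trial_id %in% sample$trial_id, , drop = FALSE] |>
    dplyr::count(reason = .data$reason, name = "n") |>
    dplyr::arrange(.data$reason)
  kept <- sample[!drop, , drop = FALSE]
  list(trials = kept, tally = tally, remaining = nrow(kept))
}
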