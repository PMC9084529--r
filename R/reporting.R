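#' Descriptive table for the overall database and an inspected sample
#'
#' Counts and percentages for the standard descriptive rows: total n,
#' interventional/observational, pre-registered, KKS, University of
#' Excellence, both, ClinicalTrials.gov and DRKS membership, plus the mean
#' start date with its standard deviation in days. Percentages use the
#' overall n of their column as denominator, except pre-registration, whose
#' denominator is the trials with known pre-registration status. Percentages
#' are kept at full precision; use [format_descriptive_table()] for the
#' half-up 2-decimal display form.
#'
#' @param trials Flagged trial tibble (columns `observational`,
#'   `preregistered`, `kks_active`, `uoe_active`, `on_ctgov`, `on_drks`,
#'   `start_date`).
#' @param sample_ids Optional vector of `trial_id`s forming the manually
#'   inspected sample; the sample columns are omitted when `NULL`.
#' @return Tibble `measure`, `overall_n`, `overall_pct` (and `sample_n`,
#'   `sample_pct`); the start-date summary is attached as attribute
#'   `"start_date_summary"`.
#' @export
build_descriptive_table <- function(trials, sample_ids = NULL) {
  assert_columns(trials, c("observational", "preregistered", "kks_active",
                           "uoe_active", "on_ctgov", "on_drks",
                           "start_date"), "trials")
  one_scope <- function(df) {
    n_total <- nrow(df)
    known_pre <- sum(df$preregistered %in% c("pre", "retro"))
    tibble(
      measure = c("n", "interventional", "observational", "preregistered",
                  "kks", "uoe", "uoe_and_kks", "on_ctgov", "on_drks"),
      n = c(n_total,
            sum(!df$observational, na.rm = TRUE),
            sum(df$observational, na.rm = TRUE),
            sum(df$preregistered == "pre", na.rm = TRUE),
            sum(df$kks_active, na.rm = TRUE),
            sum(df$uoe_active, na.rm = TRUE),
            sum(df$uoe_active & df$kks_active, na.rm = TRUE),
            sum(df$on_ctgov, na.rm = TRUE),
            sum(df$on_drks, na.rm = TRUE)),
      denom = c(rep(n_total, 3), known_pre, rep(n_total, 5))
    ) |>
      dplyr::mutate(pct = pct_of(.data$n, .data$denom))
  }
  date_summary <- function(df, scope) {
    d <- df$start_date[!is.na(df$start_date)]
    tibble(scope = scope,
           mean_start_date = mean(d),
           sd_days = sd(as.numeric(d)))
  }

  overall <- one_scope(trials)
  out <- dplyr::select(overall, "measure", overall_n = "n",
                       overall_pct = "pct")
  dates <- date_summary(trials, "overall")
  if (!is.null(sample_ids)) {
    smp <- trials[trials$trial_id %in% sample_ids, , drop = FALSE]
    s <- one_scope(smp)
    # sample share of the overall database rather than 100%
    s$pct[s$measure == "n"] <- pct_of(nrow(smp), nrow(trials))
    out$sample_n <- s$n
    out$sample_pct <- s$pct
    dates <- dplyr::bind_rows(dates, date_summary(smp, "sample"))
  }
  attr(out, "start_date_summary") <- dates
  out
}

#' @rdname build_descriptive_table
#' @param table Result of [build_descriptive_table()].
#' @export
format_descriptive_table <- function(table) {
  num <- function(x) ifelse(is.na(x), "",
                            format(round_half_up(x, 2), nsmall = 2,
                                   trim = TRUE))
  out <- dplyr::mutate(table, dplyr::across(dplyr::ends_with("_pct"), num))
  dates <- attr(table, "start_date_summary")
  if (!is.null(dates)) {
    attr(out, "start_date_summary") <- dplyr::mutate(
      dates,
      label = sprintf("%s (%s)", format(.data$mean_start_date, "%Y-%m-%d"),
                      num(.data$sd_days)))
  }
  out
}

#' Cross-table of manually found articles vs registry references
#'
#' Compares, per trial, whether a results article was found by manual search
#' with how the registry entry's reference list relates to it: the `Same`
#' article, `Additional` articles, only `Related` articles (not reporting the
#' trial's results), or `None`. The derived count of trials referencing at
#' least one results article is `Same(yes) + Additional(yes) +
#' Additional(no)` — registry-referenced results articles exist in exactly
#' those cells.
#'
#' @param manual Tibble `trial_id`, `article_found` (logical).
#' @param references Tibble `trial_id`, `reference_category` in
#'   `c("Same", "Additional", "Related", "None")`.
#' @return List: `table` (2x4 count tibble, rows `article_found` yes/no) and
#'   `n_results_referencing` (derived count).
#' @export
compare_article_references <- function(manual, references) {
  assert_columns(manual, c("trial_id", "article_found"), "manual")
  assert_columns(references, c("trial_id", "reference_category"),
                 "references")
  bad <- setdiff(references$reference_category,
                 c("Same", "Additional", "Related", "None"))
  if (length(bad) > 0) {
    stop("unknown reference categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  orphans <- c(setdiff(manual$trial_id, references$trial_id),
               setdiff(references$trial_id, manual$trial_id))
  if (length(orphans) > 0) {
    stop("trial keys present on one side only: ",
         paste(head(orphans, 5), collapse = ", "),
         if (length(orphans) > 5) " ..." else "", call. = FALSE)
  }
  df <- dplyr::inner_join(manual, references, by = "trial_id")
  levels <- c("Same", "Additional", "Related", "None")
  tab <- df |>
    dplyr::count(article_found = ifelse(.data$article_found, "yes", "no"),
                 reference_category = factor(.data$reference_category,
                                             levels = levels),
                 .drop = FALSE, name = "n") |>
    tidyr::pivot_wider(names_from = "reference_category", values_from = "n",
                       values_fill = 0L) |>
    dplyr::arrange(dplyr::desc(.data$article_found))
  n_ref <- tab$Same[tab$article_found == "yes"] +
    tab$Additional[tab$article_found == "yes"] +
    tab$Additional[tab$article_found == "no"]
  list(table = tab, n_results_referencing = as.integer(n_ref))
}

#' Run the full pipeline on simulated or supplied exports
#'
#' Orchestrates ingest, deduplication, classification, sampling, annotation
#' scoring, model fitting and descriptive reporting with per-stage row counts
#' in a manifest. Intended both as the one-call entry point for a complete
#' synthetic-study run and as a template for assembling the stages by hand.
#'
#' @param config A [generator_config()] for the simulated inputs.
#' @param seed Integer seed governing generation, matcher training, sampling.
#' @param sample_n Size of the stratified manual-inspection sample.
#' @param threshold Match-probability threshold for the classifier stage.
#' @param outdir Optional directory; when given, stage outputs are written as
#'   CSVs there.
#' @return List with `records`, `trials` (flagged unified trials), `sample`,
#'   `scores`, `fits` (model battery on the pre-registration outcome),
#'   `descriptive`, `linkage_metrics` and `manifest` (per-stage counts).
#' @export
run_pipeline <- function(config = generator_config(), seed = 1L,
                         sample_n = 200L, threshold = 0.5, outdir = NULL) {
  manifest <- list()
  sim <- simulate_registry(config, seed = seed)
  records <- harmonize_simulation(sim)
  manifest$records_ingested <- nrow(records)

  train_sim <- simulate_registry(generator_config(
    n_trials = max(300L, config$n_trials %/% 4L)), seed = seed + 1L)
  matcher <- train_matcher_from_sim(train_sim, seed = seed + 2L)
  dd <- dedupe_trials(records, matcher, threshold = threshold)
  manifest$trials_after_dedupe <- nrow(dd$trials)
  metrics <- pairwise_linkage_metrics(dd$clusters, sim$truth$records)

  flagged <- classify_trials(dd$trials)
  excl <- exclude_by_study_type(flagged)
  manifest$excluded_by_study_type <- sum(excl$tally$n)
  manifest$trials_analysable <- excl$remaining

  smp <- stratified_sample(excl$trials, n = min(sample_n, excl$remaining),
                           seed = seed + 3L)
  manifest$sample_drawn <- nrow(smp)

  ann <- simulate_annotations(smp, config, seed = seed + 4L)
  scores <- aggregate_quality(ann$annotations, ann$outcomes)
  smp_scored <- dplyr::left_join(
    smp, scores[, c("trial_id", "aggregate_fraction")], by = "trial_id")
  smp_scored <- simulate_availability(smp_scored, config, seed = seed + 5L)

  fits <- purrr::map(model_battery("preregistered",
                                   filter = filter_after_2008()),
                     ~ fit_trial_model(excl$trials, .x))
  descriptive <- build_descriptive_table(excl$trials,
                                         sample_ids = smp$trial_id)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(records, file.path(outdir, "harmonized_records.csv"),
                     progress = FALSE)
    readr::write_csv(flagged, file.path(outdir, "flagged_trials.csv"),
                     progress = FALSE)
    readr::write_csv(smp_scored, file.path(outdir, "sample_scored.csv"),
                     progress = FALSE)
    readr::write_csv(descriptive, file.path(outdir, "descriptive_table.csv"),
                     progress = FALSE)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  list(records = records, trials = flagged, sample = smp_scored,
       scores = scores, fits = fits, descriptive = descriptive,
       linkage_metrics = metrics, manifest = manifest)
}

#' Train a matcher from a simulation with ground truth
#'
#' Builds labeled pairs from a simulated registry scenario — ID-linked and
#' blocked candidate pairs labeled by the planted cluster assignment — and
#' trains the random-forest matcher on them.
#'
#' @param sim Result of [simulate_registry()].
#' @param seed Seed for forest training.
#' @param records Optional pre-harmonized record table for `sim`.
#' @return A `ctrq_matcher`.
#' @export
train_matcher_from_sim <- function(sim, seed = 1L, records = NULL) {
  records <- records %||% harmonize_simulation(sim)
  pairs <- dplyr::bind_rows(
    link_by_ids(records)[, c("id1", "id2")],
    generate_candidates(records)
  ) |> dplyr::distinct()
  feats <- pair_features(records, pairs)
  truth <- sim$truth$records
  lab <- truth$trial_uid[match(pairs$id1, truth$record_id)] ==
    truth$trial_uid[match(pairs$id2, truth$record_id)]
  train_matcher(feats, lab, seed = seed)
}
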