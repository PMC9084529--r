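#' Registration-quality rubric
#'
#' @description
#' A deterministic scoring engine for an eight-category registration-quality
#' rubric derived from STROBE, CONSORT and the WHO Trial Registration Data
#' Set. The rated categories and attainable points are:
#'
#' | category          | points | notes                                          |
#' |-------------------|--------|------------------------------------------------|
#' | title             | 0–1    | intervention waived for observational studies  |
#' | design            | 0–1    | adequate and internally consistent             |
#' | sample size       | 0–1    | given or not                                   |
#' | masking           | 0–2    | n/a for observational and open-label trials    |
#' | inclusion criteria| 0–2    | measures required for all key criteria         |
#' | primary outcome   | 0–5    | five elements, see [score_outcome()]           |
#' | secondary outcome | 0–5    | most detailed outcome, similarity rule         |
#' | intervention      | 0–2    | n/a for observational studies                  |
#'
#' Funding, contact details and result data are represented in the codebook
#' but carry no rated criteria. The rubric consumes structured annotations
#' (human judgments encoded as flags), not free text.
#'
#' @name rubric
NULL

#' Score the study title
#'
#' One point if the intervention (waived for observational studies), the
#' indication, and the outcome are all given in the title, and the titled
#' outcome is one of the primary outcomes; otherwise zero. Unspecific
#' outcomes such as "efficacy" are not penalized in themselves.
#'
#' @param annotation Tibble with logical columns `observational`,
#'   `title_has_intervention` (may be `NA` when waived),
#'   `title_has_indication`, `title_has_outcome`, `title_outcome_is_primary`.
#' @return Integer vector in `{0, 1}`.
#' @export
score_title <- function(annotation) {
  intervention_ok <- annotation$observational |
    is.na(annotation$title_has_intervention) |
    annotation$title_has_intervention
  ok <- intervention_ok &
    annotation$title_has_indication %in% TRUE &
    annotation$title_has_outcome %in% TRUE &
    annotation$title_outcome_is_primary %in% TRUE
  as.integer(ok)
}

#' Score the trial-design description
#'
#' One point for an adequate description; zero if the information is
#' insufficient or implies internal inconsistencies (e.g. registered as open
#' and non-parallel while the title claims double-blind parallel).
#'
#' @param annotation Tibble with logical columns `design_adequate`,
#'   `design_consistent`.
#' @return Integer vector in `{0, 1}`.
#' @export
score_design <- function(annotation) {
  as.integer(annotation$design_adequate %in% TRUE &
               annotation$design_consistent %in% TRUE)
}

#' Score the sample size
#'
#' One point if a sample size is given, zero otherwise.
#'
#' @param annotation Tibble with logical column `sample_size_given`.
#' @return Integer vector in `{0, 1}`.
#' @export
score_sample_size <- function(annotation) {
  as.integer(annotation$sample_size_given %in% TRUE)
}

#' Score the masking description
#'
#' Not rated (`NA`) for observational and open-label trials. Otherwise: one
#' point for a description of who was blinded ("double blind" suffices), two
#' points if the responsible party is also given, zero for insufficient
#' information.
#'
#' @param annotation Tibble with logical columns `observational`,
#'   `open_label`, `masking_who_described`, `masking_party_given`.
#' @return Integer vector in `{0, 1, 2}` with `NA` for not-applicable trials.
#' @export
score_masking <- function(annotation) {
  na <- annotation$observational %in% TRUE | annotation$open_label %in% TRUE
  pts <- ifelse(annotation$masking_who_described %in% TRUE,
                1L + (annotation$masking_party_given %in% TRUE), 0L)
  ifelse(na, NA_integer_, as.integer(pts))
}

#' Score the inclusion criteria
#'
#' Zero points if the criteria by which patients were screened are unclear;
#' one point for clear criteria; two points if diagnoses and accompanying
#' measures (e.g. cutpoints with units) are given for all key criteria.
#'
#' @param annotation Tibble with logical columns `inclusion_criteria_clear`,
#'   `inclusion_all_measured`.
#' @return Integer vector in `{0, 1, 2}`.
#' @export
score_inclusion <- function(annotation) {
  ifelse(annotation$inclusion_criteria_clear %in% TRUE,
         1L + (annotation$inclusion_all_measured %in% TRUE), 0L) |>
    as.integer()
}

#' Score a registered outcome on the five-element scale
#'
#' Zero points for insufficient information; otherwise one point each for
#' giving the type of outcome, naming a measure (e.g. a named instrument),
#' giving a time frame, giving a metric (e.g. "change from baseline"), and
#' giving an aggregation method (e.g. mean, proportion of patients). Two
#' leniency rules: survival outcomes are not penalized for a missing
#' aggregation method (Kaplan–Meier plots are the standard), and the metric
#' point is granted when the metric is inferable from the other elements or
#' no metric is sensible for the outcome.
#'
#' @param outcomes Tibble with logical columns `insufficient`, `has_type`,
#'   `has_measure`, `has_timeframe`, `has_metric`, `has_aggregation`,
#'   `is_survival`, `metric_inferable_or_moot`.
#' @return Integer vector in `0:5`.
#' @export
score_outcome <- function(outcomes) {
  metric <- outcomes$has_metric %in% TRUE |
    outcomes$metric_inferable_or_moot %in% TRUE
  aggregation <- outcomes$has_aggregation %in% TRUE |
    outcomes$is_survival %in% TRUE
  pts <- (outcomes$has_type %in% TRUE) +
    (outcomes$has_measure %in% TRUE) +
    (outcomes$has_timeframe %in% TRUE) +
    metric + aggregation
  ifelse(outcomes$insufficient %in% TRUE, 0L, as.integer(pts))
}

#' Select which outcomes to rate for each trial
#'
#' Trials may register many outcomes; only the outcome with the most detailed
#' registration is rated per role. Secondary outcomes flagged as highly
#' similar to a primary outcome are skipped where possible — when every
#' secondary is similar, the best of them is rated anyway. Ties break by
#' annotation order.
#'
#' @param outcomes Outcome-annotation tibble with `trial_id`, `role`
#'   (`"primary"`/`"secondary"`), the flag columns of [score_outcome()], and
#'   for secondaries `similar_to_primary`.
#' @return Tibble `trial_id`, `role`, selected row's flags and its
#'   `outcome_points`.
#' @export
select_rated_outcomes <- function(outcomes) {
  if (nrow(outcomes) == 0) {
    return(dplyr::mutate(outcomes, outcome_points = integer(0)))
  }
  stopifnot(all(outcomes$role %in% c("primary", "secondary")))
  scored <- outcomes |>
    dplyr::mutate(outcome_points = score_outcome(outcomes),
                  .row = dplyr::row_number())
  pick_one <- function(df, key) {
    if (key$role == "secondary") {
      dissimilar <- !df$similar_to_primary %in% TRUE
      if (any(dissimilar)) df <- df[dissimilar, , drop = FALSE]
    }
    df[order(-df$outcome_points, df$.row)[1], , drop = FALSE]
  }
  scored |>
    dplyr::group_by(.data$trial_id, .data$role) |>
    dplyr::group_modify(pick_one) |>
    dplyr::ungroup() |>
    dplyr::select(-".row")
}

#' Score the intervention description
#'
#' Not rated (`NA`) for observational studies. Zero points for insufficient
#' information; one point if the active ingredient (or, for
#' non-pharmacological studies, the intervention type) is given; two points
#' if the dosage or a detailed description is also given. Control arms are
#' not rated.
#'
#' @param annotation Tibble with logical columns `observational`,
#'   `intervention_insufficient`, `intervention_type_given`,
#'   `intervention_detail_given`.
#' @return Integer vector in `{0, 1, 2}` with `NA` where not applicable.
#' @export
score_intervention <- function(annotation) {
  na <- annotation$observational %in% TRUE
  pts <- ifelse(annotation$intervention_insufficient %in% TRUE, 0L,
                ifelse(annotation$intervention_type_given %in% TRUE,
                       1L + (annotation$intervention_detail_given %in% TRUE),
                       0L))
  ifelse(na, NA_integer_, as.integer(pts))
}

rubric_category_max <- function() {
  c(title = 1L, design = 1L, sample_size = 1L, masking = 2L, inclusion = 2L,
    primary_outcome = 5L, secondary_outcome = 5L, intervention = 2L)
}

validate_annotations <- function(annotation) {
  assert_columns(annotation, c(
    "trial_id", "observational", "open_label",
    "title_has_intervention", "title_has_indication", "title_has_outcome",
    "title_outcome_is_primary", "design_adequate", "design_consistent",
    "sample_size_given", "masking_who_described", "masking_party_given",
    "inclusion_criteria_clear", "inclusion_all_measured",
    "intervention_insufficient", "intervention_type_given",
    "intervention_detail_given"), "quality annotations")
  if (anyDuplicated(annotation$trial_id)) {
    stop("one annotation row per trial_id expected", call. = FALSE)
  }
  invisible(annotation)
}

#' Aggregate per-category scores into a quality score
#'
#' Computes every category score for each annotated trial and the aggregate
#' quality fraction: the unweighted mean over applicable categories of
#' points/attainable points ("mean of fractions"). Masking is not applicable
#' for observational and open-label trials, the intervention category for
#' observational trials, and an outcome role with no annotated outcome drops
#' out of the denominator. The alternative aggregate (total points over total
#' attainable points) is available via `method = "points_ratio"`.
#'
#' @param annotation One row per trial (see [validate_annotations()] columns).
#' @param outcomes Outcome-annotation tibble (long format, possibly several
#'   outcomes per trial and role); the most detailed outcome per role is
#'   rated via [select_rated_outcomes()].
#' @param method `"mean_of_fractions"` (default) or `"points_ratio"`.
#' @return Tibble with one row per trial: `<category>_points` and
#'   `<category>_max` for the eight categories (`NA` points where not
#'   applicable) and `aggregate_fraction` in `[0, 1]`.
#' @examples
#' ann <- tibble::tibble(
#'   trial_id = "T1", observational = FALSE, open_label = TRUE,
#'   title_has_intervention = TRUE, title_has_indication = TRUE,
#'   title_has_outcome = TRUE, title_outcome_is_primary = TRUE,
#'   design_adequate = TRUE, design_consistent = TRUE,
#'   sample_size_given = TRUE,
#'   masking_who_described = NA, masking_party_given = NA,
#'   inclusion_criteria_clear = TRUE, inclusion_all_measured = FALSE,
#'   intervention_insufficient = FALSE, intervention_type_given = TRUE,
#'   intervention_detail_given = TRUE)
#' out <- tibble::tibble(
#'   trial_id = c("T1", "T1"), role = c("primary", "secondary"),
#'   insufficient = FALSE, has_type = TRUE, has_measure = c(TRUE, FALSE),
#'   has_timeframe = TRUE, has_metric = c(TRUE, FALSE),
#'   has_aggregation = c(TRUE, FALSE), is_survival = FALSE,
#'   metric_inferable_or_moot = c(FALSE, TRUE), similar_to_primary = FALSE)
#' aggregate_quality(ann, out)$aggregate_fraction
#' @export
aggregate_quality <- function(annotation, outcomes,
                              method = c("mean_of_fractions",
                                         "points_ratio")) {
  method <- match.arg(method)
  validate_annotations(annotation)

  picked <- select_rated_outcomes(outcomes)
  get_role <- function(role) {
    sub <- picked[picked$role == role, c("trial_id", "outcome_points")]
    out <- sub$outcome_points[match(annotation$trial_id, sub$trial_id)]
    as.integer(out)
  }

  maxes <- rubric_category_max()
  scores <- tibble(
    trial_id = annotation$trial_id,
    title_points = score_title(annotation),
    design_points = score_design(annotation),
    sample_size_points = score_sample_size(annotation),
    masking_points = score_masking(annotation),
    inclusion_points = score_inclusion(annotation),
    primary_outcome_points = get_role("primary"),
    secondary_outcome_points = get_role("secondary"),
    intervention_points = score_intervention(annotation)
  )
  for (cat in names(maxes)) {
    scores[[paste0(cat, "_max")]] <- maxes[[cat]]
  }

  pts <- as.matrix(scores[paste0(names(maxes), "_points")])
  mx <- matrix(rep(maxes, each = nrow(scores)), nrow = nrow(scores))
  applicable <- !is.na(pts)
  frac <- pts / mx
  agg <- if (method == "mean_of_fractions") {
    rowSums(frac, na.rm = TRUE) / rowSums(applicable)
  } else {
    rowSums(pts, na.rm = TRUE) / rowSums(mx * applicable)
  }
  dplyr::mutate(scores, aggregate_fraction = agg)
}

#' Long per-criterion score fractions
#'
#' Reshapes an [aggregate_quality()] result into one row per trial and
#' applicable category with the score fraction — the shape consumed by
#' [criterion_time_trend()].
#'
#' @param scores Result of [aggregate_quality()].
#' @return Tibble `trial_id`, `criterion`, `points`, `max_points`,
#'   `fraction`.
#' @export
quality_scores_long <- function(scores) {
  cats <- names(rubric_category_max())
  purrr::map_dfr(cats, function(cat) {
    tibble(trial_id = scores$trial_id,
           criterion = cat,
           points = scores[[paste0(cat, "_points")]],
           max_points = scores[[paste0(cat, "_max")]])
  }) |>
    dplyr::filter(!is.na(.data$points)) |>
    dplyr::mutate(fraction = .data$points / .data$max_points)
}

#' Read quality / outcome annotation CSV files
#'
#' Annotation files follow the codebook shipped at
#' `system.file("extdata", "annotation_codebook.csv", package =
#' "ctrquality")`: one row per trial with logical flag columns (empty cells
#' are `NA`, meaning not applicable / not judged), and a companion
#' long-format outcome file with one row per annotated outcome.
#'
#' @param path CSV file path.
#' @return A tibble with flag columns parsed as logical.
#' @export
read_quality_annotations <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    trial_id = readr::col_character(),
    comment = readr::col_character(),
    .default = readr::col_logical()
  ), na = c("", "NA"), progress = FALSE, show_col_types = FALSE)
  validate_annotations(df)
  df
}

#' @rdname read_quality_annotations
#' @export
read_outcome_annotations <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    trial_id = readr::col_character(),
    role = readr::col_character(),
    comment = readr::col_character(),
    .default = readr::col_logical()
  ), na = c("", "NA"), progress = FALSE, show_col_types = FALSE)
}
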