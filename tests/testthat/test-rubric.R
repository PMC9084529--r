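test_that("the shipped worked examples reproduce their published ratings", {
  outcomes <- read_outcome_annotations(
    file.path(worked_example_dir(), "outcome_examples.csv"))
  got <- setNames(score_outcome(outcomes), outcomes$trial_id)
  expect_equal(got[["NCT00690898"]], 5L)
  expect_equal(got[["ISRCTN43578978"]], 4L)
  expect_equal(got[["NCT01973179"]], 3L)
  expect_equal(got[["NCT01012921"]], 2L)
  expect_equal(got[["DRKS00000025"]], 1L)
  expect_equal(got[["NCT00240214"]], 0L)

  cats <- read_category_examples()
  title <- cats[cats$category == "title", ]
  expect_equal(setNames(score_title(title), title$trial_id),
               c(NCT00044915 = 1L, DRKS00004434 = 0L))
  design <- cats[cats$category == "design", ]
  expect_equal(score_design(design), 0L)
  inclusion <- cats[cats$category == "inclusion", ]
  expect_equal(setNames(score_inclusion(inclusion), inclusion$trial_id),
               c(NCT02320045 = 2L, NCT01374399 = 1L, NCT01458574 = 0L))
  intervention <- cats[cats$category == "intervention", ]
  expect_equal(setNames(score_intervention(intervention),
                        intervention$trial_id),
               c(`EUCTR2007-000010-36` = 2L, NCT03429543 = 1L,
                 NCT01709812 = 0L))
})

test_that("title scoring waives the intervention for observational studies", {
  obs <- full_annotation(observational = TRUE)
  expect_equal(score_title(obs), 1L)
  missing_primary <- dplyr::mutate(full_annotation(),
                                   title_outcome_is_primary = FALSE)
  expect_equal(score_title(missing_primary), 0L)
})

test_that("masking scoring follows the who/party ladder and n/a rules", {
  base <- full_annotation()
  expect_equal(score_masking(base), 2L)
  who_only <- dplyr::mutate(base, masking_party_given = FALSE)
  expect_equal(score_masking(who_only), 1L)  # 'double blind' suffices
  neither <- dplyr::mutate(base, masking_who_described = FALSE,
                           masking_party_given = FALSE)
  expect_equal(score_masking(neither), 0L)
  expect_true(is.na(score_masking(full_annotation(open_label = TRUE))))
  expect_true(is.na(score_masking(full_annotation(observational = TRUE))))
})

test_that("outcome leniency rules substitute for survival and inferable metrics", {
  surv <- full_outcome(points = 5L) |>
    dplyr::mutate(has_aggregation = FALSE, is_survival = TRUE)
  expect_equal(score_outcome(surv), 5L)
  inferable <- full_outcome(points = 5L) |>
    dplyr::mutate(has_metric = FALSE, metric_inferable_or_moot = TRUE)
  expect_equal(score_outcome(inferable), 5L)
  insufficient <- full_outcome(points = 5L) |>
    dplyr::mutate(insufficient = TRUE)
  expect_equal(score_outcome(insufficient), 0L)
})

test_that("outcome selection takes the most detailed outcome and skips similar secondaries", {
  outcomes <- dplyr::bind_rows(
    full_outcome("T1", "primary", 3L),
    full_outcome("T1", "primary", 5L),
    full_outcome("T1", "secondary", 5L, similar_to_primary = TRUE),
    full_outcome("T1", "secondary", 3L)
  )
  picked <- select_rated_outcomes(outcomes)
  expect_equal(
    picked$outcome_points[picked$role == "primary"], 5L)
  expect_equal(
    picked$outcome_points[picked$role == "secondary"], 3L)

  # a sole similar secondary is rated anyway
  sole <- dplyr::bind_rows(
    full_outcome("T2", "primary", 4L),
    full_outcome("T2", "secondary", 2L, similar_to_primary = TRUE))
  picked2 <- select_rated_outcomes(sole)
  expect_equal(picked2$outcome_points[picked2$role == "secondary"], 2L)

  # ties break by annotation order
  tie <- dplyr::bind_rows(
    dplyr::mutate(full_outcome("T3", "primary", 4L), has_timeframe = FALSE,
                  has_aggregation = TRUE),
    full_outcome("T3", "primary", 4L))
  picked3 <- select_rated_outcomes(tie)
  expect_false(picked3$has_timeframe[picked3$role == "primary"])
})

test_that("aggregation averages per-category fractions over applicable categories", {
  ann <- full_annotation()
  outcomes <- dplyr::bind_rows(full_outcome(points = 5L),
                               full_outcome(role = "secondary", points = 5L))
  expect_equal(aggregate_quality(ann, outcomes)$aggregate_fraction, 1)

  zeroed <- dplyr::mutate(
    ann, title_has_outcome = FALSE, title_outcome_is_primary = FALSE,
    design_consistent = FALSE, sample_size_given = FALSE,
    masking_who_described = FALSE, masking_party_given = FALSE,
    inclusion_criteria_clear = FALSE, inclusion_all_measured = FALSE,
    intervention_insufficient = TRUE, intervention_type_given = FALSE,
    intervention_detail_given = FALSE)
  zero_out <- dplyr::bind_rows(full_outcome(points = 0L),
                               full_outcome(role = "secondary", points = 0L))
  expect_equal(aggregate_quality(zeroed, zero_out)$aggregate_fraction, 0)

  # hand-computed open-label vector: mean(1, 1, 1, 0.5, 0.8, 0.6, 1)
  ol <- dplyr::mutate(full_annotation(open_label = TRUE),
                      inclusion_all_measured = FALSE)
  ol_out <- dplyr::bind_rows(full_outcome(points = 4L),
                             full_outcome(role = "secondary", points = 3L))
  sc <- aggregate_quality(ol, ol_out)
  expect_true(is.na(sc$masking_points))
  expect_equal(sc$aggregate_fraction, mean(c(1, 1, 1, 0.5, 0.8, 0.6, 1)),
               tolerance = 1e-12)

  # the points-ratio alternative is available behind the method switch
  sc2 <- aggregate_quality(ol, ol_out, method = "points_ratio")
  expect_equal(sc2$aggregate_fraction, (1 + 1 + 1 + 1 + 4 + 3 + 2) / 17)
})

test_that("toggling observational moves masking and intervention out of the denominator", {
  ann_int <- full_annotation()
  ann_obs <- full_annotation(observational = TRUE)
  outs <- function(id) dplyr::bind_rows(
    full_outcome(id, points = 5L), full_outcome(id, "secondary", 5L))
  sc_int <- aggregate_quality(ann_int, outs("T1"))
  sc_obs <- aggregate_quality(ann_obs, outs("T1"))
  expect_false(is.na(sc_int$masking_points))
  expect_true(is.na(sc_obs$masking_points))
  expect_true(is.na(sc_obs$intervention_points))
  expect_equal(sc_obs$aggregate_fraction, 1)
})

test_that("setting any single positive flag never decreases a score", {
  flag_cols <- c("title_has_intervention", "title_has_indication",
                 "title_has_outcome", "title_outcome_is_primary",
                 "design_adequate", "design_consistent", "sample_size_given",
                 "masking_who_described", "masking_party_given",
                 "inclusion_criteria_clear", "inclusion_all_measured",
                 "intervention_type_given", "intervention_detail_given")
  out_cols <- c("has_type", "has_measure", "has_timeframe", "has_metric",
                "has_aggregation", "is_survival", "metric_inferable_or_moot")
  set.seed(61)
  for (i in 1:30) {
    ann <- full_annotation()
    for (col in flag_cols) ann[[col]] <- runif(1) < 0.5
    outcomes <- dplyr::bind_rows(full_outcome(points = sample(0:5, 1)),
                                 full_outcome(role = "secondary",
                                              points = sample(0:5, 1)))
    base <- aggregate_quality(ann, outcomes)$aggregate_fraction
    for (col in c(flag_cols)) {
      if (isTRUE(ann[[col]])) next
      ann2 <- ann
      ann2[[col]] <- TRUE
      expect_gte(aggregate_quality(ann2, outcomes)$aggregate_fraction, base)
    }
    for (col in out_cols) {
      out2 <- outcomes
      out2[[col]] <- TRUE
      expect_gte(aggregate_quality(ann, out2)$aggregate_fraction, base)
    }
  }
})

test_that("annotation validation flags duplicates and missing columns", {
  ann <- dplyr::bind_rows(full_annotation("T1"), full_annotation("T1"))
  expect_error(aggregate_quality(ann, full_outcome("T1")), "one annotation")
  expect_error(aggregate_quality(full_annotation()[, -2], full_outcome()),
               "missing required")
})

test_that("long score reshaping drops non-applicable categories", {
  ann <- full_annotation(observational = TRUE)
  outs <- dplyr::bind_rows(full_outcome(points = 5L),
                           full_outcome(role = "secondary", points = 4L))
  long <- quality_scores_long(aggregate_quality(ann, outs))
  expect_false(any(long$criterion %in% c("masking", "intervention")))
  expect_equal(sort(unique(long$criterion)),
               sort(c("title", "design", "sample_size", "inclusion",
                      "primary_outcome", "secondary_outcome")))
  expect_equal(long$fraction[long$criterion == "secondary_outcome"], 0.8)
})
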