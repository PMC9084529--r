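test_that("multi-registration rate zero yields only singleton clusters", {
  cfg <- generator_config(n_trials = 80, multi_registration_rate = 0,
                          ictrp_internal_dup_rate = 0)
  sim <- simulate_registry(cfg, seed = 81)
  expect_equal(nrow(sim$truth$records), 80)
  expect_equal(max(table(sim$truth$records$trial_uid)), 1)
})

test_that("record counts match the planted duplication ground truth exactly", {
  cfg <- generator_config(n_trials = 100)
  sim <- simulate_registry(cfg, seed = 82)
  n_records <- nrow(sim$aact) + nrow(sim$drks) + nrow(sim$ictrp)
  expect_equal(n_records, nrow(sim$truth$records))
  expect_equal(dplyr::n_distinct(sim$truth$records$trial_uid), 100)
  expect_equal(sum(sim$truth$trials$n_records), n_records)
})

test_that("zero title-edit rate leaves duplicate titles byte-identical", {
  cfg <- generator_config(n_trials = 60, title_edit_rate = 0,
                          multi_registration_rate = 1)
  sim <- simulate_registry(cfg, seed = 83)
  recs <- harmonize_simulation(sim)
  dup <- sim$truth$records |>
    dplyr::inner_join(sim$truth$records, by = "trial_uid",
                      relationship = "many-to-many") |>
    dplyr::filter(.data$record_id.x < .data$record_id.y)
  t1 <- recs$title[match(dup$record_id.x, recs$record_id)]
  t2 <- recs$title[match(dup$record_id.y, recs$record_id)]
  expect_true(all(t1 == t2))
  expect_true(all(title_similarity(t1, t2) == 1))
})

test_that("the same seed gives byte-identical exports", {
  cfg <- generator_config(n_trials = 60)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_registry_exports(simulate_registry(cfg, seed = 84), d1)
  p2 <- write_registry_exports(simulate_registry(cfg, seed = 84), d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  }
  # and a different seed genuinely differs
  p3 <- write_registry_exports(simulate_registry(cfg, seed = 85),
                               withr::local_tempdir())
  expect_false(identical(readLines(p1[["aact"]]), readLines(p3[["aact"]])))
})

test_that("zero-noise annotations reproduce the baseline aggregate exactly", {
  cfg <- generator_config(
    n_trials = 40,
    quality_model = list(baseline = 0.7, year_slope = 0, year0 = 2012L,
                         observational = 0, on_ctgov = 0, on_drks = 0,
                         uoe_active = 0, kks_active = 0, noise_sd = 0))
  trials <- simulate_trial_table(cfg, seed = 86)
  ann <- simulate_annotations(trials, cfg, seed = 87)
  scored <- aggregate_quality(ann$annotations, ann$outcomes)
  expect_equal(unique(round(scored$aggregate_fraction, 10)), 0.7)
})

test_that("scored aggregates equal the allocated fractions the generator reports", {
  cfg <- generator_config(n_trials = 150)
  trials <- simulate_trial_table(cfg, seed = 88)
  ann <- simulate_annotations(trials, cfg, seed = 89)
  scored <- aggregate_quality(ann$annotations, ann$outcomes)
  merged <- dplyr::inner_join(scored, ann$truth, by = "trial_id")
  expect_equal(merged$aggregate_fraction, merged$allocated_fraction,
               tolerance = 1e-9)
  # quantization error of the integer grid stays small
  expect_lt(max(abs(merged$allocated_fraction - merged$true_fraction)),
            0.05)
})

test_that("a planted 0.02/yr slope moves the cohort mean by about 0.2 per decade", {
  cfg <- generator_config(
    n_trials = 5000, year_range = c(2005L, 2015L),
    quality_model = list(baseline = 0.55, year_slope = 0.02, year0 = 2010L,
                         observational = 0, on_ctgov = 0, on_drks = 0,
                         uoe_active = 0, kks_active = 0, noise_sd = 0.05))
  trials <- simulate_trial_table(cfg, seed = 90)
  ann <- simulate_annotations(trials, cfg, seed = 91)
  scored <- aggregate_quality(ann$annotations, ann$outcomes)
  df <- dplyr::inner_join(scored, trials, by = "trial_id")
  first <- mean(df$aggregate_fraction[df$start_year == 2005])
  last <- mean(df$aggregate_fraction[df$start_year == 2015])
  expect_gt(last - first, 0.18)
  expect_lt(last - first, 0.22)
})

test_that("observational trials get intervention and masking not applicable", {
  cfg <- generator_config(n_trials = 400, observational_rate = 0.25)
  trials <- simulate_trial_table(cfg, seed = 92)
  ann <- simulate_annotations(trials, cfg, seed = 93)
  na_rate <- mean(is.na(ann$annotations$intervention_type_given))
  half <- 1.96 * sqrt(0.25 * 0.75 / 400)
  expect_lt(abs(na_rate - 0.25), half + 0.01)
  expect_true(all(is.na(
    ann$annotations$masking_who_described[ann$annotations$observational])))
})

test_that("article availability follows the planted logistic model", {
  flat <- generator_config(
    n_trials = 4000,
    article_model = c(intercept = 0, observational = 0, on_ctgov = 0,
                      on_drks = 0, uoe_active = 0, kks_active = 0,
                      registration_year = 0))
  trials <- simulate_trial_table(flat, seed = 94)
  avail <- simulate_availability(trials, flat, seed = 95)
  half <- 1.96 * sqrt(0.25 / 4000)
  expect_lt(abs(mean(avail$article_available) - 0.5), half + 0.005)

  base43 <- generator_config(
    n_trials = 5000,
    article_model = c(intercept = qlogis(0.43), observational = 0,
                      on_ctgov = 0, on_drks = 0, uoe_active = 0,
                      kks_active = 0, registration_year = 0))
  avail43 <- simulate_availability(simulate_trial_table(base43, seed = 96),
                                   base43, seed = 97)
  half43 <- 1.96 * sqrt(0.43 * 0.57 / 5000)
  expect_lt(abs(mean(avail43$article_available) - 0.43), half43 + 0.005)

  falling <- generator_config(
    n_trials = 5000,
    article_model = c(intercept = 0, observational = 0, on_ctgov = 0,
                      on_drks = 0, uoe_active = 0, kks_active = 0,
                      registration_year = -1.5))
  tr <- simulate_trial_table(falling, seed = 98)
  av <- simulate_availability(tr, falling, seed = 99)
  early <- mean(av$article_available[av$registration_year ==
                                       min(av$registration_year)])
  late <- mean(av$article_available[av$registration_year ==
                                      max(av$registration_year)])
  expect_lt(late, early)
})

test_that("generator config validates its fields", {
  expect_error(generator_config(nonsense_field = 1), "unknown")
  expect_error(generator_config(n_trials = 0), "n_trials")
  cfg <- generator_config(multi_registration_rate = 0.5)
  expect_equal(cfg$multi_registration_rate, 0.5)
})
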