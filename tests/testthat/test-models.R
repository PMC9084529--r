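test_that("2-SD standardization yields mean 0 and SD one half", {
  x <- standardize_2sd(c(0, 0, 1, 1))
  expect_equal(mean(x), 0)
  expect_equal(sd(x), 0.5)
  expect_equal(x, c(-0.433, -0.433, 0.433, 0.433), tolerance = 1e-3)

  y <- standardize_2sd(c(1, 2, 3, 4, 5))
  expect_equal(y, c(-0.632, -0.316, 0, 0.316, 0.632), tolerance = 1e-3)

  # a standardized vector is a fixed point: mean 0, sd 0.5 -> divide by 1
  expect_equal(standardize_2sd(y), y, tolerance = 1e-12)
  expect_error(standardize_2sd(rep(3, 10)), "distinct")
})

test_that("noiseless planted linear data is recovered to numerical precision", {
  set.seed(71)
  n <- 300
  df <- tibble::tibble(
    trial_id = as.character(seq_len(n)),
    observational = runif(n) < 0.3,
    on_ctgov = runif(n) < 0.6,
    kks_active = runif(n) < 0.3,
    registration_year = sample(2005:2020, n, replace = TRUE))
  ry <- standardize_2sd(df$registration_year)
  df$quality_fraction <- 0.7 - 0.1 * df$observational + 0.05 * df$on_ctgov -
    0.03 * df$kks_active + 0.08 * ry
  fit <- fit_trial_model(df, model_spec(
    "quality_fraction",
    c("observational", "on_ctgov", "kks_active", "registration_year")))
  # a noiseless response makes summary.lm warn about the perfect fit
  td <- suppressWarnings(tidy(fit))
  expect_equal(td$estimate[td$term == "observational"], -0.1,
               tolerance = 1e-10)
  expect_equal(td$estimate[td$term == "registration_year"], 0.08,
               tolerance = 1e-10)
  expect_equal(suppressWarnings(glance(fit))$r.squared, 1,
               tolerance = 1e-10)
})

test_that("a planted observational odds ratio of 0.45 is recovered at n = 20000", {
  cfg <- generator_config(
    n_trials = 20000,
    prereg_model = c(intercept = 0.65, observational = log(0.45),
                     on_ctgov = 0.16, on_drks = -0.4, uoe_active = -0.75,
                     kks_active = -0.32, registration_year = -0.14))
  tab <- simulate_trial_table(cfg, seed = 72)
  fit <- fit_trial_model(tab, model_spec(
    "preregistered",
    c("uoe_active", "kks_active", "registration_year", "sample_size",
      "observational", "on_ctgov", "on_drks")))
  or <- tidy(fit)$estimate[tidy(fit)$term == "observational"]
  expect_gt(or, 0.40)
  expect_lt(or, 0.51)
  # odds-ratio / coefficient duality
  expect_equal(log(or), coef(fit$fit)[["observational"]], tolerance = 1e-12)
})

test_that("the after-2008 filter drops boundary rows from the reported n", {
  df <- tibble::tibble(
    registration_date = as.Date(c("2008-12-31", "2009-01-01", "2015-06-01",
                                  NA)),
    preregistered = c("pre", "retro", "pre", "pre"),
    observational = c(FALSE, TRUE, FALSE, TRUE))
  fit <- fit_trial_model(df, model_spec("preregistered", "observational",
                                        filter = filter_after_2008()))
  expect_equal(fit$n_obs, 2)
})

test_that("incomplete rows are dropped per model and counted", {
  df <- tibble::tibble(
    preregistered = c(TRUE, FALSE, TRUE, NA, TRUE),
    observational = c(TRUE, FALSE, NA, TRUE, FALSE),
    registration_year = c(2010L, 2011L, 2012L, 2013L, 2014L))
  fit <- fit_trial_model(df, model_spec("preregistered",
                                        c("observational",
                                          "registration_year")))
  expect_equal(fit$n_obs, 3)
  expect_equal(fit$n_dropped, 2)
})

test_that("perfect separation is flagged rather than silently accepted", {
  df <- tibble::tibble(
    preregistered = rep(c(TRUE, FALSE), each = 20),
    observational = rep(c(FALSE, TRUE), each = 20))
  fit <- fit_trial_model(df, model_spec("preregistered", "observational"))
  expect_true(fit$separation)
})

test_that("model specs validate predictors, families and empty inputs", {
  expect_error(model_spec("preregistered", "no_such_predictor"), "unknown")
  expect_error(model_spec("quality_fraction", "kks_active",
                          family = "logistic"), "linear")
  expect_error(model_spec("preregistered", "kks_active", family = "linear"),
               "logistic")
  df <- tibble::tibble(registration_date = as.Date("2001-01-01"),
                       preregistered = TRUE, observational = FALSE)
  expect_error(fit_trial_model(df, model_spec(
    "preregistered", "observational", filter = filter_after_2008())),
    "no rows")
  battery <- model_battery("preregistered")
  expect_named(battery, c("model1", "model2", "model3", "model4"))
  expect_equal(battery$model3$predictors, "kks_active")
})

test_that("criterion time trends recover planted slopes per registry group", {
  set.seed(73)
  years <- 2006:2020
  make_group <- function(group, slope) {
    purrr::map_dfr(years, function(y) {
      tibble::tibble(
        group = group, criterion = "primary_outcome", start_year = y,
        fraction = pmin(1, pmax(0, 0.5 + slope * (y - 2006) +
                                  rnorm(40, 0, 0.05))))
    })
  }
  scores <- dplyr::bind_rows(make_group("ClinicalTrials.gov", 0.02),
                             make_group("DRKS", 0))
  trend <- criterion_time_trend(scores)
  up <- trend[trend$group == "ClinicalTrials.gov", ]
  flat <- trend[trend$group == "DRKS", ]
  expect_gt(up$slope, 0)
  expect_true(up$significant)
  expect_lt(abs(flat$slope), 0.01)
  expect_false(flat$significant)
})

test_that("criteria with too few distinct years are skipped with a warning", {
  scores <- tibble::tibble(group = "X", criterion = "design",
                           start_year = c(2010L, 2011L),
                           fraction = c(0.5, 0.6))
  expect_warning(trend <- criterion_time_trend(scores), "insufficient")
  expect_true(is.na(trend$slope))
})
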