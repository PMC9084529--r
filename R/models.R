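#' Two-standard-deviation standardization
#'
#' Centers a numeric predictor and divides by twice its sample standard
#' deviation, so that coefficients of continuous predictors are comparable in
#' magnitude to those of untransformed binary predictors. The output has mean
#' 0 and sample standard deviation 0.5.
#'
#' @param values Numeric vector with at least two distinct finite values.
#' @return Standardized numeric vector (`NA`s pass through).
#' @examples
#' standardize_2sd(c(1, 2, 3, 4, 5))
#' @export
standardize_2sd <- function(values) {
  v <- values[is.finite(values)]
  if (length(unique(v)) < 2) {
    stop("standardize_2sd needs at least two distinct values (zero SD)",
         call. = FALSE)
  }
  (values - mean(v)) / (2 * sd(v))
}

#' Specify a trial regression model
#'
#' The model families mirror the analysis design: logistic regression for
#' pre-registration and article availability, linear regression for the
#' aggregate registration-quality fraction. Registration year and sample size
#' are 2-SD standardized before fitting; binary predictors enter untouched.
#' Four canonical variants are used throughout: Model 1 (University of
#' Excellence only), Model 2 (+ year, sample size, study type, registries),
#' and Models 3/4 analogously for KKS.
#'
#' @param outcome One of `"preregistered"`, `"quality_fraction"`,
#'   `"article_available"`.
#' @param predictors Subset of `uoe_active`, `kks_active`,
#'   `registration_year`, `sample_size`, `observational`, `on_ctgov`,
#'   `on_drks`.
#' @param family `"logistic"` or `"linear"`; defaults to logistic for the
#'   binary outcomes and linear for `quality_fraction`.
#' @param filter Optional predicate `function(data) -> logical` applied
#'   before fitting. For pre-registration the conventional filter is
#'   [filter_after_2008()], restricting to registration dates after 2008
#'   (i.e. on or after 2009-01-01), the year the DRKS was introduced.
#' @param standardize Predictors to 2-SD standardize.
#' @return A `ctrq_model_spec` list.
#' @export
model_spec <- function(outcome = c("preregistered", "quality_fraction",
                                   "article_available"),
                       predictors,
                       family = NULL,
                       filter = NULL,
                       standardize = c("registration_year", "sample_size")) {
  outcome <- match.arg(outcome)
  allowed <- c("uoe_active", "kks_active", "registration_year",
               "sample_size", "observational", "on_ctgov", "on_drks")
  bad <- setdiff(predictors, allowed)
  if (length(bad) > 0) {
    stop("unknown predictor(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  family <- family %||%
    if (outcome == "quality_fraction") "linear" else "logistic"
  if (outcome == "quality_fraction" && family != "linear") {
    stop("quality_fraction requires the linear family", call. = FALSE)
  }
  if (outcome != "quality_fraction" && family != "logistic") {
    stop("binary outcomes require the logistic family", call. = FALSE)
  }
  structure(list(outcome = outcome, predictors = predictors, family = family,
                 filter = filter,
                 standardize = intersect(standardize, predictors)),
            class = "ctrq_model_spec")
}

#' @rdname model_spec
#' @param boundary First registration date kept (default 2009-01-01).
#' @export
filter_after_2008 <- function(boundary = as.Date("2009-01-01")) {
  force(boundary)
  function(data) {
    !is.na(data$registration_date) & data$registration_date >= boundary
  }
}

#' Fit a trial regression model
#'
#' Maximum-likelihood logistic or least-squares linear fit with Wald 95%
#' confidence intervals. The model specification's filter is applied first;
#' rows with
#' missing outcome or predictor values are then dropped (complete-case per
#' model) and counted. Logistic coefficients are reported as odds ratios by
#' [tidy()][generics::tidy]. Perfect separation is flagged, not silently
#' accepted.
#'
#' @param data Flagged (and, for quality, scored) trial tibble. The
#'   `preregistered` outcome is taken as `preregistered == "pre"` when the
#'   column is character; `registration_year` is derived from
#'   `registration_date` if absent.
#' @param spec A `ctrq_model_spec`.
#' @return A `ctrq_fit` object; see [tidy.ctrq_fit()] and
#'   [glance.ctrq_fit()].
#' @export
fit_trial_model <- function(data, spec) {
  stopifnot(inherits(spec, "ctrq_model_spec"))
  if (!"registration_year" %in% names(data) &&
      "registration_date" %in% names(data)) {
    data$registration_year <- lubridate::year(data$registration_date)
  }
  if (!is.null(spec$filter)) {
    keep <- spec$filter(data)
    keep[is.na(keep)] <- FALSE
    data <- data[keep, , drop = FALSE]
  }
  if (nrow(data) == 0) stop("no rows left after filtering", call. = FALSE)

  y <- switch(spec$outcome,
    preregistered = {
      v <- data$preregistered
      if (is.character(v) || is.factor(v)) {
        ifelse(as.character(v) == "unknown", NA, as.character(v) == "pre")
      } else as.logical(v)
    },
    quality_fraction = {
      col <- intersect(c("aggregate_fraction", "quality_fraction"),
                       names(data))[1]
      if (is.na(col)) stop("no quality fraction column found", call. = FALSE)
      as.numeric(data[[col]])
    },
    article_available = as.logical(data$article_available)
  )
  df <- data[, spec$predictors, drop = FALSE]
  df$.y <- y
  for (p in spec$predictors) {
    if (is.logical(df[[p]])) df[[p]] <- as.numeric(df[[p]])
  }
  complete <- stats::complete.cases(df)
  n_dropped <- sum(!complete)
  df <- df[complete, , drop = FALSE]
  if (nrow(df) == 0) stop("no complete cases to fit", call. = FALSE)
  for (p in spec$standardize) {
    df[[p]] <- standardize_2sd(df[[p]])
  }

  fml <- as.formula(paste(".y ~",
                          paste(spec$predictors, collapse = " + ")))
  separation <- FALSE
  if (spec$family == "logistic") {
    df$.y <- as.numeric(df$.y)
    fit <- withCallingHandlers(
      glm(fml, data = df, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w))) {
          separation <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    fp <- fitted(fit)
    separation <- separation || any(fp < 1e-8 | fp > 1 - 1e-8)
  } else {
    fit <- lm(fml, data = df)
  }
  structure(list(fit = fit, spec = spec, n_obs = nrow(df),
                 n_dropped = n_dropped, separation = separation),
            class = "ctrq_fit")
}

#' @export
print.ctrq_fit <- function(x, ...) {
  cat(sprintf("<ctrq_fit> %s regression of %s on %s\n", x$spec$family,
              x$spec$outcome, paste(x$spec$predictors, collapse = " + ")))
  cat(sprintf("  n = %d (%d incomplete rows dropped)%s\n", x$n_obs,
              x$n_dropped,
              if (x$separation) "; WARNING: possible separation" else ""))
  print(tidy(x))
  invisible(x)
}

#' Tidy a trial model fit
#'
#' One row per model term with the estimate, Wald 95% confidence interval and
#' p-value. For logistic models the estimate and interval are exponentiated
#' to odds ratios by default (the log of the reported odds ratio is exactly
#' the linear-predictor coefficient); linear models report coefficients on
#' the response scale with t-based intervals.
#'
#' @param x A `ctrq_fit`.
#' @param exponentiate Report odds ratios (default for logistic fits).
#' @param ... Unused.
#' @return Tibble `term`, `estimate`, `conf.low`, `conf.high`, `p.value`.
#' @method tidy ctrq_fit
#' @export
tidy.ctrq_fit <- function(x, exponentiate = x$spec$family == "logistic",
                          ...) {
  sm <- summary(x$fit)$coefficients
  est <- sm[, 1]
  se <- sm[, 2]
  p <- sm[, 4]
  if (x$spec$family == "logistic") {
    z <- qnorm(0.975)
    lo <- est - z * se
    hi <- est + z * se
  } else {
    ci <- confint(x$fit)
    lo <- ci[, 1]
    hi <- ci[, 2]
  }
  out <- tibble(term = rownames(sm), estimate = unname(est),
                conf.low = unname(lo), conf.high = unname(hi),
                p.value = unname(p))
  if (exponentiate && x$spec$family == "logistic") {
    out$estimate <- exp(out$estimate)
    out$conf.low <- exp(out$conf.low)
    out$conf.high <- exp(out$conf.high)
  }
  out
}

#' Model-level summary of a trial model fit
#'
#' @param x A `ctrq_fit`.
#' @param ... Unused.
#' @return One-row tibble: `n_obs`, `n_dropped`, `AIC`, `BIC`,
#'   `log_likelihood`, and for linear fits `r.squared` / `adj.r.squared`.
#' @method glance ctrq_fit
#' @export
glance.ctrq_fit <- function(x, ...) {
  out <- tibble(n_obs = x$n_obs, n_dropped = x$n_dropped,
                AIC = AIC(x$fit), BIC = BIC(x$fit),
                log_likelihood = as.numeric(logLik(x$fit)),
                separation = x$separation)
  if (x$spec$family == "linear") {
    sm <- summary(x$fit)
    out$r.squared <- sm$r.squared
    out$adj.r.squared <- sm$adj.r.squared
  }
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' The four canonical model variants
#'
#' Convenience constructor for the standard model battery: Model 1 and 2 test
#' University-of-Excellence status (alone, then adjusted for registration
#' year, sample size, study type and registry membership); Models 3 and 4 do
#' the same for KKS availability.
#'
#' @param outcome Outcome name as in [model_spec()].
#' @param filter Optional row filter applied to every variant (for
#'   pre-registration typically [filter_after_2008()]).
#' @return Named list of four `ctrq_model_spec`s.
#' @export
model_battery <- function(outcome, filter = NULL) {
  covs <- c("registration_year", "sample_size", "observational",
            "on_ctgov", "on_drks")
  list(
    model1 = model_spec(outcome, "uoe_active", filter = filter),
    model2 = model_spec(outcome, c("uoe_active", covs), filter = filter),
    model3 = model_spec(outcome, "kks_active", filter = filter),
    model4 = model_spec(outcome, c("kks_active", covs), filter = filter)
  )
}

#' Per-criterion time trends in registration quality
#'
#' For each registry group and rubric criterion, regresses the yearly mean
#' score fraction on the trial start year (one simple linear regression per
#' criterion per group) and reports the slope, its p-value, and whether it is
#' significant at the 0.05 level. Criteria with fewer than `min_years`
#' distinct years in a group are skipped with a warning.
#'
#' @param scores Long tibble with columns `group` (registry group),
#'   `criterion`, `start_year`, `fraction` (per-trial score fraction).
#' @param min_years Minimum distinct start years required (default 3).
#' @return Tibble `group`, `criterion`, `slope`, `p.value`, `n_years`,
#'   `significant`.
#' @export
criterion_time_trend <- function(scores, min_years = 3L) {
  assert_columns(scores, c("group", "criterion", "start_year", "fraction"),
                 "scores")
  yearly <- scores |>
    dplyr::filter(!is.na(.data$start_year), !is.na(.data$fraction)) |>
    dplyr::group_by(.data$group, .data$criterion, .data$start_year) |>
    dplyr::summarise(mean_fraction = mean(.data$fraction), .groups = "drop")

  skipped <- character(0)
  out <- yearly |>
    dplyr::group_by(.data$group, .data$criterion) |>
    dplyr::group_modify(function(df, key) {
      if (dplyr::n_distinct(df$start_year) < min_years) {
        skipped <<- c(skipped,
                      paste0(key$group, "/", key$criterion))
        return(tibble(slope = NA_real_, p.value = NA_real_,
                      n_years = dplyr::n_distinct(df$start_year)))
      }
      fit <- lm(mean_fraction ~ start_year, data = df)
      sm <- summary(fit)$coefficients
      tibble(slope = sm["start_year", 1],
             p.value = sm["start_year", 4],
             n_years = dplyr::n_distinct(df$start_year))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = !is.na(.data$p.value) & .data$p.value < 0.05)
  if (length(skipped) > 0) {
    warning("insufficient distinct years; skipped: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  out
}
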