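# Fixture builders shared across the suite. Everything is generated in code;
# no binary or large fixtures on disk.

make_record <- function(record_id, registry = "ClinicalTrials.gov",
                        title = "Velotinib Versus Placebo in Asthma",
                        registration_date = as.Date("2012-01-10"),
                        start_date = as.Date("2012-06-01"),
                        study_type = "interventional",
                        sample_size = 100L,
                        secondary_ids = NA_character_,
                        sponsor_names = "Example Clinic",
                        contact_emails = NA_character_,
                        recruiting_countries = "Germany",
                        registration_date_precision = "day",
                        start_date_precision = "day") {
  tibble::tibble(
    record_id = record_id, registry = registry, title = title,
    registration_date = registration_date,
    registration_date_precision = registration_date_precision,
    start_date = start_date, start_date_precision = start_date_precision,
    study_type = study_type, sample_size = sample_size,
    secondary_ids = secondary_ids, sponsor_names = sponsor_names,
    contact_emails = contact_emails,
    recruiting_countries = recruiting_countries
  )
}

make_records <- function(...) dplyr::bind_rows(...)

write_aact_fixture <- function(path, rows) {
  header <- paste(c("nct_id", "official_title", "study_first_submitted_date",
                    "start_date", "study_type", "enrollment",
                    "secondary_ids", "sponsor_name", "contact_email",
                    "countries"), collapse = "|")
  writeLines(c(header, rows), path)
}

# Fully-scored annotation row used as a base; tweak fields per test.
full_annotation <- function(trial_id = "T1", observational = FALSE,
                            open_label = FALSE) {
  tibble::tibble(
    trial_id = trial_id, observational = observational,
    open_label = open_label,
    title_has_intervention = if (observational) NA else TRUE,
    title_has_indication = TRUE, title_has_outcome = TRUE,
    title_outcome_is_primary = TRUE,
    design_adequate = TRUE, design_consistent = TRUE,
    sample_size_given = TRUE,
    masking_who_described = if (observational || open_label) NA else TRUE,
    masking_party_given = if (observational || open_label) NA else TRUE,
    inclusion_criteria_clear = TRUE, inclusion_all_measured = TRUE,
    intervention_insufficient = if (observational) NA else FALSE,
    intervention_type_given = if (observational) NA else TRUE,
    intervention_detail_given = if (observational) NA else TRUE
  )
}

full_outcome <- function(trial_id = "T1", role = "primary", points = 5L,
                         similar_to_primary = FALSE) {
  tibble::tibble(
    trial_id = trial_id, role = role,
    insufficient = points == 0L,
    has_type = points >= 1L, has_measure = points >= 2L,
    has_timeframe = points >= 3L, has_metric = points >= 4L,
    has_aggregation = points >= 5L,
    is_survival = FALSE, metric_inferable_or_moot = FALSE,
    similar_to_primary = similar_to_primary
  )
}

worked_example_dir <- function() {
  system.file("extdata", "worked_examples", package = "ctrquality")
}

read_category_examples <- function() {
  readr::read_csv(
    file.path(worked_example_dir(), "category_examples.csv"),
    col_types = readr::cols(trial_id = "c", category = "c", comment = "c",
                            .default = "l"),
    progress = FALSE, show_col_types = FALSE)
}

# Independent truth-table scorer for the five-element outcome scale, written
# directly from the rating rules; kept deliberately separate from the
# package implementation for oracle comparisons.
oracle_outcome_score <- function(insufficient, has_type, has_measure,
                                 has_timeframe, has_metric, has_aggregation,
                                 is_survival, metric_inferable_or_moot) {
  if (insufficient) return(0L)
  pts <- 0L
  if (has_type) pts <- pts + 1L
  if (has_measure) pts <- pts + 1L
  if (has_timeframe) pts <- pts + 1L
  if (has_metric || metric_inferable_or_moot) pts <- pts + 1L
  if (has_aggregation || is_survival) pts <- pts + 1L
  pts
}
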