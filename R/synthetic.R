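#' Configuration for the synthetic registry generator
#'
#' The generator emulates the statistical structure the analysis assumes:
#' trials recruiting in Germany registered in one or more of
#' ClinicalTrials.gov, DRKS and ICTRP partner registries, with planted
#' cross-registry duplicates (shared secondary IDs or only fuzzy-linkable via
#' perturbed titles and jittered dates), internal ICTRP duplicates, sponsor
#' strings carrying university and KKS-city tokens, a configurable
#' pre-registration model, a quality model with a positive time trend, and a
#' logistic article-availability model. Rates default to the observed
#' composition of the German registry landscape (about 24% observational
#' trials, 62%/29% ClinicalTrials.gov/DRKS membership, 7.5% University-of-
#' Excellence and 27% KKS sponsors, 6% both).
#'
#' Model coefficient lists are on the log-odds (logistic) or response
#' (linear) scale; `registration_year` coefficients apply to the
#' 2-SD-standardized year.
#'
#' @param n_trials Number of distinct trials.
#' @param ... Overrides for any default listed below.
#' @return A `ctrq_generator_config` list.
#' @export
generator_config <- function(n_trials = 2000, ...) {
  cfg <- list(
    n_trials = n_trials,
    year_range = c(2005L, 2020L),
    observational_rate = 0.243,
    excluded_type_rates = c(post_marketing = 0.001, expanded_access = 0.002,
                            diagnostic_test = 0.0005, other = 0.0005),
    registry_probs = c(ctgov = 0.55, drks = 0.25, euctr = 0.12,
                       isrctn = 0.08),
    multi_registration_rate = 0.3,
    p_shared_id = 0.7,
    shared_contact_rate = 0.85,
    ictrp_internal_dup_rate = 0.08,
    title_edit_rate = 0.08,
    date_jitter_days = 3L,
    month_precision_rate = 0.1,
    university_rate = 0.45,
    uoe_rate = 0.075,
    uoe_kks_rate = 0.06,
    kks_rate = 0.27,
    prereg_model = c(intercept = 0.65, observational = -0.8,
                     on_ctgov = 0.16, on_drks = -0.4, uoe_active = -0.75,
                     kks_active = -0.32, registration_year = -0.14),
    quality_model = list(baseline = 0.67, year_slope = 0.009,
                         year0 = 2012L, observational = -0.10,
                         on_ctgov = 0.08, on_drks = -0.01,
                         uoe_active = 0.0, kks_active = -0.03,
                         noise_sd = 0.11),
    open_label_rate = 0.25,
    article_model = c(intercept = -0.28, observational = 0.3,
                      on_ctgov = 0.38, on_drks = 0.15, uoe_active = 0.19,
                      kks_active = 0.06, registration_year = -0.27)
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad) > 0) {
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  rates <- c(cfg$multi_registration_rate, cfg$p_shared_id,
             cfg$title_edit_rate / 1, cfg$observational_rate,
             cfg$university_rate, cfg$uoe_rate, cfg$kks_rate)
  stopifnot(all(rates >= 0 & rates <= 1), cfg$n_trials > 0)
  structure(cfg, class = "ctrq_generator_config")
}

# --- name banks -------------------------------------------------------------

drug_bank <- function() {
  pre <- c("Velo", "Cora", "Ater", "Nima", "Zolu", "Brexa", "Calu", "Dexo",
           "Elri", "Fose", "Galu", "Hemi", "Ibexa", "Juva", "Kelo", "Lumi",
           "Mavo", "Nexi", "Orva", "Pexa")
  suf <- c("tinib", "mab", "stat", "pril", "sartan", "zone", "cycline",
           "parin")
  as.vector(outer(pre, suf, paste0))
}

condition_bank <- function() {
  c("Type 2 Diabetes", "Acute Ischemic Stroke", "Major Depression",
    "Chronic Heart Failure", "Rheumatoid Arthritis", "Severe Asthma",
    "Metastatic Breast Cancer", "Parkinson Disease", "Chronic Migraine",
    "Knee Osteoarthritis", "Atrial Fibrillation", "Ulcerative Colitis",
    "Chronic Hepatitis B", "Multiple Sclerosis", "Prostate Cancer",
    "Generalized Anxiety Disorder", "Psoriasis", "Chronic Kidney Disease",
    "Acute Myeloid Leukemia", "COPD")
}

# sponsor bank rows: name, is_university, uoe_entity (context row entity or
# NA), kks_entity (or NA); activity windows are resolved against the shipped
# structural context at draw time.
sponsor_bank <- function() {
  tibble::tribble(
    ~name, ~category,
    "Universitätsklinikum Heidelberg", "uoe_kks",
    "Klinikum der Universität München", "uoe_kks",
    "Charité - Universitätsmedizin Berlin", "uoe_kks",
    "Universitätsklinikum Hamburg-Eppendorf", "uoe_kks",
    "Universitätsklinikum Carl Gustav Carus, Technische Universität Dresden", "uoe_kks",
    "Universitätsklinikum Tübingen", "uoe_kks",
    "Universität Konstanz", "uoe_only",
    "RWTH Aachen, Medizinische Fakultät", "uoe_only",
    "Universität Bremen", "uoe_only",
    "Universitätsklinikum Bonn", "uoe_only",
    "Universitätsmedizin Göttingen", "uoe_only",
    "Universitätsklinikum Leipzig", "kks_university",
    "Universitätsmedizin Mainz", "kks_university",
    "Universitätsklinikum Jena", "kks_university",
    "Universitätsklinikum Essen", "kks_university",
    "Universitätsklinikum Ulm", "kks_university",
    "Universitätsklinikum Regensburg", "kks_university",
    "Universitätsklinikum Münster", "kks_university",
    "Universitätsklinikum Würzburg", "kks_university",
    "Herzzentrum Leipzig GmbH", "kks_nonuniversity",
    "Städtisches Klinikum Dresden", "kks_nonuniversity",
    "Diabetes Forschungsinstitut Mainz e.V.", "kks_nonuniversity",
    "Universitätsklinikum Schleswig-Holstein, Kiel", "university_other",
    "Universität Rostock", "university_other",
    "Universitätsklinikum Erlangen", "university_other",
    "Universität des Saarlandes, Homburg", "university_other",
    "Universität Witten/Herdecke", "university_other",
    "Boehringer Ingelheim Pharma GmbH", "other",
    "Bayer AG, Leverkusen", "other",
    "Merck KGaA, Darmstadt", "other",
    "Novartis Pharma GmbH, Nürnberg", "other",
    "Sanofi-Aventis Deutschland GmbH", "other",
    "Klinikum Ingolstadt", "other",
    "Deutsches Krebsforschungsnetz e.V.", "other",
    "CRO ClinResearch GmbH, Wiesbaden", "other"
  )
}

draw_sponsor_categories <- function(n, cfg) {
  p_uoe_kks <- cfg$uoe_kks_rate
  p_uoe_only <- max(cfg$uoe_rate - cfg$uoe_kks_rate, 0)
  p_kks_rest <- max(cfg$kks_rate - cfg$uoe_kks_rate, 0)
  p_kks_uni <- p_kks_rest * 0.75
  p_kks_non <- p_kks_rest * 0.25
  p_uni_other <- max(cfg$university_rate - cfg$uoe_rate - p_kks_uni, 0)
  p_other <- max(1 - p_uoe_kks - p_uoe_only - p_kks_uni - p_kks_non -
                   p_uni_other, 0)
  sample(c("uoe_kks", "uoe_only", "kks_university", "kks_nonuniversity",
           "university_other", "other"), n, replace = TRUE,
         prob = c(p_uoe_kks, p_uoe_only, p_kks_uni, p_kks_non, p_uni_other,
                  p_other))
}

# Resolve a sponsor name against the shipped context once, at generation
# time, giving the generator its own (regex-free downstream) activity truth.
sponsor_truth_table <- function(context = load_structural_context()) {
  bank <- sponsor_bank()
  folded <- fold_ascii(bank$name)
  uoe_rows <- which(context$kind == "uoe")
  kks_rows <- which(context$kind == "kks")
  bank$uoe_start <- as.Date(NA)
  bank$uoe_end <- as.Date(NA)
  bank$kks_open_year <- NA_integer_
  for (i in seq_len(nrow(bank))) {
    for (j in uoe_rows) {
      if (match_any_pattern(folded[i], context$pattern[j])) {
        bank$uoe_start[i] <- min(bank$uoe_start[i], context$window_start[j],
                                 na.rm = TRUE)
        we <- context$window_end[j]
        bank$uoe_end[i] <- if (is.na(we)) as.Date("2999-12-31") else
          max(bank$uoe_end[i], we, na.rm = TRUE)
      }
    }
    for (j in kks_rows) {
      if (match_any_pattern(folded[i], context$pattern[j])) {
        oy <- lubridate::year(context$window_start[j])
        bank$kks_open_year[i] <- min(bank$kks_open_year[i], oy, na.rm = TRUE)
      }
    }
  }
  bank$is_university <- stringr::str_detect(folded,
                                            stringr::fixed("universit"))
  bank
}

registry_id <- function(registry, serial, year) {
  switch(registry,
    ctgov = sprintf("NCT%08d", 10000000L + serial),
    drks = sprintf("DRKS%08d", 20000000L + serial),
    euctr = sprintf("EUCTR%04d-%06d-%02d-DE", year, serial %% 1000000L,
                    serial %% 97L),
    isrctn = sprintf("ISRCTN%08d", 30000000L + serial)
  )
}

perturb_title <- function(title, edit_rate) {
  words <- strsplit(title, " ", fixed = TRUE)[[1]]
  keep <- runif(length(words)) >= edit_rate
  out <- words[keep]
  if (length(out) == 0) out <- words[1]
  paste(out, collapse = " ")
}

jitter_date <- function(d, jitter_days) {
  d + sample(-jitter_days:jitter_days, length(d), replace = TRUE)
}

#' Simulate registry exports with known ground truth
#'
#' Generates a cohort of trials, registers each in one or more registries
#' (per `multi_registration_rate`), plants cross-registry duplicates that
#' share secondary IDs with probability `p_shared_id` (and are otherwise only
#' fuzzy-linkable through perturbed titles, jittered dates and shared contact
#' e-mails), adds internal ICTRP duplicates, and renders the records in the
#' three export dialects. Reproducible: the same config and seed give
#' byte-identical exports.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return List with `aact`, `drks`, `ictrp` (raw export tibbles in dialect
#'   schema), `truth` (list: `records` record-to-trial assignment, `trials`
#'   per-trial true flags and dates), and `config`.
#' @export
simulate_registry <- function(config = generator_config(), seed = 1L) {
  stopifnot(inherits(config, "ctrq_generator_config"))
  with_local_seed(seed, simulate_registry_impl(config))
}

simulate_registry_impl <- function(cfg) {
  n <- cfg$n_trials
  drugs <- drug_bank()
  conds <- condition_bank()
  bank <- sponsor_truth_table()

  # --- trial-level truth ---
  years <- sample(seq(cfg$year_range[1], cfg$year_range[2]), n,
                  replace = TRUE)
  start_date <- as.Date(sprintf("%d-01-01", years)) +
    sample(0:364, n, replace = TRUE)
  ex_rates <- cfg$excluded_type_rates
  type_draw <- runif(n)
  study_type <- dplyr::case_when(
    type_draw < ex_rates[1] ~ "post_marketing",
    type_draw < sum(ex_rates[1:2]) ~ "expanded_access",
    type_draw < sum(ex_rates[1:3]) ~ "diagnostic_test",
    type_draw < sum(ex_rates[1:4]) ~ "other",
    type_draw < sum(ex_rates) + cfg$observational_rate ~ "observational",
    TRUE ~ "interventional"
  )
  category <- draw_sponsor_categories(n, cfg)
  sponsor_idx <- vapply(category, function(cat) {
    idx <- which(bank$category == cat)
    idx[sample.int(length(idx), 1)]
  }, integer(1))
  sponsor <- bank$name[sponsor_idx]
  uoe_active <- !is.na(bank$uoe_start[sponsor_idx]) &
    start_date >= bank$uoe_start[sponsor_idx] &
    start_date <= bank$uoe_end[sponsor_idx]
  kks_active <- !is.na(bank$kks_open_year[sponsor_idx]) &
    lubridate::year(start_date) >= bank$kks_open_year[sponsor_idx]
  university <- bank$is_university[sponsor_idx]

  home <- sample(names(cfg$registry_probs), n, replace = TRUE,
                 prob = cfg$registry_probs)
  multi <- runif(n) < cfg$multi_registration_rate
  second <- vapply(seq_len(n), function(i) {
    if (!multi[i]) return(NA_character_)
    others <- setdiff(names(cfg$registry_probs), home[i])
    sample(others, 1, prob = cfg$registry_probs[others])
  }, character(1))
  on_ctgov <- home == "ctgov" | (!is.na(second) & second == "ctgov")
  on_drks <- home == "drks" | (!is.na(second) & second == "drks")

  year_std <- standardize_2sd(years)
  pm <- cfg$prereg_model
  lp <- pm["intercept"] + pm["observational"] *
    (study_type == "observational") +
    pm["on_ctgov"] * on_ctgov + pm["on_drks"] * on_drks +
    pm["uoe_active"] * uoe_active + pm["kks_active"] * kks_active +
    pm["registration_year"] * year_std
  prereg <- runif(n) < plogis(lp)
  reg_offset <- sample(0:270, n, replace = TRUE)
  registration_date <- ifelse(prereg, start_date - reg_offset,
                              start_date + 1 + reg_offset)
  registration_date <- as.Date(registration_date,
                               origin = as.Date("1970-01-01"))

  drug <- drugs[sample.int(length(drugs), n, replace = TRUE)]
  cond <- conds[sample.int(length(conds), n, replace = TRUE)]
  title <- ifelse(
    study_type == "observational",
    paste(drug, "Exposure and Outcomes in Patients With", cond,
          "- an Observational Study"),
    paste(drug, "Versus Placebo in Patients With", cond,
          "- a Randomized Controlled Trial"))
  sample_size <- pmax(1L, as.integer(round(rlnorm(n, 4.1, 1))))
  email <- sprintf("pi.trial%05d@%s.example.de", seq_len(n),
                   gsub("[^a-z]", "", substr(fold_ascii(sponsor), 1, 12)))

  trials <- tibble(
    trial_uid = sprintf("T%05d", seq_len(n)),
    title = title, study_type = study_type, start_date = start_date,
    registration_date = registration_date, sample_size = sample_size,
    sponsor = sponsor, email = email,
    home_registry = home, second_registry = second,
    on_ctgov = on_ctgov, on_drks = on_drks,
    university_sponsor = university, uoe_active = uoe_active,
    kks_active = kks_active, preregistered_latent = prereg,
    start_year = years
  )

  # --- record-level emission ---
  rec <- list()
  serial <- 0L
  for (i in seq_len(n)) {
    regs <- c(home[i], if (!is.na(second[i])) second[i])
    shared <- runif(1) < cfg$p_shared_id
    share_mail <- runif(1) < cfg$shared_contact_rate
    ids <- character(length(regs))
    for (k in seq_along(regs)) {
      serial <- serial + 1L
      ids[k] <- registry_id(regs[k], serial, years[i])
    }
    for (k in seq_along(regs)) {
      is_home <- k == 1
      sec_ids <- if (length(regs) > 1 && shared) ids[-k] else character(0)
      rec[[length(rec) + 1]] <- tibble(
        trial_uid = trials$trial_uid[i],
        record_id = ids[k],
        registry_key = regs[k],
        title = if (is_home) title[i] else
          perturb_title(title[i], cfg$title_edit_rate),
        registration_date = if (is_home) registration_date[i] else
          jitter_date(registration_date[i], cfg$date_jitter_days),
        start_date = if (is_home) start_date[i] else
          jitter_date(start_date[i], cfg$date_jitter_days),
        study_type = study_type[i],
        sample_size = sample_size[i],
        secondary_ids = join_multi(sec_ids) %||% NA_character_,
        sponsor = sponsor[i],
        email = if (is_home || share_mail) email[i] else
          sub("^pi\\.", "coord.", email[i])
      )
    }
    # internal ICTRP duplicate of a partner-registry record
    last_is_partner <- regs[length(regs)] %in% c("euctr", "isrctn")
    if (last_is_partner && runif(1) < cfg$ictrp_internal_dup_rate) {
      base_id <- ids[length(regs)]
      dup_id <- if (grepl("^EUCTR", base_id)) {
        sub("-DE$", "-AT", base_id)
      } else paste0(base_id, "-2")
      rec[[length(rec) + 1]] <- tibble(
        trial_uid = trials$trial_uid[i],
        record_id = dup_id,
        registry_key = regs[length(regs)],
        title = perturb_title(title[i], cfg$title_edit_rate),
        registration_date = jitter_date(registration_date[i],
                                        cfg$date_jitter_days),
        start_date = jitter_date(start_date[i], cfg$date_jitter_days),
        study_type = study_type[i],
        sample_size = sample_size[i],
        secondary_ids = NA_character_,
        sponsor = sponsor[i],
        email = if (runif(1) < cfg$shared_contact_rate) email[i] else
          sub("^pi\\.", "office.", email[i])
      )
    }
  }
  records <- dplyr::bind_rows(rec)

  month_prec <- records$registry_key %in% c("euctr", "isrctn") &
    runif(nrow(records)) < cfg$month_precision_rate

  truth_trials <- records |>
    dplyr::group_by(.data$trial_uid) |>
    dplyr::summarise(earliest_registration = min(.data$registration_date),
                     earliest_start = min(.data$start_date),
                     n_records = dplyr::n(), .groups = "drop") |>
    dplyr::right_join(trials, by = "trial_uid") |>
    dplyr::mutate(preregistered = .data$earliest_registration <=
                    .data$earliest_start)

  list(
    aact = render_aact(records[records$registry_key == "ctgov", ]),
    drks = render_drks(records[records$registry_key == "drks", ]),
    ictrp = render_ictrp(records[records$registry_key %in%
                                   c("euctr", "isrctn"), ], month_prec[
                                     records$registry_key %in%
                                       c("euctr", "isrctn")]),
    truth = list(
      records = records[, c("record_id", "trial_uid", "registry_key")],
      trials = truth_trials
    ),
    config = cfg
  )
}

study_type_label <- function(x, dialect) {
  base <- c(interventional = "Interventional",
            observational = "Observational",
            post_marketing = "Post Marketing",
            expanded_access = "Expanded Access",
            diagnostic_test = "Diagnostic Test",
            other = "Other")[x]
  if (dialect == "ictrp") {
    ifelse(x == "interventional",
           "Interventional clinical trial of medicinal product", base)
  } else base
}

render_aact <- function(r) {
  tibble(
    nct_id = r$record_id,
    official_title = r$title,
    study_first_submitted_date = format(r$registration_date, "%Y-%m-%d"),
    start_date = format(r$start_date, "%Y-%m-%d"),
    study_type = study_type_label(r$study_type, "aact"),
    enrollment = as.character(r$sample_size),
    secondary_ids = ifelse(is.na(r$secondary_ids), "", r$secondary_ids),
    sponsor_name = r$sponsor,
    contact_email = r$email,
    countries = "Germany"
  )
}

render_drks <- function(r) {
  tibble(
    drksId = r$record_id,
    title = r$title,
    created_at = format(r$registration_date, "%d.%m.%Y"),
    start_date = format(r$start_date, "%d.%m.%Y"),
    studyType = tolower(study_type_label(r$study_type, "drks")),
    targetSize = as.character(r$sample_size),
    secondaryIds = ifelse(is.na(r$secondary_ids), "", r$secondary_ids),
    `address.affiliation` = r$sponsor,
    email = r$email,
    recruitmentCountries = "Germany"
  )
}

render_ictrp <- function(r, month_prec) {
  tibble(
    TrialID = r$record_id,
    Public_title = r$title,
    Date_registration = format(r$registration_date, "%d/%m/%Y"),
    Date_enrollment = ifelse(month_prec,
                             format(r$start_date, "%m/%Y"),
                             format(r$start_date, "%d/%m/%Y")),
    Study_type = study_type_label(r$study_type, "ictrp"),
    Target_size = as.character(r$sample_size),
    Secondary_IDs = ifelse(is.na(r$secondary_ids), "", r$secondary_ids),
    Primary_sponsor = r$sponsor,
    Scientific_Contact_email = r$email,
    Countries = "Germany",
    Source_Register = ifelse(grepl("^EUCTR", r$record_id), "EUCTR",
                             "ISRCTN")
  )
}

#' Write simulated exports and ground truth to a directory
#'
#' @param sim Result of [simulate_registry()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_registry_exports <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    aact = file.path(dir, "aact_studies.txt"),
    drks = file.path(dir, "drks_export.csv"),
    ictrp = file.path(dir, "ictrp_export.csv"),
    truth_records = file.path(dir, "truth_records.csv"),
    truth_trials = file.path(dir, "truth_trials.csv")
  )
  readr::write_delim(sim$aact, paths["aact"], delim = "|", progress = FALSE)
  readr::write_csv(sim$drks, paths["drks"], progress = FALSE)
  readr::write_csv(sim$ictrp, paths["ictrp"], progress = FALSE)
  readr::write_csv(sim$truth$records, paths["truth_records"],
                   progress = FALSE)
  readr::write_csv(sim$truth$trials, paths["truth_trials"], progress = FALSE)
  invisible(paths)
}

#' Ingest all three simulated exports into one harmonized record table
#'
#' @param sim Result of [simulate_registry()].
#' @return Harmonized trial-record tibble for all emitted records.
#' @export
harmonize_simulation <- function(sim) {
  render <- function(df, dialect) {
    tmp <- tempfile(fileext = if (dialect == "AACT") ".txt" else ".csv")
    on.exit(unlink(tmp))
    delim <- if (dialect == "AACT") "|" else ","
    readr::write_delim(df, tmp, delim = delim, progress = FALSE)
    ingest_registry_export(tmp, dialect)
  }
  dplyr::bind_rows(
    render(sim$aact, "AACT"),
    render(sim$drks, "DRKS"),
    render(sim$ictrp, "ICTRP")
  )
}

# Exact nearest-representable allocation of category points so that the
# scored aggregate (mean of per-category fractions) matches the target
# fraction as closely as the integer grid allows. Category maxima are 1, 2
# or 5, so per-category fractions live on a tenths grid; a small dynamic
# program (memoized per maxima set) finds, for every reachable fraction sum,
# one allocation realizing it. Deterministic; ties resolve to the lower sum.
allocation_table_cache <- new.env(parent = emptyenv())

allocation_table <- function(maxes) {
  key <- paste(maxes, collapse = ",")
  if (!is.null(allocation_table_cache[[key]])) {
    return(allocation_table_cache[[key]])
  }
  stopifnot(all(10 %% maxes == 0))
  # best[[s]] = allocation reaching fraction sum (s-1)/10
  best <- list(integer(0))
  for (m in maxes) {
    step <- 10L %/% m
    new_best <- list()
    for (s in seq_along(best)) {
      if (is.null(best[[s]])) next
      for (k in 0:m) {
        s2 <- s + k * step
        if (length(new_best) < s2 || is.null(new_best[s2][[1]])) {
          new_best[[s2]] <- c(best[[s]], k)
        }
      }
    }
    best <- new_best
  }
  reachable <- which(!vapply(best, is.null, logical(1)))
  out <- list(sums = (reachable - 1L) / 10,
              alloc = best[reachable])
  allocation_table_cache[[key]] <- out
  out
}

allocate_category_points <- function(target, maxes) {
  target <- min(max(target, 0), 1)
  tab <- allocation_table(maxes)
  t_sum <- target * length(maxes)
  i <- which.min(abs(tab$sums - t_sum))
  as.integer(tab$alloc[[i]])
}

#' Simulate structured quality annotations with a planted trend
#'
#' For each trial the target aggregate quality fraction is
#' `baseline + year_slope * (start_year - year0) + effects + noise`, clamped
#' to `[0, 1]`; category points are then allocated on the integer grid so the
#' scored aggregate reproduces the target up to quantization, and annotation
#' flags are written accordingly. Observational trials get masking and
#' intervention not-applicable; open-label interventional trials (at
#' `open_label_rate`) get masking not-applicable.
#'
#' @param trials Flagged trial tibble with `trial_id`, `start_year`,
#'   `observational`, `on_ctgov`, `on_drks`, `uoe_active`, `kks_active`.
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return List: `annotations`, `outcomes` (codebook-shaped tibbles), and
#'   `truth` (tibble `trial_id`, `true_fraction` latent target,
#'   `allocated_fraction` the representable aggregate).
#' @export
simulate_annotations <- function(trials, config = generator_config(),
                                 seed = 1L) {
  assert_columns(trials, c("trial_id", "start_year", "observational",
                           "on_ctgov", "on_drks", "uoe_active",
                           "kks_active"), "trials")
  qm <- config$quality_model
  with_local_seed(seed, {
    n <- nrow(trials)
    open_label <- !trials$observational &
      runif(n) < config$open_label_rate
    target <- qm$baseline +
      qm$year_slope * (trials$start_year - qm$year0) +
      qm$observational * trials$observational +
      qm$on_ctgov * trials$on_ctgov + qm$on_drks * trials$on_drks +
      qm$uoe_active * trials$uoe_active +
      qm$kks_active * trials$kks_active +
      rnorm(n, 0, qm$noise_sd)
    target <- pmin(pmax(target, 0), 1)

    all_max <- rubric_category_max()
    ann <- vector("list", n)
    out <- vector("list", n)
    alloc_frac <- numeric(n)
    for (i in seq_len(n)) {
      applicable <- names(all_max)
      if (trials$observational[i]) {
        applicable <- setdiff(applicable, c("masking", "intervention"))
      } else if (open_label[i]) {
        applicable <- setdiff(applicable, "masking")
      }
      mx <- all_max[applicable]
      pts <- setNames(allocate_category_points(target[i], mx), applicable)
      alloc_frac[i] <- mean(pts / mx)
      get <- function(cat) if (cat %in% applicable) pts[[cat]] else NA_integer_
      obs <- trials$observational[i]
      ann[[i]] <- tibble(
        trial_id = trials$trial_id[i],
        observational = obs,
        open_label = open_label[i],
        title_has_intervention = if (obs) NA else get("title") == 1L,
        title_has_indication = get("title") == 1L,
        title_has_outcome = get("title") == 1L,
        title_outcome_is_primary = get("title") == 1L,
        design_adequate = TRUE,
        design_consistent = get("design") == 1L,
        sample_size_given = get("sample_size") == 1L,
        masking_who_described = if (is.na(get("masking"))) NA else
          get("masking") >= 1L,
        masking_party_given = if (is.na(get("masking"))) NA else
          get("masking") == 2L,
        inclusion_criteria_clear = get("inclusion") >= 1L,
        inclusion_all_measured = get("inclusion") == 2L,
        intervention_insufficient = if (is.na(get("intervention"))) NA else
          get("intervention") == 0L,
        intervention_type_given = if (is.na(get("intervention"))) NA else
          get("intervention") >= 1L,
        intervention_detail_given = if (is.na(get("intervention"))) NA else
          get("intervention") == 2L
      )
      outcome_flags <- function(role, p) {
        tibble(
          trial_id = trials$trial_id[i], role = role,
          insufficient = p == 0L,
          has_type = p >= 1L, has_measure = p >= 2L, has_timeframe = p >= 3L,
          has_metric = p >= 4L, has_aggregation = p >= 5L,
          is_survival = FALSE, metric_inferable_or_moot = FALSE,
          similar_to_primary = FALSE
        )
      }
      out[[i]] <- dplyr::bind_rows(
        outcome_flags("primary", pts[["primary_outcome"]]),
        outcome_flags("secondary", pts[["secondary_outcome"]])
      )
    }
    list(annotations = dplyr::bind_rows(ann),
         outcomes = dplyr::bind_rows(out),
         truth = tibble(trial_id = trials$trial_id,
                        true_fraction = target,
                        allocated_fraction = alloc_frac))
  })
}

#' Simulate article availability from the planted logistic model
#'
#' @param trials Flagged trial tibble with `observational`, `on_ctgov`,
#'   `on_drks`, `uoe_active`, `kks_active` and a year column
#'   (`registration_year` preferred, else `start_year`).
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return `trials` with a logical `article_available` column.
#' @export
simulate_availability <- function(trials, config = generator_config(),
                                  seed = 1L) {
  am <- config$article_model
  year <- if ("registration_year" %in% names(trials)) {
    trials$registration_year
  } else trials$start_year
  year_std <- if (length(unique(year[is.finite(year)])) > 1) {
    standardize_2sd(year)
  } else rep(0, nrow(trials))
  lp <- am["intercept"] +
    am["observational"] * trials$observational +
    am["on_ctgov"] * trials$on_ctgov + am["on_drks"] * trials$on_drks +
    am["uoe_active"] * trials$uoe_active +
    am["kks_active"] * trials$kks_active +
    am["registration_year"] * year_std
  with_local_seed(seed, {
    dplyr::mutate(trials,
                  article_available = runif(nrow(trials)) < plogis(lp))
  })
}

#' Simulate a flagged trial-level analysis table directly
#'
#' Trial-level shortcut past the record machinery: draws predictors with the
#' configured rates and the three outcomes (pre-registration, quality
#' fraction, article availability) from the planted models. The quality
#' fraction is left on the latent (unclamped, unquantized) scale, which makes
#' this the generator of choice for parameter-recovery and type-I-error
#' studies of the regression layer.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return Tibble with predictors, `preregistered` (logical),
#'   `quality_fraction`, `article_available`, `registration_year`,
#'   `start_year`.
#' @export
simulate_trial_table <- function(config = generator_config(), seed = 1L) {
  cfg <- config
  with_local_seed(seed, {
    n <- cfg$n_trials
    start_year <- sample(seq(cfg$year_range[1], cfg$year_range[2]), n,
                         replace = TRUE)
    registration_year <- start_year - rbinom(n, 1, 0.3)
    observational <- runif(n) < cfg$observational_rate
    category <- draw_sponsor_categories(n, cfg)
    uoe_active <- category %in% c("uoe_kks", "uoe_only")
    kks_active <- category %in% c("uoe_kks", "kks_university",
                                  "kks_nonuniversity")
    home <- sample(names(cfg$registry_probs), n, replace = TRUE,
                   prob = cfg$registry_probs)
    multi <- runif(n) < cfg$multi_registration_rate
    second <- ifelse(multi, vapply(home, function(h) {
      others <- setdiff(names(cfg$registry_probs), h)
      sample(others, 1, prob = cfg$registry_probs[others])
    }, character(1)), NA_character_)
    on_ctgov <- home == "ctgov" | (!is.na(second) & second == "ctgov")
    on_drks <- home == "drks" | (!is.na(second) & second == "drks")
    sample_size <- pmax(1L, as.integer(round(rlnorm(n, 4.1, 1))))

    ry_std <- standardize_2sd(registration_year)
    pm <- cfg$prereg_model
    lp_pre <- pm["intercept"] + pm["observational"] * observational +
      pm["on_ctgov"] * on_ctgov + pm["on_drks"] * on_drks +
      pm["uoe_active"] * uoe_active + pm["kks_active"] * kks_active +
      pm["registration_year"] * ry_std
    preregistered <- runif(n) < plogis(lp_pre)

    qm <- cfg$quality_model
    quality <- qm$baseline + qm$year_slope * (start_year - qm$year0) +
      qm$observational * observational + qm$on_ctgov * on_ctgov +
      qm$on_drks * on_drks + qm$uoe_active * uoe_active +
      qm$kks_active * kks_active + rnorm(n, 0, qm$noise_sd)

    am <- cfg$article_model
    lp_art <- am["intercept"] + am["observational"] * observational +
      am["on_ctgov"] * on_ctgov + am["on_drks"] * on_drks +
      am["uoe_active"] * uoe_active + am["kks_active"] * kks_active +
      am["registration_year"] * ry_std
    article_available <- runif(n) < plogis(lp_art)

    tibble(
      trial_id = sprintf("T%05d", seq_len(n)),
      start_year = start_year, registration_year = registration_year,
      registration_date = as.Date(sprintf("%d-07-01", registration_year)),
      observational = observational, uoe_active = uoe_active,
      kks_active = kks_active, on_ctgov = on_ctgov, on_drks = on_drks,
      sample_size = sample_size, preregistered = preregistered,
      quality_fraction = quality, article_available = article_available
    )
  })
}
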