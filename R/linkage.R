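#' Link records sharing primary or secondary IDs
#'
#' First stage of the step-wise deduplication: an edge is emitted for every
#' record pair sharing a primary ID or where one record's primary ID appears
#' among another's secondary IDs. Comparison is case-insensitive and
#' whitespace-stripped.
#'
#' @param records Harmonized trial-record tibble with unique `record_id`s.
#' @return Edge tibble with columns `id1`, `id2` (ordered so `id1 < id2`) and
#'   `evidence` (`"primary_id"` or `"secondary_id"`).
#' @export
link_by_ids <- function(records) {
  empty <- tibble(id1 = character(), id2 = character(),
                  evidence = character())
  if (nrow(records) < 2) return(empty)
  if (anyDuplicated(records$record_id)) {
    stop("record_id values must be unique within the input", call. = FALSE)
  }
  long <- tibble(
    record_id = rep(records$record_id,
                    lengths(sec <- purrr::map(
                      records$secondary_ids,
                      ~ split_multi(if (is.na(.x)) "" else .x))) + 1L),
    id = unlist(purrr::map2(records$record_id, sec, c)),
    is_primary = unlist(purrr::map(lengths(sec),
                                   ~ c(TRUE, rep(FALSE, .x))))
  )
  long$id <- normalize_id(long$id)
  long <- dplyr::distinct(long, .data$record_id, .data$id, .keep_all = TRUE)

  edges <- dplyr::inner_join(long, long, by = "id",
                             relationship = "many-to-many",
                             suffix = c("_a", "_b")) |>
    dplyr::filter(.data$record_id_a < .data$record_id_b) |>
    # a shared value must be the primary ID of at least one side
    dplyr::filter(.data$is_primary_a | .data$is_primary_b) |>
    dplyr::mutate(evidence = ifelse(.data$is_primary_a & .data$is_primary_b,
                                    "primary_id", "secondary_id")) |>
    dplyr::group_by(id1 = .data$record_id_a, id2 = .data$record_id_b) |>
    dplyr::summarise(
      evidence = if (any(.data$evidence == "primary_id")) "primary_id"
                 else "secondary_id",
      .groups = "drop")
  if (nrow(edges) == 0) empty else edges
}

#' Default blocking configuration for candidate generation
#'
#' Candidate pairs for the match classifier are restricted to records that
#' agree on a blocking key: same first title token with registration years no
#' more than `year_window` apart, unioned with pairs sharing a contact
#' e-mail. Blocking trades a documented miss rate for tractability; its
#' completeness against planted ground truth is part of the test suite.
#'
#' @param year_window Maximum registration-year gap within a title block.
#' @param max_block_size Title blocks larger than this are skipped (guards
#'   against degenerate blocks like "study").
#' @return A blocking config list.
#' @export
blocking_config <- function(year_window = 1L, max_block_size = 50L) {
  list(year_window = as.integer(year_window),
       max_block_size = as.integer(max_block_size))
}

#' Generate candidate record pairs via blocking
#'
#' @param records Harmonized trial-record tibble.
#' @param blocking Config from [blocking_config()].
#' @param exclude Optional edge tibble (e.g. from [link_by_ids()]) whose pairs
#'   are removed from the candidates.
#' @return Deduplicated tibble of candidate pairs (`id1`, `id2`, `id1 < id2`).
#' @export
generate_candidates <- function(records, blocking = blocking_config(),
                                exclude = NULL) {
  empty <- tibble(id1 = character(), id2 = character())
  if (nrow(records) < 2) return(empty)

  first_token <- vapply(normalize_title(records$title), function(t) {
    if (is.na(t) || !nzchar(t)) NA_character_
    else strsplit(t, " ", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  year <- lubridate::year(records$registration_date)

  blk <- tibble(record_id = records$record_id, token = first_token,
                year = year) |>
    dplyr::filter(!is.na(.data$token))
  keep <- blk |>
    dplyr::count(.data$token) |>
    dplyr::filter(.data$n <= blocking$max_block_size, .data$n >= 2)
  blk <- dplyr::semi_join(blk, keep, by = "token")
  title_pairs <- dplyr::inner_join(blk, blk, by = "token",
                                   relationship = "many-to-many",
                                   suffix = c("_a", "_b")) |>
    dplyr::filter(.data$record_id_a < .data$record_id_b) |>
    dplyr::filter(is.na(.data$year_a) | is.na(.data$year_b) |
                    abs(.data$year_a - .data$year_b) <= blocking$year_window) |>
    dplyr::select(id1 = "record_id_a", id2 = "record_id_b")

  emails <- tibble(record_id = rep(records$record_id,
                                   lengths(em <- record_email_sets(records))),
                   email = unlist(em))
  email_pairs <- if (nrow(emails) > 0) {
    dplyr::inner_join(emails, emails, by = "email",
                      relationship = "many-to-many",
                      suffix = c("_a", "_b")) |>
      dplyr::filter(.data$record_id_a < .data$record_id_b) |>
      dplyr::select(id1 = "record_id_a", id2 = "record_id_b")
  } else empty

  out <- dplyr::distinct(dplyr::bind_rows(title_pairs, email_pairs))
  if (!is.null(exclude) && nrow(exclude) > 0) {
    out <- dplyr::anti_join(out, exclude[, c("id1", "id2")],
                            by = c("id1", "id2"))
  }
  out
}

#' Train the random-forest duplicate-match classifier
#'
#' A probability forest over the pairwise features (shared IDs, title
#' similarity, date gaps, sample-size ratio, shared contact). Training is
#' reproducible given `seed`.
#'
#' @param features Feature tibble from [pair_features()].
#' @param labels Logical vector: is the pair a true duplicate?
#' @param seed Integer seed for the forest.
#' @param num_trees Number of trees.
#' @return A `ctrq_matcher` object exposing match probabilities via
#'   [predict_match_prob()].
#' @export
train_matcher <- function(features, labels, seed = 1L, num_trees = 300L) {
  labels <- as.logical(labels)
  if (length(unique(labels[!is.na(labels)])) < 2) {
    stop("training labels must contain both matches and non-matches",
         call. = FALSE)
  }
  x <- encode_features(features)
  df <- cbind(x, .match = factor(ifelse(labels, "match", "nonmatch"),
                                 levels = c("nonmatch", "match")))
  fit <- ranger::ranger(
    dependent.variable.name = ".match", data = df,
    probability = TRUE, num.trees = num_trees, seed = seed,
    respect.unordered.factors = TRUE
  )
  structure(list(forest = fit, feature_names = names(x), seed = seed),
            class = "ctrq_matcher")
}

#' @rdname train_matcher
#' @param matcher A `ctrq_matcher`.
#' @export
predict_match_prob <- function(matcher, features) {
  stopifnot(inherits(matcher, "ctrq_matcher"))
  x <- encode_features(features)
  p <- stats::predict(matcher$forest, data = x)$predictions
  unname(p[, "match"])
}

#' @export
print.ctrq_matcher <- function(x, ...) {
  cat("<ctrq_matcher> random-forest pairwise duplicate classifier\n")
  cat("  trees:", x$forest$num.trees,
      " OOB prediction error:", signif(x$forest$prediction.error, 3), "\n")
  invisible(x)
}

#' Classify candidate pairs with a trained matcher
#'
#' @param records Harmonized trial-record tibble.
#' @param pairs Candidate pair tibble (`id1`, `id2`), or a feature tibble
#'   already produced by [pair_features()].
#' @param matcher A `ctrq_matcher` from [train_matcher()].
#' @param threshold Match-probability threshold in (0, 1]; a pair becomes an
#'   edge iff its probability is `>= threshold`.
#' @return Edge tibble (`id1`, `id2`, `evidence = "classifier"`,
#'   `probability`).
#' @export
classify_pairs <- function(records, pairs, matcher, threshold = 0.5) {
  stopifnot(threshold > 0, threshold <= 1)
  if (nrow(pairs) == 0) {
    return(tibble(id1 = character(), id2 = character(),
                  evidence = character(), probability = numeric()))
  }
  feats <- if (all(matcher_feature_names() %in% names(pairs))) pairs
           else pair_features(records, pairs)
  p <- predict_match_prob(matcher, feats)
  out <- tibble(id1 = pairs$id1, id2 = pairs$id2,
                evidence = "classifier", probability = p)
  out[p >= threshold, , drop = FALSE]
}

#' Cluster records into trials via connected components
#'
#' Edges from the ID cascade and the classifier are combined and resolved by
#' connected components (union-find): transitive chains merge. ID-evidence
#' edges are always honored regardless of classifier output. Every input
#' record lands in exactly one cluster; records with no edges form singleton
#' clusters.
#'
#' @param records Harmonized trial-record tibble.
#' @param edges Edge tibble(s) with `id1`, `id2`, `evidence`.
#' @return Tibble `record_id`, `trial_id` (lexicographically smallest member
#'   `record_id`), `cluster_size`; the edge list used is attached as attribute
#'   `"link_evidence"`.
#' @export
build_clusters <- function(records, edges) {
  ids <- records$record_id
  edges <- edges[edges$id1 %in% ids & edges$id2 %in% ids, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges[, c("id1", "id2")], directed = FALSE,
    vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  member <- tibble(record_id = names(comp$membership),
                   component = unname(comp$membership))
  out <- member |>
    dplyr::group_by(.data$component) |>
    dplyr::mutate(trial_id = min(.data$record_id),
                  cluster_size = dplyr::n()) |>
    dplyr::ungroup() |>
    dplyr::select("record_id", "trial_id", "cluster_size")
  out <- out[match(ids, out$record_id), ]
  attr(out, "link_evidence") <- edges
  out
}

registry_preference_rank <- function(registry) {
  dplyr::case_when(
    registry == "ClinicalTrials.gov" ~ 1L,
    registry == "DRKS" ~ 2L,
    TRUE ~ 3L
  )
}

#' Merge record clusters into unified trials
#'
#' One row per trial: the registration date is the earliest member
#' registration date and the start date the earliest non-missing member start
#' date (each carrying its precision). For conflicting non-date fields the
#' ClinicalTrials.gov member is preferred, then DRKS, then ICTRP partners,
#' with ties broken by lexicographic `record_id`. `on_ctgov` / `on_drks` flag
#' whether any member record originates from that registry.
#'
#' @param records Harmonized trial-record tibble.
#' @param clusters Cluster assignment from [build_clusters()].
#' @return Unified-trial tibble keyed by `trial_id`, with `n_records` and
#'   `member_record_ids`.
#' @export
merge_clusters <- function(records, clusters) {
  df <- dplyr::inner_join(records, clusters, by = "record_id") |>
    dplyr::mutate(.pref = registry_preference_rank(.data$registry)) |>
    dplyr::arrange(.data$trial_id, .data$.pref, .data$record_id)

  first_non_na <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) NA else x[1]
  }
  min_date_with_prec <- function(d, p) {
    ok <- !is.na(d)
    if (!any(ok)) return(list(date = as.Date(NA), prec = NA_character_))
    i <- which(ok)[order(d[ok], -precision_rank(p[ok]))][1]
    list(date = d[i], prec = p[i])
  }

  df |>
    dplyr::group_by(.data$trial_id) |>
    dplyr::summarise(
      n_records = dplyr::n(),
      member_record_ids = paste(sort(.data$record_id), collapse = ";"),
      .reg_pick = list(min_date_with_prec(
        .data$registration_date, .data$registration_date_precision)),
      .sta_pick = list(min_date_with_prec(
        .data$start_date, .data$start_date_precision)),
      on_ctgov = any(.data$registry == "ClinicalTrials.gov"),
      on_drks = any(.data$registry == "DRKS"),
      title = first_non_na(.data$title),
      study_type = first_non_na(.data$study_type),
      sample_size = first_non_na(.data$sample_size),
      sponsor_names = join_multi(unique(unlist(
        purrr::map(.data$sponsor_names,
                   ~ split_multi(if (is.na(.x)) "" else .x))))),
      contact_emails = join_multi(unique(unlist(
        purrr::map(.data$contact_emails,
                   ~ split_multi(if (is.na(.x)) "" else .x))))),
      secondary_ids = join_multi(setdiff(unique(unlist(
        purrr::map(.data$secondary_ids,
                   ~ split_multi(if (is.na(.x)) "" else .x)))),
        .data$record_id)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      registration_date = as.Date(vapply(
        .data$.reg_pick, function(x) as.numeric(x$date), numeric(1)),
        origin = as.Date("1970-01-01")),
      registration_date_precision = vapply(
        .data$.reg_pick, function(x) x$prec, character(1)),
      start_date = as.Date(vapply(
        .data$.sta_pick, function(x) as.numeric(x$date), numeric(1)),
        origin = as.Date("1970-01-01")),
      start_date_precision = vapply(
        .data$.sta_pick, function(x) x$prec, character(1)),
      .after = "member_record_ids"
    ) |>
    dplyr::select(-".reg_pick", -".sta_pick")
}

#' End-to-end deduplication of harmonized records
#'
#' Runs the full step-wise process: ID-cascade edges, blocked candidate
#' generation, classifier edges (when a matcher is supplied), connected
#' components, and cluster merging.
#'
#' @param records Harmonized trial-record tibble.
#' @param matcher Optional `ctrq_matcher`; when `NULL` only ID evidence links.
#' @param threshold Classifier match threshold.
#' @param blocking Blocking config.
#' @return List with `trials` (unified-trial tibble), `clusters` (record to
#'   trial assignment) and `edges` (all link evidence).
#' @export
dedupe_trials <- function(records, matcher = NULL, threshold = 0.5,
                          blocking = blocking_config()) {
  id_edges <- link_by_ids(records)
  cls_edges <- if (!is.null(matcher)) {
    cand <- generate_candidates(records, blocking, exclude = id_edges)
    classify_pairs(records, cand, matcher, threshold)
  } else {
    tibble(id1 = character(), id2 = character(), evidence = character(),
           probability = numeric())
  }
  edges <- dplyr::bind_rows(id_edges, cls_edges)
  clusters <- build_clusters(records, edges)
  list(trials = merge_clusters(records, clusters),
       clusters = clusters, edges = edges)
}

#' Pairwise linkage quality against a ground-truth clustering
#'
#' Precision, recall and F1 over unordered record pairs: a pair counts as
#' predicted-positive when both records share a predicted cluster, and as a
#' true positive when they also share a ground-truth cluster.
#'
#' @param clusters Predicted assignment (`record_id`, `trial_id`).
#' @param truth Ground-truth assignment (`record_id`, `trial_uid` or second
#'   column).
#' @return One-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
pairwise_linkage_metrics <- function(clusters, truth) {
  pair_set <- function(ids, grp) {
    sp <- split(ids, grp)
    sp <- sp[lengths(sp) > 1]
    unlist(purrr::map(sp, function(v) {
      v <- sort(v)
      cmb <- utils::combn(v, 2)
      paste(cmb[1, ], cmb[2, ], sep = "\r")
    }), use.names = FALSE)
  }
  pred <- pair_set(clusters$record_id, clusters$trial_id)
  tru <- pair_set(truth[[1]], truth[[2]])
  tp <- length(intersect(pred, tru))
  fp <- length(setdiff(pred, tru))
  fn <- length(setdiff(tru, pred))
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  tibble(tp = tp, fp = fp, fn = fn,
         precision = precision, recall = recall, f1 = f1)
}
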