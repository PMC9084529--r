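test_that("ID cascade links shared primary and secondary IDs, brute-force checked", {
  recs <- make_records(
    make_record("NCT00000001"),
    make_record("DRKS00000001", registry = "DRKS",
                secondary_ids = "nct00000001 "),  # case/space insensitive
    make_record("EUCTR01-DE", registry = "ICTRP-partner:EUCTR",
                secondary_ids = "DRKS00000001"),
    make_record("NCT00000009"),
    make_record("DRKS00000007", registry = "DRKS"),
    make_record("ISRCTN00000003", registry = "ICTRP-partner:ISRCTN")
  )
  edges <- link_by_ids(recs)
  expect_setequal(paste(edges$id1, edges$id2),
                  c("DRKS00000001 NCT00000001", "DRKS00000001 EUCTR01-DE"))
  expect_true(all(edges$evidence == "secondary_id"))

  # brute-force all-pairs comparison agrees
  brute <- t(utils::combn(recs$record_id, 2))
  hit <- apply(brute, 1, function(p) {
    a <- recs[recs$record_id == p[1], ]
    b <- recs[recs$record_id == p[2], ]
    ids_a <- toupper(trimws(c(a$record_id, strsplit(
      ifelse(is.na(a$secondary_ids), "", a$secondary_ids), ";")[[1]])))
    ids_b <- toupper(trimws(c(b$record_id, strsplit(
      ifelse(is.na(b$secondary_ids), "", b$secondary_ids), ";")[[1]])))
    length(intersect(ids_a, ids_b)) > 0
  })
  expect_equal(nrow(edges), sum(hit))

  # chain A-B, B-C unites all three after clustering
  clusters <- build_clusters(recs, edges)
  expect_equal(max(clusters$cluster_size), 3)
  expect_equal(dplyr::n_distinct(clusters$trial_id), 4)
  expect_equal(nrow(link_by_ids(recs[4:6, ])), 0)  # disjoint IDs: no edges
})

test_that("link_by_ids rejects duplicate record ids and handles empty input", {
  expect_error(link_by_ids(make_records(make_record("A"), make_record("A"))),
               "unique")
  expect_equal(nrow(link_by_ids(make_record("A")[0, ])), 0)
})

test_that("blocking yields planted duplicate pairs and documents its misses", {
  a <- make_record("NCT00000001", title = "Velotinib in Severe Asthma",
                   registration_date = as.Date("2012-03-01"))
  b <- make_record("DRKS00000001", registry = "DRKS",
                   title = "Velotinib in Asthma Severe",
                   registration_date = as.Date("2013-01-01"))
  cand <- generate_candidates(dplyr::bind_rows(a, b))
  expect_equal(nrow(cand), 1)

  # same pair three registration years apart with no shared block key:
  # a documented blocking miss
  b2 <- dplyr::mutate(b, registration_date = as.Date("2015-03-01"),
                      title = "Completely Different Words Here")
  cand2 <- generate_candidates(dplyr::bind_rows(a, b2))
  expect_equal(nrow(cand2), 0)
})

test_that("blocking recovers at least 95% of planted duplicate pairs", {
  sim <- simulate_registry(generator_config(n_trials = 200), seed = 11)
  recs <- harmonize_simulation(sim)
  truth <- sim$truth$records
  true_pairs <- truth |>
    dplyr::inner_join(truth, by = "trial_uid",
                      relationship = "many-to-many") |>
    dplyr::filter(.data$record_id.x < .data$record_id.y) |>
    dplyr::transmute(id1 = .data$record_id.x, id2 = .data$record_id.y)
  expect_gt(nrow(true_pairs), 30)  # scenario plants enough duplicates
  covered <- dplyr::bind_rows(
    link_by_ids(recs)[, c("id1", "id2")],
    generate_candidates(recs)
  )
  found <- nrow(dplyr::inner_join(true_pairs, covered,
                                  by = c("id1", "id2")))
  expect_gte(found / nrow(true_pairs), 0.95)
})

test_that("matcher separates separable labels and refuses single-class input", {
  set.seed(21)
  n <- 400
  dup <- rep(c(TRUE, FALSE), each = n / 2)
  feats <- tibble::tibble(
    id1 = sprintf("A%03d", seq_len(n)), id2 = sprintf("B%03d", seq_len(n)),
    id_overlap = FALSE,
    title_similarity = ifelse(dup, runif(n, 0.9, 1), runif(n, 0, 0.3)),
    reg_gap_days = ifelse(dup, sample(0:5, n, TRUE),
                          sample(100:900, n, TRUE)),
    start_gap_days = ifelse(dup, sample(0:5, n, TRUE),
                            sample(100:900, n, TRUE)),
    sample_size_ratio = ifelse(dup, runif(n, 0.9, 1), runif(n, 0.1, 0.6)),
    shared_contact = dup
  )
  train_idx <- seq_len(n) %% 2 == 0
  m <- train_matcher(feats[train_idx, ], dup[train_idx], seed = 5)
  p <- predict_match_prob(m, feats[!train_idx, ])
  expect_equal(mean((p >= 0.5) == dup[!train_idx]), 1)

  expect_error(train_matcher(feats, rep(TRUE, n)), "both")
})

test_that("matcher tolerates 5% flipped labels with held-out accuracy >= 0.9", {
  set.seed(31)
  n <- 1000
  dup <- rep(c(TRUE, FALSE), each = n / 2)
  feats <- tibble::tibble(
    id1 = sprintf("A%04d", seq_len(n)), id2 = sprintf("B%04d", seq_len(n)),
    id_overlap = FALSE,
    title_similarity = ifelse(dup, runif(n, 0.8, 1), runif(n, 0, 0.4)),
    reg_gap_days = ifelse(dup, sample(0:10, n, TRUE),
                          sample(50:900, n, TRUE)),
    start_gap_days = ifelse(dup, sample(0:10, n, TRUE),
                            sample(50:900, n, TRUE)),
    sample_size_ratio = ifelse(dup, runif(n, 0.85, 1), runif(n, 0.1, 0.7)),
    shared_contact = dup & runif(n) < 0.8
  )
  labels <- dup
  flip <- sample(n, n * 0.05)
  labels[flip] <- !labels[flip]
  train_idx <- seq_len(n) %% 2 == 0
  m <- train_matcher(feats[train_idx, ], labels[train_idx], seed = 6)
  p <- predict_match_prob(m, feats[!train_idx, ])
  expect_gte(mean((p >= 0.5) == dup[!train_idx]), 0.9)
})

test_that("identical features with conflicting labels give intermediate probabilities", {
  feats <- tibble::tibble(
    id1 = sprintf("A%02d", 1:40), id2 = sprintf("B%02d", 1:40),
    id_overlap = FALSE, title_similarity = 0.5, reg_gap_days = 10L,
    start_gap_days = 10L, sample_size_ratio = 0.5, shared_contact = FALSE
  )
  labels <- rep(c(TRUE, FALSE), 20)
  m <- train_matcher(feats, labels, seed = 7)
  p <- predict_match_prob(m, feats[1, ])
  expect_gt(p, 0)
  expect_lt(p, 1)
})

test_that("raising the classifier threshold never grows the edge set", {
  sim <- simulate_registry(generator_config(n_trials = 150), seed = 12)
  recs <- harmonize_simulation(sim)
  m <- train_matcher_from_sim(simulate_registry(
    generator_config(n_trials = 200), seed = 13), seed = 14)
  cand <- generate_candidates(recs, exclude = link_by_ids(recs))
  sets <- lapply(c(0.3, 0.5, 0.7, 0.9), function(th) {
    e <- classify_pairs(recs, cand, m, threshold = th)
    paste(e$id1, e$id2)
  })
  for (i in 2:4) expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  # boundary: threshold 1 keeps only certainty-1 pairs
  e1 <- classify_pairs(recs, cand, m, threshold = 1)
  expect_true(all(e1$probability == 1))
})

test_that("clusters are connected components and merging follows the policy", {
  # 10 records, edges forming components {3,2,1,1,1,1,1}
  recs <- dplyr::bind_rows(lapply(sprintf("R%02d", 1:10), make_record))
  edges <- tibble::tibble(id1 = c("R01", "R02", "R04"),
                          id2 = c("R02", "R03", "R05"),
                          evidence = "primary_id")
  clusters <- build_clusters(recs, edges)
  expect_equal(dplyr::n_distinct(clusters$trial_id), 7)
  expect_equal(sum(clusters$cluster_size == 1), 5)
  expect_equal(nrow(clusters), 10)  # partition: every record assigned once

  # merge: earliest registration date wins; registry flags OR together;
  # non-date conflicts prefer the ClinicalTrials.gov member
  recs2 <- make_records(
    make_record("DRKS00000009", registry = "DRKS",
                registration_date = as.Date("2009-11-30"),
                title = "DRKS title", sample_size = 40L),
    make_record("NCT00000008", registry = "ClinicalTrials.gov",
                registration_date = as.Date("2010-05-01"),
                title = "CTgov title", sample_size = 60L)
  )
  cl2 <- build_clusters(recs2, tibble::tibble(
    id1 = "DRKS00000009", id2 = "NCT00000008", evidence = "secondary_id"))
  uni <- merge_clusters(recs2, cl2)
  expect_equal(nrow(uni), 1)
  expect_equal(uni$trial_id, "DRKS00000009")  # lexicographically smallest
  expect_equal(uni$registration_date, as.Date("2009-11-30"))
  expect_true(uni$on_ctgov && uni$on_drks)
  expect_equal(uni$title, "CTgov title")
  expect_equal(uni$sample_size, 60L)
})

test_that("deduplication is deterministic given identical inputs and seed", {
  sim <- simulate_registry(generator_config(n_trials = 120), seed = 15)
  recs <- harmonize_simulation(sim)
  m <- train_matcher_from_sim(simulate_registry(
    generator_config(n_trials = 150), seed = 16), seed = 17)
  d1 <- dedupe_trials(recs, m)
  d2 <- dedupe_trials(recs, m)
  expect_identical(d1$clusters, d2$clusters)
  expect_identical(d1$trials, d2$trials)
  # partition invariant
  expect_equal(sum(unique(d1$clusters[c("trial_id", "cluster_size")])$
                     cluster_size), nrow(recs))
})
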