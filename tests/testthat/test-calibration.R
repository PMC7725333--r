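ann_scores <- function(pos, neg) {
  tibble::tibble(
    sequence_id = sprintf("S%03d", seq_len(length(pos) + length(neg))),
    score_bits = c(pos, neg),
    db_annotation_matches_profile = rep(c(TRUE, FALSE), c(length(pos), length(neg)))
  )
}

test_that("perfectly separated scores trace a clean ROC", {
  roc <- roc_curve(ann_scores(c(10, 9), c(1, 2)))
  at9 <- roc[roc$threshold == 9, ]
  expect_equal(at9$tpr, 1.0)
  expect_equal(at9$fpr, 0.0)
  expect_equal(at9$precision, 1.0)
  # thresholds descend; TPR/FPR are non-increasing as the threshold rises
  expect_true(all(diff(roc$threshold) < 0))
  expect_true(all(diff(roc$tpr) >= 0))
  expect_true(all(diff(roc$fpr) >= 0))
})

test_that("a tied positive and negative score give TPR equal to FPR", {
  roc <- roc_curve(ann_scores(5, 5))
  expect_equal(roc$tpr, roc$fpr)
})

test_that("one-class inputs are rejected", {
  expect_error(roc_curve(ann_scores(c(1, 2), numeric())), class = "glyco_input_error")
  expect_error(roc_curve(ann_scores(numeric(), c(1, 2))), class = "glyco_input_error")
})

test_that("ROC points match brute-force confusion matrices exactly", {
  for (seed in c(3, 17, 99)) {
    set.seed(seed)
    n <- 50
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.4, 0.6))
    if (!any(labels)) labels[1] <- TRUE
    if (all(labels)) labels[1] <- FALSE
    scores <- round(stats::rnorm(n, ifelse(labels, 52, 38), 8), 1)
    tbl <- tibble::tibble(
      sequence_id = as.character(seq_len(n)), score_bits = scores,
      db_annotation_matches_profile = labels
    )
    roc <- roc_curve(tbl)
    expect_equal(nrow(roc), length(unique(scores)))
    for (i in seq_len(nrow(roc))) {
      cm <- oracle_confusion(scores, labels, roc$threshold[i])
      expect_equal(unlist(roc[i, c("tp", "fp", "fn", "tn")]), cm)
    }
  }
})

test_that("the chosen threshold under perfect separation has zero errors", {
  roc <- roc_curve(ann_scores(c(60, 55, 52), c(30, 28, 12)))
  for (crit in c("mcc", "f1", "youden")) {
    ch <- choose_threshold(roc, crit)
    expect_equal(ch$threshold, 52) # top of the separating gap
    at <- roc[roc$threshold == ch$threshold, ]
    expect_equal(at$fp + at$fn, 0L)
  }
})

test_that("criterion maximization matches exhaustive search", {
  set.seed(8)
  for (case in 1:6) {
    pos <- round(stats::rnorm(12, 50, 8), 1)
    neg <- round(stats::rnorm(15, 40, 8), 1)
    roc <- roc_curve(ann_scores(pos, neg))
    scores <- c(pos, neg)
    labels <- rep(c(TRUE, FALSE), c(length(pos), length(neg)))
    mcc_of <- function(t) {
      cm <- oracle_confusion(scores, labels, t)
      den <- sqrt(prod(c(cm["tp"] + cm["fp"], cm["tp"] + cm["fn"], cm["tn"] + cm["fp"], cm["tn"] + cm["fn"])))
      if (den == 0) 0 else (cm[["tp"]] * cm[["tn"]] - cm[["fp"]] * cm[["fn"]]) / den
    }
    cand <- sort(unique(scores), decreasing = TRUE)
    best_val <- max(vapply(cand, mcc_of, numeric(1)))
    winners <- cand[vapply(cand, mcc_of, numeric(1)) == best_val]
    ch <- choose_threshold(roc, "mcc")
    expect_equal(ch$threshold, max(winners)) # stringent tie-break
    expect_equal(ch$value, best_val, tolerance = 1e-12)
  }
})

test_that("two-normal mixtures recover the analytic boundary", {
  db <- generate_score_db(500, 500, pos_mean = 55, neg_mean = 30, sd = 5, seed = 7)
  ch <- choose_threshold(roc_curve(db), "mcc")
  expect_gte(ch$threshold, 40)
  expect_lte(ch$threshold, 45)
  # convergence: at 10k per class the estimate sits within +/-1 bit of the
  # equal-likelihood boundary (55+30)/2 = 42.5
  db2 <- generate_score_db(10000, 10000, pos_mean = 55, neg_mean = 30, sd = 5, seed = 11)
  ch2 <- choose_threshold(roc_curve(db2), "mcc")
  expect_lt(abs(ch2$threshold - 42.5), 1)
})

test_that("a score discontinuity picks the top of the largest gap", {
  # plateau from 705 down to 303, then a detached tail from 57 to 41
  scores <- c(seq(705, 303, by = -2), seq(57, 41, by = -2))
  labels <- scores >= 303
  roc <- roc_curve(tibble::tibble(
    sequence_id = as.character(seq_along(scores)),
    score_bits = scores, db_annotation_matches_profile = labels
  ))
  ch <- choose_threshold(roc, "largest_gap")
  expect_equal(ch$threshold, 303)
  expect_equal(ch$value, 303 - 57)
})

test_that("ROC agrees with an independent implementation on the same sweep", {
  skip_if_not_installed("pROC")
  db <- generate_score_db(80, 120, pos_mean = 50, neg_mean = 35, sd = 6, seed = 13)
  roc <- roc_curve(db)
  ref <- pROC::roc(
    response = db$db_annotation_matches_profile, predictor = db$score_bits,
    direction = "<", quiet = TRUE
  )
  # compare sensitivities at matching specificities over our thresholds
  ref_pts <- pROC::coords(ref, x = roc$threshold - 1e-9, input = "threshold",
    ret = c("sensitivity", "specificity"), transpose = FALSE
  )
  expect_equal(roc$tpr, ref_pts$sensitivity, tolerance = 1e-9)
  expect_equal(1 - roc$fpr, ref_pts$specificity, tolerance = 1e-9)
})

test_that("scatter partition places thresholds inside inter-cloud gaps", {
  set.seed(21)
  scatter <- tibble::tibble(
    seq_id = sprintf("S%02d", 1:20),
    family = rep(c("A", "B"), each = 10),
    score_a = c(stats::rnorm(10, 300, 10), stats::rnorm(10, 150, 10)),
    score_b = c(stats::rnorm(10, 140, 10), stats::rnorm(10, 310, 10))
  )
  out <- scatter_partition(scatter, "A", "B")
  thr_a <- out$thresholds$threshold[out$thresholds$profile == "A"]
  expect_gt(thr_a, max(scatter$score_a[scatter$family == "B"]))
  expect_lt(thr_a, min(scatter$score_a[scatter$family == "A"]))
  expect_false(any(out$thresholds$degenerate))
  expect_true(out$review_required)
})

test_that("a sibling sequence is excluded by raising the threshold above it", {
  # the divergent-retaining-dehydratase situation: one cross-family sequence
  # (PdeG analogue) scores high on the sibling profile; the chosen threshold
  # must sit above it
  scatter <- tibble::tibble(
    seq_id = sprintf("S%02d", 1:11),
    family = c(rep("GPE05331", 8), rep("PdeG", 3)),
    score_a = c(480, 470, 455, 452, 449, 447, 442, 440, 410, 180, 170),
    score_b = c(rep(60, 8), 400, 390, 385)
  )
  out <- scatter_partition(scatter, "GPE05331", "PdeG")
  thr <- out$thresholds$threshold[out$thresholds$profile == "GPE05331"]
  expect_gt(thr, 410) # excludes the cross-scoring sequence
  expect_lte(thr, 440)
})

test_that("identical clouds flag a degenerate partition", {
  scatter <- tibble::tibble(
    seq_id = sprintf("S%02d", 1:8),
    family = rep(c("A", "B"), each = 4),
    score_a = rep(c(100, 105, 110, 115), 2),
    score_b = rep(c(100, 105, 110, 115), 2)
  )
  out <- scatter_partition(scatter, "A", "B")
  expect_true(all(out$thresholds$degenerate))
  expect_error(
    scatter_partition(scatter[c(1, 5:8), ], "A", "B"),
    class = "glyco_input_error"
  )
})

test_that("seed thresholds are the minimum self-scores", {
  seeds <- list(gpe_id = "GPE50010", exp_scores = c(410, 432, 560))
  expect_equal(seed_threshold(seeds, "t_exp"), 410)
  seeds$extend_scores <- c(seeds$exp_scores, 395)
  expect_equal(seed_threshold(seeds, "t_extend"), 395)
  expect_error(
    seed_threshold(list(gpe_id = "GPE50010", exp_scores = c(410)), "t_extend"),
    class = "glyco_input_error"
  )
  expect_error(seed_threshold(list(exp_scores = numeric()), "t_exp"), class = "glyco_input_error")
})

test_that("T_extend never exceeds T_exp when the extended set contains the seeds", {
  set.seed(37)
  for (case in 1:10) {
    exp_scores <- round(stats::runif(sample(3:8, 1), 200, 600), 1)
    extend_scores <- c(exp_scores, round(stats::runif(sample(1:6, 1), 150, 650), 1))
    seeds <- list(gpe_id = "GPEx", exp_scores = exp_scores, extend_scores = extend_scores)
    expect_lte(seed_threshold(seeds, "t_extend"), seed_threshold(seeds, "t_exp"))
  }
})

test_that("the synthetic score database is reproducible and well-centred", {
  a <- generate_score_db(400, 400, seed = 5)
  b <- generate_score_db(400, 400, seed = 5)
  expect_identical(a, b)
  pos <- a$score_bits[a$db_annotation_matches_profile]
  neg <- a$score_bits[!a$db_annotation_matches_profile]
  expect_lt(abs(mean(pos) - 55), 3 * 5 / sqrt(400))
  expect_lt(abs(mean(neg) - 30), 3 * 5 / sqrt(400))
  # near-zero spread separates the classes completely
  tight <- generate_score_db(50, 50, sd = 1e-6, seed = 2)
  expect_gt(
    min(tight$score_bits[tight$db_annotation_matches_profile]),
    max(tight$score_bits[!tight$db_annotation_matches_profile])
  )
  expect_error(generate_score_db(0, 5), class = "glyco_input_error")
  expect_error(generate_score_db(5, 5, sd = 0), class = "glyco_input_error")
})
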