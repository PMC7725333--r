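#' ROC curve over annotated bit scores
#'
#' Sweeps every distinct score as an inclusive threshold (a sequence is
#' predicted a family member when its score is >= the threshold) and
#' tabulates the confusion matrix against database annotations, which are
#' assumed correct.
#'
#' @param scores Tibble with columns `score_bits` and
#'   `db_annotation_matches_profile` (logical), one row per sequence; or a
#'   data frame with those columns.
#' @return A tibble ordered by decreasing threshold: `threshold`, `tp`,
#'   `fp`, `fn`, `tn`, `tpr`, `fpr`, `precision`.
#' @export
roc_curve <- function(scores) {
  s <- scores$score_bits
  y <- scores$db_annotation_matches_profile
  if (any(!is.finite(s))) input_error("scores must be finite")
  if (!any(y) || all(y)) input_error("ROC requires at least one positive and one negative sequence")
  thr <- sort(unique(s), decreasing = TRUE)
  P <- sum(y)
  N <- sum(!y)
  tp <- vapply(thr, function(t) sum(y & s >= t), integer(1))
  fp <- vapply(thr, function(t) sum(!y & s >= t), integer(1))
  tibble(
    threshold = thr, tp = tp, fp = fp, fn = P - tp, tn = N - fp,
    tpr = tp / P, fpr = fp / N,
    precision = ifelse(tp + fp == 0, NA_real_, tp / (tp + fp))
  )
}

roc_mcc <- function(roc) {
  tp <- as.numeric(roc$tp)
  fp <- as.numeric(roc$fp)
  fn <- as.numeric(roc$fn)
  tn <- as.numeric(roc$tn)
  num <- tp * tn - fp * fn
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  ifelse(den == 0, 0, num / den)
}

#' Choose an operating threshold from a ROC sweep
#'
#' Default criterion is the Matthews correlation coefficient; F1 and
#' Youden's J are alternatives. Ties are broken towards the *highest*
#' threshold — the most stringent operating point. The `largest_gap`
#' criterion instead returns the score at the upper edge of the widest gap
#' between consecutive distinct scores, for score distributions that
#' separate into a high plateau and a low tail rather than tracing a usable
#' ROC.
#'
#' @param roc Tibble from [roc_curve()].
#' @param criterion One of `"mcc"`, `"f1"`, `"youden"`, `"largest_gap"`.
#' @return A list: `threshold`, `criterion`, `value` (criterion value at
#'   the chosen point, or the gap width for `largest_gap`).
#' @export
choose_threshold <- function(roc, criterion = c("mcc", "f1", "youden", "largest_gap")) {
  criterion <- match.arg(criterion)
  if (criterion == "largest_gap") {
    thr <- sort(roc$threshold, decreasing = TRUE)
    if (length(thr) < 2) input_error("largest_gap needs at least two distinct scores")
    gaps <- thr[-length(thr)] - thr[-1]
    i <- which(gaps == max(gaps))
    i <- i[length(i)] # lowest upper edge among equal gaps: most inclusive plateau
    return(list(threshold = thr[i], criterion = criterion, value = max(gaps)))
  }
  val <- switch(criterion,
    mcc = roc_mcc(roc),
    f1 = with(roc, ifelse(2 * tp + fp + fn == 0, 0, 2 * tp / (2 * tp + fp + fn))),
    youden = roc$tpr - roc$fpr
  )
  best <- which(val == max(val))
  # stringency bias: among equally good operating points take the highest
  # threshold
  i <- best[which.max(roc$threshold[best])]
  list(threshold = roc$threshold[i], criterion = criterion, value = val[i])
}

#' Per-axis thresholds from a two-profile bit-score scatter
#'
#' For sibling enzyme families whose database annotations cannot separate
#' them, every sequence is scored against both profiles and thresholds are
#' read off the scatter: along each axis, the widest margin between the
#' self-family cloud (above) and the cross-family cloud (below). When the
#' clouds overlap on an axis no clean margin exists; the returned threshold
#' then maximizes Youden's J along that axis and the result is flagged
#' degenerate. Either way the decision is marked curator-reviewable and the
#' scatter data are returned for inspection.
#'
#' @param scatter Tibble with columns `seq_id`, `family` (values
#'   `profile_a`/`profile_b`), `score_a`, `score_b`.
#' @param profile_a,profile_b Family labels used in `family`.
#' @return A list: `thresholds` (tibble with `profile`, `threshold`,
#'   `margin`, `degenerate`), `scatter` (the input), `review_required`
#'   (always `TRUE`: scatter thresholds are manual-practice decisions).
#' @export
scatter_partition <- function(scatter, profile_a = "A", profile_b = "B") {
  fam <- scatter$family
  if (sum(fam == profile_a) < 2 || sum(fam == profile_b) < 2) {
    input_error("scatter_partition needs at least two sequences per family cloud")
  }
  axis_threshold <- function(self_scores, cross_scores) {
    lo <- max(cross_scores)
    hi <- min(self_scores)
    if (hi > lo) {
      list(threshold = (hi + lo) / 2, margin = hi - lo, degenerate = FALSE)
    } else {
      # overlapping clouds: best empirical split, flagged for the curator
      cand <- sort(unique(c(self_scores, cross_scores)), decreasing = TRUE)
      j <- vapply(cand, function(t) {
        mean(self_scores >= t) - mean(cross_scores >= t)
      }, numeric(1))
      best <- cand[which.max(j)]
      list(threshold = best, margin = hi - lo, degenerate = TRUE)
    }
  }
  a <- axis_threshold(scatter$score_a[fam == profile_a], scatter$score_a[fam == profile_b])
  b <- axis_threshold(scatter$score_b[fam == profile_b], scatter$score_b[fam == profile_a])
  list(
    thresholds = tibble(
      profile = c(profile_a, profile_b),
      threshold = c(a$threshold, b$threshold),
      margin = c(a$margin, b$margin),
      degenerate = c(a$degenerate, b$degenerate)
    ),
    scatter = scatter,
    review_required = TRUE
  )
}

#' Seed self-score thresholds (T_exp / T_extend)
#'
#' T_exp is the minimum self-score of the experimentally characterized
#' seeds against their own profile; T_extend is the minimum over the
#' extended homologue set. Used directly as the profile threshold when the
#' database cannot support a ROC sweep, or when a narrow profile must not
#' be diluted below its own seeds.
#'
#' @param seeds A list (or `SeedScores`-like object) with `gpe_id`,
#'   `exp_scores` (non-empty numeric) and optionally `extend_scores`.
#' @param mode `"t_exp"` or `"t_extend"`.
#' @return The threshold in bits.
#' @export
seed_threshold <- function(seeds, mode = c("t_exp", "t_extend")) {
  mode <- match.arg(mode)
  if (is.null(seeds$exp_scores) || length(seeds$exp_scores) == 0) {
    input_error("seed scores of experimentally characterized sequences are required")
  }
  if (mode == "t_exp") {
    return(min(seeds$exp_scores))
  }
  if (is.null(seeds$extend_scores) || length(seeds$extend_scores) == 0) {
    input_error(paste0(
      "no extended dataset for ", seeds$gpe_id %||% "profile",
      "; t_extend is undefined"
    ))
  }
  min(seeds$extend_scores)
}

#' Synthetic annotated score set for calibration
#'
#' Two-component normal score mixture with labels, standing in for a
#' database sweep: positives (annotation matches the profile) around
#' `pos_mean`, negatives around `neg_mean`, common standard deviation,
#' truncated at zero.
#'
#' @param n_pos,n_neg Component sizes (>= 1).
#' @param pos_mean,neg_mean Component means in bits.
#' @param sd Common standard deviation (> 0).
#' @param seed Random seed.
#' @return A tibble: `sequence_id`, `score_bits`,
#'   `db_annotation_matches_profile`.
#' @export
generate_score_db <- function(n_pos, n_neg, pos_mean = 55, neg_mean = 30, sd = 5, seed = 1) {
  if (n_pos < 1 || n_neg < 1) input_error("n_pos and n_neg must be >= 1")
  if (sd <= 0) input_error("sd must be > 0")
  set.seed(seed)
  tibble(
    sequence_id = sprintf("SEQ%06d", seq_len(n_pos + n_neg)),
    score_bits = pmax(0, round(c(
      stats::rnorm(n_pos, pos_mean, sd),
      stats::rnorm(n_neg, neg_mean, sd)
    ), 4)),
    db_annotation_matches_profile = rep(c(TRUE, FALSE), c(n_pos, n_neg))
  )
}
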