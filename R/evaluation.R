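#' Build train/test splits of the association data
#'
#' Three designs over the known positive pairs:
#' * `cv5`: k-fold partition of the positives (each fold in turn is the test
#'   set).
#' * `transductive`: a random holdout whose every test miRNA and disease
#'   still appears in some training pair (partially observed entities).
#' * `inductive_disease`: entire diseases are held out — no pair of a test
#'   disease remains in training (completely new diseases).
#'
#' @param pairs Data frame `miRNA_id`, `disease_id` of known positives.
#' @param mode Split design.
#' @param seed Split seed.
#' @param k Number of folds for `cv5`.
#' @param holdout_frac Fraction of pairs (transductive) or diseases
#'   (inductive) held out.
#' @param holdout_diseases Explicit disease set for `inductive_disease`
#'   (overrides `holdout_frac`).
#' @return A list of `md_split` objects (one per fold for `cv5`, otherwise
#'   length one) with elements `train`, `test_pos`, `mode`, `seed`.
#' @export
make_splits <- function(pairs, mode = c("cv5", "transductive",
                                        "inductive_disease"),
                        seed = 0L, k = 5, holdout_frac = 0.2,
                        holdout_diseases = NULL) {
  mode <- match.arg(mode)
  pairs <- tibble::as_tibble(pairs[c("miRNA_id", "disease_id")])
  if (nrow(pairs) == 0) abort("no association pairs to split")
  n <- nrow(pairs)

  mk <- function(train, test_pos) {
    structure(list(train = train, test_pos = test_pos, mode = mode,
                   seed = seed), class = "md_split")
  }

  if (mode == "cv5") {
    fold <- with_stream(seed, sample(rep_len(seq_len(k), n)))
    return(lapply(seq_len(k), function(f) {
      mk(pairs[fold != f, ], pairs[fold == f, ])
    }))
  }

  if (mode == "transductive") {
    test_idx <- with_stream(seed, sample.int(n, round(holdout_frac * n)))
    train <- pairs[-test_idx, ]
    test <- pairs[test_idx, ]
    visible <- test$miRNA_id %in% train$miRNA_id &
      test$disease_id %in% train$disease_id
    # pairs that would orphan an entity go back to training
    train <- dplyr::bind_rows(train, test[!visible, ])
    return(list(mk(train, test[visible, ])))
  }

  diseases <- sort(unique(pairs$disease_id))
  if (is.null(holdout_diseases)) {
    n_hold <- max(1L, round(holdout_frac * length(diseases)))
    holdout_diseases <- with_stream(seed, sample(diseases, n_hold))
  }
  if (!all(holdout_diseases %in% diseases)) {
    abort("held-out disease absent from the dataset")
  }
  test <- pairs[pairs$disease_id %in% holdout_diseases, ]
  train <- pairs[!pairs$disease_id %in% holdout_diseases, ]
  list(mk(train, test))
}

#' @export
print.md_split <- function(x, ...) {
  cat(sprintf("<md_split %s: %d train / %d test positives>\n",
              x$mode, nrow(x$train), nrow(x$test_pos)))
  invisible(x)
}

#' Sample test-time negative pairs at a fixed positive:negative rate
#'
#' Negatives are drawn uniformly without replacement from unlabeled pairs
#' within the test entity universe (miRNAs and diseases visible in the test
#' positives), excluding every known positive (train and test).
#'
#' @param split An `md_split`.
#' @param nr Negatives per positive (1, 5 or 10 in the standard protocol).
#' @param seed Sampling seed.
#' @return Tibble of negative pairs.
#' @export
sample_test_negatives <- function(split, nr = 1, seed = 0L) {
  stopifnot(inherits(split, "md_split"))
  mirnas <- unique(split$test_pos$miRNA_id)
  diseases <- unique(split$test_pos$disease_id)
  cand <- tidyr::expand_grid(miRNA_id = mirnas, disease_id = diseases)
  known <- dplyr::bind_rows(split$train, split$test_pos)
  key <- paste(cand$miRNA_id, cand$disease_id, sep = "\r")
  cand <- cand[!key %in% paste(known$miRNA_id, known$disease_id, sep = "\r"), ]
  n_neg <- nr * nrow(split$test_pos)
  if (nrow(cand) < n_neg) {
    abort(sprintf("only %d candidate negatives for %d requested",
                  nrow(cand), n_neg))
  }
  with_stream(seed, cand[sample.int(nrow(cand), n_neg), ])
}

#' Area under the ROC curve
#'
#' Computed as the rank statistic
#' \eqn{P(s_{pos} > s_{neg}) + \tfrac12 P(s_{pos} = s_{neg})} (the
#' normalised Mann-Whitney U), so it is invariant under strictly monotone
#' score transforms.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1 or logical).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(as.integer(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) abort("AUC needs both classes")
  r <- rank(scores)   # midranks handle ties as half-wins
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Average precision
#'
#' The discrete sum \eqn{AP = \sum_k (R_k - R_{k-1}) P_k} over the
#' descending-score sweep, with tied scores entering as one group (no linear
#' interpolation of the precision-recall curve).
#'
#' @inheritParams auc
#' @return AP in \[0, 1\].
#' @export
average_precision <- function(scores, labels) {
  labels <- as.integer(labels)
  if (sum(labels) == 0) abort("AP needs at least one positive")
  thr <- sort(unique(scores), decreasing = TRUE)
  grp <- match(scores, thr)
  pos_at <- tapply(labels, grp, sum)
  tot_at <- tapply(rep(1, length(grp)), grp, sum)
  tp <- cumsum(pos_at[as.character(seq_along(thr))])
  np <- cumsum(tot_at[as.character(seq_along(thr))])
  prec <- tp / np
  rec <- tp / sum(labels)
  sum(diff(c(0, rec)) * prec)
}

#' Thresholded confusion-matrix metrics
#'
#' Sensitivity, specificity, accuracy, precision, F1 and the Matthews
#' correlation coefficient at a fixed score threshold. Undefined ratios
#' (empty denominators) are reported as 0, including MCC's degenerate case —
#' so an all-positive predictor on balanced data scores SN = 1, SP = 0,
#' ACC = 0.5, MCC = 0.
#'
#' @inheritParams auc
#' @param threshold Score cut-off for calling a pair positive (default 0.5).
#' @return A tibble with columns `SN`, `SP`, `ACC`, `Pre`, `F1`, `MCC`,
#'   `threshold`.
#' @export
threshold_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  safe <- function(num, den) if (den == 0) 0 else num / den
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  sn <- safe(tp, tp + fn)
  pre <- safe(tp, tp + fp)
  tibble::tibble(
    SN = sn,
    SP = safe(tn, tn + fp),
    ACC = safe(tp + tn, tp + fp + tn + fn),
    Pre = pre,
    F1 = safe(2 * pre * sn, pre + sn),
    MCC = if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den,
    threshold = threshold
  )
}

#' True positives among the top-n scored pairs
#'
#' Counts label-1 pairs among the `n` highest scores; boundary ties break by
#' stable identifier order when `ids` is supplied (row order otherwise).
#'
#' @inheritParams auc
#' @param n Cut-off (default 100); truncated to the number of pairs.
#' @param ids Optional character vector for deterministic tie-breaking.
#' @return Integer count in \[0, n\].
#' @export
top_n_hits <- function(scores, labels, n = 100, ids = NULL) {
  labels <- as.integer(labels)
  n <- min(n, length(scores))
  ord <- if (is.null(ids)) order(-scores) else order(-scores, ids)
  sum(labels[ord[seq_len(n)]])
}

#' Full metric report for a scored test set
#'
#' @param predictions Data frame with `score` and `label` columns (e.g. a
#'   labeled [predict_scores()] table).
#' @param nr The positive:negative rate the test set was built with
#'   (reported alongside).
#' @param threshold Threshold for the confusion-matrix metrics.
#' @param top_n Cut-off for the top-n hit count.
#' @return A one-row tibble `AUC`, `AP`, `SN`, `SP`, `ACC`, `Pre`, `F1`,
#'   `MCC`, `TopN`, `nr`, `threshold` (class `md_metrics`).
#' @export
evaluate_predictions <- function(predictions, nr = NA_real_, threshold = 0.5,
                                 top_n = 100) {
  s <- predictions$score
  y <- as.integer(predictions$label)
  ids <- if (all(c("miRNA_id", "disease_id") %in% names(predictions))) {
    paste(predictions$miRNA_id, predictions$disease_id)
  } else {
    NULL
  }
  out <- dplyr::bind_cols(
    tibble::tibble(AUC = auc(s, y), AP = average_precision(s, y)),
    threshold_metrics(s, y, threshold)[, c("SN", "SP", "ACC", "Pre", "F1", "MCC")],
    tibble::tibble(TopN = top_n_hits(s, y, top_n, ids), nr = nr,
                   threshold = threshold)
  )
  structure(out, class = c("md_metrics", class(out)))
}
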