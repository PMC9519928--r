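demo_pairs <- function(n_m = 12, n_d = 8, frac = 0.4, seed = 1) {
  withr::with_seed(seed, {
    all <- tidyr::expand_grid(miRNA_id = sprintf("m%02d", 1:n_m),
                              disease_id = sprintf("d%02d", 1:n_d))
    all[runif(nrow(all)) < frac, ]
  })
}

test_that("cv folds are disjoint, cover all positives and are seed-stable", {
  pairs <- demo_pairs()
  folds <- make_splits(pairs, "cv5", seed = 3)
  expect_length(folds, 5)
  test_keys <- lapply(folds, function(f) {
    paste(f$test_pos$miRNA_id, f$test_pos$disease_id)
  })
  expect_equal(anyDuplicated(unlist(test_keys)), 0)
  expect_setequal(unlist(test_keys), paste(pairs$miRNA_id, pairs$disease_id))
  for (f in folds) {
    expect_equal(nrow(dplyr::inner_join(f$train, f$test_pos,
                                        by = c("miRNA_id", "disease_id"))), 0)
  }
  folds2 <- make_splits(pairs, "cv5", seed = 3)
  expect_identical(folds[[1]]$test_pos, folds2[[1]]$test_pos)
})

test_that("transductive test entities all appear in training", {
  sp <- make_splits(demo_pairs(), "transductive", seed = 5)[[1]]
  expect_true(all(sp$test_pos$miRNA_id %in% sp$train$miRNA_id))
  expect_true(all(sp$test_pos$disease_id %in% sp$train$disease_id))
  expect_equal(nrow(dplyr::inner_join(sp$train, sp$test_pos,
                                      by = c("miRNA_id", "disease_id"))), 0)
})

test_that("inductive splits exclude every pair of the held-out diseases", {
  pairs <- demo_pairs()
  sp <- make_splits(pairs, "inductive_disease", seed = 2)[[1]]
  expect_false(any(sp$test_pos$disease_id %in% sp$train$disease_id))
  expect_setequal(
    paste(dplyr::bind_rows(sp$train, sp$test_pos)$miRNA_id,
          dplyr::bind_rows(sp$train, sp$test_pos)$disease_id),
    paste(pairs$miRNA_id, pairs$disease_id)
  )
  expect_error(
    make_splits(pairs, "inductive_disease", holdout_diseases = "ghost"),
    "absent"
  )
})

test_that("test negatives respect the rate, the exclusions and the seed", {
  # a split whose test universe is large enough for a 1:5 rate
  sp <- structure(list(
    train = tidyr::expand_grid(miRNA_id = sprintf("m%02d", 1:10),
                               disease_id = sprintf("d%02d", 1:3)),
    test_pos = tibble::tibble(miRNA_id = sprintf("m%02d", 1:6),
                              disease_id = sprintf("d%02d", 4:9)),
    mode = "transductive", seed = 1L
  ), class = "md_split")
  for (nr in c(1, 5)) {
    neg <- sample_test_negatives(sp, nr = nr, seed = 4)
    expect_equal(nrow(neg), nr * nrow(sp$test_pos))
    known <- dplyr::bind_rows(sp$train, sp$test_pos)
    expect_equal(nrow(dplyr::inner_join(neg, known,
                                        by = c("miRNA_id", "disease_id"))), 0)
  }
  expect_identical(sample_test_negatives(sp, 1, seed = 4),
                   sample_test_negatives(sp, 1, seed = 4))
  # 6 x 6 universe minus 6 positives leaves 30 < 60 candidates
  expect_error(sample_test_negatives(sp, nr = 10, seed = 4), "candidate")
})

test_that("AUC equals exhaustive pair counting and handles ties", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  for (seed in 1:5) {
    withr::with_seed(seed, {
      s <- round(runif(40), 2)   # rounding forces ties
      y <- rbinom(40, 1, 0.4)
    })
    if (sum(y) == 0 || sum(y) == 40) next
    expect_equal(auc(s, y), oracle_auc(s, y), tolerance = 1e-12)
    # invariance under strictly monotone transforms
    expect_equal(auc(plogis(3 * s - 1), y), auc(s, y), tolerance = 1e-12)
  }
  expect_error(auc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("AP matches the naive sweep and its closed forms", {
  expect_equal(average_precision(c(0.9, 0.7, 0.3), c(1, 1, 0)), 1)
  # single positive at rank r: AP = 1/r
  for (r in c(1, 3, 7)) {
    s <- seq(1, 0.1, length.out = 10)
    y <- replace(rep(0, 10), r, 1)
    expect_equal(average_precision(s, y), 1 / r, tolerance = 1e-12)
  }
  for (seed in 1:5) {
    withr::with_seed(seed, {
      s <- round(runif(30), 1)
      y <- rbinom(30, 1, 0.3)
    })
    if (sum(y) == 0) next
    expect_equal(average_precision(s, y), oracle_ap(s, y), tolerance = 1e-12)
  }
  expect_error(average_precision(c(0.1), c(0)), "positive")
})

test_that("AP is at least prevalence for better-than-random rankings", {
  hits <- 0; total <- 0
  for (seed in 1:100) {
    withr::with_seed(seed, {
      y <- rbinom(50, 1, 0.3)
      s <- y * 0.2 + runif(50)   # mild signal: beats random on average
    })
    if (sum(y) == 0) next
    if (auc(s, y) < 0.5) next
    total <- total + 1
    hits <- hits + (average_precision(s, y) >= mean(y) - 1e-12)
  }
  expect_equal(hits, total)
})

test_that("threshold metrics reproduce the degenerate all-positive row", {
  y <- rep(c(1, 0), 50)
  m <- threshold_metrics(rep(1, 100), y)
  expect_equal(m$SN, 1)
  expect_equal(m$SP, 0)
  expect_equal(m$ACC, 0.5)
  expect_equal(m$MCC, 0)
  perfect <- threshold_metrics(y, y)
  expect_equal(unlist(perfect[c("SN", "SP", "ACC", "Pre", "F1", "MCC")]),
               c(SN = 1, SP = 1, ACC = 1, Pre = 1, F1 = 1, MCC = 1))
})

test_that("threshold metrics match the direct confusion-matrix formulas", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      s <- runif(60)
      y <- rbinom(60, 1, 0.5)
    })
    m <- threshold_metrics(s, y, threshold = 0.5)
    tp <- sum(s >= 0.5 & y == 1); fp <- sum(s >= 0.5 & y == 0)
    tn <- sum(s < 0.5 & y == 0); fn <- sum(s < 0.5 & y == 1)
    expect_equal(m$SN, tp / (tp + fn))
    expect_equal(m$SP, tn / (tn + fp))
    expect_equal(m$Pre, tp / (tp + fp))
    expect_equal(m$ACC, (tp + tn) / 60)
    expect_equal(m$F1, 2 * tp / (2 * tp + fp + fn), tolerance = 1e-12)
    expect_equal(m$MCC,
                 (tp * tn - fp * fn) /
                   sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(8, {
    s <- runif(80)
    y <- rbinom(80, 1, 0.4)
  })
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc(s, y), ref, tolerance = 1e-12)
})

test_that("top-n hit counting is exact with deterministic tie-breaks", {
  y <- c(rep(1, 120), rep(0, 30))
  s <- c(seq(1, 0.5, length.out = 120), seq(0.4, 0, length.out = 30))
  expect_equal(top_n_hits(s, y, 100), 100)
  expect_equal(top_n_hits(1 - s, y, 30), 0)   # negatives now rank first
  # constructed 150-pair instance vs exhaustive count
  withr::with_seed(3, {
    s2 <- round(runif(150), 1)
    y2 <- rbinom(150, 1, 0.3)
    ids <- sprintf("p%03d", sample(150))
  })
  ord <- order(-s2, ids)
  expect_equal(top_n_hits(s2, y2, 100, ids), sum(y2[ord[1:100]]))
  expect_equal(top_n_hits(s2, y2, 500), sum(y2))   # n truncates
})

test_that("evaluate_predictions bundles every reported metric", {
  withr::with_seed(2, {
    pred <- tibble::tibble(
      miRNA_id = sprintf("m%02d", 1:40), disease_id = "d1",
      score = runif(40), label = rbinom(40, 1, 0.5)
    )
  })
  rep <- evaluate_predictions(pred, nr = 1)
  expect_named(rep, c("AUC", "AP", "SN", "SP", "ACC", "Pre", "F1", "MCC",
                      "TopN", "nr", "threshold"))
  expect_equal(rep$AUC, auc(pred$score, pred$label))
  expect_true(rep$MCC >= -1 && rep$MCC <= 1)
})
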