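#' Assemble pair feature vectors
#'
#' The feature vector for a pair (m, d) is the concatenation
#' `[E_m | E_d | F_m | S_d]`: the two structural embedding rows, the miRNA's
#' family one-hot vector, and the disease's semantic-similarity row over the
#' training disease set. Entities absent from the trained network fall back
#' to zero embedding rows; the biological blocks remain defined for them.
#'
#' @param pairs Data frame with columns `miRNA_id`, `disease_id`.
#' @param embedding An [train_sdne()] result.
#' @param fam_encoder A [family_encoder()].
#' @param tree The disease [ontology()].
#' @param training_diseases Column set of the similarity block.
#' @param delta Semantic-similarity decay factor.
#' @return Numeric matrix, one row per pair.
#' @export
assemble_pair_features <- function(pairs, embedding, fam_encoder, tree,
                                   training_diseases, delta = 0.5) {
  E_m <- embedding_rows(embedding, pairs$miRNA_id)
  E_d <- embedding_rows(embedding, pairs$disease_id)
  F_m <- family_one_hot(fam_encoder, pairs$miRNA_id)
  uniq_d <- unique(pairs$disease_id)
  S_rows <- semantic_feature_rows(tree, uniq_d, training_diseases, delta)
  S_d <- S_rows[match(pairs$disease_id, uniq_d), , drop = FALSE]
  X <- cbind(E_m, E_d, F_m, S_d)
  colnames(X) <- c(
    sprintf("Em_%03d", seq_len(ncol(E_m))),
    sprintf("Ed_%03d", seq_len(ncol(E_d))),
    sprintf("fam_%s", colnames(F_m)),
    sprintf("sim_%s", colnames(S_d))
  )
  rownames(X) <- NULL
  X
}

#' Sample negative miRNA-disease pairs for training
#'
#' Uniform sample without replacement from the unlabeled complement
#' (miRNA x disease) minus the known pairs.
#'
#' @param known_pairs Data frame `miRNA_id`, `disease_id` of known positives.
#' @param mirnas,diseases Candidate entity universes.
#' @param ratio Negatives per positive (default 1).
#' @param seed Sampling seed.
#' @return Tibble of sampled negative pairs.
#' @export
sample_training_negatives <- function(known_pairs, mirnas, diseases,
                                      ratio = 1, seed = 0L) {
  all_pairs <- tidyr::expand_grid(
    miRNA_id = as.character(mirnas), disease_id = as.character(diseases)
  )
  key <- paste(all_pairs$miRNA_id, all_pairs$disease_id, sep = "\r")
  known <- paste(known_pairs$miRNA_id, known_pairs$disease_id, sep = "\r")
  cand <- all_pairs[!key %in% known, ]
  n_neg <- round(ratio * nrow(known_pairs))
  if (n_neg > nrow(cand)) {
    abort(sprintf("need %d negatives but only %d unlabeled pairs available",
                  n_neg, nrow(cand)))
  }
  with_stream(seed, cand[sample.int(nrow(cand), n_neg), ])
}

#' Train the random forest association classifier
#'
#' A probability forest with 350 trees over the assembled pair features;
#' association scores are class-1 probabilities. Deterministic given `seed`.
#'
#' @param features Numeric feature matrix (rows = pairs).
#' @param labels Binary labels (0/1), both classes present.
#' @param n_estimators Number of trees (default 350).
#' @param seed Forest seed.
#' @return An `md_model` wrapping the fitted forest and its feature-length
#'   contract.
#' @export
train_model <- function(features, labels, n_estimators = 350, seed = 0L) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) abort("both classes must be present")
  if (nrow(features) != length(labels)) abort("one label per feature row")
  df <- as.data.frame(features)
  df$.label <- factor(labels, levels = c(0, 1))
  forest <- ranger::ranger(
    dependent.variable.name = ".label", data = df,
    num.trees = n_estimators, probability = TRUE,
    seed = seed, num.threads = 1
  )
  structure(
    list(forest = forest, n_features = ncol(features),
         feature_names = colnames(features), n_estimators = n_estimators,
         seed = seed),
    class = "md_model"
  )
}

#' @export
print.md_model <- function(x, ...) {
  cat(sprintf("<md_model: %d-tree probability forest over %d features>\n",
              x$n_estimators, x$n_features))
  invisible(x)
}

#' Score miRNA-disease pairs
#'
#' @param model A fitted [train_model()] result.
#' @param pairs Data frame `miRNA_id`, `disease_id`.
#' @param features Feature matrix aligned with `pairs` (from
#'   [assemble_pair_features()]).
#' @return A tibble `miRNA_id`, `disease_id`, `score` with scores in
#'   \[0, 1\] (class `md_predictions`).
#' @export
predict_scores <- function(model, pairs, features) {
  stopifnot(inherits(model, "md_model"))
  if (ncol(features) != model$n_features) {
    abort(sprintf("feature length %d does not match the fitted contract %d",
                  ncol(features), model$n_features))
  }
  pr <- predict(model$forest, data = as.data.frame(features),
                num.threads = 1)$predictions[, "1"]
  out <- tibble::tibble(
    miRNA_id = pairs$miRNA_id, disease_id = pairs$disease_id,
    score = as.numeric(pr)
  )
  structure(out, class = c("md_predictions", class(out)))
}
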