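# per-disease table of ancestor nodes with their semantic contributions:
# each tree code of d contributes delta^(hops) to the node owning each of its
# prefixes; multi-position nodes keep the maximum
semantic_contributions <- function(tree, disease_id, delta = 0.5) {
  codes <- tree$records$tree_code[tree$records$disease_id == disease_id]
  if (length(codes) == 0) return(NULL)
  owner <- setNames(tree$codes$owner_id, tree$codes$code)
  rows <- lapply(codes, function(code) {
    segs <- strsplit(code, ".", fixed = TRUE)[[1]]
    prefixes <- vapply(seq_along(segs),
                       function(k) paste(segs[1:k], collapse = "."), "")
    tibble::tibble(
      node = unname(owner[prefixes]),
      contribution = delta^(length(segs) - seq_along(segs))
    )
  })
  dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$node) |>
    dplyr::summarise(contribution = max(.data$contribution), .groups = "drop")
}

#' Semantic contribution of an ancestor to a disease
#'
#' In the Wang similarity measure a disease contributes 1 to itself and each
#' ancestor t receives \eqn{\Delta_d(t) = \max_{t'} \delta \cdot \Delta_d(t')}
#' over t's children on paths to d, i.e. \eqn{\delta^{h}} for the best
#' position h hops above d. Diseases occupying several tree positions take
#' the maximum over positions.
#'
#' @param tree An [ontology()].
#' @param disease_id The disease whose ancestor chart is evaluated.
#' @param ancestor_id An ancestor-or-self of `disease_id` (a disease id or an
#'   implicit category code).
#' @param delta Contribution decay factor per level, in (0, 1); default 0.5.
#' @return The contribution value in (0, 1].
#' @export
semantic_contribution <- function(tree, disease_id, ancestor_id, delta = 0.5) {
  stopifnot(inherits(tree, "ontology"), delta > 0, delta < 1)
  tab <- semantic_contributions(tree, disease_id, delta)
  if (is.null(tab) || !ancestor_id %in% tab$node) {
    abort(sprintf("%s is not an ancestor of %s", ancestor_id, disease_id))
  }
  tab$contribution[tab$node == ancestor_id]
}

#' Semantic similarity between two diseases
#'
#' \deqn{sim(d_1, d_2) = \frac{\sum_{t \in T_1 \cap T_2}
#'   (\Delta_{d_1}(t) + \Delta_{d_2}(t))}{DV(d_1) + DV(d_2)}}
#' where \eqn{T_i} is the ancestor-or-self node set of \eqn{d_i} and
#' \eqn{DV(d) = \sum_{t \in T_d} \Delta_d(t)}. Diseases absent from the
#' ontology are similar only to themselves.
#'
#' @inheritParams semantic_contribution
#' @param d1,d2 Disease identifiers.
#' @return Similarity in \[0, 1\]; symmetric; 1 when `d1 == d2`.
#' @examples
#' onto <- ontology(data.frame(disease_id = c("A", "B"),
#'                             tree_code = c("C04", "C04.100")))
#' semantic_similarity(onto, "A", "B")  # (1 + 0.5) / (1 + 1.5) = 0.6
#' @export
semantic_similarity <- function(tree, d1, d2, delta = 0.5) {
  if (identical(d1, d2)) return(1)
  t1 <- semantic_contributions(tree, d1, delta)
  t2 <- semantic_contributions(tree, d2, delta)
  if (is.null(t1) || is.null(t2)) return(0)
  shared <- intersect(t1$node, t2$node)
  if (length(shared) == 0) return(0)
  num <- sum(t1$contribution[match(shared, t1$node)]) +
    sum(t2$contribution[match(shared, t2$node)])
  num / (sum(t1$contribution) + sum(t2$contribution))
}

#' Disease-by-disease semantic similarity matrix
#'
#' @inheritParams semantic_contribution
#' @param diseases Disease identifiers spanning the rows/columns (the fitted
#'   training set; a new disease's feature vector is its similarity row over
#'   this fixed set).
#' @return A symmetric matrix with unit diagonal and entries in \[0, 1\].
#' @export
semantic_similarity_matrix <- function(tree, diseases, delta = 0.5) {
  diseases <- as.character(diseases)
  tabs <- lapply(diseases, semantic_contributions, tree = tree, delta = delta)
  n <- length(diseases)
  S <- diag(1, n)
  dimnames(S) <- list(diseases, diseases)
  dv <- vapply(tabs, function(t) if (is.null(t)) 0 else sum(t$contribution), 0)
  for (i in seq_len(n)) {
    ti <- tabs[[i]]
    if (is.null(ti)) next
    for (j in seq_len(n)) {
      if (j >= i) break
      tj <- tabs[[j]]
      if (is.null(tj)) next
      shared <- intersect(ti$node, tj$node)
      if (length(shared) == 0) next
      num <- sum(ti$contribution[match(shared, ti$node)]) +
        sum(tj$contribution[match(shared, tj$node)])
      S[i, j] <- S[j, i] <- num / (dv[i] + dv[j])
    }
  }
  S
}

#' Similarity feature rows for arbitrary diseases
#'
#' Each disease's feature vector is its similarity to the fixed training
#' disease set, computed from its ontology position alone — so diseases
#' unseen in training still get informative features.
#'
#' @inheritParams semantic_contribution
#' @param diseases Diseases to featurise (rows).
#' @param training_diseases The fitted column set.
#' @return Matrix `length(diseases)` x `length(training_diseases)`.
#' @export
semantic_feature_rows <- function(tree, diseases, training_diseases,
                                  delta = 0.5) {
  diseases <- as.character(diseases)
  training_diseases <- as.character(training_diseases)
  out <- matrix(0, length(diseases), length(training_diseases),
                dimnames = list(diseases, training_diseases))
  ttrain <- lapply(training_diseases, semantic_contributions,
                   tree = tree, delta = delta)
  dvtrain <- vapply(ttrain, function(t) if (is.null(t)) 0 else sum(t$contribution), 0)
  for (i in seq_along(diseases)) {
    ti <- semantic_contributions(tree, diseases[i], delta)
    for (j in seq_along(training_diseases)) {
      if (identical(diseases[i], training_diseases[j])) {
        out[i, j] <- 1
        next
      }
      if (is.null(ti) || is.null(ttrain[[j]])) next
      shared <- intersect(ti$node, ttrain[[j]]$node)
      if (length(shared) == 0) next
      num <- sum(ti$contribution[match(shared, ti$node)]) +
        sum(ttrain[[j]]$contribution[match(shared, ttrain[[j]]$node)])
      out[i, j] <- num / (sum(ti$contribution) + dvtrain[j])
    }
  }
  out
}

#' Fit a miRNA family one-hot encoder
#'
#' Fixes the family vocabulary on the training miRNAs; miRNAs whose family is
#' absent from the map (or unseen at transform time) fall into a reserved
#' `"unknown"` column, so every vector has exactly one 1.
#'
#' @param families A data frame `mirna_id`, `family` (the family map).
#' @param training_mirnas miRNAs fixing the vocabulary.
#' @return A `family_encoder`.
#' @export
family_encoder <- function(families, training_mirnas) {
  map <- setNames(as.character(families$family), families$mirna_id)
  vocab <- sort(unique(unname(map[as.character(training_mirnas)])))
  vocab <- c(vocab[!is.na(vocab)], "unknown")
  structure(list(map = map, vocab = vocab), class = "family_encoder")
}

#' One-hot family features for miRNAs
#'
#' @param encoder A [family_encoder()].
#' @param mirna_ids miRNAs to encode.
#' @return Indicator matrix `length(mirna_ids)` x `length(vocabulary)`; each
#'   row sums to 1.
#' @export
family_one_hot <- function(encoder, mirna_ids) {
  stopifnot(inherits(encoder, "family_encoder"))
  fam <- unname(encoder$map[as.character(mirna_ids)])
  fam[is.na(fam) | !fam %in% encoder$vocab] <- "unknown"
  F <- matrix(0, length(mirna_ids), length(encoder$vocab),
              dimnames = list(as.character(mirna_ids), encoder$vocab))
  F[cbind(seq_along(mirna_ids), match(fam, encoder$vocab))] <- 1
  F
}
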