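#' Assign ontology-derived category labels to diseases
#'
#' The side-supervised task labels each disease with a coarse ontology
#' category: the first-level tree-code prefix, except under the infection
#' branch where the second-level prefix is used (infection categories are
#' otherwise too heterogeneous). A disease with several tree codes takes the
#' label of its lexicographically smallest code; diseases without any
#' ontology record get the reserved label `"Others"`.
#'
#' @param tree An [ontology()].
#' @param diseases Character vector of disease identifiers to label.
#' @param infection_roots Top-level code(s) treated as the infection branch
#'   (`"C01"` in the medical subject-headings vocabulary).
#' @return A tibble `disease_id`, `category` (class `category_labeling`).
#' @export
assign_disease_categories <- function(tree, diseases,
                                      infection_roots = "C01") {
  stopifnot(inherits(tree, "ontology"))
  rec <- tree$records
  label_one <- function(d) {
    codes <- sort(rec$tree_code[rec$disease_id == d])
    if (length(codes) == 0) return("Others")
    segs <- strsplit(codes[1], ".", fixed = TRUE)[[1]]
    depth <- if (segs[1] %in% infection_roots) 2L else 1L
    paste(segs[seq_len(min(depth, length(segs)))], collapse = ".")
  }
  out <- tibble::tibble(
    disease_id = as.character(diseases),
    category = vapply(as.character(diseases), label_one, "", USE.NAMES = FALSE)
  )
  structure(out, class = c("category_labeling", class(out)))
}

#' Merge rare categories into a common "Others" bin
#'
#' Categories with fewer than `min_size` member diseases are relabeled
#' `"Others"` to keep the label space dense enough for the side task.
#'
#' @param labeling A [assign_disease_categories()] result.
#' @param min_size Minimum category size to survive (default 10).
#' @return The relabeled `category_labeling`.
#' @export
collapse_rare_categories <- function(labeling, min_size = 10) {
  counts <- table(labeling$category)
  rare <- names(counts)[counts < min_size]
  out <- dplyr::mutate(
    labeling,
    category = ifelse(.data$category %in% rare, "Others", .data$category)
  )
  structure(out, class = c("category_labeling", class(tibble::as_tibble(out))))
}

#' ReliefF feature importance
#'
#' Multiclass ReliefF over a samples-by-features matrix: for each sampled
#' instance R, find its k nearest hits (same class) and, per other class C,
#' its k nearest misses, under Manhattan distance on range-normalised
#' features. Each feature's weight is decreased by the mean hit difference
#' and increased by the prior-weighted mean miss difference,
#' `diff(f, a, b) = |a_f - b_f| / (max_f - min_f)` (0 for constant
#' features). With `n_samples = NULL` every instance is used, neighbour ties
#' break by index, and the result is deterministic and permutation-invariant.
#'
#' @param X Numeric matrix (instances x features), e.g. enriched disease-PCG
#'   profiles.
#' @param y Class labels, one per row (e.g. disease categories).
#' @param k_neighbors Neighbours per class (default 10); classes with fewer
#'   members contribute all they have and the update normalises by the actual
#'   neighbour count.
#' @param n_samples Number of instances sampled without replacement;
#'   `NULL` (default) uses all instances.
#' @param seed Seed for the instance sample (only used when `n_samples` is
#'   smaller than the number of instances).
#' @return A `relieff_importance` object: per-feature weights and the
#'   descending ranking (stable index tie-break).
#' @export
relieff_importance <- function(X, y, k_neighbors = 10, n_samples = NULL,
                               seed = 0L) {
  X <- as.matrix(X)
  if (nrow(X) == 0 || ncol(X) == 0) abort("empty feature matrix")
  y <- as.character(y)
  if (length(y) != nrow(X)) abort("one label per row required")
  classes <- unique(y)
  if (length(classes) < 2) abort("ReliefF needs at least two classes")

  n <- nrow(X); p <- ncol(X)
  rng <- apply(X, 2, function(col) diff(range(col)))
  scale <- ifelse(rng > 0, 1 / rng, 0)        # constant features: diff == 0
  Xs <- sweep(X, 2, scale, `*`)               # range-normalised copy
  prior <- table(y)[classes] / n

  idx <- seq_len(n)
  if (!is.null(n_samples) && n_samples < n) {
    idx <- with_stream(seed, sort(sample.int(n, n_samples)))
  }
  n_used <- length(idx)

  W <- numeric(p)
  for (r in idx) {
    d <- rowSums(abs(sweep(Xs, 2, Xs[r, ], `-`)))   # Manhattan to all rows
    for (cl in classes) {
      members <- which(y == cl)
      members <- members[members != r]
      if (length(members) == 0) next
      k_use <- min(k_neighbors, length(members))
      ord <- members[order(d[members], members)][seq_len(k_use)]
      diffs <- colSums(abs(Xs[ord, , drop = FALSE] -
                             matrix(Xs[r, ], k_use, p, byrow = TRUE)))
      if (cl == y[r]) {
        W <- W - diffs / (n_used * k_use)
      } else {
        wC <- prior[[cl]] / (1 - prior[[y[r]]])
        W <- W + wC * diffs / (n_used * k_use)
      }
    }
  }
  feature_ids <- colnames(X) %||% as.character(seq_len(p))
  structure(
    list(
      weights = setNames(as.numeric(W), feature_ids),
      ranking = order(-W, seq_len(p)),
      n_samples = n_used, k_neighbors = k_neighbors
    ),
    class = "relieff_importance"
  )
}

#' @export
print.relieff_importance <- function(x, ...) {
  cat(sprintf(
    "<relieff_importance: %d features, top: %s>\n", length(x$weights),
    paste(names(x$weights)[head(x$ranking, 3)], collapse = ", ")
  ))
  invisible(x)
}

#' Select the top-K most important PCGs
#'
#' @param importance A [relieff_importance()].
#' @param K Number of features to keep (default 100).
#' @return Character vector of the K top-ranked feature (PCG) identifiers,
#'   in rank order.
#' @export
select_top_pcgs <- function(importance, K = 100) {
  stopifnot(inherits(importance, "relieff_importance"))
  p <- length(importance$weights)
  if (K > p) abort(sprintf("K = %d exceeds the %d available features", K, p))
  names(importance$weights)[importance$ranking[seq_len(K)]]
}
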