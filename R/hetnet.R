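#' Build the heterogeneous miRNA-disease-PCG adjacency
#'
#' Assembles the symmetric block matrix over node order
#' \[miRNAs | diseases | selected PCGs\]:
#' \deqn{A = [Z_m, A_{md}, A_{mp}; A_{md}^T, Z_d, A_{dp};
#'           A_{mp}^T, A_{dp}^T, A_p]}
#' where the miRNA-miRNA and disease-disease blocks are zero, the
#' miRNA-disease block holds training associations (weight 1), the
#' miRNA-PCG and disease-PCG blocks hold the enriched profile weights
#' restricted to the selected PCGs, and \eqn{A_p} is the undirected
#' projection of the PCG network on the selected PCGs (edge iff either
#' direction exists, weight 1).
#'
#' @param train_pairs Data frame of training miRNA-disease associations with
#'   columns `miRNA_id`, `disease_id`.
#' @param mirna_profiles,disease_profiles Enriched entity-by-PCG weight
#'   matrices with PCG column names (full profile width is fine; columns are
#'   restricted to `selected_pcgs` here).
#' @param pcg_net The directed [pcg_network()].
#' @param selected_pcgs Character vector of selected PCG ids (the top-K set).
#' @param forbidden_pairs Optional data frame of pairs that must NOT appear
#'   in `train_pairs` (leakage guard for evaluation splits); any overlap is
#'   an error.
#' @return A `hetnet` object: symmetric adjacency, node ids and kinds.
#' @export
build_heterogeneous_adjacency <- function(train_pairs, mirna_profiles,
                                          disease_profiles, pcg_net,
                                          selected_pcgs,
                                          forbidden_pairs = NULL) {
  stopifnot(inherits(pcg_net, "pcg_network"))
  selected_pcgs <- as.character(selected_pcgs)
  unknown <- setdiff(selected_pcgs, pcg_net$pcg_registry$ids)
  if (length(unknown) > 0) {
    abort(sprintf("selected PCGs not in the network: %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  if (!is.null(forbidden_pairs) && nrow(train_pairs) > 0) {
    key <- function(p) paste(p$miRNA_id, p$disease_id, sep = "\r")
    if (any(key(train_pairs) %in% key(forbidden_pairs))) {
      abort("test associations detected in the training adjacency")
    }
  }
  mirnas <- rownames(mirna_profiles)
  diseases <- rownames(disease_profiles)
  n_m <- length(mirnas); n_d <- length(diseases); n_p <- length(selected_pcgs)
  n <- n_m + n_d + n_p
  A <- matrix(0, n, n)
  ids <- c(mirnas, diseases, selected_pcgs)
  dimnames(A) <- list(ids, ids)

  if (nrow(train_pairs) > 0) {
    im <- match(train_pairs$miRNA_id, mirnas)
    id <- match(train_pairs$disease_id, diseases)
    keep <- !is.na(im) & !is.na(id)
    A[cbind(im[keep], n_m + id[keep])] <- 1
  }
  A[seq_len(n_m), n_m + n_d + seq_len(n_p)] <-
    mirna_profiles[, selected_pcgs, drop = FALSE]
  A[n_m + seq_len(n_d), n_m + n_d + seq_len(n_p)] <-
    disease_profiles[, selected_pcgs, drop = FALSE]

  # A_p: undirected projection of the directed PCG graph on the selected set
  pidx <- registry_index(pcg_net$pcg_registry, selected_pcgs)
  sub <- pcg_net$adjacency[pidx, pidx, drop = FALSE]
  Ap <- as.matrix((sub + Matrix::t(sub)) > 0) * 1
  diag(Ap) <- 0
  A[n_m + n_d + seq_len(n_p), n_m + n_d + seq_len(n_p)] <- Ap

  A[lower.tri(A)] <- 0
  A <- A + t(A)   # symmetrise from the upper triangle
  structure(
    list(
      adjacency = A,
      node_ids = ids,
      node_kind = rep(c("miRNA", "disease", "PCG"), c(n_m, n_d, n_p)),
      n_m = n_m, n_d = n_d, n_p = n_p
    ),
    class = "hetnet"
  )
}

#' @export
print.hetnet <- function(x, ...) {
  cat(sprintf(
    "<hetnet: %d miRNAs + %d diseases + %d PCGs, %d undirected edges>\n",
    x$n_m, x$n_d, x$n_p, sum(x$adjacency > 0) / 2
  ))
  invisible(x)
}
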