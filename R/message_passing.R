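#' Weight profiles over the PCG network
#'
#' A weight profile attaches one non-negative association weight per PCG node
#' to a single miRNA or disease. Originally non-zero entries are "known" and
#' are never modified by propagation; zero entries are "unknown" and get
#' inferred weights.
#'
#' @param entity_id Identifier of the miRNA or disease the profile belongs to.
#' @param w Numeric vector of node weights, indexed like the network's PCG
#'   registry.
#' @param known_mask Logical vector marking known entries; defaults to
#'   `w > 0`.
#' @return A `weight_profile` object.
#' @export
weight_profile <- function(entity_id, w, known_mask = NULL) {
  w <- as.numeric(w)
  if (any(!is.finite(w)) || any(w < 0)) abort("weights must be finite and >= 0")
  known_mask <- known_mask %||% (w > 0)
  if (length(known_mask) != length(w)) abort("known_mask length mismatch")
  structure(
    list(entity_id = entity_id, w = w, known_mask = as.logical(known_mask)),
    class = "weight_profile"
  )
}

# propagation operator: w_new(i) = 1/sqrt(d_in(i)) * sum_{j -> i} w(j)/sqrt(d_out(j))
# as a sparse matrix so one step is a single matvec
propagation_operator <- function(net) {
  adj <- net$adjacency   # adj[j, i] = 1 for edge j -> i
  din <- net$in_degree
  dout <- net$out_degree
  sj <- ifelse(dout > 0, 1 / sqrt(dout), 0)
  si <- ifelse(din > 0, 1 / sqrt(din), 0)
  # P[i, j] = si[i] * adj[j, i] * sj[j]; w_new = P %*% w_old
  Matrix::Diagonal(x = si) %*% Matrix::t(adj) %*% Matrix::Diagonal(x = sj)
}

#' One synchronous message-passing step
#'
#' Every unknown node i (known_mask FALSE) receives
#' \eqn{w(i) = d_{in}(i)^{-1/2} \sum_{j \in Par(i)} w(j) / \sqrt{d_{out}(j)}},
#' where Par(i) are its parents in the directed PCG network; all reads come
#' from the previous state. Known nodes keep their original weights; unknown
#' nodes with no parents stay 0.
#'
#' @param net A [pcg_network()].
#' @param profile A [weight_profile()] indexed over `net`'s PCG registry.
#' @return The updated `weight_profile`.
#' @export
propagate_once <- function(net, profile) {
  enrich_profile(net, profile, iterations = 1L)
}

#' Enrich a profile by repeated message passing
#'
#' Applies `iterations` synchronous propagation steps. Each iteration
#' recomputes every unknown node from the full previous state, so weights
#' inferred in earlier iterations are overwritten, not frozen; information
#' travels one hop per iteration. `iterations = 0` returns the input
#' unchanged. One iteration is the default operating point.
#'
#' @inheritParams propagate_once
#' @param iterations Number of propagation steps (t >= 0).
#' @return The enriched `weight_profile`.
#' @examples
#' net <- pcg_network(tibble::tibble(
#'   source = c("a", "b"), target = c("b", "c"),
#'   relation = "activates"
#' ))
#' p <- weight_profile("mir-x", c(1, 0, 0))
#' enrich_profile(net, p, iterations = 2)$w
#' @export
enrich_profile <- function(net, profile, iterations = 1L) {
  stopifnot(inherits(net, "pcg_network"), inherits(profile, "weight_profile"))
  n <- length(net$pcg_registry)
  if (length(profile$w) != n) {
    abort(sprintf("profile has %d entries but network has %d PCGs",
                  length(profile$w), n))
  }
  W <- enrich_matrix(net, matrix(profile$w, nrow = 1),
                     matrix(profile$known_mask, nrow = 1), iterations)
  weight_profile(profile$entity_id, W[1, ], profile$known_mask)
}

#' Vectorised enrichment of many profiles at once
#'
#' Row r of the output equals [enrich_profile()] applied to row r of the
#' input. The step is linear in the unknown block, so one iteration is a
#' sparse matrix product followed by restoring the known entries.
#'
#' @inheritParams propagate_once
#' @param profiles Numeric entity-by-PCG weight matrix.
#' @param known_masks Logical matrix of the same shape; defaults to
#'   `profiles > 0`.
#' @param iterations Number of propagation steps.
#' @return The enriched weight matrix.
#' @export
enrich_matrix <- function(net, profiles, known_masks = NULL, iterations = 1L) {
  stopifnot(inherits(net, "pcg_network"))
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 0) abort("iterations must be >= 0")
  profiles <- as.matrix(profiles)
  known_masks <- known_masks %||% (profiles > 0)
  if (!all(dim(known_masks) == dim(profiles))) {
    abort("known_masks shape does not match profiles")
  }
  if (ncol(profiles) != length(net$pcg_registry)) {
    abort("profile columns do not match the network's PCG registry")
  }
  if (iterations == 0) return(profiles)
  P <- propagation_operator(net)
  known_vals <- profiles[known_masks]
  W <- profiles
  for (t in seq_len(iterations)) {
    W <- as.matrix(Matrix::tcrossprod(W, P))  # W %*% t(P): row-wise propagation
    W[known_masks] <- known_vals              # known-value conservation
  }
  dimnames(W) <- dimnames(profiles)
  W
}

#' Build an entity-by-PCG profile matrix from an association table
#'
#' @param assoc An [association_table()] whose `right_id` column holds PCG
#'   identifiers.
#' @param net A [pcg_network()] supplying the column order.
#' @param entity_ids Row order; defaults to the entities present in `assoc`.
#' @return A numeric matrix with entity rows and PCG columns.
#' @export
profiles_from_association <- function(assoc, net, entity_ids = NULL) {
  entity_ids <- entity_ids %||% sort(unique(assoc$left_id))
  keep <- assoc$right_id %in% net$pcg_registry$ids &
    assoc$left_id %in% entity_ids
  a <- assoc[keep, ]
  W <- matrix(0, length(entity_ids), length(net$pcg_registry),
              dimnames = list(entity_ids, net$pcg_registry$ids))
  W[cbind(match(a$left_id, entity_ids),
          registry_index(net$pcg_registry, a$right_id))] <- a$weight
  W
}
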