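#' SDNE configuration
#'
#' Hyperparameters for the structural deep network embedding autoencoder:
#' two sigmoid encoder layers (sizes `encoder_sizes`, default 1000 then 128)
#' and one sigmoid decoder layer back to the input dimension. `beta` (> 1)
#' up-weights reconstruction of observed edges, `alpha` weighs the
#' first-order proximity loss pulling linked nodes' codes together, and `nu`
#' L2-regularises the weights. Training is full-batch (or mini-batch for
#' larger graphs) adaptive-moment gradient descent, deterministic given
#' `seed`.
#'
#' @param encoder_sizes Hidden layer sizes; the last entry is the embedding
#'   dimension.
#' @param alpha First-order loss weight.
#' @param beta Reconstruction penalty for observed edges (> 1).
#' @param nu L2 regularisation weight.
#' @param epochs,batch_size,learning_rate Optimisation settings.
#' @param seed Seed for weight initialisation and batch shuffling.
#' @return An `sdne_config` list.
#' @export
sdne_config <- function(encoder_sizes = c(1000, 128), alpha = 0.05, beta = 5,
                        nu = 1e-4, epochs = 200, batch_size = 256,
                        learning_rate = 1e-3, seed = 0L) {
  if (beta <= 1) abort("beta must be > 1")
  if (any(c(encoder_sizes, epochs, batch_size, learning_rate) <= 0) ||
      alpha < 0 || nu < 0) {
    abort("sdne_config values must be positive (alpha, nu >= 0)")
  }
  structure(
    list(
      encoder_sizes = as.integer(encoder_sizes),
      embedding_dim = as.integer(encoder_sizes[length(encoder_sizes)]),
      alpha = alpha, beta = beta, nu = nu, epochs = as.integer(epochs),
      batch_size = as.integer(batch_size), learning_rate = learning_rate,
      seed = as.integer(seed)
    ),
    class = "sdne_config"
  )
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Train a structural deep network embedding
#'
#' Minimises
#' \deqn{L = \sum_i \|(\hat x_i - s_i) \odot b_i\|^2
#'   + \alpha \sum_{i<j} s_{ij} \|y_i - y_j\|^2 + \nu \sum \|W\|^2}
#' where \eqn{s_i} is row i of the (symmetric) adjacency, \eqn{\hat x_i} its
#' autoencoder reconstruction, \eqn{y_i} the embedding code, and
#' \eqn{b_{ij} = \beta} for observed edges and 1 otherwise. The second-order
#' term makes nodes with shared neighbourhoods similar; the first-order term
#' makes linked nodes similar. Gradients are exact (hand-derived backprop)
#' and optimised with Adam.
#'
#' @param net A `hetnet` (or plain symmetric numeric matrix).
#' @param config An [sdne_config()].
#' @param verbose Print per-epoch loss every 50 epochs.
#' @return An `sdne_embedding`: `embedding` (nodes x dim, rownames = node
#'   ids), `loss` per-epoch totals, and the config.
#' @export
train_sdne <- function(net, config = sdne_config(), verbose = FALSE) {
  S <- if (inherits(net, "hetnet")) net$adjacency else as.matrix(net)
  if (!isSymmetric(unname(S), tol = 1e-12)) abort("adjacency must be symmetric")
  n <- nrow(S)
  sizes <- c(n, config$encoder_sizes)
  nl <- length(sizes) - 1L

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  # encoder stack + single decoder layer back to the input dimension
  W <- vector("list", nl + 1L)
  b <- vector("list", nl + 1L)
  for (l in seq_len(nl)) {
    W[[l]] <- glorot(sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  W[[nl + 1L]] <- glorot(sizes[nl + 1], n)
  b[[nl + 1L]] <- numeric(n)

  adam_m <- lapply(c(W, b), function(p) p * 0)
  adam_v <- lapply(c(W, b), function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; tstep <- 0
  lr <- config$learning_rate

  # reconstruction penalty and Laplacian are fixed given the row set; for
  # full-batch training (the usual case here) compute them once
  B2_full <- matrix(1, n, n)
  B2_full[S > 0] <- config$beta^2
  full_batch <- n <= config$batch_size
  L_full <- if (full_batch) diag(rowSums(S)) - S else NULL

  loss_hist <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    perm <- if (full_batch) seq_len(n) else sample.int(n)
    batches <- split(perm, ceiling(seq_along(perm) / config$batch_size))
    epoch_loss <- 0
    for (I in batches) {
      if (full_batch) {
        X <- S; B2 <- B2_full; Lb <- L_full
      } else {
        X <- S[I, , drop = FALSE]
        B2 <- B2_full[I, , drop = FALSE]
        Sb <- S[I, I, drop = FALSE]
        Lb <- diag(rowSums(Sb)) - Sb
      }

      # forward
      H <- vector("list", nl + 1L)
      A_in <- X
      for (l in seq_len(nl)) {
        H[[l]] <- sigmoid_affine(A_in %*% W[[l]], b[[l]])
        A_in <- H[[l]]
      }
      Y <- H[[nl]]
      Xhat <- sigmoid_affine(Y %*% W[[nl + 1L]], b[[nl + 1L]])

      R <- Xhat - X
      l2nd <- sum(R * R * B2)
      LbY <- Lb %*% Y
      l1st <- sum(Y * LbY)
      if (!is.finite(l2nd + l1st)) {
        abort(sprintf("SDNE loss diverged (epoch %d): l2nd=%g l1st=%g",
                      epoch, l2nd, l1st))
      }
      epoch_loss <- epoch_loss + l2nd + config$alpha * l1st

      # backward (fused elementwise kernels in src/sdne_kernels.cpp)
      gW <- vector("list", nl + 1L)
      gb <- vector("list", nl + 1L)
      dA <- recon_backprop(Xhat, X, B2)
      gW[[nl + 1L]] <- crossprod(Y, dA) + 2 * config$nu * W[[nl + 1L]]
      gb[[nl + 1L]] <- colSums(dA)
      dH <- tcrossprod(dA, W[[nl + 1L]]) + config$alpha * 2 * LbY
      for (l in rev(seq_len(nl))) {
        dA <- sigmoid_backprop(dH, H[[l]])
        below <- if (l == 1) X else H[[l - 1L]]
        gW[[l]] <- crossprod(below, dA) + 2 * config$nu * W[[l]]
        gb[[l]] <- colSums(dA)
        if (l > 1) dH <- tcrossprod(dA, W[[l]])
      }

      # fused Adam update over all parameters (in-place)
      tstep <- tstep + 1
      lr_t <- lr * sqrt(1 - beta2^tstep) / (1 - beta1^tstep)
      grads <- c(gW, gb)
      params <- c(W, b)
      for (k in seq_along(params)) {
        adam_step(params[[k]], adam_m[[k]], adam_v[[k]], grads[[k]],
                  lr_t, beta1, beta2, eps)
      }
      W <- params[seq_len(nl + 1L)]
      b <- params[nl + 1L + seq_len(nl + 1L)]
    }
    loss_hist[epoch] <- epoch_loss +
      config$nu * sum(vapply(W, function(w) sum(w^2), 0))
    if (verbose && epoch %% 50 == 0) {
      message(sprintf("epoch %d: loss %.4f", epoch, loss_hist[epoch]))
    }
  }

  # final codes for all nodes
  A_in <- S
  for (l in seq_len(nl)) {
    A_in <- sigmoid_affine(A_in %*% W[[l]], b[[l]])
  }
  E <- A_in
  rownames(E) <- rownames(S)
  structure(
    list(embedding = E, loss = loss_hist, config = config,
         node_ids = rownames(S)),
    class = "sdne_embedding"
  )
}

#' @export
print.sdne_embedding <- function(x, ...) {
  cat(sprintf(
    "<sdne_embedding: %d nodes x %d dims, final loss %.4f>\n",
    nrow(x$embedding), ncol(x$embedding), x$loss[length(x$loss)]
  ))
  invisible(x)
}

#' Embedding rows for a miRNA-disease pair
#'
#' Entities absent from the trained network (new miRNAs or diseases) map to
#' the zero vector.
#'
#' @param embedding An [train_sdne()] result.
#' @param mirna_id,disease_id Entity identifiers.
#' @return A list with `E_m` and `E_d`, each of the embedding dimension.
#' @export
extract_pair_embeddings <- function(embedding, mirna_id, disease_id) {
  stopifnot(inherits(embedding, "sdne_embedding"))
  list(
    E_m = embedding_row(embedding, mirna_id),
    E_d = embedding_row(embedding, disease_id)
  )
}

embedding_row <- function(embedding, id) {
  if (id %in% rownames(embedding$embedding)) {
    embedding$embedding[id, ]
  } else {
    numeric(ncol(embedding$embedding))
  }
}

# rows of the embedding for a vector of ids, zero rows for absent entities
embedding_rows <- function(embedding, ids) {
  E <- matrix(0, length(ids), ncol(embedding$embedding))
  hit <- ids %in% rownames(embedding$embedding)
  E[hit, ] <- embedding$embedding[ids[hit], , drop = FALSE]
  rownames(E) <- ids
  E
}
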