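# Independent reference implementations used to cross-check the package.
# These deliberately use the slowest, most literal formulation of each
# definition and share no code with the implementation under test.

# Message passing: literal per-node evaluation of the propagation rule.
naive_propagate <- function(edges_df, w0, known_mask, iterations = 1) {
  ids <- sort(unique(c(edges_df$source, edges_df$target, names(w0))))
  w <- setNames(rep(0, length(ids)), ids)
  w[names(w0)] <- w0
  known <- setNames(rep(FALSE, length(ids)), ids)
  known[names(known_mask)] <- known_mask
  d_out <- table(factor(edges_df$source, levels = ids))
  d_in <- table(factor(edges_df$target, levels = ids))
  for (t in seq_len(iterations)) {
    w_new <- w
    for (i in ids) {
      if (known[[i]]) next
      parents <- edges_df$source[edges_df$target == i]
      if (length(parents) == 0) {
        w_new[[i]] <- 0
        next
      }
      w_new[[i]] <- sum(w[parents] / sqrt(d_out[parents])) / sqrt(d_in[[i]])
    }
    w <- w_new
  }
  w
}

# random directed multi-relational edge table over n nodes
random_edge_table <- function(n, n_edges, seed) {
  withr::with_seed(seed, {
    src <- sample(n, n_edges, replace = TRUE)
    tgt <- sample(n, n_edges, replace = TRUE)
    keep <- src != tgt
    tibble::tibble(
      source = sprintf("g%03d", src[keep]),
      target = sprintf("g%03d", tgt[keep]),
      relation = sample(c("binding", "inhibits", "activates", "regulates",
                          "catalyzes"), sum(keep), replace = TRUE)
    )
  })
}

# ReliefF: literal O(n^2 p) reference following the textbook update
naive_relieff <- function(X, y, k = 10) {
  X <- as.matrix(X); y <- as.character(y)
  n <- nrow(X); p <- ncol(X)
  rng <- apply(X, 2, max) - apply(X, 2, min)
  diff_f <- function(f, a, b) {
    if (rng[f] == 0) return(0)
    abs(X[a, f] - X[b, f]) / rng[f]
  }
  dist_ab <- function(a, b) sum(vapply(seq_len(p), diff_f, 0, a = a, b = b))
  prior <- table(y) / n
  W <- numeric(p)
  for (r in seq_len(n)) {
    d <- vapply(seq_len(n), dist_ab, 0, a = r)
    for (cl in unique(y)) {
      members <- setdiff(which(y == cl), r)
      if (length(members) == 0) next
      k_use <- min(k, length(members))
      nb <- members[order(d[members], members)][seq_len(k_use)]
      for (f in seq_len(p)) {
        s <- sum(vapply(nb, function(m) diff_f(f, r, m), 0))
        if (cl == y[r]) {
          W[f] <- W[f] - s / (n * k_use)
        } else {
          W[f] <- W[f] + (prior[[cl]] / (1 - prior[[y[r]]])) * s / (n * k_use)
        }
      }
    }
  }
  W
}

# Wang-measure contribution by exhaustive upward path enumeration
oracle_contributions <- function(records, disease_id, delta = 0.5) {
  codes <- records$tree_code[records$disease_id == disease_id]
  # owner of a code: the recorded disease if any, else the code itself
  owner <- function(code) {
    o <- records$disease_id[records$tree_code == code]
    if (length(o) > 0) o[1] else code
  }
  best <- list()
  for (code in codes) {
    segs <- strsplit(code, ".", fixed = TRUE)[[1]]
    for (k in seq_along(segs)) {
      anc_code <- paste(segs[1:k], collapse = ".")
      node <- owner(anc_code)
      val <- delta^(length(segs) - k)
      if (is.null(best[[node]]) || val > best[[node]]) best[[node]] <- val
    }
  }
  unlist(best)
}

oracle_similarity <- function(records, d1, d2, delta = 0.5) {
  if (identical(d1, d2)) return(1)
  c1 <- oracle_contributions(records, d1, delta)
  c2 <- oracle_contributions(records, d2, delta)
  if (is.null(c1) || is.null(c2)) return(0)
  shared <- intersect(names(c1), names(c2))
  if (length(shared) == 0) return(0)
  (sum(c1[shared]) + sum(c2[shared])) / (sum(c1) + sum(c2))
}

# random ontology: forest of trees as (disease_id, tree_code) records
random_ontology_records <- function(n_nodes, n_roots = 2, seed = 1) {
  withr::with_seed(seed, {
    codes <- character(n_nodes)
    for (i in seq_len(n_nodes)) {
      if (i <= n_roots) {
        codes[i] <- sprintf("C%02d", i)
      } else {
        parent <- codes[sample(i - 1, 1)]
        codes[i] <- paste0(parent, ".", sprintf("%03d", i))
      }
    }
    tibble::tibble(disease_id = sprintf("dz%03d", seq_len(n_nodes)),
                   tree_code = codes)
  })
}

# AUC by exhaustive pair counting
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (sp in pos) for (sn in neg) {
    total <- total + (sp > sn) + 0.5 * (sp == sn)
  }
  total / (length(pos) * length(neg))
}

# AP by a literal descending sweep over unique thresholds
oracle_ap <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0
  ap <- 0
  n_pos <- sum(labels == 1)
  for (t in thr) {
    called <- scores >= t
    prec <- sum(labels[called] == 1) / sum(called)
    rec <- sum(labels[called] == 1) / n_pos
    ap <- ap + (rec - prev_recall) * prec
    prev_recall <- rec
  }
  ap
}

small_world <- function(seed = 1, ...) {
  simulate_world(synthetic_config(
    n_pcg = 80, n_mirna = 20, n_disease = 12, n_categories = 2,
    signal_pcgs_per_category = 8, seed = seed, ...
  ))
}

fast_sdne <- function(epochs = 60, seed = 0) {
  sdne_config(encoder_sizes = c(100, 16), epochs = epochs, seed = seed)
}
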