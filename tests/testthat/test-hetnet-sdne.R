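test_that("the 3x3 single-entity adjacency assembles as the block equation", {
  net <- pcg_network(tibble::tibble(source = "g1", target = "g1",
                                    relation = "binding")[0, ],
                     pcg_ids = "g1")
  M <- matrix(0.5, 1, 1, dimnames = list("m1", "g1"))
  D <- matrix(0.3, 1, 1, dimnames = list("d1", "g1"))
  hn <- build_heterogeneous_adjacency(
    tibble::tibble(miRNA_id = "m1", disease_id = "d1"), M, D, net, "g1"
  )
  expect_equal(unname(hn$adjacency),
               rbind(c(0, 1, 0.5), c(1, 0, 0.3), c(0.5, 0.3, 0)))
  expect_equal(hn$node_ids, c("m1", "d1", "g1"))
})

test_that("an empty association set zeroes only the miRNA-disease block", {
  net <- pcg_network(random_edge_table(20, 40, 1))
  ids <- net$pcg_registry$ids
  M <- matrix(runif(2 * length(ids)), 2, dimnames = list(c("m1", "m2"), ids))
  D <- matrix(runif(3 * length(ids)), 3,
              dimnames = list(c("d1", "d2", "d3"), ids))
  sel <- ids[1:10]
  empty <- tibble::tibble(miRNA_id = character(), disease_id = character())
  hn <- build_heterogeneous_adjacency(empty, M, D, net, sel)
  expect_true(all(hn$adjacency[1:2, 3:5] == 0))
  expect_equal(hn$adjacency[1:2, 6:15], M[, sel], ignore_attr = TRUE)
})

test_that("assembled adjacencies are exactly symmetric with zero diagonal blocks", {
  for (seed in 1:5) {
    net <- pcg_network(random_edge_table(30, 90, seed))
    ids <- net$pcg_registry$ids
    M <- withr::with_seed(seed, matrix(runif(4 * length(ids)), 4,
                                       dimnames = list(paste0("m", 1:4), ids)))
    D <- withr::with_seed(seed + 1,
                          matrix(runif(3 * length(ids)), 3,
                                 dimnames = list(paste0("d", 1:3), ids)))
    pairs <- tibble::tibble(miRNA_id = c("m1", "m2"),
                            disease_id = c("d1", "d3"))
    hn <- build_heterogeneous_adjacency(pairs, M, D, net, ids[1:15])
    A <- hn$adjacency
    expect_identical(A, t(A))
    expect_true(all(A[1:4, 1:4] == 0))   # Z_m
    expect_true(all(A[5:7, 5:7] == 0))   # Z_d
    # PCG block is the undirected projection with weight 1
    Ap <- A[8:22, 8:22]
    expect_true(all(Ap %in% c(0, 1)))
  }
})

test_that("unknown selected PCGs and leaked test pairs are rejected", {
  net <- pcg_network(random_edge_table(10, 20, 2))
  ids <- net$pcg_registry$ids
  M <- matrix(0, 1, length(ids), dimnames = list("m1", ids))
  D <- matrix(0, 1, length(ids), dimnames = list("d1", ids))
  pairs <- tibble::tibble(miRNA_id = "m1", disease_id = "d1")
  expect_error(
    build_heterogeneous_adjacency(pairs, M, D, net, "nope"),
    "not in the network"
  )
  expect_error(
    build_heterogeneous_adjacency(pairs, M, D, net, ids[1],
                                  forbidden_pairs = pairs),
    "test associations"
  )
})

two_cliques <- function() {
  A <- matrix(0, 20, 20)
  A[1:10, 1:10] <- 1
  A[11:20, 11:20] <- 1
  diag(A) <- 0
  rownames(A) <- colnames(A) <- sprintf("n%02d", 1:20)
  A
}

test_that("training is deterministic given the seed", {
  A <- two_cliques()
  cfg <- sdne_config(encoder_sizes = c(50, 8), epochs = 30, seed = 5)
  e1 <- train_sdne(A, cfg)
  e2 <- train_sdne(A, cfg)
  expect_identical(e1$embedding, e2$embedding)
  e3 <- train_sdne(A, sdne_config(encoder_sizes = c(50, 8), epochs = 30,
                                  seed = 6))
  expect_false(identical(e1$embedding, e3$embedding))
})

test_that("codes separate two disjoint cliques", {
  emb <- train_sdne(two_cliques(),
                    sdne_config(encoder_sizes = c(50, 8), epochs = 200))
  E <- emb$embedding
  D <- as.matrix(dist(E))
  intra <- c(D[1:10, 1:10][upper.tri(D[1:10, 1:10])],
             D[11:20, 11:20][upper.tri(D[11:20, 11:20])])
  inter <- D[1:10, 11:20]
  expect_lt(mean(intra), mean(inter))
})

test_that("loss decreases over training (1% tolerance) and is finite", {
  emb <- train_sdne(two_cliques(),
                    sdne_config(encoder_sizes = c(50, 8), epochs = 100))
  expect_true(all(is.finite(emb$loss)))
  expect_lte(emb$loss[length(emb$loss)], emb$loss[1] * 1.01)
})

test_that("structural twins get matching codes", {
  # nodes 1 and 2 have identical adjacency rows by construction
  A <- matrix(0, 8, 8)
  A[1, 3:5] <- A[2, 3:5] <- 1
  A[3:5, 1] <- A[3:5, 2] <- 1
  A[6, 7] <- A[7, 6] <- 1
  rownames(A) <- colnames(A) <- paste0("v", 1:8)
  emb <- train_sdne(A, sdne_config(encoder_sizes = c(30, 6), epochs = 100))
  expect_lt(max(abs(emb$embedding[1, ] - emb$embedding[2, ])), 1e-3)
})

test_that("asymmetric adjacencies are rejected", {
  A <- two_cliques()
  A[1, 2] <- 0.7
  expect_error(train_sdne(A, fast_sdne()), "symmetric")
})

test_that("pair extraction returns codes or zero vectors of the right length", {
  A <- two_cliques()
  emb <- train_sdne(A, sdne_config(encoder_sizes = c(30, 6), epochs = 20))
  pe <- extract_pair_embeddings(emb, "n01", "n11")
  expect_equal(unname(pe$E_m), unname(emb$embedding["n01", ]))
  expect_equal(length(c(pe$E_m, pe$E_d)), 12)
  pe2 <- extract_pair_embeddings(emb, "n01", "unseen-disease")
  expect_identical(pe2$E_d, numeric(6))
})
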