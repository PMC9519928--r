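toy_net <- function() {
  # a -> c, b -> c, b -> d
  pcg_network(tibble::tibble(
    source = c("a", "b", "b"), target = c("c", "c", "d"),
    relation = "activates"
  ))
}

test_that("the worked 4-node propagation values reproduce", {
  net <- toy_net()
  w0 <- setNames(c(1, 0.5, 0, 0), c("a", "b", "c", "d"))
  p <- enrich_profile(net, weight_profile("m", w0[net$pcg_registry$ids]))
  w <- setNames(p$w, net$pcg_registry$ids)
  expect_equal(w[["c"]], (1 / sqrt(2)) * (1 + 0.5 / sqrt(2)), tolerance = 1e-9)
  expect_equal(w[["d"]], 0.5 / sqrt(2), tolerance = 1e-9)
  expect_equal(w[["a"]], 1)   # known values conserved
  expect_equal(w[["b"]], 0.5)
})

test_that("exactly the zero nodes with a nonzero parent gain weight in step 1", {
  for (seed in 1:5) {
    edges <- random_edge_table(30, 60, seed)
    net <- pcg_network(edges)
    ids <- net$pcg_registry$ids
    w0 <- withr::with_seed(seed, ifelse(runif(length(ids)) < 0.3, 1, 0))
    p1 <- propagate_once(net, weight_profile("x", w0))
    gained <- ids[w0 == 0 & p1$w > 0]
    expected <- ids[w0 == 0 & vapply(seq_along(ids), function(i) {
      parents <- net$edges$source_index[net$edges$target_index == i]
      any(w0[parents] > 0)
    }, TRUE)]
    expect_setequal(gained, expected)
  }
})

test_that("information travels one hop per iteration along a chain", {
  net <- pcg_network(tibble::tibble(
    source = c("a", "b"), target = c("b", "c"), relation = "regulates"
  ))
  w0 <- setNames(c(1, 0, 0), c("a", "b", "c"))[net$pcg_registry$ids]
  p1 <- enrich_profile(net, weight_profile("m", w0), iterations = 1)
  p2 <- enrich_profile(net, weight_profile("m", w0), iterations = 2)
  expect_equal(setNames(p1$w, net$pcg_registry$ids)[c("a", "b", "c")],
               c(a = 1, b = 1, c = 0))
  expect_equal(setNames(p2$w, net$pcg_registry$ids)[c("a", "b", "c")],
               c(a = 1, b = 1, c = 1))
})

test_that("zero iterations is the identity and negative counts error", {
  net <- toy_net()
  w0 <- c(1, 0, 0, 0)
  p <- enrich_profile(net, weight_profile("m", w0), iterations = 0)
  expect_identical(p$w, w0)
  expect_error(enrich_profile(net, weight_profile("m", w0), iterations = -1),
               ">= 0")
})

test_that("all-zero profiles stay zero and empty parents give 0, not NaN", {
  net <- toy_net()
  p <- propagate_once(net, weight_profile("m", rep(0, 4)))
  expect_identical(p$w, rep(0, 4))
  # a has no parents and unknown mask: stays exactly 0
  w0 <- setNames(c(0, 1, 0, 0), c("a", "b", "c", "d"))
  p2 <- propagate_once(net, weight_profile("m", w0[net$pcg_registry$ids]))
  expect_identical(setNames(p2$w, net$pcg_registry$ids)[["a"]], 0)
  expect_false(anyNA(p2$w))
})

test_that("a second iteration is a fixed point when all parents are known", {
  # star: known hub feeding unknown leaves only
  net <- pcg_network(tibble::tibble(
    source = "hub", target = c("l1", "l2", "l3"), relation = "activates"
  ))
  ids <- net$pcg_registry$ids
  w0 <- ifelse(ids == "hub", 1, 0)
  p1 <- enrich_profile(net, weight_profile("m", w0), iterations = 1)
  p2 <- enrich_profile(net, weight_profile("m", w0), iterations = 2)
  expect_equal(p1$w, p2$w, tolerance = 1e-12)
})

test_that("matrix enrichment matches the per-node oracle on random graphs", {
  for (seed in 1:8) {
    edges <- random_edge_table(50, 150, seed)
    net <- pcg_network(edges)
    ids <- net$pcg_registry$ids
    W0 <- withr::with_seed(seed + 100, {
      m <- matrix(runif(5 * length(ids)), 5)
      m[m < 0.6] <- 0
      m
    })
    colnames(W0) <- ids
    W1 <- enrich_matrix(net, W0, iterations = 1)
    dedup <- unique(net$edges[c("source", "target")])
    for (r in 1:5) {
      ref <- naive_propagate(dedup, setNames(W0[r, ], ids),
                             setNames(W0[r, ] > 0, ids))
      expect_lt(max(abs(W1[r, ] - ref[ids])), 1e-12)
    }
  }
})

test_that("matrix and per-profile paths agree", {
  edges <- random_edge_table(40, 120, 42)
  net <- pcg_network(edges)
  n <- length(net$pcg_registry)
  W0 <- withr::with_seed(1, matrix(runif(3 * n) * (runif(3 * n) < 0.4), 3))
  W2 <- enrich_matrix(net, W0, iterations = 2)
  for (r in 1:3) {
    p <- enrich_profile(net, weight_profile("e", W0[r, ]), iterations = 2)
    expect_lt(max(abs(W2[r, ] - p$w)), 1e-12)
  }
})

test_that("known entries are conserved bit-identically and scaling is linear", {
  edges <- random_edge_table(60, 200, 3)
  net <- pcg_network(edges)
  n <- length(net$pcg_registry)
  w0 <- withr::with_seed(2, runif(n) * (runif(n) < 0.3))
  mask <- w0 > 0
  p1 <- enrich_profile(net, weight_profile("m", w0), iterations = 3)
  expect_identical(p1$w[mask], w0[mask])
  p2 <- enrich_profile(net, weight_profile("m", 2 * w0), iterations = 3)
  expect_equal(p2$w, 2 * p1$w, tolerance = 1e-12)
})

test_that("nodes unreachable within t hops stay at zero", {
  # path a -> b -> c -> d -> e
  net <- pcg_network(tibble::tibble(
    source = c("a", "b", "c", "d"), target = c("b", "c", "d", "e"),
    relation = "catalyzes"
  ))
  ids <- net$pcg_registry$ids
  w0 <- ifelse(ids == "a", 1, 0)
  for (t in 1:3) {
    p <- enrich_profile(net, weight_profile("m", w0), iterations = t)
    w <- setNames(p$w, ids)
    reach <- letters[1:(t + 1)]
    expect_true(all(w[setdiff(ids, reach)] == 0))
    expect_true(all(w[reach] > 0))
  }
})

test_that("shape mismatches are rejected", {
  net <- toy_net()
  expect_error(enrich_profile(net, weight_profile("m", c(1, 0))), "PCGs")
  expect_error(enrich_matrix(net, matrix(0, 2, 4), matrix(TRUE, 1, 4)),
               "shape")
})
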