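# MinHash estimation, LSH-forest retrieval, k-NN graphs, tree layouts.

test_that("minhash signatures are deterministic and flag empty inputs", {
  fp <- fraglib:::new_fingerprint("x", c(3, 17, 200), 1024)
  s1 <- minhash_signature(fp, d = 64, seed = 7)
  s2 <- minhash_signature(fp, d = 64, seed = 7)
  expect_identical(s1$values, s2$values)
  expect_length(s1$values, 64L)
  expect_equal(estimate_jaccard(s1, s2), 1)

  s3 <- minhash_signature(fp, d = 64, seed = 8)
  expect_error(estimate_jaccard(s1, s3), "seed")

  empty <- minhash_signature(fraglib:::new_fingerprint("x", integer(), 1024),
                             d = 64, seed = 7)
  expect_true(empty$empty)
  expect_true(all(empty$values == fraglib:::.MINHASH_P))
})

test_that("minhash concentrates around the true Jaccard (d = 128)", {
  set.seed(101)
  hits <- 0L
  for (t in 1:200) {
    shared <- sample(1024, 40)
    a <- fraglib:::new_fingerprint("x", c(shared, sample(setdiff(1:1024, shared), 40)[1:20]), 1024)
    b_only <- sample(setdiff(1:1024, a$bits), 20)
    b <- fraglib:::new_fingerprint("x", c(shared, b_only), 1024)
    true_j <- exact_jaccard(a, b)
    sa <- minhash_signature(a, d = 128, seed = t)
    sb <- minhash_signature(b, d = 128, seed = t)
    if (abs(estimate_jaccard(sa, sb) - true_j) <= 0.15) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)
})

test_that("minhash is unbiased over random pairs", {
  fps <- synthetic_fingerprints(200, n_bits = 1024, n_clusters = 20,
                                density = 60, flip = 10, seed = 77)
  M <- minhash_matrix(fps, d = 128, seed = 42)
  set.seed(78)
  errs <- replicate(1000, {
    p <- sample(200, 2)
    mean(M[p[1], ] == M[p[2], ]) - exact_jaccard(fps[[p[1]]], fps[[p[2]]])
  })
  expect_lt(abs(mean(errs)), 0.01)
})

test_that("lsh forest retrieves items and approximates nearest neighbors", {
  # analog pairs: each item's true nearest neighbor is its close twin
  fps <- synthetic_fingerprints(100, n_bits = 512, n_clusters = 50,
                                density = 40, flip = 5, seed = 21)
  M <- minhash_matrix(fps, d = 128, seed = 42)
  idx <- build_index(M)
  # an indexed item finds itself
  one <- build_index(M[1, , drop = FALSE])
  self <- query_index(one, query_row = M[1, ], k = 1)
  expect_equal(self$id, 1L)
  expect_equal(self$distance, 0)

  # recall of the true nearest neighbor (exact Tanimoto scan oracle)
  found <- 0L
  for (i in 1:100) {
    sims <- vapply(seq_along(fps), function(j) exact_jaccard(fps[[i]], fps[[j]]),
                   numeric(1))
    sims[i] <- -1
    truth <- which.max(sims)
    res <- query_index(idx, item = i, k = 1, n_candidates = 10)
    if (nrow(res) && res$id[1] == truth) found <- found + 1L
  }
  expect_gte(found / 100, 0.5)

  expect_error(build_index(list(minhash_signature(fps[[1]], d = 32, seed = 1),
                                minhash_signature(fps[[2]], d = 64, seed = 1))),
               "mixed")
})

test_that("knn graph is undirected, deduplicated, truncated and bounded", {
  fps <- synthetic_fingerprints(30, n_bits = 256, n_clusters = 3,
                                density = 30, flip = 4, seed = 33)
  idx <- build_index(minhash_matrix(fps, d = 64, seed = 42))
  expect_warning(g3 <- knn_graph(build_index(minhash_matrix(fps[1:3], d = 64, seed = 42)),
                                 k = 50, kc = 10),
                 "truncating")
  expect_equal(nrow(g3$edges), 3L)    # complete graph on 3 nodes

  g <- suppressWarnings(knn_graph(idx, k = 5, kc = 10))
  expect_true(all(g$edges$i < g$edges$j))
  expect_false(any(duplicated(g$edges[, c("i", "j")])))
  expect_true(all(g$edges$weight >= 0 & g$edges$weight <= 1))
})

test_that("spanning tree layout has n-1 edges and deterministic coordinates", {
  fps <- synthetic_fingerprints(60, n_bits = 256, n_clusters = 4,
                                density = 30, flip = 5, seed = 55)
  idx <- build_index(minhash_matrix(fps, d = 64, seed = 42))
  g <- suppressWarnings(knn_graph(idx, k = 8, kc = 10))
  lay <- spanning_tree_layout(g, idx, seed = 2)
  expect_equal(nrow(lay$tree_edges), 60L - 1L)     # spanning tree after linking
  expect_equal(nrow(lay$coordinates), 60L)
  lay2 <- spanning_tree_layout(g, idx, seed = 2)
  expect_identical(lay$coordinates, lay2$coordinates)
  lay3 <- spanning_tree_layout(g, idx, seed = 3)
  expect_false(identical(lay$coordinates, lay3$coordinates))

  # MST drops the heavy chord: path weights 1,2,3 plus a chord of 10
  pg <- structure(list(edges = data.frame(i = c(1, 2, 3, 1), j = c(2, 3, 4, 4),
                                          weight = c(.1, .2, .3, 1)),
                       n = 4L, k = 3L, kc = 1L, ids = 1:4),
                  class = "knn_graph")
  play <- spanning_tree_layout(pg, seed = 1)
  expect_equal(nrow(play$tree_edges), 3L)
  expect_false(any(play$tree_edges$weight == 1))
})

test_that("two far-apart clusters get exactly one component link", {
  a <- synthetic_fingerprints(15, n_bits = 1024, n_clusters = 1, density = 50,
                              flip = 3, seed = 61)
  b <- lapply(synthetic_fingerprints(15, n_bits = 1024, n_clusters = 1,
                                     density = 50, flip = 3, seed = 62),
              function(fp) fraglib:::new_fingerprint(fp$kind,
                                                     1024 - fp$bits + 1, 1024))
  fps <- c(a, b)
  idx <- build_index(minhash_matrix(fps, d = 64, seed = 42))
  g <- suppressWarnings(knn_graph(idx, k = 5, kc = 10))
  lay <- spanning_tree_layout(g, idx, seed = 4)
  expect_equal(lay$n_component_links, 1L)
})
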