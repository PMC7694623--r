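# Chemical-space mapping: MinHash encoding of fingerprints, LSH-forest
# indexing, c-approximate k-nearest-neighbor graphs and spanning-tree
# layouts.
#
# MinHash signatures use d independent universal hash functions
# h_i(x) = (a_i x + b_i) mod p over the on-bit indices; the fraction of
# matching signature slots is an unbiased estimator of the Jaccard
# similarity of the underlying bit sets. The LSH forest stores, per tree,
# the items sorted by a fixed-width string key built from a seeded
# permutation of signature slots; queries descend from the longest shared
# prefix until enough candidates are collected.

.MINHASH_P <- 67108859   # prime < 2^26: products with bit indices stay exact

.minhash_params <- function(d, seed) {
  set.seed(seed)
  list(a = sample.int(.MINHASH_P - 1L, d, replace = TRUE),
       b = sample.int(.MINHASH_P, d, replace = TRUE) - 1L)
}

#' MinHash signature of a fingerprint
#'
#' @param fp A `fingerprint`.
#' @param d Signature dimension (default 128).
#' @param seed Seed for the hash family; signatures are only comparable
#'   when built with the same `d` and `seed`.
#' @return A `minhash_signature` with fields `values`, `d`, `seed`,
#'   `empty`. All-zero fingerprints get a sentinel signature (all slots at
#'   the hash modulus) and are flagged `empty`.
#' @export
minhash_signature <- function(fp, d = 128L, seed = 42L) {
  par <- .minhash_params(d, seed)
  vals <- .minhash_values(fp$bits, par, d)
  structure(list(values = vals, d = as.integer(d), seed = as.integer(seed),
                 empty = length(fp$bits) == 0L),
            class = "minhash_signature")
}

.minhash_values <- function(bits, par, d) {
  if (length(bits) == 0L) return(rep(.MINHASH_P, d))
  # d x |bits| hash table; row-wise minima
  H <- (outer(par$a, bits) + par$b) %% .MINHASH_P
  if (length(bits) == 1L) as.numeric(H) else apply(H, 1L, min)
}

#' MinHash signatures for a list of fingerprints
#'
#' Batch version of [minhash_signature()] sharing one hash family.
#'
#' @param fps List of fingerprints.
#' @inheritParams minhash_signature
#' @return A `minhash_matrix`: numeric matrix (n x d) with attributes
#'   `seed` and `empty` (logical vector).
#' @export
minhash_matrix <- function(fps, d = 128L, seed = 42L) {
  par <- .minhash_params(d, seed)
  M <- t(vapply(fps, function(fp) .minhash_values(fp$bits, par, d),
                numeric(d)))
  attr(M, "seed") <- as.integer(seed)
  attr(M, "empty") <- vapply(fps, function(fp) length(fp$bits) == 0L, logical(1L))
  M
}

#' Estimate Jaccard similarity from two MinHash signatures
#'
#' Fraction of equal signature slots; an unbiased estimator of the Jaccard
#' similarity of the underlying sets.
#'
#' @param a,b `minhash_signature` objects with matching `d` and `seed`.
#' @return Estimated similarity in \[0, 1\].
#' @export
estimate_jaccard <- function(a, b) {
  if (a$d != b$d || a$seed != b$seed) {
    stop("signatures built with different d or seed are not comparable")
  }
  mean(a$values == b$values)
}

#' Build an LSH-forest index over MinHash signatures
#'
#' @param signatures A `minhash_matrix` (from [minhash_matrix()]) or list
#'   of `minhash_signature` objects with identical `d`/`seed`.
#' @param n_trees Number of prefix trees (default 8).
#' @param prefix_len Slots per tree key (default 8).
#' @param ids Optional item identifiers (default sequential integers).
#' @return A finalized `lsh_forest` index.
#' @export
build_index <- function(signatures, n_trees = 8L, prefix_len = 8L, ids = NULL) {
  if (is.list(signatures) && !is.matrix(signatures)) {
    d <- unique(vapply(signatures, `[[`, integer(1L), "d"))
    sd <- unique(vapply(signatures, `[[`, integer(1L), "seed"))
    if (length(d) != 1L || length(sd) != 1L) {
      stop("mixed signature dimensions or seeds")
    }
    M <- t(vapply(signatures, `[[`, numeric(d[1L]), "values"))
    attr(M, "seed") <- sd
  } else {
    M <- signatures
  }
  n <- nrow(M); d <- ncol(M)
  if (is.null(ids)) ids <- seq_len(n)
  stopifnot(length(ids) == n)
  prefix_len <- min(prefix_len, d)
  seed <- attr(M, "seed")
  if (is.null(seed)) seed <- 42L

  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    set.seed(seed * 131L + t)
    perm <- sample.int(d, prefix_len)
    keys <- apply(M[, perm, drop = FALSE], 1L, function(v) {
      paste(sprintf("%08.0f", v), collapse = "")
    })
    ord <- order(keys)
    trees[[t]] <- list(perm = perm, keys = keys[ord], items = ord)
  }
  structure(list(trees = trees, signatures = M, ids = ids, n = n,
                 d = d, prefix_len = prefix_len, seed = seed),
            class = "lsh_forest")
}

# items whose (sorted) tree key starts with `prefix`
.prefix_range <- function(keys, prefix) {
  which(startsWith(keys, prefix))
}

#' Query an LSH forest
#'
#' Collects candidates from all trees, descending from the longest key
#' prefix until at least `n_candidates` distinct items are found, then
#' returns the top `k` by estimated Jaccard distance.
#'
#' @param index An `lsh_forest`.
#' @param query_row Signature values of the query (numeric vector of
#'   length `d`), or an item index via `item =`.
#' @param k Neighbors to return.
#' @param n_candidates Candidate pool size before ranking (default
#'   `10 * k`).
#' @param item Optional item index in the index; excluded from its own
#'   result list.
#' @return data.frame with columns `id`, `distance`, sorted by distance.
#' @export
query_index <- function(index, query_row = NULL, k = 1L,
                        n_candidates = 10L * k, item = NULL) {
  if (!is.null(item)) query_row <- index$signatures[item, ]
  cand <- integer()
  for (len in seq.int(index$prefix_len, 1L)) {
    for (t in index$trees) {
      qkey <- paste(sprintf("%08.0f", query_row[t$perm[seq_len(len)]]),
                    collapse = "")
      hit <- .prefix_range(t$keys, qkey)
      if (length(hit)) cand <- union(cand, t$items[hit])
    }
    if (length(setdiff(cand, item)) >= n_candidates) break
  }
  cand <- setdiff(cand, item)
  if (length(cand) < min(k, index$n - length(item))) {
    # prefix trees found too few sharers (distant query); fall back to a
    # scan so small graphs stay complete
    cand <- setdiff(seq_len(index$n), item)
  }
  if (length(cand) == 0L) {
    return(data.frame(id = index$ids[integer()], distance = numeric()))
  }
  sims <- rowMeans(index$signatures[cand, , drop = FALSE] ==
                   matrix(query_row, length(cand), index$d, byrow = TRUE))
  ord <- order(1 - sims, cand)
  top <- utils::head(ord, k)
  data.frame(id = index$ids[cand[top]], distance = 1 - sims[top])
}

#' c-approximate k-nearest-neighbor graph
#'
#' For every indexed item, `k * kc` candidates are retrieved through the
#' augmented LSH-forest query and the `k` nearest by estimated Jaccard
#' distance kept; the union of directed neighbor lists is symmetrized into
#' an undirected weighted graph (each edge stored once with `i < j`).
#'
#' @param index An `lsh_forest`.
#' @param k Neighbors per node (default 50; truncated to n-1 with a
#'   warning when k >= n).
#' @param kc Augmented-query factor (default 10).
#' @return A `knn_graph`: data.frame `edges` (i, j, weight), `n`, `k`,
#'   `kc`, plus the node `ids`.
#' @export
knn_graph <- function(index, k = 50L, kc = 10L) {
  n <- index$n
  if (n < 2L) stop("need at least 2 indexed items")
  if (k >= n) {
    warning(sprintf("k = %d >= n = %d; truncating to %d", k, n, n - 1L))
    k <- n - 1L
  }
  ei <- integer(); ej <- integer(); ew <- numeric()
  for (i in seq_len(n)) {
    res <- query_index(index, k = k, n_candidates = k * kc, item = i)
    if (nrow(res) == 0L) next
    j <- match(res$id, index$ids)
    ei <- c(ei, pmin(i, j)); ej <- c(ej, pmax(i, j)); ew <- c(ew, res$distance)
  }
  edges <- data.frame(i = ei, j = ej, weight = ew)
  edges <- edges[!duplicated(edges[, c("i", "j")]), , drop = FALSE]
  edges <- edges[edges$i != edges$j, , drop = FALSE]
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, n = n, k = k, kc = kc, ids = index$ids),
            class = "knn_graph")
}

#' @export
print.knn_graph <- function(x, ...) {
  cat(sprintf("<knn_graph: %d nodes, %d edges (k=%d, kc=%d)>\n",
              x$n, nrow(x$edges), x$k, x$kc))
  invisible(x)
}

#' Spanning-tree layout of a k-NN graph
#'
#' Extracts the minimum spanning tree (per connected component) of the
#' neighbor graph, links components by the lightest estimated
#' inter-component edge discovered over seeded candidate pairs, and embeds
#' the resulting tree in 2D with a seeded force-directed layout.
#'
#' @param g A `knn_graph`.
#' @param index Optional `lsh_forest` used to estimate inter-component
#'   link weights; without it, links get weight 1.
#' @param seed Layout seed.
#' @return A `space_layout`: `tree_edges` (i, j, weight, link flag),
#'   `coordinates` (id, x, y), `n_component_links`.
#' @export
spanning_tree_layout <- function(g, index = NULL, seed = 1L) {
  stopifnot(inherits(g, "knn_graph"), g$n >= 1L)
  ig <- igraph::graph_from_data_frame(
    data.frame(from = g$edges$i, to = g$edges$j, weight = g$edges$weight),
    directed = FALSE,
    vertices = data.frame(name = seq_len(g$n))
  )
  mst <- igraph::mst(ig, weights = igraph::E(ig)$weight)
  el <- igraph::as_edgelist(mst, names = TRUE)
  tree_edges <- data.frame(i = as.integer(el[, 1L]), j = as.integer(el[, 2L]),
                           weight = igraph::E(mst)$weight, link = FALSE)

  comp <- igraph::components(mst)$membership
  n_links <- 0L
  while (length(unique(comp)) > 1L) {
    cids <- sort(unique(comp))
    c1 <- which(comp == cids[1L]); c2 <- which(comp != cids[1L])
    set.seed(seed + n_links)
    s1 <- if (length(c1) > 20L) sample(c1, 20L) else c1
    s2 <- if (length(c2) > 20L) sample(c2, 20L) else c2
    best <- c(s1[1L], s2[1L]); best_w <- 1.0
    if (!is.null(index)) {
      for (u in s1) for (v in s2) {
        w <- 1 - mean(index$signatures[u, ] == index$signatures[v, ])
        if (w < best_w) { best <- c(u, v); best_w <- w }
      }
    }
    tree_edges <- rbind(tree_edges,
                        data.frame(i = min(best), j = max(best),
                                   weight = best_w, link = TRUE))
    comp[comp == comp[best[2L]]] <- comp[best[1L]]
    n_links <- n_links + 1L
  }

  tg <- igraph::graph_from_data_frame(
    data.frame(from = tree_edges$i, to = tree_edges$j,
               weight = pmax(tree_edges$weight, 1e-6)),
    directed = FALSE,
    vertices = data.frame(name = seq_len(g$n))
  )
  set.seed(seed)
  xy <- igraph::layout_with_fr(tg, weights = 1 / pmax(igraph::E(tg)$weight, 1e-3))
  coords <- data.frame(id = g$ids, x = xy[, 1L], y = xy[, 2L])
  structure(list(tree_edges = tree_edges, coordinates = coords,
                 n_component_links = n_links),
            class = "space_layout")
}

#' @export
print.space_layout <- function(x, ...) {
  cat(sprintf("<space_layout: %d nodes, %d tree edges, %d component links>\n",
              nrow(x$coordinates), nrow(x$tree_edges), x$n_component_links))
  invisible(x)
}

#' Write chemical-space outputs as CSV
#'
#' @param g A `knn_graph`.
#' @param layout A `space_layout`.
#' @param edges_path,layout_path Output CSV paths.
#' @param labels Optional per-node dataset labels for the layout CSV.
#' @return Invisibly, the two paths.
#' @export
write_chemspace_csv <- function(g, layout, edges_path, layout_path,
                                labels = NULL) {
  utils::write.csv(g$edges, edges_path, row.names = FALSE)
  df <- layout$coordinates
  if (!is.null(labels)) df$dataset <- labels
  utils::write.csv(df, layout_path, row.names = FALSE)
  invisible(c(edges_path, layout_path))
}
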