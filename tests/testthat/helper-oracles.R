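# Shared helpers: independent brute-force oracles and small fixtures.
# The oracles deliberately avoid the package's SSSR/descriptor code paths.

# All simple cycles of a molecular graph (as atom-index vectors), by DFS
# from each atom; practical for the <= 12 heavy-atom oracle fixtures.
enumerate_cycles <- function(m) {
  n <- n_atoms(m)
  adj <- lapply(seq_len(n), function(a) integer())
  for (b in seq_len(n_bonds(m))) {
    i <- m$bfrom[b]; j <- m$bto[b]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  cycles <- list()
  seen_keys <- character()
  path <- integer()
  dfs <- function(start, v) {
    path[[length(path) + 1L]] <<- v
    for (w in adj[[v]]) {
      if (w == start && length(path) >= 3L) {
        key <- paste(sort(path), collapse = ",")
        if (!(key %in% seen_keys)) {
          seen_keys <<- c(seen_keys, key)
          cycles[[length(cycles) + 1L]] <<- path
        }
      } else if (!(w %in% path) && w > start) {
        dfs(start, w)
      }
    }
    path <<- path[-length(path)]
  }
  for (s in seq_len(n)) dfs(s, s)
  cycles
}

# Brute-force spiro/bridgehead classification, independent of the
# package's SSSR machinery:
#  - spiro: the single shared atom of two cycles meeting at exactly one
#    atom (from the full simple-cycle set);
#  - bridgehead (Menger form): atom a such that some partner atom b is
#    joined to a by >= 3 internally-vertex-disjoint paths each with at
#    least one internal atom. Any direct a-b bond is removed first, so
#    ortho-fused systems (decalin, naphthalene) have no bridgeheads while
#    genuinely bridged ones (norbornane, adamantane) do.
oracle_spiro_bridgehead <- function(m) {
  n <- n_atoms(m)
  cycles <- enumerate_cycles(m)
  spiro <- logical(n)
  if (length(cycles) >= 2L) {
    for (i in seq_len(length(cycles) - 1L)) {
      for (j in seq.int(i + 1L, length(cycles))) {
        shared <- intersect(cycles[[i]], cycles[[j]])
        if (length(shared) == 1L) spiro[shared] <- TRUE
      }
    }
  }
  bridge <- logical(n)
  if (n_bonds(m) > 0L && length(cycles) >= 2L) {
    el <- cbind(m$bfrom, m$bto)
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    ring_atoms <- unique(unlist(cycles))
    degs <- igraph::degree(g)
    cand <- intersect(ring_atoms, which(degs >= 3L))
    for (a in cand) {
      for (b in cand) {
        if (b <= a) next
        g2 <- g
        e <- igraph::get_edge_ids(g2, c(a, b))
        if (e > 0) g2 <- igraph::delete_edges(g2, e)
        k <- tryCatch(igraph::vertex_connectivity(g2, source = a, target = b),
                      error = function(e2) 0L)
        if (k >= 3L) { bridge[a] <- TRUE; bridge[b] <- TRUE }
      }
    }
  }
  bridge[spiro] <- FALSE
  c(n_spiro = sum(spiro), n_bridgehead = sum(bridge))
}

# Brute-force median of all pairwise Tanimoto values via full sort.
oracle_median_pairwise <- function(fps) {
  n <- length(fps)
  vals <- numeric(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) vals <- c(vals, tanimoto(fps[[i]], fps[[j]]))
  }
  sorted <- sort(vals)
  k <- length(sorted)
  if (k %% 2L == 1L) sorted[(k + 1L) / 2L]
  else mean(sorted[c(k / 2L, k / 2L + 1L)])
}

# Exact Jaccard between two fingerprints' bit sets.
exact_jaccard <- function(a, b) {
  u <- length(union(a$bits, b$bits))
  if (u == 0L) 1.0 else length(intersect(a$bits, b$bits)) / u
}

block_by_name <- function(blocks, name) {
  blocks[[which(vapply(blocks, `[[`, character(1L), "name") == name)]]
}

# building blocks shared across test files (inertness asserted in
# test-synthetic.R; other files just consume them)
BLOCKS <- default_building_blocks(verify = FALSE)
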