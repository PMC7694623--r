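# Canonical SMILES output.
#
# Atom ranks come from iterative neighborhood refinement seeded with an
# order-independent atom invariant (element, degree, charge, hydrogen
# count, aromaticity, ring membership and the sorted vector of graph
# distances to every other atom in the component). Remaining ties are
# broken one atom at a time and the refinement re-run; tied classes in
# chemically ordinary graphs are automorphism orbits, so the resulting
# string does not depend on input atom order. Output is written in
# aromatic (lower-case) form; stereo annotations are not emitted, matching
# the stereochemistry-free convention used by the curation pipeline.

# rank rows of a numeric matrix lexicographically; equal rows share a rank
.row_ranks <- function(K) {
  cols <- lapply(seq_len(ncol(K)), function(j) K[, j])
  ord <- do.call(order, cols)
  Ks <- K[ord, , drop = FALSE]
  new_class <- c(TRUE, rowSums(Ks[-1L, , drop = FALSE] !=
                               Ks[-nrow(Ks), , drop = FALSE]) > 0)
  ranks <- integer(nrow(K))
  ranks[ord] <- cumsum(new_class)
  ranks
}

canonical_ranks <- function(m) {
  n <- n_atoms(m)
  if (n == 1L) return(1L)
  nbrs <- atom_neighbors(m)
  abonds <- atom_bonds(m)
  deg <- lengths(nbrs)
  maxd <- max(deg, 1L)

  # capped distance histogram per atom: order-independent tie reducer
  DH <- matrix(0L, n, 10L)
  for (s in seq_len(n)) {
    d <- rep(-1L, n); d[s] <- 0L
    frontier <- s; depth <- 0L
    while (length(frontier)) {
      depth <- depth + 1L
      nxt <- unique(unlist(nbrs[frontier]))
      nxt <- nxt[d[nxt] < 0L]
      d[nxt] <- depth
      frontier <- nxt
    }
    DH[s, ] <- tabulate(pmin(d[d > 0L], 10L), nbins = 10L)
  }

  # wildcards first so fragment SMILES lead with their attachment point
  elem_code <- match(m$element, c("*", setdiff(names(.ATOMIC_WEIGHTS), "*")))
  K0 <- cbind(elem_code, deg, m$charge, m$hcount, as.integer(m$arom),
              as.integer(m$ring_atom), DH)
  ranks <- .row_ranks(K0)

  # directed bond table, built once: da = atom, dother = neighbor,
  # dslot = column of the atom's neighbor-code matrix
  da <- c(m$bfrom, m$bto)
  dother <- c(m$bto, m$bfrom)
  dborder <- rep(m$border, 2L)
  ord_a <- order(da)
  da <- da[ord_a]; dother <- dother[ord_a]; dborder <- dborder[ord_a]
  dslot <- sequence(tabulate(da, nbins = n))
  fill_idx <- cbind(da, dslot + 1L)

  # vectorized descending sort of the neighbor-code columns (degree <= 4
  # covers organic molecules; a sorting network avoids per-atom sort calls)
  sort_cols <- function(K) {
    nc <- ncol(K) - 1L
    cx <- function(i, j) {
      hi <- pmax(K[, i + 1L], K[, j + 1L]); lo <- pmin(K[, i + 1L], K[, j + 1L])
      K[, i + 1L] <<- hi; K[, j + 1L] <<- lo
    }
    if (nc >= 2L) cx(1L, 2L)
    if (nc >= 3L) { cx(2L, 3L); cx(1L, 2L) }
    if (nc >= 4L) { cx(3L, 4L); cx(2L, 3L); cx(1L, 2L) }
    if (nc >= 5L) {
      for (p in seq_len(nc)) for (q in seq.int(1L, nc - 1L)) cx(q, q + 1L)
    }
    K
  }

  refine <- function(ranks) {
    repeat {
      K <- matrix(-1, n, 1L + maxd)
      K[, 1L] <- ranks
      K[fill_idx] <- dborder * 1e6 + ranks[dother]
      K <- sort_cols(K)
      new_ranks <- .row_ranks(K)
      if (max(new_ranks) == max(ranks)) return(new_ranks)
      ranks <- new_ranks
    }
  }

  ranks <- refine(ranks)
  while (max(ranks) < n) {
    tied_rank <- which.max(tabulate(ranks) > 1L)
    a <- which(ranks == tied_rank)[1L]
    ranks <- ranks * 2L
    ranks[a] <- ranks[a] - 1L
    ranks <- refine(.row_ranks(matrix(ranks, ncol = 1L)))
  }
  ranks
}

# implied hydrogen count for an atom as written without brackets
.implied_hcount <- function(m, a, abonds) {
  el <- m$element[a]
  if (el == "*") return(0L)
  if (!(el %in% .ORGANIC_SUBSET)) return(NA_integer_)
  used <- .valence_used(m, a, abonds)
  vals <- .DEFAULT_VALENCES[[el]]
  fit <- vals[vals >= used]
  if (length(fit) == 0L) return(NA_integer_)
  if (m$arom[a] && el %in% c("N", "P", "O", "S", "Se")) return(0L)
  as.integer(fit[1L] - used)
}

.atom_token <- function(m, a, abonds, stereo = FALSE) {
  el <- m$element[a]
  if (el == "*") return("*")
  sym <- if (m$arom[a]) tolower(el) else el
  spart <- if (stereo && nzchar(m$stereo[a])) m$stereo[a] else ""
  needs_bracket <- !(el %in% .ORGANIC_SUBSET) ||
    m$charge[a] != 0L || nzchar(spart) ||
    (m$arom[a] && !(tolower(el) %in% c("b", "c", "n", "o", "p", "s")))
  if (!needs_bracket) {
    imp <- .implied_hcount(m, a, abonds)
    if (is.na(imp) || imp != m$hcount[a]) needs_bracket <- TRUE
  }
  if (!needs_bracket) return(sym)
  h <- m$hcount[a]
  hpart <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
  chg <- m$charge[a]
  cpart <- if (chg == 0L) "" else if (chg == 1L) "+" else if (chg == -1L) "-"
           else sprintf("%+d", chg)
  paste0("[", sym, spart, hpart, cpart, "]")
}

.bond_token <- function(m, b) {
  if (m$barom[b]) return("")
  o <- m$border[b]
  if (o == 2) return("=")
  if (o == 3) return("#")
  # explicit single between two aromatic atoms (e.g. biaryl bond)
  if (m$arom[m$bfrom[b]] && m$arom[m$bto[b]]) return("-")
  ""
}

#' Canonical SMILES of a molecule
#'
#' Deterministic, input-order-independent SMILES string. Re-parsing and
#' re-canonicalizing the output reproduces the identical string (the
#' canonical form is a fixed point). Disconnected components are written
#' dot-separated in lexicographic order of their component strings.
#'
#' @param m A sanitized `molecule`.
#' @return A single SMILES string.
#' @export
to_canonical_smiles <- function(m) {
  .write_smiles(m, stereo = FALSE)
}

# Internal writer; stereo = TRUE additionally emits retained tetrahedral
# marks (used when serializing stereo-decorated synthetic fixtures).
.write_smiles <- function(m, stereo = FALSE) {
  stopifnot(is_molecule(m))
  if (!isTRUE(m$sanitized)) stop("molecule must be sanitized")
  n <- n_atoms(m)
  ranks <- canonical_ranks(m)
  comp <- mol_components(m)
  abonds <- atom_bonds(m)
  nbrs <- atom_neighbors(m)

  write_component <- function(atoms) {
    start <- atoms[which.min(ranks[atoms])]
    visited <- rep(FALSE, n)
    used_bond <- rep(FALSE, n_bonds(m))
    children <- vector("list", n)        # tree-child bond indices, in order
    closure_tok <- vector("list", n)     # closure digit tokens per atom
    next_digit <- 0L

    order_nbrs <- function(a) {
      bs <- abonds[[a]]
      other <- ifelse(m$bfrom[bs] == a, m$bto[bs], m$bfrom[bs])
      bs[order(ranks[other])]
    }

    # pass 1: DFS assigns tree bonds and ring-closure digits; the closing
    # (later-visited) endpoint carries the bond symbol
    dfs <- function(a) {
      visited[a] <<- TRUE
      for (b in order_nbrs(a)) {
        if (used_bond[b]) next
        other <- if (m$bfrom[b] == a) m$bto[b] else m$bfrom[b]
        if (visited[other]) {
          used_bond[b] <<- TRUE
          next_digit <<- next_digit + 1L
          lbl <- if (next_digit < 10L) as.character(next_digit)
                 else sprintf("%%%02d", next_digit)
          closure_tok[[other]] <<- c(closure_tok[[other]], lbl)
          closure_tok[[a]] <<- c(closure_tok[[a]], paste0(.bond_token(m, b), lbl))
        } else {
          used_bond[b] <<- TRUE
          children[[a]] <<- c(children[[a]], b)
          dfs(other)
        }
      }
    }
    dfs(start)

    # pass 2: emit with all closure digits known
    emit <- function(a, in_bond) {
      out <- if (is.na(in_bond)) "" else .bond_token(m, in_bond)
      out <- paste0(out, .atom_token(m, a, abonds, stereo = stereo),
                    paste(closure_tok[[a]], collapse = ""))
      kids <- children[[a]]
      nk <- length(kids)
      for (k in seq_along(kids)) {
        b <- kids[[k]]
        other <- if (m$bfrom[b] == a) m$bto[b] else m$bfrom[b]
        sub <- emit(other, b)
        out <- if (k < nk) paste0(out, "(", sub, ")") else paste0(out, sub)
      }
      out
    }
    emit(start, NA_integer_)
  }

  comp_ids <- unique(comp)
  strs <- vapply(comp_ids, function(ci) write_component(which(comp == ci)),
                 character(1L))
  paste(sort(strs), collapse = ".")
}
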