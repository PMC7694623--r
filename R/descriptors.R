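# Structural descriptors computed identically for compounds and fragments.
#
# All counts exclude wildcard attachment points, so decorating a molecule
# with a cleavage stub changes no descriptor value. Ring quantities are
# based on the smallest set of smallest rings; a ring is aromatic iff all
# of its atoms are aromatic and aliphatic otherwise, so the ring-count
# identity n_aliphatic + n_aromatic = n_rings holds by construction.

#' Element and heavy-atom counts
#'
#' @param m A sanitized `molecule`.
#' @return Named numeric vector with `n_carbon`, `n_oxygen`, `n_nitrogen`,
#'   `n_heavy`. Wildcards are excluded; heavy atoms are all non-hydrogen,
#'   non-wildcard atoms.
#' @export
atom_counts <- function(m) {
  el <- m$element
  c(n_carbon = sum(el == "C"),
    n_oxygen = sum(el == "O"),
    n_nitrogen = sum(el == "N"),
    n_heavy = sum(el != "H" & el != "*"))
}

#' Ring profile
#'
#' Ring counts from the smallest set of smallest rings. A ring is aromatic
#' iff all its atoms are aromatic; a heterocycle contains at least one
#' non-carbon ring atom.
#'
#' @param m A sanitized `molecule`.
#' @return Named numeric vector: `n_rings`, `n_aliphatic_rings`,
#'   `n_aromatic_rings`, `n_heterocycles`, `n_aliphatic_heterocycles`,
#'   `n_aromatic_heterocycles`.
#' @export
ring_profile <- function(m) {
  rings <- m$sssr
  if (length(rings) == 0L) {
    return(c(n_rings = 0, n_aliphatic_rings = 0, n_aromatic_rings = 0,
             n_heterocycles = 0, n_aliphatic_heterocycles = 0,
             n_aromatic_heterocycles = 0))
  }
  arom <- vapply(rings, function(r) all(m$arom[r]), logical(1L))
  hetero <- vapply(rings, function(r) any(m$element[r] != "C"), logical(1L))
  c(n_rings = length(rings),
    n_aliphatic_rings = sum(!arom),
    n_aromatic_rings = sum(arom),
    n_heterocycles = sum(hetero),
    n_aliphatic_heterocycles = sum(hetero & !arom),
    n_aromatic_heterocycles = sum(hetero & arom))
}

# spiro atoms: the single shared atom of two rings joined at one atom;
# bridgeheads: atoms of >= 3 ring bonds belonging to two rings that share
# >= 2 bonds (ortho-fused systems sharing a single bond have none).
.spiro_bridgehead <- function(m) {
  rings <- m$sssr
  nr <- length(rings)
  if (nr < 2L) return(c(n_spiro = 0, n_bridgehead = 0))
  ring_bond_sets <- lapply(rings, function(r) {
    vapply(seq_along(r), function(k) {
      bond_between(m, r[k], r[if (k == length(r)) 1L else k + 1L])
    }, integer(1L))
  })
  abonds <- atom_bonds(m)
  n_ring_bonds_at <- vapply(seq_len(n_atoms(m)), function(a) {
    sum(m$ring_bond[abonds[[a]]])
  }, numeric(1L))

  spiro <- logical(n_atoms(m))
  bridge <- logical(n_atoms(m))
  for (i in seq_len(nr - 1L)) {
    for (j in seq.int(i + 1L, nr)) {
      shared_atoms <- intersect(rings[[i]], rings[[j]])
      if (length(shared_atoms) == 1L) {
        spiro[shared_atoms] <- TRUE
      } else if (length(shared_atoms) >= 2L) {
        shared_bonds <- intersect(ring_bond_sets[[i]], ring_bond_sets[[j]])
        if (length(shared_bonds) >= 2L) {
          cand <- shared_atoms[n_ring_bonds_at[shared_atoms] >= 3L]
          bridge[cand] <- TRUE
        }
      }
    }
  }
  bridge[spiro] <- FALSE
  c(n_spiro = sum(spiro), n_bridgehead = sum(bridge))
}

# Potential stereocenters, constitution-based: a carbon with four distinct
# substituents (implicit hydrogens included), whether or not a configuration
# is assigned. Substituents are compared by iteratively refined environment
# signatures rooted at each neighbor with the candidate atom masked out.
.potential_chiral_carbons <- function(m) {
  n <- n_atoms(m)
  if (n == 0L) return(0L)
  nbrs <- atom_neighbors(m)
  abonds <- atom_bonds(m)
  count <- 0L
  for (a in seq_len(n)) {
    if (m$element[a] != "C" || m$arom[a]) next
    nb <- nbrs[[a]]
    if (any(m$border[abonds[[a]]] > 1)) next     # sp3 carbons only
    # wildcard stubs mark an unspecified attachment; for stereocenter
    # detection they count like hydrogens so capping never creates or
    # destroys a center (wildcard neutrality)
    heavy_nb <- nb[m$element[nb] != "*"]
    h_eff <- m$hcount[a] + (length(nb) - length(heavy_nb))
    if (length(heavy_nb) + h_eff != 4L) next
    if (h_eff >= 2L) next                        # two identical substituents
    sigs <- vapply(heavy_nb, function(root) .branch_signature(m, root, a, nbrs),
                   character(1L))
    if (anyDuplicated(sigs) == 0L) count <- count + 1L
  }
  count
}

# BFS signature of the branch rooted at `root`, never crossing `blocked`.
# Wildcard atoms are treated as extra hydrogens on their neighbor, so a
# capped fragment branch signs identically to the uncapped one.
.branch_signature <- function(m, root, blocked, nbrs) {
  seen <- c(blocked, root)
  parts <- character()
  frontier <- root
  repeat {
    lab <- vapply(frontier, function(a) {
      nb <- nbrs[[a]]
      n_wild <- sum(m$element[nb] == "*")
      paste0(m$element[a], if (m$arom[a]) "a" else "", m$charge[a], ":",
             m$hcount[a] + n_wild)
    }, character(1L))
    parts <- c(parts, paste(sort(lab), collapse = ","))
    nxt <- integer()
    for (a in frontier) {
      for (nb in nbrs[[a]]) {
        if (m$element[nb] == "*") next
        if (!(nb %in% seen)) { nxt <- c(nxt, nb); seen <- c(seen, nb) }
      }
    }
    if (length(nxt) == 0L || length(parts) > 64L) break
    frontier <- nxt
  }
  paste(parts, collapse = "|")
}

#' Complexity measures
#'
#' Spiro atoms, bridgehead atoms, fraction of sp3 carbons and fraction of
#' (potential) chiral carbons. Chirality is detected from constitution, so
#' molecules whose stereo annotations were stripped still report their
#' stereogenic carbons.
#'
#' @param m A sanitized `molecule`.
#' @return Named numeric vector: `n_spiro`, `n_bridgehead`, `frac_sp3`,
#'   `frac_chiral_c`. Fractions are 0 for molecules without carbon.
#' @export
complexity_measures <- function(m) {
  sb <- .spiro_bridgehead(m)
  carbons <- which(m$element == "C")
  nc <- length(carbons)
  if (nc == 0L) {
    return(c(sb, frac_sp3 = 0, frac_chiral_c = 0))
  }
  abonds <- atom_bonds(m)
  sp3 <- vapply(carbons, function(a) {
    !m$arom[a] && all(m$border[abonds[[a]]] <= 1)
  }, logical(1L))
  c(sb,
    frac_sp3 = sum(sp3) / nc,
    frac_chiral_c = .potential_chiral_carbons(m) / nc)
}

#' Full descriptor vector
#'
#' Assembles the 14 structural descriptors (atom counts, ring profile,
#' spiro/bridgehead counts, sp3 and chiral-carbon fractions) plus the
#' average molecular weight into one named vector.
#'
#' @param m A sanitized `molecule`.
#' @return Named numeric vector of length 15.
#' @export
descriptor_profile <- function(m) {
  c(atom_counts(m), ring_profile(m), complexity_measures(m),
    amw = average_molecular_weight(m))
}

#' Descriptor table for a list of molecules
#'
#' @param mols List of sanitized molecules.
#' @return A data.frame with one row per molecule, columns as in
#'   [descriptor_profile()].
#' @export
descriptor_table <- function(mols) {
  rows <- lapply(mols, descriptor_profile)
  as.data.frame(do.call(rbind, rows))
}
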