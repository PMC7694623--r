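# Sanitization: ring perception, aromaticity perception, valence checking
# and implicit-hydrogen resolution.
#
# The aromaticity model is a per-ring Hueckel count on the smallest set of
# smallest rings, iterated to a fixed point so that fused systems (e.g.
# indole written in kekulized form) are perceived ring by ring. A ring atom
# carrying a double bond that leaves the candidate ring blocks aromatization
# of that ring unless the partner atom is already aromatic; consequently
# cross-conjugated rings such as quinones (and ring-carbonyl tautomers such
# as 2-pyridone) are treated as non-aromatic, which keeps the valence model
# free of aromatic atoms with exocyclic double bonds.

#' Sanitize a molecule
#'
#' Perceives rings and aromaticity, validates valences and resolves
#' implicit hydrogen counts. Called automatically by [parse_smiles()];
#' exported for molecules modified programmatically.
#'
#' @param m A `molecule`.
#' @return The sanitized `molecule` (ring/aromatic annotations filled,
#'   `hcount` resolved, `sanitized = TRUE`).
#' @export
sanitize_molecule <- function(m) {
  stopifnot(is_molecule(m))
  m <- .perceive_rings(m)
  m <- .promote_aromatic_bonds(m)
  # hydrogens are resolved on the (possibly kekulized) input structure and
  # then frozen when Hueckel perception aromatizes a ring, so a pyrrole
  # nitrogen written kekulized keeps its hydrogen
  m <- .assign_hydrogens(m)
  m <- .hueckel_aromatize(m)
  m$sanitized <- TRUE
  m
}

# ---- ring perception -------------------------------------------------------

# Ring bonds = bonds in some cycle (non-bridges); SSSR built greedily from
# shortest cycles through each ring bond, kept while independent over GF(2).
.perceive_rings <- function(m) {
  nb <- n_bonds(m)
  na <- n_atoms(m)
  m$ring_bond <- rep(FALSE, nb)
  m$ring_atom <- rep(FALSE, na)
  m$sssr <- list()
  if (nb == 0L) return(m)

  nbrs <- atom_neighbors(m)
  abonds <- atom_bonds(m)

  # shortest alternative path from bfrom to bto avoiding bond b
  shortest_cycle <- function(b) {
    src <- m$bfrom[b]; dst <- m$bto[b]
    dist <- rep(NA_integer_, na); par <- rep(NA_integer_, na)
    dist[src] <- 0L
    queue <- src
    while (length(queue)) {
      a <- queue[[1L]]; queue <- queue[-1L]
      bs <- abonds[[a]]
      for (k in seq_along(bs)) {
        bb <- bs[k]
        if (bb == b) next
        other <- if (m$bfrom[bb] == a) m$bto[bb] else m$bfrom[bb]
        if (is.na(dist[other])) {
          dist[other] <- dist[a] + 1L
          par[other] <- a
          if (other == dst) {
            path <- dst
            while (path[1L] != src) path <- c(par[path[1L]], path)
            return(path)
          }
          queue <- c(queue, other)
        }
      }
    }
    NULL
  }

  cycles <- list()
  for (b in seq_len(nb)) {
    p <- shortest_cycle(b)
    if (!is.null(p)) {
      m$ring_bond[b] <- TRUE
      cycles[[length(cycles) + 1L]] <- p  # atom cycle (bond b closes it)
    }
  }
  if (length(cycles) == 0L) return(m)
  m$ring_atom[unique(unlist(cycles))] <- TRUE

  # bond-index vectors per cycle
  cyc_bonds <- lapply(seq_along(cycles), function(ci) {
    p <- cycles[[ci]]
    bs <- integer(length(p))
    for (k in seq_along(p)) {
      a <- p[k]; b2 <- p[if (k == length(p)) 1L else k + 1L]
      bs[k] <- bond_between(m, a, b2)
    }
    bs
  })

  n_rings <- nb - na + length(unique(mol_components(m)))
  ord <- order(lengths(cyc_bonds))
  basis <- matrix(FALSE, nrow = 0L, ncol = nb)
  chosen <- integer()
  for (ci in ord) {
    if (length(chosen) >= n_rings) break
    vec <- rep(FALSE, nb); vec[cyc_bonds[[ci]]] <- TRUE
    red <- vec
    # GF(2) reduction against current basis
    for (r in seq_len(nrow(basis))) {
      pivot <- which(basis[r, ])[1L]
      if (red[pivot]) red <- xor(red, basis[r, ])
    }
    if (any(red)) {
      basis <- rbind(basis, red)
      chosen <- c(chosen, ci)
    }
  }
  m$sssr <- lapply(chosen, function(ci) as.integer(cycles[[ci]]))
  m
}

# ---- aromaticity -----------------------------------------------------------

.promote_aromatic_bonds <- function(m) {
  if (length(m$sssr) == 0L) {
    if (any(m$arom)) stop("sanitize error: aromatic atom outside any ring")
    return(m)
  }
  # Bonds written between two input-aromatic atoms inside a ring without an
  # explicit single/double symbol are aromatic.
  for (b in seq_len(n_bonds(m))) {
    if (m$ring_bond[b] && m$arom[m$bfrom[b]] && m$arom[m$bto[b]] &&
        m$border[b] == 1 && !m$barom[b] && !nzchar(m$bstereo[b])) {
      # only promote when the default (unwritten) single bond was used --
      # the parser records explicit '-' identically, an accepted ambiguity
      # resolved by requiring ring membership and both flags.
      m$border[b] <- 1.5
      m$barom[b] <- TRUE
    }
  }
  m
}

.hueckel_aromatize <- function(m) {
  if (length(m$sssr) == 0L) return(m)
  abonds <- atom_bonds(m)

  pi_contrib <- function(a, ring, is_arom) {
    # returns electron contribution of atom a within candidate ring, or NA
    # if the atom disqualifies the ring
    if (is_arom[a]) return(1L)
    el <- m$element[a]
    if (!(el %in% .AROMATIC_ELEMENTS)) return(NA_integer_)
    bs <- abonds[[a]]
    dbl_in <- 0L; dbl_out_ok <- 0L
    for (b in bs) {
      if (m$border[b] == 3) return(NA_integer_)
      if (m$border[b] == 2) {
        other <- if (m$bfrom[b] == a) m$bto[b] else m$bfrom[b]
        if (other %in% ring) dbl_in <- dbl_in + 1L
        else if (is_arom[other]) dbl_out_ok <- dbl_out_ok + 1L
        else return(NA_integer_)   # exocyclic double to non-aromatic atom
      }
    }
    if (dbl_in > 1L) return(NA_integer_)
    if (dbl_in == 1L) return(1L)
    if (dbl_out_ok >= 1L) return(0L)
    # no double bond: lone-pair donors
    chg <- m$charge[a]
    if (el == "C") {
      if (chg == -1L) return(2L)
      if (chg == 1L) return(0L)
      return(NA_integer_)          # saturated carbon blocks aromaticity
    }
    if (el %in% c("N", "P")) {
      if (chg == 1L) return(NA_integer_)
      return(2L)                   # pyrrole-type
    }
    if (el %in% c("O", "S", "Se")) return(2L)
    if (el == "B") return(0L)
    NA_integer_
  }

  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (ring in m$sssr) {
      if (all(m$arom[ring])) next
      contribs <- vapply(ring, pi_contrib, integer(1L), ring = ring,
                         is_arom = m$arom)
      if (anyNA(contribs)) next
      tot <- sum(contribs)
      if (tot >= 6L && (tot - 2L) %% 4L == 0L) {
        m$hfixed[ring] <- TRUE      # keep kekule-derived hydrogen counts
        m$arom[ring] <- TRUE
        for (k in seq_along(ring)) {
          a <- ring[k]; b2 <- ring[if (k == length(ring)) 1L else k + 1L]
          bi <- bond_between(m, a, b2)
          m$border[bi] <- 1.5
          m$barom[bi] <- TRUE
        }
        changed <- TRUE
      }
    }
  }

  bad <- which(m$arom & !m$ring_atom)
  if (length(bad)) stop("sanitize error: aromatic atom outside any ring")
  m
}

# ---- valence / implicit hydrogens ------------------------------------------

.max_valence <- function(el, charge) {
  base <- .DEFAULT_VALENCES[[el]]
  if (is.null(base)) return(Inf)   # metals etc.: no check
  mx <- max(base)
  if (charge > 0L && el %in% c("N", "O", "S", "P", "Se")) mx <- mx + charge
  if (charge < 0L) mx <- mx + charge   # e.g. O- -> 1, N- -> 2 (from base 3? see below)
  if (el == "N" && charge < 0L) mx <- 3L + charge
  if (el == "C" && charge != 0L) mx <- 4L - abs(charge)
  if (el == "B" && charge == -1L) mx <- 4L
  mx
}

# Valence used by explicit bonds. Aromatic carbon participates in the ring
# pi system with one double bond (n aromatic bonds count n + 1); aromatic
# heteroatoms follow the lone-pair convention (aromatic bonds count 1 each,
# pyridine-type nitrogens are handled by the zero-implicit-H rule).
.valence_used <- function(m, a, abonds) {
  bs <- abonds[[a]]
  if (length(bs) == 0L) return(0L)
  n_ar <- sum(m$barom[bs])
  rest <- sum(m$border[bs][!m$barom[bs]])
  if (n_ar > 0L) {
    extra <- if (m$element[a] == "C") 1L else 0L
    as.integer(n_ar + extra + rest)
  } else {
    as.integer(ceiling(sum(m$border[bs]) - 1e-9))
  }
}

.assign_hydrogens <- function(m) {
  abonds <- atom_bonds(m)
  for (a in seq_len(n_atoms(m))) {
    el <- m$element[a]
    if (el == "*") { m$hcount[a] <- 0L; next }
    used <- .valence_used(m, a, abonds)
    if (m$hfixed[a]) {
      total <- used + m$hcount[a]
      if (total > .max_valence(el, m$charge[a])) {
        stop(sprintf("valence error: %s%+d with valence %d",
                     el, m$charge[a], total))
      }
      next
    }
    vals <- .DEFAULT_VALENCES[[el]]
    if (is.null(vals)) { m$hcount[a] <- 0L; next }
    chg <- m$charge[a]
    if (chg != 0L && el %in% c("C", "N", "O", "P", "S", "Se")) {
      # charge-adjusted valences: N+ -> 4, O- -> 1, C+/- -> 3, ...
      vals <- if (el == "C") pmax(4L - abs(chg), 0L)
              else sort(unique(pmax(vals + chg, 0L)))
    }
    fit <- vals[vals >= used]
    if (length(fit) == 0L) {
      stop(sprintf("valence error: %s with valence %d exceeds maximum %d",
                   el, used, max(vals)))
    }
    # aromatic heteroatoms never carry implicit hydrogens (pyrrole-type
    # N-H must be written as [nH]); aromatic C follows the standard rule
    target <- fit[1L]
    if (m$arom[a] && el %in% c("N", "P", "O", "S", "Se")) target <- used
    m$hcount[a] <- as.integer(target - used)
  }
  m
}
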