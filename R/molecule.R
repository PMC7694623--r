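# Molecular graph model used throughout the package.
#
# A molecule is a plain list with parallel atom vectors and parallel bond
# vectors plus ring/aromaticity annotations filled in by sanitize_molecule().
# Attachment points (cleavage stubs) are wildcard atoms with element "*";
# they carry no mass and no hydrogens and are excluded from all descriptor
# counts.

#' @keywords internal
"_PACKAGE"

# Standard (isotope-averaged) atomic weights, g/mol.
.ATOMIC_WEIGHTS <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Si = 28.086, P = 30.974, S = 32.065, Cl = 35.453, Se = 78.971,
  Br = 79.904, I = 126.904,
  Li = 6.941, Na = 22.990, K = 39.098, Rb = 85.468, Cs = 132.905,
  Be = 9.012, Mg = 24.305, Ca = 40.078, Sr = 87.62, Ba = 137.327,
  Al = 26.982, Ga = 69.723, Ge = 72.63, As = 74.922, Sn = 118.71,
  Sb = 121.76, Te = 127.6, Pb = 207.2, Bi = 208.98,
  Ti = 47.867, V = 50.942, Cr = 51.996, Mn = 54.938, Fe = 55.845,
  Co = 58.933, Ni = 58.693, Cu = 63.546, Zn = 65.38, Ag = 107.868,
  Cd = 112.411, Pt = 195.084, Au = 196.967, Hg = 200.59,
  `*` = 0.0
)

# Default valence lists for implicit-hydrogen resolution (organic subset
# semantics); elements absent from this table never receive implicit H.
.DEFAULT_VALENCES <- list(
  H = 1L, B = 3L, C = 4L, N = c(3L, 5L), O = 2L, F = 1L,
  Si = 4L, P = c(3L, 5L), S = c(2L, 4L, 6L), Cl = 1L,
  Se = c(2L, 4L, 6L), Br = 1L, I = 1L
)

# Elements writable without brackets in SMILES.
.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I", "*")

# Elements that may carry the aromatic flag.
.AROMATIC_ELEMENTS <- c("B", "C", "N", "O", "P", "S", "Se")

new_molecule <- function(element = character(), charge = integer(),
                         arom = logical(), hcount = integer(),
                         hfixed = logical(), stereo = character(),
                         bfrom = integer(), bto = integer(),
                         border = numeric(), barom = logical(),
                         bstereo = character()) {
  structure(list(
    element = element, charge = charge, arom = arom,
    hcount = hcount, hfixed = hfixed, stereo = stereo,
    bfrom = bfrom, bto = bto, border = border, barom = barom,
    bstereo = bstereo,
    ring_atom = rep(FALSE, length(element)),
    ring_bond = rep(FALSE, length(bfrom)),
    sssr = list(),
    sanitized = FALSE
  ), class = "molecule")
}

#' Number of atoms in a molecule
#'
#' @param m A `molecule` object.
#' @return Integer atom count (wildcard attachment points included).
#' @export
n_atoms <- function(m) length(m$element)

#' Number of bonds in a molecule
#'
#' @param m A `molecule` object.
#' @return Integer bond count.
#' @export
n_bonds <- function(m) length(m$bfrom)

#' Heavy-atom count
#'
#' Counts atoms that are neither hydrogen nor wildcard attachment points.
#'
#' @param m A `molecule` object.
#' @return Integer count.
#' @export
n_heavy_atoms <- function(m) sum(m$element != "H" & m$element != "*")

#' Attachment points of a molecule
#'
#' Attachment points are wildcard atoms (element `"*"`) marking where a
#' cleaved bond used to be.
#'
#' @param m A `molecule` object.
#' @return Integer vector of atom indices.
#' @export
attachment_points <- function(m) which(m$element == "*")

is_molecule <- function(x) inherits(x, "molecule")

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule: %d atoms, %d bonds%s>\n", n_atoms(x), n_bonds(x),
              if (isTRUE(x$sanitized)) paste0(", ", to_canonical_smiles(x)) else " (unsanitized)"))
  invisible(x)
}

# Adjacency list: for each atom, integer vector of bond indices.
atom_bonds <- function(m) {
  nb <- vector("list", n_atoms(m))
  if (n_bonds(m) == 0L) return(nb)
  idx <- c(seq_len(n_bonds(m)), seq_len(n_bonds(m)))
  at <- c(m$bfrom, m$bto)
  split_idx <- split(idx, factor(at, levels = seq_len(n_atoms(m))))
  lapply(split_idx, as.integer)
}

# Neighbor atom indices per atom.
atom_neighbors <- function(m) {
  n <- n_atoms(m)
  if (n_bonds(m) == 0L) return(rep(list(integer()), n))
  at <- c(m$bfrom, m$bto)
  other <- c(m$bto, m$bfrom)
  unname(split(other, factor(at, levels = seq_len(n))))
}

bond_between <- function(m, i, j) {
  hit <- which((m$bfrom == i & m$bto == j) | (m$bfrom == j & m$bto == i))
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

#' Average molecular weight
#'
#' Sums standard (isotope-averaged) atomic weights over all atoms including
#' implicit hydrogens. Wildcard attachment points contribute zero mass, so a
#' fragment weighs the same as the fragment with its stubs deleted. Additive
#' over disconnected components.
#'
#' @param m A sanitized `molecule`.
#' @return Mass in g/mol.
#' @export
average_molecular_weight <- function(m) {
  stopifnot(is_molecule(m))
  if (!isTRUE(m$sanitized)) stop("molecule must be sanitized")
  w <- .ATOMIC_WEIGHTS[m$element]
  if (anyNA(w)) {
    stop("no atomic weight for element(s): ",
         paste(unique(m$element[is.na(w)]), collapse = ", "))
  }
  sum(w) + sum(m$hcount) * .ATOMIC_WEIGHTS[["H"]]
}

# Connected components of the molecular graph; returns integer membership.
mol_components <- function(m) {
  n <- n_atoms(m)
  comp <- integer(n)
  nbrs <- atom_neighbors(m)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      a <- queue[[1L]]; queue <- queue[-1L]
      for (nb in nbrs[[a]]) {
        if (comp[nb] == 0L) { comp[nb] <- cid; queue <- c(queue, nb) }
      }
    }
  }
  comp
}

# Extract the sub-molecule induced by a set of atom indices. Bonds with one
# endpoint outside the set are dropped (callers add wildcards beforehand when
# cleaving). Returns an unsanitized molecule; hydrogen counts are kept.
subset_molecule <- function(m, atoms) {
  atoms <- sort(unique(as.integer(atoms)))
  map <- integer(n_atoms(m)); map[atoms] <- seq_along(atoms)
  keep_b <- which(m$bfrom %in% atoms & m$bto %in% atoms)
  out <- new_molecule(
    element = m$element[atoms], charge = m$charge[atoms],
    arom = m$arom[atoms], hcount = m$hcount[atoms],
    hfixed = m$hfixed[atoms], stereo = m$stereo[atoms],
    bfrom = map[m$bfrom[keep_b]], bto = map[m$bto[keep_b]],
    border = m$border[keep_b], barom = m$barom[keep_b],
    bstereo = m$bstereo[keep_b]
  )
  out
}

# Add an atom; returns list(mol, index).
add_atom <- function(m, element, charge = 0L, arom = FALSE, hcount = 0L,
                     hfixed = FALSE, stereo = "") {
  m$element <- c(m$element, element)
  m$charge <- c(m$charge, as.integer(charge))
  m$arom <- c(m$arom, arom)
  m$hcount <- c(m$hcount, as.integer(hcount))
  m$hfixed <- c(m$hfixed, hfixed)
  m$stereo <- c(m$stereo, stereo)
  m$ring_atom <- c(m$ring_atom, FALSE)
  m$sanitized <- FALSE
  list(mol = m, index = length(m$element))
}

add_bond <- function(m, i, j, order = 1, arom = FALSE, stereo = "") {
  m$bfrom <- c(m$bfrom, as.integer(i))
  m$bto <- c(m$bto, as.integer(j))
  m$border <- c(m$border, order)
  m$barom <- c(m$barom, arom)
  m$bstereo <- c(m$bstereo, stereo)
  m$ring_bond <- c(m$ring_bond, FALSE)
  m$sanitized <- FALSE
  m
}

#' Does a molecule carry stereochemical annotations?
#'
#' Checks for tetrahedral (`@`/`@@`) atom marks and directional
#' (`/`, `\`) bond marks retained from parsing.
#'
#' @param m A `molecule`.
#' @return Logical scalar.
#' @export
has_stereochemistry <- function(m) {
  any(nzchar(m$stereo)) || any(nzchar(m$bstereo))
}

# Reorder atoms by a permutation (perm[i] = new position of atom i).
# Used by property tests to verify canonicalization is order-invariant.
permute_molecule <- function(m, perm) {
  stopifnot(length(perm) == n_atoms(m))
  inv <- order(perm)
  out <- new_molecule(
    element = m$element[inv], charge = m$charge[inv], arom = m$arom[inv],
    hcount = m$hcount[inv], hfixed = m$hfixed[inv], stereo = m$stereo[inv],
    bfrom = perm[m$bfrom], bto = perm[m$bto],
    border = m$border, barom = m$barom, bstereo = m$bstereo
  )
  sanitize_molecule(out)
}
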