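# RECAP retrosynthetic fragmentation, restricted to terminal fragments.
#
# Eleven cleavage rules modelled on the widely used 2020-era reference
# dialect of the RECAP bond set: amide, ester, amine, urea, ether, olefin,
# quaternary nitrogen, aromatic nitrogen-aliphatic carbon, lactam
# nitrogen-aliphatic carbon, aromatic carbon-aromatic carbon and
# sulphonamide. A cleavage event either scissors one acyclic bond (both
# children receive a wildcard attachment point) or, for the amine, ether
# and urea chemistries, excises the central heteroatom/carbonyl unit and
# caps every released substituent, mirroring the reference reaction
# products. No rule ever touches a ring bond. Wildcard atoms never
# participate in a match, so capped fragments are stable (leaf closure).
#
# Per-rule environments, in graph-predicate form:
#   amide      C(=O)-N scission; N neutral with a second heavy substituent;
#              carbons flanked by two nitrogens belong to the urea rule
#   ester      C(=O)-O scission; ester oxygen keeps its fragment
#   amine      excision of an acyclic neutral amine N with no adjacent
#              C=O/C=N/C=S or S=O/P=O, at least two multi-atom substituents
#   urea       excision of the N-C(=O)-N carbonyl unit; both N capped
#   ether      excision of an acyclic C-O-C oxygen; both carbons must carry
#              at least one further heavy neighbor (no stranded methyls)
#   olefin     scission of an acyclic aliphatic C=C double bond
#   quaternary_nitrogen      scission of each acyclic bond from an N+ with
#              four heavy neighbors
#   aromatic_N_aliphatic_C   scission of the exocyclic n-C(sp3) bond
#   lactam_N_aliphatic_C     scission of the exocyclic bond from a ring
#              amide nitrogen to an aliphatic carbon
#   aromatic_C_aromatic_C    scission of the biaryl c-c single bond
#   sulphonamide             scission of the acyclic N-S(=O)(=O) bond

.recap_ctx <- function(m) {
  abonds <- atom_bonds(m)
  nbrs <- atom_neighbors(m)
  n <- n_atoms(m)
  carbonyl <- vapply(seq_len(n), function(a) {
    if (m$element[a] != "C") return(FALSE)
    bs <- abonds[[a]]
    any(m$border[bs] == 2 &
        m$element[ifelse(m$bfrom[bs] == a, m$bto[bs], m$bfrom[bs])] %in% c("O", "S"))
  }, logical(1L))
  list(abonds = abonds, nbrs = nbrs, carbonyl = carbonyl)
}

.bond_other <- function(m, b, a) if (m$bfrom[b] == a) m$bto[b] else m$bfrom[b]

# N adjacent to C=O/C=N/C=S or to S=O / P=O (amide-, sulfonamide-like)
.n_deactivated <- function(m, a, ctx) {
  for (nb in ctx$nbrs[[a]]) {
    el <- m$element[nb]
    if (el == "C") {
      bs <- ctx$abonds[[nb]]
      oth <- ifelse(m$bfrom[bs] == nb, m$bto[bs], m$bfrom[bs])
      if (any(m$border[bs] == 2 & m$element[oth] %in% c("O", "N", "S"))) return(TRUE)
    } else if (el %in% c("S", "P")) {
      bs <- ctx$abonds[[nb]]
      oth <- ifelse(m$bfrom[bs] == nb, m$bto[bs], m$bfrom[bs])
      if (any(m$border[bs] == 2 & m$element[oth] == "O")) return(TRUE)
    }
  }
  FALSE
}

.match_amide <- function(m, ctx) {
  out <- list()
  for (b in seq_len(n_bonds(m))) {
    if (m$ring_bond[b] || m$border[b] != 1) next
    i <- m$bfrom[b]; j <- m$bto[b]
    for (sw in 1:2) {
      cc <- if (sw == 1L) i else j
      nn <- if (sw == 1L) j else i
      if (m$element[cc] != "C" || m$arom[cc] || !ctx$carbonyl[cc]) next
      if (m$element[nn] != "N" || m$charge[nn] != 0L) next
      n_n <- sum(m$element[ctx$nbrs[[cc]]] == "N")
      if (n_n >= 2L) next                       # urea carbon
      heavy_sub <- sum(m$element[ctx$nbrs[[nn]]] != "*")
      if (heavy_sub < 2L) next                  # primary amide N
      out[[length(out) + 1L]] <- list(rule = "amide", bonds = b, excise = integer())
      break
    }
  }
  out
}

.match_ester <- function(m, ctx) {
  out <- list()
  for (b in seq_len(n_bonds(m))) {
    if (m$ring_bond[b] || m$border[b] != 1) next
    i <- m$bfrom[b]; j <- m$bto[b]
    for (sw in 1:2) {
      cc <- if (sw == 1L) i else j
      oo <- if (sw == 1L) j else i
      if (m$element[cc] != "C" || m$arom[cc] || !ctx$carbonyl[cc]) next
      if (m$element[oo] != "O" || m$charge[oo] != 0L) next
      others <- setdiff(ctx$nbrs[[oo]], cc)
      if (length(others) != 1L || m$element[others] != "C") next
      out[[length(out) + 1L]] <- list(rule = "ester", bonds = b, excise = integer())
      break
    }
  }
  out
}

.match_amine <- function(m, ctx) {
  out <- list()
  for (a in which(m$element == "N" & m$charge == 0L & !m$arom)) {
    if (m$ring_atom[a]) next
    if (.n_deactivated(m, a, ctx)) next
    bs <- ctx$abonds[[a]]
    if (any(m$border[bs] != 1)) next
    subs <- ctx$nbrs[[a]]
    real <- subs[m$element[subs] != "*"]
    if (length(real) < 2L) next
    multi <- sum(lengths(ctx$nbrs[real]) >= 2L)
    if (multi < 2L) next
    out[[length(out) + 1L]] <- list(rule = "amine", bonds = bs, excise = a)
  }
  out
}

.match_urea <- function(m, ctx) {
  out <- list()
  for (cc in which(m$element == "C" & !m$arom)) {
    if (!ctx$carbonyl[cc] || m$ring_atom[cc]) next
    bs <- ctx$abonds[[cc]]
    n_bonds_sel <- bs[m$border[bs] == 1 &
                      m$element[ifelse(m$bfrom[bs] == cc, m$bto[bs], m$bfrom[bs])] == "N"]
    if (length(n_bonds_sel) < 2L) next
    if (any(m$ring_bond[n_bonds_sel])) next
    ns <- ifelse(m$bfrom[n_bonds_sel] == cc, m$bto[n_bonds_sel], m$bfrom[n_bonds_sel])
    if (any(m$charge[ns] != 0L)) next
    # the carbonyl O (or S) leaves with the carbon
    ox <- bs[m$border[bs] == 2]
    ox_at <- ifelse(m$bfrom[ox] == cc, m$bto[ox], m$bfrom[ox])
    out[[length(out) + 1L]] <- list(rule = "urea", bonds = n_bonds_sel,
                                    excise = c(cc, ox_at))
  }
  out
}

.match_ether <- function(m, ctx) {
  out <- list()
  for (a in which(m$element == "O" & m$charge == 0L & !m$arom)) {
    if (m$ring_atom[a]) next
    subs <- ctx$nbrs[[a]]
    if (length(subs) != 2L) next
    if (any(m$element[subs] != "C")) next
    if (any(ctx$carbonyl[subs])) next            # ester linkage
    if (any(lengths(ctx$nbrs[subs]) < 2L)) next  # would strand a methyl
    bs <- ctx$abonds[[a]]
    if (any(m$border[bs] != 1)) next
    out[[length(out) + 1L]] <- list(rule = "ether", bonds = bs, excise = a)
  }
  out
}

.match_olefin <- function(m, ctx) {
  out <- list()
  for (b in seq_len(n_bonds(m))) {
    if (m$ring_bond[b] || m$border[b] != 2 || m$barom[b]) next
    i <- m$bfrom[b]; j <- m$bto[b]
    if (m$element[i] != "C" || m$element[j] != "C") next
    if (m$arom[i] || m$arom[j]) next
    if (m$charge[i] != 0L || m$charge[j] != 0L) next
    out[[length(out) + 1L]] <- list(rule = "olefin", bonds = b, excise = integer())
  }
  out
}

.match_quaternary_n <- function(m, ctx) {
  out <- list()
  for (a in which(m$element == "N" & m$charge == 1L)) {
    subs <- ctx$nbrs[[a]]
    if (length(subs) != 4L || m$hcount[a] != 0L) next
    if (any(m$element[subs] == "*")) next
    bs <- ctx$abonds[[a]]
    for (b in bs) {
      if (m$ring_bond[b] || m$border[b] != 1) next
      other <- .bond_other(m, b, a)
      if (m$element[other] != "C") next
      out[[length(out) + 1L]] <- list(rule = "quaternary_nitrogen",
                                      bonds = b, excise = integer())
    }
  }
  out
}

.match_aromatic_n_aliphatic_c <- function(m, ctx) {
  out <- list()
  for (b in seq_len(n_bonds(m))) {
    if (m$ring_bond[b] || m$border[b] != 1) next
    i <- m$bfrom[b]; j <- m$bto[b]
    for (sw in 1:2) {
      nn <- if (sw == 1L) i else j
      cc <- if (sw == 1L) j else i
      if (m$element[nn] != "N" || !m$arom[nn] || m$charge[nn] != 0L) next
      if (m$element[cc] != "C" || m$arom[cc]) next
      if (ctx$carbonyl[cc]) next                 # N-acyl belongs to amide
      out[[length(out) + 1L]] <- list(rule = "aromatic_N_aliphatic_C",
                                      bonds = b, excise = integer())
      break
    }
  }
  out
}

.match_lactam_n_aliphatic_c <- function(m, ctx) {
  out <- list()
  for (a in which(m$element == "N" & !m$arom & m$charge == 0L & m$ring_atom)) {
    bs <- ctx$abonds[[a]]
    ring_bs <- bs[m$ring_bond[bs]]
    in_lactam <- any(vapply(ring_bs, function(b) {
      other <- .bond_other(m, b, a)
      m$element[other] == "C" && ctx$carbonyl[other]
    }, logical(1L)))
    if (!in_lactam) next
    for (b in bs) {
      if (m$ring_bond[b] || m$border[b] != 1) next
      cc <- .bond_other(m, b, a)
      if (m$element[cc] != "C" || m$arom[cc] || ctx$carbonyl[cc]) next
      out[[length(out) + 1L]] <- list(rule = "lactam_N_aliphatic_C",
                                      bonds = b, excise = integer())
    }
  }
  out
}

.match_aromatic_c_aromatic_c <- function(m, ctx) {
  out <- list()
  for (b in seq_len(n_bonds(m))) {
    if (m$ring_bond[b] || m$border[b] != 1 || m$barom[b]) next
    i <- m$bfrom[b]; j <- m$bto[b]
    if (m$element[i] == "C" && m$arom[i] && m$element[j] == "C" && m$arom[j]) {
      out[[length(out) + 1L]] <- list(rule = "aromatic_C_aromatic_C",
                                      bonds = b, excise = integer())
    }
  }
  out
}

.match_sulphonamide <- function(m, ctx) {
  out <- list()
  for (b in seq_len(n_bonds(m))) {
    if (m$ring_bond[b] || m$border[b] != 1) next
    i <- m$bfrom[b]; j <- m$bto[b]
    for (sw in 1:2) {
      ss <- if (sw == 1L) i else j
      nn <- if (sw == 1L) j else i
      if (m$element[ss] != "S") next
      if (m$element[nn] != "N" || m$charge[nn] != 0L || m$arom[nn]) next
      bs <- ctx$abonds[[ss]]
      oth <- ifelse(m$bfrom[bs] == ss, m$bto[bs], m$bfrom[bs])
      if (sum(m$border[bs] == 2 & m$element[oth] == "O") < 2L) next
      heavy_sub <- sum(m$element[ctx$nbrs[[nn]]] != "*")
      if (heavy_sub < 2L) next
      out[[length(out) + 1L]] <- list(rule = "sulphonamide", bonds = b,
                                      excise = integer())
      break
    }
  }
  out
}

.RECAP_MATCHERS <- list(
  amide = .match_amide,
  ester = .match_ester,
  amine = .match_amine,
  urea = .match_urea,
  ether = .match_ether,
  olefin = .match_olefin,
  quaternary_nitrogen = .match_quaternary_n,
  aromatic_N_aliphatic_C = .match_aromatic_n_aliphatic_c,
  lactam_N_aliphatic_C = .match_lactam_n_aliphatic_c,
  aromatic_C_aromatic_C = .match_aromatic_c_aromatic_c,
  sulphonamide = .match_sulphonamide
)

#' The 11 default RECAP cleavage rules
#'
#' Returns the rule set in its fixed documented order. Each rule carries
#' its name and matcher; the matcher reports cleavage events (bonds to
#' scissor and, for amine/ether/urea, atoms to excise).
#'
#' @return Named list of rule objects, length 11.
#' @export
default_rules <- function() {
  lapply(stats::setNames(names(.RECAP_MATCHERS), names(.RECAP_MATCHERS)),
         function(nm) structure(list(name = nm, matcher = .RECAP_MATCHERS[[nm]]),
                                class = "cleavage_rule"))
}

# All cleavage events for a molecule under a rule set.
recap_matches <- function(m, rules = default_rules()) {
  ctx <- .recap_ctx(m)
  out <- list()
  for (r in rules) out <- c(out, r$matcher(m, ctx))
  out
}

#' Find cleavable bonds
#'
#' @param m A sanitized, curated `molecule`.
#' @param rules Rule set from [default_rules()].
#' @return data.frame with columns `bond` (bond index) and `rule`; each
#'   bond is reported once per rule that matches it. Ring bonds never
#'   appear.
#' @export
find_cleavable_bonds <- function(m, rules = default_rules()) {
  matches <- recap_matches(m, rules)
  if (length(matches) == 0L) {
    return(data.frame(bond = integer(), rule = character(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(matches, function(mt) {
    data.frame(bond = mt$bonds, rule = mt$rule, stringsAsFactors = FALSE)
  }))
  unique(df)
}

# Apply one cleavage event: scissor `bonds`, drop `excise` atoms, cap the
# surviving endpoints with wildcards, return the sanitized components.
apply_cleavage <- function(m, bonds, excise = integer()) {
  if (any(m$ring_bond[bonds])) stop("cannot cleave a ring bond")
  cap_atoms <- unique(c(m$bfrom[bonds], m$bto[bonds]))
  cap_atoms <- setdiff(cap_atoms, excise)
  for (a in cap_atoms) {
    res <- add_atom(m, "*")
    m <- add_bond(res$mol, a, res$index, order = 1)
  }
  drop_bonds <- unique(c(bonds, which(m$bfrom %in% excise | m$bto %in% excise)))
  keep_atoms <- setdiff(seq_len(n_atoms(m)), excise)
  map <- integer(n_atoms(m)); map[keep_atoms] <- seq_along(keep_atoms)
  keep_b <- setdiff(seq_len(n_bonds(m)), drop_bonds)
  frag <- new_molecule(
    element = m$element[keep_atoms], charge = m$charge[keep_atoms],
    arom = m$arom[keep_atoms], hcount = m$hcount[keep_atoms],
    hfixed = m$hfixed[keep_atoms], stereo = m$stereo[keep_atoms],
    bfrom = map[m$bfrom[keep_b]], bto = map[m$bto[keep_b]],
    border = m$border[keep_b], barom = m$barom[keep_b],
    bstereo = m$bstereo[keep_b]
  )
  comp <- mol_components(frag)
  lapply(unique(comp), function(ci) {
    sanitize_molecule(subset_molecule(frag, which(comp == ci)))
  })
}

#' Cleave a single acyclic bond
#'
#' Rule-independent scission: both children receive a wildcard attachment
#' point where the bond was. Heavy atoms are conserved (children's heavy
#' atoms sum to the parent's).
#'
#' @param m A sanitized `molecule`.
#' @param bond Bond index.
#' @return List of two sanitized `molecule` children.
#' @export
cleave_bond <- function(m, bond) {
  stopifnot(isTRUE(m$sanitized), bond >= 1L, bond <= n_bonds(m))
  if (m$ring_bond[bond]) stop("cannot cleave a ring bond")
  apply_cleavage(m, bond)
}

#' Terminal RECAP fragments
#'
#' Recursively applies every matching cleavage event, exploring the full
#' fragmentation hierarchy (deduplicated on canonical SMILES), and returns
#' only the leaves: fragments in which no rule matches any more. A
#' molecule with no cleavable bond yields an empty leaf set (the root is
#' never its own fragment). Leaves below the heavy-atom floor are
#' discarded.
#'
#' @param m A sanitized, curated `molecule`.
#' @param rules Rule set from [default_rules()].
#' @param min_fragment_heavy_atoms Minimum heavy atoms a leaf must have
#'   (default 0: no floor).
#' @return A `fragmentation_result`: `leaf_smiles` (sorted canonical
#'   wildcard SMILES), `leaves` (molecules in the same order),
#'   `hierarchy_size` (distinct intermediate fragments explored) and
#'   `rules_fired` (named counts over distinct fragmentation nodes).
#' @export
terminal_fragments <- function(m, rules = default_rules(),
                               min_fragment_heavy_atoms = 0L) {
  stopifnot(isTRUE(m$sanitized))
  leaf_env <- new.env(parent = emptyenv())   # smiles -> molecule
  node_env <- new.env(parent = emptyenv())   # smiles -> TRUE (visited)
  rules_fired <- integer(0)
  n_intermediate <- 0L

  visit <- function(mol, smi, is_root) {
    if (exists(smi, envir = node_env)) return(invisible())
    assign(smi, TRUE, envir = node_env)
    matches <- recap_matches(mol, rules)
    if (length(matches) == 0L) {
      if (!is_root) assign(smi, mol, envir = leaf_env)
      return(invisible())
    }
    if (!is_root) n_intermediate <<- n_intermediate + 1L
    for (mt in matches) {
      rules_fired[mt$rule] <<- (if (is.na(rules_fired[mt$rule])) 0L
                                else rules_fired[mt$rule]) + 1L
      children <- apply_cleavage(mol, mt$bonds, mt$excise)
      for (child in children) {
        csmi <- to_canonical_smiles(child)
        visit(child, csmi, is_root = FALSE)
      }
    }
    invisible()
  }
  visit(m, to_canonical_smiles(m), is_root = TRUE)

  smis <- sort(ls(leaf_env))
  mols <- lapply(smis, get, envir = leaf_env)
  if (min_fragment_heavy_atoms > 0L && length(smis)) {
    keep <- vapply(mols, n_heavy_atoms, numeric(1L)) >= min_fragment_heavy_atoms
    smis <- smis[keep]; mols <- mols[keep]
  }
  structure(list(leaf_smiles = smis, leaves = mols,
                 hierarchy_size = n_intermediate,
                 rules_fired = rules_fired),
            class = "fragmentation_result")
}

#' @export
print.fragmentation_result <- function(x, ...) {
  cat(sprintf("<fragmentation_result: %d terminal fragments, %d intermediates>\n",
              length(x$leaf_smiles), x$hierarchy_size))
  if (length(x$leaf_smiles)) cat(" ", paste(x$leaf_smiles, collapse = "  "), "\n")
  invisible(x)
}
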