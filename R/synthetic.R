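# Synthetic-data generator.
#
# Fixture molecules are assembled from fragmentation-inert building blocks
# joined by linkages drawn from the eleven cleavage chemistries, so the
# exact terminal-fragment set of every molecule is known at construction
# time (by capping blocks with wildcards where bonds are formed) without
# ever calling the fragmenter. Decorations (counterions, charges, stereo
# marks, disallowed elements, duplicates) carry per-record ground-truth
# curation outcomes.

# Each block: name, SMILES, and one or two attachment points
# (atom index within the parsed SMILES, handle tag).
.BLOCK_DEFS <- list(
  list(name = "acetyl",            smiles = "C(C)=O",              attach = list(c(1, "acyl"))),
  list(name = "benzoyl",           smiles = "C(=O)c1ccccc1",       attach = list(c(1, "acyl"))),
  list(name = "furoyl",            smiles = "C(=O)c1ccco1",        attach = list(c(1, "acyl"))),
  list(name = "thienoyl",          smiles = "C(=O)c1cccs1",        attach = list(c(1, "acyl"))),
  list(name = "cyclopropanoyl",    smiles = "C(=O)C1CC1",          attach = list(c(1, "acyl"))),
  list(name = "pivaloyl",          smiles = "C(=O)C(C)(C)C",       attach = list(c(1, "acyl"))),
  list(name = "anilino",           smiles = "Nc1ccccc1",           attach = list(c(1, "amine_H"), c(5, "aryl"))),
  list(name = "cyclohexylamino",   smiles = "NC1CCCCC1",           attach = list(c(1, "amine_H"))),
  list(name = "phenethylamino",    smiles = "NCCc1ccccc1",         attach = list(c(1, "amine_H"))),
  list(name = "morpholino",        smiles = "N1CCOCC1",            attach = list(c(1, "amine_H"))),
  list(name = "piperidino",        smiles = "N1CCCCC1",            attach = list(c(1, "amine_H"))),
  list(name = "isobutoxy",         smiles = "OCC(C)C",             attach = list(c(1, "hydroxyl"))),
  list(name = "phenoxy",           smiles = "Oc1ccccc1",           attach = list(c(1, "hydroxyl"))),
  list(name = "cyclopentyloxy",    smiles = "OC1CCCC1",            attach = list(c(1, "hydroxyl"))),
  list(name = "thf_methoxy",       smiles = "OCC1CCOC1",           attach = list(c(1, "hydroxyl"))),
  list(name = "phenyl",            smiles = "c1ccccc1",            attach = list(c(1, "aryl"), c(4, "aryl"))),
  list(name = "tolyl",             smiles = "c1ccc(C)cc1",         attach = list(c(1, "aryl"))),
  list(name = "naphthyl",          smiles = "c1ccc2ccccc2c1",      attach = list(c(1, "aryl"))),
  list(name = "thienyl",           smiles = "c1ccsc1",             attach = list(c(1, "aryl"))),
  list(name = "furyl",             smiles = "c1ccoc1",             attach = list(c(1, "aryl"))),
  list(name = "pyridyl",           smiles = "c1ccncc1",            attach = list(c(1, "aryl"))),
  list(name = "propyl",            smiles = "CCC",                 attach = list(c(1, "alkyl"), c(3, "alkyl"))),
  list(name = "isobutyl",          smiles = "CC(C)C",              attach = list(c(1, "alkyl"))),
  list(name = "cyclohexylmethyl",  smiles = "CC1CCCCC1",           attach = list(c(1, "alkyl"))),
  list(name = "neopentyl",         smiles = "CC(C)(C)C",           attach = list(c(1, "alkyl"))),
  list(name = "cyclopropylmethyl", smiles = "CC1CC1",              attach = list(c(1, "alkyl"))),
  list(name = "besyl",             smiles = "S(=O)(=O)c1ccccc1",   attach = list(c(1, "sulfonyl"))),
  list(name = "mesyl",             smiles = "S(C)(=O)=O",          attach = list(c(1, "sulfonyl"))),
  list(name = "pyrrolyl",          smiles = "[nH]1cccc1",          attach = list(c(1, "azole_nH"))),
  list(name = "indolyl",           smiles = "[nH]1ccc2ccccc21",    attach = list(c(1, "azole_nH"))),
  list(name = "imidazolyl",        smiles = "[nH]1ccnc1",          attach = list(c(1, "azole_nH"))),
  list(name = "pyrrolidinonyl",    smiles = "N1CCCC1=O",           attach = list(c(1, "lactam_NH"))),
  list(name = "valerolactamyl",    smiles = "N1CCCCC1=O",          attach = list(c(1, "lactam_NH"))),
  list(name = "quinuclidinyl",     smiles = "N12CCC(CC1)CC2",      attach = list(c(1, "quat_N")))
)

# linkage chemistry -> handles required left/right and what gets inserted
.LINKAGE_DEFS <- list(
  amide = list(left = "acyl", right = "amine_H", insert = "none"),
  ester = list(left = "acyl", right = "hydroxyl", insert = "none"),
  amine = list(left = c("alkyl", "aryl"), right = c("alkyl", "aryl"), insert = "N"),
  urea = list(left = "amine_H", right = "amine_H", insert = "CO"),
  ether = list(left = c("alkyl", "aryl"), right = c("alkyl", "aryl"), insert = "O"),
  olefin = list(left = c("alkyl", "aryl"), right = c("alkyl", "aryl"), insert = "CC"),
  quaternary_nitrogen = list(left = "quat_N", right = "alkyl", insert = "none"),
  aromatic_N_aliphatic_C = list(left = "azole_nH", right = "alkyl", insert = "none"),
  lactam_N_aliphatic_C = list(left = "lactam_NH", right = "alkyl", insert = "none"),
  aromatic_C_aromatic_C = list(left = "aryl", right = "aryl", insert = "none"),
  sulphonamide = list(left = "sulfonyl", right = "amine_H", insert = "none")
)

#' Default building blocks
#'
#' Fragmentation-inert moieties with tagged attachment points, covering
#' every handle chemistry the eleven linkages need (acyl, amine, hydroxyl,
#' aryl, alkyl, sulfonyl, plus dedicated aromatic-N-H, lactam-N-H and
#' caged-amine blocks for the special-case chemistries). Inertness of
#' every block - raw and wildcard-capped - is verified at call time, so a
#' rule-dialect change surfaces as an immediate error rather than silent
#' test rot.
#'
#' @param verify Check RECAP-inertness of every block (default TRUE).
#' @return List of `building_block` objects (`name`, `smiles`, `molecule`,
#'   `attach`).
#' @export
default_building_blocks <- function(verify = TRUE) {
  blocks <- lapply(.BLOCK_DEFS, function(b) {
    mol <- parse_smiles(b$smiles)
    attach <- lapply(b$attach, function(a) {
      list(atom = as.integer(a[[1L]]), handle = a[[2L]])
    })
    structure(list(name = b$name, smiles = b$smiles, molecule = mol,
                   attach = attach),
              class = "building_block")
  })
  if (verify) {
    for (b in blocks) {
      raw <- terminal_fragments(b$molecule)
      if (length(raw$leaf_smiles)) {
        stop(sprintf("building block '%s' is not fragmentation-inert", b$name))
      }
      capped <- .cap_block(b$molecule,
                           vapply(b$attach, `[[`, integer(1L), "atom"),
                           quat = FALSE, olefin_atoms = integer())
      cres <- terminal_fragments(capped)
      if (length(cres$leaf_smiles)) {
        stop(sprintf("capped building block '%s' fragments further", b$name))
      }
    }
  }
  blocks
}

# Bond a new neighbor to an attachment atom: fixed-H atoms (e.g. [nH])
# give up one hydrogen; implicit-H atoms adjust automatically.
.consume_h <- function(m, a) {
  if (m$hfixed[a] && m$hcount[a] > 0L) m$hcount[a] <- m$hcount[a] - 1L
  m
}

# Cap a block at the given atoms with wildcards (the construction-time
# expected-leaf builder; never calls the fragmenter). For olefin
# attachments, the linker CH2 that stays with the block is inserted first.
.cap_block <- function(mol, atoms, quat = FALSE, olefin_atoms = integer()) {
  m <- mol
  for (a in atoms) {
    m <- .consume_h(m, a)
    if (a %in% olefin_atoms) {
      res <- add_atom(m, "C"); m <- res$mol
      m <- add_bond(m, a, res$index)
      carrier <- res$index
    } else {
      carrier <- a
    }
    if (quat && m$element[carrier] == "N") m$charge[carrier] <- 1L
    res <- add_atom(m, "*"); m <- res$mol
    m <- add_bond(m, carrier, res$index)
  }
  sanitize_molecule(m)
}

# Merge two molecules; returns list(mol, offset of m2's atom indices).
.merge_mols <- function(m1, m2) {
  off <- n_atoms(m1)
  mol <- new_molecule(
    element = c(m1$element, m2$element),
    charge = c(m1$charge, m2$charge),
    arom = c(m1$arom, m2$arom),
    hcount = c(m1$hcount, m2$hcount),
    hfixed = c(m1$hfixed, m2$hfixed),
    stereo = c(m1$stereo, m2$stereo),
    bfrom = c(m1$bfrom, m2$bfrom + off),
    bto = c(m1$bto, m2$bto + off),
    border = c(m1$border, m2$border),
    barom = c(m1$barom, m2$barom),
    bstereo = c(m1$bstereo, m2$bstereo)
  )
  list(mol = mol, offset = off)
}

#' Assemble a molecule from building blocks
#'
#' Joins consecutive blocks with the given linkage chemistries and records
#' the expected terminal fragments: each block, capped with a wildcard at
#' every formed bond position (computed structurally, independent of the
#' fragmenter). Interior blocks need two attachment points with compatible
#' handles.
#'
#' @param blocks List of `building_block` objects (length k).
#' @param linkages Character vector of linkage names (length k - 1), each
#'   one of the eleven cleavage chemistries.
#' @return A `synthetic_molecule`: `molecule`, `smiles`,
#'   `expected_leaves` (sorted canonical wildcard SMILES), `linkages_used`,
#'   `blocks_used`.
#' @export
assemble_molecule <- function(blocks, linkages = character()) {
  k <- length(blocks)
  stopifnot(k >= 1L, length(linkages) == k - 1L)

  # choose attachment atoms: block i uses its handle-compatible points for
  # linkage i-1 (left side = previous linkage's right role) and linkage i
  used_attach <- vector("list", k)     # per block: integer atoms in use
  olefin_attach <- vector("list", k)
  quat_attach <- vector("list", k)
  for (i in seq_len(k)) {
    used_attach[[i]] <- integer()
    olefin_attach[[i]] <- integer()
    quat_attach[[i]] <- integer()
  }
  pick <- function(block, handles, taken) {
    for (at in block$attach) {
      if (at$handle %in% handles && !(at$atom %in% taken)) return(at$atom)
    }
    stop(sprintf("block '%s' has no free attachment with handle %s",
                 block$name, paste(handles, collapse = "/")))
  }

  joints <- vector("list", max(k - 1L, 0L))
  for (li in seq_along(linkages)) {
    ld <- .LINKAGE_DEFS[[linkages[li]]]
    if (is.null(ld)) stop("unknown linkage chemistry: ", linkages[li])
    aL <- pick(blocks[[li]], ld$left, used_attach[[li]])
    aR <- pick(blocks[[li + 1L]], ld$right, used_attach[[li + 1L]])
    used_attach[[li]] <- c(used_attach[[li]], aL)
    used_attach[[li + 1L]] <- c(used_attach[[li + 1L]], aR)
    if (ld$insert == "CC") {
      olefin_attach[[li]] <- c(olefin_attach[[li]], aL)
      olefin_attach[[li + 1L]] <- c(olefin_attach[[li + 1L]], aR)
    }
    if (linkages[li] == "quaternary_nitrogen") {
      quat_attach[[li]] <- c(quat_attach[[li]], aL)
    }
    joints[[li]] <- list(left = aL, right = aR, insert = ld$insert,
                         quat = linkages[li] == "quaternary_nitrogen")
  }

  # merge blocks and wire the joints
  mol <- blocks[[1L]]$molecule
  offsets <- c(0L, integer(k - 1L))
  for (i in seq.int(2L, length.out = k - 1L)) {
    mg <- .merge_mols(mol, blocks[[i]]$molecule)
    mol <- mg$mol
    offsets[i] <- mg$offset
  }
  for (li in seq_along(linkages)) {
    j <- joints[[li]]
    aL <- j$left + offsets[li]
    aR <- j$right + offsets[li + 1L]
    mol <- .consume_h(mol, aL)
    mol <- .consume_h(mol, aR)
    if (j$insert == "none") {
      mol <- add_bond(mol, aL, aR)
      if (j$quat) mol$charge[aL] <- 1L
    } else if (j$insert == "N") {
      res <- add_atom(mol, "N"); mol <- res$mol
      mol <- add_bond(mol, aL, res$index)
      mol <- add_bond(mol, res$index, aR)
    } else if (j$insert == "O") {
      res <- add_atom(mol, "O"); mol <- res$mol
      mol <- add_bond(mol, aL, res$index)
      mol <- add_bond(mol, res$index, aR)
    } else if (j$insert == "CO") {
      rc <- add_atom(mol, "C"); mol <- rc$mol
      ro <- add_atom(mol, "O"); mol <- ro$mol
      mol <- add_bond(mol, rc$index, ro$index, order = 2)
      mol <- add_bond(mol, aL, rc$index)
      mol <- add_bond(mol, rc$index, aR)
    } else if (j$insert == "CC") {
      r1 <- add_atom(mol, "C"); mol <- r1$mol
      r2 <- add_atom(mol, "C"); mol <- r2$mol
      mol <- add_bond(mol, r1$index, r2$index, order = 2)
      mol <- add_bond(mol, aL, r1$index)
      mol <- add_bond(mol, r2$index, aR)
    }
  }
  mol <- sanitize_molecule(mol)

  expected <- character()
  if (k >= 2L) {
    expected <- vapply(seq_len(k), function(i) {
      capped <- .cap_block(blocks[[i]]$molecule, used_attach[[i]],
                           quat = length(quat_attach[[i]]) > 0L,
                           olefin_atoms = olefin_attach[[i]])
      to_canonical_smiles(capped)
    }, character(1L))
    expected <- sort(unique(expected))
  }
  structure(list(molecule = mol, smiles = to_canonical_smiles(mol),
                 expected_leaves = expected,
                 linkages_used = linkages,
                 blocks_used = vapply(blocks, `[[`, character(1L), "name")),
            class = "synthetic_molecule")
}

#' Fixture specification
#'
#' @param n_molecules Number of molecules to generate.
#' @param linkage_mix Named probability weights over the eleven linkage
#'   chemistries (default uniform).
#' @param blocks_per_molecule Integer vector of allowed chain lengths
#'   (default 2:3; chains of 1 yield molecules with no expected leaves).
#' @param decoration Named probabilities for `salt`, `charge`, `stereo`,
#'   `element` (disallowed element swap) and `duplicate`.
#' @param seed Seed; generation is fully reproducible.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_molecules = 100L,
                         linkage_mix = NULL,
                         blocks_per_molecule = c(2L, 3L),
                         decoration = c(salt = 0, charge = 0, stereo = 0,
                                        element = 0, duplicate = 0),
                         seed = 1L) {
  if (is.null(linkage_mix)) {
    linkage_mix <- stats::setNames(rep(1, length(.LINKAGE_DEFS)),
                                   names(.LINKAGE_DEFS))
  }
  linkage_mix <- linkage_mix / sum(linkage_mix)
  dec <- c(salt = 0, charge = 0, stereo = 0, element = 0, duplicate = 0)
  dec[names(decoration)] <- decoration
  structure(list(n_molecules = as.integer(n_molecules),
                 linkage_mix = linkage_mix,
                 blocks_per_molecule = as.integer(blocks_per_molecule),
                 decoration = dec, seed = as.integer(seed)),
            class = "fixture_spec")
}

# blocks compatible with a handle set
.blocks_with_handle <- function(blocks, handles) {
  ok <- vapply(blocks, function(b) {
    hs <- vapply(b$attach, `[[`, character(1L), "handle")
    any(hs %in% handles)
  }, logical(1L))
  which(ok)
}

# pick a block chain for a linkage sequence, or NULL if some interior
# position has no block offering both required handles on distinct atoms
.build_chain <- function(blocks, links) {
  k <- length(links) + 1L
  chain <- vector("list", k)
  for (i in seq_len(k)) {
    need <- character()
    if (i > 1L) need_r <- .LINKAGE_DEFS[[links[i - 1L]]]$right else need_r <- NULL
    if (i < k) need_l <- .LINKAGE_DEFS[[links[i]]]$left else need_l <- NULL
    cand <- Filter(function(bi) {
      hs <- vapply(blocks[[bi]]$attach, `[[`, character(1L), "handle")
      if (!is.null(need_r) && !is.null(need_l)) {
        if (length(hs) < 2L) return(FALSE)
        # two distinct attachment atoms must cover the two roles
        for (p in seq_along(hs)) for (q in seq_along(hs)) {
          if (p != q && hs[p] %in% need_r && hs[q] %in% need_l) return(TRUE)
        }
        return(FALSE)
      }
      if (!is.null(need_r)) return(any(hs %in% need_r))
      if (!is.null(need_l)) return(any(hs %in% need_l))
      TRUE
    }, seq_along(blocks))
    if (length(cand) == 0L) return(NULL)
    chain[[i]] <- blocks[[cand[sample.int(length(cand), 1L)]]]
  }
  list(chain = chain, links = links)
}

#' Generate a synthetic fixture dataset
#'
#' Seeded and fully reproducible. Each record carries ground truth: the
#' expected terminal-fragment set (empty for single-block molecules), the
#' expected curation outcome (`keep`, `reject_element` or `duplicate`)
#' and the expected curated canonical SMILES. Decorations emulate raw
#' database records: appended counterions, protonated/deprotonated sites,
#' stereo marks and disallowed-element swaps.
#'
#' @param spec A [fixture_spec()].
#' @param blocks Building blocks (default [default_building_blocks()]).
#' @return List with `smiles` (raw record SMILES), `ids`, `ground_truth`
#'   (data.frame: id, outcome, curated_smiles, n_blocks, linkages) and
#'   `expected_leaves` (named list id -> character vector).
#' @export
generate_fixture <- function(spec = fixture_spec(),
                             blocks = default_building_blocks(verify = FALSE)) {
  set.seed(spec$seed)
  n <- spec$n_molecules
  ids <- sprintf("SYN%05d", seq_len(n))
  smiles <- character(n)
  outcome <- character(n)
  curated <- character(n)
  nblocks <- integer(n)
  linkstr <- character(n)
  leaves <- vector("list", n)
  names(leaves) <- ids
  base_pool <- list()   # previously generated, for duplicates

  for (i in seq_len(n)) {
    dup_roll <- stats::runif(1)
    if (dup_roll < spec$decoration[["duplicate"]] && length(base_pool) > 0L) {
      src <- base_pool[[sample.int(length(base_pool), 1L)]]
      smiles[i] <- src$smiles
      outcome[i] <- "duplicate"
      curated[i] <- src$curated
      leaves[[i]] <- src$leaves
      nblocks[i] <- src$nblocks
      linkstr[i] <- src$linkstr
      next
    }
    k <- spec$blocks_per_molecule[sample.int(length(spec$blocks_per_molecule), 1L)]
    built <- NULL
    if (k == 1L) {
      built <- list(chain = blocks[sample.int(length(blocks), 1L)],
                    links = character(0))
    } else {
      for (attempt in seq_len(20L)) {
        links <- sample(names(spec$linkage_mix), k - 1L, replace = TRUE,
                        prob = spec$linkage_mix)
        built <- .build_chain(blocks, links)
        if (!is.null(built)) break
      }
      if (is.null(built)) {
        # always satisfiable: a single linkage between two blocks
        links <- sample(names(spec$linkage_mix), 1L, prob = spec$linkage_mix)
        built <- .build_chain(blocks, links)
      }
    }
    syn <- assemble_molecule(built$chain, built$links)
    chain_len <- length(built$chain)
    links_used <- built$links
    base <- syn$molecule
    base_smi <- syn$smiles
    out <- "keep"
    rec_mol <- base

    if (stats::runif(1) < spec$decoration[["element"]]) {
      cand <- which(rec_mol$element == "C" & !rec_mol$arom & !rec_mol$ring_atom &
                    rec_mol$hcount >= 2L & rec_mol$charge == 0L)
      if (length(cand)) {
        a <- cand[[1L]]
        rec_mol$element[a] <- "Fe"
        rec_mol$hcount[a] <- 0L
        rec_mol$hfixed[a] <- TRUE
        rec_mol <- sanitize_molecule(rec_mol)
        out <- "reject_element"
      } else {
        # all-ring molecules: graft the disallowed atom onto any C-H site
        site <- which(rec_mol$element == "C" & rec_mol$hcount >= 1L)
        if (length(site)) {
          a <- site[[1L]]
          rec_mol <- .consume_h(rec_mol, a)
          res <- add_atom(rec_mol, "Fe", hfixed = TRUE)
          rec_mol <- add_bond(res$mol, a, res$index)
          rec_mol <- sanitize_molecule(rec_mol)
          out <- "reject_element"
        }
      }
    }
    if (out == "keep" && stats::runif(1) < spec$decoration[["charge"]]) {
      cand <- which(rec_mol$element == "N" & !rec_mol$arom &
                    rec_mol$charge == 0L & rec_mol$hcount >= 1L)
      cand <- cand[vapply(cand, function(a) {
        !.n_deactivated(rec_mol, a, .recap_ctx(rec_mol))
      }, logical(1L))]
      if (length(cand)) {
        a <- cand[[1L]]
        rec_mol$charge[a] <- 1L
        rec_mol$hcount[a] <- rec_mol$hcount[a] + 1L
        rec_mol$hfixed[a] <- TRUE
        rec_mol <- sanitize_molecule(rec_mol)
      }
    }
    if (out == "keep" && stats::runif(1) < spec$decoration[["stereo"]]) {
      cand <- which(rec_mol$element == "C" & !rec_mol$arom &
                    rec_mol$hcount == 1L)
      if (length(cand)) rec_mol$stereo[cand[[1L]]] <- "@"
    }
    rec_smi <- .write_smiles(rec_mol, stereo = TRUE)
    if (out == "keep" && stats::runif(1) < spec$decoration[["salt"]]) {
      rec_smi <- paste0(rec_smi, sample(c(".[Na+]", ".[K+]", ".Cl"), 1L))
    }

    smiles[i] <- rec_smi
    outcome[i] <- out
    curated[i] <- if (out == "keep") base_smi else NA_character_
    leaves[[i]] <- if (out == "keep") syn$expected_leaves else character()
    nblocks[i] <- chain_len
    linkstr[i] <- paste(links_used, collapse = "+")
    if (out == "keep") {
      base_pool[[length(base_pool) + 1L]] <-
        list(smiles = rec_smi, curated = base_smi, leaves = syn$expected_leaves,
             nblocks = nblocks[i], linkstr = linkstr[i])
    }
  }

  # records identical to an earlier kept record are duplicates even when
  # the duplicate roll did not fire (same canonical form)
  gt <- data.frame(id = ids, outcome = outcome, curated_smiles = curated,
                   n_blocks = nblocks, linkages = linkstr,
                   stringsAsFactors = FALSE)
  first_seen <- !duplicated(gt$curated_smiles) | is.na(gt$curated_smiles)
  gt$outcome[gt$outcome == "keep" & !first_seen] <- "duplicate"
  list(smiles = smiles, ids = ids, ground_truth = gt,
       expected_leaves = leaves)
}

#' Synthetic clustered fingerprint population
#'
#' Random bit vectors organized around cluster centers with flip noise --
#' a stand-in for fingerprints of compound series sharing scaffolds. Used
#' by the diversity and chemical-space benchmarks.
#'
#' @param n Population size.
#' @param n_bits Fingerprint length (default 1024).
#' @param n_clusters Number of cluster centers (1 = one scaffold family).
#' @param density On-bits per center.
#' @param flip Bits dropped and added per member (noise level).
#' @param seed Seed.
#' @param kind Fingerprint kind label.
#' @return List of `fingerprint` objects.
#' @export
synthetic_fingerprints <- function(n, n_bits = 1024L, n_clusters = 20L,
                                   density = 60L, flip = 8L, seed = 1L,
                                   kind = "circular_r2_1024") {
  set.seed(seed)
  centers <- lapply(seq_len(n_clusters), function(i) sample.int(n_bits, density))
  lapply(seq_len(n), function(i) {
    ct <- centers[[((i - 1L) %% n_clusters) + 1L]]
    drop <- sample(ct, min(flip, length(ct)))
    addb <- sample(setdiff(seq_len(n_bits), ct), flip)
    new_fingerprint(kind, c(setdiff(ct, drop), addb), n_bits)
  })
}
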