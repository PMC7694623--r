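# Standardization / curation pipeline.
#
# Raw collections are turned into curated unique molecules by applying, in
# order: functional-group normalization, largest-component selection,
# element filtering, neutralization + reionization, tautomer
# canonicalization, stereochemistry removal, a molecular-weight ceiling and
# canonical-SMILES deduplication. Every dropped record is logged with the
# step and reason, so kept + rejections + duplicates always reconciles with
# the parsed input count.

#' Curation configuration
#'
#' @param allowed_elements Permitted element symbols; molecules containing
#'   any other (non-wildcard) element are rejected.
#' @param amw_max Molecular-weight ceiling in g/mol; a molecule at exactly
#'   `amw_max` is kept (the filter is `<=`).
#' @param steps Ordered character vector of enabled steps, a subset of the
#'   default order.
#' @param tautomer_cap Maximum number of tautomers enumerated per molecule.
#' @return A `curation_config` list.
#' @export
curation_config <- function(allowed_elements = c("H", "B", "C", "N", "O", "F",
                                                 "Si", "P", "S", "Cl", "Se",
                                                 "Br", "I"),
                            amw_max = 1300,
                            steps = c("normalize", "largest_component",
                                      "element_filter", "neutralize",
                                      "tautomer", "strip_stereo",
                                      "amw_filter", "dedupe"),
                            tautomer_cap = 1000L) {
  stopifnot(amw_max > 0, length(allowed_elements) > 0)
  structure(list(allowed_elements = allowed_elements, amw_max = amw_max,
                 steps = steps, tautomer_cap = as.integer(tautomer_cap)),
            class = "curation_config")
}

# ---- normalization ---------------------------------------------------------

# Fixed ordered transform list. Each transform returns the edited molecule
# or NULL when it does not apply; normalize_structure() iterates the list
# to a fixed point.
.norm_nitro <- function(m, nbrs, abonds) {
  for (a in which(m$element == "N" & m$charge == 0L)) {
    bs <- abonds[[a]]
    dbl_o <- bs[m$border[bs] == 2 &
                m$element[ifelse(m$bfrom[bs] == a, m$bto[bs], m$bfrom[bs])] == "O"]
    if (length(dbl_o) != 2L) next
    oxy <- ifelse(m$bfrom[dbl_o] == a, m$bto[dbl_o], m$bfrom[dbl_o])
    if (any(m$charge[oxy] != 0L)) next
    if (any(lengths(nbrs[oxy]) != 1L)) next
    if (sum(m$border[bs]) < 5) next              # pentavalent form only
    pick <- dbl_o[1L]
    o <- if (m$bfrom[pick] == a) m$bto[pick] else m$bfrom[pick]
    m$border[pick] <- 1
    m$charge[o] <- -1L
    m$charge[a] <- 1L
    return(m)
  }
  NULL
}

.norm_azide <- function(m, nbrs, abonds) {
  for (b in which(m$element == "N" & m$charge == 0L)) {
    bs <- abonds[[b]]
    if (length(bs) != 2L || any(m$border[bs] != 2)) next
    ends <- ifelse(m$bfrom[bs] == b, m$bto[bs], m$bfrom[bs])
    if (any(m$element[ends] != "N")) next
    term <- ends[lengths(nbrs[ends]) == 1L & m$charge[ends] == 0L]
    if (length(term) == 0L) next
    m$charge[b] <- 1L
    m$charge[term[1L]] <- -1L
    return(m)
  }
  NULL
}

.norm_sulfoxide <- function(m, nbrs, abonds) {
  for (s in which(m$element == "S" & m$charge == 1L)) {
    bs <- abonds[[s]]
    for (b in bs) {
      o <- if (m$bfrom[b] == s) m$bto[b] else m$bfrom[b]
      if (m$element[o] == "O" && m$charge[o] == -1L &&
          m$border[b] == 1 && length(nbrs[[o]]) == 1L) {
        m$charge[s] <- 0L
        m$charge[o] <- 0L
        m$border[b] <- 2
        m$hcount[o] <- 0L
        return(m)
      }
    }
  }
  NULL
}

.NORMALIZE_TRANSFORMS <- list(
  nitro = .norm_nitro,
  azide = .norm_azide,
  sulfoxide = .norm_sulfoxide
)

#' Normalize functional-group representations
#'
#' Applies a fixed ordered list of transforms (charge-separated nitro,
#' azide normal form, sulfoxide double-bond form) until a fixed point is
#' reached; molecules already in normal form are returned unchanged.
#'
#' @param m A sanitized `molecule`.
#' @return A sanitized, normalized `molecule`.
#' @export
normalize_structure <- function(m) {
  stopifnot(isTRUE(m$sanitized))
  for (iter in seq_len(25L)) {
    nbrs <- atom_neighbors(m)
    abonds <- atom_bonds(m)
    applied <- FALSE
    for (tn in names(.NORMALIZE_TRANSFORMS)) {
      out <- .NORMALIZE_TRANSFORMS[[tn]](m, nbrs, abonds)
      if (!is.null(out)) {
        m <- tryCatch(sanitize_molecule(out), error = function(e) {
          stop(sprintf("normalization error in transform '%s': %s",
                       tn, conditionMessage(e)))
        })
        applied <- TRUE
        break
      }
    }
    if (!applied) return(m)
  }
  m
}

#' Select the largest connected component
#'
#' Keeps the component with the most heavy atoms; ties are broken by larger
#' molecular weight, then by lexicographically smallest canonical SMILES,
#' so the choice is deterministic.
#'
#' @param m A sanitized `molecule`.
#' @return A single-component sanitized `molecule`.
#' @export
select_largest_component <- function(m) {
  stopifnot(isTRUE(m$sanitized))
  comp <- mol_components(m)
  ids <- unique(comp)
  if (length(ids) == 1L) return(m)
  subs <- lapply(ids, function(ci) sanitize_molecule(subset_molecule(m, which(comp == ci))))
  heavy <- vapply(subs, n_heavy_atoms, numeric(1L))
  amw <- vapply(subs, average_molecular_weight, numeric(1L))
  top <- which(heavy == max(heavy) & amw == max(amw[heavy == max(heavy)]))
  if (length(top) > 1L) {
    # canonical SMILES tie-break only when needed (it is the costly step)
    smi <- vapply(subs[top], to_canonical_smiles, character(1L))
    top <- top[order(smi)]
  }
  subs[[top[1L]]]
}

#' Neutralize charges and reionize acidic sites
#'
#' Protonates anionic sites and deprotonates protonated cationic sites to
#' bring the net charge as close to zero as chemically possible; permanent
#' cations (quaternary nitrogen) are left charged and compensated, where
#' possible, by deprotonating the strongest acidic O-H sites (sulfonic,
#' then carboxylic, then phenolic). Anions adjacent to a positively
#' charged atom (nitro, azide, N-oxide normal forms) are preserved.
#'
#' @param m A sanitized, single-component `molecule`.
#' @return A sanitized `molecule`.
#' @export
neutralize_and_reionize <- function(m) {
  stopifnot(isTRUE(m$sanitized))
  nbrs <- atom_neighbors(m)
  # uncharge anions
  for (a in which(m$charge < 0L & m$element %in% c("O", "S", "N", "C"))) {
    if (any(m$charge[nbrs[[a]]] > 0L)) next
    m$hcount[a] <- m$hcount[a] + abs(m$charge[a])
    m$hfixed[a] <- TRUE
    m$charge[a] <- 0L
  }
  # uncharge protonated cations
  for (a in which(m$charge > 0L & m$element %in% c("N", "S", "P", "O"))) {
    strip <- min(m$charge[a], m$hcount[a])
    if (strip <= 0L) next
    m$hcount[a] <- m$hcount[a] - strip
    m$hfixed[a] <- TRUE
    m$charge[a] <- m$charge[a] - strip
  }
  m <- sanitize_molecule(m)
  net <- sum(m$charge)
  if (net > 0L) {
    m <- .deprotonate_acids(m, net)
  }
  m
}

# deprotonate up to n_needed most-acidic O-H sites
.deprotonate_acids <- function(m, n_needed) {
  nbrs <- atom_neighbors(m)
  abonds <- atom_bonds(m)
  acidity <- function(o) {
    # smaller = more acidic
    att <- nbrs[[o]]
    if (length(att) != 1L) return(NA_real_)
    c_at <- att[1L]
    bs <- abonds[[c_at]]
    others <- ifelse(m$bfrom[bs] == c_at, m$bto[bs], m$bfrom[bs])
    has_dbl_o <- any(m$border[bs] == 2 & m$element[others] == "O")
    if (m$element[c_at] == "S" && has_dbl_o) return(1)   # sulfonic/sulfinic
    if (m$element[c_at] == "P" && has_dbl_o) return(2)   # phosphonic
    if (m$element[c_at] == "C" && has_dbl_o) return(3)   # carboxylic
    if (m$arom[c_at]) return(4)                          # phenolic
    NA_real_
  }
  cand <- which(m$element == "O" & m$charge == 0L & m$hcount >= 1L)
  if (length(cand) == 0L) return(m)
  acid <- vapply(cand, acidity, numeric(1L))
  keep <- !is.na(acid)
  cand <- cand[keep]; acid <- acid[keep]
  if (length(cand) == 0L) return(m)
  ranks <- canonical_ranks(m)
  ord <- cand[order(acid, ranks[cand])]
  for (o in utils::head(ord, n_needed)) {
    m$hcount[o] <- m$hcount[o] - 1L
    m$hfixed[o] <- TRUE
    m$charge[o] <- -1L
  }
  sanitize_molecule(m)
}

# ---- tautomers -------------------------------------------------------------

# All 1,3 proton shifts a=b-c(H) -> a(H)-b=c with at least one heteroatom
# terminus; aromatic systems are left untouched (aromatization happens via
# re-perception after a shift, e.g. 2-pyridone -> 2-hydroxypyridine).
.tautomer_neighbors <- function(m) {
  out <- list()
  abonds <- atom_bonds(m)
  hetero <- c("N", "O", "S")
  for (b2 in seq_len(n_bonds(m))) {
    if (m$barom[b2] || m$border[b2] != 2) next
    for (dir in 1:2) {
      a <- if (dir == 1L) m$bfrom[b2] else m$bto[b2]
      b <- if (dir == 1L) m$bto[b2] else m$bfrom[b2]
      if (!(m$element[b] %in% c("C", "N"))) next   # pivot: no S/P shifts
      if (!(m$element[a] %in% c("C", hetero))) next
      for (b1 in abonds[[b]]) {
        if (b1 == b2 || m$barom[b1] || m$border[b1] != 1) next
        c_at <- if (m$bfrom[b1] == b) m$bto[b1] else m$bfrom[b1]
        if (c_at == a) next
        if (!(m$element[c_at] %in% c("C", hetero))) next
        if (m$element[a] == "C" && m$element[c_at] == "C") next
        if (m$hcount[c_at] < 1L) next
        if (m$charge[a] != 0L || m$charge[c_at] != 0L) next
        mm <- m
        mm$border[b2] <- 1
        mm$border[b1] <- 2
        if (mm$hfixed[c_at]) mm$hcount[c_at] <- mm$hcount[c_at] - 1L
        if (mm$hfixed[a]) mm$hcount[a] <- mm$hcount[a] + 1L
        mm <- tryCatch(sanitize_molecule(mm), error = function(e) NULL)
        if (!is.null(mm)) out[[length(out) + 1L]] <- mm
      }
    }
  }
  out
}

.tautomer_score <- function(m) {
  rp <- ring_profile(m)
  n_co <- 0L; n_cn <- 0L
  for (b in seq_len(n_bonds(m))) {
    if (m$barom[b] || m$border[b] != 2) next
    els <- sort(c(m$element[m$bfrom[b]], m$element[m$bto[b]]))
    if (identical(els, c("C", "O"))) n_co <- n_co + 1L
    if (identical(els, c("C", "N"))) n_cn <- n_cn + 1L
  }
  100 * rp[["n_aromatic_rings"]] + 4 * n_co + 2 * n_cn
}

#' Canonical tautomer
#'
#' Enumerates tautomers reachable by 1,3 proton shifts (bounded,
#' breadth-first, deduplicated on canonical SMILES), scores each form
#' (aromatic rings strongly preferred, then carbonyl over enol, then
#' imine), and returns the best-scoring tautomer; ties are broken by
#' lexicographically smallest canonical SMILES so any input tautomer of the
#' same set maps to the same output.
#'
#' @param m A sanitized `molecule`.
#' @param cap Enumeration bound; when reached the best form found so far is
#'   returned with a warning.
#' @return A sanitized `molecule`.
#' @export
canonical_tautomer <- function(m, cap = 1000L) {
  stopifnot(isTRUE(m$sanitized))
  seen <- new.env(parent = emptyenv())
  start_smi <- to_canonical_smiles(m)
  assign(start_smi, m, envir = seen)
  queue <- list(m)
  while (length(queue) > 0L) {
    cur <- queue[[1L]]
    queue <- queue[-1L]
    for (t in .tautomer_neighbors(cur)) {
      smi <- to_canonical_smiles(t)
      if (!exists(smi, envir = seen)) {
        if (length(ls(seen)) >= cap) {
          warning("tautomer enumeration cap reached; returning best found")
          queue <- list()
          break
        }
        assign(smi, t, envir = seen)
        queue <- c(queue, list(t))
      }
    }
  }
  smis <- ls(seen)
  cands <- lapply(smis, get, envir = seen)
  scores <- vapply(cands, .tautomer_score, numeric(1L))
  best <- order(-scores, smis)[1L]
  cands[[best]]
}

# ---- remaining steps -------------------------------------------------------

#' Remove stereochemical annotations
#'
#' Clears tetrahedral and double-bond stereo marks; the constitution is
#' unchanged.
#'
#' @param m A `molecule`.
#' @return The `molecule` without stereo annotations.
#' @export
strip_stereochemistry <- function(m) {
  m$stereo <- rep("", n_atoms(m))
  m$bstereo <- rep("", n_bonds(m))
  m
}

#' Element filter
#'
#' @param m A sanitized `molecule`.
#' @param allowed Permitted element symbols (wildcards always pass).
#' @return List with `pass` (logical) and `offending` (character vector of
#'   disallowed elements present).
#' @export
element_filter <- function(m, allowed = curation_config()$allowed_elements) {
  off <- setdiff(unique(m$element), c(allowed, "*"))
  list(pass = length(off) == 0L, offending = off)
}

#' Curate a dataset
#'
#' Applies the standardization pipeline to every record of a molecule
#' table, in the step order given by the configuration. Rejected records
#' and duplicates are logged; the invariant
#' `kept + rejections + duplicates = inputs` always holds.
#'
#' @param raw A `molecule_table` of parsed molecules.
#' @param cfg A [curation_config()].
#' @return A `curation_result` with fields `kept` (a `molecule_table`),
#'   `smiles` (canonical SMILES of kept records), `rejections` (data.frame
#'   id/step/reason) and `duplicate_map` (named character vector mapping
#'   dropped duplicate id to the retained id).
#' @export
curate_dataset <- function(raw, cfg = curation_config()) {
  n <- length(raw$ids)
  kept_ids <- character()
  kept_mols <- list()
  kept_smiles <- character()
  rej <- list()
  dup_map <- character()
  seen_smiles <- new.env(parent = emptyenv())

  for (i in seq_len(n)) {
    id <- raw$ids[i]
    mol <- raw$molecules[[i]]
    failed <- NULL
    for (step in cfg$steps) {
      res <- tryCatch({
        switch(step,
          normalize = { mol <- normalize_structure(mol); NULL },
          largest_component = { mol <- select_largest_component(mol); NULL },
          element_filter = {
            ef <- element_filter(mol, cfg$allowed_elements)
            if (!ef$pass) paste0("disallowed element: ",
                                 paste(ef$offending, collapse = ",")) else NULL
          },
          neutralize = { mol <- neutralize_and_reionize(mol); NULL },
          tautomer = { mol <- canonical_tautomer(mol, cfg$tautomer_cap); NULL },
          strip_stereo = { mol <- strip_stereochemistry(mol); NULL },
          amw_filter = {
            amw <- average_molecular_weight(mol)
            if (amw > cfg$amw_max) sprintf("AMW %.2f > %.0f", amw, cfg$amw_max)
            else NULL
          },
          dedupe = NULL,
          stop("unknown curation step: ", step))
      }, error = function(e) conditionMessage(e))
      if (!is.null(res)) { failed <- list(step = step, reason = res); break }
    }
    if (!is.null(failed)) {
      rej[[length(rej) + 1L]] <- data.frame(id = id, step = failed$step,
                                            reason = failed$reason,
                                            stringsAsFactors = FALSE)
      next
    }
    smi <- to_canonical_smiles(mol)
    if ("dedupe" %in% cfg$steps && exists(smi, envir = seen_smiles)) {
      dup_map[id] <- get(smi, envir = seen_smiles)
      next
    }
    assign(smi, id, envir = seen_smiles)
    kept_ids <- c(kept_ids, id)
    kept_mols <- c(kept_mols, list(mol))
    kept_smiles <- c(kept_smiles, smi)
  }

  rejections <- if (length(rej)) do.call(rbind, rej)
                else data.frame(id = character(), step = character(),
                                reason = character(), stringsAsFactors = FALSE)
  structure(list(
    kept = new_molecule_table(kept_ids, kept_mols,
                              rep(if (length(raw$provenance)) raw$provenance[1L]
                                  else "unknown", length(kept_ids))),
    smiles = kept_smiles,
    rejections = rejections,
    duplicate_map = dup_map,
    n_input = n
  ), class = "curation_result")
}

#' @export
print.curation_result <- function(x, ...) {
  cat(sprintf("<curation_result: %d in, %d kept, %d rejected, %d duplicates>\n",
              x$n_input, length(x$kept$ids), nrow(x$rejections),
              length(x$duplicate_map)))
  invisible(x)
}

#' Write curated molecules with descriptors as CSV
#'
#' Column layout follows the published dataset schema: ID, Smiles, AMW,
#' atom counts, ring counts, bridgehead count, sp3 and chiral-carbon
#' fractions and a semicolon-joined Fragments column (filled by the
#' fragmentation stage; empty otherwise).
#'
#' @param result A `curation_result`.
#' @param path Output CSV path.
#' @param fragments Optional named list (id -> character vector of fragment
#'   SMILES).
#' @return The data.frame written, invisibly.
#' @export
write_curated_csv <- function(result, path, fragments = NULL) {
  mols <- result$kept$molecules
  ids <- result$kept$ids
  desc <- if (length(mols)) descriptor_table(mols) else NULL
  frag_col <- vapply(ids, function(id) {
    f <- fragments[[id]]
    if (is.null(f)) "" else paste(f, collapse = ";")
  }, character(1L))
  df <- data.frame(
    ID = ids,
    Smiles = result$smiles,
    AMW = if (is.null(desc)) numeric() else round(desc$amw, 3),
    NumC = if (is.null(desc)) numeric() else desc$n_carbon,
    NumO = if (is.null(desc)) numeric() else desc$n_oxygen,
    NumN = if (is.null(desc)) numeric() else desc$n_nitrogen,
    NumHeavy = if (is.null(desc)) numeric() else desc$n_heavy,
    NumAliphaticRings = if (is.null(desc)) numeric() else desc$n_aliphatic_rings,
    NumAromaticRings = if (is.null(desc)) numeric() else desc$n_aromatic_rings,
    NumHeterocycles = if (is.null(desc)) numeric() else desc$n_heterocycles,
    NumBridgeheads = if (is.null(desc)) numeric() else desc$n_bridgehead,
    FracSp3 = if (is.null(desc)) numeric() else round(desc$frac_sp3, 4),
    FracChiralC = if (is.null(desc)) numeric() else round(desc$frac_chiral_c, 4),
    Fragments = frag_col,
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
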