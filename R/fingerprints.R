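# Molecular fingerprints: native circular (Morgan-type) fingerprints and
# MACCS structural keys evaluated through OpenBabel.

.FP_HASH_P <- 2147483647
.FP_HASH_MUL <- 1000003

# deterministic integer hash fold (values stay < 2^31 so doubles are exact)
.hash_fold <- function(h, x) ((h %% .FP_HASH_P) * .FP_HASH_MUL + x) %% .FP_HASH_P

.hash_vec <- function(xs) {
  h <- 17
  for (x in xs) h <- .hash_fold(h, x)
  h
}

new_fingerprint <- function(kind, bits, nbits) {
  structure(list(kind = kind, bits = sort(unique(as.integer(bits))),
                 nbits = as.integer(nbits)),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint %s: %d/%d bits set>\n", x$kind, length(x$bits), x$nbits))
  invisible(x)
}

#' Circular (Morgan-type) fingerprint
#'
#' Hashes circular atom environments of radius 0..`radius` onto a fixed
#' number of bits. Initial atom invariants combine element, degree,
#' hydrogen count, charge, aromaticity and ring membership; wildcard
#' attachment points are a distinct atom type. Deterministic.
#'
#' @param m A sanitized `molecule`.
#' @param radius Environment radius (default 2).
#' @param n_bits Fingerprint length (default 1024).
#' @return A `fingerprint` of kind `"circular_r2_1024"` (or analogous).
#' @export
circular_fingerprint <- function(m, radius = 2L, n_bits = 1024L) {
  stopifnot(isTRUE(m$sanitized))
  n <- n_atoms(m)
  abonds <- atom_bonds(m)
  elem_code <- vapply(m$element, function(e) sum(utf8ToInt(e)), numeric(1L))
  inv <- vapply(seq_len(n), function(a) {
    .hash_vec(c(elem_code[a], length(abonds[[a]]), m$hcount[a],
                m$charge[a] + 10, as.integer(m$arom[a]),
                as.integer(m$ring_atom[a])))
  }, numeric(1L))
  all_ids <- inv
  for (r in seq_len(radius)) {
    inv_new <- vapply(seq_len(n), function(a) {
      bs <- abonds[[a]]
      if (length(bs) == 0L) return(.hash_vec(c(r, inv[a])))
      other <- ifelse(m$bfrom[bs] == a, m$bto[bs], m$bfrom[bs])
      pair <- sort(m$border[bs] * 10 * .FP_HASH_MUL %% .FP_HASH_P + inv[other])
      .hash_vec(c(r, inv[a], pair))
    }, numeric(1L))
    inv <- inv_new
    all_ids <- c(all_ids, inv)
  }
  bits <- (all_ids %% n_bits) + 1L
  kind <- sprintf("circular_r%d_%d", radius, n_bits)
  new_fingerprint(kind, bits, n_bits)
}

# parse obabel -ofpt hex dump blocks into on-bit key numbers (1-based)
.parse_fpt_hex <- function(lines) {
  out <- list()
  cur <- NULL
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      if (!is.null(cur)) out[[length(out) + 1L]] <- cur
      cur <- character()
    } else if (!is.null(cur)) {
      cur <- c(cur, strsplit(trimws(ln), "[ \t]+")[[1L]])
    }
  }
  if (!is.null(cur)) out[[length(out) + 1L]] <- cur
  hexval <- function(word) {
    digs <- strtoi(strsplit(word, "")[[1L]], 16L)
    Reduce(function(acc, d) acc * 16 + d, digs, accumulate = FALSE)
  }
  lapply(out, function(words) {
    words <- words[nzchar(words)]
    nw <- length(words)
    bits <- integer()
    for (w in seq_len(nw)) {
      v <- hexval(words[w])            # numeric: words can exceed 2^31 - 1
      if (is.na(v) || v == 0) next
      pos <- 0L
      while (v > 0) {
        if (v %% 2 == 1) bits <- c(bits, (nw - w) * 32L + pos + 1L)
        v <- v %/% 2
        pos <- pos + 1L
      }
    }
    bits
  })
}

#' MACCS structural keys
#'
#' Evaluates the 166 MACCS key substructure definitions through the
#' OpenBabel command line tool (`obabel`), batched over a list of
#' molecules. Tiny fragments may legitimately set no key at all.
#'
#' @param mols List of sanitized molecules (or a single molecule).
#' @return A list of `fingerprint` objects of kind `"keys_166"` (a single
#'   `fingerprint` if a single molecule was given).
#' @export
keys_fingerprint <- function(mols) {
  single <- is_molecule(mols)
  if (single) mols <- list(mols)
  smiles <- vapply(mols, to_canonical_smiles, character(1L))
  ob <- Sys.which("obabel")
  if (!nzchar(ob)) stop("MACCS keys require the 'obabel' command line tool")
  inf <- tempfile(fileext = ".smi")
  on.exit(unlink(inf), add = TRUE)
  writeLines(paste(smiles, seq_along(smiles)), inf)
  raw <- suppressWarnings(
    system2(ob, c(shQuote(inf), "-ofpt", "-xfMACCS", "-xh"),
            stdout = TRUE, stderr = FALSE)
  )
  keysets <- .parse_fpt_hex(raw)
  if (length(keysets) != length(smiles)) {
    stop(sprintf("obabel returned %d fingerprints for %d molecules",
                 length(keysets), length(smiles)))
  }
  fps <- lapply(keysets, function(b) new_fingerprint("keys_166", b[b <= 166L], 166L))
  if (single) fps[[1L]] else fps
}

#' Tanimoto similarity between two fingerprints
#'
#' `|A intersect B| / |A union B|`; defined as 1 when both fingerprints are
#' all-zero (two empty bit sets are identical objects).
#'
#' @param a,b `fingerprint` objects of the same kind and length.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  if (!identical(a$kind, b$kind) || a$nbits != b$nbits) {
    stop("fingerprint kind/length mismatch: ", a$kind, " vs ", b$kind)
  }
  u <- length(union(a$bits, b$bits))
  if (u == 0L) return(1.0)
  length(intersect(a$bits, b$bits)) / u
}

#' Dense 0/1 matrix from a list of fingerprints
#'
#' @param fps List of `fingerprint` objects of one kind.
#' @return Numeric matrix, one row per fingerprint.
#' @export
fingerprint_matrix <- function(fps) {
  stopifnot(length(fps) > 0L)
  kinds <- unique(vapply(fps, `[[`, character(1L), "kind"))
  if (length(kinds) != 1L) stop("mixed fingerprint kinds")
  nb <- fps[[1L]]$nbits
  X <- matrix(0, nrow = length(fps), ncol = nb)
  for (i in seq_along(fps)) X[i, fps[[i]]$bits] <- 1
  X
}
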