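# SMILES reader.
#
# Supports the organic subset, bracket atoms with isotope/charge/H-count/
# tetrahedral marks, aromatic lower-case atoms, ring closures (including
# %nn), branches, dot-separated components and directional bond marks.
# Stereo annotations are parsed and retained on the molecule; they are only
# removed by strip_stereochemistry() so that the stripping step is testable
# in isolation.

.TWO_LETTER_ORGANIC <- c("Cl", "Br")

#' Parse a SMILES string into a molecule
#'
#' The returned molecule is sanitized: rings are perceived, aromaticity is
#' perceived (kekulized aromatic rings are converted to their aromatic
#' form), valences are checked against the element valence model and
#' implicit hydrogens are resolved.
#'
#' @param s A single non-empty SMILES string.
#' @param sanitize Run [sanitize_molecule()] on the result (default `TRUE`).
#' @return A `molecule` object.
#' @seealso [to_canonical_smiles()]
#' @examples
#' m <- parse_smiles("c1ccccc1")
#' n_atoms(m)
#' @export
parse_smiles <- function(s, sanitize = TRUE) {
  if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(s)) {
    stop("parse error: SMILES must be a single non-empty string")
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  m <- new_molecule()

  prev <- NA_integer_          # previous atom index
  stack <- integer()           # branch stack
  pending_bond <- NULL         # explicit bond symbol awaiting next atom
  ring_open <- list()          # closure digit -> list(atom, bondsym)

  i <- 1L
  make_bond <- function(m, from, to, sym) {
    order <- 1; arom <- FALSE; stereo <- ""
    if (!is.null(sym)) {
      if (sym == "=") order <- 2
      else if (sym == "#") order <- 3
      else if (sym == ":") { order <- 1.5; arom <- TRUE }
      else if (sym == "-") order <- 1
      else if (sym %in% c("/", "\\")) { order <- 1; stereo <- sym }
    }
    add_bond(m, from, to, order = order, arom = arom, stereo = stereo)
  }

  attach_atom <- function(idx) {
    if (!is.na(prev)) {
      m <<- make_bond(m, prev, idx, pending_bond)
    }
    pending_bond <<- NULL
    prev <<- idx
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      if (is.na(prev)) stop("parse error: branch with no preceding atom")
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) stop("parse error: unmatched ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending_bond <- ch
      i <- i + 1L
    } else if (ch == ".") {
      prev <- NA_integer_
      pending_bond <- NULL
      i <- i + 1L
    } else if (ch == "%" || grepl("[0-9]", ch)) {
      if (ch == "%") {
        if (i + 2L > n) stop("parse error: truncated %nn ring closure")
        num <- paste0(chars[i + 1L], chars[i + 2L])
        i <- i + 3L
      } else {
        num <- ch
        i <- i + 1L
      }
      if (is.na(prev)) stop("parse error: ring closure with no atom")
      key <- num
      if (!is.null(ring_open[[key]])) {
        op <- ring_open[[key]]
        sym <- if (!is.null(pending_bond)) pending_bond else op$bondsym
        if (op$atom == prev) stop("parse error: self ring closure")
        m <- make_bond(m, op$atom, prev, sym)
        ring_open[[key]] <- NULL
        pending_bond <- NULL
      } else {
        ring_open[[key]] <- list(atom = prev, bondsym = pending_bond)
        pending_bond <- NULL
      }
    } else if (ch == "[") {
      close <- NA_integer_
      for (j in seq.int(i + 1L, min(n, i + 30L))) {
        if (chars[j] == "]") { close <- j; break }
      }
      if (is.na(close)) stop("parse error: unmatched '['")
      body <- paste(chars[seq.int(i + 1L, close - 1L)], collapse = "")
      at <- .parse_bracket_atom(body)
      res <- add_atom(m, at$element, charge = at$charge, arom = at$arom,
                      hcount = at$hcount, hfixed = TRUE, stereo = at$stereo)
      m <- res$mol
      attach_atom(res$index)
      i <- close + 1L
    } else {
      # organic subset / aromatic / wildcard atom
      sym <- NULL
      if (i < n && paste0(ch, chars[i + 1L]) %in% .TWO_LETTER_ORGANIC) {
        sym <- paste0(ch, chars[i + 1L]); i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I", "*")) {
        sym <- ch; i <- i + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        sym <- ch; i <- i + 1L
      } else {
        stop(sprintf("parse error: unexpected character '%s' at position %d", ch, i))
      }
      arom <- sym %in% c("b", "c", "n", "o", "p", "s")
      elem <- if (arom) toupper(sym) else sym
      res <- add_atom(m, elem, charge = 0L, arom = arom,
                      hcount = 0L, hfixed = FALSE, stereo = "")
      m <- res$mol
      attach_atom(res$index)
    }
  }
  if (length(stack)) stop("parse error: unmatched '('")
  if (length(ring_open)) stop("parse error: unclosed ring bond(s)")
  if (n_atoms(m) == 0L) stop("parse error: no atoms")
  if (sanitize) m <- sanitize_molecule(m) else m$sanitized <- FALSE
  m
}

# Bracket-atom body, e.g. "nH", "N+", "O-", "C@H", "13CH3", "Se", "Fe+2".
.parse_bracket_atom <- function(body) {
  rx <- "^([0-9]*)([A-Za-z][a-z]?|\\*)(@{1,2})?(H[0-9]*)?([+-][0-9]*|[+]+|[-]+)?$"
  mt <- regmatches(body, regexec(rx, body))[[1L]]
  if (length(mt) == 0L) stop(sprintf("parse error: bad bracket atom [%s]", body))
  sym <- mt[3L]
  arom <- FALSE
  if (sym == tolower(sym) && sym != "*") {
    arom <- TRUE
    sym <- paste0(toupper(substr(sym, 1L, 1L)), substr(sym, 2L, nchar(sym)))
  }
  if (sym != "*" && !(sym %in% names(.ATOMIC_WEIGHTS)) && sym != "H") {
    stop(sprintf("parse error: unknown element '%s'", sym))
  }
  stereo <- if (is.na(mt[4L]) || !nzchar(mt[4L])) "" else mt[4L]
  hpart <- mt[5L]
  hcount <- 0L
  if (!is.na(hpart) && nzchar(hpart)) {
    hcount <- if (hpart == "H") 1L else as.integer(substring(hpart, 2L))
  }
  cpart <- mt[6L]
  charge <- 0L
  if (!is.na(cpart) && nzchar(cpart)) {
    if (cpart %in% c("+", "-")) {
      charge <- if (cpart == "+") 1L else -1L
    } else if (grepl("^[+]+$", cpart)) {
      charge <- nchar(cpart)
    } else if (grepl("^[-]+$", cpart)) {
      charge <- -nchar(cpart)
    } else {
      charge <- as.integer(cpart)
    }
  }
  list(element = sym, arom = arom, hcount = hcount,
       charge = as.integer(charge), stereo = stereo)
}
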