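# Molecule-table input/output.
#
# A molecule table couples parsed molecules with stable ids and a
# provenance (dataset) label. Reading never aborts on a bad record: each
# input row ends up either in the table or in the parse report's failure
# list, so counts always reconcile (n_parsed + failures = n_input).

new_molecule_table <- function(ids = character(), molecules = list(),
                               provenance = character()) {
  stopifnot(length(ids) == length(molecules))
  if (anyDuplicated(ids)) stop("ids must be unique within a molecule table")
  structure(list(ids = ids, molecules = molecules,
                 provenance = provenance),
            class = "molecule_table")
}

#' @export
print.molecule_table <- function(x, ...) {
  cat(sprintf("<molecule_table: %d records, dataset '%s'>\n",
              length(x$ids), if (length(x$provenance)) x$provenance[1L] else ""))
  invisible(x)
}

#' @export
length.molecule_table <- function(x) length(x$ids)

.auto_ids <- function(n, offset = 0L) sprintf("R%06d", offset + seq_len(n))

# Parse a character vector of SMILES into a table + report.
.parse_records <- function(smiles, ids, dataset) {
  n <- length(smiles)
  mols <- vector("list", n)
  ok <- logical(n)
  reasons <- character(n)
  for (i in seq_len(n)) {
    res <- tryCatch(parse_smiles(smiles[i]), error = function(e) e)
    if (inherits(res, "error")) {
      msg <- conditionMessage(res)
      reasons[i] <- if (grepl("valence error", msg)) "valence_error" else "unparsable"
    } else {
      mols[[i]] <- res
      ok[i] <- TRUE
    }
  }
  failures <- data.frame(index = which(!ok),
                         id = ids[!ok],
                         reason = reasons[!ok],
                         stringsAsFactors = FALSE)
  table <- new_molecule_table(ids = ids[ok], molecules = mols[ok],
                              provenance = rep(dataset, sum(ok)))
  report <- structure(list(n_input = n, n_parsed = sum(ok),
                           failures = failures),
                      class = "parse_report")
  list(table = table, report = report)
}

#' @export
print.parse_report <- function(x, ...) {
  cat(sprintf("<parse_report: %d input, %d parsed, %d failed>\n",
              x$n_input, x$n_parsed, nrow(x$failures)))
  invisible(x)
}

#' Read a table of molecules from disk
#'
#' Supported formats: `smi` (one SMILES plus optional whitespace-separated
#' id per line), `csv` (configurable SMILES/id column names, matching the
#' published `Smiles`/`ID` schema by default) and `sdf` (V2000, read-only,
#' converted via OpenBabel). Records that fail to parse are collected in
#' the report rather than aborting the read; missing ids are auto-assigned
#' `R000001`, `R000002`, ... in input order.
#'
#' @param path Input file.
#' @param format One of `"smi"`, `"csv"`, `"sdf"`; default guessed from the
#'   file extension.
#' @param dataset Provenance label stored with every record.
#' @param smiles_col,id_col Column names used for `csv` input.
#' @return A list with elements `table` (a `molecule_table`) and `report`
#'   (a `parse_report`).
#' @export
read_molecule_table <- function(path, format = c("auto", "smi", "csv", "sdf"),
                                dataset = "unknown",
                                smiles_col = "Smiles", id_col = "ID") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, smi = "smi", csv = "csv", sdf = "sdf",
                     stop("cannot guess format from extension: ", ext))
  }
  if (format == "smi") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) return(.parse_records(character(), character(), dataset))
    parts <- strsplit(trimws(lines), "[ \t]+")
    smiles <- vapply(parts, `[[`, character(1L), 1L)
    ids <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else NA_character_,
                  character(1L))
    miss <- is.na(ids)
    ids[miss] <- .auto_ids(length(ids))[miss]
  } else if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (nrow(df) == 0L) return(.parse_records(character(), character(), dataset))
    if (!(smiles_col %in% names(df))) {
      stop(sprintf("SMILES column '%s' not found in %s", smiles_col, path))
    }
    smiles <- as.character(df[[smiles_col]])
    ids <- if (id_col %in% names(df)) as.character(df[[id_col]])
           else .auto_ids(length(smiles))
  } else {
    smi_lines <- .sdf_to_smiles(path)
    if (length(smi_lines) == 0L) return(.parse_records(character(), character(), dataset))
    parts <- strsplit(trimws(smi_lines), "[ \t]+")
    smiles <- vapply(parts, `[[`, character(1L), 1L)
    ids <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else NA_character_,
                  character(1L))
    miss <- is.na(ids)
    ids[miss] <- .auto_ids(length(ids))[miss]
  }
  if (anyDuplicated(ids)) {
    dup <- duplicated(ids)
    ids[dup] <- paste0(ids[dup], "_dup", cumsum(dup)[dup])
  }
  .parse_records(smiles, ids, dataset)
}

# SDF -> SMILES via the OpenBabel command line tool.
.sdf_to_smiles <- function(path) {
  ob <- Sys.which("obabel")
  if (!nzchar(ob)) stop("SDF input requires the 'obabel' command line tool")
  out <- suppressWarnings(
    system2(ob, c("-isdf", shQuote(path), "-osmi"), stdout = TRUE, stderr = FALSE)
  )
  out[nzchar(trimws(out))]
}

#' Write a molecule table as a .smi file
#'
#' One `SMILES id` pair per line, canonical SMILES.
#'
#' @param table A `molecule_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_smi <- function(table, path) {
  smiles <- vapply(table$molecules, to_canonical_smiles, character(1L))
  writeLines(paste(smiles, table$ids), path)
  invisible(path)
}
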