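# Fragment-library assembly, ranking and cross-library overlap.
#
# A fragment's Count is the number of distinct source compounds whose
# terminal-fragment set contains it (set semantics: a fragment occurring
# twice in one parent counts once); Proportion is Count divided by the
# dataset's processed-compound count.

#' Build a fragment library
#'
#' @param curated A `curation_result` (defines the processed-compound
#'   denominator and the valid ids).
#' @param fragments_per_compound Named list: compound id -> character
#'   vector of canonical fragment SMILES (a set; duplicates are collapsed).
#' @param dataset_name Library label; defaults to the curated table's
#'   provenance.
#' @return A `fragment_library`: `dataset_name`, `n_source_compounds`,
#'   `records` data.frame (fragment_smiles, count, proportion, descriptor
#'   columns) sorted by count descending then fragment SMILES.
#' @export
build_library <- function(curated, fragments_per_compound,
                          dataset_name = NULL) {
  ids <- names(fragments_per_compound)
  unknown <- setdiff(ids, curated$kept$ids)
  if (length(unknown)) {
    stop("unknown compound id(s): ", paste(utils::head(unknown, 5L), collapse = ", "))
  }
  if (is.null(dataset_name)) {
    dataset_name <- if (length(curated$kept$provenance)) curated$kept$provenance[1L]
                    else "unknown"
  }
  n_src <- length(curated$kept$ids)
  frag_sets <- lapply(fragments_per_compound, unique)
  all_frags <- unlist(frag_sets, use.names = FALSE)
  if (length(all_frags) == 0L) {
    records <- data.frame(fragment_smiles = character(), count = integer(),
                          proportion = numeric(), stringsAsFactors = FALSE)
    return(structure(list(dataset_name = dataset_name,
                          n_source_compounds = n_src, records = records),
                     class = "fragment_library"))
  }
  tab <- table(all_frags)
  smiles <- names(tab)
  count <- as.integer(tab)
  ord <- order(-count, smiles)
  smiles <- smiles[ord]; count <- count[ord]
  desc <- descriptor_table(lapply(smiles, parse_smiles))
  records <- cbind(
    data.frame(fragment_smiles = smiles, count = count,
               proportion = count / n_src, stringsAsFactors = FALSE),
    desc
  )
  rownames(records) <- NULL
  structure(list(dataset_name = dataset_name, n_source_compounds = n_src,
                 records = records),
            class = "fragment_library")
}

#' @export
print.fragment_library <- function(x, ...) {
  cat(sprintf("<fragment_library '%s': %d fragments from %d compounds>\n",
              x$dataset_name, nrow(x$records), x$n_source_compounds))
  invisible(x)
}

#' Most frequent fragments unique to one library
#'
#' Ranks the fragments of `lib` that occur in none of the other libraries
#' by count (descending), ties broken by canonical SMILES, and returns the
#' first `n` records.
#'
#' @param lib A `fragment_library`.
#' @param others List of `fragment_library` objects defining the exclusion
#'   set (empty list: plain top-n).
#' @param n How many records to return (fewer if not enough unique ones).
#' @return data.frame of the selected records.
#' @export
top_unique_frequent <- function(lib, others = list(), n = 10L) {
  stopifnot(n >= 1L)
  excl <- unique(unlist(lapply(others, function(o) o$records$fragment_smiles)))
  rec <- lib$records
  rec <- rec[!(rec$fragment_smiles %in% excl), , drop = FALSE]
  rec <- rec[order(-rec$count, rec$fragment_smiles), , drop = FALSE]
  rownames(rec) <- NULL
  utils::head(rec, n)
}

#' Overlap report over named key sets
#'
#' Exact set arithmetic on canonical keys (curated compound SMILES or
#' wildcard fragment SMILES). Reports per-set sizes, per-set unique counts
#' (members found in no other set), the pairwise intersection matrix and
#' the all-way intersection, always together with the denominators.
#'
#' @param sets Named list (>= 2) of character vectors.
#' @return An `overlap_report`: `set_names`, `sizes`, `unique_counts`,
#'   `pairwise` (matrix), `allway_count`, `allway_members`.
#' @export
overlap_report <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  nm <- names(sets)
  k <- length(sets)
  pairwise <- matrix(0L, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      pairwise[i, j] <- length(intersect(sets[[i]], sets[[j]]))
    }
  }
  unique_counts <- vapply(seq_len(k), function(i) {
    others <- unique(unlist(sets[-i]))
    sum(!(sets[[i]] %in% others))
  }, integer(1L))
  names(unique_counts) <- nm
  allway <- Reduce(intersect, sets)
  structure(list(set_names = nm,
                 sizes = vapply(sets, length, integer(1L)),
                 unique_counts = unique_counts,
                 pairwise = pairwise,
                 allway_count = length(allway),
                 allway_members = sort(allway)),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("<overlap_report>\n sizes:\n")
  print(x$sizes)
  cat(" unique to each set:\n")
  print(x$unique_counts)
  cat(" pairwise intersections:\n")
  print(x$pairwise)
  cat(sprintf(" shared by all %d sets: %d\n", length(x$set_names), x$allway_count))
  invisible(x)
}

#' Write an overlap report as JSON
#'
#' @param report An `overlap_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_overlap_json <- function(report, path) {
  payload <- list(
    set_names = report$set_names,
    sizes = as.list(report$sizes),
    unique_counts = as.list(report$unique_counts),
    pairwise = report$pairwise,
    allway_count = report$allway_count,
    allway_members = report$allway_members
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.LIBRARY_COLUMNS <- c("Fragments", "Dataset", "Count", "Proportion", "AMW",
                      "NumC", "NumO", "NumN", "NumHeavy",
                      "NumAliphaticRings", "NumAromaticRings",
                      "NumHeterocycles", "NumBridgeheads",
                      "FracSp3", "FracChiralC")

#' Write a fragment library as CSV
#'
#' Column order: Fragments, Dataset, Count, Proportion, AMW, then the
#' descriptor columns of the published schema. The round trip through
#' [read_library()] is lossless.
#'
#' @param lib A `fragment_library`.
#' @param path Output CSV path.
#' @return The data.frame written, invisibly.
#' @export
write_library <- function(lib, path) {
  r <- lib$records
  df <- data.frame(
    Fragments = r$fragment_smiles,
    Dataset = rep(lib$dataset_name, nrow(r)),
    Count = r$count,
    Proportion = r$proportion,
    AMW = if (nrow(r)) r$amw else numeric(),
    NumC = if (nrow(r)) r$n_carbon else numeric(),
    NumO = if (nrow(r)) r$n_oxygen else numeric(),
    NumN = if (nrow(r)) r$n_nitrogen else numeric(),
    NumHeavy = if (nrow(r)) r$n_heavy else numeric(),
    NumAliphaticRings = if (nrow(r)) r$n_aliphatic_rings else numeric(),
    NumAromaticRings = if (nrow(r)) r$n_aromatic_rings else numeric(),
    NumHeterocycles = if (nrow(r)) r$n_heterocycles else numeric(),
    NumBridgeheads = if (nrow(r)) r$n_bridgehead else numeric(),
    FracSp3 = if (nrow(r)) r$frac_sp3 else numeric(),
    FracChiralC = if (nrow(r)) r$frac_chiral_c else numeric(),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Read a fragment library CSV
#'
#' Validates the column layout and the stored proportions (recomputed from
#' Count and the inferred source-compound total must agree to 1e-9).
#'
#' @param path CSV written by [write_library()].
#' @param n_source_compounds Source-compound denominator; inferred from
#'   the first record when omitted.
#' @return A `fragment_library`.
#' @export
read_library <- function(path, n_source_compounds = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(.LIBRARY_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("malformed library CSV, missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    return(structure(list(dataset_name = "unknown",
                          n_source_compounds = if (is.null(n_source_compounds)) 0L
                                               else n_source_compounds,
                          records = data.frame(fragment_smiles = character(),
                                               count = integer(),
                                               proportion = numeric(),
                                               stringsAsFactors = FALSE)),
                     class = "fragment_library"))
  }
  if (is.null(n_source_compounds)) {
    n_source_compounds <- round(df$Count[1L] / df$Proportion[1L])
  }
  bad <- which(abs(df$Count / n_source_compounds - df$Proportion) > 1e-9)
  if (length(bad)) {
    stop(sprintf("library CSV row %d: stored proportion %.12f != %d/%d",
                 bad[1L], df$Proportion[bad[1L]], df$Count[bad[1L]],
                 n_source_compounds))
  }
  records <- data.frame(
    fragment_smiles = df$Fragments, count = as.integer(df$Count),
    proportion = df$Proportion,
    n_carbon = df$NumC, n_oxygen = df$NumO, n_nitrogen = df$NumN,
    n_heavy = df$NumHeavy, n_aliphatic_rings = df$NumAliphaticRings,
    n_aromatic_rings = df$NumAromaticRings, n_heterocycles = df$NumHeterocycles,
    n_bridgehead = df$NumBridgeheads, frac_sp3 = df$FracSp3,
    frac_chiral_c = df$FracChiralC, amw = df$AMW,
    stringsAsFactors = FALSE
  )
  structure(list(dataset_name = df$Dataset[1L],
                 n_source_compounds = as.integer(n_source_compounds),
                 records = records),
            class = "fragment_library")
}
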