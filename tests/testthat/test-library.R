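# Fragment-library assembly, ranking, overlap and CSV round trips.

make_curated <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("M%03d", seq_along(smiles))
  tbl <- fraglib:::new_molecule_table(ids, lapply(smiles, parse_smiles),
                                      rep("toy", length(ids)))
  curate_dataset(tbl)
}

test_that("counts use distinct-parent set semantics and exact proportions", {
  cu <- make_curated(c("CC(=O)Nc1ccccc1", "CC(=O)Nc1ccc(C)cc1",
                       "CC(=O)Nc1ccc(NC(C)=O)cc1", "c1ccccc1"))
  frags <- lapply(cu$kept$molecules, function(m) terminal_fragments(m)$leaf_smiles)
  names(frags) <- cu$kept$ids
  lib <- build_library(cu, frags)
  expect_equal(lib$n_source_compounds, 4L)
  rec <- lib$records
  # acetyl appears in three parents (twice in one of them -> still 3)
  expect_equal(rec$count[rec$fragment_smiles == "*C(C)=O"], 3L)
  expect_equal(rec$proportion, rec$count / 4)
  # sum of counts equals sum of per-compound distinct fragments
  expect_equal(sum(rec$count), sum(lengths(lapply(frags, unique))))
  # sorted by count desc then smiles
  expect_false(is.unsorted(-rec$count))
  expect_error(build_library(cu, list(NOPE = "*C")), "unknown compound id")
})

test_that("library build is independent of input compound order", {
  smiles <- c("CC(=O)Nc1ccccc1", "CC(=O)OCC(C)C", "CCS(=O)(=O)Nc1ccccc1")
  cu1 <- make_curated(smiles)
  cu2 <- make_curated(rev(smiles), ids = sprintf("M%03d", 3:1))
  fr <- function(cu) {
    f <- lapply(cu$kept$molecules, function(m) terminal_fragments(m)$leaf_smiles)
    names(f) <- cu$kept$ids
    f
  }
  l1 <- build_library(cu1, fr(cu1))
  l2 <- build_library(cu2, fr(cu2))
  expect_identical(l1$records$fragment_smiles, l2$records$fragment_smiles)
  expect_identical(l1$records$count, l2$records$count)
})

test_that("top_unique_frequent ranks exclusively-owned fragments", {
  cu <- make_curated(c("CC(=O)Nc1ccccc1", "CC(=O)NC1CCCCC1", "CCOC(=O)CC"))
  frags <- lapply(cu$kept$molecules, function(m) terminal_fragments(m)$leaf_smiles)
  names(frags) <- cu$kept$ids
  lib <- build_library(cu, frags)
  other_cu <- make_curated("CC(=O)Nc1ccc(C)cc1")
  other_fr <- lapply(other_cu$kept$molecules,
                     function(m) terminal_fragments(m)$leaf_smiles)
  names(other_fr) <- other_cu$kept$ids
  other <- build_library(other_cu, other_fr)

  top <- top_unique_frequent(lib, list(other), n = 10)
  expect_false("*C(C)=O" %in% top$fragment_smiles)   # shared with other
  expect_true("*Nc1ccccc1" %in% top$fragment_smiles)
  # no exclusions: plain top-n by count with smiles tie-break
  plain <- top_unique_frequent(lib, list(), n = 2)
  expect_equal(nrow(plain), 2L)
  expect_equal(plain$count, sort(plain$count, decreasing = TRUE))
  ties <- plain$fragment_smiles[plain$count == max(plain$count)]
  expect_identical(ties, sort(ties))
})

test_that("overlap_report does exact set arithmetic with denominators", {
  rep1 <- overlap_report(list(A = c("a", "b", "c"), B = c("b", "c", "d")))
  expect_equal(rep1$pairwise["A", "B"], 2L)
  expect_equal(rep1$pairwise["A", "B"], rep1$pairwise["B", "A"])
  expect_equal(unname(rep1$unique_counts), c(1L, 1L))
  expect_equal(unname(rep1$sizes), c(3L, 3L))

  five <- rep(list(c("x", "y")), 5)
  names(five) <- paste0("S", 1:5)
  rep2 <- overlap_report(five)
  expect_equal(rep2$allway_count, 2L)

  sets <- list(P = c("X", "p1"), Q = c("X", "q1"), R = c("X", "r1"),
               S = c("X", "s1"), T = c("X", "t1"))
  rep3 <- overlap_report(sets)
  expect_equal(rep3$allway_count, 1L)
  expect_equal(rep3$allway_members, "X")
  # unique + shared-with-others = set size
  for (nm in names(sets)) {
    shared <- sum(sets[[nm]] %in% unlist(sets[names(sets) != nm]))
    expect_equal(rep3$unique_counts[[nm]] + shared, rep3$sizes[[nm]])
  }
  expect_error(overlap_report(list(A = "a")), "length")
})

test_that("library CSV round trip is lossless and validated", {
  cu <- make_curated(c("CC(=O)Nc1ccccc1", "CC(=O)OCC(C)C"))
  frags <- lapply(cu$kept$molecules, function(m) terminal_fragments(m)$leaf_smiles)
  names(frags) <- cu$kept$ids
  lib <- build_library(cu, frags)
  path <- tempfile(fileext = ".csv")
  df <- write_library(lib, path)
  expect_identical(names(df), fraglib:::.LIBRARY_COLUMNS)

  lib2 <- read_library(path)
  expect_equal(lib2$n_source_compounds, lib$n_source_compounds)
  expect_identical(lib2$records$fragment_smiles, lib$records$fragment_smiles)
  expect_identical(lib2$records$count, lib$records$count)
  expect_equal(lib2$records$amw, lib$records$amw, tolerance = 1e-6)

  # stored proportion inconsistent with count -> validation error names the row
  bad <- utils::read.csv(path)
  bad$Proportion[1] <- bad$Proportion[1] + 1e-3
  badpath <- tempfile(fileext = ".csv")
  utils::write.csv(bad, badpath, row.names = FALSE)
  expect_error(read_library(badpath, n_source_compounds = lib$n_source_compounds),
               "row 1")

  # empty library: header-only CSV, read back as empty
  empty <- build_library(make_curated("c1ccccc1"), list())
  p2 <- tempfile(fileext = ".csv")
  write_library(empty, p2)
  back <- read_library(p2)
  expect_equal(nrow(back$records), 0L)
})
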