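# Molecule model: parsing, canonicalization, molecular weight, table I/O.

test_that("parse_smiles builds sanitized molecules and rejects bad input", {
  m <- parse_smiles("CCO")
  expect_equal(n_atoms(m), 3L)
  expect_equal(length(m$sssr), 0L)

  benz <- parse_smiles("c1ccccc1")
  expect_equal(n_atoms(benz), 6L)
  expect_true(all(benz$arom))
  expect_equal(length(benz$sssr), 1L)

  expect_error(parse_smiles("C(C)(C)(C)(C)C"), "valence error")
  expect_error(parse_smiles("notsmiles!"), "parse error")
  expect_error(parse_smiles(""), "parse error")
  expect_error(parse_smiles("C1CC"), "unclosed ring")
})

test_that("stereo annotations are parsed, retained, and only stripped on demand", {
  m <- parse_smiles("C[C@H](N)C(=O)O")
  expect_true(has_stereochemistry(m))
  mb <- parse_smiles("C/C=C/C")
  expect_true(has_stereochemistry(mb))
  expect_false(has_stereochemistry(strip_stereochemistry(m)))
  expect_equal(to_canonical_smiles(strip_stereochemistry(m)),
               to_canonical_smiles(parse_smiles("CC(N)C(=O)O")))
})

test_that("canonical SMILES is input-order invariant and a fixed point", {
  pairs <- list(c("OCC", "CCO"),
                c("c1ccccc1", "C1=CC=CC=C1"),
                c("CC(=O)Nc1ccccc1", "O=C(C)Nc1ccccc1"),
                c("C1CC2CCC1C2", "C2CC1CCC2C1"))
  for (p in pairs) {
    expect_identical(to_canonical_smiles(parse_smiles(p[1])),
                     to_canonical_smiles(parse_smiles(p[2])), info = p[1])
  }
  set.seed(31)
  fx <- generate_fixture(fixture_spec(n_molecules = 40, seed = 31), BLOCKS)
  for (s in fx$ground_truth$curated_smiles[fx$ground_truth$outcome == "keep"]) {
    m <- parse_smiles(s)
    can <- to_canonical_smiles(m)
    expect_identical(to_canonical_smiles(parse_smiles(can)), can, info = s)
    perm <- sample(n_atoms(m))
    expect_identical(to_canonical_smiles(fraglib:::permute_molecule(m, perm)),
                     can, info = paste("permuted", s))
  }
})

test_that("canonical equivalence agrees with an independent toolkit oracle", {
  skip_if_not_installed("ChemmineOB")
  ob_can <- function(s) trimws(strsplit(ChemmineOB::convertFormat("SMI", "CAN", s),
                                        "[\t\n]")[[1]][1])
  cases <- list(c("OCC", "CCO"), c("CN(=O)=O", "CN(=O)=O"),
                c("c1ccc2[nH]ccc2c1", "C1=CC2=C(C=C1)C=CN2"))
  for (p in cases) {
    mine <- identical(to_canonical_smiles(parse_smiles(p[1])),
                      to_canonical_smiles(parse_smiles(p[2])))
    oracle <- identical(ob_can(p[1]), ob_can(p[2]))
    expect_identical(mine, oracle, info = paste(p, collapse = " vs "))
  }
})

test_that("average molecular weight matches periodic-table sums and conventions", {
  expect_equal(average_molecular_weight(parse_smiles("O")), 18.015, tolerance = 0.01)
  expect_equal(average_molecular_weight(parse_smiles("c1ccccc1")), 78.11,
               tolerance = 0.01)
  # wildcard stubs are massless
  expect_equal(average_molecular_weight(parse_smiles("*C(C)=O")),
               average_molecular_weight(parse_smiles("CC=O")) - 1.008,
               tolerance = 1e-9)
  # additive over disconnected components
  salt <- parse_smiles("CC(=O)O.CC(=O)O")
  expect_equal(average_molecular_weight(salt),
               2 * average_molecular_weight(parse_smiles("CC(=O)O")),
               tolerance = 1e-9)
})

test_that("read_molecule_table reconciles parsed plus failures with input", {
  smi <- tempfile(fileext = ".smi")
  writeLines(c("CCO mol1", "c1ccccc1 mol2", "CC(C)(C)(C)(C)C mol3",
               "garbage$$ mol4"), smi)
  res <- read_molecule_table(smi, dataset = "toy")
  expect_equal(res$report$n_input, 4L)
  expect_equal(res$report$n_parsed, 2L)
  expect_equal(res$report$n_parsed + nrow(res$report$failures),
               res$report$n_input)
  expect_setequal(res$report$failures$reason, c("valence_error", "unparsable"))

  # auto ids for csv without id column
  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(Smiles = c("CCO", "CCN", "CCC")), csv, row.names = FALSE)
  res2 <- read_molecule_table(csv, dataset = "toy")
  expect_equal(res2$table$ids, c("R000001", "R000002", "R000003"))
  expect_error(read_molecule_table(csv, smiles_col = "smiles_missing"),
               "not found")

  # empty file is an empty table, not an error
  empty <- tempfile(fileext = ".smi")
  writeLines(character(), empty)
  res3 <- read_molecule_table(empty, dataset = "toy")
  expect_equal(res3$report$n_input, 0L)
  expect_equal(length(res3$table$ids), 0L)
})

test_that("sdf input is read through the conversion path", {
  smi_in <- c("CCO", "c1ccccc1")
  sdf <- tempfile(fileext = ".sdf")
  system2(Sys.which("obabel"),
          c(paste0("-:", shQuote(smi_in[1])), paste0("-:", shQuote(smi_in[2])),
            "-osdf", "-O", shQuote(sdf)),
          stdout = FALSE, stderr = FALSE)
  res <- read_molecule_table(sdf, format = "sdf", dataset = "toy")
  expect_equal(res$report$n_parsed, 2L)
  expect_setequal(vapply(res$table$molecules, to_canonical_smiles, character(1)),
                  vapply(smi_in, function(s) to_canonical_smiles(parse_smiles(s)),
                         character(1), USE.NAMES = FALSE))
})
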