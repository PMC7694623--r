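# Standardization pipeline: per-step behavior and whole-pipeline
# bookkeeping.

cs <- function(x) to_canonical_smiles(if (is_molecule(x)) x else parse_smiles(x))

test_that("normalization fixes functional-group representations idempotently", {
  expect_identical(cs(normalize_structure(parse_smiles("CN(=O)=O"))),
                   cs("C[N+](=O)[O-]"))
  expect_identical(cs(normalize_structure(parse_smiles("C[N+](=O)[O-]"))),
                   cs("C[N+](=O)[O-]"))
  expect_identical(cs(normalize_structure(parse_smiles("CN=N=N"))),
                   cs("CN=[N+]=[N-]"))
  expect_identical(cs(normalize_structure(parse_smiles("c1ccccc1"))),
                   cs("c1ccccc1"))
  m <- normalize_structure(parse_smiles("CN(=O)=O"))
  expect_identical(cs(normalize_structure(m)), cs(m))
})

test_that("largest-component selection keeps the parent, deterministically", {
  expect_identical(cs(select_largest_component(parse_smiles("CC(=O)[O-].[Na+]"))),
                   cs("CC(=O)[O-]"))
  expect_identical(cs(select_largest_component(parse_smiles("CCO"))), cs("CCO"))
  expect_identical(cs(select_largest_component(parse_smiles("C.C"))), "C")
})

test_that("neutralize/reionize zeroes removable charges and spares permanent ones", {
  expect_identical(cs(neutralize_and_reionize(parse_smiles("CC(=O)[O-]"))),
                   cs("CC(=O)O"))
  expect_identical(cs(neutralize_and_reionize(parse_smiles("C[N+](C)(C)C"))),
                   cs("C[N+](C)(C)C"))
  expect_identical(cs(neutralize_and_reionize(parse_smiles("CC(=O)O"))),
                   cs("CC(=O)O"))
  # zwitterion: both sites neutralized
  expect_identical(cs(neutralize_and_reionize(parse_smiles("C[NH2+]CC(=O)[O-]"))),
                   cs("CNCC(=O)O"))
  # nitro normal form survives uncharging
  m <- neutralize_and_reionize(normalize_structure(parse_smiles("CN(=O)=O")))
  expect_identical(cs(m), cs("C[N+](=O)[O-]"))
  # permanent cation plus acid: strongest acid carries the compensating charge
  bet <- neutralize_and_reionize(parse_smiles("C[N+](C)(C)CC(=O)O"))
  expect_identical(cs(bet), cs("C[N+](C)(C)CC(=O)[O-]"))
})

test_that("canonical tautomer converges and prefers carbonyl/aromatic forms", {
  expect_identical(cs(canonical_tautomer(parse_smiles("C=C(O)C"))), cs("CC(C)=O"))
  expect_identical(cs(canonical_tautomer(parse_smiles("c1ccccc1"))), cs("c1ccccc1"))
  a <- cs(canonical_tautomer(parse_smiles("O=C1C=CC=CN1")))
  b <- cs(canonical_tautomer(parse_smiles("Oc1ccccn1")))
  expect_identical(a, b)
  # amide is preferred over its imidol form
  expect_identical(cs(canonical_tautomer(parse_smiles("CC(=O)NC"))),
                   cs("CC(=O)NC"))
})

test_that("element filter applies the allowed-element list", {
  f <- element_filter(parse_smiles("CC[Fe]CC"))
  expect_false(f$pass); expect_equal(f$offending, "Fe")
  expect_true(element_filter(parse_smiles("CC[Se]CC"))$pass)
  expect_true(element_filter(parse_smiles("CC[Si](C)(C)C"))$pass)
  expect_true(element_filter(parse_smiles("*CC"))$pass)  # wildcards exempt
})

test_that("curate_dataset reconciles counts and applies boundaries", {
  tbl <- fraglib:::new_molecule_table(
    c("a", "b", "c", "d"),
    list(parse_smiles("c1ccccc1"), parse_smiles("C1=CC=CC=C1"),
         parse_smiles("CC(=O)[O-].[Na+]"), parse_smiles("CC[Fe]CC")),
    rep("toy", 4))
  res <- curate_dataset(tbl)
  expect_equal(length(res$kept$ids) + nrow(res$rejections) +
                 length(res$duplicate_map), 4L)
  expect_equal(length(res$kept$ids), 2L)         # benzene + acetic acid
  expect_equal(unname(res$duplicate_map["b"]), "a")
  expect_equal(res$rejections$step, "element_filter")
  expect_true(cs("CC(=O)O") %in% res$smiles)

  # AMW boundary: exactly at the ceiling passes, above does not
  hexane <- parse_smiles("CCCCCC")   # 86.178
  cfg_at <- curation_config(amw_max = average_molecular_weight(hexane))
  cfg_below <- curation_config(amw_max = average_molecular_weight(hexane) - 0.01)
  tb <- fraglib:::new_molecule_table("h", list(hexane), "toy")
  expect_equal(length(curate_dataset(tb, cfg_at)$kept$ids), 1L)
  rej <- curate_dataset(tb, cfg_below)
  expect_equal(nrow(rej$rejections), 1L)
  expect_equal(rej$rejections$step, "amw_filter")
})

test_that("step order matters: salts survive only if desalting precedes the element filter", {
  tbl <- fraglib:::new_molecule_table("s", list(parse_smiles("CC(=O)[O-].[Na+]")),
                                      "toy")
  default_res <- curate_dataset(tbl)
  expect_equal(length(default_res$kept$ids), 1L)
  cfg <- curation_config(steps = c("normalize", "element_filter",
                                   "largest_component", "neutralize",
                                   "tautomer", "strip_stereo", "amw_filter",
                                   "dedupe"))
  swapped <- curate_dataset(tbl, cfg)
  expect_equal(nrow(swapped$rejections), 1L)
  expect_match(swapped$rejections$reason, "Na")
})

test_that("curation is idempotent on its own output", {
  fx <- generate_fixture(fixture_spec(
    n_molecules = 60, seed = 77,
    decoration = c(salt = .25, charge = .15, stereo = .2, element = .1,
                   duplicate = .1)), BLOCKS)
  pr <- fraglib:::.parse_records(fx$smiles, fx$ids, "syn")
  cu <- curate_dataset(pr$table)
  cu2 <- curate_dataset(cu$kept)
  expect_equal(length(cu2$kept$ids), length(cu$kept$ids))
  expect_equal(nrow(cu2$rejections), 0L)
  expect_equal(length(cu2$duplicate_map), 0L)
  expect_identical(sort(cu2$smiles), sort(cu$smiles))
})
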