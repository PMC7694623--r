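# Synthetic-data generator: block inertness, assembly oracles, fixture
# reproducibility and decoration ground truth.

test_that("every default building block is fragmentation-inert, with full handle coverage", {
  blocks <- default_building_blocks(verify = TRUE)   # verification IS the test
  expect_gte(length(blocks), 20L)
  handles <- unique(unlist(lapply(blocks, function(b) {
    vapply(b$attach, `[[`, character(1L), "handle")
  })))
  expect_true(all(c("acyl", "amine_H", "hydroxyl", "aryl", "alkyl",
                    "sulfonyl") %in% handles))
  nms <- vapply(blocks, `[[`, character(1L), "name")
  expect_true("benzoyl" %in% nms)   # acetophenone-like
  expect_true("furoyl" %in% nms)    # acetylfuran-like
})

test_that("assembly forms the requested linkage with construction-time leaves", {
  acet <- block_by_name(BLOCKS, "acetyl")
  anil <- block_by_name(BLOCKS, "anilino")
  syn <- assemble_molecule(list(acet, anil), "amide")
  expect_identical(syn$smiles, to_canonical_smiles(parse_smiles("CC(=O)Nc1ccccc1")))
  expect_setequal(syn$expected_leaves, c("*C(C)=O", "*Nc1ccccc1"))

  single <- assemble_molecule(list(acet), character())
  expect_length(single$expected_leaves, 0L)

  # 3 blocks, 2 linkages: middle block carries two stubs
  syn3 <- assemble_molecule(list(acet, anil, block_by_name(BLOCKS, "phenyl")),
                            c("amide", "aromatic_C_aromatic_C"))
  expect_length(syn3$expected_leaves, 3L)
  n_stub <- vapply(syn3$expected_leaves, function(s) {
    length(attachment_points(parse_smiles(s)))
  }, integer(1L))
  expect_equal(sort(unname(n_stub)), c(1L, 1L, 2L))
  expect_error(assemble_molecule(list(acet, acet), "amide"), "no free attachment")
})

test_that("expected leaves equal fragmenter output across all 11 chemistries", {
  fx <- generate_fixture(fixture_spec(n_molecules = 80, seed = 19), BLOCKS)
  gt <- fx$ground_truth
  seen <- character()
  for (i in seq_along(fx$ids)) {
    if (gt$outcome[i] != "keep") next
    m <- parse_smiles(gt$curated_smiles[i])
    res <- terminal_fragments(m)
    expect_identical(res$leaf_smiles, fx$expected_leaves[[i]],
                     info = gt$curated_smiles[i])
    seen <- union(seen, strsplit(gt$linkages[i], "+", fixed = TRUE)[[1]])
  }
  expect_gte(length(setdiff(seen, "")), 9L)   # near-complete chemistry coverage
})

test_that("fixture generation is seeded and byte-reproducible", {
  f1 <- generate_fixture(fixture_spec(n_molecules = 25, seed = 4,
                                      decoration = c(salt = .3, charge = .2,
                                                     stereo = .3, element = .1,
                                                     duplicate = .1)), BLOCKS)
  f2 <- generate_fixture(fixture_spec(n_molecules = 25, seed = 4,
                                      decoration = c(salt = .3, charge = .2,
                                                     stereo = .3, element = .1,
                                                     duplicate = .1)), BLOCKS)
  expect_identical(f1$smiles, f2$smiles)
  expect_identical(f1$ground_truth, f2$ground_truth)
  f3 <- generate_fixture(fixture_spec(n_molecules = 25, seed = 5), BLOCKS)
  expect_false(identical(f1$smiles, f3$smiles))
})

test_that("decoration probabilities drive curation ground truth", {
  clean <- generate_fixture(fixture_spec(n_molecules = 30, seed = 2), BLOCKS)
  expect_true(all(clean$ground_truth$outcome %in% c("keep", "duplicate")))

  poisoned <- generate_fixture(fixture_spec(n_molecules = 30, seed = 2,
                                            decoration = c(element = 1)), BLOCKS)
  expect_true(all(poisoned$ground_truth$outcome == "reject_element"))
  pr <- fraglib:::.parse_records(poisoned$smiles, poisoned$ids, "syn")
  cu <- curate_dataset(pr$table)
  expect_equal(length(cu$kept$ids), 0L)
  expect_true(all(cu$rejections$step == "element_filter"))
})

test_that("decorated records still curate to the undecorated canonical form", {
  fx <- generate_fixture(fixture_spec(n_molecules = 40, seed = 6,
                                      decoration = c(salt = 1, stereo = 1)), BLOCKS)
  pr <- fraglib:::.parse_records(fx$smiles, fx$ids, "syn")
  expect_equal(pr$report$n_parsed, 40L)
  expect_true(any(grepl("\\.", fx$smiles)))            # salts present
  expect_true(any(grepl("@", fx$smiles)))              # stereo marks present
  cu <- curate_dataset(pr$table)
  gt <- fx$ground_truth
  for (i in seq_along(fx$ids)) {
    if (gt$outcome[i] != "keep") next
    expect_identical(cu$smiles[match(fx$ids[i], cu$kept$ids)],
                     gt$curated_smiles[i], info = fx$smiles[i])
  }
})
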