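# RECAP rules, bond finding, cleavage mechanics and terminal fragments.

RULE_NAMES <- c("amide", "ester", "amine", "urea", "ether", "olefin",
                "quaternary_nitrogen", "aromatic_N_aliphatic_C",
                "lactam_N_aliphatic_C", "aromatic_C_aromatic_C",
                "sulphonamide")

leaves_of <- function(s, ...) terminal_fragments(parse_smiles(s), ...)$leaf_smiles

test_that("the default rule set has the eleven documented chemistries", {
  rules <- default_rules()
  expect_length(rules, 11L)
  expect_setequal(names(rules), RULE_NAMES)
  expect_identical(names(rules), RULE_NAMES)   # fixed documented order
})

test_that("cleavable-bond search matches rule environments, never ring bonds", {
  expect_equal(nrow(find_cleavable_bonds(parse_smiles("CC"))), 0L)
  df <- find_cleavable_bonds(parse_smiles("CC(=O)Nc1ccccc1"))
  expect_equal(nrow(df), 1L)
  expect_equal(df$rule, "amide")
  # cyclic amides: the ring C(=O)-N bond is off limits
  for (s in c("O=C1CCCCN1", "O=C1CCCN1", "O=C1NCCCC1C")) {
    m <- parse_smiles(s)
    df <- find_cleavable_bonds(m)
    expect_true(all(!m$ring_bond[df$bond]), info = s)
    expect_false("amide" %in% df$rule, info = s)
  }
})

test_that("cleave_bond caps both children and conserves heavy atoms", {
  m <- parse_smiles("CCCC")
  kids <- cleave_bond(m, fraglib:::bond_between(m, 2L, 3L))
  expect_length(kids, 2L)
  expect_setequal(vapply(kids, to_canonical_smiles, character(1)),
                  c("*CC", "*CC"))
  ring <- parse_smiles("C1CCCCC1")
  expect_error(cleave_bond(ring, 1L), "ring bond")

  set.seed(42)
  fx <- generate_fixture(fixture_spec(n_molecules = 40, seed = 42), BLOCKS)
  checked <- 0L
  for (s in fx$ground_truth$curated_smiles[fx$ground_truth$outcome == "keep"]) {
    m <- parse_smiles(s)
    open_bonds <- which(!m$ring_bond)
    if (length(open_bonds) == 0L) next
    b <- open_bonds[sample.int(length(open_bonds), 1L)]
    kids <- cleave_bond(m, b)
    expect_equal(sum(vapply(kids, n_heavy_atoms, numeric(1))),
                 n_heavy_atoms(m), info = s)
    checked <- checked + 1L
  }
  expect_gt(checked, 20L)
})

test_that("terminal fragments match hand-derived leaf sets", {
  expect_length(leaves_of("CC"), 0L)
  expect_setequal(leaves_of("CC(=O)Nc1ccccc1"), c("*C(C)=O", "*Nc1ccccc1"))
  # amide + aryl ester: the acyl-oxygen bond is scissored, so the ester
  # oxygen stays on the aryl core and both acetyl stubs collapse to one
  expect_setequal(leaves_of("CC(=O)Nc1ccc(OC(C)=O)cc1"),
                  c("*C(C)=O", "*Nc1ccc(cc1)O*"))
  expect_length(leaves_of("O=C1CCCCN1"), 0L)
  # excision chemistries drop the central heteroatom unit
  expect_setequal(leaves_of("CCNCC"), "*CC")          # amine N excised
  expect_setequal(leaves_of("CCOCC"), "*CC")          # ether O excised
  expect_setequal(leaves_of("CCNC(=O)NCC"), "*NCC")   # urea C=O excised
  expect_setequal(leaves_of("CCS(=O)(=O)NCC"), c("*NCC", "*S(CC)(=O)=O"))
  expect_setequal(leaves_of("CCn1cccc1"), c("*CC", "*n1cccc1"))
  expect_setequal(leaves_of("O=C1CCCN1CCC"), c("*CCC", "*N1CCCC1=O"))
  expect_setequal(leaves_of("c1ccc(-c2ccccc2)cc1"), "*c1ccccc1")
  expect_setequal(leaves_of("CC=CC"), "*CC")
})

test_that("leaves are closed under re-fragmentation and order-invariant", {
  fx <- generate_fixture(fixture_spec(n_molecules = 30, seed = 9,
                                      blocks_per_molecule = c(2L, 3L)), BLOCKS)
  set.seed(9)
  for (i in seq_along(fx$ids)) {
    if (fx$ground_truth$outcome[i] != "keep") next
    m <- parse_smiles(fx$ground_truth$curated_smiles[i])
    res <- terminal_fragments(m)
    for (leaf in res$leaves) {
      expect_length(terminal_fragments(leaf)$leaf_smiles, 0L)
    }
    # atom-order permutation must not change the leaf set
    perm <- sample(n_atoms(m))
    res_p <- terminal_fragments(fraglib:::permute_molecule(m, perm))
    expect_identical(res_p$leaf_smiles, res$leaf_smiles,
                     info = fx$ground_truth$curated_smiles[i])
  }
})

test_that("a repeated fragment counts once per parent (set semantics)", {
  # two identical amide arms on one core give one acetyl leaf
  res <- terminal_fragments(parse_smiles("CC(=O)Nc1ccc(NC(C)=O)cc1"))
  expect_equal(sum(res$leaf_smiles == "*C(C)=O"), 1L)
})

test_that("min_fragment_heavy_atoms floors the leaf set", {
  all_leaves <- leaves_of("Cn1cccc1")
  expect_true("*C" %in% all_leaves)
  floored <- leaves_of("Cn1cccc1", min_fragment_heavy_atoms = 3L)
  expect_false("*C" %in% floored)
  expect_true("*n1cccc1" %in% floored)
})
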