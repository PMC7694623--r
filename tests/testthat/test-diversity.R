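# Fingerprints and the median pairwise-similarity diversity statistic.

test_that("fingerprints are deterministic and discriminating", {
  b1 <- circular_fingerprint(parse_smiles("c1ccccc1"))
  b2 <- circular_fingerprint(parse_smiles("c1ccccc1"))
  ch <- circular_fingerprint(parse_smiles("C1CCCCC1"))
  expect_identical(b1$bits, b2$bits)
  expect_false(identical(b1$bits, ch$bits))
  expect_gte(length(circular_fingerprint(parse_smiles("C"))$bits), 1L)
  expect_equal(b1$nbits, 1024L)

  k <- keys_fingerprint(list(parse_smiles("c1ccccc1"), parse_smiles("C"),
                             parse_smiles("c1ccccc1")))
  expect_identical(k[[1]]$bits, k[[3]]$bits)
  expect_equal(k[[1]]$nbits, 166L)
  expect_true(162L %in% k[[1]]$bits)      # benzene sets the aromatic key
  expect_lte(length(k[[2]]$bits), 2L)     # methane: nearly empty
})

test_that("tanimoto follows the set formula with the all-zero convention", {
  fa <- fraglib:::new_fingerprint("x", c(1, 2), 8)
  fb <- fraglib:::new_fingerprint("x", c(2, 3), 8)
  fz <- fraglib:::new_fingerprint("x", integer(), 8)
  expect_equal(tanimoto(fa, fa), 1)
  expect_equal(tanimoto(fa, fb), 1 / 3)
  expect_equal(tanimoto(fa, fb), tanimoto(fb, fa))
  expect_equal(tanimoto(fa, fraglib:::new_fingerprint("x", c(5, 6), 8)), 0)
  expect_equal(tanimoto(fz, fz), 1)       # both empty: identical objects
  expect_equal(tanimoto(fa, fz), 0)
  expect_error(tanimoto(fa, fraglib:::new_fingerprint("y", 1, 16)), "mismatch")
})

test_that("median_pairwise equals the full-sort oracle for both kinds", {
  mols <- lapply(c("CCO", "CCN", "c1ccccc1", "c1ccncc1", "CC(=O)O",
                   "CC(=O)Nc1ccccc1", "C1CCCCC1", "CCCC", "c1cc[nH]c1",
                   "CC(C)CO"), parse_smiles)
  circ <- lapply(mols, circular_fingerprint)
  keys <- keys_fingerprint(mols)
  expect_equal(median_pairwise(circ), oracle_median_pairwise(circ))
  expect_equal(median_pairwise(keys), oracle_median_pairwise(keys))

  # n = 50 synthetic fingerprints, even and odd pair counts
  for (n in c(50L, 51L)) {
    fps <- synthetic_fingerprints(n, n_bits = 64, n_clusters = 5,
                                  density = 12, flip = 3, seed = n)
    expect_equal(median_pairwise(fps), oracle_median_pairwise(fps), info = n)
  }
  expect_equal(median_pairwise(list(
    fraglib:::new_fingerprint("x", 1:4, 8),
    fraglib:::new_fingerprint("x", 1:4, 8),
    fraglib:::new_fingerprint("x", 1:4, 8))), 1)
  expect_error(median_pairwise(list(fraglib:::new_fingerprint("x", 1, 8))),
               "at least 2")
})

test_that("median_pairwise is permutation-invariant in population order", {
  fps <- synthetic_fingerprints(40, n_bits = 128, n_clusters = 4,
                                density = 20, flip = 4, seed = 3)
  ref <- median_pairwise(fps)
  set.seed(4)
  expect_equal(median_pairwise(fps[sample(40)]), ref)
})

test_that("sampled_median is exact below the sample size and seeded above it", {
  fps <- synthetic_fingerprints(100, seed = 8)
  r <- sampled_median(fps, diversity_config(sample_size = 10000, seed = 1))
  expect_false(r$sampled)
  expect_equal(r$averaged_median, median_pairwise(fps))

  big <- synthetic_fingerprints(800, n_bits = 128, n_clusters = 10,
                                density = 16, flip = 4, seed = 12)
  cfg <- diversity_config(n_samples = 4, sample_size = 300, seed = 99)
  r1 <- sampled_median(big, cfg)
  r2 <- sampled_median(big, cfg)
  expect_true(r1$sampled)
  expect_length(r1$per_sample_medians, 4L)
  expect_identical(r1$per_sample_medians, r2$per_sample_medians)
  expect_equal(r1$averaged_median, mean(r1$per_sample_medians))
  expect_gte(r1$averaged_median, 0); expect_lte(r1$averaged_median, 1)
})

test_that("one decorated scaffold family is less diverse than unrelated scaffolds", {
  one <- synthetic_fingerprints(120, n_clusters = 1, density = 60, flip = 6,
                                seed = 5)
  many <- synthetic_fingerprints(120, n_clusters = 20, density = 60, flip = 6,
                                 seed = 5)
  m_one <- sampled_median(one)$averaged_median
  m_many <- sampled_median(many)$averaged_median
  expect_gt(m_one, m_many)
})
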