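---
title: "Building and characterizing fragment libraries with fraglib"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and characterizing fragment libraries with fraglib}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fraglib)
```

`fraglib` turns raw compound collections into curated datasets, terminal
fragment libraries and their chemoinformatic characterization. This
vignette explains the models and conventions behind each stage, the
tunable parameters, the synthetic data the package validates itself on,
and the known limitations.

## The molecular model

Molecules are small labelled graphs: atoms carry element, formal charge,
aromaticity, resolved hydrogen count and ring membership; bonds carry
order (1, 2, 3, or aromatic) and ring membership. Attachment points —
the positions where a fragment used to be bonded to the rest of its
parent — are wildcard atoms (element `"*"`, zero mass, no hydrogens).
SMILES input covers the organic subset, bracket atoms with charge and
hydrogen counts, ring closures, branches and dot-separated components.
Tetrahedral (`@`) and double-bond (`/`, `\`) stereo annotations are
parsed and *retained* on the object; they are only removed by
`strip_stereochemistry()`, so the stripping step of the curation pipeline
is observable and testable in isolation.

Three conventions matter downstream:

* **Aromaticity** is perceived per ring (smallest set of smallest rings)
  with a Hückel electron count, iterated to a fixed point so kekulized
  fused systems (indole, naphthalene) are recognized ring by ring. A
  ring atom carrying a double bond that leaves the ring blocks
  aromatization unless the partner is itself aromatic; consequently
  quinones and ring-carbonyl forms such as 2-pyridone are treated as
  non-aromatic. This keeps the valence model simple (no aromatic atoms
  with exocyclic double bonds) at the cost of a stricter aromaticity
  notion than some toolkits use.
* **Canonicalization** ranks atoms by iterative neighborhood refinement
  seeded with an order-independent invariant (element, degree, charge,
  hydrogen count, aromaticity, ring membership and a capped histogram of
  graph distances). Remaining ties are broken one atom at a time and
  refinement re-run; tied classes in chemical graphs are automorphism
  orbits for all practical purposes, and property tests (random atom
  permutations; an OpenBabel cross-check) guard the assumption. Output
  is stereo-free, matching the stereochemistry-free convention of the
  curated datasets. Canonicalization is idempotent: one extra round trip
  never changes the string.
* **Masses** are sums of standard isotope-averaged atomic weights,
  including implicit hydrogens. Wildcards weigh nothing, so a fragment
  weighs the same as the fragment with its stubs deleted. Note the
  corollary: capping a position replaces one hydrogen, so the AMW of a
  capped molecule is ~1.008 g/mol below its uncapped parent — the mass
  is deliberately *not* wildcard-neutral, while all 14 structural
  descriptors are.

## Curation

`curate_dataset()` applies, in order: functional-group normalization
(charge-separated nitro, azide normal form, sulfoxide double-bond form),
largest-component selection (most heavy atoms, ties by mass then by
canonical SMILES), an element whitelist (default H, B, C, N, O, F, Si,
P, S, Cl, Se, Br, I), neutralization and reionization, canonical
tautomer selection, stereochemistry removal, a molecular-weight ceiling
(default 1300 g/mol, *inclusive*: a molecule at exactly 1300 is kept)
and deduplication on the final canonical SMILES (first occurrence kept).
Records that fail to parse, or fail a filter, are logged with the step
and reason, so the ledger always reconciles:
`kept + rejected + duplicates = parsed`.

The element filter deliberately runs *after* largest-component
selection, so a valid parent is never rejected because of its metal
counterion; the step order is configurable, and reversing it is itself
under test. The published text behind this pipeline lists the tool
functions without a total order, so the order here is the package's own
choice, made for that salt-survival property.

The uncharger protonates anions and deprotonates protonated cations,
but preserves anions adjacent to a positive center (nitro, azide
normal forms) and leaves permanent cations (quaternary nitrogen)
untouched; the reionizer then lets the strongest acidic O–H sites
(sulfonic > phosphonic > carboxylic > phenolic) carry any charge that
cannot be removed, so betaine-like zwitterions come out net neutral.

The tautomer canonicalizer enumerates 1,3 proton shifts (a=b–c(H) →
a(H)–b=c) with carbon or nitrogen pivots and at least one N/O/S
terminus, breadth-first, deduplicated on canonical SMILES, bounded by a
configurable cap (default 1000; reaching it returns the best form found
with a warning). Forms are scored 100 × aromatic rings + 4 × C=O +
2 × C=N with a lexicographic canonical-SMILES tie-break, so any input
tautomer within rule coverage maps to the same output: enols collapse
onto ketones, imidols onto amides, and — given the aromaticity model
above — 2-pyridone and 2-hydroxypyridine both canonicalize to the
aromatic hydroxypyridine form. The scoring table is a convention, not a
thermodynamic claim; what matters for library building is convergence.

## Terminal RECAP fragments

Fragmentation follows the 11 retrosynthetic bond chemistries — amide,
ester, amine, urea, ether, olefin, quaternary nitrogen, aromatic
N–aliphatic C, lactam N–aliphatic C, aromatic C–aromatic C,
sulphonamide — in the dialect of the widely used 2020-era reference
implementation. Eight chemistries scissor one acyclic bond and cap both
children with wildcards. Three are *excisions*, mirroring the reference
reaction products: the amine nitrogen, the ether oxygen and the urea
carbonyl unit are removed entirely and every released substituent is
capped. The amine and ether rules additionally require multi-atom
substituents, so no cut strands a lone methyl. No rule ever touches a
ring bond, and wildcards never participate in a match — capped
fragments are stable, which gives the leaf-closure property
(`terminal_fragments()` of any returned leaf is empty).

`terminal_fragments()` explores the full fragmentation hierarchy
recursively (all matching cleavage events at every node, deduplicated on
canonical SMILES) and returns only the leaves — fragments in which no
rule matches any more. A molecule with no cleavable bond contributes no
fragments: the root is never its own leaf. Because the hierarchy is
explored exhaustively with set semantics, the leaf set is independent of
cleavage order (verified by permutation tests). A `min_fragment_heavy_atoms`
floor is available but defaults to 0, since genuinely tiny fragments
(an acetyl stub, a methyl on an aromatic nitrogen) are legitimate
library members.

One dialect consequence worth knowing: in an aryl ester the scissored
bond is acyl-C–O, so the ester oxygen stays with the aryl fragment
(`CC(=O)Oc1...` yields `*C(C)=O` and `*Oc1...`), and an acetanilide
bearing an additional aryl acetate yields two distinct leaves, not
three, because both acetyl stubs collapse to the same canonical form.

## Descriptors

The descriptor vector holds 14 structural features plus AMW: C/O/N and
heavy-atom counts; ring counts from the smallest set of smallest rings,
split into aromatic (all ring atoms aromatic) and aliphatic, with the
same split for heterocycles (≥ 1 non-carbon ring atom); spiro atoms (the
single shared atom of two rings meeting at one atom); bridgehead atoms
(atoms with ≥ 3 ring bonds in two rings sharing ≥ 2 bonds — ortho-fused
systems like decalin have none); the fraction of sp3 carbons (aromatic
carbons count in the denominator); and the fraction of potential
stereogenic carbons. Chirality is detected from constitution — a
tetrahedral carbon with four distinguishable substituents, assigned or
not — because the curated datasets are stereo-free yet the chiral-carbon
fraction remains informative. Wildcards are excluded from every count
and are hydrogen-like for stereocenter detection, so capping a fragment
changes none of the 14 features. The ring identity
`aliphatic + aromatic = total` holds by construction and is asserted
across every generated dataset; spiro/bridgehead classification is
validated against an independent brute-force oracle (all simple cycles,
plus a Menger-style three-disjoint-paths criterion for bridgeheads) on
all fixture molecules of ≤ 12 heavy atoms.

## Diversity

Structural diversity is the median of all pairwise Tanimoto similarities
over a fingerprint population — lower median, more diverse library. Two
fingerprints are provided: a native circular (Morgan-type) fingerprint of
radius 2 hashed to 1024 bits, with wildcards as a distinct atom type,
and the 166 MACCS keys evaluated through OpenBabel. Two small
conventions: the similarity of two all-zero fingerprints is defined as 1
(tiny fragments can set no MACCS key, and two empty bit sets are
identical objects), and the median of an even number of pairs is the
mean of the two middle values.

The exact median never materializes the n² similarity values: the
population is processed in row blocks (BLAS cross-products) and every
pair is binned into an exact integer histogram over
(intersection, union) popcount pairs, from which the median is read off.
This makes the exact statistic practical at tens of thousands of
fingerprints in bounded memory. For larger populations (or by
configuration) `sampled_median()` draws seeded random samples without
replacement — default 10 samples of 10,000; the test and acceptance runs
use the faster 10 × 1,000 preset, which published methodology considers
adequate for large-collection diversity — computes each sample's median
and averages them. Populations at or below the sample size are evaluated
exactly and flagged `sampled = FALSE`.

## Chemical-space maps

Fingerprints are MinHash-encoded with d (default 128) universal hash
functions over the on-bit indices; the fraction of matching signature
slots is an unbiased estimator of Jaccard similarity (bias < 0.01 over
random pairs, by Monte Carlo). Signatures are indexed in an LSH forest
(default 8 prefix trees over seeded slot permutations); queries descend
from the longest shared key prefix until k·kc candidates are found
(k = 50, kc = 10 by default), then rank candidates by estimated distance.
When the prefix trees return fewer than k sharers — distant queries,
tiny indexes — the query falls back to a scan so small graphs stay
complete. The per-node neighbor lists are symmetrized into an undirected
weighted graph, reduced to a minimum spanning tree per component
(igraph), components linked by the lightest estimated inter-component
edge found over seeded candidate pairs, and the tree embedded in 2D by a
seeded force-directed layout. Topology (tree structure, component
count) is the deliverable; the visual aesthetics of any particular
rendering are not.

Edge weights are estimated (MinHash) distances rather than exact
Tanimoto — that is what keeps the construction near-linear — so ranks
among near-equidistant neighbors carry estimator noise of roughly
±1/√d. The neighbor-recall benchmark therefore uses populations
structured like screening data: analog series of about a dozen members,
where the true 10 nearest neighbors of an item are its series mates.
On such data the graph recovers ≥ 0.99 of exact-scan 10-NN; on
populations where dozens of items are mutually near-equidistant, recall
against an exact scan is limited by estimator resolution, not by the
index.

## Synthetic study data

All validation runs on generated data with known ground truth. The
generator assembles molecules from a pool of 34 fragmentation-inert
building blocks (verified inert at load time, so a rule-dialect change
fails loudly), joined by linkages drawn from the 11 chemistries; the
expected terminal fragments are constructed at assembly time by capping
each block at its formed-bond positions — never by calling the
fragmenter, keeping the oracle independent. Decorations emulate raw
database records: appended counterions, protonated/deprotonated sites,
stereo marks, disallowed-element swaps and duplicates, each with its
expected curation outcome recorded. Defaults: 2–3 blocks per molecule,
uniform linkage mix, decoration rates of 8–15 % in the curation
benchmark — rates chosen once to resemble the salt/charge/stereo load of
real collection dumps.

What the fixtures do *not* emulate: macrocycles, reagent-class outliers,
tautomer-rich heterocycle systems beyond the 1,3-shift family, isotopes,
and the long-tail size distribution of natural-product databases.
Passing the suite certifies the machinery (exact fragment recovery,
reconciling curation, oracle-equal statistics), not the chemistry of any
particular external collection.

Problem sizes used by the validation suite and `scripts/acceptance.R`:
500 assembled molecules for fragment recovery, a 2,000-record decorated
fixture for curation, exact-vs-sampled medians on a 20,000-fingerprint
population, and 1,000 fingerprints for the MinHash/k-NN benchmarks —
sizes at which every statistic is computed exactly where an exact method
exists.

## Numerical and degenerate-input conventions

* Valence checking uses charge-adjusted default valences; parse-time
  valence errors are recorded as rejections, never raised through a
  table read.
* Empty inputs: an empty file reads as an empty table; an empty fragment
  library writes a header-only CSV; descriptor means of an empty library
  are reported as explicit NA, not zeros; `frac_sp3` of a carbon-free
  molecule is 0.
* All randomness (diversity sampling, MinHash hash family, LSH
  permutations, layouts, fixtures) flows from explicit integer seeds;
  identical configuration and seed give byte-identical CSV/JSON outputs.
* Proportions are stored exactly (`count / n_source_compounds`);
  `read_library()` re-validates them to 1e-9 and names the offending row
  on mismatch.

## Known limitations

* The SMILES dialect omits isotopes and does not emit directional bond
  stereo; canonical output is stereo-free by design.
* Aromaticity is stricter than some toolkits (exocyclic-carbonyl rings
  are aliphatic), which shifts individual tautomer winners and aromatic
  ring counts relative to other software — consistently so within the
  package.
* Canonicalization relies on the refinement-orbit assumption; adversarial
  regular graphs (not chemical structures) could defeat it.
* Ring amines are not cleaved (the 11-rule set used here has a
  quaternary-nitrogen rule, not the cyclic-amine rule some variants use).
* MACCS keys depend on the OpenBabel implementation of the key
  definitions; other toolkits' MACCS bits differ in well-known ways.
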