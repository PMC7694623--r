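# fraglib

Fragment libraries are a cornerstone of fragment-based drug discovery:
instead of screening whole compounds, one screens (or designs from) the
small recurring substructures that synthetic chemistry can actually make
and join. `fraglib` builds and characterizes such libraries from compound
collections — natural-product databases, food-chemical collections,
screening decks — entirely in R. It is aimed at chemoinformaticians who
need a reproducible, scriptable path from raw SMILES tables to curated
datasets, terminal-fragment libraries, descriptor and diversity profiles,
cross-library overlap reports and approximate-neighbor chemical-space
maps.

## What it computes

* **Curation** — each record is standardized through a fixed sequence:
  functional-group normalization, largest-component (salt) selection, an
  element whitelist (H, B, C, N, O, F, Si, P, S, Cl, Se, Br, I),
  neutralization and reionization, canonical tautomer selection,
  stereochemistry removal, a molecular-weight ceiling (AMW ≤ 1300 g/mol)
  and canonical-SMILES deduplication. Every drop is logged, so
  `kept + rejected + duplicates = parsed` always holds.
* **RECAP terminal fragments** — retrosynthetic cleavage at 11 bond
  chemistries (amide, ester, amine, urea, ether, olefin, quaternary
  nitrogen, aromatic N–aliphatic C, lactam N–aliphatic C, aromatic
  C–aromatic C, sulphonamide), applied recursively; only leaves of the
  fragmentation hierarchy are kept, with `*` wildcard atoms marking the
  cleaved positions. A fragment's **Count** is the number of distinct
  parent compounds containing it; **Proportion** = Count / processed
  compounds.
* **Descriptors** — 14 structural features (C/O/N/heavy-atom counts,
  ring counts split by aromaticity and heteroatom content, spiro and
  bridgehead atoms, fraction of sp3 carbons, fraction of potential
  stereogenic carbons) plus the average molecular weight, computed
  identically for compounds and fragments (wildcards are invisible).
* **Diversity** — median of all pairwise Tanimoto similarities
  `T(A,B) = |A∩B| / |A∪B|` over Morgan-type circular fingerprints
  (radius 2, 1024 bits) or MACCS keys (166 bits, via OpenBabel). Large
  populations are summarized by averaging the medians of seeded random
  samples (default 10 × 10,000); the exact median is still available at
  scale through a streaming histogram over (intersection, union) counts.
* **Chemical-space maps** — fingerprints are MinHash-encoded (d = 128),
  indexed in an LSH forest, queried for a c-approximate k-nearest-neighbor
  graph (k = 50, kc = 10), reduced to a minimum spanning tree and embedded
  in 2D with a seeded force-directed layout.
* **Synthetic study data** — a seeded generator assembles molecules from
  fragmentation-inert building blocks joined by the 11 cleavage
  chemistries, so the exact expected terminal fragments and curation
  outcomes of every record are known by construction. All validation runs
  on these fixtures; no external downloads are needed.

## Worked example

```r
library(fraglib)

# a tiny collection: two acetanilides, an ester, a salt and a duplicate
smi <- tempfile(fileext = ".smi")
writeLines(c("CC(=O)Nc1ccccc1 m1",
             "CC(=O)Nc1ccc(C)cc1 m2",
             "CC(=O)OCC(C)C m3",
             "CC(=O)[O-].[Na+] m4",
             "O=C(C)Nc1ccccc1 m5"), smi)

rd <- read_molecule_table(smi, dataset = "demo")
cu <- curate_dataset(rd$table)
cu
#> <curation_result: 5 in, 4 kept, 0 rejected, 1 duplicates>

frags <- lapply(cu$kept$molecules,
                function(m) terminal_fragments(m)$leaf_smiles)
names(frags) <- cu$kept$ids
lib <- build_library(cu, frags)
lib$records[, c("fragment_smiles", "count", "proportion")]
#>   fragment_smiles count proportion
#> 1         *C(C)=O     3       0.75
#> 2   *Nc1ccc(C)cc1     1       0.25
#> 3      *Nc1ccccc1     1       0.25
#> 4        *OCC(C)C     1       0.25
```

The acetanilide `m5` is recognized as a duplicate of `m1` after
canonicalization; the sodium acetate record survives as acetic acid but
has no cleavable bond, so it contributes no fragments; the acetyl
fragment `*C(C)=O` is found in three of the four processed compounds
(count 3, proportion 0.75).

For multi-dataset studies, `run_pipeline()` orchestrates
curate → fragment → profile → diversity → overlap → map and writes
stable CSV/JSON outputs plus a reconciling run manifest; see the
vignette (`vignettes/fraglib-methods.Rmd`) for the full model
description.

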