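---
title: "clonescreen: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{clonescreen: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(clonescreen)
```

This vignette is the package's own account of the statistics it computes,
the assumptions behind them, and the choices made where the underlying
method description left the design open. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. The analysis model

### Cell quality control

A cell enters the analysis only when its barcode carries **exactly one
productive heavy (IGH) contig and exactly one productive light (IGK or
IGL) contig**, both with a non-empty CDR3 amino-acid sequence. Barcodes
with zero or multiple chains of either type (doublets, failed assemblies)
are dropped and tallied per reason in the QC report attached to the
`filter_cells()` result.

**Assumption made explicit:** the productivity filter is applied *before*
counting chains. A barcode with two heavy contigs of which one is
non-productive therefore counts as having one heavy chain and is kept.
The alternative (count first, filter later) is stricter; upstream
filtered contig tables are already productive-biased, so the difference
is small in practice, but it is an assumption, not a fact about the
source method, and non-productive contigs are retained at read time so
the decision is auditable.

### Clonotyping

Clones are keyed by the exact **CDRH3+CDRL3 amino-acid pair** (strings
upper-cased and trimmed on ingest; comparison is exact after that). The
source workflow first groups by nucleotide identity and then merges
families with identical amino acids; since the merged amino-acid key is
the final definition, the package implements that key directly.

Scopes: `per_sample` (default; one sample is one mouse-organ repertoire,
so this realizes per-mouse-per-organ clonotyping), `per_mouse` (organs
pooled), `global` (used for cross-repertoire overlap, where identity of
the key across samples is what matters).

Derived per-clone quantities:

* `size` — distinct member barcodes; `expanded` is `size >= 2`, so a
  singleton clone is unexpanded by definition.
* `isotype` — modal heavy-chain isotype over member cells. `Unknown`
  cells vote. **Tie-break (ours, for determinism):** prefer non-Unknown
  isotypes, then alphabetical order.
* `n_variants_nt` / `n_variants_aa` — distinct (VH, VL) full-length
  nucleotide pairs, and distinct translated pairs. Cells whose VH/VL
  length is not a multiple of 3 are excluded from the amino-acid count
  with a warning (not from the nucleotide count).

### SHM counting

`count_shm()` compares equal-length gapped alignments column by column
and counts positions where both characters are in `{A,C,G,T}` and
differ. Gap (`-`, `.`) and `N` columns never count. When a per-column
region mask is available, only `V` and `J` columns count, which excludes
the junction/NP region; without a mask the whole alignment is used,
because upstream outputs do not always delimit regions. This is a stated
approximation: with no mask, junction columns where the "germline" row is
a filled-in consensus can contribute. Heavy- and light-chain counts are
summed per cell before clone averaging, giving one mean per clone.

### Overlap, V–J pairing, position-frequency matrices

* Jaccard index on **clone keys** (not cells): `|A∩B| / |A∪B|`, defined
  as 0 for two empty sets.
* Organ-overlapping clones: same key in bone marrow and spleen of one
  mouse. Public clones: same key in ≥ 2 mice. Both are pure
  set-intersection operations on keys.
* `vj_pairing_counts()` tabulates clones per (heavy gene, light gene)
  combination using each clone's representative variant; genes whose
  total count falls below `label_threshold` (conventionally 2 or 5) are
  pooled into `"other"`, and conservation holds: the matrix sums to the
  clone count.
* `cdr3_pfm()` restricts to the modal CDR3 length (ties → shorter) and
  returns per-position frequencies over the 20 standard residues.
  Non-standard characters (`*`, `X`) are dropped from a column before
  normalization, so every column sums to 1 (to 1e-9).

### Similarity networks

Per clone pair, Levenshtein distances are computed separately for the
heavy and light CDR3s and combined by the edge rule:

* `sum` (default): edge iff `d_H + d_L <= threshold` — one combined
  "edit distance of 5 amino acids or less".
* `both_chains`: edge iff `d_H <= threshold` and `d_L <= threshold`.

The method description behind this is ambiguous ("calculates the edit
distance separately for HC and LC" vs a single captioned distance), so
both readings are exposed and neither is asserted as canonical. The
comparison is inclusive (`<=`). All pairs are computed exactly — no
banding heuristics; repertoires here are hundreds of clones, so the
O(n²) cost is trivial.

`annotate_convergence()` keys every node by
(VH gene, VL gene, |CDRH3|, |CDRL3|) and flags components containing
≥ 2 antigen-specific nodes from different keys: clones that reached
similar CDR3s through different germline genes, the signature of
convergent motifs.

### Selection for expression

Three rules, unioned, with all satisfied reasons kept as tags:
(a) the `top_n` largest IgG-majority clones per (mouse, organ) group;
(b) expanded IgG-majority organ-overlapping clones (the "expanded"
qualifier is applied deliberately — the rule text concerns expanded IgG
clones); (c) public clones, with no isotype restriction. Reported
selections of this kind fix a per-group count that is not recoverable
from their totals, so `top_n` is configuration (default 10) and the
*rule*, not the count, is what the package reproduces.

Each selected clone's **representative variant** is the (VH, VL)
nucleotide pair supported by the most unique barcodes, ties broken by
the lexicographically smallest concatenated sequence.

### Binder classification

`call_binders()`: a clone whose antibody failed to express is
`no_expression`; otherwise it is a `binder` iff
`OD450 >= fold × negative_control_od` with `fold = 3` — "at least three
times" is implemented inclusively. `specificity_summary()` computes
`100 × binders / tested` where *tested* excludes `no_expression` (that
reproduces printed ratios of the form 31/99, where failed expressions
are shown separately). Percentages are reported to one decimal with
standard rounding; note that 3/21 = 14.29 therefore prints as 14.3 even
though truncated displays show 14.2 for the same ratio.

The claim "expansion is not correlated with specificity" is
operationalized — the source states no statistic — as a **rank-biserial
correlation** between expansion rank and binder status with a seeded
permutation p-value (default 10,000 permutations). That choice is ours
and is labeled as such.

### Transcriptome stage

Deliberately minimal, mirroring the standard toolkit path with fixed
reference thresholds: cells `< 0.20` mitochondrial fraction (`mt-`
prefix); BCR genes (Ig V/D/J segments, constant regions, `Jchain`)
removed by symbol prefix so clonotype identity cannot drive clustering;
per-cell scaling to 10,000 followed by `log1p`; top-2000 genes by
variance of the log data; per-gene standardization clipped at ±10; PCA
to 15 components; a shared-nearest-neighbor graph (k = 20, Jaccard
weights, edges below 1/15 pruned); Louvain community detection at
resolution 0.5. **Open parameters fixed by us:** k and the community
algorithm flavor are not specified upstream; k = 20 with SNN-Jaccard
weighting is the de-facto standard and keeps well-separated groups
intact. Cluster labels are `0..K-1` by decreasing size.

DE uses a two-sided Wilcoxon rank-sum on normalized values for genes
detected in ≥ `min.pct = 0.25` of either group, Bonferroni correction
over the genes actually tested, significance at adjusted p < 0.01, and
`logFC = log((mean(expm1(a)) + 1) / (mean(expm1(b)) + 1))` (natural log,
pseudocount 1), ranked descending. The test choice mirrors the reference
ecosystem's default and is stated, not asserted as the source's.

## 2. The synthetic generator: what it emulates

`simulate_repertoire()` states a world with the repertoire structure the analysis
assumes:

| parameter | default | why |
|---|---|---|
| cells per sample | 3200 | typical per-mouse yield of a 5′ immune-profiling run |
| BM percent expanded | 75 | bone-marrow plasma-cell repertoires are dominated by expanded clones |
| spleen percent expanded | 35 | spleen repertoires described as mostly unexpanded |
| clone-size law | truncated Zipf, max 100 | heavy-tailed expansion; exponent *solved*, see below |
| SHM rate | 0.01 /base | gives ≈ 6.6 substitutions/cell over 663 germline V+J bases, a realistic memory/PC load |
| variant rate | 0.2 | a minority of cells found new within-clone variants |
| isotype coherence | 0.85 | clones are isotype-coherent but not pure |
| specificity (3m / 12m / 18m) | 0.31 / 0.07 / 0.07 | young/old screening rates the workflow must resolve |
| planted overlapping / public | 5 per mouse / 2 | small planted sets recoverable exactly |
| QC-fail barcodes | 8% | doublets/orphans at a realistic filtered-output level |
| ELISA | control 0.1; binder lognormal(log 1.0, 0.25); non-binder lognormal(log 0.12, 0.3); 15% expression failure | separable OD distributions over a plausible background |

**Calibration is analytic, not fitted:** with sizes
`P(k) ∝ k^-a` on `1..100`, the percent expanded is
`100(1 − 1/H(a))`, so `a` is solved by root-finding from the target
(75 → a ≈ 1.138). Unreachable targets raise a config error. At the
default this yields ≈ 205 clones per 3,200-cell BM sample — "a few
hundred clones per repertoire", a realistic scale.

Per clone the generator emits: germline VH/JH/VL/JL (fixed random
sequences per gene name), a founder mutated from germline at the SHM
rate, variants created from the founder (1–2 extra substitutions) by a
rate-0.2 rule over cells, per-cell isotypes, and contigs whose
`sequence_alignment`/`germline_alignment` pair reproduces the planted
substitutions exactly — `count_shm` recovers them with no noise.
Public clones are planted in the first configured organ only, so planted
public and organ-overlapping sets are disjoint and each is recoverable
exactly.

`simulate_expression()` plants: cluster markers (fold 4 on 25
genes/cluster), per-cell mitochondrial fractions realized to within
rounding (the mito total is computed from the drawn non-mito total, so a
planted 0.19/0.21 straddle of the 0.20 cutoff is honored), 10 Ig genes
for removal testing, and optional binder-vs-rest DE (fold 2 on the 10
best-expressed non-marker genes — planting DE on near-zero genes would
make the effect undetectable by construction and the recovery test
meaningless).

**What the generator does not emulate** — and therefore what a green
test does *not* establish: SHM hotspots and lineage structure
(substitutions are i.i.d. per base; no indels, so alignments are
trivially gapless), germinal-center dynamics, biased V(D)J recombination
and real germline sequences, ambient RNA/doublet expression artifacts,
batch effects, and any affinity biology linking sequence to OD. Green
tests establish that the *computations* are correct on data with the
assumed structure, not that the biology is modeled.

## 3. Numerical and degenerate-input conventions

* Clone ordering is by (group, clone key), independent of input row
  order; `assign_clones` is idempotent and order-invariant (tested).
* Expansion-profile ties are broken by clone key; rank is 1-based.
* `jaccard(∅, ∅) = 0` by convention.
* Empty contig tables, empty selections, single-clone profiles, and
  clones with no usable alignments (SHM flagged `NA`, excluded from
  group comparisons) are all legal and tested.
* PFM columns sum to 1 within 1e-9; a column consisting entirely of
  non-standard residues would be all-zero (accepted degenerate case).
* Permutation p-values use the `(1 + #{|null| ≥ |obs|}) / (n + 1)`
  estimator, so they are never 0 and are seed-stable to ±0.01 at 10,000
  permutations (tested across seeds).
* All randomness flows through R's RNG from a single seed; repeated
  pipeline runs at a fixed seed produce byte-identical TSVs (checksummed
  in the acceptance suite).

## 4. Known limitations

* Clonotype keys are exact string matches; no allowance for CDR3
  sequencing errors (that is what the similarity network is for).
* SHM without a region mask can include junction columns (see above).
* The transcriptome stage is a minimal reference path — no batch
  integration, no UMAP, no cell-type annotation; cluster *count* on real
  data is data-dependent and is deliberately not an acceptance target.
* `read_contigs()` maps only the unified-schema columns; dialect columns
  outside it (e.g. 10x `raw_clonotype_id`) are ignored.
* Production-scale repertoires (tens of thousands of cells) and their
  data-dependent results (cluster counts, marker lists) require real
  deposited data and are out of desk-scale scope; the tests run the
  same code paths at reduced n and say so.
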