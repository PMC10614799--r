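---
title: "Methods: residue-level enrichment for protein function annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residue-level enrichment for protein function annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitenrich)
```

## The model

`sitenrich` annotates enzymatic (or other site-defined) function by
comparing local structural environments, not global folds. The working
assumptions are:

1. A residue's functional role is captured by a fixed-dimension
   embedding of its local atomic environment, produced by an external
   pre-trained model and consumed here as-is. Vectors are **not**
   renormalised on load: cosine similarity is used throughout, so only
   directions matter.
2. If a query protein performs function $F$, the database residues of
   $F$'s reference site should concentrate near the top of the list of
   database residues ranked by their maximum similarity to any query
   residue.
3. Raw enrichment scores are not comparable across classes — class size
   and, above all, the strong correlation between the embeddings of one
   site's residues inflate the null ES differently per class — so
   significance must come from function-specific empirical null
   distributions, not from a label-permutation null (which overstates
   significance under within-set correlation).

The pipeline for one query is: pLDDT filter → cosine similarity matrix
→ max-similarity ranking (recording, for every database residue, the
query residue achieving the max) → per-class weighted Kolmogorov–Smirnov
running sum → leading-edge extraction and back-mapping → empirical
p-values → Benjamini–Hochberg FDR across the classes tested for that
protein. A significant call requires $q \le \alpha$ *and* a positive
enrichment score; depletion is never annotated.

## The reference database

A reference entry is one curated enzyme: a structure, a chain, and its
catalytic residues. Because curated sites average fewer than five
catalytic residues — too few for a stable rank statistic — the active
site is expanded to every chain residue with at least one atom within
**3.5 Å** (inclusive) of any catalytic-residue atom, a distance chosen
to capture hydrogen-bonding partners. Ligands, waters and all other
heteroatoms are removed first; alternate conformers other than altloc
"A"/blank are dropped; hydrogens, when present, participate in the
distance test unless `heavy_only = TRUE`. Residues keep their author
(PDB) numbering and insertion codes everywhere — nothing is ever
renumbered. Function classes are catalytic-mechanism classes with an
explicit class → EC mapping (a class is more specific than an EC number
in some cases); the database enforces that a class maps to a single EC
number.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `cutoff` (site expansion) | 3.5 | Å | captures residues that can hydrogen-bond to a catalytic residue; inclusive boundary |
| `plddt_threshold` | 70 | pLDDT | the usual high-confidence bound for predicted models; inclusive |
| `exponent` ($p$) | 1 | — | weights hits by their similarity, as in weighted gene-set enrichment; $p = 0$ gives the classic K-S statistic |
| `alpha` | 0.001 | FDR | the significance plateau for protein-level precision/recall; exposed because precision/recall trade off through it |
| `min_size` (backgrounds) | 50 | null scores | below this, empirical tail fractions are too coarse; such classes are reported unscored rather than mis-scored |
| `pseudocount` | on | — | add-one smoothing keeps $p > 0$ so BH input is never exactly zero |
| `min_coverage` | 0.75 | fraction | structural filter: at least 75% of reference catalytic residues identified (inclusive) |
| `max_rmsd` | 5 | Å | structural filter: all-atom RMSD of matched catalytic residues (strict `<`) |
| `min_pairs` | 2 | residues | an RMSD over fewer than two residues is meaningless |

## Numerical choices

- **Running sum.** Hit and miss contributions are accumulated as two
  separate cumulative sums and subtracted. This makes the two exact
  identities hold in floating point: ES is exactly ±1 when every
  in-class residue precedes (trails) every out-of-class residue, and
  the final value of the sum is exactly 0. The peak is the earliest
  index attaining the maximum of $|S|$; when two positions tie in $|S|$
  at machine precision with opposite signs, the reported sign follows
  this earliest-index rule.
- **Ties in ranking.** Database rows with equal scores are ordered by
  ascending flat-row index (stable sort); the best-matching query
  residue under tied similarities is the lowest query index. Results
  are therefore reproducible bit for bit.
- **Degenerate inputs.** A class with zero in-class or zero out-of-class
  members in the ranked list is unscored; an all-zero weight vector, an
  empty query after confidence filtering, zero-norm embedding vectors
  (reported with the offending residue's identity) and empty backgrounds
  are errors, not silent NAs.
- **Kabsch.** SVD of the cross-covariance with a determinant sign
  correction, so the rotation is always proper (det +1), including for
  collinear point sets (rank-deficient cross-covariance). Atom
  correspondence within a matched residue pair uses PDB atom names;
  atoms missing on either side are dropped pairwise; hydrogens are
  excluded from RMSD by default.
- **Mann–Whitney U baseline.** Midranks for ties; the one-sided p-value
  is computed by exhaustive enumeration over all label assignments while
  $\binom{N}{m}$ is small (exact even under ties) and by the
  tie-corrected normal approximation with continuity correction
  otherwise.
- **Boundaries.** Site expansion and coverage are inclusive (≤ 3.5 Å,
  ≥ 75%); the RMSD filter is strict (< 5 Å); pLDDT filtering is
  inclusive (≥ 70) — following the natural reading of "within",
  "at least" and "less than".

## Design choices that were genuinely open

- **Leading edge.** The default is the standard gene-set-enrichment
  convention: in-class members at or before the positive running-sum
  peak. An alternative reading — members whose *individual* ranked score
  reaches the score at the peak — is available as
  `leading_edge_mode = "score"`. Only positive ES produces an
  annotation.
- **Empirical p tail.** $p = \#\{d_i \ge s\}/|D|$ (upper tail): large
  enrichment must mean small p.
- **FDR family.** BH is applied per query protein across its tested
  classes; classes lacking a background are excluded from the family and
  reported unscored.
- **Self-exclusion.** When a protein that is itself a reference is
  scored (as happens when reference proteins serve as background
  corpus), its own database rows are excluded by structure identifier.
  On by default for background construction, off for ordinary
  annotation.
- **One-to-one catalytic matching.** When one reference catalytic
  residue could pair with several same-type query residues (or vice
  versa), pairs are assigned greedily by descending embedding
  similarity, keeping both sides unique.
- **Embedding file formats.** A tab-separated dialect (metadata columns,
  then `e0..e{D-1}`; round-trips to ≥ 12 significant digits) for
  inspection and interchange, and a versioned serialized container for
  scale (bitwise round-trip). Reference databases and backgrounds use
  the same versioned-container approach.

## The synthetic generators: what they emulate, and what they do not

The generators reproduce the *statistical* structure the method relies
on, with no external data:

- function classes are unit vectors ("centroids") on the embedding
  sphere, placed by rejection sampling so every pair is at least
  `centroid_separation` radians apart;
- a site residue is its class centroid plus isotropic Gaussian noise of
  expected norm `noise_sd`, renormalised — so `noise_sd` is
  approximately the within-class angular scatter in radians, and the
  separation-to-noise ratio is the single knob controlling difficulty;
- query proteins are uniform random unit vectors (background) with
  optional planted site residues and an optional pLDDT column with a
  configurable low-confidence fraction;
- toy 3-D fixtures provide catalytic coordinate sets related by a known
  rigid transform plus coordinate noise, and complete miniature studies
  (reference structures, a query structure with a planted site copy,
  null structures) for the structural filters, embedded by a
  deterministic mock backend whose vectors are a pure hash of
  (amino-acid type, 10 Å atom-element environment, seed).

Default study conditions: 5 classes, 1 site per class, 6 residues per
site, dimension 32, `noise_sd = 0.2`, `centroid_separation = 0.8` (four
times the noise scale — the regime in which planted sites are reliably
recoverable), 50-residue queries. Problem sizes in the tests and the
acceptance script (1000-protein null corpora, 100–200 query
repetitions) were chosen as the smallest sizes at which the calibration
and recovery properties are statistically meaningful.

What passing tests on these fixtures **does not** show about real data:
real embedding models produce anisotropic, hierarchically structured
similarity landscapes (homologous classes are close; ours are
near-orthogonal); real proteins have thousands of residues, low-complexity
regions that produce systematic spurious hits, and classes of very
different sizes; and the mock backend's hash-based vectors have none of
the smoothness of a learned embedding — two environments differing by a
single atom embed as unrelated vectors. The fixtures validate the
statistics and the plumbing, not the biology.

## A note on significance at small background sizes

With $C$ tested classes and a background of $|D|$ nulls per class, the
smallest attainable BH-adjusted q-value is $C \cdot (1 + 0)/(1 + |D|)$
(pseudocount on). At the packaged study scale (5 classes, $|D| = 1000$)
that floor is ≈ 0.005, *above* the default `alpha = 0.001`: a planted
site can rank first with a perfect enrichment score yet not be called
significant. Moreover the empirical nulls here are heavy-tailed — the
residues of one class are strongly correlated, so a pure-noise protein
occasionally produces ES = 1 for some class; this is precisely the
phenomenon that makes label-permutation nulls invalid and
function-specific empirical nulls necessary. The acceptance script
therefore reports the planted class's median q alongside top-1 accuracy
and the null calibration, rather than a sensitivity that is structurally
zero at this scale. At realistic background sizes (tens of thousands of
corpus proteins) the floor drops well below the threshold.

## Known limitations

- The quality of annotation is bounded by the reference database: one
  reference site per mechanism, curated catalytic residues, and an
  embedding model that makes functional sites cluster. None of these is
  produced by this package.
- The weighted K-S statistic over-rewards internally correlated sets;
  the empirical nulls absorb most but not all of this, and proteins far
  outside the background distribution (e.g. very low-complexity
  predicted structures) can still yield false positives — hence the
  structural coverage/RMSD filters.
- The db→query best-match mapping is many-to-one: several database
  residues may map to the same query residue, and a planted residue may
  be claimed by no database residue, so residue-level recall is
  systematically below precision.
- `expandActiveSite` computes a dense atom-distance matrix; it is meant
  for single sites (hundreds of atoms), not whole-proteome neighbour
  searches.
- The MWU exact-enumeration path is exponential in the class size and is
  automatically replaced by the normal approximation beyond small
  configurations.
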