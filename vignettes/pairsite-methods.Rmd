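---
title: "Partner-specific interface prediction: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partner-specific interface prediction: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pairsite)
```

This vignette is the package's own account of the science it implements: the
models and their assumptions, the parameters that matter, what the synthetic
data generator does and does not emulate, and the places where the design was
genuinely open and a choice had to be made.

## The prediction problem

Given two proteins A and B known (or hypothesized) to form a complex, the
package predicts which cross-chain residue pairs are in contact and, from
those pair scores, which residues of each chain form the partner-specific
binding site.  A contact is defined geometrically: the minimum distance over
the two residues' heavy (non-hydrogen) atoms is strictly below 6.0 Å.  This
definition is conventional in pair-level interface prediction and makes the
labels a pure function of the coordinates, which the package exploits
everywhere: fixture ground truth is always recomputed from geometry, never
stored.

Partner-specificity is the point: a protein that binds several partners
through different faces gets a different answer for each partner, because
every prediction is conditioned on the features of both chains.

## Residue encoding

Each residue carries a sequence block and, in structural mode, a structural
block.

**Sequence block (64 values).**  Identity one-hot over a 22-symbol alphabet
(the 20 standard residues in alphabetical one-letter order, then `X` for
unknown/nonstandard, then a gap symbol reserved for window padding); the
20-column PSSM (log-odds) and PSFM (frequency) rows of a sequence profile;
the profile's per-position information content; and a conservation score
`1 − H(p)/log 20` mapping column entropy to `[0, 1]`.  Profiles are read
from PSI-BLAST ASCII files when available.  Without one, a deterministic
pseudo-profile substitutes: the BLOSUM62 row of the residue as log-odds and
its background-weighted softmax (half-bit convention) as frequencies.  This
is a graceful degradation, not a claim of equivalence — a real profile
carries family information a substitution row cannot.

**Structural block (15 values).**  8-class secondary structure one-hot
(`H G I E B T S -`) from an internal backbone-dihedral assigner: φ/ψ in the
canonical α region form `H` runs (≥ 4), α runs of 3 become `G`, β-region
runs (≥ 2) become `E`, short α fragments `T`, everything else `-`.  The
classes `I`, `B`, `S` are never emitted by these rules but stay in the
alphabet so externally computed assignments can be ingested with the same
encoding.  Relative solvent accessibility is Shrake–Rupley SASA of the
isolated (unbound) chain — probe 1.4 Å, 100 deterministic golden-spiral test
points per atom, element van-der-Waals radii — normalized by the residue
type's theoretical maximum and clipped to `[0, 1]`.  Half-sphere exposure
counts neighboring Cα atoms within 12 Å split by the side-chain hemisphere
(true Cβ when present, a pseudo-Cβ from the flanking Cα geometry otherwise,
which also covers glycine); contact number is their sum.  Three geometry
descriptors complete the block: Kyte–Doolittle hydrophobicity, a protrusion
proxy (neighbor-count deficit relative to the chain mean), and a radial
depth proxy (normalized distance from the chain centroid).

**Environments.**  Sequence features are concatenated over an 11-residue
sliding window; positions beyond the termini contribute a padding vector
whose gap one-hot slot is set, keeping vector lengths constant.  Structural
environments use the Voronoi neighborhood: two residues are neighbors iff
their Cα cells share a facet in the Voronoi diagram of the chain's Cα atoms,
equivalently iff a Delaunay edge joins them.  For each real-valued feature
the neighborhood contributes `(Σ, mean, max, min)`; for each one-hot feature
it contributes class counts.  An empty neighborhood contributes zeros (the
max/min are undefined there; the convention is flagged internally rather
than invented).  The tessellation is computed per chain — features describe
each partner in its unbound state, so neighborhoods must not cross the
interface.

In sequence-only mode the encoding is the windowed sequence block alone, so
both modes have fixed, documented vector lengths (704 per residue in
sequence mode; 945 in structural mode).

## Delaunay adjacency

No 3-D tessellation routine ships with the environment's R stack, so the
package computes Delaunay adjacency directly by empty-circumsphere
enumeration in compiled code: every point quadruple whose circumsphere
contains no other point strictly inside contributes its six edges.  This is
O(n⁵) in the worst case but exact, robust, and fast for chain-sized point
sets (well under a second at n = 150; chains here are tens of residues).
Fully degenerate clouds (coplanar/collinear) are perturbed by a seeded
jitter of 1e-4 Å and retried; near-cospherical ties are absorbed by a
relative tolerance of 1e-9.  Convex-hull (unbounded-cell) edges are kept —
no long-edge pruning — which is the permissive reading of the neighborhood
definition; the tests' brute-force oracle uses the same convention.

## The two-step classifier

Step 1 is a binary gradient-boosted tree ensemble (xgboost, logistic
objective) over concatenated residue-pair vectors.  Because the pair
relation is symmetric, every sampled pair enters training in both orderings
(AB and BA, block-swapped vectors), and at prediction time the two
orderings' scores are averaged — so the final score matrix transposes
exactly under chain swap, by construction.

Step 2 consumes the same features plus the step-1 score and its structural
pairwise environments: the four statistics of `F(r, j)` over the Voronoi
neighbors `r` of `i`, of `F(i, s)` over the neighbors of `j`, and of
`F(r, s)` over both jointly (12 values; in sequence mode only the score is
appended).  The intent is spatial coherence: real binding sites are
contiguous patches, so a pair surrounded by high-scoring pairs deserves a
higher score.

Class imbalance is handled at training time only: per complex, all contact
pairs are kept and at most three times as many non-contact pairs are drawn
uniformly (residues without coordinates remain eligible — apo/holo
conformational changes make "inaccessible" residues legitimate negatives).
Evaluation never samples.  The sampling RNG derives a per-complex substream
by hashing the complex identifier, so adding or removing a complex leaves
the other complexes' draws untouched.

**Out-of-fold stacking.**  Feeding step 2 the in-sample predictions of a
step-1 model trained on the same rows would leak labels.  Step-1 scores for
training complexes therefore come from K-fold (K = 5) out-of-fold models
over complexes.  This was an open design point — the original two-step
formulation does not state its mechanism — and out-of-fold prediction is the
standard leakage-safe choice.  Its cost is a mild train/predict distribution
shift in the step-1 score feature (out-of-fold scores are noisier than the
final model's), discussed below.

**Hyperparameters.**  Defaults are fixed rather than searched: tree depth 6,
500 rounds, learning rate 0.1, subsample 1, single thread (bit-for-bit
reproducibility).  Everything is overridable through
`default_model_params()`.  All toy-data runs in the tests and the
acceptance script use a scaled-down configuration — depth 4, 60 rounds,
learning rate 0.2 — matched to the synthetic problem size (12 complexes,
chains of 20–32 residues, a few thousand sampled pairs), where deeper/longer
boosting only overfits.  Training rows are sorted canonically (complex,
ordering, indices) before fitting so results do not depend on input order.

## From pair scores to binding sites

With all `n = len(A) × len(B)` pair scores sorted descending (ties broken by
ascending pair indices — a fixed, documented convention), a residue's score
is

`Is(α) = Σ_{k=0}^{⌊log₂ n⌋} Xc(α, 2ᵏ) / 2ᵏ`,

where `Xc(α, 2ᵏ)` counts pairs containing α among the `2ᵏ` top-scored pairs
(bucket sizes capped at `n`).  The index convention (integer k from 0, last
bucket at `⌊log₂ n⌋`) is stated explicitly because the summation bound
"k ≤ log₂ n" admits several readings; the chosen one is pinned by an
independent brute-force oracle in the tests.  The function is rank-based —
any strictly increasing transform of the score matrix leaves it unchanged —
and monotone: raising a pair score never lowers the scores of its two
residues.  One caveat of deterministic tie-breaking: for an exactly
symmetric homodimer matrix, mirror pairs are tied and a bucket boundary can
fall between the two members, so the two chains' profiles can differ
slightly at ties; the symmetry that does hold exactly is profile swap under
transposition of a tie-free matrix.

Scores are then smoothed along the sequence with weights (¼, ½, ¼), termini
renormalized — interfaces are locally contiguous in sequence more often than
not.  Smoothing precedes calibration: an isotonic (pool-adjacent-violators)
regression of interface labels on smoothed scores from held-out complexes
maps any score to a non-decreasing expected precision in `[0, 1]`.  The
order smoothing-then-calibration was open; calibrating the quantity users
threshold on (the smoothed score) keeps the expected-precision
interpretation honest.

A maximum-score baseline (`Is_max(α) = max_j F(α, j)`) ships alongside for
comparison, since earlier pair predictors scored residues that way.

## Evaluation

Leave-one-out over complexes: each complex is scored by a two-step model
trained on all the others (sampled); the left-out complex is scored in full.
Contact prediction is summarized by ROC-AUC pooled over all complexes' pairs
and averaged per complex (complexes lacking both classes are skipped from
the average, kept in the pool), plus pooled PR-AUC — prevalence here is a
few percent, and PR curves expose what ROC hides under imbalance.  ROC-AUC
is computed by the Mann–Whitney rank statistic with midranks; PR-AUC by
step-wise interpolation over tie blocks across the full recall range.
Binding-site predictions additionally get MCC, precision, recall,
specificity and NPV at the threshold maximizing MCC (scanned over all
distinct scores, ties resolved to the lowest threshold).

The partner-specificity analysis groups chains that are >90% identical by
global alignment and occur in several complexes, collects for each
interaction the smoothed site scores of its own interface residues versus
residues that are interface only in the protein's *other* interactions, and
compares the pooled groups with a two-sided Mann–Whitney U test (exact
enumeration when both groups have ≤ 8 observations — valid under ties —
normal approximation with tie correction otherwise).

## The synthetic data generator

`make_toy_complex()` builds two backbones from ideal internal coordinates
(NeRF chain extension; φ/ψ templates for helix, strand, coil; side chains as
Cβ only — sufficient for contacts, exposure and accessibility) and places
the partner on a skew-line arrangement: the inter-chain distance is minimal
at the designated interface centers and grows monotonically away from them,
so a contact patch of the requested width per chain is forced geometrically.
The placement gap, tilt and roll are searched deterministically until
exactly that many residues per chain are in contact; the realized contact
residues are the interface designation, and labels are recomputed from
coordinates by `compute_contacts()` whenever needed.

Synthetic profiles tie conservation to interface membership the way real
profiles do — weakly and noisily: every residue draws a baseline
concentration, one residue in five anywhere in the chain is spuriously
conserved, and interface residues add a boost of random per-residue strength
scaled by `informativeness` (at 0 both classes are identically distributed;
at 1 strongly but not perfectly separated).  Benchmark sets use
`informativeness = 0.9`, chain lengths 20–32, interface widths 5–7 (roughly
a quarter of a chain, patch-like rather than razor-thin), and optional
complex pairs re-using one chain with a different partner and interface, the
shared chain's profile marking the union of its interfaces as real
conservation would.

**What the generator does not emulate — and what that implies.**  Toy chains
are quasi-one-dimensional, so Voronoi neighborhoods nearly coincide with
sequence neighbors, and interface labels are a deterministic function of the
conserved patch plus geometry with razor-sharp boundaries.  Three
consequences show up reproducibly in the leave-one-out results and are
worth stating because they invert findings that hold on real data: (i)
smoothed per-residue conservation is essentially the optimal site ranking
on this data, so the learned pipeline matches but does not beat that
feature-only baseline; (ii) the second step's neighborhood aggregation
reduces to sequence smoothing and cannot improve site PR-AUC over step 1;
(iii) the unsmoothed maximum baseline edges out the rank-based score with
smoothing, the reverse of the ordering observed on real benchmarks, where
pair predictions are far noisier and interfaces are two-dimensional surface
patches.  Passing tests on this generator therefore demonstrate mechanical
correctness, determinism, symmetry and learnability — not that the stacked
step or the rank scoring function dominate their baselines on real
complexes.

## Numerical choices and degenerate inputs

* Contact threshold strictly `<` 6.0 Å; pairs with a coordinate-less residue
  are labeled non-contact and flagged.
* Delaunay: jitter 1e-4 Å (seeded) only for rank-deficient clouds; ≤ 4
  points form a complete graph; residues without Cα are neighborless and
  flagged.
* Empty Voronoi neighborhoods: environment zeros plus a missing flag.
* Rank-score bucket sizes capped at `n`; tie-break lexicographic.
* Smoothing termini renormalize the (¼, ½, ¼) weights over the available
  neighbors.
* Isotonic calibration keeps the upper fitted value at tied scores and
  clips to `[0, 1]`; single-class calibration data is an error, not a
  silent constant.
* Problem sizes in tests and the acceptance script: 12 complexes, chains of
  20–32 residues, depth-4/60-round boosters — the scale at which the toy
  benchmark is informative.

## Known limitations

* Only the first model of a PDB file is read; mmCIF, assemblies and symmetry
  expansion are out of scope.
* The internal secondary-structure assigner is dihedral-only (no hydrogen
  bonds): π-helices, bridges and bends are never assigned.
* The geometry descriptor set is a documented, versioned choice of proxies,
  not a reproduction of any external descriptor suite.
* Homodimers recorded as a single chain are not expanded; only cross-chain
  pairs are scored.
* The pseudo-profile fallback carries no evolutionary information beyond the
  substitution matrix; sequence-mode accuracy with real profiles is expected
  to differ.
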