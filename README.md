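# dmanet

Bipartite link prediction of drug–microbe associations (DMAs) in R.

Many orally administered drugs are metabolized — activated, inactivated, or
made toxic — by members of the human microbiome, but assaying every
drug × microbe combination is infeasible. `dmanet` ranks candidate
associations computationally from three ingredients: drug chemistry, microbe
genome sequence, and a sparse table of known associations.

## The method

Given drugs $D = \{d_1,\dots,d_m\}$, microbes $B = \{b_1,\dots,b_n\}$ and a
known edge set $E$ of the bipartite graph $G=(D,B,E)$:

1. **Drug similarity.** Each drug is encoded as a 1,024-bit functional-class
   circular fingerprint $\mathbf{f}_d$. The plain similarity is the Tanimoto
   coefficient
   $S(d_i,d_j) = \mathbf{f}_{d_i}\cdot\mathbf{f}_{d_j}\,/\,
   (\|\mathbf{f}_{d_i}\| + \|\mathbf{f}_{d_j}\| - \mathbf{f}_{d_i}\cdot\mathbf{f}_{d_j})$.
   An atom-contribution *weighted* variant deletes each atom $k$ of the
   comparison drug in turn, re-fingerprints the remainder, sets the atom's
   weight to $w_j^k = |S(d_i,d_j) - S(d_i,d_j^k)|$, sums atom weights onto
   the fingerprint bits they cover, and rescores the pair with
   $S_d(d_i,d_j) = \sum_q \min(f_{d_i}^q, w_{bit_q} f_{d_j}^q) /
   \sum_q \max(f_{d_i}^q, w_{bit_q} f_{d_j}^q)$.
2. **Microbe similarity.** Exact Smith–Waterman local alignment (match +1,
   mismatch −1, linear gap penalty 2), normalized as
   $S_b(A,B) = sw(G_A,G_B)/\sqrt{sw(G_A,G_A)\,sw(G_B,G_B)} \in [0,1]$.
3. **Pair embedding.** Every node owns a *key dictionary*: its side-mates
   sorted by descending similarity, itself first. The embedding of a pair
   $(d_x, b_p)$ reads, at key position $i$ of $d_x$'s dictionary, the
   similarity $S_d(d_x, n_i)$ if key drug $n_i$ is associated with $b_p$ in
   the training data and 0 otherwise; the microbe half mirrors this, and the
   halves are concatenated into $\mathbf{e}(d_x,b_p)$ of length $g = L_d + L_b$.
4. **Attention + classifier.** A per-feature attention subnetwork gates each
   embedding column, $\tilde F = E \odot M$ with $M \in (0,1)^{k\times g}$,
   and a small feed-forward network (hidden ReLU layer, two-neuron sigmoid
   output) turns each gated row into an association probability. Both are
   trained jointly by plain SGD on clipped binary cross-entropy with an
   L2 penalty (defaults: learning rate 0.9, batch 3,000, 2,000 epochs,
   λ = 2·10⁻⁴).
5. **Evaluation.** 5-fold cross-validation in the positive-unlabeled
   setting (all unlabeled pairs as negatives), AUROC/AUPRC, and
   interpretability diagnostics: per-key embedding profiles, attention
   column importances, top-*l* key masking curves, neighbor-rank checks and
   per-microbe candidate ranking.

A planted-cluster synthetic generator (drug families × microbe clades with
preferential within-cluster association) makes the entire pipeline testable
without external databases.

## Worked example

```r
library(dmanet)
ds  <- generate_synthetic()            # default planted world (seed 0)
ss  <- synthetic_similarities(ds)
rep <- run_cv(ss$sim_d, ss$sim_b, ds$assoc,
              config = train_config(epochs = 300, seed = 1), seed = 1)
rep
```

prints

```
<CV report: mean AUROC 0.911, mean AUPRC 0.758 (pooled 0.910 / 0.729)>
 fold     auroc     auprc n_test_pos n_test_neg
    1 0.9026735 0.7218184         41        104
    2 0.9180288 0.8235301         40        104
    3 0.8961538 0.6663160         40        104
    4 0.9088942 0.7297103         40        104
    5 0.9310680 0.8477290         40        103
```

i.e. on a 40-drug × 18-microbe world with 201 planted associations the
5-fold CV recovers held-out edges with mean AUROC 0.911 — far above the
0.5 of a label-permuted control — because structurally similar drugs share
microbes by construction. The neighbor-rank diagnostic makes the mechanism
visible:

```r
nc <- neighbor_check("d001", "b001", ss$sim_d, ds$assoc, top_k = 9)
# -> 8 of the top 9 most similar drugs share the microbe
```

Real data go through the same functions via `read_drug_table()` (TSV of
`id<TAB>SMILES`, or SDF), `read_microbe_fasta()` and `load_associations()`;
see `inst/cli/dmanet.R` for a ready-made command-line front end
(`drug-sim`, `microbe-sim`, `synth`, `cv`, `rank`).

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the model,
its assumptions, every tunable parameter, what the synthetic generator does
and does not emulate, and the numerical design choices.
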