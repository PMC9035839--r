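# Independent oracles used across the suite. Each reimplements the checked
# quantity from its definition, by brute force, never by calling the
# package's own computation path.

# Tanimoto as explicit set counting on on-bit index sets
oracle_tanimoto_sets <- function(a_bits, b_bits) {
  un <- length(union(a_bits, b_bits))
  if (un == 0) 0 else length(intersect(a_bits, b_bits)) / un
}

# exhaustive local alignment: every monotone matching of residue pairs,
# internal gap positions charged linearly (recursive C++ enumeration,
# structurally independent of the DP kernel)
oracle_sw <- function(a, b, match = 1L, mismatch = -1L, gap = 2L) {
  dmanet:::.sw_enumerate_cpp(a, b, match, mismatch, gap)
}

# AUROC by exhaustive concordant-pair counting (ties count 1/2)
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# AUPRC by step integration over descending unique thresholds, each
# precision/recall recomputed from scratch
oracle_auprc <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(labels == 1)
  ap <- 0; prev_rec <- 0
  for (t in th) {
    sel <- scores >= t
    prec <- sum(labels[sel] == 1) / sum(sel)
    rec <- sum(labels[sel] == 1) / n1
    ap <- ap + prec * (rec - prev_rec)
    prev_rec <- rec
  }
  ap
}

random_dna <- function(len) paste(sample(c("A", "C", "G", "T"), len, TRUE),
                                  collapse = "")

# random binary fingerprint pair as dmanet_fp objects
random_fp <- function(n_on = 40L, nbits = 1024L) {
  dmanet:::.fp_from_bits(sample.int(nbits, n_on), nbits)
}

# small, fast training configuration for pipeline-level tests (reduced epoch
# budget relative to the 2000-epoch default purely for suite runtime; see
# the methods vignette)
fast_config <- function(epochs = 300L, seed = 1L, ...) {
  train_config(epochs = as.integer(epochs), seed = as.integer(seed), ...)
}

# default planted synthetic world with its similarity matrices, cached per
# session because several test files use it
synth_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_synthetic()
      cache <<- c(list(ds = ds), synthetic_similarities(ds))
    }
    cache
  }
})
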