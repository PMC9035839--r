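# ---------------------------------------------------------------------------
# Nearest-neighbor key dictionaries and bidirectional pair embeddings.
#
# Every node owns a key dictionary: all nodes of its own side sorted by
# descending similarity to the owner, the owner itself first ("key 1"). The
# embedding of a candidate pair (d_x, b_p) reads, at key position i of
# d_x's dictionary, the similarity S_d(d_x, n_i) if key drug n_i is
# associated with b_p in the training fold and 0 otherwise; the microbe
# half mirrors this with the sides swapped, and the two halves are
# concatenated. By default the pair's own nodes are excluded from the
# instantiated key sets, so an embedding never reads the pair's own
# association bit (no label leakage).
# ---------------------------------------------------------------------------

#' Build sorted nearest-neighbor key dictionaries
#'
#' For every node of a square similarity matrix: keys sorted by descending
#' similarity to the owner with the owner forced first; ties broken by
#' ascending registry index. Optionally truncated to the first `L` keys.
#'
#' @param sim a `dmanet_sim` (directed drug matrices are symmetrized first)
#' @param L dictionary length including the self key (default: full side)
#' @return object of class `dmanet_dicts`: list with `ids`, `key_idx`
#'   (node x L matrix of registry indices) and `key_sim` (matching
#'   similarities; position 1 is the self key with similarity 1)
#' @export
build_dictionaries <- function(sim, L = NULL) {
  stopifnot(inherits(sim, "dmanet_sim"))
  sym <- symmetrize_similarity(sim)
  v <- sym$values
  n <- length(sym$ids)
  if (is.null(L)) L <- n
  L <- min(as.integer(L), n)
  if (L < 1L) stop("dictionary length must be >= 1")
  key_idx <- matrix(0L, n, L)
  key_sim <- matrix(0, n, L)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(-v[i, others], others)]
    keys <- c(i, ord)[seq_len(L)]
    key_idx[i, ] <- keys
    key_sim[i, ] <- c(1, v[i, ord])[seq_len(L)]
  }
  structure(list(ids = sym$ids, key_idx = key_idx, key_sim = key_sim, L = L),
            class = "dmanet_dicts")
}

#' @export
print.dmanet_dicts <- function(x, ...) {
  cat(sprintf("<key dictionaries: %d nodes, %d keys each>\n",
              length(x$ids), x$L))
  invisible(x)
}

.node_index <- function(id, ids, what) {
  if (is.character(id)) {
    i <- match(id, ids)
    if (is.na(i)) stop("unknown ", what, " id: ", id)
    i
  } else as.integer(id)
}

#' Microbe-specific drug neighbor aggregation (drug half of the embedding)
#'
#' Entry i of the returned vector is `S_d(d_x, n_i)` when the i-th key of
#' d_x's dictionary is a drug associated with `b_p` in the training
#' associations, else 0. With `include_self = FALSE` (default) `d_x` itself
#' is removed from the instantiated set, so key position 1 always holds 0.
#'
#' @param d_x drug id or index
#' @param b_p microbe id or index
#' @param dict_d drug dictionaries from [build_dictionaries()]
#' @param assoc_train training-fold `dmanet_assoc`
#' @param include_self restore the literal self-key reading (leaks the
#'   pair's own label into the feature; off by default)
#' @return numeric vector of length `dict_d$L`
#' @export
msdna <- function(d_x, b_p, dict_d, assoc_train, include_self = FALSE) {
  d <- .node_index(d_x, dict_d$ids, "drug")
  b <- .node_index(b_p, assoc_train$microbe_ids, "microbe")
  e <- assoc_train$edges
  np <- e$drug[e$microbe == b]
  if (!include_self) np <- setdiff(np, d)
  dict_d$key_sim[d, ] * (dict_d$key_idx[d, ] %in% np)
}

#' Drug-specific microbe neighbor aggregation (microbe half)
#'
#' Exact mirror of [msdna()] with the sides swapped: entry j reads
#' `S_b(b_p, m_j)` when the j-th key microbe of `b_p`'s dictionary is
#' associated with `d_x` in the training associations.
#'
#' @param b_p microbe id or index
#' @param d_x drug id or index
#' @param dict_b microbe dictionaries
#' @param assoc_train training-fold `dmanet_assoc`
#' @param include_self as in [msdna()]
#' @return numeric vector of length `dict_b$L`
#' @export
dsmna <- function(b_p, d_x, dict_b, assoc_train, include_self = FALSE) {
  b <- .node_index(b_p, dict_b$ids, "microbe")
  d <- .node_index(d_x, assoc_train$drug_ids, "drug")
  e <- assoc_train$edges
  ms <- e$microbe[e$drug == d]
  if (!include_self) ms <- setdiff(ms, b)
  dict_b$key_sim[b, ] * (dict_b$key_idx[b, ] %in% ms)
}

#' Embed drug-microbe pairs as stacked bidirectional neighbor vectors
#'
#' Row per pair: `[msdna || dsmna]`, a matrix of shape (k, L_d + L_b).
#' Deterministic given its inputs.
#'
#' @param pairs data.frame/matrix with two columns (drug, microbe), ids or
#'   indices
#' @param dict_d,dict_b dictionaries from [build_dictionaries()]
#' @param assoc_train training-fold `dmanet_assoc`
#' @param include_self as in [msdna()]
#' @return numeric matrix with rownames `"<drug id>|<microbe id>"`
#' @export
embed_pairs <- function(pairs, dict_d, dict_b, assoc_train, include_self = FALSE) {
  pairs <- as.data.frame(pairs)
  g <- dict_d$L + dict_b$L
  if (nrow(pairs) == 0L) {
    return(matrix(numeric(), 0L, g))
  }
  di <- vapply(pairs[[1]], .node_index, 0L, dict_d$ids, "drug")
  bi <- vapply(pairs[[2]], .node_index, 0L, dict_b$ids, "microbe")
  A <- association_matrix(assoc_train)
  E <- matrix(0, nrow(pairs), g)
  # per-microbe / per-drug association index sets, computed once
  drugs_of <- lapply(seq_along(assoc_train$microbe_ids), function(b) which(A[, b] == 1L))
  microbes_of <- lapply(seq_along(assoc_train$drug_ids), function(d) which(A[d, ] == 1L))
  for (r in seq_len(nrow(pairs))) {
    d <- di[r]; b <- bi[r]
    np <- drugs_of[[b]]
    ms <- microbes_of[[d]]
    if (!include_self) { np <- np[np != d]; ms <- ms[ms != b] }
    E[r, seq_len(dict_d$L)] <-
      dict_d$key_sim[d, ] * (dict_d$key_idx[d, ] %in% np)
    E[r, dict_d$L + seq_len(dict_b$L)] <-
      dict_b$key_sim[b, ] * (dict_b$key_idx[b, ] %in% ms)
  }
  rownames(E) <- paste(dict_d$ids[di], dict_b$ids[bi], sep = "|")
  E
}
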