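# ---------------------------------------------------------------------------
# Drug similarity: plain and atom-contribution-weighted Tanimoto.
#
# The weighted variant follows the similarity-map idea: with d_i fixed as
# the reference, each atom k of the comparison drug d_j is deleted in turn,
# the remainder re-fingerprinted, and the absolute change in Tanimoto
# similarity becomes the atom's weight. Atom weights are summed over each
# on-bit's covered atoms, and the weighted Tanimoto
#   S_d = sum_q min(f_i^q, w_q f_j^q) / sum_q max(f_i^q, w_q f_j^q)
# rescores the pair with the comparison side weighted. The resulting matrix
# is directed (rows = reference drug).
# ---------------------------------------------------------------------------

.drug_mols <- function(drugs) {
  mols <- attr(drugs, "mols")
  if (is.null(mols)) {
    mols <- lapply(drugs$smiles, parse_smiles)
    names(mols) <- drugs$id
  }
  mols
}

#' Per-atom contribution weights of a comparison drug
#'
#' For each atom k of the comparison molecule, deletes the atom (with its
#' bonds), fingerprints the remainder, and records
#' `w_k = |S(ref, comp) - S(ref, comp minus atom k)|`. An empty remainder
#' has an empty fingerprint, so its similarity term is 0.
#'
#' @param reference,comparison `dmanet_mol` objects or SMILES strings
#' @param radius,nbits fingerprint parameters
#' @return list with `weights` (one per comparison atom, >= 0) and
#'   `base_similarity`
#' @export
atom_weights <- function(reference, comparison, radius = 2L, nbits = 1024L) {
  if (is.character(reference)) reference <- parse_smiles(reference)
  if (is.character(comparison)) comparison <- parse_smiles(comparison)
  fp_ref <- fingerprint(reference, radius, nbits)
  fp_cmp <- fingerprint(comparison, radius, nbits)
  base <- tanimoto(fp_ref, fp_cmp)
  w <- vapply(seq_len(comparison$n_atoms), function(k) {
    fpk <- fingerprint(delete_atom(comparison, k), radius, nbits)
    abs(base - tanimoto(fp_ref, fpk))
  }, numeric(1))
  list(weights = w, base_similarity = base)
}

#' Aggregate atom weights onto fingerprint bits
#'
#' The weight of on-bit q is the sum of the weights of all atoms covered by
#' the substructure environments that set q; off-bits weigh 0.
#'
#' @param comparison_fp `dmanet_fp` of the comparison drug
#' @param atom_w numeric vector of per-atom weights (1-based atom indexing
#'   consistent with the fingerprinted molecule)
#' @return numeric vector of length `nbits`
#' @export
bit_weights <- function(comparison_fp, atom_w) {
  stopifnot(inherits(comparison_fp, "dmanet_fp"))
  if (length(atom_w) != comparison_fp$n_atoms) {
    stop("atom weight vector does not match molecule atom count")
  }
  w <- numeric(comparison_fp$nbits)
  for (q in seq_along(comparison_fp$on_bits)) {
    w[comparison_fp$on_bits[q]] <- sum(atom_w[comparison_fp$bit_atoms[[q]]])
  }
  w
}

#' Weighted Tanimoto similarity
#'
#' `sum_q min(f_i^q, w_q f_j^q) / sum_q max(f_i^q, w_q f_j^q)` over the
#' folded bit positions; binary fingerprints, real weights on the comparison
#' side. Zero denominator gives 0. With unit weights this reduces exactly to
#' the plain Tanimoto coefficient.
#'
#' @param reference_fp,comparison_fp `dmanet_fp` objects of equal width
#' @param bit_w numeric weight per bit
#' @return similarity in \[0, 1\]
#' @export
weighted_tanimoto <- function(reference_fp, comparison_fp, bit_w) {
  if (reference_fp$nbits != comparison_fp$nbits ||
      length(bit_w) != reference_fp$nbits) {
    stop("fingerprint/weight length mismatch")
  }
  fi <- .as_bitvec(reference_fp)
  fj <- .as_bitvec(comparison_fp) * bit_w
  den <- sum(pmax(fi, fj))
  if (den == 0) 0 else sum(pmin(fi, fj)) / den
}

#' Pairwise drug similarity matrix
#'
#' `mode = "plain"` gives the symmetric Tanimoto matrix with unit diagonal.
#' `mode = "weighted"` computes the atom-contribution-weighted Tanimoto with
#' the row drug as reference; the matrix is directed and stored as such
#' (kind `"drug_weighted"`). Drugs may be given as a drug table
#' (data.frame with `id`, `smiles`, see [read_drug_table()]) or as a named
#' list of precomputed `dmanet_fp` fingerprints (in which case only plain
#' mode is available -- weighted mode needs the molecules).
#'
#' @param drugs drug table or named list of `dmanet_fp`
#' @param mode `"plain"` or `"weighted"`
#' @param radius,nbits fingerprint parameters
#' @return a `dmanet_sim`
#' @export
drug_similarity_matrix <- function(drugs, mode = c("plain", "weighted"),
                                   radius = 2L, nbits = 1024L) {
  mode <- match.arg(mode)
  if (is.list(drugs) && !is.data.frame(drugs) &&
      all(vapply(drugs, inherits, TRUE, "dmanet_fp"))) {
    if (mode == "weighted") stop("weighted mode requires molecules, not bare fingerprints")
    fps <- drugs
    ids <- names(fps)
    if (is.null(ids)) ids <- sprintf("drug%d", seq_along(fps))
  } else {
    mols <- .drug_mols(drugs)
    ids <- drugs$id
    fps <- lapply(seq_along(mols), function(i) {
      tryCatch(fingerprint(mols[[i]], radius, nbits),
               error = function(e) stop("fingerprinting failed for drug '",
                                        ids[i], "': ", conditionMessage(e)))
    })
  }
  m <- length(fps)
  S <- matrix(0, m, m)
  if (mode == "plain") {
    for (i in seq_len(m)) {
      S[i, i] <- 1
      for (j in seq_len(m)[-seq_len(i)]) {
        S[i, j] <- S[j, i] <- tanimoto(fps[[i]], fps[[j]])
      }
    }
    return(similarity_matrix(S, ids, "drug_plain"))
  }
  # weighted: per comparison drug j, precompute atom-deleted fingerprints
  deleted <- lapply(seq_len(m), function(j) {
    lapply(seq_len(mols[[j]]$n_atoms), function(k) {
      fingerprint(delete_atom(mols[[j]], k), radius, nbits)
    })
  })
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      base <- tanimoto(fps[[i]], fps[[j]])
      aw <- vapply(deleted[[j]], function(fpk) abs(base - tanimoto(fps[[i]], fpk)),
                   numeric(1))
      bw <- bit_weights(fps[[j]], aw)
      S[i, j] <- weighted_tanimoto(fps[[i]], fps[[j]], bw)
    }
  }
  similarity_matrix(S, ids, "drug_weighted")
}

#' Symmetrize a similarity matrix for neighbor ranking
#'
#' The weighted drug similarity is directed (it depends on which drug is the
#' reference); where a single scalar per unordered pair is needed (network
#' edge weights, sorted neighbor dictionaries) the mean of the two
#' directions is used, and the diagonal is pinned to 1 (a drug is maximally
#' similar to itself). Symmetric kinds pass through unchanged.
#'
#' @param sim a `dmanet_sim`
#' @return a symmetric `dmanet_sim`
#' @export
symmetrize_similarity <- function(sim) {
  stopifnot(inherits(sim, "dmanet_sim"))
  if (sim$kind != "drug_weighted") return(sim)
  v <- (sim$values + t(sim$values)) / 2
  diag(v) <- 1
  similarity_matrix(v, sim$ids, "drug_plain")
}

# --- co-association networks ----------------------------------------------

.coassociation_graph <- function(sim_values, ids, inc) {
  # inc: |side| x |other side| binary incidence; edge iff two rows share a column
  co <- inc %*% t(inc)
  adj <- co > 0
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- ids
  ends <- igraph::as_edgelist(g, names = FALSE)
  igraph::E(g)$weight <- sim_values[ends]
  g
}

#' Build the drug similarity network Net_d
#'
#' Undirected graph on drugs: an edge joins two drugs iff they associate
#' with at least one common microbe in the supplied (training-fold)
#' associations; the edge weight is the drug similarity (symmetrized if the
#' matrix is directed).
#'
#' @param sim drug `dmanet_sim`
#' @param assoc a `dmanet_assoc` restricted to training positives
#' @return an `igraph` graph with `weight` edge attribute
#' @export
build_drug_network <- function(sim, assoc) {
  stopifnot(identical(sim$ids, assoc$drug_ids))
  sym <- symmetrize_similarity(sim)
  .coassociation_graph(sym$values, sim$ids, association_matrix(assoc))
}

#' Build the microbe similarity network Net_b
#'
#' Mirror of [build_drug_network()]: microbes are joined iff they share an
#' associated drug; weights are microbe similarities.
#'
#' @param sim microbe `dmanet_sim`
#' @param assoc a `dmanet_assoc`
#' @return an `igraph` graph with `weight` edge attribute
#' @export
build_microbe_network <- function(sim, assoc) {
  stopifnot(identical(sim$ids, assoc$microbe_ids))
  .coassociation_graph(sim$values, sim$ids, t(association_matrix(assoc)))
}
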