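# ---------------------------------------------------------------------------
# Microbe similarity: normalized Smith-Waterman local alignment.
#
# Scoring is +1 match / -1 mismatch / linear gap penalty of 2 per gapped
# position; 'N' scores as a mismatch against everything. The pairwise score
# is normalized by the geometric mean of the self-scores:
#   S_b(A,B) = sw(A,B) / sqrt(sw(A,A) * sw(B,B))
# which is guaranteed to lie in [0, 1] because
# sw(A,B) <= match * min(|A|,|B|) = min(sw(A,A), sw(B,B)).
# ---------------------------------------------------------------------------

#' Alignment scoring parameters
#' @param match positive match score (default +1)
#' @param mismatch non-positive mismatch score (default -1)
#' @param gap positive per-position linear gap penalty (default 2)
#' @return list of validated scoring parameters
#' @export
alignment_params <- function(match = 1L, mismatch = -1L, gap = 2L) {
  match <- as.integer(match); mismatch <- as.integer(mismatch); gap <- as.integer(gap)
  if (match <= 0L) stop("match score must be positive")
  if (mismatch > 0L) stop("mismatch score must be <= 0")
  if (gap <= 0L) stop("gap penalty must be positive")
  list(match = match, mismatch = mismatch, gap = gap)
}

.check_seq <- function(x) {
  if (!is.character(x) || length(x) != 1L || !nzchar(x)) stop("empty sequence")
  x <- toupper(x)
  if (grepl("[^ACGTN]", x)) stop("sequence contains characters outside {A,C,G,T,N}")
  x
}

#' Smith-Waterman local alignment score
#'
#' Exact local-alignment dynamic program (no heuristic seeding): zero first
#' row/column, `H[i,j] = max(H[i-1,j-1] + s, H[i-1,j] - gap,
#' H[i,j-1] - gap, 0)`; the score is the maximum over all cells.
#'
#' @param a,b nucleotide sequences over A,C,G,T,N
#' @param params see [alignment_params()]
#' @return nonnegative integer score
#' @export
smith_waterman <- function(a, b, params = alignment_params()) {
  a <- .check_seq(a); b <- .check_seq(b)
  .sw_score_cpp(a, b, params$match, params$mismatch, params$gap)
}

# centered subsequence cap for genome-scale inputs
.cap_seq <- function(x, max_len) {
  n <- nchar(x)
  if (n <= max_len) return(x)
  start <- (n - max_len) %/% 2 + 1L
  substr(x, start, start + max_len - 1L)
}

#' Normalized local-alignment similarity between two microbes
#'
#' @param a,b sequences or single rows of a microbe table
#' @param params see [alignment_params()]
#' @param max_seq_len sequences longer than this are replaced by their
#'   centered subsequence of this length (runtime cap; default 50000)
#' @return similarity in \[0, 1\]
#' @export
microbe_similarity <- function(a, b, params = alignment_params(),
                               max_seq_len = 50000L) {
  if (is.data.frame(a)) a <- a$sequence
  if (is.data.frame(b)) b <- b$sequence
  a <- .cap_seq(.check_seq(a), max_seq_len)
  b <- .cap_seq(.check_seq(b), max_seq_len)
  saa <- .sw_score_cpp(a, a, params$match, params$mismatch, params$gap)
  sbb <- .sw_score_cpp(b, b, params$match, params$mismatch, params$gap)
  if (saa == 0L || sbb == 0L) return(0)
  .sw_score_cpp(a, b, params$match, params$mismatch, params$gap) / sqrt(saa * sbb)
}

#' Pairwise microbe similarity matrix
#'
#' Symmetric with unit diagonal. Self-scores are computed, not assumed equal
#' to sequence length, so non-default scoring parameters stay correct (an
#' all-N sequence, whose self-score is 0, maps to similarity 0 off the
#' diagonal and 1 on it).
#'
#' @param microbes data.frame with `id`, `sequence`
#' @param params see [alignment_params()]
#' @param max_seq_len runtime cap, see [microbe_similarity()]
#' @return a `dmanet_sim` of kind `"microbe"`
#' @export
microbe_similarity_matrix <- function(microbes, params = alignment_params(),
                                      max_seq_len = 50000L) {
  seqs <- vapply(microbes$sequence, function(s) .cap_seq(.check_seq(s), max_seq_len), "")
  n <- length(seqs)
  self <- vapply(seqs, function(s)
    .sw_score_cpp(s, s, params$match, params$mismatch, params$gap), numeric(1))
  S <- diag(1, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)[-seq_len(i)]) {
      v <- if (self[i] == 0 || self[j] == 0) 0 else
        .sw_score_cpp(seqs[i], seqs[j], params$match, params$mismatch, params$gap) /
        sqrt(self[i] * self[j])
      S[i, j] <- S[j, i] <- v
    }
  }
  similarity_matrix(S, microbes$id, "microbe")
}
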