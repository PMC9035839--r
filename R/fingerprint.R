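# ---------------------------------------------------------------------------
# Functional-class circular fingerprints.
#
# Morgan-style iteration seeded with pharmacophoric atom roles (donor,
# acceptor, cation, anion, aromatic, halogen) rather than element identity,
# folded onto a fixed-width binary vector.  Alongside the bit vector the
# fingerprint keeps, for every on-bit, the union of atom indices covered by
# the substructure environments that set the bit -- the map the
# atom-contribution similarity weighting consumes.
# ---------------------------------------------------------------------------

.hash_ints <- function(xs) {
  # deterministic 31-bit polynomial hash; doubles stay exact (< 2^53)
  h <- 17
  for (x in xs) h <- (h * 31 + (x %% 2147483647)) %% 2147483647
  h
}

.atom_invariants <- function(mol) {
  donor    <- mol$elem %in% c("N", "O") & mol$nH > 0L
  acceptor <- mol$elem %in% c("N", "O") & mol$charge <= 0L
  cation   <- mol$charge > 0L
  anion    <- mol$charge < 0L
  halogen  <- mol$elem %in% c("F", "Cl", "Br", "I")
  as.numeric(donor) + 2 * as.numeric(acceptor) + 4 * as.numeric(cation) +
    8 * as.numeric(anion) + 16 * as.numeric(mol$aromatic) +
    32 * as.numeric(halogen)
}

#' Circular functional-class fingerprint
#'
#' Computes a folded binary fingerprint of `nbits` bits by iterating
#' neighbourhood hashing `radius` times over pharmacophoric atom-role
#' invariants, together with a bit-to-atom map: for every on-bit, the set of
#' atom indices contained in at least one substructure environment hashed to
#' that bit (an environment of radius r around atom a covers a and all
#' atoms within r bonds).
#'
#' @param mol a `dmanet_mol` (see [parse_smiles()]), or a SMILES string
#' @param radius maximum environment radius in bonds (default 2)
#' @param nbits folded fingerprint width (default 1024)
#' @return an object of class `dmanet_fp`: list with `nbits`, `on_bits`
#'   (sorted 1-based bit indices), `bit_atoms` (named list: bit index ->
#'   integer atom indices), `n_atoms`
#' @export
fingerprint <- function(mol, radius = 2L, nbits = 1024L) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  stopifnot(inherits(mol, "dmanet_mol"))
  n <- mol$n_atoms
  if (n == 0L) {
    return(structure(list(nbits = as.integer(nbits), on_bits = integer(),
                          bit_atoms = list(), n_atoms = 0L),
                     class = "dmanet_fp"))
  }
  adj <- .adjacency_list(mol)
  inv <- .atom_invariants(mol)

  # atoms within distance r of each atom, grown incrementally
  cover <- as.list(seq_len(n))
  bit_atoms <- new.env(parent = emptyenv())
  note <- function(bit, atoms) {
    key <- as.character(bit)
    cur <- bit_atoms[[key]]
    bit_atoms[[key]] <- if (is.null(cur)) atoms else union(cur, atoms)
  }
  for (a in seq_len(n)) note(.hash_ints(c(0, inv[a])) %% nbits + 1L, a)

  for (r in seq_len(radius)) {
    new_inv <- numeric(n)
    for (a in seq_len(n)) {
      nb <- adj[[a]]
      if (is.null(nb)) {
        new_inv[a] <- .hash_ints(c(r, inv[a]))
      } else {
        key <- order(nb[, 2], inv[nb[, 1]], nb[, 1])
        parts <- as.vector(t(cbind(nb[key, 2], inv[nb[key, 1]])))
        new_inv[a] <- .hash_ints(c(r, inv[a], parts))
      }
      grown <- unique(c(cover[[a]],
                        if (!is.null(nb)) unlist(cover[nb[, 1]], use.names = FALSE)))
      cover[[a]] <- grown
    }
    inv <- new_inv
    for (a in seq_len(n)) note(.hash_ints(c(0, inv[a])) %% nbits + 1L, cover[[a]])
  }

  bits <- sort(as.integer(ls(bit_atoms)))
  structure(list(
    nbits = as.integer(nbits),
    on_bits = bits,
    bit_atoms = mget(as.character(bits), envir = bit_atoms),
    n_atoms = n
  ), class = "dmanet_fp")
}

#' @export
print.dmanet_fp <- function(x, ...) {
  cat(sprintf("<fingerprint: %d/%d bits on, %d atoms>\n",
              length(x$on_bits), x$nbits, x$n_atoms))
  invisible(x)
}

# construct a dmanet_fp directly from on-bit indices (synthetic random-bits
# mode; no atom map)
.fp_from_bits <- function(on_bits, nbits = 1024L) {
  structure(list(nbits = as.integer(nbits),
                 on_bits = sort(unique(as.integer(on_bits))),
                 bit_atoms = list(), n_atoms = 0L),
            class = "dmanet_fp")
}

.as_bitvec <- function(fp) {
  v <- numeric(fp$nbits); v[fp$on_bits] <- 1; v
}

#' Tanimoto coefficient
#'
#' For binary fingerprints a and b this is a.b / (a.a + b.b - a.b), i.e.
#' |A∩B| / |A∪B| on the on-bit sets. Two all-zero vectors score 0 by
#' convention.
#'
#' @param fa,fb `dmanet_fp` objects or equal-length numeric 0/1 vectors
#' @return similarity in \[0, 1\]
#' @export
tanimoto <- function(fa, fb) {
  if (inherits(fa, "dmanet_fp") && inherits(fb, "dmanet_fp")) {
    if (fa$nbits != fb$nbits) stop("fingerprint length mismatch")
    ab <- length(intersect(fa$on_bits, fb$on_bits))
    un <- length(fa$on_bits) + length(fb$on_bits) - ab
    return(if (un == 0) 0 else ab / un)
  }
  if (length(fa) != length(fb)) stop("fingerprint length mismatch")
  ab <- sum(fa * fb)
  den <- sum(fa * fa) + sum(fb * fb) - ab
  if (den == 0) 0 else ab / den
}
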