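#' @useDynLib dmanet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Minimal molecular graph machinery.
#
# No R cheminformatics toolkit is assumed: a molecule is a plain graph of
# typed atoms and bonds, built either from a SMILES string or a V2000
# molblock.  This supports exactly what the fingerprinting and
# atom-deletion similarity weighting need: element, formal charge,
# aromaticity, implicit hydrogen count, and connectivity.
# ---------------------------------------------------------------------------

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

# allowed valence states; smallest state accommodating the bonded degree wins
.VALENCES <- list(
  B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L), S = c(2L, 4L, 6L),
  F = 1L, Cl = 1L, Br = 1L, I = 1L, H = 1L
)

.new_mol <- function(elem, charge, aromatic, nH_explicit, bonds) {
  structure(list(
    n_atoms = length(elem),
    elem = elem, charge = as.integer(charge), aromatic = aromatic,
    nH = nH_explicit,              # filled by .assign_implicit_h
    nH_explicit = nH_explicit,     # NA where implicit
    bonds = bonds                  # data.frame(a1, a2, order, arom)
  ), class = "dmanet_mol")
}

#' @export
print.dmanet_mol <- function(x, ...) {
  cat(sprintf("<molecule: %d atoms, %d bonds>\n", x$n_atoms, nrow(x$bonds)))
  invisible(x)
}

# degree in bonded-valence units: aromatic bonds count 1 each plus one
# shared pi contribution per aromatic atom
.bonded_degree <- function(mol) {
  used <- numeric(mol$n_atoms)
  b <- mol$bonds
  if (nrow(b)) {
    ord <- ifelse(b$arom, 1, b$order)
    for (r in seq_len(nrow(b))) {
      used[b$a1[r]] <- used[b$a1[r]] + ord[r]
      used[b$a2[r]] <- used[b$a2[r]] + ord[r]
    }
  }
  used + as.numeric(mol$aromatic)
}

.assign_implicit_h <- function(mol) {
  used <- .bonded_degree(mol)
  nH <- integer(mol$n_atoms)
  for (a in seq_len(mol$n_atoms)) {
    if (!is.na(mol$nH_explicit[a])) { nH[a] <- mol$nH_explicit[a]; next }
    vs <- .VALENCES[[mol$elem[a]]]
    if (is.null(vs)) { nH[a] <- 0L; next }
    vs <- vs + mol$charge[a]
    ok <- vs[vs >= used[a]]
    nH[a] <- if (length(ok)) as.integer(ok[1] - used[a]) else 0L
  }
  mol$nH <- nH
  mol
}

# --- SMILES ----------------------------------------------------------------

#' Parse a SMILES string into a molecular graph
#'
#' Supports the organic subset, bracket atoms with charge/H-count/isotope,
#' aromatic lower-case atoms, branches, ring closures (including `%nn`),
#' bond symbols `- = # :` (directional `/` and `\` read as single bonds),
#' and dot-disconnected components. Stereochemistry is parsed but ignored.
#' Implicit hydrogens follow standard valence rules with charge adjustment.
#'
#' @param smiles a single SMILES string
#' @return a `dmanet_mol` object
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  s <- trimws(smiles)
  if (!nzchar(s)) stop("empty SMILES")

  elem <- character(); charge <- integer(); arom <- logical(); nHx <- integer()
  b_a1 <- integer(); b_a2 <- integer(); b_ord <- numeric(); b_arom <- logical()

  prev <- NA_integer_
  stack <- integer()
  pending <- NA_character_          # explicit bond symbol awaiting next atom
  rings <- list()                   # closure label -> list(atom, bond)

  add_atom <- function(el, ar, ch, nh) {
    elem[[length(elem) + 1L]] <<- el
    charge[[length(charge) + 1L]] <<- ch
    arom[[length(arom) + 1L]] <<- ar
    nHx[[length(nHx) + 1L]] <<- nh
    length(elem)
  }
  add_bond <- function(a1, a2, sym) {
    if (is.na(a1)) return(invisible())
    aromatic_bond <- FALSE
    if (is.na(sym)) {
      if (arom[a1] && arom[a2]) aromatic_bond <- TRUE
      ord <- 1
    } else {
      ord <- switch(sym, "-" = 1, "/" = 1, "\\" = 1, "=" = 2, "#" = 3, ":" = 1,
                    stop("unsupported bond symbol: ", sym))
      if (sym == ":") aromatic_bond <- TRUE
    }
    b_a1[[length(b_a1) + 1L]] <<- a1
    b_a2[[length(b_a2) + 1L]] <<- a2
    b_ord[[length(b_ord) + 1L]] <<- ord
    b_arom[[length(b_arom) + 1L]] <<- aromatic_bond
  }
  close_ring <- function(label, atom, sym) {
    if (!is.null(rings[[label]])) {
      open <- rings[[label]]
      use <- if (!is.na(open$bond)) open$bond else sym
      add_bond(open$atom, atom, use)
      rings[[label]] <<- NULL
    } else {
      rings[[label]] <<- list(atom = atom, bond = sym)
    }
  }

  i <- 1L; n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(s, i, n), fixed = TRUE)
      if (j < 0) stop("unclosed bracket atom in SMILES: ", smiles)
      body <- substr(s, i + 1L, i + j - 2L)
      m <- regmatches(body, regexec(
        "^([0-9]*)(\\*|[A-Z][a-z]?|[a-z][a-z]?)(@TH[12]|@{1,2})?(H[0-9]*)?([+-][0-9]*|[+]+|[-]+)?(:[0-9]+)?$",
        body))[[1]]
      if (!length(m)) stop("cannot parse bracket atom [", body, "] in ", smiles)
      sym <- m[3]
      ar <- sym %in% c("b", "c", "n", "o", "p", "s", "se", "as")
      el <- if (ar) paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, 10)) else sym
      hh <- m[5]
      nh <- if (!nzchar(hh)) 0L else if (hh == "H") 1L else as.integer(substr(hh, 2, 10))
      cs <- m[6]
      chg <- 0L
      if (nzchar(cs)) {
        if (grepl("^[+-][0-9]+$", cs)) {
          chg <- as.integer(cs)
        } else {
          chg <- nchar(cs) * (if (substr(cs, 1, 1) == "+") 1L else -1L)
        }
      }
      a <- add_atom(el, ar, chg, nh)
      add_bond(prev, a, pending); pending <- NA_character_
      prev <- a
      i <- i + j
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending <- ch; i <- i + 1L
    } else if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) stop("unbalanced ')' in SMILES: ", smiles)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") {
      prev <- NA_integer_; pending <- NA_character_; i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch, prev, pending); pending <- NA_character_; i <- i + 1L
    } else if (ch == "%") {
      lab <- substr(s, i + 1L, i + 2L)
      if (!grepl("^[0-9]{2}$", lab)) stop("bad ring closure %", lab)
      close_ring(lab, prev, pending); pending <- NA_character_; i <- i + 3L
    } else {
      two <- substr(s, i, i + 1L)
      if (two %in% c("Cl", "Br")) {
        a <- add_atom(two, FALSE, 0L, NA_integer_)
        add_bond(prev, a, pending); pending <- NA_character_; prev <- a
        i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        a <- add_atom(ch, FALSE, 0L, NA_integer_)
        add_bond(prev, a, pending); pending <- NA_character_; prev <- a
        i <- i + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        a <- add_atom(toupper(ch), TRUE, 0L, NA_integer_)
        add_bond(prev, a, pending); pending <- NA_character_; prev <- a
        i <- i + 1L
      } else {
        stop("unexpected character '", ch, "' in SMILES: ", smiles)
      }
    }
  }
  if (length(Filter(Negate(is.null), rings))) {
    stop("unclosed ring bond in SMILES: ", smiles)
  }
  bonds <- data.frame(a1 = b_a1, a2 = b_a2, order = b_ord, arom = b_arom)
  .assign_implicit_h(.new_mol(elem, charge, arom, nHx, bonds))
}

# --- SDF (V2000) -----------------------------------------------------------

# Parse the concatenated molblocks of an SDF file. Returns list of
# list(id =, mol =); id is the first title line (or "mol<k>").
.parse_sdf <- function(lines) {
  recs <- split(lines, cumsum(c(0, head(lines, -1) == "$$$$")))
  out <- list()
  for (rec in recs) {
    rec <- rec[rec != "$$$$"]
    if (!any(nzchar(trimws(rec)))) next
    id <- trimws(rec[1])
    counts <- rec[4]
    na <- as.integer(substr(counts, 1, 3))
    nb <- as.integer(substr(counts, 4, 6))
    if (is.na(na) || is.na(nb)) stop("bad V2000 counts line: '", counts, "'")
    atom_lines <- rec[5:(4 + na)]
    elem <- trimws(substr(atom_lines, 32, 34))
    charge <- integer(na); arom <- logical(na)
    b_a1 <- integer(); b_a2 <- integer(); b_ord <- numeric(); b_arom <- logical()
    if (nb > 0) {
      bond_lines <- rec[(5 + na):(4 + na + nb)]
      b_a1 <- as.integer(substr(bond_lines, 1, 3))
      b_a2 <- as.integer(substr(bond_lines, 4, 6))
      code <- as.integer(substr(bond_lines, 7, 9))
      b_arom <- code == 4L
      b_ord <- ifelse(b_arom, 1, code)
    }
    for (ln in grep("^M  CHG", rec, value = TRUE)) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
      k <- f[1]
      for (t in seq_len(k)) charge[f[2 * t]] <- f[2 * t + 1]
    }
    if (length(b_a1)) {
      arom[unique(c(b_a1[b_arom], b_a2[b_arom]))] <- TRUE
    }
    bonds <- data.frame(a1 = b_a1, a2 = b_a2, order = b_ord, arom = b_arom)
    mol <- .assign_implicit_h(.new_mol(elem, charge, arom,
                                       rep(NA_integer_, na), bonds))
    out[[length(out) + 1L]] <- list(id = if (nzchar(id)) id else
      sprintf("mol%d", length(out) + 1L), mol = mol)
  }
  out
}

# --- graph edits -----------------------------------------------------------

#' Delete one atom from a molecule
#'
#' Removes atom `k` and its incident bonds, renumbering the remaining atoms
#' contiguously. Hydrogen counts of the former neighbours are kept as they
#' were (open valences are left unfilled); the result may be disconnected or
#' empty.
#'
#' @param mol a `dmanet_mol`
#' @param k atom index to delete (1-based)
#' @return a `dmanet_mol` with `n_atoms - 1` atoms
#' @export
delete_atom <- function(mol, k) {
  stopifnot(inherits(mol, "dmanet_mol"), k >= 1L, k <= mol$n_atoms)
  keep <- setdiff(seq_len(mol$n_atoms), k)
  remap <- integer(mol$n_atoms); remap[keep] <- seq_along(keep)
  b <- mol$bonds
  b <- b[b$a1 != k & b$a2 != k, , drop = FALSE]
  b$a1 <- remap[b$a1]; b$a2 <- remap[b$a2]
  rownames(b) <- NULL
  m <- .new_mol(mol$elem[keep], mol$charge[keep], mol$aromatic[keep],
                mol$nH_explicit[keep], b)
  m$nH <- mol$nH[keep]
  m
}

.adjacency_list <- function(mol) {
  adj <- vector("list", mol$n_atoms)
  b <- mol$bonds
  if (nrow(b)) for (r in seq_len(nrow(b))) {
    code <- if (b$arom[r]) 5 else b$order[r]
    adj[[b$a1[r]]] <- rbind(adj[[b$a1[r]]], c(b$a2[r], code))
    adj[[b$a2[r]]] <- rbind(adj[[b$a2[r]]], c(b$a1[r], code))
  }
  adj
}
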