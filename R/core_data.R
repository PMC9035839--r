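# ---------------------------------------------------------------------------
# Domain containers and file I/O.
#
# Ids are opaque strings; every container carries an ordered id registry and
# that registry order is the single source of index truth. All files are
# id-keyed plain text (TSV / FASTA / YAML), so internal indexing never leaks.
# ---------------------------------------------------------------------------

#' Read a drug table
#'
#' `tsv` format is two tab-separated columns `id<TAB>smiles` (a header line
#' `id\tsmiles` is tolerated); `sdf` is a concatenated V2000 SD file whose
#' record title lines carry the ids. Every molecule is parsed at load time;
#' rows that fail to parse are collected into a rejection report attached as
#' `attr(x, "rejections")` rather than silently dropped.
#'
#' @param path file path
#' @param format `"tsv"` or `"sdf"`
#' @return data.frame with columns `id`, `smiles` (`smiles` is `NA` for sdf
#'   input) and attributes `mols` (named list of parsed molecules) and
#'   `rejections` (data.frame id/reason)
#' @export
read_drug_table <- function(path, format = c("tsv", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("drug table not found: ", path)
  rej <- data.frame(id = character(), reason = character())
  if (format == "tsv") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) && grepl("^id\\t", lines[1], ignore.case = TRUE)) {
      lines <- lines[-1]
    }
    if (!length(lines)) {
      warning("empty drug table: ", path)
      out <- data.frame(id = character(), smiles = character())
      attr(out, "mols") <- list(); attr(out, "rejections") <- rej
      return(out)
    }
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- vapply(parts, length, 1L) < 2L
    if (any(bad)) stop("malformed drug table row(s): ",
                       paste(which(bad), collapse = ", "))
    ids <- vapply(parts, `[[`, "", 1L)
    smiles <- vapply(parts, `[[`, "", 2L)
    dup <- ids[duplicated(ids)]
    if (length(dup)) stop("duplicate drug id(s): ", paste(unique(dup), collapse = ", "))
    mols <- vector("list", length(ids)); names(mols) <- ids
    keep <- logical(length(ids))
    for (i in seq_along(ids)) {
      m <- tryCatch(parse_smiles(smiles[i]), error = function(e) e)
      if (inherits(m, "error")) {
        rej <- rbind(rej, data.frame(id = ids[i], reason = conditionMessage(m)))
      } else {
        mols[[ids[i]]] <- m; keep[i] <- TRUE
      }
    }
    out <- data.frame(id = ids[keep], smiles = smiles[keep])
    attr(out, "mols") <- mols[out$id]
  } else {
    recs <- .parse_sdf(readLines(path, warn = FALSE))
    if (!length(recs)) warning("empty SDF: ", path)
    ids <- vapply(recs, `[[`, "", "id")
    dup <- ids[duplicated(ids)]
    if (length(dup)) stop("duplicate drug id(s): ", paste(unique(dup), collapse = ", "))
    out <- data.frame(id = ids, smiles = NA_character_)
    mols <- lapply(recs, `[[`, "mol"); names(mols) <- ids
    attr(out, "mols") <- mols
  }
  attr(out, "rejections") <- rej
  out
}

#' Write a drug table (TSV)
#' @param drugs data.frame with `id`, `smiles`
#' @param path output path
#' @export
write_drug_table <- function(drugs, path) {
  writeLines(paste(drugs$id, drugs$smiles, sep = "\t"), path)
  invisible(path)
}

#' Read microbe sequences from FASTA
#'
#' The id is the record header up to the first whitespace. Sequences are
#' uppercased; IUPAC ambiguity codes other than A/C/G/T are mapped to N
#' (which scores as a mismatch in alignment) with a warning.
#'
#' @param path FASTA path
#' @return data.frame with columns `id`, `sequence`
#' @export
read_microbe_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate microbe id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) stop("empty sequence for id(s): ",
                               paste(ids[!nzchar(seqs)], collapse = ", "))
  odd <- grepl("[^ACGTN]", seqs)
  if (any(odd)) {
    warning("non-ACGTN characters mapped to N in: ",
            paste(ids[odd], collapse = ", "))
    seqs <- gsub("[^ACGTN]", "N", seqs)
  }
  data.frame(id = ids, sequence = unname(seqs))
}

#' Write microbe sequences to FASTA
#' @param microbes data.frame with `id`, `sequence`
#' @param path output path
#' @param width line wrap width
#' @export
write_microbe_fasta <- function(microbes, path, width = 70L) {
  set <- Biostrings::BStringSet(microbes$sequence)
  names(set) <- microbes$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# --- associations ----------------------------------------------------------

#' Construct a bipartite association set
#'
#' @param drug_ids ordered drug id registry (size m)
#' @param microbe_ids ordered microbe id registry (size n)
#' @param edges data.frame/matrix with two columns of 1-based indices
#'   (drug index, microbe index); duplicates are removed
#' @return object of class `dmanet_assoc`
#' @export
associations <- function(drug_ids, microbe_ids, edges) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2 && nrow(edges) > 0) stop("edges needs two columns")
  if (nrow(edges) == 0) {
    edges <- data.frame(drug = integer(), microbe = integer())
  } else {
    edges <- data.frame(drug = as.integer(edges[[1]]),
                        microbe = as.integer(edges[[2]]))
  }
  if (nrow(edges)) {
    stopifnot(all(edges$drug >= 1L), all(edges$drug <= length(drug_ids)),
              all(edges$microbe >= 1L), all(edges$microbe <= length(microbe_ids)))
    edges <- unique(edges)
    edges <- edges[order(edges$drug, edges$microbe), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(drug_ids = as.character(drug_ids),
                 microbe_ids = as.character(microbe_ids),
                 edges = edges),
            class = "dmanet_assoc")
}

#' @export
print.dmanet_assoc <- function(x, ...) {
  cat(sprintf("<associations: %d drugs x %d microbes, %d edges (universe %d)>\n",
              length(x$drug_ids), length(x$microbe_ids), nrow(x$edges),
              length(x$drug_ids) * length(x$microbe_ids)))
  invisible(x)
}

#' Binary association matrix
#' @param assoc a `dmanet_assoc`
#' @return m x n 0/1 matrix with id dimnames
#' @export
association_matrix <- function(assoc) {
  A <- matrix(0L, length(assoc$drug_ids), length(assoc$microbe_ids),
              dimnames = list(assoc$drug_ids, assoc$microbe_ids))
  if (nrow(assoc$edges)) A[cbind(assoc$edges$drug, assoc$edges$microbe)] <- 1L
  A
}

#' Load associations from a two-column TSV of (drug id, microbe id)
#'
#' Duplicate rows are deduplicated. Rows with ids missing from the
#' registries follow `unknown`: `"skip"` drops them with a warning (default),
#' `"error"` aborts.
#'
#' @param path TSV path
#' @param drug_ids,microbe_ids id registries
#' @param unknown `"skip"` or `"error"`
#' @return a `dmanet_assoc`
#' @export
load_associations <- function(path, drug_ids, microbe_ids,
                              unknown = c("skip", "error")) {
  unknown <- match.arg(unknown)
  if (!file.exists(path)) stop("association table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty association table: ", path)
    return(associations(drug_ids, microbe_ids,
                        data.frame(drug = integer(), microbe = integer())))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 2L
  if (any(bad)) stop("malformed association row(s): ",
                     paste(which(bad), collapse = ", "))
  d <- vapply(parts, `[[`, "", 1L)
  b <- vapply(parts, `[[`, "", 2L)
  di <- match(d, drug_ids); bi <- match(b, microbe_ids)
  miss <- is.na(di) | is.na(bi)
  if (any(miss)) {
    msg <- paste0(d[miss], "\t", b[miss], collapse = "; ")
    if (unknown == "error") stop("unknown id(s) in association table: ", msg)
    warning(sum(miss), " association row(s) with unknown ids skipped: ", msg)
  }
  out <- associations(drug_ids, microbe_ids,
                      data.frame(drug = di[!miss], microbe = bi[!miss]))
  message(sprintf("loaded associations: m=%d drugs, n=%d microbes, |E|=%d",
                  length(drug_ids), length(microbe_ids), nrow(out$edges)))
  out
}

#' Write associations to a two-column TSV of ids
#' @param assoc a `dmanet_assoc`
#' @param path output path
#' @export
write_associations <- function(assoc, path) {
  writeLines(paste(assoc$drug_ids[assoc$edges$drug],
                   assoc$microbe_ids[assoc$edges$microbe], sep = "\t"), path)
  invisible(path)
}

# --- similarity matrices ---------------------------------------------------

#' Construct a similarity matrix container
#'
#' @param values square numeric matrix with entries in \[0, 1\]
#' @param ids id registry (rows == columns)
#' @param kind `"drug_plain"`, `"drug_weighted"` (directed: rows are the
#'   reference drug) or `"microbe"`
#' @return object of class `dmanet_sim`
#' @export
similarity_matrix <- function(values, ids, kind = c("drug_plain", "drug_weighted", "microbe")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop(kind, " similarity matrix must be square")
  if (nrow(values) != length(ids)) stop("id registry does not match matrix dimension")
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1 + 1e-12)) {
    stop("similarity values must lie in [0, 1]")
  }
  if (kind %in% c("drug_plain", "microbe")) {
    if (any(abs(diag(values) - 1) > 1e-9)) stop("unit diagonal required for kind ", kind)
    if (kind == "microbe" && any(abs(values - t(values)) > 1e-9)) {
      stop("microbe similarity must be symmetric")
    }
  }
  dimnames(values) <- list(ids, ids)
  structure(list(ids = as.character(ids), values = values, kind = kind),
            class = "dmanet_sim")
}

#' @export
print.dmanet_sim <- function(x, ...) {
  cat(sprintf("<similarity matrix: %s, %d ids>\n", x$kind, length(x$ids)))
  invisible(x)
}

#' Write / read a similarity matrix as TSV with id header row and column
#'
#' The round trip is lossless: values are written with full precision
#' (`%.17g`).
#'
#' @param sim a `dmanet_sim`
#' @param path file path
#' @export
write_similarity_matrix <- function(sim, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(c(sim$kind, sim$ids), collapse = "\t"), con)
  for (i in seq_along(sim$ids)) {
    writeLines(paste(c(sim$ids[i], sprintf("%.17g", sim$values[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_similarity_matrix
#' @export
read_similarity_matrix <- function(path) {
  if (!file.exists(path)) stop("similarity matrix not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  kind <- hdr[1]; ids <- hdr[-1]
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  if (length(body) != length(ids)) stop("non-square similarity matrix in ", path)
  row_ids <- vapply(body, `[[`, "", 1L)
  if (!identical(row_ids, ids)) stop("row/column id registry mismatch in ", path)
  vals <- t(vapply(body, function(p) as.numeric(p[-1]), numeric(length(ids))))
  if (length(ids) == 1L) vals <- matrix(vals, 1, 1)
  similarity_matrix(vals, ids, kind = kind)
}

# --- config ----------------------------------------------------------------

#' Read a YAML configuration file
#' @param path YAML path
#' @return named list
#' @export
read_config <- function(path) yaml::read_yaml(path)
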