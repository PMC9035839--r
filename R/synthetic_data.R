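# ---------------------------------------------------------------------------
# Planted-cluster synthetic data.
#
# Emulates the statistical structure the predictor exploits: drugs come in
# structural families (high within-family fingerprint similarity), microbes
# in sequence clusters, and each drug family preferentially associates with
# its matched microbe cluster -- so a positive pair's drug finds its
# nearest neighbors among the other drugs of the same microbe. Everything
# is generated from one seeded RNG stream and is bitwise reproducible.
# ---------------------------------------------------------------------------

#' Synthetic dataset configuration
#'
#' Defaults give 4 drug clusters x 10 drugs and 3 microbe clusters x 6
#' microbes; a drug cluster associates with its matched microbe cluster
#' with probability 0.8 and with the others with probability 0.02, and 1%
#' of all pair labels are flipped as noise.
#'
#' @param n_drug_clusters,drugs_per_cluster drug-side layout
#' @param n_microbe_clusters,microbes_per_cluster microbe-side layout
#' @param fingerprint_mode `"random_bits"` (direct fingerprints, no
#'   chemistry needed) or `"smiles_library"` (drug families drawn from the
#'   packaged homologous-series SMILES library)
#' @param n_on_bits prototype on-bit count in random_bits mode
#' @param bit_flip_rate per-bit within-cluster flip probability
#' @param seq_len microbe prototype sequence length
#' @param seq_mutation_rate per-base within-cluster substitution rate
#' @param assoc_within_prob,assoc_cross_prob association probabilities for
#'   matched vs unmatched cluster pairs (within > cross for learnability)
#' @param label_noise per-cell label flip probability
#' @param seed RNG seed
#' @return list of class `dmanet_synth_config`
#' @export
synth_config <- function(n_drug_clusters = 4L, drugs_per_cluster = 10L,
                         n_microbe_clusters = 3L, microbes_per_cluster = 6L,
                         fingerprint_mode = c("random_bits", "smiles_library"),
                         n_on_bits = 60L, bit_flip_rate = 0.01,
                         seq_len = 240L, seq_mutation_rate = 0.05,
                         assoc_within_prob = 0.8, assoc_cross_prob = 0.02,
                         label_noise = 0.01, seed = 0L) {
  fingerprint_mode <- match.arg(fingerprint_mode)
  probs <- c(bit_flip_rate, seq_mutation_rate, assoc_within_prob,
             assoc_cross_prob, label_noise)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (assoc_within_prob <= assoc_cross_prob) {
    stop("assoc_within_prob must exceed assoc_cross_prob for a learnable instance")
  }
  structure(as.list(environment()), class = "dmanet_synth_config")
}

.random_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len, TRUE),
                                   collapse = "")

.mutate_seq <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(ch)) < rate
  if (any(hit)) {
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  }
  paste(ch, collapse = "")
}

.smiles_library <- function() {
  path <- system.file("extdata", "smiles_library.tsv", package = "dmanet")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Generate a planted-cluster synthetic dataset
#'
#' Drug clusters are a prototype fingerprint (or a homologous SMILES
#' family) plus per-member bit flips; microbe clusters a random prototype
#' sequence plus point substitutions; drug cluster c is matched to microbe
#' cluster `((c-1) mod n_microbe_clusters) + 1` and associates with its
#' members with `assoc_within_prob`, with all others with
#' `assoc_cross_prob`; finally each cell's label flips with probability
#' `label_noise`.
#'
#' @param config a [synth_config()]
#' @return list of class `dmanet_synth`: `drugs` (data.frame or NULL),
#'   `fingerprints` (named list of `dmanet_fp`, always present),
#'   `microbes`, `assoc`, `drug_clusters`, `microbe_clusters`, `config`
#' @export
generate_synthetic <- function(config = synth_config()) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  m <- config$n_drug_clusters * config$drugs_per_cluster
  n <- config$n_microbe_clusters * config$microbes_per_cluster
  drug_ids <- sprintf("d%03d", seq_len(m))
  microbe_ids <- sprintf("b%03d", seq_len(n))
  drug_clusters <- rep(seq_len(config$n_drug_clusters),
                       each = config$drugs_per_cluster)
  microbe_clusters <- rep(seq_len(config$n_microbe_clusters),
                          each = config$microbes_per_cluster)

  drugs <- NULL
  if (config$fingerprint_mode == "random_bits") {
    fps <- vector("list", m); names(fps) <- drug_ids
    for (c_i in seq_len(config$n_drug_clusters)) {
      proto <- logical(1024L)
      proto[sample.int(1024L, config$n_on_bits)] <- TRUE
      for (k in which(drug_clusters == c_i)) {
        flip <- stats::runif(1024L) < config$bit_flip_rate
        fps[[k]] <- .fp_from_bits(which(xor(proto, flip)))
      }
    }
  } else {
    lib <- .smiles_library()
    fams <- unique(lib$family)
    if (config$n_drug_clusters > length(fams)) {
      stop("smiles library has only ", length(fams), " families")
    }
    smiles <- character(m)
    for (c_i in seq_len(config$n_drug_clusters)) {
      fam <- lib$smiles[lib$family == fams[c_i]]
      members <- which(drug_clusters == c_i)
      smiles[members] <- rep_len(fam, length(members))
    }
    drugs <- data.frame(id = drug_ids, smiles = smiles)
    fps <- lapply(smiles, function(s) fingerprint(parse_smiles(s)))
    names(fps) <- drug_ids
  }

  microbes <- data.frame(id = microbe_ids, sequence = character(n))
  for (c_j in seq_len(config$n_microbe_clusters)) {
    proto <- .random_seq(config$seq_len)
    for (k in which(microbe_clusters == c_j)) {
      microbes$sequence[k] <- .mutate_seq(proto, config$seq_mutation_rate)
    }
  }

  matched <- ((drug_clusters - 1L) %% config$n_microbe_clusters) + 1L
  P <- matrix(config$assoc_cross_prob, m, n)
  for (i in seq_len(m)) P[i, microbe_clusters == matched[i]] <- config$assoc_within_prob
  A <- matrix(stats::runif(m * n) < P, m, n)
  flip <- matrix(stats::runif(m * n) < config$label_noise, m, n)
  A <- xor(A, flip)
  edges <- which(A, arr.ind = TRUE)
  assoc <- associations(drug_ids, microbe_ids,
                        data.frame(drug = edges[, 1], microbe = edges[, 2]))

  structure(list(drugs = drugs, fingerprints = fps, microbes = microbes,
                 assoc = assoc, drug_clusters = drug_clusters,
                 microbe_clusters = microbe_clusters, config = config),
            class = "dmanet_synth")
}

#' @export
print.dmanet_synth <- function(x, ...) {
  cat(sprintf("<synthetic dataset: %d drugs (%d clusters), %d microbes (%d clusters), %d edges>\n",
              length(x$fingerprints), x$config$n_drug_clusters,
              nrow(x$microbes), x$config$n_microbe_clusters,
              nrow(x$assoc$edges)))
  invisible(x)
}

#' Similarity matrices of a synthetic dataset
#'
#' Plain Tanimoto on the generated fingerprints and normalized local
#' alignment on the generated sequences.
#'
#' @param ds a `dmanet_synth`
#' @param params alignment scoring, see [alignment_params()]
#' @return list with `sim_d` and `sim_b`
#' @export
synthetic_similarities <- function(ds, params = alignment_params()) {
  list(sim_d = drug_similarity_matrix(ds$fingerprints, mode = "plain"),
       sim_b = microbe_similarity_matrix(ds$microbes, params))
}

#' Write a synthetic dataset to a directory
#'
#' Emits `microbes.fa`, `assoc.tsv`, `truth.json` and either `drugs.tsv`
#' (smiles_library mode) or `fingerprints.tsv` (random_bits mode; id and
#' comma-separated on-bit indices per row).
#'
#' @param ds a `dmanet_synth`
#' @param dir output directory (created if missing)
#' @return the directory, invisibly
#' @export
write_synthetic <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_microbe_fasta(ds$microbes, file.path(dir, "microbes.fa"))
  write_associations(ds$assoc, file.path(dir, "assoc.tsv"))
  if (!is.null(ds$drugs)) {
    write_drug_table(ds$drugs, file.path(dir, "drugs.tsv"))
  } else {
    writeLines(vapply(names(ds$fingerprints), function(id)
      paste0(id, "\t", paste(ds$fingerprints[[id]]$on_bits, collapse = ",")),
      ""), file.path(dir, "fingerprints.tsv"))
  }
  jsonlite::write_json(
    list(drug_clusters = ds$drug_clusters,
         microbe_clusters = ds$microbe_clusters,
         config = unclass(ds$config)),
    file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' The frozen worked-toy instance
#'
#' A fixed 5-drug / 3-microbe dataset with hand-enumerable similarity,
#' network and embedding values, used as the cross-module oracle fixture in
#' the test suite: small real molecules, 10-nt sequences, six associations.
#'
#' @return a `dmanet_synth`-shaped list with `drugs`, `fingerprints`,
#'   `microbes`, `assoc`
#' @export
worked_toy <- function() {
  drugs <- data.frame(
    id = c("D1", "D2", "D3", "D4", "D5"),
    smiles = c("CCO", "CCN", "CCC", "Oc1ccccc1", "CC(=O)O"))
  microbes <- data.frame(
    id = c("M1", "M2", "M3"),
    sequence = c("ACGTACGTAC", "ACGTACGTTT", "TTTTCCCCGG"))
  assoc <- associations(drugs$id, microbes$id,
                        data.frame(drug = c(1L, 2L, 1L, 3L, 4L, 5L),
                                   microbe = c(1L, 1L, 2L, 2L, 3L, 3L)))
  fps <- lapply(drugs$smiles, function(s) fingerprint(parse_smiles(s)))
  names(fps) <- drugs$id
  structure(list(drugs = drugs, fingerprints = fps, microbes = microbes,
                 assoc = assoc, drug_clusters = NULL, microbe_clusters = NULL,
                 config = NULL),
            class = "dmanet_synth")
}
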