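test_that("config validation enforces a learnable world", {
  expect_error(synth_config(assoc_within_prob = 0.1, assoc_cross_prob = 0.2),
               "exceed")
  expect_error(synth_config(bit_flip_rate = 1.5), "probabilities")
})

test_that("zero noise gives identical members within every cluster", {
  cfg <- synth_config(n_drug_clusters = 2L, drugs_per_cluster = 3L,
                      n_microbe_clusters = 2L, microbes_per_cluster = 2L,
                      bit_flip_rate = 0, seq_mutation_rate = 0,
                      seq_len = 40L, seed = 7L)
  ds <- generate_synthetic(cfg)
  for (c_i in 1:2) {
    mem <- which(ds$drug_clusters == c_i)
    for (k in mem[-1]) {
      expect_equal(tanimoto(ds$fingerprints[[mem[1]]], ds$fingerprints[[k]]), 1)
    }
    memb <- which(ds$microbe_clusters == c_i)
    expect_equal(microbe_similarity(ds$microbes$sequence[memb[1]],
                                    ds$microbes$sequence[memb[2]]), 1)
  }
})

test_that("with pure within-cluster associations every positive drug finds its co-associated neighbors", {
  cfg <- synth_config(assoc_within_prob = 1, assoc_cross_prob = 0,
                      label_noise = 0, bit_flip_rate = 0,
                      seq_mutation_rate = 0, seed = 3L)
  ds <- generate_synthetic(cfg)
  A <- association_matrix(ds$assoc)
  l_star <- cfg$drugs_per_cluster
  for (e in seq_len(nrow(ds$assoc$edges))) {
    d <- ds$assoc$edges$drug[e]; b <- ds$assoc$edges$microbe[e]
    co <- sum(A[, b] == 1) - 1            # other drugs sharing the microbe
    expect_gte(co, l_star - 1)
  }
})

test_that("association counts sit inside the closed-form binomial band", {
  cfg <- synth_config()                   # the default stated world
  ds <- generate_synthetic(cfg)
  m <- cfg$n_drug_clusters * cfg$drugs_per_cluster
  n <- cfg$n_microbe_clusters * cfg$microbes_per_cluster
  cells_within <- m * cfg$microbes_per_cluster   # each drug matches 1 cluster
  cells_cross <- m * n - cells_within
  p_w <- cfg$assoc_within_prob * (1 - cfg$label_noise) +
    (1 - cfg$assoc_within_prob) * cfg$label_noise
  p_c <- cfg$assoc_cross_prob * (1 - cfg$label_noise) +
    (1 - cfg$assoc_cross_prob) * cfg$label_noise
  mu <- cells_within * p_w + cells_cross * p_c
  sdv <- sqrt(cells_within * p_w * (1 - p_w) + cells_cross * p_c * (1 - p_c))
  expect_lt(abs(nrow(ds$assoc$edges) - mu), qnorm(0.995) * sdv)
})

test_that("generation is bitwise reproducible and seed-sensitive", {
  d1 <- generate_synthetic(synth_config(seed = 5L))
  d2 <- generate_synthetic(synth_config(seed = 5L))
  expect_identical(d1$fingerprints, d2$fingerprints)
  expect_identical(d1$microbes, d2$microbes)
  expect_identical(d1$assoc$edges, d2$assoc$edges)
  d3 <- generate_synthetic(synth_config(seed = 6L))
  expect_false(identical(d1$assoc$edges, d3$assoc$edges))
})

test_that("smiles_library mode produces valid molecules in homologous families", {
  cfg <- synth_config(fingerprint_mode = "smiles_library",
                      n_drug_clusters = 3L, drugs_per_cluster = 4L, seed = 2L)
  ds <- generate_synthetic(cfg)
  expect_false(is.null(ds$drugs))
  expect_equal(nrow(ds$drugs), 12)
  sim <- drug_similarity_matrix(ds$drugs, "plain")
  within <- sim$values[1, 2]                    # same family
  across <- sim$values[1, 9]                    # different family
  expect_gt(within, across)
})

test_that("planted clusters are recoverable by single linkage at zero noise", {
  cfg <- synth_config(bit_flip_rate = 0, seq_mutation_rate = 0, seed = 9L)
  ds <- generate_synthetic(cfg)
  ss <- synthetic_similarities(ds)
  cut_d <- cutree(hclust(as.dist(1 - ss$sim_d$values), method = "single"),
                  k = cfg$n_drug_clusters)
  expect_equal(length(unique(paste(cut_d, ds$drug_clusters))),
               cfg$n_drug_clusters)           # perfect agreement up to relabel
  cut_b <- cutree(hclust(as.dist(1 - ss$sim_b$values), method = "single"),
                  k = cfg$n_microbe_clusters)
  expect_equal(length(unique(paste(cut_b, ds$microbe_clusters))),
               cfg$n_microbe_clusters)
})

test_that("written datasets round-trip through the package loaders", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(fingerprint_mode = "smiles_library",
                      n_drug_clusters = 2L, drugs_per_cluster = 3L,
                      n_microbe_clusters = 2L, microbes_per_cluster = 2L,
                      seq_len = 50L, seed = 4L)
  ds <- generate_synthetic(cfg)
  write_synthetic(ds, dir)
  drugs <- read_drug_table(file.path(dir, "drugs.tsv"))
  expect_equal(drugs$id, ds$drugs$id)
  expect_equal(drugs$smiles, ds$drugs$smiles)
  mb <- read_microbe_fasta(file.path(dir, "microbes.fa"))
  expect_equal(mb, ds$microbes)
  suppressMessages(a <- load_associations(file.path(dir, "assoc.tsv"),
                                          drugs$id, mb$id))
  expect_identical(a$edges, ds$assoc$edges)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$drug_clusters, ds$drug_clusters)
})

test_that("the worked toy is frozen", {
  t1 <- worked_toy(); t2 <- worked_toy()
  expect_identical(t1$fingerprints, t2$fingerprints)
  expect_identical(t1$assoc$edges, t2$assoc$edges)
  expect_equal(nrow(t1$drugs), 5)
  expect_equal(nrow(t1$microbes), 3)
})

test_that("learnability degrades monotonically with noise", {
  # 3 noise levels x a small seed set; reduced epochs for runtime
  levels <- list(c(bit = 0.00, lab = 0.00), c(bit = 0.05, lab = 0.05),
                 c(bit = 0.30, lab = 0.35))
  mean_auc <- numeric(length(levels))
  for (li in seq_along(levels)) {
    aucs <- c()
    for (sd in 1:2) {
      cfg <- synth_config(bit_flip_rate = levels[[li]]["bit"],
                          label_noise = levels[[li]]["lab"], seed = sd,
                          n_drug_clusters = 3L, drugs_per_cluster = 6L,
                          n_microbe_clusters = 2L, microbes_per_cluster = 4L,
                          seq_len = 120L)
      ds <- generate_synthetic(cfg)
      ss <- synthetic_similarities(ds)
      r <- run_cv(ss$sim_d, ss$sim_b, ds$assoc,
                  config = fast_config(epochs = 120L, seed = sd), seed = sd)
      aucs <- c(aucs, r$mean_auroc)
    }
    mean_auc[li] <- mean(aucs)
  }
  expect_gt(mean_auc[1], mean_auc[3])
  expect_gte(mean_auc[1] + 0.02, mean_auc[2])  # non-increasing up to noise
})
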