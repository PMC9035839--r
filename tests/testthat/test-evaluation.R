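test_that("cross-validation plans partition positives and negatives", {
  a <- associations(sprintf("d%d", 1:5), sprintf("b%d", 1:4),
                    data.frame(drug = rep(1:5, 2), microbe = rep(1:4, 3)[1:10]))
  plan <- make_cv_plan(a, seed = 9)
  expect_equal(as.integer(table(plan$positives$fold)), rep(2L, 5))
  # union of test folds = all samples, pairwise disjoint
  key <- function(df) paste(df$drug, df$microbe)
  expect_setequal(key(plan$positives), key(a$edges))
  expect_false(any(duplicated(key(plan$positives))))
  expect_false(any(duplicated(key(plan$negatives))))
  expect_equal(nrow(plan$negatives), 5 * 4 - 10)
  # 3x2 toy with 2 positives, negative_ratio = all -> 4 negatives
  toy <- associations(c("x", "y", "z"), c("p", "q"),
                      data.frame(drug = c(1, 2), microbe = c(1, 2)))
  expect_error(make_cv_plan(toy), "fewer positives")
  plan2 <- make_cv_plan(toy, n_folds = 2, seed = 1)
  expect_equal(nrow(plan2$negatives), 4)
  # subsampled negatives
  plan3 <- make_cv_plan(a, negative_ratio = 0.5, seed = 1)
  expect_equal(nrow(plan3$negatives), 5)
})

test_that("auroc/auprc match brute-force oracles", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
  expect_error(auprc(1:3, c(0, 0, 0)), "both classes")
  # 6-sample hand case with a tie
  s <- c(0.9, 0.7, 0.7, 0.4, 0.3, 0.1); y <- c(1, 0, 1, 1, 0, 0)
  expect_equal(auroc(s, y), oracle_auroc(s, y))
  expect_equal(auprc(s, y), oracle_auprc(s, y))
  set.seed(51)
  for (i in 1:40) {
    n <- sample(4:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))      # force both classes
    s <- round(runif(n), sample(c(1, 2, 7), 1))  # rounding induces ties
    expect_equal(auroc(s, y), oracle_auroc(s, y), tolerance = 1e-12)
    expect_equal(auprc(s, y), oracle_auprc(s, y), tolerance = 1e-12)
  }
})

test_that("embedding profiles and feature importance are column means", {
  E <- matrix(0, 3, 4)
  p <- embedding_profiles(E, c(1, 0, 0))
  expect_equal(p$positive, numeric(4))
  expect_equal(p$unlabeled, numeric(4))
  E2 <- matrix(1:12, 3, 4)
  p2 <- embedding_profiles(E2, c(1, 0, 0))
  expect_equal(p2$positive, as.numeric(E2[1, ]))   # single positive row
  expect_error(embedding_profiles(E2, c(1, 1, 1)), "unlabeled")
  expect_equal(feature_importance(matrix(0.3, 5, 2)), rep(0.3, 2))
  expect_equal(feature_importance(matrix(c(0.2, 0.8), 1, 2)), c(0.2, 0.8))
  M <- matrix(runif(12), 3, 4)
  expect_equal(feature_importance(M),
               vapply(1:4, function(j) mean(M[, j]), numeric(1)))
})

test_that("neighbor_check ranks by similarity and flags co-association", {
  ds <- worked_toy()
  sim <- drug_similarity_matrix(ds$drugs, "plain")
  # microbe with no other associated drug -> 0 flagged
  a0 <- associations(ds$drugs$id, ds$microbes$id,
                     data.frame(drug = 1L, microbe = 1L))
  nc <- neighbor_check("D1", "M1", sim, a0, top_k = 3)
  expect_equal(nc$n_associated_top_k, 0)
  expect_equal(nrow(nc$table), 4)
  expect_equal(nc$table$similarity, sort(nc$table$similarity, decreasing = TRUE))
  # all of the top 3 associated -> 3 of top 3
  top3 <- nc$table$drug[1:3]
  a3 <- associations(ds$drugs$id, ds$microbes$id,
                     data.frame(drug = match(top3, ds$drugs$id), microbe = 1L))
  expect_equal(neighbor_check("D1", "M1", sim, a3, top_k = 3)$n_associated_top_k, 3)
  expect_error(neighbor_check("nope", "M1", sim, a3), "unknown drug")
})

test_that("rank_candidates orders by probability with id tie-break", {
  w <- synth_world()
  pl <- train_pipeline(w$sim_d, w$sim_b, w$ds$assoc,
                       config = fast_config(epochs = 60L))
  b <- w$ds$assoc$microbe_ids[1]
  r_all <- rank_candidates(pl, b, exclude_known = FALSE)
  r_new <- rank_candidates(pl, b, exclude_known = TRUE)
  deg <- sum(association_matrix(w$ds$assoc)[, 1])
  expect_equal(nrow(r_all) - nrow(r_new), deg)
  expect_equal(r_all$score, sort(r_all$score, decreasing = TRUE))
  # equal scores rank in id order: score ties within a constant model
  m0 <- pl$model
  m0$pred <- lapply(m0$pred, function(p) p * 0)
  pl0 <- pl; pl0$model <- m0
  r0 <- rank_candidates(pl0, b, exclude_known = FALSE)
  expect_equal(r0$drug, sort(r0$drug))
  expect_error(rank_candidates(pl, "nope"), "unknown microbe")
})

test_that("top-l masking degenerates and recovers as expected", {
  w <- synth_world()
  plan <- make_cv_plan(w$ds$assoc, seed = 5)
  cfg <- fast_config(epochs = 80L)
  full <- run_cv(w$sim_d, w$sim_b, w$ds$assoc, plan = plan, config = cfg)
  at_full <- run_cv(w$sim_d, w$sim_b, w$ds$assoc, plan = plan, config = cfg,
                    top_l = max(length(w$ds$assoc$drug_ids),
                                length(w$ds$assoc$microbe_ids)))
  expect_identical(at_full$per_fold, full$per_fold)   # l = block length is a no-op
  expect_warning(
    clamped <- run_cv(w$sim_d, w$sim_b, w$ds$assoc, plan = plan, config = cfg,
                      top_l = 10000L), "clamped")
  expect_identical(clamped$per_fold, full$per_fold)
})

test_that("fold metrics are invariant to pair presentation order", {
  w <- synth_world()
  plan <- make_cv_plan(w$ds$assoc, seed = 2)
  cfg <- fast_config(epochs = 40L)
  r1 <- run_cv(w$sim_d, w$sim_b, w$ds$assoc, plan = plan, config = cfg)
  plan_shuf <- plan
  ordp <- withr::with_seed(99, sample.int(nrow(plan$positives)))
  ordn <- withr::with_seed(98, sample.int(nrow(plan$negatives)))
  plan_shuf$positives <- plan$positives[ordp, ]
  plan_shuf$negatives <- plan$negatives[ordn, ]
  r2 <- run_cv(w$sim_d, w$sim_b, w$ds$assoc, plan = plan_shuf, config = cfg)
  # row order only changes floating-point accumulation order inside the
  # (single-batch) gradient sums, so metrics agree to numerical noise
  expect_equal(r1$per_fold$auroc, r2$per_fold$auroc, tolerance = 1e-6)
  expect_equal(r1$per_fold$auprc, r2$per_fold$auprc, tolerance = 1e-6)
})
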