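# ---------------------------------------------------------------------------
# Cross-validation, ranking metrics and interpretability diagnostics.
#
# Known associations are positives; unlabeled pairs act as negatives
# (positive-unlabeled evaluation). Both sets are partitioned into 5 folds;
# in every round the co-association networks and instantiated neighbor
# sets are rebuilt from the training-fold positives only, so no test label
# can reach a feature.
# ---------------------------------------------------------------------------

#' Build a cross-validation plan
#'
#' Positives (the association edges) and negatives (sampled from the
#' unlabeled complement of the m x n pair universe) are shuffled with the
#' seed and split into `n_folds` near-equal groups; each group serves as
#' the test set exactly once.
#'
#' @param assoc a `dmanet_assoc`
#' @param n_folds number of folds (default 5)
#' @param negative_ratio `"all"` to use every unlabeled pair (default), or
#'   a positive number: negatives = ratio x positives, sampled
#' @param seed RNG seed
#' @return object of class `dmanet_cv_plan` with `positives` and
#'   `negatives` data.frames carrying a `fold` column
#' @export
make_cv_plan <- function(assoc, n_folds = 5L, negative_ratio = "all", seed = 1L) {
  n_folds <- as.integer(n_folds)
  pos <- assoc$edges
  if (nrow(pos) < n_folds) stop("fewer positives (", nrow(pos),
                                ") than folds (", n_folds, ")")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  A <- association_matrix(assoc)
  neg_idx <- which(A == 0L)                      # column-major cell indices
  neg <- data.frame(drug = ((neg_idx - 1L) %% nrow(A)) + 1L,
                    microbe = ((neg_idx - 1L) %/% nrow(A)) + 1L)
  if (!identical(negative_ratio, "all")) {
    want <- min(nrow(neg), ceiling(as.numeric(negative_ratio) * nrow(pos)))
    neg <- neg[sample.int(nrow(neg), want), , drop = FALSE]
  }
  assign_folds <- function(df) {
    df <- df[sample.int(nrow(df)), , drop = FALSE]
    df$fold <- rep(seq_len(n_folds), length.out = nrow(df))
    df[order(df$drug, df$microbe), , drop = FALSE]
  }
  structure(list(assoc = assoc, positives = assign_folds(pos),
                 negatives = assign_folds(neg), n_folds = n_folds,
                 seed = as.integer(seed)),
            class = "dmanet_cv_plan")
}

#' @export
print.dmanet_cv_plan <- function(x, ...) {
  cat(sprintf("<CV plan: %d folds, %d positives, %d negatives, seed %d>\n",
              x$n_folds, nrow(x$positives), nrow(x$negatives), x$seed))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank-based (ties averaged): the probability that a random positive
#' scores above a random negative, counting ties 1/2.
#'
#' @param scores numeric scores
#' @param labels 0/1 labels, both classes present
#' @return AUROC in \[0, 1\]
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required for AUROC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise integration (average precision): descending unique score
#' thresholds, tied scores processed as one block;
#' `sum_i precision_i * (recall_i - recall_{i-1})`.
#'
#' @param scores numeric scores
#' @param labels 0/1 labels, both classes present
#' @return AUPRC in (0, 1\]
#' @export
auprc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1)
  if (n1 == 0 || n1 == length(labels)) stop("both classes required for AUPRC")
  ord <- order(-scores)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp_g <- tapply(y, grp, sum)
  n_g <- tapply(rep(1, length(y)), grp, sum)
  tp <- cumsum(tp_g); np <- cumsum(n_g)
  prec <- tp / np; rec <- tp / n1
  sum(prec * diff(c(0, rec)))
}

.fold_assoc <- function(assoc, pos_keep) {
  associations(assoc$drug_ids, assoc$microbe_ids,
               pos_keep[, c("drug", "microbe"), drop = FALSE])
}

.apply_top_l <- function(E, L_d, L_b, l) {
  if (is.null(l)) return(E)
  keep <- c(seq_len(L_d) <= min(l, L_d), seq_len(L_b) <= min(l, L_b))
  E[, !keep] <- 0
  E
}

#' Run 5-fold cross-validation of the full pipeline
#'
#' For every round: the training-fold positives define the associations
#' visible to the embedder, training pairs (train positives + train
#' negatives) are embedded and the model trained, then the held-out pairs
#' are embedded under the same training associations and scored.
#'
#' @param sim_d drug similarity (`dmanet_sim`)
#' @param sim_b microbe similarity (`dmanet_sim`)
#' @param assoc full `dmanet_assoc`
#' @param plan optional precomputed [make_cv_plan()] (built from `assoc`,
#'   `negative_ratio`, `seed` otherwise)
#' @param config a [train_config()]
#' @param L_d,L_b dictionary truncation lengths (default: full sides)
#' @param include_self see [msdna()]
#' @param top_l optional top-l key mask applied to both embedding blocks
#' @param negative_ratio,seed used when `plan` is NULL
#' @return object of class `dmanet_cv_report`: per-fold and mean/pooled
#'   AUROC and AUPRC, loss traces, config snapshot
#' @export
run_cv <- function(sim_d, sim_b, assoc, plan = NULL, config = train_config(),
                   L_d = NULL, L_b = NULL, include_self = FALSE, top_l = NULL,
                   negative_ratio = "all", seed = 1L) {
  if (is.null(plan)) plan <- make_cv_plan(assoc, 5L, negative_ratio, seed)
  dict_d <- build_dictionaries(sim_d, L_d)
  dict_b <- build_dictionaries(sim_b, L_b)
  if (!is.null(top_l) && top_l > max(dict_d$L, dict_b$L)) {
    warning("top-l = ", top_l, " exceeds block length; clamped")
  }
  per <- data.frame()
  traces <- list()
  pooled_scores <- numeric(); pooled_labels <- integer()
  for (f in seq_len(plan$n_folds)) {
    tr_pos <- plan$positives[plan$positives$fold != f, , drop = FALSE]
    te_pos <- plan$positives[plan$positives$fold == f, , drop = FALSE]
    tr_neg <- plan$negatives[plan$negatives$fold != f, , drop = FALSE]
    te_neg <- plan$negatives[plan$negatives$fold == f, , drop = FALSE]
    assoc_tr <- .fold_assoc(assoc, tr_pos)
    E_tr <- embed_pairs(rbind(tr_pos[, 1:2], tr_neg[, 1:2]), dict_d, dict_b,
                        assoc_tr, include_self)
    Y_tr <- c(rep(1L, nrow(tr_pos)), rep(0L, nrow(tr_neg)))
    E_te <- embed_pairs(rbind(te_pos[, 1:2], te_neg[, 1:2]), dict_d, dict_b,
                        assoc_tr, include_self)
    Y_te <- c(rep(1L, nrow(te_pos)), rep(0L, nrow(te_neg)))
    E_tr <- .apply_top_l(E_tr, dict_d$L, dict_b$L, top_l)
    E_te <- .apply_top_l(E_te, dict_d$L, dict_b$L, top_l)
    fold_cfg <- config
    fold_cfg$seed <- (config$seed * 131L + f) %% .Machine$integer.max
    model <- train_model(E_tr, Y_tr, fold_cfg)
    P <- predict(model, E_te)
    per <- rbind(per, data.frame(fold = f, auroc = auroc(P, Y_te),
                                 auprc = auprc(P, Y_te),
                                 n_test_pos = nrow(te_pos),
                                 n_test_neg = nrow(te_neg)))
    traces[[f]] <- model$trace
    pooled_scores <- c(pooled_scores, P)
    pooled_labels <- c(pooled_labels, Y_te)
  }
  structure(list(per_fold = per,
                 mean_auroc = mean(per$auroc), mean_auprc = mean(per$auprc),
                 pooled_auroc = auroc(pooled_scores, pooled_labels),
                 pooled_auprc = auprc(pooled_scores, pooled_labels),
                 traces = traces, config = config, plan_seed = plan$seed,
                 top_l = top_l),
            class = "dmanet_cv_report")
}

#' @export
print.dmanet_cv_report <- function(x, ...) {
  cat(sprintf("<CV report: mean AUROC %.3f, mean AUPRC %.3f (pooled %.3f / %.3f)>\n",
              x$mean_auroc, x$mean_auprc, x$pooled_auroc, x$pooled_auprc))
  print(x$per_fold, row.names = FALSE)
  invisible(x)
}

#' Mean embedding profiles by label
#'
#' Column means of the embedding matrix split into positive and unlabeled
#' rows: the per-key-position mass distribution of each class.
#'
#' @param E embedding matrix
#' @param labels 0/1 labels per row (both classes present)
#' @return list with `positive` and `unlabeled` mean vectors
#' @export
embedding_profiles <- function(E, labels) {
  stopifnot(nrow(E) == length(labels))
  if (!any(labels == 1) || !any(labels == 0)) {
    stop("need at least one positive and one unlabeled row")
  }
  list(positive = colMeans(E[labels == 1, , drop = FALSE]),
       unlabeled = colMeans(E[labels == 0, , drop = FALSE]))
}

#' Global feature importance from the attention matrix
#'
#' The importance of feature dimension i is the mean of column i of M.
#'
#' @param M attention matrix (k x g)
#' @return numeric vector of length g, entries in (0, 1)
#' @export
feature_importance <- function(M) colMeans(as.matrix(M))

#' Predictive performance while retaining only the first l key positions
#'
#' For every l in `l_values`, all embedding entries beyond key position l
#' (in each directional block) are zeroed, the model is retrained and
#' evaluated under the same CV plan.
#'
#' @param sim_d,sim_b,assoc,plan,config,L_d,L_b,include_self as in [run_cv()]
#' @param l_values integer vector of l values
#' @return data.frame with columns `l`, `mean_auroc`, `mean_auprc`
#' @export
top_l_experiment <- function(sim_d, sim_b, assoc, l_values, plan = NULL,
                             config = train_config(), L_d = NULL, L_b = NULL,
                             include_self = FALSE) {
  if (is.null(plan)) plan <- make_cv_plan(assoc, 5L, "all", config$seed)
  out <- data.frame()
  for (l in l_values) {
    rep_l <- run_cv(sim_d, sim_b, assoc, plan = plan, config = config,
                    L_d = L_d, L_b = L_b, include_self = include_self,
                    top_l = l)
    out <- rbind(out, data.frame(l = l, mean_auroc = rep_l$mean_auroc,
                                 mean_auprc = rep_l$mean_auprc))
  }
  out
}

#' Neighbor-rank check for one drug-microbe pair
#'
#' Ranks all other drugs by similarity to the reference drug (descending,
#' ties by registry order) and flags which of them are associated with the
#' reference microbe.
#'
#' @param drug_id,microbe_id reference pair (ids or indices)
#' @param sim drug `dmanet_sim`
#' @param assoc a `dmanet_assoc`
#' @param top_k how many top-ranked drugs to summarize (default 10)
#' @return list with `table` (rank, drug id, similarity, associated flag)
#'   and `n_associated_top_k`
#' @export
neighbor_check <- function(drug_id, microbe_id, sim, assoc, top_k = 10L) {
  d <- .node_index(drug_id, assoc$drug_ids, "drug")
  b <- .node_index(microbe_id, assoc$microbe_ids, "microbe")
  sym <- symmetrize_similarity(sim)
  others <- setdiff(seq_along(sym$ids), d)
  ord <- others[order(-sym$values[d, others], others)]
  A <- association_matrix(assoc)
  tab <- data.frame(rank = seq_along(ord), drug = sym$ids[ord],
                    similarity = sym$values[d, ord],
                    associated = A[ord, b] == 1L)
  top_k <- min(top_k, nrow(tab))
  list(table = tab, n_associated_top_k = sum(tab$associated[seq_len(top_k)]),
       top_k = top_k)
}

#' Fit the full pipeline on all known associations
#'
#' Embeds the complete m x n pair universe (positives labeled 1, unlabeled
#' pairs 0) and trains the attention/classifier stack; the result can score
#' and rank candidate pairs.
#'
#' @param sim_d,sim_b similarity matrices
#' @param assoc full `dmanet_assoc`
#' @param config a [train_config()]
#' @param L_d,L_b,include_self as in [run_cv()]
#' @return object of class `dmanet_pipeline`
#' @export
train_pipeline <- function(sim_d, sim_b, assoc, config = train_config(),
                           L_d = NULL, L_b = NULL, include_self = FALSE) {
  dict_d <- build_dictionaries(sim_d, L_d)
  dict_b <- build_dictionaries(sim_b, L_b)
  A <- association_matrix(assoc)
  univ <- expand.grid(drug = seq_along(assoc$drug_ids),
                      microbe = seq_along(assoc$microbe_ids))
  E <- embed_pairs(univ, dict_d, dict_b, assoc, include_self)
  Y <- A[cbind(univ$drug, univ$microbe)]
  model <- train_model(E, Y, config)
  structure(list(model = model, dict_d = dict_d, dict_b = dict_b,
                 assoc = assoc, include_self = include_self),
            class = "dmanet_pipeline")
}

#' Rank candidate drugs for a microbe by predicted probability
#'
#' Scores every drug against the microbe with the trained pipeline and
#' sorts descending; ties are broken by drug id. Known positives can be
#' excluded from the ranking.
#'
#' @param pipeline a [train_pipeline()] result
#' @param microbe_id microbe id or index
#' @param exclude_known drop the microbe's known positive drugs
#' @return data.frame with `rank`, `drug`, `score`, `known`
#' @export
rank_candidates <- function(pipeline, microbe_id, exclude_known = TRUE) {
  assoc <- pipeline$assoc
  b <- .node_index(microbe_id, assoc$microbe_ids, "microbe")
  pairs <- data.frame(drug = seq_along(assoc$drug_ids), microbe = b)
  E <- embed_pairs(pairs, pipeline$dict_d, pipeline$dict_b, assoc,
                   pipeline$include_self)
  P <- predict(pipeline$model, E)
  A <- association_matrix(assoc)
  known <- A[, b] == 1L
  tab <- data.frame(drug = assoc$drug_ids, score = P, known = known)
  if (exclude_known) tab <- tab[!tab$known, , drop = FALSE]
  tab <- tab[order(-tab$score, tab$drug), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab[, c("rank", "drug", "score", "known")]
}

#' Label-permuted control associations
#'
#' Replaces the edge set by a uniformly random edge set of the same size
#' over the same pair universe (seeded); destroys any structure linking
#' similarity to association while preserving density.
#'
#' @param assoc a `dmanet_assoc`
#' @param seed RNG seed
#' @return a `dmanet_assoc`
#' @export
permuted_associations <- function(assoc, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  m <- length(assoc$drug_ids); n <- length(assoc$microbe_ids)
  cells <- sample.int(m * n, nrow(assoc$edges))
  associations(assoc$drug_ids, assoc$microbe_ids,
               data.frame(drug = ((cells - 1L) %% m) + 1L,
                          microbe = ((cells - 1L) %/% m) + 1L))
}
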