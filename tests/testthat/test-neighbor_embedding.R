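make_sim <- function(v, ids, kind = "microbe") {
  # convenience wrapper for small hand matrices
  similarity_matrix(v, ids, kind)
}

test_that("dictionaries sort keys by descending similarity, self first, ties by index", {
  v <- matrix(c(1, 0.2, 0.9,
                0.2, 1, 0.5,
                0.9, 0.5, 1), 3, 3, byrow = TRUE)
  d <- build_dictionaries(make_sim(v, c("a", "b", "c")))
  expect_equal(d$key_idx[1, ], c(1L, 3L, 2L))      # self, 0.9, 0.2
  expect_equal(d$key_sim[1, ], c(1, 0.9, 0.2))
  # all off-diagonal ties -> registry order after self
  vt <- matrix(0.5, 3, 3); diag(vt) <- 1
  dt <- build_dictionaries(make_sim(vt, c("a", "b", "c")))
  expect_equal(dt$key_idx[2, ], c(2L, 1L, 3L))
  # 20-node random matrix vs independent argsort oracle
  set.seed(31)
  n <- 20
  m <- matrix(runif(n * n), n, n); m <- (m + t(m)) / 2; diag(m) <- 1
  dn <- build_dictionaries(make_sim(m, sprintf("x%02d", 1:n)))
  for (i in 1:n) {
    others <- setdiff(1:n, i)
    expect_equal(dn$key_idx[i, ], c(i, others[order(-m[i, others], others)]))
  }
  # truncation keeps the first L keys
  d5 <- build_dictionaries(make_sim(m, sprintf("x%02d", 1:n)), L = 5)
  expect_equal(d5$key_idx, dn$key_idx[, 1:5])
})

toy_context <- function() {
  ds <- worked_toy()
  sim_d <- drug_similarity_matrix(ds$drugs, "plain")
  sim_b <- microbe_similarity_matrix(ds$microbes)
  list(ds = ds, sim_d = sim_d, sim_b = sim_b,
       dict_d = build_dictionaries(sim_d), dict_b = build_dictionaries(sim_b))
}

test_that("msdna/dsmna implement the keyed neighbor aggregation", {
  ctx <- toy_context()
  # microbe with no associated drugs besides d_x -> zero vector
  a0 <- associations(ctx$ds$drugs$id, ctx$ds$microbes$id,
                     data.frame(drug = 1L, microbe = 1L))
  expect_equal(msdna("D1", "M1", ctx$dict_d, a0), numeric(5))
  # microbe associated exactly with d_x's nearest neighbor
  nn <- ctx$dict_d$key_idx[1, 2]                  # D1's nearest neighbor
  a1 <- associations(ctx$ds$drugs$id, ctx$ds$microbes$id,
                     data.frame(drug = nn, microbe = 1L))
  v <- msdna("D1", "M1", ctx$dict_d, a1)
  expect_equal(which(v != 0), 2L)
  expect_equal(v[2], ctx$dict_d$key_sim[1, 2])
  # brute-force Eq over all keys for every pair of the toy
  A <- association_matrix(ctx$ds$assoc)
  for (d in 1:5) for (b in 1:3) {
    got <- msdna(d, b, ctx$dict_d, ctx$ds$assoc)
    want <- numeric(5)
    for (i in 1:5) {
      ni <- ctx$dict_d$key_idx[d, i]
      if (ni != d && A[ni, b] == 1) want[i] <- ctx$dict_d$key_sim[d, i]
    }
    expect_identical(got, want)
    gotb <- dsmna(b, d, ctx$dict_b, ctx$ds$assoc)
    wantb <- numeric(3)
    for (j in 1:3) {
      mj <- ctx$dict_b$key_idx[b, j]
      if (mj != b && A[d, mj] == 1) wantb[j] <- ctx$dict_b$key_sim[b, j]
    }
    expect_identical(gotb, wantb)
  }
  expect_error(msdna("nope", "M1", ctx$dict_d, ctx$ds$assoc), "unknown drug")
})

test_that("embed_pairs stacks [msdna || dsmna] rows deterministically", {
  ctx <- toy_context()
  E0 <- embed_pairs(data.frame(drug = integer(), microbe = integer()),
                    ctx$dict_d, ctx$dict_b, ctx$ds$assoc)
  expect_equal(dim(E0), c(0L, 8L))
  univ <- expand.grid(drug = 1:5, microbe = 1:3)
  E <- embed_pairs(univ, ctx$dict_d, ctx$dict_b, ctx$ds$assoc)
  expect_equal(dim(E), c(15L, 8L))
  A <- association_matrix(ctx$ds$assoc)
  for (r in seq_len(nrow(univ))) {
    d <- univ$drug[r]; b <- univ$microbe[r]
    expect_identical(E[r, ], c(msdna(d, b, ctx$dict_d, ctx$ds$assoc),
                               dsmna(b, d, ctx$dict_b, ctx$ds$assoc)))
    expect_lte(sum(E[r, ] != 0), sum(A[, b]) + sum(A[d, ]))
    expect_true(all(E[r, ] >= 0 & E[r, ] <= 1))
  }
  # id-typed pairs give the same rows
  Eid <- embed_pairs(data.frame(drug = "D2", microbe = "M1"),
                     ctx$dict_d, ctx$dict_b, ctx$ds$assoc)
  expect_identical(unname(Eid[1, ]), unname(E[univ$drug == 2 & univ$microbe == 1, ]))
})

test_that("an embedding never reads its own association bit", {
  ctx <- toy_context()
  with_edge <- ctx$ds$assoc
  edges_wo <- with_edge$edges[!(with_edge$edges$drug == 1 &
                                  with_edge$edges$microbe == 1), ]
  without_edge <- associations(with_edge$drug_ids, with_edge$microbe_ids, edges_wo)
  p <- data.frame(drug = 1L, microbe = 1L)
  expect_identical(embed_pairs(p, ctx$dict_d, ctx$dict_b, with_edge),
                   embed_pairs(p, ctx$dict_d, ctx$dict_b, without_edge))
  # with include_self = TRUE the literal reading leaks, visible at key 1
  Ein <- embed_pairs(p, ctx$dict_d, ctx$dict_b, with_edge, include_self = TRUE)
  expect_equal(unname(Ein[1, 1]), 1)
  expect_equal(unname(embed_pairs(p, ctx$dict_d, ctx$dict_b, with_edge)[1, 1]), 0)
})

test_that("embeddings are invariant to registry permutation", {
  ctx <- toy_context()
  perm_d <- c(4L, 2L, 5L, 1L, 3L)
  drugs_p <- ctx$ds$drugs[perm_d, ]
  sim_d_p <- drug_similarity_matrix(drugs_p, "plain")
  dict_d_p <- build_dictionaries(sim_d_p)
  remap <- match(ctx$ds$drugs$id, drugs_p$id)
  assoc_p <- associations(drugs_p$id, ctx$ds$microbes$id,
                          data.frame(drug = remap[ctx$ds$assoc$edges$drug],
                                     microbe = ctx$ds$assoc$edges$microbe))
  for (d in ctx$ds$drugs$id) for (b in ctx$ds$microbes$id) {
    v1 <- msdna(d, b, ctx$dict_d, ctx$ds$assoc)
    v2 <- msdna(d, b, dict_d_p, assoc_p)
    # same (key id -> value) map for nonzero entries; key order may differ
    # among exact similarity ties, the values read per id may not
    n1 <- setNames(v1, ctx$dict_d$ids[ctx$dict_d$key_idx[match(d, ctx$dict_d$ids), ]])
    n2 <- setNames(v2, dict_d_p$ids[dict_d_p$key_idx[match(d, dict_d_p$ids), ]])
    n1 <- n1[n1 != 0]; n2 <- n2[n2 != 0]
    expect_identical(n1[order(names(n1))], n2[order(names(n2))])
  }
})

test_that("positive pairs concentrate mass at early key positions on planted data", {
  w <- synth_world()
  dict_d <- build_dictionaries(w$sim_d)
  dict_b <- build_dictionaries(w$sim_b)
  univ <- expand.grid(drug = seq_along(w$ds$assoc$drug_ids),
                      microbe = seq_along(w$ds$assoc$microbe_ids))
  E <- embed_pairs(univ, dict_d, dict_b, w$ds$assoc)
  Y <- association_matrix(w$ds$assoc)[cbind(univ$drug, univ$microbe)]
  prof <- embedding_profiles(E, Y)
  l_star <- w$ds$config$drugs_per_cluster
  expect_gt(mean(prof$positive[1:l_star]), mean(prof$positive[(l_star + 1):dict_d$L]))
})
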