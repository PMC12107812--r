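test_that("similarity samples equal the brute-force double loop", {
  smis <- diverse_smiles()[1:10]
  fps <- lapply(smis, morganFingerprint)
  vals <- intraSimilarity(fps)
  expect_length(vals, 10 * 9 / 2)
  # oracle: explicit double loop
  oracle <- c()
  for (i in 1:9) for (j in (i + 1):10)
    oracle <- c(oracle, tanimotoSimilarity(fps[[i]], fps[[j]]))
  expect_equal(vals, oracle)
  expect_true(all(vals >= 0 & vals <= 1))
  # n identical molecules -> constant 1
  expect_equal(intraSimilarity(rep(list("CCO"), 4)), rep(1, 6))
  expect_length(intraSimilarity(as.list(smis[1:3])), 3L)
  expect_error(intraSimilarity(list("C")), "at least 2")
})

test_that("inter-set similarities cover all cross pairs symmetrically", {
  A <- lapply(c("CCO", "CCC"), morganFingerprint)
  B <- lapply(c("c1ccccc1", "CCN", "CCCl"), morganFingerprint)
  v <- interSimilarity(A, B)
  expect_length(v, 6L)
  expect_equal(sort(v), sort(interSimilarity(B, A)))
  expect_equal(interSimilarity(list("CCO"), list("CCO")), 1)
  expect_error(interSimilarity(list(), A), "non-empty")
})

test_that("evolution summaries recompute from raw population records", {
  tab <- toy_table()
  st <- newGA("C", popsize = 5L, fitness = surrogate_spec(),
              mutation = mutationParams(minInc = 1L, maxInc = 5L),
              fragments = tab, seed = 31L)
  st <- runGA(st, 3L)
  summ <- evolutionSummary(st)
  expect_identical(nrow(summ), 4L)  # generations 0..3
  expect_true(all(diff(summ$min_cost) <= 1e-12))
  # oracle recomputation from the snapshots
  ph <- st@popHistory
  for (g in 0:3) {
    rows <- ph[ph$generation == g, ]
    expect_equal(summ$min_cost[summ$generation == g], min(rows$cost))
    expect_equal(summ$median_cost[summ$generation == g],
                 median(rows$cost))
    expect_equal(summ$max_cost[summ$generation == g], max(rows$cost))
  }
  single <- evolutionSummary(ph[ph$generation == 0, ])
  expect_identical(nrow(single), 1L)
  expect_error(evolutionSummary(data.frame()), "empty history")
})

test_that("chemical-space projection agrees with an independent PCA", {
  set.seed(42)
  X <- matrix(rbinom(20 * 64, 1, 0.3), 20, 64)
  pr <- projectChemicalSpace(X, nComponents = 5L, perplexity = 4,
                             seed = 1L)
  expect_identical(dim(pr$coordinates), c(20L, 2L))
  expect_gt(pr$varianceFraction, 0)
  expect_lte(pr$varianceFraction, 1)
  # oracle: eigendecomposition of the covariance matrix
  Xc <- scale(X, center = TRUE, scale = FALSE)
  eig <- eigen(crossprod(Xc) / (nrow(X) - 1), symmetric = TRUE)
  oracle_scores <- Xc %*% eig$vectors[, 1:5]
  for (k in 1:5) {
    # eigenvector signs are arbitrary: compare up to a flip
    err <- min(sum((pr$scores[, k] - oracle_scores[, k])^2),
               sum((pr$scores[, k] + oracle_scores[, k])^2))
    expect_lt(err, 1e-16 + 1e-8 * sum(oracle_scores[, k]^2))
  }
  expect_equal(pr$varianceFraction,
               sum(eig$values[1:5]) / sum(eig$values), tolerance = 1e-8)
  # duplicated fingerprint rows map to identical component scores
  X2 <- rbind(X, X[1, ])
  pr2 <- projectChemicalSpace(X2, nComponents = 5L, perplexity = 4,
                              seed = 1L)
  expect_equal(pr2$scores[21, ], pr2$scores[1, ])
  expect_error(projectChemicalSpace(X, nComponents = 50L),
               "more samples")
})

test_that("relative-to-absolute free energy conversion is exact", {
  # identity: molecule i is the representative
  r <- rbfeToAbfe(freeEnergyRecord(ddgI = -1, dgR = -6.22, ddgR = -1))
  expect_equal(unname(r["dg"]), -6.22)
  # worked arithmetic with the reference absolute value
  r2 <- rbfeToAbfe(freeEnergyRecord(ddgI = -2, dgR = -6.22, ddgR = -1,
                                    errDdgI = 0.3, errDgR = 0.4,
                                    errDdgR = 0))
  expect_equal(unname(r2["dg"]), -7.22)
  expect_equal(unname(r2["err"]), 0.5)  # 3-4-5 quadrature triple
  expect_error(freeEnergyRecord(0, 0, 0, errDdgI = -0.1), "errors")
  # linearity in every argument, against independent recomputation
  set.seed(8)
  for (i in 1:100) {
    v <- rnorm(3, 0, 5); e <- abs(rnorm(3, 0, 1))
    out <- rbfeToAbfe(freeEnergyRecord(v[1], v[2], v[3], e[1], e[2],
                                       e[3]))
    expect_equal(unname(out["dg"]), v[1] + v[2] - v[3])
    expect_equal(unname(out["err"]), sqrt(sum(e^2)))
    # error output unaffected by sign flips of the energies
    flip <- rbfeToAbfe(freeEnergyRecord(-v[1], -v[2], -v[3], e[1], e[2],
                                        e[3]))
    expect_equal(unname(flip["err"]), unname(out["err"]))
  }
})
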