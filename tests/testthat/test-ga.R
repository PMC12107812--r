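test_that("Boltzmann selection probabilities follow the formula", {
  # beta = 0 -> uniform
  expect_equal(selectionProbabilities(c(0.1, 0.9, 0.5), 0), rep(1 / 3, 3))
  # equal costs -> uniform at any beta
  expect_equal(selectionProbabilities(rep(2.5, 4), 7), rep(0.25, 4))
  # hand evaluation: costs (0, ln 2), beta 1 -> (2/3, 1/3)
  expect_equal(selectionProbabilities(c(0, log(2)), 1), c(2 / 3, 1 / 3))
  # shift invariance to machine precision
  set.seed(10)
  for (i in 1:20) {
    costs <- runif(8, 0, 3)
    shift <- runif(1, -100, 100)
    expect_equal(selectionProbabilities(costs, 1.7),
                 selectionProbabilities(costs + shift, 1.7),
                 tolerance = 1e-14)
  }
  # infinite costs are excluded; all-infinite errors
  p <- selectionProbabilities(c(0.2, Inf, 0.4), 1)
  expect_equal(p[2], 0)
  expect_equal(sum(p), 1)
  expect_error(selectionProbabilities(c(Inf, Inf), 1), "selection error")
})

test_that("roulette draws match their analytic distribution", {
  st <- new("GAState", population = lapply(1:4, function(i) {
    ind <- makeIndividual(c("C", "CC", "CCC", "CCCC")[i], as.integer(i))
    ind@cost <- c(0, 0.5, 1, 2)[i]
    ind
  }), popsize = 4L, beta = 1, fragments = fragmentTable("*C"),
  fitness = surrogate_spec(), mutation = mutationParams())
  # beta = 0: uniform within 3 sigma over 1e5 draws
  st@beta <- 0
  set.seed(1)
  draws <- table(vapply(selectParents(st, 1e5L), idx, integer(1)))
  expect_true(all(abs(draws - 25000) < 3 * sqrt(1e5 * 0.25 * 0.75)))
  # huge beta: the best individual dominates
  st@beta <- 1000
  set.seed(2)
  best <- vapply(selectParents(st, 1e4L), idx, integer(1))
  expect_gte(mean(best == 1L), 0.999)
  expect_length(selectParents(st, 0L), 0L)
})

test_that("merge-and-truncate keeps the best unique individuals", {
  mk <- function(smi, i, cost) {
    ind <- makeIndividual(smi, as.integer(i)); ind@cost <- cost; ind
  }
  old <- list(mk("C", 1, 0.2), mk("CC", 2, 0.4), mk("CCC", 3, 0.9))
  new_ <- list(mk("CCCC", 4, 0.3), mk("CCCCC", 5, 0.95))
  kept <- mergeAndTruncate(old, new_, 3L)
  expect_equal(vapply(kept, cost, numeric(1)), c(0.2, 0.3, 0.4))
  # empty offspring -> unchanged
  expect_identical(vapply(mergeAndTruncate(old, list(), 3L), smiles,
                          character(1)),
                   vapply(old[order(c(0.2, 0.4, 0.9))], smiles,
                          character(1)))
  # offspring all better -> full replacement
  better <- list(mk("N", 6, 0.01), mk("O", 7, 0.02), mk("CN", 8, 0.03))
  expect_setequal(vapply(mergeAndTruncate(old, better, 3L), smiles,
                         character(1)), c("N", "O", "CN"))
  # ties break toward the older (lower-idx) individual
  tie <- mergeAndTruncate(list(mk("C", 1, 0.5)), list(mk("N", 9, 0.5)), 1L)
  expect_identical(smiles(tie[[1]]), "C")
})

test_that("initialization pads with unique mutants and evaluates", {
  tab <- toy_table()
  st <- newGA("C", popsize = 5L, fitness = surrogate_spec(),
              mutation = mutationParams(minInc = 1L, maxInc = 6L),
              fragments = tab, seed = 3L)
  smi <- vapply(population(st), smiles, character(1))
  expect_length(unique(smi), 5L)
  expect_true("C" %in% smi)
  expect_true(all(is.finite(vapply(population(st), cost, numeric(1)))))
  # duplicate seeds are collapsed before padding
  st2 <- newGA(c("C", "C"), popsize = 1L, fitness = surrogate_spec(),
               mutation = mutationParams(), fragments = tab)
  expect_length(population(st2), 1L)
  expect_error(newGA("not_a_smiles_(", popsize = 2L,
                     fitness = surrogate_spec(),
                     fragments = tab), "no valid seed")
})

test_that("the GA maintains elitism, uniqueness and resumable state", {
  tab <- toy_table()
  st <- newGA("C", popsize = 8L, pc = 0.5, beta = 1,
              fitness = surrogate_spec(),
              mutation = mutationParams(minSize = 0L, maxSize = 1L,
                                        minInc = -1L, maxInc = 6L),
              fragments = tab, seed = 21L)
  expect_identical(runGA(st, 0L)@generation, 0L)  # no-op
  st <- runGA(st, 6L)
  expect_identical(st@generation, 6L)
  # pointwise dominance of sorted cost vectors, generation by generation
  ph <- st@popHistory
  for (g in 1:6) {
    prev <- sort(ph$cost[ph$generation == g - 1])
    cur <- sort(ph$cost[ph$generation == g])
    expect_true(all(cur <= prev + 1e-12))
  }
  # no duplicate SMILES in any generation snapshot
  for (g in 0:6) {
    smi <- ph$smiles[ph$generation == g]
    expect_identical(anyDuplicated(smi), 0L)
  }
  # best-so-far monotone across calls
  gs <- generationStats(st)
  expect_true(all(diff(gs$best_cost) <= 1e-12))
  expect_true(all(is.finite(gs$acceptance_rate)))
})

test_that("identical seeds give identical campaigns", {
  tab <- toy_table()
  run <- function() {
    st <- newGA("C", popsize = 6L, fitness = surrogate_spec(),
                mutation = mutationParams(minInc = 1L, maxInc = 4L),
                fragments = tab, seed = 77L)
    runGA(st, 4L)
  }
  a <- run(); b <- run()
  expect_identical(sort(vapply(population(a), smiles, character(1))),
                   sort(vapply(population(b), smiles, character(1))))
  expect_equal(generationStats(a), generationStats(b))
})

test_that("checkpoints round-trip and resume seamlessly", {
  tab <- toy_table()
  st <- newGA("C", popsize = 6L, fitness = surrogate_spec(),
              mutation = mutationParams(minInc = 1L, maxInc = 4L),
              fragments = tab, seed = 5L)
  st <- runGA(st, 2L)
  f <- tempfile(fileext = ".pbz2")
  saveCheckpoint(st, f)
  back <- loadCheckpoint(f)
  expect_identical(
    lapply(population(st), function(x) list(x@smiles, x@cost)),
    lapply(population(back), function(x) list(x@smiles, x@cost)))
  # truncated file -> load error
  raw <- readBin(f, "raw", file.info(f)$size)
  f2 <- tempfile(fileext = ".pbz2")
  writeBin(raw[seq_len(20)], f2)
  expect_error(loadCheckpoint(f2), "load error")
  # an RDS that is not a campaign state is rejected
  f3 <- tempfile(fileext = ".pbz2")
  saveRDS(list(1), f3)
  expect_error(loadCheckpoint(f3), "campaign")
})

test_that("campaign outputs land on disk with the expected shapes", {
  tab <- toy_table()
  st <- newGA("C", popsize = 4L, fitness = surrogate_spec(),
              mutation = mutationParams(minInc = 1L, maxInc = 4L),
              fragments = tab, seed = 9L, deffnm = "unit")
  st <- runGA(st, 2L)
  td <- tempfile("outs"); dir.create(td)
  paths <- writeCampaignOutputs(st, td)
  expect_true(all(file.exists(paths)))
  hist <- read.delim(paths["history"])
  expect_true(all(c("generation", "idx", "smiles", "cost", "score",
                    "qed", "sa_score", "accepted") %in% colnames(hist)))
})
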