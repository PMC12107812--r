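test_that("cost fitness composes desirabilities into 1 - D", {
  # all properties exactly at target -> every d_i = 1 -> cost 0
  rc <- register_fixed_backend("fix_m10", -10)
  smi <- fake_descriptors("CCO", qed = 0.75, sa = 3)
  spec <- fitnessSpec("cost", receptors = list(rc))
  out <- evaluateFitness(makeIndividual(smi), spec)
  expect_equal(out@cost, 0)
  expect_equal(unname(out@props["score"]), -10)

  # midpoints: d = (0.5, 0.5, 0.5) -> cost 0.5
  rc <- register_fixed_backend("fix_m6", -6)
  smi <- fake_descriptors("CCC", qed = 0.425, sa = 5)
  out <- evaluateFitness(makeIndividual(smi),
                         fitnessSpec("cost", receptors = list(rc)))
  expect_equal(out@cost, 0.5)

  # the seed fragment at its published property values: the score sits
  # above the acceptable window, its desirability clamps to 0, cost = 1
  rc <- register_fixed_backend("fix_seed", -1.59)
  smi <- fake_descriptors("OCc1ccccc1", qed = 0.57, sa = 1.14)
  out <- evaluateFitness(makeIndividual(smi),
                         fitnessSpec("cost", receptors = list(rc)))
  expect_equal(out@cost, 1)
})

test_that("score-only fitness is the raw backend score", {
  spec <- surrogate_spec()
  out <- evaluateFitness(makeIndividual("C"), spec)
  expect_equal(out@cost, -0.345)
  # monotone segment: a larger molecule (<= 35 heavy atoms) scores lower
  small <- evaluateFitness(makeIndividual("CCC"), spec)
  large <- evaluateFitness(makeIndividual("CCCCCCCC"), spec)
  expect_lt(large@cost, small@cost)
})

test_that("multi-receptor fitness generalizes the single-receptor cost", {
  # a multi-receptor spec holding one on-target receptor reduces exactly
  # to the single-receptor cost
  rc <- register_fixed_backend("fix_m6b", -6)
  multi_single <- new("FitnessSpec", name = "cost_multi_receptor",
                      desirabilities = defaultDesirabilities(),
                      receptors = list(rc))
  for (smi in diverse_smiles()[1:12]) {
    s <- fake_descriptors(smi, qed = runif(1, 0.2, 0.7),
                          sa = runif(1, 2, 6))
    single <- evaluateFitness(makeIndividual(s),
                              fitnessSpec("cost", receptors = list(rc)))
    multi <- evaluateFitness(makeIndividual(s), multi_single)
    expect_equal(multi@cost, single@cost, tolerance = 1e-12)
  }
  # duplicating a receptor while splitting its weight changes nothing
  des <- defaultDesirabilities()
  half <- des$vina_score; half@w <- 0.5
  des$vina_score_1 <- half; des$vina_score_2 <- half
  s <- fake_descriptors("CCO", qed = 0.4, sa = 4)
  dup <- evaluateFitness(
    makeIndividual(s),
    fitnessSpec("cost_multi_receptor", desirabilities = des,
                receptors = list(rc, rc)))
  single <- evaluateFitness(makeIndividual(s),
                            fitnessSpec("cost", receptors = list(rc)))
  expect_equal(dup@cost, single@cost, tolerance = 1e-12)

  # hand-computed selectivity case: on-target d=1; the anti-target score
  # -8 maps through the mirrored ramp (l=-10, t=-2) to d = 2/8 = 0.25;
  # qed and sa at target -> cost = 1 - 0.25^(1/4)
  on <- register_fixed_backend("fix_on", -10)
  s <- fake_descriptors("CCCC", qed = 0.75, sa = 3)
  anti2 <- register_fixed_backend("fix_anti2", -8)
  anti2$direction <- "maximize"
  out <- evaluateFitness(
    makeIndividual(s),
    fitnessSpec("cost_multi_receptor", receptors = list(on, anti2)))
  expect_equal(out@cost, 1 - 0.25^(1 / 4), tolerance = 1e-12)

  expect_error(fitnessSpec("cost_multi_receptor",
                           receptors = list(on)), ">= 2 receptors")
})

test_that("evaluation failures poison only the affected individual", {
  registerScorerBackend("flaky", function(individual, receptorSpec) {
    if (individual@smiles == "CCO") stop("no pose")
    list(score = -3, pose = "p")
  })
  spec <- fitnessSpec("cost_only_score",
                      receptors = list(list(backend = "flaky")))
  inds <- lapply(c("CC", "CCO", "CCC"), makeIndividual)
  out <- suppressWarnings(evaluatePopulation(inds, spec))
  expect_equal(vapply(out, cost, numeric(1)), c(-3, Inf, -3))
})

test_that("fitness callables are validated against the engine contract", {
  good <- function(individual, ...) { individual@cost <- 0.5; individual }
  expect_length(validateFitnessCallable(good), 0)
  # returns nothing
  bad1 <- function(individual) NULL
  expect_match(validateFitnessCallable(bad1), "does not return Individual",
               all = FALSE)
  # wrong arity
  bad2 <- function() 1
  expect_match(validateFitnessCallable(bad2), "first argument",
               all = FALSE)
  expect_match(validateFitnessCallable("not even a function"),
               "cannot source|not a function", all = FALSE)
})
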