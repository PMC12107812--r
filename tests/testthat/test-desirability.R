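test_that("desirability transforms hit their knot and example values", {
  d <- defaultDesirabilities()
  # boundaries
  expect_equal(largerTheBest(0.1, d$qed), 0)
  expect_equal(largerTheBest(0.75, d$qed), 1)
  expect_equal(smallerTheBest(-10, d$vina_score), 1)
  expect_equal(smallerTheBest(-2, d$vina_score), 0)
  # linear midpoints of the default table
  expect_equal(largerTheBest(0.425, d$qed), 0.5)
  expect_equal(smallerTheBest(-6, d$vina_score), 0.5)
  # clamps
  expect_equal(largerTheBest(0.9, d$qed), 1)
  expect_equal(smallerTheBest(-1.59, d$vina_score), 0)
  # nominal shape
  p <- desirabilityParams("nominal_the_best", l = 0, t = 2, u = 6,
                          r1 = 1, r2 = 2)
  expect_equal(nominalTheBest(2, p), 1)
  expect_equal(nominalTheBest(0, p), 0)
  expect_equal(nominalTheBest(6, p), 0)
  expect_equal(nominalTheBest(4, p), 0.25)
  # parameter ordering violations
  expect_error(desirabilityParams("larger_the_best", l = 1, t = 0.5),
               "l < t")
  expect_error(desirabilityParams("smaller_the_best", t = 5, u = 1),
               "t < u")
  expect_error(desirabilityParams("nominal_the_best", l = 0, t = 5, u = 2),
               "l < t < u")
})

test_that("weighted geometric mean aggregates like the formula", {
  expect_equal(weightedGeometricMean(c(0.5, 0.5, 0.5)), 0.5)
  expect_equal(weightedGeometricMean(c(1, 0.25)), 0.5)
  expect_equal(weightedGeometricMean(c(0, 0.9, 0.8)), 0)  # annihilator
  # zero-weight factors are ignored, even at zero desirability
  expect_equal(weightedGeometricMean(c(0, 0.5), c(0, 1)), 0.5)
  expect_error(weightedGeometricMean(c(0.5), c(-1)), "negative")
  expect_error(weightedGeometricMean(numeric(0), numeric(0)), "non-empty")
  expect_error(weightedGeometricMean(c(0.5, 0.5), c(0, 0)), "positive")
})

test_that("randomized transforms stay in range, monotone and bounded", {
  set.seed(2024)
  for (i in 1:1000) {
    ps <- sort(runif(3, -50, 50))
    if (any(diff(ps) == 0)) next
    r <- runif(1, 0.2, 5)
    shape <- sample(c("larger_the_best", "smaller_the_best",
                      "nominal_the_best"), 1)
    p <- switch(shape,
      larger_the_best = desirabilityParams(shape, l = ps[1], t = ps[2],
                                           r = r),
      smaller_the_best = desirabilityParams(shape, t = ps[1], u = ps[2],
                                            r = r),
      nominal_the_best = desirabilityParams(shape, l = ps[1], t = ps[2],
                                            u = ps[3], r1 = r, r2 = r))
    xs <- sort(runif(7, -60, 60))
    dv <- applyDesirability(xs, p)
    expect_true(all(dv >= 0 & dv <= 1))
    if (shape == "larger_the_best") expect_true(all(diff(dv) >= -1e-12))
    if (shape == "smaller_the_best") expect_true(all(diff(dv) <= 1e-12))
    if (shape == "nominal_the_best")
      expect_equal(applyDesirability(p@t, p), 1)
    # aggregation bound: min(d) <= D <= max(d)
    w <- runif(length(dv), 0.1, 3)
    if (all(dv > 0)) {
      D <- weightedGeometricMean(dv, w)
      expect_gte(D, min(dv) - 1e-12)
      expect_lte(D, max(dv) + 1e-12)
    }
  }
})

test_that("unit-exponent ramps are exactly linear between their knots", {
  d <- defaultDesirabilities()
  set.seed(7)
  x <- runif(100, 0.1, 0.75)
  expect_equal(largerTheBest(x, d$qed), (x - 0.1) / (0.75 - 0.1))
  y <- runif(100, -10, -2)
  expect_equal(smallerTheBest(y, d$vina_score), (-2 - y) / (-2 + 10))
})

test_that("desirability parameters round-trip through configuration keys", {
  d <- defaultDesirabilities()
  for (p in d) {
    back <- desirabilityFromConfig(desirabilityToConfig(p))
    expect_equal(back@shape, p@shape)
    expect_equal(back@t, p@t)
    expect_equal(back@w, p@w)
  }
  # absent limits are legal for shapes whose formula never uses them
  p <- desirabilityFromConfig(list(Function = "SmallerTheBest",
                                   LowerLimit = "-", UpperLimit = -2,
                                   Target = -10, r = 1, w = 1))
  expect_true(is.na(p@l))
  expect_equal(smallerTheBest(-6, p), 0.5)
})
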