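test_that("james_point reproduces the closed-form components", {
  # mirrored 2:1 allocation: observed equals expected weighted proportion
  comp <- james_point(gt2(c(36, 12, 19), c(18, 6, 9)))
  expect_equal(comp$P_D, 0.28)
  expect_equal(comp$P_O, 0.15 / 0.72)
  expect_equal(comp$P_E, comp$P_O)
  expect_equal(comp$kappa_term, 0)
  expect_equal(comp$jbi, 0.64)

  expect_equal(james_point(gt2(c(50, 50, 0), c(50, 50, 0)))$jbi, 0.5)
  expect_equal(james_point(gt2(c(0, 100, 0), c(100, 0, 0)))$jbi, 1)
  # mostly-IDK case: P_O = 0 so the index is (1 + P_D - (1 - P_D)) / 2
  expect_equal(james_point(gt2(c(15, 0, 85), c(0, 15, 85)))$jbi, 0.85)
})

test_that("an all-IDK table is undefined by default, 1 under the convention", {
  x <- gt2(c(0, 0, 100), c(0, 0, 100))
  comp <- james_point(x)
  expect_false(comp$defined)
  expect_true(is.na(comp$jbi))
  expect_equal(james_point(x, undefined_as_one = TRUE)$jbi, 1)

  est <- james_bi(x)
  expect_true(all(c("undefined", "degenerate") %in% est$flags))
  est1 <- james_bi(x, undefined_as_one = TRUE)
  expect_equal(est1$value, 1)
  expect_equal(c(est1$ci_low, est1$ci_high), c(1, 1))
})

test_that("weight schemes are validated and non-default weights are honoured", {
  expect_error(james_weights(2, incorrect = 1.5), "\\[0, 1\\]")
  expect_error(james_weights(2, w = matrix(0.5, 3, 3)), "2 x 2")
  # uniform weights make observed and expected proportions both 1/2,
  # so the index is (1 + P_D)/2 for any table
  wu <- james_weights(2, correct = 0.5, incorrect = 0.5)
  comp <- james_point(gt2(c(50, 17, 0), c(25, 8, 0)), weights = wu)
  expect_equal(comp$P_O, 0.5)
  expect_equal(comp$P_E, 0.5)
  expect_equal(comp$jbi, 0.5)
})

test_that("jackknife CIs reproduce the published intervals", {
  expect_ci(james_bi(gt2(c(50, 50, 0), c(50, 50, 0))), 0.43, 0.57)
  big <- james_bi(gt2(c(557, 427, 756), c(418, 573, 764)))
  expect_equal(round(big$value, 2), 0.68)
  expect_ci(big, 0.66, 0.69)
})

test_that("identical leave-one-out values give a flagged zero-width CI", {
  # fully unblinded: every replicate evaluates to exactly 0
  est <- james_bi(gt2(c(30, 0, 0), c(0, 30, 0)))
  expect_equal(est$value, 0)
  expect_equal(est$se, 0)
  expect_true("zero_width_ci" %in% est$flags)
})

test_that("degenerate leave-one-out replicates are dropped with a warning", {
  x <- gt2(c(1, 0, 0), c(0, 1, 5))
  expect_warning(est <- james_bi(x), "replicate")
  expect_true("replicate_degenerate" %in% est$flags)
})

test_that("the index stays in [0, 1] on random non-degenerate tables", {
  set.seed(31)
  for (i in 1:300) {
    x <- rand_table(k = sample(2:3, 1))
    j <- james_point(x)$jbi
    expect_true(is.na(j) || (j >= 0 && j <= 1))
  }
})

test_that("simultaneous arm and guess permutation leaves the index unchanged", {
  set.seed(32)
  for (i in 1:50) {
    x <- rand_table(k = 3)
    p <- sample(3)
    y <- guess_table(x$counts[p, c(p, 4)], arms = x$arms[p],
                     guesses = x$guesses[p])
    expect_equal(james_point(y)$jbi, james_point(x)$jbi)
  }
})

test_that("scaling all counts keeps the point and shrinks the jackknife SE", {
  x <- gt2(c(36, 12, 19), c(18, 6, 9))
  base <- james_bi(x)
  prev_se <- base$se
  for (c in c(2L, 4L, 8L)) {
    xc <- guess_table(x$counts * c)
    ec <- james_bi(xc)
    expect_equal(ec$value, base$value)
    expect_lt(ec$se, prev_se)
    prev_se <- ec$se
  }
})

test_that("proportional arm rows imply P_O = P_E and JBI = (1 + P_D)/2", {
  set.seed(33)
  for (i in 1:30) {
    a <- c(rpois(2, 8) + 1, rpois(1, 5))
    c <- sample(1:4, 1)
    x <- gt2(a, c * a)
    comp <- james_point(x)
    expect_equal(comp$P_O, comp$P_E)
    expect_equal(comp$jbi, (1 + comp$P_D) / 2)
  }
})
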