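test_that("bang_arm reproduces the published arm estimates and CIs", {
  x <- gt2(c(36, 12, 19), c(18, 6, 9))
  a <- bang_arm(x, "A")
  expect_equal(a$value, 24 / 67)
  expect_ci(a, 0.17, 0.54)
  b <- bang_arm(x, 2)
  expect_equal(round(b$value, 2), -0.36)
  expect_ci(b, -0.63, -0.10)
  expect_true("unequal_allocation" %in% a$flags)

  # balanced guessing: exact zero
  expect_equal(bang_arm(gt2(c(50, 50, 0), c(50, 50, 0)), 1)$value, 0)
})

test_that("a unanimous arm yields a flagged zero-width CI", {
  est <- bang_arm(gt2(c(42, 0), c(19, 2)), "A")
  expect_equal(est$value, 1)
  expect_equal(c(est$ci_low, est$ci_high), c(1, 1))
  expect_true("zero_width_ci" %in% est$flags)
})

test_that("the contrast and scaled-binomial formulations agree on random arms", {
  set.seed(41)
  for (i in 1:300) {
    x <- rand_table()
    j <- sample(2, 1)
    row <- x$counts[j, ]
    corr <- row[j]; inc <- row[setdiff(1:2, j)]; n <- sum(row)
    if (corr + inc == 0) next
    eq3 <- (2 * corr / (corr + inc) - 1) * (corr + inc) / n
    expect_equal(bang_arm(x, j)$value, unname(eq3))
  }
})

test_that("an all-IDK arm is an explicit error, not a silent zero", {
  x <- gt2(c(0, 0, 50), c(10, 5, 5))
  expect_error(bang_arm(x, 1), "only IDK")
  expect_error(bang_arm(x, "A"), "degenerate")
  expect_silent(e <- bang_arm(x, 2))
  expect_error(bang_arm(x, 5), "arm must be")
  expect_error(bang_arm(x, "Z"), "arm must be")
})

test_that("one-sided intervals use z at level 1 - alpha on the requested side", {
  x <- gt2(c(36, 12, 19), c(18, 6, 9))
  two <- bang_arm(x, 1)
  lo <- bang_arm(x, 1, alternative = "greater")
  hi <- bang_arm(x, 1, alternative = "less")
  z95 <- qnorm(0.95)
  expect_equal(lo$ci_low, two$value - z95 * two$se)
  expect_equal(lo$ci_high, 1)
  expect_equal(hi$ci_high, two$value + z95 * two$se)
  expect_equal(hi$ci_low, -1)
})

test_that("sumBI adds the arm indices at full precision", {
  expect_equal(bang_sum(gt2(c(15, 0, 85), c(0, 15, 85)))$value, 0.30)
  expect_equal(round(bang_sum(gt2(c(42, 0), c(19, 2)))$value, 2), 0.19)
  # the sum uses unrounded components: 24/67 - 12/33
  expect_equal(bang_sum(gt2(c(36, 12, 19), c(18, 6, 9)))$value,
               24 / 67 - 12 / 33)
  expect_error(bang_sum(blinding_fixtures()$disulfiram), "exactly two arms")
})

test_that("swapping arms (with guess labels) swaps the BBIs, sumBI invariant", {
  set.seed(42)
  for (i in 1:100) {
    x <- rand_table()
    y <- guess_table(x$counts[2:1, c(2:1, 3)], arms = x$arms[2:1],
                     guesses = x$guesses[2:1])
    expect_equal(bang_arm(y, 1)$value, bang_arm(x, 2)$value)
    expect_equal(bang_arm(y, 2)$value, bang_arm(x, 1)$value)
    expect_equal(bang_sum(y)$value, bang_sum(x)$value)
  }
})

test_that("multi-arm tables are reported with a caveat flag", {
  d <- blinding_fixtures()$disulfiram
  e <- bang_arm(d, "ribo")
  expect_true("multi_arm" %in% e$flags)
  expect_equal(e$value, (64 - (22 + 36)) / 174 * -1 * -1)  # (correct - incorrect)/n
  expect_equal(e$value, (64 - 58) / 174)
})

test_that("likert tables collapse by default and support graded weights", {
  statin <- blinding_fixtures()$statin
  coll <- bang_arm(statin, 1)
  expect_equal(coll$value, (82 - 25) / 277)
  wtd <- bang_arm(statin, 1, likert = "weighted")
  expect_equal(wtd$value, (38 + 0.5 * 44 - 0.5 * 21 - 4) / 277)
  expect_equal(round(wtd$value, 2), 0.16)
  expect_ci(wtd, 0.11, 0.21)
  expect_true("likert_weighted" %in% wtd$flags)
  expect_equal(round(bang_sum(statin, likert = "weighted")$value, 2), 0.16)
})

test_that("index and sum respect their ranges after truncation", {
  set.seed(43)
  for (i in 1:100) {
    x <- rand_table()
    for (j in 1:2) {
      e <- bang_arm(x, j)
      expect_true(e$value >= -1 && e$value <= 1)
      expect_true(e$ci_low >= -1 && e$ci_high <= 1)
    }
    s <- bang_sum(x)
    expect_true(s$value >= -2 && s$value <= 2)
  }
  # extreme case: complete opposite guessing in both arms
  s <- bang_sum(gt2(c(0, 100, 0), c(100, 0, 0)))
  expect_equal(s$value, -2)
  expect_equal(c(s$ci_low, s$ci_high), c(-2, -2))
})
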