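test_that("wilson_ci matches its closed form and the score interval in stats", {
  expect_equal(round(wilson_ci(15, 15), 4), c(low = 0.7961, high = 1.0000))
  expect_equal(round(wilson_ci(0, 15), 4), c(low = 0.0000, high = 0.2039))
  # p-hat = 0.5: symmetric about 0.5
  w <- wilson_ci(5, 10)
  expect_equal(unname(w[1] + w[2]), 1)
  expect_true(w[1] < 0.5 && w[2] > 0.5)
  # independent oracle: prop.test without continuity correction
  for (x in c(0, 1, 7, 19, 20)) {
    ref <- stats::prop.test(x, 20, correct = FALSE)$conf.int
    expect_equal(unname(wilson_ci(x, 20)), as.numeric(ref), tolerance = 1e-10)
  }
  expect_error(wilson_ci(1, 0), "trials")
  expect_error(wilson_ci(5, 3), "successes")
})

test_that("simple_point is the between-arm difference in active-guess proportions", {
  expect_equal(simple_point(gt2(c(15, 0), c(0, 15))), 1)
  expect_equal(simple_point(gt2(c(36, 12), c(18, 6))), 0)
  expect_equal(simple_point(gt2(c(7, 3), c(7, 3))), 0)
  # IDK responses are excluded on the way in
  expect_equal(simple_point(gt2(c(15, 0, 85), c(0, 15, 85))), 1)
  expect_error(simple_point(gt2(c(0, 0, 100), c(0, 0, 100))), "only IDK")
  expect_error(simple_point(blinding_fixtures()$disulfiram), "two arms")
})

test_that("the MOVER interval reproduces the published SBI CIs", {
  e <- simple_bi(gt2(c(15, 0, 85), c(0, 15, 85)))
  expect_equal(e$value, 1)
  expect_ci(e, 0.71, 1.00)
  expect_true("idk_excluded" %in% e$flags)
  expect_equal(e$n, 30)

  ai <- simple_bi(gt2(c(557, 427, 756), c(418, 573, 764)))
  expect_equal(round(ai$value, 2), 0.14)
  expect_ci(ai, 0.10, 0.19)
  expect_equal(ai$n, 557 + 427 + 418 + 573)
})

test_that("certain guessing in both arms pins the upper bound at 1", {
  for (n in c(20, 200, 2000)) {
    e <- simple_bi(gt2(c(n, 0), c(0, n)))
    expect_equal(e$value, 1)
    expect_equal(e$ci_high, 1)
    expect_lt(e$ci_low, 1)
  }
  # lower bound approaches 1 as certainty grows
  expect_gt(simple_bi(gt2(c(2000, 0), c(0, 2000)))$ci_low,
            simple_bi(gt2(c(20, 0), c(0, 20)))$ci_low)
})

test_that("swapping the arm rows flips the sign and mirrors the CI", {
  set.seed(51)
  for (i in 1:50) {
    x <- rand_table(with_idk = FALSE)
    y <- guess_table(x$counts[2:1, ], arms = x$arms[2:1], guesses = x$guesses)
    ex <- simple_bi(x); ey <- simple_bi(y)
    expect_equal(ey$value, -ex$value)
    expect_equal(ey$ci_low, -ex$ci_high)
    expect_equal(ey$ci_high, -ex$ci_low)
  }
})

test_that("the point estimate is invariant to scaling one arm's counts", {
  x <- gt2(c(36, 12), c(18, 6))
  for (c in c(2L, 5L)) {
    y <- guess_table(rbind(x$counts[1, ] * c, x$counts[2, ]))
    expect_equal(simple_point(y), simple_point(x))
  }
})

test_that("the CI contains the point and narrows as counts scale up", {
  set.seed(52)
  for (i in 1:30) {
    x <- rand_table(with_idk = FALSE)
    e <- simple_bi(x)
    expect_true(e$ci_low <= e$value && e$value <= e$ci_high)
    e4 <- simple_bi(guess_table(x$counts * 4L))
    expect_lt(e4$ci_high - e4$ci_low, e$ci_high - e$ci_low)
  }
})

test_that("sumBI equals twice SBI on tables without IDK responses", {
  set.seed(53)
  for (i in 1:100) {
    x <- rand_table(with_idk = FALSE)
    expect_equal(bang_sum(x)$value, 2 * simple_point(x))
  }
})
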