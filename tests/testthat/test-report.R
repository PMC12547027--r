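test_that("interpretation labels follow the ad-hoc cutoffs", {
  j <- new_est <- blindex:::new_blind_est
  jbi <- new_est("JBI", 0.64, 0.05, c(0.55, 0.73), 0.95, "jackknife-normal", 100)
  expect_match(interpret_estimates(list(jbi)), "CI lower limit > 0.5")

  border <- new_est("JBI", 0.52, 0.06, c(0.40, 0.64), 0.95, "jackknife-normal", 69)
  expect_match(interpret_estimates(list(border)), "random guess")

  low <- new_est("JBI", 0.30, 0.02, c(0.26, 0.34), 0.95, "jackknife-normal", 500)
  expect_match(interpret_estimates(list(low)), "not be successful")

  full <- new_est("BBI_A", 1, 0, c(1, 1), 0.95, "multinomial-normal", 42,
                  flags = "zero_width_ci")
  expect_match(interpret_estimates(list(full)), "complete correct guessing")

  zero <- new_est("BBI_A", 0, 0.1, c(-0.2, 0.2), 0.95, "multinomial-normal", 100)
  expect_match(interpret_estimates(list(zero), stringent = TRUE), "perfect")
  expect_match(interpret_estimates(list(zero), stringent = FALSE), "perfect")

  mid <- new_est("BBI_B", 0.25, 0.1, c(0.05, 0.45), 0.95, "multinomial-normal", 100)
  expect_match(interpret_estimates(list(mid), stringent = TRUE), "0.2 cutoff")
  expect_match(interpret_estimates(list(mid), stringent = FALSE), "success")

  sbi <- new_est("SBI", 0.14, NA, c(0.10, 0.19), 0.95, "wilson-mover", 1975)
  expect_match(interpret_estimates(list(sbi)), "no interpretation guidance")
})

test_that("the acupuncture report carries the published story", {
  rep <- blinding_report(blinding_fixtures()$acupuncture)
  txt <- paste(render_report(rep, "text"), collapse = "\n")
  expect_match(txt, "BBI_active = 1.00 (1.00, 1.00)", fixed = TRUE)
  expect_match(txt, "JBI = 0.44", fixed = TRUE)
  expect_match(txt, "no IDK response option")
  expect_match(txt, "zero-width CI")
})

test_that("reports are a pure function of their input", {
  x <- blinding_fixtures()$hypothetical_06
  r1 <- blinding_report(x)
  r2 <- blinding_report(x)
  expect_identical(render_report(r1, "json"), render_report(r2, "json"))
  expect_identical(r1$labels, r2$labels)
})

test_that("JSON rendering keeps full precision and an empty notes array", {
  rep <- blinding_report(gt2(c(50, 50, 0), c(50, 50, 0), scale = "ternary"))
  js <- render_report(rep, "json")
  expect_match(js, '"notes":[]', fixed = TRUE)
  parsed <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_named(parsed, c("input", "estimates", "labels", "notes"))
  vals <- vapply(parsed$estimates, function(e) e$value, numeric(1))
  orig <- vapply(rep$estimates, function(e) e$value, numeric(1))
  expect_equal(signif(vals, 12), signif(unname(orig), 12))
  expect_error(render_report(rep, "xml"))
})

test_that("degenerate inputs produce a complete, flagged report", {
  rep <- blinding_report(gt2(c(0, 0, 100), c(0, 0, 100)))
  expect_named(rep$estimates, c("JBI", "BBI_A", "BBI_B", "sumBI", "SBI"))
  for (nm in c("BBI_A", "BBI_B", "sumBI", "SBI"))
    expect_true("undefined" %in% rep$estimates[[nm]]$flags)
  expect_true(any(grepl("only IDK", rep$notes)))
})

test_that("estimate formatting avoids negative zero at display precision", {
  e <- blindex:::new_blind_est("SBI", -0.0011, NA, c(-0.19, 0.22), 0.95,
                               "wilson-mover", 72)
  expect_equal(format(e), "SBI = 0.00 (-0.19, 0.22)")
})
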