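# Shorthand two-arm table builder used throughout the suite.
gt2 <- function(a, b, ...) guess_table(rbind(A = a, B = b), ...)

# Random non-degenerate k-arm guess table. Ensures every arm has at least
# one response and (when required) at least one non-IDK response per arm.
rand_table <- function(k = 2, max_n = 60, with_idk = TRUE, nonidk = TRUE) {
  repeat {
    m <- matrix(rpois(k * (k + 1), lambda = 6), k, k + 1)
    if (!with_idk) m[, k + 1] <- 0L
    if (any(rowSums(m) == 0)) next
    if (nonidk && any(rowSums(m[, seq_len(k), drop = FALSE]) == 0)) next
    return(guess_table(m))
  }
}

expect_ci <- function(est, low, high, tol = 1e-8) {
  expect_equal(round(est$ci_low, 2), low, tolerance = tol)
  expect_equal(round(est$ci_high, 2), high, tolerance = tol)
}
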