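#' Wilson score interval for a binomial proportion
#'
#' The score-based interval
#' \deqn{\frac{\hat p + z^2/2n \pm z\sqrt{\hat p(1-\hat p)/n + z^2/4n^2}}{1 + z^2/n},}
#' with \eqn{z = z_{1-\alpha/2}}. Bounds lie in `[0, 1]` and the interval has
#' nonzero width for any finite `trials`, including boundary counts — the
#' property that lets the Simple index avoid the zero-width intervals of
#' normality-based methods.
#'
#' @param successes,trials non-negative integers, `successes <= trials`,
#'   `trials >= 1`.
#' @param alpha two-sided error rate.
#' @return numeric length-2 vector `(low, high)`.
#' @examples
#' wilson_ci(15, 15)   # (0.796, 1)
#' @export
wilson_ci <- function(successes, trials, alpha = 0.05) {
  if (trials < 1) stop("trials must be >= 1", call. = FALSE)
  if (successes < 0 || successes > trials)
    stop("successes must lie in [0, trials]", call. = FALSE)
  z <- stats::qnorm(1 - alpha / 2)
  p <- successes / trials
  centre <- p + z^2 / (2 * trials)
  half <- z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2))
  c(low = (centre - half) / (1 + z^2 / trials),
    high = (centre + half) / (1 + z^2 / trials))
}

# Reduce a table to the 2x2 (no-IDK) format the Simple index requires,
# recording exclusions. Errors if an arm would be left empty.
.sbi_table <- function(x) {
  validate_guess_table(x)
  if (length(x$arms) != 2L)
    stop("the Simple index is defined for exactly two arms", call. = FALSE)
  drop_idk(x)
}

#' Simple blinding index: point estimate
#'
#' The between-arm difference in the proportion guessing the *active*
#' treatment (the first guess category),
#' \deqn{SBI = \hat P_A - \hat P_B
#'   = \frac{n_{AA}}{n_{AA}+n_{BA}} - \frac{n_{AB}}{n_{AB}+n_{BB}},}
#' on 2x2 data; 0 is perfect blinding, range `[-1, 1]`. The index is designed
#' for questionnaires without an IDK option; tables carrying IDK responses
#' are reduced via [drop_idk()] with the exclusions recorded, never silently.
#'
#' @param x a two-arm [guess_table()] (binary, ternary or Likert; non-binary
#'   input is collapsed/reduced first).
#' @return the point estimate as a plain number.
#' @examples
#' simple_point(guess_table(rbind(A = c(15, 0), B = c(0, 15))))  # 1
#' @export
simple_point <- function(x) {
  b <- .sbi_table(x)
  m <- b$counts
  m[1, 1] / sum(m[1, 1:2]) - m[2, 1] / sum(m[2, 1:2])
}

#' Simple blinding index with Wilson-score (MOVER) confidence interval
#'
#' Point estimate as [simple_point()]; the CI combines the two per-arm Wilson
#' score intervals by the MOVER/Newcombe hybrid: with arm bounds
#' \eqn{(l_1, u_1)} and \eqn{(l_2, u_2)} around \eqn{\hat p_1, \hat p_2} and
#' \eqn{d = \hat p_1 - \hat p_2},
#' \deqn{\Big(d - \sqrt{(\hat p_1 - l_1)^2 + (u_2 - \hat p_2)^2},\;
#'        d + \sqrt{(u_1 - \hat p_1)^2 + (\hat p_2 - l_2)^2}\Big),}
#' truncated to `[-1, 1]`. The interval is never zero-width for finite
#' samples and is not forced to be symmetric.
#'
#' @inheritParams simple_point
#' @param alpha two-sided error rate.
#' @return a `blind_est` named `"SBI"` with `method = "wilson-mover"`; the
#'   `idk_excluded` flag marks tables reduced from the IDK format, and `n`
#'   is the analytical sample size after exclusion.
#' @examples
#' simple_bi(guess_table(rbind(A = c(15, 0, 85), B = c(0, 15, 85))))
#' @export
simple_bi <- function(x, alpha = 0.05) {
  b <- .sbi_table(x)
  m <- b$counts
  n1 <- sum(m[1, 1:2]); n2 <- sum(m[2, 1:2])
  p1 <- m[1, 1] / n1; p2 <- m[2, 1] / n2
  d <- p1 - p2
  w1 <- wilson_ci(m[1, 1], n1, alpha)
  w2 <- wilson_ci(m[2, 1], n2, alpha)
  ci <- c(max(-1, d - sqrt((p1 - w1[1])^2 + (w2[2] - p2)^2)),
          min(1, d + sqrt((w1[2] - p1)^2 + (p2 - w2[1])^2)))
  se <- NA_real_  # the MOVER interval is not derived from a single SE
  flags <- character(0)
  if (length(b$excluded) && sum(b$excluded) > 0) flags <- "idk_excluded"
  est <- new_blind_est("SBI", d, se, ci, 1 - alpha, "wilson-mover",
                       as.integer(n1 + n2), flags)
  est$excluded <- b$excluded
  est
}
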