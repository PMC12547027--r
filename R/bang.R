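# Arm-level core on a numeric count row (length k+1, IDK last), arm index j.
# Counts may be fractional (population evaluation). Returns both algebraic
# forms of the index — the direct multinomial contrast and the
# scaled-binomial product — which agree whenever any non-IDK response exists.
.bbi_core <- function(row, j, k) {
  n <- sum(row)
  if (n <= 0) stop("empty arm", call. = FALSE)
  corr <- row[j]
  inc <- sum(row[seq_len(k)]) - corr
  p1 <- corr / n
  p2 <- inc / n
  eq2 <- p1 - p2
  eq3 <- if (corr + inc > 0)
    (2 * corr / (corr + inc) - 1) * (corr + inc) / n
  else NA_real_
  list(est = unname(eq2), eq3 = unname(eq3),
       var = unname((p1 + p2 - (p1 - p2)^2) / n),
       n = n, all_idk = corr + inc == 0)
}

# Weighted five-level core: weights +1 (strongly correct), +0.5 (somewhat
# correct), -0.5 (somewhat incorrect), -1 (strongly incorrect), 0 (IDK),
# estimate sum(w p) with multinomial variance [sum(w^2 p) - (sum(w p))^2]/n.
.bbi_likert_core <- function(row5, arm) {
  w <- c(1, 0.5, -0.5, -1, 0)
  if (arm == 2L) w <- c(-1, -0.5, 0.5, 1, 0)
  n <- sum(row5)
  if (n <= 0) stop("empty arm", call. = FALSE)
  p <- row5 / n
  list(est = sum(w * p), eq3 = sum(w * p),
       var = (sum(w^2 * p) - sum(w * p)^2) / n,
       n = n, all_idk = sum(row5[1:4]) == 0)
}

.bang_one <- function(x, arm, likert) {
  k <- length(x$arms)
  if (is.character(arm)) arm <- match(arm, x$arms)
  if (is.na(arm) || arm < 1L || arm > k)
    stop("arm must be an index in 1..", k, " or an arm label", call. = FALSE)
  if (x$scale == "likert5" && likert == "weighted") {
    core <- .bbi_likert_core(x$likert[arm, ], arm)
    core$weighted <- TRUE
  } else {
    if (x$scale == "likert5") x <- collapse_likert(x)
    core <- .bbi_core(x$counts[arm, ], arm, k)
    core$weighted <- FALSE
  }
  if (core$all_idk)
    stop("arm '", x$arms[arm], "' has only IDK responses: ",
         "the Bang index is undefined (degenerate arm)", call. = FALSE)
  if (!core$weighted && !isTRUE(all.equal(core$est, core$eq3)))
    stop("internal error: the two Bang formulations disagree", call. = FALSE)
  core$arm <- arm
  core
}

.bang_flags <- function(x) {
  k <- length(x$arms)
  flags <- character(0)
  if (k > 2L) flags <- c(flags, "multi_arm")
  if (k == 2L && length(unique(arm_totals(x))) > 1L)
    flags <- c(flags, "unequal_allocation")
  if (length(x$excluded) && sum(x$excluded) > 0) flags <- c(flags, "idk_excluded")
  flags
}

.one_or_two_sided_ci <- function(value, se, alpha, alternative, range) {
  if (alternative == "two.sided") {
    z <- stats::qnorm(1 - alpha / 2)
    ci <- c(value - z * se, value + z * se)
  } else {
    z <- stats::qnorm(1 - alpha)
    ci <- if (alternative == "greater") c(value - z * se, range[2])
          else c(range[1], value + z * se)
  }
  c(max(range[1], ci[1]), min(range[2], ci[2]))
}

#' Arm-specific Bang blinding index
#'
#' For arm `j`, the Bang index is the within-arm contrast between the
#' probability of guessing one's own treatment and of guessing another
#' treatment,
#' \deqn{BBI_j = \hat P(\mathrm{correct} \mid j) - \hat P(\mathrm{incorrect} \mid j),}
#' with IDK responses kept in the denominator. It ranges over `[-1, 1]`:
#' 0 is perfect blinding (or balanced random guessing), positive values mean
#' an excess of correct guesses, negative values opposite guessing. The
#' asymptotic variance is the multinomial-contrast form
#' \eqn{\{p_1 + p_2 - (p_1 - p_2)^2\}/n_j}. The equivalent scaled-binomial
#' formulation is evaluated alongside and asserted equal; the two differ only
#' for an all-IDK arm, where both are taken as undefined and an error is
#' raised rather than silently reporting 0.
#'
#' Five-level Likert tables are collapsed to ternary by default;
#' `likert = "weighted"` instead applies graded weights
#' (+1, +0.5, -0.5, -1, 0) to the uncollapsed responses.
#'
#' The index assumes a two-arm 1:1 design; unequal allocation or more than
#' two arms are reported rather than refused, with `unequal_allocation` /
#' `multi_arm` caveat flags.
#'
#' @param x a [guess_table()].
#' @param arm arm index (1-based) or arm label.
#' @param alpha error rate; the CI level is `1 - alpha`.
#' @param alternative `"two.sided"` (default) or a one-sided option
#'   (`"greater"`/`"less"`), giving `value ± z_(1-alpha) * SE` on the
#'   requested side.
#' @param likert `"collapse"` (default) or `"weighted"` for 2x5 tables.
#' @return a `blind_est` with `method = "multinomial-normal"`, truncated to
#'   `[-1, 1]`; a zero variance yields a flagged zero-width interval.
#' @examples
#' gt <- guess_table(rbind(A = c(36, 12, 19), B = c(18, 6, 9)))
#' bang_arm(gt, "A")
#' @export
bang_arm <- function(x, arm, alpha = 0.05,
                     alternative = c("two.sided", "greater", "less"),
                     likert = c("collapse", "weighted")) {
  alternative <- match.arg(alternative)
  likert <- match.arg(likert)
  validate_guess_table(x)
  core <- .bang_one(x, arm, likert)
  flags <- .bang_flags(x)
  if (core$weighted) flags <- c(flags, "likert_weighted")
  se <- sqrt(core$var)
  ci <- .one_or_two_sided_ci(core$est, se, alpha, alternative, c(-1, 1))
  if (se == 0) flags <- c(flags, "zero_width_ci", "degenerate")
  new_blind_est(paste0("BBI_", x$arms[core$arm]), core$est, se, ci,
                1 - alpha, "multinomial-normal", as.integer(round(core$n)), flags)
}

#' Study-level sum of the two Bang indices
#'
#' `sumBI = BBI_A + BBI_B`, a between-arm summary despite being a sum:
#' under "same guess" patterns the two arm indices cancel. Its range is
#' `[-2, 2]`. The variance is `Var_A + Var_B` (arms independent by
#' randomization) with a normal CI.
#'
#' @inheritParams bang_arm
#' @return a `blind_est` named `"sumBI"`.
#' @examples
#' bang_sum(guess_table(rbind(A = c(15, 0, 85), B = c(0, 15, 85))))
#' @export
bang_sum <- function(x, alpha = 0.05,
                     alternative = c("two.sided", "greater", "less"),
                     likert = c("collapse", "weighted")) {
  alternative <- match.arg(alternative)
  likert <- match.arg(likert)
  validate_guess_table(x)
  if (length(x$arms) != 2L)
    stop("sumBI is defined for exactly two arms", call. = FALSE)
  a <- .bang_one(x, 1L, likert)
  b <- .bang_one(x, 2L, likert)
  flags <- .bang_flags(x)
  if (a$weighted) flags <- c(flags, "likert_weighted")
  value <- a$est + b$est
  se <- sqrt(a$var + b$var)
  ci <- .one_or_two_sided_ci(value, se, alpha, alternative, c(-2, 2))
  if (se == 0) flags <- c(flags, "zero_width_ci", "degenerate")
  new_blind_est("sumBI", value, se, ci, 1 - alpha, "multinomial-normal",
                as.integer(round(a$n + b$n)), flags)
}
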