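#' Weight scheme for the James blinding index
#'
#' Constant cell weights `w[i, j]` (guess `i`, arm `j`) entering the weighted
#' observed and expected guess proportions: by convention 0 for a correct
#' guess, 0.5 for an incorrect guess, and 1 for IDK. The IDK weight enters
#' the index through its closed form (the `1 + P_D` term) rather than the
#' double sums, but is carried for documentation and validation. For designs
#' with more than two arms the same default applies to every incorrect cell;
#' any alternative matrix in `[0, 1]` may be supplied.
#'
#' @param k number of arms.
#' @param correct,incorrect,idk default weights.
#' @param w optional full `k x k` matrix (rows = guesses, columns = arms)
#'   overriding `correct`/`incorrect`.
#' @return object of class `james_weights`.
#' @export
james_weights <- function(k, correct = 0, incorrect = 0.5, idk = 1, w = NULL) {
  if (is.null(w)) {
    w <- matrix(incorrect, k, k)
    diag(w) <- correct
  }
  if (!is.matrix(w) || nrow(w) != k || ncol(w) != k)
    stop("w must be a ", k, " x ", k, " matrix", call. = FALSE)
  if (any(w < 0 | w > 1) || idk < 0 || idk > 1)
    stop("all weights must lie in [0, 1]", call. = FALSE)
  structure(list(w = w, idk = idk, k = k), class = "james_weights")
}

# Core evaluation on a plain numeric k x (k+1) count matrix (rows = arms,
# last column = IDK). Counts may be fractional: the same routine evaluates
# the population index on expected counts.
.jbi_core <- function(m, w) {
  k <- nrow(m)
  N <- sum(m)
  PD <- sum(m[, k + 1L]) / N
  if (PD >= 1) {
    return(list(P_D = 1, P_O = NA_real_, P_E = NA_real_,
                kappa_term = NA_real_, jbi = NA_real_, defined = FALSE))
  }
  P <- t(m[, seq_len(k), drop = FALSE]) / N        # P[i, j]: guess i, arm j
  PO <- sum(w * P) / (1 - PD)
  Pi_ <- rowSums(P)                                # guess marginals
  Pj <- rowSums(m) / N                             # arm marginals
  PDj <- m[, k + 1L] / N
  PE <- sum(w * (Pi_ %o% (Pj - PDj))) / (1 - PD)^2
  if (PE <= 0)
    stop("degenerate table: expected weighted proportion P_E is zero", call. = FALSE)
  kap <- (PO - PE) / PE
  list(P_D = PD, P_O = PO, P_E = PE, kappa_term = kap,
       jbi = (1 + PD + (1 - PD) * kap) / 2, defined = TRUE)
}

#' James blinding index: point estimate and components
#'
#' Evaluates the James index
#' \deqn{JBI = \{1 + P_D + (1 - P_D)(P_O - P_E)/P_E\}/2,}
#' where \eqn{P_D} is the IDK proportion, and \eqn{P_O} and \eqn{P_E} are the
#' weighted observed and expected guess proportions; \eqn{(P_O - P_E)/P_E} is
#' the kappa-like disagreement term. JBI lies in `[0, 1]`; 1 is perfect
#' blinding and values near 0.5 indicate random guessing. When every response
#' is IDK (\eqn{P_D = 1}) the index is undefined through a division by zero;
#' by default it is returned as `NA` with a degeneracy flag, or as 1 under
#' the `undefined_as_one` convention.
#'
#' Likert (2x5) tables are collapsed to ternary before evaluation.
#'
#' @param x a [guess_table()].
#' @param weights a [james_weights()]; default 0 / 0.5 / 1.
#' @param undefined_as_one adopt the convention JBI = 1 when \eqn{P_D = 1}.
#' @return a list with `P_D`, `P_O`, `P_E`, `kappa_term`, `jbi`, `defined`.
#' @examples
#' james_point(guess_table(rbind(A = c(36, 12, 19), B = c(18, 6, 9))))
#' @export
james_point <- function(x, weights = NULL, undefined_as_one = FALSE) {
  validate_guess_table(x)
  if (x$scale == "likert5") x <- collapse_likert(x)
  k <- length(x$arms)
  if (is.null(weights)) weights <- james_weights(k)
  stopifnot(inherits(weights, "james_weights"), weights$k == k)
  comp <- .jbi_core(x$counts, weights$w)
  if (!comp$defined && undefined_as_one) comp$jbi <- 1
  comp
}

#' Leave-one-respondent-out James index replicates
#'
#' Returns the `N` leave-one-out index values used by the jackknife variance.
#' `method = "grouped"` evaluates one replicate per occupied cell and repeats
#' it by the cell count (an exact optimization); `method = "naive"` expands
#' the table to respondent-level records and re-tallies the remaining `N - 1`
#' records for every respondent. The two must agree exactly.
#'
#' @param x a [guess_table()] (ternary/binary/multi-arm; Likert is collapsed).
#' @param weights a [james_weights()] or `NULL` for the default.
#' @param method `"grouped"` or `"naive"`.
#' @return numeric vector of length `N`; replicates whose subtable leaves the
#'   index undefined are `NA`.
#' @export
james_jackknife <- function(x, weights = NULL, method = c("grouped", "naive")) {
  method <- match.arg(method)
  validate_guess_table(x)
  if (x$scale == "likert5") x <- collapse_likert(x)
  k <- length(x$arms)
  if (is.null(weights)) weights <- james_weights(k)
  m <- x$counts
  eval1 <- function(mm) {
    tryCatch({
      cc <- .jbi_core(mm, weights$w)
      if (cc$defined) cc$jbi else NA_real_
    }, error = function(e) NA_real_)
  }
  if (method == "grouped") {
    vals <- counts <- numeric(0)
    for (j in seq_len(nrow(m))) for (i in seq_len(ncol(m))) {
      if (m[j, i] > 0L) {
        mm <- m; mm[j, i] <- mm[j, i] - 1L
        vals <- c(vals, eval1(mm)); counts <- c(counts, m[j, i])
      }
    }
    return(rep(vals, counts))
  }
  # naive: respondent-level re-tally
  codes <- rep(seq_along(m), as.vector(m))          # cell id per respondent
  N <- length(codes)
  out <- numeric(N)
  for (r in seq_len(N)) {
    mm <- m
    mm[codes[r]] <- mm[codes[r]] - 1L
    out[r] <- eval1(mm)
  }
  out
}

#' James blinding index with jackknife confidence interval
#'
#' Computes the James index on the full table and a normal-approximation CI
#' from the leave-one-respondent-out jackknife variance
#' \eqn{\hat V = \frac{N-1}{N}\sum_r (\theta_{(-r)} - \bar\theta_{(\cdot)})^2,}
#' with the interval centred on the full-sample point estimate and truncated
#' to `[0, 1]`. Replicates whose subtable leaves the index undefined are
#' dropped from the variance with a warning and a `replicate_degenerate`
#' flag. A zero jackknife variance yields a zero-width interval, flagged.
#'
#' @inheritParams james_point
#' @param alpha two-sided error rate; the CI level is `1 - alpha`.
#' @param weights a [james_weights()] or `NULL` for the default scheme.
#' @return a `blind_est` with `method = "jackknife-normal"` (or `"none"` when
#'   the index is undefined on the full table).
#' @examples
#' james_bi(guess_table(rbind(A = c(50, 50, 0), B = c(50, 50, 0))))
#' @export
james_bi <- function(x, alpha = 0.05, weights = NULL, undefined_as_one = FALSE) {
  validate_guess_table(x)
  flags <- character(0)
  if (x$scale == "likert5") x <- collapse_likert(x)
  if (length(x$excluded) && sum(x$excluded) > 0) flags <- c(flags, "idk_excluded")
  N <- n_total(x)
  comp <- james_point(x, weights = weights)
  if (!comp$defined) {
    flags <- c(flags, "degenerate", if (!undefined_as_one) "undefined")
    val <- if (undefined_as_one) 1 else NA_real_
    ci <- if (undefined_as_one) c(1, 1) else c(NA_real_, NA_real_)
    return(new_blind_est("JBI", val, if (undefined_as_one) 0 else NA_real_,
                         ci, 1 - alpha, "none", N, flags, comp))
  }
  if (N < 2L) stop("jackknife requires N >= 2", call. = FALSE)
  reps <- james_jackknife(x, weights = weights, method = "grouped")
  if (anyNA(reps)) {
    flags <- c(flags, "replicate_degenerate")
    warning(sum(is.na(reps)), " leave-one-out replicate(s) left the index ",
            "undefined and were dropped from the jackknife variance")
    reps <- reps[!is.na(reps)]
  }
  n_rep <- length(reps)
  v <- (n_rep - 1) / n_rep * sum((reps - mean(reps))^2)
  se <- sqrt(v)
  z <- stats::qnorm(1 - alpha / 2)
  ci <- c(max(0, comp$jbi - z * se), min(1, comp$jbi + z * se))
  if (se == 0) flags <- c(flags, "zero_width_ci", "degenerate")
  new_blind_est("JBI", comp$jbi, se, ci, 1 - alpha, "jackknife-normal",
                N, flags, comp)
}
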