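#' Specify a blinding scenario for simulation
#'
#' A scenario fixes, for each arm, the multinomial probabilities of the
#' guess categories (the `k` treatment guesses plus IDK) and the arm sample
#' size, together with a seed. These are the population analogues of the
#' guess tables the estimators consume.
#'
#' @param probs numeric `k x (k+1)` matrix, one row per arm, each row
#'   summing to 1 (tolerance `1e-12`); last column = IDK probability.
#'   A `k x k` matrix is accepted and padded with a zero IDK column.
#' @param n per-arm sample sizes (length `k`, recycled from length 1).
#' @param seed integer seed driving [simulate_table()] and
#'   [coverage_experiment()].
#' @param arms optional arm labels.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(probs, n, seed = 1L, arms = NULL) {
  if (!is.matrix(probs)) probs <- matrix(probs, nrow = 1)
  k <- nrow(probs)
  if (k < 2L) stop("a scenario needs at least two arms", call. = FALSE)
  if (ncol(probs) == k) probs <- cbind(probs, 0)
  if (ncol(probs) != k + 1L)
    stop("probs must be k x (k+1) (last column = IDK)", call. = FALSE)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  bad <- abs(rowSums(probs) - 1) > 1e-12
  if (any(bad))
    stop("probability rows must sum to 1 (arm ", which(bad)[1], " sums to ",
         format(rowSums(probs)[bad][1], digits = 15), ")", call. = FALSE)
  n <- rep_len(as.integer(n), k)
  if (any(is.na(n) | n < 0)) stop("arm sizes must be >= 0", call. = FALSE)
  if (is.null(arms)) arms <- rownames(probs)
  if (is.null(arms)) arms <- LETTERS[seq_len(k)]
  rownames(probs) <- arms
  structure(list(probs = probs, n = n, seed = as.integer(seed), arms = arms),
            class = "scenario_spec")
}

#' Named scenario presets
#'
#' Two-arm population analogues of the canonical response patterns:
#' `"all_idk"` (every respondent answers IDK), `"opposite_guess"` (guesses
#' invert assignment), `"random_guess"` (uninformative 50/50 guessing),
#' `"same_guess_active"` (both arms guess the active treatment), and
#' `"unblinded"` (every respondent guesses correctly).
#'
#' @param name preset name.
#' @param n per-arm sample size (default 100).
#' @param seed integer seed.
#' @return a [scenario_spec()].
#' @export
scenario_preset <- function(name = c("all_idk", "opposite_guess", "random_guess",
                                     "same_guess_active", "unblinded"),
                            n = 100, seed = 1L) {
  name <- match.arg(name)
  probs <- switch(name,
    all_idk           = rbind(c(0, 0, 1),     c(0, 0, 1)),
    opposite_guess    = rbind(c(0, 1, 0),     c(1, 0, 0)),
    random_guess      = rbind(c(0.5, 0.5, 0), c(0.5, 0.5, 0)),
    same_guess_active = rbind(c(0.9, 0.1, 0), c(0.9, 0.1, 0)),
    unblinded         = rbind(c(1, 0, 0),     c(0, 1, 0)))
  scenario_spec(probs, n = n, seed = seed)
}

#' Draw one guess table from a scenario
#'
#' Each arm's guess counts are drawn from the multinomial distribution with
#' the scenario's probabilities. Reproducible: the same spec (including its
#' seed) always yields the same table.
#'
#' @param spec a [scenario_spec()].
#' @return a [guess_table()].
#' @export
simulate_table <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  .simulate_table_unseeded(spec)
}

.simulate_table_unseeded <- function(spec) {
  k <- nrow(spec$probs)
  m <- matrix(0L, k, k + 1L)
  for (j in seq_len(k))
    if (spec$n[j] > 0L)
      m[j, ] <- as.integer(stats::rmultinom(1, spec$n[j], spec$probs[j, ]))
  guess_table(m, arms = spec$arms,
              scale = if (all(m[, k + 1L] == 0L)) "binary" else "ternary")
}

#' Population blinding-index values for a scenario
#'
#' Evaluates the population versions of the indices on the expected counts
#' `n_j * p_j`: the same closed forms as the estimators, applied to
#' probabilities instead of observed frequencies. Under an all-IDK scenario
#' the population James index is undefined (`NA`), matching the sample-side
#' convention, and the Bang/Simple values are undefined as well.
#'
#' @param spec a [scenario_spec()] (two arms for `sumBI`/`SBI`).
#' @return named numeric vector with elements `JBI`, `BBI_A`, `BBI_B` (one
#'   per arm for multi-arm scenarios), `sumBI`, `SBI`; undefined entries are
#'   `NA`.
#' @export
population_indices <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  k <- nrow(spec$probs)
  m <- spec$probs * spec$n          # expected counts, possibly fractional
  w <- james_weights(k)$w
  jbi <- tryCatch({
    cc <- .jbi_core(m, w)
    if (cc$defined) cc$jbi else NA_real_
  }, error = function(e) NA_real_)
  bbi <- vapply(seq_len(k), function(j) {
    tryCatch({
      core <- .bbi_core(m[j, ], j, k)
      if (core$all_idk) NA_real_ else core$est
    }, error = function(e) NA_real_)
  }, numeric(1))
  names(bbi) <- paste0("BBI_", spec$arms)
  out <- c(JBI = jbi, bbi)
  if (k == 2L) {
    out["sumBI"] <- sum(bbi)
    nonidk <- m[, 1:2]
    out["SBI"] <- if (any(rowSums(nonidk) == 0)) NA_real_ else
      nonidk[1, 1] / sum(nonidk[1, ]) - nonidk[2, 1] / sum(nonidk[2, ])
  }
  out
}

#' Coverage and bias experiment for the index estimators
#'
#' Repeatedly simulates tables under a scenario, estimates the requested
#' indices with their confidence intervals, and summarizes empirical CI
#' coverage of the population value, mean bias, and Monte-Carlo standard
#' errors. Replicates where an estimator is undefined (degenerate draw) are
#' dropped for that index and counted.
#'
#' Reproducibility: the scenario seed generates one sub-seed per replicate
#' up front, so results do not depend on evaluation order.
#'
#' @param spec a two-arm [scenario_spec()].
#' @param reps number of replicates (>= 1).
#' @param alpha CI error rate.
#' @param indices subset of `c("BBI_A", "BBI_B", "sumBI", "SBI", "JBI")`;
#'   the James jackknife makes `"JBI"` the costly one, so it is opt-in.
#' @param true population values; defaults to [population_indices()].
#' @return data frame with one row per index: `true`, `mean_est`, `bias`,
#'   `mc_se` (MC error of the bias), `coverage`, `cover_se`, `reps_used`.
#' @examples
#' sc <- scenario_spec(rbind(c(0.4, 0.3, 0.3), c(0.3, 0.4, 0.3)),
#'                     n = 50, seed = 42)
#' coverage_experiment(sc, reps = 200, indices = "BBI_A")
#' @export
coverage_experiment <- function(spec, reps, alpha = 0.05,
                                indices = c("BBI_A", "BBI_B", "sumBI", "SBI"),
                                true = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (length(spec$arms) != 2L)
    stop("coverage_experiment supports two-arm scenarios", call. = FALSE)
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  allowed <- c(paste0("BBI_", spec$arms), "sumBI", "SBI", "JBI")
  canon <- c("BBI_A", "BBI_B", "sumBI", "SBI", "JBI")
  indices <- match.arg(indices, choices = unique(c(canon, allowed)),
                       several.ok = TRUE)
  # map canonical BBI_A/BBI_B onto the actual arm labels
  indices <- unique(ifelse(indices == "BBI_A", paste0("BBI_", spec$arms[1]),
                    ifelse(indices == "BBI_B", paste0("BBI_", spec$arms[2]),
                           indices)))
  pop <- population_indices(spec)
  names(pop)[names(pop) == paste0("BBI_", spec$arms[1])] <- paste0("BBI_", spec$arms[1])
  if (is.null(true)) true <- pop

  set.seed(spec$seed)
  subseeds <- sample.int(2147483646L, reps)
  est <- cov <- matrix(NA_real_, reps, length(indices),
                       dimnames = list(NULL, indices))
  for (r in seq_len(reps)) {
    set.seed(subseeds[r])
    tab <- .simulate_table_unseeded(spec)
    for (idx in indices) {
      e <- tryCatch({
        if (idx == "JBI") james_bi(tab, alpha = alpha)
        else if (idx == "sumBI") bang_sum(tab, alpha = alpha)
        else if (idx == "SBI") simple_bi(tab, alpha = alpha)
        else bang_arm(tab, sub("^BBI_", "", idx), alpha = alpha)
      }, error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(e) && !is.na(e$value)) {
        est[r, idx] <- e$value
        tv <- true[[idx]]
        if (!is.na(e$ci_low) && !is.na(tv))
          cov[r, idx] <- as.numeric(e$ci_low <= tv && tv <= e$ci_high)
      }
    }
  }
  out <- lapply(indices, function(idx) {
    ev <- est[, idx]; cv <- cov[, idx]
    used <- sum(!is.na(ev))
    covered <- mean(cv, na.rm = TRUE)
    data.frame(index = idx, true = unname(true[[idx]]),
               mean_est = mean(ev, na.rm = TRUE),
               bias = mean(ev, na.rm = TRUE) - true[[idx]],
               mc_se = stats::sd(ev, na.rm = TRUE) / sqrt(max(used, 1L)),
               coverage = covered,
               cover_se = sqrt(covered * (1 - covered) / max(sum(!is.na(cv)), 1L)),
               reps_used = used, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
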