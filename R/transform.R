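#' Collapse a five-level Likert guess table to three levels
#'
#' Combines "strongly" and "somewhat" beliefs per guessed treatment:
#' guess-A = strongly-A + somewhat-A, guess-B = somewhat-B + strongly-B,
#' IDK preserved. The grand total is unchanged.
#'
#' @param x a [guess_table()] with `scale = "likert5"`.
#' @return a ternary [guess_table()].
#' @export
collapse_likert <- function(x) {
  validate_guess_table(x)
  if (x$scale != "likert5")
    stop("collapse_likert() requires a likert5 table", call. = FALSE)
  out <- guess_table(x$counts, arms = x$arms, guesses = x$guesses, scale = "ternary")
  out$excluded <- x$excluded
  out$trans <- c(x$trans, "collapsed 5-level Likert to ternary (strong+somewhat)")
  out
}

#' Combine arms (and their guess categories) of a guess table
#'
#' Pools arms and guess categories according to partitions of the existing
#' labels, e.g. merging low- and high-dose arms of a three-arm trial into a
#' single treated arm for two-arm indices. Each cell of the combined table is
#' the sum of its constituent cells; IDK always maps to IDK, and the grand
#' total is unchanged. The i-th group in `arm_groups` is aligned with the
#' i-th group in `guess_groups` so positional correctness is preserved.
#'
#' @param x a [guess_table()] (ternary or multi-arm).
#' @param arm_groups named list of character vectors partitioning `x$arms`;
#'   names become the new arm labels.
#' @param guess_groups named list partitioning `x$guesses`; defaults to
#'   `arm_groups` applied to the guess labels.
#' @return a [guess_table()] with one row/column per group.
#' @examples
#' d <- guess_table(rbind(low  = c(41, 66, 30, 44),
#'                        high = c(27, 72, 24, 51),
#'                        ribo = c(22, 36, 64, 52)))
#' combine_arms(d, list(disulfiram = c("low", "high"), riboflavin = "ribo"))
#' @export
combine_arms <- function(x, arm_groups, guess_groups = NULL) {
  validate_guess_table(x)
  if (x$scale == "likert5")
    stop("combine_arms() does not operate on likert5 tables; collapse first",
         call. = FALSE)
  if (is.null(guess_groups)) {
    guess_groups <- lapply(arm_groups, function(g) x$guesses[match(g, x$arms)])
    names(guess_groups) <- names(arm_groups)
  }
  .check_partition(arm_groups, x$arms, "arm")
  .check_partition(guess_groups, x$guesses, "guess")
  if (length(arm_groups) != length(guess_groups))
    stop("arm_groups and guess_groups must have the same number of groups", call. = FALSE)

  k2 <- length(arm_groups)
  m <- matrix(0L, k2, k2 + 1L)
  for (i in seq_len(k2)) {
    rows <- match(arm_groups[[i]], x$arms)
    for (j in seq_len(k2)) {
      cols <- match(guess_groups[[j]], x$guesses)
      m[i, j] <- sum(x$counts[rows, cols])
    }
    m[i, k2 + 1L] <- sum(x$counts[rows, length(x$arms) + 1L])
  }
  out <- guess_table(m, arms = names(arm_groups), guesses = names(guess_groups),
                     scale = if (all(m[, k2 + 1L] == 0L)) "binary" else "ternary")
  out$excluded <- x$excluded
  out$trans <- c(x$trans, sprintf("combined %d arms into %d", length(x$arms), k2))
  out
}

.check_partition <- function(groups, labels, what) {
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop(what, "_groups must be a named list", call. = FALSE)
  flat <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(flat))
    stop(what, " partition repeats label(s): ",
         paste(flat[duplicated(flat)], collapse = ", "), call. = FALSE)
  missing <- setdiff(labels, flat)
  if (length(missing))
    stop(what, " partition does not cover: ", paste(missing, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(flat, labels)
  if (length(extra))
    stop("unknown ", what, " label(s): ", paste(extra, collapse = ", "), call. = FALSE)
  invisible(groups)
}

#' Exclude "I don't know" responses from a guess table
#'
#' Removes the IDK column, shrinking each arm's total by its IDK count.
#' The excluded counts are recorded on the returned table (field `excluded`)
#' and surfaced by downstream reports — respondents are never silently
#' discarded. This is the reduction the Simple blinding index requires, since
#' it operates on the 2x2 format.
#'
#' @param x a [guess_table()].
#' @return a binary [guess_table()] with an all-zero IDK column.
#' @export
drop_idk <- function(x) {
  validate_guess_table(x)
  if (x$scale == "likert5") x <- collapse_likert(x)
  k <- length(x$arms)
  idk <- idk_counts(x)
  if (all(idk == 0L)) {
    if (x$scale == "binary") return(x)
    out <- x; out$scale <- "binary"
    return(out)
  }
  m <- x$counts[, seq_len(k), drop = FALSE]
  degenerate <- rowSums(m) == 0L
  if (any(degenerate))
    stop("arm(s) with only IDK responses: ", paste(x$arms[degenerate], collapse = ", "),
         call. = FALSE)
  out <- guess_table(m, arms = x$arms, guesses = x$guesses, scale = "binary")
  excl <- stats::setNames(as.integer(idk), x$arms)
  out$excluded <- if (length(x$excluded)) x$excluded + excl else excl
  out$trans <- c(x$trans, sprintf("excluded %d IDK response(s)", sum(idk)))
  out
}
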