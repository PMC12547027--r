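#' Cross-tabulated treatment guesses for a blinded trial
#'
#' A `guess_table` holds the counts of post-randomization treatment guesses
#' cross-tabulated by randomized arm: one row per arm, one column per
#' treatment-guess category, plus a final "I don't know" (IDK) column. The
#' guess category at ordinal position `j` is the *correct* guess for the arm
#' in row `j`; correctness is positional, never by string matching of labels.
#'
#' Two-arm data without an IDK response option (a "2x2" questionnaire) are
#' represented with an all-zero IDK column and `scale = "binary"`, so that
#' every estimator consumes the same type. Five-level Likert data
#' ("strongly/somewhat believe A", "somewhat/strongly believe B", IDK) are
#' carried alongside their three-level collapse in the `likert` field with
#' `scale = "likert5"`.
#'
#' @param counts integer matrix of guess counts with one row per arm. Accepted
#'   shapes for `k` arms: `k x k` (no IDK column recorded; a zero IDK column is
#'   appended), `k x (k+1)` (last column = IDK), or `2 x 5` for Likert data
#'   (columns: strongly-A, somewhat-A, somewhat-B, strongly-B, IDK).
#' @param arms character vector of arm labels; defaults to the row names of
#'   `counts`, else `"A"`, `"B"`, ...
#' @param guesses character vector of treatment-guess labels (excluding IDK);
#'   defaults to the arm labels (guess `j` = "I received the treatment of
#'   arm `j`").
#' @param scale one of `"auto"`, `"binary"`, `"ternary"`, `"likert5"`.
#'   `"auto"` infers `"likert5"` from a 2x5 `counts`, `"binary"` from an
#'   absent or all-zero IDK column, and `"ternary"` otherwise.
#' @return an object of class `guess_table` with fields `arms`, `guesses`,
#'   `counts` (`k x (k+1)` integer matrix, IDK last), `scale`, `likert`
#'   (`2 x 5` matrix or `NULL`), `excluded` (named count of respondents
#'   removed by transformations such as [drop_idk()]), and `trans`
#'   (character log of transformations applied).
#' @examples
#' # The unequal-allocation 2x3 example: 36/12/19 vs 18/6/9
#' gt <- guess_table(rbind(A = c(36, 12, 19), B = c(18, 6, 9)))
#' gt
#' # A 2x2 questionnaire without an IDK option
#' guess_table(rbind(active = c(42, 0), sham = c(19, 2)))
#' @seealso [read_crosstab()], [read_long()], [collapse_likert()],
#'   [combine_arms()], [drop_idk()]
#' @export
guess_table <- function(counts, arms = NULL, guesses = NULL, scale = "auto") {
  scale <- match.arg(scale, c("auto", "binary", "ternary", "likert5"))
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  k <- nrow(counts)
  if (k < 2L) stop("a guess table needs at least two arms", call. = FALSE)
  if (is.null(arms)) arms <- rownames(counts)
  if (is.null(arms)) arms <- LETTERS[seq_len(k)]
  if (anyDuplicated(arms)) stop("duplicate arm labels", call. = FALSE)

  likert <- NULL
  if (k == 2L && ncol(counts) == 5L && scale %in% c("auto", "likert5")) {
    scale <- "likert5"
    likert <- .check_counts(counts, arms, .likert_labels())
    counts <- cbind(likert[, 1L] + likert[, 2L],
                    likert[, 3L] + likert[, 4L],
                    likert[, 5L])
  } else if (scale == "likert5") {
    stop("scale = \"likert5\" requires a 2 x 5 count matrix", call. = FALSE)
  }

  if (ncol(counts) == k) counts <- cbind(counts, 0L)  # no IDK column recorded
  if (ncol(counts) != k + 1L)
    stop(sprintf("counts must be %d x %d or %d x %d (last column = IDK)",
                 k, k, k, k + 1L), call. = FALSE)

  if (is.null(guesses)) guesses <- arms
  if (length(guesses) != k) stop("need one guess label per arm", call. = FALSE)
  if (anyDuplicated(c(guesses, "IDK"))) stop("duplicate guess labels", call. = FALSE)
  counts <- .check_counts(counts, arms, c(guesses, "IDK"))

  if (scale == "auto") scale <- if (all(counts[, k + 1L] == 0L)) "binary" else "ternary"
  if (scale == "binary" && any(counts[, k + 1L] != 0L))
    stop("scale = \"binary\" is incompatible with nonzero IDK counts", call. = FALSE)

  x <- structure(list(arms = as.character(arms),
                      guesses = as.character(guesses),
                      counts = counts, scale = scale, likert = likert,
                      excluded = integer(0), trans = character(0)),
                 class = "guess_table")
  validate_guess_table(x)
}

# shared integer/negativity checks; returns integer matrix with dimnames
.check_counts <- function(m, arms, cols) {
  storage.mode(m) <- "double"
  for (r in seq_len(nrow(m))) for (c in seq_len(ncol(m))) {
    v <- m[r, c]
    if (is.na(v) || v < 0 || v != round(v))
      stop(sprintf("count for arm '%s', guess '%s' must be a non-negative integer (got %s)",
                   arms[r], cols[c], format(v)), call. = FALSE)
  }
  storage.mode(m) <- "integer"
  dimnames(m) <- list(arms, cols)
  m
}

.likert_labels <- function() {
  c("strongly_A", "somewhat_A", "somewhat_B", "strongly_B", "IDK")
}

#' Validate a guess table's invariants
#'
#' Checks non-negative integer counts, at least one response per arm, the
#' binary-scale IDK constraint, and (for Likert tables) agreement between the
#' stored 2x5 counts and their three-level collapse.
#'
#' @param x a [guess_table()].
#' @return `x`, invisibly unchanged, or an error describing the violation.
#' @export
validate_guess_table <- function(x) {
  stopifnot(inherits(x, "guess_table"))
  k <- length(x$arms)
  m <- x$counts
  if (!is.integer(m) || any(m < 0L)) stop("counts must be non-negative integers", call. = FALSE)
  if (nrow(m) != k || ncol(m) != k + 1L) stop("counts dimension mismatch", call. = FALSE)
  empty <- rowSums(m) == 0L
  if (any(empty))
    stop("arm(s) with no responses: ", paste(x$arms[empty], collapse = ", "), call. = FALSE)
  if (x$scale == "binary" && any(m[, k + 1L] != 0L))
    stop("binary-scale table has nonzero IDK counts", call. = FALSE)
  if (x$scale == "likert5") {
    if (is.null(x$likert) || k != 2L) stop("likert5 table must carry 2 x 5 counts", call. = FALSE)
    coll <- cbind(x$likert[, 1L] + x$likert[, 2L],
                  x$likert[, 3L] + x$likert[, 4L], x$likert[, 5L])
    if (!all(coll == m)) stop("counts do not equal the collapsed Likert counts", call. = FALSE)
  }
  invisible(x)
}

n_total <- function(x) sum(x$counts)
arm_totals <- function(x) rowSums(x$counts)
idk_counts <- function(x) x$counts[, length(x$arms) + 1L]

#' @export
print.guess_table <- function(x, ...) {
  k <- length(x$arms)
  cat(sprintf("Treatment-guess table: %d arms, scale = %s, N = %d\n",
              k, x$scale, n_total(x)))
  print(x$counts)
  if (!is.null(x$likert)) {
    cat("Five-level Likert counts:\n")
    print(x$likert)
  }
  if (length(x$excluded) && sum(x$excluded) > 0L)
    cat(sprintf("Excluded respondents: %d (%s)\n", sum(x$excluded),
                paste(sprintf("%s: %d", names(x$excluded), x$excluded), collapse = ", ")))
  if (length(x$trans))
    cat("Transformations:", paste(x$trans, collapse = "; "), "\n")
  invisible(x)
}
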