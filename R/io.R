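#' Read a guess cross-tabulation from CSV
#'
#' Reads a cross-tab CSV with a header row of guess labels (optionally ending
#' in `IDK`), one data row per arm, the first cell of each row being the arm
#' label. Five-level Likert files are recognized by the documented header set
#' (`strongly_A, somewhat_A, somewhat_B, strongly_B, IDK`, configurable via
#' `likert_labels`).
#'
#' @param file path or connection to a CSV file.
#' @param scale forced response scale, or `NULL` to infer: `"likert5"` on the
#'   Likert header, `"binary"` when the IDK column is absent or all zero,
#'   `"ternary"` otherwise.
#' @param likert_labels the five column labels identifying a Likert file.
#' @return a [guess_table()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("arm,guessA,guessB,IDK", "A,36,12,19", "B,18,6,9"), f)
#' read_crosstab(f)
#' @export
read_crosstab <- function(file, scale = NULL, likert_labels = .likert_labels()) {
  df <- utils::read.csv(file, check.names = FALSE, colClasses = "character",
                        strip.white = TRUE)
  if (ncol(df) < 3L) stop("cross-tab CSV needs an arm column and at least two guess columns",
                          call. = FALSE)
  arms <- df[[1L]]
  cols <- names(df)[-1L]
  if (anyDuplicated(cols)) stop("duplicate guess labels in header: ",
                                paste(cols[duplicated(cols)], collapse = ", "), call. = FALSE)
  if (anyDuplicated(arms)) stop("duplicate arm labels: ",
                                paste(arms[duplicated(arms)], collapse = ", "), call. = FALSE)
  m <- matrix(NA_real_, nrow(df), length(cols), dimnames = list(arms, cols))
  for (r in seq_len(nrow(df))) for (c in seq_along(cols)) {
    v <- suppressWarnings(as.numeric(df[r, c + 1L]))
    if (is.na(v) || v < 0 || v != round(v))
      stop(sprintf("cell (arm '%s', column '%s') is not a non-negative integer: '%s'",
                   arms[r], cols[c], df[r, c + 1L]), call. = FALSE)
    m[r, c] <- v
  }

  is_likert <- length(cols) == 5L && all(cols == likert_labels) && nrow(df) == 2L
  if (is_likert && (is.null(scale) || scale == "likert5"))
    return(guess_table(m, arms = arms, scale = "likert5"))

  has_idk <- toupper(cols[length(cols)]) == "IDK"
  guesses <- if (has_idk) cols[-length(cols)] else cols
  if (length(guesses) != nrow(df))
    stop(sprintf("expected %d guess columns for %d arms, found %d",
                 nrow(df), nrow(df), length(guesses)), call. = FALSE)
  guess_table(m, arms = arms, guesses = guesses,
              scale = if (is.null(scale)) "auto" else scale)
}

#' Write a guess table as a cross-tab CSV
#'
#' Inverse of [read_crosstab()]. Likert tables are written with their five
#' original columns; other tables with their guess columns plus `IDK` (the
#' IDK column is omitted for binary tables).
#'
#' @param x a [guess_table()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_crosstab <- function(x, file) {
  validate_guess_table(x)
  if (x$scale == "likert5") {
    m <- x$likert
  } else if (x$scale == "binary") {
    m <- x$counts[, seq_along(x$arms), drop = FALSE]
  } else {
    m <- x$counts
  }
  lines <- c(paste(c("arm", colnames(m)), collapse = ","),
             vapply(seq_len(nrow(m)),
                    function(r) paste(c(x$arms[r], m[r, ]), collapse = ","),
                    character(1)))
  writeLines(lines, file)
  invisible(file)
}

#' Read respondent-level guess records
#'
#' Builds a [guess_table()] from a long-format CSV with one row per
#' respondent, tallying each (arm, guess) pair. Record order never affects
#' the result.
#'
#' @param file path or connection to a CSV file.
#' @param arm_col,guess_col column names holding the arm and guess values.
#' @param idk_token the guess value meaning "I don't know" (default `"IDK"`).
#' @param arms,guesses label vectors fixing row/column order; by default the
#'   sorted unique values found in the file, with guess `j` taken as correct
#'   for arm `j`.
#' @return a [guess_table()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(arm = c("A", "A", "B"), guess = c("gA", "IDK", "gB")),
#'           f, row.names = FALSE)
#' read_long(f, guesses = c("gA", "gB"))
#' @export
read_long <- function(file, arm_col = "arm", guess_col = "guess",
                      idk_token = "IDK", arms = NULL, guesses = NULL) {
  df <- utils::read.csv(file, check.names = FALSE, colClasses = "character",
                        strip.white = TRUE)
  for (col in c(arm_col, guess_col))
    if (!col %in% names(df)) stop("missing column: ", col, call. = FALSE)
  a <- df[[arm_col]]; g <- df[[guess_col]]
  if (any(is.na(a) | a == "")) stop("record(s) with missing arm value", call. = FALSE)
  if (is.null(arms)) arms <- sort(unique(a))
  if (is.null(guesses)) guesses <- sort(unique(setdiff(g, idk_token)))
  bad <- setdiff(unique(g), c(guesses, idk_token))
  if (length(bad))
    stop("unknown guess value(s): ", paste(sQuote(bad), collapse = ", "),
         " (declared: ", paste(c(guesses, idk_token), collapse = ", "), ")",
         call. = FALSE)
  bad_arm <- setdiff(unique(a), arms)
  if (length(bad_arm))
    stop("unknown arm value(s): ", paste(sQuote(bad_arm), collapse = ", "), call. = FALSE)
  m <- table(factor(a, levels = arms),
             factor(ifelse(g == idk_token, "IDK", g), levels = c(guesses, "IDK")))
  guess_table(unclass(m)[seq_along(arms), , drop = FALSE],
              arms = arms, guesses = guesses)
}

#' Expand a guess table into respondent-level records
#'
#' One row per respondent, in deterministic (arm-major, guess-major) order;
#' the exact inverse of [read_long()] up to record order.
#'
#' @param x a [guess_table()].
#' @param idk_token string written for IDK responses.
#' @return a data frame with columns `arm` and `guess`.
#' @export
long_records <- function(x, idk_token = "IDK") {
  validate_guess_table(x)
  labs <- c(x$guesses, idk_token)
  arm <- rep(rep(x$arms, ncol(x$counts)), as.vector(x$counts))
  guess <- rep(rep(labs, each = nrow(x$counts)), as.vector(x$counts))
  data.frame(arm = arm, guess = guess, stringsAsFactors = FALSE)
}
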