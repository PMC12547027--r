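#' @title Index estimate container
#' @description Internal constructor for a single blinding-index estimate:
#'   point value, standard error, confidence bounds, CI method, the sample
#'   size actually used, and any degeneracy flags raised on the way.
#' @param index short index name, e.g. `"JBI"`, `"BBI_A"`, `"sumBI"`, `"SBI"`.
#' @param value point estimate (may be `NA` with the `"undefined"` flag).
#' @param se standard error or `NA`.
#' @param ci length-2 numeric, already truncated to the index range.
#' @param level confidence level, e.g. 0.95.
#' @param method one of `"jackknife-normal"`, `"multinomial-normal"`,
#'   `"wilson-mover"`, `"none"`.
#' @param n sample size used (after any exclusions).
#' @param flags character vector drawn from `"degenerate"`, `"zero_width_ci"`,
#'   `"undefined"`, `"unequal_allocation"`, `"idk_excluded"`, `"multi_arm"`,
#'   `"likert_weighted"`, `"replicate_degenerate"`.
#' @param components optional list of intermediate quantities.
#' @return object of class `blind_est`.
#' @keywords internal
new_blind_est <- function(index, value, se, ci, level, method, n,
                          flags = character(0), components = NULL) {
  stopifnot(length(ci) == 2L)
  value <- unname(value); se <- unname(se); ci <- unname(ci)
  if (!is.na(se) && !is.na(ci[1]) && !is.na(ci[2]) && ci[1] <= ci[2] &&
      !is.na(se) && se == 0 && isTRUE(ci[1] == ci[2]))
    flags <- union(flags, "zero_width_ci")
  structure(list(index = index, value = value, se = se,
                 ci_low = ci[1], ci_high = ci[2], level = level,
                 method = method, n = n, flags = unique(flags),
                 components = components),
            class = "blind_est")
}

#' Format an index estimate in `value (low, high)` style
#'
#' @param x a `blind_est`.
#' @param digits decimal places (default 2, the conventional presentation).
#' @param ... unused.
#' @return a character scalar such as `"JBI = 0.64 (0.55, 0.73)"`.
#' @export
format.blind_est <- function(x, digits = 2, ...) {
  fm <- function(v) {
    if (is.na(v)) return("undefined")
    s <- sprintf("%.*f", digits, v)
    # negative zero prints as plain zero at display precision
    if (grepl("^-0\\.?0*$", s)) s <- sub("^-", "", s)
    s
  }
  if (is.na(x$value)) return(sprintf("%s = undefined", x$index))
  sprintf("%s = %s (%s, %s)", x$index, fm(x$value), fm(x$ci_low), fm(x$ci_high))
}

#' @export
print.blind_est <- function(x, ...) {
  cat(format(x), sprintf("[%d%% CI, %s, n = %d]\n",
                         round(100 * x$level), x$method, x$n))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.blind_est <- function(x, ...) {
  data.frame(index = x$index, value = x$value, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, level = x$level,
             method = x$method, n = x$n,
             flags = paste(x$flags, collapse = ";"),
             stringsAsFactors = FALSE)
}
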