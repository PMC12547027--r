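#' Interpret blinding-index estimates against the ad-hoc cutoffs
#'
#' Applies the conventional interpretation rules: the James index suggests
#' blinding success above 0.5 (more convincingly when the CI lower limit
#' exceeds 0.5) and random guessing when its CI contains 0.5; the Bang
#' indices are judged against `|0.2|` (stringent) or `|0.3|` (less
#' stringent), their sign read as correct-guess excess (positive) versus
#' opposite guessing (negative); sumBI is described as a between-arm summary
#' without an established cutoff; the Simple index carries no published
#' interpretation guidance and is labelled accordingly rather than given an
#' invented threshold. Labels are a pure function of the estimates and their
#' flags.
#'
#' @param estimates a list of `blind_est` objects.
#' @param stringent use the `|0.2|` Bang cutoff (default) instead of `|0.3|`.
#' @return named character vector of labels, one per estimate.
#' @export
interpret_estimates <- function(estimates, stringent = TRUE) {
  vapply(estimates, .interpret_one, character(1), stringent = stringent)
}

.interpret_one <- function(e, stringent) {
  stopifnot(inherits(e, "blind_est"))
  if ("undefined" %in% e$flags || is.na(e$value))
    return("undefined (degenerate input; no interpretable estimate)")
  idx <- e$index
  if (idx == "JBI") {
    if (!is.na(e$ci_low) && e$ci_low > 0.5)
      return("blinding success (CI lower limit > 0.5)")
    if (!is.na(e$ci_low) && e$ci_low <= 0.5 && e$ci_high >= 0.5)
      return("random guess (CI includes 0.5)")
    if (e$value > 0.5) return("blinding success (point estimate > 0.5)")
    return("blinding may not be successful (point estimate and CI below 0.5)")
  }
  if (startsWith(idx, "BBI")) {
    cut <- if (stringent) 0.2 else 0.3
    if ("zero_width_ci" %in% e$flags && abs(e$value) == 1) {
      return(if (e$value > 0)
        "complete correct guessing within arm; see study-level indices"
        else "complete opposite guessing within arm; see study-level indices")
    }
    if (e$value == 0) return("perfect blinding (BBI = 0)")
    if (abs(e$value) < cut)
      return(sprintf("blinding success (|BBI| < %.1f cutoff)", cut))
    return(if (e$value > 0)
      sprintf("correct-guess excess beyond the %.1f cutoff (possible unblinding)", cut)
      else sprintf("opposite guessing beyond the %.1f cutoff", cut))
  }
  if (idx == "sumBI")
    return("between-arm difference summary (a sum by construction; no established cutoff)")
  if (idx == "SBI")
    return("no interpretation guidance available")
  "no interpretation rule for this index"
}

#' Full blinding report for one guess table
#'
#' Computes every requested index on the table (James with jackknife CI,
#' per-arm Bang and sumBI with normal CIs, Simple with Wilson/MOVER CI),
#' attaches cutoff-based interpretation labels, and collects caveat notes:
#' IDK exclusions, unequal allocation, degeneracies, transformations applied.
#' Degenerate inputs (e.g. an all-IDK arm) never abort the report; the
#' affected index is included as undefined with a note.
#'
#' @param x a [guess_table()].
#' @param alpha two-sided error rate for all CIs.
#' @param indices subset of `c("JBI", "BBI", "sumBI", "SBI")`.
#' @param stringent Bang cutoff choice, see [interpret_estimates()].
#' @param likert Likert handling for the Bang indices ([bang_arm()]).
#' @param undefined_as_one James all-IDK convention ([james_bi()]).
#' @return an object of class `blinding_report` with fields `input`,
#'   `estimates`, `labels`, `notes`.
#' @examples
#' blinding_report(guess_table(rbind(A = c(42, 0), B = c(19, 2))))
#' @export
blinding_report <- function(x, alpha = 0.05,
                            indices = c("JBI", "BBI", "sumBI", "SBI"),
                            stringent = TRUE,
                            likert = c("collapse", "weighted"),
                            undefined_as_one = FALSE) {
  likert <- match.arg(likert)
  indices <- match.arg(indices, several.ok = TRUE)
  validate_guess_table(x)
  k <- length(x$arms)
  notes <- character(0)
  ests <- list()
  add_note <- function(msg) notes <<- c(notes, msg)

  try_est <- function(name, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        add_note(sprintf("%s: %s", name, conditionMessage(e)))
        new_blind_est(name, NA_real_, NA_real_, c(NA_real_, NA_real_),
                      1 - alpha, "none", n_total(x),
                      c("undefined", "degenerate"))
      }),
      warning = function(w) {
        add_note(sprintf("%s: %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }

  if ("JBI" %in% indices)
    ests$JBI <- try_est("JBI", james_bi(x, alpha = alpha,
                                        undefined_as_one = undefined_as_one))
  if ("BBI" %in% indices) {
    if (k == 2L) {
      for (j in 1:2) {
        nm <- paste0("BBI_", x$arms[j])
        ests[[nm]] <- try_est(nm, bang_arm(x, j, alpha = alpha, likert = likert))
      }
    } else {
      add_note("BBI/sumBI assume a two-arm design; reported per arm with a multi-arm caveat")
      for (j in seq_len(k)) {
        nm <- paste0("BBI_", x$arms[j])
        ests[[nm]] <- try_est(nm, bang_arm(x, j, alpha = alpha, likert = likert))
      }
    }
  }
  if ("sumBI" %in% indices && k == 2L)
    ests$sumBI <- try_est("sumBI", bang_sum(x, alpha = alpha, likert = likert))
  if ("SBI" %in% indices && k == 2L)
    ests$SBI <- try_est("SBI", simple_bi(x, alpha = alpha))

  # surface flags as notes
  for (e in ests) {
    if ("unequal_allocation" %in% e$flags && startsWith(e$index, "BBI"))
      add_note(sprintf("%s: arms are not 1:1; the Bang index assumes equal allocation",
                       e$index))
    if ("idk_excluded" %in% e$flags && e$index == "SBI")
      add_note(sprintf(
        "SBI: %d IDK response(s) excluded; analytical sample size reduced to %d",
        sum(x$counts[, k + 1L]) + if (length(x$excluded)) sum(x$excluded) else 0L,
        e$n))
    if ("zero_width_ci" %in% e$flags)
      add_note(sprintf("%s: zero-width CI from a zero asymptotic variance", e$index))
    if ("likert_weighted" %in% e$flags)
      add_note(sprintf("%s: graded weights applied to 5-level Likert responses", e$index))
  }
  if (x$scale == "binary" && all(idk_counts(x) == 0L) && !length(x$excluded))
    add_note("2x2 format: the questionnaire offered no IDK response option")
  for (tr in x$trans) add_note(paste0("input transformation: ", tr))
  notes <- unique(notes)

  structure(list(
    input = list(arms = x$arms, arm_totals = as.integer(arm_totals(x)),
                 idk = as.integer(idk_counts(x)), N = n_total(x),
                 scale = x$scale,
                 excluded = as.list(x$excluded),
                 transformations = x$trans),
    estimates = ests,
    labels = interpret_estimates(ests, stringent = stringent),
    notes = notes), class = "blinding_report")
}

#' Serialize a blinding report
#'
#' `format = "text"` renders estimates in the conventional
#' `value (low, high)` style at two decimals with labels and notes;
#' `format = "json"` emits the stable schema with keys `input`,
#' `estimates` (array of index records at full precision), `labels`,
#' `notes`.
#'
#' @param report a [blinding_report()].
#' @param format `"text"` or `"json"`.
#' @return a character scalar (JSON) or character vector of lines (text).
#' @export
render_report <- function(report, format = c("text", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "blinding_report"))
  if (format == "json") {
    est_records <- lapply(unname(report$estimates), function(e) {
      list(index = e$index, value = e$value, se = e$se,
           ci_low = e$ci_low, ci_high = e$ci_high, level = e$level,
           ci_method = e$method, n = e$n, flags = as.list(e$flags))
    })
    obj <- list(input = report$input, estimates = est_records,
                labels = as.list(report$labels),
                notes = as.list(report$notes))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null",
                            null = "null"))
  }
  lines <- c(sprintf("Blinding report: %d arms (%s), N = %d, scale = %s",
                     length(report$input$arms),
                     paste(report$input$arms, collapse = ", "),
                     report$input$N, report$input$scale))
  for (e in report$estimates) {
    lines <- c(lines, sprintf("  %-28s %s", format(e),
                              report$labels[[e$index]]))
  }
  if (length(report$notes)) {
    lines <- c(lines, "Notes:", paste0("  - ", report$notes))
  }
  lines
}

#' @export
print.blinding_report <- function(x, ...) {
  writeLines(render_report(x, "text"))
  invisible(x)
}
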