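#' Bundled example blinding datasets
#'
#' A named list of [guess_table()] objects covering the canonical response
#' patterns and a set of real-trial guess tables from the blinding-assessment
#' literature, spanning every supported input format: 2x3 tables, a 2x2
#' questionnaire without an IDK option, two 2x5 Likert questionnaires, and a
#' three-arm 3x4 table together with its two-arm combined version.
#'
#' Hypothetical patterns (`hypothetical_01` .. `hypothetical_07`): all-IDK;
#' opposite guessing in both arms; uninformative 50/50 guessing; half
#' correct, half IDK; mostly IDK with a sliver of correct guesses;
#' unbalanced 2:1 allocation with mirrored guess proportions; the same
#' without IDK responses.
#'
#' Real trials: `ai_echo` (AI versus sonographer echocardiogram reading,
#' cardiologists assessed), `violins` (new versus old violins, blinded
#' soloists), `statin` (low/high-dose statin versus placebo, 5-level Likert,
#' arms combined), `spinal_manual` (spinal manual therapy versus placebo,
#' 5-level responses), `acupuncture` (active versus sham acupuncture, 2x2
#' format), `disulfiram` (low/high-dose disulfiram versus riboflavin, 3x4)
#' and `disulfiram_combined` (its two-arm collapse).
#'
#' @return named list of `guess_table` objects.
#' @seealso [fixture_manifest()] for published reference values,
#'   [write_fixtures()] to emit them as CSV.
#' @export
blinding_fixtures <- function() {
  gt <- function(a, b, ...) guess_table(rbind(A = a, B = b), ...)
  list(
    hypothetical_01 = gt(c(0, 0, 100), c(0, 0, 100), scale = "ternary"),
    hypothetical_02 = gt(c(0, 100, 0), c(100, 0, 0), scale = "ternary"),
    hypothetical_03 = gt(c(50, 50, 0), c(50, 50, 0), scale = "ternary"),
    hypothetical_04 = gt(c(50, 0, 50), c(0, 50, 50)),
    hypothetical_05 = gt(c(15, 0, 85), c(0, 15, 85)),
    hypothetical_06 = gt(c(36, 12, 19), c(18, 6, 9)),
    hypothetical_07 = gt(c(50, 17, 0), c(25, 8, 0), scale = "ternary"),
    ai_echo       = gt(c(557, 427, 756), c(418, 573, 764)),
    violins       = guess_table(rbind(new = c(15, 18, 0), old = c(13, 18, 5))),
    statin        = guess_table(rbind(statin = c(38, 44, 21, 4, 170),
                                      placebo = c(11, 16, 21, 8, 83))),
    spinal_manual = guess_table(rbind(manual = c(0, 4, 3, 0, 32),
                                      placebo = c(0, 6, 3, 0, 32))),
    acupuncture   = guess_table(rbind(active = c(42, 0), sham = c(19, 2))),
    disulfiram    = guess_table(rbind(low  = c(41, 66, 30, 44),
                                      high = c(27, 72, 24, 51),
                                      ribo = c(22, 36, 64, 52))),
    disulfiram_combined = guess_table(rbind(disulfiram = c(206, 54, 95),
                                            riboflavin = c(58, 64, 52)))
  )
}

#' Published reference values for the bundled datasets
#'
#' One row per bundled dataset, with the point estimates reported in the
#' blinding-assessment literature for that table, rounded to two decimals as
#' published. `NA` marks cells that are not applicable (degenerate all-IDK
#' input; indices that do not handle the 3x4 format) or whose published
#' estimation method is not reproducible from the table alone.
#' `bbi_method` records which Bang variant the published Likert analyses
#' used (`"weighted"` graded weights for `statin`, plain `"collapse"`
#' elsewhere).
#'
#' @return data frame with columns `name`, `file`, `scale`, `jbi`, `bbi_a`,
#'   `bbi_b`, `sumbi`, `sbi`, `bbi_method`, `description`.
#' @export
fixture_manifest <- function() {
  df <- function(name, scale, jbi, bbi_a, bbi_b, sumbi, sbi, method, desc)
    data.frame(name = name, file = paste0(name, ".csv"), scale = scale,
               jbi = jbi, bbi_a = bbi_a, bbi_b = bbi_b, sumbi = sumbi,
               sbi = sbi, bbi_method = method, description = desc,
               stringsAsFactors = FALSE)
  rbind(
    df("hypothetical_01", "ternary", NA,    NA,    NA,    NA,    NA,   "collapse",
       "all respondents answer IDK; James undefined (or 1), Bang/Simple degenerate"),
    df("hypothetical_02", "ternary", 1,    -1,    -1,    -2,    -1,    "collapse",
       "opposite guessing in both arms"),
    df("hypothetical_03", "ternary", 0.5,   0,     0,     0,     0,    "collapse",
       "uninformative 50/50 guessing"),
    df("hypothetical_04", "ternary", 0.5,   0.5,   0.5,   1,     1,    "collapse",
       "half correct, half IDK in each arm"),
    df("hypothetical_05", "ternary", 0.85,  0.15,  0.15,  0.30,  1,    "collapse",
       "mostly IDK with a sliver of correct guesses"),
    df("hypothetical_06", "ternary", 0.64,  0.36, -0.36,  0,     0,    "collapse",
       "2:1 allocation, mirrored guess proportions, some IDK"),
    df("hypothetical_07", "ternary", 0.51,  0.49, -0.52, -0.02, -0.01, "collapse",
       "2:1 allocation, mirrored guess proportions, no IDK"),
    df("ai_echo",         "ternary", 0.68,  0.07,  0.09,  0.16,  0.14, "collapse",
       "AI vs sonographer echocardiogram interpretation, cardiologists assessed"),
    df("violins",         "ternary", 0.52, -0.09,  0.14,  0.05,  0.04, "collapse",
       "new vs old violins, renowned soloists"),
    df("statin",          "likert5", 0.75,  0.16,  0.01,  0.16,  0.28, "weighted",
       "low/high-dose statin vs placebo (combined, ~2:1), 5-level Likert"),
    df("spinal_manual",   "likert5", 0.91,  0.03, -0.07, -0.04, -0.10, "collapse",
       "spinal manual therapy vs placebo, outcome assessors"),
    df("acupuncture",     "binary",  0.44,  1,    -0.81,  0.19,  0.10, "collapse",
       "active vs sham acupuncture, 2x2 questionnaire"),
    df("disulfiram",      "ternary", NA,    NA,    NA,    NA,    NA,   "collapse",
       "3-arm disulfiram/riboflavin table; two-arm indices need the combined version"),
    df("disulfiram_combined", "ternary", 0.52, 0.43, 0.03, 0.46, 0.32, "collapse",
       "disulfiram arms combined against riboflavin (~2:1 allocation)")
  )
}

#' Write the bundled datasets as cross-tab CSV files
#'
#' Emits every bundled dataset via [write_crosstab()] plus `manifest.csv`
#' ([fixture_manifest()]). Output is deterministic: regenerated files are
#' byte-identical across runs.
#'
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest with file paths.
#' @export
write_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fx <- blinding_fixtures()
  for (nm in names(fx)) write_crosstab(fx[[nm]], file.path(dir, paste0(nm, ".csv")))
  man <- fixture_manifest()
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE,
                   quote = TRUE)
  invisible(transform(man, file = file.path(dir, file)))
}
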