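---
title: "Estimating blinding success: models, intervals and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating blinding success: models, intervals and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blindex)
```

## The data model

A blinding assessment asks each respondent (participant, clinician, outcome
assessor, ...) which treatment they believe they received. With arms
$j = A, B, \ldots$ and guesses $i$ (one per arm, plus "I don't know", IDK),
the data form a $k \times (k+1)$ contingency table of counts $n_{ij}$ with
$N = \sum n_{ij}$. `guess_table()` is that container. Three conventions
matter:

* **Correctness is positional.** The guess category at position $j$ is the
  correct guess for arm $j$. Labels are never string-matched; this keeps
  estimation independent of how a file labels its columns.
* **The 2x2 format is the same type.** Questionnaires without an IDK option
  produce a table whose IDK column is identically zero
  (`scale = "binary"`), so every estimator consumes one type. Reading a
  cross-tab whose IDK column is absent or all zero infers the binary scale.
* **Likert data carry both representations.** A 2x5 questionnaire
  ("strongly/somewhat believe A", "somewhat/strongly believe B", IDK) is
  stored with its five-level counts and their three-level collapse
  (strong + somewhat per guessed treatment), kept consistent by the
  validator.

Respondents removed by a transformation — [drop_idk()] before the Simple
index, for instance — are recorded on the table and surfaced in reports,
never silently discarded, because exclusions shrink the analytical sample
size.

## The three indices

### James index

$$\mathrm{JBI} = \tfrac12\left[1 + P_D + (1 - P_D)\,\frac{P_O - P_E}{P_E}\right],$$

with $P_D$ the IDK proportion and, writing $P_{ij} = n_{ij}/N$,

$$P_O = \frac{\sum_{i,j} w_{ij} P_{ij}}{1 - P_D}, \qquad
  P_E = \frac{\sum_{i,j} w_{ij} P_{i\cdot}(P_{\cdot j} - P_{Dj})}{(1 - P_D)^2},$$

where the sums run over the treatment guesses. $(P_O - P_E)/P_E$ is a
kappa-type agreement contrast: the index measures disagreement beyond
chance, scaled to $[0, 1]$ with 1 as perfect blinding and 0.5 as random
guessing. The default weights $w_{ij}$ are 0 for a correct guess, 0.5 for an
incorrect guess, and 1 for IDK, which is why the IDK proportion dominates
the index. `james_weights()` accepts any matrix in $[0,1]$; for more than
two arms the same 0/0.5 default is applied to every incorrect cell, since no
canonical multi-arm weight matrix exists (weights are acknowledged to be
subjective there).

Degenerate cases are explicit rather than silent:

* $P_D = 1$ (every response IDK): the index is $1$ or undefined depending on
  convention, because of a division by zero. The default returns `NA` with
  an `undefined` flag; `undefined_as_one = TRUE` adopts the value-1 reading.
* $P_E = 0$ with $P_D < 1$: an error, since the kappa term has no value.

**Variance.** The shipped interval is a leave-one-respondent-out jackknife:
$$\hat V = \frac{N-1}{N} \sum_{r=1}^{N} (\theta_{(-r)} - \bar\theta_{(\cdot)})^2,$$
with the normal interval centred on the *full-sample* estimate (not the
jackknife mean) and truncated to $[0,1]$. Because respondents within a cell
are exchangeable, only one replicate per occupied cell needs evaluating,
repeated by its count; `james_jackknife()` exposes both this grouped form
and the naive per-respondent loop, and the test suite asserts their exact
equality on every bundled dataset. Replicates whose subtable leaves the
index undefined (for instance, removing the last non-IDK respondent) are
dropped from the variance with a warning and flag. A closed-form
(delta-method) variance for the James index exists in the literature; it is
deliberately not shipped — the jackknife reproduces the published intervals
for the bundled datasets except two cases discussed under *Known
discrepancies*.

### Bang index

Per arm $j$, with IDK kept in the denominator $n_j$,
$$\mathrm{BBI}_j = \hat P(\text{correct} \mid j) - \hat P(\text{incorrect} \mid j),$$
range $[-1, 1]$, 0 perfect, positive = correct-guess excess, negative =
opposite guessing. An algebraically equivalent scaled-binomial form
$[2 n_{\text{corr}}/(n_{\text{corr}}+n_{\text{inc}}) - 1]\cdot
(n_{\text{corr}}+n_{\text{inc}})/n_j$ is computed alongside and asserted
equal; the two differ only when an arm is entirely IDK, where the package
raises an explicit degenerate-arm error instead of choosing between
"undefined" and "0" (software packages differ here, and silence would hide
the degeneracy).

The variance is the multinomial-contrast form
$\{p_1 + p_2 - (p_1 - p_2)^2\}/n_j$ with a normal interval truncated to
$[-1,1]$; a unanimous arm has zero variance and a flagged zero-width
interval — a real weakness of normality-based intervals that the report
surfaces rather than papers over. One-sided intervals
($\text{value} \pm z_{1-\alpha}\,SE$ on the requested side) are available.
`bang_sum()` adds the two arm indices (range $[-2,2]$); its variance is
$V_A + V_B$ by randomization independence. sumBI is computed from the
*unrounded* arm indices.

The index assumes two arms with 1:1 allocation. Unequal allocation and
multi-arm tables are estimated anyway — refusing would be unhelpful — but
carry `unequal_allocation` / `multi_arm` caveat flags that reports turn
into notes.

**Likert handling.** For 2x5 tables the default collapses to three levels
first. `likert = "weighted"` instead applies graded weights
$(+1, +0.5, -0.5, -1, 0)$ to the five ordered categories with variance
$\{\sum w^2 p - (\sum w p)^2\}/n$. Both variants appear in published
analyses of the bundled Likert datasets (one trial each), so both are
first-class; collapse is the default because it matches the James-side
convention and requires no weight choice.

### Simple index

$$\mathrm{SBI} = \frac{n_{AA}}{n_{AA}+n_{BA}} - \frac{n_{AB}}{n_{AB}+n_{BB}},$$

the between-arm difference in the proportion guessing the *active*
treatment, on 2x2 data. The index deliberately omits IDK — its authors
discourage offering the option — so ternary input is reduced via
`drop_idk()` with the lost sample size flagged and reported. The CI is the
MOVER/Newcombe hybrid of two Wilson score intervals: with per-arm Wilson
bounds $(l_1, u_1)$, $(l_2, u_2)$ around $\hat p_1, \hat p_2$ and
$d = \hat p_1 - \hat p_2$,
$$\left(d - \sqrt{(\hat p_1 - l_1)^2 + (u_2 - \hat p_2)^2},\;
       d + \sqrt{(u_1 - \hat p_1)^2 + (\hat p_2 - l_2)^2}\right).$$
Among the score-based constructions for a difference of proportions, this
hybrid is the one that reproduces every published SBI interval for the
bundled datasets; it is asymmetric where the data demand and never
zero-width for finite samples. No continuity-corrected or exact variant is
offered.

## Interpretation

`blinding_report()` assembles all indices with labels from the conventional
ad-hoc cutoffs: JBI > 0.5 (strengthened when the CI lower limit exceeds
0.5; a CI containing 0.5 is labelled random guessing, a reproducible rule
in place of eyeballing "≈ 0.5"), |BBI| < 0.2 or < 0.3 by the `stringent`
flag, and *no* cutoff for SBI or sumBI — none has been established, and the
package does not invent one. Reports always print estimates and intervals
alongside labels; blinding success is not reduced to a binary verdict, and
no hypothesis tests or p-values are provided. An "unblinded" finding is a
result, not an error: the CLI exits 0 on it.

## The simulator

`scenario_spec()` fixes per-arm multinomial guess probabilities, arm sizes
and a seed; `simulate_table()` draws one table per arm from the multinomial.
Named presets cover the canonical patterns (all-IDK, opposite guess, random
guess, same-guess-active, unblinded). `population_indices()` evaluates the
same closed forms on expected counts, so the estimators and their population
values cannot drift apart — a property the tests exercise by checking that
the population routine applied to each bundled pattern's empirical
proportions reproduces its sample estimates exactly.

`coverage_experiment()` reports empirical CI coverage, mean bias and
Monte-Carlo errors. One scenario seed generates a fixed vector of
per-replicate sub-seeds up front, so results are independent of evaluation
order. The test suite verifies ~95% coverage of the Bang interval at
$p = (0.4, 0.3, 0.3)$ with 200 per arm over 2000 replicates (band
0.93–0.97, i.e. nominal ± ~4 binomial MC standard errors), and that the
absolute bias of Bang, Simple and James estimators shrinks as $n$ doubles
from 50 to 800 (800 replicates per size, within twice the summed MC
errors). The simulator draws independent multinomials per arm — it does not
emulate clustered guessing, within-respondent repeated assessments over
time, item nonresponse distinct from IDK, or guess probabilities that
depend on outcomes; passing tests therefore validate the estimators'
sampling behaviour, not those real-data complications.

## Known discrepancies in published reference values

`fixture_manifest()` records the published two-decimal reference values for
the bundled datasets, and the acceptance tests regress the package against
all of them. Three cells are knowingly irreproducible from the stated
formulas, and the corresponding assertions fail by 0.01 by design rather
than being excluded:

* two published sumBI values equal the sum of the *displayed* (rounded) arm
  indices, while the other published sumBI values are full-precision sums;
  no single rounding rule reproduces both, and this package always reports
  the full-precision sum;
* one published arm-B Bang value for a Likert dataset matches neither the
  collapsed nor the weighted variant (its arm-A companion and CI identify
  the weighted variant exactly, which the manifest records for that row).

Two further published James CIs (one endpoint each, off by 0.01) derive
from the closed-form variance rather than the jackknife and are documented
here instead of asserted. The three-arm disulfiram table's published James
value likewise reflects an unstated multi-arm weight choice; the default
generalization gives 0.57 and the manifest leaves that cell blank.

## Numerical and scale choices

All published-value regressions run at two decimals, the precision trial
reports use. Default $\alpha = 0.05$, two-sided. Intervals are truncated to
each index's range after the normal approximation ("−1.06" style
untruncated bounds are therefore reported as −1). Displayed values round
negative zero to plain zero; JSON output keeps full precision (round-trip
tested at 12 significant digits). Property-style tests use $10^4$ random
tables for the algebraic identities (sumBI $= 2\cdot$SBI on 2x2 data; the
two Bang formulations) and a few hundred for symmetry properties; the
jackknife equality check covers every bundled dataset including the largest
($N = 3495$). These sizes keep the default suite under a minute while
leaving the identities no room to hide.

## Limitations

The James jackknife is the only shipped James variance; users wanting the
closed form must compute it elsewhere. Bang intervals are asymptotic — no
exact or bootstrap option. Multi-arm support extends the James index fully
but the Bang and Simple indices only with caveats, mirroring their design.
Respondents who decline to answer at all (distinct from IDK) are outside
the data model; exclude them upstream and report the exclusion — the
tables only count recorded guesses.
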