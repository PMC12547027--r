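# blindex

Blinding indices for randomized controlled trials.

In a blinded trial, participants (or clinicians, outcome assessors,
coordinators) are asked after randomization which treatment they believe they
received: the active treatment, the control, or — when the questionnaire
offers it — "I don't know" (IDK). `blindex` estimates the success of blinding
from these treatment-guess data, cross-tabulated by randomized arm, using the
three indices in common use:

* **James blinding index (JBI)** — disagreement beyond chance across arms,

  JBI = [1 + P_D + (1 − P_D)·(P_O − P_E)/P_E] / 2,

  where P_D is the IDK proportion and P_O, P_E are weighted observed and
  expected guess proportions (weights 0 for a correct guess, 0.5 for an
  incorrect guess, 1 for IDK; (P_O − P_E)/P_E is a kappa-like term). Range
  0–1, 1 = perfect blinding, values near 0.5 = random guessing, > 0.5 the
  ad-hoc success cutoff. Confidence intervals come from a
  leave-one-respondent-out jackknife. Handles two or more arms and any guess
  scale.

* **Bang blinding index (BBI)** — one index per arm,

  BBI_j = P(correct guess | arm j) − P(incorrect guess | arm j),

  with IDK responses in the denominator; range −1 to 1, 0 = perfect blinding,
  |BBI| < 0.2 (stringent) or < 0.3 (less stringent) the ad-hoc cutoffs, and a
  negative sign indicating opposite guessing. The study-level **sumBI** is
  BBI_A + BBI_B. Normal CIs use the multinomial-contrast variance
  [p₁ + p₂ − (p₁ − p₂)²]/n; one-sided intervals are available. A weighted
  variant (+1, +0.5, −0.5, −1) handles five-level Likert questionnaires.

* **Simple blinding index (SBI)** — the between-arm difference in the
  proportion guessing the *active* treatment on 2x2 data (IDK excluded, with
  exclusions reported), range −1 to 1, 0 = perfect blinding. CIs combine two
  Wilson score intervals by the MOVER/Newcombe method, which avoids the
  zero-width intervals the normal-theory indices can produce.

The package also provides cross-tab and respondent-level CSV input, Likert
collapsing, arm combining and IDK exclusion transforms, cutoff-based
interpretation reports (text or JSON), a multinomial scenario simulator with
coverage/bias experiments, a bundled collection of example datasets from the
blinding-assessment literature, and a small command line tool
(`exec/blindex.R`).

## Worked example

An acupuncture trial collected guesses without an IDK option (2x2 format):
all 42 active-arm participants guessed "active", as did 19 of 21 sham-arm
participants.

```r
library(blindex)
x <- guess_table(rbind(active = c(42, 0), sham = c(19, 2)))
blinding_report(x)
```

```
Blinding report: 2 arms (active, sham), N = 63, scale = binary
  JBI = 0.44 (0.35, 0.52)      random guess (CI includes 0.5)
  BBI_active = 1.00 (1.00, 1.00) complete correct guessing within arm; see study-level indices
  BBI_sham = -0.81 (-1.00, -0.56) opposite guessing beyond the 0.2 cutoff
  sumBI = 0.19 (-0.06, 0.44)   between-arm difference summary (a sum by construction; no established cutoff)
  SBI = 0.10 (-0.01, 0.29)     no interpretation guidance available
Notes:
  - BBI_active: arms are not 1:1; the Bang index assumes equal allocation
  - BBI_active: zero-width CI from a zero asymptotic variance
  - BBI_sham: arms are not 1:1; the Bang index assumes equal allocation
  - 2x2 format: the questionnaire offered no IDK response option
```

The report shows why the indices are complementary: within the active arm
everyone guessed correctly (BBI_active = 1, a degenerate zero-width interval),
but the sham arm guessed "active" almost as often, so the study-level
summaries (sumBI = 0.19, SBI = 0.10) indicate comparable *same guess*
behaviour in both arms rather than unblinding, while the James index sits
below 0.5 because it penalizes the absence of IDK variability.

Other entry points:

```r
fx <- blinding_fixtures()            # bundled example datasets
james_bi(fx$hypothetical_06)         # JBI = 0.64 (0.55, 0.73)
bang_arm(fx$statin, 1, likert = "weighted")   # graded-weight Likert Bang index
simple_bi(fx$ai_echo)                # SBI = 0.14 (0.10, 0.19), IDK excluded

sc <- scenario_spec(rbind(c(0.4, 0.3, 0.3), c(0.3, 0.4, 0.3)), n = 200, seed = 1)
coverage_experiment(sc, reps = 1000)  # CI coverage / bias of the estimators
```

Command line:

```sh
Rscript exec/blindex.R fixtures --out fixtures/
Rscript exec/blindex.R compute --input fixtures/acupuncture.csv --indices all
Rscript exec/blindex.R simulate --scenario inst/extdata/scenario_random_guess.json --reps 1000 --coverage
```

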