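---
title: "Models and methods behind samediff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind samediff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(samediff)
```

## The task and the psychometric model

samediff analyzes *same/different* magnitude-comparison experiments: an
observer memorizes a reference stimulus (a 600 ms visual duration, or a
24-dot array) and then judges, trial by trial, whether test stimuli match
it. Unlike two-alternative forced-choice designs, this task produces a
*bump-shaped* psychometric curve: the proportion of "same" responses peaks
near the reference and falls off on both sides.

The package fits that curve with a Gaussian on a log magnitude axis,

$$ p(x) = A \exp\!\left(-\frac{(\log_{10} x - \mu)^2}{2\sigma^2}\right), $$

and reads off three quantities:

* **PSE** $= 10^{\mu}$ — the point of subjective equality, the test
  magnitude most often judged equal to the reference. A PSE *below* the
  reference means test magnitudes were *over*estimated.
* **Bias** $= (\mathrm{Ref} - \mathrm{PSE})/\mathrm{Ref} \times 100\%$ —
  the signed percent shift (positive = overestimation).
* **Weber fraction** $= 10^{\sigma} - 1$ — a dimensionless precision
  index; smaller is more precise. It is invariant to the log base used
  for fitting, provided $\sigma$ is exponentiated in the same base, so the
  base-10 choice here is purely a reproducibility convention. A secondary
  accessor, `weber_fraction_jnd()`, exposes the just-noticeable-difference
  formulation $(10^{\sigma} - 10^{-\sigma})/2$, which agrees with the
  antilog form to second order in $\sigma$.

Goodness of fit is $R^2 = 1 - SS_\mathrm{res}/SS_\mathrm{tot}$ on the
per-level proportions.

### Fitting choices

Fits are performed on the per-level proportions, unweighted by default:
each of the nine levels contributes one point, even though the reference
level carries three times the trials (18 vs 6 per decoding phase). This is
the simplest reading of curve-fitting on proportion plots; a
binomial-count weighting is available via `weighted = TRUE` for users who
prefer it, and on the synthetic data the two options give nearly identical
peaks.

The optimizer is bounded L-BFGS-B with multistart initialization: $\mu$ at
every observed level, $\sigma \in \{0.05, 0.1, 0.2\}$ log10 units, and $A$
at the maximum observed proportion; the start with the lowest residual sum
of squares wins, with the deterministic start order breaking ties, and the
winner is polished with a tight-tolerance refinement pass. $A$ is bounded
to $(0, 1]$ (observed peaks sit visibly below 1), $\sigma$ to
$(0.001, 2)$. A solution with $\sigma$ at its upper bound, $A$ at its
floor, or flat input proportions is *flagged* as non-converged — it is
returned with `converged = FALSE` and a warning, never as a silent
number. L-BFGS-B's "linesearch breakdown" return (code 52) is accepted as
convergence: it occurs routinely when residuals reach machine precision on
noise-free data, where the returned point is the minimizer.

## Protocol generation

Test levels are generated *outward* from the reference anchor,
$x_k = \mathrm{ref} \cdot r^{k}$ for $k = -4..4$ with
$r = (\mathrm{extreme}/\mathrm{ref})^{1/4}$, then rounded
half-away-from-zero for display. Outward generation, not end-to-end
interpolation, is what reproduces the canonical duration list
284–1268 ms after rounding (interpolation rounds one level to 724). The
unrounded values are retained for fitting. The dot-numerosity levels are
stored as the explicit published list (11, 14, 17, 20, 24, 29, 35, 42,
51): no single-ratio spacing rule reproduces the 17 (the outward rule
rounds that level to 16), so the published levels are taken verbatim.

A decoding phase presents each non-reference level 6 times and the
reference 18 times — 66 trials — in a uniformly shuffled, seed-reproducible
order. Session plans lay out the block structure: the while-running kinds
run training → encoding → 3-min rest → baseline T1 → encoding → 3-min
warm-up → test while running → rest → encoding → baseline T2, twice, for
3 × 2 × 66 = 396 decoding trials; the after-running kind has an 8-min
pre-baseline rest, an 8-min run with no stimuli, and the test immediately
after the treadmill stops (no T2; 264 trials). Training-to-criterion is
represented as a fixed nine-trial placeholder phase: simulating human
learning is out of scope, and the constant preserves the block's shape.
The heart-rate targeting rule is the age-predicted-maximum formula
$208 - 0.7 \cdot \mathrm{age}$, with the exercise target at 80% of it.

## The synthetic observer

No raw data ship with the package, so every downstream stage is exercised
against a generative observer whose structure mirrors what the analysis
assumes. The observer perceives test magnitude $x$ through a multiplicative
gain $g$ (phase-specific), forms the internal log difference
$d = \ln(g x / \mathrm{ref}) + \varepsilon$ with
$\varepsilon \sim N(0, \sigma_s^2 + \sigma_m^2)$ (sensory plus
memory-trace noise), and answers "same" when $|d| < c$, the criterion
half-width. With probability $\lambda$ it lapses and guesses "same" with
probability $\gamma$. The closed form of $P(\text{"same"})$
(`analytic_p_same()`) is a difference of normal CDFs; it is symmetric in
$\ln x$ and peaks *exactly* at $x = \mathrm{ref}/g$, which is what makes
gain recovery a sharp end-to-end audit: simulate with a known $g$, fit,
and compare the fitted PSE against $\mathrm{ref}/g$.

Defaults were chosen once, as study-scale conditions:

| parameter | duration | numerosity | rationale |
|---|---|---|---|
| $\sigma_s$ (ln units) | 0.11 | 0.07 | with $\sigma_m$, $c$: fitted Wf ≈ 0.23 / 0.14 — duration noisier than numerosity |
| $\sigma_m$ (ln units) | 0.10 | 0.06 | memory-trace noise of the encoded reference |
| $c$ (ln units) | 0.25 | 0.17 | sets curve width jointly with the noise |
| $\lambda$, $\gamma$ | 0.12, 0.5 | 0.12, 0.5 | puts the fitted peak near 0.86, below 1 as observed |
| while-running gain | 600/513 | 1 | duration dilates under running; numerosity does not |
| between-subject SD | 0.06 (log units) | 0.06 | ±12% PSE scatter across a 15-participant cohort |

Cohort simulation draws per-participant log-normal perturbations of gain
and criterion, then simulates every decoding phase with its own shuffled
schedule. All randomness flows from one root seed, split hierarchically
per participant and phase, so identical seeds reproduce trial tables
byte-for-byte.

The generator emulates what the inference machinery needs — Gaussian-shaped
same-curves on a log axis, a gain-induced peak shift, between-participant
spread, binomial trial noise, evenly spaced trial times, and a heart-rate
trace that ramps to 80% of the age-predicted maximum within 3 minutes and
plateaus for 5. It deliberately does *not* model sequential effects,
criterion drift within a session, learning or fatigue, response times, or
any biomechanics of running. Passing tests therefore certify the analysis
pipeline (design arithmetic, fitting, bootstrap calibration, recovery),
not any claim about real observers.

## Inference machinery

**Bootstrap Z-test.** Aggregate trials are resampled with replacement (as
many draws as the original count, the trial row being the resampling
unit), re-aggregated and refit; the fitted peaks across iterations form
the bootstrap distribution (10,000 iterations by default). Two conditions
are compared by
$Z = |\bar{m}_a - \bar{m}_b| / \sqrt{se_a^2 + se_b^2}$ with a two-sided
normal p-value, at a Bonferroni-corrected threshold ($\alpha/k$; 0.0167
for the canonical three-contrast family). Bootstrap refits start from the
full-data point estimate (plus a wider-width companion start) and skip the
polish pass: the peak spread across resamples dwarfs optimizer
granularity. Non-converged iterations are excluded and counted; more than
10% failures marks the result unstable.

**Paired t and effect size.** Per-participant PSE contrasts use a paired
t-test on log10 PSE differences (the scale on which individual PSEs
scatter symmetrically; a linear-unit option exists), with Cohen's
$d = \bar{\Delta}/s_\Delta$.

**Default JZS Bayes factor.** `jzs_log10_bf()` computes the one-sample
(equivalently paired) default Bayes factor for a t-design: a Cauchy prior
with scale 0.707 on the standardized effect under the alternative. The
Cauchy is written as a normal scale mixture with inverse-gamma(1/2,
$r^2/2$) mixing density, and the resulting one-dimensional integral is
evaluated with adaptive quadrature on the likelihood *ratio*, which stays
stable for large $t$. The unit tests check it against an independent
oracle that integrates the noncentral-t likelihood over the Cauchy prior
directly.

**Median split.** To ask whether an after-running effect is present only
in the first trials, baseline and test trials are split at the median of
the time since the run ended, with ties assigned to the early half
(convention; the split is otherwise ambiguous), and each half is
bootstrap-compared independently. A half covering fewer than four levels
(including the all-ties degenerate case) raises an insufficient-data
error.

**Precision correlation.** Condition-averaged Weber fractions from two
tasks are correlated with a two-sided Pearson test.

## Numerical and design choices at the open points

* **Resampling unit**: the trial row, on aggregate data — the simplest
  scheme consistent with "as many independent samples as the full
  dataset". Participant-level resampling would answer a different
  (hierarchical) question.
* **Two-sided p-values** throughout.
* **Log base 10** internally everywhere; PSE and Weber fraction are
  base-invariant, so this is fixed purely for reproducibility.
* **Trial pacing**: 300/66 s per decoding trial, spreading 66 trials over
  the nominal 5-minute test phase; only the median split depends on trial
  times, and only through their order.
* **Heart ramp shape**: a saturating exponential with rate constant
  $3.5/\mathrm{ramp}$, chosen so the noise-free trace starts exactly at
  rest and closes to within 2% of target by the ramp's end.

## Problem sizes used by the tests

The shipped suite runs everything at the canonical design sizes (15
participants, 396 trials each) but scales iteration counts to keep the
suite brisk, as a deliberate package choice: bootstrap unit tests use
200–500 iterations (the default remains 10,000), the Type-I calibration
uses 200 null cohorts × 150 bootstrap iterations, the paired-t power
check 100 cohorts, and the median-split null calibration 100 cohorts of 8
participants × 100 iterations. The calibration properties these check are
iteration-count-robust: the Z statistic depends on bootstrap SEs, which
are stable to a few percent at 150 iterations.

## Known limitations

* The generative observer is one of several structures (criterion drift
  and clock-rate/pacemaker formulations would produce similar curves);
  the package implements the gain + criterion form because it makes the
  PSE prediction exact and testable.
* Published per-participant results that depend on the original raw data
  (individual PSEs, the exact between-task correlation, exact Cohen's d
  values) are not reproducible from simulation; the property-based suite
  (oracle equivalence of the fitter, base invariance, bootstrap
  determinism and centering, recovery closure) stands in for them.
* Repeated-measures ANOVA with sphericity corrections is intentionally
  not wrapped: standard off-the-shelf tests cover it, and nothing in the
  pipeline depends on it.
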