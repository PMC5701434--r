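---
title: "Why total symptom scores inherit the latent trait's exponential shape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Why total symptom scores inherit the latent trait's exponential shape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latentexp)
```

## The model

Large general-population surveys repeatedly find that total depressive-symptom
scores are distributed almost exponentially: plotted with frequency on a log
axis against raw score, the right tail is a straight line, with a departure
only at the lowest scores. `latentexp` implements a generative model that
reproduces and explains this pattern, using a CIS-R-like instrument as the
concrete scale: 14 negative-symptom items probed by 57 binary questions, each
endorsed question contributing one point, total score 0–57.

The process model has three ingredients:

1. **Latent trait.** Each respondent carries a single unobserved severity
   $X \ge 0$ drawn from an exponential distribution with rate $\lambda$
   (density $\lambda e^{-\lambda x}$, mean and standard deviation $1/\lambda$).
2. **Thresholds.** Every respondent–question pair gets its own threshold
   $T_{rq}$, independent across respondents and across questions (local
   independence). Thresholds are normal with a question-specific mean
   $\mu_q$ and a standard deviation $\sigma$ shared across questions, or —
   as a limiting regime — uniform on $(a, b)$ applied identically to every
   question.
3. **Scoring.** Question $q$ is endorsed by respondent $r$ exactly when
   $X_r > T_{rq}$ (strict; ties have probability zero under the continuous
   model and score 0). The total score is the row sum of endorsements.

### Calibration: percentile points

The threshold means are not free parameters. Each question's mean is set to
the *percentile point* of its general-population prevalence $p_q$: the
upper-tail quantile $\mu_q = -\ln(p_q)/\lambda$ solving
$P(X > \mu_q) = p_q$. A question endorsed by 5.49% of the population gets
$\mu = -\ln(0.0549) = 2.90$ at $\lambda = 1$. The upper-tail (not lower-tail)
reading of "percentile point" is forced by that worked pair: the lower-tail
quantile of 5.49% would be 0.056, nowhere near 2.90. At $\sigma = 0$ the
calibration is exact — every question's endorsement probability equals its
table prevalence — which the tests exploit as a recovery check.

Under threshold noise the marginal endorsement probability has the closed
form
$$P(X > T) = \Phi(-\mu/\sigma)
  + e^{\lambda^2\sigma^2/2 - \lambda\mu}\,\Phi(\mu/\sigma - \lambda\sigma),$$
the first term being the chance of a negative threshold (always exceeded by
the nonnegative latent trait). The second term is computed in log space:
at $\lambda\sigma = 12$ the naive product multiplies $e^{72}$ by a Gaussian
tail of the same magnitude and overflows. The closed form is production code;
the test suite re-derives every value by adaptive quadrature over the
threshold density and requires agreement to $10^{-6}$.

## The prevalence table

The published record prints only one of the 57 question prevalences (5.49%
for the first somatic-symptom question); the full survey table is not
available. The package therefore ships a **synthetic** 57-row fixture
(`fixture_prevalence_table()`): row 1 pinned to 0.0549, the other 56 drawn
once (seed 20200817) log-uniformly on $[0.01, 0.35]$ and committed to
`inst/extdata/prevalence_cisr_synthetic.csv`. Symptom endorsement rates in
general-population surveys are right-skewed and mostly fall in that range,
which is what the log-uniform draw emulates; no claim is made that the 56
values match any real survey. Values are stored with six decimals so a CSV
round trip is bit-exact. `generate_prevalence_table()` produces fresh tables
for sensitivity work.

What this means for interpretation: passing tests show the *mechanism* —
that calibrated thresholds with spread produce exponential-looking totals —
for plausible prevalence inputs. They do not validate the model against real
CIS-R response data, which the simulation study itself never had.

## The analytic oracle

Conditional on $X = x$, the endorsement indicators are independent Bernoulli
with probabilities $p_q(x) = \Phi((x - \mu_q)/\sigma)$ (or the clamped ramp
$(x-a)/(b-a)$ for uniform thresholds), so the conditional total is
Poisson-binomial. The exact marginal pmf is
$$P(S = k) = \int_0^\infty \lambda e^{-\lambda x}\,
  \mathrm{PB}(k;\, p_1(x),\dots,p_Q(x))\, dx.$$
The Poisson-binomial pmf is computed by iterative convolution (dynamic
programming, $O(Q^2)$; $Q = 57$ makes anything fancier pointless), and the
integral by composite 15-node Gauss–Legendre quadrature on $[0, U]$ with $U$
the $1-10^{-10}$ latent quantile, the residual tail mass assigned the
Poisson-binomial pmf at $U$. Panels double until successive pmfs agree
within `tol` (default $10^{-8}$) in sup norm; non-convergence is an error
that reports the achieved difference. For the uniform family the integrand
has kinks at the bounds, so the domain is split there first — without the
split, convergence stalls one order of magnitude above the default
tolerance. The degenerate $\sigma = 0$ case is computed exactly from sorted
threshold means (the score is a deterministic step function of $x$), since
quadrature against step discontinuities converges too slowly to be honest.

The oracle is sampling-noise free, so it serves two roles: validating the
Monte-Carlo engine (total-variation distance $\le 0.01$ at $n = 10^5$ on a
10-question instrument, measured ~0.003–0.007 across all nine conditions)
and measuring log-linearity claims exactly.

## Diagnostics and their conventions

The original study judged linearity graphically; a test suite needs numbers.
The package's conventions:

* **Histogram fits.** `fit_log_linear()` regresses $\ln(\text{count})$ on
  score by unweighted OLS — the numeric analogue of judging a semi-log plot
  by eye. A Poisson GLM would weight bins differently; it is a reasonable
  alternative, not the default, because the target of inference is the
  straight-line appearance itself.
* **Right tail** means scores from the modal score upward; the low-score
  region below the mode is exactly where the empirical literature reports
  departures. **Full range** starts at 0 and is the appropriate policy for
  the uniform-threshold regime, whose distribution has no left-of-mode bump.
* **Sparse bins** (count below 5 by default) are excluded — $\ln 0$ is
  undefined and near-empty far-tail bins would dominate the fit — and fewer
  than 8 usable bins is an explicit "insufficient tail" error rather than a
  silent fit.
* **The ceiling bin is excluded by default.** The maximum score of a bounded
  instrument is right-censored: it absorbs all latent mass beyond the
  highest threshold. Under uniform$(0,5)$ thresholds at $\lambda = 1$ this
  is a visible atom of mass $e^{-5} \approx 0.0067$ (every respondent with
  $X > 5$ scores 57), sitting far above the log-linear trend. The exact pmf
  is log-linear with $R^2 = 0.9999$ over scores 0–56 and $R^2 = 0.95$ if
  the censored atom is forced into the fit. Normal-family conditions leave
  that bin essentially empty, so the default is inert there.
* **Skewness** is the adjusted Fisher–Pearson statistic
  $g_1\sqrt{n(n-1)}/(n-2)$, the form survey software reports.
* $R^2$ thresholds are used only where the input is noise-free (oracle pmf,
  $R^2 \ge 0.98$); Monte-Carlo claims are tested as *orderings* (skewness
  strictly decreasing in $\sigma$; tail $R^2$ at $\sigma \in \{2,3,4\}$
  above $\sigma = 1$; $\lambda = 2$ compensating for small $\sigma$), which
  are robust to sampling noise where absolute cutoffs are not.

## The condition grid

`condition_grid()` enumerates the nine study conditions — $\lambda = 1$ with
$\sigma \in \{1,2,3,4\}$, $\lambda \in \{2,3\}$ with $\sigma \in \{1,2\}$,
and $\lambda = 1$ with uniform$(0,5)$ — at $n = 10{,}000$ respondents each,
the size of the population surveys the simulation emulates. Per-condition
seeds are derived from a master seed by a stable polynomial hash of the
condition identifier, so adding a condition never shifts the streams of the
others. `run_grid()` writes per-condition totals, histograms, tail-fit JSON
and normal/log-scale plots, and returns a machine-readable summary row per
condition; plots drop zero-count bins (no pseudo-counts), matching the fit
policy, and are artifacts only — no test asserts on rendered output.

```{r grid, eval = FALSE}
summary <- run_grid(condition_grid(20200817), out_dir = "grid_out")
summary[, c("condition", "skewness", "slope", "r_squared", "modal_score")]
```

Test problem sizes: ordering and recovery properties use $n = 10^5$ (three
binomial standard errors on a 5% prevalence are then $\pm 0.2$ percentage
points); the grid reproducibility check runs at the survey size
$n = 10{,}000$. The multi-question prevalence-recovery property adjusts its
per-question bound for the number of simultaneous comparisons (Bonferroni);
an unadjusted 3-SE bound applied to 456 independent checks would be expected
to fail somewhere by construction.

## Design choices where the record is silent

* **Per-question thresholds.** Whether the original simulation drew one
  threshold per item (shared by its four questions) or one per question is
  not recoverable from the published record; calibration is defined per
  question ("all 57 symptoms"), so thresholds are drawn per question.
* **Prevalence granularity.** The survey rates are treated as
  question-level endorsement probabilities, one per each of the 57
  questions, for the same reason.
* **Negative thresholds are kept.** Truncating them would distort exactly
  the large-$\sigma$ regime the study is about; a respondent with a negative
  threshold simply always endorses that question.
* **Item-to-prevalence join is positional.** The published record names only
  the first row; the fixture preserves order, and the join key is
  (item, question-within-item).

## Limitations

The simulator makes no attempt at item-level realism beyond the stated
model: no measurement error on the latent trait, no guessing, no
within-person threshold correlation, no polytomous scoring (Likert-scored
scales enter only through the threshold-counting arithmetic, e.g. 16 items
$\times$ 3 thresholds = 48 for a CES-D-like scale). Estimating $\lambda$ or
$\sigma$ from real survey data is out of scope; the rates 1–3 and spreads
1–4 are illustrative values spanning the regime where the total score
transitions from threshold-dominated (skewed but not log-linear) to
latent-dominated (log-linear).
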