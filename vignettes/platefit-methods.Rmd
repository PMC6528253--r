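---
title: "How platefit analyses plate assays: models, transforms and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How platefit analyses plate assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(platefit)
```

platefit is a headless pipeline for end-point assays read out in multi-well
plates: dose–response screens, receptor–ligand binding, enzyme initial-rate
kinetics. One numeric *plate setup* matrix declares which wells are
replicates of which condition ("test" value — a compound concentration, a
substrate concentration, a time point); any number of *groups* (datasets
with that same layout) are then screened for outliers, transformed,
aggregated and fitted in a fixed order. This vignette explains each stage,
the statistical model behind it, and the choices made where more than one
defensible design existed.

## The data model

A layout is any rectangular matrix whose non-blank cells hold finite test
values; wells carrying the same value form a *replicate set*. Matching is by
exact numeric equality of the parsed values — the labels are data, not
display strings, so `0.1` and `0.10` are the same test but `0.1` and
`0.1000001` are not. Blank layout cells are unused wells. A blank *data*
cell at a labelled well is a *missing* observation: it is excluded from all
statistics but is not an outlier, and reports keep the two apart. All
user-facing output names wells in A1 convention (row letter, 1-based column
number).

Everything is tabular: groups are tibbles with one row per labelled well
(`group`, `row`, `col`, `well`, `test`, `value`, `masked`), so the pipeline
stages compose with ordinary data-frame tools and the pipe.

## Pipeline order

Per group the stages always run in this order, with unconfigured stages
skipped (and logged as skipped):

1. **Outlier screen** (optional) — on raw values, before any transform.
2. **Baseline subtraction** (optional).
3. **Normalisation** (optional).
4. **Scaling** (optional).
5. **Aggregation** of replicates into means with a variation measure.
6. **Model fit** to the means.

The screen runs first so that a gross outlier cannot corrupt the baseline
or normalisation reference means. Because Grubbs' decision is invariant
under affine maps of a replicate set, screening before or after
baseline/normalisation would flag the same wells; running it first is still
the right order because the *reference means* consumed by stages 2–3 must
already exclude flagged wells.

Each stage of each group is logged with the quantities it actually used
(reference mean and n, flagged wells with their statistics, start and final
fit parameters), so a run can be audited from the plain-text log alone.

## Outlier screening: Grubbs' test

Within one replicate set with usable values $x_1,\dots,x_n$ (unmasked,
non-missing), the statistic is

$$G = \frac{\max_i |x_i - \bar{x}|}{s},$$

with $s$ the sample standard deviation. The two-sided critical value at
level $\alpha$ is

$$G_{crit} = \frac{n-1}{\sqrt{n}}
  \sqrt{\frac{t^2_{\alpha/(2n),\,n-2}}{\,n-2+t^2_{\alpha/(2n),\,n-2}}},$$

where $t_{\alpha/(2n),\,n-2}$ is the upper $\alpha/(2n)$ quantile of
Student's t with $n-2$ degrees of freedom. When $G > G_{crit}$ the
farthermost value is masked.

Design choices, made explicit because reasonable implementations differ:

* **Two-sided, $\alpha = 0.05$ by default.** Plate artefacts (a clogged
  tip, an evaporated well) can displace a value in either direction;
  $\alpha$ is a configuration knob.
* **Single pass, at most one value flagged per set per run.** Replicate
  sets on plates are small ($n$ of 2–4 is typical), and iterating Grubbs on
  such sets degenerates quickly ($n=3$ after one removal cannot be tested
  at all). An iterative mode is possible future work.
* **Sets with $n < 3$ or zero spread are skipped** and recorded with the
  reason; no decision is possible there.
* **Ties in the deviation go to the earliest well in row-major order**, for
  determinism.
* **Manual masks are honoured**: a well masked by hand never enters
  $\bar{x}$ or $s$.

A structural limit worth knowing: $G$ can never exceed $(n-1)/\sqrt{n}$,
which is $1.5$ at $n = 4$ against a critical value of $1.481$. Moderate
outliers (a few noise-SDs) at $n = 4$ are therefore often undetectable *by
any* single-outlier test of this form; the screen is designed for gross
errors, and the simulator's default displacement (six response ranges)
reflects that regime. Under the null the flagging rate is at most
$\alpha$ by construction; the test suite verifies this on 10,000 simulated
quadruplicate sets.

## Transforms and aggregation

*Baseline subtraction* subtracts the mean of the unmasked replicates of a
designated test; afterwards that set has mean exactly 0. *Normalisation*
divides by the mean of another designated test (error if that mean is 0);
afterwards that set has mean exactly 1. *Scaling* multiplies by a constant
(so percent-of-control displays are `normalise` + `scale = 100`). Reference
means are computed **per group**, never pooled: groups are independent
datasets that happen to share a layout, and a plate-to-plate offset in one
group must not leak into another. Selecting the same test for baseline and
normalisation is rejected up front — after subtraction its mean is 0 and
the normalisation would be degenerate.

Aggregation reports, per test value: the mean over usable replicates, the
replicate count, and one of three variation half-widths —

* `sd`: sample standard deviation ($n-1$ denominator),
* `sem`: $s/\sqrt{n}$,
* `ci95`: $t_{0.975,\,n-1} \cdot s/\sqrt{n}$.

The $n-1$ denominator and the t-based (rather than $1.96\sigma$) interval
are deliberate: replicate counts of 2–4 dominate plate work, where the
normal approximation to the CI is badly anticonservative. A set whose
usable count is 0 becomes a *fully masked* point: it appears in tables,
carries no mean, and is excluded from plots and fits. Variation needs
$n \ge 2$.

## Models and fitting

Two models are offered. The **four-parameter logistic** (4PL) is

$$y = bottom + \frac{top - bottom}{1 + (x/ec_{50})^{hill}},$$

parameterised so that $x = ec_{50}$ is exactly the inflection/midpoint —
the EC50 or IC50 read directly off the fit. With $hill > 0$ the response
falls from $top$ to $bottom$ as $x$ grows (inhibition curves); $hill < 0$
rises. At $x = 0$ the limit value is used, so zero-dose controls can sit on
the curve. The **linear** model $y = a + bx$ serves initial-rate enzyme
kinetics and other straight-line readouts.

The fit minimises the unweighted sum of squared residuals **between the
replicate means and the curve** — the averaged values are the fit target,
not the raw wells. With unequal usable counts per test this weights tests
equally rather than wells; that is the intended semantics of averaging
first.

Numerical choices:

* **Levenberg–Marquardt** with multiplicative damping: $\lambda$ starts at
  $10^{-3}$, is divided by 10 after an accepted step and multiplied by 10
  after a rejected one, with Marquardt's $\mathrm{diag}(J^TJ)$ scaling.
  Convergence is declared when the relative SSR decrease falls below
  $10^{-10}$ or the gradient norm below $10^{-10}$, capped at 1000
  iterations. Steps that produce non-finite residuals are rejected; if no
  finite downhill step exists the best-so-far parameters are returned with
  `converged = FALSE`.
* **$ec_{50}$ is fitted as $\log ec_{50}$** internally, which keeps it
  positive without constraints and makes the parameter scale roughly
  symmetric over dose ranges spanning decades; results are reported on the
  natural scale (the standard error via the delta method,
  $se(ec_{50}) = ec_{50} \cdot se(\log ec_{50})$).
* **Start values**: $top$/$bottom$ from the responses at the extreme ends
  of the dose range, $ec_{50}$ from the sampled dose nearest the midpoint
  response (clamped into the positive dose range), $hill = \pm 1$ by the
  direction of the trend. A flat series yields a degenerate guess with a
  warning. Any start can be supplied explicitly — the headless equivalent
  of re-fitting from manually entered values — and `gof_stats()` evaluates
  manual parameters with the same definitions the fitter reports.
* **Standard errors** come from $\hat\sigma^2 (J^TJ)^{-1}$ at the optimum
  when the residual degrees of freedom are $\ge 1$ and the normal matrix is
  well-conditioned (reciprocal condition number $> 10^{-12}$); otherwise
  they are reported as `NA` rather than as garbage.
* **Goodness of fit**: SSR; $R^2 = 1 - SSR/TSS$ about the mean response
  (negative values are allowed and reported — they mean "worse than a
  constant"); $RMSE = \sqrt{SSR/dof}$ when $dof \ge 1$.
* **Zero doses in the 4PL**: a zero-dose point that served as the baseline
  or normalisation reference is excluded from the 4PL fit — after the
  transform it is pinned at the reference value by construction and carries
  no dose–response information. Any other zero dose is included through the
  $x = 0$ limit. The linear model always keeps $x = 0$.

The linear model runs through the same optimiser (it converges in one step
from the closed-form seed); the test suite holds it to the closed-form
ordinary-least-squares solution, and holds the 4PL path against an
independent Levenberg–Marquardt implementation and a brute-force grid
search.

## The simulator, and what passing tests do and do not show

`simulate_plate()` generates the synthetic plates used throughout the test
suite: one row per dose, `n_replicates` columns, responses from the true
model plus i.i.d. Gaussian noise, and optionally `floor(frac × wells)`
wells displaced by ± `outlier_magnitude` response ranges with random sign.
Gaussian replicate noise is the distributional assumption under which
Grubbs' test and the t-based intervals are exact, so the simulator measures
the pipeline under its own model. Its defaults are the validation
conditions used by the tests and the acceptance script: 8 doses spanning
$10^{-2}$–$10^2$, 4 replicates, noise SD of 2 % of the response range, and
gross outliers at 6 response ranges.

What the simulator deliberately does **not** model: spatial plate artefacts
(edge evaporation, thermal gradients), serial-dilution error propagation
(which correlates errors across doses), heteroscedastic detector noise, and
drift over read time. Passing tests therefore demonstrate correctness of
the algorithms under clean assumptions, not robustness to systematic plate
pathologies — for those, the per-well masks and the audit log are the
intended tools.

Validation problem sizes (chosen to estimate the quantities to well under
their tolerances): 10,000 null quadruplicate sets for the type-I rate; 200
seeded plates for EC50 recovery (median relative error ≈ 2 % at 2 %-of-range
noise) and for screen sensitivity/false-positive rates; 100 random problems
for the OLS equivalence.

## Files, determinism and the CLI

Inputs are CSV (layout matrix; data blocks stacked under a group-name row,
separated by a blank row; or one CSV per group) or `.xlsx` workbooks with
`PlateSetup` and `Data` sheets in the same block convention. All results
are written as tab-separated sheet files (`results`, `aggregated`,
`outliers`, `config`) plus the run log and one plot (PNG or SVG) per group;
plain text keeps runs diffable, versionable and inspectable without a
spreadsheet program, and identical inputs and configuration produce
byte-identical tables. The `exec/platefit` script exposes `run` and
`simulate` subcommands with exit status 0 (all groups fitted), 2 (some
groups failed — failures are isolated per group) or 1 (fatal).

## Known limitations

* The 4PL fit is unweighted over means; no 5PL, weighting scheme, or
  shared-parameter (global) fitting across groups.
* Grubbs screening flags at most one outlier per replicate set per run and
  cannot operate on sets smaller than 3.
* No confidence bands on fitted curves; parameter SEs assume the usual
  local quadratic approximation.
* Colour-coded group detection from spreadsheets is not supported; the
  stacked named-block convention replaces it.
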