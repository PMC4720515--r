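---
title: "Measuring transcriptional drift: models, conventions and design notes"
author: "txdrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring transcriptional drift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txdrift)
```

# The model

Aging transcriptomes do not simply scale genes up or down; genes within
one pathway drift in opposing directions away from the expression pattern
of young adults. `txdrift` measures this with per-gene *transcriptional
drift*, the log fold-change against a young reference,

$$\mathrm{td}_{g,s} \;=\; \log_b\!\frac{\mathrm{cpm}_{g,s} + c}{\mathrm{ref}_g + c},$$

and summarizes a group of $n$ genes by the *drift-variance*

$$\mathrm{dv} \;=\; \frac{1}{n-1}\sum_{i=1}^{n}\bigl(\mathrm{td}_i - \overline{\mathrm{td}}\bigr)^2 .$$

A pathway whose members hold their youthful stoichiometry has a small dv
regardless of coordinated up/down regulation; members diverging in
opposite directions inflate it. dv is dispersion *across genes* within
one sample group — deliberately distinct from transcriptional noise,
the variance of one gene across replicates.

Assumptions worth stating explicitly:

* expression is depth-normalized to cpm only; no gene-length correction,
  because a gene is only ever compared with itself across ages;
* drift is measured relative to one fixed reference age, so every result
  is conditional on that choice (the reference age is recorded in the
  `YoungReference` object);
* dv compares groups of *identical gene universes*; the min-detection
  filter is applied once, when the `DriftMatrix` is built.

# The young reference and the self-reference trap

With replicated young samples there are two defensible constructions.
*Pooled mean* (`method = "pooled_mean"`) averages all reference-age
replicates per gene: downstream drift values are less noisy, but the
reference-age samples then have artificially small drift-variance, so the
API flags them `selfReferential` and `runDriftPipeline` refuses Levene
comparisons involving them rather than trusting callers to remember.
*Holdout* (`method = "holdout"`) sets aside named samples as the
reference; they are removed from every downstream group, and the
remaining young replicates show a real, testable drift-variance. With
few young replicates the holdout route makes every downstream value
depend on a single sample — the pooled route is the default for that
reason.

# Tunable parameters

| parameter | where | default | meaning |
|---|---|---|---|
| `logBase` | `computeDrift` | 2 | base of the log fold-change; 2, e, 10. Changing it rescales every td by a constant and all dv by its square, and leaves every Levene p-value unchanged (asserted in the tests), so it is a display choice, not a modelling one. |
| `pseudocount` | `computeDrift` | 0.5 cpm | offset guarding zeros at later ages. It shrinks log-ratios of low-expression genes toward 0, so a large value biases dv downward; 0.5 cpm is negligible for genes above ~5 cpm. |
| `minDetection` | `computeDrift` | >0 | genes whose expression is zero in any reference replicate are dropped, never imputed. |
| `trimFraction` | `robustLevene` | 0.10 | fraction trimmed from *each* tail before the group center is taken; with heavy-tailed drift distributions the trimmed-mean center discounts outliers the way the median does, while retaining more efficiency. `trim = 0` with `center = "mean"` is the classical Levene test, with `center = "median"` the classical Brown–Forsythe test (both identities are asserted against an independent implementation). |
| `rule` | `classifyAttenuation` | `mean_abs_td` | a gene is attenuated iff its mean \|td\| across the shared ages is strictly smaller under treatment. "Attenuation" is not formalized in the drift literature; this is the minimal reading of "keeping expression close to the young state". A `per_age_majority` alternative is provided; the transcriptome-scale counts are robust to the choice because the binomial test only needs the direction of each comparison. |
| `windowDays` | `estimateMortality` | 3 | centered moving-average window on the day axis, matching a three-scores-per-week cadence; a window at or below the scoring interval is the identity. |
| `G` | `gompertzFromMeanLifespan` | — | Gompertz slope in 1/day. When only a mean lifespan is published, A is solved for a chosen G; nematode cohorts typically fall in G ∈ [0.2, 0.5]/day, and the power results reported by the acceptance script are insensitive across that range. |

# The synthetic generator

`generateTranscriptome` emulates the statistical structure the analysis
assumes, with known ground truth for recovery tests:

* per gene, a direction $s_g = \pm 1$ (balanced by default) and a rate
  $r_g \sim \Gamma(\text{mean } 0.10,\ \text{sd } 0.07)$ in log2 units
  per day — chosen so the transcriptome-wide dv reaches ≈1.2 log2² by day
  10, the magnitude seen in nematode aging time courses;
* systematic drift $s_g r_g \,\mathrm{clock}(t)^{\gamma}$ with
  $\gamma = 1$ (near-linear growth; the literature's drift-plots are
  roughly monotone on the day scale but no parametric form is
  established, so $\gamma$ is exposed);
* the treated arm's drift *clock* runs at $(1-a)$ of the control rate
  from the treatment-start age onward. The default $a = 0.7$ mirrors the
  observation that a treated day-10 transcriptome can resemble a control
  day-3 one; drift accrued before a delayed start is not undone;
* replicate noise N(0, 0.2) in log2 units; negative-binomial counts
  (dispersion 0.05) at log-normal library sizes around 25 million reads;
* the study design is a day 1/3/5/10 time course with three biological
  replicates and an untreated reference age.

The closed-form expectation
$\mathrm{dv}(t) = \mathrm{Var}(s\,r)\,\mathrm{clock}(t)^{2\gamma} + \sigma^2_{\text{noise}}$
stored in the truth object deliberately excludes count-sampling noise and
pseudocount shrinkage; tests that check it therefore run in the
transparent-measurement regime (Poisson counts at deep libraries, minimal
pseudocount). Two drift mechanisms are offered — a deterministic trend
plus replicate noise (default), and a random-walk mode with per-arm
cumulative increments — because the underlying mechanism of drift
(programmed change vs progressive loss of control) is not settled.

What the generator does **not** emulate: batch effects, library-prep
biases, gene–gene correlation beyond the shared direction/rate structure,
contamination from other tissues or life stages, and compositional
effects beyond what renormalization induces. Passing recovery tests shows
the pipeline is correct and well calibrated under the stated model; it
does not show robustness to artifacts real data may carry.

# Mortality modelling

The hazard is the canonical demographic Gompertz form
$h(t) = A e^{G t}$, survival
$S(t) = \exp\{-(A/G)(e^{Gt}-1)\}$; $G = 0$ degenerates to the
exponential. Fitting is by maximum likelihood on death times with
right-censoring support, on the $(\log A, \log G)$ scale to enforce
positivity — not by regression on the smoothed log-hazard, which is kept
as a diagnostic (`estimateMortality`). The treatment-effect model for
power calculations is an *additive day shift* of death times (a parallel
displacement of the log-mortality curve), matching how period-specific
interventions present; a proportional-hazards effect would be a different
claim. Animal-days at risk per scoring interval are counted as
animals-at-interval-start × interval width; with three scorings per week
the difference from actuarial conventions is immaterial at cohort sizes
of interest.

`powerOfDetection` simulates replicate two-arm experiments and counts
Mantel–Haenszel log-rank rejections, with a Wilson 95% CI on the power.
Its null behavior (power ≈ α) and the log-rank test's type-I calibration
are asserted in the tests.

# Numerical conventions

* **Quartiles/whiskers**: type-7 (linear interpolation) quartiles;
  whiskers at the most extreme observations within 1.5·IQR. Outliers are
  counted for plotting and *never* removed from variances or tests.
* **Binning**: half-open $[e_i, e_{i+1})$ with an overflow bin above the
  last edge; ages below the first edge are an error, never dropped.
* **Binomial tails**: computed in log space (`pbinom(log.p = TRUE)`);
  two-sided p doubles the smaller tail, capped at 1; results are floored
  at 1e-300 so a p-value is never 0. Reporting layers may render
  "P < 1e-100"-style bounds, but the stored value is the computed number.
* **Degenerate inputs**: identical Levene groups give W = 0, p = 1; a
  two-group t test with both groups constant and equal gives t = 0,
  p = 1, flagged; a constant dv vector makes Spearman's rho NA with a
  warning rather than an arbitrary value.
* **Ties**: log-rank ties are handled with the hypergeometric variance;
  Spearman p uses the tie-corrected t approximation.
* **Seeds**: every stochastic routine takes a seed and restores the
  caller's RNG state; the generator derives fixed sub-streams from one
  master seed so any sub-result is reproducible in isolation.
* **Text I/O**: floats are written with `%.17g`, so TSV round trips are
  bit-exact.

# Problem sizes in the test suite

The suite exercises the pipeline at 100–5,000 genes and cohorts of
100–30,000 animals: large enough that Monte-Carlo calibration bands
(e.g. type-I error in (0.035, 0.065) over 1,000 null simulations) and
recovery tolerances (Gompertz parameters within 10% at n = 5,000; dv
within 2% of the closed form at 5,000 genes) are meaningful, small enough
that the default run completes in a few minutes. The acceptance script
uses 600 replicates of 1,500-per-arm experiments for the power
computation.

# Known limitations

* Drift is only as meaningful as the young reference; cohorts without a
  biologically young anchor cannot use the metric.
* dv conflates all sources of between-gene dispersion; count noise and
  pseudocount shrinkage bias it (upward and downward respectively), so
  absolute dv values are comparable only within one processing
  configuration — which is why all comparisons go through the Levene
  machinery on identically processed groups.
* The attenuation classifier is directional, not effect-sized: a gene
  barely below its control counterpart counts as attenuated. The
  binomial summary inherits this; it answers "is the direction
  systematic", not "how strong is the attenuation".
* Differential-expression calling, enrichment analysis and read-level
  processing are out of scope; the package consumes count matrices and
  produces drift statistics.
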