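---
title: "ANCOVA for qPCR cycle thresholds: model, assumptions, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ANCOVA for qPCR cycle thresholds: model, assumptions, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpcrmlm)
```

## The model

qPCR reports, per sample and gene, the cycle threshold CT: the number of
amplification cycles until fluorescence crosses a detection limit. With
perfect per-cycle doubling, CT is (minus) a base-2 logarithm of starting
template, so CT values are already on the log scale on which normal-theory
tests are reasonable.

The classic 2^−ΔΔCT workflow normalises each sample by subtracting a
reference (housekeeping) gene's CT and compares the group means of the
differences — a difference-in-differences on two *different* measurements.
The subtraction fixes the reference gene's weight at 1. `qpcrmlm`'s central
object is instead the ANCOVA fit

$$
\mathrm{CT}^{\mathrm{target}}_i \;=\; \beta_0
 + \beta_T\,\mathbb{1}[\text{treated}_i]
 + \textstyle\sum_j \gamma_j\,\mathbb{1}[\text{donor}_i = j]
 + k\,\mathrm{CT}^{\mathrm{ref}}_i + \varepsilon_i ,
$$

estimated by ordinary least squares (`qpcr_mlm()`, `analyze_ancova()`). The
reference weight $k$ is a free parameter: near 1 when the reference gene
really does track sample quality, near 0 when it carries no information, in
which case the model quietly ignores it instead of injecting its noise into
the contrast. A significantly negative $k$ has no biological reading and
should be treated as a red flag for the assay.

Interpretation conventions used throughout:

* Estimates are in CT units and stay on the log scale; a **positive**
  treatment coefficient (or ΔΔCT) means **higher** CT, i.e. *less*
  transcript. `fold_change(x) = 2^-x` is provided as a separate, explicit
  back-transform and is exact only at 100% efficiency.
* Two-sided p-values come from the Student t distribution with $n - p$
  residual degrees of freedom, never the normal: the intended sample sizes
  are of order 10.
* The treatment factor's baseline is its control level; every other
  factor's baseline is the lexicographically first level.

## Amplification efficiency and scale invariance

If a gene amplifies with fractional efficiency $e \in (0, 1]$, one cycle
multiplies template by $1 + e$ and the measured CT is a base-$(1+e)$
logarithm. By the change-of-base identity it differs from the nominal
base-2 quantity by the constant factor $\log_2(1+e)$
(`efficiency_scaled_ct()`). In the ANCOVA, rescaling the reference column by
any $c > 0$ divides $\hat k$ by $c$ and leaves every other coefficient's
t-statistic and p-value bit-for-bit unchanged; rescaling the response
rescales all coefficients but again leaves t and p alone. Efficiency
differences between target and reference — the main documented failure mode
of 2^−ΔΔCT — therefore cannot move the treatment inference. The test suite
asserts this to ten significant digits for $c \in \{0.5, \log_2 1.9, 3\}$.

## Numerical choices

* The OLS engine uses a QR (orthogonal) decomposition, not explicit normal
  equations, for conditioning when covariates are nearly collinear; it is
  cross-checked in the tests against an SVD pseudo-inverse oracle and
  against `stats::lm` to 1e-8 or better.
* Rank deficiency is a **hard error** naming the collinear columns. At
  $n \approx 10$, silently aliasing a column (as `lm` does) changes the
  meaning of the remaining terms; we refuse instead.
* `n > p` is enforced as a floor, with $n \ge 2p$ recommended in the error
  text, the usual lower bound of regression sample-size rules of thumb.
* Missing CT cells are `NA`, never sentinel values (a 0 or 40 silently
  biases a linear fit); model construction drops incomplete samples and
  reports the count.
* Group comparisons use the pooled-variance (Student) two-sample t by
  default, which is exactly calibrated under a Gaussian null — `var_equal =
  FALSE` switches to Welch. Degenerate zero-variance inputs, which arise in
  simulation edge cases, have a defined convention: equal constants give
  t = 0, p = 1; unequal constants give p = 0 with a warning.
* Technical replicates collapse by the mean (triplicate wells), with a
  median option for outlier-heavy plates.

## What the simulation framework emulates

`qpcr_scenario()` / `rejection_rates()` / `scenario_grid()` estimate the
empirical type I error and power of three analyses of the same synthetic
experiment — the ANCOVA treatment term (MLM), the pooled t on target −
reference (ddCT), and the pooled t on the target alone (dCT):

* **Design**: 5 treated vs 5 control independent samples (think one sample
  per donor), the smallest design the method is intended for; unpaired.
* **Margins**: unit-variance, mean-zero reference and noise margins —
  Gaussian, or standardised exponential for right skew (skewness +2), or
  its negation for left skew. Effects are expressed in SD units, the only
  scale the problem fixes.
* **Correlation**: target = $\rho z_R + \sqrt{1-\rho^2}\, z_E$. Linear
  mixing makes the Pearson correlation exactly $\rho$ for *any* margins;
  the price is that the target's skewness is attenuated by the mixing. We
  accept that because the correlation values are the quantitatively
  specified quantity and the skew is qualitative.
* **Contaminated reference**: `reference_effect = 1` adds one SD to the
  treated samples' reference CT — a reference gene that responds to
  treatment. In that regime only dCT remains calibrated at every $\rho$;
  ddCT is anticonservative everywhere and the MLM inflates once $\rho > 0$
  (the fitted $k$ transfers the reference shift into the treatment term).
* **Power scenarios** default to a 2 SD target shift. With 5 vs 5 samples
  this puts the reference-free test near 79% power and leaves visible
  headroom above and below, so the power *ordering* of the three methods —
  the scientifically meaningful pattern — is resolvable at Monte-Carlo
  resolution. Published comparisons of this kind do not pin down their
  alternative effect size, so power values are checked as orderings, not
  as point targets.
* **Determinism**: replicate $i$ of a scenario reseeds the generator from a
  hash of (scenario seed, $i$); grid rows derive their seeds from the base
  seed the same way. Results are therefore bit-reproducible and independent
  of execution order, at the cost of a per-replicate `set.seed` call.
* **Replicates**: 10,000 per scenario by default, putting the Monte-Carlo
  standard error of a 5% rate at ±0.22 percentage points; the test suite
  runs its calibration grid at this size in a few minutes on one CPU.

What passing these simulations does *not* show about real data: margins are
exchangeable across samples (no plate or batch structure), technical
replicates are not simulated, both genes have equal variance, and the
reference contamination is a pure mean shift. Real qPCR adds donor pairing,
heteroscedasticity and occasional non-amplification, none of which the
generator models.

## Calibration facts the suite asserts

Under the Gaussian null with a clean reference, all three methods are
*exactly* calibrated (the pooled t and the ANCOVA t are exact), and the
suite checks each rate against 5% within 3 Monte-Carlo standard errors at
every correlation. Under skewed margins at $n = 5 + 5$, small-sample t
procedures drift a little **conservative** — rejection rates in the 3–5%
range — so the suite asserts the one-sided property that no method becomes
anticonservative under the skewed null, rather than forcing 5% equality the
underlying statistics do not satisfy.

## Design decisions that were genuinely open

* **Fixed effects only.** Donor enters as a fixed factor. A random-intercept
  variant is attractive for paired designs but is unidentifiable in the
  unpaired simulated design (one observation per donor) and is not needed to
  reproduce the worked example; it is deliberately out of scope.
* **Model interface over subtraction pipelines.** The package follows the
  classic R modelling idiom — one fitting function returning a classed
  object with `summary`/`coef`/`predict`/`simulate` methods — because the
  contribution *is* a model, and because it makes the ddCT methods
  one-liners built from the same parts rather than a separate code path.
* **Wilcoxon option.** A rank-based alternative to the ddCT t-test is
  provided (`method = "wilcoxon"`) for skew-robust analyses but is not used
  in any calibration claim.
* **CSV dialect**: comma-separated, header row, decimal point, UTF-8; gene
  names match case-sensitively (silent aliasing of near-identical gene
  symbols is worse than an error).

## Known limitations

Effect estimates are in CT units, not fold changes; converting to fold
changes at efficiency below 100% requires an external efficiency estimate.
Both the ANCOVA and ddCT assume the reference gene is stable under
treatment — the contaminated-reference simulations quantify exactly how
wrong things go when it is not, and the reference-free dCT column is the
fallback in that regime. Multi-level treatments are analysed one two-level
contrast at a time, and heteroscedasticity-robust standard errors are not
offered.
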