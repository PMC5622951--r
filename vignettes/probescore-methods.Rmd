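---
title: "Methods: probe-level S-scores, One-Class SAM, and companion statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probe-level S-scores, One-Class SAM, and companion statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probescore)
```

## The problem

Adolescent binge-ethanol studies of the rodent prefrontal cortex measure
treatment effects on three very different kinds of data: probe-level
fluorescence from PM-only transcriptome arrays (thousands of transcript
clusters, a handful of biological replicates), per-animal behavioral
endpoints (righting-reflex times, object-recognition times, light–dark
box occupancy), and follow-up assays (qPCR Ct values against multiple
reference genes, ELISA optical densities against a standard curve).
`probescore` implements the full analysis chain for such a design — two
ages × two sexes × ethanol/control with paired treated↔control arrays —
with every stage testable against simulated data of known truth.

## The S-score on PM-only arrays

Classical S-score analysis standardized PM−MM probe-pair differences.
Modern transcriptome arrays carry no mismatch probes, so here the
probe-pair difference is the *between-chip* difference of the same probe.
For a treated/control pair with scale factors $s_T, s_C$:

$$z_j = \frac{s_T I_{jT} - s_C I_{jC}}{\gamma\,(s_T I_{jT} + s_C I_{jC}) + \alpha},
\qquad S_g = \frac{1}{\sqrt{n_g}} \sum_{j \in g} z_j .$$

The construction preserves the statistic's defining properties: relative
change is measured at the probe level, errors are equalized across the
intensity range before summation, the per-cluster sum is scaled by
$\sqrt{n_g}$, and the null distribution is standard normal.

**Error-model estimation.** The scheme is deliberately robust rather than
least-squares, because genuinely differential probes are outliers under
the null fit:

* *Scale factors* equalize 2%-trimmed mean intensity; each chip is scaled
  to the geometric mean of the two trimmed means, so a pure rescaling of
  one chip is absorbed exactly.
* $\gamma$ (dimensionless) is set so the median absolute standardized
  difference over the central 50% of summed intensities equals the
  standard-normal reference value 0.6745.
* $\alpha$ (intensity units) is set from the lowest summed-intensity
  quartile as the excess dispersion not explained by $\gamma$, floored at
  zero. It matters only where signal approaches the additive background.

**Post-hoc standardization.** By default each pair's S-score vector is
centered at its median and scaled by MAD/0.6745. This guarantees the
advertised N(0,1) null even when the linear error model is misspecified;
`standardize = FALSE` exposes the raw error-model-only scores. Both
behaviors are useful: the raw scores diagnose the error model (on the
default simulation their SD is already within ~10% of 1), the
standardized scores are what downstream SAM consumes.

**Replicates.** Pairwise scores are computed within sex — each
treated↔control pair is one biological replicate, one column of the
replicate matrix. When a biological replicate has exactly one pairwise
score, no averaging occurs; the package adopts this one-pair-one-replicate
reading throughout (a 5-male + 4-female design per age yields the
nine-column replicate matrix). Columns are not rescaled after assembly;
any variance consequences are absorbed by SAM's $s_0$ and its permutation
null.

## One-Class SAM

The test asks whether a cluster's mean S-score across the $k$ replicate
columns deviates from zero:

$$d_i = \frac{\bar{x}_i}{se_i + s_0}.$$

* **$s_0$** is tuned on the Tusher grid (percentiles 0, 5, …, 100 of the
  per-row standard errors), minimizing the coefficient of variation of
  the d statistic's MAD across standard-error quantile windows. When the
  windowing is ill-conditioned (fewer than 20 rows, or constant standard
  errors) the documented fallback is the median standard error. Note that
  on data with little variance heterogeneity this criterion is flat up to
  sampling noise for large $s_0$ and systematically penalizes small
  $s_0$, so it legitimately selects a high percentile there; calibration
  is unaffected because the permutation null uses the same $s_0$.
* **The null** multiplies each replicate column by ±1 and recomputes $d$
  with the same $s_0$ — a one-class analysis has no labels to permute.
  With $2^k \le$ `n_perm` all sign patterns are enumerated (all 512 for
  $k = 9$), making the run exactly reproducible regardless of seed.
* **Calling.** For a symmetric threshold $\Delta$, the estimated FDR is
  $\hat\pi_0 \cdot \overline{V(\Delta)} / R(\Delta)$, where
  $\overline{V}$ is the *mean* count of null $|d| \ge \Delta$ across sign
  patterns, $R$ the observed count, and $\hat\pi_0$ the proportion of
  observed $d$ inside the central 50% of the pooled null (capped at 1).
  The selected $\Delta$ is the smallest achieving the target; a cluster's
  q-value is the smallest estimated FDR at which it would be called. We
  use the mean rather than the classical median of exceedance counts
  because with automatic $\Delta$ selection the median estimator
  collapses to zero at the observed maximum in roughly half of pure-null
  datasets (the observed pattern's maximum ranks below the median of the
  per-pattern maxima), producing a guaranteed false call; the mean — to
  which the observed-equivalent identity pattern always contributes —
  keeps the null false-call proportion at its nominal level, which the
  test suite measures at 0.05 over 20 seeded null runs. One-sided calling
  (`side = "up"`/`"down"`) is available behind a flag; the default is the
  single symmetric threshold.
* Exceedance counting uses a $10^{-9}$ relative tie tolerance so the
  identity sign pattern, which reproduces the observed $d$ up to
  floating-point noise, counts against its own threshold.

## Gene-level track

The vendor signal-summarization chain is out of scope; its documented
stand-in is: log2(x + offset), quantile normalization across samples
(`limma::normalizeQuantiles`), and per-cluster median polish, returning
overall + sample effects. Fixed per-probe affinities are absorbed by the
polish row effects up to a per-cluster additive constant (rescaling one
probe can shift the median row effect), so sample *contrasts* — what all
downstream models consume — are affinity-invariant; the tests assert
exactly that. The default offset of 1 protects zero intensities; the
noise-free closed-form checks use offset 0, where a fold-2 spike
summarizes to exactly 1.0 log2 units.

Per-cluster `~ treatment * sex` models use sum-to-zero contrasts; with
two-level factors every term has 1 df and the Type-III F equals the
squared Wald t from the full fit, which is how the package computes all
clusters in one pass of matrix algebra. Empirical-Bayes moderation
(`limma::squeezeVar`) is on by default, with `moderate = FALSE` for plain
ANOVA and `prior_df` exposed for explicit shrinkage control (infinite
prior df pools all residual variances). Significance uses the
uncorrected p < 0.01 gate of the original two-track design;
`intersect_lists()` supports the cross-track and cross-age comparisons.

With asymmetric differential expression, quantile normalization leaks a
small treatment-correlated shift into null clusters; at the default scale
(≤ 4% spiked clusters) the effect on the p < 0.01 gate is negligible, but
at toy scale (dozens of clusters) it is visible — the type-I-error tests
therefore run on null data.

## Enrichment, behavior, assays

* **Over-representation** is the one-sided hypergeometric upper tail with
  BH adjustment across sets. The universe is all clusters on the array
  (the standard array-background convention; the original service-based
  analysis does not state its background). Sets are intersected with the
  universe before testing.
* **Factorial ANOVA** (2 or 3 factors) uses Type-III sums of squares with
  sum-to-zero contrasts (`car::Anova`); constant responses return F = 0,
  p = 1 explicitly, and aliased terms are rejected by name.
* **SNK post hoc** sorts group means and compares spans with studentized-
  range critical differences $q(\alpha, r, df_e)\sqrt{MSE/\tilde n}$,
  $\tilde n$ the harmonic mean cell size (the standard unbalanced-cell
  extension; group sizes of 6–11 per cell are typical here). Quantiles
  come from `qtukey`, validated against published tables, so any error df
  is supported. The stepwise protection rule blocks every comparison
  nested inside a non-significant span. An omnibus-significance gate is
  enforced with a `force` override.
* **qPCR**: technical wells averaged per sample × gene; ΔCt against the
  arithmetic mean of the reference Cts (equivalently, geometric-mean
  normalization of expression — the standard multi-reference convention,
  as the combination rule is not stated in the source protocols);
  relative quantities rescaled so the baseline group's mean is exactly 1.
* **ELISA**: ordinary least-squares line of OD on standard concentration,
  inverted for samples, divided by protein input (ng/μg). Linear rather
  than 4PL, as the minimal documented choice; extrapolation outside the
  standards' OD range is rejected unless explicitly allowed.

## The synthetic-data generators

`simulate_probe_data()` draws per-cluster baselines
$x_g \sim \mathrm{logN}(\log 300, 1)$, fixed per-probe affinities
$a_j \sim \mathrm{logN}(0, 0.5^2)$, and intensities
$a_j x_{gc} e^{\eta} + \mathcal{N}(50, 20^2)$ truncated at zero, with
$\eta \sim \mathcal{N}(0, 0.1^2)$ and a multiplicative fold change in
ethanol samples of spiked clusters. This
multiplicative-plus-additive structure is the minimal one under which an
intensity-proportional error with an additive floor is the *correct*
standardization, which is what makes the closed loop meaningful: the
generator's effective multiplicative coefficient is
$\sigma_{mult}/\sqrt{2}$, and the error-model fit recovers it within 15%
at 20,000 probes. The default design mirrors the study scale — 2 ages ×
2 sexes × ethanol/control, 5 male + 4 female pairs per age, 5,000
clusters × 4 probes as a desk-scale stand-in for a full transcriptome
array. Truncation at zero (rather than resampling) is documented and
negligible at the default parameters.

What the generator does **not** emulate: spatial chip artifacts,
hybridization-batch effects, sex-chromosome dosage, probe
cross-hybridization, and heavy-tailed outlier probes. Passing tests
therefore demonstrate the statistics' correctness and calibration under
the stated noise model, not robustness to every failure mode of real
arrays. Platform-level noise parameters for real transcriptome arrays are
not published; the defaults are calibration targets for the pipeline, not
estimates of the physical platform.

The behavioral, qPCR, and ELISA generators are direct parametric draws
(Gaussian around group means; $Ct = base - \log_2 expr + noise$ with
triplicate wells; $OD = a + b \cdot conc + noise$) whose ground truth is
attached to the output, enabling exact noise-free closed loops.

## Numerical choices and degenerate inputs

* γ is floored at $10^{-8}$ (identical chips would otherwise give 0); a
  zero denominator $\varepsilon_j$ (both intensities and α zero) is a
  degenerate-input error, as are all-zero chips.
* `sam_d` with a constant row and $s_0 = 0$ is a division-by-zero error;
  with $s_0 > 0$ it is defined.
* Probe matrices are written with 17 significant digits and parsed with
  base R's `strtod`, making write→read round trips bit-exact.
* Intensities live on the linear scale in all interchange formats; log
  transforms are internal to consumers.
* The NOR training-time rule retains animals with *more than* 10 s of
  investigation: exactly 10.0 s is excluded.

## Problem sizes

The test suite and acceptance checks run at desk scale, chosen to keep
each property measurable: null calibration on 5,000 clusters × 4 probes;
FDR calibration as 20 seeded spiked runs of 2,000 clusters (80 spiked at
fold 2) with the nine-pair design and the exact 512-pattern null;
sensitivity monotonicity over folds 1.2/1.5/2.0 averaged over 4 seeds
each; brute-force SAM equivalence on 5 clusters × 4 replicates;
enumeration oracles for the hypergeometric tail up to N = 20.

## Known limitations

* The error model is linear in summed intensity; saturation at the high
  end of real scanners is not modeled (the post-hoc standardization
  absorbs global misspecification but not intensity-local bias).
* FDR estimates with very few replicate columns ($2^k$ small) are
  coarse; with $k = 2$ the null has only 4 patterns and calling is
  effectively impossible — the package requires $k \ge 2$ and leaves
  power to the design.
* The SNK variant uses a single harmonic-mean cell size for all spans
  rather than per-pair harmonic means; with mildly unbalanced designs the
  difference is small, and the exact variant used by legacy commercial
  stats packages is not documented.
* `fit_two_factor` covers the fully crossed two-factor design only; the
  replicate pairing is deliberately ignored at the gene level (pairs
  enter only the S-score track).
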