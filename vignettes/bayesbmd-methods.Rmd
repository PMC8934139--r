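---
title: "Bayesian model-averaged benchmark dose estimation for genomic dose-response data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian model-averaged benchmark dose estimation for genomic dose-response data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayesbmd)
```

## Scope and workflow

`bayesbmd` estimates transcriptomic points of departure from multi-dose
expression experiments. The workflow mirrors the standard genomic
dose-response pipeline used in toxicogenomics:

1. **Screening** — per probe: fold change, one-way ANOVA, and
   Williams-type monotone trend tests with resampling null distributions;
   Benjamini-Hochberg adjustment across probes; an AND-filter on fold
   change and a chosen test's p-value.
2. **Model fitting** — seven continuous dose-response models fitted per
   probe by MCMC under a normal likelihood.
3. **Benchmark dose estimation** — each posterior draw is inverted to a
   BMD under a benchmark response (BMR) definition; per-model BMD
   posteriors are combined by posterior model weights into a
   model-averaged (BMA) BMD distribution summarized as BMD (median),
   BMDL (5th percentile) and BMDU (95th percentile).
4. **Pathway aggregation** — probe BMDs collapse to genes, genes to
   gene-set categories; Fisher's exact two-tailed test flags enriched
   categories; the median of enriched categories' median BMDs is the
   biological-effect point of departure (BEPOD), which can be compared
   to apical PODs by log10 Pearson correlation and RMSD.

Inputs are expected as normalized, log-transformed intensities or counts
(the declared `log_base` — 2, 10 or natural — only affects the fold-change
back-transformation). The minimum dose group is treated as the control
throughout; samples are canonicalized into ascending dose order on read,
so column order in the input file never affects a result.

## Screening statistics

**Fold change.** For dose level $i$ with mean log response $\bar x_i$ and
control mean $\bar x_0$, the response ratio is $r_i = b^{\bar x_i - \bar
x_0}$ for log base $b$. Ratios below one are reported as $-1/r_i$, so the
magnitude is always $\ge 1$; the probe's fold change is the candidate of
maximum magnitude across levels (absmax). The default screen removes
probes with $|f| < 2$.

**Monotone trend.** The isotonic (monotone) MLE of the group means is the
weighted max-min estimator
$$\hat\mu_i = \max_{u \le i} \min_{u \le v \le K}
  \frac{\sum_{j=u}^{v} n_j \bar X_j}{\sum_{j=u}^{v} n_j},$$
computed by weighted pool-adjacent-violators (the two forms are
identical; the test suite checks this against the literal enumeration).
The Williams-type statistic standardizes the isotonic means against the
control,
$$T = \max_{i \ge 1} \frac{|\hat\mu_i - \bar X_0|}
  {s\sqrt{1/n_i + 1/n_0}},$$
with $s$ the unbiased pooled within-group SD over **all** groups
including the control (standard Williams practice; the source material
for this pipeline does not specify the pooling set). The maximum runs
over treated levels only. The trend direction is not assumed: both
monotone fits are evaluated and the direction with the larger $T$ is
reported.

**Resampling p-values.** The null distribution of $T$ is simulated by
permuting dose labels across all samples (the Williams variant) or by
resampling with replacement from the pooled sample (the Oriogen-type
variant, which shares the monotone statistic and differs only in its
bootstrap null — a documented interpretation of a method the source
pipeline describes only as "adapted" under a monotonicity assumption).
The direction is re-chosen in every replicate, and the p-value uses the
+1 correction $p = (1 + \#\{T_b \ge T\})/(B+1)$, bounded below by
$1/(B+1)$; $B$ defaults to 1,000. Constant probes are assigned $p = 1$
(every permutation reproduces $T = 0$). An exhaustive enumeration path
exists for $n \le 8$ and is used in tests.

**Filter rule.** A probe passes when $|f| \ge$ `fold_change_cutoff`
(inclusive) **and** the selected test's p-value (raw by default,
BH-adjusted on request) is `< p_cutoff` (strict). The inclusive/strict
boundary pair and the raw-p default are package conventions; only the
fold-change cutoff of 2 is inherited from the upstream practice.

## The seven dose-response models

With doses rescaled by the maximum dose to $x \in [0,1]$, adversity
direction $s = \pm 1$ fixed per probe from the sign of (top-dose mean −
control mean), and all effect magnitudes positive:

| model | mean function | parameters |
|---|---|---|
| linear | $a + s\,b\,x$ | $a, b$ |
| power | $a + s\,b\,x^g$ | $a, b, g$ |
| hill | $a + s\,b\,x^g/(c^g + x^g)$ | $a, b, g, c$ |
| exp2 | $a\,e^{s b x}$ | $a, b$ |
| exp3 | $a\,e^{s (b x)^g}$ | $a, b, g$ |
| exp4 | $a\,(c - (c-1)e^{-b x})$ | $a, b, c$ |
| exp5 | $a\,(c - (c-1)e^{-(b x)^g})$ | $a, b, c, g$ |

plus a residual SD $\sigma$ in every model. Shape parameters $g$ are
bounded below by 1 (finite slope at dose zero, monotone curves); the
hill $c$ is the half-maximal dose on the rescaled axis; exp4/exp5 carry
their direction in $c$ ($c > 1$ increasing, $0 < c < 1$ decreasing).
These are the standard continuous parameterizations used by benchmark
dose software for continuous endpoints; exp3 nests exp2 and exp5 nests
exp4 exactly at $g = 1$, and power nests linear.

Observed responses are modeled as
$y \sim \mathrm{Normal}(f_k(x\,|\,\theta_k), \sigma)$.

## Priors

Priors are data-adaptive configuration, not constants (the exact prior
tables of the upstream web system are not public; these defaults are this
package's own choices and can be overridden via the `priors` argument):

* background $a$: normal centered at the observed control mean, SD
  $\max(5\,\mathrm{sd}(y), 1)$; truncated to $a > 0$ for the exponential
  family (a multiplicative background requires a positive level — on
  log-scale expression data this is essentially always satisfied);
* effect $b$: half-normal, scale $2\,\mathrm{range}(y) + 0.1$ for
  linear/power/hill (response-scale effects), 1.5 for exp2/exp3
  (dimensionless rates), 5 for exp4/exp5 (rates on the rescaled axis);
* shape $g$: uniform on $[1, 18]$;
* hill $c$: uniform on $(0, 30]$ rescaled dose units;
* exp4/exp5 $c$: **effect-scaled** — half-normal on the plateau change
  $|c - 1|$ with scale $(2\,\mathrm{range}(y)+0.1)/|\bar y_0|$, truncated
  to $(1, 20]$ (increasing) or $(0, 1)$ (decreasing). A uniform density
  on $(1, 20]$ would put most prior mass on plateau changes of several
  log2 decades, far beyond any real expression effect; matching the
  implied response-scale prior to the half-normal effect prior of the
  other models is both more realistic and measurably better calibrated;
* $\sigma$: half-normal, scale $\max(2\,\mathrm{sd}(y), 0.05)$.

## Posterior computation

Sampling uses an adaptive random-walk Metropolis kernel written in C++:
a component-wise phase with per-parameter step adaptation (target
acceptance 44%) for the first half of warmup, then joint
multivariate-normal proposals whose covariance is the running empirical
covariance of the chain, with a global scale adapted toward 23%
acceptance and frozen at the end of warmup. The joint phase is essential:
the effect/shape pairs $(b, g)$ of the power and exponential models are
strongly correlated (posterior correlations above 0.9 are routine), and
component-wise proposals alone leave effective sample sizes an order of
magnitude lower. The production default follows the established
empirical settings for this class of sampler — one chain, 30,000
iterations, 50% warmup. The test suite and acceptance battery run at
5,000–10,000 iterations, this package's chosen validation scale; low
acceptance rates or effective sample sizes flag (never fail) a fit. All
randomness flows through R's RNG, so `set.seed()` makes every stage
bit-reproducible.

**Model weights.** The posterior model weights are
$\pi(M_k\,|\,y) \propto \hat f(y\,|\,M_k)\,\pi(M_k)$ with uniform prior
weights by default. The marginal likelihood $\hat f$ is estimated by
**bridge sampling** (Meng-Wong iteration with a multivariate-normal
proposal matched to the posterior draws), falling back to a
Laplace-Metropolis estimate when the posterior covariance is degenerate;
the estimator used is recorded in the fit's metadata. An earlier
Laplace-only implementation systematically inflated the evidence of
weakly identified models (a diffuse posterior inflates the covariance
volume term); bridge estimates were validated against brute-force grid
integration of the posterior.

**Model averaging.** The BMA BMD distribution is realized by sampling a
model index from the weights and then a uniform draw from that model's
BMD sample; summaries are the empirical 50th/5th/95th percentiles.

## BMD inversion

Two BMR definitions are supported: a relative change of the background
response, $|f(\mathrm{BMD}) - f(0)| = \mathrm{rel} \times f(0)$, and a
standard-deviation shift, $|f(\mathrm{BMD}) - f(0)| = k\sigma$ with
$\sigma$ the draw's own residual SD (the NTP genomic default, $k = 1$,
is the package default). Every model inverts in closed form; an
independent bisection root-finder exists as a cross-check. Draws whose
curve never reaches the target (saturating models with a plateau below
the BMR) or whose solution exceeds 100× the maximum dose are **capped**
at that bound and counted in a per-probe `capped_fraction` — a failed,
missing, or negative BMD is structurally impossible, which is the
zero-failure contract the acceptance battery verifies. Estimates above
the maximum dose are kept (flagged `above_max_dose`); an explicit
`exclude_above_max_dose()` helper reproduces the comparison convention of
other tools, which the estimation itself never applies.

## Pathway aggregation and BEPOD

Probes mapping to more than one gene are removed; multiple probes per
gene average their BMD/BMDL/BMDU. Category statistics (min, max, mean,
median BMD; median BMDL/BMDU) are computed over the category's genes
that have BMD estimates. Enrichment is Fisher's exact two-tailed test on
the 2×2 table of category membership against possession of a BMD
estimate; the universe is all uniquely-mapped genes in the annotation
(the platform), a documented assumption — the alternative (restricting
to screened genes) would shrink every margin equally and mostly rescale
p-values. Enriched categories satisfy $p < 0.05$ (strict), more than one
gene with a BMD (strict), and percentage $\ge 3\%$ (inclusive). The
BEPOD is the median of enriched categories' median BMDs, with the
mean-of-middle-two convention for even counts. POD/BEPOD agreement uses
Pearson correlation and RMSD on log10 values. Annotation arrives as
local GMT and probe-map files; no live database access is performed, and
no multiple-testing correction is applied across categories (the
enrichment filter operates on raw Fisher p-values by design).

## The synthetic experiment generator

`simulate_experiment()` emulates a short-term in-vivo transcriptomic
design: five dose levels (control plus four geometric doses, default
0/12.5/25/50/100), 4 samples per level, log2-scale intensities with
backgrounds uniform on 6–10 and residual SDs on 0.05–0.2. Responsive
probes draw a generating model, a direction, shape parameters
($g \sim U(1.2, 3)$; hill half-max 1–3× the BMD; exp4/exp5 plateaus at
`plateau_margin` (default 1.5–4) times the BMR target — deliberately the
weakly identified near-plateau regime), and a true BMD log-uniform on
0.1–2× the maximum dose, beyond the tested range at the top so the
extrapolation-flag path is exercised; the effect parameter is then
solved so the true BMD is exact. A `max_effect` cap (4 log2 units)
shrinks the residual SD where a convex shape would otherwise imply an
absurd top-dose effect, and an optional `min_effect` floor raises it to
emulate uniformly strong responders (the cap always wins). One designed
category collects the lowest-BMD responsive genes; remaining responsive
genes scatter among background categories with the nulls.

What the generator does **not** emulate: probe-level array artifacts,
batch effects, normalization residue, correlated noise across probes, or
heteroscedasticity. Passing tests therefore demonstrate correctness of
the statistics and the estimation machinery under the stated model, not
robustness to real-data pathologies.

## Validation design (what the test suite checks)

* **Oracle equivalence** — isotonic means against the literal max-min
  enumeration; Fisher p-values against hypergeometric enumeration; BH
  against the step-up recursion; closed-form BMD inversion against
  bisection.
* **Size** — the permutation trend test's rejection rate under a global
  null stays inside the binomial 99% band at $\alpha = 0.05$.
* **Zero failures** — a 200-probe, seven-model battery (5,000
  iterations) yields no missing, non-finite, or negative BMD/BMDL.
* **Interval calibration** — a matched-prior study: per model, truth is
  drawn from the same fixed moderate-scale priors used in fitting
  (shape $g$ on $[1,5]$, plateau ratios within a factor ~3, $\sigma$
  half-normal 0.3), data simulated at 50 samples per level, and central
  90% BMD intervals are required to cover the truth at 90% ± 7 points.
  Matched priors are the regime in which nominal coverage is a theorem,
  so this isolates implementation error from prior disagreement. When
  truth is instead drawn from distributions narrower than the package's
  deliberately diffuse shape priors (the generator's own defaults),
  measured coverage of the saturating models drops to roughly 0.83–0.86
  — a known, documented consequence of diffuse priors on weakly
  identified shape parameters, not an implementation defect.
* **Point-estimate recovery** — on a recoverable-truth experiment (60
  strong responders from the monotone non-saturating shapes, top-dose
  effects ≥ 1.5 log2 units, log-spaced doses 0/3/10/30/100 bracketing
  every true BMD, 8 samples per level) the log-scale correlation between
  BMA BMDs and truth must reach 0.9. Saturating truths whose plateau
  sits near the BMR are excluded from this particular check because
  their BMD is weakly identified at any effect size — they are assessed
  by the calibration study instead, and all seven models are still
  fitted and averaged here.
* **Enrichment truth** — the designed low-BMD category passes the
  enrichment filters in ≥ 95% of seeded replicates and the BEPOD falls
  below the background categories' median BMD.
* **Determinism** — identical configuration and seed reproduce every
  output file byte for byte.

Problem sizes (200-probe battery, 100-replicate calibration per model,
500-replicate size study at $B = 500$, 20 enrichment replicates) are the
package's chosen desk-scale validation design.

## Numerical choices and edge cases

* Dose rescaling by the maximum dose stabilizes sampling across datasets
  whose dose units span orders of magnitude; BMDs are rescaled back, and
  multiplying all doses by a constant multiplies every BMD draw by the
  same constant exactly.
* Zero-variance or non-finite probes are flagged invalid at intake (a
  constant probe has $s = 0$ and no defined trend statistic).
* Ties in the fold-change absmax keep the first (lowest-dose) candidate;
  ties in dose sorting keep file order.
* The bridge iteration runs on shifted log scales to avoid overflow;
  out-of-support proposal draws contribute zero numerator mass.
* The posterior covariance used for proposals and the fallback Laplace
  estimate carries a small ridge so boundary-pinned parameters (e.g.,
  $g$ piling at 1) cannot degenerate it.
* `summarize_bmd()` uses R's default type-7 empirical quantiles.

## Known limitations

* A single chain is the default (matching upstream practice); the
  `chains` setting pools independent restarts but no cross-chain R-hat
  gate is applied — diagnostics flag rather than fail.
* Marginal likelihoods from bridge sampling on 2,500–15,000 draws carry
  Monte Carlo error of a few hundredths of a nat; weights between
  near-equivalent models (linear vs exp2 at small rates) are accordingly
  fuzzy — which is precisely the regime where model averaging, rather
  than selection, is the point.
* Under a 1-SD BMR, probes whose true BMD lies near or beyond the top
  dose necessarily have top-dose effects comparable to the noise; no
  estimator can locate their BMD precisely, and the package reports that
  honestly through wide intervals and `above_max_dose` flags.
* The normal likelihood is not robust to outlier samples; screening
  (ANOVA/trend) offers partial protection only.
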