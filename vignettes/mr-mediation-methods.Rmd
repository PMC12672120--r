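---
title: "Methods: two-sample MR with mediation from summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR with mediation from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The problem and the causal model

`mrmediate` estimates causal effects from GWAS summary statistics alone, in
the two-sample Mendelian randomization (MR) design: genetic variants serve as
instrumental variables for an exposure measured in one study population,
while their effects on the outcome come from a second, non-overlapping
population. The motivating application is gene-expression exposures
(cis-eQTLs for druggable genes), metabolite mediators measured in small
specialized GWAS (such as cerebrospinal-fluid metabolomics), and a rare
binary disease outcome from a large biobank, but nothing in the code is
specific to those traits.

The instrumental-variable assumptions are the usual three: the variant is
associated with the exposure (relevance), shares no confounder with the
outcome (independence), and affects the outcome only through the exposure
(exclusion). The estimators differ in how much violation of exclusion they
tolerate, which is why the package always reports several.

The mediation extension adds an intermediate trait. Writing $\beta_1$ for the
exposure$\to$mediator effect, $\beta_2$ for mediator$\to$outcome and
$\beta_0$ for the total exposure$\to$outcome effect, the indirect effect is
the product $\beta_1\beta_2$, the direct effect is
$\beta_0 - \beta_1\beta_2$, and the mediated proportion is
$\beta_1\beta_2/\beta_0$. All outcome-scale effects are log odds ratios; odds
ratios appear only in reporting columns.

## Instrument processing

**Harmonization.** Outcome effects are aligned to the exposure's effect
allele: identical allele pairs pass through, swapped pairs flip the sign of
the outcome beta and reflect its allele frequency, and strand-complement
codings are complemented first. Palindromic variants (A/T, G/C) are
unresolvable from alleles, so allele frequency decides: if both frequencies
are outside the ambiguous window around 0.5 (half-width
`palindromic_eaf_window`, default 0.08, the de-facto standard of
summary-data MR tooling) the variant is kept or sign-flipped according to
whether the frequencies fall on the same side; otherwise it is dropped. A
missing frequency on a palindromic variant also drops it — the conservative
choice, since strand cannot be resolved. This rule makes every downstream
estimate invariant to how either study coded its alleles, a property the
test suite asserts.

**Selection.** Instruments must satisfy association $p <$ `pval_max`
(default $5\times10^{-8}$), minor allele frequency $>$ `maf_min` (default
0.01), and a single-variant F statistic $\ge$ `f_min` (default 20), with
$R^2 = 2\,\mathrm{MAF}(1-\mathrm{MAF})\beta^2$ and
$F = R^2(N-2)/(1-R^2)$. MAF is computed as $\min(\mathrm{eaf}, 1-\mathrm{eaf})$
because input tables carry effect-allele frequency. When a gene region is
supplied, positions must lie within `cis_kb` (default 1,000 kb, inclusive at
the boundary) of the gene's span.

**Clumping.** Greedy: repeatedly keep the remaining variant with the smallest
p-value and discard every variant within `clump_kb` (default 10,000 kb) whose
squared LD correlation with it is at least `clump_r2` (default 0.1). Ties on
p-value are broken by larger F, then lexicographic variant id, so results are
reproducible bit-for-bit. The LD r² here is a correlation between genotypes,
distinct from the instrument-strength R² above.

**Genomic control.** For mediator GWAS assembled from heterogeneous batches,
`genomic_control_adjust()` computes $\lambda_{GC}$ as the median association
$\chi^2$ over 0.4549 (the $\chi^2_1$ median) and, when $\lambda_{GC} > 1$,
inflates all standard errors by $\sqrt{\lambda_{GC}}$ and recomputes
p-values. $\lambda_{GC} \le 1$ leaves the set untouched: genomic control
corrects inflation, never deflates. It is applied per trait set; nothing in
the interface couples traits.

## Estimators

With ratios $r_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ and weights
$w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$ (first-order standard errors, the
dominant convention):

* **IVW** is $\sum w_j r_j / \sum w_j$, identical to weighted least squares
  of outcome on exposure effects through the origin. The default
  *multiplicative random-effects* model scales the fixed-effect SE by
  $\sqrt{\max(1, Q/(k-1))}$: heterogeneity can widen but never narrow the
  interval. The fixed model is a flag; it is also the exactly-calibrated
  version used in the null-calibration benchmark, because the
  random-effects floor makes the default deliberately conservative under
  homogeneity.
* **Wald ratio** handles single-instrument exposures; `mr_ivw()` falls back
  to it automatically, which is also the primary-method policy of the
  screening and mediation drivers (IVW for $k \ge 2$, Wald ratio for
  $k = 1$).
* **MR-Egger** fits $\hat\beta_{Yj} = a + b\,\hat\beta_{Xj}$ by weighted
  least squares ($1/\sigma_{Yj}^2$) after orienting all exposure effects
  non-negative. Standard errors are scaled by $\sqrt{\max(1, RSS/(k-2))}$
  and inference uses t with $k-2$ df. The intercept $a$ estimates average
  directional pleiotropy. A design with no variation in exposure effects is
  rejected as rank-deficient rather than silently returning an unstable fit.
* **Weighted median**: the interpolated weighted 50th percentile of the
  ordered ratios with midpoint convention $s^*_j = s_j - w_j/2$; consistent
  while valid instruments carry over half the weight. Its SE comes from a
  seeded parametric bootstrap (default 5,000 draws) that redraws both
  exposure and outcome effects from their sampling distributions.
* **Mode estimators**: the argmax, on a 512-point grid spanning the ratio
  range, of a normal-kernel density with modified Silverman bandwidth
  $0.9\min(\mathrm{sd}, \mathrm{IQR}/1.349)k^{-1/5}$ times
  `bandwidth_factor` (default 1, exposed because the bandwidth is the one
  genuinely arbitrary constant here). Uniform kernel weights give the simple
  mode, inverse-variance weights the weighted mode. All ratios identical is
  a zero-bandwidth degenerate case and returns the common ratio. SEs are
  bootstrap, as above.

## Sensitivity suite

Cochran's Q (against the fixed-effect IVW slope, $\chi^2_{k-1}$), the Egger
intercept test, leave-one-out IVW, and the Steiger directionality test
(instrument $R^2$ summed per trait, correlations compared through Fisher's z
at the two studies' sample sizes; on a binary outcome the outcome-side $R^2$
is a log-odds-scale approximation and is flagged as such).

**MR-PRESSO.** The observed statistic is the weighted residual sum
$\sum_j (\hat\beta_{Yj} - \hat b_{(-j)}\hat\beta_{Xj})^2/\sigma_{Yj}^2$ with
leave-one-out IVW slopes $\hat b_{(-j)}$. Its null distribution is simulated
(`n_sim`, default 1,000 — a desk-scale default; reference implementations
default larger) by redrawing effects around the leave-one-out fit, with
add-one smoothing $(1 + \#\{RSS^* \ge RSS\})/(n_{sim}+1)$ so p-values are
never zero. Per-variant outlier p-values compare each observed residual
contribution to its simulated distribution, Bonferroni-corrected at
$\alpha/k$. When outliers are flagged, the corrected IVW estimate on the
pruned set is reported, with a distortion p-value obtained by comparing the
observed estimate shift against shifts from removing random subsets of the
same size — a pragmatic null for "how much would dropping any such subset
move the estimate".

**Power.** `mr_power()` implements the standard normal approximation for a
binary outcome,
$\Phi(|\log OR|\sqrt{n\,R^2\,cf(1-cf)} - z_{1-\alpha/2})$. At $OR = 1$ it
returns $\alpha/2$ — the one-tailed margin of the two-sided test — which is
the formula's lower bound and is documented rather than patched.

## Mediation

The three legs are estimated by the primary-method policy; the indirect
effect uses the Sobel/delta SE
$\sqrt{\beta_2^2 SE_1^2 + \beta_1^2 SE_2^2}$ and a two-sided normal test.

Two design choices deserve emphasis:

* **The proportion CI treats the total effect as fixed**:
  $SE_{prop} = |SE_{ind}/\beta_0|$, giving a symmetric Wald interval. This is
  the rule consistent with reporting a proportion, its z statistic and its
  CI as a single internally-coherent triple (the interval is then
  estimate $\pm\ 1.96\cdot$estimate$/z$). The full two-term delta method,
  which adds $\beta_0$'s own uncertainty, is available via
  `method = "delta2"` and is always wider. Proportions outside $[0,1]$
  (sign-discordant paths, or an indirect effect exceeding the total) are
  reported verbatim with an `inconsistent_mediation` flag — never truncated.
* **Step 2 excludes the exposure's instruments by default.** A variant that
  acts on the mediator *through the exposure* affects the outcome through
  both the mediator and the exposure's direct path, so its
  mediator$\to$outcome ratio estimates $\beta_0/\beta_1$, not $\beta_2$,
  whenever a direct effect exists. Restricting the mediator leg to the
  mediator's own instruments (those not genome-wide significant for the
  exposure) removes this contamination; the option
  `exclude_exposure_instruments = FALSE` restores the naive behaviour.

Screens across many exposures report the primary estimate per exposure with
Benjamini–Hochberg q-values (via `stats::p.adjust`) computed over the
scanned family; exposures with no selectable instruments are kept as NA rows
with a reason, so the family size is the scan as designed. The mediation
driver gates entry on raw $p < 0.05$ for both the exposure and the mediator
against the outcome; FDR flags are reported alongside but do not gate.

## The synthetic generator

`simulate_triple()` draws GWAS summary statistics directly — no
individual-level genotypes — which is sufficient for every estimator under
test and keeps a full replicate in the low milliseconds. Per-variant true
effects follow the path diagram exactly: exposure effects $\gamma_j$,
mediator effects $\gamma_j\beta_1 + \pi^{med}_j$, outcome effects
$\gamma_j(\delta + \beta_1\beta_2) + \pi^{med}_j\beta_2 + \pi^{out}_j$, so
the implied total effect obeys $\beta_0 = \delta + \beta_1\beta_2$ by
construction. Observed effects are $N(\text{true}, se^2)$ with
$se = 1/\sqrt{n_{eff}\cdot 2\,\mathrm{maf}(1-\mathrm{maf})}$ and
$n_{eff} = n\cdot cf(1-cf)$ for the binary outcome (the logistic-score
approximation, which reproduces the very large standard errors of a heavily
imbalanced biobank phenotype).

Default sample sizes mirror the emulated study regimes: exposure
$n = 31{,}684$ (blood cis-eQTL scale), mediator $n = 291$ (CSF metabolite
scale), outcome $n = 431{,}880$ with case fraction $1{,}083/446{,}911
\approx 0.0024$. Both published case/control tallies for the outcome are
shipped as `finngen_presets` (`abstract` and `table1`); the default follows
the former, and no adjudication between them is attempted. A
`strong_fraction` (default 0.5) of variants get exposure effects scaled to a
z-score drawn from `strong_z` (default 8–16), guaranteeing
genome-wide-significant instruments; `strong_sign = "positive"` fixes their
orientation, which matters only when planting directional pleiotropy
(directional pleiotropy is defined relative to instrument orientation —
with random signs it averages out after Egger's re-orientation).
`med_instrument_fraction` designates disjoint variants as mediator-specific
instruments via the $\pi^{med}$ slot: without them the mediator would have
no instruments of its own and step 2 of any mediation analysis would be
impossible, which is not how multi-GWAS mediation designs work in practice.
Pleiotropy plants $\pi^{out} \sim N(\mu, sd^2)$ on
`round(invalid_fraction * n_variants)` randomly chosen variants (balanced:
$\mu = 0$; directional: $\mu \ne 0$).

LD enters as an AR(1) correlation matrix ($r = \rho^{|i-j|}$, positive
definite for $\rho < 1$) used by clumping; observed effect noise is drawn
independently per variant, a documented simplification — the generator
emulates the *marginal* sampling behaviour of summary statistics, not the
joint correlation of neighbouring test statistics. Consequences: passing
tests demonstrate estimator correctness under independent instruments and
the configured pleiotropy patterns; they say nothing about fine-mapping
resolution, sample overlap between studies, winner's-curse bias at marginal
instruments, or real metabolite correlation structure, none of which the
generator attempts to model.

## Benchmarks and problem sizes

The `benchmark_*()` functions are the package's standing validation
experiments; one master seed fans out deterministically to per-replicate
seeds. Sizes were chosen as the smallest that make the Monte-Carlo error
comfortably smaller than the tolerance being asserted:

* **Null calibration** — 1,000 replicates of the default (null) regime at 30
  variants; fixed-effect IVW, whose z statistic is exactly standard normal
  under this null, so the rejection rate estimates 5% up to binomial noise
  ($\pm 0.7$% SE).
* **Mediation recovery** — 200 replicates of a strong-instrument regime
  (instrument z 20–40, mediator $n = 31{,}684$, balanced outcome): replicate
  noise in the proportion is then ~0.03 SD, so the replicate mean isolates
  estimator bias rather than ratio-of-noisy-means artefacts. The default
  (paper-regime) mediator sample of 291 is far too small to instrument a
  mediator at genome-wide significance — in the emulated design the
  mediator GWAS brings its own established instruments, which is what the
  strong regime represents.
* **Egger pleiotropy recovery** — 100 replicates, directional pleiotropy
  mean 0.02 on all instruments; the intercept's replicate mean is compared
  within twice its Monte-Carlo SE, and the induced IVW bias is checked for
  sign.
* **Weighted-median robustness** — 100 replicates with pleiotropy mean 0.12
  on 40% of instruments, sized so the IVW bias clearly exceeds 0.1 while
  the majority-valid weighted median stays within 0.05 of truth.
* **MR-PRESSO detection** — 100 replicates of a 10-instrument design with
  one outcome effect inflated by 10 SEs (detected essentially always) and
  matched clean replicates for the per-variant false-flag rate.

## Numerical choices and degenerate inputs

Simulated p-values are floored at $10^{-300}$ to respect the $(0,1]$
contract under extreme z-scores. Bootstrap SEs of exactly zero (all
resampled estimates identical) are replaced by machine epsilon so the
estimate record's interval invariants hold. All RNG consumption goes through
a save/restore wrapper, so library calls never perturb a caller's RNG
stream. File round-trips serialize numerics at 15 significant digits and
missing values as `NA`. Empty instrument selections warn and return an empty
set (screens turn them into NA rows); an empty variant intersection at
harmonization, by contrast, is an error, because nothing downstream is
defined.

## Known limitations

Summary-level only (no Baron–Kenny regressions on individual-level data); a
single mediator at a time, with no joint multi-mediator decomposition; no
multivariable MR or colocalization; no GWAS-VCF input, LD-score regression,
or coordinate liftover; LD matrices are inputs, never estimated from
genotype panels. The Steiger test and the power calculation both rely on
log-odds-scale approximations for binary outcomes and should be read as
directional guidance rather than exact inference.
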