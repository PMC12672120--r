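# mrmediate

Two-sample Mendelian randomization (MR) with two-step mediation analysis for
GWAS summary statistics.

The package is built for a common epidemiological question: does an exposure
with genetic instruments (for example the expression of a druggable gene,
instrumented by cis-eQTLs) causally affect a binary disease outcome, and how
much of that effect runs through an intermediate trait such as a metabolite?
It implements the whole summary-level workflow — instrument quality control,
allele harmonization, six causal-effect estimators, a full sensitivity suite,
FDR screening across many exposures, and product-of-coefficients mediation —
together with a seeded synthetic GWAS generator with known causal truth, so
every estimator can be validated against simulation before it touches real
data.

## The model

For instrument *j* with effect β̂<sub>Xj</sub> (SE σ<sub>Xj</sub>) on the
exposure and β̂<sub>Yj</sub> (SE σ<sub>Yj</sub>) on the outcome, the Wald
ratio is β̂<sub>Yj</sub>/β̂<sub>Xj</sub>. The primary estimator is the
inverse-variance-weighted (IVW) mean of the ratios with weights
w<sub>j</sub> = β̂<sub>Xj</sub>²/σ<sub>Yj</sub>², equivalent to weighted least
squares through the origin; by default its standard error is inflated by
√max(1, Q/(k−1)) (multiplicative random effects), where Q is Cochran's
heterogeneity statistic. MR-Egger adds a free intercept estimating average
directional pleiotropy; the weighted median and the simple/weighted mode
estimators are robust to invalid instruments; MR-PRESSO detects and removes
pleiotropic outliers by a simulated residual-sum test; the Steiger test
checks causal direction by comparing the variance explained in the two
traits.

Instruments must pass p < 5×10⁻⁸, minor allele frequency > 0.01, single-
variant F = R²(N−2)/(1−R²) ≥ 20 with R² = 2·MAF·(1−MAF)·β², an optional
±1,000 kb cis window around the gene, and greedy LD clumping (r² < 0.1
within 10,000 kb).

For mediation, three MR legs give β₁ (exposure→mediator), β₂
(mediator→outcome) and β₀ (total exposure→outcome). The indirect effect is
β₁β₂ with Sobel standard error √(β₂²SE₁² + β₁²SE₂²), and the mediated
proportion is β₁β₂/β₀ with a symmetric Wald interval.

## Worked example

Simulate a gene → metabolite → disease triple with a true mediated
proportion of 0.12/0.20 = 60%, then recover it:

```r
library(mrmediate)

cfg <- sim_config(
  n_variants = 30, beta1_true = 0.3, beta2_true = 0.4, direct_true = 0.08,
  strong_fraction = 0.5, med_instrument_fraction = 0.3,
  n_med = 31684, case_fraction = 0.5,
  strong_z = c(20, 40), med_strong_z = c(20, 40), seed = 42)
sim <- simulate_triple(cfg)

res <- run_mediation(sim$exposure, sim$mediator, sim$outcome,
                     ld = sim$ld, region = sim$region)
recovery_report(sim$truth, res)
#>    parameter true estimated        error
#> 1      beta1  0.3 0.2901193 -0.009880692
#> 2      beta2  0.4 0.4028189  0.002818935
#> 3      beta0  0.2 0.1915691 -0.008430946
#> 4 proportion  0.6 0.6100440  0.010043994
```

Each row compares the true path coefficient with its three-step MR estimate;
all four are recovered to within single-replicate sampling noise (averaged
over 200 replicates the proportion is unbiased to < 0.02; see the benchmarks
below).

All estimators and diagnostics on one harmonized pair:

```r
pair <- harmonize(sim$exposure, sim$outcome)
mr_all(pair, n_boot = 500, seed = 1)          # ivw, egger, median, modes
cochran_q(pair)                               # heterogeneity
mr_presso(pair, n_sim = 1000, seed = 1)       # outlier detection
```

Config-driven runs (`run_scan()`, `run_mediate()`, YAML configs, tidy TSV +
log outputs) cover multi-exposure scans; a thin command-line wrapper lives at
`inst/scripts/mrmediate.R`.

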