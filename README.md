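# acutetox

Tools for acute aquatic-toxicity assessment and water-quality-criteria (WQC)
groundwork: probit LC50 estimation from dose-mortality experiments,
screening of heterogeneous literature toxicity records, species mean acute
value (SMAV) aggregation, species sensitivity distribution (SSD) ranking
with HC5 estimation, and inter-chemical toxicity extrapolation models with
leave-one-out cross-validation and external validation. It is written for
ecotoxicologists and risk assessors who need the full path from raw
mortality counts (or an ECOTOX-style extract) to ranked sensitivities,
candidate test species, and cross-chemical predictions — reproducibly, with
every intermediate table on disk.

## The statistics in brief

**Probit LC50.** Mortality at concentration $c$ is modelled as
$\Phi(a(\log_{10} c - \log_{10}\mathrm{LC}_{50}))$, linearised as
$y = ax + b$ with $y = \Phi^{-1}(p) + 5$ (the classical probit) and
$x = \log_{10} c$. Then $\mathrm{LC}_p = 10^{(\Phi^{-1}(p)+5-b)/a}$, so the
LC50 solves $y = 5$. Fitting is empirical-probit least squares (default) or
binomial maximum likelihood; confidence intervals by the delta method on
$\log_{10}\mathrm{LC}_{50}$ or Fieller's theorem.

**SMAV and SSD.** A species' SMAV for a chemical is the geometric mean of
its acceptable acute values (LC50/EC50 at 48 h for daphnids/midges, 96 h
for fish, mollusks, shrimp, others). Species are ranked by SMAV and given
plotting positions $i/(N+1)$; a species below 15% cumulative probability is
a sensitive test-species candidate. HC5, the SSD's 5th percentile
$10^{\mu + \sigma\Phi^{-1}(0.05)}$ under a log-normal fit, is the basis of
WQC.

**Inter-chemical extrapolation.** For chemicals sharing ≥ 3 species,
$\log_{10}(\text{predicted}) = a\log_{10}(\text{surrogate}) + b$ by OLS;
models with slope p-value > 0.05 are removed, the rest are validated
internally by leave-one-out RMSEP (log10 units) and externally by relative
error and a 5-fold acceptability check.

A seeded synthetic-data generator draws species sensitivities from a
multivariate log10-normal with configurable inter-chemical correlation and
dose-mortality data from the exact binomial-probit mechanism, so every
stage is testable end to end without any download.

## Worked example

```r
library(acutetox)

# --- probit LC50 from a dose-mortality table (10 fish per dose) ---
doses <- dose_groups(c(100, 160, 250, 400, 630), 10, c(1, 2, 5, 8, 10))
fit <- fit_probit(doses, method = "empirical-ols")
fit
#> Probit dose-mortality fit (empirical-ols)
#>   y = 3.6031 * log10(conc) + -3.6113   (probit + 5 scale)
#>   R-squared: 0.9805
#>   dose groups used: 4
#>   LC50: 245.4 ug/L
lc50_ci(fit, 0.95)
#>    lower    upper
#> 220.2451 273.5224
```

The fitted line says mortality climbs 3.6 probit units per tenfold
concentration increase; solving it at probit 5 gives the LC50, 245 µg/L,
with a 95% delta-method interval of 220–274 µg/L. (The 100%-mortality group
has no empirical probit and is dropped, hence 4 groups used.)

```r
# --- full pipeline on a synthetic ECOTOX-style extract ---
cfg <- synthetic_config(seed = 33, n_species = 30, rho = 0.9)
paths <- make_fixture_bundle(cfg, "fixtures")
res <- run_pipeline(paths[["records"]], observed = paths[["observed"]],
                    out_dir = "out")
#> screen: 120 records in, 120 kept, 0 rejected
#> smav: 120 species-chemical entries (4 chemicals)
#> ssd: ranked 4 chemical(s), subset = all
#> ice-fit: 12 models fitted, 12 retained at alpha = 0.05
#> ice-validate: 12 predictions, 12 within 5-fold

head(rank_and_probability(res$smavs, chemical = "Zn"), 3)
#>   chemical species  smav  rank cumulative_probability
#> 1 Zn       S0028    7.26     1                 0.0323
#> 2 Zn       S0013   18.5      2                 0.0645
#> 3 Zn       S0003   40.8      3                 0.0968
```

The three most Zn-sensitive of the 30 simulated species sit at cumulative
probabilities 3.2–9.7% — all below the 15% screen
(`is_sensitive_candidate()`), so they would be recommended as test species.
With the strong simulated inter-chemical correlation (ρ = 0.9) all 12
directed pair models are significant and every external prediction lands
within 5-fold of the observed value, e.g.:

```r
head(res$validation[, c(1, 3:6)], 3)
#>   surrogate_chemical predicted_chemical observed predicted relative_error
#> 1 Cd                 Cu                     158.      153.         0.0374
#> 2 Cd                 Pb                     631.      522.         0.172
#> 3 Cd                 Zn                     316.      284.         0.101
```

A thin command-line wrapper over the same functions is at
`inst/scripts/toxpipe.R` (subcommands `fit-lc50`, `screen`, `smav`, `ssd`,
`ice-fit`, `ice-validate`, `simulate`, `run-all`).

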