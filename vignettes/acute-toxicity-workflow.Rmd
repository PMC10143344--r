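---
title: "Acute toxicity assessment: probit LC50, species sensitivity distributions and inter-chemical extrapolation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acute toxicity assessment: probit LC50, species sensitivity distributions and inter-chemical extrapolation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acutetox)
```

`acutetox` implements the statistical workflow behind acute aquatic-toxicity
assessment of chemicals (typically heavy metals) and the derivation of
candidate test species for water quality criteria (WQC): probit LC50
estimation from dose-mortality experiments, screening and aggregation of
heterogeneous literature toxicity records into species mean acute values
(SMAVs), species sensitivity distribution (SSD) ranking with HC5 estimation,
and inter-chemical correlation models that extrapolate one chemical's
toxicity from another's. This vignette explains the models, their
assumptions, the parameters that matter, and the design decisions taken
where the methodology was genuinely open.

## The probit dose-mortality model

An acute test exposes groups of organisms (classically ten fish per
concentration) to a geometric series of concentrations for a fixed duration
and records deaths. The probit model assumes individual log10 tolerances are
normally distributed, so the mortality proportion at concentration $c$ is

$$\Pr(\text{death}) = \Phi\!\big(a\,(\log_{10} c - \log_{10} \mathrm{LC}_{50})\big),$$

which linearises as $y = a\,x + b$ with $x = \log_{10} c$ and $y$ the
*probit* of mortality, $\Phi^{-1}(p) + 5$. We keep the classical +5 offset:
published fitted equations are reported on that scale, and on it the LC50 is
read off by solving $y = 5$:

$$\mathrm{LC}_p = 10^{(\Phi^{-1}(p) + 5 - b)/a}.$$

Two fitting routes are offered:

* **`empirical-ols`** (default): ordinary least squares of the empirical
  probits on $\log_{10}$ concentration. This is the classical hand-computed
  workflow and the one that yields a fitted line with an $R^2$, which is how
  such fits are conventionally reported. Groups with 0% or 100% mortality
  have no empirical probit; the default policy `"drop"` removes them
  (classical practice), while `"correct"` keeps them with the shrunken
  proportion $(r + 0.5)/(n + 1)$.
* **`mle`**: the binomial likelihood under a probit link, fitted by
  iteratively reweighted least squares (`stats::glm`). It uses every group,
  weights them properly, and is the better-calibrated choice for simulation
  work; $R^2$ is reported as unavailable because the model is not a
  least-squares line.

All logarithms are base 10 throughout: published fitted equations only
reproduce their printed LC50s under base-10 logs, and SSD practice works in
log10 concentration units.

Confidence intervals for the LC50 use the delta method on
$\log_{10}\mathrm{LC}_{50} = (5 - b)/a$ by default, with Fieller's theorem
as an option. Fieller does not assume the ratio is approximately normal and
returns an unbounded set (reported as an open interval with a warning) when
the slope is poorly determined. In repeated sampling at realistic designs
the MLE-based delta interval attains close to its nominal 95% coverage; the
empirical-probit version undercovers slightly because unweighted OLS
ignores the binomial variance structure — one reason `mle` is preferred for
parameter-recovery studies.

## Screening records and species mean acute values

Literature and database extracts mix endpoints, durations and taxa. The
machine-checkable screening rule keeps acute endpoints only — LC50 or EC50 —
at the taxon-appropriate duration: 48 h for daphnids and midges, 96 h for
fish, mollusks, shrimp and other aquatic animals. Everything else is
rejected with a machine-readable reason code, and the kept and rejected
sets always partition the input. Judgment-based exclusions (unsuitable
dilution water, insensitive life stages, unscientific designs) cannot be
automated; an optional logical `prescreened_ok` column carries such expert
decisions into the same partition. Duration matching is exact by default
(the rules state fixed durations) with a configurable tolerance.

Each species' acceptable values for a chemical are aggregated into the SMAV
as their geometric mean, $10^{\overline{\log_{10} v}}$ — the standard
species-level summary, invariant to record order and equivariant under
rescaling. Species names are matched on a normalized form (trimmed,
whitespace-collapsed, case-folded); no taxonomic name resolution is
attempted.

## SSD ranking, sensitive species and HC5

For one chemical, species are ranked by SMAV from most to least sensitive
and assigned the plotting position

$$P_i = \frac{i}{N + 1},$$

so a species ranked 6th of 64 sits at $6/65 = 9.23\%$. Ties in SMAV are
broken lexicographically by species name: ranks stay deterministic integers,
matching the convention of published rank tables (no midranks). A species
whose cumulative probability falls strictly below 15% is flagged as a
sensitive test-species candidate — the conventional screening threshold for
recommending a species for WQC derivation. The `subset = "native"` option
re-runs the ranking on the native-flagged species only, reproducing the
two-track analysis (all freshwater species vs. native species).

HC5 — the concentration expected to leave 95% of species unaffected — is
computed from a log-normal SSD by default: $\mu$ and $\sigma$ are the mean
and sample standard deviation ($n - 1$ denominator) of the log10 SMAVs and
$\mathrm{HC}_p = 10^{\mu + \sigma \Phi^{-1}(p)}$. The log-normal is the
conventional SSD family and closes the loop with the synthetic-data
generator, which draws species sensitivities from exactly that family. An
empirical alternative — linear interpolation of log10 SMAV against the
plotting positions, flat beyond the observed range — is available for
distribution-free checks; at small $N$ (below about 19 species) the
smallest plotting position exceeds 5%, so the empirical HC5 clamps to the
most sensitive species and should be read as a bound.

## Inter-chemical extrapolation models

When two chemicals share at least three species with SMAVs, their
sensitivities are related by the log-log regression

$$\log_{10}(\text{predicted toxicity}) = a \cdot \log_{10}(\text{surrogate toxicity}) + b,$$

fitted by OLS across the shared species. The two directions of a chemical
pair are distinct models and both are fitted. Models are fitted on SMAVs,
not raw records — the species-level summary established by the screening
stage. The slope p-value (equal, for simple OLS, to the regression F-test,
an identity the test suite asserts to 1e-9) filters the models: only
`p_value > alpha` is removed, so a p-value exactly at the 0.05 boundary is
kept, matching the strict "greater than" convention of the filtering rule.

Internal validation is leave-one-out cross-validation: each pair is held
out in turn, the model refitted, and the held-out log10 value predicted;
RMSEP is the root mean square of those errors, **in log10 concentration
units** — the model's fitting scale, and the only scale on which typical
published RMSEP magnitudes (order 0.7–1) are plausible. External validation
predicts a held-out species' toxicity from its measured surrogate value and
reports the relative error $|{\hat y} - y|/y$ plus a $k$-fold acceptability
check (default 5-fold, about the inter-laboratory spread of acute values
for a single species and chemical). Relative errors are kept unrounded
internally and rounded to whole percent only for display.

## The synthetic-data generator

No public accession provides the assembled toxicity dataset such analyses
are run on, so the package generates data with the statistical structure
the analysis assumes and treats parameter recovery as the test of
correctness.

* **Species sensitivities**: each species' log10 sensitivities across $k$
  chemicals are multivariate normal with per-chemical means `mu`, standard
  deviations `sigma`, and a single exchangeable pairwise correlation `rho`
  (a full correlation matrix was considered and rejected as needless
  complexity for the tests; `rho` must satisfy $\rho \ge -1/(k-1)$ for
  positive semi-definiteness). Records are emitted in the conformant
  acute format (fish, LC50, 96 h) so the screening stage passes them
  through untouched, which is what the round-trip tests require.
* **Dose-mortality data**: deaths at concentration $c$ are binomial with
  probability $\Phi(a\,(\log_{10} c - \log_{10}\mathrm{LC}_{50}))$ — the
  exact mechanism the probit fit assumes.
* **Defaults** (chosen once as a realistic acute heavy-metal study, and not
  revisited): four metals; `mu = c(2.2, 2.5, 2.8, 2.7)` log10 µg/L, centring
  the SSDs in the hundreds of µg/L where acute fish LC50s for these metals
  sit; `sigma = 0.8` log10 units, since SSDs typically span two to three
  orders of magnitude; `rho = 0.8`, the strong inter-metal correlation that
  makes extrapolation models worth fitting; the dose design
  100/160/250/400/630 µg/L (a geometric factor-1.6 series) with 10 organisms
  per dose, the classical acute design; `true_lc50 = 250` µg/L (centre of
  the design) and `true_slope = 3` probit units per log10 µg/L, typical of
  published fitted equations; `native_fraction = 0.3`.
* Seeds are mandatory; every draw flows from the config seed, and the same
  config reproduces byte-identical fixture files.

What the generator does *not* emulate: taxonomic structure in the
correlations, water-chemistry covariates of bioavailability (hardness, pH,
DOC), censored or interval endpoints, and the heavy-tailed measurement
error of real inter-laboratory data. Passing recovery tests therefore show
the estimators are correct under the model's own assumptions — not that the
model is adequate for any particular field dataset.

## Numerical choices and degenerate inputs

* Ties in SMAV ranking: lexicographic by normalized species name.
* Identical SMAVs everywhere: the SSD fit warns and returns $\sigma = 0$;
  HC$_p$ collapses to the common value.
* All concentrations identical, or fewer than two usable groups after
  extreme-mortality adjustment: an error, not a silent fit.
* Mortality strictly decreasing with dose: a warning (the fit proceeds and
  reports a negative slope; LC$_p$ machinery refuses only slope 0).
* Leave-one-out refits that become singular are skipped with a warning and
  reported as a count rather than poisoning the RMSEP.
* Problem sizes in the test suite (e.g. 200 replicates per group size for
  probit recovery, 100 replicates per correlation setting for end-to-end
  retention, 1000 species for HC5 calibration) were chosen so each
  stochastic check has comfortable binomial margin around its asserted
  bound while the whole suite stays quick to run.

## A worked run

```{r, eval = FALSE}
cfg <- synthetic_config(seed = 33, n_species = 30, rho = 0.9)
paths <- make_fixture_bundle(cfg, "fixtures")
res <- run_pipeline(paths[["records"]], observed = paths[["observed"]],
                    out_dir = "out")
res$models_retained
rank_and_probability(res$smavs, chemical = "Zn")
```

The pipeline logs stage counts (records in = kept + rejected, species,
models fitted and retained) to `message()` and writes every intermediate
table as CSV, so a run is fully inspectable and, with fixed inputs,
byte-reproducible. A thin command-line wrapper over these functions ships
in `inst/scripts/toxpipe.R` with subcommands `fit-lc50`, `screen`, `smav`,
`ssd`, `ice-fit`, `ice-validate`, `simulate` and `run-all`.

## Known limitations

* Only the duration/endpoint screening rules are automated; the expert
  judgment embedded in real data curation must arrive via `prescreened_ok`.
* No unit conversion: values are µg/L throughout.
* No water-chemistry normalisation (hardness, pH, biotic ligand models),
  no chronic endpoints, no time-to-event modelling of intermediate
  observation times, and no multi-predictor extrapolation models.
* Published R² values and asymmetric confidence intervals for specific
  fitted equations cannot be reproduced without the underlying raw
  mortality counts; the package validates its interval and fit machinery by
  simulation instead.
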