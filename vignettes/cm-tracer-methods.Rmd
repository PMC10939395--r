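---
title: "Inferring actively grazing constitutive mixotrophs from labeled-prey amplicon experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring actively grazing constitutive mixotrophs from labeled-prey amplicon experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmtracer)
library(dplyr)
```

## The measurement problem

Constitutive mixotrophs (CMs) are plankton that maintain their own
chloroplasts *and* ingest prey. Standard field methods mis-state their
abundance in opposite directions: short fluorescently-labeled-prey
incubations under-count grazers, while taxonomy-based reclassification of
microscopy datasets counts every *capable* mixotroph as if it were
grazing, an over-count. The ±BrdU labeled-prey design sits in between. A
water sample is incubated in triplicate with bacterial prey grown on
bromodeoxyuridine (+BrdU) or without it (−BrdU). A grazer that ingests
and digests labeled prey incorporates BrdU into its DNA during
replication; immunoprecipitation then enriches grazer DNA in the +BrdU
libraries only. Comparing 18S V4 amplicon composition between the two
treatments identifies the ASVs that were eating bacteria during the
incubation, and the chloroplast-bearing subset of those are the actively
grazing CMs.

`cmtracer` implements the computational half of this design: the
classification screen, the genus-level bridge to microscopy counts, the
potential-versus-active abundance bookkeeping, and the quasi-likelihood
environmental regressions — plus a synthetic-data generator with known
ground truth so that every stage is testable without field data.

## The classification screen

For one experiment (one station and date), with triplicate samples per
treatment:

1. **Filtering.** ASVs assigned to bacteria, metazoans, fungi or
   macroalgae are removed, as are singletons. Group membership comes from
   an editable keyword table (`default_lineage_keywords()`) matched
   case-insensitively against every rank of the Silva-style lineage; the
   groups are standard but any keyword list is a curatorial choice, so
   the table is data, not code. "Singleton" is ambiguous in common usage;
   the default reads it as *total read count across the experiment equals
   1* (`singleton_rule = "total_one"`), with *present in exactly one
   sample* selectable.
2. **Normalization.** Each sample is converted to percentages of its
   total tags. This happens *after* filtering (the screen operates on the
   analyzed dataset); `normalize_before_filter = TRUE` provides the other
   reading for sensitivity analysis. Per-sample sums are checked to 100
   within 1e-9 relative tolerance.
3. **Averaging and subtraction.** Replicate percentages are averaged per
   treatment over the union ASV universe (absent = 0%), then
   `diff_pct = mean_plus − mean_minus` in percentage points. Averaging
   percentages per replicate (rather than pooling counts) weights
   replicates equally regardless of depth; `pool_replicates = TRUE`
   offers the pooled alternative.
4. **Calling.** An ASV is a bacterivore iff `diff_pct > 0` **and**
   `diff_pct > bacterivore_min_diff_pct`; both inequalities are strict,
   so 0 and the threshold itself are rejected. The threshold (default
   0.1) is interpreted in percentage points of total tags — the same
   units the subtraction is performed in; since other denominators could
   be read into "0.1% of the average total amplicon abundance", the value
   is configurable. A bacterivore with a plastid-bearing lineage is an
   active CM.

Two structural properties follow from the arithmetic and are enforced by
tests: the differences across a shared ASV universe sum to zero
(compositional mass conservation), and raising the threshold can only
shrink the bacterivore set.

The screen is deliberately conservative. It favours abundant amplicons,
damps replicate variability, and guards against nonspecific recovery of
very abundant DNA (diatoms, for instance, are plastid-bearing but not
grazing; a spurious +/− difference would elevate them). The cost is
insensitivity to rare grazers — a false-negative bias the tracer design
accepts.

## From ASVs to cells: genus matching

Amplicon taxonomy and microscopy taxonomy meet only at genus level.
`extract_genus()` normalizes both sides: it strips qualifier tokens
(`sp.`, `spp.`, `cf.`, `uncultured`, `marine`, `alveolate`,
`freshwater`, ...), takes the first remaining token, and refuses
supra-generic names by suffix (-phyceae, -ales, -phyta, ...), returning
`NA` for labels like "dinophyceae uncultured eukaryote". Matching is
case-insensitive on the normalized genus. Microscopy labels are not
otherwise standardized: rather than guessing a normalization used by any
particular lab, the qualifier and suffix lists are package constants a
user can inspect, and unresolvable microscopy taxa simply never match
(they still count in the phototroph total).

For station *s* and date *t*, the **active** genus set `A(s, t)` contains
the genera of that experiment's CM ASVs; the **potential** set
`P(s) = ∪_t A(s, t)` is its union over all dates at that station — a
genus ever seen grazing there is potentially grazing always. Activity is
strictly per-station: a genus grazing at one station on a date does not
make it active at the other station that day, because the matching rule
is defined per sampling date at each station. Abundances sum
`cells ml⁻¹` of plastid-bearing microscopy taxa whose genus is in the
respective set; proportions divide by the total phototroph abundance.
Subset ordering (`0 ≤ active ≤ potential ≤ total`) is then a theorem,
and the potential−active gap measures how much a capacity-based census
would overstate grazing.

Experiments and microscopy join on exact (station, date) — both come from
the same water collection, so there is no temporal interpolation. Since
the quantitative anchor is light microscopy, estimates represent CM taxa
large enough to identify microscopically (roughly >10–15 µm); smaller
grazers are visible to the amplicon side only and are deliberately not
converted to abundances.

## Environmental regressions

The response data are counts made under variable effort: the number of
cells identified on however many Sedgewick-rafter grids were scanned to
reach ~300 cells. The natural model is a log-link GLM with
`offset = log(grids_counted)` and a variance inflated beyond Poisson, so
the abundance model is **quasipoisson** (variance φµ) on counted
active-CM cells, and the proportion model is **quasibinomial** (variance
φµ(1−µ), logit link) on the active fraction of phototrophs. An offset is
accepted on the proportion model too, though offsets are unconventional
for binomial links; the shipped pipeline uses it only for abundance.
Fitting is IRLS via `stats::glm()` (tolerance 1e-10, up to 100
iterations; non-convergence is flagged, never silent), dispersion is the
Pearson estimate `φ = Σr²_P/(n−p)`, and Wald inference uses a t(n−p)
reference (configurable to normal). Replicate counts are kept as separate
rows and any row with a missing covariate is dropped and counted.

Before fitting, covariates are pruned by iterated **variance inflation
factor**: `VIF_j = 1/(1−R²_j)` from the OLS of covariate *j* on the rest
(with intercept, on the raw unstandardized design), removing the largest
`VIF ≥ 5` and recomputing until all are below 5. Ties break by column
order, which makes the procedure deterministic and
permutation-predictable; exactly collinear columns report `Inf` rather
than erroring. The VIF is computed in-package so that degenerate designs
are handled as values, with `car::vif` serving as an independent
cross-check in the test suite.

The signal screen then reports, for every retained covariate with
two-sided `p < 0.5`, only the sign of its coefficient. A 0.5 threshold is
far weaker than conventional significance — it flags "any hint of
direction", not evidence — and the package implements it verbatim with
the threshold exposed (`signal_alpha`) rather than endorsing it. A blank
in the resulting sign matrix conflates "no signal" with "removed for
collinearity", which is a genuine ambiguity of the convention; the
underlying fits and the VIF report are returned so users can tell the
two apart. Station-level covariate contrasts use paired two-tailed
t-tests (α = 0.05), with zero-variance difference vectors reported as
degenerate limits instead of errors.

## The synthetic-data generator

The generators produce data with the statistical structure the analysis
assumes, under the conditions of the two-station, year-long study design
the pipeline targets — not a simulation of any particular estuary.

**±BrdU experiments** (`simulate_brdu_experiment()`). A baseline
composition is drawn from a symmetric Dirichlet (concentration 0.5 over
1 000 ASVs: a realistic long-tailed amplicon rank-abundance curve). A
planted minority of plastid-bearing ASVs is pinned to a fixed baseline
(0.75% each) and multiplied by an enrichment factor (2) in the +BrdU
composition, which is then renormalized — enrichment acts on
*proportions*, as it must for compositional data, which yields a closed
form for the expected difference used as the test oracle:
`E[diff] = 100·b(f/Z − 1)` with `Z = 1 + Σ_planted b(f−1)`. With the
defaults this is ≈0.55 pp per planted ASV, comfortably above the 0.1 pp
call threshold but small enough that the screen is actually exercised.
Replicate incubation variability is Dirichlet jitter with precision
5 000 — "moderate": at 1% abundance it adds per-replicate noise of about
0.12 pp, the same order as the multinomial noise at depth 50 000 —
followed by multinomial read sampling (depth 50 000, 3 replicates per
treatment). These values were fixed analytically from the
signal-to-noise budget above before any recovery test was run. The
generator does **not** simulate PCR bias, chimeras, ribosomal
copy-number variation or immunoprecipitation efficiency, so passing
recovery tests demonstrate the screen's arithmetic and thresholds, not
robustness to those artifacts.

**Microscopy** (`simulate_microscopy()`). Taxon concentrations are
log-normal (sdlog 0.4) around sinusoidal seasonal group profiles with
group-specific phases, over a community whose genera overlap the
amplicon genus pool and include deliberately unmatchable labels
("unidentified centric diatom") and non-plastid ciliates. Grids counted
are chosen so at least 300 cells are counted per sample at 1 µl per
grid, mirroring the counting-effort convention behind the offset.

**Environment** (`simulate_env_series()`). Covariates come from a
Gaussian copula with common correlation 0.3, mapped to realistic
estuarine means and spreads; effects β are expressed per covariate
standard deviation. Because quasi-likelihoods are not generative, counts
are drawn negative-binomial with `size = µ/(φ−1)` (variance exactly φµ)
and proportions beta-binomial with `ρ = (φ−1)/(m−1)` (variance matching
quasibinomial at the configured φ) — mechanisms that *match the quasi
variance functions* rather than claim to be the field's true noise
process.

**Full study** (`simulate_study()`). Two stations × 24 dates, one shared
ASV universe; each station draws its planted CM ASVs per date from a
station pool (40 candidates, half shared between stations) so the
unique/shared ASV partition is non-trivial. The complete ground truth —
planted sets per experiment, station pools, β, seed, all generator
parameters — is serialized to `truth.json` beside the generated inputs.
One emergent behaviour worth knowing: because the potential set is a
union over dates, occasional false-positive calls accumulate into it
over a 48-experiment study, so synthetic potential proportions saturate
higher than one would expect of field data with a richer genus pool.
That is a property of the small synthetic community, not of the
estimator.

## Numerical and degenerate-input choices

- Counts must be non-negative integers at read time; nothing is coerced.
- A sample with zero total reads is an error naming the sample (its
  percentages are undefined), while a fully filtered experiment returns
  an empty result (an empty study is a value, not a bug).
- A zero phototroph total makes proportions undefined: error.
- Exact collinearity: `VIF = Inf` (clamped when `1 − R² ≤ ε_machine`);
  rank-deficient GLM designs are refused naming the aliased column.
- Dates are ISO-8601 strings compared lexically; stations are opaque
  labels.
- Standard errors with one sampling date are `NA`, with the mean still
  reported.
- All generators take an integer seed and restore RNG state; identical
  seed and parameters give byte-identical outputs.

## Problem sizes in the shipped tests

The test suite validates the classifier on 100 seeded experiments at the
full study conditions (1 000 ASVs, depth 50 000), GLM recovery on 200
replicates of n = 200 with φ = 2 (mean coefficient bias below 0.05,
≥90% sign recovery), and null calibration of the 0.05-level screen over
500 runs at n = 57 — sizes chosen so the whole suite runs in about a
minute while keeping Monte-Carlo error well inside the asserted margins.
`scripts/acceptance.R` re-derives the same quantities from scratch at
run time.

## Limitations

The pipeline inherits the tracer design's scope: it detects constitutive
mixotrophs that ate *bacteria* during a 24-h incubation, not other
mixotroph types, other prey, or grazing rates; presence/absence of
labeled-prey ingestion is the only signal. Genus-level matching cannot
separate congeneric grazers from non-grazers in the microscopy counts,
and the abundance estimates only represent taxa identifiable by light
microscopy. The environmental stage is a screen, not a model selection:
no interactions, no temporal autocorrelation, no mixed effects.
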