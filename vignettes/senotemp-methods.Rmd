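---
title: "Methods: temporal senescence meta-analysis and the event-driven network model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal senescence meta-analysis and the event-driven network model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the methodological choices behind the two halves
of `senotemp`: the temporal meta-analysis of senescence-versus-control
transcriptomic comparisons, and the event-driven ordinary differential
equation (ODE) model of DNA-damage-induced (DDIS) and oncogene-induced
(OIS) senescence. It records what each method assumes, which constants
are external facts versus package choices, and where the limits are.

# Part I: the meta-analysis

## The database layer

The unit of analysis is a *comparison*: one senescent-versus-control
contrast from one study, annotated with inducer category, control type,
cell line, timepoint (value plus unit: days, population doublings, or
unknown) and intervention. A database is a triple of studies,
comparisons and per-comparison gene statistics (logFC, p), validated for
referential integrity, p in (0, 1], finite logFC and controlled
vocabularies. The packaged fixture `senomic_studies.csv` transcribes a
printed 119-study inventory of human fibroblast senescence
transcriptomics; its platform column is `"unknown"` throughout because
the printed table does not record platforms, and two entries outside the
controlled vocabularies (an unstated senescence type and an apoptosis
arm) were dropped from the typed columns during transcription.

Temporal binning follows the published scheme: non-replicative
comparisons with day-denominated times fall into 0–4, 5–7, 8–11, 12–14
and 15+ day bins; replicative (REP) comparisons split at 41+ days, with
population-doubling or unstated ages conservatively assigned to the
0–40 group (`REP0_40`), since a doubling count does not map to days.
Unknown times for non-REP inducers are `UNBINNED` and excluded from
binned statistics.

## The inverted-p statistic and median calls

Each (gene, comparison) pair is scored by the inverted p-value
`sign(logFC) / p`, which places significant up- and downregulation at
opposite ends of a single scale; a zero logFC has no direction and maps
to `NA`. Aggregation across comparisons of one inducer uses the
*median* inverted p, and a gene is called regulated when
`|median| >= 1 / alpha` (alpha = 0.05 by default). The median is the
right aggregator here because single extreme studies should not carry a
call; the cost is reduced power when fewer than three comparisons exist.

Before aggregation, gross per-study errors are removed by Tukey fences
computed per gene and time bin: values outside
`[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` (type-7 quartiles) are dropped in a
single pass. Groups smaller than four observations are left untouched —
quartiles of two or three points are not meaningful. A single pass is
deliberate: iterating the rule until fixpoint would progressively trim
genuine heavy tails.

## The core signature and recovery scoring

Genes called regulated in DDIS, OIS, REP and bystander (BYS) senescence
simultaneously form the four-way cell of an exact Venn partition; the
partition assigns every called gene to exactly one intersection cell
(the tests verify disjointness and exhaustiveness). Core genes carry a
direction, or `inducer_dependent` when the four calls disagree in sign.

Because the real study corpus cannot be shipped, performance is measured
on a seeded synthetic database with planted truth: core genes regulated
in all four inducers, inducer-specific genes, null genes and a small
marker panel with biologically motivated profiles (CDKN1A, CDKN2A,
MDM2, IL6, CXCL8, IL1B, HES1, HEY1). `score_recovery()` reports the
fraction of planted core genes recovered in the four-way cell
(sensitivity) and the fraction of planted null genes that leak into it
(false positive rate).

## What the generator emulates — and what it does not

`generate_database()` draws, per (study, gene), a study-level random
effect (`study_sd`, default 0.2) shared across that study's comparisons,
and per comparison a residual `N(0, 2 sigma^2 / n)` around the planted
mean, emulating a two-arm design with `n = 3` replicates per arm and
per-gene residual `sigma = 0.3`. The reported p-value simulates the
two-sample t-test the source study would have run: a pooled variance
estimate `s^2 ~ sigma^2 chi^2_df / df` is drawn and the two-sided tail
of `t = logFC / (s sqrt(2/n))` on `df = 2n - 2` degrees of freedom is
returned, so null-gene p-values are exactly uniform and p is coherent
with the logFC realisation. With probability `outlier_prob` (default
0.01) a gross shift of ±6 logFC units is added after p is computed,
emulating annotation or normalisation blunders.

The generator does **not** emulate: gene–gene correlation,
platform-specific mean–variance trends, missing genes per platform,
batch structure beyond the single study effect, or confounding between
time and study. Intervention comparisons (p53 or RelA inhibition) are
planted as multiplicative attenuation (default 0.2) of the relevant
marker means, one study per intervention comparison — intervention
studies in the wild are distinct experiments, and giving them a shared
study effect would fabricate within-group correlation.

These defaults are the study conditions for all reported operating
characteristics; they were fixed before measurement and are not tuned to
the outcomes.

## Rank tests and the clustering correction

Paired (signed-rank) and unpaired (rank-sum) tests are computed with
exact two-sided p-values for small samples *including ties*: the null
distribution of the statistic over tie-averaged ranks is built by
generating-function convolution over doubled ranks, which is equivalent
to full enumeration of sign assignments or group labellings (the test
suite checks this equivalence directly against brute-force
enumeration). Larger samples use the normal approximation with tie and
continuity corrections. No multiple-testing correction is applied
anywhere; stars map p to the conventional 0.05/0.01/0.001/0.0001
thresholds.

The inhibition contrast compares intervention-flagged comparisons of one
inducer (excluding REP, capped at day 27) against intervention-free
comparisons at days 1–11. Comparisons from one study share its random
effect, so treating them as independent inflates the type-I rate; the
contrast therefore aggregates to **one mean logFC per study per group**
before testing. This is the standard cluster-to-summary remedy and is
what keeps the measured type-I rate near its nominal level.

## Enrichment

`preranked_enrichment()` is a minimal weighted Kolmogorov–Smirnov
running-sum scorer (weight exponent 1): |ES| ≤ 1 by construction, the
null comes from gene-label permutation, NES normalises by the mean
|null ES| of the same sign, and the permutation p is computed among
same-sign null draws so it is approximately uniform for a random set.
It exists to rank recovered signatures against planted sets; it is not a
replacement for a full enrichment stack (no multi-set FDR, no
leading-edge extraction).

# Part II: the event-driven network model

## Structure and assumptions

The model tracks thirteen species — RAS, DDR, p53/pp53, p21, p16,
p38/pp38, NF-κB/pNF-κB, IL-6, NOTCH1 and NICD — in arbitrary
concentration and time units (AU). Design assumptions:

* **Activation is phosphorylation.** p53, p38 and NF-κB each exist in
  inactive/active pairs; activation is Michaelis–Menten in the inactive
  form and driven by the upstream signal (DDR for p53; RAS + a DDR
  contribution for p38; pp38 for NF-κB).
* **Repressions are divisive.** pp53 represses p38 synthesis and
  phosphorylation (`1/(1 + theta pp53)`, `1/(1 + phi pp53)`); NICD
  represses NF-κB activation (`1/(1 + psi NICD)`). Divisive terms keep
  rates positive at any state.
* **Everything degrades first-order**, so every isolated subsystem has
  a finite steady state.
* **Inputs are parameters, not species.** `RAS_input` and `DDR_input`
  with transfer rates `kRASF`, `kDDRF`, `kDDRFRAS` define the condition.

Events change parameters (set or scale) and/or scale state variables at
a fixed time, with the integration restarted at every event:
senescence induction at t = 40 AU, the Notch switch (a 20-fold step
reduction of the NOTCH1 cleavage rate, releasing NF-κB from NICD
repression) at t = 65 AU, and a horizon of 100 AU. Days post-induction
map to AU as `t = 40 + 5 * days`, so the switch sits at day 5 and the
horizon at day 12. Knockdowns are induction-time events scaling the
species level and its formation rate(s) by `kd_scale` (default 0.1) —
knockdown, not knockout.

The DDIS preset carries a small constitutive RAS input (0.5) and a
RAS-to-DDR coupling from t = 0, with the damage input
(`DDR_input = 5`, `kDDRF = 14`, `kRASF = 0.3`) applied at induction;
the OIS preset has no external damage input and applies
(`RAS_input = 5`, `kRASF = 1`, `kDDRFRAS = 5.75`) at induction, so its
DDR is entirely hyperproliferation-derived.

## The parameter file is the contract

`inst/extdata/reference_parameters.csv` holds the single calibrated
parameter set. It was calibrated once, by a scripted seeded search,
until all twelve phenotype criteria passed, and then frozen; the code
never adjusts it. Overrides go through
`build_reference_model(parameters = ...)`.

## The twelve phenotype criteria

The qualitative claims the model must reproduce state directions only
("higher", "later", "decreased"). `criteria_config()` makes the margins
explicit package choices: sustained expression means ≥ 1.2× the
pre-induction baseline, "higher/lower" means a ratio ≥ 1.1 or ≤ 0.9,
onset crossings use 1.5× baseline, the p16 delay margin is 2 AU, and
the IL-6 onset window after the switch is 5 AU. Expression comparisons
use trapezoidal time-means over windows rather than endpoint values,
because the claims concern sustained phenotypes. Each criterion reports
a signed relative margin (positive iff passed, worst sub-part for
multi-part criteria), so near-misses are visible. One interpretation
choice: the "p53 knockdown upregulates p38" claim is evaluated in DDIS
(where the p53 arm dominates); the OIS sub-result is reported in the
details attribute rather than gating the pass.

## Numerical choices

* `deSolve::lsoda` with `rtol = 1e-8`, `atol = 1e-10`; the suite checks
  that halving tolerances moves trajectories by less than 0.1%.
* The initial state is the pre-induction fixed point (long relaxation
  polished by damped Newton with a finite-difference Jacobian), so the
  pre-induction segment is flat; the simulator records the maximal
  derivative at induction entry and warns above 1e-6.
* Integration restarts exactly at event times; chaining windows with
  carried state reproduces a single full-window call to better than
  1e-6 (events before a window's start re-apply their parameter parts,
  while state scalings are assumed baked into the carried state).
* Reported values are clipped to zero from below at −1e-9 only.

## Dynamic sensitivity

`dynamic_sensitivity()` perturbs one parameter *as an event*: the run is
repeated with the parameter scaled by `1 + delta` from the event time
onward (canonical times T20/T40/T60/T80 bracket induction and the
switch) and reports the scaled sensitivity
`S(t) = (y_pert - y) / (y delta)`. Before the event the runs are
identical, so `S = 0` exactly; where the nominal trajectory is below
1e-12 the quotient is meaningless and reported as 0 with a flag. The
forward estimate is verified against central differences in the test
suite.

# Limitations

* The meta-analysis operating characteristics (sensitivity, FPR, power,
  type-I) are statements about the synthetic generator's world, not
  about any real corpus.
* The ODE model is a single-cell caricature: no cell population
  structure, no stochasticity, no spatial signalling, and arbitrary
  units that are comparable only within a simulation.
* The criteria margins quantify robustness to numerical noise, not
  biological effect sizes.
* The exact rank tests are exponential-equivalent only through the
  convolution trick; beyond the `exact_limit` the normal approximation
  is used and p-values near machine precision are not meaningful.
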