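---
title: "Inferring predator-prey dynamics from eDNA qPCR surveys"
author: "ednadyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring predator-prey dynamics from eDNA qPCR surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ednadyn)
```

## The inference problem

Environmental DNA (eDNA) surveys detect species from water samples rather
than from captured animals. A typical pond campaign visits a set of ponds
monthly through the amphibian breeding season, takes a few one-litre water
samples per pond per visit, and runs each sample in qPCR triplicate with a
species-specific assay. The scientific question `ednadyn` addresses is
whether the *dynamics* of different species — their month-to-month entries
into and disappearances from ponds — are associated: do prey colonize ponds
that predators have left, do predators follow their prey?

The chain has four stages, each a module of the package:

1. **Assay calibration** (`fit_standard_curve`): a dilution series gives the
   linear relation $C_q = a\,\ln x + b$ between quantification cycle and
   relative DNA amount $x$, the amplification efficiency
   $E = 10^{-1/(a \ln 10)} - 1$, and the limits of detection and
   quantification.
2. **Detection scoring** (`call_detections`): replicate-level positivity
   (back-calculated quantity above the LOD) is aggregated to a site-month
   detection call under the two-replicate rule; site-months never sampled
   stay missing.
3. **Transition encoding** (`encode_transitions`, `cooccurrence_matrix`):
   presence/absence across a pair of consecutive months becomes one of four
   transition states per species per site — stay zero `--`, persist `++`,
   enter `-+`, disappear `+-` — and a row-conditional co-occurrence matrix
   counts, for every ordered pair of (species, state) events, how often the
   row event was accompanied by the column event, divided by how often the
   row event happened.
4. **Permutation inference** (`cooc_test`): each species' transition states
   are shuffled across sites, independently per species, preserving every
   species' transition-type frequencies (and hence the temporal
   autocorrelation they summarize) while destroying cross-species
   association. Comparing the empirical matrix with this null classifies
   cells as occurring *more* or *less* often than expected by chance.

## The statistical model and its conventions

The permutation scheme conditions on each species' observed multiset of
transitions; under the null hypothesis of no cross-species association (and
site exchangeability) all assignments of those transitions to sites are
equally likely. Conventions, all configurable:

* **P-values** use the add-one rule $p = (1 + \#\text{extreme}) / (1 + B)$
  with ties counted as extreme, so a finite number of permutations can
  never produce $p = 0$ and the test remains valid.
* **Sidedness**: two-sided by default, doubling the smaller tail and
  capping at 1. A cell significant at level $\alpha$ is directional:
  `more_than_expected` when the empirical proportion sits in the upper
  tail, `less_than_expected` in the lower.
* **Scope**: same-species cells are excluded from testing by default
  (their null is degenerate given the per-species frequencies) but are
  reported descriptively. No multiple-testing correction is applied by
  default, matching the per-cell chance statements the test is designed
  for; p-values are reported so any correction can be applied downstream.
* **Month pairs** are tested separately (May–June, June–July); transitions
  are never pooled across pairs.
* **Missingness**: a site missing in either month of a pair is dropped for
  *all* species in that pair (complete-pair analysis), keeping joint counts
  well defined on a common site set.

### Validity versus exactness of the nominal level

For a continuous test statistic a permutation p-value satisfies
$P(p \le \alpha) \approx \alpha$. The co-occurrence proportion is *not*
continuous: with $n \approx 30$ sites a cell's null distribution often has
only a handful of support points (for a rare column event, the joint count
is hypergeometric with a support of 3–5 values). Ties then concentrate
probability mass at the empirical value, and because ties count toward the
tail the achieved rejection rate at $\alpha = 0.05$ falls well below 0.05.
The package's calibration experiments under the no-interaction scenario
measure per-cell rejection rates of roughly 1–2% at the pond-survey design
size. This is conservatism, not anti-conservatism: the test never rejects
more often than nominal under the null (a property the test suite checks),
but a user should not expect the nominal level to be achieved exactly at
small $n$. Larger site sets, or column events with mid-range frequencies,
bring the achieved level closer to nominal.

## qPCR scoring choices

* The curve is fitted by ordinary least squares on per-level *mean* Cq of
  amplifying replicates (robust to unbalanced dropout at the dilute end);
  all-replicate fitting is available via `use_replicates = TRUE`.
* **LOD** is the lowest concentration with at least 95% of replicates
  amplifying; **LOQ** additionally requires the coefficient of variation of
  back-calculated concentration at the level to be at most 0.35. Both
  thresholds are conventional replicate-rate defaults and are arguments of
  `compute_lod_loq`.
* The site positivity rule — at least two biological or two technical
  replicates above the LOD — is implemented by pooling positive replicates
  within the site-month (any two positives necessarily arise either from
  one sample's technical replicates or from two distinct samples, so the
  pooled count and the explicit two-case rule coincide at the default
  threshold; a `strict` mode keeps the explicit cases separately).
* A no-amplification well is encoded as an empty Cq field, never 0 or 50;
  Cq values are constrained to the 50-cycle protocol window.

## What the synthetic generator emulates

`make_scenario` reproduces the design of a breeding-season pond campaign:
31 ponds, 3 consecutive months, 2 amphibian prey (A1, A2) and 2 predatory
fish (F1, F2), 3 water samples per pond-month each in qPCR triplicate, and
~15% of later pond-months unsampled (month 1 never missing, dropout
missing-completely-at-random — field causes such as pond drying are not
modelled).

Occupancy follows a per-site colonization/extinction chain: month-1
presence is Bernoulli($\psi_0$); afterwards an empty site is colonized with
probability $\gamma$ and an occupied one goes extinct with probability
$\epsilon$ per month. The predator-prey interaction multiplies prey
$\gamma$ by $\theta_{col}$ and prey $\epsilon$ by $\theta_{ext}$ where at
least one predator was present in the *preceding* month, and predator
$\gamma$ by $\phi$ where at least one prey was present (products capped at
1, caps counted). Conditioning on the preceding month avoids simultaneity
and matches the transition framing; a `same_month` alternative (predators
updated first) is switchable in `occupancy_params`. The any-predator OR
rule is the simplest model consistent with guild-level avoidance; a
consequence worth knowing is that conditioning on a *single* predator
species' absence only partially removes predation pressure, which dilutes
single-species-pair signals (see the power note below).

Base rates, chosen once as a realistic breeding-season contrast and shared
by all presets: prey $\psi_0 = 0.25, \gamma = 0.6, \epsilon = 0.15$ (a
colonization wave of breeding amphibians) and predators
$\psi_0 = 0.5, \gamma = 0.05, \epsilon = 0.05$ (resident fish at about half
the ponds). The observation layer uses 3 × 3 replicates, per-replicate
detection probability 0.8 given presence, false-amplification probability
0.005 given absence, log-normal relative DNA amounts (meanlog
$\ln 0.1$, sdlog 1), Cq noise sd 0.35 cycles, and the shared assay line
$C_q = -1.526 \ln x + 41.232$ with LOD 0.01. Replicates whose noisy Cq
would pass 50 cycles are recorded as non-amplifying, as an instrument
would.

Presets differ only in size and interaction: `null_model` (31 ponds, all
multipliers 1), `strong_avoidance` (60 ponds, $\theta_{col} = 0.1$,
$\theta_{ext} = 5$, $\phi = 2$), `paper_like` (31 ponds with the avoidance
multipliers and 15% dropout). Interaction magnitudes are calibration
choices for a clearly detectable effect, not field estimates. One RNG
stream per dataset makes identical (preset, seed) calls bit-identical.

What the generator does **not** emulate: spatial structure between ponds,
pond-size covariates, disease dynamics, inhibition, within-season detection
heterogeneity beyond the replicate Bernoulli layer, and non-random
missingness. Tests passing on synthetic data therefore validate the
*inference machinery*, not the field realism of any particular dataset.

## Power at the study design size

Simulation at the package's design points shows two properties a user
should expect:

* Under `strong_avoidance` (60 ponds), the guild-level finding — some
  predator × prey instantiation of (row predator `--`, column prey `-+`)
  flagged more-than-expected in at least one month-pair panel — is
  recovered in over 90% of datasets. The *single* pre-specified pair
  (F2 row, A1 column) alone is flagged in only about half of datasets,
  because under the OR rule the other predator maintains suppression at
  half the F2-free ponds.
* Under `null_model`, per-cell rejection at $\alpha = 0.05$ runs at 1–2%
  (the conservatism discussed above).

The test suite runs these experiments at 1000 null datasets × 500
permutations and 200 avoidance datasets × 1000 permutations; sizes chosen
to keep Monte-Carlo error on the measured rates small relative to the
bands being checked.

## A worked run

```{r example, eval = FALSE}
ds <- make_scenario("paper_like", seed = 1)
det <- call_detections(ds$wells, ds$curve,
                       roles = setNames(ds$species$role, ds$species$species_id),
                       months = 1:3)
tt <- encode_transitions(det$matrix, c(1, 2))   # May-June
res <- cooc_test(tt, n_perm = 10000, seed = 42)
res
plot(res)
summarize_study(det$matrix, ds$wells, ds$curve)
```

`run_pipeline` chains the same steps and writes every artifact (detection
calls, detection matrix, per-pair transition tables and test TSVs, study
summary) with a provenance header carrying the config hash, seed and
package version, so a rerun reproduces outputs byte for byte.

## Numerical and degenerate-input behaviour

* `quantify_cq` inverts `predict` exactly (round-trip at machine
  precision); comparisons of empirical and permuted proportions are exact
  because both are ratios of integer counts over identical denominators.
* Rows whose event never occurs have undefined proportions, reported as
  `NA` (never 0), carry no p-values, and are listed in a message.
* A species with a constant transition vector yields a degenerate null:
  all its cells get $p = 1$ and direction `none`.
* Non-negative fitted slopes and out-of-range efficiencies flag the curve
  invalid with a warning rather than erroring, so screening runs can
  proceed.
* All probabilities after interaction multipliers are capped to $[0, 1]$
  and the number of caps is recorded on the simulated object.

## Known limitations

* The permutation test treats sites as exchangeable; spatial structure
  among ponds would violate the null without detection.
* Conservatism at small $n$ (above) means borderline effects need more
  sites or more frequent column events to be flagged.
* Detection-layer false negatives bias transitions toward `--`/`-+`
  switching noise; at the default replicate design this is negligible
  (site-level sensitivity given presence is effectively 1), but sparse
  replicate designs would need the observation layer modelled explicitly.
* The per-cell chance statements are not corrected for multiple
  comparisons by default; with 96 cross-species cells per panel some
  flagged cells are expected under a global null.
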