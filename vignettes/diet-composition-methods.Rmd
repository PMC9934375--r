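---
title: "Diet composition from stomach contents: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diet composition from stomach contents: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietcomp)
```

## The problem

Stomach-content analysis describes what a predator eats from a sample of
stomachs: here, broadbill swordfish taken by a drift-gillnet fishery in the
California Current, but the machinery is generic for any piscivore diet
study with per-stomach prey records. Each stomach carries haul and fish
covariates (eye-to-fork length in cm, date, position, sea-surface
temperature) and a list of prey occurrences: a taxon, a count of
individuals, an as-found weight in grams, digestion-state tallies on the
six-point scale (1 fresh ... 6 fully digested slurry), hard-part counts and
length measurements.

Three processing rules come straight from the laboratory protocol:

* **Minimum numbers.** Sagittal otoliths and squid beaks occur in pairs, so
  the larger member of each pair count is the minimum number of individuals
  those parts represent; intact individuals are added on top
  (`minimum_number()`). The additive treatment of beaks *and* otoliths in a
  single occurrence row is our generalization; in practice a row carries one
  hard-part family.
* **Net-feeding exclusion.** Large fresh chunks (digestion state 1-2) are
  taken to be prey scavenged from the net at capture and are discarded. No
  numeric mass threshold defines "large" in the field protocol, so the
  exclusion is flag-driven, with an optional mean-item-mass threshold
  (`mass_threshold_g`, default off) for synthetic studies.
* **Secondary prey** (prey of prey) are discarded by flag.

A stomach whose only contents were excluded is reclassified as empty, and
empty or slurry-only stomachs never enter percentage denominators.

## Indices of prey importance

With $k$ stomachs containing food, the relative measures of prey quantity
(RMPQs) for taxon $j$ are the percent frequency of occurrence
$\%F_j = 100 F_j / k$, percent composition by number
$\%N_j = 100 N_j / \sum N$, and percent composition by weight
$\%W_j = 100 W_j / \sum W$. Weights are as-found totals: no back-calculation
of ingested mass from hard parts, so long-digested prey contribute little
weight.

Three combined indices rank taxa:

* **Geometric index of importance.** With $n = 3$ RMPQs,
  $GII_j = (\%W_j + \%N_j + \%F_j)/\sqrt{n}$ and
  $\%GII_j = (\%W_j + \%N_j + \%F_j)/n$. The two differ only by the factor
  $\sqrt{3}$; $\%GII$ lives on a 0-100 scale.
* **Index of relative importance.**
  $IRI_j = (\%N_j + \%W_j)\,\%F_j$ (the classical Pinkas form), normalized
  to $\%IRI_j = 100\, IRI_j / \sum_j IRI_j$.
* **Prey-specific IRI.** Let $\%N_{ji}$ be the percent of stomach $i$'s
  total count belonging to taxon $j$ (similarly $\%W_{ji}$). The
  prey-specific abundances $\%PN_j, \%PW_j$ average these within-stomach
  percentages **over the stomachs containing taxon $j$**, and
  $\%PSIRI_j = \%F_j(\%PN_j + \%PW_j)/200$. Writing
  $pN_j = \%F_j \%PN_j / 100$ for the stomach-averaged composition, the
  identity $\%PSIRI_j = (pN_j + pW_j)/2$ holds exactly and the column sums
  to 100.

Two conventions deserve a note. First, dividing the prey-specific sums by
all $k$ stomachs instead of the occupied ones destroys the prey-specific
interpretation; that literal variant is retained behind
`psiri(divisor = "all")` for auditability only. Second, the stomach-averaged
compositions $pN, pW$ used inside the PSIRI identity are not the pooled
$\%N, \%W$ of the RMPQ table — the two coincide only when every stomach
holds the same total count. Published tables commonly apply the identity to
their pooled columns; `psiri_from_rmpq()` supports exactly that use.

Following the minimum-sample rule, `index_table()` refuses to estimate
indices from fewer than 10 stomachs with food, since small samples are known
to produce biased index values.

## Sample-size sufficiency

`rarefaction_curve()` randomizes the order in which stomachs are
accumulated (100 permutations by default) and tracks the number of distinct
prey taxa — at the lowest identified level, unidentified categories
included — against the number of stomachs examined, reporting the mean and a
mean ± 2 sd band. `asymptote_slope_test()` fits an ordinary least-squares
line to the rightmost 4 points of the mean curve and tests the slope against
zero (t test, `n_points - 2` df): a slope indistinguishable from zero is
read as the curve having reached its asymptote. The test is applied to the
mean curve, not to individual permutation curves. Degenerate tails (zero
residual variance) short-circuit to p = 1 for a flat line and p = 0, with a
warning, for an exactly sloped one.

For verification, `n_permutations = "all"` enumerates every ordering
(guarded at k ≤ 8); the test suite checks this against the closed-form
expectation $E[S(d)] = \sum_t \left(1 - \binom{k-F_t}{d}/\binom{k}{d}\right)$,
an independent route to the same quantity.

## Stratified comparisons

Stomachs are stratified by predator size (small < 165 cm EFL, large
≥ 165 cm), area (within the Southern California Bight, i.e. strictly east of
120°30′W = longitude > −120.5; the exact boundary falls offshore), fishing
season (Aug 15 - Jan 31, labelled by the starting year, so January belongs
to the previous season), and half-season (Aug 15 - Nov 7 versus Nov 8 -
Jan 31). Exact boundary cases are pinned by tests: 165 cm is large, Nov 7 is
first-half, Nov 8 second-half. Missing covariates give missing labels, not
errors; dates outside the season window warn, keep their season year by the
month rule, and lose only the half-season label.

`bootstrap_gii_compare()` quantifies between-stratum differences: 1000
bootstrap replicates resample stomachs with replacement within each group
(observed group sizes preserved; the stomach, not the prey item, is the
resampling unit), recompute per-taxon GII in each group, and record which
group is higher. A taxon is significantly more important in a group when it
wins more than 95% of replicates. Ties — possible when replicates coincide —
count in neither tail, keeping the two one-sided rules symmetric, so the
nominal false-positive rate under exchangeability is at most 10% (two 5%
tails). Both groups must hold at least 10 stomachs with food.

## Ordination

Counts are chord-transformed (`chord_transform()`: rows scaled to unit
Euclidean norm, so Euclidean distance equals chord distance), which
down-weights rare taxa; taxa found in fewer than 4 stomachs are dropped
beforehand (`min_stomachs`, the study default). Categorical predictors
become X−1 dummies against a declared reference level; fishing seasons are
grouped (2007, 2008-2010, 2011-2014 by default) to keep observations per
level reasonable. Continuous predictors are centered but not rescaled —
the constrained fraction is invariant to affine rescaling, so
standardization is cosmetic here.

`fit_rda()` regresses the centered transformed response on the centered
predictors; the constrained fraction is the fitted sum of squares over the
total, axes come from the singular values of the fitted matrix, and each
variable's pseudo-F is its marginal drop in explained sum of squares per df
over the full-model residual mean square. `rda_permutation_test()` permutes
the rows of the tested variable only (other predictors fixed) — simple and
exact under the null of exchangeability — giving
$p = (1 + \#\{F^* \ge F\})/(1 + n_{perm})$ with floor
$1/(1+n_{perm})$ (0.005 at the default 199 permutations). Whether the
original study's software used the same scheme is unknown; we document ours
and do not claim equivalence.

## The synthetic generator

Because no raw stomach records are published with this class of study, the
package carries a first-class generator (`simulate_dataset()`). Per-taxon
counts are negative binomial with mean $\mu$ and size $\theta$
(Var $= \mu + \mu^2/\theta$; stated explicitly because conventions differ)
with a log link on covariates: EFL slope, within-SCB offset, half-season
offset, per-season offsets, and a linear or quadratic (unimodal) SST
response. Defaults emulate the study conditions: EFL uniform on 74-245 cm,
SST on 14.3-21.9 °C, dates inside Aug 15 - Jan 31 over seasons 2007-2014,
longitudes straddling −120.5°, foodless-stomach probability 7/299, and
digestion-state probabilities placing 91% of items in states 4-5.
Individual weights are lognormal, down-scaled by a per-state retention
factor (1, 0.9, 0.7, 0.4, 0.15, 0.02) so that long-digested prey contribute
little weight, as in real material. Hard parts are emitted so that
`minimum_number()` reconstructs the drawn count exactly, and lengths are
recorded only for state-1/2 individuals. These laws are assumptions stated
in the config, not estimates from any dataset.

`study_scale_fixture()` is a deterministic, seeded dataset shaped like the
study sample — 299 stomachs, 292 with food, 60 taxa all present, and
per-axis sample-size margins matching the published composition table by
construction (the seven foodless stomachs are jointly assigned areas and
sizes so all three margins hold simultaneously). It exists to smoke-test the
full pipeline; its prey contents are draws, so index *values* computed from
it are not the published ones — only the margins and richness are.

What passing tests on synthetic data do **not** show: real stomach data have
taxon co-occurrence structure, observer effects, and digestion-driven
detection biases that the generator's conditionally independent
negative-binomial draws do not emulate. Results about calibration (bootstrap
false-positive rates, permutation p uniformity) transfer to real data only
insofar as stomachs are exchangeable sampling units.

## Numerical choices and test scale

* Prey-size means/medians print truncated toward zero to whole mm (217.5 →
  217), matching diet-table convention; full precision is retained in
  `raw_*` columns. Summaries need ≥ 2 specimens; single measurements report
  as a range only.
* Index tables sort by GII descending with ties broken by %IRI then
  taxon_id; report output rounds to 2 decimals, but tests always compare
  unrounded values.
* All resampling takes one root seed and derives an independent child seed
  per permutation/replicate, so runs are reproducible and outputs embed
  their seed.
* Values printed as "<0.1" g or "<0.01" % in the shipped reference tables
  are parsed at the interval midpoint with a censoring flag.
* Test problem sizes are chosen to exercise the asymptotics while keeping
  the default suite around a minute: exhaustive rarefaction at 5 stomachs
  (120 orderings), bootstrap calibration over 25 datasets × 1000 replicates,
  planted-effect detection over 15 datasets with groups of ~100, identity
  sweeps over 1000 random 10-stomach datasets, and NB moment checks at
  10,000 stomachs.

## Known limitations

* The net-feeding mass rule is a stand-in for observer judgment; only the
  flag-driven path reflects the real protocol.
* GAM-style smooth covariate effects on individual taxa are out of scope;
  the generator nonetheless produces covariate-dependent NB counts so such
  models can be fitted externally.
* The RDA permutation test is marginal (tested variable permuted, others
  fixed); under strong predictor collinearity a residual-permutation scheme
  can behave differently.
* Richness estimators beyond rarefaction (Chao, ACE, coverage-based
  variants) are deliberately absent.
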