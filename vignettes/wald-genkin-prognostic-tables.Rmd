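---
title: "Wald-Genkin prognostic tables: model, estimation and sequential classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wald-Genkin prognostic tables: model, estimation and sequential classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waldgenkin)
```

## The screening problem

Talent screening in artistic swimming asks, for a 10-13-year-old girl,
whether her morphofunctional profile resembles that of already-trained
athletes of her age. The Wald-Genkin approach answers with a *prognostic
table*: a short list of binary criteria, each carrying two deciban weights
(one if the criterion is present, one if absent), applied by simple
summation until a decision threshold is crossed. The method is a
practitioner-friendly packaging of Wald's sequential probability ratio
test with Kullback's divergence used to rank and prune the criteria.

The package implements the whole pipeline: index computation and
binarization, estimation of the weights from two cohorts, table assembly,
sequential classification, and a reconstruction oracle that recovers the
integer cohort counts behind a published table from its printed, rounded
coefficients.

## The nine criteria

Each subject is reduced to nine binary statements, in a fixed canonical
order (`criteria()`):

1. actual vital lung capacity over predicted ("proper") VLC above 1;
2. biceps index — relative circumference gain under tension — above 6.7%;
3. body-weight deficit: weight below $M - \delta_R$ for the height
   interval of a regression-scale norm table;
4. "Forward bend" hold above 10 s;
5. "Splits" floor distance below 0 cm (negative values arise under the
   bench-elevated protocol used with athletes);
6. Stange breath-hold above the age norm;
7. Genchi breath-hold above the age norm;
8. Erisman index (chest circumference minus half body length) below 0 cm;
9. "Crab position" palm-heel distance below 60 cm.

The supporting indices are $i_e = t - 0.5\,l$ (Erisman, cm),
$\mathrm{pVLC} = 0.041\,l - 0.018\,b - 3.7$ (litres, $l$ in cm, $b$ in
years), and $i_b = (l_{b1} - l_{b2})/l_{b2}$ (biceps). Two conventions
are worth making explicit, because prose descriptions of the method are
often loose about them:

* **Ratio orientation.** The criterion is *actual / proper* VLC above 1
  — the direction in which trained athletes exceed untrained peers. The
  package computes `vlc_ratio(vlc_actual, pvlc)` accordingly.
* **Strict inequalities.** Every criterion is strict in its printed
  direction ("more than", "less than"); a value exactly at the threshold
  is *absent*. The biceps comparison is made on the unrounded fraction
  against 0.067, so 6.67% counts as below 6.7%.

Missing measurements mark the dependent criteria *missing* (`NA`); they
are never imputed, and the classifier skips such rows rather than scoring
them as absence — absence is an informative observation here, not a null.

Weight and breath-hold norms differ by country and revision, so they are
runtime configuration (`norm_table()`, `read_norms()`), with half-open
`[min, max)` intervals. `default_norms()` is a synthetic stand-in on the
scale of published schoolgirl standards, intended for tests and examples.

## Estimation

For criterion $k$, let $d_1$ of $s_1$ athletes and $d_2$ of $s_2$
controls have the criterion present. The presence-gradation predictive
coefficient is the deciban log-likelihood ratio

$$\mathrm{PC}^{+}_k = 10 \log_{10} \frac{d_1/s_1}{d_2/s_2},$$

and the absence gradation replaces each proportion by its complement.
(The formula is sometimes written with prior group probabilities $p_1,
p_2$ multiplied in; with equal priors they cancel, and equal priors are
the convention this package adopts — it is the only reading under which
published tables of this family reproduce.) The criterion's weight for
ranking and pruning is the presence-term Kullback informativeness

$$I_k = \tfrac{1}{2}\, \mathrm{PC}^{+}_k \,\bigl(100\,d_1/s_1 -
100\,d_2/s_2\bigr),$$

which is non-negative and zero exactly at equal proportions. Classical
Kullback divergence sums the analogous term over both gradations; the
single-term form is the convention of this table family and the default,
with `both_gradations = TRUE` available in `informativeness()`.

Assembly (`prognostic_table()`) sorts criteria by descending
informativeness and drops rows strictly below the cutoff (default 30.0; a
row exactly at the cutoff is retained). Ties are broken by the canonical
criterion order — the traditional advice is to order ties arbitrarily,
but a deterministic rule makes runs reproducible, and we adopt it as a
deliberate deviation. A warning flags tables outside the 7-10-row range
usually considered sufficient.

**Display rounding.** Coefficients are carried unrounded and displayed
half-up to 1 decimal; informativeness is computed *from the unrounded
coefficient* and displayed half-up to 2 decimals. The order matters: one
reference row gives 254.46 from the unrounded coefficient where the
rounded one would give 253.33. `round_half_up()` implements the half-up
convention (base R's `round()` rounds half to even).

**Zero cells.** The likelihood ratio is undefined when any of $d$ or
$s - d$ is zero. The default continuity correction adds 0.5 to all four
cells of the 2x2 table (Haldane-Anscombe), *and is applied only when a
zero cell occurs*, so non-degenerate counts — including every count of
the reference instrument — are never perturbed. `smoothing = 0` turns
degenerate counts into errors instead.

## Sequential classification

`predict()` on a fitted table walks its rows from the top, adding the
presence or absence coefficient as observed, and stops at the first step
where the cumulative sum reaches $+T$ (outcome `success`) or $-T$
(`low_probability`); reaching the threshold exactly counts as crossing.
If the table is exhausted the outcome is `uncertain` and further
examination is indicated. The threshold comes from the allowable error
$\alpha$ as $T = \mathrm{round}\bigl(10 \log_{10}((1-\alpha)/\alpha)\bigr)$:
5% gives 13 points, 0.1% gives 30. (Practitioner summaries quote "8-30
points" for prediction probabilities 80-99.9%; the formula actually gives
6 points at 80% — 8 points corresponds to about 86%. The package follows
the formula.)

By default sums use the 1-decimal display coefficients, because the
printed table is the published instrument a practitioner applies;
`rounded = FALSE` switches to full-precision sums for sensitivity
analysis.

## The reconstruction oracle

Raw subject-level data behind the reference artistic-swimming instrument
were never published — only the rounded table. But with $s_1 = s_2 = 15$,
a printed presence/absence pair constrains $(d_1, d_2)$ strongly:
`invert_pc_pair()` searches all $(d_1, d_2) \in [0, s_1] \times [0, s_2]$
for pairs whose unrounded coefficients display as the printed pair. Every
pair of the reference instrument inverts uniquely, and the forward
formulas then reproduce all 27 printed numbers (`reproduce_reference()`).
This over-determination is also the package's flagship test: the full
instrument is rebuilt from nothing but its own printed coefficients.

## The synthetic cohort generator

Because no raw data exist, validation rests on synthetic cohorts with the
statistical structure the method assumes, at two tiers:

* **Binary tier** (`generate_binary_cohort()`): presence/absence profiles
  drawn per criterion either with *fixed counts* — exactly $d$ presences
  on a seeded random subset, so estimation recovers the counts exactly —
  or as independent Bernoulli draws with per-group probabilities. The
  default sizes, 15 athletes vs 15 controls, emulate the reference study
  design.
* **Measurement tier** (`generate_measurement_cohort()`): full raw
  records back-solved from target profiles. Each field is drawn from a
  plausible base distribution for 12-year-old girls (normal heights
  around 152 ± 6 cm, ages 12 ± 0.85 y, and so on — fixture choices, not
  empirical claims) and then placed on the side of its criterion
  threshold the target demands, so `binarize()` provably reproduces the
  target profile.

Criteria are generated independently: the reference publication reports
no correlation structure, so none is emulated. That is the main respect
in which passing tests do not speak to real data — real morphofunctional
criteria are correlated (they share a latent training/ability factor),
which would make sequential sums cross thresholds faster and change error
rates. The generator also ignores measurement error and the anthropometric
covariance of real cohorts. What the synthetic tests *do* establish is
the estimation arithmetic, the table assembly rules, the classifier
semantics, and the calibration of the threshold under the method's own
generating model.

`simulate_error_rates()` closes the loop: it draws fresh subjects from
each group's presence probabilities (default: the table's own $d/s$),
classifies them, and reports outcome rates with Monte-Carlo standard
errors. Under the generating model of the reference table, the
misclassification rates at $T = 13$ stay below the nominal 5% (most
mass crosses the correct threshold within two or three steps), and a
stricter threshold can only reduce misclassification on common random
numbers.

## Numerical choices and problem sizes

* Rounding: half away from zero with a $10^{-8}$ representation guard;
  all display rounding is confined to printing and export columns.
* The inversion search is vectorised over the full count grid; a single
  table reconstructs in well under a second.
* Test suites run the Monte-Carlo validation at 2,000 subjects per group
  and the acceptance checks at 10,000 per group; parameter-recovery
  checks use cohorts of 15, 150 and 1,500 per group, five replicates
  each. These sizes give Monte-Carlo standard errors a few times smaller
  than the margins asserted.
* CSV/YAML round trips carry 15 significant digits; the subject reader
  rejects decimal commas outright (a real hazard for data entered under
  Eastern European locales) rather than mis-parsing them.

## Known limitations

* The instrument is specific to its reference population
  (12-year-old girls, 15 + 15 design); the package generalises the
  arithmetic but not the norms or the criterion set's validity.
* Binary gradations only; multi-level gradations and asymmetric
  $\alpha/\beta$ thresholds are out of scope.
* No confidence intervals on coefficients — with $s = 15$ they would be
  wide, and the published method does not define them.
* The "Splits below 0 cm" criterion presumes the bench-elevated athlete
  protocol; for subjects measured floor-level the criterion can only be
  absent, which the user must keep in mind when screening controls.
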