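---
title: "Family-adjusted short-stature screening in Turner syndrome: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-adjusted short-stature screening in Turner syndrome: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turnerscreen)
```

## The problem

Short stature is a cardinal feature of Turner syndrome, but not every
affected girl is frankly short: childhood height is strongly influenced by
parental height, so a girl with tall parents can have a substantial Turner
growth deficit while remaining above the population −2 SDS cut-off.
Screening her height against her *family's* expectation — the lower end of
the parental target range (LTR) — detects this. This package implements
that evaluation end to end: converting measurements to standard deviation
scores (SDS) on a growth reference, computing mid-parental height (MPH) and
the LTR, classifying each girl against population and family thresholds,
tabulating age-stratified sensitivities, and generating synthetic cohorts
with the statistical structure of a real Turner clinic population so that
the whole pipeline is testable at desk scale. It reproduces the figures of
a published audit of a dedicated Turner clinic, whose printed counts,
contingency table and 14-girl data table serve as fixtures.

## The LMS growth-reference engine

Anthropometric references tabulate, on an age grid, a Box–Cox power $L$, a
median $M$ and a coefficient of variation $S$. A measurement $x$ at age $t$
converts to an SDS by

$$z = \frac{(x/M(t))^{L(t)} - 1}{L(t)\,S(t)}, \qquad
  z = \frac{\log(x/M(t))}{S(t)} \;\; (L \to 0),$$

with $L$, $M$ and $S$ each linearly interpolated in age between grid rows
(the convention of the standard LMS software). Numerical choices:

* **Branch switch.** The log branch is used when $|L| < 10^{-7}$; the two
  branches agree to well below measurement precision there, which is pinned
  by a continuity test.
* **No extrapolation.** Ages outside the grid raise an error, never a
  clamp: silent clamping would corrupt SDS values near the grid bounds.
* **Inverse transform.** $x = M (1 + L S z)^{1/L}$ requires
  $1 + L S z > 0$; for $L < 0$ this bounds $z$ above at $1/(|L|S)$ (and
  below at $-1/(LS)$ for $L > 0$), and values outside it raise a domain
  error reporting the admissible bound.
  The round-trip $z \to x \to z$ is the identity to $10^{-9}$, tested over
  $z \in [-4, 4]$.
* **Gestation indexing.** The birthweight reference is indexed by completed
  weeks of gestation; whole-week records map to week + 0.0.

National references (e.g. UK 1990) are copyrighted and are therefore
**user-supplied** as `age,L,M,S` CSV files via `read_lms_table()`. The
package ships analytic stand-ins (`synthetic_height_reference()`,
`synthetic_birthweight_reference()`) whose $M$ curves are smooth closed
forms with $L = 1$ and constant $S$, so every expected value in the test
suite is computable by hand. With $L = 1$ the transform reduces to
$z = (x - M)/(M S)$ exactly, which the calibration below exploits.

## Mid-parental height and the target range

For a daughter, $\mathrm{MPH} = (\text{mother} + \text{father} - 12.5)/2$
cm and $\mathrm{LTR} = \mathrm{MPH} - 8.5$ cm, taking 8.5 cm as two
standard deviations of the target range. Both constants are configurable
(Tanner-derived systems admit variants) with these conventional values as
defaults. MPH and LTR are converted to SDS at an adult reference age of 20
years on the female height reference.

Parental heights carry provenance — `measured`, `reported` or `missing` —
because reported heights are systematically biased (fathers tend to
overestimate, mothers to underestimate). Reported heights are carried
through with their flag, never silently treated as measured; a missing
parent yields `completeness = "insufficient"` and no numeric target range,
forcing callers to branch per stratum.

## Classification and sensitivity tables

Every threshold comparison is strict: `short_population` is height SDS
$< -2$ (so a girl at exactly −2.00 is *not* short), `below_family` is
height SDS $<$ LTR SDS, and birthweight cut-offs count SDS strictly below
each threshold. Age bands follow the 1–5 / 5.1–10 / 10.1–16 year
convention, implemented as $(1,5]$, $(5,10]$, $(10,16]$; older girls are
reported in an `out_of_band` row. Since every subject has Turner syndrome,
the proportion flagged is a sensitivity; the age-banded table carries the
partition identities (below + at-or-above = total per band; bands sum to
overall) as invariants.

Percentages are displayed with half-to-even rounding — integer for
table-style percentages, one decimal where the audit prints one — so
78/92 → 85, 36/135 → 26.7 and 13/800 → 1.6. One published figure (94/172
printed as 54.6) reflects truncation rather than rounding;
`percent_format(mode = "truncate")` reproduces it and is documented as a
compatibility mode only. The printed sources also disagree with themselves
in places (85% vs an overall table row of 76/92 = 83% for the below-LTR
count; 71% vs 74% for the 1–5 y band; two mean ages for the same stratum).
The package computes from counts and surfaces both figures in tests and
documentation without adjudicating.

The crude-screening worked example (`crude_screening_yield()`) estimates,
from annual births, the female fraction, a prevalence of 1 in 2000 female
births and a 3rd-centile cut-off, how many girls screen short and how many
of them have Turner syndrome. In compatibility mode the intermediate
counts are rounded as in the published back-of-envelope (nearest hundred /
nearest integer), giving 800 and 13 and a predictive value of 1.6%. That
figure is a positive predictive value — true positives among screen
positives — and is labelled PPV here even though it is sometimes loosely
called a specificity.

## The synthetic cohort generator

No case-note data are deposited, so the generator emulates the cohort's
stated structure. Each girl receives:

* an age at first accurate measurement from a truncated normal
  (mean 7.05, SD 4.05, range [1.31, 18.5] years);
* parental heights from independent normals, with provenance drawn from
  the 94/37/41 both/one/neither-measured census (given "neither", both
  heights are reported rather than missing with probability 15/41);
  reported heights are the true heights biased by +2 cm (father) and
  −2 cm (mother);
* a height SDS
  $z = c \cdot z_{\mathrm{MPH}} + D(\mathrm{age}) + k + \varepsilon$,
  where $c$ is the parent–child coupling, $D$ the Turner deficit, $k$ a
  mild-karyotype offset and $\varepsilon$ Gaussian residual; her height in
  cm is the inverse LMS transform at her age, and the pipeline re-derives
  the SDS as it would for a real case note;
* a karyotype from the clinic census of the both-measured stratum
  (probabilities out of 94), with the milder mosaicisms 45,X/46,XX and
  45,X/47,XXX receiving the offset;
* a birthweight SDS from a normal centred on the observed median (−0.91)
  and a gestation from a discrete 27–44-week distribution centred on 39–40
  weeks, converted to grams through the birthweight reference so that the
  record is internally consistent.

**Deficit shape.** No longitudinal model is published, so $D$ is the
simplest shape consistent with the described growth pattern — low-normal
velocity for the first 3–4 years, then height falling away from the
centiles: a constant deficit to a plateau age of 4 years, then a linear
decline, continuous at the knot. The default slope of −0.12 SDS/year takes
the deficit from its early-childhood level to roughly the −3 SDS
neighbourhood (≈20 cm below the adult female mean) by late adolescence.
The deficit is a configuration object so condition-specific curves can be
slotted in.

**Calibration.** `default_sim_config()` solves the free parameters once so
the generated cohort matches the audit's observed structure: height SDS
−2.63 ± 0.94 and LTR SDS −1.77 ± 0.81. On an $L = 1$, constant-$S$
reference the mid-parental SDS is an exact linear (hence Gaussian)
transform of parental heights, so parental means/SDs follow in closed form
from the LTR targets (equal parental SDs and a 13 cm mean sex gap are
fixed choices); the deficit intercept and the residual SD then absorb the
remaining mean and variance. The parent–child coupling (0.4, in the range
reported for childhood height on mid-parental SDS) and the mild-karyotype
offset (+0.6 SDS) are documented choices the targets do not identify; the
published audit gives no parent–child correlation, so the coupling is an
explicit configuration default, not an estimate.

**Oracle.** Conditional on age and karyotype, the gap
$z_{\mathrm{girl}} - z_{\mathrm{LTR}}$ is Gaussian with closed-form mean
and variance, so the below-LTR rate is a mixture expectation of normal
probabilities, computed by one-dimensional numerical integration over the
age distribution (`sim_expected_moments()`). This analytic route is
independent of the sampling path and is used to check Monte-Carlo output;
at the default calibration it gives ≈0.80, close to — and computed
independently of — the audit's 78/92 = 85% (the audit's own table row
reads 76/92 = 83%).

**What the generator does not emulate.** Secular trends, measurement
error, longitudinal correlation within girls (each girl contributes one
measurement), referral bias linking age at presentation to severity,
growth-hormone treatment, and comorbidities. Passing tests therefore show
that the *pipeline arithmetic* is correct under the stated distributional
structure, not that the structure captures every feature of a clinic
population.

**Randomness.** One seeded stream per `simulate_cohort()` call; the
caller's RNG state is saved and restored, and identical `(config, seed)`
pairs produce byte-identical cohorts.

## Pipeline rules

Exclusions are explicit configuration, because in the original audit they
were applied as prose judgements: a minimum age (records at ≤ 1 year are
signalled, logged with a reason and counted, never silently dropped), a
manual id blacklist for clinically implausible records, and an automatic
birthweight screen ($|$BW SDS$| > 3$) that removes a record from the
birthweight analysis only. The birthweight denominator is the
post-exclusion count (135 in the audit, which reproduces its printed
26.7%; the pre-exclusion 136 is available by passing an explicit
denominator). When a record carries both a raw height and a precomputed
SDS, the SDS wins and a note is emitted — fixtures carry SDS, raw cohorts
carry cm, and the rule prevents silent reference-dependence. The run
manifest reconciles every input record as analysed or excluded-with-reason
and carries a config hash so reruns are verifiably identical.

## Problem sizes and test budget

The test suite simulates cohorts of 5,000–10,000 girls for the
parameter-recovery and goodness-of-fit checks (Monte-Carlo SE of a rate at
n = 5,000 is ≈0.007, comfortably below the ±0.05 calibration tolerance)
and a few hundred for pipeline behaviour; the whole suite runs in well
under a minute on one CPU. These sizes are the package's own choice of
desk-scale precision.

## Known limitations

* The boys' target-height variant is deliberately not implemented; the
  formula here is the daughter convention only.
* No specificity/ROC analysis: the data contain only affected girls, so
  only sensitivity is estimable, and the crude-screening PPV example is a
  population back-of-envelope, not a screening-programme model.
* The analytic references are stand-ins; real analyses must supply a
  national LMS table, and results inherit that table's accuracy.
* Shrinkage corrections for very tall or short parents are out of scope.
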