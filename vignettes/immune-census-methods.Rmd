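---
title: "Methods: a whole-body immune-cell census with lognormal uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a whole-body immune-cell census with lognormal uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its method: what is being
estimated, under which model, with which tunable parameters, and what the
synthetic validation does and does not demonstrate.

## The estimation problem

The quantity of interest is the number (and mass) of each of eleven major
immune cell types — T, B, plasma and NK cells; neutrophils, eosinophils,
basophils and mast cells; macrophages, monocytes and dendritic cells — in
every tissue of a standardized reference person, and the margins over
tissues and types. The core identity is simple:

    cells(tissue, type) = density(tissue, type) [cells/g] x organ mass [g]
    mass(tissue, type)  = cells(tissue, type) x representative cell mass [g]

Everything difficult lives in the density term: evidence is heterogeneous
(areal histology counts, flow-cytometry fractions, whole-organ totals,
multiplexed-imaging fields), spans several orders of magnitude between
tissues, disagrees within a (tissue, type) pair by up to an order of
magnitude, and is missing entirely for many pairs. The package's job is to
put all of that on one scale — cells per gram with a multiplicative error
factor — and to propagate those errors honestly into the totals.

## The uncertainty currency

Every uncertain quantity is a `lognormal_estimate`: a point value (the
median of a lognormal) and a multiplicative error factor `ferror >= 1`
whose log is the shape parameter `s`. An `ferror` of 2 means one sigma
spans half to double the value. The choice is forced by the data: spreads
of ±10x cannot be additive-Gaussian, and products (density x mass x cell
mass) stay closed-form lognormal, with shapes adding in quadrature.

Three operations carry the analysis:

* **Moment-matched fitting.** Values reported as mean ± SE are converted
  by matching the lognormal's mean and variance to the normal's:
  `s^2 = ln(1 + (se/mean)^2)`, point value `mean * exp(-s^2/2)`. Matching
  moments is closed-form and parameter-free; an optimizer-based fit would
  add tuning without changing anything material. The point value is the
  *median* of the fitted lognormal. Whether published point estimates are
  medians or means of their error distributions is generally unknowable;
  the median is the geometric-scale center, consistent with the geometric
  pooling used everywhere else, and the difference (a factor of
  `exp(s^2/2)`) is a few percent at typical ferrors. Fits are refused when
  `se/mean > 3`: beyond that the normal puts appreciable mass below zero
  and no lognormal matches it meaningfully.

* **Analytic products** for chains of multiplicative factors.

* **Bootstrap sums.** Sums of lognormals have no closed form, so totals
  get percentile CIs from 1,000 seeded draws (the default `n_draws`;
  raising it to 1e5 moves 95% bounds by under 1%). Estimates that share an
  evidence source — extrapolations of one cell type filled from one pool —
  share a single standard-normal deviate per draw: perfect correlation,
  the conservative reading, since treating them as independent would let
  shared bias cancel in the margins.

Inverse-variance combination in log space (weights `1/s^2`) merges
independent methods estimating the same density. An exact estimate
(`ferror = 1`) carries infinite weight; two disagreeing exact estimates
raise an error rather than average silently.

## From evidence to densities

All lengths are handled in centimetres internally; readers convert the
micrometre columns. Areal histology counts become volumetric densities via
the stereological thickness correction `rho = n / (A (T + D))` — a section
of thickness `T` captures every cell whose centre lies within one cell
diameter `D` of it. Volumetric densities become per-gram densities by
*division* by the tissue's specific gravity (1.03 g/mL, 0.91 g/mL for
adipose): the conversion is sometimes described as multiplication, but
cells/cm³ divided by g/cm³ is what yields cells/g, and the ≤3% difference
between the two specific gravities is negligible against the density
errors. Fractions of nucleated cells multiply a reference nucleated
density; whole-organ totals divide by the organ mass.

Repeated records of one (tissue, type) pair pool by geometric mean, with
`s^2 = (mean(s_i^2) + var(ln v_i)) / k` — declared measurement error and
observed between-record spread both contribute, shrunk by the record
count. This deliberately overstates uncertainty slightly when records
agree by luck; the alternative (taking only the larger term) understates
it when k is small, which is the dangerous direction here.

Multiplexed-imaging fields (400 x 400 um, beam thickness negligible, so
`T = 0`) use per-type effective diameters defaulting to 7.5 um for
lymphocytes, 10–12 um for granulocytes and monocytes, 17 um for
macrophages and dendritic cells — all overridable where measured diameters
exist. Samples are screened once per tissue: totals with |z| > 1.96
against the stratum mean and population SD are dropped (population SD and
a single pass are the simplest faithful reading of a z-score screen;
strata under three samples pass through with a warning since the score is
meaningless there). Screening is per tissue, not global, because totals
differ legitimately between organs. Aggregation is hierarchical: geometric
mean over a patient's positive fields, then over patients, with
`s^2 = s_between^2/k + mean(s_within^2)/n_bar`. Zero-count fields are
excluded from the geometric mean rather than floored — a pseudo-count
would bias exactly the low-abundance types the screen is meant to protect
— and the zero fraction is reported alongside. The within/between
combination formula is a documented choice; nothing in the method's
description pins it down further.

Literature and multiplex estimates of the same pair combine by
inverse-variance weighting. A `multiplex_weight` multiplier (default 1)
can up-weight imaging in lymphatic tissues; at the default, the imaging
method's typically smaller ferror already gives it most of the weight, so
the multiplier exists for sensitivity analysis rather than as a tuned
constant. Deconvolution-derived counts never enter the census — they are a
validation contrast only, and the census is bit-identical with or without
them.

## Gap filling

Pairs with no direct human evidence are filled two ways and the results
geometric-averaged: cross-species (geometric mean of rodent/monkey records
for the same pair, each ferror inflated x1.5) and tissue-group (geometric
mean of the same cell type across same-group tissues, ferror from the
between-tissue spread, floored at 1.5). The penalty and floor have no
published values; 1.5 is chosen once so that an extrapolated density can
never out-weigh a direct measurement in any later combination, which is
the property that actually matters. The species penalty is applied in the
extrapolation step only — non-human records never merge into direct
evidence — so it cannot be applied twice. Pairs whose two strategies
disagree by more than a factor of 2 are flagged for review rather than
resolved. Eosinophils, mast cells and basophils are never extrapolated
outside their home tissues (GI tract/marrow/spleen/nodes/thymus;
connective tissue/barrier lamina propria/marrow; marrow/blood): for
tissue-restricted types, absence of evidence is evidence of absence, and a
group mean would manufacture cells that are not there. Every filled pair
lands in an audit log, and extrapolations of one cell type within one
tissue group share a correlation group in the bootstrap.

## Cell masses

Sizes are spheres: `V = (pi/6) d^3`, with diameter ranges collapsed to the
geometric mean of their endpoints (sizes are treated as lognormal
throughout). Blood-smear measurements are shrunk by 0.7 — flattened cells
read large — with the measurement context carried as an input column, not
guessed. Volumes pool geometrically with a log-space SE; mass is volume
x 1.07 g/mL, the ~0.02 g/mL between-type variation being far below the
volume uncertainty. Macrophages are the exception to one-mass-per-type:
their size is strongly niche-dependent, so resolution goes tissue-specific
record, then the tissue's monocyte-replenishment class aggregate, then the
global macrophage pool. In the mass census the per-type mass error is
shared across all tissues of that type (one size estimate feeds them all),
sampled as a second, fully correlated bootstrap component on top of the
count errors. For macrophages this overstates the correlation between
tissues resolved from different records — the conservative direction.

## Reference persons and scenarios

Organ masses follow ICRP-style reference anatomy for a 73-kg male, 60-kg
female and 32-kg 10-year-old; densities are taken as sex- and
age-independent, so person scaling is exactly linear per organ. Lymph-node
mass is tabulated only for the male; for the others it is interpolated by
body-mass ratio. The interpolation variable (body mass vs age vs lymphatic
mass) is genuinely open; body mass is the choice because it is the one
variable defined for all three persons and the spleen — the best-measured
lymphatic organ — scales with it.

Perturbation scenarios are multiplicative modifiers: a mass modifier
scales a tissue (optionally only a fraction of it, giving an effective
factor `1 + fraction (factor - 1)`), a density modifier scales one
(tissue, type) pair. Lymphadenopathy arithmetic runs on explicit volume
factors (diameter ratio cubed — doubling gives 8) rather than on absolute
node volumes, whose published reference values are not internally
consistent (a 0.5-cm-diameter sphere is ~0.065 cm³, not 0.5 cm³).

## What the synthetic world is, and is not

The generator builds a full input bundle around a known truth: group-level
density scales (marrow ~6e8, lymphatic ~1.7e9, epithelium ~2-4e7,
adipose/muscle 2-5e5 cells/g) with 0.15 log10 per-tissue jitter, immune
compositions per tissue group shaped like the real ones (neutrophils ~80%
of marrow, lymphocytes ~85% of lymphatic tissue, mast cells ~a quarter of
barrier epithelia, macrophages ~70% of liver), restricted types zeroed
outside their tissues. Around that truth it draws three lognormal
literature records per observed pair at ferror 1.6, Poisson field counts
for the lymphoid organs (5 patients x 4 fields, with an optional 0.15
between-patient lognormal effect), compositional deconvolution fractions
with a 1.3-ferror anchor, and size records at 0.08 log SD including
smear-inflated ones. Pairs contributing more than 1e9 cells always carry
direct evidence — in the real corpus, extrapolation only ever fills minor
tissues — and the missing-pair probability (0.15) operates on the rest.
Every stochastic step runs under an explicit seed; identical seeds give
byte-identical bundles.

Run end to end, this preset yields a male grand total of order 1.8e12
cells and ~1 kg of immune-cell mass, and the 95% CI of the grand total
covers the generating truth in ~95 of 100 seeded replicates (the packaged
experiment uses 100 replicates at 1,000 draws each; the log10 bias of
recovered densities is below 0.02). With all noise parameters at zero the
pipeline reproduces the truth to rounding error, which pins down the
plumbing as distinct from the statistics.

What passing these tests shows: the estimators are unbiased on their own
model, the error propagation is calibrated, and the pipeline's wiring is
exact. What they cannot show: that real literature evidence is unbiased
around the true density (publication and method biases have no synthetic
counterpart), that real between-patient variation is lognormal, or that
the true compositions match the generator's. Conclusions about the real
census inherit the quality of the transcribed evidence tables, not of
these tests.

## Numerical conventions and limitations

Analytic 95% intervals use z = 1.96 on the log scale; bootstrap intervals
use the 2.5/97.5 percentiles of seeded draws; reported point totals are
sums of member point values (not means of draws), so margins conserve
exactly — by-tissue, by-type and grand sums agree to 1e-9 relative.
Headline tables round to one significant digit; CSV output keeps full
precision. Zero densities are represented by an explicit sentinel
(value 0, infinite ferror) that never enters log-space arithmetic.

Known limitations: no ratio/power algebra beyond products (nothing in the
census needs it); no Bayesian pooling across tissues; fraction inputs are
treated as exact unless an SE column is supplied; the scenario engine is
multiplicative only and does not model redistribution between tissues; and
organ-mass uncertainty is taken as negligible, which matters most for the
lymph nodes, whose reference mass is the least certain input of the whole
analysis.
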