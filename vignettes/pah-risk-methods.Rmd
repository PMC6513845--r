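---
title: "Methods: probabilistic inhalation risk assessment for PM2.5-bound PAHs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probabilistic inhalation risk assessment for PM2.5-bound PAHs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pahrisk)
```

## The problem

Polycyclic aromatic hydrocarbons adsorbed on fine particulate matter
(PM2.5) enter the body through inhalation, and several congeners are
established or probable human carcinogens. A defensible population-level
risk statement therefore has to combine three very different data sources —
congener concentration monitoring, congener-specific potency factors, and
survey-based time-activity and anthropometric data — and to propagate the
variability of each through to a lifetime cancer-risk distribution rather
than a single point estimate. `pahrisk` implements that chain as a set of
small, pipeable functions over tibbles, each stage testable in isolation.

## Toxicity weighting and source screening

Mixture toxicity is expressed on the benzo[a]pyrene scale:
$\mathrm{TEQ} = \sum_i C_i \cdot \mathrm{TEF}_i$ over the 16 priority
congeners. TEQ is linear in the concentrations, so unit handling is
trivial: the package carries concentrations and TEQ in ng/m³ end to end.
The default TEF table is the Nisbet–LaGoy scheme. One potency value is
genuinely ambiguous across scheme variants — dibenz[a,h]anthracene appears
as both 1 and 5 in the literature — so `default_tef_table(dba_tef = )`
makes it an explicit, documented argument instead of a buried constant
(default 1).

Below-detection observations are substituted, not dropped: the policy
(`half_lod` default, `zero`, `lod_over_sqrt2`) is an argument on every
analysis function, because the choice is a genuine analyst decision that
must stay visible. I/O keeps raw values so CSV round trips are lossless.

Source screening uses three diagnostic ratios — Fle/Pyr, BaP/BghiP,
BaP/(BaP+Chr) — computed on city-mean concentrations (not means of
per-sample ratios, which are biased for ratios of noisy quantities and
would not match the one-ratio-per-city convention of monitoring reports).
The shipped interval table maps ratio ranges to gasoline/diesel/coal
labels and is deliberately editable with citations, since such ranges vary
across the apportionment literature; classification is a deterministic
interval lookup with a majority-vote consensus ("mixed" on ties,
"unclassified" outside all intervals).

## Distribution machinery

Three families cover every stochastic input: lognormal (TEQ, cancer slope
factor), normal (exposure time, children's body weight) and uniform (the
truncation multiplier of the uncertainty analysis).

Two parameterization paths exist for the lognormal because published
summaries come in two dialects. Moment matching
($\sigma^2 = \log(1+s^2/m^2)$, $\mu = \log m - \sigma^2/2$) reproduces a
reported arithmetic mean ± SD exactly; the log-scale MLE
(`fit_lognormal()`) is used when the raw series is available, as in the
pipeline's per-season TEQ fits. Both are exposed, and the seasonal fit is
the default for seasonal outputs (an annual fit is used for the annual
rows and for ILCR, which addresses lifetime exposure and has no seasonal
dimension).

Truncated distributions are sampled by renormalized inverse-CDF
transformation: a uniform draw is mapped through the quantile function
restricted to the truncation probability interval. This renormalizes the
distribution properly (no probability atoms at the bounds, unlike
clipping) and has a property worth paying for: each draw is a pathwise
monotone function of the truncation bound under common random numbers,
which the two-dimensional Monte-Carlo analysis exploits (below). Closed
forms for truncated normal and lognormal moments serve as oracles for the
sampled moments in the test suite.

Reproducibility uses one master seed fanned out into named substreams
(`teq`, `et`, `csf`, `bw`, one per pipeline stage and stratum) by a
deterministic integer hash. Adding a stochastic variable to a simulation
therefore never perturbs another variable's draws, and DI and ILCR runs
from the same master seed share their TEQ and ET draws exactly.

The 95th percentile — the headline risk statistic — is always the type-7
(linearly interpolated order statistic) sample quantile, fixed and
documented because different quantile rules differ visibly at n = 10,000.

## Exposure and risk simulation

Daily intake is $\mathrm{DI} = \mathrm{TEQ}\cdot\mathrm{IR}\cdot
\mathrm{ET}/24$ (ng/day); lifetime risk is
$\mathrm{ILCR} = (\mathrm{TEQ}\cdot\mathrm{IR}\cdot\mathrm{CF}\cdot
\mathrm{ED}\cdot\mathrm{ET}\cdot\mathrm{EF})\cdot\mathrm{CSF} /
(\mathrm{BW}\cdot\mathrm{AT})$, dimensionless. The risk formula is stated
in pg/m³ with a mg/pg conversion factor while results are conventionally
reported in ng; the package resolves this by carrying TEQ in ng/m³
everywhere and applying a single internal ×1000 conversion, with CF
defaulting to $10^{-9}$ mg/pg. Averaging time is in hours; a
years-to-hours conversion is explicit (`at_years` → `years·365·24`).

Default Monte-Carlo size is 10,000 iterations per stratum. The cancer
slope factor is lognormal with GM 3.14 (mg/kg·day)⁻¹ and GSD 1.80. Body
weight is stochastic for children only (normal, truncated positive);
adults use a point value — enforced by the constructor, since an
accidental adult BW distribution would silently change the adult/child
comparison. Exposure time may be exactly 24 h/day, supporting the
full-day comparison in which DI reduces to TEQ·IR.

Risk bands follow the usual regulatory reading: below $10^{-6}$
acceptable, $10^{-6}$–$10^{-4}$ potential, above $10^{-4}$ a concern; the
boundary values belong to "potential" (the band is stated inclusively).

The exposure-factor set (IR, ED, EF, AT, point BW per stratum) must be
supplied explicitly: `run_pipeline()` refuses to run without a population
configuration. `default_exposure_config()` provides documented synthetic
placeholders for experimentation, with exposure-time means inside typical
urban survey ranges (adults roughly 2–6 h/day, children 3–7 h/day) — they
are stand-ins, not survey estimates.

## Sensitivity and uncertainty

Sensitivity is the partial correlation between each stochastic input and
ILCR: the correlation of the residuals after linearly regressing both the
input and the output on the remaining inputs. The default is Pearson on
the raw draws, with `transform = "rank"` and `"log"` exposed: the choice
is not canonical across risk software, so it is an auditable argument. The
log transform doubles as an internal consistency oracle — the risk formula
is exactly linear in log-inputs, so log-scale coefficients must be ±1 up
to truncation effects, and the test suite asserts exactly that. Degenerate
inputs yield `NA` with a warning rather than a spurious coefficient, and
the default input set is the stratum's actually-stochastic variables (TEQ,
ET, CSF, plus BW for children).

The slope-factor distribution has no published maximum, so the truncation
bound is the one uncertain parameter: the bound is
$\exp(\log\mathrm{GM} + k\log\mathrm{GSD})$ with $k$ uniform on $[2, 4]$,
sampled by Latin hypercube (exactly one draw per equal-width stratum,
delegated to the `lhs` package). The outer loop (default 100 draws of $k$,
uncertainty) wraps an inner variability loop (default 10,000 iterations)
that recomputes the 95th-percentile ILCR. All inner loops share one seed
substream — common random numbers — so the 2.5th–97.5th percentile
interval of the outer values isolates truncation uncertainty from inner
Monte-Carlo noise. Two consequences are tested: a collapsed $k$-range
gives an exactly zero-width interval, and widening the $k$-range can never
shrink the interval, because each inner 95th percentile is monotone in the
bound under shared draws.

## The synthetic generator

The generator exists so that every downstream stage is exercised on data
with the statistical structure the analysis assumes. Per city, daily
congener concentrations are independent lognormals (GSD 1.8) whose
geometric means are a fixed composition scaled by season factors (winter
1.8, spring 1.05, autumn 1.0, summer 0.85) and a winter enrichment of 1.6
on the 4–6-ring congeners. With a baseline high-ring share of 0.8, these
constants put the winter high-ring mass share near
$0.8 \times 1.6 / (0.8 \times 1.6 + 0.2) \approx 0.865$ and the
winter/summer total-concentration ratio near 3.1 — inside the
84–92% and 1.7–5.0 bands characteristic of urban PM2.5 PAH records — and
the five city scale factors (0.45–1.10) put annual mean totals around
7–18 ng/m³. The exposure-survey generator draws truncated-normal
exposure times on [0, 24] h/day and point or normal body weights per
stratum.

What the generator does **not** emulate: day-to-day autocorrelation from
meteorology, inter-congener correlation, gas-phase partitioning, and
below-detection censoring (flags are supported in the table format but the
generator emits detects only). Tests passing on synthetic data therefore
validate the statistical machinery and calibration bands, not the
field realism of any particular monitoring campaign.

## Problem sizes and numerical choices

Unit and property tests run at n between 500 and 10⁵ draws, chosen so the
full suite completes in well under a minute while keeping Monte-Carlo
standard errors a factor of a few below every asserted tolerance
(e.g. a sample-mean check at n = 10⁵ has a relative SE of ~0.3% against a
2% band). Parameter-recovery checks use 10⁴ observations per congener, the
size at which the log-scale MLE pins GM and GSD within 5%. The
two-dimensional analysis is tested at full size (100 × 10,000), which runs
in seconds.

Degenerate inputs are first-class: zero-SD specs are point masses, a
zero denominator in a diagnostic ratio yields `NA` (undefined) rather than
an error, empty simulations refuse to produce percentiles, and a
degenerate uniform $k$-range is allowed (it is the no-uncertainty limit).
Ties in the source vote return "mixed" rather than an arbitrary label.

## Known limitations

Only the inhalation route of particulate-bound, outdoor PAHs is modelled —
no dermal or ingestion exposure, no indoor microenvironments, no gas-phase
congeners — so absolute risks are lower bounds in settings where those
pathways matter. Inputs are treated as mutually independent (no copulas),
seasonal aggregation is unweighted by sampling-day counts, and the
diagnostic-ratio intervals are screening heuristics, not a receptor model.
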