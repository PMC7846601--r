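---
title: "Peat and tree carbon accounting: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peat and tree carbon accounting: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peatcarbon)
```

# The problem

Boreal forested peatlands hold carbon in two very different pools: tree
biomass, built over the lifetime of the current even-aged stand (typically
the ~200 years since the last fire), and the peat column, accumulated over
millennia. Comparing the two fairly requires putting them on a common
timescale. `peatcarbon` implements the full accounting chain for one site:
a combined radiocarbon + lead-210 chronology for the peat core, carbon
density and accumulation-rate profiles, charcoal-delimited post-fire
horizons, ring-width-based annual tree biomass, and the final peat-versus-
tree comparison over both the whole record and the post-fire window.

All depths are in cm, positive downward, with contiguous half-open
increments `[top, bottom)` and the surface at 0. Ages are in calibrated
years BP (BP = 1950 CE), so a core collected in 2017 CE has surface age
`ce_to_bp(2017) = -67`.

# Chronology

## Radiocarbon calibration

`calibrate()` evaluates the posterior of the calendar age $\theta$ given a
conventional radiocarbon age $y \pm \sigma_y$ on a 1-yr calendar grid:

$$p(\theta) \propto \exp\left(-\frac{(y - \mu(\theta))^2}
  {2(\sigma_y^2 + \sigma_c(\theta)^2)}\right)$$

with $\mu, \sigma_c$ linearly interpolated from an IntCal-style curve. The
grid is truncated where mass falls below $10^{-12}$ of the mode and
renormalized; an error is raised if meaningful mass (more than $10^{-4}$
of the mode) is cut by the curve edge. Multimodal posteriors are kept in
full. Summaries are the weighted median and the *central* 2.5–97.5%
quantile interval — not an HPD region — because central intervals are
deterministic, order-respecting, and sufficient for median-based
reporting. Because published "±" values on calibrated dates are often
ambiguous (1σ vs half a 95% interval), both are reported: `sigma_equiv` is
half the central 68.27% interval, and `interval_95` the 95% one. No
reservoir or offset corrections are applied: dates are assumed to come
from terrestrial plant macrofossils.

## Lead-210: constant rate of supply

The CRS model assumes a constant flux $P$ of unsupported 210Pb to the
surface. With $A(z)$ the unsupported inventory below depth $z$,

$$t(z) = \frac{1}{\lambda}\ln\frac{A(0)}{A(z)}, \qquad
  \lambda = \ln 2 / 22.3\ \mathrm{yr^{-1}},$$

where 22.3 yr is the 210Pb half-life (the decay constant is configurable).
Supported activity is estimated by `estimate_supported()` as the mean of
the deepest `tail_n` measurements — the profile must therefore be measured
a few centimetres past the dateable range into the asymptotic zone — since
no 226Ra assay is part of this workflow. Age uncertainties follow by
first-order propagation of the activity measurement sigmas through the
inventory sums. Horizons with non-positive remaining inventory are beyond
the dateable range and are dropped with a log notice.

Two numerical facts matter here. First, CRS ages diverge as $A(z) \to 0$,
so only horizons younger than `crs_max_age` (default 150 yr, about five
half-lives — roughly the accepted limit of 210Pb dating) are admitted into
the age-depth model. Second, recovery of a noise-free synthetic profile is
exact (~1e-13 yr) throughout the credible range, but not arbitrarily deep:
at ~30 half-lives the unsupported signal (~1e-9 Bq/kg) sits below the
double-precision resolution of `total - supported`, a representability
limit rather than a model error.

## The combined age-depth model

`build_ensemble()` is a transparent Monte-Carlo piecewise-linear
interpolator in the classical (clam-style) tradition. Per iteration it
draws one age per dated horizon — 14C horizons from their calibrated
posteriors, 210Pb and surface horizons from Gaussians — and redraws until
the sequence increases strictly with depth (up to 1000 attempts, then the
iteration is discarded with a log notice; fewer than 50% acceptances abort
with advice to inspect reversals). Rejection-and-redraw, rather than date
deletion, preserves all data and is unbiased under weak reversals.
Accepted draws are interpolated to the 1-cm depth grid; medians, central
95% bands, and per-increment deposition times (iteration-wise slope
quantiles, yr cm^-1) summarize the ensemble.

An autoregressive accumulation prior (Bacon-style) was deliberately not
used: the chronology feeds only deposition times and horizon lookups, for
which the piecewise-linear model is well-posed, deterministic under a
fixed seed, and fast (2000 iterations on a 95-cm core run in about two
seconds). The default is `mc_iterations = 2000` with a mandatory seed; on
noise-free inputs the ensemble collapses to the deterministic linear
model, and medians are stable to ±2 yr under doubling of the iteration
count. When a 210Pb horizon and a 14C date fall on the same depth the
14C date is kept (it enters the horizon list first) and a notice is
logged.

# Fire horizons

`detect_layers()` defines a charcoal layer as a maximal run of increments
with at least `charcoal_threshold` macroscopic fragments cm^-3 (default 1:
presence), merging runs separated by less than `charcoal_min_gap` (default
2 cm) of clean peat. The defaults are configurable and logged because
field practice identifies distinct charcoal-rich horizons without a single
universal count threshold; raising the threshold can only reduce the
number of layers. The post-fire boundary is the *top* of the shallowest
layer — the first increment deposited after the fire — so the post-fire
stock integrates `[0, last_fire_depth)`. The layer-top convention (rather
than the midpoint) was chosen because charcoal within the layer was
deposited by, not after, the fire.

# Carbon accounting

Per increment, with the default peat carbon fraction of 0.50 of organic
matter (configurable):

* `om_density = bulk_density * om_fraction` (g cm^-3),
* `c_density = 0.5 * om_density` (g C cm^-3),
* `CAR = 1e4 * c_density / deposition_time` (g C m^-2 yr^-1),
* `cumulative_stock = 10 * cumsum(c_density * thickness)` (kg C m^-2).

CAR integrated back against deposition time reproduces the total stock as
an exact algebraic identity (asserted to 1e-9 relative in the tests), and
stocks are invariant under mass-weighted re-binning of increments.

`lorca()` divides the total carbon mass by the basal calibrated age
itself: the cal BP scale of the basal date spans peat initiation to
present for the purposes of this long-term mean, and this convention is
the one that reproduces published worked values exactly (22.6 kg m^-2
over 1255 yr gives 18.0 g C m^-2 yr^-1; adding the 67-yr surface offset
would not). Its sigma propagates the basal-age sigma only; the stock is
treated as exact. `rerca()` uses calendar denominators `coring_year -
horizon_year` (67 and 117 yr for a 2017 core), locates the horizon depth
by inverse interpolation of the ensemble, and interpolates linearly within
a partially covered increment; its uncertainty comes from the ensemble's
95% depth interval. RERCA and LORCA are reported side by side but never
compared programmatically — surface peat has undergone far less
decomposition than older peat, so the two rates are not commensurable, and
every report repeats that caveat.

# Tree biomass

Ring widths (Tucson .rwl, 0.01 mm units, `999`/`-9999` terminators — the
two dominant dialects) are read per measured radius; `combine_radii()`
averages radii sharing an id prefix *before* any biomass conversion,
because DBH is a single physical quantity per stem. `dbh_series()` doubles
the cumulative mean-of-radii width and rescales multiplicatively so the
final year equals the measured field DBH, absorbing bark thickness and
missed-pith bias that ring measurements cannot see; locally absent rings
are retained as zero increments.

Aboveground biomass is a sum of power-law components
$m = \beta_1 D^{\beta_2}$ (kg, D in cm). The shipped
`default_allometry()` carries generic boreal-conifer magnitudes and an
explicit provenance string stating it is a development default:
published, site-appropriate coefficients must be injected (via
`allometry_set()` or the config file) for scientific use, and all tests
requiring exact numbers inject known coefficients. Belowground biomass is
evaluated with every configured root equation (functions of DBH or of
AGB); the central value is their mean and the reported range their
min/max, a convention labelled as such in outputs since published root
estimates rarely identify one canonical equation. Tree carbon is 0.50 of
total biomass (configurable). Census stems below the 1 cm DBH protocol
limit are rejected with a log notice.

# The synthetic-site generator

`generate_core()` and `generate_trees()` forward-simulate everything the
pipeline consumes, with the truth retained, so every stage has a recovery
test with no external data. The three presets (`cas0`, `cas50`, `cas100`)
encode a paludification gradient fixed at design time by closed-form
arithmetic from the study conditions they emulate: organic layers of
38/69/95 cm; basal ages 1255/7667/7522 cal yr BP; a last fire at 175–177
cal yr BP capping the profile at 24–26 cm; a fast Sphagnum acrotelm
(deposition times ~3–4 yr cm^-1, OM density 0.075–0.09 g cm^-3, hence CAR
above 100 g C m^-2 yr^-1 and a 1950-present RERCA near 120 g C m^-2
yr^-1) over dense woody peat (0.11–0.18 g cm^-3, CAR below ~12, below 5
in the mid-core ligneous zone of the two thicker profiles); total stocks
of 22.7/46.0/66.0 kg C m^-2; and 20-tree even-aged cohorts established in
1839/1839/1838 CE with mean DBH targets 10.0/9.1/5.6 cm. Noise defaults
are study-like: 14C lab sigmas of 45–69 yr, 5% CV on 210Pb activities,
10% CV on ring widths; one `noise_scale` multiplier scales them jointly.

Two generator conventions keep the noise-free limit exactly invertible:
the remaining unsupported 210Pb inventory below the deepest measured
increment is assigned to that increment (so the CRS sum equals the true
inventory at every boundary), and at `noise_scale = 0` the 14C horizons
are emitted as exact known-age entries, since a zero-sigma radiocarbon
measurement is not meaningful. The 210Pb profile is measured to 30–32 cm,
a few centimetres past the dateable range, so the supported level can be
estimated from a genuinely asymptotic tail.

What the generator does *not* emulate — and what passing recovery tests
therefore do not establish about real cores — includes: decomposition
dynamics and any decay correction of apparent rates (rates here are
"apparent" by construction), compaction history (segments specify final
densities directly), calibration-curve plateaus and multimodal calendar
posteriors (the synthetic curve is monotone and near-identity), age
reversals from reworked macrofossils, within-increment density
heterogeneity, and stand mortality or recruitment (the cohort is fixed;
the census contains exactly the cohort trees, so synthetic stand density
is not field-realistic).

# Problem sizes and numerical conventions

Defaults: 1-yr calibration grid; 2000 ensemble iterations (tests use
200–800 for speed; the acceptance script uses the full 2000); rejection
budget 1000 redraws per iteration; CRS admission cutoff 150 yr;
charcoal threshold 1 fragment cm^-3 with 2 cm merge gap. Report tables
round half away from zero to one decimal while CSV outputs keep full
precision, so printed values match publication conventions without losing
testability. Degenerate inputs are handled explicitly: empty fire records
date nothing and warn; zero tree stocks flag ratios as undefined; zero
deposition times leave CAR undefined for that increment with a log
notice; an all-subthreshold charcoal profile yields an empty record, and
`postfire_stock()` then returns the total stock with a warning.

# Limitations

The age-depth model is an interpolator, not an accumulation-process
model: it cannot bridge hiatuses or down-weight outliers, and its
between-horizon uncertainty is driven entirely by the dated horizons.
LORCA and RERCA are apparent rates; converting them into net carbon
balance would require a decomposition model, which is out of scope. The
default allometry is a placeholder by design. The comparison module
propagates no uncertainty into ratios beyond reporting component sigmas
side by side.
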