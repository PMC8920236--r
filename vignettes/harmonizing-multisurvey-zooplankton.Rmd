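---
title: "Harmonizing multi-survey zooplankton monitoring data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing multi-survey zooplankton monitoring data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zoopint)
library(dplyr)
```

## The problem

Estuarine zooplankton monitoring programs run for decades under independent
management. Each program decides which taxa to count, at what taxonomic
rank, for which life stages and size classes, and those decisions change:
species are added to counting lists (sometimes years after they invade),
genus-level categories are split into species mid-series, and rarely-seen
groups are counted by one program only. The raw union of such tables is
unusable for community analysis — apparent differences in composition and
diversity across surveys or through time are dominated by counting
decisions, not ecology.

`zoopint` makes these data comparable. This vignette documents the model
behind each step, the tunable parameters and their defaults, what the
bundled simulator does and does not emulate, and the design choices made
where the problem left room.

## Data model

The counting unit is a **category**: a scientific name on a fixed six-rank
ladder (Phylum > Class > Order > Family > Genus > Species) combined with an
opaque life-stage label, within a size class (Micro/Meso/Macro). Intermediate
ranks (suborders etc.) are deliberately out of model: survey taxa lists are
published at these six ranks, and a fixed ladder makes "lowest common rank"
well defined. Life stages are compared by exact string; each
(taxon, life stage) is an independent analysis unit.

Taxa lists attach validity years to each category (`StartYear`, open-ended
`EndYear`, and an optional `RestartYear` for categories removed and later
re-added — the intervening years are treated as not counted, the only
reading consistent with re-addition). `IntroYear` records the introduction
year of non-natives. Validity is tracked at year granularity, matching how
the source programs document their list changes.

A crucial convention, taken from how the source programs actually count: a
higher-rank category ("*Tortanus* spp.", an "other" bin) **excludes** taxa
counted separately at lower ranks in the same survey. So a bin plus its
split-off species sum exactly to the clade — this is what makes rollup
summation correct and double-count-free.

## Standardization

`read_survey()` maps each survey's dialect (column names, wide or long
layout, species codes, reporting units) onto a standard long schema; unit
conversions are multiplicative factors in the survey descriptor (e.g.
×1000 for counts per litre). `bind_and_split()` assigns
`SampleID = "{Source} {Station} {Datetime} {SizeClass}"` — unique and
human-auditable; nothing in the source schemas prescribes a construction —
and splits into an environment table (one row per sample; fields a survey
does not measure are `NA`) and a catch table, joinable on `SampleID`
without loss.

Surveys sometimes recorded CPUE = 0 in years before a category entered
their counting list. Those abundances were unknown, not zero, so
`zeros_to_na()` recodes them `NA` — except for non-native taxa before
their introduction year, where the true abundance really was zero and the
0 is kept. Nonzero values are never touched.

`sampling_effort()` summarizes a program's intensity as the mean number of
station visits per station per month, averaged to a yearly or monthly
timestep. Only station-months with at least one sample enter the means:
a station never visited in a year says nothing about the effort expended
at the stations that were, and this reading makes "two visits a month"
report an effort of exactly 2.

`qc_flowmeter()` screens sampled volumes before they enter CPUE. A volume
is flagged when its log deviates from the group median (same survey, size
class and station — or date, selectable, since both groupings are
defensible) by more than 3 MADs; the MAD is floored at 0.01 log units so a
group of near-identical volumes does not flag trivial jitter. Flagged
volumes are replaced by the mean of unflagged volumes in the group; groups
too small to judge (< 3) are screened against survey-wide statistics, and a
flagged volume with no donor is set missing and logged un-imputable. The
threshold is a screening choice, not an estimate of instrument error, and
every replacement is logged.

## Taxonomic harmonization

### Community mode

For each category *x*, `plan_community()` walks up the rank ladder from
*x*'s own rank and selects the lowest rank L whose ancestor-of-*x* is a
category in **every** survey in scope (life stage matching exactly,
validity intersecting the requested year range). All categories in that
clade map to a single summed group at L; categories with no such rank are
dropped as orphans. A survey is credited with a clade only when it carries
the bin at exactly that name and rank — a taxa list cannot certify that an
enumeration of species is exhaustive, but the presence of the "other" bin
guarantees clade coverage by construction.

`apply_plan()` operates strictly within each sample (data from different
samples are never aggregated): group CPUE is the sum of constituent CPUEs
present in that sample, dropped categories are removed, and each input
record contributes to exactly one output row or is dropped.

Missing constituents pose a genuine ambiguity: a recorded 0 is knowledge,
a recorded `NA` (from the zero-recoding above) is ignorance. The default
sum treats `NA` as not-counted (`NA + 2 = 2`), going `NA` only when every
constituent is unknown — summation must not destroy known catch that the
recoding deliberately preserved. The strict alternative (`na_rule =
"propagate"`) poisons a group on any unknown constituent, for analyses
where partial sums would bias comparisons; the choice is exposed because
either convention is defensible.

### Conservation as a validity check

Harmonization only relabels catch within a sample, so the per-sample total
CPUE must be invariant up to the orphans. `validate_conservation()` fits
an ordinary least-squares regression (with intercept; plain, unadjusted
R²) of harmonized on raw per-sample totals, and separately checks exact
equality after excluding dropped categories from the raw side. On data
with no orphans the regression is the identity with R² = 1 to machine
precision; with orphans, the per-sample difference equals exactly the
dropped catch. The `community` CLI subcommand fails (exit 3) if this check
is violated, because a violation can only mean a defect in the plan or its
application.

### Taxa-of-interest mode

For users querying particular taxa rather than whole communities,
`plan_taxa_of_interest()` builds an "All *X*" group per requested taxon by
summing every category inside the clade in each survey, and **retains**
the constituents. The All-group is comparable across surveys, but
organisms in summed groups appear twice, so the plan is flagged
non-exclusive and its output must not feed multivariate or community-level
analyses. On any sample, the All-group equals the community-mode group at
the same rank — the two summation paths are checked against each other in
the test suite.

### Correcting resolution changes through time

`time_correct()` reduces each survey's list to the categories counted in
every year of the analysis window — the least-common-denominator idea
applied through time. Applied alone this would discard every species that
invaded mid-window, so an `intro_lag` (years) retains any introduced
species first counted within the lag of its introduction year; `Inf`
retains all of them. The default lag is 0 (no exception) because the right
tolerance depends on how promptly the analyst believes programs added
invaders. When both corrections are requested the time correction runs
first, then the cross-survey plan is built on the reduced lists — coarsen
in time, then across surveys.

## Physical and derived quantities

- **Salinity.** `ec_to_salinity()` implements the Practical Salinity
  Scale 1978 at atmospheric pressure (valid for S in 2–42) with the
  Hill et al. extension below 2, which pins S(0) = 0 and leaves a
  discontinuity of at most ~3·10⁻⁴ at the branch point. Temperatures are
  applied as supplied, the convention of the conversion used by the source
  data pipeline; at field-probe accuracy the distinction between
  temperature scales is immaterial. Field probes report specific
  conductance (compensated to 25 °C), so the default first converts back
  to in-situ conductivity with the standard 1.91 %/°C linear compensation;
  pass `specific_conductance = FALSE` for raw conductivity. Inputs are
  mS/cm. Values above 42 are returned with a warning.
- **Volume and CPUE.** Volume = flowmeter counts × flowmeter constant ×
  net mouth area (m³); constants are per-survey configuration since they
  are instrument properties. CPUE = organisms counted / subsample
  fraction / volume, in individuals m⁻³.
- **Biomass.** Carbon concentration = CPUE × literature carbon mass per
  individual (µg) for the taxon/life stage; taxa without a literature value
  get `NA`, not 0, so literature gaps stay visible.
- **Counting precision.** Under Poisson counting the relative 95% CI
  half-width of a count n is 1.96/√n (400 organisms → ±10%, the design
  target of the divider-tray protocol); 2·CV gives the same number at
  n = 400, and the exact chi-squared interval is available as an option.
  The aliquot protocol's concentration band (200–400 ml⁻¹) and aliquot
  range (5–20) bound counts between 1,000 and 8,000 organisms per sample.
- **Gear flags.** Meso (net) and micro (pump) gears overlap in sampled
  taxa; `flag_undersampled()` compares total CPUE per taxon over matched
  station/dates sampled by both, flagging the losing gear when the ratio
  leaves `[threshold, 1/threshold]`. The default threshold 0.75 retains a
  taxon whose net catch is 80% of its pump catch — the near-tie worth
  keeping — while flagging the order-of-magnitude disparities typical of
  genuinely mis-matched gear. Flags mark records; nothing is deleted.

## The simulator

`simulate_program()` exists so that every pipeline stage is testable with
known truth and no external data. Per survey, station visit and size
class, it draws per-taxon realized densities — mean-corrected lognormal
around a configured mean (individuals m⁻³), optionally with a seasonal
log-sine term — aggregates them into the survey's active categories under
the exact bin-exclusion and taxa-list censoring semantics above, draws a
lognormal sampled volume and a Poisson organism count at the configured
subsample fraction and gear efficiency, and emits each survey's table in
its own dialect (long, wide, or species-coded) plus a truth table.
Determinism: per-survey seeds derive from the run seed, so one seed fixes
all output bytes.

Canned scenarios (`make_resolution_scenario()`) encode the situations the
harmonization was built for: the split-genus case, a single-survey orphan
phylum, a mid-series genus-to-species promotion, an introduced species
first counted one year after arrival, and a `recovery` calibration design.
The default scenarios sample three stations monthly with lognormal sigma
0.4 and densities of 5–80 individuals m⁻³ — variability and abundances in
the range typical of estuarine copepod monitoring. The recovery design
instead uses sigma 0.15, no seasonality, unit efficiency and ~100–400
expected organisms per count: a calibration check should isolate estimator
bias from sampling noise, and at these settings the Monte-Carlo standard
error of a 1,000-sample mean is ~0.5%, so the 2% recovery criterion sits
about four standard errors out.

What the simulator does **not** emulate: spatial structure and advection,
overdispersed (contagious) counts beyond the lognormal mixing, gear
selectivity as a function of body size, observation error in environmental
variables, or realistic upper-estuary species composition. Passing tests
therefore demonstrate that the *integration machinery* is correct —
standardization is lossless, rollups conserve catch, censoring and
introduction conventions are honoured, known efficiencies are recovered —
not that any ecological model of a real estuary is.

## Numerical choices and degenerate inputs

- Rank ties: if a survey counts a taxon at two ranks simultaneously
  (species and its bin), the resolution credited is the lowest (finest).
- Conservation tolerance: exact-equality checks use a 10⁻⁹ relative
  tolerance, far above double-precision summation error at realistic
  sample sizes but far below any real discrepancy.
- Empty inputs: `bind_and_split()` of zero records returns two empty
  tables with full headers; a plan over an empty survey set or an empty
  size class is an error, not an empty plan.
- CSV conventions: UTF-8, RFC 4180, missing values as literal `"NA"`
  (the source ecosystem's convention); doubles round-trip exactly.
- The regression in `validate_conservation()` computes R² directly from
  residual and total sums of squares (undefined, `NA`, when all raw totals
  are equal).

## Problem sizes used in the checks

The test suite and acceptance script run the conservation and recovery
checks on ~1,080-sample simulations (two to three surveys, five stations,
monthly sampling over six to nine years) and the plan-vs-brute-force
comparison on 200 random instances of up to 5 surveys and 40 categories
over a 189-node taxonomy — sizes chosen so each property is exercised well
past the scale where bookkeeping errors would surface, while the whole
suite runs in a couple of minutes on one CPU.

## Known limitations

- The six-rank ladder cannot express suborder-level counting categories;
  such categories must be mapped to the nearest modeled rank upstream.
- Nomenclature is taken at face value: no synonym resolution against
  external taxonomic services.
- `time_correct()` keys the intro-lag exception on the list's `IntroYear`;
  absent introduction metadata, an invader is treated as native and may be
  discarded by the temporal correction.
- The undersampling comparison assesses reported data, not gear catch
  efficiency; its flags inherit any laboratory sieving conventions embedded
  in the source data.
- Salinity conversion targets the practical scale only; no TEOS-10
  absolute salinity.
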