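---
title: "The ground-sensor data pathway: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ground-sensor data pathway: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenosense)
```

Long-running ground-based deployments — phenology towers carrying paired
pyranometers and quantum (PAR) sensors, and understory networks of
temperature/humidity nodes — produce data that arrives dirty: logger
exports in vendor-specific layouts that change without notice, records
structurally corrupted by sensor faults or radio interference,
timestamps wrong by whole hours because a field laptop was reconfigured,
and stretches of silence where a node died. `phenosense` implements the
pathway from those raw files to analysis-ready products: validated
ingestion, sun-time QA, physical-range and sky-condition filtering,
coverage-aware aggregation, vegetation and micro-climate indices, and
interpolated spatial fields with honest reliability layers. This
vignette explains the models behind each stage, the parameters that
matter, and the choices we made where the design was genuinely open.

## Time is local standard time, everywhere

Field equipment is configured to local *standard* time with
daylight-saving switching disabled, and the library follows suit: no
function ever applies a DST rule. Internally timestamps are `POSIXct`
in the `"UTC"` zone purely so that R's timezone machinery cannot
interfere; the clock value *is* the local standard clock value.
Records are stamped at the **start** of each sampling interval, and
aggregation buckets are labelled by bucket start, consistently.

## Solar geometry and clock-shift detection

Timezone and DST misconfigurations displace timestamps by whole hours.
Sun time exposes this. We compute solar position with the standard
low-precision NOAA/Spencer equations (Fourier-series declination and
equation of time; zenith from the spherical triangle), accurate to a
few hundredths of a degree in declination and well under two minutes in
sunrise time — orders of magnitude tighter than the whole-hour question
being asked. `expected_sunrise()` uses the conventional −0.833°
altitude for the refraction-corrected horizon and flags polar day/night
instead of erroring.

Observed sunrise is detected in the incoming radiation series
(`detect_observed_sunrise()`) as the first timestamp at which a 3-point
smoothed irradiance exceeds `max(5 units, 2 % of the day's maximum)`
and stays above it for 2 consecutive samples. The dual threshold is
deliberate: an absolute floor rejects sensor zero-offset noise, while
the relative term keeps dim (but not overcast) days usable. Both knobs
and the persistence window are exposed as arguments.

`estimate_clock_shift()` takes the **median** of the per-day
(observed − expected) offsets over at least 3 usable days and rounds it
to the nearest whole hour. The median, not the mean: overcast mornings
can only bias a day's detection *late*, and a robust centre ignores
them. The estimate is refused when the per-day offsets disperse more
than 30 minutes (median absolute deviation around the whole-hour
candidate) — beyond that the premise of a single constant shift is not
supported by the data. Detection is one-sided late by construction
(threshold crossing + persistence + sampling resolution), typically
10–20 minutes at 15-min sampling; since the method only ever rounds to
whole hours this bias is immaterial, and the same reasoning is why
sub-hour hardware drift is *reported* (as dispersion) but never
corrected.

## Ingestion: quarantine, never repair

Logger exports are parsed against a registry of **dialects**
(delimiter, header, timestamp format, layout, missing-value
sentinels). Two exemplar dialects ship built in — a wide single-node
tower export and a long multi-node wireless export — standing in for
the vendor layouts that in practice vary; `register_dialect()` adds
more. `sniff_format()` only ever returns a *uniquely* consistent
dialect; zero or multiple matches raise explicit errors listing which
check failed per dialect, because a guessed format is how silent
corruption enters an archive.

Malformed records (wrong column count, unparseable timestamp or value,
unknown channel, timestamp running backwards) are quarantined whole,
never patched: each appears in the `ingestion_report` with its record
index and cause, and the accounting invariant
`accepted + quarantined == physical records` holds for every input.
Missing-value sentinels are accepted but become explicit `gap` records.
Every resulting table carries provenance (source file, dialect, user,
options, timestamps of each later operation), and `merge_tables()`
resolves duplicate keys first-wins with every conflict reported.

## Filters and aggregation

- **Range check** — values outside the channel's physical range from
  the sensor specification sheet (RH 0–100 %, PAR 0–2,500 µmol m⁻² s⁻¹,
  shortwave 0–1,280 W m⁻², rain ≤ 1,270 mm h⁻¹, soil moisture 0–100 %
  VWC, air temperature −40–123.8 °C) are flagged `out_of_range`. We use
  the widest vendor range per channel so either vendor's valid data
  passes; narrower specs can be supplied. Checks change flags only,
  never values.
- **Midday window** — half-open `[10:00, 14:00)` by default, the
  operational choice for index derivation near maximum sun elevation.
  Half-open so a boundary sample can never be counted twice.
- **Cloud filter** — a record survives only if a *simultaneous*
  incoming-PAR reading is strictly above 900 µmol m⁻² s⁻¹
  ("more than", hence `>` not `≥`). The tower's `par_in` applies to
  the whole deployment, so partnering is by timestamp; records with no
  partner are dropped and counted rather than passed through.
- **Aggregation** — hourly/daily/monthly means, extremes or counts,
  emitted only when at least `min_coverage` (default 0.75) of the
  bucket's expected samples are present; under-covered buckets are
  explicit gaps. A near-empty daily mean is worse than a missing one.
- **Gap report** — maximal runs of missing samples per (node, channel)
  on the expected grid, with per-node downtime totals, as a
  network-health proxy.

## Derived products

**Footprint.** Radiation flux sensors view up to ~85° from nadir, so a
sensor `h` metres above the surface integrates a ground disc of radius
`tan(85°)·h ≈ 11.43·h` — the basis for mounting-height decisions and
for the spatial coverage radius (at 5 m above the canopy, ≥ 50 m).

**Broadband NDVI/EVI2.** With paired pyranometers (~300–1,100 nm) and
PAR sensors (400–700 nm) above and below, the PAR-band reflectance is
`ρ_PAR = PAR_out / PAR_in` and the NIR band is approximated by the
energy difference, `ρ_NIR = (SW_out − PAR_out^W) / (SW_in − PAR_in^W)`,
with PAR converted to W m⁻² by the quantum factor 4.57 µmol J⁻¹ used
package-wide (consistency between synthesis and derivation is what
matters; the constant's absolute accuracy is secondary). Then
`NDVI = (ρ_NIR − ρ_PAR)/(ρ_NIR + ρ_PAR)`; with no blue band available,
EVI is realised as the two-band variant
`EVI2 = 2.5 (ρ_NIR − ρ_PAR)/(ρ_NIR + 2.4 ρ_PAR + 1)`. Reflectances are
only defined above an incoming floor (`par_in` > 100 µmol m⁻² s⁻¹ and
`sw_in` > 50 W m⁻²) because the ratios explode near dawn and dusk;
out-of-bound ratios are flagged, not clipped. Indices are computed on
filtered *instantaneous* records and then averaged per day
(mean-of-ratios): the alternative, indices of daily-mean fluxes, mixes
sun angles within the day and was rejected.

**LAI.** NDVI→LAI conversion is ecosystem-specific, so the package
ships *no* built-in factors: the user supplies either a linear factor
(`LAI = c·max(NDVI, 0)`) or a saturating Beer-law form
`LAI = −(1/k)·ln((NDVI_max − NDVI)/(NDVI_max − NDVI_min))`, with NDVI
at or above saturation clipped and flagged.

**VPD.** Magnus saturation vapour pressure
`e_s = 0.6108·exp(17.27 T/(T + 237.3))` kPa and
`VPD = e_s (1 − RH/100)`.

## Spatial fields and reliability

Node coordinates live in a local planar frame (metres, x east, y
north). Three deterministic layout constructors mirror field practice:
transects (gradients, ecotones), concentric rings around a point of
interest such as a flux tower ("star"), and regular grids.

Scalar fields are interpolated by inverse-distance weighting with
exponent `p = 2` and no search cutoff — the simplest scheme that is
exact at the nodes and provably bounded by the input extremes (a convex
combination). No claim of geostatistical optimality is made; the
interpolation is pluggable and kriging was deliberately left out.

Every field comes with a co-registered **reliability** layer: per cell,
the fraction of *installed* sensors within the coverage radius
(default: the footprint radius for the node's mounting height) that are
currently *working*; 0 where no sensor is in range at all. The
definition makes the visual contract testable: reliability is 1 under
full coverage, drops cell-wise monotonically as sensors fail, and
`frame_sequence()` preserves the animation cadence through total
outages (frames with undefined values and zero reliability rather than
missing frames).

## The synthetic generator, and what passing tests mean

`make_deployment_series()` emulates the study conditions end to end:
clear-sky shortwave as `peak · cos(zenith)` (default peak
1,000 W m⁻², a representative clear-sky maximum; no aerosol model —
sufficient to exercise sunrise detection and cloud filtering, which is
its job), PAR as 45 % of shortwave energy, 15-minute sampling, canopy
reflectances constructed by *inverting* the NDVI formula
(`ρ_PAR = 0.05` fixed, `ρ_NIR` solved from the prescribed trajectory)
so the derivation chain has exact ground truth, a logistic seasonal
green-up as the default trajectory, overcast days at probability 0.2
(irradiance scaled to 5–25 % of clear sky, below the 900-µmol cut at
midday), sinusoidal air temperature (25 ± 6 °C peaking at 15:00) with
anti-phase humidity, and noise following the sensor accuracy sheet:
multiplicative for radiation (5 % default), additive for temperature
(0.3 °C) and humidity (2.5 %RH). Defects are injected exactly as
specified: whole-hour shifts, per-sensor failure windows (records
absent, as from a dead sensor), and structural corruption of written
logger records at a given rate.

What the generator does *not* emulate matters for interpretation:
aerosols, partial cloud within a day, spectral (rather than broadband)
canopy behaviour, rainfall and wind, sensor drift and fouling. Passing
the round-trip tests therefore demonstrates that the *pipeline* is
lossless and self-consistent — that filters, conversions and
aggregations introduce no error of their own — not that broadband NDVI
tracks any particular field ecosystem, which is a property of sensors
and canopies, not software.

Problem sizes in the test suite (7-day deployments, a handful of nodes,
1,000-record ingestion fixtures, 140 seeded shift-recovery trials) were
chosen as the smallest sizes at which the properties under test are
non-trivial and stable across seeds.

## Numerical and degenerate-input choices

- Sentinels (`-9999`, `NAN`, `NaN`) become `gap` records; they are
  never interpreted as numbers.
- `ndvi()` is `NA` when `ρ_NIR + ρ_PAR = 0`; reflectances are `NA`
  below the incoming floor or when the NIR denominator is ≤ 0, each
  with a status naming the reason.
- IDW at a cell within 1 nm of a node returns that node's value
  exactly (no 0/0).
- Polar day/night: flagged conditions, all-zero or all-positive
  irradiance series, never errors.
- Duplicate-key merges: deterministic first-wins plus a conflict
  report.
- Aggregation of an empty or all-flagged table returns an empty
  result, not an error.

## Known limitations

Whole-hour shifts only — genuine drift needs GPS/NTP discipline at the
logger. The broadband NIR approximation inherits the pyranometer's
upper wavelength cut. Reliability is a coverage ratio, not an error
model. The planar frame ignores geodesy, which is fine at the ≤ 1 km
scale of these deployments.
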