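---
title: "Mapping summer heat stress with ssimap: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping summer heat stress with ssimap: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssimap)
```

`ssimap` maps perceived summer heat stress: it evaluates the Summer Simmer
Index (SSI) over co-registered temperature and humidity rasters, classifies
the result into ordered thermal-comfort categories, builds those rasters
from station observations when only point data exist, and apportions zone
populations across the resulting stress classes. This vignette is the
package's own account of the underlying models, the parameters that matter,
and the design decisions taken where more than one defensible choice
existed.

## The index and its classification

The SSI is an apparent temperature on the Fahrenheit scale,

$$\mathrm{SSI} = a\,[T_a - (b - c\,U_r)(T_a - p)] - o,$$

with frozen default constants $a = 1.98$, $b = 0.55$, $c = 0.0055$ per
percent humidity, pivot $p = 58$ °F and offset $o = 56.83$. The constants
live in `ssi_constants()` and are injected into `compute_ssi()` rather than
inlined, so tests can verify the defaults and any deliberate override is
explicit. Two structural properties follow directly from the formula and
are asserted as tests over a dense $(T_a, U_r)$ lattice: the index is
strictly increasing in temperature for every humidity
($\partial\,\mathrm{SSI}/\partial T_a = a(1 - b + c\,U_r) > 0$), and the
humidity effect changes sign at the 58 °F pivot — moist air feels hotter
above it, cooler below it, and at exactly 58 °F humidity has no effect
($1.98 \times 58 - 56.83 = 58.01$).

Units: inputs may be Celsius or Fahrenheit and the result may be displayed
in either, but the index itself — and therefore classification — is always
computed on the Fahrenheit scale. The Celsius display conversion is the
plain affine map applied to the index value; it is cosmetic, and
`classify_grid()` expects Fahrenheit-scale input.

The classification scheme is an ordered partition of the SSI line into
half-open intervals $[\ell, u)$ with bounds 70, 77, 83, 91, 100, 112, 125,
150 °F. Two interval-edge policies had to be decided because the published
interpretation table leaves them open:

* **Below 70 °F.** The table starts at 70, but interpolated highland or
  cool-season pixels legitimately fall below it. Rather than failing or
  silently merging them into the lowest class, an explicit code-0 "Below
  scale" category covers $(-\infty, 70)$.
* **Exactly 150 °F.** The printed intervals are "125 ≤ SSI < 150" and
  "150 < SSI", leaving 150 itself unassigned. `ssimap` closes the top
  category's lower bound, assigning 150 to "Deadly Hot", so the partition
  is total. This is a documented deviation from the printed table.

Two of the eight intervals share the label "Cold" and two share "Extremely
Hot"; all eight keep distinct integer codes. A six-label summer legend
(Cold, Cool, Comfortable, Warm, Hot, So Hot) is provided as an alternative
labelling of the same codes. No authoritative mapping from the eight
intervals onto the six labels exists, so the default (codes 0–1 → Cold,
2 → Cool, 3 → Comfortable, 4 → Warm, 5 → Hot, 6–8 → So Hot) is a
configuration, overridable through `ssi_scheme("sixclass", six_labels =)`.

Humidity outside $[0, 100]$ is rejected with an error counting the
offending cells; silent clamping would hide corrupted inputs. A `clamp_rh`
flag (CLI `--clamp-rh`) exists for rasters with small interpolation
overshoots, and the full pipeline uses it for the humidity surface, whose
kriged values can stray a fraction of a percent outside the physical range.

## Raster model and map algebra

A grid is a numeric matrix (row 1 northernmost, pixel-is-area) with a
GDAL-style affine geotransform, a CRS identifier string, and a nodata
sentinel (−9999 for continuous layers, 255 for categorical). Rotated
geotransforms are rejected: interpolation products are axis-aligned, and
supporting rotation would complicate every downstream operation for no
practical gain.

Two deliberate strictness choices:

* **No implicit resampling.** `ssi_grid_map()` refuses misaligned inputs
  (shape, CRS, or geotransform drift beyond 10⁻⁶ of a pixel) and names the
  differing component. Auto-warping would silently smooth humidity extremes
  — exactly the values a heat-stress analysis cares about. Re-gridding is
  an explicit external pre-step.
* **Nodata propagates.** An output cell is nodata wherever either input is
  nodata, with no interpolation across gaps.

Area summaries (`class_area_fractions()`) weight cells by $|dx|\,|dy|$ in
projected CRSs. For geographic (degree) grids each row is weighted by the
cosine of its center latitude — sufficient at city scale, where the error
relative to full ellipsoidal cell areas is far below the classification
uncertainty; this approximation is the documented accuracy note.

Rasters are exchanged as ESRI ASCII grids with a JSON sidecar carrying the
CRS and a dtype tag (float vs uint8), and categorical layers carry a JSON
legend sidecar so a reloaded map knows its scheme. Values are written at 17
significant digits: the text format then round-trips IEEE doubles exactly,
which is what makes the file-based CLI pipeline bit-identical to the
in-process pipeline under a fixed seed. (A 32-bit float storage convention
was considered and rejected: in a text format it buys nothing and would
break exact pipeline equivalence.)

## Station-to-surface interpolation

Temperature correlates strongly with altitude, so the interpolation model
uses elevation as a covariate: **regression-kriging**, i.e.

$$z(s) = \beta_0 + \beta_1\,\mathrm{elev}(s) + \varepsilon(s),$$

an ordinary-least-squares drift on elevation (for temperature, $\beta_1$ is
the empirical lapse rate) followed by ordinary kriging of the residuals
$\varepsilon$. This uses the covariate for the same purpose as cokriging
with a DEM — borrowing strength from topography where stations are sparse —
while remaining fully specifiable: cokriging additionally requires a
modelled cross-covariance that no available source pins down. The choice is
a deliberate, documented substitution.

The residual model is estimated in two steps. The Matheron estimator bins
station pairs by separation distance,
$\gamma(h) = \frac{1}{2N(h)}\sum (z_i - z_j)^2$, with 12 lags by default up
to half the station bounding-box diagonal (beyond that, pair counts thin
out and the estimator is unstable). A parametric model — exponential by
default, spherical and Gaussian available — is then fitted by weighted
least squares with pair counts as weights, using box-constrained
quasi-Newton optimisation (nugget, partial sill ≥ 0, range > 0) from three
range starts to avoid the local minima typical of variogram objectives.

Prediction solves the ordinary-kriging system of $n + 1$ equations with a
Lagrange multiplier enforcing unit-sum weights, over the 16 nearest
stations by default (a global solve when $n \le 16$). Numerical behaviour
at the edges is pinned down explicitly:

* weights always sum to 1 to within 10⁻⁹ (asserted property);
* with a zero nugget the predictor is exact at station locations;
* duplicate station coordinates — which make the system singular — are
  averaged into one record with a warning at construction time;
* a numerically zero variogram (noiseless residuals, e.g. stations exactly
  affine in elevation) short-circuits to the pure drift surface rather
  than attempting a singular solve;
* kriging weights are reported in station order, not distance order, so
  results are deterministic and directly comparable to an independent
  dense solve of the same system (the cross-check used in tests).

Distances are planar in the working CRS; geographic coordinates must be
projected first. Humidity surfaces use the same machinery, with the
elevation drift on by default (humidity is also elevation-structured in
coastal-mountain terrain); a config flag disables it.

## Population exposure

Zones are population-bearing polygons in the grid's CRS. Cell membership is
decided by a cell-center-in-polygon test (even-odd ray casting, so holes
and multipolygons need no special casing) rather than exact polygon
clipping: it is deterministic, fast, and at the package's default
resolutions the boundary-cell error is small; the caveat matters only when
zones are narrow relative to the pixel size.

Each zone's population is spread uniformly within the zone (areal
weighting — the standard assumption when no finer dasymetric data exist)
and distributed across categories in proportion to covered valid-cell area.
Integer counts come from largest-remainder rounding with ties broken by
ascending category code, so per-zone counts sum *exactly* to the zone
population and tables are reproducible bit for bit. Zones covering no valid
cell contribute their whole population to an explicit "Unclassified" row
rather than disappearing. Both population shares and area shares are
reported side by side — they answer different questions (who is exposed
vs. how much land is affected), and conflating them is a common reading
error with this kind of table.

## The synthetic world

The generator builds a miniature Mediterranean-like scenario: a coastal
plain rising to inland mountains (south-to-north elevation ramp plus
band-limited relief noise), summer temperature decreasing with elevation at
the standard environmental lapse rate (−6.5 °C/km) from a 30 °C sea-level
base, humidity decreasing with elevation (75 % at the coast to high-30s %
in the highlands, mirroring the humid-plain/dry-highland contrast of such
regions), stations sampled at grid cells without replacement, and a
rectangular tessellation of zones whose populations decay exponentially
with mean elevation (scale height 300 m) — residents concentrate on the
plain.

Spatially correlated residuals are produced by FFT circulant-embedding
spectral synthesis with an exponential correlogram, matching the
interpolation module's default variogram family so that recovery is
well-posed; negative embedding eigenvalues are clipped and the field is
empirically re-normalised to zero mean and the configured standard
deviation. Everything is a pure function of the config seed: generation
saves and restores the caller's RNG state, and equal seeds give
bit-identical bundles.

Default parameters and why:

| parameter | default | rationale |
|---|---|---|
| grid | 120 × 120 cells at 250 m | full pipeline in seconds; 30 m runs are a config choice, not a default |
| relief | 1500 m | plain-to-mountain contrast typical of a Mediterranean coastal city |
| base temperature | 30 °C | hot-summer lowland mean |
| lapse rate | −0.0065 °C/m | standard environmental lapse rate |
| humidity | 75 % base, −0.025 %/m | humid coast, dry highland (~37 % at full relief) |
| residual sd | 0.5 °C (temp), 2 % (RH) | station-scale microclimate noise |
| residual range | 15 km | see below |
| stations | 60 | a realistic provincial network density |
| zones / population | 16 / 10⁶ | enough zones for conservation tests at negligible cost |

The residual correlation range deserves a note. The generator is calibrated
so that the pipeline's classified map agrees with the truth-derived
classification on at least 90 % of cells at the default noise level — the
regime in which the workflow is meant to operate. That requires the
residual field to be *resolvable* by the station network: with 60 stations
on a 30 km domain (≈ 3.9 km spacing), a short-range residual (e.g. 5 km)
is irreducibly unrecoverable between stations — even kriging with the true
covariance parameters cannot reach 90 % agreement — whereas a mesoscale
15 km range (half the domain width) can. The default is therefore 15 km,
representing regional-scale residual structure (marine influence, synoptic
gradients) rather than sub-grid microclimate.

What the generator does **not** emulate: urban heat-island morphology (no
land-use term), anisotropy, non-Gaussian residuals, station siting bias
toward low elevations, temporal structure, and observation error distinct
from field noise (station values are exact reads of the truth surface).
Passing recovery tests on this world therefore demonstrates that the
estimators are correct and that the covariate logic works — not that
real-city accuracy will match the synthetic diagnostics.

## Problem sizes and runtime

The test suite and the acceptance script run the full pipeline on the
default 120 × 120 scenario (14 400 kriging targets per surface, two
surfaces, plus a drift-free comparison), grid–scalar equivalence on ten
200 × 200 random grids against literal per-cell loops, and the CLI chain on
30–40 cell-wide scenarios in subprocesses. The moving-neighborhood kriging
solver caches the factorised system per distinct neighbor set, which makes
the dense-grid solve roughly five times faster than a naive per-cell solve
at identical results.

## Known limitations

* The index uses temperature and humidity only — no wind, radiation, or
  acclimatisation terms; it is a summer heat-stress screen, not a complete
  thermal-comfort model, and it has no meaning for cold stress.
* Interpolation assumes a single linear elevation drift over the domain;
  inversions (valley cold pools) violate it.
* The variogram is isotropic and stationary.
* Areal weighting assumes uniform population density within a zone; with
  strongly heterogeneous zones the per-category counts inherit that
  assumption, and the `--majority` whole-zone assignment is a sensitivity
  check, not a fix.
* Geographic-CRS areas use per-row cosine-latitude weighting, adequate at
  city scale only.
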