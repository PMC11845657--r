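---
title: "flockr: methods, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{flockr: methods, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flockr)
```

This vignette documents the models behind each module, the tunable
parameters that matter (with units, defaults, and the reasoning behind
them), what the synthetic generator does and does not emulate, and the
design choices made where the problem was genuinely open. It states no
empirical results beyond what the test suite computes.

## 1. Ingestion, projection, smoothing

GPS tracks arrive as GPX or CSV (per-row: time, member id, lat/lon or
easting/northing). Geographic coordinates are projected to UTM (WGS84,
Krüger series, sub-millimeter accurate) so that distances and areas are
planar meters. The zone is chosen from the mean position of *all* samples
and every member is forced into it: group spans are kilometer-scale, and a
mixed-zone group would make within-group distances meaningless. Samples
spanning more than two zones abort with advice to override the zone
manually.

Each member's track is smoothed with a cubic smoothing spline per
coordinate against time. The penalty defaults to per-track **generalized
cross-validation**: GPS noise magnitude varies wildly with canopy and
terrain, so a fixed penalty has no principled value; an explicit override
is available (`smoothing = 0` is the interpolating limit). Members are
then resampled onto a common grid at `dt = 1` s covering the intersection
of their time ranges. The native 10 Hz rate adds noise, not information,
at marching speeds (~1 m/s ≈ 1 m per sample at 1 Hz, comparable to the
noise floor). Sampling gaps longer than `max_gap = 60` s are filled by the
spline but flagged in a mask that downstream features honor, so long
outages cannot fabricate kinematics.

## 2. Rest detection and movement periods

A member is resting when they stay within a **100 m² area for at least
120 s** — equivalently, average speed below ≈ 0.83 m/s, the boundary of a
very slow outdoor stroll. "Area" is operationalized as a bounding **disc**
(diameter 2·√(100/π) ≈ 11.28 m): the criterion should not depend on the
compass orientation of a resting huddle, which rules out squares and
bounding boxes; the choice is config-exposed. Detection marks every
timepoint covered by *any* qualifying window (maximal-window coverage),
then merges runs — this matches an exhaustive all-windows oracle in the
tests.

A **group rest** requires a nonempty common core: an interval during which
every member is inside one of their individual rests. Chained overlaps
without a common moment do not qualify (a rolling rest where someone is
always moving is not a group break). The group interval then spans from
the earliest member start to the latest member end — first-in to last-out.
Movement periods are the complement, trimmed by 30 s per side to cut
transition dynamics; with no rest found, the span is split into two equal
halves so cross-period features remain defined. Periods shorter than 120 s
after trimming are dropped (too short for windowed features).

## 3. The Path-Adapted Coordinate System

The group path is a smoothing spline through the centroid positions (or a
user-supplied route), pre-sampled densely at 0.1 m spacing with an
arc-length table. Foot points are computed by projection onto the dense
polyline; with 0.1 m spacing the arc-length and distance errors are far
below the 0.01 m contract. Nearest-point ties on self-approaching paths
(hairpins) are broken by **temporal continuity** — the candidate whose arc
length is closest to the member's previous foot point — preventing the
along-path coordinate from teleporting across a switchback. The lateral
sign comes from the cross product of the path tangent with the offset
vector: left of travel is negative.

Note one subtlety exercised by the tests: PACS is relative to the
**centroid path**, so if a formation's lateral offsets do not average to
zero, each member's PACS-x is their offset *minus* the formation mean.
Supplying the route as a predetermined path recovers route-relative
offsets exactly.

The centroid-heading transform (rotation by the centroid's instantaneous
velocity direction) is retained purely as the baseline for artifact
comparisons; frames with centroid speed below 0.3 m/s have no defined
heading and are masked. The acceptance suite asserts the qualitative
artifact claim — a member trailing a turn sweeps laterally in the baseline
with amplitude more than twice its PACS value, inflating intra-group
location entropy — but not any particular percentage, which is
data-dependent.

## 4. Feature families

**Velocity.** Speeds and acceleration magnitudes from central differences
on the smoothed grid (one-sided at the ends; lower phase error than
forward differences). Cross-member statistics use the **population**
variance: the group *is* the population at each timepoint. Acceleration
features carry a `low_confidence` flag — consumer GPS cannot resolve
acceleration reliably, and they are included for completeness only.

**Spatiotemporal.** Stretch index (mean distance to centroid), convex-hull
area, and Voronoi cells clipped to the hull by half-plane intersection —
the clipped cells partition the hull exactly, which the tests verify to
1e−9 against a Monte-Carlo rejection-sampling oracle and to 1e−6 relative
on 1,000 random frames. The length/width ratio and the spatial
exploration index are computed in PACS. Cross-period distribution
consistency uses, per member and PACS axis, the variance-ratio F statistic
(larger over smaller — the problem gives no natural numerator) and the
exact 1-D Wasserstein distance, averaged over period pairs.

**Clustering.** Per-frame DBSCAN, plus a hierarchical density method:
single linkage on mutual-reachability distances with the dendrogram cut at
the distance threshold and small clusters dissolved to outliers. No
HDBSCAN implementation exists in the available R stack, and at ≤ 9 points
per frame the stability-based cluster extraction of full HDBSCAN
degenerates anyway; the simplified method keeps the contract (density
clustering, outliers, membership confidence) with a confidence surrogate:
the ratio of the cluster's smallest core distance to the member's own,
capped at 1. Cluster consistency is the mean **adjusted Rand index**
between consecutive frames with outliers as singletons (the field names
the metric but not a formula; ARI is the standard chance-corrected
choice, and it is config-swappable). A small parameter grid
(min size {2,3} × threshold {5,10} m) emits separately-named features for
robustness.

**Leadership.** Headings are unit velocity vectors; samples below 0.3 m/s
are masked (direction is noise-dominated near rest). The directional
correlation `C_ij(τ)` is the mean dot product of member *i*'s heading with
member *j*'s `τ` seconds later, over a ±10 s lag grid at `dt` steps. The
maximizing lag is the delay; ties resolve to the smallest |τ| and exact
zeros contribute no edge. Node scores are mean delays over all partners
(the choice of "all" over "significant only" is deliberate: with ≤ 8
partners a significance filter would be noisier than the mean). Hierarchy
quality counts the fraction of edges pointing from higher to lower score,
and loops as strongly connected components with more than one node —
bounded and deterministic where raw cycle enumeration is neither.
Cross-period instability is the mean fraction of member pairs whose edge
state (absent / i→j / j→i) differs between two periods' graphs — a
transparent edit-distance operationalization, config-swappable.

**Regularity.** Location entropy is the Shannon entropy (base 2) of a
member's PACS positions histogrammed into 1 m bins inside a window
centered on their mean location; the default window is 100 m² (10 × 10
bins) and out-of-window frames clip to the border bins. The construction
is a distribution, so Shannon entropy of the normalized histogram is the
right functional (the sports literature's "approximate entropy of the
histogram" naming notwithstanding — sample-entropy variants apply to
series, not histograms). Bin edges must be shared across any comparison;
`series_entropy` accepts explicit shared breaks for that reason, and the
turn-artifact tests widen the window so that the baseline's ~30 m sweep is
measured rather than clipped.

Movement predictability fits a VAR on **first-differenced** positions
(positions themselves are integrated and non-stationary) over a rolling
window of 100 samples — 95 training, 5 forecast — advancing by the
horizon so forecasts never overlap. Order 1 by default, config-exposed.
Forecasts are re-integrated and scored as RMSE in position space. VARX
adds the other members' differenced positions as contemporaneous exogenous
regressors, with the observed exogenous path used over the forecast window
(the standard known-exogenous protocol) and automatic ridge stabilization
(flagged) on collinear inputs. Windows with singular fits are skipped and
counted.

**Doctrine.** Foot-march guidance: members 2–5 m apart (closed interval),
pace below 1.7 m/s (the outdoor "fast walk" boundary; doctrine pace is
≈ 1.1–1.3 m/s), breaks on a regular schedule. Break regularity is the
population SD of onset gaps and durations (tiny counts; a sample SD would
be undefined at n = 1). Column length is the PACS-y range per frame.

## 5. The synthetic generator

`simulate_march` states a world matching the study structure: 6–9 members
(default 8) marching a curvilinear waypoint route at 1.1 m/s (4 km/h
doctrine pace) in a staggered column (3 m along-path spacing, ±1.5 m
lateral), a designated leader steering by the route tangent, every
follower copying its influencer's realized heading at a configured delay
(default: leader → all at 2 s) blended with a formation-restoring pull
(gain 0.08 s⁻¹) under a bounded turn rate (1.5 rad/s), heading noise of
0.1 rad·s^(−1/2), scheduled halts (default: the doctrine schedule — 15 min
after the first 45 min, then 10 min every 50 min, truncated to the march),
and finally i.i.d. Gaussian GPS noise of 1.5 m (typical consumer-grade
sports GPS). One RNG stream, seeded; identical seeds reproduce output
bit-identically.

What it does **not** emulate: gait dynamics, terrain- or fatigue-dependent
pace, GPS dropouts and multipath (noise is white, not autocorrelated),
groups that fully split, or behavior during rests. A green test on
simulated marches therefore establishes that the pipeline recovers *known
structure of this kind* (rest schedules, formation geometry, heading-copy
delays, predictability orderings) — not that it is robust to every
pathology of field GPS.

`simulate_feature_outcome_dataset` provides the prediction fixture:
i.i.d. standard-normal features, a linear outcome with configurable
support, coefficients, and noise, mirroring the 16-group × 69-feature
scale of a small multi-group study.

## 6. The prediction harness

Group feature vectors are stacked, features present in no group dropped,
missing entries median-imputed (flagged), and columns z-scored (the
selection should not depend on feature units; constant columns become 0).
Leave-one-out evaluation re-imputes per training fold (no leakage), runs
the selector on the training rows, fits OLS on the selected columns, and
predicts the held-out row. Predictive R² is **pooled** over held-out
predictions — single-observation folds have no per-fold R². Explanatory R²
comes from a full-data selection and fit. Selection stability is the mean
pairwise Jaccard index of the per-fold selected sets (two empty sets count
as agreeing). Diagnostics mirror the standard OLS checklist: Shapiro–Wilk
normality, mean residual, Ljung–Box serial independence, and a
Goldfeld–Quandt variance-ratio test between outer thirds ordered by
fitted value.

The default selector is L1-penalized regression with inner
cross-validation (deterministic fold assignment, seeded); the slot accepts
any `(X, y) → indices` function. The FDR-controlled dummy-variable
selector used in the upstream study is intentionally out of scope. If a
fold selects more features than OLS can support, the strongest marginal
correlates are kept. A caveat the tests document explicitly: at n = 16
with 69 candidates, *no* L1 selector reliably recovers a 5-feature support
(the information-theoretic requirement is roughly n ≳ 2k·log(p/k) ≈ 26);
what holds robustly, and what the suite asserts, is strong *enrichment* of
informative features among the selections. This instability is precisely
why the harness measures selection stability at all.

## 7. Numerical choices and degenerate inputs

- Foot-point search windows: 50 m around the previous foot point (plus
  global search on the first frame); ties broken by temporal continuity.
- Collinear or < 3-member frames: hull area 0, Voronoi cells `NA`, masked.
- Zero-width PACS frames mask the length/width ratio.
- Members farther than 500 m from the path are flagged, never dropped.
- HCS ratio reports an `Inf` sentinel (with window counts attached) when
  all proximate time is highly correlated.
- Empty selections fall back to intercept-only fits, flagged per fold.
- All entropies are base-2 (bits) unless `base = exp(1)` is requested.

## 8. Known limitations

Sub-group dynamics after a full split are out of scope (the clustering
features detect the split; nothing downstream models the fragments).
Altitude is ignored (2-D throughout). The hierarchical clustering method
is a deliberate simplification of HDBSCAN (documented above). Leadership
delays are bounded by `max_lag = 10` s — slower influence registers as
the nearest in-range lag. The VAR default order of 1 underfits strongly
periodic motion; raise `order` for such data.
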