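---
title: "Consistency sheaves for heterogeneous telemetry: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consistency sheaves for heterogeneous telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sheaftrack)
```

## The model

`sheaftrack` treats a sensor network as an abstract simplicial complex:
vertices are sensors, and every group of sensors observing a common
quantity is a face.  A sheaf on the complex attaches a stalk (value space)
to each face and a restriction map to each inclusion of faces; the
restriction maps carry raw readings into a common comparison frame.  For
the bear-tracking instantiation the frame is UTM meters: the vehicle GPS is
registered by a WGS84→UTM conversion (altitude ×0.3048 from feet), the
free-text landmark by a geocoder, the receiver's five-vector by coordinate
projections, and the VHF range/bearing by polar→rectangular conversion
followed by vector addition to the receiver position.  The bear edge's
stalk is planar (R²) because the VHF reading carries no elevation; the
human faces keep R³, so the radius on those faces mixes horizontal and
vertical meters.  That asymmetry is deliberate and matches the sensors'
actual information content.

Disagreement is measured per face by the spread
σ̂(Y) = sqrt(mean of squared distances to the multiset mean).  The
displayed formula for σ̂ admits two typographic readings (mean squared
deviation vs. a trace of a covariance); we use the RMS-deviation reading,
the unique one under which ε carries meters, the two-point spread is half
the distance, and the mean-substitution monotonicity lemma that justifies
extending assignments by face means goes through.  The consistency radius
is the maximum face spread; it equals the smallest ε at which the vertex
readings extend to a pseudosection of the ε-approximate consistency
structure, and the test suite verifies that equivalence against a bisection
oracle on randomly generated sheaves.

The pseudosection definition's second condition compares, for each face,
every multiset obtained by *replacing one* restricted vertex value with the
face's own value; a union reading of the same expression exists, but the
replace-one form is the one consistent with the definition's expanded
restatement, so that is what `is_pseudosection()` implements.

## Covers, measures, filtration

At a tolerance ε, the faces with spread ≤ ε are consistent, and there is a
unique full antichain of vertex subsets whose induced subcomplexes are
consistent and maximal.  `maximal_consistent_covers()` computes it two
ways: brute-force enumeration of maximal consistent vertex subsets (the
default up to 15 vertices — exact and fast at these sizes), and the
constructive recursion that splits on each vertex of an inconsistent face,
memoized, with a lexicographic default face order.  Uniqueness makes the
two provably equivalent; the acceptance tests check equality and
order-invariance on random complexes.

A cover is measured by the rank of its order ideal in the Boolean lattice:
r̄(A) = |↓A| − (n+1), normalized by the maximum 2ⁿ−(n+1) so the coarsest
cover (all sensors mutually consistent) scores exactly 1.  Both the raw
rank and the normalized fraction are reported, since the fraction is the
more interpretable number.

The filtration sweeps ε through 0 and every distinct positive spread.
Two documented choices:

- the ε = 0 step is always emitted, with faces of exactly zero spread
  treated as consistent there;
- tied spreads enter at a single landmark (the worked examples happen to
  have one face per landmark, but ties are possible in general, e.g. after
  rounding).

Floating-point note: registration round trips leave residues of order
1e-10 m, so "zero" spreads from real conversions are tiny positive numbers
and can create near-zero landmarks.  This is faithful behavior; round the
spreads first if presentation-level landmarks are wanted.

## Timeline semantics

Sensors report on different clocks, so per-timestamp vertex assignments
are built by last-observation-carried-forward, either event-driven (the
union of reading times) or resampled on a fixed grid.  Carried-forward
values have no expiry by default.  A consequence worth stating: under
motion, carried-forward readings of a *past* position are genuinely
inconsistent with fresh readings, and the radius series reflects that.
The noise-free end-to-end test therefore freezes both tracks; it
demonstrates that the registration pipeline is exact, not that LOCF is
harmless under motion.

Bearing convention: the polar conversion is applied literally with the
x-axis paired with cos θ (easting, mathematical convention).  Only this
convention reproduces the worked receiver→bear prediction to ~1 m; a
compass convention (clockwise from north) misses by hundreds of meters but
is available as an option for data logged that way.

Geocoding is pluggable and offline: a grid mock (addresses name a cell,
geocoding returns its center — error bounded by cell_size·√2/2), an exact
coder for noise-free tests, and a lookup table.  A geocoder failure leaves
the text vertex unassigned at that timestamp, which skips the affected
timestamps with a warning rather than aborting the series.

## The synthetic generator

`simulate_session()` emulates the study structure: 2-hour sessions, 16
receiver stops spaced uniformly in 300–420 s, collar fixes every 900 s,
vehicle log every 10 s, and a stationary-collar flag.  Defaults chosen
where the study design does not pin a value:

| parameter | default | rationale |
|---|---|---|
| collar GPS SD | 15 m | typical store-on-board wildlife collar accuracy |
| receiver / vehicle GPS SD | 5 m | handheld consumer GPS |
| elevation SD | 5 m | GPS vertical error, same order as horizontal |
| VHF range SD | 100 m | coarse range codes (375–1500 m categories) |
| VHF bearing SD | 5° | handheld Yagi bearing repeatability |
| human walk SD | 3 m/√s | a searching vehicle's diffusion between stops |
| bear walk SD | 0.3 m/√s | a mostly-resting bear |
| start separation | ~922 m | the magnitude of the worked VHF/collar discrepancy |

VHF error is applied in polar coordinates — range and bearing separately —
because that is the physical measurement; the `range_proportional` option
scales both SDs by range/1000 m, the mechanism that reproduces the
qualitative finding that VHF degrades with distance and hence the
decreasing radius trend as the team approaches the bear (asserted with a
Theil–Sen slope in the acceptance tests).  Range quantization to the
distance-code table is optional.  What the generator does *not* emulate:
road-constrained vehicle motion, terrain, HDOP-correlated GPS error, or
VHF multipath; passing tests show the machinery is correct under the
stated error model, not that real urban telemetry behaves this way.

## The comparison dynamic linear model

State: planar bear and human positions as random walks with process
variance proportional to elapsed time (irregular sampling is native).
Observations: five forms — vehicle GPS, receiver GPS, street sign, collar
GPS (all direct position readings) and VHF (human − bear, the signed
(−1, +1) row) — subsetted at each instant to whatever actually reported,
each schematic row expanded to easting/northing rows with a shared SD per
sensor.  The printed source for the update step omits the innovation
covariance inverse in the mean term; the standard Kalman gain (with the
inverse) is implemented, as the covariance line and the literature require.

Numerics: Cholesky-based innovation solves, covariance symmetrization each
step, a diffuse prior (first available position readings, 10⁶ m² variance,
first-step likelihood included).  The MLE optimizes log-SDs by Nelder-Mead
with up to two restarts from the incumbent (a fresh simplex reliably
escapes premature collapse, which we observed producing log-likelihoods
tens of units below the optimum on pooled problems).  The likelihood is
cross-checked in tests against a closed-form joint multivariate-normal
evaluation of the stacked observation sequence — exact for linear-Gaussian
models and entirely independent of the Kalman recursion.

Problem sizes: the pooled parameter-recovery experiment uses 12 sessions
with the study's stop/collar structure and the vehicle GPS thinned to
120 s, this package's chosen balance between statistical information and
iteration cost.  Recovery of the five observation SDs is within 30% at
that size; identifiability degrades if the observation SD is far below the
state diffusion between that sensor's readings (the likelihood then lets
the SD collapse toward a boundary — the plausible origin of
implausibly-small published MLEs of this type, e.g. a few centimeters for
a GPS unit).

Smoothing (backward pass), Monte-Carlo estimation, and model selection are
out of scope.

## Other numerical choices

- Faces are canonicalized as sorted vertex tuples; all iteration orders are
  deterministic, so covers and filtrations are bit-reproducible.
- Global-section equality tolerance defaults to 1e-6 m.
- UTM conversion uses the Krüger series (6th order in the third
  flattening) forward and Newton iteration on the conformal latitude
  inverse; round trips close to ~1e-10 m, and the forward map is tested
  against an independent Snyder-series implementation to < 1 m.  Validity
  is restricted to latitudes in (−80, 84).
- Composite restriction maps are composed along a deterministic chain and
  cached; the composition law is checked by `verify_commutativity()` as a
  test utility, not a runtime gate.

## Known limitations

- Brute-force cover enumeration is exponential in the vertex count; beyond
  ~15 vertices the memoized recursion is used, which is exact but can
  still blow up on adversarial complexes.
- The radius mixes units across faces when stalks do (elevation on human
  faces, none on the bear edge).
- LOCF timelines conflate measurement disagreement with staleness under
  fast motion; a maximum-age option or explicit time-topologized models
  would separate them.
- The DLM excludes elevation and assumes Gaussian errors with shared
  per-sensor SDs across axes.
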