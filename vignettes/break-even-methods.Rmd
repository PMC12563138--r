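---
title: "Estimating the break-even point of graft substitution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the break-even point of graft substitution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breakeven)
```

## The estimand and the model

When a bone substitute is placed — here, in the elevated maxillary sinus of
rabbits — two opposed processes run in parallel: new bone forms, and the
graft material is resorbed. Histomorphometry quantifies both as percentages
of the evaluated tissue area at a few biopsy times. The break-even point is
the moment of substitution equilibrium: the time `t*` at which the new-bone
fraction first equals the residual-graft fraction, together with the common
level `y*` at which they meet. Materials that cross early are replaced
rapidly by living bone; materials that cross late, or never, persist as a
scaffold.

With measurements at two times the estimator assumes linear progression in
between and, where needed, shortly beyond. Writing the bone line as
`B(t) = a_b + b_b t` and the graft line as `G(t) = a_g + b_g t`, each fitted
exactly through its two observations,

$$t^* = \frac{a_g - a_b}{b_b - b_g}, \qquad y^* = a_b + b_b\,t^*.$$

Everything else in the package exists to make this one formula usable and
honest: choosing *which* two time points to fit, deciding when the solution
deserves to be reported, and measuring how wrong the linearity assumption
can make it.

## Segment selection

With more than two time points, the two observations closest to the
anticipated crossing give the most reliable secant. `select_segment()` scans
adjacent pairs in time order on the per-timepoint group means and returns
the earliest pair across which the sign of `bone − graft` changes or touches
zero. If the difference never changes sign, the crossing is anticipated
beyond the data and the last pair is returned, so that any projection starts
from the most recent trend. Ties are impossible by construction: the scan is
deterministic and a zero difference at a shared endpoint is counted as a
crossing at that endpoint.

## Validity classification

Two fitted lines almost always intersect somewhere; the scientific question
is whether the intersection means anything. `estimate_break_even()` assigns
one of five statuses:

* `within_interval` — `t*` lies inside the fitted segment. An interpolation;
  the best case.
* `extrapolated` — `t*` lies beyond the last observation but within
  `max_extrapolation_factor × t_end`. Reported, but footnoted in rendered
  tables: the estimate assumes linear behavior past the data.
* `not_reached` — the projection exceeds that bound. The coordinates are
  withheld (rendered `NA`); the raw projection is kept in
  `projected_time_days` for diagnostics only.
* `already_crossed` — the crossing precedes the first observation while bone
  already exceeds graft there; equilibrium happened before sampling began.
* `divergent` — no forward crossing exists: the lines are parallel, or bone
  sits below graft with a widening gap.

`max_extrapolation_factor` defaults to 1.5. There is no biological formula
for how far a two-point linear projection stays trustworthy; in the bundled
dataset the accepted projections lie at 1.06× and 1.37× the last
observation, while the rejected series projects to 1.77×, and 1.5 is a
round bound separating those regimes. It is a configuration parameter
precisely because it is a judgment call: sensitivity of the classification
to it is one line of code to check.

Two classification details are deliberate choices. First, the divergence
rule is orientation-agnostic: the natural phrasing "divergent when
`slope_bone ≤ slope_graft`" is correct for the canonical orientation
(bone ascending from below, graft descending), but it would break the
symmetry of the intersection itself — swapping the two tissue roles leaves
`t*` and `y*` unchanged, and the classification honors that for every
convergent pair. Separating lines are labelled `divergent` when bone is
below graft and `already_crossed` when it is above. Second, boundary hits
are absorbed with a relative tolerance of 1e-9: when the crossing falls on a
segment endpoint, floating-point jitter must not flip an interpolation into
an extrapolation.

## Units, inputs and reporting

Input tables carry explicit time units; conversion uses 7 days per week and
30 days per month. Every week-denominated series in the bundled data is
exact under this rule; the only month-denominated quantity is a 6-month
endpoint (180 d) in a series whose classification is insensitive to any
defensible day count for "6 months". Percentages are validated to `[0, 100]`
with `bone + graft ≤ 100`, and animal-level replicates are averaged to group
means per time point before fitting — published tables report group means,
and the estimator should treat both input forms identically. Raw replicates
are retained for the bootstrap.

Internal values are never rounded; `render_report()` formats to 1 decimal by
default (with a `digits` override), prints `NA` for non-convergent rows, and
marks extrapolated estimates with an `a` footnote.

## The simulator: what it emulates, and what it does not

Bone healing is not linear: formation accelerates and then plateaus,
resorption is fastest early. To measure what that does to a linear
estimator, the simulator provides nonlinear ground truth:

$$B(t) = b_{max}\,(1 - e^{-k_{bone} t}), \qquad
  G(t) = g_{res} + (g_0 - g_{res})\,e^{-k_{graft} t}.$$

These monomolecular/exponential forms are the simplest curves with the
qualitative phases seen in multi-interval healing data — rapid early change,
late stabilization; a logistic bone option is included for sigmoidal early
growth. The reference scenario used throughout the tests
(`b_max = 40`%, `k_bone = 0.05`/d, `g_0 = 50`%, `g_res = 0`,
`k_graft = 0.03`/d) crosses at ≈ 21.4 d at levels comparable to the rabbit
data. The true crossing is found by hand-rolled bisection to 1e-6 d — the
difference `B − G` is strictly increasing, so the root is unique — and the
tests cross-check it against both a fine grid scan and Brent's method.

Measurement noise is additive Gaussian on the percent scale, truncated to
`[0, 100]`, with bone and graft rescaled proportionally when their sum
exceeds 100% so the compositional constraint survives noise. The published
tables provide no inter-animal variance, so `noise_sd` defaults are
illustrative, not calibrated. The simulator does **not** emulate correlated
bone/graft errors, per-animal random effects, attrition, or between-study
heterogeneity (section orientation, graft volume) — so passing simulation
tests says the estimator behaves as designed under its own assumptions, not
that real sinus biopsies satisfy them.

`bias_study()` runs simulate → estimate repeatedly and reports bias and
RMSE of the linear estimate against the bisection truth, plus the fraction
of replicates with a usable status. One integer seed, applied once, drives
all replicates in order, so every result is reproducible from the design
alone. Two structural facts the test suite verifies: the estimator is exact
when the dynamics really are linear, and `|bias|` shrinks monotonically as
the sampling times bracket the true crossing more tightly — the practical
design advice being that biopsy times should straddle the anticipated
crossing.

`bootstrap_break_even()` resamples animals with replacement within time
points (the randomization unit of these studies) and returns a percentile
interval (95% default) for `t*`, recording the fraction of non-convergent
resamples rather than silently dropping them.

## Numerical and scale choices

Tolerances: crossing consistency to 1e-9%, boundary absorption 1e-9
(relative), bisection 1e-6 d, grid-scan oracles at 1e-3 d. The test suite
checks 1000 random trend pairs against the grid oracle, 100-to-200
replicates per invariance property, and bootstrap/bias studies at 50–500
replicates — sizes chosen so the whole suite exercises every property in
about a minute on a laptop-class single core; all statistical assertions are
deterministic under fixed seeds.

## Limitations

The estimator is deliberately the two-point linear method: it inherits that
method's bias under curvature (quantified, not corrected, by the simulator)
and its blindness to what happens between and beyond biopsies. Percentages
from different studies need not be commensurable — section orientation and
evaluated-area definitions differ — so series are analyzed independently and
cross-material orderings should be read as illustrative. Dimension loss is
computed only when total areas are supplied; the bundled dataset has none.
No nonlinear model is ever fitted to real two-point data: with two
observations per curve the kinetic parameters are unidentifiable, and
pretending otherwise would only disguise the extrapolation.
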