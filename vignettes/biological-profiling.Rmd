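---
title: "Biological profiling of fragmentary long-bone assemblages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biological profiling of fragmentary long-bone assemblages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteoprofile)
```

Highly fragmented skeletal assemblages — typical of cannibalised or
otherwise anthropogenically processed Pleistocene deposits — resist the
classical toolkit of skeletal biology: no complete bones to measure, no
articulated individuals to sex and age, and sample sizes of a handful of
individuals. `osteoprofile` implements four quantitative stages that
together reconstruct biological profiles from such material, plus a
synthetic-data module that makes every stage testable end to end without
access to scan data.

1. A **composition test**: is the demographic make-up of the assemblage
   (females / males / juveniles) plausible as a random sample from a
   mortality-structured reference population?
2. **Osteometric stature** reconstruction from long-bone lengths.
3. **Cross-sectional geometry** (CSG) of diaphyseal cortical rings, the
   standard beam-model robusticity quantities.
4. **Geometric morphometrics** of cross-sectional shape: semilandmarks,
   generalized Procrustes analysis (GPA), PCA, group ellipses, wireframes.

This vignette explains the models, the parameters that matter, the design
decisions taken where conventions were genuinely open, and what the
synthetic data do and do not establish about real material.

## The composition test

An assemblage composition is a triple $n = (n_F, n_M, n_J)$ of
adult/adolescent females, adult/adolescent males and juveniles (0–14
years), with MNI $= \sum_i n_i$. A mortality profile is a probability
vector $p = (p_F, p_M, p_J)$: the expected category distribution of deaths
in a population. Profiles can be entered directly, parameterized by a
juvenile death fraction and an adult sex ratio
(`profile_from_components()`), or normalized from the observed counts of a
well-documented reference assemblage (`profile_from_counts()`). No
life-table values are hard-coded: published mortality models (e.g.
Ledermann-type tables for life expectancies of 25–35 years) enter as
user-supplied profiles.

A profile is scaled to a finite reference population of $N$ individuals
(default $N = 60$) by largest-remainder rounding, with remainder ties
broken in fixed category order F, M, JUV so the construction is
deterministic. The resulting integer counts $K = (K_F, K_M, K_J)$ never
deviate from the real-valued quota $N p_i$ by a full individual.

The test asks how often random draws of MNI individuals from that
population reproduce the observed composition *exactly*. Both sampling
schemes are provided:

* with replacement — multinomial:
  $P(n) = \binom{\mathrm{MNI}}{n_F\, n_M\, n_J} \prod_i p_i^{n_i}$;
* without replacement — multivariate hypergeometric:
  $P(n) = \prod_i \binom{K_i}{n_i} \big/ \binom{N}{\mathrm{MNI}}$.

```{r composition}
profile <- profile_from_counts(c(3, 4, 5), "reference_3_4_5")
refpop <- build_reference_population(profile, 60)
observed <- assemblage_composition(c(4, 0, 2), "observed")
exact_prob_without_replacement(observed, refpop)
```

`monte_carlo_prob()` re-implements the resampling route (default 10,000
iterations, the conventional scale for this test); it is an unbiased
estimator of the closed forms and is retained both for fidelity to the
resampling formulation and for future extensions with finer categories,
but the analytic method is the reporting default wherever the closed form
exists — a Monte Carlo estimate of a quantity we can compute exactly only
adds noise. In grids built by `composition_test_table()`, Monte Carlo
cells draw from deterministic substreams derived from (seed, row, column),
so results do not depend on evaluation order. Probabilities are flagged
`*` below 0.05 and `**` below 0.01.

Two modelling choices deserve emphasis. "Match" means exact equality of
the three category counts; no ordering and no finer age structure is
compared. If a study distinguishes, say, neonates from older juveniles,
the three-category probabilities computed here are upper bounds on the
finer-grained match probabilities — a deliberately conservative behaviour.
And the test conditions on the MNI: it asks about composition given
assemblage size, not about the size itself.

## Stature

Stature is estimated by linear regression on maximum bone length (MaxL),
using Sjøvold-type sex-unknown formulae. The default registry carries
femur $S = 2.71\,\mathrm{MaxL_{cm}} + 45.86$ (SEE 4.49 cm) and tibia
$S = 3.29\,\mathrm{MaxL_{cm}} + 47.34$ (SEE 4.15 cm); both are
user-overridable via `regression_spec()`, and additional elements or
population-specific equations can be registered the same way. A femur
preserving only its biomechanical length (BML) has MaxL reconstructed
first by the linear conversion $\mathrm{MaxL} = 1.037\,\mathrm{BML} +
11.2$ (mm).

```{r stature}
meas <- data.frame(
  specimen_id = c("FemA", "TibA", "TibB"),
  element = c("femur", "tibia", "tibia"),
  maxl_mm = c(408, 313, 292),
  individual = c("ind1", "ind1", "ind2"))
estimate_statures(meas)
```

When one individual preserves both a femur and a tibia, only the femoral
estimate is kept (`prefer_femur = TRUE`): Neandertal distal limb segments
are relatively short, so tibial formulae calibrated on *Homo sapiens*
proportions are the less portable of the two. Statures are rounded to the
nearest centimetre for display only; `group_stature_summary()` aggregates
the unrounded values (rounding first would visibly shift small-sample
means and standard deviations).

Group comparisons use Welch's unequal-variances t-test computed from
summary statistics (`welch_t_test()`), because comparative samples are
typically available only as published means and standard deviations. The
reported p-value is two-sided; halve it for a directional hypothesis
specified in advance.

## Cross-sectional geometry

A section is a cortical ring: a periosteal polygon with an endosteal
polygon inside it, in the anatomical frame +y = anterior, +x = lateral
(right-side convention; left sections are mirrored about the y-axis before
analysis so sides can be pooled). Vertex winding is normalized to
counterclockwise — input order is not trusted — and rings are checked for
self-intersection at construction.

All quantities derive from exact Green's-theorem polygon moments
(`polygon_moments()`), with the medullary cavity removed by composite-area
subtraction: endosteal moments are transferred to the cortical centroid by
the parallel-axis theorem and subtracted. From $I_x$, $I_y$, $I_{xy}$
about the cortical centroid the principal decomposition gives
$I_{\max} \ge I_{\min}$ and the orientation $\theta$. $\theta$ is reported
as the direction of the *major geometric axis* (the eigenvector of the
orientation tensor with the larger second moment) measured from +x, in
$(-\pi/2, \pi/2]$: an anteroposteriorly elongated section has
$\theta \approx \pi/2$, a mediolaterally elongated one $\theta \approx 0$.
The polar section modulus is computed as $Z_p = J / r_{\max}$ with
$J = I_{\max} + I_{\min}$ and $r_{\max}$ the largest distance from the
cortical centroid to the periosteal contour — the standard biomechanical
definition of torsional/average bending strength for irregular sections.
A principal-axis section modulus was the plausible alternative; $J /
r_{\max}$ was chosen because it is the definition most comparative
datasets report.

Section locations are percentages of BML measured **from the distal end**
(femur 35/50/80, tibia 20/35/50, optionally 65 for both), so the femoral
80% section is subtrochanteric. The radius uses a landmark location
instead: `locate_interosseous_crest()` picks, from a distal-to-proximal
series of sections, the one with the greatest medial periosteal extension
from its centroid, with ties resolved to the most distal section.

Accuracy is governed by ring resolution. Polygon moments are exact for
the polygon itself; what matters is how well the polygon samples the
smooth contour. For smooth shapes, 720 vertices put every property within
a few hundredths of a percent of the limit (the test suite asserts < 0.05%
change on doubling beyond 720); scan-extracted contours at comparable
density need no resampling.

## Cross-sectional shape

`extract_semilandmarks()` casts $k = 21$ equiangular rays from the
cortical centroid, the first ray anterior (+y), proceeding laterally
(clockwise in the right-side frame), and records the farthest periosteal
and nearest endosteal intersection per ray: 42 ordered landmarks per
section, periosteal 1–21 and endosteal 22–42, with pairs $i$ and $i+21$ on
a common ray. Fixed-angle radial sampling is the common automated scheme
for diaphyseal sections; no semilandmark sliding is applied —
bending-energy or chord-distance sliding optimizes an objective the
downstream analyses never use, and a fixed scheme keeps configurations
strictly comparable across specimens. The extraction centre is the
cortical centroid, so eccentric medullary canals shift endosteal (not
periosteal) landmarks — exactly the cortical-distribution signal the
analysis targets.

`generalized_procrustes()` centres each configuration, scales it to unit
centroid size, and iteratively rotates all configurations to the evolving
consensus (least squares, reflections forbidden) until the consensus moves
by less than $10^{-10}$ or 100 iterations. Because the standard algorithm
leaves a global rotation unresolved (the result inherits the first
specimen's arbitrary orientation), the output is put in a canonical
orientation: the consensus is rotated so its first landmark — the anterior
periosteal semilandmark — points along +y. This makes GPA output strictly
invariant to similarity transforms of the inputs (the test suite asserts
agreement to $10^{-8}$ under random rotations, scalings and translations)
while keeping the anatomical frame readable in plots and wireframes.

`shape_pca()` performs PCA on the covariance of the flattened Procrustes
coordinates — covariance, not correlation, the standard for Procrustes
data, and with divisor $n$ rather than $n-1$, so eigenvalues are
per-specimen mean squared deviations, their sum equals the total
Procrustes variance exactly, and duplicating a dataset leaves the spectrum
unchanged. Loading signs follow a fixed convention (largest-magnitude
coordinate positive) so scores are reproducible run to run. Analyses are
run separately per section location; pooling locations would mix
within-bone with between-individual variation.

Group scatter is summarized by normal-theory ellipses
(`group_confidence_ellipse()`): centre at the group mean, semi-axes
$\sqrt{\lambda_i \, \chi^2_{2}(0.95)}$ from the covariance eigenvalues.
`wireframe_config()` renders `mean + score × loading` at scores $\pm 0.1$,
the conventional magnitude for visualizing shape-space axes.

## Synthetic data

`section_spec()` defines four parametric ring families, sampled radially
so contours are star-shaped and simple: concentric circular and elliptical
annuli, an eccentric-canal variant, and a "buttressed" family carrying a
von Mises-shaped radial bump on the periosteal ring (default position
posteromedial, 225° from +x for a right bone) that emulates localized
cortical reinforcement. Closed-form CSG oracles (ellipse moments plus
parallel-axis composition) are attached wherever they exist, and the
independent checks in the test suite add a pixel-integration oracle
computed from the analytic region definitions. Radial Gaussian noise is
applied after the oracle is computed and is capped at 5% of the minimum
cortical thickness so noisy rings remain simple.

`generate_assemblage()` draws MNI individuals without replacement with
category probability proportional to remaining count × weight: equal
weights reproduce the multivariate hypergeometric null (verified by
goodness of fit), skewed weights implement deliberate selection. The test
suite uses this to show the composition test's rejection rate rises
monotonically with selection bias. `generate_shape_sample()` builds
two-group landmark samples (jittered templates, landmark noise, default
0.1 mm on ~15 mm rings) for which GPA + PCA must recover the known group
contrast on PC1 — e.g. a circular-ring group against an anteroposteriorly
elongated one, the qualitative contrast reported between Neandertal and
*Homo sapiens* lower-limb sections.

What the generators deliberately do not emulate: real cortical drift and
asymmetric remodelling, porosity, periosteal rugosity, taphonomic surface
loss, and the correlated (non-isotropic) measurement error of
scan-extracted contours. Passing tests therefore establish the
*correctness of the computations* — moments against closed forms,
resampling against exact pmfs, GPA/PCA against invariance and recovery
properties — not the anatomical realism of any particular input. Applied
conclusions inherit the usual caveats of the input data, not of this
implementation.

## Numerical choices and problem sizes

* Composition test: exact forms are used for reporting; Monte Carlo
  default 10,000 iterations. Validation runs in the test suite use
  100,000 iterations against a 4-standard-error band, enumeration checks
  at MNI ≤ 6, N ≤ 20, and 400–1000 replicates per point for the power
  curve.
* CSG validation: 1440-vertex rings against closed forms and a
  1500 × 1500 pixel-integration oracle, at 0.2% tolerance; invariance
  checks at machine precision.
* GPA: tolerance $10^{-10}$, max 100 iterations; typical samples converge
  in well under 10.
* Shape experiments: 20 specimens per group, 3% parameter jitter, 0.1 mm
  landmark noise.
* Degenerate inputs fail loudly: zero-area or self-intersecting rings,
  endosteal rings outside periosteal ones, zero-size landmark
  configurations, all-zero count vectors and out-of-range probabilities
  all raise errors rather than propagate.

## Known limitations

* The composition test operates on three categories only; studies that
  match finer age classes will obtain smaller probabilities than the
  three-category closed forms reported here.
* Stature SEEs are carried through unchanged from the regression specs;
  group summaries do not propagate per-specimen SEE into the group
  standard deviation.
* $Z_p$ uses the $J / r_{\max}$ convention; datasets computed with
  principal-axis section moduli are comparable only approximately.
* Sections are assumed already anatomically oriented; 3D alignment of
  fragments to reference bones is upstream of this package and out of
  scope, as are mesh processing, body-mass standardization of robusticity
  and cortical-thickness mapping.
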