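---
title: "Methods: foraging habitat selection for nest-observed farmland songbirds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: foraging habitat selection for nest-observed farmland songbirds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Chick-provisioning Skylarks (*Alauda arvensis*) are central-place
foragers: every feeding flight starts and ends at the nest, so the choice
of a foraging site trades off the distance flown against what a habitat
offers — accessible ground under an open sward, and abundant, diverse
arthropod prey. `larkscape` implements the full analysis chain for
nest-based foraging observations of this kind:

1. **Home ranges** — a single study-wide radius (the nest-weighted 95th
   percentile of flight distances) defines a disc around each nest.
2. **Distance-weighted availability** — how much of each habitat a pair
   effectively has at its disposal, discounting far area.
3. **Resource selection** — a binomial additive model contrasting landing
   points against uniform pseudo-absence points, with permutation
   variable importance.
4. **Compositional analysis** — whole-season habitat use versus
   availability per nest, tested with a randomized one-sample Wilk's
   lambda and ranked pairwise.
5. **Seasonal use** — per-habitat mixed logistic models of use over the
   day of the breeding season.
6. **Foraging parameters** — feeding frequencies, flight distances, MCP95
   areas, and their trend models.

A synthetic-data generator with known ground truth drives every stage, so
each statistical claim in the test-suite is checked against either an
independent oracle or the generating parameters.

## Calendar and geometry conventions

All coordinates are planar metric (meters); distances are Euclidean. The
study extent is a few kilometers, so no geodesy is involved. Day 1 of the
breeding season is April 25 (the earliest documented hatch date in the
emulated study), applied within each calendar year; the convention is
configurable through `study_config(day_one = )`.

Polygon work — GeoJSON reading/writing, clipping patches against the
home-range disc, point-in-polygon location — is done by a small planar
geometry layer (`clip_polygon()`, Sutherland–Hodgman against a convex
clipper; shoelace areas; even-odd ray casting). The disc is a 256-vertex
polygon *circumscribed* around the true circle, so landing points exactly
at the radius (the point that defines the 95th percentile!) are inside
it; the cost is a +1e-4 relative area overshoot, far below every
tolerance used downstream.

## Home-range radius and weighted surface area

Every safe landing point carries weight $1/n_i$ ($n_i$ = safe points of
its nest), so each nest contributes equally. The radius is the smallest
distance whose cumulative normalized weight reaches 0.95 — no
interpolation, which keeps the definition exact under unequal weights and
invariant to duplicating any nest's points.

Availability inside a disc is computed on a 5-m grid (symmetric about the
nest, so a nest on a habitat boundary splits 50/50 exactly). With
distance weighting, a cell at distance $d$ gets weight
$\hat f(d) / (2\pi d)$, where $\hat f$ is the nest-weighted histogram
(10-m bins) of all flight distances: the observed distance-use profile
converted into a per-unit-area intensity. With flat weighting the result
reduces to the plain area share — a testable limit the suite exercises
against exact polygon areas. Unmapped area inside a disc is excluded from
the denominator and reported as a coverage gap, never silently
renormalized away.

## Resource-selection model

For each mapped nest, 240 pseudo-absence points are drawn uniformly over
the disc (rejection sampling, redrawn out of coverage gaps and
covariate-missing patches). The model is

```
use ~ s(cover) + s(biomass) + s(diversity) + s(distance) + s(nest, bs = "re")
```

binomial with logit link, penalized regression splines (`mgcv`, basis
dimension k = 10, ML smoothness selection). Presences of a nest share
total weight 1 and so do its pseudo-absences, implementing "nests equal"
and "absences = presences" simultaneously, per nest and globally.

Two numerical choices deserve note:

* **Weight scale.** The equalizing weights sum to ~2 × number of nests.
  Used raw, a weighted likelihood behaves as if only that many
  observations existed and shrinks every smooth to a powerless straight
  line; scaled to sum to the number of rows it overstates the information
  carried by unequal weights and inflates type-I error (15–25% at nominal
  5% in our null simulations). The fit therefore rescales the weights so
  that $\sum w = \sum w^2$ (the Kish effective sample size), which
  restored ~5% null rejection in 60-replicate calibration runs while
  leaving all relative weights untouched. The same rescaling is applied
  in the seasonal-use models; the Gaussian mixed models are unaffected
  because `lmer` weights are scale-invariant.
* **Classification reference.** Selection curves are the centered smooths
  with pointwise 95% CIs; "preferred" means the lower bound exceeds 0 on
  the link scale, "avoided" the upper bound is below it. The intercept,
  the other covariates (held at their medians) and the nest effect do not
  enter the curve.

Permutation importance permutes one column at a time (the four covariates
and the nest label), predicts with the unchanged model, and scores
$1 - r$ (Pearson, probability scale, floored at 0), averaged over 100
replicates and normalized to percentages. Permutation is global (not
within nest) — the cited procedure does not restate the variant, so the
choice is recorded here.

## Compositional analysis

Categories are habitats present in at least one-third of home ranges
(configurable); everything else pools into "other". If that pool is empty
— possible in fine mosaics where every habitat clears the threshold — the
empty category is dropped rather than propagating undefined log-ratios.
Per nest, the difference
$d_{ij} = \ln(u_{ij}/u_{i,\mathrm{ref}}) - \ln(a_{ij}/a_{i,\mathrm{ref}})$
uses the category available to the most nests as the reference (lambda is
reference-invariant; a ubiquitous reference minimizes missing cells).
Zero used proportions are replaced by 0.0001 — the standard compositional
convention — without renormalization; cells where a category is
unavailable are filled by the column mean (mean substitution), with a
`drop_incomplete` switch for nest deletion instead.

The statistic is the one-sample Wilk's lambda
$\Lambda = \det(R_1)/\det(R_0)$ (SSCP about the mean over SSCP about
zero); the all-zero matrix resolves to 1. Its null distribution comes
from flipping the sign of each nest's difference vector with probability
1/2 — exchangeability of the use and availability labels within a nest —
with $p = (1 + \#\{\Lambda_\mathrm{rand} \le \Lambda_\mathrm{obs}\}) /
(1 + N)$, 1000 iterations by default. The test-suite checks this p-value
against exhaustive $2^8$ enumeration at n = 8, the lambda itself against
an independent Hotelling-$T^2$ route to 1e-10, and the type-I error
(0.03–0.07 over 500 null datasets).

The ranking matrix holds, for each ordered category pair, the mean
pairwise log-ratio difference and its one-sample t statistic over the
nests where both categories are available; a category's rank is the
number of categories it beats. The zero-use replacement makes ranks of
*rare* categories noisy — a nest that simply never drew a flight to a
scarce habitat contributes a log-ratio near $\ln 10^{-4}$ — which is why
the parameter-recovery experiment for the ranking uses a fine mosaic
(1.5-ha fields) where every range holds every category.

## Seasonal-use and foraging-trend models

The seasonal design has one row per in-range safe landing point of every
nest whose range contains the focal habitat; the response is whether the
point fell in it. "Nests equally weighted per day of observation" is
implemented as observation weights $1/(\text{points of that nest on that
day})$, Kish-rescaled as above, in a `glmmTMB` binomial mixed model with
day of season, weighted surface area, and a year indicator (dropped
automatically for single-year designs). Prediction curves run over days
1–100 at the mean weighted surface area of the included nests, and are
classified against that availability line.

Feeding frequency divides the landing points of a session by its minutes
(×60); ambiguous landings still count as visits — the ambiguity is about
*where* the bird landed, not *whether* it fed. Sessions not ended before
sunset are excluded, as are nests with unclear brood size. The per-session
identity `per_h == per_h_chick * brood_size` is asserted exactly. MCP95
retains the 95% of a nest's safe points closest to their centroid (same
smallest-order-statistic convention as the radius) and takes the convex
hull; nests under 20 points are excluded. Trend models are `lmer` LMMs
(day, chick age, daytime, temperature, wind, radio-tag, year; nest random
intercept; weights $1/n_i$) and a linear model for MCP95 area.

## The synthetic generator

The generator emulates the observed structure of a two-year Central
European farmland study; its defaults are the study conditions, chosen
once and not revisited:

* **Mosaic**: a 3.4-km square of rectangular fields averaging 5.1 ha,
  winter wheat 35%, sugar beet 21%, corn 10%, flower strips 5%, plus
  barley/rape/fallow/grassland, with 4-m field-path strips between field
  columns.
* **Nests**: 96 found; 22 inactive before observation, 15 unobservable, 8
  with chicks too old — 51 observed, of which 42 have mapped covariates
  and 12 a radio-tagged parent; hatch dates span late April to mid July
  with the observed monthly pattern.
* **Flights**: landing cells on a 5-m grid within 500 m get probability
  $\propto \exp(-d/\lambda_d) \times w(\text{habitat}, \text{day})$.
  $\lambda_d = 40$ m: the 2-D kernel implies a Gamma(2, $\lambda$)
  distance law whose 95th percentile ($\approx 4.74\lambda = 190$ m) and
  mean ($2\lambda = 80$ m) bracket the emulated study's 188-m radius and
  86-m mean flight distance. The grid sampling makes the landing law
  exactly computable, which the kernel tests exploit.
* **Attractiveness**: base weights from the observed use/availability
  pattern (flower strips and field paths ~2×, wheat and beet slightly
  under 1, residual habitats 0.6), multiplied by an accessibility factor
  declining logistically around 70% vegetation cover (the avoidance
  threshold the study reports), and by per-nest, per-patch lognormal
  site-fidelity multipliers (sdlog = 1) emulating the substantial
  between-nest variation the study's nest random effect picks up.
* **Sessions**: up to 10 flights or 90 min; feeding gaps exponential with
  mean 5.9 min — the protocol stops at the 10th visit, so the session
  frequency estimator carries a 10/9 stopping bias, and 5.9 min encodes a
  mean *observed* frequency of ~11.3 visits/h. Brood sizes 1–5 (mean
  ~3.5), 2.4% of landings ambiguous, starvation at 3/178.
* **Covariates**: negative-binomial counts per insect order with
  habitat × half-month means, lognormal dry mass, logistic crop growth
  read by three observers at ±10 noise rounded to 10% steps; 3% of
  patches unsampled to exercise the imputation path.

What the generator does *not* emulate: directional commuting to one or
two favourite spots beyond what lognormal patch fidelity produces,
weather-dependent behavior, territoriality, or prey depletion. Two
consequences are visible in the synthetic headline numbers and should not
be read as field predictions: simulated flight clouds are more isotropic
than real birds', so mean MCP95 areas come out larger than the ~3 ha of
real Skylarks; and the configured attractiveness differences are
consistent across all nests, so the whole-season compositional lambda is
much smaller (stronger apparent selection) than the non-significant
value a real, heterogeneous population produced. Passing tests therefore
demonstrate that the estimators recover what the generator put in — not
that real data would show these effect sizes.

## Problem sizes used by the checks

The test-suite runs the full pipeline at reduced scale: recovery
experiments use 8 nests (distance importance, 100 seeds), 40 nests
(compositional rank, 100 seeds) and 70 nests (seasonal decay, 100 seeds
— the short within-nest observation window leaves most of the seasonal
information between nests, so this contrast needs the largest campaign)
on 1.3–1.5-km mosaics with a 10-m landing grid and 15-m availability
grid; the calibration check draws 500 null datasets of 8 nests. The
acceptance script runs the full 96-nest study at the default grids. These
sizes were chosen so that every stochastic assertion has comfortable
power while a complete run stays in the minutes range on one CPU.

## Known limitations

* Polygons are single rings; holes are not supported (the generated
  mosaics have none; real shapefile imports would need pre-processing).
* Thin linear features (4-m field paths) are under-sampled by coarse
  availability grids; at the default 5-m grid the bias is ~1 part in 5 of
  their area share.
* The compositional zero-use convention (0.0001) makes ranks of rare
  categories unstable — a property of the method, preserved deliberately.
* `glmmTMB` Wald p-values and `lmerTest` Satterthwaite p-values are
  approximations; the suite asserts signs and calibrated rejection rates,
  not digit-exact coefficient tables.
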