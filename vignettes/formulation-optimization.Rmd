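---
title: "Optimizing formulation conditions with thin-plate-spline response surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing formulation conditions with thin-plate-spline response surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsmspline)
```

## The problem

Microfluidic devices load cargo such as siRNA into lipid nanoparticles or
extracellular vesicles by mixing two streams — for example, vesicle lipids
in ethanol against siRNA in buffer — under pump-pressure control. The two
pump pressures jointly determine three properties of the product that pull
in different directions: mean particle size (nm, smaller is better),
polydispersity index (PdI, a dimensionless width of the size distribution
in [0, 1], smaller is better), and loading efficiency (LE%, the percentage
of supplied siRNA that ends up encapsulated, larger is better). Because a
single run of the device is expensive, the practical question is how to
map all three responses over the pressure plane from roughly ten runs and
pick the best compromise — with an honest statement of how trustworthy
that pick is.

`rsmspline` implements that workflow end to end: a central composite
design (CCD) over the two pressures, one thin-plate-spline (TPS) response
surface per measured response, leave-one-out cross-validation (LOOCV) of
each surface, a multi-objective optimum over the fitted surfaces, and a
bootstrap assessment of the optimum's stability.

## The design

`make_ccd()` builds the standard two-factor CCD: the 2^2 factorial
corners at coded levels ±1, four axial runs at coded distance α along the
axes, and replicated center runs. The default α = √2 is the rotatable
choice for two factors, which puts all eight non-center runs at the same
coded distance from the center, so prediction uncertainty depends only on
the distance from the middle of the region. With two center replicates
this is the classic 10-run layout. Natural (hPa) and coded units are
linked by the affine map `natural = low + (coded + 1)/2 × (high − low)`;
the bounds that define the map travel with the design as `factor_spec`
records, are written to and read from the design CSV, and for a rotatable
design can be inferred back from the file (the extreme values on each
axis are the axial runs, at coded ±√2).

## The surface model

Each response is modelled separately as an exact thin-plate spline in
coded space,

$$f(x) = c_0 + c^\top x + \sum_i w_i\,\phi(\lVert x - x_i\rVert),
\qquad \phi(r) = r^2 \log r,\ \phi(0) = 0,$$

with side conditions $\sum_i w_i = 0$ and $\sum_i w_i x_i = 0$ that make
the radial part orthogonal to affine trends. The coefficients solve the
augmented dense system with the kernel matrix plus λI on the kernel
block. Three numerical choices matter:

* **Replicate averaging.** An interpolant cannot take two values at one
  point, so exact duplicates of a coordinate (the center replicates) are
  averaged into a single node before solving; coordinates are considered
  duplicated when they agree to 1e-9 in coded units. The raw runs are
  kept: the bootstrap resamples physical runs and averages only inside
  each refit.
* **Coded space.** The TPS kernel is not scale-invariant; fitting in
  coded −1..+1 units makes two pressures with different natural ranges
  commensurate, and makes the fit independent of the unit chosen for the
  bounds (relabelling hPa as kPa leaves the coded optimum unchanged).
* **Modelling scale.** Particle size spans a wide relative range and is
  modelled as log10(size); PdI and LE% are modelled on their own scales.
  The scale is a per-response setting.

λ = 0 (exact interpolation) is the default: the design has almost no
internal replication from which to estimate a noise level, and the
surfaces are read qualitatively. For noisier tables, `gcv_lambda()`
scores a ridge λ ≥ 0 by generalized cross-validation; at λ = 0 the GCV
criterion is a degenerate 0/0 and is treated as infinite, so its
minimizer is always strictly positive. A fit needs at least k + 3
distinct, non-collinear node locations (5 for two factors) and rejects
anything less with a diagnosis.

## Scoring a surface: leave-one-out correlation

`loocv_r()` holds out one *physical* run at a time — a center
replicate's twin stays in the fit — refits, predicts the held-out
response, and reports the Pearson correlation r between held-out
predictions and observations on the modelling scale. On a 10-run design
this is a blunt but honest instrument: r near 1 means the design
resolves that response's shape; r near 0 means the surface is mostly
reproducing noise, and its map should be read as a trend at best. The
suite checks both regimes: noiseless smooth responses give r > 0.99, and
pure-noise responses give |r| well below 0.5 on average.

## The multi-objective optimum

`find_optimum()` scalarizes the fitted surfaces into one score. Each
surface's predictions over the search grid are min–max normalized to
[0, 1]; maximized responses are reflected so 0 is always ideal; the
default score is the weighted Euclidean distance to the ideal point,
with equal weights. A Derringer-style overall desirability (weighted
geometric mean of d = 1 − u, maximized) is available via
`objective_spec(method = "desirability")` — the two agree for a single
response and differ, deliberately, in how they trade responses off. The
combination rule is stated this explicitly because the optimum depends
on it; published tables produced by closed-source optimization software
rarely state theirs.

The search is a dense grid (201 × 201 by default) over the design's
pressure box — no extrapolation beyond the coded box unless a wider box
is requested — followed by box-constrained quasi-Newton polish started
from the best cell, with the normalization anchors frozen. Exact ties on
the grid break to the first (row-major) cell, which makes the search
deterministic. Flat surfaces (degenerate normalization) are dropped from
the score with a warning rather than poisoning it.

One subtlety the test suite documents: the optimum returned is the
optimum *of the fitted interpolant*. An exact TPS through nine nodes of
a quadratic bowl whose minimum is far from any node can place its own
minimum visibly elsewhere; with densely sampled nodes the two coincide.
That is a property of exact interpolation, not of the optimizer, and it
is why LOOCV accuracy should be consulted before trusting the optimum's
location.

## Bootstrap stability of the optimum

`bootstrap_optimum()` resamples the n physical runs with replacement B
times; each resample refits all surfaces and re-optimizes, and the B
optima are summarized component-wise by mean and SD. Resamples with
fewer than the minimum distinct coordinates are redrawn (and counted).
Each resample draws its indices from its own deterministic substream of
the master seed, so a run is bit-reproducible and the first 1000
resamples of a B = 5000 run are exactly the B = 1000 run — comparing
summaries across B therefore isolates Monte-Carlo convergence.
`bootstrap_stability()` turns a set of summaries into a spread table:
the maximum spread of each component's mean across B, relative to its
magnitude, flagged stable below 1% by default.

Inside each resample the optimizer runs grid-only at 61 × 61: profiling
showed the polish step changes the resulting B-mean by under 0.01% of
the factor range while costing several times the grid search, and the
average over resamples smooths grid quantization anyway. The one-shot
optimum keeps the full 201 × 201 + polish.

Because duplicated draws of the same run collapse in the
replicate-averaging step, an exact-interpolation bootstrap effectively
varies *which* runs are present. With only 10 runs the resulting SDs on
the optimal pressures are honest and wide (tens of hPa); the stability
check across B asks a different question — whether B was large enough —
and is tight (well under 1%) whenever the bootstrap has converged.

## The synthetic study conditions

`synthetic_config()` encodes the study conditions every test and the
acceptance script run under. The truth functions are quadratic bowls and
a dome in the normalized offset from their optimum — deliberately *not*
TPS functions, so fitting always faces model mismatch. Defaults, chosen
once from the application the package mirrors: pressure boxes 400–800
and 350–750 hPa with the joint optimum at the center (600, 550) hPa,
echoing designs whose center runs sit near the sweet spot; size floor
195 nm on a log10 scale rising by 0.13 log-units per squared normalized
radius; PdI floor 0.29 (+0.07 curvature); LE% peak 19.3 (−4.5
curvature). Noise SDs are σ = 0.02 log10-units for size, 0.06 for PdI
and 0.8 percentage points for LE%: relative to each response's signal
range over the design these put size and LE% in the well-resolved regime
and PdI in the noise-dominated one, reproducing the qualitative accuracy
ordering (r for size and LE% high, r for PdI low) that these assays show
in practice — DLS polydispersity is by far the noisiest of the three
readouts. The generator also emits assay fixtures (an 11-fraction
density-gradient profile with free siRNA in fractions 1–3 and joint
siRNA/particle peaks in 8–9, a fluorescence pair with a configured true
LE% of 11, and luciferase tables with configured true suppressions of
52.7% and 85.2%) that are exactly self-consistent with the scalar
metrics.

What the generator does **not** emulate: pressure-dependent
heteroscedasticity, drift between runs, correlated errors between size
and PdI (which share one DLS measurement), non-quadratic ridge-shaped
optima, or outliers. Passing the recovery and stability checks therefore
shows the estimators work under smooth, independent, homoscedastic
noise; it does not certify behavior on pathological instruments.

## Scalar assay metrics

The five metrics are deliberately small, explicit functions:
`loading_efficiency()` (blank subtracted from numerator and denominator,
negative results clamped to 0 with a warning; the denominator is the
total *supplied* siRNA), `mfir()` (sample over untreated MFI),
`suppression_ratio()` (per-well luminescence normalized by protein, then
100 × (1 − mean ratio); a delta-method SD is attached for reporting),
`colocalized_fractions()` (both channels above thresholds defaulting to
10% of each channel's maximum — the default makes a usually qualitative
read-off explicit and configurable), and `peak_area_ratio()` (analyte
over internal standard; the reference internal standard, a 17:0–20:4
phosphatidylinositol at 0.38 µmol/L, is recorded as metadata).

## Reproducibility plumbing

`run_pipeline()` chains the stages and writes every artifact — design,
responses, surface model files, grids, accuracy, optimum, bootstrap
table (one row per B with means and SDs), stability table, manifest —
into one directory, each stamped with a 32-bit hash of the semantic
configuration (the output path is excluded from the hash). CSVs are
written with 17 significant digits so write→read round trips are
bit-stable; reruns of one configuration are byte-identical except for
the timestamped log. Stage failures abort with a condition object
carrying the stage name. Configurations can live in JSON files;
`inst/scripts/run_pipeline.R` is a thin shell wrapper over the same
functions.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` run the workflow at the sizes
the methods are designed for: 10-run designs; 100 random fit instances
against an independently coded dense solve; 50 simulated experiments for
the accuracy-ordering check; 20 low-noise experiments for optimum
recovery (success defined as within 5% of each factor's range, observed
in ≥ 90%); and the full bootstrap ladder B = 1000…5000 (15 000
resamples) for the stability check. These sizes keep a complete run in
the low minutes on one core while exercising every code path at the
scale it targets.

## A worked run

```{r example, eval = FALSE}
library(rsmspline)

factors <- list(factor_spec("pressure_A", 400, 800),
                factor_spec("pressure_B", 350, 750))
design <- make_ccd(factors, alpha = "rotatable", n_center = 2)

sim <- generate_experiment(synthetic_config(seed = 1), design)

cfg <- pipeline_config(factors = factors, seed = 1,
                       outdir = tempfile("run_"))
res <- run_pipeline(cfg)

sapply(res$accuracy, `[[`, "r")   # LOOCV r per response
res$optimum                        # pressures + predicted responses
res$stability                      # spread of bootstrap means across B
```

## Known limitations

* Exactly interpolating splines transmit every quirk of a 10-run table
  into the surface; the LOOCV r is the only internal guard. Use
  `gcv_lambda()` when replicate scatter is visible.
* The bootstrap on n = 10 runs is coarse: resamples are subsets in
  effect, the optimum distribution is discrete-ish, and SDs should be
  read as order-of-magnitude statements.
* Two factors only are visualized; the math is dimension-generic but the
  grid search cost grows exponentially with factors.
* The distance and desirability scalarizations can disagree on strongly
  asymmetric trade-offs; the choice is a modelling decision the user
  owns.
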