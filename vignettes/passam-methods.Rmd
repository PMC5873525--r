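---
title: "Quantifying passive aerosol sampler deposits: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying passive aerosol sampler deposits: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(passam)
```

## The measurement problem

A mesh-capped passive deposition sampler is a small SEM stub whose
substrate collects airborne particles by gravitational settling and
Brownian diffusion during a deployment of duration $t$.  The deposit is
imaged by electron microscopy, segmented into individual particles, and
inverted to an airborne mass concentration.  For particle $i$ with
aerodynamic diameter $d_{a,i}$ and mass $m_i$, the deposited flux is
$\gamma(d_{a,i})\, v_{dep}(d_{a,i})\, C$ per unit area, where
$v_{dep}$ is the quiescent-air deposition velocity and $\gamma \le 1$
the attenuation by the protective mesh cap.  Inverting and summing over
the particles found on analysed area $A$:

$$ C \;=\; \frac{1}{A\,t}\sum_i \frac{m_i}{\gamma(d_{a,i})\,
   v_{dep}(d_{a,i})} . $$

This is the unique dimensionally consistent flux inversion; the
per-particle contributions are retained in the output of
`concentration_total()` for audit.  The analysed area $A$ is the summed
area of the analysed image fields.  Because the deposition flux per unit
area is uniform in expectation, no rescaling by the fraction of the
opening covered by the images (51% in the default configuration) is
applied; that fraction is carried as metadata and flagged in the CLI
output.

## The three mesh-attenuation models

The mesh cap's effect is the contested part of the analysis chain.
`gamma_apply()` implements three variants:

* **mesh** — the wind-tunnel power law
  $\gamma_m = 5.95\times 10^{-3}\, X^{-0.439}$ with
  $X = d_a v_t/\nu$ (settling parameter; $v_t$ terminal settling
  velocity of the unit-density sphere of diameter $d_a$, $\nu$ kinematic
  viscosity).  Because $X \propto d_a^3$ in the no-slip regime, the
  power law grows without bound for fine particles: their deposit is
  divided by a large $\gamma$, i.e. fine mass is strongly discounted.
* **hybrid** — the power law capped at the open-area ratio of the mesh,
  $\gamma = \min(\gamma_m, 0.27)$.  The cap expresses that a mesh whose
  open fraction is 0.27 cannot *enhance* transmission above purely
  geometric blocking for small, flow-following particles.
* **area** — the constant $\gamma = 0.27$ at every size: geometric
  blocking only, appropriate when there is no wind to interact with the
  mesh (the wind-tunnel law was derived under flow).

Since $\gamma_{hybrid} \le \gamma_{mesh}$ and
$\gamma_{hybrid} \le 0.27$ pointwise and $C \propto 1/\gamma$ per
particle, inferred concentrations order as
$C_{hybrid} \ge C_{mesh}$ and $C_{hybrid} \ge C_{area}$ on any particle
table — a property the test suite checks on random tables, and one
useful for catching sign errors in any reimplementation.

## Microphysics

* **Slip correction** (`slip_correction()`): the single-expression form
  $C_c = 1 + (\lambda/d)(2.514 + 0.800\,e^{-0.55 d/\lambda})$, with the
  mean free path scaled from 66.5 nm (293.15 K, 101.325 kPa) with
  temperature and pressure.
* **Settling** (`settling_velocity()`): Stokes with slip,
  $v_t = \rho_0 d_a^2 g C_c/(18\mu)$, $\rho_0 = 1000$ kg m$^{-3}$; a
  warning (not an error) is raised above 100 µm where Stokes drag
  degrades.
* **Viscosity**: Sutherland's law
  $\mu = 1.458\times10^{-6}\,T^{1.5}/(T+110.4)$; both $\mu$ and
  $\lambda$ are overridable in `air_environment()` so any reference
  convention can be reproduced exactly.
* **Deposition velocity** (`deposition_velocity()`): the quiescent
  combined settling + diffusion form
  $v = v_t/(1 - e^{-v_t \delta_b / D})$ through a laminar boundary layer
  of thickness $\delta_b$ (default 1 mm).  It has the correct limits
  ($v \to v_t$ for coarse particles, $v \to D/\delta_b$ for ultrafine
  ones, $v \ge \max(v_t, D/\delta_b)$ everywhere) and reduces to pure
  settling for all supra-micron particles, which carry the mass here.
  An impaction term is deliberately omitted: the measured wind speed in
  the motivating deployments was 0 m s$^{-1}$.  $\delta_b$ is the one
  free parameter of the deposition model; at 1 mm the diffusive branch
  only matters below ~0.1 µm, far below the imaging resolution, so
  results are insensitive to it in practice.

### Diameter conventions

The microscope measures a projected area, summarised as the
projected-area diameter $d_{pa}$ (circle of equal area).  The package
converts with two shape factors (defaults 1.6 volume, 1.4 dynamic — the
values commonly applied to heterogeneous mineral dust):

* volume: $V = (\pi/6)\, d_{pa}^3 / S_V$, hence mass
  $m = \rho_p V$ (`particle_mass()`; pg when µm and g cm$^{-3}$);
* volume-equivalent diameter $d_{ve} = d_{pa} S_V^{-1/3}$;
* aerodynamic diameter from
  $d_a^2 C_c(d_a) \rho_0 = d_{ve}^2 C_c(d_{ve}) \rho_p/\chi$, solved by
  fixed-point iteration to $10^{-6}$ µm
  (`projected_to_aerodynamic()`; the closed no-slip form
  $d_a = d_{ve}\sqrt{\rho_p/(\chi\rho_0)}$ is available and exact for
  supra-micron particles).

The volume convention with $S_V$ in the denominator is chosen so that
$S_V = \chi = 1, \rho_p = 1$ g cm$^{-3}$ is an exact identity
configuration (tested).  Published conventions differ on whether 1.6 is
a divisor of the sphere volume or a general $k$ in $V = k d^3$; the
default is **not** silently changed — override
`material_properties()` if your convention differs.

## Image processing

Images are integer matrices (8- or 16-bit); plain-text PGM is the
exchange format (`read_pgm()`/`write_pgm()`) because the deliverable
environment has no TIFF/PNG reader — converting microscope TIFFs is a
one-liner upstream (`convert img.tif img.pgm`).

**Thresholding** (`threshold_image()`): two histogram criteria, chosen
to match the reported workflow.  *Rényi entropy*: the threshold
maximising the summed order-$\alpha$ Rényi entropies of the two classes;
$\alpha = 1$ (the default) is the classic maximum-entropy (Kapur)
criterion.  The full three-threshold weighted combination that some
implementations apply is not reproduced; $\alpha$ is exposed instead.
*Triangle*: maximum distance from the histogram to the chord joining the
peak to the far end of its longer tail.

**Labelling** (`extract_particles()`): 8-connected components (the
particle-analysis default; 4-connectivity available), labelled via the
pixel-adjacency graph.  Area is the integer pixel count divided by
(px/µm)²; no sub-pixel sizing, matching the one-pixel minimum rule.

**Filtering** (`filter_particles()`): the three exclusion rules — area
at least one pixel (0.34 µm² at 1.71 px/µm), area at most 10⁴ µm²
(larger objects cannot have passed the mesh cap), and exclusion of
border-touching particles, whose truncated area is unknowable.  The
analytic cost of the edge rule is
`edge_exclusion_fraction()`: $1-(W-d)(H-d)/(WH)$, about 3.9% for 10-µm
particles on a 450 × 600 µm field and rapidly smaller for finer ones.

### Thresholding under uncorrelated noise, and the refinement pass

Both histogram criteria place the threshold near the foot of the
background peak — about 3σ above the background mean on the synthetic
images this package renders.  Real SEM backgrounds are spatially
correlated, so this is harmless there; under the renderer's *iid*
Gaussian noise model, however, a 0.79-Mpx field has hundreds of lone
background pixels beyond 3.3σ, which enter the mask as one-pixel
"particles" and occasionally attach to a particle rim.  This is a
property of the noise model, not of the criteria (verified against an
independent implementation of the triangle method, which picks the same
threshold).  `threshold_image(refine = TRUE)` adds one ISODATA-style
reassignment: each initial foreground pixel is kept only if its
intensity is closer to the foreground class mean than to the background
class mean.  Noise pixels (a few σ above background) fall far below the
class midpoint and are removed; true particle pixels are untouched.  The
refinement is off by default (the field workflow's rules are kept
verbatim) and on in the synthetic round-trip tests, which is what a
green round-trip test does and does not establish: segmentation and
sizing are exact to ±1 px per particle *given* a mask cleaned of
uncorrelated-noise artefacts.  Entropy-criterion thresholds additionally
drift with the foreground fraction, so the round-trip tests use the
triangle criterion, whose peak-to-tail geometry is stable across the
noise levels and surface loadings tested.

## Fraction conventions

`fraction_efficiency()` weights each particle's contribution by a
collection-efficiency curve in $d_a$:

* `step` — ideal indicator at the cut diameter;
* `lognormal_sigmoid` — $1 - \Phi(\ln(d_a/d_{50})/\ln \sigma_g)$, the
  sharp impactor-like curve (default $\sigma_g = 1.1$ for PM10/PM2.5);
* `iso_respirable` — the shallow respirable convention
  $0.5\,(1+e^{-0.06 d_a})\,(1-\Phi(\ln(d_a/4.25)/\ln 1.5))$, whose 50%
  point falls at 4.0 µm (tested to ±0.005).

With these, PM2.5 ≤ respirable ≤ PM10 ≤ total on any particle table.
Field blanks are corrected by subtracting the group mean
(`blank_correct()`); negative corrected values are preserved unchanged,
since truncation would bias group means upward.  Size distributions
(`size_distribution()`) are reported as $dM/d\log d_a$ — each bin's mass
divided by its log10 width — so instruments with different bin grids can
be overlaid; mass outside the grid is accumulated into reported
under/overflow attributes, never dropped silently.

## Comparison statistics

* `icc_mixed()` — REML fit of
  `value ~ location + time + (1 | occasion)` (lme4), with
  $\mathrm{ICC} = \sigma^2_b/(\sigma^2_b+\sigma^2_w)$: the share of
  post-fixed-effect variance that separates measurement occasions.
  Zero between-variance estimates (REML truncation) yield ICC 0 with a
  `singular` flag.
* `icc_bootstrap_ci()` — basic bootstrap interval
  $(2\hat\theta - q_{0.975},\, 2\hat\theta - q_{0.025})$ clipped to
  $[0,1]$.  The default resampling is **parametric** (responses
  simulated from the REML fit and refitted).  Design rationale: with 12
  occasions the dominant uncertainty is the between-occasion variance;
  resampling replicates within occasions holds it essentially fixed and
  produced ~55–60% empirical coverage at nominal 95% in our
  simulations, the occasion-level cluster bootstrap ~62%, the
  parametric bootstrap ~79%.  Both nonparametric units remain available
  (`unit =`).  Known limitation, stated rather than hidden: even the
  parametric *basic* interval is anti-conservative at 12 clusters; the
  test suite asserts the measured behaviour, not nominal coverage.
* `model_deviation_test()` — per measurement, the squared distance to
  the reference instrument's occasion mean; analysis models are compared
  by **paired** t-tests on these squared deviations, paired by sampler,
  because every model is a deterministic transform of the same raw
  deposit (an unpaired test would discard that structure).
* `origin_regression()` — slope $\sum xy/\sum x^2$ with the uncentred
  through-origin $R^2$; `descriptives()` — mean, SD, CV, median,
  type-7 (linear interpolation) quartiles, min, max.

## The synthetic world

`simulate_deposition()` draws a lognormal mass-size distribution
(defaults MMAD 5 µm, GSD 2, 1 mg m$^{-3}$ — a single coarse mode on the
concentration scale of workplace mineral dust) on an 80-bin log grid of
aerodynamic diameter (0.2–50 µm), converts bin mass to expected particle
counts through the per-particle mass (the discrete form of the
Hatch–Choate mass–number relation), deposits Poisson counts with
expectation $N_j = n_j \gamma(d_{a,j}) v_{dep}(d_{a,j}) A t$, places
them uniformly, and back-computes image-plane sizes by inverting the
aerodynamic conversion.  The attached ground truth records the
recoverable concentration on the grid and its exact Poisson standard
error $\sqrt{\sum_j N_j c_j^2}$, so round-trip tests can assert recovery
within 3 SE without re-deriving the error budget.

`render_image()` draws each particle as a disc of **matching projected
area** — the `round(area·ppm²)` pixels nearest the centre — rather than
by a centre-in-circle test, whose Gauss-circle rasterisation error (up
to several pixels per disc) would defeat per-particle ±1 px validation.
Discs clip at the border and are recoverable as edge-touching.  The
noise model is additive iid Gaussian only; charging, focus, astigmatism
and spatially correlated background are *not* emulated, so a green
imaging round trip establishes the correctness of the segmentation
arithmetic, not robustness to real SEM artefacts.  Touching particles
are not split (no watershed): at high surface loading, merging is a
known bias of the pipeline, and the synthetic layouts used for
validation keep discs separated.

`simulate_study()` generates the variance-component world of the ICC:
occasion fixed means (default an additive 4 × 3 grid around
0.5 mg m$^{-3}$) plus a Normal between-occasion effect and replicate
noise (defaults 0.045 (mg m$^{-3}$)² each, the magnitude reported for
passive-sampler PM10 data).

## Numerical choices and degenerate inputs

* Fixed-point iterations for the diameter conversions stop at
  $10^{-6}$ µm and error after 100 iterations (never observed below
  100 µm).
* `deposition_velocity()` evaluates $v_t/(-\mathrm{expm1}(-x))$ for
  accuracy at small $x$ and returns the analytic limit $D/\delta_b$
  below $x = 10^{-12}$; huge $x$ returns $v_t$ exactly.
* Constant images have no defined threshold: empty mask plus warning.
* Empty particle tables quantify to 0 with a warning; empty blank
  groups are a configuration error.
* Ties in the triangle criterion and in disc rasterisation are broken
  by index — all pipelines are bit-reproducible under a fixed seed, and
  every stochastic entry point takes one.
* The deposition simulator refuses expected counts above 10⁷.

## Known limitations

* The mesh-factor power law is implemented as printed over all sizes;
  its original wind-tunnel validity range is not modelled.
* No interception or electrostatic deposition terms; no wind dependence.
* Segmentation does not split touching particles.
* ICC confidence intervals are anti-conservative for designs with few
  occasions (see above).
* The field study's printed concentrations, deviations and ICCs are not
  reproducible from code: the underlying raw data were never deposited.
  Nothing in this vignette states an empirical result that the test
  suite or `scripts/acceptance.R` does not itself compute.
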