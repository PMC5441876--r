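---
title: "Modeling the evolution of bacterial migration through soft agar"
author: "chemomigrate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the evolution of bacterial migration through soft agar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemomigrate)
```

# The system

When chemotactic *E. coli* are inoculated at the center of a low-viscosity
(0.3% w/v) agar plate, they consume nutrient locally, create a radial
nutrient gradient, and chase it outward. The outermost edge of the expanding
colony — the migrating front — moves at a constant speed `s` once an initial
growth phase has passed. Selecting cells repeatedly from that front selects
simultaneously on swimming and growth, and the two traits trade off: in rich
medium faster migration evolves through faster swimming at the cost of
growth, in minimal medium through faster growth at the cost of swimming.

`chemomigrate` implements the quantitative machinery needed to study this
process end to end: a reaction-diffusion front simulator, a mapping from
single-cell swimming statistics to the simulator's transport coefficients, a
run–tumble trajectory classifier, image-based front-speed measurement, a
G-matrix/selection-gradient model of correlated-trait evolution, and
synthetic-data generators that give every stage a ground truth.

# The reaction-diffusion model

Cell density $\rho(r,t)$ (cells/mL) and a single attractant/nutrient
$c(r,t)$ (mM) evolve according to the classic Keller–Segel system with Monod
growth:

$$\partial_t \rho = D_b \nabla^2 \rho
  - \nabla\!\cdot\!\left(\frac{k_0 K_D}{(K_D + c)^2}\,\rho\,\nabla c\right)
  + k_g\,\rho\,\frac{c}{K_g + c},$$

$$\partial_t c = D_c \nabla^2 c - \frac{k_g}{Y}\,\rho\,\frac{c}{K_g + c}.$$

The three flux/reaction terms are undirected motility (diffusion constant
$D_b$, cm²/h), chemotaxis down the receptor law
$\chi(c) = k_0 K_D/(K_D+c)^2$ (chemotactic coefficient $k_0$, cm²/h;
receptor binding constant $K_D$, mM), and Monod growth (maximum rate $k_g$,
1/h; half-saturation $K_g$, mM). Consumption mirrors growth through a
constant yield $Y$ (cells/mL/mM). A single nutrient suffices because the
outermost rich-medium front chases serine while minimal medium contains only
galactose; secondary rings are deliberately unmodeled.

Shipped presets (`rd_params_preset()`) transcribe the founder parameter
sets: rich medium (`c0` = 1 mM serine-like attractant, `KD` = 2 mM,
`kg` = 1.23/h, `Kg` = 0.13 mM, `Y` = 5e7) and minimal medium (`c0` = 0.18 mM
galactose, `KD` = 0.1 mM, `kg` = 0.125/h, `Y` = 3e8), both with
agar-corrected transport (next section). The minimal-medium `Kg` is not
legible in the available source material; the package defaults to 1e-3 mM,
sub-saturating relative to `c0` (growth then runs at essentially `kg` until
the nutrient is nearly exhausted). Fitted front speeds are insensitive to
`Kg` well below `c0` — halving or doubling 1e-3 mM moves `s` by far less
than the acceptance tolerance — because the wave is fed by the nutrient flux
rather than the shape of the uptake curve near depletion.

## Numerics

The solver (`rd_simulate()`, in C++) integrates the 1-D axisymmetric
reduction with the Laplacian $(1/r)\partial_r(r\,\partial_r\cdot)$ and
no-flux boundaries at the plate center and edge, using a conservative
finite-volume discretization: central differences for both diffusion terms,
first-order upwinding on the face chemotactic velocity
$u = \chi(c)\,\partial_r c$ (the standard positivity-robust choice for
Keller–Segel advection), and explicit time stepping bounded by the diffusive
stability limit and the advective CFL condition. The Monod consumption step
is exponential (Patankar-type): $c \to c\,e^{-\lambda \Delta t}$ with
$\lambda = k_g \rho / ((K_g + c) Y)$, and growth is credited as exactly $Y$
times the nutrient consumed. This keeps $c \ge 0$ unconditionally (no
time-step collapse as $c \to 0$) and makes the mass-balance identity
$\int \Delta\rho\, dV = Y \int \Delta c\, dV$ hold to roundoff; the test
suite checks it to 1%, along with positivity
($\min \rho \ge -10^{-9} \max\rho$) and $0 \le c \le c_0$.

The initial condition spreads the inoculum (default $10^6$ cells) uniformly
over a central disc of 0.25 cm radius and 0.4 cm effective depth — a 10 µL
spot on a 15 cm plate; the front speed is insensitive to this footprint.
Integration stops early once the leading density tail (1e3 cells/mL)
reaches the outermost cell, because later front positions would be distorted
by the no-flux wall and are discarded anyway.

## Front extraction and the migration rate

`front_position()` locates, per snapshot, the outermost radius where $\rho$
crosses a threshold (default 10% of the instantaneous spatial maximum,
linearly interpolated between grid points); positions within 0.5 cm of the
domain edge are flagged invalid. `migration_rate()` regresses radius on time
by ordinary least squares over a late-time window and reports the slope,
standard error and $R^2$. In the traveling-wave regime the fitted speed
varies by less than 3% as the threshold sweeps 0.05–0.3 of the maximum
(tested), and $R^2 > 0.99$.

Two protocol choices deserve explanation:

* **Window.** `migration_rate()` defaults to the last 50% of the trace,
  which excludes the initial growth phase. The *reproduction protocol*
  (`repro_settings()`), however, regresses over the final 25%: in
  axisymmetric geometry the front also carries a curvature transient that
  decays like $1/r$ and persists beyond half of a 12-hour rich-medium trace
  (the instantaneous front speed still rises from 0.598 to 0.607 cm/h over
  the final quarter, toward a planar asymptote of 0.64 cm/h). A half-trace
  window therefore systematically underestimates the asymptotic rate.
* **Grid.** The solver's default spacing is 50 µm. The reproduction protocol
  uses 100 µm: halving the spacing changes the fitted speed by less than
  0.1% in both media (a convergence check is part of the suite), and the
  coarser grid keeps full landscape sweeps cheap.

With these settings the founder presets yield `s` = 0.598 cm/h (rich, 12 h)
and 0.083 cm/h (minimal, 48 h). In the chemotaxis-free, nutrient-saturated
limit the solver reproduces the Fisher–KPP pulled-front speed
$2\sqrt{D_b k_g}$ within its slow algebraic relaxation (tested within 10%
after inoculating at carrying density to skip the growth lag).

# From single cells to transport coefficients

Motility consists of runs (nearly straight swimming at speed $|v_r|$,
~0.5–1 s) interrupted by tumbles that reorient the cell. In agar the matrix
adds forced reorientations: encounters with the gel act like collisions with
a concentration-dependent mean free path. `agar_transport()` maps a strain's
bulk swimming statistics — run speed $|v_r|$ (µm/s) and tumble frequency
$\alpha_0$ (1/s) — to the plate-scale coefficients at agar concentration
$C$:

$$D_b = \frac{v_r^2}{3\,(\gamma\,\alpha_0 + v_r/\ell_D(C))}, \qquad
  k_0 = \frac{v_r\,\ell_k(C)}{3}, \qquad
  \ell(C) = \ell_{\mathrm{ref}}\,\frac{C_{\mathrm{ref}}}{C}.$$

The diffusivity keeps a weak dependence on the intrinsic tumble rate while
chemotaxis is scattering-dominated. The three constants
($\gamma = 0.01745$, $\ell_D = 105.9$ µm and $\ell_k = 2878$ µm at
$C = 0.3\%$) were calibrated once, jointly, against published agar-corrected
coefficients for seven strains spanning both media; the calibrated mapping
reproduces every row within 10% with no per-strain adjustment
(`strain_transport_table()`, tested). Both coefficients are monotone:
non-decreasing in run speed, non-increasing in tumble frequency and in agar
concentration (tested). At $C = 0$ the mapping returns the liquid-culture
reference values (`liquid_transport()`: $D_b$ = 0.0576, $k_0$ = 6.12 cm²/h)
unchanged; the microscopic estimate does not extrapolate continuously to
those literature values — run–tumble kinematics alone under-predicts liquid
diffusivity — so the liquid reference is a lookup, not a limit, and the
mapping is capped at it. The functional form sits behind a strategy
interface (`scattering_strategy()`), so alternative published corrections
can be swapped in without touching callers.

# Run–tumble classification

`segment_runs_tumbles()` implements an iterative adaptive-threshold
classifier. Velocities come from central differences
(`compute_kinematics()`; one-sided and flagged at the endpoints), and the
angular velocity $\omega(t)$ is the angle between adjacent velocity vectors
per frame interval. Internally the threshold $\alpha$ is an angle per frame,
so that the two comparisons the rules need — against $\omega$ and against a
displacement angle — are dimensionally uniform; reports also give rad/s.

A tumble is initiated when $\omega(t)$ and $\omega(t+1)$ both exceed
$\alpha$, or when $\omega(t)$ exceeds $\alpha$ and the angle between the
displacement vectors $x(t-2)-x(t)$ and $x(t)-x(t+2)$ exceeds $\alpha$ — the
one-frame rule that catches reorientations faster than the 33 ms frame
interval. A run is initiated only when $\omega(t)$, $\omega(t+1)$,
$\omega(t+2)$ all lie at or below $\alpha$ (ties count as below, for
determinism). Tumbles can therefore be instantaneous while runs span at
least four frames (enforced). The threshold starts at 2 rad/frame (the
published procedure does not print its initial value; convergence makes the
choice immaterial) and is iterated ten times as
$\alpha \leftarrow c \times \mathrm{median}(\omega_{\mathrm{runs}})$ with
$c = 5$, typically converging in fewer than five iterations; an iteration
that finds no run frames keeps the previous threshold and flags the cell.

`motility_stats()` excludes sustained tumblers (mean tumble duration
\> 0.4 s), drops boundary-interrupted runs from run statistics (a run is
interrupted when adjacent to frames within 5 µm of the chamber wall — the
margin is a package choice, not published), and computes tumble bias (bulk
time fraction spent tumbling) and tumble frequency (bulk tumbles per bulk
second) per cell before averaging. `ccdf()` gives the survival function of
run durations under the right-open convention — the fraction of runs
*strictly longer* than $\tau$ — with a percentile bootstrap band. A
pluggable `circling_filter` hook exists for wall-induced circling; the
default is a no-op because the published detection procedure is not
reproducible from the available text.

On seeded 200-cell synthetic ensembles spanning mean run durations
0.3–1.0 s, the classifier recovers the generator's mean run duration and
tumble frequency within 15% (tested); the floor on accuracy is the
four-frame minimum run length at 30 frames/s, which censors the shortest
runs of an exponential duration distribution.

# Synthetic data

`gen_run_tumble_trajectory()` draws alternating run/tumble intervals in
continuous time — durations exponential with the requested means (published
sources give only means and SDs; exponential is the minimal run–tumble
model), per-run speeds normal (truncated at zero), turn angles
wrapped-normal with random sign (mean 68°, SD 36°, the classic tumble-angle
scale; the true law is not published and both are configurable) — then
samples positions at the frame rate with additive centroid noise, reflecting
specularly off the circular chamber wall and flagging near-wall frames.
Per-frame labels are derived from the event list by one rule, so labels and
events are mutually consistent by construction (tested by re-derivation),
and identical seeds give bit-identical output. Defaults emulate a
founder-like rich-medium cell: 0.66 s runs at 18.7 ± 7.1 µm/s, 0.18 s
tumbles, 30 frames/s, in a 200-µm-diameter chamber.

`gen_colony_image_series()` renders a radially expanding Gaussian annulus
over a constant background with additive Gaussian noise and a programmed
constant front speed, returning the ground-truth radii alongside the
frames. `gen_phenotype_population()` draws phenotypes from
$\mathcal{N}(\bar\phi, G)$.

What these generators deliberately do not emulate: optics (no point-spread
function, vignetting or illumination drift), secondary rings, cell-level
heterogeneity of motility parameters within one trajectory, hydrodynamic
wall interactions, and 3-D swimming. Tests passing on this synthetic data
therefore validate the algorithms' correctness and calibration, not their
robustness to every artifact of real movies and webcam images.

# Image-based front tracking

`front_trace_from_stack()` chains the published measurement procedure:
median projection of the first six frames as background (median, not mean,
so a single corrupted frame has no effect — tested), subtraction with
clipping at zero, colony center via edge detection plus circular Hough
transform, then per-frame front radius. Edge detection is a compact
Sobel-magnitude detector with hysteresis thresholds auto-scaled from the
gradient distribution, feeding a parametric Hough accumulator (C++); no
installed package provides these primitives. In rich-medium mode, radial
intensity profiles are measured in 36 azimuthal sectors — not averaged over
the full circle, out of respect for departures from circularity — and the
sector-median of the outermost local maximum above a noise floor is
reported; profiles stop at the inscribed circle because corner bins hold too
few pixels to average noise down. The sector count and the median
aggregation are package choices; the published text says only that profiles
were not azimuthally averaged. In minimal-medium mode (signal-to-background
near 2) the Hough transform locates the front circle directly; because
gradient maxima sit on a ring's flanks rather than its crest, the radius is
refined to the peak of the full azimuthal mean profile within a window
around the Hough circle, with parabolic sub-pixel interpolation.
`front_speed()` shares the regression contract of `migration_rate()`;
flagged frames are dropped, never interpolated. End to end, programmed
speeds of 0.05–0.6 cm/h are recovered within 2% at signal-to-noise 5
(tested).

# The selection model

Evolution of the founder-normalized phenotype vector
$\phi = [\tilde v_r, \tilde k_g]^T$ under selection for faster migration is
modeled by the Lande response $\phi = G\beta + \phi_0$, with

$$G = \begin{pmatrix} \sigma_{v}^2 & \rho_G\,\sigma_{v}\sigma_{k} \\
\rho_G\,\sigma_{v}\sigma_{k} & \sigma_{k}^2 \end{pmatrix}$$

the genetic covariance of the two traits ($\rho_G < 0$ encodes the
trade-off) and $\beta$ the selection gradient — the gradient of the
(normalized) migration rate over phenotype space, obtained by
`fit_selection_gradient()` as a least-squares plane through the simulated
landscape $\tilde s(\tilde v_r, \tilde k_g)$ (`migration_landscape()`). A
`use_log` flag fits $\log \tilde s$ instead, matching the logarithmic
definition of selection strength; near the founder, where $\tilde s = 1$,
the two gradients agree to first order.

**A caution on the unit-normalized gradient.** $\hat\beta$ is *not* an
invariant of the biology: it depends on the extent of the grid the plane is
fit to (the surfaces are curved, so wider grids average different secant
slopes) and on the axis convention. On founder-normalized axes over the
founder-to-evolved span — the package's fixed convention — the rich-medium
landscape gives $\hat\beta_{RM} \approx [0.52, 0.85]$ and the minimal-medium
landscape $\hat\beta_{MM} \approx [0.22, 0.98]$. The minimal-medium value is
extremely sensitive: extending the growth-rate axis deep into the
traveling-wave regime flips the direction from growth-dominated to
speed-dominated (as far as $[0.98, 0.22]$ at $k_g$ up to 1.5/h), because
normalization by the slow founder rate amplifies the speed sensitivity of
the fast-wave region while the $\sqrt{k_g}$-like concavity dilutes the
growth secant. The plane fit's residual is correspondingly large in minimal
medium, where the landscape contains an abrupt transition (next paragraph)
and is poorly described by any plane. Comparisons of $\hat\beta$ across
studies are only meaningful with the fit region and axis convention stated.

The minimal-medium landscape contains a sharp transition near
$k_g \approx 0.2$/h — located by `kg_sweep_minimal()` as the point of
steepest change in $s(k_g)$ (0.175/h on the default 8-point sweep) — that
separates diffusion-dominated expansion from a chemotactic traveling wave.
The founder (0.125/h) sits below it, which is why founder minimal-medium
colonies expand diffusively.

`predict_response()` gives the predicted direction of evolution
$G\beta/\lVert G\beta\rVert$ (invariant to positive rescaling of either
factor, tested); `direction_agreement_sweep()` maps its dot product with an
observed direction over $(\sigma_v, \sigma_k, \rho_G)$. Because the
direction depends on the standard deviations only through their ratio, the
sweep reports, per $\rho_G$, the ratio interval where the dot product
clears an agreement threshold (default 0.95; no published cutoff exists).
With the published gradient directions and observed phenotype shifts, rich
medium agrees for $\sigma_v/\sigma_k \gtrsim 1$ and minimal medium only for
ratios below about one half — the qualitative conclusion that the
environment sets which trait has the genetic room to respond.

`stochastic_selection()` relaxes the linearity assumption: each round draws
`n_pop` = 1000 phenotypes from $\mathcal{N}(\phi_t, G)$, scores them by
bilinear interpolation on the landscape (nearest-edge clamping outside,
flagged), keeps the fastest 10% (truncation selection — the published
supplement does not state its scheme), and advances to their mean. In the
small-variance limit on a linear landscape the mean per-round displacement
aligns with $G\beta$ (dot > 0.99 averaged over replicates, tested), and on
a flat landscape it is an unbiased random walk (tested).

# Problem sizes and reproduction presets

`run_reproduction()` packages the named end-to-end experiments
(`founder_rich_s`, `founder_minimal_s`, `table3_transport`, `beta_vectors`,
`kg_transition`, `classifier_recovery`) with deterministic settings and
JSON reports; `scripts/acceptance.R` runs the same computations from
scratch. The problem sizes — 100 µm grid, 0.25 h snapshots, 12 h rich / 48 h
minimal horizons, 5×5 landscape grids, an 8-point growth-rate sweep,
200-cell classifier ensembles — are chosen so the full suite completes in
minutes while every reported quantity is grid- and size-converged to well
inside its comparison tolerance.

# Known limitations

* The model omits receptor adaptation, transient trapping in the agar
  matrix, multi-nutrient secondary fronts and oxygen dynamics; absolute
  predicted speeds exceed measured plate speeds for the founder (a
  known property of this model class), so comparisons are most meaningful
  between parameter sets, not against wet-lab absolutes.
* The agar-scattering calibration is anchored at $C = 0.3\%$; the $1/C$
  mean-free-path extrapolation is untested away from that concentration,
  and the liquid limit is handled by lookup rather than extrapolation.
* Unit-normalized selection gradients are presentation-dependent (above);
  the package fixes one convention and reports it.
* The synthetic generators validate algorithmic correctness, not robustness
  to real-world imaging artifacts.
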