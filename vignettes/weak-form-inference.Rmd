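---
title: "Weak-form inference of cell migration and proliferation from scratch assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weak-form inference of cell migration and proliferation from scratch assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A scratch (wound-healing) assay follows a confluent cell monolayer after a
strip has been cleared; the cleared region is re-occupied by a combination
of random cell motion, directed motion, and proliferation. `scratchpde`
models the cell number density $C(\mathbf{x}, t)$ (cells/µm², with time in
hours) with an advection–diffusion–reaction (ADR) equation

$$\frac{\partial C}{\partial t}
  = \nabla \cdot \big(D(C)\,\nabla C\big)
  - \nabla \cdot \big(C\, v_f(C)\, \mathbf{v}_{\mathrm{unit}}\big)
  + r(C),$$

with $\mathbf{v}_{\mathrm{unit}}$ a unit vector perpendicular to the wound
and density-dependent coefficients restricted to a quadratic ansatz:

$$D(C) = \theta_0 + \theta_1 C + \theta_2 C^2,\qquad
  v_f(C) = \theta_3 + \theta_4 C + \theta_5 C^2,\qquad
  r(C) = \theta_6 C + \theta_7 C^2.$$

A constant reaction term is excluded by construction: growth or death at
zero density is unphysical. Diffusion represents undirected migration
(µm²/hr), advection a directed bias (µm/hr), and the logistic-type reaction
combines proliferation ($\theta_6 > 0$, 1/hr) with crowding effects
($\theta_7 < 0$); the density at which $r$ vanishes,
$K = -\theta_6/\theta_7$, is the carrying capacity. In the three-term
reaction–diffusion notation used for sensitivity scans, $D_0 = \theta_0$,
$C_1 = \theta_6$, $C_2 = \theta_7$. Note that $K$ is the positive root of
$r(C) = C_1 C + C_2 C^2$, i.e. $-C_1/C_2$; writing the same ratio with the
coefficients in the opposite order does not survive dimensional analysis
([cells/µm²] must come out), and `carrying_capacity()` implements the
dimensionally consistent form.

## Two-stage inference

**Stage 1 — Variational System Identification (VSI).** The PDE residual is
tested in weak (Galerkin) form against piecewise-linear finite-element
basis functions $N_k$, transferring one derivative onto the weights so that
only first spatial derivatives of the noisy data field are ever formed.
Binned, smoothed density data are interpolated nodally
($d_i(t) = C^h(x_i, t)$), the time derivative is a backward difference
across frames, and each interior node and frame contributes one row of the
linear system $y = \Xi\,\theta$, with one library column per ansatz term
(`build_library()`). Dirichlet conditions are imposed on the whole
boundary, so boundary weighting rows are dropped and no Neumann term
appears. Least squares (`solve_ls()`), greedy backward elimination
(`stepwise_regression()`), and elbow selection (`select_model()`) then
identify a parsimonious operator set.

**Stage 2 — PDE-constrained refinement.** The selected model is re-fit by
minimizing the squared space–time $L^2$ misfit between a full nonlinear
forward solution and the data (`misfit_loss()`), over the active
coefficients only, with bound-constrained L-BFGS-B and gradients from the
discrete adjoint of the implemented backward-Euler/Newton scheme
(`loss_gradient()`, `refine_parameters()`). Refinement never changes the
selected operators. Active diffusivity coefficients are bounded below by
zero, and positivity of $D(C)$ over the observed density range is checked
after the fit.

## Numerical choices

* **Quadrature.** Gauss–Legendre rules exact to polynomial degree ≥ 4
  (3-point segments, 6-point triangles): integrands reach degree 3 in the
  interpolated density for the quadratic ansatz, so quadrature error is
  removed from all comparisons.
* **Time stepping.** Implicit backward Euler with an analytic Jacobian and
  Newton tolerances $10^{-8}$ (absolute) and $10^{-9}$ (relative). The
  first-order accuracy in $\Delta t$ and second-order accuracy in $h$ are
  verified against the separation-of-variables solution of the heat
  equation in the test suite.
* **Newton globalization.** A plain Newton iteration is tried first;
  failures fall back to residual-norm backtracking and then to a recursive
  half-stepping *predictor* whose result seeds a final Newton solve of the
  full step, so the accepted state always satisfies the single-step
  residual and the discrete adjoint stays exact. This matters because the
  single-step problem can lose its physical solution branch entirely at
  aggressive trial coefficients: continuation in the step size shows a fold
  (turning point) near $\theta_6 \Delta t \approx 1$. For the same reason
  the noise-free closure experiments use hourly frames, where the step
  problem is well-posed even at twice the generating coefficients.
* **Optimizer tolerance.** `optim`'s `factr` maps the bound-constrained
  quasi-Newton stopping rule onto relative objective reduction. On
  noise-free closure problems the misfit decays through ~10 orders of
  magnitude, so the default is `factr = 10` (≈ machine precision);
  the pipeline uses `factr = 1e3` on noisy data, whose misfit floor is far
  above machine precision.
* **Degenerate inputs.** Rank-deficient active column sets fall back to
  the minimum-norm least-squares solution (flagged); an empty active set
  returns the zero model with loss $|y|^2$; a Hessian that is not positive
  definite is pseudo-inverted with the flat directions reported.
* **Selection floors and ties.** On noise-free data all elimination-path
  losses sit at machine noise, so the relative elbow rule carries an
  absolute floor of $10^{-12}|y|^2$; stepwise ties (losses within
  $10^{-12}$ relative, or within a $\chi^2_1$ quantile of the estimated
  noise variance on noisy data) are resolved by dropping the
  higher-order term, preferring simpler density dependence.

## Estimator design for counting noise

The observation process is bin counting: with ~10 cells per 100 µm bin the
per-bin density noise is ≈ 30%, independently re-drawn each frame. Four
design choices, each validated on noise-free data first, make the pipeline
robust in this regime:

1. **Midpoint library evaluation** (`scheme = "midpoint"`). Evaluating the
   library columns at the same frame as the backward difference correlates
   the column noise with the target noise and produces a large spurious
   *negative* diffusivity (both contain the same frame's counting error;
   the covariance scales like noise variance / $\Delta t$). Evaluating at
   the nodal average of the two frames cancels this covariance exactly for
   stationary noise; the cost is an $O(\Delta t)$ consistency error, which
   the test suite shows vanishing under refinement. The `"backward"`
   default remains exactly consistent with the implicit solver and closes
   to machine precision on noise-free solver-generated data.
2. **Derivative stride.** The backward difference spans at least the
   temporal smoothing window (11 frames at the 20-min cadence), so the
   moving-average windows of its two endpoint frames do not overlap and
   their noise stays independent.
3. **Raw refinement targets.** The 150 µm spatial filter injects
   ≈ 3.3×10³ µm² of spatial variance — more than double the physical
   diffusion spread $2 D T \approx 1.4\times 10^3$ µm² over 48 h at
   $D = 30$ µm²/hr — so fitting *smoothed* profiles systematically crushes
   the inferred diffusivity. Smoothing exists to stabilize the
   *derivatives* taken in stage 1; stage 2 takes no data derivatives and
   therefore fits the raw binned fields, whose noise is independent across
   frames and averages out of the trajectory misfit. Initial and boundary
   (Dirichlet) traces, which *drive* the forward solve, are smoothed in
   time only: that suppresses their counting noise by ≈ √6 without
   smearing the profile (a forward solve from an artificially widened
   scratch compensates by suppressing $D$, and from a raw noisy initial
   profile by inflating it — diffusion is the model's only mechanism for
   dissipating initial spikes).
4. **Model adoption.** At these conditions the weak-form loss is almost
   exactly flat in the diffusion direction (dropping $\theta_0$ changes
   the residual sum of squares by $\chi^2 \approx 0.2$): the 48-hour
   diffusion length $\sqrt{2DT} \approx 54$ µm is below one bin, so no
   selection rule can retain diffusion from the library alone, even though
   the wound-edge dynamics require it. When selection returns a pure
   reaction model the pipeline adds the constant-diffusivity term back
   before refinement, where trajectory fitting makes $D$ identifiable.
   This mirrors the standard practice of adopting a three-term
   reaction–diffusion model when the elbow flattens early, and of
   expanding a model whose diffusion sensitivities stay low.

Model selection itself offers two rules. The relative rule
(`rel_tolerance = 0.05`) matches published elbow curves where the loss
floor reflects model error. On calibrated synthetic counts the floor is
sampling noise and scales differently: any fixed relative tolerance is
either far above or far below the noise scale, so
`select_model(rel_tolerance = NULL)` compares the loss growth of a
$k$-term model against a $\chi^2_{8-k}$ quantile of the noise variance
estimate $\hat\sigma^2 = \mathrm{loss}_{\mathrm{full}}/(n-8)$.

## Uncertainty

`loss_contours()` scans the misfit over pairs of active parameters
(others fixed at their inferred values; default ±50%, 41×41 grid),
normalized by the grid minimum. The reaction pair shows the characteristic
elongated valley: an affine $C_1$–$C_2$ trade-off whose flat direction has
slope set by the mean observed density, so the carrying capacity
$-C_1/C_2$ is sharply estimated while the growth rate is not. The
diffusion directions are shallow, consistent with the weak identifiability
discussed above.

`laplace_covariance()` builds a local Gaussian approximation at the
minimum: covariance $2\hat\sigma^2 H^{-1}$ with $H$ the misfit Hessian by
central differences of the adjoint gradient, and
$\hat\sigma^2 = \mathrm{misfit}/(\text{residual dof})$. The convention is
recorded in the output. Calibration holds in the regime the approximation
describes — independent observation noise around an exact model class: in
repeated-seed recovery experiments driven by the true initial/boundary
traces, the empirical scatter of the recovered coefficients matches the
Laplace standard deviations and ≥ 90% of runs fall within 3 sd. When the
forward solve is instead driven by per-replicate noisy traces, residuals
acquire correlated components and the naive Laplace bands under-cover;
this limitation is intrinsic to the convention, not to its implementation.

## The synthetic generator

`generate_dataset()` emulates the observation process of a live-microscopy
scratch assay with nuclear markers: a tanh-edged scratch of width 400 µm
in a plateau at $10^{-3}$ cells/µm² (observed assay densities stay below
$2\times10^{-3}$), evolved by the truth model with zero-flux boundaries,
then observed by drawing per-bin Poisson counts and placing that many
centroids uniformly in each bin, for four replicate wells. Defaults: 2 mm
domain, 100 µm bins, frames every 20 min over 48 h (the cadence the
150 µm / 3 h 40 min smoothing windows were tuned for; the temporal filter
is inert at coarser cadences such as the 12-h profile series), 100 µm
strip width so a plateau bin holds ~10 cells, and truth
$\theta_0 = 30$ µm²/hr, $\theta_6 = 0.05$/hr, $\theta_7 = -30$
($K \approx 1.67\times10^{-3}$ cells/µm²). The scratch edge relaxes over
one bin so the initial profile is resolvable on the analysis mesh —
steeper edges produce piecewise-linear interpolation undershoot, negative
densities, and a clipping bias in closure experiments.

By default the truth is solved with one backward-Euler step per frame, so
the analysis discretization matches the generating one exactly and
recovery errors isolate observation noise. `n_substeps` refines the
generating integration for cadences long relative to the reaction time
scale: the 12-h profile series (`jin_like_profile_set()`, six seeding
densities, three replicates, $\theta_0 \in [8, 22]$ µm²/hr and
$\theta_6 \in [0.012, 0.036]$/hr) uses 15-min substeps, and its far-field
growth then matches $e^{\theta_6 t}$ to ~1%.

Aspects of real data the generator does **not** emulate: cell-to-cell
positional correlations (counts are independent Poisson draws per frame,
the worst case for time differences — real frame-to-frame noise is
correlated because cells persist), segmentation artifacts (merged or
missed nuclei), drift or illumination fields, replicate-to-replicate
variation in the initial scratch geometry (all replicates here share one
truth trajectory), and any delay or history dependence in migration.
Passing recovery tests therefore demonstrates correctness of the inference
machinery under calibrated counting noise, not robustness to every failure
mode of microscopy data.

## Problem sizes used in validation

The noise-free closure studies use the reference 1D configuration — a
uniform 42-element mesh — with hourly frames over 48 h; noisy recovery
uses the default generator above (10 seeds, four replicates each);
uncertainty calibration uses 20 seeds. Contour scans default to 41×41
grids. Convergence studies refine from 8 to 64 elements in space and from
$\Delta t = 0.1$ to $10^{-3}$ (dimensionless heat-equation setup).

## Known limitations

* Bins must hold enough cells for a continuum description: shrinking the
  bin size at fixed cell density raises the per-bin relative counting
  noise like $1/\sqrt{\text{count}}$ and degrades recovery — the reason
  binning at 50–100 µm (rather than finer) is the practical regime.
* Advection is carried through the library but the refinement path is not
  stabilized (no SUPG); strongly advection-dominated regimes are outside
  the intended use, matching the finding that advective terms drop out of
  scratch-assay closure models.
* Identifiability of the full quadratic ansatz from a single initial
  condition is not guaranteed; multiple coefficient sets can reproduce
  the same trajectories, which is why sensitivity scans and the Laplace
  summary are part of the workflow rather than an afterthought.
* The Laplace noise convention treats residuals as independent; see above
  for when that fails.
* 2D support covers meshing, interpolation, library assembly, and the
  forward solver on structured triangulations; the high-level
  `scratch_pipeline()` convenience chain is 1D (profiles averaged along
  the scratch), the configuration in which parameter recovery can be
  verified at interactive cost.
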