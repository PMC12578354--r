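# scratchpde

Inference of advection–diffusion–reaction (ADR) models of collective cell
migration and proliferation from scratch (wound-healing) assay data.

A scratch assay clears a strip in a confluent cell monolayer and images
its closure; the observed density field mixes the contributions of random
cell motion, directed motion, and proliferation, which the raw closure
fraction cannot disentangle. `scratchpde` separates them by fitting the
PDE

&nbsp;&nbsp;&nbsp;&nbsp;∂C/∂t = ∇·(D(C)∇C) − ∇·(C v_f(C) **v**) + r(C)

to binned nuclear-centroid density fields C(x, t) (cells/µm²), with the
quadratic ansatz D(C) = θ₀ + θ₁C + θ₂C², v_f(C) = θ₃ + θ₄C + θ₅C²,
r(C) = θ₆C + θ₇C², in two stages:

1. **Variational System Identification (VSI)** — linear regression of the
   weak (Galerkin) form of the residual on piecewise-linear finite
   elements, so only first derivatives ever touch the noisy data;
   greedy backward elimination over the 8-term operator library with
   elbow-based model selection yields a parsimonious model.
2. **PDE-constrained refinement** — the selected coefficients are re-fit
   by bound-constrained quasi-Newton (L-BFGS-B) minimization of the
   space–time L² misfit between a full nonlinear forward solve (implicit
   backward Euler + Newton) and the data, with gradients from the discrete
   adjoint. Diffusivities are constrained nonnegative.

Post-inference, two-parameter loss contours and a local Gaussian (Laplace)
covariance quantify sensitivity; the carrying capacity K = −θ₆/θ₇
summarizes the logistic reaction. A synthetic scratch-assay generator with
per-bin Poisson count sampling provides ground-truth datasets, so every
stage is verifiable by parameter recovery without any external data.

Intended users: quantitative cell biologists and modelers analyzing
scratch/wound-healing assays, and anyone studying weak-form PDE discovery
on noisy spatiotemporal count data.

## Worked example

Generate a synthetic assay at the default study conditions — 2 mm domain,
400 µm scratch, plateau 10⁻³ cells/µm² (~10 cells per 100 µm bin), frames
every 20 min for 48 h, four replicate wells, truth θ₀ = 30 µm²/hr,
θ₆ = 0.05/hr, θ₇ = −30 — and run the full pipeline:

```r
library(scratchpde)

dataset <- generate_dataset(synthetic_spec(seed = 1))
out <- scratch_pipeline(dataset)

out$selected                 # operators kept by the noise-calibrated elbow
#> [1] 6 7
out$active                   # after adopting constant diffusivity
#> [1] 0 6 7
print(out$refined)
#> <refine_result> loss 0.0302751 -> 0.0276832 in 56 evaluations
#>   theta**: theta0=31.89, theta6=0.050271, theta7=-30.995
carrying_capacity(out$refined$model)
#> [1] 0.001621922
```

Selection keeps the linear and quadratic reaction terms; the diffusion
signal is invisible to the weak-form library at this noise level (the
48-hour diffusion length, ~54 µm, is below one bin), so the pipeline adopts
the three-term reaction–diffusion model before refinement — the same model
adoption used in practice when the elbow flattens early. Refinement then
recovers the generating coefficients: θ₀ within ~6%, θ₆ within ~1%, and a
carrying capacity within ~3% of the true 1.67×10⁻³ cells/µm². The Laplace
summary puts honest widths on those numbers:

```r
print(laplace_covariance(out$refined$model, out$raw_series,
                         ibvp = lapply(out$raw_series, ibvp_from_series)))
#> <laplace_summary> covariance = 2 * sigma2 * H^-1; sigma2 = misfit / residual dof
#>   theta0 = 31.89 +- 2.19
#>   theta6 = 0.050271 +- 0.000881
#>   theta7 = -30.995 +- 0.659
```

Wound-closure quantification works on any 1D field (2D fields are first
averaged along the scratch):

```r
f1 <- collapse_to_1d(dataset$field)      # 1D fields pass through unchanged
closure_metrics(f1)$closure              # |d_start - d_end| / d_start
```

A thin command-line front-end wrapping these functions is installed at
`inst/cli/scratchpde` (subcommands `ingest`, `closure`, `vsi`, `simulate`,
`refine`, `synth`).

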