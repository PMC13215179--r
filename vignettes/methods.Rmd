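---
title: "Physics-informed velocimetry from tracer transport: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physics-informed velocimetry from tracer transport: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The inverse problem

Dynamic contrast-enhanced MRI of the rodent brain yields a time series of
3D tracer-concentration proxies after an infusion into the cerebrospinal
fluid. `tracerflow` reconstructs from such a series the **steady** velocity
field `u`, the pressure `P`, and the hydraulic permeability `K` of the
tissue, under three governing equations:

- advection–diffusion transport of the tracer,
  `c_t + u · ∇c = D ∇²c`, with constant diffusivity `D`;
- incompressibility, `∇ · u = 0`;
- Darcy's law for porous-media flow, `u = −K ∇P`, with `K = κ/μ`
  (intrinsic permeability over viscosity).

Reconstructing three velocity components from one scalar observable with no
boundary conditions is ill-posed. Substituting Darcy's law reduces the
unknowns to two scalar fields and yields the two residuals actually
minimized:

- transport: `c_t − (K∇P) · ∇c − D ∇²c = 0`
- continuity: `∇K · ∇P + K ∇²P = 0`

The permeability field doubles as a learned spatial map that lets the
solution span the orders-of-magnitude velocity contrast between open
conduits (perivascular and subarachnoid spaces) and porous parenchyma.

## Identifiability and the permeability gauge

`K` and `P` enter the equations only through products. Multiplying `K` by a
constant `a` and dividing `P` by `a` changes neither residual nor the
velocity: absolute permeability and pressure are identifiable only up to
this gauge factor, while their spatial *variations* are identified. The
package fixes the gauge by the characteristic pressure `P_char`
(default 1000 Pa, the order of intracranial pressure differences); all
velocity statements are gauge-invariant, and the test suite checks this
invariance end-to-end.

# Nondimensionalization and the data-driven gauge

The gauge is not merely cosmetic: the *balance* between the transport and
continuity losses is not gauge-invariant. If `P_char` is far from the
scale of the actual pressure drops, starred velocities are far from order
one, the transport residual collapses relative to continuity, and the
continuity term's trivial minimum (shrink `K`, flatten `P` — its residual
is homogeneous in both) captures the optimization. The pipeline therefore
sets the gauge from data: `P_char = U_est · L_char / K_char`, with `U_est`
the 90th percentile of front-tracking speeds, which puts starred
velocities at order one. A fixed `P_char` can still be supplied.

Raw magnitudes span many decades (`κ` alone covers `1e-10`–`1e-6` mm²), so
all optimization happens on starred (nondimensional) quantities. The scales
(`compute_scales()`) are: `L_char` = largest mask extent; `K_char` = max
hydraulic permeability of the prior; `c_char` = series maximum;
`U_char = K_char P_char / L_char`; `t_char = L_char / U_char`; and the
global Péclet number `Pe_g = U_char L_char / D`. The starred transport
equation becomes `c_t* + u* · ∇*c = (1/Pe_g) ∇*²c`. Network inputs are
additionally affine-mapped to (−1, 1) per axis, the numerically stable
range for `tanh` networks. The exact characteristic-scale definitions are
not uniquely dictated by the physics; the set above is chosen so that the
stated invariants hold and the gauge property is explicit.

# The model

Four multilayer perceptrons approximate clean concentration `c*(t*, x*)`,
observation noise `σ(t*, x*)`, pressure `P*(x*)` and permeability
`K*(x*)`. Reference sizes are 5 layers of 200/66/150/150 neurons; desk-scale
runs shrink widths via `default_network_specs(width_scale=)`. Three
constraints hold *by construction* rather than through penalty terms:

- **Bounded permeability.** `K* = C1 · exp(C2 · sigmoid(raw))` with
  `C1 = K*max`, `C2 = log K*min − log K*max`, so `K*` can never leave its
  physical band no matter what the network outputs.
- **Darcy's law.** Velocity is *defined* as `u* = −K* ∇P*`; the pressure
  gradient comes from an exact forward-mode Jacobian of the pressure
  network.
- **Steadiness.** `P*` and `K*` take only spatial inputs, so `∂u*/∂t ≡ 0`.

Engine details (no autodiff framework exists in the target R environment,
so all of this is hand-derived and verified against numerical gradients in
the test suite): weight normalization on every dense layer (direction /
magnitude reparameterization), adaptive residual connections with a
per-layer learnable gate initialized at 0 (identity-dominant start),
polynomial feature expansion of degree 5 per coordinate (cross terms
configurable, off by default), `tanh` activations throughout, and a
softplus-plus-floor (`1e-6`) positivity map on the noise output — the
positivity map is our choice; any smooth positive map would do.

## Derivatives in the loss

PDE residuals need `c_t`, `∇c`, `∇²c`, `∇P`, `∇²P`, `∇K`. During training
these are taken with compact central differences so that each residual is
a fixed linear combination of plain network evaluations at stencil points,
and parameter gradients reduce to ordinary backpropagation over the
stacked stencil batch. The default step is the *voxel spacing* (and scan
interval) in starred units: probing the network at the data's own
resolution averages out sub-voxel network wiggle that a much finer step
would expose, a deliberate regularization of the residuals at desk scale.
The analytic Jacobian path cross-checks the stencils in the tests;
velocity evaluation always uses the analytic path.

# Preprocessing and data-driven priors

- **Concentration proxy.** `SER = (S_t − S_0)/S_0 × 100`; series are
  normalized by their global in-mask maximum to a 0–100 scale
  (normalization constant kept for round-tripping). Non-positive baselines
  are masked as artifacts, not clipped. Volumes are smoothed with the
  separable `[0.2, 1, 0.2]/1.4` acquisition kernel.
- **Exclusion mask.** Voxels whose full-series signal range is below three
  times their baseline range never saw tracer and are excluded, as are
  caller-supplied anatomical regions (infusion site, ventricles). For
  synthetic cases the Dirichlet source patch is excluded, mirroring the
  exclusion of the infusion site in vivo.
- **Permeability prior.** Early arrival rule: voxels exceeding the arrival
  threshold within 16 minutes get `1e-6` mm² (the effective permeability of
  an open 6 µm conduit), all others `1e-10` mm²; the binary map is
  Gaussian-smoothed (SD 1 voxel = "sharp" prior, 3 voxels = "smooth") and
  rescaled so its maximum returns exactly to the high value. On the
  normalized 0–100 proxy scale the in-vivo threshold of 150% raw
  enhancement corresponds to ~60 (peak enhancement ≈ 250%), which is the
  default used for synthetic observations.
- **Velocity prior by front tracking.** For voxels lying on an
  iso-concentration surface with gradient magnitude above threshold, the
  normal front speed is `v_n = −c_t/|∇c|` and the vector estimate
  `v_n ∇c/|∇c|`; estimates from all levels and times are pooled per voxel
  (steady flow) with confidence weights proportional to `|∇c|`. The
  reference front-tracking algorithm is described only in an unavailable
  supplement; this level-set normal-speed formulation is its natural 3D,
  curve-free analog and is validated against simulator ground truth
  (median speed error < 15% on advection-dominated fronts). Front tracking
  ignores diffusion, hence is biased where diffusion dominates — the
  physics stages correct this.

# Staged training

Optimization is divided into initialization and full training; without
initialization the coupled problem lands in poor local minima (the
package's ablation test reproduces this). The grouped loss is
`L = Σ_α m_α ⟨(λ_α,i r_α,i)^q⟩` with global weights `m_α`, per-point
residual-based attention (RBA) weights `λ`, and norm exponent `q`.

| Stage | Terms (global weight, q) | Trains |
|---|---|---|
| 0 | permeability prior fit, low/high regions (100 / 1, q=2) | K |
| 1 | concentration+noise NLL (100); velocity-prior fit (100, q=2); physics at 1e-16 | c, σ, P |
| 2, 3 | transport (10, TD-scaled) + continuity (1e-2), q=2 | P, K |
| 4 | data (100) + transport (10, TD) + continuity (1e-2), q=2 | c, P, K |
| 5 | data (10) + transport (10, TD) + continuity (1e-2), q=1 | c, P, K |

Notes on the open points this table decides:

- Stage 0 fits log-permeability, with the residual normalized by the width
  of the log-band; the low-permeability region carries weight 100 versus 1
  for the high region because it is vastly larger in volume yet easier to
  fit.
- The stage-1 velocity-prior term matches `u* = −K*∇P*` to front-tracking
  estimates at prior locations only, confidence-weighted, and updates the
  pressure network only (the permeability stays at its stage-0 fit, being
  refined later by physics).
- Stages 2 and 3 are identical physics blocks run consecutively with a
  fresh optimizer state between them; the reference schedule lists them
  separately without stating a difference.
- Physics-only stages freeze the concentration and noise networks: the
  transport residual is constrained on the clean signal, and without a data
  term the concentration fit would otherwise drift.
- Noise-aware NLL (`log σ + r²/2σ²`) is used only in stage 1; later data
  terms use plain residuals per the staged weighting table.

## TD-RBA

Physical residuals vary by orders of magnitude over time (sharp early
fronts versus faint late spread). Each subterm keeps per-point attention
weights updated as `λ ← γλ + η r/max(r)` (`γ = 0.999`, `η = 0.01` —
update constants are not stated by the reference and are configurable),
and the transport weights are divided by the per-time scale
`C(t) = max(|c_x|, |c_y|, |c_z|, |c_t − (1/Pe_g)∇²c|)` evaluated on the
clean signal over a spatial sample (floored at `1e-8`). The same scaled
weights, plus a 1% uniform floor, define the resampling distribution over
the collocation pool, focusing batches on high-error regions while keeping
full support. A sensitivity filter drops collocation points whose clean
signal or gradient is below 1% thresholds — from the *physics* constraint
only, never from concentration training — and the per-time discard
fraction is logged.

## Optimization

Per stage: minibatch Adam with a tenfold learning-rate decay across the
stage and Polyak (exponential-moving-average) parameter averaging,
followed by an optional full-batch L-BFGS polish on a fixed subsample (the
standard two-phase recipe for physics-informed training). Divergence
triggers a rollback to stage-start parameters with a halved step, bounded
retries. Optimizer, rates and iteration counts are not specified by the
reference; all live in `default_schedule()` / `train_control()` with the
defaults used throughout the tests. Observations are split 50/50 into
training and held-out halves; validation never touches gradients.

Three desk-scale adaptations deserve emphasis, all measured in this
package's own experiments and all configurable back to the literal
reading:

- **The NLL stage roughs in, the joint stages sharpen.** With the noise
  field free, the per-point NLL optimum `σ = |r|` turns the objective into
  a log-residual (geometric-mean) loss, which tolerates large local errors;
  the stage-4 plain data term at full step size does the actual sharpening.
  Iteration budgets are allocated accordingly.
- **Physics gradients and the concentration network.**
  `train_control(physics_into_c = FALSE)` (default) keeps the transport
  residual from backpropagating into the concentration network in the
  joint stages: at desk scale that gradient is dominated by
  concentration-fit error and measurably degrades the fit it is supposed
  to refine.
- **Conservative physics steps in the joint stages.** The stage learning
  rate is tuned for the data term; pressure and permeability refine at a
  much smaller per-network rate (`lr_net`). With accurate initialization
  the transport residual's information content at desk scale is marginal
  — its floor is set by concentration-fit error, and aggressive descent
  overfits velocity to that error (the test suite's ablation shows
  initialization, not refinement, carries most of the velocity accuracy
  at this scale; at full scale, with sub-2% concentration fits over a
  whole brain, the balance shifts toward the physics).

# The synthetic world

`make_case()` chains permeability map → Darcy flow → transport → noise:

- **Maps**: procedurally generated channel skeletons (seeded random walks,
  dilated), binary `1e-10`/`1e-6` mm², Gaussian-smoothed with SD 3
  ("smooth"), 1 ("sharp"), or 1 with a more intricate branched layout
  ("realistic"), then rescaled so the maximum returns to `1e-6` mm².
  Real anatomy is not used: the "realistic" style reproduces the
  *statistical* challenge (sharp, convoluted interfaces), not mouse
  geometry.
- **Flow**: cell-centered finite volumes with harmonic-mean face
  permeabilities (the standard scheme for discontinuous coefficients),
  Dirichlet inlet/outlet patches, no-flux walls — a desk-scale stand-in
  for the reference's ~2M-element FEM. The default pressure drop follows
  the 1D Darcy estimate targeting ~3 µm/s peak speeds, the scale inferred
  in vivo for open conduits.
- **Transport**: minmod-limited (MUSCL) advection plus explicit diffusion
  with automatic stable sub-stepping: positivity-preserving and free of
  new extrema like plain upwinding, but without upwinding's numerical
  diffusion (`u·h/2`, comparable to the physical `D` at these speeds and
  spacings), which would otherwise contaminate the ground truth an
  inverse method is judged against. The tracer source is a time-limited
  Dirichlet patch on the inlet (10-minute infusion at proxy level 100),
  then released.
- **Noise**: Gaussian with SD `base_sd + signal_scaling·|c|`
  (defaults 0.5 and 0.02 on the 0–100 scale — "mild" noise, a few percent
  of the signal norm, consistent with a high-quality preclinical scan).

What a green test on this world does **not** establish: performance under
real partial-volume effects, motion/registration artifacts, non-Darcy flow
in large open spaces, pulsatile components, or anatomically realistic
geometry. The simulator is itself built on the Darcy assumption, so it
cannot falsify that assumption — only the inference machinery.

# Numerical choices and degenerate inputs

- Finite-difference step `h = 2e-3` (starred) everywhere in training;
  manufactured-solution tests use smaller steps to isolate truncation.
- The local Péclet field uses the ratio of time-averaged magnitudes
  (`mean_t|u·∇c| / mean_t|D∇²c|`); the overline placement in its defining
  ratio is ambiguous, and the alternative (average of ratios) is available
  via a flag. The denominator is floored at `1e-3` of its median positive
  value.
- Angular errors skip voxels below a speed floor (default `1e-3` × median
  reference speed): direction is meaningless in near-stagnant voxels and
  dominates the error otherwise.
- Zero baseline range in the exclusion rule gives threshold zero: any
  positive change retains the voxel (documented edge case).
- An all-low permeability prior (no voxel passes arrival) warns and
  proceeds; an empty front-tracking prior warns and stage 1 fits
  concentration only.
- Ensemble uncertainty uses the population SD across members.

# Known limitations

- Steady-flow assumption; no pulsatile or time-varying components.
- Desk-scale budgets: grids of 16³–32³ and shrunken networks in tests; the
  reference operated at 100 µm over a whole mouse brain with 5×150–200
  networks and GPU budgets. Error targets transfer only approximately
  across that gap, which is why the acceptance checks are tagged
  scaled-down.
- Absolute `K` and `P` are reported in the chosen gauge only.
- The advection–diffusion confound of front tracking biases the prior
  toward outward speeds where diffusion dominates; the physics stages, not
  the prior, carry the burden there.
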