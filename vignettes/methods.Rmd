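---
title: "Methods: emulation, sensitivity analysis and history matching for cardiac electromechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cardioemu)
```

This vignette records the models the package implements, the numerical
choices behind them, and the design decisions that were genuinely open.
Everything quantitative stated here is computed by the test suite or by
`scripts/acceptance.R`; nothing is asserted that the code does not
check.

## The statistical workflow

The package targets the hierarchical calibration and sensitivity
workflow used for multiscale cardiac electromechanics models. A
simulator with outputs $f_1, \dots, f_M$ over a $D$-dimensional box of
parameters is approximated output-by-output with Gaussian-process
emulators; variance-based sensitivity analysis apportions each output's
variance to the parameters; history matching excludes regions of the box
whose emulated outputs cannot match measured targets. Sub-models
(tissue activation, ventricular and atrial cells, passive mechanics,
circulation) are analysed first, unimportant parameters are frozen, the
surviving plausible regions are intersected, and the composite simulator
is analysed over the reduced space.

### Gaussian-process emulators

Each emulator assumes

$$E[f(x)] = \beta_0 + \sum_{i=1}^D \beta_i x_i, \qquad
  C[f(x), f(x')] = k(x, x'),$$

with an exponentiated quadratic kernel by default (per-dimension
lengthscales, signal variance, optional nugget) and Matérn-5/2 as an
alternative; the test suite checks that swapping kernels moves held-out
$R^2$ by less than 0.05 on a smooth response, so the default is not
load-bearing.

Choices the literature leaves open, and what this package does:

* **Scaling.** Inputs are rescaled to the unit box (using the space's
  bounds when the training design carries them, otherwise the training
  ranges); outputs are centred and scaled by their training mean and
  standard deviation. This is standard and makes one set of
  hyperparameter bounds serve every output.
* **Estimation.** The trend $\beta$ is profiled out by generalised least
  squares and the signal variance by its closed-form estimate
  $\hat\sigma_f^2 = r^\top C^{-1} r / n$, leaving only log-lengthscales
  and the log nugget-to-signal ratio to the optimiser (L-BFGS-B,
  analytic gradients for the exponentiated quadratic, five seeded
  restarts by default). Profiling the variance removes the scale
  degeneracy the full marginal likelihood exhibits on noise-free,
  polynomial-like data, where it otherwise drifts to an inflated signal
  variance with an over-long lengthscale and meaningless predictive
  variances.
* **Bounds.** Lengthscales are capped at twice the unit box (the usual
  kriging cap: beyond that the kernel degenerates into an
  ill-conditioned global polynomial that the linear trend already
  covers). The fitted nugget ratio is bounded above by $10^{-4}$: the
  simulators here are deterministic, but a small nugget regularises the
  factorisation. `nugget = "fixed", nugget_value = 0` gives pure
  interpolation up to jitter; the final factorisation retries upward
  from a jitter of $10^{-12}\,\hat\sigma_f^2$, which is what makes the
  training-point interpolation check at $10^{-6}$ relative pass.
* **Predictive variance** includes the generalised-least-squares
  contribution of the estimated trend, so extrapolation is penalised
  through both the kernel and the trend uncertainty; points outside the
  training box are flagged, not clipped.

Cross-validation is 5-fold with a seeded fold assignment; per fold the
held-out points are scored by $R^2 = 1 - RSS/TSS$ and by the independent
standard error, the percentage of held-out observations within two
posterior standard deviations of the posterior mean.

### Sobol total effects

Saltelli designs stack two base blocks $A$ and $B$ with the $D$ radial
blocks $AB_i$ ($A$ with column $i$ from $B$), $N(D+2)$ rows in total.
The total effect uses Jansen's estimator

$$S_{T,i} = \frac{\tfrac{1}{2N}\sum_j \left(f(A_j) - f(AB_{i,j})\right)^2}
                 {\widehat{\mathrm{Var}}[f]},$$

chosen over the original Saltelli form for its lower variance; it is
validated against a brute-force double-loop Monte-Carlo oracle in the
tests. First-order indices are computed alongside (from the $B$ vs
$AB_i$ differences) but retention uses total effects only.

* The base blocks are independent seeded Latin hypercubes. A
  low-discrepancy base sequence would reduce the Monte-Carlo constant;
  no Sobol'-sequence generator is available to this package, and at the
  base sizes used (2048–8192) the Latin hypercube estimator reproduces
  the closed-form Ishigami indices within ±0.03, which is the accuracy
  the workflow needs.
* When emulators (rather than an exact function) are evaluated, the
  estimator is averaged over posterior draws and the across-draw
  standard deviation is reported. Draws are taken **independently per
  design point** (mean + sd·z): joint draws at tens of thousands of
  points would require a dense covariance factorisation that does not
  scale, and for well-trained emulators the across-draw dispersion is
  small anyway (the tests check it shrinks as the training set grows).
  Independent draws slightly inflate the variance estimate; this is the
  same trade the field's toolchain makes at scale.
* Ranking takes each parameter's **maximum** total effect across
  outputs first, then normalises the maxima to sum to one, and retains
  the shortest prefix of the descending ranking whose cumulative share
  reaches the threshold (default 0.90). Taking the maximum first keeps
  a parameter that dominates a single output even if it is irrelevant
  elsewhere, which is the conservative choice for a screening step.
  Negative Monte-Carlo estimates are clipped to zero for ranking and
  display only; raw matrices are stored untouched.
* Signed effects multiply $S_{T,i}$ for output $j$ by the sign of the
  emulator's trend coefficient $\beta_i$, giving the direction of the
  (monotone component of the) interaction.

### History matching

The implausibility of a point is

$$I(x) = \max_i \sqrt{\frac{(E[f_i(x)|D] - \mu_i)^2}
                           {\sigma^2[f_i(x)|D] + \sigma_i^2}},$$

and a wave = train emulators on the cumulative successful runs →
evaluate a fresh Latin hypercube test cloud (100 000 points at paper
scale, smaller in the desk presets) → split plausible/implausible at
$I_{th}$ → propose the next simulation batch. Wave diagnostics report
the percentage of non-implausible points, mean and max $I$, and mean and
max of the ratio of emulator predictive variance to target variance.

* The final threshold defaults to 3 by the 3-sigma rule; schedules must
  be non-increasing and are validated.
* New simulation points are selected **from the non-implausible
  region** by space-filling (maximin) subsampling. One reading of the
  wave description selects from the implausible region instead; that
  contradicts the logic of refining the emulators where the answer
  lives, so the package follows standard practice and exposes a
  `from_implausible` flag for the other behaviour.
* Plausibility uses $I \le I_{th}$ (boundary plausible). Boundaries
  matter little at cloud sizes used.
* `intersect_regions` pairs plausible clouds over disjoint parameter
  blocks by independently shuffling each cloud's rows (seeded) and
  binding columns, truncated to the smallest cloud: marginals are
  preserved exactly and blocks are paired independently, which is the
  correct null coupling when the sub-models share no parameters.

## The surrogate forward models

These four models are first-class, tested simulators whose role is to
reproduce the *statistical structure* the workflow assumes — a
deterministic multi-output map over a box, smooth in most directions,
with physiologically interpretable parameters and a failure mode — at
desk scale. They are surrogates authored for this package, not
reimplementations of the cluster-scale 3-D models they stand in for.

### Anisotropic Eikonal activation

The activation time field solves
$\nabla t_a^\top V(x) \nabla t_a = 1$ with
$V = CV_f^2\, ff^\top + (k_{ft} CV_f)^2 (I - ff^\top)$ on a regular 2-D
or 3-D grid with region labels: ventricular and atrial myocardium, a
one-node fast endocardial conduction strip covering 70% of the
apico-basal length (scaling $k_{FEC}$), a Bachmann-bundle strip
($k_{BB}$), and a non-conducting atrioventricular insulation plane.
Activation starts at an atrial lead site at $t=0$ and a ventricular
lead site at $t = AV_{delay} \in [100, 200]$ ms.

The solver is Gauss–Seidel sweeping over the $2^d$ orderings with a
segment-based local solver: for each admissible neighbour pair the
update minimises $(1-\lambda) t_A + \lambda t_B + \sqrt{e^\top W e}$
with $W = V^{-1}$, solved in closed form (a quadratic in $\lambda$).
Sweeps repeat until the field is stationary to $10^{-6}$ ms. Units are
mm and ms throughout (conduction velocities in mm/ms = m/s).

Known discretisation properties, asserted in the tests: axis-aligned and
straight-ray anisotropic fronts are exact to well under 2% at
$h = 0.5$ mm; the solution never exceeds the 8-neighbour graph-Dijkstra
bound; multi-source solutions equal the pointwise minimum of
single-source solutions except in the O(h) collision band of the two
fronts, where the segment interpolation may undercut by less than one
grid spacing.

### Calcium and active tension

The calcium transient is phenomenological: per beat
$Ca(t) = Ca_{dias} + Ca_{amp}\cdot amp\_scale \cdot g(t)$ with $g$ a
double exponential (rise $\tau_r$, decay
$\tau_d \cdot decay\_scale$) normalised to unit peak; beats superpose
additively and pacing stops when the peak is beat-to-beat stable to
0.1%. Three multipliers map ionic-conductance roles onto the transient:
`amp_scale` (L-type calcium conductance), `decay_scale`
(exchanger/SR-uptake), `buffer_scale` (total troponin, applied to the
binding kinetics in the tension model).

Tension follows a reduced regulation-and-crossbridge scheme: troponin
binding $c' = k_{TRPN}\,buffer\_scale\,[(Ca/ca_{50})^{n_{TRPN}}(1-c) -
c]$; a permissive fraction relaxing at rate $k_u$ toward a Hill function
of $c$ with midpoint $TRPN_{50}$ and exponent $n_{Tm}$, normalised so
full occupancy is fully permissive; and an unbound/weak/strong pool
whose on-rates scale with $\nu$ (U→W, gated by the permissive fraction)
and $\mu$ (W→S) around a base cycling rate $k_b = 0.004$/ms, with
off-rates pinned so that sustained full permissiveness gives the duty
ratio $S = r_s$ and $W/S = r_w$. Isometric tension is
$T = T_{ref}\, S / r_s$, so saturating calcium drives $T \to T_{ref}$
exactly (checked to 1%); an optional velocity factor
$\mathrm{clip}(1 - A_{eff}\tanh(\phi v), 0, 1)$ multiplies it. The
length-dependence parameters $\beta_0, \beta_1$ and distortion rates
$\gamma_s, \gamma_w$ are accepted for interface completeness and are
inert in the isometric surrogate.

Integration is explicit RK4 at 0.02 ms (the conventional ionic-model
step; features are grid-converged to 1% already at 0.1 ms, which the
pipeline uses). The troponin ODE limits how hard the calcium input can
saturate: rates scale as $(Ca/ca_{50})^{n_{TRPN}}$, so saturation tests
use ~10× $ca_{50}$ rather than arbitrarily large calcium. The base rate
$k_b$ was chosen once so that default rise (~170 ms to peak) and
relaxation times are in the mammalian working-myocardium range.

### Passive mechanics

The Guccione law is implemented exactly as stated in the field:
$\Psi = \tfrac{a}{2}(e^Q - 1) + \tfrac{\kappa}{2}(\log J)^2$ with
$Q = b_f E_{ff}^2 + 2 b_{ft}(E_{fs}^2 + E_{fn}^2) + b_t(E_{ss}^2 +
E_{nn}^2 + 2E_{sn}^2)$ and $\kappa = 1000$ kPa. The second
Piola–Kirchhoff stress is the exact component-wise gradient at fixed
$J$ (e.g. $S_{ff} = a b_f E_{ff} e^Q$), verified against central finite
differences to $10^{-6}$ relative over random strains.

Chamber inflation treats the wall as a thin incompressible sphere under
equibiaxial stretch $\lambda$ (radial stretch $\lambda^{-2}$): the
cavity pressure is $p = 2\bar\sigma h/r$ with
$\bar\sigma = \tfrac{\lambda^2}{2}(S_{ff} + S_{ss}) - \lambda^{-4}
S_{nn}$, $r = r_0\lambda$, $h = h_0/\lambda^2$, and volume
$V_0 \lambda^3$. Inflation solves for $\lambda \in [1, 3]$ by bisection
to $10^{-8}$ relative; unloading inverts it for $V_0$ to $10^{-6}$
relative (round trips verified at $10^{-4}$). Compliance is positive
and, above a few mmHg, decreasing (strain stiffening); at very low
pressures the thin-wall law has a brief compliance plateau, which is why
the stiffening assertion starts at 6 mmHg.

### Closed-loop circulation

Eight volumes (four chambers, four tubes) evolve under:

* chamber pressure = thin-wall Guccione passive law (RV bulk stiffness
  scaled by $a_{LvRv}$) + one-fibre active term
  $\tfrac{1}{3} T_{drive}(t) \ln(1 + V_{wall}/V)$ (RV drive scaled by
  $T_{ref,LvRv}$) + pericardial pressure;
* pericardium: $p_{peri} = k_{peri}\max(0, \sum V_{ch} -
  V_{peri,ref})/A_{peri}$, shared by all chambers — a volume-excess
  penalty producing diastolic ventricular interaction;
* valves and venous outlets: Bernoulli orifices
  $q = A\sqrt{2\Delta p/\rho}$ ($\rho = 1.05$ g/mL), no regurgitation or
  inertance;
* tubes: power law $p = p_{X0}\, p_{ref}(V/V_{ref})^{k/3}$ with
  reference volumes = adjacent valve area × tube length;
* peripheries: linear resistors
  $q = \Delta p / (R\,\Delta p_{ref}/q_{ref})$ with the patient-derived
  $q_{ref} = 82$ mL/s and reference drops 90.01 / 11.25 mmHg.

$T_{drive}$ is the cell tension transient averaged over activation
offsets spread uniformly across $[onset, onset + TAT]$, with atria at
$t=0$ and ventricles at the AV delay. Integration is fixed-step RK4 at
0.1 ms internally, 1 ms output, five beats to near-steady state; the
closed loop conserves total volume to machine precision and the run
reports the last-beat periodicity residual. A negative or non-finite
volume marks the run failed — failures are data carried as success
flags, mirroring how cluster-scale studies lose a fraction of their
runs, not exceptions.

Constants the constitutive choice leaves open were fixed once at
physiological values and are exposed as parameters: tube reference
pressures (92.5 / 16 / 2.5 / 4.75 mmHg), pericardial effective area
(2000 mm²) and engagement volume (200 mL, chosen so the penalty is
active at end diastole — it must be for the pericardium to mediate the
opposite-signed LV/RV end-diastolic volume responses the tests check),
unloaded chamber volumes (55/65/30/30 mL), and the activation windows
used by the feature extractor. The twenty features are extracted from
the final beat: ventricular EDV/EDP at ventricular activation onset,
ESV as the volume minimum, peak pressure and centred-difference dp/dt
extrema; atrial EDV just before atrial onset, ESV and peak pressure
within the atrial contraction window (onset + smearing + 150 ms by
default, configurable), and the v-wave maximum volume while the AV
valve is closed.

At the default configuration the model ejects ~41 mL per beat at an LV
peak pressure of ~108 mmHg with left/right stroke volumes balanced to
~2%. Its responses reproduce the qualitative physiology the workflow is
meant to detect: higher systemic/pulmonary resistance raises the
corresponding ventricle's peak pressure and end-systolic volume, higher
pulmonary resistance starves left-atrial venous return, stiffer
ventricles eject less, and a stiff pericardium converts an LV dilation
into an RV end-diastolic volume *decrease*.

## The hierarchical pipeline

`run_submodel_stage()` runs design → simulate → emulate →
cross-validate → GSA → rank/retain (→ optional history-matching waves)
for one registered forward model; a stage whose mean cross-validation
$R^2$ drops below 0.5 on any output is flagged and the pipeline
continues with a warning (the dp/dt features of the circulation stage
are the usual offenders — centred differences of a valve-switching
pressure trace are the least smooth outputs in the problem).

`run_full_analysis()` chains the stages: self-consistent targets are
generated by simulating a known point of the activation and
ventricular-cell models (5% standard deviations), history matching
shrinks those blocks, the plausible clouds are resampled with
replacement and paired with a Latin hypercube over the unconstrained
block (`intersect_regions`), a maximin subsample forms the final design
(120 points over 12 parameters in the desk preset), the composite chain
(activation → cell tension → circulation → twenty features) is run on
it, per-output emulators are cross-validated, and a screened Sobol
analysis — whose A/B blocks draw constrained columns from the plausible
clouds so no sample leaves the emulators' training space — produces the
final ranking and signed-effect matrix.

Problem sizes are configuration, not code: the `"desk"` preset (70-run
stages, 6000-point test clouds, 120-point final design, 20 posterior
draws) is chosen so the whole analysis runs in minutes on one CPU; the
`"paper"` preset records the cluster-scale constants (200/500 training
runs, 100 000-point clouds, base screening sequence of 2000, 1000
draws) for users with the budget to run them.

## What the surrogates do and do not show

Passing tests on these surrogates demonstrate that the *machinery* —
designs, emulators, estimators, waves, intersection, screening — is
correct and deterministic under seeding, and that the forward models
reproduce the qualitative multi-scale couplings listed above. They do
not demonstrate anything about a specific patient's heart: the
surrogates have no 3-D geometry, no mechano-electrical feedback, no
valve regurgitation or inertance, a one-node-thick analogue of the
fast-conduction anatomy, and failure rates far below those of 3-D
mechanics solvers (the failure *pathway* is exercised; the failure
*rate* is not matched). Quantities like the 45-of-117 parameter
reduction of the full-scale study depend on the real simulator and are
out of reach at desk scale by construction; what is reproduced exactly
are the patient-derived constants (82 mL/s, 70 bpm, the tube wall
areas) and the closed-form benchmarks of every statistical component.

## Numerical summary

| Component | Method | Tolerance / step |
|---|---|---|
| GPE fit | L-BFGS-B on profiled likelihood, 5 restarts | jitter 1e-8 (fit), escalating from 1e-12 (final) |
| Sobol | Jansen on Saltelli blocks | n_base 2048–8192 ⇒ ±0.02–0.03 |
| HM | waves at I_th = 3 | test clouds 2000–100000 |
| Eikonal | Gauss–Seidel segment solver | stationary to 1e-6 ms, h = 0.5 mm |
| Cell | RK4 | 0.02 ms (0.1 ms in pipeline) |
| Inflation | bisection on λ ∈ [1,3] | 1e-8 relative |
| Circulation | RK4 | 0.1 ms internal, 1 ms output, 5 beats |
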