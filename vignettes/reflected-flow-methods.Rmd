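---
title: "Models and methods: self-organising auxin patterning along the root axis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: self-organising auxin patterning along the root axis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootauxin)
```

## The reflected-flow mechanism

Auxin reaches the early root from the shoot and is carried towards the
root tip by the polarly localised efflux carrier PIN1 (acropetal
transport). Auxin regulates its own carrier in two opposing ways: at low
concentration it activates *PIN1* expression, while above a threshold it
promotes PIN1 degradation. These two feedbacks suffice for a distal auxin
maximum to organise itself a few cells from the root end in a file of
initially identical cells, with no pre-assigned carrier layout:

1. low-auxin cells express PIN1 and pump auxin tipward, so auxin piles up
   in the terminal cell (cell 1), which has no distal neighbour to export
   to;
2. auxin diffuses back from the loaded terminal cell into cell 2 (the
   *reflected* flow);
3. once cell 2 crosses the degradation threshold `q3`, its PIN1 is
   destroyed, its export towards cell 1 collapses, and the maximum moves
   from cell 1 into cell 2;
4. the same sequence repeats in cells 3, 4, ... until acropetal pumping
   and reflected diffusion balance, leaving a stationary maximum several
   cells from the boundary.

`rootauxin` implements this mechanism in three nested models: a 1D cell
file of fixed length (`steady_state_1d()`, `integrate_1d()`), a 2D
provascular/epidermal layout (`steady_state_2d()`), and a hybrid
stochastic model of a growing, dividing file (`simulate_root()`).

## Rate laws

Concentrations are expressed in abstract concentration units (cu) and
time in time units (tu); no SI conversion is attempted. Per cell `i`:

* influx `alpha` (cu/tu) enters the basal cell `N` only; in growing-root
  simulations `alpha(t) = alpha0 + k t` emulates the increasing output of
  the developing shoot;
* degradation is first order, `Kd * a`, and subsumes conjugation,
  oxidation and losses to unmodelled lateral tissue;
* diffusion between neighbours is `D * (a_j - a_i)`, antisymmetric, so
  every pairwise exchange conserves auxin;
* active transport exports `K0 * PIN_i * a_i` from cell `i` to cell
  `i - 1` (strictly acropetal; cell 1 exports nothing);
* PIN1 synthesis is the bounded, monotone generalized Hill function
  `k1 u / (1 + u + v)` with `u = (a/q1)^h1`, `v = (a/q2)^h1`: zero at
  zero auxin, turning on near the activation threshold `q1` and
  saturating at `k1 / (1 + (q1/q2)^h1)` beyond `q2`;
* PIN1 degradation is the rational polynomial
  `k2 PIN (1 + (a/q3)^h2)`: basal turnover `k2 PIN` at low auxin and a
  steep increase once auxin passes `q3`, the sharper the larger `h2`.

The mechanistically meaningful parameters are `q3` and `h2` (where and
how sharply auxin shuts its own transport down), `D` (how strongly the
reflected flow feeds back), and `alpha/Kd` (the total stationary auxin
content, since at stationarity `sum(a) = alpha/Kd` exactly — an identity
the test suite asserts algebraically).

The displayed functional forms above are this package's own commitments,
chosen from the generalized-Hill family to satisfy the qualitative
contracts that define the mechanism (boundedness, monotonicity,
threshold behaviour). Readers porting parameter values from other
implementations of this model class should check the functional forms
first; the shapes, not specific coefficients, carry the mechanism.

## The two bundled parameter sets

`param_preset("basic")` and `param_preset("robust")` were estimated by
coordinatewise calibration of the 1D model (N = 50) against the
characteristic behaviours of the system: a stable stationary maximum in
cell 5 at `alpha = 1` whose profile matches a reporter line scan after
affine rescaling; tolerance of single-cell auxin fluctuations up to a few
cu; a proximal march of the maximum and a loss of stability (onset of
oscillations) as `alpha` grows; and splitting into twin tip/base maxima
when the transport constant `K0` drops below 0.05, the regime of strong
transport-inhibitor treatment. The robust set shares this structure but
carries a much sharper auxin response of PIN1 degradation (`h2 = 10` at
`q3 = 3.26` rather than `h2 = 6` at `q3 = 2`): its stationary solution
set is richer (more folds along the influx continuation, additional
interior maxima under perturbation), behaviour characteristic of
fibrous-root species, whereas the soft-threshold basic set behaves like a
taproot system.

```{r presets}
basic <- param_preset("basic")
unlist(basic$transport)
```

A worked stationary solution:

```{r steady}
ss <- steady_state_1d(basic$transport, N = 50)
ss
which.max(ss$profile$a)
```

## Numerical choices

* **Stiff integration.** The thresholded PIN1 degradation makes the
  system stiff (local rates of order `k2 (a_max/q3)^h2`, hundreds of
  1/tu). The fixed-length models integrate with the implicit
  backward-differentiation (BDF) family via deSolve, at `rtol = 1e-8`,
  `atol = 1e-10`.
* **Steady states.** The Cauchy problem from zero initial data is relaxed
  for ~2000 tu and polished by damped Newton iteration (analytically
  assembled Jacobian for the 1D system; central finite differences with
  step `1e-7 * max(1, |x|)` on the 2D grid) to a residual max-norm below
  `1e-10`. Zero initial data means all concentrations
  exactly zero, which reproduces the developmental transient (the
  reflected-flow sequence above) rather than jumping to an arbitrary
  solution of this strongly multistable system.
* **Stability.** Leading eigenvalue of the Jacobian at the converged
  state; negative means linearly stable.
* **Continuation.** Pseudo-arclength continuation with a secant predictor
  and Newton corrector on the arclength-augmented system; steps adapt
  between `1e-7` and `ds_max`, folds are sign changes of the parameter's
  arclength derivative. Crossing counts of a vertical line in the
  (parameter, state) plane count the stationary solutions known to the
  branch — a lower bound on the true number, cross-checked in the test
  suite against multistart Newton at small N.
* **Hybrid engine.** The growing root advances by classic 4th-order
  Runge-Kutta steps whose size is the smaller of `dt_max` and a
  stability-limited bound from the current stiffest local rate; steps
  that would drive a concentration negative are halved and retried.
  Phase completions are inhomogeneous point processes: each cell
  accumulates the integral of its current phase's hazard and fires
  when the integral crosses a pre-drawn unit-exponential threshold
  (the accumulated-hazard construction, the only consistent reading of
  state-dependent completion "probabilities"). The crossing time is
  located by bisection to 1e-6 tu; the event (phase change or division)
  is applied atomically and integration resumes, so no event can be
  skipped within a step. The test suite verifies the sampling against
  analytic survival curves for both constant and time-varying hazards.
* **Growth dilution.** Elongation dilutes all intensive concentrations at
  rate `(dr/dt)/r`. This is what makes maintenance of the pattern in a
  growing root conditional on a rising influx: at constant `alpha` the
  fixed total `alpha/Kd` is spread over ever more (and growing) cells
  until the supra-threshold zone vanishes and the distal maximum is
  lost.
* **Division.** A dividing cell is replaced by two daughters of half its
  size that inherit its concentrations unchanged, so auxin amounts
  `a * r` are conserved exactly across divisions (asserted in the
  tests); both daughters restart the growth phase.
* **Sloughing.** Root-cap turnover is a cap policy: when more than
  `slough_cap` (default 5) cells lie distal to the global auxin maximum,
  cell 1 is removed. Two guards keep the stand-in from misfiring: the
  policy never triggers while the maximum sits at the basal boundary
  cell (a base-heavy profile has no root cap), and the running
  simulation checks it at most once per 25 tu, so turnover cannot
  outpace division.

## The Division Factor and cell-type zonation

Cell division rates along the axis are bimodal: one mitotic peak at the
root-cap initial, silence at the quiescent centre (QC) immediately next
to it, and a second broad peak in the meristem, fading into the
non-dividing differentiation zone. A single auxin readout cannot produce
this; the model adds a *Division Factor* — a hypothetical morphogen
bundling the division-promoting action of ethylene and the inhibitory
action of cytokinin — with three processes:

* **synthesis** `beta g^2 / (T^2 + g^2)` with `g = max(a_i - a_{i+1}, 0)`:
  confined to cells where auxin drops towards the base, i.e. the
  proximal flank of the auxin maximum, and zero on flat or rising
  profiles (scale `T = 0.1` cu; the basal cell, with no proximal
  neighbour, synthesises nothing). The one-sided form is forced by the
  target distribution: a sigmoid with a positive value at zero gradient
  would flood the long flat proximal file with synthesis and the factor
  could never be "negligibly low" in the differentiation zone;
* **degradation** `kdeg DivF (1 + (a/q4)^h3) / (1 + (a/q5)^h4)`: basal
  below `q4`, a high plateau above `q5` (ratio `(q5/q4)^h3`, about 10 for
  the presets). High degradation at high auxin keeps the factor out of
  the columella and the maximum cell, so its peak lands in the cell
  next to the auxin maximum — the QC;
* **diffusion**, which spreads the factor proximally into the meristem,
  giving a smooth decline towards the base (smoother than the sharp
  drop towards the tip, where degradation is high).

The idle-phase completion hazard is the two-exponent generalized Hill
bell `f_IP(Y)`: low at Division Factor deficiency (differentiation zone,
columella) and excess (QC), maximal at intermediate levels (meristem).
Reading position and division activity together labels the file:
columella, root-cap initial (the maximum cell), QC, vascular initials,
meristem, differentiation zone (`classify_cells()`).

## What the growing-root simulations show

Three regimes, all driven by the same machinery:

* under the slow developmental ramp `alpha = 0.3 + 1.7e-5 t`
  (`run_experiment("grow_root")`), the root grows from three cells while
  the maximum stays within a few cells of the root end; growth eventually
  outruns the influx and the maximum is lost — in these parameter
  conditions after several tens of cells (the run reports the exact
  count), after which divisions cease because the Division Factor needs
  the gradient, and the root arrests;
* under a ramp coordinated with growth (`7e-4` cu/tu², the
  `ram_patterning` protocol), the maximum detaches from the boundary and
  holds a constant distal offset while the meristem cycles, and the full
  zonation above can be read out;
* the stochastic bootstrap from three cells can arrest (if no division
  fires before the seeded gradient decays, the rising influx floods the
  short file); the patterning analysis conditions on successful
  establishment and resamples arrested realizations, reporting the
  attempt count.

Problem sizes used throughout the packaged analyses: N = 50 cells (1D),
8 x 50 (2D), growth horizons of a few thousand tu — the scales at which
the patterning phenomena express themselves while every analysis stays
desk-scale.

## Known limitations

* The functional forms and both parameter sets are this package's own
  reconstructions of the model class; quantitative landmarks that depend
  on a specific published coefficient table (e.g. the exact influx value
  at which the maximum first occupies a given cell) will differ between
  parameterisations even though the qualitative sequence is preserved.
* In the 2D layout the four epidermal rows act as a distributed auxin
  sink that roughly halves the auxin mass per provascular row. With the
  1D-calibrated `Kd = 0.02` the detached interior maximum does not
  survive this drain: the 2D stationary maximum sits at the boundary
  column. Halving `Kd` restores an interior 2D maximum (column 5 at
  `Kd = 0.011`) but displaces the 1D landmarks; no single `Kd` satisfies
  both with these rate-law shapes. The joint trade-off is a property of
  the reconstruction, documented rather than hidden: the corresponding
  acceptance check is expected to fail.
* The synthetic data generator (the models themselves plus the bundled
  synthetic reporter profile) emulates concentration fields, not images:
  real DR5::GUS line scans carry staining saturation, optical blur and
  segmentation error far beyond the additive Gaussian noise assumed in
  `compare_profile()`; agreement with the synthetic reference shows the
  machinery works, not that the model fits any particular experiment.
* No PIN polarisation dynamics, no basipetal transport, no root-born
  auxin synthesis: the models address the early root, where acropetal
  flux from the shoot dominates. The loss of the maximum in long roots
  marks the boundary of that regime rather than a prediction about
  mature roots.
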