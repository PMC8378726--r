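---
title: "Methods: switching robust control of the delayed MAP plant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: switching robust control of the delayed MAP plant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapswitch)
```

This vignette is the package's own account of the model, the design and
certification machinery, and the numerical choices behind them.  Everything
quantitative stated here is computed by the test-suite or by
`scripts/acceptance.R`; this text explains *why* the pieces look the way
they do.

## The plant and what the generator emulates

The regulated variable is mean arterial pressure (MAP).  The model is the
classical first-order delayed response to vasoactive drug infusion,

$$\dot x(t) = -\tfrac{1}{\tau} x(t) + \tfrac{\theta(t)}{\tau}\, u(t-h),
\qquad M(t) = x(t) + M_0,$$

with state $x$ the pressure deviation from the baseline $M_0 = 100$ mmHg,
input $u$ the infusion rate (ml/hr), drug sensitivity
$\theta(t) \in [-9.5, -0.25]$ mmHg/(ml/hr) the scheduling parameter
(negative: the drug lowers pressure), distribution lag $\tau$ (nominal
35 s, range $[10, 60]$) and transport delay $h$ (nominal 40 s, range
$[20, 60]$).  The recirculation term that some versions of this model carry
is fixed to zero — experimental studies find it absent in most patients —
and $\theta$ is treated as a measurable scalar.

The synthetic-patient generator (`sample_patients()`,
`make_trajectory()`) emulates exactly this: uniform draws of $\tau$ and
$h$ over their ranges (the literature gives ranges, not distributions;
uniform is the least-informative choice) and piecewise-linear sensitivity
trajectories.  The reference scenario (`fig7_like`) rises on $[0, 400]$ s,
holds on $[400, 1100]$ s, rises again from 1100 s until the full range is
covered, then holds — at sup-rate 0.0085 (mmHg/(ml/hr))/s, the reference
rate for this scenario.  The piecewise-linear representation is deliberate:
the supremum of $|\dot\theta|$, the quantity the dwell-time certificate
bounds, is then exact (the maximum segment slope).

What the generator does **not** emulate, and what passing tests therefore
do not establish for real data: measurement noise and sensor dynamics,
online estimation of $\theta$ (an extended Kalman filter would sit between
the patient and the supervisor in a deployment), drug interactions,
recirculation, and the exact shape of the reference scenario trajectory,
whose numeric breakpoints are available only as a figure — `fig7_like`
reproduces the described ramp/hold structure, not the figure's pixel
values.  The initial 150 mmHg pressure enters as a decaying initial
condition of the state ($x(0) = 50$), exactly as the model equations
prescribe: with the setpoint equal to the baseline, steady-state infusion
tends to zero, so the infusion bound is stressed only transiently.

## Smith predictor and LFT separation

Over one operating region $\Theta_i = [\theta_i^-, \theta_i^+]$ with center
$\theta_i$ and half-width $\Delta_i$, the LPV plant is split into a nominal
LTI two-port plus a normalized time-varying gain
$\delta(t) = (\theta(t) - \theta_i)/\Delta_i$, $|\delta| \le 1$
(`build_uncertainty_lft()`).  The half-width normalization is a design
choice: the L2-induced norm of a memoryless gain is its supremum magnitude,
so the uncertainty norm bound is exactly 1 and the small-gain threshold
becomes 1.  (The printed weight constant 7.2118 is reproduced only under
the half-width reading of the uncertainty width; the full-width reading is
inconsistent with it, which is why half-width is adopted.)

The delay never enters the design loop: the Smith predictor
$\Pi_i = G_{22} - G_{22} e^{-sh}$ (for stable $G_{22}$ only; plants with
unstable modes are rejected) is added in parallel from the input to the
measurement, giving the augmented plant with delay-free $G_{22}$, which is
then decomposed into a delay-free design plant $\tilde G$ and a residual
$\Pi_1$ on the uncertainty channel so that

$$M(s) = F_l(\tilde G(s), C(s))\, e^{-sh} + \Pi_1(s).$$

The literal block contents of the decomposition are not prescribed
anywhere usable; the package instead *defines* correctness by this
identity, which the test-suite verifies to $10^{-8}$ relative mismatch on a
frequency grid against the directly-closed loop for ten random stabilizing
controllers.  For the MAP plant $G_{11} = 0$ and $\Pi_1 \equiv 0$; the
generic construction (with $\Pi_1 = G_{11}(1 - e^{-sh})$) is retained and
tested so the module is not special-cased to this plant.

## Mixed-sensitivity synthesis

Each region's controller solves the two-block problem
$\min_C \| [\,W_s S;\ W_k C S\,] \|_\infty$, $S = (1 + G_0 C)^{-1}$, with
the region's delay-free nominal plant $G_0 = \theta_i/(\tau_0 s + 1)$ and
the weight template

$$W_s(s) = e^{-h_0/\tau_0} \frac{s + 0.055}{10 s + 5.5\times10^{-4}},
\qquad W_k = e^{-h_0/\tau_0}\,(\Delta_i + 2.715\,|\theta_i|).$$

$W_s$ has DC gain $\approx 31.9$: a near-integrator (pole at
$-5.5\times10^{-5}$) that bounds the steady-state error at a few percent
of the step — the $\pm 5$ mmHg specification is checked directly in
simulation rather than enforced by exact integrator augmentation.  $W_k$
carries the additive uncertainty bound: the frozen-plant error over the
region and over the $\tau$/$h$ ranges satisfies
$|G_\Delta| \le \Delta_i + |\theta_i|\,\sup_\omega(|e^{-j\omega\Delta h}-1| +
|\Delta\tau\, j\omega/(\tau_0 j\omega + 1)|)$, whose supremum is
$2 + \Delta\tau/\tau_0 = 2.7143$ analytically (the template rounds it to
2.715).  Weights are printed only for region 1; the same template with
region-specific $(\theta_i, \Delta_i)$ is applied to all regions, which is
what the $W_k$ formula already suggests.

Implementation choices worth recording:

* **Single-Riccati construction.**  With measurement $y = w - G_0 u$ the
  w-to-y feedthrough is square and invertible, so an exact observer
  reconstructs the generalized-plant state asymptotically and the output-
  feedback problem collapses to state feedback: one Riccati equation
  (solved via the stable Hamiltonian subspace), bisected over $\gamma$ to
  tolerance $10^{-4}$.  The filter Riccati solution is identically zero;
  this was verified analytically, and the achieved closed-loop norm is
  always re-checked by frequency sweep.
* **Weight regularization.**  $W_s$ has a direct feedthrough
  ($e^{-8/7}/10$), which the Riccati construction cannot absorb; inside
  synthesis only, $W_s$ is cascaded with a roll-off pole at 1 rad/s
  (about 30 times the loop bandwidth $1/\tau_0 \approx 0.03$ rad/s).  The
  achieved $\gamma$ is always evaluated against the *exact* $W_s$; the
  regularization changes it below the bisection tolerance.
* **Back-off within the $\gamma$-ball.**  The exact bisection-optimal
  central controller is aggressive: it doubles the initial-condition
  overshoot and, near the feasibility boundary, can acquire a spurious
  very fast pole (observed at $-87$ rad/s for region 4) that ruins the
  Lyapunov certificate's conditioning.  Since any $\gamma < 1$ satisfies
  the robust-stability threshold, the returned controller is the central
  controller at $\gamma_{design} = \gamma_{opt} + \tfrac12(1 -
  \gamma_{opt})$ — the margin to the threshold is split between
  performance and robustness.  When $\gamma_{opt} \ge 1$ (the full-range
  single-region design) a minimal 0.1% back-off is used and the robust
  check fails, as it should.
* **Robust check channel.**  The $\theta$-only LFT channel recovers the
  LPV dynamics exactly but does not see the $\tau$/$h$ uncertainty, and
  under it even a full-range single controller would scrape through.  The
  design loop therefore checks the additive channel weighted by $W_k$
  (threshold 1), which reproduces both the reference pass
  ($\gamma = 0.944 < 1$ for region 1) and the reference failure of a
  single full-range controller, whose DC bound
  $|W_k C S|(0) \to W_k/|\theta_c| = 1.17 > 1$ is unbeatable by any
  controller with integral action.  Both channels are exported.
* **Realization.**  Controllers are balanced-truncated at Hankel tolerance
  $10^{-4}$ (order 3 to 2; the discarded state carries $<10^{-4}$ of the
  Hankel energy and the achieved norm is unchanged to four digits).

The five-region partition yields $\gamma_{opt} =$ 0.943, 0.966, 0.981,
0.995, 0.997 — all below 1, with the margin shrinking toward the
low-sensitivity end: the partition was evidently constructed to make
$e^{-h_0/\tau_0}(\Delta_i/|\theta_i| + 2.715) < 1$ with just enough room,
and regions 4–5 pass by less than 1%.  The refinement loop
(`partition_and_design()`) bisects any failing region at its midpoint —
the simplest rule consistent with "repeat with a smaller range".

## Dwell-time certificate

The switched delay-free closed loop $\dot\xi = A_{q(t)}(\theta(t))\xi$ uses
the block matrix of plant and controller.  Per region, on a dense $\theta$
grid (201 points; for scalar $\theta$ this is exhaustive to the grid
resolution), the package solves
$A_i'(\theta) Q + Q A_i(\theta) = -2\lambda_i Q - I$ and extracts
$\mu_i \le \mathrm{eig}(Q) \le M_i$, $L_{Qi} = \sup \|dQ/d\theta\|$
(central differences), $\beta_i = (1 + 2\lambda_i\mu_i)/L_{Qi}$, then
$\beta_{max} = \min_i \beta_i$, the dwell time $h_D$, and the admissible
rate.  Substitution residuals are checked below $10^{-10}$ everywhere.

Three choices control the conservatism of this certificate, all of them
coordinate or parameter freedoms that leave its validity untouched:

* **$\lambda_i$.**  The eigenvalue condition allows any
  $\lambda_i \le d_{min}/2$.  The documented default takes 90% of that
  (a 10% eigenvalue margin), but smaller shifts give smaller, flatter $Q$
  families and a larger admissible rate, so the pipeline uses
  `lambda_margin = "auto"`, which picks the $\beta_i$-maximizing fraction
  per region from a fixed candidate list.
* **Coordinates.**  The constants are realization-dependent.  The grid is
  evaluated in coordinates preconditioned by $Q(\theta^*)^{-1/2}$, with the
  anchor $\theta^*$ searched over a coarse grid (the $\|dQ/d\theta\|$ peak
  is the natural choice).  This tightens $M_i/\mu_i$ from $10^3$–$10^5$ in
  raw coordinates to 10–25.
* **Certified interval.**  Hysteresis keeps controller $i$ active up to
  half a band (0.2) beyond its region at interior boundaries, so
  certification extends the grid accordingly — the overlapping-interval
  picture that the hysteresis geometry implies.

With these choices the reference bank certifies at
$\beta_{max} \approx 2.9\times10^{-3}$ and $h_D \approx 1.1\times10^{3}$ s.
Two structural facts keep the certificate conservative.  First, the
mixed-sensitivity controller cancels the plant pole exactly while the
design drives the closed-loop bandwidth to essentially the same frequency,
leaving a near-defective slow eigenvalue pair whose Lyapunov solutions are
intrinsically ill-conditioned.  Second, the admissible rate is a bound on
the *absolute* $|\dot\theta|$, but the low-sensitivity regions see the
largest *relative* gain variation per unit $\theta$, so region 5 dominates
$L_Q$ — a scalar back-of-envelope bound for that region already caps
$\beta_5$ near $10^{-2}$, and the multivariable non-normality costs another
factor of a few.  Reference constants for this architecture
($\beta_{max} = 0.0279$, $h_D = 472.71$ s) come from a vertex-LMI
construction with a constant Lyapunov matrix whose ingredients are not
reproducible from the printed material; the grid certificate lands within a
factor of ten of both, which is what the acceptance suite asserts.

Both admissible-rate readings are reported and neither is silently chosen:
the bound actually used to clear the reference scenario compares
$\sup|\dot\theta|$ with $\beta_{max}$ alone, while the full bound also
contains $|d_{i,i+1}|/h_D \approx 4\times10^{-4}$ — note that with the
*reference* constants that term evaluates to $8.5\times10^{-4}$, below the
reference scenario rate 0.0085, so the full reading is not satisfied by the
reference numbers either.  The scenario is simulated at 0.0085 regardless
(it is the study condition); `verify_trajectory()` reports both verdicts.

## Supervisor and simulation

Hysteresis half-width 0.2 is the unique value reproducing the reference
switching table from the region boundaries (up-switches at
$-5.60, -2.83, -1.22, -0.40$; down at $-6.00, -3.23, -1.62, -0.80$).  The
supervisor is a pure function of $(\theta, \text{current index})$; moves
are limited to one region per step, and oscillations smaller than the
half-width never toggle it.

The simulator integrates with a fixed step ($dt = 0.1$ s over 2000 s by
default; $dt \le \min(\tau, h)/10$ is enforced):

* plant and the delay-free predictor branch by exact zero-order-hold
  recursions; controllers by exact ZOH discretization via the augmented
  matrix exponential (robust to the near-integrator pole);
* the input delay as a `round(h/dt)`-sample circular buffer (no drug
  effect reaches the plant before $h$, which the tests check against the
  open-loop decay law);
* the Smith predictor's delayed branch as an FIR filter — the ZOH impulse
  response of $e^{-sh}G_{22}$ truncated at $8\tau_0$, within 1% of the true
  frequency response out to well past the loop bandwidth;
* bumpless transfer: at a switch the incoming controller state is set to
  the minimum-norm state reproducing the outgoing command (least squares
  on the output matrix); cold start is available for ablation;
* actuator saturation to $[0, 180]$ ml/hr with back-calculation anti-windup
  (gain 0.2 1/s along the same least-squares direction); a no-clamp mode
  exposes the raw command;
* initial conditions: $x(0) = 50$ mmHg (the 150 mmHg start), controller
  states zero, delay buffer zero;
* a blow-up guard flags (never throws on) divergence so that failing
  configurations still produce scoreable traces.

Performance metrics are defined in `performance_metrics()` (settling =
entry into the ±5 mmHg band for the remainder of the run; undershoot =
worst dip below the setpoint after first crossing; steady-state band over
the final 20% of each constant-$\theta$ hold; oscillation = sustained error
sign alternation with amplitude > 1 mmHg).  The specifications state
targets, not definitions, so these definitions are the package's own and
are exercised on synthetic traces with known metric values.

Halving $dt$ moves the terminal MAP by well under 0.1 mmHg; the problem
sizes used throughout (2000 s scenarios at $dt = 0.1$, 201-point
certification grids, 400–600-point frequency grids with golden-section
refinement) were chosen as the coarsest settings whose results are
grid-converged at the 1% level.

## Known limitations

* Scalar $\theta$ only; vector scheduling is out of scope.
* Stable $G_{22}$ only (classical Smith predictor; no unified predictor
  for unstable plants).
* The certificate is sufficient, not tight: the true switched loop
  tolerates much faster parameter variation than $\beta_{max}$ certifies,
  as the (certificate-violating, specification-passing) reference scenario
  itself demonstrates.
* No measurement noise or $\theta$-estimation error is modeled; the
  supervisor sees the true scheduling signal.
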