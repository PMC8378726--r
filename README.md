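# mapswitch

Supervisory switching robust control for a delayed LPV blood-pressure
plant: design, certify, simulate.

## The problem

Post-surgical hypertensive patients are brought from an elevated mean
arterial pressure (MAP, ~150 mmHg) down to a 100 mmHg target by continuous
infusion of a vasoactive drug (e.g. sodium nitroprusside).  The standard
first-order model of the MAP response is

```
G(s) = ΔM(s)/I(s) = k / (τ s + 1) · e^(-h s)
```

with drug sensitivity `k = θ(t) ∈ [-9.5, -0.25]` mmHg/(ml/hr) varying in
time across patients and within a patient, distribution lag
`τ ∈ [10, 60]` s (nominal 35 s) and transport delay `h ∈ [20, 60]` s
(nominal 40 s).  One fixed controller cannot cover the 38-fold sensitivity
spread robustly, so `mapswitch` implements a supervisory architecture:

1. **Partition** the sensitivity range into operating regions
   `Θ_i = [θ_i⁻, θ_i⁺]` (five regions by default).
2. **Design** one LTI controller per region by two-block mixed-sensitivity
   H∞ synthesis, `min_C ‖[W_s S; W_k C S]‖_∞` with
   `S = (1 + G₀C)⁻¹`, on the delay-free design plant obtained with a
   classical Smith predictor `Π_i = G₂₂ - G₂₂ e^{-sh}`; robust stability of
   each region is checked by the small-gain condition
   `‖F_l(G̃, C) e^{-sh} + Π₁‖_∞ < 1/‖Δ‖` against an additive uncertainty
   bound covering the gain spread and the τ/h uncertainty.
3. **Certify** switched-loop stability by a dwell-time argument: per-region
   shifted Lyapunov solutions `A_i'Q + Q A_i = -2λ_i Q - I` on a dense θ
   grid give constants `(λ_i, μ_i, M_i, L_Qi)`, a per-region rate bound
   `β_i = (1 + 2λ_i μ_i)/L_Qi`, the dwell time
   `h_D = max_i 2 M_i ln(M_i/μ_i)/(1 + 2λ_i μ_i - L_Qi β)` and an
   admissible bound on `|θ̇(t)|`.
4. **Supervise** at run time with hysteresis switching (±0.2 around each
   region boundary) and simulate the full delayed closed loop against the
   clinical specifications: settle within 10 min, undershoot < 10 mmHg,
   steady state within ±5 mmHg, infusion within 0–180 ml/hr, no sustained
   oscillation.

Audience: control engineers and computational-physiology researchers who
want a reproducible, scriptable implementation of the full
design–certify–simulate chain for delayed LPV plants with one scheduling
parameter.

## Worked example

```r
library(mapswitch)

r1 <- operating_region(-9.5, -5.8, 1)
make_weights(r1)$Wk
#> [1] 7.213587           # control-sensitivity weight e^{-8/7}(Δ₁ + 2.715|θ₁|)

des <- design_controller(r1)
des
#> <synthesis_result> region 1 [-9.5, -5.8], theta_i = -7.65
#>   gamma_opt = 0.9432, achieved = 0.9703 (design level 0.9716), controller order 2

robust_stability_check(des)$margin
#> [1] 0.0647             # > 0: the region passes the small-gain condition
```

`gamma_opt` is the bisection optimum of the stacked norm; the returned
controller is deliberately taken slightly inside the feasible set (half the
margin to the robustness threshold 1), which tames the transient without
affecting robustness — `achieved` is its stacked norm re-evaluated with the
exact printed weights.

The whole chain, from partition to scored simulation:

```r
res <- run_pipeline()
res$design_table[, c("region", "theta_nominal", "Wk", "gamma_opt", "robust_pass")]
#>   region theta_nominal    Wk gamma_opt robust_pass
#> 1      1        -7.65  7.21      0.943 TRUE
#> 2      2        -4.42  4.26      0.966 TRUE
#> 3      3        -2.22  2.18      0.981 TRUE
#> 4      4        -1.01  1.01      0.995 TRUE
#> 5      5        -0.425 0.424     0.997 TRUE

glance(res$dwell)
#>   beta_max    beta   h_D rate_beta_max rate_full
#> 1  0.00289 0.00144 1120.       0.00289  0.000357

res$performance
#>   metric                  value threshold pass
#> 1 settling_time_min      3.82          10 TRUE
#> 2 undershoot_mmHg        7.81          10 TRUE
#> 3 steady_state_band_mmHg 0.0270         5 TRUE
#> 4 oscillation            0              0 TRUE
#> 5 infusion_min_ml_hr     0              0 TRUE
#> 6 infusion_max_ml_hr     1.19         180 TRUE
```

Reading the numbers: the five regions all achieve `γ < 1`, so each
controller tolerates its region's gain spread plus the lag/delay
uncertainty.  The certificate admits parameter rates up to
`β_max ≈ 2.9e-3` (mmHg/(ml/hr))/s with a dwell time of ~1100 s — the
grid-Lyapunov certificate is conservative; see the methods vignette.  The
simulated full-range scenario (θ ramping −9.5 → −0.25 with two ramp/hold
phases, four supervisor switches) meets all five clinical items; MAP never
drops below 92.2 mmHg and settles in under 4 minutes.

`autoplot(res$trace)` plots MAP, infusion and the active controller;
`autoplot(res$trajectory)` the scheduling trajectory;
`plot_mixed_sensitivity(res$bank[[1]])` the weighted frequency responses.

A thin CLI over the same functions lives in `inst/cli/mapswitch.R`
(`pipeline`, `report`, `fixtures` subcommands).

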