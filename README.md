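# bcl2switch

Quantitative models of the cell-death switch that kills mitotically
arrested cells, for systems biologists studying anti-mitotic
chemosensitivity. During drug-induced mitotic arrest, transcriptional
silencing depletes the unstable anti-apoptotic protein Mcl-1; together
with Bcl-xL it sequesters the pore-forming effector Bak, so its decay
slowly releases Bak, which oligomerizes into mitochondrial membrane
pores and triggers cytochrome-c (CytC) release — the committed step of
apoptosis. The package asks, and answers quantitatively: how does an
hours-long exponential decay produce a minutes-scale, all-or-none death
switch, and what makes individual cells and cell lines differ in when
and whether they die?

It provides five connected layers:

1. **Kinetics** — stiff-ODE models of Bak pore assembly
   (`build_model()`, `simulate_network()`): Mcl-1 turnover and
   sequestration, a dimerization ladder `B_n + B_n <-> B_2n` up to pore
   size *A* (tetramer: *A* = 4; massively oligomeric: *A* = 256), and
   CytC exchange `gamma_m [B_A][C_m] - gamma_c [C_c]`. Metrics:
   `momp_time()` (first half-maximal release) and `switch_duration()`
   (0.1 to 0.5 release rise time).
2. **Analytics** — the quasi-static closed forms: exponential free-Mcl-1
   decay, the sequestration isotherm `B_1 = B_T/(1 + M/K_M)`, a Hill
   release function with coefficient *A* and midpoint `K_C`
   (`calibrate_kc()`), the MOMP delay
   `T_c = (1/delta_M) ln((M_0-M_s)/(M_1/2-M_s))`, and the sharpness
   bound `dT >= ln(9)/(A delta_M)` — sharp switching requires pores with
   hundreds of subunits.
3. **Single-cell death model** — the large-pore threshold limit: a cell
   dies when `m0 e^{-t/tau_M} + x0 e^{-t/tau_X}` (inhibitor-to-Bak
   ratios) falls to its threshold (`death_time()`, vectorized).
4. **Population and empirical curves** — log-normal cell-to-cell
   variability mapped to mitotic survival curves by Monte Carlo or
   deterministic quadrature, and exit-corrected survival curves from
   time-lapse fate tables under independent competing risks
   (`estimate_hazards()`, `corrected_survival()`, `exit_curve()`).
5. **Calibration and synthesis** — constrained two-stage least squares
   (random search + Hooke-Jeeves pattern search) recovering population
   parameters from control + knockdown curve sets (`fit_survival()`,
   `fit_decay()`), and a synthetic-data module (`ground_truth()`,
   `generate_fates()`, ...) that produces every input format from known
   truth.

## Worked example

```r
library(bcl2switch)

## tetramer-pore model with the bundled reference constants
traj <- simulate_network(build_model(reference_params("I")),
                         horizon = 30 * 3600)
c(momp_h = momp_time(traj) / 3600,
  switch_h = switch_duration(traj) / 3600)
#>   momp_h switch_h
#> 2.386817 1.189885
```

Half-maximal CytC release occurs 2.39 h after arrest onset, and the
release fraction needs 1.19 h to climb from 0.1 to 0.5 — the tetramer
pore yields a delayed but *gradual* commitment, with the rise time a
large fraction of the delay. The closed-form reduction explains both
numbers:

```r
qs <- quasi_static_from_kinetics(reference_params("I"))
c(K_C = qs$K_C, delay_h = momp_delay(qs) / 3600,
  bound_h = switch_bound(4, 1.3e-4) / 3600)
#>       K_C   delay_h   bound_h
#> 10.000000  2.368993  1.173731
```

The calibrated critical Bak-monomer level is 10 nM, the analytic delay
(2.37 h) matches the simulation within 1%, and the pore-size bound
`ln(9)/(A delta_M)` (1.17 h for *A* = 4) is nearly attained — a tetramer
cannot switch faster than this. Making the pore massively oligomeric
sharpens the ideal switch as 1/*A* (the *A* = 256 bound is 66 s),
although with the bundled 256-mer constants the simulated rise is slowed
again by the Bak mass locked in ladder intermediates; see the methods
vignette for when the bound is tight.

Population layer, knockdown effect:

```r
pop <- cell_population(mu_m = log(4), sigma_m = 0.45, mu_x = log(2.5),
                       sigma_x = 0.5, sigma_b = 0.15,
                       tau_M = 4, tau_X = 12)
tg <- seq(0, 24, by = 6)
ctrl <- survival_curve_quadrature(pop, tg)
mkd  <- survival_curve_quadrature(apply_knockdown(pop, "mcl1", 0.2), tg)
round(rbind(control = ctrl$surviving_fraction,
            mcl1_kd = mkd$surviving_fraction), 3)
#>          [,1]  [,2]  [,3]  [,4]  [,5]
#> control 1.000 0.978 0.608 0.185 0.033
#> mcl1_kd 0.995 0.848 0.475 0.163 0.032
```

All control cells are alive at arrest entry, 61% survive 12 h, 3% reach
24 h. Knocking Mcl-1 down to 20% of its median depresses the early and
mid curve (0.98 to 0.85 at 6 h, 0.61 to 0.48 at 12 h) while the late
tail, which is governed by the longer-lived Bcl-xL arm, barely moves —
the model's quantitative statement of which arm protects when.

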