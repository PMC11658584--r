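# codepend

Compartmental dynamics, threshold analysis, sensitivity analysis and
optimal control for the co-dependence of alcohol drinking and tobacco
smoking.

Drinking and smoking spread through social contact and reinforce each
other: smokers are more likely to start drinking and vice versa, and
people who quit may relapse. `codepend` implements a seven-compartment
social-contagion model of this system — susceptible `S`, drinkers `D`,
smokers `M`, co-dependent `Dm`, and recovered classes `Rd`, `Rm`, `Rdm`
that relapse back to susceptibility — for researchers in behavioural
epidemiology and public-health policy who want a tested, reproducible
implementation of the full analysis pipeline rather than one-off
scripts.

The recruitment mechanism is a pair of state-dependent forces of
co-dependence,

    alpha1 = a1 (D + Dm),   alpha2 = a2 (M + Dm),

feeding the ordinary differential equations

    S'   = xi + g1 Rd + g2 Rm + g3 Rdm - (alpha1 + alpha2 + mu) S
    D'   = alpha1 S - (mu + phi1 + d1 + alpha2) D
    M'   = alpha2 S - (mu + phi2 + d2 + alpha1) M
    Dm'  = alpha2 D + alpha1 M - (mu + phi3 + k1) Dm
    Rd'  = d1 D - (mu + g1) Rd
    Rm'  = d2 M - (mu + g2) Rm
    Rdm' = k1 Dm - (mu + g3) Rdm

(all rates per week). The package provides:

* **Dynamics** — the uncontrolled right-hand side and a fixed-step
  fourth-order Runge-Kutta integrator (`simulate_model()`), with
  positivity and boundedness guarantees checked numerically.
* **Thresholds and equilibria** — closed-form reproduction numbers
  `R0D = a1 xi / (mu (mu + phi1 + d1))` and
  `R0M = a2 xi / (mu (mu + phi2 + d2))`, their next-generation-matrix
  construction with `R0 = max(R0D, R0M)`, closed-form submodel endemic
  equilibria, analytic Jacobians, and stability verdicts with an
  explicit residual contract (`reproduction_numbers()`,
  `stability_report()`, `drinker_equilibria()`, `endemic_equilibrium()`).
* **Sensitivity** — analytic normalized forward indices (elasticities)
  of the reproduction numbers with a finite-difference cross-check,
  Latin-hypercube sampling with partial rank correlation coefficients,
  response surfaces and percentile summaries (`forward_index()`,
  `global_sensitivity()`, `r0_surface()`).
* **Optimal control** — a five-control Pontryagin problem (two
  prevention controls scaling recruitment, three treatment controls
  adding recovery) with quadratic control costs, solved by a
  forward-backward Runge-Kutta sweep with relaxed clamped updates
  (`optimal_control()`), plus efficacy trajectories and a first-order
  optimality probe.
* **A thin CLI** — `inst/exec/codepend` with subcommands
  `simulate | stability | indices | lhs-prcc | surface |
  optimal-control`, YAML configs, and a manifest per run.

## Worked example

```r
library(codepend)
p <- baseline_params()          # literature baseline, weekly rates

reproduction_numbers(p)
#> R0 (co-dependence) = 0.603690  [drinkers 0.391257, smokers 0.603690]

stability_report(p)
#> DMFE-full equilibrium (stable, R0 = 0.60369)
#>        S        D        M       Dm       Rd       Rm      Rdm
#> 8.403361 0.000000 0.000000 0.000000 0.000000 0.000000 0.000000
#> residual 0.000e+00, leading eigenvalue real part -0.0626269, R0-consistent: TRUE
```

Both habits are subcritical at baseline (`R0D = 0.391`, `R0M = 0.604`,
both below 1), so the habit-free state `S = xi/mu = 8.40` is locally —
and, by numerical probe, globally — attracting, and the eigenvalue
verdict agrees with the threshold criterion. Elasticities quantify the
leverage of each rate: a 1% rise in the drinker contact rate `a1`
raises `R0D` by 1%, while a 1% rise in natural mortality `mu` lowers it
by about 1.93%:

```r
sensitivity_indices(p)[c(2, 7, 16), ]
#>    target parameter     index
#> 2     R0D        a1  1.000000
#> 7     R0D        mu -1.925359
#> 16    R0M        a2  1.000000
```

The reference control scenario starts from
`(S, D, M, Dm, Rd, Rm, Rdm)(0) = (0.6, 0.2, 0.1, 0.06, 0.02, 0, 0)`
with state costs `A = 100`, control costs `w = 0.5` over 52 weeks:

```r
sol <- optimal_control(p, horizon = 52, step = 0.01)
summary(sol)
#> Forward-backward sweep: 17 iterations, converged = TRUE
#> Objective: 33.388301 with control, 297.620266 without (reduction 88.8%)

i4 <- which.min(abs(sol$times - 4))
round(sol$states[i4, c("D", "Dm")], 6)
#>        D       Dm
#> 0.002544 0.000676

min(control_efficacy(sol, compartment = "D")[sol$times >= 10])
#> [1] 0.9981557
```

Under the optimal policy the drinker compartment collapses from 0.2 to
about 0.0025 by week 4 and the co-dependent compartment to about
0.0007; from week 10 onward the controls suppress more than 99% of the
drinker burden relative to the uncontrolled baseline, at an 88.8%
reduction in total cost.

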