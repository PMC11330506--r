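# sedpnr

Simulation and analysis toolkit for the **SEDPNR** compartmental model
of rumor and misinformation diffusion in online social networks.

## The problem

When a rumor spreads on a social platform, users don't just flip from
"unaware" to "spreading". They get exposed, hesitate, take sides, argue
against the rumor, and eventually disengage. SEDPNR captures this with
six compartments — **S**usceptible, **E**xposed, **D**oubtful,
**P**ositively infected (spreading the rumor), **N**egatively infected
(countering it), and **R**estrained (disengaged) — coupled by a linear,
mass-conserving system of ODEs:

```
ds/dt = μ₁e + μ₂d − αs
de/dt = αs − (β₁+β₂+γ+μ₁)e
dd/dt = γe − (β₃+β₄+μ₂)d
dp/dt = β₁e + β₃d − λ₁p
dn/dt = β₂e + β₄d − λ₂n
dr/dt = λ₁p + λ₂n
```

All rates are per day. The package provides:

* deterministic integration (adaptive `lsoda` and forward Euler) with
  conservation/positivity guarantees (`sedpnr_integrate`,
  `check_decay_bounds`);
* stability analysis: next-generation `R0 = max(β₁/λ₁, β₂/λ₂)`,
  Jacobian (exact and as-printed variants), eigenvalue die-out
  verdicts, equilibria, and a Lyapunov diagnostic
  (`basic_reproduction_number`, `sedpnr_jacobian`,
  `eigenvalue_conditions`, `sedpnr_equilibrium`, `stability_report`);
* stochastic agent-based simulation on hand-rolled Barabási–Albert
  scale-free graphs, with power-law tail fitting and superspreader
  seeding (`generate_scale_free`, `simulate_network`, `fit_power_law`);
* constant-hazard SI/SIR/SIS/SEDIS baselines and comparison tables
  (`run_baseline`, `comparison_table`);
* scenarios: time-windowed interventions, a seven-compartment distrust
  extension, and country-level parameterization from HDI and internet
  penetration (`run_intervention`, `run_distrust`, `country_rates`,
  `stiffness_run`);
* a CLI and JSON/CSV round-trip I/O (`sedpnr_cli`, `load_config`,
  `write_trajectory_csv`).

See the methods vignette (`vignettes/sedpnr-methods.Rmd`) for the
science, the numerical choices, and the known discrepancies in the
published benchmark values.

## Worked example

```r
library(sedpnr)

f <- fixtures("sensitivity_a01")   # α = 0.1 benchmark parameter set
f$params
#> SEDPNR parameters:
#>   alpha    0.1
#>   beta1    0.05
#>   beta2    0.05
#>   beta3    0.05
#>   beta4    0.05
#>   gamma    0.025
#>   lambda1  0.035
#>   lambda2  0.035
#>   mu1      0.01
#>   mu2      0.1

traj <- sedpnr_integrate(f$params, f$init, t_end = 100)
traj
#> SEDPNR trajectory: 100 steps, scheme = adaptive
#>   total population: 3e+05   peak P+N: 136863 at step 28

peak_infection(traj)
#> $value
#> [1] 136863.3
#>
#> $step
#> [1] 28

stability_report(f$params)
#> SEDPNR stability report
#>   R0 = 1.428571 (next-generation check: agrees)
#>   delta1/2/3 =  0.01204837  0.01565034 -0.21565034
#>   max Re(eigenvalue, 3x3) = -0.0616978
#>   dies out (printed conditions): FALSE  | (numeric): TRUE

# stochastic run on a scale-free contact graph
net <- generate_scale_free(2000, 2, seed = 42)
fit_power_law(node_degrees(net))$exponent
#> [1] 2.638111
```

The same runs are available from the command line via a JSON config:

```sh
cat > demo.json <<'EOF'
{"alpha": 0.1, "gamma": 0.025,
 "beta1": 0.05, "beta2": 0.05, "beta3": 0.05, "beta4": 0.05,
 "lambda1": 0.035, "lambda2": 0.035, "mu1": 0.01, "mu2": 0.1,
 "init_s": 299990, "init_p": 5, "init_n": 5, "t_end": 100}
EOF
Rscript inst/cli/sedpnr.R simulate --config demo.json --out runs/demo
# peak P+N = 136863 at step 28
```

This writes `trajectory.csv` and `metadata.json` into `runs/demo`;
`analyze`, `network`, `compare` and `scenario` subcommands work the
same way (see `?sedpnr_cli`).

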