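# modmet

Is a modular metabolism a robust metabolism? `modmet` is a model system for
answering that question directly: it generates random, atom-explicit,
mass-conserving chemical reaction systems whose **substance-graph
modularity** can be tuned, simulates their mass-action kinetics to
equilibrium, applies four classes of mass-conserving perturbations
(metabolic or genetic, local or global), and measures how robustness and
relaxation time scale with network modularity. It is aimed at systems
biologists and network scientists studying structure-function relations in
artificial chemistries.

## The model in brief

* **Generator.** Atom species are split into `n_groups` proto-modules.
  Molecules are random atom multisets; reactions are built by randomly
  splitting and recombining molecules, so every reaction conserves every
  atom species exactly. A fraction *f* of reactions stays within one
  proto-module; the rest are bridges with a substrate in one group and a
  product in another. *f* is the modularity dial: the projected substance
  graph (metabolites as vertices, an edge when two metabolites share a
  reaction) becomes more modular as *f* → 1. The metabolite count `N_M` is
  an output of the construction.
* **Modularity.** Q = Σᵢ (eᵢᵢ − aᵢ²) over vertex groups, maximized by a
  deterministic greedy agglomeration and validated against an exact
  brute-force oracle (≤ 12 vertices).
* **Kinetics.** Mass-action with implicit enzymes, signed normal rate
  constants (sign = direction), explicit Euler integration with clipping at
  zero. Metabolites consumed by no reaction are sinks and drain at rate λc;
  metabolites produced by no reaction are sources, and the drained mass is
  recycled to them, so total mass is conserved exactly. Relaxation
  stops when the L1 rate of change falls below `eps`; the time to that point
  is the relaxation time τ.
* **Perturbations.** Metabolic: swap total masses of metabolite pairs until
  a fraction θ of the system mass has been redistributed. Genetic: replace
  `n_replace` reactions under the original construction rules. Both conserve
  total mass exactly; both come in local (one detected module) and global
  flavours.
* **Robustness.** Unrobustness = mean over a metabolite set of
  |c − c′| / rms(c, c′); robustness is its reciprocal, system-wide (R_sys)
  or over the directly perturbed metabolites (R_foc).

## A worked example

```r
library(modmet)

sys <- generate_reaction_system(generator_config(local_fraction = 0.75),
                                seed = 42) |>
  sample_rate_constants(kinetics_config())
sys
#> <reaction_system> 89 metabolites, 200 reactions (150 within-group, 50 bridge)
#>   groups: 3 x 8 atom species; sources: 13, sinks: 14

part <- detect_modules(substance_graph(sys))
part
#> <module_partition> 89 vertices in 4 modules, Q = 0.3437

eq <- relax(sample_initial_state(sys, kinetics_config()), sys,
            kinetics_config())
eq
#> <trajectory_result> converged after 610428 steps (tau = 6104.28)

shock <- metabolic_perturbation(eq$final_state, sys, "global", theta = 0.2,
                                partition = part)
eq2 <- relax(shock$state, sys, kinetics_config())
robustness(eq$final_state, eq2$final_state)                    # R_sys
#> [1] 1.136191
robustness(eq$final_state, eq2$final_state, shock$record$focal_set)  # R_foc
#> [1] 1.026802
eq2$tau
#> [1] 2783.53
```

Read: after redistributing 20% of the system's mass, the average rescaled
concentration change over all 89 metabolites corresponds to a system-wide
robustness of about 1.14; the directly swapped metabolites moved slightly
more (focal robustness 1.03). The perturbed system found its new
equilibrium in 2784 time units.

The ensemble layer repeats this over many realizations and f values:

```r
sw <- run_sweep(f_values = c(0.5, 0.75, 1.0), n_realizations = 50, seed = 1)
tidy(sw)              # per-(f, class) means and standard errors
summarize_trends(sw)  # Spearman rho of each measure against mean Q
autoplot(sw)          # R and tau versus Q, per perturbation class
```

A thin command-line front end is installed with the package
(`system.file("cli", "modmet.R", package = "modmet")`) with subcommands
`generate`, `project`, `modularity`, `simulate`, `perturb` and `sweep`;
reaction
systems round-trip losslessly through a structured JSON format
(`write_system_json()` / `read_system_json()`).

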