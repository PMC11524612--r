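# chlorodyn

Chloride and potassium ion dynamics in a conductance-based neuron model.

`chlorodyn` is an R package for studying how intracellular chloride
accumulation turns GABAergic inhibition into excitation and drives
seizure-like events in a single-compartment neuron. It implements a
Hodgkin–Huxley-type membrane coupled to three dynamic ion concentrations
(extracellular K⁺, intracellular Na⁺ and Cl⁻), with a Na⁺/K⁺ pump, KCC2
and NKCC1 cotransporters, GABA_A receptor input carrying both chloride
and bicarbonate, and first-order potassium exchange with a bath. On top
of the model it provides:

* a compiled fixed-step RK4 integrator (with an adaptive `deSolve`
  cross-check), spike detection, and firing-pattern classification
  (resting, subthreshold oscillation, tonic firing, periodic bursting,
  bursting interrupted by depolarization block, stable depolarization
  block);
* a fixed-point toolkit: damped-Newton stationary solves, Jacobian
  eigenvalue stability analysis, pseudo-arclength branch continuation,
  saddle-node and Hopf detection with bisection refinement, and the
  voltage/E_Cl crossover that separates inhibitory from depolarizing
  GABA;
* scenario presets for the standard stimulation protocols
  (chloride-loading sweeps, GABA steps and spike trains with or without
  HCO₃⁻ counterflux, potassium-bath washout), a YAML scenario schema,
  grid scans, and a command-line front end.

## The model in brief

The state is `(V, m, n, h, K_o, Na_i, Cl_i)`. The membrane equation is

    C dV/dt = − gK n⁴ (V−E_K) − gNa m³h (V−E_Na)
              − gKL (V−E_K) − gNaL (V−E_Na) − gClL (V−E_Cl)
              − ρ_pump/γ − g_GABA (V−E_Cl) − r·g_GABA (V−E_HCO3)

with Nernstian reversal potentials that move with the concentrations,
`E_HCO3 = −13 mV` fixed, and `r = 0.2` the bicarbonate/chloride
conductance ratio of the GABA_A receptor. The three ion balances follow
the same membrane currents (conversion factor γ), the 2:3 pump
stoichiometry, Nernst-like KCC2/NKCC1 cotransport, and bath exchange
`−ε_K (K_o − K_bath)`; intracellular K⁺ and extracellular Na⁺/Cl⁻ are
closed by electroneutrality with a fixed volume ratio β = 7. With the
bath decoupled the system conserves
`Q = (γC/τ_ion) V + K_o − Na_i + Cl_i`, which organizes the whole
analysis: fixed points form a one-parameter family, and each initial
condition can only reach attractors on its own level set of `Q`. See the
methods vignette (`vignettes/chloride-dynamics.Rmd`) for the full
equations, numerics, and design decisions.

## Worked example

```r
library(chlorodyn)
p <- neuron_params(eps_k = 0)              # bath-decoupled model

find_fixed_point(p, "Cl_i", 5.97)
#> <fixed_point> Cl_i = 5.97: V = -70.6862 mV, Cl_i = 5.97 mM [stable], residual 2.22e-15

br <- continue_branch(p, "Cl_i", c(5, 20)) # the fixed-point branch
br
#> <neuron_branch> 58 points, Cl_i in [5, 20.0206]
#>   stability: saddle=31, stable=16, unstable_focus=11

detect_bifurcations(br)
#> $sn
#>        par         V     Cl_i      K_o     Na_i
#> 2 6.333918 -52.24436 6.335286 2.576219 27.46476
#> 1 7.884935 -59.13993 7.883136 4.577135 18.15598
#> $hb
#>        par         V     Cl_i      K_o    Na_i
#> 1 18.91906 -35.59497 18.91906 16.84089 27.6075

gaba_crossover(br)
#> $V
#> [1] -36.38268
#> $par
#> [1] 17.1268
```

The resting state at low chloride sits at −70.7 mV. The branch is
S-shaped: the stable resting sheet ends at a saddle-node fold at
[Cl⁻]ᵢ ≈ 7.88 mM (the second fold at 6.33 mM closes the hysteresis
loop), an unstable middle sheet follows, and a stable
depolarization-block sheet appears above a Hopf bifurcation at
≈ 18.9 mM. Along the branch the fixed-point voltage crosses the chloride
reversal potential at ≈ −36.4 mV: below that voltage a pure chloride
conductance is inhibitory, above it depolarizing.

Trajectories tell the same story from the flow side:

```r
s  <- neuron_state(V = -70.74, K_o = 2.99, Na_i = 20.06, Cl_i = 12.5)
tr <- integrate_neuron(s, p, t_end = 120000)   # 120 s of model time
tr
#> <neuron_trace> 120001 samples over 120000 ms (completed); 1110 spikes
classify_firing(tr)
#> <firing_pattern> tonic_firing: 1055 spikes, 1 bursts, DB 0% of 118 s window
```

A chloride load of 12.5 mM puts the neuron on a level set with no
resting state, and it fires tonically. With bicarbonate counterflux
enabled, a sustained 10 Hz GABA spike train ratchets a *resting* neuron
up the level sets — depolarizing drift, then sustained firing, then
stable depolarization block — while the same train with `r_hco3 = 0`
merely hyperpolarizes it; see the scenario presets
(`list_presets()`, `scenario_preset("fig3")`) and the acceptance tests.

A thin CLI wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","chlorodyn",package="chlorodyn"))') \
    branch --preset fig1B --out-dir out/
```

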