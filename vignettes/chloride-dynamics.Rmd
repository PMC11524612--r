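---
title: "Chloride-potassium dynamics in a single-compartment neuron: model, numerics, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chloride-potassium dynamics in a single-compartment neuron: model, numerics, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chlorodyn)
```

## The model

`chlorodyn` implements a single-compartment Hodgkin-Huxley-type neuron in
which the membrane potential is coupled to three dynamic ion
concentrations. The state is the 7-vector
$(V, m, n, h, [\mathrm{K}^+]_o, [\mathrm{Na}^+]_i, [\mathrm{Cl}^-]_i)$.
The current balance is

$$C \frac{dV}{dt} = -g_K n^4 (V - E_K) - g_{Na} m^3 h (V - E_{Na})
  - g_{KL}(V - E_K) - g_{NaL}(V - E_{Na}) - g_{ClL}(V - E_{Cl})
  - \frac{\rho_{pump}}{\gamma} - I_{GABA},$$

with Traub-Miles-type gating kinetics
$\dot{x} = \alpha_x(V)(1 - x) - \beta_x(V)\,x$ for $x \in \{m, n, h\}$.
All reversal potentials are Nernstian, $E = 26.64\,\ln(c_{out}/c_{in})$ mV
(the prefactor fixed at its 310 K value; chloride's ratio is inverted),
and move with the concentrations. The Na$^+$/K$^+$ pump rate is a product
of logistic activations in $[\mathrm{Na}^+]_i$ and $[\mathrm{K}^+]_o$
saturating at $\rho$; KCC2 and NKCC1 cotransport is Nernst-like
(`cotransporter_fluxes()`); and the three ion balances follow the
membrane currents with the conversion factor $\gamma$ (which encodes
surface area, intracellular volume and the Faraday constant), pump
stoichiometry 2:3, electroneutral cotransport, and first-order exchange
of extracellular potassium with a bath,
$-\varepsilon_K([\mathrm{K}^+]_o - [\mathrm{K}^+]_{bath})$.

GABA$_A$ input carries both chloride and bicarbonate. The receptor
conductance $g_{GABA}(t)$ contributes $g_{GABA}(V - E_{Cl})$ plus
$r\,g_{GABA}(V - E_{HCO_3})$ to the current balance, with the
bicarbonate/chloride conductance ratio $r = 0.2$ and $E_{HCO_3}$ held at
$-13$ mV (the intracellular bicarbonate pool is treated as buffered:
carbonic-anhydrase regeneration is fast on these time scales). Only the
chloride component enters the chloride balance; the bicarbonate
counterflux moves charge but not any tracked ion, which is what lets
sustained GABA input push the system across conserved-charge level sets
(below).

The remaining concentrations are slaved by electroneutrality and fixed
total ion content:
$[\mathrm{K}^+]_i = 100 - [\mathrm{Na}^+]_i + [\mathrm{Cl}^-]_i$,
$[\mathrm{Na}^+]_o = 135 - \beta([\mathrm{Na}^+]_i - 20)$,
$[\mathrm{Cl}^-]_o = 145 - \beta([\mathrm{Cl}^-]_i - 6)$, with the
volume ratio $\beta = 7$ held fixed (no osmotic volume dynamics). A
closure driven to a non-positive concentration is treated as leaving the
model's validity region and raises an error rather than being clamped,
so failed integrations are diagnosable.

### Units and the ion time scale

The units contract is: $V$ in mV, $t$ in ms, concentrations in mM,
conductances in mS/cm$^2$, currents in µA/cm$^2$, fluxes in mM/s. Because
$\gamma$ and the pump/cotransporter strengths are per-second quantities
while the voltage equations live on milliseconds, the three ion balances
are divided by `tau_ion` (default $10^3$, i.e. ms per second). This makes
ion concentrations evolve on seconds while spikes evolve on
milliseconds, which is the separation of time scales the whole analysis
rests on. `tau_ion` is exposed as an ordinary parameter.

### The sign of the GABA terms

Every current enters $dV/dt$ with the conventional $-g(V - E)$ sign, the
GABA terms included: a pure chloride conductance then hyperpolarizes
whenever $V > E_{Cl}$, which is the defining property of GABAergic
inhibition at normal chloride loads. A `gaba_sign = +1` parameter flips
only the two GABA terms to a $+g(V-E)$ form; under that variant GABA
input would inject outward current at rest, and it is retained purely so
the two conventions can be compared.

## The conserved charge and its consequences

With the bath decoupled ($\varepsilon_K = 0$) and no bicarbonate-carrying
input, the membrane currents that move the tracked ions are exactly the
currents of the voltage equation, so

$$Q \;=\; \frac{\gamma C}{\tau_{ion}} V + [\mathrm{K}^+]_o -
  [\mathrm{Na}^+]_i + [\mathrm{Cl}^-]_i$$

is a constant of motion (`conserved_charge()`; `flux_charge_residual()`
checks the underlying identity, which holds to $\sim 10^{-14}$ mM/s at
machine precision and to $\sim 10^{-12}$ mM along $3 \times 10^6$-step
RK4 trajectories). Three structural consequences follow, and the package
is built around them:

1. **Fixed points form a one-parameter family.** Only six of the seven
   stationarity conditions are independent, so `find_fixed_point()`
   clamps $[\mathrm{Cl}^-]_i$, solves the 6-dimensional subsystem by
   damped Newton iteration, and then *verifies* (rather than assumes)
   that the omitted chloride balance vanishes; if it does not — e.g. if
   bath coupling is on — an `inconsistency` error reports that the
   clamping assumption broke, and the full 7-dimensional solve with the
   GABA conductance as the free parameter is the right tool.
2. **The full Jacobian has a structural zero eigenvalue** (left
   eigenvector $\nabla Q$) at every fixed point. Stability on the
   chloride-clamped branch is therefore classified from the Jacobian of
   the system reduced to a level set of $Q$ (chloride eliminated by the
   conservation law), which removes the structural zero exactly instead
   of discarding whichever numerical eigenvalue happens to be smallest.
   The full 7x7 spectrum is kept alongside
   (`jacobian_eigenvalues(..., reduced = FALSE)`).
3. **Initial conditions select their attractor by level set.** A
   trajectory can only reach states on its own $Q$ level set: the
   asymptotic resting chloride after a chloride load depends on the
   initial condition, the sustained-spiking onset in initial
   $[\mathrm{Cl}^-]_i$ is the level set on which the resting fixed point
   ceases to exist (the level set tangent to the branch at the
   saddle-node), and the stable depolarization-block onset is the level
   set of the Hopf point. Bicarbonate counterflux and bath exchange both
   break the conservation, which is precisely why GABA-with-HCO$_3^-$
   input can ratchet the neuron up the level sets into seizure-like
   firing and why a low-potassium bath can pull it back down.

## Stimulation protocols

Two deterministic GABA protocols are provided. A **step**
(`step_protocol()`) is a constant conductance inside a window. A **spike
train** (`spike_train_protocol()`) places regular presynaptic spikes at
`1000/frequency` ms intervals inside `[onset, offset]`; each spike
launches a causal kernel. The default kernel is the sum form
$A_0[e^{-\Delta/\tau_1} + e^{-\Delta/\tau_2}]$ gated at the spike time (a
literal delta-function weighting would vanish almost everywhere); the
conventional difference-form biexponential synapse is available as
`kernel_form = "difference"`. The kernel constants are package choices,
not published values: $\tau_1 = 5$ ms, $\tau_2 = 1$ ms, and $A_0 = 5/3$
mS/cm$^2$ so that a 10 Hz train time-averages $\approx 0.1$ mS/cm$^2$,
the order of the step-protocol regime. Scenario presets built on spike
trains carry an `amplitude_unpublished` annotation and should be read
qualitatively.

## Numerics

**Integration.** The reference integrator is fixed-step classical RK4,
compiled, with `dt = 0.02` ms — comfortably stable for
Hodgkin-Huxley-scale dynamics; spike detection (upward crossing of
$-20$ mV with 2 ms refractory separation, linearly interpolated) runs on
the undecimated voltage stream while the stored trace is decimated to 1
sample/ms by default. The identical right-hand side is also integrated
by the adaptive stiff solver of **deSolve** (`method = "lsoda"`, rtol
$10^{-8}$) as an independent cross-check; the test suite requires
agreement (subthreshold voltage to 0.1 mV; spike counts and slow
variables on spiking scenarios) and spike-count invariance under halving
`dt`.

**Fixed points and continuation.** Newton iterations use
finite-difference Jacobians with per-variable scaled central steps
($10^{-6} \max(1, |x_i|)$) and residuals rescaled so the ion equations
(which carry the $1/\tau_{ion}$ factor) count at the same magnitude as
the voltage equation; convergence is $10^{-10}$ on the scaled residual,
giving raw right-hand-side residuals below $10^{-8}$ everywhere on a
branch. Branches are continued by pseudo-arclength (secant predictor,
Newton corrector orthogonal to the tangent in a scaled metric, adaptive
step) with two safeguards that reject a step: the corrector landing far
from the predictor (a sheet jump) or the branch direction reversing (a
zigzag at a sharp fold). A branch that returns to its starting point has
traversed a closed hysteresis loop and stops. Saddle-nodes are located
as folds (extrema of the parameter along arclength, where the leading
real eigenvalue crosses zero) and refined by bisection on solution
existence from the pre-fold side; Hopf points as zero crossings of the
leading complex-pair real part, refined by bisection with fresh solves;
both to $5 \times 10^{-3}$ in the parameter. Points with
$|\mathrm{Re}\,\lambda| < 10^{-6}$ are classified `marginal`, which keeps
the bracketing robust.

**Classification.** The firing vocabulary is
`resting`, `subthreshold_oscillation`, `tonic_firing`,
`periodic_bursting`, `bursting_with_DB`, `stable_DB`, assigned by fixed
decision rules: depolarization block is a 2 s window with mean $V >
-50$ mV, no spikes, and peak-to-peak ripple under 5 mV (the flatness
requirement separates a genuine plateau from the large-amplitude
subthreshold oscillation that precedes it); `stable_DB` requires the
block to hold through the final 20 s; bursts are segmented at
interspike intervals above 5x the within-burst median, and tonic firing
requires an ISI coefficient of variation below 0.5. The
tonic-versus-bursting rule is an operationalization — the distinction is
usually made by eye — and windows under 60 s flag burst-class labels as
low-confidence rather than failing.

**Transition searches.** `find_transition()` is a plain bisection on a
user predicate and requires the predicate to differ at the bracket
endpoints. The packaged searches for chloride-loading thresholds probe
with 300 s of model time per bisection step (the transients near these
boundaries are tens of seconds to minutes long) and use predicates that
ignore the initial transient: *sustained spiking* means spikes in the
second half of the probe window, because near-threshold relaxations fire
a short volley in the first second before settling; *stable
depolarization block* means the final-60 s label is `stable_DB`.

**Problem sizes in the tests.** The test suite runs the same analyses at
reduced scale: 120-150 s transition probes with 0.05 mM bisection
tolerance, 5-30 s solver-agreement scenarios, and 120 s classification
horizons for the chloride sweep; the acceptance script
(`scripts/acceptance.R`) runs the full 300 s probes and the spec'd
refinement tolerances.

## What the scenarios do and do not emulate

The scenario presets reproduce the study conditions this model family is
used for: chloride loading of a bath-decoupled neuron, step and
spike-train GABA input with or without bicarbonate counterflux, and
potassium-bath washout at exchange rates
$\varepsilon_K \in \{0.0025, 0.025, 0.25\}$ s$^{-1}$. They do not emulate
osmotic volume changes (the volume ratio is fixed), bicarbonate
concentration dynamics ($E_{HCO_3}$ is constant), oxygen or glial
dynamics, stochastic channel noise, or network interactions. Passing
tests therefore demonstrate the internal consistency of this
deterministic single-compartment idealization, not quantitative
agreement with recordings.

## Known limitations

* **Dynamics-dependent reference values are convention-sensitive.** The
  equilibrium-derived quantities this package computes (the fold of the
  fixed-point branch near 7.89 mM, the resting potential near
  $-70.7$ mV, the voltage/$E_{Cl}$ crossover) are invariant to the ion
  time-scale factor, to how the extracellular-potassium balance treats
  the volume ratio, and to any common scaling of the gating rates,
  because none of those change where the right-hand side vanishes.
  Quantities that depend on the *dynamics* — the Hopf position on the
  branch, loading-trajectory endpoints, step-GABA firing and
  depolarization-block thresholds — are not: in particular, a common
  temperature-like factor on the gating rates moves the Hopf point by
  more than a millimolar while leaving every equilibrium quantity
  untouched. This parameterization fixes that factor at 1 (the gating
  rate functions are used exactly as written); reference values for the
  dynamic quantities reported elsewhere for closely related
  parameterizations may therefore differ from what this implementation
  computes, and the acceptance suite reports such disagreements rather
  than absorbing them.
* **The conservation law pins trajectory endpoints.** Under the printed
  bath-decoupled equations the asymptotic resting chloride after a load
  is determined by the initial conserved charge; descriptions of this
  model family in which different initial chloride loads relax to a
  common resting chloride imply some conservation-breaking ingredient
  (dynamic $[\mathrm{K}^+]_i$ bookkeeping, bath leak, or volume
  dynamics) that is outside this model's printed form.
* Near the depolarization-block onset the approach to the stable focus
  is critically slow, so classifier-based threshold estimates carry a
  probe-length bias of a few tenths of a millimolar; the
  continuation-based Hopf location does not.
* The validity region ends where a closure empties a compartment
  ($[\mathrm{Cl}^-]_o > 0$ requires $[\mathrm{Cl}^-]_i < 26.7$ mM at
  $\beta = 7$); searches are capped there.

## A worked tour

```{r tour, eval = FALSE}
p <- neuron_params(eps_k = 0)          # bath-decoupled

# the fixed-point branch in clamped chloride, with stability
br  <- continue_branch(p, "Cl_i", c(5, 20))
bif <- detect_bifurcations(br)
bif$sn; bif$hb                          # saddle-node(s) and Hopf
gaba_crossover(br)                      # where V = E_Cl along the branch

# a chloride-loading trajectory and its classification
s  <- neuron_state(V = -70.74, K_o = 2.99, Na_i = 20.06, Cl_i = 12.5)
tr <- integrate_neuron(s, p, t_end = 120000)
classify_firing(tr)

# GABA train with bicarbonate counterflux from rest
rest <- find_fixed_point(p, "Cl_i", 5.9)$state
tr2  <- integrate_neuron(rest, p, spike_train_protocol(10, onset = 5000),
                         t_end = 1e6)
classify_firing(tr2, window = 60000)   # ends in depolarization block
```
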