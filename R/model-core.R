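# Right-hand side of the coupled voltage/ion system and all of its pieces,
# exposed as pure, stateless evaluations. Gating kinetics follow the
# hippocampal-neuron rate functions; reversal potentials are Nernstian and
# move with the ion concentrations; the Na/K pump, KCC2 and NKCC1 close the
# ion budget; extracellular potassium optionally exchanges with a bath.

# x / (1 - exp(-x / y)) with the removable singularity at x = 0 handled by
# its analytic limit (series y + x/2 for |x| below the branch cut).
vtrap <- function(x, y) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-6
  out[small] <- y + x[small] / 2
  out[!small] <- x[!small] / (1 - exp(-x[!small] / y))
  out
}

#' Voltage-gated channel opening and closing rates
#'
#' Rate functions (1/ms) of the transient sodium activation `m` and
#' inactivation `h` and the delayed-rectifier potassium activation `n`.
#' The removable singularities of `alpha_m` (V = -54), `beta_m` (V = -27)
#' and `alpha_n` (V = -52) are evaluated by their analytic limits.
#'
#' @param V Membrane potential (mV); may be a vector.
#' @return A data.frame with columns `alpha_m, beta_m, alpha_h, beta_h,
#'   alpha_n, beta_n`, one row per element of `V`.
#' @export
#' @examples
#' gating_rates(-52)$alpha_n # 0.16, the limit value
gating_rates <- function(V) {
  if (any(!is.finite(V))) stop("V must be finite")
  data.frame(
    alpha_m = 0.32 * vtrap(V + 54, 4),
    beta_m  = 0.28 * vtrap(-(V + 27), 5),
    alpha_h = 0.128 * exp(-(V + 50) / 18),
    beta_h  = 4 / (1 + exp(-(V + 27) / 5)),
    alpha_n = 0.032 * vtrap(V + 52, 5),
    beta_n  = 0.5 * exp(-(V + 57) / 40)
  )
}

#' Voltage steady state of the gating variables
#'
#' `alpha / (alpha + beta)` for each of `m`, `n`, `h` at a fixed voltage.
#'
#' @param V Membrane potential (mV), scalar.
#' @return Named vector `c(m, n, h)`.
#' @export
steady_gating <- function(V) {
  r <- gating_rates(V)
  c(m = r$alpha_m / (r$alpha_m + r$beta_m),
    n = r$alpha_n / (r$alpha_n + r$beta_n),
    h = r$alpha_h / (r$alpha_h + r$beta_h))
}

#' Electroneutrality closures
#'
#' The intracellular potassium and extracellular sodium and chloride
#' concentrations are slaved to the dynamic concentrations by
#' electroneutrality and fixed total ion content:
#' `K_i = 100 - Na_i + Cl_i`, `Na_o = 135 - beta (Na_i - 20)`,
#' `Cl_o = 145 - beta (Cl_i - 6)` (mM, with `beta` the volume ratio).
#'
#' @param Na_i,Cl_i Intracellular sodium and chloride (mM, positive).
#' @param params A [neuron_params()] object.
#' @return Named list `K_i`, `Na_o`, `Cl_o` (mM).
#' @export
#' @examples
#' closures(20, 6, neuron_params()) # K_i = 86, Na_o = 135, Cl_o = 145
closures <- function(Na_i, Cl_i, params) {
  if (any(Na_i <= 0) || any(Cl_i <= 0))
    stop("Na_i and Cl_i must be positive")
  out <- list(
    K_i  = params$k_total - Na_i + Cl_i,
    Na_o = params$na_o_base - params$beta * (Na_i - params$na_i_ref),
    Cl_o = params$cl_o_base - params$beta * (Cl_i - params$cl_i_ref)
  )
  if (any(out$K_i <= 0) || any(out$Na_o <= 0) || any(out$Cl_o <= 0))
    stop("domain violation: closure yields a non-positive concentration ",
         "(state left the model's validity region)")
  out
}

#' Nernst reversal potentials
#'
#' `E_Na = 26.64 ln(Na_o/Na_i)`, `E_K = 26.64 ln(K_o/K_i)`,
#' `E_Cl = 26.64 ln(Cl_i/Cl_o)` (chloride carries negative charge, so its
#' ratio is inverted), with the closed concentrations from [closures()].
#'
#' @param state A 7-component state vector (see [neuron_state()]).
#' @param params A [neuron_params()] object.
#' @return Named list `E_Na`, `E_K`, `E_Cl` (mV).
#' @export
reversal_potentials <- function(state, params) {
  state <- validate_state(state)
  cl <- closures(state[["Na_i"]], state[["Cl_i"]], params)
  k <- params$nernst_coef
  list(E_Na = k * log(cl$Na_o / state[["Na_i"]]),
       E_K  = k * log(state[["K_o"]] / cl$K_i),
       E_Cl = k * log(state[["Cl_i"]] / cl$Cl_o))
}

#' Mixed GABA-A reversal potential
#'
#' Conductance-weighted average of the chloride and bicarbonate reversal
#' potentials, `E_GABA = (E_Cl + r E_HCO3) / (1 + r)` with `r` the
#' HCO3-/Cl- conductance ratio; it always lies between `E_Cl` and `E_hco3`.
#'
#' @param E_Cl Chloride reversal potential (mV); may be a vector.
#' @param params A [neuron_params()] object.
#' @return `E_GABA` (mV).
#' @export
gaba_reversal <- function(E_Cl, params) {
  (E_Cl + params$r_hco3 * params$E_hco3) / (1 + params$r_hco3)
}

#' Na+/K+ pump rate
#'
#' `rho_pump = rho / (1 + exp((25 - Na_i)/3)) / (1 + exp(3.5 - K_o))`
#' (mM/s): a product of logistic activations in intracellular sodium and
#' extracellular potassium, saturating at the maximal rate `rho`.
#'
#' @param Na_i,K_o Concentrations (mM); may be vectors.
#' @param params A [neuron_params()] object.
#' @return Pump rate (mM/s), in `(0, rho)`.
#' @export
#' @examples
#' pump_rate(25, 3.5, neuron_params()) # both factors 1/2: 0.25 * rho = 0.2
pump_rate <- function(Na_i, K_o, params) {
  params$rho / (1 + exp((25 - Na_i) / 3)) / (1 + exp(3.5 - K_o))
}

#' KCC2 and NKCC1 cotransporter fluxes
#'
#' Nernst-like cotransporter rates (mM/s):
#' `rho_kcc2 = U_kcc2 ln(K_i Cl_i / (K_o Cl_o))` (chloride and potassium
#' extrusion when the product gradient is outward) and
#' `rho_nkcc1 = U_nkcc1 f(K_o) [ln(K_o Cl_o / (K_i Cl_i)) +
#' ln(Na_o Cl_o / (Na_i Cl_i))]` with the logistic activation
#' `f(K_o) = 1 / (1 + exp(16 - K_o))`.
#'
#' @param state A 7-component state vector.
#' @param params A [neuron_params()] object.
#' @return Named list `rho_kcc2`, `rho_nkcc1` (mM/s) and `f_Ko`.
#' @export
cotransporter_fluxes <- function(state, params) {
  state <- validate_state(state)
  cl <- closures(state[["Na_i"]], state[["Cl_i"]], params)
  K_o <- state[["K_o"]]; Na_i <- state[["Na_i"]]; Cl_i <- state[["Cl_i"]]
  f_Ko <- 1 / (1 + exp(16 - K_o))
  list(
    rho_kcc2 = params$U_kcc2 * log((cl$K_i * Cl_i) / (K_o * cl$Cl_o)),
    rho_nkcc1 = params$U_nkcc1 * f_Ko *
      (log((K_o * cl$Cl_o) / (cl$K_i * Cl_i)) +
       log((cl$Na_o * cl$Cl_o) / (Na_i * Cl_i))),
    f_Ko = f_Ko
  )
}

#' Per-channel membrane currents
#'
#' All currents in uA/cm^2, positive outward: voltage-gated `I_Na`
#' (`gNa m^3 h (V - E_Na)`) and `I_K` (`gK n^4 (V - E_K)`), the three leaks,
#' the pump current `rho_pump / gamma` (net one positive charge expelled per
#' cycle), and the two GABA components `g_gaba (V - E_Cl)` and
#' `r_hco3 g_gaba (V - E_hco3)`.
#'
#' @param state A 7-component state vector.
#' @param params A [neuron_params()] object.
#' @param g_gaba GABA-A conductance at the moment of evaluation (mS/cm^2).
#' @return Named list of currents plus the reversal potentials used.
#' @export
membrane_currents <- function(state, params, g_gaba = 0) {
  state <- validate_state(state)
  E <- reversal_potentials(state, params)
  V <- state[["V"]]
  list(
    I_Na  = params$gNa * state[["m"]]^3 * state[["h"]] * (V - E$E_Na),
    I_K   = params$gK * state[["n"]]^4 * (V - E$E_K),
    I_NaL = params$gNaL * (V - E$E_Na),
    I_KL  = params$gKL * (V - E$E_K),
    I_ClL = params$gClL * (V - E$E_Cl),
    I_pump = pump_rate(state[["Na_i"]], state[["K_o"]], params) / params$gamma,
    I_gaba_cl = g_gaba * (V - E$E_Cl),
    I_gaba_hco3 = params$r_hco3 * g_gaba * (V - params$E_hco3),
    E = E
  )
}

#' Time derivatives of the full 7-dimensional state
#'
#' The complete right-hand side: the current balance for `dV/dt`, first-order
#' gating kinetics for `m`, `n`, `h`, and the three ion balances (potassium
#' efflux through voltage-gated and leak channels, pump 2:3 stoichiometry,
#' KCC2/NKCC1 cotransport, bath diffusion; sodium influx and pump/NKCC1;
#' chloride influx through the leak and GABA-A channels and cotransport).
#' Ion fluxes are expressed per second and divided by `tau_ion` to the ms
#' time base. Every current enters `dV/dt` as `-g (V - E)`; with
#' `gaba_sign = +1` the two GABA terms instead enter with the opposite
#' (literal-transcription) sign.
#'
#' @param state A 7-component state vector.
#' @param params A [neuron_params()] object.
#' @param g_gaba GABA-A conductance (mS/cm^2) at the evaluation time.
#' @param t Time (ms); only used to evaluate `protocol` when given.
#' @param protocol Optional stimulus protocol (see [step_protocol()] and
#'   [spike_train_protocol()]) evaluated at `t` in place of `g_gaba`.
#' @return Named derivative vector (V in mV/ms, gating per ms, ions mM/ms).
#' @export
#' @examples
#' p <- neuron_params(eps_k = 0)
#' s <- neuron_state(V = -70, K_o = 3, Na_i = 20, Cl_i = 6)
#' neuron_rhs(s, p)
neuron_rhs <- function(state, params, g_gaba = 0, t = 0, protocol = NULL) {
  if (!is.null(protocol)) g_gaba <- gaba_conductance(t, protocol)
  state <- validate_state(state)
  cur <- membrane_currents(state, params, g_gaba)
  co <- cotransporter_fluxes(state, params)
  rp <- pump_rate(state[["Na_i"]], state[["K_o"]], params)
  r <- gating_rates(state[["V"]])

  I_gaba <- params$gaba_sign * (cur$I_gaba_cl + cur$I_gaba_hco3)
  dV <- (-cur$I_K - cur$I_Na - cur$I_KL - cur$I_NaL - cur$I_ClL -
           cur$I_pump + I_gaba) / params$C

  dm <- r$alpha_m * (1 - state[["m"]]) - r$beta_m * state[["m"]]
  dn <- r$alpha_n * (1 - state[["n"]]) - r$beta_n * state[["n"]]
  dh <- r$alpha_h * (1 - state[["h"]]) - r$beta_h * state[["h"]]

  g <- params$gamma
  dK_o <- (g * (cur$I_K + cur$I_KL) - 2 * rp - co$rho_nkcc1 + co$rho_kcc2 -
             params$eps_k * (state[["K_o"]] - params$K_bath)) / params$tau_ion
  dNa_i <- (-g * (cur$I_Na + cur$I_NaL) - 3 * rp + co$rho_nkcc1) /
    params$tau_ion
  dCl_i <- (g * (cur$I_ClL + cur$I_gaba_cl) + 2 * co$rho_nkcc1 -
              co$rho_kcc2) / params$tau_ion

  c(V = dV, m = dm, n = dn, h = dh, K_o = dK_o, Na_i = dNa_i, Cl_i = dCl_i)
}

#' Derived quantities at a state
#'
#' Reversal potentials (including the mixed GABA reversal), closed
#' concentrations, pump and cotransporter fluxes, NKCC1 activation and
#' per-channel currents, bundled for trace annotation and reporting.
#'
#' @inheritParams neuron_rhs
#' @return Named list.
#' @export
derived_quantities <- function(state, params, g_gaba = 0) {
  state <- validate_state(state)
  cl <- closures(state[["Na_i"]], state[["Cl_i"]], params)
  cur <- membrane_currents(state, params, g_gaba)
  co <- cotransporter_fluxes(state, params)
  c(cur$E,
    list(E_GABA = gaba_reversal(cur$E$E_Cl, params)),
    cl, co,
    list(rho_pump = pump_rate(state[["Na_i"]], state[["K_o"]], params)),
    cur[setdiff(names(cur), "E")])
}

#' Flux-charge consistency residual
#'
#' In this model the membrane currents that move the tracked ions are the
#' same currents that drive the concentration balances, so
#' `gamma * (I_K + I_Na + I_Cl + I_pump + I_gaba_cl)` must equal the
#' flux-implied net charge-transfer rate
#' `tau_ion * d(K_o - Na_i + Cl_i)/dt` whenever bath exchange is off
#' (`eps_k = 0`). The bicarbonate component of the GABA current is excluded:
#' it is carried by an ion pool the model holds constant. This identity is
#' the redundancy that makes the fixed points of the conservative system a
#' one-parameter family, and (scaled by `gamma/tau_ion`) it implies the
#' conserved charge `Q = (gamma C / tau_ion) V + K_o - Na_i + Cl_i`.
#'
#' @inheritParams neuron_rhs
#' @return The residual (mM/s); analytically zero when `eps_k = 0`.
#' @export
flux_charge_residual <- function(state, params, g_gaba = 0) {
  cur <- membrane_currents(state, params, g_gaba)
  d <- neuron_rhs(state, params, g_gaba)
  total_I <- cur$I_K + cur$I_KL + cur$I_Na + cur$I_NaL + cur$I_ClL +
    cur$I_pump + cur$I_gaba_cl
  flux_rate <- params$tau_ion *
    (d[["K_o"]] - d[["Na_i"]] + d[["Cl_i"]]) +
    params$eps_k * (state[["K_o"]] - params$K_bath)
  params$gamma * total_I - flux_rate
}

#' Conserved charge of the bath-decoupled system
#'
#' `Q = (gamma C / tau_ion) V + K_o - Na_i + Cl_i` (mM), constant along any
#' trajectory with `eps_k = 0` and no bicarbonate-carrying GABA input. Each
#' level set of `Q` carries its own resting state, which is why the
#' asymptotic resting chloride depends on the initial condition.
#'
#' @inheritParams neuron_rhs
#' @return Scalar `Q` (mM).
#' @export
conserved_charge <- function(state, params) {
  state <- validate_state(state)
  (params$gamma * params$C / params$tau_ion) * state[["V"]] +
    state[["K_o"]] - state[["Na_i"]] + state[["Cl_i"]]
}
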