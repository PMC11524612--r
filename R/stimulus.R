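# GABA conductance protocols and bath coupling, evaluated as pure functions
# of time. Two protocol shapes: a constant conductance inside a window, and
# a deterministic regular spike train convolved with a biexponential kernel.

#' Step GABA conductance protocol
#'
#' Constant conductance `G_gaba` for `t` in `[t0, tn]`, zero outside.
#'
#' @param G_gaba Conductance (mS/cm^2), non-negative.
#' @param t0,tn Window start and end (ms), `t0 <= tn`.
#' @return Object of class `c("step_protocol", "gaba_protocol")`.
#' @export
step_protocol <- function(G_gaba, t0 = 0, tn = Inf) {
  stopifnot(G_gaba >= 0, t0 <= tn)
  structure(list(type = "step", G_gaba = G_gaba, t0 = t0, tn = tn),
            class = c("step_protocol", "gaba_protocol"))
}

#' Spike-train GABA conductance protocol
#'
#' A regular presynaptic train at `frequency` Hz gated to `[onset, offset]`;
#' each spike at `t_i` launches a causal kernel. `kernel_form = "sum"` uses
#' `A0 [exp(-(t - t_i)/tau1) + exp(-(t - t_i)/tau2)]` (value `2 A0` at the
#' spike); `"difference"` uses the conventional biexponential synapse
#' `A0 [exp(-(t - t_i)/tau1) - exp(-(t - t_i)/tau2)]` (zero at the spike,
#' rising to a positive peak; requires `tau1 >= tau2`). Spike times are
#' deterministic: `t_i = onset + i * 1000/frequency`.
#'
#' Defaults for the kernel: `tau1 = 5` ms, `tau2 = 1` ms, and `A0 = 5/3`
#' mS/cm^2, chosen so that a 10 Hz train time-averages about 0.1 mS/cm^2
#' (the order of the step-protocol regime); all three should be stated
#' explicitly in scenario files.
#'
#' @param frequency Spike rate (Hz), positive.
#' @param A0 Kernel amplitude (mS/cm^2), non-negative.
#' @param tau1,tau2 Kernel time constants (ms), positive.
#' @param onset,offset Stimulation window (ms).
#' @param kernel_form `"sum"` or `"difference"`.
#' @return Object of class `c("spike_train_protocol", "gaba_protocol")`.
#' @export
spike_train_protocol <- function(frequency, A0 = 5 / 3, tau1 = 5, tau2 = 1,
                                 onset = 0, offset = Inf,
                                 kernel_form = c("sum", "difference")) {
  kernel_form <- match.arg(kernel_form)
  stopifnot(frequency > 0, A0 >= 0, tau1 > 0, tau2 > 0, onset <= offset)
  if (kernel_form == "difference" && tau1 < tau2)
    stop("difference kernel requires tau1 >= tau2 (decay >= rise)")
  structure(list(type = "train", frequency = frequency, A0 = A0,
                 tau1 = tau1, tau2 = tau2, onset = onset, offset = offset,
                 kernel_form = kernel_form),
            class = c("spike_train_protocol", "gaba_protocol"))
}

#' Absent GABA input
#' @return A step protocol with zero conductance.
#' @export
no_gaba <- function() step_protocol(0, 0, 0)

#' Presynaptic spike times of a train protocol
#'
#' @param protocol A [spike_train_protocol()].
#' @param t_max Truncate the (possibly unbounded) train at this time (ms).
#' @return Numeric vector of spike times (ms), strictly increasing.
#' @export
spike_times_of <- function(protocol, t_max = protocol$offset) {
  stopifnot(inherits(protocol, "spike_train_protocol"))
  period <- 1000 / protocol$frequency
  last <- min(protocol$offset, t_max)
  if (!is.finite(last)) stop("t_max must be finite for an unbounded train")
  if (last < protocol$onset) return(numeric(0))
  seq(protocol$onset, last, by = period)
}

#' Evaluate a GABA protocol at given times
#'
#' @param t Times (ms); may be a vector.
#' @param protocol A [step_protocol()] or [spike_train_protocol()].
#' @return `g_GABA(t)` (mS/cm^2), same length as `t`.
#' @export
#' @examples
#' gaba_conductance(50, step_protocol(0.5, 0, 100))
gaba_conductance <- function(t, protocol) {
  UseMethod("gaba_conductance", protocol)
}

#' @export
gaba_conductance.step_protocol <- function(t, protocol) {
  ifelse(t >= protocol$t0 & t <= protocol$tn, protocol$G_gaba, 0)
}

#' @export
gaba_conductance.spike_train_protocol <- function(t, protocol) {
  if (!length(t)) return(numeric(0))
  ti <- spike_times_of(protocol, t_max = max(t))
  sgn <- if (protocol$kernel_form == "sum") 1 else -1
  vapply(t, function(tt) {
    d <- tt - ti
    d <- d[d >= 0]
    if (!length(d)) return(0)
    protocol$A0 * sum(exp(-d / protocol$tau1) + sgn * exp(-d / protocol$tau2))
  }, numeric(1))
}

#' Bath coupling settings
#'
#' First-order exchange of extracellular potassium with a fixed reservoir:
#' the term `-eps_k (K_o - K_bath)` of the potassium balance.
#'
#' @param K_bath Bath potassium (mM), non-negative.
#' @param eps_k Exchange rate (1/s), non-negative (0 decouples the bath).
#' @return Object of class `bath_protocol`.
#' @export
bath_protocol <- function(K_bath = 3, eps_k = 0.25) {
  stopifnot(K_bath >= 0, eps_k >= 0)
  structure(list(K_bath = K_bath, eps_k = eps_k), class = "bath_protocol")
}

# conductance as the compiled integrator evaluates it (cross-check hook)
rhs_probe_g <- function(t, protocol) g_at_cpp(t, protocol_to_c(protocol))

# Flat numeric encoding handed to the compiled integrator.
protocol_to_c <- function(protocol) {
  if (is.null(protocol)) protocol <- no_gaba()
  stopifnot(inherits(protocol, "gaba_protocol"))
  if (inherits(protocol, "step_protocol")) {
    c(type = 1, g = protocol$G_gaba, t0 = protocol$t0, t1 = protocol$tn,
      a0 = 0, tau1 = 1, tau2 = 1, period = 0, form = 0)
  } else {
    c(type = 2, g = 0, t0 = protocol$onset, t1 = protocol$offset,
      a0 = protocol$A0, tau1 = protocol$tau1, tau2 = protocol$tau2,
      period = 1000 / protocol$frequency,
      form = if (protocol$kernel_form == "sum") 0 else 1)
  }
}
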