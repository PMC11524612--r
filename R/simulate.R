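# Time integration of the 7-dimensional system and the trace container.

params_to_c <- function(p) {
  c(p$C, p$gNa, p$gK, p$gNaL, p$gKL, p$gClL, p$gamma, p$rho, p$U_kcc2,
    p$U_nkcc1, p$eps_k, p$K_bath, p$beta, p$E_hco3, p$r_hco3,
    p$nernst_coef, p$tau_ion, p$gaba_sign, p$k_total, p$na_o_base,
    p$cl_o_base, p$na_i_ref, p$cl_i_ref)
}

#' Integrate the neuron model
#'
#' Advances the full state `(V, m, n, h, K_o, Na_i, Cl_i)` from `initial`
#' to `t_end`. The reference method is fixed-step fourth-order Runge-Kutta
#' (compiled; default `dt = 0.02` ms, stable for Hodgkin-Huxley-scale
#' dynamics), with spike detection running on the undecimated voltage
#' stream (upward crossing of `spike_threshold` with a refractory
#' separation). `method = "lsoda"` integrates the identical right-hand side
#' with the adaptive stiff solver of \pkg{deSolve} as an independent
#' cross-check (spikes are then detected on the sampled trace, so keep
#' `record_dt` fine when using it).
#'
#' @param initial Initial state, from [neuron_state()].
#' @param params A [neuron_params()] object. The bath coupling is taken from
#'   `params$eps_k` / `params$K_bath` unless `bath` overrides it.
#' @param protocol A GABA protocol ([step_protocol()],
#'   [spike_train_protocol()]) or `NULL` for no input.
#' @param t_end End time (ms).
#' @param dt RK4 step (ms).
#' @param record_dt Sampling interval of the stored trace (ms); the
#'   integrator itself always steps at `dt`.
#' @param method `"rk4"` (reference) or `"lsoda"` (adaptive cross-check,
#'   relative tolerance 1e-8).
#' @param bath Optional [bath_protocol()] overriding `eps_k` and `K_bath`.
#' @param t0 Start time (ms).
#' @param spike_threshold,refractory Spike detection settings (mV, ms).
#' @param stop_when_converged If `TRUE`, stop early once every state
#'   variable varies by less than `converge_tol` over a
#'   `converge_window` ms window containing no spikes.
#' @param converge_window,converge_tol Convergence window (ms) and absolute
#'   tolerance applied to all state variables.
#' @param max_spikes Stop early after this many spikes (0 = never); useful
#'   for spiking-onset searches.
#' @return A `neuron_trace`: list with `t` (ms), `state` (matrix, one row
#'   per sample), `g_gaba`, `spikes` (times, ms), `status` (one of
#'   `"completed"`, `"converged"`, `"domain_error"`, `"spike_budget"`),
#'   `final_state`, `t_final`, and the run metadata. A domain violation
#'   mid-run (a closure driven to a non-positive concentration) aborts with
#'   the offending time and state in the error message, so integration
#'   failures are diagnosable rather than silently clamped.
#' @export
#' @examples
#' p <- neuron_params(eps_k = 0)
#' s <- neuron_state(V = -70.74, K_o = 2.99, Na_i = 20.06, Cl_i = 5.97)
#' tr <- integrate_neuron(s, p, t_end = 1000)
#' tail(as.data.frame(tr)[, c("t_ms", "V_mV", "Cl_i_mM")], 3)
integrate_neuron <- function(initial, params, protocol = NULL,
                             t_end = 1000, dt = 0.02, record_dt = 1,
                             method = c("rk4", "lsoda"), bath = NULL,
                             t0 = 0, spike_threshold = -20, refractory = 2,
                             stop_when_converged = FALSE,
                             converge_window = 10000, converge_tol = 1e-4,
                             max_spikes = 0) {
  method <- match.arg(method)
  initial <- validate_state(initial)
  stopifnot(inherits(params, "neuron_params"), dt > 0, t_end > t0)
  if (!is.null(bath)) {
    stopifnot(inherits(bath, "bath_protocol"))
    params <- neuron_params_update(params, eps_k = bath$eps_k,
                                   K_bath = bath$K_bath)
  }
  record_every <- max(1L, as.integer(round(record_dt / dt)))

  if (method == "rk4") {
    res <- integrate_cpp(unname(initial), params_to_c(params),
                         protocol_to_c(protocol), t0, t_end, dt,
                         record_every, spike_threshold, refractory,
                         stop_when_converged, converge_window,
                         converge_tol, as.integer(max_spikes))
    state <- res$y
    tvec <- res$t
    gvec <- res$g_gaba
    spikes <- res$spikes
    status_code <- res$status
    final_state <- setNames(res$y_final, state_names())
    t_final <- res$t_final
  } else {
    rhs_desolve <- function(t, y, parms) {
      list(rhs_cpp(t, y, parms$pc, parms$sc))
    }
    times <- seq(t0, t_end, by = record_dt)
    sol <- deSolve::lsoda(unname(initial), times, rhs_desolve,
                          parms = list(pc = params_to_c(params),
                                       sc = protocol_to_c(protocol)),
                          rtol = 1e-8, atol = 1e-10, maxsteps = 50000)
    tvec <- sol[, 1]
    state <- unname(sol[, 2:8, drop = FALSE])
    gvec <- gaba_conductance(tvec, if (is.null(protocol)) no_gaba()
                             else protocol)
    spikes <- detect_spikes_v(tvec, state[, 1], spike_threshold, refractory)
    status_code <- 0
    final_state <- setNames(state[nrow(state), ], state_names())
    t_final <- tvec[length(tvec)]
  }

  status <- c("completed", "converged", "domain_error",
              "spike_budget")[status_code + 1]
  if (status == "domain_error") {
    stop("domain violation at t = ", signif(t_final, 8), " ms; state: ",
         paste(signif(final_state, 6), collapse = ", "))
  }
  colnames(state) <- state_names()
  structure(list(t = tvec, state = state, g_gaba = gvec, spikes = spikes,
                 status = status, final_state = final_state,
                 t_final = t_final,
                 params = params, protocol = protocol,
                 solver = list(method = method, dt = dt,
                               record_dt = record_dt,
                               spike_threshold = spike_threshold,
                               refractory = refractory)),
            class = "neuron_trace")
}

# parameter update that preserves validation
neuron_params_update <- function(params, ...) {
  do.call(neuron_params, modifyList(unclass(params), list(...)))
}

#' @export
print.neuron_trace <- function(x, ...) {
  cat("<neuron_trace> ", length(x$t), " samples over ",
      signif(x$t_final - x$t[1], 6), " ms (", x$status, "); ",
      length(x$spikes), " spikes\n", sep = "")
  invisible(x)
}

#' Tidy data.frame view of a trace
#'
#' One row per recorded sample with state and reversal potentials
#' (`t_ms, V_mV, m, n, h, K_o_mM, Na_i_mM, Cl_i_mM, E_Na, E_K, E_Cl,
#' E_GABA, g_gaba`).
#'
#' @param x A `neuron_trace`.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return A data.frame.
#' @export
as.data.frame.neuron_trace <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
  s <- x$state
  p <- x$params
  K_i <- p$k_total - s[, "Na_i"] + s[, "Cl_i"]
  Na_o <- p$na_o_base - p$beta * (s[, "Na_i"] - p$na_i_ref)
  Cl_o <- p$cl_o_base - p$beta * (s[, "Cl_i"] - p$cl_i_ref)
  E_Na <- p$nernst_coef * log(Na_o / s[, "Na_i"])
  E_K <- p$nernst_coef * log(s[, "K_o"] / K_i)
  E_Cl <- p$nernst_coef * log(s[, "Cl_i"] / Cl_o)
  data.frame(t_ms = x$t, V_mV = s[, "V"], m = s[, "m"], n = s[, "n"],
             h = s[, "h"], K_o_mM = s[, "K_o"], Na_i_mM = s[, "Na_i"],
             Cl_i_mM = s[, "Cl_i"], E_Na = E_Na, E_K = E_K, E_Cl = E_Cl,
             E_GABA = gaba_reversal(E_Cl, p), g_gaba = x$g_gaba)
}

#' Export a trace as tidy CSV with a JSON metadata sidecar
#'
#' @param trace A `neuron_trace`.
#' @param path CSV output path; metadata is written to `paste0(path,
#'   ".meta.json")`.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  df <- as.data.frame(trace)
  write.csv(format(df, digits = 17, trim = TRUE), path, row.names = FALSE,
            quote = FALSE)
  meta <- list(params = unclass(trace$params),
               protocol = if (is.null(trace$protocol)) NULL
                          else unclass(trace$protocol),
               solver = trace$solver, status = trace$status,
               n_spikes = length(trace$spikes))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Asymptotic state of a scenario
#'
#' Integrates until every state variable varies by less than `tol` over a
#' window of `convergence_window` ms (with no spikes in the window), or
#' until `t_max`.
#'
#' @inheritParams integrate_neuron
#' @param convergence_window Window length (ms).
#' @param tol Absolute per-variable tolerance over the window.
#' @param t_max Give up after this much model time (ms).
#' @return The converged state (named vector, with attributes `t` and
#'   `trace`), or the character string `"non-stationary"`.
#' @export
steady_state_of <- function(initial, params, protocol = NULL,
                            convergence_window = 10000, tol = 1e-4,
                            t_max = 3e5, dt = 0.02) {
  tr <- integrate_neuron(initial, params, protocol, t_end = t_max, dt = dt,
                         stop_when_converged = TRUE,
                         converge_window = convergence_window,
                         converge_tol = tol)
  if (tr$status != "converged") return("non-stationary")
  out <- tr$final_state
  attr(out, "t") <- tr$t_final
  attr(out, "trace") <- tr
  out
}
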