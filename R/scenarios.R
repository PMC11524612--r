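# Scenario presets encoding the stimulation protocols of the study
# (chloride-loading sweeps, GABA step and spike-train input with or without
# bicarbonate counterflux, potassium-bath coupling), a YAML schema for
# user-defined scenarios, and the runner / grid scanner on top of the
# simulator, classifier and bifurcation modules.

SCENARIO_SCHEMA_VERSION <- 1L

#' Define a simulation/analysis scenario
#'
#' A scenario bundles a parameter set, an initial state (possibly partial:
#' gating is completed to its voltage steady state; `resolve` can replace
#' the state by a computed fixed point), a GABA protocol, the horizon, and
#' which analyses to run.
#'
#' @param name Scenario name.
#' @param params A [neuron_params()] object.
#' @param initial Named list with `Cl_i`, `Na_i`, `K_o` and optionally `V`.
#' @param resolve How to complete the initial state: `"given"` uses the
#'   supplied `V`; `"rest"` replaces the state by the resting fixed point
#'   (conservative chloride-clamped solve when `eps_k = 0`, the
#'   bath-coupled fixed point otherwise); `"db"` uses the depolarized
#'   (depolarization-block) fixed point of the bath-decoupled system at the
#'   given `Cl_i` as the starting condition.
#' @param protocol A GABA protocol or `NULL`.
#' @param t_end Simulation horizon (ms).
#' @param analyses Character subset of `c("classify", "branch",
#'   "crossover")`.
#' @param branch_par,branch_range Continuation settings when `"branch"` is
#'   requested.
#' @param classify_window Analysis window for [classify_firing()] (ms).
#' @param annotations Free-form metadata list (kept through YAML
#'   round-trips); presets whose published protocol omits the spike-train
#'   kernel amplitude carry `amplitude_unpublished = TRUE` here.
#' @return Object of class `neuron_scenario`.
#' @export
scenario <- function(name, params = neuron_params(), initial,
                     resolve = c("given", "rest", "db"), protocol = NULL,
                     t_end = 60000, analyses = "classify",
                     branch_par = "Cl_i", branch_range = c(5, 20),
                     classify_window = Inf, annotations = list()) {
  resolve <- match.arg(resolve)
  stopifnot(inherits(params, "neuron_params"), is.list(initial))
  if (resolve == "given" && is.null(initial$V))
    stop("scenario field 'initial.V' is required when resolve = 'given'")
  for (f in c("K_o", "Na_i", "Cl_i"))
    if (is.null(initial[[f]]))
      stop("scenario field 'initial.", f, "' is required")
  bad <- setdiff(analyses, c("classify", "branch", "crossover"))
  if (length(bad))
    stop("unknown analysis: ", paste(bad, collapse = ", "))
  structure(list(name = name, schema_version = SCENARIO_SCHEMA_VERSION,
                 params = params, initial = initial, resolve = resolve,
                 protocol = protocol, t_end = t_end, analyses = analyses,
                 branch_par = branch_par, branch_range = branch_range,
                 classify_window = classify_window,
                 annotations = annotations),
            class = "neuron_scenario")
}

#' @export
print.neuron_scenario <- function(x, ...) {
  cat("<neuron_scenario> ", x$name, ": t_end = ", x$t_end, " ms, ",
      "analyses = ", paste(x$analyses, collapse = "+"), "\n", sep = "")
  invisible(x)
}

resolve_initial <- function(sc) {
  ini <- sc$initial
  if (sc$resolve == "given") {
    return(neuron_state(V = ini$V, m = ini$m %||% NA, n = ini$n %||% NA,
                        h = ini$h %||% NA, K_o = ini$K_o,
                        Na_i = ini$Na_i, Cl_i = ini$Cl_i))
  }
  if (sc$resolve == "rest") {
    guess <- neuron_state(V = ini$V %||% -70, K_o = ini$K_o,
                          Na_i = ini$Na_i, Cl_i = ini$Cl_i)
    fp <- if (sc$params$eps_k == 0)
      find_fixed_point(sc$params, "Cl_i", ini$Cl_i, guess)
    else
      find_fixed_point(sc$params, "g_gaba", 0, guess)
    return(fp$state)
  }
  # "db": depolarized fixed point of the bath-decoupled system
  p0 <- neuron_params_update(sc$params, eps_k = 0)
  guess <- neuron_state(V = ini$V %||% -30, K_o = ini$K_o,
                        Na_i = ini$Na_i, Cl_i = ini$Cl_i)
  find_fixed_point(p0, "Cl_i", ini$Cl_i, guess)$state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a scenario
#'
#' Deterministic given the scenario (the model has no randomness): resolves
#' the initial state, integrates if any trace-based analysis is requested,
#' classifies the firing pattern, and/or continues a fixed-point branch
#' with bifurcation detection and the voltage/E_Cl crossover.
#'
#' @param sc A [scenario()].
#' @param dt RK4 step (ms).
#' @param ... Passed on to [integrate_neuron()].
#' @return List with (depending on `analyses`) `trace`, `pattern`,
#'   `branch`, `bifurcations`, `crossover`, plus `initial_state` and the
#'   scenario itself.
#' @export
run_scenario <- function(sc, dt = 0.02, ...) {
  stopifnot(inherits(sc, "neuron_scenario"))
  out <- list(scenario = sc)
  needs_trace <- "classify" %in% sc$analyses ||
    !all(sc$analyses %in% c("branch", "crossover"))
  if (needs_trace || sc$resolve != "given")
    out$initial_state <- resolve_initial(sc)
  if (needs_trace) {
    out$trace <- integrate_neuron(out$initial_state, sc$params,
                                  sc$protocol, t_end = sc$t_end, dt = dt,
                                  ...)
    if ("classify" %in% sc$analyses)
      out$pattern <- classify_firing(out$trace,
                                     window = sc$classify_window)
  }
  if (any(c("branch", "crossover") %in% sc$analyses)) {
    out$branch <- continue_branch(sc$params, sc$branch_par,
                                  sc$branch_range)
    if ("branch" %in% sc$analyses)
      out$bifurcations <- detect_bifurcations(out$branch)
    if ("crossover" %in% sc$analyses)
      out$crossover <- gaba_crossover(out$branch)
  }
  out
}

#' Scenario presets for the published stimulation protocols
#'
#' `list_presets()` names the available presets; `scenario_preset(name)`
#' builds one. The presets encode: the chloride-loading sweep of the
#' bath-decoupled model (`fig1D` ... `fig1I`, initial `[Na+]i = 20.06` mM
#' and `[K+]o = 2.99` mM with increasing initial chloride, started from
#' -70.74 mV), its fixed-point branch (`fig1B`) and the branch/E_Cl
#' crossover (`fig2B`); pure-chloride GABA trains onto a resting neuron
#' (`fig2D`, 25 Hz; `fig2F`, 80 Hz; bicarbonate conductance disabled); a
#' 10 Hz train with bicarbonate counterflux driving the neuron from rest
#' toward depolarization block (`fig3`); potassium-bath washout of a
#' depolarization-block state at three exchange rates (`fig4A`, `fig4F1`,
#' `fig4F2`); the step-GABA steady-state branch under bath coupling
#' (`fig8A`); and spike-train input with bath coupling and rebound after
#' stimulus offset (`fig9A`, 10 Hz). Spike-train presets carry the
#' annotation `amplitude_unpublished = TRUE`: the source protocol states
#' only the frequencies, so kernel amplitude and time constants are this
#' package's defaults and those scenarios are qualitative.
#'
#' @param name A preset name from `list_presets()`.
#' @return `scenario_preset()` returns a [scenario()]; `list_presets()` a
#'   character vector.
#' @export
scenario_preset <- function(name) {
  p0 <- neuron_params(eps_k = 0)   # bath-decoupled
  pb <- function(eps) neuron_params(eps_k = eps, K_bath = 3)
  ini1 <- function(cl) list(V = -70.74, K_o = 2.99, Na_i = 20.06,
                            Cl_i = cl)
  train <- function(f, onset = 0, offset = Inf)
    spike_train_protocol(f, onset = onset, offset = offset)
  ann_tr <- list(amplitude_unpublished = TRUE)
  sweep_cl <- c(fig1D = 5.97, fig1E = 9.88, fig1F = 10.23, fig1G = 10.93,
                fig1H = 11.99, fig1I = 12.5)
  if (name %in% names(sweep_cl)) {
    return(scenario(name, p0, ini1(sweep_cl[[name]]), "given",
                    t_end = 120000, classify_window = Inf))
  }
  switch(name,
    fig1B = scenario("fig1B", p0, ini1(5.97), "given", analyses = "branch",
                     branch_range = c(5, 20), t_end = 0),
    fig2B = scenario("fig2B", p0, ini1(5.97), "given",
                     analyses = c("branch", "crossover"),
                     branch_range = c(5, 20), t_end = 0),
    fig2D = scenario("fig2D", neuron_params(eps_k = 0, r_hco3 = 0),
                     list(K_o = 2.99, Na_i = 20.06, Cl_i = 7.85), "rest",
                     protocol = train(25, onset = 500), t_end = 30000,
                     annotations = ann_tr),
    fig2F = scenario("fig2F", neuron_params(eps_k = 0, r_hco3 = 0),
                     list(K_o = 2.99, Na_i = 20.06, Cl_i = 7.85), "rest",
                     protocol = train(80, onset = 500), t_end = 30000,
                     annotations = ann_tr),
    fig3 = scenario("fig3", p0,
                    list(K_o = 2.99, Na_i = 20.06, Cl_i = 7.85), "rest",
                    protocol = train(10, onset = 1e5), t_end = 7e5,
                    annotations = ann_tr),
    fig4A = scenario("fig4A", pb(0.0025),
                     list(K_o = 6, Na_i = 20, Cl_i = 18.75), "db",
                     t_end = 120000),
    fig4F1 = scenario("fig4F1", pb(0.025),
                      list(K_o = 6, Na_i = 20, Cl_i = 18.75), "db",
                      t_end = 120000),
    fig4F2 = scenario("fig4F2", pb(0.25),
                      list(K_o = 6, Na_i = 20, Cl_i = 18.75), "db",
                      t_end = 60000),
    fig8A = scenario("fig8A", pb(0.25),
                     list(K_o = 3, Na_i = 20, Cl_i = 6), "rest",
                     analyses = "branch", branch_par = "g_gaba",
                     branch_range = c(0, 3), t_end = 0),
    fig9A = scenario("fig9A", pb(0.025),
                     list(K_o = 3, Na_i = 20, Cl_i = 6), "rest",
                     protocol = train(10, onset = 1e5, offset = 6e5),
                     t_end = 8e5, annotations = ann_tr),
    stop("unknown preset '", name, "'; see list_presets()")
  )
}

#' @rdname scenario_preset
#' @export
list_presets <- function() {
  c("fig1B", "fig1D", "fig1E", "fig1F", "fig1G", "fig1H", "fig1I",
    "fig2B", "fig2D", "fig2F", "fig3", "fig4A", "fig4F1", "fig4F2",
    "fig8A", "fig9A")
}

#' Read or write a scenario as YAML
#'
#' The schema is a flat mapping with blocks `params` (see
#' [neuron_params()] names; omitted entries take defaults), `initial`,
#' `stimulus` (`type: step|train` plus the protocol fields) and the
#' run/analysis settings. Presets round-trip losslessly.
#'
#' @param sc A [scenario()].
#' @param path File path.
#' @return `read_scenario()` a scenario; `write_scenario()` the path,
#'   invisibly.
#' @export
write_scenario <- function(sc, path) {
  stopifnot(inherits(sc, "neuron_scenario"))
  stim <- if (is.null(sc$protocol)) NULL
  else if (inherits(sc$protocol, "step_protocol"))
    list(type = "step", G_gaba = sc$protocol$G_gaba, t0 = sc$protocol$t0,
         tn = sc$protocol$tn)
  else
    list(type = "train", frequency = sc$protocol$frequency,
         A0 = sc$protocol$A0, tau1 = sc$protocol$tau1,
         tau2 = sc$protocol$tau2, onset = sc$protocol$onset,
         offset = sc$protocol$offset,
         kernel_form = sc$protocol$kernel_form)
  doc <- list(name = sc$name, schema_version = sc$schema_version,
              params = lapply(unclass(sc$params), as.numeric),
              initial = sc$initial, resolve = sc$resolve, stimulus = stim,
              t_end = sc$t_end, analyses = as.list(sc$analyses),
              branch_par = sc$branch_par,
              branch_range = as.list(sc$branch_range),
              classify_window = sc$classify_window,
              annotations = sc$annotations)
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  doc <- yaml::read_yaml(path)
  need <- function(f) {
    if (is.null(doc[[f]])) stop("scenario schema error at '", f,
                                "': field missing")
    doc[[f]]
  }
  params <- do.call(neuron_params, doc$params %||% list())
  stim <- doc$stimulus
  protocol <- if (is.null(stim)) NULL
  else if (identical(stim$type, "step"))
    step_protocol(stim$G_gaba, stim$t0 %||% 0, stim$tn %||% Inf)
  else if (identical(stim$type, "train"))
    spike_train_protocol(stim$frequency, stim$A0, stim$tau1, stim$tau2,
                         stim$onset %||% 0, stim$offset %||% Inf,
                         stim$kernel_form %||% "sum")
  else stop("scenario schema error at 'stimulus.type': must be step|train")
  scenario(need("name"), params, need("initial"),
           doc$resolve %||% "given", protocol, need("t_end"),
           unlist(doc$analyses %||% "classify"),
           doc$branch_par %||% "Cl_i",
           unlist(doc$branch_range %||% c(5, 20)),
           doc$classify_window %||% Inf, doc$annotations %||% list())
}

#' Grid scan over two scenario axes
#'
#' Repeats a scenario while varying two fields over finite lists, running
#' each cell with [run_scenario()] and collecting one summary row per
#' cell: the firing-pattern label, spike and burst counts and DB occupancy
#' for trace analyses, and the detected SN/HB parameter values for branch
#' analyses.
#'
#' @param template A [scenario()].
#' @param axis1,axis2 Named lists `list(field = , values = )`, where
#'   `field` is a dotted path into the scenario (e.g. `"params.eps_k"`,
#'   `"protocol.frequency"`, `"initial.Cl_i"`).
#' @param ... Passed to [run_scenario()].
#' @return A tidy data.frame, one row per grid cell.
#' @export
grid_scan <- function(template, axis1, axis2 = NULL, ...) {
  stopifnot(inherits(template, "neuron_scenario"))
  vals2 <- if (is.null(axis2)) NA else axis2$values
  rows <- list()
  for (v1 in axis1$values) for (v2 in vals2) {
    sc <- set_scenario_field(template, axis1$field, v1)
    if (!is.null(axis2)) sc <- set_scenario_field(sc, axis2$field, v2)
    res <- run_scenario(sc, ...)
    row <- data.frame(a1 = v1, a2 = v2)
    names(row) <- c(axis1$field, if (is.null(axis2)) "axis2"
                    else axis2$field)
    if (!is.null(res$pattern)) {
      row$label <- res$pattern$label
      row$n_spikes <- res$pattern$stats$n_spikes
      row$n_bursts <- res$pattern$stats$n_bursts
      row$db_occupancy <- res$pattern$stats$db_occupancy
    }
    if (!is.null(res$bifurcations)) {
      row$sn <- if (nrow(res$bifurcations$sn)) res$bifurcations$sn$par[1]
                else NA_real_
      row$hb <- if (nrow(res$bifurcations$hb))
        utils::tail(res$bifurcations$hb$par, 1) else NA_real_
    }
    rows[[length(rows) + 1]] <- row
  }
  do.call(rbind, rows)
}

set_scenario_field <- function(sc, field, value) {
  parts <- strsplit(field, ".", fixed = TRUE)[[1]]
  if (length(parts) == 1) {
    sc[[parts]] <- value
    return(sc)
  }
  block <- parts[1]; leaf <- parts[2]
  if (block == "params") {
    sc$params <- do.call(neuron_params_update,
                         c(list(sc$params), setNames(list(value), leaf)))
  } else if (block %in% c("initial", "protocol", "annotations")) {
    if (is.null(sc[[block]]))
      stop("scenario has no '", block, "' to modify")
    sc[[block]][[leaf]] <- value
  } else stop("unknown scenario field: ", field)
  sc
}
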