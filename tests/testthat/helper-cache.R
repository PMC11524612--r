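# Shared fixtures, computed lazily once per test run and cached: the
# bath-decoupled continuation branch and its bifurcations are used by
# several files and are not free to recompute.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

p_conservative <- function() neuron_params(eps_k = 0)

cl_branch <- function() cached("cl_branch", {
  continue_branch(p_conservative(), "Cl_i", c(5, 20))
})

cl_bif <- function() cached("cl_bif", detect_bifurcations(cl_branch()))

fig8_params <- function() neuron_params(eps_k = 0.25, K_bath = 3)

fig8_rest <- function() cached("fig8_rest", {
  find_fixed_point(fig8_params(), "g_gaba", 0)
})

# deterministic pseudo-random valid states for property tests
random_states <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    neuron_state(V = runif(1, -90, 0), K_o = runif(1, 2, 12),
                 Na_i = runif(1, 10, 30), Cl_i = runif(1, 3, 18))
  })
}

# a minimal synthetic trace object for classifier unit tests
synthetic_trace <- function(t, V, params = neuron_params(),
                            spike_threshold = -20, refractory = 2) {
  structure(list(
    t = t,
    state = cbind(V = V, m = 0, n = 0, h = 1, K_o = 3, Na_i = 20,
                  Cl_i = 6),
    g_gaba = rep(0, length(t)),
    spikes = detect_spikes(t, V, spike_threshold, refractory),
    status = "completed",
    final_state = c(V = V[length(V)], m = 0, n = 0, h = 1, K_o = 3,
                    Na_i = 20, Cl_i = 6),
    t_final = t[length(t)],
    params = params, protocol = NULL,
    solver = list(method = "synthetic", dt = NA, record_dt = NA,
                  spike_threshold = spike_threshold,
                  refractory = refractory)),
    class = "neuron_trace")
}
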