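# Integration: reference RK4 vs the adaptive cross-check, convergence in
# dt, trace bookkeeping, early stopping, and failure modes.

test_that("a trajectory started at a stable fixed point stays there", {
  p <- p_conservative()
  fp <- find_fixed_point(p, "Cl_i", 6)
  tr <- integrate_neuron(fp$state, p, t_end = 10000)
  expect_lt(max(abs(tr$state[, "V"] - fp$state[["V"]])), 0.01)
  expect_length(tr$spikes, 0)
})

test_that("RK4 and the adaptive solver agree on a subthreshold scenario", {
  p <- p_conservative()
  s <- neuron_state(V = -70.74, K_o = 2.99, Na_i = 20.06, Cl_i = 5.97)
  tr_rk <- integrate_neuron(s, p, t_end = 5000, record_dt = 1)
  tr_ls <- integrate_neuron(s, p, t_end = 5000, record_dt = 1,
                            method = "lsoda")
  expect_lt(max(abs(tr_rk$state[, "V"] - tr_ls$state[, "V"])), 0.1)
  expect_lt(max(abs(tr_rk$state[, "Cl_i"] - tr_ls$state[, "Cl_i"])), 1e-3)
})

test_that("RK4 and the adaptive solver agree on a spiking scenario up to
          spike count and slow-variable error", {
  p <- p_conservative()
  s <- neuron_state(V = -70.74, K_o = 2.99, Na_i = 20.06, Cl_i = 12.5)
  tr_rk <- integrate_neuron(s, p, t_end = 5000, record_dt = 0.1)
  tr_ls <- integrate_neuron(s, p, t_end = 5000, record_dt = 0.1,
                            method = "lsoda")
  expect_equal(length(tr_rk$spikes), length(tr_ls$spikes))
  expect_lt(max(abs(tr_rk$state[, "Cl_i"] - tr_ls$state[, "Cl_i"])), 1e-3)
})

test_that("the spike count is invariant under halving dt", {
  p <- p_conservative()
  s <- neuron_state(V = -70.74, K_o = 2.99, Na_i = 20.06, Cl_i = 12.5)
  n1 <- length(integrate_neuron(s, p, t_end = 20000, dt = 0.02)$spikes)
  n2 <- length(integrate_neuron(s, p, t_end = 20000, dt = 0.01)$spikes)
  expect_identical(n1, n2)
})

test_that("gating variables remain inside [0, 1] along an accepted
          trajectory", {
  p <- p_conservative()
  s <- neuron_state(V = -70.74, K_o = 2.99, Na_i = 20.06, Cl_i = 13)
  tr <- integrate_neuron(s, p, t_end = 20000)
  g <- tr$state[, c("m", "n", "h")]
  expect_gte(min(g), -1e-12)
  expect_lte(max(g), 1 + 1e-12)
})

test_that("the conserved charge is flat to solver precision when the bath
          is decoupled and GABA is off", {
  p <- p_conservative()
  s <- neuron_state(V = -70.74, K_o = 2.99, Na_i = 20.06, Cl_i = 11)
  tr <- integrate_neuron(s, p, t_end = 30000)
  q <- (p$gamma * p$C / p$tau_ion) * tr$state[, "V"] +
    tr$state[, "K_o"] - tr$state[, "Na_i"] + tr$state[, "Cl_i"]
  expect_lt(max(abs(q - q[1])), 1e-10)
  expect_equal(q[1], conserved_charge(s, p))
})

test_that("steady_state_of returns the fixed point when started on it and
          'non-stationary' for a persistently spiking scenario", {
  p <- p_conservative()
  fp <- find_fixed_point(p, "Cl_i", 6)
  ss <- steady_state_of(fp$state, p, convergence_window = 2000,
                        tol = 1e-5, t_max = 30000)
  expect_false(identical(ss, "non-stationary"))
  expect_equal(unname(ss[1:7]), unname(fp$state), tolerance = 1e-6)
  spiking <- neuron_state(V = -70.74, K_o = 2.99, Na_i = 20.06, Cl_i = 13)
  expect_identical(
    steady_state_of(spiking, p, convergence_window = 5000, tol = 1e-4,
                    t_max = 40000),
    "non-stationary")
})

test_that("trace data.frame and CSV export carry the documented columns
          and metadata", {
  p <- p_conservative()
  s <- neuron_state(V = -70, K_o = 3, Na_i = 20, Cl_i = 8)
  tr <- integrate_neuron(s, p, step_protocol(0.2, 0, 500), t_end = 1000)
  df <- as.data.frame(tr)
  expect_identical(names(df),
                   c("t_ms", "V_mV", "m", "n", "h", "K_o_mM", "Na_i_mM",
                     "Cl_i_mM", "E_Na", "E_K", "E_Cl", "E_GABA", "g_gaba"))
  expect_true(all(diff(df$t_ms) > 0))
  # E_GABA is the weighted average of the exported E_Cl
  expect_equal(df$E_GABA, (df$E_Cl + 0.2 * -13) / 1.2, tolerance = 1e-12)
  f <- tempfile(fileext = ".csv")
  write_trace_csv(tr, f)
  back <- read.csv(f)
  expect_equal(nrow(back), nrow(df))
  expect_equal(back$V_mV, df$V_mV, tolerance = 1e-12)
  meta <- jsonlite::read_json(paste0(f, ".meta.json"))
  expect_equal(meta$params$gNa, 30)
  expect_equal(meta$solver$method, "rk4")
})

test_that("a domain violation mid-run aborts with the offending time
          attached", {
  p <- p_conservative()
  # chloride loading large enough that the closure empties Cl_o
  s <- neuron_state(V = -30, K_o = 8, Na_i = 25, Cl_i = 27)
  expect_error(integrate_neuron(s, p, t_end = 5000),
               "domain violation at t = ")
})

test_that("spike-budget early exit reports its status and stops promptly", {
  p <- p_conservative()
  s <- neuron_state(V = -70.74, K_o = 2.99, Na_i = 20.06, Cl_i = 13)
  tr <- integrate_neuron(s, p, t_end = 120000, max_spikes = 3)
  expect_identical(tr$status, "spike_budget")
  expect_length(tr$spikes, 3)
  expect_lt(tr$t_final, 120000)
})
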