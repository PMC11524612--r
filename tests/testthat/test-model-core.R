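# Unit tests for the model's pure evaluations: gating kinetics, closures,
# reversal potentials, pump and cotransporter fluxes, and the assembled
# right-hand side.

test_that("gating rates take their analytic limit values at the removable
          singularities and special points", {
  expect_equal(gating_rates(-52)$alpha_n, 0.032 * 5)
  expect_equal(gating_rates(-54)$alpha_m, 0.32 * 4)
  expect_equal(gating_rates(-27)$beta_m, 0.28 * 5)
  expect_equal(gating_rates(-57)$beta_n, 0.5)
  expect_equal(gating_rates(-50)$alpha_h, 0.128)
  expect_equal(gating_rates(-27)$beta_h, 2)
  expect_error(gating_rates(NaN), "finite")
})

test_that("gating rates are finite, non-negative and continuous across a
          dense voltage grid", {
  V <- seq(-120, 60, by = 1e-3)
  r <- gating_rates(V)
  for (nm in names(r)) {
    expect_true(all(is.finite(r[[nm]])), info = nm)
    expect_true(all(r[[nm]] >= 0), info = nm)
    # no singular spikes: successive values change smoothly
    expect_lt(max(abs(diff(r[[nm]]))), 0.01)
  }
})

test_that("electroneutrality closures reproduce the reference values and
          reject non-physical states", {
  p <- neuron_params()
  cl <- closures(20, 6, p)
  expect_equal(cl$Na_o, 135)
  expect_equal(cl$Cl_o, 145)
  expect_equal(cl$K_i, 86)
  expect_error(closures(-1, 6, p), "positive")
  # beta (Cl_i - 6) exceeding 145 empties the extracellular compartment
  expect_error(closures(20, 30, p), "domain violation")
})

test_that("reversal potentials follow the Nernst equation with closed
          outer concentrations", {
  p <- neuron_params()
  s <- neuron_state(V = -70, K_o = 2.99, Na_i = 20, Cl_i = 6)
  E <- reversal_potentials(s, p)
  # oracle: direct evaluation of the Nernst expression
  expect_equal(E$E_Cl, 26.64 * log(6 / 145), tolerance = 1e-12)
  expect_equal(E$E_K, 26.64 * log(2.99 / 86), tolerance = 1e-12)
  expect_equal(E$E_Na, 26.64 * log(135 / 20), tolerance = 1e-12)
  # E_Cl = 0 when the chloride ratio is one: Cl_i = 145 - 7 (Cl_i - 6)
  s0 <- neuron_state(V = -70, K_o = 3, Na_i = 20, Cl_i = 187 / 8)
  expect_equal(reversal_potentials(s0, p)$E_Cl, 0, tolerance = 1e-12)
})

test_that("E_Cl is strictly increasing in Cl_i and E_K in K_o", {
  p <- neuron_params()
  ecl <- vapply(seq(1, 25, by = 0.25), function(cl)
    reversal_potentials(neuron_state(V = -70, K_o = 3, Na_i = 20,
                                     Cl_i = cl), p)$E_Cl, numeric(1))
  expect_true(all(diff(ecl) > 0))
  ek <- vapply(seq(2, 12, by = 0.25), function(ko)
    reversal_potentials(neuron_state(V = -70, K_o = ko, Na_i = 20,
                                     Cl_i = 6), p)$E_K, numeric(1))
  expect_true(all(diff(ek) > 0))
})

test_that("the GABA reversal is the conductance-weighted average of E_Cl
          and E_HCO3 and lies between them", {
  p <- neuron_params()
  expect_equal(gaba_reversal(-13, p), -13)
  expect_equal(gaba_reversal(-84.85, p), (-84.85 + 0.2 * -13) / 1.2)
  expect_equal(gaba_reversal(-50, neuron_params(r_hco3 = 0)), -50)
  set.seed(7)
  for (ecl in runif(50, -120, 20)) {
    eg <- gaba_reversal(ecl, p)
    expect_gte(eg, min(ecl, p$E_hco3))
    expect_lte(eg, max(ecl, p$E_hco3))
    # affine in E_Cl with weight 1/(1 + r)
    expect_equal(eg, gaba_reversal(0, p) + ecl / 1.2, tolerance = 1e-12)
  }
})

test_that("the pump rate hits its half-saturation product exactly and
          saturates at rho", {
  p <- neuron_params()
  expect_equal(pump_rate(25, 3.5, p), 0.25 * p$rho)
  expect_equal(pump_rate(1e3, 1e3, p), p$rho)
  # oracle: direct evaluation of the two logistic factors
  expect_equal(pump_rate(20.06, 2.99, p),
               0.8 / (1 + exp((25 - 20.06) / 3)) / (1 + exp(3.5 - 2.99)),
               tolerance = 1e-12)
  # monotone in both arguments
  na <- seq(5, 40, by = 0.5)
  expect_true(all(diff(pump_rate(na, 3, p)) > 0))
  ko <- seq(1, 10, by = 0.25)
  expect_true(all(diff(pump_rate(20, ko, p)) > 0))
})

test_that("cotransporter fluxes follow their Nernst-like forms", {
  p <- neuron_params()
  s <- neuron_state(V = -70, K_o = 2.99, Na_i = 20, Cl_i = 6)
  co <- cotransporter_fluxes(s, p)
  expect_equal(co$f_Ko, 1 / (1 + exp(16 - 2.99)), tolerance = 1e-12)
  # oracle: independent evaluation with the closed concentrations
  expect_equal(co$rho_nkcc1,
               0.1 * (1 / (1 + exp(16 - 2.99))) *
                 (log((2.99 * 145) / (86 * 6)) +
                    log((135 * 145) / (20 * 6))),
               tolerance = 1e-12)
  expect_equal(co$rho_kcc2, 0.3 * log((86 * 6) / (2.99 * 145)),
               tolerance = 1e-12)
  # KCC2 flux vanishes when the K.Cl product gradient vanishes
  ko_star <- 86 * 6 / 145
  s0 <- neuron_state(V = -70, K_o = ko_star, Na_i = 20, Cl_i = 6)
  expect_equal(cotransporter_fluxes(s0, p)$rho_kcc2, 0, tolerance = 1e-12)
  expect_equal(cotransporter_fluxes(
    neuron_state(V = -70, K_o = 16, Na_i = 20, Cl_i = 6), p)$f_Ko, 0.5)
})

test_that("the null model (all conductances, pumps, transporters off) has
          zero derivative at gating steady state", {
  p <- neuron_params(gNa = 0, gK = 0, gNaL = 0, gKL = 0, gClL = 0,
                     rho = 0, U_kcc2 = 0, U_nkcc1 = 0, eps_k = 0)
  s <- neuron_state(V = -60, K_o = 3, Na_i = 20, Cl_i = 6)
  expect_equal(unname(neuron_rhs(s, p)), rep(0, 7), tolerance = 1e-14)
})

test_that("gating components of the rhs vanish at the voltage steady
          state", {
  p <- neuron_params()
  s <- neuron_state(V = -48.3, K_o = 4, Na_i = 18, Cl_i = 8)
  d <- neuron_rhs(s, p)
  expect_equal(unname(d[c("m", "n", "h")]), c(0, 0, 0), tolerance = 1e-14)
})

test_that("compiled and R right-hand sides agree at random states", {
  p <- neuron_params()
  for (s in random_states(20)) {
    d_r <- neuron_rhs(s, p, g_gaba = 0.3)
    d_c <- chlorodyn:::rhs_raw(s, p, g_gaba = 0.3)
    expect_equal(unname(d_r), d_c, tolerance = 1e-12)
  }
})

test_that("flux-charge consistency holds at random valid states", {
  p <- neuron_params(eps_k = 0)
  set.seed(42)
  for (s in random_states(100)) {
    g <- runif(1, 0, 0.5)
    expect_lt(abs(flux_charge_residual(s, p, g_gaba = g)), 1e-9)
  }
  # also with bath exchange on (the eps term is accounted for explicitly)
  pb <- neuron_params(eps_k = 0.25)
  for (s in random_states(20, seed = 7))
    expect_lt(abs(flux_charge_residual(s, pb)), 1e-9)
})

test_that("the literal-sign switch flips only the GABA contribution to
          dV/dt", {
  s <- neuron_state(V = -60, K_o = 3, Na_i = 20, Cl_i = 8)
  p_minus <- neuron_params(eps_k = 0)
  p_plus <- neuron_params(eps_k = 0, gaba_sign = 1)
  d0 <- neuron_rhs(s, p_minus, g_gaba = 0)
  dm <- neuron_rhs(s, p_minus, g_gaba = 0.4)
  dp <- neuron_rhs(s, p_plus, g_gaba = 0.4)
  expect_equal(unname(dp[["V"]] - d0[["V"]]),
               -unname(dm[["V"]] - d0[["V"]]), tolerance = 1e-12)
  # ion equations are unaffected by the switch
  expect_equal(dm[c("K_o", "Na_i", "Cl_i")], dp[c("K_o", "Na_i", "Cl_i")])
  expect_error(neuron_params(gaba_sign = 2), "gaba_sign")
})

test_that("parameter sets round-trip through YAML and the bundled table
          file reproduces the published constants", {
  p <- neuron_params(eps_k = 0.025, r_hco3 = 0)
  f <- tempfile(fileext = ".yaml")
  write_params(p, f)
  expect_identical(unclass(read_params(f)), unclass(p))
  tab <- read_params(system.file("extdata", "table1.yaml",
                                 package = "chlorodyn"))
  expect_identical(tab$gNa, 30)
  expect_identical(tab$gamma, 0.03)
  expect_identical(tab$U_kcc2, 0.3)
  expect_identical(tab$beta, 7)
  expect_identical(tab$K_bath, 3)
  expect_error(neuron_params(bogus = 1), "unknown parameter")
})
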