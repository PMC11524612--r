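# Fixed-point solves, Jacobian spectra, continuation, and saddle-node /
# Hopf location on the bath-decoupled chloride branch.

test_that("the damped Newton solver finds roots of a known nonlinear
          system", {
  # oracle: x^2 = 2, y^3 = x with analytic solution
  f <- function(z) c(z[1]^2 - 2, z[2]^3 - z[1])
  sol <- chlorodyn:::newton_solve(f, c(1, 1), tol = 1e-12)
  expect_true(sol$converged)
  expect_equal(sol$x, c(sqrt(2), 2^(1 / 6)), tolerance = 1e-10)
})

test_that("the finite-difference Jacobian matches an analytic Jacobian", {
  f <- function(x) c(sin(x[1]) * x[2], x[1]^2 + exp(x[2]))
  x0 <- c(0.7, -0.3)
  J <- chlorodyn:::fd_jacobian(f, x0)
  J_true <- rbind(c(cos(0.7) * -0.3, sin(0.7)),
                  c(2 * 0.7, exp(-0.3)))
  expect_equal(J, J_true, tolerance = 1e-8)
})

test_that("fixed points on the resting segment are stable with tiny
          residuals and the documented voltage", {
  p <- p_conservative()
  fp <- find_fixed_point(p, "Cl_i", 5)
  expect_identical(fp$stability, "stable")
  expect_lt(fp$residual_norm, 1e-8)
  expect_true(all(Re(fp$eigenvalues) < 0))
  expect_equal(fp$state[["V"]], -76.5, tolerance = 0.1)
  # chloride balance closed by the flux-charge redundancy
  expect_lt(abs(fp$residual[7] * p$tau_ion), 1e-6)
  # the full 7x7 spectrum carries the structural zero eigenvalue
  expect_lt(min(abs(fp$eigenvalues_full)), 1e-9)
})

test_that("clamped-chloride solves with bath exchange on raise the
          inconsistency error", {
  p <- neuron_params(eps_k = 0.25, K_bath = 3)
  expect_error(find_fixed_point(p, "Cl_i", 6), "inconsistency")
})

test_that("the chloride branch is S-shaped: stable rest below the fold,
          unstable middle, stable depolarized top", {
  br <- cl_branch()
  expect_identical(br$par_name, "Cl_i")
  expect_gte(max(br$par), 20)
  expect_true(is.null(br$truncated))
  expect_setequal(unique(br$stability),
                  c("stable", "saddle", "unstable_focus"))
  # resting end stable, middle segment saddle, top stable
  expect_identical(br$stability[1], "stable")
  expect_identical(br$stability[length(br$par)], "stable")
  # every branch point satisfies the full 7-d stationarity
  res <- vapply(seq_along(br$par), function(i)
    max(abs(chlorodyn:::rhs_raw(br$states[i, ], br$params))), numeric(1))
  expect_lt(max(res), 1e-8)
})

test_that("an unstable fixed point exists between the fold and the Hopf
          and a stable one above the Hopf", {
  p <- p_conservative()
  br <- cl_branch()
  mid <- which.min(abs(br$par - 12) +
                     ifelse(br$stability == "stable", 100, 0))
  fp12 <- find_fixed_point(p, "Cl_i", 12,
                           setNames(br$states[mid, ], state_names()))
  expect_gt(max(Re(fp12$eigenvalues)), 0)
  top <- which.max(br$par)
  fp20 <- find_fixed_point(p, "Cl_i", 20,
                           setNames(br$states[top, ], state_names()))
  expect_identical(fp20$stability, "stable")
})

test_that("eigenvalue stability agrees with simulated perturbations at
          branch points", {
  p <- p_conservative()
  br <- cl_branch()
  pick <- function(lab, near) {
    ok <- which(br$stability == lab)
    ok[which.min(abs(br$par[ok] - near))]
  }
  idx <- c(pick("stable", 6), pick("stable", 7.5), pick("saddle", 9),
           pick("saddle", 12), pick("stable", 19.5))
  for (i in idx) {
    st <- setNames(br$states[i, ], state_names())
    st[["V"]] <- st[["V"]] + 0.1
    tr <- integrate_neuron(st, p, t_end = 8000)
    dv_end <- abs(tr$final_state[["V"]] - br$states[i, "V"])
    if (br$stability[i] == "stable") {
      expect_lt(dv_end, 0.1)
    } else {
      expect_gt(max(abs(tr$state[, "V"] - br$states[i, "V"])), 1)
    }
  }
})

test_that("the saddle-node sits at the fold of the branch and survives
          step halving", {
  bif <- cl_bif()
  expect_gte(nrow(bif$sn), 1)
  expect_equal(nrow(bif$hb), 1)
  sn <- max(bif$sn$par)    # the fold bounding the resting branch
  hb <- bif$hb$par
  # fold location from the branch geometry: the conserved charge is
  # extremal along arclength exactly where a level set is tangent to the
  # branch, i.e. at the saddle-node; its first local maximum must
  # coincide with the detected fold
  br <- cl_branch()
  q <- br$states[, "K_o"] - br$states[, "Na_i"] + br$states[, "Cl_i"]
  fold_idx <- which(diff(sign(diff(q))) == -2)[1] + 1
  expect_equal(br$par[fold_idx], sn, tolerance = 0.05)
  # halving the continuation step does not move SN or HB
  br2 <- continue_branch(p_conservative(), "Cl_i", c(5, 20),
                         step0 = 0.025)
  bif2 <- detect_bifurcations(br2)
  expect_equal(max(bif2$sn$par), sn, tolerance = 0.02)
  expect_equal(bif2$hb$par, hb, tolerance = 0.02)
})

test_that("the branch voltage / E_Cl crossover is bracketed by branch
          points and a crossing-free branch yields NULL", {
  br <- cl_branch()
  cx <- gaba_crossover(br)
  expect_false(is.null(cx))
  p <- br$params
  ecl <- vapply(seq_along(br$par), function(i) {
    st <- br$states[i, ]
    p$nernst_coef * log(st[["Cl_i"]] /
                          (p$cl_o_base - p$beta * (st[["Cl_i"]] -
                                                     p$cl_i_ref)))
  }, numeric(1))
  gap <- br$states[, "V"] - ecl
  i <- max(which(gap[-length(gap)] * gap[-1] < 0))
  lo <- min(br$states[i:(i + 1), "V"]); hi <- max(br$states[i:(i + 1), "V"])
  expect_gte(cx$V, lo - 0.5)
  expect_lte(cx$V, hi + 0.5)
  # the resting segment alone never crosses E_Cl
  br_low <- continue_branch(p_conservative(), "Cl_i", c(5, 6.5))
  expect_null(gaba_crossover(br_low))
})

test_that("branch CSV and bifurcation JSON exports are well formed", {
  br <- cl_branch()
  f <- tempfile(fileext = ".csv")
  write_branch_csv(br, f)
  back <- read.csv(f)
  expect_identical(names(back)[1], "Cl_i")
  expect_equal(nrow(back), length(br$par))
  js <- jsonlite::fromJSON(
    bifurcation_summary_json(cl_bif(), gaba_crossover(br)))
  expect_true(all(c("sn", "hb", "crossover_V") %in% names(js)))
  expect_equal(length(js$hb), 1)
})
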