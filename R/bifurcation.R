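# Stationary solutions of the full system, Jacobian eigenvalue stability,
# branch continuation in [Cl-]i or G_GABA, and saddle-node / Hopf location.
#
# In the bath-decoupled case (eps_k = 0, no GABA) the flux-charge redundancy
# makes the fixed points a one-parameter family: we clamp [Cl-]i, solve the
# 6-dimensional subsystem (dV = dm = dn = dh = dK_o = dNa_i = 0) by Newton
# iteration, and verify that the omitted chloride balance is satisfied by
# the redundancy rather than assuming it. The same redundancy gives the full
# 7x7 Jacobian a structural zero eigenvalue (left eigenvector = gradient of
# the conserved charge), so stability along that branch is classified from
# the Jacobian of the system reduced to a level set of the conserved charge,
# which removes the structural zero exactly. With bath coupling on
# (eps_k > 0) the redundancy is broken, fixed points are isolated, and the
# full 7-dimensional system is solved with G_GABA as the free parameter.

# constant-conductance stimulus encoding for the compiled right-hand side
const_gaba_stim <- function(g_gaba) {
  c(type = 1, g = g_gaba, t0 = -1e300, t1 = 1e300, a0 = 0, tau1 = 1,
    tau2 = 1, period = 0, form = 0)
}

rhs_raw <- function(state, params, g_gaba = 0) {
  rhs_cpp(0, unname(state), params_to_c(params), const_gaba_stim(g_gaba))
}

# central finite-difference Jacobian, step scaled per variable
fd_jacobian <- function(f, x, h_base = 1e-6) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(NA_real_, length(f0), n)
  for (i in seq_len(n)) {
    h <- h_base * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    J[, i] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

# damped Newton iteration; f must return a residual vector of length(x)
newton_solve <- function(f, x0, tol = 1e-10, maxit = 60) {
  x <- x0
  fx <- tryCatch(f(x), error = function(e) NULL)
  if (is.null(fx)) stop("no-solution: residual undefined at initial guess")
  for (it in seq_len(maxit)) {
    if (max(abs(fx)) < tol)
      return(list(x = x, residual = fx, iterations = it - 1,
                  converged = TRUE))
    J <- fd_jacobian(f, x)
    step <- tryCatch(solve(J, fx), error = function(e)
      tryCatch(qr.solve(J, fx), error = function(e2) NULL))
    if (is.null(step) || any(!is.finite(step))) break
    lambda <- 1
    repeat {
      xn <- x - lambda * step
      fn <- tryCatch(f(xn), error = function(e) NULL)
      if (!is.null(fn) && all(is.finite(fn)) &&
          (max(abs(fn)) < max(abs(fx)) || lambda <= 1 / 64)) break
      lambda <- lambda / 2
      if (lambda < 1 / 1024) { fn <- NULL; break }
    }
    if (is.null(fn)) break
    x <- xn; fx <- fn
  }
  list(x = x, residual = fx, iterations = maxit,
       converged = max(abs(fx)) < tol)
}

# residual scale: voltage/gating equations are O(1) per ms while the ion
# equations carry the 1/tau_ion factor; rescale so Newton tolerances bite
residual_scale <- function(params) c(1, 1, 1, 1, rep(params$tau_ion, 3))

#' Find a stationary solution of the neuron model
#'
#' Solves for a fixed point with one quantity clamped. `clamp = "Cl_i"`
#' holds intracellular chloride fixed and solves the 6-dimensional
#' subsystem by Newton iteration (the bath-decoupled branch, where fixed
#' points form a one-parameter family); the omitted chloride balance is
#' then verified to vanish by the flux-charge redundancy, and an
#' `inconsistency` error is raised if it does not. `clamp = "g_gaba"`
#' treats the (step) GABA conductance as the clamped parameter and solves
#' all 7 equations.
#'
#' @param params A [neuron_params()] object.
#' @param clamp `"Cl_i"` or `"g_gaba"`.
#' @param value The clamped value (mM or mS/cm^2).
#' @param guess Initial state guess (see [neuron_state()]); gating defaults
#'   to its voltage steady state.
#' @param g_gaba Constant GABA conductance when `clamp = "Cl_i"`.
#' @param tol Newton tolerance on the scaled residual.
#' @param eig_tol Stability-classification tolerance on eigenvalue real
#'   parts.
#' @return A `fixed_point`: list with `state` (full 7-vector), `clamp`,
#'   `value`, `g_gaba`, `residual_norm` (max absolute raw right-hand side),
#'   `eigenvalues` (stability-relevant spectrum: reduced 6x6 on the
#'   conservative branch, full 7x7 otherwise), `eigenvalues_full`,
#'   `stability` (`stable`, `saddle`, `unstable_focus`, `marginal`), and
#'   `conserved` (whether the reduced spectrum was used).
#' @export
#' @examples
#' \donttest{
#' p <- neuron_params(eps_k = 0)
#' fp <- find_fixed_point(p, "Cl_i", 5,
#'   guess = neuron_state(V = -70, K_o = 3, Na_i = 20, Cl_i = 5))
#' fp$state[["V"]] # about -70.7 mV
#' }
find_fixed_point <- function(params, clamp = c("Cl_i", "g_gaba"), value,
                             guess = NULL, g_gaba = 0, tol = 1e-10,
                             eig_tol = 1e-6) {
  clamp <- match.arg(clamp)
  if (is.null(guess))
    guess <- neuron_state(V = -70, K_o = 3, Na_i = 20,
                          Cl_i = if (clamp == "Cl_i") value else 6)
  guess <- validate_state(guess)
  sc <- residual_scale(params)

  if (clamp == "Cl_i") {
    free <- 1:6
    make_state <- function(x) c(x, value)
    gg <- g_gaba
  } else {
    free <- 1:7
    make_state <- function(x) x
    gg <- value
  }
  f <- function(x) (rhs_raw(make_state(x), params, gg) * sc)[free]
  sol <- newton_solve(f, unname(guess)[free], tol = tol)
  if (!sol$converged)
    stop("no-solution: Newton failed to converge (clamp ", clamp, " = ",
         value, ")")
  state <- setNames(make_state(sol$x), state_names())
  raw <- rhs_raw(state, params, gg)
  if (clamp == "Cl_i" && abs(raw[7] * params$tau_ion) > 1e-6)
    stop("inconsistency: clamped-chloride residual ",
         signif(raw[7] * params$tau_ion, 3), " mM/s; the flux-charge ",
         "redundancy does not hold here (is eps_k nonzero, or does the ",
         "GABA input carry bicarbonate?)")
  conserved <- clamp == "Cl_i" && params$eps_k == 0 &&
    (gg == 0 || params$r_hco3 == 0)
  ev_full <- jacobian_eigenvalues(state, params, g_gaba = gg,
                                  reduced = FALSE)
  ev <- if (conserved)
    jacobian_eigenvalues(state, params, g_gaba = gg, reduced = TRUE)
  else ev_full
  structure(list(state = state, clamp = clamp, value = value, g_gaba = gg,
                 residual = raw, residual_norm = max(abs(raw)),
                 eigenvalues = ev, eigenvalues_full = ev_full,
                 stability = classify_stability(ev, eig_tol),
                 conserved = conserved),
            class = "fixed_point")
}

#' @export
print.fixed_point <- function(x, ...) {
  cat("<fixed_point> ", x$clamp, " = ", signif(x$value, 6), ": V = ",
      signif(x$state[["V"]], 6), " mV, Cl_i = ",
      signif(x$state[["Cl_i"]], 6), " mM [", x$stability,
      "], residual ", signif(x$residual_norm, 3), "\n", sep = "")
  invisible(x)
}

#' Jacobian eigenvalues at a state
#'
#' Eigenvalues (1/ms) of the Jacobian of the right-hand side, computed by
#' central finite differences with per-variable scaled steps. With
#' `reduced = TRUE` the system is first restricted to a level set of the
#' conserved charge of the bath-decoupled model (chloride eliminated),
#' giving the 6 stability-relevant eigenvalues without the structural zero.
#'
#' @param state A 7-component state vector (or a `fixed_point`).
#' @param params A [neuron_params()] object.
#' @param g_gaba Constant GABA conductance.
#' @param reduced Use the level-set-reduced 6x6 Jacobian.
#' @return Complex eigenvalues sorted by decreasing real part.
#' @export
jacobian_eigenvalues <- function(state, params, g_gaba = 0,
                                 reduced = FALSE) {
  if (inherits(state, "fixed_point")) {
    g_gaba <- state$g_gaba
    state <- state$state
  }
  f <- function(x) rhs_raw(x, params, g_gaba)
  J <- fd_jacobian(f, unname(state))
  if (reduced) {
    # d Cl_i / d(other vars) along a level set of the conserved charge
    a <- params$gamma * params$C / params$tau_ion
    d <- c(-a, 0, 0, 0, -1, 1)
    J <- J[1:6, 1:6] + outer(J[1:6, 7], d)
  }
  ev <- eigen(J, only.values = TRUE)$values
  ev[order(-Re(ev))]
}

#' Classify stability from a spectrum
#'
#' `stable` if every real part is below `-tol`; `marginal` if the leading
#' real part lies within `tol` of zero; otherwise `saddle` when the leading
#' unstable eigenvalue is real and `unstable_focus` when it is a complex
#' pair.
#'
#' @param eigenvalues Complex eigenvalues.
#' @param tol Real-part tolerance (1/ms).
#' @return A character label.
#' @export
classify_stability <- function(eigenvalues, tol = 1e-6) {
  re <- Re(eigenvalues)
  lead <- max(re)
  if (lead < -tol) return("stable")
  if (abs(lead) <= tol) return("marginal")
  im <- Im(eigenvalues)[which.max(re)]
  if (abs(im) > tol) "unstable_focus" else "saddle"
}

lead_real_part <- function(ev, imag_tol = 1e-9) {
  # leading real part among (numerically) real eigenvalues / complex pairs
  re <- Re(ev); im <- abs(Im(ev))
  real_ev <- re[im <= imag_tol]
  cplx_ev <- re[im > imag_tol]
  c(real = if (length(real_ev)) max(real_ev) else -Inf,
    cplx = if (length(cplx_ev)) max(cplx_ev) else -Inf)
}

#' Continue a fixed-point branch
#'
#' Traces the branch of stationary solutions as one parameter varies, by
#' pseudo-arclength continuation in the scaled (state, parameter) space:
#' a secant tangent predictor, a Newton corrector orthogonal to the
#' tangent, and adaptive step control. Folds (saddle-nodes) are traversed
#' rather than stopped at, so the S-shaped branches in both `Cl_i` (the
#' bath-decoupled chloride branch) and `g_gaba` (step-GABA input under
#' bath coupling) are covered end to end.
#'
#' @param params A [neuron_params()] object.
#' @param par_name `"Cl_i"` or `"g_gaba"`.
#' @param range Length-2 parameter interval to cover.
#' @param guess Starting state guess at `range[1]`.
#' @param step0 Initial parameter step.
#' @param max_step Largest accepted parameter step.
#' @param max_points Safety cap on branch length.
#' @param g_gaba Constant GABA conductance (only for the `Cl_i` branch).
#' @return A `neuron_branch`: list with `par_name`, `par` (values along the
#'   branch), `states` (matrix), `eigenvalues` (list, stability-relevant
#'   spectrum per point), `stability`, `lead_re`/`lead_im`, `params`,
#'   `conserved`, and `truncated` (reason, if the branch left the model's
#'   validity region before covering `range`).
#' @export
continue_branch <- function(params, par_name = c("Cl_i", "g_gaba"),
                            range, guess = NULL, step0 = 0.05,
                            max_step = 4 * step0, max_points = 2000,
                            g_gaba = 0) {
  par_name <- match.arg(par_name)
  stopifnot(length(range) == 2, range[2] >= range[1])
  if (is.null(guess))
    guess <- neuron_state(V = -70, K_o = 3, Na_i = 20,
                          Cl_i = if (par_name == "Cl_i") range[1] else 6)
  continue_engine(params, par_name, range, guess, step0, max_step,
                  max_points, g_gaba)
}

branch_point <- function(fp) {
  list(par = fp$value, state = fp$state, ev = fp$eigenvalues,
       ev_full = fp$eigenvalues_full, stability = fp$stability)
}

assemble_branch <- function(pts, par_name, params, conserved, g_gaba = 0,
                            truncated = NULL) {
  lead <- vapply(pts, function(p) {
    i <- which.max(Re(p$ev))
    c(Re(p$ev[i]), Im(p$ev[i]))
  }, numeric(2))
  structure(list(
    par_name = par_name,
    par = vapply(pts, function(p) p$par, numeric(1)),
    states = do.call(rbind, lapply(pts, function(p) p$state)),
    eigenvalues = lapply(pts, function(p) p$ev),
    eigenvalues_full = lapply(pts, function(p) p$ev_full),
    stability = vapply(pts, function(p) p$stability, character(1)),
    lead_re = lead[1, ], lead_im = lead[2, ],
    params = params, conserved = conserved, g_gaba = g_gaba,
    truncated = truncated),
    class = "neuron_branch")
}

continue_engine <- function(params, par_name, range, guess, step0,
                            max_step, max_points, g_gaba) {
  conservative <- par_name == "Cl_i"
  sc <- residual_scale(params)
  # arclength metric weights: voltage in ~50 mV units, concentrations in
  # ~5 mM units, gating fractions and conductance order one
  if (conservative) {
    w <- c(1 / 50, 1, 1, 1, 1 / 5, 1 / 5, 1 / 5)
    par_idx <- 7
    nfree <- 7
    resid <- function(z) (rhs_raw(z[1:7], params, g_gaba) * sc)[1:6]
    par_floor <- 0.5       # branch may fold back toward lower chloride
  } else {
    w <- c(1 / 50, 1, 1, 1, 1 / 5, 1 / 5, 1 / 5, 1)
    par_idx <- 8
    nfree <- 8
    resid <- function(z) rhs_raw(z[1:7], params, z[8]) * sc
    par_floor <- range[1] - 0.25
  }
  reduced <- conservative && params$eps_k == 0 &&
    (g_gaba == 0 || params$r_hco3 == 0)
  eig <- function(z) {
    st <- setNames(z[1:7], state_names())
    gg <- if (conservative) g_gaba else z[8]
    jacobian_eigenvalues(st, params, g_gaba = gg, reduced = reduced)
  }
  solve_nat <- function(v, st_guess) {
    if (conservative)
      find_fixed_point(params, "Cl_i", v, st_guess, g_gaba = g_gaba)
    else
      find_fixed_point(params, "g_gaba", v, st_guess)
  }

  fp0 <- solve_nat(range[1], guess)
  h_nat <- max(step0 / 5, 1e-3)
  fp1 <- solve_nat(range[1] + h_nat, fp0$state)
  z0 <- c(unname(fp0$state), if (!conservative) range[1])
  z1 <- c(unname(fp1$state), if (!conservative) range[1] + h_nat)
  tz <- (z1 - z0) * w
  tz <- tz / sqrt(sum(tz^2))
  pts <- list(branch_point(fp0), branch_point(fp1))
  z <- z1
  h <- step0
  truncated <- NULL
  while (length(pts) < max_points) {
    zp <- z + h * tz / w
    f <- function(zz) c(resid(zz), sum(tz * (zz - zp) * w))
    sol <- tryCatch(newton_solve(f, zp, tol = 1e-10),
                    error = function(e) list(converged = FALSE))
    ok <- isTRUE(sol$converged) && sol$x[par_idx] > par_floor &&
      all(sol$x[5:7] > 0) && all(is.finite(sol$x))
    if (ok) {
      # corrector must stay local and keep moving forward along the
      # branch, otherwise it has jumped sheets or reversed at a fold
      dz <- (sol$x - z) * w
      ndz <- sqrt(sum(dz^2))
      ok <- ndz <= 4 * h && ndz > 0 && sum(dz * tz) / ndz > 0.1
    }
    if (!ok) {
      h <- h / 2
      if (h < step0 / 256) {
        truncated <- "continuation stalled (left the validity region?)"
        break
      }
      next
    }
    znew <- sol$x
    state <- setNames(znew[1:7], state_names())
    ev <- eig(znew)
    pts[[length(pts) + 1]] <- list(par = znew[par_idx], state = state,
                                   ev = ev, ev_full = ev,
                                   stability = classify_stability(ev))
    tz_new <- (znew - z) * w
    tz <- tz_new / sqrt(sum(tz_new^2))
    z <- znew
    h <- min(h * 1.2, max_step)
    # done once we are past the requested range (moving forward again
    # after any folds)
    if (znew[par_idx] > range[2]) break
    # a hysteresis loop that returns to the starting point is complete
    if (length(pts) > 10 &&
        sqrt(sum(((znew - z0) * w)^2)) < max(h, step0)) {
      truncated <- "closed loop"
      break
    }
  }
  assemble_branch(pts, par_name, params, conserved = reduced,
                  g_gaba = g_gaba, truncated = truncated)
}

#' @export
print.neuron_branch <- function(x, ...) {
  cat("<neuron_branch> ", length(x$par), " points, ", x$par_name,
      " in [", signif(min(x$par), 6), ", ", signif(max(x$par), 6), "]",
      if (!is.null(x$truncated)) paste0(" (truncated: ", x$truncated, ")"),
      "\n", sep = "")
  tb <- table(x$stability)
  cat("  stability:", paste(names(tb), tb, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Export a branch as CSV
#'
#' One row per branch point: parameter, state, leading eigenvalue real and
#' imaginary part, stability label.
#'
#' @param branch A `neuron_branch`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_branch_csv <- function(branch, path) {
  df <- data.frame(par = branch$par, branch$states,
                   lead_re = branch$lead_re, lead_im = branch$lead_im,
                   stability = branch$stability)
  names(df)[1] <- branch$par_name
  write.csv(format(df, digits = 17, trim = TRUE), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Locate and refine saddle-node and Hopf points on a branch
#'
#' Scans the branch for zero crossings of the leading real eigenvalue
#' (saddle-node) and of the leading complex-pair real part (Hopf), then
#' refines each by bisection in the parameter with fresh Newton solves.
#' On the pseudo-arclength `g_gaba` branch, saddle-nodes are the folds
#' (extrema of the parameter along the branch) and are refined by
#' bisection on solution existence from the pre-fold side.
#'
#' @param branch A `neuron_branch`.
#' @param tol Bisection tolerance in the parameter.
#' @return List with data.frames `sn` and `hb` (columns `par`, `V`,
#'   `Cl_i`, `K_o`, `Na_i`), either possibly empty.
#' @export
detect_bifurcations <- function(branch, tol = 5e-3) {
  n <- length(branch$par)
  if (n < 3) return(list(sn = empty_bif(), hb = empty_bif()))
  params <- branch$params
  clamp <- branch$par_name
  solve_at <- function(v, st) {
    if (clamp == "Cl_i") {
      g <- st; g[7] <- v
      find_fixed_point(params, "Cl_i", v, setNames(g, state_names()),
                       g_gaba = branch$g_gaba)
    } else {
      find_fixed_point(params, "g_gaba", v, setNames(st, state_names()))
    }
  }
  sn <- empty_bif(); hb <- empty_bif()
  dp <- diff(branch$par)

  # saddle-nodes: folds of the branch (extrema of the parameter along
  # arclength, where the leading real eigenvalue crosses zero), refined by
  # bisection on solution existence from the pre-fold side
  for (i in seq_len(n - 2)) {
    if (dp[i] == 0 || dp[i + 1] == 0) next
    if (sign(dp[i]) * sign(dp[i + 1]) < 0) {
      st <- branch$states[i, ]
      lo <- branch$par[i]                     # solution exists here
      hi <- branch$par[i + 1] + sign(dp[i]) * 4 * tol # beyond the fold
      while (abs(hi - lo) > tol) {
        mid <- (lo + hi) / 2
        fp <- tryCatch(solve_at(mid, st), error = function(e) NULL)
        same_sheet <- !is.null(fp) &&
          abs(fp$state[["V"]] - st[["V"]]) < 10
        if (same_sheet) { lo <- mid; st <- fp$state } else hi <- mid
      }
      sn <- rbind(sn, bif_row((lo + hi) / 2,
                              setNames(st, state_names())))
    }
  }

  # Hopf: real part of the leading complex pair crossing zero, refined by
  # bisection in the parameter along a locally monotone segment
  leads <- vapply(branch$eigenvalues, lead_real_part, numeric(2))
  for (i in seq_len(n - 1)) {
    if (!is.finite(leads["cplx", i]) || !is.finite(leads["cplx", i + 1]))
      next
    if (sign(leads["cplx", i]) * sign(leads["cplx", i + 1]) < 0 &&
        dp[i] != 0) {
      lo <- branch$par[i]; hi <- branch$par[i + 1]
      st <- branch$states[i, ]
      s_lo <- sign(leads["cplx", i])
      ok <- TRUE
      while (abs(hi - lo) > tol) {
        mid <- (lo + hi) / 2
        fp <- tryCatch(solve_at(mid, st), error = function(e) NULL)
        if (is.null(fp)) { ok <- FALSE; break }
        s_mid <- sign(lead_real_part(fp$eigenvalues)["cplx"])
        if (s_mid == s_lo) { lo <- mid; st <- fp$state } else hi <- mid
      }
      if (ok) {
        fp <- solve_at((lo + hi) / 2, st)
        hb <- rbind(hb, bif_row((lo + hi) / 2, fp$state))
      }
    }
  }
  list(sn = dedupe_bif(sn, 2 * tol), hb = dedupe_bif(hb, 2 * tol))
}

# merge detections that refined to (numerically) the same point
dedupe_bif <- function(df, eps) {
  if (nrow(df) < 2) return(df)
  df <- df[order(df$par), ]
  keep <- c(TRUE, diff(df$par) > eps)
  df[keep, , drop = FALSE]
}

bif_row <- function(par, state) {
  data.frame(par = par, V = state[["V"]], Cl_i = state[["Cl_i"]],
             K_o = state[["K_o"]], Na_i = state[["Na_i"]])
}

empty_bif <- function() data.frame(par = numeric(0), V = numeric(0),
                                   Cl_i = numeric(0), K_o = numeric(0),
                                   Na_i = numeric(0))

#' Voltage at which the fixed-point branch crosses the chloride reversal
#'
#' Along a `Cl_i` branch, finds where the fixed-point voltage equals
#' `E_Cl([Cl-]i)`. Below this voltage a pure chloride conductance is
#' hyperpolarizing (GABA inhibitory); above it, depolarizing. The crossing
#' is bracketed on the branch and refined by bisection with fresh
#' fixed-point solves.
#'
#' @param branch A `neuron_branch` continued in `Cl_i`.
#' @param tol Bisection tolerance in the parameter (mM).
#' @return List with `V` (crossing voltage, mV), `par` (the `Cl_i` at the
#'   crossing), or `NULL` if the branch has no crossing.
#' @export
gaba_crossover <- function(branch, tol = 1e-3) {
  stopifnot(branch$par_name == "Cl_i")
  params <- branch$params
  ecl <- function(state) {
    cl <- closures(state[["Na_i"]], state[["Cl_i"]], params)
    params$nernst_coef * log(state[["Cl_i"]] / cl$Cl_o)
  }
  gap <- vapply(seq_along(branch$par), function(i) {
    branch$states[i, "V"] - ecl(setNames(branch$states[i, ],
                                         state_names()))
  }, numeric(1))
  idx <- which(gap[-1] * gap[-length(gap)] < 0)
  if (!length(idx)) return(NULL)
  i <- idx[1]
  lo <- branch$par[i]; hi <- branch$par[i + 1]
  st <- branch$states[i, ]
  s_lo <- sign(gap[i])
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    g <- st; g[7] <- mid
    fp <- find_fixed_point(params, "Cl_i", mid, setNames(g, state_names()))
    s_mid <- sign(fp$state[["V"]] - ecl(fp$state))
    if (s_mid == s_lo) { lo <- mid; st <- fp$state } else hi <- mid
  }
  g <- st; g[7] <- (lo + hi) / 2
  fp <- find_fixed_point(params, "Cl_i", (lo + hi) / 2,
                         setNames(g, state_names()))
  list(V = fp$state[["V"]], par = (lo + hi) / 2)
}

#' Bifurcation summary as JSON
#'
#' @param bif Output of [detect_bifurcations()].
#' @param crossover Optional output of [gaba_crossover()].
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The path (invisibly) or a JSON string.
#' @export
bifurcation_summary_json <- function(bif, crossover = NULL, path = NULL) {
  out <- list(sn = bif$sn$par, hb = bif$hb$par,
              crossover_V = if (is.null(crossover)) NULL else crossover$V)
  if (is.null(path))
    return(as.character(jsonlite::toJSON(out, digits = NA,
                                         null = "null")))
  jsonlite::write_json(out, path, digits = NA, null = "null")
  invisible(path)
}
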