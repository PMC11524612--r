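#' Model parameters for the single-compartment neuron
#'
#' Builds the full parameter set of the coupled voltage/ion model. Defaults
#' are the published constants of the model's parameter table: membrane
#' capacitance and conductances, the current-to-flux conversion factor
#' `gamma` (which encodes surface area, intracellular volume and the Faraday
#' constant, so those have no separate fields), pump and cotransporter
#' strengths, bath coupling, the fixed bicarbonate reversal potential and the
#' HCO3-/Cl- conductance ratio of the GABA-A receptor, the Nernst prefactor
#' at 310 K, the electroneutrality-closure constants, and the slow-timescale
#' factor `tau_ion` that converts the per-second ion fluxes to the
#' millisecond time base of the voltage equations.
#'
#' @param ... Named overrides of any default, e.g. `eps_k = 0`, `r_hco3 = 0`.
#'
#' @details Units contract: voltage mV, time ms, concentrations mM,
#'   conductances mS/cm^2, currents uA/cm^2, fluxes mM/s. `gaba_sign = -1`
#'   gives every membrane current the conventional `-g (V - E)` contribution
#'   to `dV/dt`; setting `gaba_sign = +1` flips only the two GABA terms to a
#'   `+g (V - E)` form (a literal-transcription variant retained for
#'   comparison, under which GABA input would inject outward current).
#'
#' @return A named list of class `neuron_params`.
#' @export
#' @examples
#' p <- neuron_params(eps_k = 0)
#' p$gNa
neuron_params <- function(...) {
  p <- list(
    C       = 1,     # membrane capacitance, uF/cm^2
    gNa     = 30,    # maximal voltage-gated Na+ conductance, mS/cm^2
    gK      = 20,    # maximal delayed-rectifier K+ conductance, mS/cm^2
    gNaL    = 0.04,  # Na+ leak, mS/cm^2
    gKL     = 0.1,   # K+ leak, mS/cm^2
    gClL    = 0.1,   # Cl- leak, mS/cm^2
    gamma   = 0.03,  # current -> flux conversion, mM cm^2 / (s uA)
    rho     = 0.8,   # maximal Na/K pump rate, mM/s
    U_kcc2  = 0.3,   # KCC2 cotransporter strength, mM/s
    U_nkcc1 = 0.1,   # NKCC1 cotransporter strength, mM/s
    eps_k   = 0.25,  # K+ diffusion rate to bath, 1/s
    K_bath  = 3,     # bath potassium, mM
    beta    = 7,     # intra/extracellular volume ratio
    E_hco3  = -13,   # bicarbonate reversal potential, mV (held fixed)
    r_hco3  = 0.2,   # HCO3-/Cl- conductance ratio of the GABA-A receptor
    nernst_coef = 26.64, # RT/F at 310 K, mV
    tau_ion = 1000,  # ms per unit of the (per-second) ion-flux equations
    gaba_sign = -1,  # -1: conventional -g(V-E) GABA terms; +1: literal form
    # electroneutrality closure constants (mM)
    k_total   = 100, # [K+]i + [Na+]i - [Cl-]i
    na_o_base = 135, # [Na+]o at the [Na+]i reference
    cl_o_base = 145, # [Cl-]o at the [Cl-]i reference
    na_i_ref  = 20,
    cl_i_ref  = 6
  )
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over))))
      stop("all parameter overrides must be named")
    unknown <- setdiff(names(over), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(over)] <- over
  }
  validate_params(structure(p, class = "neuron_params"))
}

validate_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  for (nm in names(p)) {
    if (!num1(p[[nm]])) stop("parameter '", nm, "' must be a finite scalar")
    p[[nm]] <- as.numeric(p[[nm]])
  }
  nonneg <- c("gNa", "gK", "gNaL", "gKL", "gClL", "gamma", "rho",
              "U_kcc2", "U_nkcc1", "eps_k", "K_bath", "tau_ion")
  for (nm in nonneg)
    if (p[[nm]] < 0) stop("parameter '", nm, "' must be >= 0")
  if (p$C <= 0) stop("C must be > 0")
  if (p$beta <= 0) stop("beta must be > 0")
  if (p$r_hco3 < 0 || p$r_hco3 > 1) stop("r_hco3 must lie in [0, 1]")
  if (!p$gaba_sign %in% c(-1, 1)) stop("gaba_sign must be -1 or +1")
  p
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("<neuron_params>\n")
  v <- unlist(x)
  cat(paste0("  ", format(names(v), width = 12), " = ", format(v)),
      sep = "\n")
  invisible(x)
}

#' Read or write a parameter set as a flat YAML mapping
#'
#' Parameter files are flat `name: value` mappings using the same names as
#' [neuron_params()]. Missing entries take their defaults, so a file holding
#' only the published parameter-table constants round-trips exactly. The
#' bundled file `system.file("extdata", "table1.yaml", package = "chlorodyn")`
#' reproduces that table.
#'
#' @param path File path.
#' @param params A `neuron_params` object.
#' @return `read_params()` returns a `neuron_params`; `write_params()` the
#'   path, invisibly.
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("parameter file must be a mapping")
  do.call(neuron_params, raw)
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "neuron_params"))
  yaml::write_yaml(lapply(unclass(params), as.numeric), path,
                   precision = 15)
  invisible(path)
}

#' Construct a model state vector
#'
#' The dynamical state is the 7-vector `(V, m, n, h, K_o, Na_i, Cl_i)`:
#' membrane potential (mV), the three Hodgkin-Huxley gating fractions, and
#' extracellular potassium, intracellular sodium and intracellular chloride
#' (mM). Gating variables omitted (`NA`) are completed to their voltage
#' steady state `alpha/(alpha + beta)` at `V`.
#'
#' @param V Membrane potential, mV.
#' @param m,n,h Gating fractions in `[0, 1]`, or `NA` to use the steady state
#'   at `V`.
#' @param K_o,Na_i,Cl_i Concentrations, mM (must be positive).
#' @return Named numeric vector of length 7.
#' @export
#' @examples
#' neuron_state(V = -70.74, K_o = 2.99, Na_i = 20.06, Cl_i = 5.97)
neuron_state <- function(V, m = NA, n = NA, h = NA, K_o, Na_i, Cl_i) {
  if (!is.finite(V)) stop("V must be finite")
  g <- steady_gating(V)
  if (is.na(m)) m <- g[["m"]]
  if (is.na(n)) n <- g[["n"]]
  if (is.na(h)) h <- g[["h"]]
  s <- c(V = V, m = m, n = n, h = h, K_o = K_o, Na_i = Na_i, Cl_i = Cl_i)
  validate_state(s)
}

validate_state <- function(s) {
  if (length(s) != 7) stop("state must have 7 components")
  names(s) <- state_names()
  if (any(!is.finite(s))) stop("state must be finite")
  if (any(s[c("m", "n", "h")] < 0 | s[c("m", "n", "h")] > 1))
    stop("gating variables must lie in [0, 1]")
  if (any(s[c("K_o", "Na_i", "Cl_i")] <= 0))
    stop("concentrations must be positive")
  s
}

state_names <- function() c("V", "m", "n", "h", "K_o", "Na_i", "Cl_i")
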