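#' Kinetic parameters for the Bak pore-formation network
#'
#' Bundles the rate constants and pore size of the simplified Bcl-2 network:
#' Mcl-1 synthesis and first-order degradation, reversible sequestration of
#' Bak monomer by Mcl-1, a ladder of successive dimerizations
#' (B_n + B_n <-> B_2n) up to the active pore size `A`, and reversible
#' cytochrome-c translocation driven by the size-A species. Units are nM and
#' seconds throughout.
#'
#' Degradation acts on free Mcl-1 only; Mcl-1 held in the Mcl-1:Bak complex
#' is protected, so the free pool relaxes as a single exponential whenever
#' binding and oligomerization are fast relative to `delta_M` (see the
#' quasi-static reduction in [quasi_static()]).
#'
#' @param pore_size Number of Bak subunits in the active pore. Must be a
#'   power of two (reachable by successive dimerizations) and >= 2; 4 for
#'   the tetramer model, 256 for the massively oligomeric model.
#' @param sigma_M Basal Mcl-1 synthesis rate during mitosis (nM/s).
#' @param delta_M First-order Mcl-1 degradation rate (1/s).
#' @param alpha_M,beta_M Bak/Mcl-1 association (1/nM/s) and dissociation
#'   (1/s) rates; their ratio `beta_M/alpha_M` is the dissociation constant
#'   K_M.
#' @param alpha_12,beta_12 Monomer -> dimer association/dissociation rates.
#' @param alpha_24,beta_24 Dimer -> tetramer association/dissociation rates.
#' @param alpha_other,beta_other Rates for all higher dimerization steps.
#' @param gamma_m CytC mitochondria -> cytoplasm translocation rate per unit
#'   active-pore concentration (1/nM/s). Defaults to the bundled reference
#'   value for the chosen pore size (5000 for A = 4, 0.5 otherwise).
#' @param gamma_c CytC cytoplasm -> mitochondria return rate (1/s).
#' @return A `kinetic_params` object (a validated list).
#' @seealso [reference_params()], [build_model()], [simulate_network()]
#' @export
kinetic_params <- function(pore_size = 4,
                           sigma_M = 5e-6, delta_M = 1.3e-4,
                           alpha_M = 0.05, beta_M = 0.5,
                           alpha_12 = 0.05, beta_12 = 500,
                           alpha_24 = 0.05, beta_24 = 0.05,
                           alpha_other = 1, beta_other = 1,
                           gamma_m = if (pore_size == 4) 5000 else 0.5,
                           gamma_c = 0.5) {
  A <- pore_size
  if (length(A) != 1L || !is.finite(A) || A < 2 ||
      abs(A - 2^round(log2(A))) > 1e-8) {
    stop("invalid model: pore_size must be a power of 2 reachable by ",
         "successive dimerizations (got ", A, ")")
  }
  A <- as.integer(round(A))
  p <- list(pore_size = A, sigma_M = sigma_M, delta_M = delta_M,
            alpha_M = alpha_M, beta_M = beta_M,
            alpha_12 = alpha_12, beta_12 = beta_12,
            alpha_24 = alpha_24, beta_24 = beta_24,
            alpha_other = alpha_other, beta_other = beta_other,
            gamma_m = gamma_m, gamma_c = gamma_c)
  rates <- unlist(p[-1])
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("validation error: all rates must be finite and >= 0")
  }
  class(p) <- "kinetic_params"
  p
}

#' Reference parameter sets for the tetramer and 256-mer pore models
#'
#' Returns the bundled reference initial conditions and rate constants used
#' throughout the package: initial free Mcl-1 3000 nM, Mcl-1:Bak complex
#' 1000 nM (all Bak sequestered), mitochondrial CytC 1000 nM, and the rate
#' set in [kinetic_params()] defaults. The only parameter that differs
#' between the two models is the CytC translocation rate `gamma_m`.
#'
#' @param model `"I"` (tetramer pore, A = 4) or `"II"` (256-subunit pore).
#' @return A `kinetic_params` object.
#' @export
reference_params <- function(model = c("I", "II")) {
  model <- match.arg(model)
  if (model == "I") kinetic_params(pore_size = 4, gamma_m = 5000)
  else kinetic_params(pore_size = 256, gamma_m = 0.5)
}

#' Initial state of the pore-formation network
#'
#' @param params A `kinetic_params` object (fixes the set of Bak oligomer
#'   sizes).
#' @param B Concentrations of the Bak oligomer species (nM), one per size
#'   1, 2, 4, ..., A. Defaults to all zero (all Bak starts sequestered).
#' @param M_free Free Mcl-1 (nM).
#' @param MB Mcl-1:Bak complex (nM).
#' @param C_m,C_c Mitochondrial and cytoplasmic CytC (nM).
#' @return An `initial_state` object. Total Bak `B_T = sum(n * B_n) + MB`
#'   and total CytC `C_T = C_m + C_c` are conserved quantities of the model.
#' @export
initial_state <- function(params, B = NULL, M_free = 3000, MB = 1000,
                          C_m = 1000, C_c = 0) {
  stopifnot(inherits(params, "kinetic_params"))
  sizes <- 2^(0:log2(params$pore_size))
  if (is.null(B)) B <- numeric(length(sizes))
  if (length(B) != length(sizes)) {
    stop("B must have one entry per oligomer size (", length(sizes), ")")
  }
  vals <- c(B, M_free, MB, C_m, C_c)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("validation error: concentrations must be finite and >= 0")
  }
  structure(list(B = B, M_free = M_free, MB = MB, C_m = C_m, C_c = C_c,
                 sizes = sizes,
                 B_T = sum(sizes * B) + MB, C_T = C_m + C_c),
            class = "initial_state")
}

#' Build the reaction network for a given pore size
#'
#' Assembles the species list and per-step dimerization rates for the
#' network: Mcl-1 turnover, Mcl-1 + B_1 <-> MB, the dimerization ladder
#' B_n + B_n <-> B_2n for n = 1, 2, ..., A/2, and CytC exchange
#' `gamma_m * [B_A] * [C_m] - gamma_c * [C_c]` driven by the size-A species
#' only.
#'
#' @param params A `kinetic_params` object.
#' @return A `bak_pore_model` with elements `params`, `sizes` (oligomer
#'   sizes, log2(A)+1 of them), `species` (all state-variable names),
#'   `alpha`/`beta` (ladder rates per step), and `model_tag`.
#' @export
build_model <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  A <- params$pore_size
  k <- log2(A)
  sizes <- 2^(0:k)
  nstep <- k
  alpha <- c(params$alpha_12, params$alpha_24,
             rep(params$alpha_other, max(0, nstep - 2)))[seq_len(nstep)]
  beta <- c(params$beta_12, params$beta_24,
            rep(params$beta_other, max(0, nstep - 2)))[seq_len(nstep)]
  tag <- if (A == 4) "Model I" else if (A == 256) "Model II"
         else sprintf("A=%d", A)
  structure(list(params = params, sizes = sizes,
                 species = c(paste0("B", sizes), "M", "MB", "Cm", "Cc"),
                 alpha = alpha, beta = beta, model_tag = tag),
            class = "bak_pore_model")
}

# Mass-action right-hand side shared by both models. State layout:
# B_1..B_A, M, MB, Cm, Cc. Dimerization step i consumes two B_{sizes[i]}.
make_rhs <- function(model) {
  ns <- length(model$sizes)
  alpha <- model$alpha
  beta <- model$beta
  p <- model$params
  function(t, y, parms) {
    B <- y[1:ns]
    M <- y[ns + 1]; MB <- y[ns + 2]; Cm <- y[ns + 3]; Cc <- y[ns + 4]
    dB <- numeric(ns)
    for (i in seq_len(ns - 1)) {
      f <- alpha[i] * B[i]^2 - beta[i] * B[i + 1]
      dB[i] <- dB[i] - 2 * f
      dB[i + 1] <- dB[i + 1] + f
    }
    seq_f <- p$alpha_M * M * B[1] - p$beta_M * MB
    dB[1] <- dB[1] - seq_f
    dM <- p$sigma_M - p$delta_M * M - seq_f
    flux <- p$gamma_m * B[ns] * Cm - p$gamma_c * Cc
    list(c(dB, dM, seq_f, -flux, flux))
  }
}

#' Integrate the pore-formation network
#'
#' Integrates the stiff ODE system with `deSolve::ode(method = "lsoda")`
#' and checks the two conservation laws (total Bak and total CytC) on the
#' returned trajectory. The output grid only affects interpolation of the
#' switch metrics; the solver chooses its own internal steps.
#'
#' @param model A `bak_pore_model`.
#' @param init An `initial_state`; defaults to the bundled reference state.
#' @param horizon Simulation horizon (s).
#' @param dt Output grid step (s). The default 10 s is far below the
#'   hour-scale Mcl-1 decay that paces the switch, so linear interpolation
#'   error on crossing times is negligible.
#' @param rtol,atol Solver tolerances.
#' @return A `pore_trajectory`: list with `times` (s), `conc` (matrix, one
#'   column per species), `species`, `sizes`, `model_tag`, `B_T`, `C_T`,
#'   and the maximum relative conservation deviations.
#' @export
simulate_network <- function(model, init = initial_state(model$params),
                             horizon, dt = 10, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "bak_pore_model"), horizon > 0)
  if (!identical(length(init$B), length(model$sizes))) {
    stop("initial state does not match the model's oligomer sizes")
  }
  y0 <- c(init$B, init$M_free, init$MB, init$C_m, init$C_c)
  names(y0) <- model$species
  times <- seq(0, horizon, by = dt)
  out <- deSolve::ode(y0, times, make_rhs(model), parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  istate <- attr(out, "istate")[1]
  if (!is.null(istate) && istate < 0) {
    cond <- simpleError(paste0("integrator failure (istate=", istate,
                               ") at t=", max(out[, 1])))
    cond$last_state <- out[nrow(out), ]
    stop(cond)
  }
  conc <- out[, -1, drop = FALSE]
  mn <- min(conc)
  if (mn < -1e-6) {
    stop("negative concentration ", format(mn),
         " far below the -1e-9 nM floor; tighten solver tolerances")
  }
  if (mn < -1e-9) {
    warning("negative concentrations (min ", format(mn),
            " nM) below the -1e-9 nM floor")
  }
  ns <- length(model$sizes)
  bt <- conc[, 1:ns, drop = FALSE] %*% model$sizes + conc[, ns + 2]
  ct <- conc[, ns + 3] + conc[, ns + 4]
  structure(list(times = out[, 1], conc = conc, species = model$species,
                 sizes = model$sizes, model_tag = model$model_tag,
                 B_T = init$B_T, C_T = init$C_T,
                 max_bak_dev = max(abs(bt - init$B_T)) / init$B_T,
                 max_cytc_dev = max(abs(ct - init$C_T)) / init$C_T),
            class = "pore_trajectory")
}

#' @export
print.pore_trajectory <- function(x, ...) {
  cat(x$model_tag, "trajectory:", length(x$times), "points over",
      max(x$times) / 3600, "h;", length(x$species), "species\n")
  cat(sprintf("conservation dev: Bak %.2e, CytC %.2e\n",
              x$max_bak_dev, x$max_cytc_dev))
  invisible(x)
}

#' Tidy export of a trajectory
#'
#' @param x A `pore_trajectory`.
#' @param row.names,optional,... Passed through for S3 compatibility.
#' @return A long data frame with columns `time_s`, `species`,
#'   `concentration_nM`.
#' @export
as.data.frame.pore_trajectory <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(time_s = rep(x$times, times = length(x$species)),
             species = rep(x$species, each = length(x$times)),
             concentration_nM = as.vector(x$conc),
             stringsAsFactors = FALSE)
}

#' Cytoplasmic CytC fraction along a trajectory
#'
#' @param traj A `pore_trajectory`.
#' @return Numeric vector `Cc / (Cc + Cm)` on the output grid.
#' @export
cytc_release <- function(traj) {
  stopifnot(inherits(traj, "pore_trajectory"))
  cc <- traj$conc[, "Cc"]
  cm <- traj$conc[, "Cm"]
  cc / (cc + cm)
}

# First time the CytC fraction reaches `level`, by linear interpolation
# between grid points. 0 if already at/above the level at t = 0; NA if the
# level is never reached; error if the fraction crosses the level more than
# once (the switch metric is then ill-defined).
crossing_time <- function(traj, level) {
  fr <- cytc_release(traj)
  above <- fr >= level
  ups <- which(!above[-length(above)] & above[-1])
  n_cross <- length(ups) + as.integer(above[1])
  if (n_cross > 1) {
    stop("ambiguity error: CytC fraction crosses ", level, " more than once")
  }
  if (above[1]) return(0)
  if (length(ups) == 0) return(NA_real_)
  i <- ups[1]
  t <- traj$times
  t[i] + (level - fr[i]) / (fr[i + 1] - fr[i]) * (t[i + 1] - t[i])
}

#' MOMP time: first half-maximal CytC translocation
#'
#' @param traj A `pore_trajectory`.
#' @return Time (s) at which the cytoplasmic CytC fraction first reaches
#'   0.5 (interpolated); 0 if already there at t = 0; `NA` if never.
#' @export
momp_time <- function(traj) crossing_time(traj, 0.5)

#' Switch duration: CytC fraction rise from 0.1 to 0.5
#'
#' The sharpness metric of the death switch: the time for the cytoplasmic
#' CytC fraction to increase from 0.1 to 0.5.
#'
#' @param traj A `pore_trajectory`.
#' @return Duration (s), or `NA` if the fraction never reaches 0.5.
#' @export
switch_duration <- function(traj) {
  t50 <- crossing_time(traj, 0.5)
  if (is.na(t50)) return(NA_real_)
  t10 <- crossing_time(traj, 0.1)
  t50 - t10
}
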