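# Shared, lazily computed reference simulations so that expensive stiff
# integrations run once per test session.
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

reference_traj <- function(model = "I", dt = 10) {
  key <- paste0("ref_", model, "_", dt)
  cached(key, {
    pars <- reference_params(model)
    horizon <- if (model == "I") 30 * 3600 else 40 * 3600
    simulate_network(build_model(pars), horizon = horizon, dt = dt)
  })
}

# pore-size sweep at the reference rates with the strong-pore CytC
# coupling (gamma_m = 5000), intermediate ladder steps at the
# "all other oligomers" rates
sweep_traj <- function(A) {
  cached(paste0("sweep_", A), {
    pars <- kinetic_params(pore_size = A, gamma_m = 5000)
    simulate_network(build_model(pars), horizon = 20 * 3600, dt = 10)
  })
}

# brute-force death-time oracle: scan I(t) on a 1-second grid
scan_death_time <- function(m0, x0, tau_M, tau_X, theta, t_max = 200) {
  tt <- seq(0, t_max, by = 1 / 3600)
  I <- m0 * exp(-tt / tau_M) + x0 * exp(-tt / tau_X)
  if (I[1] <= theta) return(0)
  i <- which(I <= theta)[1]
  if (is.na(i)) return(Inf)
  tt[i]
}

# closed-form K_C from the ladder equilibrium products (independent check
# of the numeric calibration)
ladder_kc <- function(params) {
  model <- build_model(params)
  K <- model$beta / model$alpha
  k <- length(K)
  exp((log(params$gamma_c / params$gamma_m) +
         sum(2^(k - seq_len(k)) * log(K))) / params$pore_size)
}

# reference three-condition synthetic fitting problem (shared by fitting
# tests and the acceptance suite)
recovery_problem <- function(seed = 42) {
  cached(paste0("recovery_", seed), {
    true_pop <- cell_population(mu_m = log(4), sigma_m = 0.45,
                                mu_x = log(2.5), sigma_x = 0.5,
                                sigma_b = 0.15, tau_M = 4, tau_X = 12)
    tg <- seq(0, 30, by = 2)
    qc <- function(p, lab) {
      survival_curve_quadrature(p, tg, nodes = 32, label = lab)
    }
    curves <- list(
      control = qc(true_pop, "control"),
      mcl1kd = qc(apply_knockdown(true_pop, "mcl1", 0.2), "mcl1kd"),
      bclxlkd = qc(apply_knockdown(true_pop, "bclxl", 0.2), "bclxlkd"))
    gt <- ground_truth(pop = true_pop, noise = 0.1, seed = seed)
    blots <- generate_blots(gt, 3)
    dec <- generate_decay_series(gt, 0:8)
    fd <- fit_decay(dec$time_h, dec$level)
    list(true_pop = true_pop, true_kd = c(m = 0.2, x = 0.2),
         curves = curves, blots = blots, tau_hat = fd$tau,
         problem = fit_problem(curves, blots,
                               tau_M_bounds = fd$tau * c(0.75, 1.33)),
         truth_par = c(mu_m = log(4), sigma_m = 0.45, mu_x = log(2.5),
                       sigma_x = 0.5, sigma_b = 0.15, log_tau_M = log(4),
                       log_tau_X = log(12), kd_m = 0.2, kd_x = 0.2))
  })
}
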