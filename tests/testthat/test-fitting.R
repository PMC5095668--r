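test_that("exponential decay fitting: exact, degenerate, and noisy data", {
  t <- c(0, 2, 4, 8)
  fd <- fit_decay(t, 2 * exp(-t / 4))
  expect_equal(fd$A_0, 2, tolerance = 1e-6)
  expect_equal(fd$tau, 4, tolerance = 1e-6)
  expect_equal(fd$half_life, 4 * log(2), tolerance = 1e-6)

  expect_warning(fdc <- fit_decay(t, rep(1.5, 4)), "do not decay")
  expect_true(fdc$at_bound)

  # 5% multiplicative noise, 8 points, 200 replicates: median tau
  # recovers the truth within 10%
  set.seed(19)
  taus <- replicate(200, {
    tt <- seq(0, 10, length.out = 8)
    lv <- exp(-tt / 3) * rlnorm(8, 0, 0.05)
    fit_decay(tt, lv)$tau
  })
  expect_lt(abs(stats::median(taus) - 3) / 3, 0.1)
})

test_that("objective is zero at the generating parameters and >= 0", {
  rp <- recovery_problem()
  expect_lt(survival_objective(rp$truth_par, rp$problem), 1e-6)
  off <- rp$truth_par
  off[["mu_m"]] <- off[["mu_m"]] + 0.2
  expect_gt(survival_objective(off, rp$problem), 0)
})

test_that("objective sensitivity mirrors knockdown asymmetry", {
  # a Bcl-xL-dominant line cares more about mu_x than an
  # Mcl-1-dominant line does
  tg <- seq(0, 30, by = 2)
  mk_prob <- function(mu_m, mu_x) {
    pop <- cell_population(mu_m = mu_m, sigma_m = 0.4, mu_x = mu_x,
                           sigma_x = 0.4, sigma_b = 0.1, tau_M = 4,
                           tau_X = 12)
    curves <- list(
      control = survival_curve_quadrature(pop, tg, nodes = 32),
      bclxlkd = survival_curve_quadrature(
        apply_knockdown(pop, "bclxl", 0.2), tg, nodes = 32))
    blots <- data.frame(protein = c("mcl1_bak", "bclxl_bak"),
                        mean = exp(c(mu_m, mu_x)),
                        sd = 0.3 * exp(c(mu_m, mu_x)))
    list(par = c(mu_m = mu_m, sigma_m = 0.4, mu_x = mu_x, sigma_x = 0.4,
                 sigma_b = 0.1, log_tau_M = log(4), log_tau_X = log(12),
                 kd_m = 0.2, kd_x = 0.2),
         prob = fit_problem(curves, blots, tau_M_bounds = c(3, 5)))
  }
  xdom <- mk_prob(mu_m = log(1.2), mu_x = log(5))
  mdom <- mk_prob(mu_m = log(5), mu_x = log(1.2))
  bump <- function(case) {
    p <- case$par
    p[["mu_x"]] <- p[["mu_x"]] + log(1.1)
    survival_objective(p, case$prob)
  }
  expect_gt(bump(xdom), bump(mdom))
})

test_that("pattern search descends monotonically and respects bounds", {
  sphere <- function(x) sum((x - c(0.3, -0.2))^2)
  res <- pattern_search(sphere, c(0.9, 0.9), lower = c(-1, -1),
                        upper = c(1, 1), step_tol = 1e-5)
  expect_true(all(diff(res$trace$sse) <= 0))
  expect_equal(res$par, c(0.3, -0.2), tolerance = 1e-3)

  # bounds collapsed to a point return that point
  res2 <- pattern_search(sphere, c(0.5, 0.5), lower = c(0.5, 0.5),
                         upper = c(0.5, 0.5))
  expect_equal(res2$par, c(0.5, 0.5))
  expect_equal(res2$value, sphere(c(0.5, 0.5)))
})

test_that("fit_survival is deterministic given the seed", {
  rp <- recovery_problem()
  f1 <- fit_survival(rp$problem, n_random = 40, n_starts = 2, seed = 5,
                     maxit = 5)
  f2 <- fit_survival(rp$problem, n_random = 40, n_starts = 2, seed = 5,
                     maxit = 5)
  expect_identical(f1$parameters, f2$parameters)
  expect_identical(f1$sse, f2$sse)
  expect_true(all(diff(f1$trace$sse) <= 0))
  expect_true(all(f1$parameters >= rp$problem$lower - 1e-12) &&
                all(f1$parameters <= rp$problem$upper + 1e-12))
})

test_that("knockdown conditions break the control-only degeneracy", {
  # Under control-only data a wrong Mcl-1 median can be compensated by
  # the other parameters; the knockdown conditions reject the same
  # compensation. Profile the objective at mu_m fixed 0.3 log units high.
  rp <- recovery_problem()
  prob_ctrl <- fit_problem(rp$curves["control"], rp$blots,
                           tau_M_bounds = rp$tau_hat * c(0.75, 1.33))
  wrong_mu <- rp$truth_par[["mu_m"]] + 0.3
  lower <- prob_ctrl$lower
  upper <- prob_ctrl$upper
  lower[["mu_m"]] <- wrong_mu
  upper[["mu_m"]] <- wrong_mu
  start <- rp$truth_par
  start[["mu_m"]] <- wrong_mu
  prof <- pattern_search(
    function(p) survival_objective(p, prob_ctrl),
    start, lower, upper, maxit = 60, step_tol = 1e-4)
  # compensation succeeds on the control curve alone ...
  expect_lt(prof$value, 2e-5)
  # ... but the same parameters misfit the three-condition problem badly
  expect_gt(survival_objective(prof$par, rp$problem), 50 * prof$value)
})

test_that("scaled two-stage fit recovers ratios and their ordering", {
  rp <- recovery_problem()
  fit <- fit_survival(rp$problem, n_random = 300, n_starts = 3,
                      seed = 21, maxit = 60)
  expect_lt(abs(fit$parameters[["mu_m"]] - log(4)), 0.25)
  expect_lt(abs(fit$parameters[["mu_x"]] - log(2.5)), 0.25)
  expect_gt(fit$parameters[["mu_m"]], fit$parameters[["mu_x"]])
  expect_gte(nrow(fit$restarts), 3)
  # fitted tau_M honors its measurement-derived bounds
  expect_gte(exp(fit$parameters[["log_tau_M"]]), rp$tau_hat * 0.75 - 1e-9)
  expect_lte(exp(fit$parameters[["log_tau_M"]]), rp$tau_hat * 1.33 + 1e-9)
})

test_that("fit problems and results round-trip through files", {
  rp <- recovery_problem()
  dir <- tempfile()
  dir.create(dir)
  for (cond in names(rp$curves)) {
    write_survival_curve(rp$curves[[cond]],
                         file.path(dir, paste0(cond, ".tsv")))
  }
  utils::write.table(rp$blots, file.path(dir, "blots.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- file.path(dir, "problem.yaml")
  yaml::write_yaml(list(
    curves = list(control = "control.tsv", mcl1kd = "mcl1kd.tsv",
                  bclxlkd = "bclxlkd.tsv"),
    blots = "blots.tsv",
    tau_M_bounds = rp$tau_hat * c(0.75, 1.33)), cfg)
  prob <- read_fit_problem(cfg)
  expect_equal(prob$lower, rp$problem$lower)
  expect_equal(prob$upper, rp$problem$upper)
  expect_equal(prob$curves$control$surviving_fraction,
               rp$curves$control$surviving_fraction, tolerance = 1e-9)
  expect_lt(survival_objective(rp$truth_par, prob), 1e-6)

  fit <- fit_survival(prob, n_random = 20, n_starts = 1, seed = 1,
                      maxit = 3)
  out <- tempfile()
  write_fit_result(fit, out)
  pd <- utils::read.delim(file.path(out, "parameters.tsv"))
  expect_equal(pd$search_scale, unname(fit$parameters), tolerance = 1e-9)
  expect_true(file.exists(file.path(out, "restarts.tsv")))
})
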