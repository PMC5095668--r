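qs_ref <- quasi_static(M_0 = 3000, M_s = 0.038, delta_M = 1.3e-4,
                       B_T = 1000, K_M = 10, A = 4, K_C = 10)

test_that("free Mcl-1 decay: boundary values and full-model agreement", {
  expect_equal(free_mcl1(0, qs_ref), 3000)
  expect_equal(free_mcl1(1e9, qs_ref), qs_ref$M_s, tolerance = 1e-12)
  # the 256-mer model's simulated free Mcl-1 at 2 h matches within 5%
  tr2 <- reference_traj("II")
  qs2 <- quasi_static_from_kinetics(reference_params("II"))
  i <- which(tr2$times == 7200)
  expect_lt(abs(tr2$conc[i, "M"] - free_mcl1(7200, qs2)) /
              free_mcl1(7200, qs2), 0.05)
})

test_that("Bak monomer follows the sequestration isotherm", {
  expect_equal(bak_monomer(0, qs_ref), 1000)
  expect_equal(bak_monomer(10, qs_ref), 500)   # M = K_M half-saturation
  expect_equal(bak_monomer(990, qs_ref), 10)   # Table-derived arithmetic
})

test_that("CytC release is a numerically stable Hill function", {
  expect_equal(cytc_fraction(qs_ref$K_C, qs_ref), 0.5)
  b110 <- qs_ref$K_C * (1 / 9)^(1 / qs_ref$A)
  expect_equal(cytc_fraction(b110, qs_ref), 0.1, tolerance = 1e-12)
  expect_equal(critical_bak(qs_ref, 0.1), b110, tolerance = 1e-12)

  qs256 <- quasi_static(M_0 = 3000, M_s = 0, delta_M = 1.3e-4, B_T = 1000,
                        K_M = 10, A = 256, K_C = 100)
  expect_gt(cytc_fraction(1.01 * qs256$K_C, qs256), 0.9)  # no overflow
  expect_equal(cytc_fraction(0, qs256), 0)

  # strictly increasing in B_1 through the responsive band (the Hill
  # form saturates to exactly 0/1 in double precision outside it);
  # nondecreasing everywhere
  b <- seq(90, 110, by = 0.25)
  expect_true(all(diff(cytc_fraction(b, qs256)) > 0))
  expect_true(all(diff(cytc_fraction(seq(1, 300, 1), qs256)) >= 0))
  for (b1 in c(10, 50, 90)) {
    fr <- vapply(c(4, 16, 64, 256), function(A) {
      cytc_fraction(b1, quasi_static(M_0 = 3000, M_s = 0,
                                     delta_M = 1.3e-4, B_T = 1000,
                                     K_M = 10, A = A, K_C = 100))
    }, numeric(1))
    expect_true(all(diff(fr) < 0))
  }
})

test_that("K_C calibration matches the ladder-equilibrium closed form", {
  p1 <- reference_params("I")
  p2 <- reference_params("II")
  expect_equal(calibrate_kc(p1), ladder_kc(p1), tolerance = 1e-8)
  expect_equal(calibrate_kc(p2), ladder_kc(p2), tolerance = 1e-8)
  expect_equal(calibrate_kc(p1), 10, tolerance = 1e-8)
  p3 <- kinetic_params(pore_size = 16, gamma_m = 50, beta_24 = 0.2)
  expect_equal(calibrate_kc(p3), ladder_kc(p3), tolerance = 1e-8)
})

test_that("MOMP delay: closed-form properties and numeric agreement", {
  # no delay when the threshold sits at the initial level
  m12 <- critical_mcl1(qs_ref, 0.5)
  qs0 <- quasi_static(M_0 = m12, M_s = 0, delta_M = 1.3e-4, B_T = 1000,
                      K_M = 10, A = 4, K_C = 10)
  expect_equal(momp_delay(qs0), 0)
  # doubling M_0 adds exactly ln(2)/delta_M
  qsa <- quasi_static(M_0 = 3000, M_s = 0, delta_M = 1.3e-4, B_T = 1000,
                      K_M = 10, A = 4, K_C = 10)
  qsb <- quasi_static(M_0 = 6000, M_s = 0, delta_M = 1.3e-4, B_T = 1000,
                      K_M = 10, A = 4, K_C = 10)
  expect_equal(momp_delay(qsb) - momp_delay(qsa), log(2) / 1.3e-4,
               tolerance = 1e-10)
  # synthesis floor above threshold -> never fires
  qs_never <- quasi_static(M_0 = 3000, M_s = 2000, delta_M = 1.3e-4,
                           B_T = 1000, K_M = 10, A = 4, K_C = 10)
  expect_identical(momp_delay(qs_never), Inf)
  # matches the tetramer-model simulation within 10%
  qs1 <- quasi_static_from_kinetics(reference_params("I"))
  t50 <- momp_time(reference_traj("I"))
  expect_lt(abs(momp_delay(qs1) - t50) / t50, 0.1)
})

test_that("switch-sharpness bound: constant, limit, and numeric check", {
  expect_equal(switch_bound(4, 1) * 4, log(9))
  expect_equal(log(9), 2.197, tolerance = 1e-3)
  expect_lt(switch_bound(2^26, 1.3e-4), 1e-3)
  expect_equal(switch_bound(4, 1.3e-4), 4225, tolerance = 1e-3)
  expect_gt(switch_duration(reference_traj("I")), switch_bound(4, 1.3e-4))
})

test_that("saturated-regime sharpness identity is exact", {
  for (A in c(4, 16, 256)) {
    qs <- quasi_static(M_0 = 3000, M_s = 0, delta_M = 1.3e-4, B_T = 1000,
                       K_M = 10, A = A, K_C = 100)
    expect_equal(switch_sharpness(qs, saturated = TRUE),
                 switch_bound(A, qs$delta_M), tolerance = 1e-12)
  }
})

test_that("analytic delay tracks simulation across rates and pore sizes", {
  # tetramer model at reference concentrations; 256-mer in a
  # sequestration-light regime (K_M = 1000 nM, high M_0, fast ladder)
  # where the pseudo-equilibrium premises hold
  cases <- list(
    list(A = 4, beta_M = 0.5, alpha_24 = 0.05, beta_24 = 0.05,
         M0 = 3000, d = 1e-5),
    list(A = 4, beta_M = 0.5, alpha_24 = 0.05, beta_24 = 0.05,
         M0 = 3000, d = 1e-3),
    list(A = 256, beta_M = 50, alpha_24 = 0.5, beta_24 = 0.5,
         M0 = 1e5, d = 1.3e-4),
    list(A = 256, beta_M = 50, alpha_24 = 0.5, beta_24 = 0.5,
         M0 = 1e5, d = 1e-3))
  for (cs in cases) {
    pars <- kinetic_params(pore_size = cs$A, beta_M = cs$beta_M,
                           delta_M = cs$d, alpha_24 = cs$alpha_24,
                           beta_24 = cs$beta_24, gamma_m = 5000)
    init <- initial_state(pars, M_free = cs$M0)
    tc <- momp_delay(quasi_static_from_kinetics(pars, init))
    tr <- simulate_network(build_model(pars), init,
                           horizon = 2.5 * tc,
                           dt = max(2, round(tc / 3000)))
    expect_lt(abs(momp_time(tr) - tc) / momp_time(tr), 0.1)
  }
})
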