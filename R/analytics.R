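#' Quasi-static reduction parameters
#'
#' When Mcl-1 binding and Bak oligomerization equilibrate fast relative to
#' Mcl-1 degradation, the network collapses to a single slow variable: free
#' Mcl-1 decays exponentially from `M_0` toward the synthesis floor
#' `M_s = sigma_M / delta_M`; Bak monomer follows as
#' `B_1 = B_T / (1 + M/K_M)`; and the steady cytoplasmic CytC fraction is a
#' Hill function of `B_1` with coefficient `A` and midpoint `K_C`.
#'
#' @param M_0 Initial free Mcl-1 (nM); must exceed `M_s`.
#' @param M_s Steady-state free Mcl-1 `sigma_M/delta_M` (nM).
#' @param delta_M Mcl-1 degradation rate (1/s).
#' @param B_T Total Bak (nM).
#' @param K_M Mcl-1:Bak dissociation constant `beta_M/alpha_M` (nM).
#' @param A Pore subunit count (>= 2).
#' @param K_C Critical Bak-monomer level at which CytC release is
#'   half-maximal (nM); see [calibrate_kc()].
#' @return A `quasi_static` object.
#' @export
quasi_static <- function(M_0, M_s, delta_M, B_T, K_M, A, K_C) {
  stopifnot(M_0 > M_s, M_s >= 0, delta_M > 0, B_T > 0, K_M > 0, K_C > 0,
            A >= 2)
  structure(list(M_0 = M_0, M_s = M_s, delta_M = delta_M, B_T = B_T,
                 K_M = K_M, A = A, K_C = K_C), class = "quasi_static")
}

#' Derive quasi-static parameters from a kinetic parameter set
#'
#' @param params A [kinetic_params()] object.
#' @param init An [initial_state()]; supplies `M_0` and `B_T`.
#' @return A `quasi_static` object with `K_C` calibrated numerically from
#'   the network (see [calibrate_kc()]).
#' @export
quasi_static_from_kinetics <- function(params,
                                       init = initial_state(params)) {
  quasi_static(M_0 = init$M_free,
               M_s = params$sigma_M / params$delta_M,
               delta_M = params$delta_M, B_T = init$B_T,
               K_M = params$beta_M / params$alpha_M,
               A = params$pore_size, K_C = calibrate_kc(params))
}

#' Free Mcl-1 decay in the reduced model
#'
#' `M(t) = M_s + (M_0 - M_s) * exp(-delta_M * t)`.
#'
#' @param t Time (s), vectorized.
#' @param p A `quasi_static` object.
#' @return Free Mcl-1 (nM).
#' @export
free_mcl1 <- function(t, p) {
  stopifnot(all(t >= 0))
  p$M_s + (p$M_0 - p$M_s) * exp(-p$delta_M * t)
}

#' Bak monomer level at a given free Mcl-1 level
#'
#' With most Bak either Mcl-1-bound or monomeric,
#' `B_1 = B_T / (1 + M/K_M)`.
#'
#' @param M_free Free Mcl-1 (nM), vectorized.
#' @param p A `quasi_static` object.
#' @return Bak monomer (nM).
#' @export
bak_monomer <- function(M_free, p) {
  stopifnot(all(M_free >= 0))
  p$B_T / (1 + M_free / p$K_M)
}

#' Steady cytoplasmic CytC fraction as a Hill function of Bak monomer
#'
#' `f = B_1^A / (B_1^A + K_C^A)`, evaluated in log space so that A = 256
#' does not overflow.
#'
#' @param B_1 Bak monomer (nM), vectorized.
#' @param p A `quasi_static` object.
#' @return Fraction in `[0, 1]`.
#' @export
cytc_fraction <- function(B_1, p) {
  stopifnot(all(B_1 >= 0))
  stats::plogis(p$A * (log(B_1) - log(p$K_C)))
}

#' Critical Bak-monomer level for a given release fraction
#'
#' Inverts the Hill form: `B_1(f) = K_C * (f/(1-f))^(1/A)`.
#'
#' @param p A `quasi_static` object.
#' @param frac Target CytC fraction in (0, 1).
#' @return Bak monomer level (nM).
#' @export
critical_bak <- function(p, frac) {
  stopifnot(frac > 0, frac < 1)
  p$K_C * exp(log(frac / (1 - frac)) / p$A)
}

#' Critical free-Mcl-1 level for a given release fraction
#'
#' Inverts [cytc_fraction()] composed with [bak_monomer()]:
#' `M(f) = K_M * (B_T / B_1(f) - 1)`. With `saturated = TRUE` the `- 1` is
#' dropped (the `M >> K_M` regime, `M(f) = K_M * B_T / B_1(f)`), which is
#' the form under which the switch-sharpness identity
#' `delta_M * dT = ln(9)/A` is exact.
#'
#' @param p A `quasi_static` object.
#' @param frac Target CytC fraction in (0, 1).
#' @param saturated Use the `M >> K_M` approximation.
#' @return Free Mcl-1 (nM); in the full form the value is <= 0 when the
#'   required Bak monomer level meets or exceeds `B_T`, i.e. the fraction
#'   is unreachable even at complete Mcl-1 depletion.
#' @export
critical_mcl1 <- function(p, frac, saturated = FALSE) {
  b1 <- critical_bak(p, frac)
  if (saturated) p$K_M * p$B_T / b1 else p$K_M * (p$B_T / b1 - 1)
}

#' Analytical MOMP delay
#'
#' Time for free Mcl-1 to decay from `M_0` to the half-release level
#' `M_1/2`: `T_c = (1/delta_M) * log((M_0 - M_s) / (M_1/2 - M_s))`. Returns
#' 0 if the system starts at or past threshold (`M_1/2 >= M_0`) and `Inf`
#' if the synthesis floor keeps Mcl-1 above threshold forever
#' (`M_1/2 <= M_s`).
#'
#' @param p A `quasi_static` object.
#' @return Delay (s).
#' @export
momp_delay <- function(p) {
  m12 <- critical_mcl1(p, 0.5)
  if (m12 >= p$M_0) return(0)
  if (m12 <= p$M_s) return(Inf)
  log((p$M_0 - p$M_s) / (m12 - p$M_s)) / p$delta_M
}

#' Analytical switch sharpness of the reduced model
#'
#' Time for free Mcl-1 to decay from the 1/10-release level to the
#' half-release level. In the saturated (`M >> K_M`, zero synthesis floor)
#' regime this equals the pore-size bound [switch_bound()] exactly.
#'
#' @param p A `quasi_static` object.
#' @param saturated Use the `M >> K_M` form of [critical_mcl1()] and drop
#'   the synthesis floor.
#' @return Duration (s).
#' @export
switch_sharpness <- function(p, saturated = FALSE) {
  m12 <- critical_mcl1(p, 0.5, saturated = saturated)
  m110 <- critical_mcl1(p, 0.1, saturated = saturated)
  if (saturated) return(log(m110 / m12) / p$delta_M)
  stopifnot(m12 > p$M_s)
  log((m110 - p$M_s) / (m12 - p$M_s)) / p$delta_M
}

#' Pore-size lower bound on the switch duration
#'
#' `dT_min = ln(9) / (A * delta_M)`. The constant `ln(9) ~ 2.197` is the
#' log-odds gap between 10% and 50% release; the bound is independent of
#' the initial Mcl-1 level and of the detailed ladder rate constants.
#'
#' @param A Pore subunit count.
#' @param delta_M Mcl-1 degradation rate (1/s).
#' @return Lower bound on the 0.1 -> 0.5 release duration (s).
#' @export
switch_bound <- function(A, delta_M) {
  stopifnot(A >= 2, delta_M > 0)
  log(9) / (A * delta_M)
}

#' Calibrate the critical Bak-monomer level K_C from the full network
#'
#' `K_C` is the Bak monomer concentration at which the steady cytoplasmic
#' CytC fraction is 1/2. It is determined by the dimerization dissociation
#' constants and the CytC exchange rates: the ladder equilibrium gives the
#' active-pore concentration for a clamped `B_1`, and the CytC balance
#' `gamma_m * B_A * C_m = gamma_c * C_c` gives the release fraction. This
#' routine computes the steady fraction through those network relations and
#' root-finds the half-release point in log space.
#'
#' @param params A [kinetic_params()] object.
#' @return `K_C` (nM).
#' @export
calibrate_kc <- function(params) {
  model <- build_model(params)
  steady_frac <- function(log_b1) {
    log_bn <- log_b1
    for (i in seq_along(model$alpha)) {
      log_bn <- 2 * log_bn - log(model$beta[i] / model$alpha[i])
    }
    # release fraction gamma_m*B_A / (gamma_m*B_A + gamma_c), log space
    stats::plogis(log(params$gamma_m / params$gamma_c) + log_bn)
  }
  r <- stats::uniroot(function(lb) steady_frac(lb) - 0.5,
                      lower = -60, upper = 60, tol = 1e-12)
  exp(r$root)
}
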