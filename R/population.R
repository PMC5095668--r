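#' Log-normal cell-line population model
#'
#' Describes one cell line (and drug condition) by independent log-normal
#' distributions of Mcl-1, Bcl-xL and Bak abundance, the two inhibitor
#' decay time constants, and the death threshold. Per sampled cell the
#' ratios `m0 = M/B` and `x0 = X/B` feed the threshold death model, and Bak
#' variability enters the threshold as `theta = theta_ref * B/B_ref`
#' (threshold proportional to total Bak), with `B_ref = exp(mu_b)` the
#' median Bak level.
#'
#' RNAi knockdown is modeled as a multiplicative shift of the targeted
#' protein's median (log-scale location shift) leaving its spread
#' unchanged.
#'
#' "Fold variation" of a protein is reported as `exp(2*sigma)`, the ratio
#' of its 84th to 16th percentile.
#'
#' @param mu_m,sigma_m Log-scale mean and SD of the Mcl-1/Bak-scale
#'   distribution (the Mcl-1 level in threshold units).
#' @param mu_x,sigma_x Same for Bcl-xL.
#' @param mu_b,sigma_b Same for Bak level.
#' @param tau_M,tau_X Inhibitor decay time constants (hours).
#' @param theta_ref Death threshold at the reference (median) Bak level.
#' @param knockdown_m,knockdown_x Multiplicative knockdown factors in
#'   (0, 1] applied to the Mcl-1 / Bcl-xL medians.
#' @return A `cell_population` object.
#' @export
cell_population <- function(mu_m, sigma_m, mu_x, sigma_x, mu_b = 0,
                            sigma_b = 0, tau_M, tau_X, theta_ref = 1,
                            knockdown_m = 1, knockdown_x = 1) {
  stopifnot(sigma_m >= 0, sigma_x >= 0, sigma_b >= 0, tau_M > 0,
            tau_X > 0, theta_ref > 0,
            knockdown_m > 0, knockdown_m <= 1,
            knockdown_x > 0, knockdown_x <= 1)
  structure(list(mu_m = mu_m, sigma_m = sigma_m, mu_x = mu_x,
                 sigma_x = sigma_x, mu_b = mu_b, sigma_b = sigma_b,
                 tau_M = tau_M, tau_X = tau_X, theta_ref = theta_ref,
                 knockdown_m = knockdown_m, knockdown_x = knockdown_x),
            class = "cell_population")
}

#' Fold variation of a log-normal spread parameter
#'
#' @param sigma Log-scale SD.
#' @return `exp(2*sigma)`: the 84th/16th percentile ratio.
#' @export
fold_variation <- function(sigma) exp(2 * sigma)

#' Apply an RNAi knockdown to a population
#'
#' @param pop A [cell_population()].
#' @param target `"mcl1"` or `"bclxl"`.
#' @param factor Multiplicative median reduction in (0, 1].
#' @return The modified population.
#' @export
apply_knockdown <- function(pop, target = c("mcl1", "bclxl"), factor) {
  target <- match.arg(target)
  stopifnot(factor > 0, factor <= 1)
  if (target == "mcl1") pop$knockdown_m <- pop$knockdown_m * factor
  else pop$knockdown_x <- pop$knockdown_x * factor
  pop
}

#' Sample single cells from a population
#'
#' Draws independent log-normal `M`, `X`, `B` (knockdowns shift the `M`/`X`
#' medians) and forms each cell's threshold-model state.
#'
#' @param pop A [cell_population()].
#' @param n Number of cells (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @return A [cell_state()] with `n` rows.
#' @export
sample_cells <- function(pop, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  M <- stats::rlnorm(n, pop$mu_m + log(pop$knockdown_m), pop$sigma_m)
  X <- stats::rlnorm(n, pop$mu_x + log(pop$knockdown_x), pop$sigma_x)
  B <- stats::rlnorm(n, pop$mu_b, pop$sigma_b)
  cell_state(m0 = M / B, x0 = X / B, tau_M = pop$tau_M, tau_X = pop$tau_X,
             theta = pop$theta_ref * B / exp(pop$mu_b))
}

new_survival_curve <- function(time_h, fraction, label = "control",
                               source = "model", n_effective = NA,
                               se = NULL) {
  d <- data.frame(time_h = time_h, surviving_fraction = fraction)
  if (!is.null(se)) d$se <- se
  attr(d, "label") <- label
  attr(d, "source") <- source
  attr(d, "n_effective") <- n_effective
  class(d) <- c("survival_curve", "data.frame")
  d
}

#' Monte-Carlo mitotic survival curve
#'
#' Fraction of sampled cells whose deterministic death time exceeds each
#' grid time. The pointwise Monte-Carlo standard error is at most
#' `0.5/sqrt(n)`.
#'
#' @param pop A [cell_population()].
#' @param times Time grid (hours) starting at 0.
#' @param n Number of sampled cells.
#' @param seed Optional integer seed.
#' @param label Condition tag stored on the curve.
#' @return A `survival_curve` data frame (`time_h`, `surviving_fraction`)
#'   with attributes `label`, `source = "monte_carlo"`, `n_effective`.
#' @export
survival_curve <- function(pop, times, n = 1e5, seed = NULL,
                           label = "control") {
  stopifnot(times[1] == 0, !is.unsorted(times))
  cells <- sample_cells(pop, n, seed)
  dt <- death_time(cells)
  frac <- vapply(times, function(T) mean(dt > T), numeric(1))
  new_survival_curve(times, frac, label = label, source = "monte_carlo",
                     n_effective = n)
}

# Equal-probability quantile-midpoint nodes for a log-normal factor; a
# zero-sigma distribution collapses to its median with unit weight. The
# midpoint rule in probability space is robust for the bounded, saturating
# integrands that arise here (it beats Gauss-Hermite, whose polynomial
# basis converges slowly once the survival kernel flattens at 1).
lognormal_nodes <- function(mu, sigma, nodes) {
  if (sigma == 0) return(list(v = exp(mu), w = 1))
  u <- (seq_len(nodes) - 0.5) / nodes
  list(v = stats::qlnorm(u, mu, sigma), w = rep(1 / nodes, nodes))
}

#' Deterministic survival curve by log-normal quadrature
#'
#' Evaluates `P(t_c > T) = P(M e1 + X e2 > theta_ref * B^2 / B_ref)` (with
#' `e1 = exp(-T/tau_M)`, `e2 = exp(-T/tau_X)`) by equal-probability
#' quadrature over the log-normal `B` and `X` distributions and the exact
#' conditional log-normal tail of `M`. The result is noise-free, which
#' keeps the fitting objective deterministic.
#'
#' @param pop A [cell_population()].
#' @param times Time grid (hours) starting at 0.
#' @param nodes Quadrature nodes per log-normal dimension (accuracy
#'   control; error decays roughly as `nodes^-2`).
#' @param label Condition tag.
#' @return A `survival_curve` with `source = "quadrature"`.
#' @export
survival_curve_quadrature <- function(pop, times, nodes = 128,
                                      label = "control") {
  stopifnot(times[1] == 0, !is.unsorted(times))
  mu_m <- pop$mu_m + log(pop$knockdown_m)
  xq <- lognormal_nodes(pop$mu_x + log(pop$knockdown_x), pop$sigma_x,
                        nodes)
  bq <- lognormal_nodes(pop$mu_b, pop$sigma_b, nodes)
  nT <- length(times); nx <- length(xq$v); nb <- length(bq$v)
  e1 <- exp(-times / pop$tau_M)
  e2 <- exp(-times / pop$tau_X)
  cB <- pop$theta_ref * bq$v^2 / exp(pop$mu_b)
  # arrays laid out (T, x, b)
  R <- rep(cB, each = nT * nx) - as.vector(outer(e2, xq$v))
  E1 <- rep(e1, times = nx * nb)
  q <- numeric(length(R))
  pos <- R > 0
  q[!pos] <- 1
  if (pop$sigma_m > 0) {
    q[pos] <- stats::plnorm(R[pos] / E1[pos], mu_m, pop$sigma_m,
                            lower.tail = FALSE)
  } else {
    q[pos] <- as.numeric(exp(mu_m) * E1[pos] > R[pos])
  }
  w <- rep(rep(xq$w, each = nT), times = nb) * rep(bq$w, each = nT * nx)
  frac <- rowSums(matrix(q * w, nrow = nT))
  new_survival_curve(times, pmin(pmax(frac, 0), 1), label = label,
                     source = "quadrature", n_effective = Inf)
}
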