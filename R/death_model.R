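#' Per-cell state of the threshold death model
#'
#' In the large-pore limit the death switch fires the moment free Bak
#' monomer reaches its critical level, which translates into a threshold on
#' the total inhibitory capacity: a cell dies when
#' `I(t) = m(t) + x(t)` drops to `theta`, where `m` and `x` are the free
#' Mcl-1 and Bcl-xL levels relative to Bak, each scaled by its dissociation
#' constant, and `theta ~ B_T/K_c` is the (dimensionless) death threshold.
#' The absolute dissociation constants never appear: they are absorbed into
#' the dimensionless ratios.
#'
#' All fields are recycled to a common length, so a `cell_state` holds one
#' cell or a whole sampled population.
#'
#' @param m0,x0 Initial Mcl-1/Bak and Bcl-xL/Bak ratios (dimensionless,
#'   >= 0).
#' @param tau_M,tau_X Decay time constants of the two inhibitors (hours,
#'   > 0).
#' @param theta Death threshold (> 0).
#' @param m_s,x_s Optional additive decay floors (default 0; the standard
#'   model uses floorless exponentials).
#' @return A `cell_state` data frame.
#' @export
cell_state <- function(m0, x0, tau_M, tau_X, theta, m_s = 0, x_s = 0) {
  d <- data.frame(m0 = m0, x0 = x0, tau_M = tau_M, tau_X = tau_X,
                  theta = theta, m_s = m_s, x_s = x_s)
  if (any(d$m0 < 0) || any(d$x0 < 0) || any(d$tau_M <= 0) ||
      any(d$tau_X <= 0) || any(d$theta <= 0) || any(d$m_s < 0) ||
      any(d$x_s < 0)) {
    stop("invalid cell state: need m0, x0, floors >= 0 and tau, theta > 0")
  }
  class(d) <- c("cell_state", "data.frame")
  d
}

#' Total inhibitory capacity of a cell over time
#'
#' `I(t) = m_s + (m0 - m_s) exp(-t/tau_M) + x_s + (x0 - x_s) exp(-t/tau_X)`;
#' strictly decreasing whenever `m0 + x0 > m_s + x_s`.
#'
#' @param cells A [cell_state()] (one row, with `t` vectorized; or many
#'   rows with `t` scalar or of matching length).
#' @param t Time since arrest entry (hours).
#' @return Inhibition level(s), dimensionless.
#' @export
inhibition <- function(cells, t) {
  stopifnot(inherits(cells, "cell_state"), all(t >= 0))
  with(cells, m_s + (m0 - m_s) * exp(-t / tau_M) +
              x_s + (x0 - x_s) * exp(-t / tau_X))
}

#' Deterministic death time of each cell
#'
#' Solves `I(t_c) = theta` for the unique crossing time of the (monotone)
#' inhibition decay. Cells already at or below threshold at arrest entry
#' die at t = 0; cells whose decay floors keep `I` above threshold never
#' die (`Inf`). Single-exponential and equal-time-constant cases use the
#' closed form; the general two-exponential case uses vectorized bracketed
#' bisection (guaranteed by monotonicity).
#'
#' @param cells A [cell_state()] of any length.
#' @param tol Absolute time tolerance of the bisection (hours); default
#'   1 second.
#' @return Numeric vector of death times (hours).
#' @export
death_time <- function(cells, tol = 1 / 3600) {
  stopifnot(inherits(cells, "cell_state"))
  n <- nrow(cells)
  out <- rep(NA_real_, n)
  I0 <- cells$m0 + cells$x0
  floor_ <- cells$m_s + cells$x_s
  imm <- I0 <= cells$theta
  out[imm] <- 0
  nev <- !imm & floor_ >= cells$theta
  out[nev] <- Inf
  todo <- which(!imm & !nev)
  if (length(todo) == 0) return(out)
  cc <- cells[todo, , drop = FALSE]
  target <- cc$theta - cc$m_s - cc$x_s        # residual to be carried by
  am <- cc$m0 - cc$m_s                        # the decaying components
  ax <- cc$x0 - cc$x_s
  res <- rep(NA_real_, nrow(cc))
  xconst <- ax == 0
  mconst <- am == 0
  eqtau <- !xconst & !mconst & cc$tau_M == cc$tau_X
  res[xconst] <- cc$tau_M[xconst] * log(am[xconst] / target[xconst])
  res[mconst] <- cc$tau_X[mconst] * log(ax[mconst] / target[mconst])
  res[eqtau] <- cc$tau_M[eqtau] * log((am[eqtau] + ax[eqtau]) /
                                        target[eqtau])
  gen <- which(is.na(res))
  if (length(gen)) {
    g <- cc[gen, , drop = FALSE]
    gcells <- g; class(gcells) <- class(cc)
    lo <- numeric(nrow(g))
    hi <- 10 * pmax(g$tau_M, g$tau_X)
    # extend the bracket where needed (possible only for extreme m0/theta)
    for (it in 1:60) {
      bad <- inhibition(gcells, hi) > g$theta
      if (!any(bad)) break
      hi[bad] <- 2 * hi[bad]
    }
    while (max(hi - lo) > tol) {
      mid <- (lo + hi) / 2
      above <- inhibition(gcells, mid) > g$theta
      lo[above] <- mid[above]
      hi[!above] <- mid[!above]
    }
    res[gen] <- (lo + hi) / 2
  }
  out[todo] <- pmax(res, 0)
  out
}
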