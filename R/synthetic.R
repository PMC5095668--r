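#' Piecewise-constant hazard specification
#'
#' @param start Segment start times (hours), beginning at 0, increasing.
#' @param rate Nonnegative hazard rate (per hour) on each segment; the
#'   last segment extends to infinity.
#' @return A `pc_hazard` object.
#' @export
pc_hazard <- function(start, rate) {
  stopifnot(length(start) == length(rate), start[1] == 0,
            !is.unsorted(start, strictly = TRUE), all(rate >= 0))
  structure(list(start = start, rate = rate), class = "pc_hazard")
}

# cumulative hazard at times t (vectorized)
pc_cumhaz <- function(h, t) {
  ends <- c(h$start[-1], Inf)
  vapply(t, function(ti) {
    sum(h$rate * pmax(0, pmin(ti, ends) - h$start))
  }, numeric(1))
}

# draw n event times by inverting the cumulative hazard; Inf if the total
# hazard is exhausted (trailing zero rate)
pc_sample <- function(h, n) {
  u <- stats::rexp(n)
  ends <- c(h$start[-1], Inf)
  seg_h <- h$rate * (ends - h$start)          # hazard mass per segment
  cum0 <- c(0, cumsum(seg_h))[seq_along(h$start)]
  out <- rep(Inf, n)
  for (i in seq_along(h$start)) {
    sel <- u >= cum0[i] & u < cum0[i] + seg_h[i] & h$rate[i] > 0
    out[sel] <- h$start[i] + (u[sel] - cum0[i]) / h$rate[i]
  }
  out
}

#' Ground truth for synthetic single-cell data
#'
#' Defines everything needed to synthesize the pipeline's inputs: the
#' death process (either a [cell_population()] whose sampled cells die by
#' the threshold model, or an explicit piecewise-constant death hazard),
#' an independent piecewise-constant mitotic-exit hazard, the imaging
#' horizon, and the multiplicative measurement noise used for blot and
#' decay-series synthesis. The default exit hazard mimics the delayed
#' onset of slippage: no exits for the first 5 h in arrest, then a
#' constant 0.2/h.
#'
#' @param pop A [cell_population()] death process (or `NULL` when
#'   `death_hazard` is given).
#' @param death_hazard Optional [pc_hazard()] replacing the population
#'   death process (used for hazard-level validation).
#' @param exit_hazard A [pc_hazard()] for mitotic exit.
#' @param censor_time Imaging horizon (hours).
#' @param noise Log-scale SD of multiplicative measurement noise for
#'   blot/decay synthesis.
#' @param seed Integer seed; every generated artifact is a deterministic
#'   function of the ground truth and this seed.
#' @return A `ground_truth` object.
#' @export
ground_truth <- function(pop = NULL, death_hazard = NULL,
                         exit_hazard = pc_hazard(c(0, 5), c(0, 0.2)),
                         censor_time = 48, noise = 0.1, seed = 1) {
  if (is.null(pop) == is.null(death_hazard)) {
    stop("supply exactly one of pop or death_hazard")
  }
  stopifnot(inherits(exit_hazard, "pc_hazard"), censor_time > 0,
            noise >= 0)
  structure(list(pop = pop, death_hazard = death_hazard,
                 exit_hazard = exit_hazard, censor_time = censor_time,
                 noise = noise, seed = as.integer(seed)),
            class = "ground_truth")
}

#' Synthesize a single-cell fate table
#'
#' Per cell, a death time is drawn from the ground-truth death process and
#' an exit time independently from the exit hazard; the recorded fate is
#' whichever comes first, censored at the imaging horizon.
#'
#' @param gt A [ground_truth()].
#' @param n Number of cells.
#' @return A [fate_table()].
#' @export
generate_fates <- function(gt, n) {
  stopifnot(inherits(gt, "ground_truth"), n >= 1)
  set.seed(gt$seed + 1L)
  tdeath <- if (!is.null(gt$death_hazard)) {
    pc_sample(gt$death_hazard, n)
  } else {
    death_time(sample_cells(gt$pop, n))
  }
  texit <- pc_sample(gt$exit_hazard, n)
  t_ev <- pmin(tdeath, texit, gt$censor_time)
  fate <- ifelse(t_ev >= gt$censor_time, "censored",
                 ifelse(tdeath <= texit, "death", "exit"))
  t_ev <- pmin(t_ev, gt$censor_time)
  fate_table(cell_id = sprintf("cell%05d", seq_len(n)), entry_h = 0,
             fate = fate, fate_h = t_ev)
}

#' Synthesize replicate western-blot summaries
#'
#' Replicate measurements of the population medians of the Mcl-1/Bak,
#' Bcl-xL/Bak and Bak levels with multiplicative log-normal noise,
#' summarized as mean and SD per protein, mirroring small-N quantitative
#' blot summaries.
#'
#' @param gt A [ground_truth()] with a population death process.
#' @param replicates Number of replicate measurements (>= 2).
#' @return Data frame with columns `protein`, `mean`, `sd`, `n`.
#' @export
generate_blots <- function(gt, replicates = 3) {
  stopifnot(inherits(gt, "ground_truth"), replicates >= 2,
            !is.null(gt$pop))
  set.seed(gt$seed + 2L)
  truth <- c(mcl1_bak = exp(gt$pop$mu_m - gt$pop$mu_b),
             bclxl_bak = exp(gt$pop$mu_x - gt$pop$mu_b),
             bak = exp(gt$pop$mu_b))
  reps <- vapply(truth, function(v) {
    v * stats::rlnorm(replicates, 0, gt$noise)
  }, numeric(replicates))
  data.frame(protein = names(truth), mean = apply(reps, 2, mean),
             sd = apply(reps, 2, stats::sd), n = replicates,
             row.names = NULL)
}

#' Synthesize a protein decay time course
#'
#' Median relative levels `exp(-t / tau_M)` with multiplicative log-normal
#' measurement noise, as input for [fit_decay()].
#'
#' @param gt A [ground_truth()] with a population death process.
#' @param timepoints Sampling times (hours, >= 3 of them).
#' @return Data frame with columns `time_h`, `level`.
#' @export
generate_decay_series <- function(gt, timepoints) {
  stopifnot(inherits(gt, "ground_truth"), length(timepoints) >= 3,
            !is.null(gt$pop))
  set.seed(gt$seed + 3L)
  lev <- exp(-timepoints / gt$pop$tau_M) *
    stats::rlnorm(length(timepoints), 0, gt$noise)
  data.frame(time_h = timepoints, level = lev)
}
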