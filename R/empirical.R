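#' Single-cell fate table
#'
#' One record per imaged cell: when it entered mitotic arrest, what
#' happened to it (death in arrest, mitotic exit/slippage, or censoring at
#' the end of imaging), and when, measured from its own arrest entry.
#'
#' @param cell_id Unique identifiers.
#' @param entry_h Arrest entry time since drug addition (hours).
#' @param fate One of `"death"`, `"exit"`, `"censored"` per cell.
#' @param fate_h Time of the fate event since arrest entry (hours, >= 0);
#'   censored cells carry their last observed time.
#' @return A `fate_table` data frame.
#' @export
fate_table <- function(cell_id, entry_h = 0, fate, fate_h) {
  d <- data.frame(cell_id = cell_id, entry_h = entry_h, fate = fate,
                  fate_h = fate_h, stringsAsFactors = FALSE)
  if (nrow(d) == 0) stop("fate table must contain at least one cell")
  if (!all(d$fate %in% c("death", "exit", "censored"))) {
    stop("fate must be one of 'death', 'exit', 'censored'")
  }
  if (any(!is.finite(d$fate_h)) || any(d$fate_h < 0) ||
      any(!is.finite(d$entry_h)) || any(d$entry_h < 0)) {
    stop("entry_h and fate_h must be finite and >= 0")
  }
  class(d) <- c("fate_table", "data.frame")
  d
}

#' Read / write fate tables as tab-delimited text
#'
#' Columns: `cell_id`, `entry_h`, `fate`, `fate_h`. The reader validates
#' the fate vocabulary and nonnegativity.
#'
#' @param path File path.
#' @return `read_fate_table` returns a validated [fate_table()].
#' @export
read_fate_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "entry_h", "fate", "fate_h")
  if (!all(need %in% names(d))) {
    stop("fate table file must have columns ", paste(need, collapse = ", "))
  }
  fate_table(d$cell_id, d$entry_h, d$fate, d$fate_h)
}

#' @rdname read_fate_table
#' @param tab A [fate_table()].
#' @export
write_fate_table <- function(tab, path) {
  stopifnot(inherits(tab, "fate_table"))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Binned cause-specific hazard estimation
#'
#' Under the independent-hazards model, mitotic death and mitotic exit are
#' competing events with rates that may vary over time in arrest but do
#' not depend on each other. The cause-specific hazard of each event in a
#' bin is estimated as events / person-time at risk in the bin
#' (occurrence/exposure); a cell leaves the risk set at its fate time,
#' whatever the fate, so exposure accumulates only while a cell is alive
#' and in arrest. This is the maximum-likelihood rate of a
#' piecewise-constant hazard and, unlike dividing by the bin-start risk
#' count, is not biased downward when an appreciable fraction of the risk
#' set departs within one bin. Time is each cell's own time in arrest
#' (its `fate_h`).
#'
#' @param tab A [fate_table()].
#' @param binwidth Bin width (hours); ignored when `bins` is given.
#' @param bins Optional explicit bin edges (must start at 0 and cover all
#'   fate times).
#' @return A `hazard_estimate` data frame with columns `bin_start`,
#'   `bin_end`, `at_risk` (cells in arrest at bin start), `exposure`
#'   (person-hours at risk in the bin), `deaths`, `exits`,
#'   `death_hazard`, `exit_hazard` (per hour). Bins with zero exposure
#'   get `NA` hazards (a gap).
#' @export
estimate_hazards <- function(tab, binwidth = 1, bins = NULL) {
  stopifnot(inherits(tab, "fate_table"))
  tmax <- max(tab$fate_h)
  if (tmax <= 0) stop("degenerate fate table: no positive observation time")
  if (is.null(bins)) {
    bins <- seq(0, binwidth * ceiling(tmax / binwidth + 1e-9), by = binwidth)
  }
  if (bins[1] != 0 || max(bins) < tmax) {
    stop("bins must start at 0 and cover all observed fate times")
  }
  k <- length(bins) - 1
  idx <- findInterval(tab$fate_h, bins, rightmost.closed = TRUE)
  deaths <- tabulate(idx[tab$fate == "death"], nbins = k)
  exits <- tabulate(idx[tab$fate == "exit"], nbins = k)
  leaves <- tabulate(idx, nbins = k)
  at_risk <- nrow(tab) - c(0, cumsum(leaves))[1:k]
  exposure <- vapply(seq_len(k), function(j) {
    sum(pmax(0, pmin(tab$fate_h, bins[j + 1]) - bins[j]))
  }, numeric(1))
  dh <- ifelse(exposure > 0, deaths / exposure, NA_real_)
  eh <- ifelse(exposure > 0, exits / exposure, NA_real_)
  structure(data.frame(bin_start = bins[-length(bins)], bin_end = bins[-1],
                       at_risk = at_risk, exposure = exposure,
                       deaths = deaths, exits = exits,
                       death_hazard = dh, exit_hazard = eh),
            class = c("hazard_estimate", "data.frame"))
}

#' Exit-corrected mitotic survival curve
#'
#' The probability that a cell survives in mitotic arrest given that it
#' does not exit: `S(T) = exp(-sum of death_hazard x width over bins <= T)`.
#' Exits act as independent censoring of the death process. The attached
#' `se` column is the Poisson standard error
#' `S * sqrt(sum d_j / exposure_j^2)` of the cumulative hazard.
#'
#' @param h A [estimate_hazards()] result.
#' @return A `survival_curve` (time 0 prepended at fraction 1) with
#'   `source = "empirical_corrected"`; attribute `gap` flags undefined
#'   (empty-risk-set) bins, whose effect propagates as `NA`.
#' @export
corrected_survival <- function(h) {
  stopifnot(inherits(h, "hazard_estimate"))
  w <- h$bin_end - h$bin_start
  S <- exp(-cumsum(h$death_hazard * w))
  se <- S * sqrt(cumsum(ifelse(h$exposure > 0,
                               h$deaths / h$exposure^2, NA)))
  cv <- new_survival_curve(c(0, h$bin_end), c(1, S),
                           label = "corrected", source = "empirical_corrected",
                           n_effective = h$at_risk[1], se = c(0, se))
  attr(cv, "gap") <- anyNA(h$death_hazard)
  cv
}

#' Mitotic exit curve
#'
#' The cumulative probability that a cell has exited arrest given that it
#' stays alive: `E(T) = 1 - exp(-sum of exit_hazard x width over bins <= T)`.
#'
#' @param h A [estimate_hazards()] result.
#' @return A `survival_curve`-shaped data frame (`time_h`,
#'   `cum_exit_fraction`, `se`) with `source = "empirical_exit"`.
#' @export
exit_curve <- function(h) {
  stopifnot(inherits(h, "hazard_estimate"))
  w <- h$bin_end - h$bin_start
  G <- exp(-cumsum(h$exit_hazard * w))
  se <- G * sqrt(cumsum(ifelse(h$exposure > 0,
                               h$exits / h$exposure^2, NA)))
  d <- data.frame(time_h = c(0, h$bin_end), cum_exit_fraction = c(0, 1 - G),
                  se = c(0, se))
  attr(d, "source") <- "empirical_exit"
  attr(d, "gap") <- anyNA(h$exit_hazard)
  class(d) <- c("exit_curve", "data.frame")
  d
}

#' Raw (uncorrected) survival-in-arrest
#'
#' Fraction of cells still alive and in mitotic arrest at each time, i.e.
#' every departure (death or exit) counts against it. Correcting for the
#' competing exit process ([corrected_survival()]) can only raise the
#' death-only survival estimate, so the corrected curve dominates this one
#' pointwise whenever exits are present.
#'
#' @param tab A [fate_table()].
#' @param times Evaluation grid (hours), within the observation horizon.
#' @return A `survival_curve` with `source = "empirical_raw"`.
#' @export
raw_survival <- function(tab, times) {
  stopifnot(inherits(tab, "fate_table"))
  gone <- tab$fate_h[tab$fate != "censored"]
  frac <- vapply(times, function(T) 1 - sum(gone <= T) / nrow(tab),
                 numeric(1))
  new_survival_curve(times, frac, label = "raw", source = "empirical_raw",
                     n_effective = nrow(tab))
}

#' Read / write survival curves as tab-delimited text
#'
#' Columns: `time_h`, `surviving_fraction`, `condition`, `source`.
#'
#' @param path File path.
#' @return `read_survival_curve` returns a `survival_curve`.
#' @export
read_survival_curve <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("time_h", "surviving_fraction", "condition", "source")
  if (!all(need %in% names(d))) {
    stop("curve file must have columns ", paste(need, collapse = ", "))
  }
  if (any(d$surviving_fraction < 0 | d$surviving_fraction > 1, na.rm = TRUE)) {
    stop("surviving_fraction must lie in [0, 1]")
  }
  new_survival_curve(d$time_h, d$surviving_fraction,
                     label = d$condition[1], source = d$source[1])
}

#' @rdname read_survival_curve
#' @param curve A `survival_curve`.
#' @export
write_survival_curve <- function(curve, path) {
  stopifnot(inherits(curve, "survival_curve"))
  d <- data.frame(time_h = curve$time_h,
                  surviving_fraction = curve$surviving_fraction,
                  condition = attr(curve, "label"),
                  source = attr(curve, "source"))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
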