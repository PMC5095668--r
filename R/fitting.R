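#' Single-exponential decay fit
#'
#' Least-squares fit of `f(t) = A_0 * exp(-t / tau)` to a measured decay
#' series (e.g. quantitative blot time courses of Mcl-1 during arrest).
#' For fixed `tau` the amplitude has the closed-form profile
#' `A_0(tau) = sum(l e) / sum(e^2)`, so the fit reduces to a bounded 1-D
#' minimization over `log(tau)`, which is deterministic and cannot
#' diverge. Non-decaying data push `tau` to its upper bound, which is
#' reported with a warning.
#'
#' @param time Time points (>= 3).
#' @param level Measured levels (> 0).
#' @param tau_max Upper bound on the time constant; defaults to 50x the
#'   observation span.
#' @return List with `A_0`, `tau`, `half_life` (`tau * log(2)`), `rss`,
#'   `fitted`, and `at_bound`.
#' @export
fit_decay <- function(time, level, tau_max = NULL) {
  stopifnot(length(time) >= 3, length(level) == length(time),
            all(level > 0), all(is.finite(time)), all(is.finite(level)))
  span <- diff(range(time))
  stopifnot(span > 0)
  if (is.null(tau_max)) tau_max <- 50 * span
  tau_min <- span / 1e4
  prof <- function(logtau) {
    e <- exp(-time / exp(logtau))
    a0 <- sum(level * e) / sum(e^2)
    sum((level - a0 * e)^2)
  }
  opt <- stats::optimize(prof, c(log(tau_min), log(tau_max)), tol = 1e-10)
  at_bound <- opt$minimum > log(tau_max) - 1e-4
  tau <- if (at_bound) tau_max else exp(opt$minimum)
  if (at_bound) {
    warning("levels do not decay over the observed span; ",
            "tau fixed at its upper bound ", format(tau_max))
  }
  e <- exp(-time / tau)
  a0 <- sum(level * e) / sum(e^2)
  list(A_0 = a0, tau = tau, half_life = tau * log(2),
       rss = sum((level - a0 * e)^2), fitted = a0 * e, at_bound = at_bound)
}

# Free parameters of the survival fit, on the search scale (log for time
# constants; mu_* are already log-medians). theta_ref is fixed at 1: the
# survival model is exactly invariant under a joint rescaling of the M and
# X medians and the threshold, so the threshold sets the unit in which the
# protein ratios are expressed.
fit_par_names <- c("mu_m", "sigma_m", "mu_x", "sigma_x", "sigma_b",
                   "log_tau_M", "log_tau_X", "kd_m", "kd_x")

par_to_population <- function(par, condition = "control") {
  pop <- cell_population(mu_m = par[["mu_m"]], sigma_m = par[["sigma_m"]],
                         mu_x = par[["mu_x"]], sigma_x = par[["sigma_x"]],
                         mu_b = 0, sigma_b = par[["sigma_b"]],
                         tau_M = exp(par[["log_tau_M"]]),
                         tau_X = exp(par[["log_tau_X"]]), theta_ref = 1)
  if (condition == "mcl1kd") pop <- apply_knockdown(pop, "mcl1", par[["kd_m"]])
  if (condition == "bclxlkd") pop <- apply_knockdown(pop, "bclxl", par[["kd_x"]])
  pop
}

#' Assemble a constrained survival-curve fitting problem
#'
#' Bundles the target (exit-corrected) survival curves per condition with
#' the measurement-derived constraints. Western-blot summaries (mean, SD
#' of the relative Mcl-1 and Bcl-xL levels) become hard box bounds
#' `log(mean -/+ 2 SD)` on the log-medians, and the measured Mcl-1 decay
#' time constant becomes a box on `tau_M`. All conditions share every
#' parameter except the knockdown factor applying to the targeted protein.
#'
#' @param curves Named list of survival curves (data frames with `time_h`
#'   and `surviving_fraction`); names from `control`, `mcl1kd`, `bclxlkd`.
#' @param blots Data frame from [generate_blots()] (columns `protein`,
#'   `mean`, `sd`) or equivalent, with proteins `mcl1_bak` and
#'   `bclxl_bak` measured in threshold units.
#' @param tau_M_bounds Length-2 bounds on the Mcl-1 decay constant (hours),
#'   e.g. from [fit_decay()] of a measured time course.
#' @param tau_X_bounds,sigma_max,sigma_b_max,kd_bounds Remaining box
#'   bounds; defaults cover the plausible biological ranges (Bcl-xL decay
#'   constants of a few to tens of hours, up to ~20-fold protein
#'   variation, modest Bak variability, 5-50% residual after RNAi).
#' @param weights Optional named per-condition weights (default 1).
#' @return A `fit_problem` object.
#' @export
fit_problem <- function(curves, blots, tau_M_bounds,
                        tau_X_bounds = c(2, 40), sigma_max = 1.5,
                        sigma_b_max = 0.5, kd_bounds = c(0.05, 0.5),
                        weights = NULL) {
  stopifnot(is.list(curves), length(curves) >= 1,
            all(names(curves) %in% c("control", "mcl1kd", "bclxlkd")))
  get_blot <- function(protein) {
    i <- match(protein, blots$protein)
    if (is.na(i)) stop("blot summary missing protein ", protein)
    c(blots$mean[i], blots$sd[i])
  }
  mb <- get_blot("mcl1_bak"); xb <- get_blot("bclxl_bak")
  lo_mu <- function(b) log(max(b[1] - 2 * b[2], b[1] / 10))
  hi_mu <- function(b) log(b[1] + 2 * b[2])
  lower <- c(mu_m = lo_mu(mb), sigma_m = 0, mu_x = lo_mu(xb), sigma_x = 0,
             sigma_b = 0, log_tau_M = log(tau_M_bounds[1]),
             log_tau_X = log(tau_X_bounds[1]), kd_m = kd_bounds[1],
             kd_x = kd_bounds[1])
  upper <- c(mu_m = hi_mu(mb), sigma_m = sigma_max, mu_x = hi_mu(xb),
             sigma_x = sigma_max, sigma_b = sigma_b_max,
             log_tau_M = log(tau_M_bounds[2]),
             log_tau_X = log(tau_X_bounds[2]), kd_m = kd_bounds[2],
             kd_x = kd_bounds[2])
  if (any(lower > upper)) stop("configuration error: empty bound box")
  w <- rep(1, length(curves)); names(w) <- names(curves)
  if (!is.null(weights)) w[names(weights)] <- weights
  structure(list(curves = curves, lower = lower, upper = upper,
                 weights = w), class = "fit_problem")
}

#' Sum-of-squares objective of a survival fit
#'
#' Deterministic residual: model curves are computed by log-normal
#' quadrature ([survival_curve_quadrature()]), never Monte Carlo, so the
#' pattern search sees a noise-free surface. Quadrature failure returns a
#' large penalty value flagged with attribute `failed`.
#'
#' @param par Named parameter vector (see `fit_problem` bounds for names
#'   and scales).
#' @param problem A [fit_problem()].
#' @param nodes Quadrature nodes per dimension.
#' @return The weighted sum of squared survival-fraction residuals.
#' @export
survival_objective <- function(par, problem, nodes = 32) {
  sse <- 0
  for (cond in names(problem$curves)) {
    dat <- problem$curves[[cond]]
    mod <- tryCatch(
      survival_curve_quadrature(par_to_population(par, cond),
                                dat$time_h, nodes = nodes),
      error = function(e) NULL)
    if (is.null(mod) || anyNA(mod$surviving_fraction)) {
      return(structure(1e6, failed = TRUE))
    }
    sse <- sse + problem$weights[[cond]] *
      sum((mod$surviving_fraction - dat$surviving_fraction)^2)
  }
  sse
}

# Hooke-Jeeves pattern search on the box [lower, upper]: greedy coordinate
# exploration around the base point plus accelerating pattern moves along
# the direction of recent progress, with step halving on failure. Steps
# are the fraction `step` of each coordinate's box width. Accepted bases
# never increase the objective.
pattern_search <- function(fn, x0, lower, upper, step = 0.25,
                           step_tol = 1e-3, maxit = 500) {
  width <- upper - lower
  width[width == 0] <- 1
  evals <- 0L
  fwrap <- function(x) {
    evals <<- evals + 1L
    fn(x)
  }
  explore <- function(x, fx, s) {
    for (j in seq_along(x)) {
      for (sg in c(1, -1)) {
        cand <- x
        cand[j] <- min(max(x[j] + sg * s * width[j], lower[j]), upper[j])
        if (cand[j] == x[j]) next
        fc <- fwrap(cand)
        if (fc < fx) {
          x <- cand
          fx <- fc
          break
        }
      }
    }
    list(x = x, f = fx)
  }
  b <- pmin(pmax(x0, lower), upper)
  fb <- fwrap(b)
  trace <- data.frame(iteration = 0L, sse = fb, step = step)
  for (it in seq_len(maxit)) {
    if (step < step_tol) break
    ex <- explore(b, fb, step)
    if (ex$f < fb) {
      # pattern move: extrapolate along the successful direction
      repeat {
        p <- pmin(pmax(ex$x + (ex$x - b), lower), upper)
        b <- ex$x
        fb <- ex$f
        fp <- fwrap(p)
        ex <- explore(p, fp, step)
        if (ex$f >= fb) break
      }
    } else {
      step <- step / 2
    }
    trace <- rbind(trace,
                   data.frame(iteration = it, sse = fb, step = step))
  }
  list(par = b, value = fb, trace = trace, evals = evals)
}

#' Two-stage constrained least-squares survival fit
#'
#' Stage 1 draws `n_random` parameter vectors uniformly on the search
#' scale (log-uniform medians and time constants) inside the constraint
#' box and scores them; stage 2 runs a Hooke-Jeeves pattern search
#' (initial step 0.25 of each coordinate's box width, accelerating
#' pattern moves, step halving, termination at step fraction < `step_tol`
#' or `maxit` base iterations) from each of the `n_starts` best points.
#'
#' @param problem A [fit_problem()].
#' @param n_random Stage-1 sample size (>= `n_starts`).
#' @param n_starts Number of local searches.
#' @param seed Integer seed; the whole procedure is deterministic given it.
#' @param nodes Quadrature nodes for the objective.
#' @param maxit,step_tol Pattern-search controls.
#' @return A `fit_result`: `parameters` (named vector on the search
#'   scale), `population` (best-fit control [cell_population()]),
#'   `knockdown` (fitted factors), `sse`, `restarts` (per-start table),
#'   and `trace` of the winning search.
#' @export
fit_survival <- function(problem, n_random = 2000, n_starts = 10,
                         seed = NULL, nodes = 32, maxit = 500,
                         step_tol = 1e-3) {
  stopifnot(inherits(problem, "fit_problem"), n_random >= n_starts,
            n_starts >= 1)
  if (!is.null(seed)) set.seed(seed)
  lower <- problem$lower; upper <- problem$upper
  d <- length(lower)
  draws <- matrix(stats::runif(n_random * d), ncol = d)
  draws <- sweep(sweep(draws, 2, upper - lower, "*"), 2, lower, "+")
  colnames(draws) <- names(lower)
  sse1 <- apply(draws, 1, function(p) survival_objective(p, problem, nodes))
  ord <- order(sse1)[seq_len(n_starts)]
  best <- NULL
  restarts <- data.frame()
  for (i in ord) {
    res <- pattern_search(function(p) survival_objective(p, problem, nodes),
                          draws[i, ], lower, upper, maxit = maxit,
                          step_tol = step_tol)
    restarts <- rbind(restarts,
                      data.frame(start_sse = sse1[i], final_sse = res$value,
                                 iterations = max(res$trace$iteration),
                                 evals = res$evals))
    if (is.null(best) || res$value < best$value) best <- res
  }
  structure(list(parameters = best$par,
                 population = par_to_population(best$par),
                 knockdown = c(mcl1 = unname(best$par[["kd_m"]]),
                               bclxl = unname(best$par[["kd_x"]])),
                 sse = best$value, restarts = restarts,
                 trace = best$trace),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("constrained survival fit: sse =", format(x$sse), "over",
      nrow(x$restarts), "restarts\n")
  print(round(x$parameters, 4))
  invisible(x)
}

#' Read a fitting problem from a YAML configuration
#'
#' The configuration names the per-condition curve files (tab-delimited,
#' as written by [write_survival_curve()]), the blot-summary file
#' (tab-delimited: `protein`, `mean`, `sd`), the Mcl-1 decay-constant
#' bounds, and optionally any of the remaining bound settings of
#' [fit_problem()]. Relative paths are resolved against the
#' configuration file's directory.
#'
#' @param path YAML file path.
#' @return A [fit_problem()].
#' @export
read_fit_problem <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(path)
  resolve <- function(f) {
    if (file.exists(f)) f else file.path(base, f)
  }
  stopifnot(!is.null(cfg$curves), !is.null(cfg$blots),
            !is.null(cfg$tau_M_bounds))
  curves <- lapply(cfg$curves, function(f) read_survival_curve(resolve(f)))
  blots <- utils::read.delim(resolve(cfg$blots))
  extra <- cfg[intersect(names(cfg),
                         c("tau_X_bounds", "sigma_max", "sigma_b_max",
                           "kd_bounds", "weights"))]
  do.call(fit_problem,
          c(list(curves = curves, blots = blots,
                 tau_M_bounds = unlist(cfg$tau_M_bounds)),
            lapply(extra, unlist)))
}

#' Export a fit result as structured text
#'
#' Writes `parameters.tsv` (one row per parameter, search scale and
#' natural scale) and `restarts.tsv` (the ranked per-start outcomes)
#' into a directory.
#'
#' @param fit A `fit_result`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_fit_result <- function(fit, dir) {
  stopifnot(inherits(fit, "fit_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nat <- fit$parameters
  nat[c("log_tau_M", "log_tau_X")] <- exp(nat[c("log_tau_M", "log_tau_X")])
  pd <- data.frame(parameter = names(fit$parameters),
                   search_scale = unname(fit$parameters),
                   natural_scale = unname(nat))
  utils::write.table(pd, file.path(dir, "parameters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rs <- fit$restarts[order(fit$restarts$final_sse), ]
  utils::write.table(cbind(rank = seq_len(nrow(rs)), rs, sse = fit$sse),
                     file.path(dir, "restarts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
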