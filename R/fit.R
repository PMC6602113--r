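#' Root-mean-squared deviation between two traces
#'
#' @param model_trace,data_trace [opf_trace] objects on the same time grid
#'   (the model trace is evaluated on the data grid by the solver).
#' @return RMSD of the O2 columns (uM).
#' @export
rmsd <- function(model_trace, data_trace) {
  stopifnot(inherits(model_trace, "opf_trace"),
            inherits(data_trace, "opf_trace"))
  if (nrow(model_trace) != nrow(data_trace) ||
      max(abs(model_trace$time_s - data_trace$time_s)) > 1e-8)
    stop("traces are not on a shared time grid", call. = FALSE)
  sqrt(mean((model_trace$o2_uM - data_trace$o2_uM)^2))
}

# Seeded differential-evolution minimiser (DE/rand/1/bin) with box bounds.
# Derivative-free global search; the caller seeds the RNG.  A length-2
# f_weight gives per-generation dithering of the differential weight,
# which helps escape deceptive basins.
de_minimise <- function(fn, lower, upper, pop = 24, maxgen = 150,
                        f_weight = c(0.5, 1.0), cr = 0.9, reltol = 1e-8,
                        patience = 50, max_eval = 20000) {
  d <- length(lower)
  x <- matrix(stats::runif(pop * d, lower, upper), nrow = pop, byrow = TRUE)
  val <- apply(x, 1, fn)
  n_eval <- pop
  best_hist <- min(val)
  stall <- 0L
  for (g in seq_len(maxgen)) {
    if (n_eval >= max_eval) break
    fw <- if (length(f_weight) == 2)
      stats::runif(1, f_weight[1], f_weight[2]) else f_weight
    idx <- seq_len(pop)
    for (i in idx) {
      abc <- sample(idx[-i], 3)
      donor <- x[abc[1], ] + fw * (x[abc[2], ] - x[abc[3], ])
      donor <- pmin(pmax(donor, lower), upper)
      cross <- stats::runif(d) < cr
      cross[sample.int(d, 1)] <- TRUE
      trial <- ifelse(cross, donor, x[i, ])
      v <- fn(trial)
      n_eval <- n_eval + 1L
      if (v <= val[i]) { x[i, ] <- trial; val[i] <- v }
    }
    new_best <- min(val)
    if (best_hist - new_best <= reltol * (abs(best_hist) + 1e-300))
      stall <- stall + 1L else stall <- 0L
    best_hist <- new_best
    if (stall >= patience) break
  }
  i <- which.min(val)
  list(par = x[i, ], value = val[i], n_eval = n_eval,
       converged = stall >= patience || n_eval < max_eval)
}

# Sum of squared O2 deviations between model and data over an experiment
# set, after the baseline cut; also returns per-experiment RMSD.  Solver
# console chatter from pathological parameter vectors is swallowed; such
# vectors simply get an infinite objective.
fit_objective <- function(experiments, k, baseline_s = 100,
                          rtol = 1e-8, atol = 1e-10) {
  sq <- 0; per_rmsd <- numeric(length(experiments))
  for (i in seq_along(experiments)) {
    ex <- experiments[[i]]
    utils::capture.output(
      r <- try(suppressWarnings({
        traj <- opf_simulate(ex$conditions, k, times = ex$trace$time_s,
                             rtol = rtol, atol = atol)
        m <- strip_baseline(trajectory_trace(traj), baseline_s)
        d <- strip_baseline(ex$trace, baseline_s)
        if (nrow(m) != nrow(d)) stop("truncated model trajectory")
        m$o2_uM - d$o2_uM
      }), silent = TRUE))
    if (inherits(r, "try-error") || any(!is.finite(r)))
      return(list(ssq = Inf, rmsd = NULL))
    sq <- sq + sum(r^2)
    per_rmsd[i] <- sqrt(mean(r^2))
  }
  list(ssq = sq, rmsd = per_rmsd)
}

#' Fit the free rate constants to oxygen-consumption experiments
#'
#' The global fitting protocol: the free constants (by default `kox`,
#' `ka1`, `ka2` and `kg`; `k1`, `kdtt`, `kdiff` and `o2_sat` are
#' experimentally calibrated and stay fixed) are estimated by minimising
#' the unweighted sum of squared O2 deviations over all experiments, after
#' the 100-s baseline cut.  The search is a seeded, derivative-free
#' differential evolution in log10-parameter space within
#' `[1e-8, 1e3]` per constant, followed by a Nelder-Mead polish.  The whole
#' search is repeated `n_repeats` times from independent seeded random
#' starts (repeat r uses `seed + r`); results are ranked ascending by
#' average per-experiment RMSD and the repeat-to-repeat spread of each
#' constant is reported -- a constant the data do not constrain shows a
#' wide spread.
#'
#' @param experiments an [opf_experiments] set (traces plus conditions).
#' @param constants starting/fixed constants, an [opf_constants]; its fixed
#'   mask decides what is fitted.
#' @param n_repeats number of independent repeats of the fit.
#' @param seed master seed; repeat r uses `seed + r`.
#' @param baseline_s baseline cut applied before comparison (s).
#' @param control list overriding search settings: `pop`, `maxgen`,
#'   `f_weight`, `cr`, `reltol`, `patience`, `max_eval`, `polish` (logical),
#'   `log_bounds` (length-2).
#' @return An object of class `opf_fit`.  `coef()` returns the rank-1
#'   constants, `summary()` the per-constant spread across repeats,
#'   `predict()` model traces, `residuals()` per-experiment residuals,
#'   `plot()` an overlay of data and fit, and `simulate()` noisy synthetic
#'   traces from the fitted model.
#' @export
opf_fit <- function(experiments, constants = opf_constants(),
                    n_repeats = 10, seed = 1, baseline_s = 100,
                    control = list()) {
  stopifnot(inherits(experiments, "opf_experiments"))
  constants <- as_opf_constants(constants)
  free <- free_names(constants)
  if (!length(free)) stop("no free constants to fit", call. = FALSE)
  ctl <- utils::modifyList(list(pop = 24, maxgen = 150,
                                f_weight = c(0.5, 1.0),
                                cr = 0.9, reltol = 1e-8, patience = 50,
                                max_eval = 20000, polish = TRUE,
                                nm_maxit = 600,
                                log_bounds = c(-8, 3),
                                search_rtol = 1e-6, search_atol = 1e-8),
                           control)
  lower <- rep(ctl$log_bounds[1], length(free))
  upper <- rep(ctl$log_bounds[2], length(free))
  # search with a slightly relaxed solver tolerance for speed; every
  # reported RMSD is re-evaluated at the tight default tolerance below
  obj <- function(theta) {
    k <- constants
    k[free] <- 10^theta
    fit_objective(experiments, k, baseline_s,
                  rtol = ctl$search_rtol, atol = ctl$search_atol)$ssq
  }
  results <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    res <- with_seed(seed + r, {
      de <- de_minimise(obj, lower, upper, pop = ctl$pop,
                        maxgen = ctl$maxgen, f_weight = ctl$f_weight,
                        cr = ctl$cr, reltol = ctl$reltol,
                        patience = ctl$patience, max_eval = ctl$max_eval)
      if (isTRUE(ctl$polish)) {
        pen <- function(theta) {
          if (any(theta < lower) || any(theta > upper)) return(Inf)
          obj(theta)
        }
        # two Nelder-Mead rounds: the restart re-inflates the simplex and
        # escapes premature collapse along flat directions
        for (round in 1:2) {
          nm <- stats::optim(de$par, pen, method = "Nelder-Mead",
                             control = list(maxit = ctl$nm_maxit,
                                            reltol = 1e-12))
          de$n_eval <- de$n_eval + nm$counts[["function"]]
          if (nm$value < de$value) {
            de$par <- nm$par; de$value <- nm$value
          }
        }
      }
      de
    })
    k_fit <- constants
    k_fit[free] <- 10^res$par
    ob <- fit_objective(experiments, k_fit, baseline_s)
    avg <- if (is.null(ob$rmsd)) NA_real_ else mean(ob$rmsd)
    results[[r]] <- list(constants = k_fit, per_rmsd = ob$rmsd,
                         avg_rmsd = avg, ssq = ob$ssq,
                         repeat_index = r, seed = seed + r,
                         converged = res$converged, n_eval = res$n_eval)
  }
  ok <- vapply(results, function(x) is.finite(x$avg_rmsd), logical(1))
  if (!any(ok))
    stop("no fitting repeat converged", call. = FALSE)
  ord <- order(vapply(results, `[[`, numeric(1), "avg_rmsd"),
               vapply(results, `[[`, numeric(1), "repeat_index"))
  results <- results[ord]
  par_mat <- t(vapply(results, function(x) unclass(x$constants)[free],
                      numeric(length(free))))
  colnames(par_mat) <- free
  spread <- data.frame(
    constant = free,
    best = par_mat[1, ],
    median = apply(par_mat, 2, stats::median),
    min = apply(par_mat, 2, min),
    max = apply(par_mat, 2, max),
    cv = apply(par_mat, 2, function(v) stats::sd(v) / mean(v)),
    row.names = NULL)
  structure(list(results = results, spread = spread, free = free,
                 experiments = experiments, baseline_s = baseline_s,
                 seed = seed, control = ctl, par_matrix = par_mat),
            class = "opf_fit")
}

#' @export
coef.opf_fit <- function(object, ...) object$results[[1]]$constants

#' @export
print.opf_fit <- function(x, ...) {
  best <- x$results[[1]]
  cat(sprintf(
    "Repeated fit of the oxidative folding model: %d repeats, %d experiments\n",
    length(x$results), length(x$experiments)))
  cat(sprintf("Best repeat (#%d): average RMSD %.4g uM\n",
              best$repeat_index, best$avg_rmsd))
  for (nm in x$free)
    cat(sprintf("  %-4s = %.4g 1/(uM s)\n", nm, best$constants[[nm]]))
  invisible(x)
}

#' @export
summary.opf_fit <- function(object, ...) {
  rmsds <- vapply(object$results, `[[`, numeric(1), "avg_rmsd")
  out <- list(spread = object$spread, avg_rmsd = rmsds,
              n_repeats = length(object$results))
  class(out) <- "summary.opf_fit"
  out
}

#' @export
print.summary.opf_fit <- function(x, ...) {
  cat(sprintf("Fit ensemble: %d repeats, average RMSD %.4g-%.4g uM\n",
              x$n_repeats, min(x$avg_rmsd), max(x$avg_rmsd)))
  cat("Per-constant spread across repeats (wide cv => unidentifiable):\n")
  print(x$spread, digits = 4)
  invisible(x)
}

#' @export
predict.opf_fit <- function(object, conditions = NULL, ...) {
  k <- coef(object)
  if (inherits(conditions, "opf_conditions"))
    return(trajectory_trace(opf_simulate(conditions, k)))
  lapply(object$experiments, function(ex)
    trajectory_trace(opf_simulate(ex$conditions, k,
                                  times = ex$trace$time_s)))
}

#' @export
residuals.opf_fit <- function(object, ...) {
  k <- coef(object)
  lapply(object$experiments, function(ex) {
    m <- strip_baseline(
      trajectory_trace(opf_simulate(ex$conditions, k,
                                    times = ex$trace$time_s)),
      object$baseline_s)
    d <- strip_baseline(ex$trace, object$baseline_s)
    data.frame(time_s = d$time_s, residual_uM = d$o2_uM - m$o2_uM)
  })
}

#' @export
plot.opf_fit <- function(x, ...) {
  preds <- predict(x)
  xr <- range(unlist(lapply(x$experiments, function(e) e$trace$time_s)))
  yr <- range(unlist(lapply(x$experiments, function(e) e$trace$o2_uM)))
  graphics::plot(NA, xlim = xr, ylim = yr, xlab = "time (s)",
                 ylab = "O2 (uM)",
                 main = "O2 consumption: data (points) vs fit (lines)", ...)
  for (i in seq_along(x$experiments)) {
    tr <- x$experiments[[i]]$trace
    graphics::points(tr$time_s, tr$o2_uM, col = i, pch = 20, cex = 0.3)
    graphics::lines(preds[[i]]$time_s, preds[[i]]$o2_uM, col = i, lwd = 2)
  }
  invisible(x)
}

#' @export
simulate.opf_fit <- function(object, nsim = 1, seed = NULL,
                             noise = noise_spec(), ...) {
  k <- coef(object)
  with_seed(seed, {
    replicate(nsim, simplify = FALSE,
      lapply(object$experiments, function(ex) {
        ns <- noise; ns$seed <- NULL
        generate_trace(k, ex$conditions, ns)
      }))
  })
}

#' Fit-report table of a fit ensemble
#'
#' Constants-by-repeat table with per-experiment and average RMSD columns,
#' in rank order (rank 1 = lowest average RMSD).
#'
#' @param fit an [opf_fit] object.
#' @return A data.frame, one row per repeat.
#' @export
fit_report <- function(fit) {
  stopifnot(inherits(fit, "opf_fit"))
  rows <- lapply(seq_along(fit$results), function(i) {
    res <- fit$results[[i]]
    k <- as.list(unclass(res$constants))
    per <- stats::setNames(as.list(res$per_rmsd),
                           sprintf("rmsd_exp%d", seq_along(res$per_rmsd)))
    c(list(rank = i, repeat_index = res$repeat_index, seed = res$seed,
           converged = res$converged), k, per,
      list(avg_rmsd = res$avg_rmsd))
  })
  do.call(rbind, lapply(rows, as.data.frame))
}
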