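#' Calibrate electrode-cell oxygen exchange from a recovery trace
#'
#' The open Clarke cell exchanges O2 with the environment.  After chemical
#' depletion of O2 (sodium dithionite), the recovery of the reading follows
#' `O2(t) = O2_sat * (1 - exp(-kdiff * t))`; a least-squares fit of that
#' curve yields the first-order exchange rate `kdiff` and the saturation
#' level `O2_sat`.
#'
#' @param recovery_trace an [opf_trace] starting near 0 uM and rising.
#' @return An object of class `opf_diffusion_fit` with elements `kdiff`
#'   (1/s), `o2_sat` (uM) and the underlying `nls` fit.
#' @examples
#' tr <- generate_trace(opf_constants(), recovery_conditions(duration = 600),
#'                      noise_spec(sd = 0))
#' coef(calibrate_diffusion(tr))
#' @export
calibrate_diffusion <- function(recovery_trace) {
  stopifnot(inherits(recovery_trace, "opf_trace"))
  t <- recovery_trace$time_s; o2 <- recovery_trace$o2_uM
  rise <- o2[length(o2)] - o2[1]
  slope0 <- stats::coef(stats::lm(o2 ~ t))[["t"]]
  if (rise <= 0 || slope0 <= 0 ||
      rise < 0.05 * max(abs(o2), 1))
    stop("no recovery signal: trace is flat or falling", call. = FALSE)
  sat0 <- max(o2) * 1.05
  kd0 <- max(slope0 / sat0, 1e-6)
  fit <- minpack.lm::nlsLM(o2 ~ sat * (1 - exp(-kd * t)),
                           start = list(sat = sat0, kd = kd0),
                           lower = c(0, 0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  structure(list(kdiff = cf[["kd"]], o2_sat = cf[["sat"]], fit = fit),
            class = "opf_diffusion_fit")
}

#' @export
coef.opf_diffusion_fit <- function(object, ...)
  c(kdiff = object$kdiff, o2_sat = object$o2_sat)

#' @export
print.opf_diffusion_fit <- function(x, ...) {
  cat(sprintf(
    "Electrode O2 exchange: kdiff = %.4g 1/s, O2_sat = %.4g uM (RSE %.3g uM)\n",
    x$kdiff, x$o2_sat, summary(x$fit)$sigma))
  invisible(x)
}

#' Calibrate the Ero1p/O2 and DTT rate constants from Pdi1p-free assays
#'
#' DTT-driven assays contain only Ero1p and DTT -- no Pdi1p, no GSH -- so
#' the observed O2 consumption is governed by just two constants: `kdtt`
#' (DTT reduction of any Ero1p disulfide) and `k1` (the terminal reaction of
#' reduced Ero1p with O2).  Both are estimated by joint least squares over a
#' DTT titration series; these experimentally determined values are then
#' held fixed in the global fit.
#'
#' @param dtt_experiments an [opf_experiments] set of DTT assays.
#' @param constants template [opf_constants] supplying the remaining
#'   (inert, since Pdi1p and GSH are absent) constants and the start point.
#' @param baseline_s baseline cut before comparison (s).
#' @return An object of class `opf_dtt_fit` with elements `k1`, `kdtt`,
#'   `per_rmsd`, `avg_rmsd`.
#' @export
calibrate_ero1_dtt <- function(dtt_experiments, constants = opf_constants(),
                               baseline_s = 100) {
  stopifnot(inherits(dtt_experiments, "opf_experiments"))
  constants <- as_opf_constants(constants)
  has_enzymes <- vapply(dtt_experiments, function(ex)
    conditions_total(ex$conditions, "pdi") > 0 ||
      ex$conditions$init[["GSH"]] > 0 ||
      any(ex$conditions$injections$species %in%
            c("GSH", "PDI_ox", "PDI_mix", "PDI_red")), logical(1))
  if (any(has_enzymes))
    stop("DTT calibration experiments must contain Ero1p and DTT only",
         call. = FALSE)
  dtt_tot <- vapply(dtt_experiments, function(ex)
    ex$conditions$init[["DTT_red"]] +
      sum(ex$conditions$injections$amount_uM[
        ex$conditions$injections$species == "DTT_red"]), numeric(1))
  if (all(dtt_tot == 0))
    stop("no signal: DTT absent in all experiments", call. = FALSE)
  obj <- function(theta) {
    k <- constants
    k[c("k1", "kdtt")] <- 10^theta
    fit_objective(dtt_experiments, k, baseline_s)$ssq
  }
  start <- log10(c(constants[["k1"]], constants[["kdtt"]]))
  nm <- stats::optim(start, obj, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-12))
  # restart once from the optimum to escape a premature simplex collapse
  nm2 <- stats::optim(nm$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  if (nm2$value < nm$value) nm <- nm2
  k_fit <- constants
  k_fit[c("k1", "kdtt")] <- 10^nm$par
  ob <- fit_objective(dtt_experiments, k_fit, baseline_s)
  structure(list(k1 = k_fit[["k1"]], kdtt = k_fit[["kdtt"]],
                 constants = k_fit, per_rmsd = ob$rmsd,
                 avg_rmsd = mean(ob$rmsd), ssq = ob$ssq,
                 convergence = nm$convergence),
            class = "opf_dtt_fit")
}

#' @export
coef.opf_dtt_fit <- function(object, ...)
  c(k1 = object$k1, kdtt = object$kdtt)

#' @export
print.opf_dtt_fit <- function(x, ...) {
  cat(sprintf(
    "DTT-branch calibration: k1 = %.4g, kdtt = %.4g 1/(uM s); avg RMSD %.4g uM\n",
    x$k1, x$kdtt, x$avg_rmsd))
  invisible(x)
}
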