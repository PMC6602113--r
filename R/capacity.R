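#' Cell-level parameters of the in vivo capacity calculus
#'
#' Copy numbers, ER volume, growth and the per-molecule oxidation rate used
#' to translate the in vitro kinetics into whole-cell supply and demand.
#' Defaults: 28,000 Pdi1p and 5,200 Ero1p molecules per cell, an ER volume
#' of 0.3 um^3 (midpoint of the 0.2-0.4 um^3 range -- the one volume that
#' reproduces the 155/29 uM concentrations), a 120-min doubling time, and
#' ~15 disulfide bonds formed per minute per Pdi1p molecule at saturation.
#'
#' @param pdi_copies,ero_copies molecules per cell.
#' @param er_volume_um3 ER volume (um^3).
#' @param doubling_time_min culture doubling time (min).
#' @param per_pdi_rate disulfide bonds per minute per Pdi1p molecule.
#' @export
cell_parameters <- function(pdi_copies = 28000, ero_copies = 5200,
                            er_volume_um3 = 0.3, doubling_time_min = 120,
                            per_pdi_rate = 15) {
  vals <- c(pdi_copies, ero_copies, er_volume_um3, doubling_time_min,
            per_pdi_rate)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all cell parameters must be finite and > 0", call. = FALSE)
  structure(list(pdi_copies = pdi_copies, ero_copies = ero_copies,
                 er_volume_um3 = er_volume_um3,
                 doubling_time_min = doubling_time_min,
                 per_pdi_rate = per_pdi_rate), class = "opf_cell")
}

AVOGADRO <- 6.02214076e23

#' Convert a molecule count in a compartment volume to a concentration
#'
#' @param n molecules (>= 0).
#' @param v_um3 compartment volume (um^3, > 0).
#' @return Concentration in uM.
#' @examples
#' round(molecules_to_concentration(28000, 0.3))  # 155
#' round(molecules_to_concentration(5200, 0.3))   # 29
#' @export
molecules_to_concentration <- function(n, v_um3) {
  if (any(v_um3 <= 0)) stop("volume must be > 0", call. = FALSE)
  if (any(n < 0)) stop("molecule count must be >= 0", call. = FALSE)
  n / (AVOGADRO * v_um3 * 1e-15) * 1e6
}

# Accept either a degradation-rate or a half-life column.
proteome_deg_rate <- function(proteome) {
  if ("deg_rate_per_min" %in% names(proteome))
    return(proteome$deg_rate_per_min)
  if ("half_life_min" %in% names(proteome))
    return(log(2) / proteome$half_life_min)
  stop("proteome table needs `deg_rate_per_min` or `half_life_min`",
       call. = FALSE)
}

#' Proteome-wide disulfide-bond demand
#'
#' The maximum number of disulfide bonds the cell needs to form per minute
#' to keep pace with protein turnover and growth dilution:
#' \deqn{k_{Cys} = \sum_i A_i \lfloor Cys_i / 2 \rfloor (k_i + \ln 2 / t_d)}
#' where \eqn{A_i} is the abundance of protein i (molecules/cell),
#' \eqn{Cys_i} its cysteine count (only even numbers of cysteines can be
#' oxidized, hence the floor), \eqn{k_i} its degradation rate (1/min) and
#' \eqn{t_d} the doubling time (min).  An upper limit: it assumes every
#' cysteine pair of every ER-routed protein becomes a catalysed disulfide.
#'
#' @param proteome data.frame with columns `abundance`, `n_cys` and one of
#'   `deg_rate_per_min` / `half_life_min` (converted via ln 2).
#' @param t_d doubling time (min).
#' @return List with `total` (bonds/min/cell) and per-protein
#'   `contributions`.
#' @examples
#' k_cys(data.frame(abundance = 1, n_cys = 3, deg_rate_per_min = 0),
#'       t_d = 120)$total  # ln(2)/120
#' @export
k_cys <- function(proteome, t_d = 120) {
  if (t_d <= 0) stop("doubling time must be > 0", call. = FALSE)
  stopifnot(all(c("abundance", "n_cys") %in% names(proteome)))
  if (any(proteome$abundance < 0))
    stop("abundances must be >= 0", call. = FALSE)
  if (any(proteome$n_cys < 0) || any(proteome$n_cys %% 1 != 0))
    stop("cysteine counts must be non-negative integers", call. = FALSE)
  ki <- proteome_deg_rate(proteome)
  if (any(ki < 0)) stop("degradation rates must be >= 0", call. = FALSE)
  contrib <- proteome$abundance * floor(proteome$n_cys / 2) *
    (ki + log(2) / t_d)
  list(total = sum(contrib), contributions = contrib)
}

#' Whole-cell Pdi1p oxidation capacity
#'
#' Supply side of the calculus: copies times the saturating per-molecule
#' rate.  Also reported rounded to one significant figure, the precision at
#' which such an estimate is honest.
#'
#' @param cell a [cell_parameters()] object.
#' @return List with `total` (bonds/min/cell) and `rounded` (1 significant
#'   figure).
#' @export
pdi_capacity <- function(cell = cell_parameters()) {
  stopifnot(inherits(cell, "opf_cell"))
  total <- cell$pdi_copies * cell$per_pdi_rate
  list(total = total, rounded = signif(total, 1))
}

#' Supply-versus-demand report for oxidative folding
#'
#' @param proteome proteome table, see [k_cys()].
#' @param cell a [cell_parameters()] object.
#' @return An object of class `opf_capacity_report` with demand, supply,
#'   their ratio and per-protein demand contributions.
#' @export
capacity_report <- function(proteome, cell = cell_parameters()) {
  demand <- k_cys(proteome, cell$doubling_time_min)
  supply <- pdi_capacity(cell)
  structure(list(demand = demand$total, supply = supply$total,
                 supply_rounded = supply$rounded,
                 ratio = supply$total / demand$total,
                 contributions = demand$contributions, cell = cell),
            class = "opf_capacity_report")
}

#' @export
print.opf_capacity_report <- function(x, ...) {
  cat("Oxidative folding capacity vs demand (per cell)\n")
  cat(sprintf("  demand  (k_Cys): %.4g disulfide bonds/min\n", x$demand))
  cat(sprintf("  supply (Pdi1p) : %.4g bonds/min (~%g)\n",
              x$supply, x$supply_rounded))
  cat(sprintf("  supply:demand  : %.3g\n", x$ratio))
  invisible(x)
}

#' Predicted capacity gain on Pdi1p or Ero1p overexpression
#'
#' For each fold f, the scanned protein's total (initial plus injected) is
#' scaled by f, the assay is simulated, and the capacity is read off as the
#' maximum windowed O2-consumption rate (one O2 consumed corresponds to one
#' disulfide formed, the two-electron reduction of O2 to H2O2).  The curve
#' is normalised to fold 1.
#'
#' @param k an [opf_constants] object.
#' @param base_conditions baseline assay; default is the in vitro reference
#'   condition of 5 uM Pdi1p / 1 uM Ero1p (injected at 100 s) / 40 mM GSH.
#' @param folds fold-overexpression grid (>= 0); fold 1 is always included.
#' @param scan `"pdi"` or `"ero"`.
#' @param window_s,baseline_s rate-extraction settings.
#' @return An object of class `opf_oxcurve`: data.frame with `fold`,
#'   `capacity_uM_s`, `fold_change` (exactly 1 at fold 1).
#' @export
predict_overexpression <- function(k = opf_constants(),
                                   base_conditions =
                                     gsh_assay_conditions(pdi = 5),
                                   folds = c(1, 2, 5, 10),
                                   scan = c("pdi", "ero"),
                                   window_s = 10, baseline_s = 100) {
  scan <- match.arg(scan)
  if (any(folds < 0)) stop("folds must be >= 0", call. = FALSE)
  folds <- sort(unique(c(1, folds)))
  cap <- numeric(length(folds))
  for (i in seq_along(folds)) {
    cond <- scale_species(base_conditions, scan, folds[i])
    tr <- try(trajectory_trace(opf_simulate(cond, k)), silent = TRUE)
    if (inherits(tr, "try-error"))
      stop(sprintf("simulation failed at fold %g: %s", folds[i],
                   attr(tr, "condition")$message), call. = FALSE)
    cap[i] <- max_consumption_rate(tr, window_s, baseline_s)
  }
  base <- cap[folds == 1]
  structure(data.frame(fold = folds, capacity_uM_s = cap,
                       fold_change = cap / base),
            class = c("opf_oxcurve", "data.frame"), scan = scan)
}

scale_species <- function(cond, scan = c("pdi", "ero"), fold) {
  scan <- match.arg(scan)
  states <- if (scan == "pdi") c("PDI_ox", "PDI_mix", "PDI_red")
            else c("ERO_rr", "ERO_r1", "ERO_act_ox", "ERO_act_red")
  cond$init[states] <- cond$init[states] * fold
  sel <- cond$injections$species %in% states
  cond$injections$amount_uM[sel] <- cond$injections$amount_uM[sel] * fold
  cond
}

#' @export
plot.opf_oxcurve <- function(x, ...) {
  graphics::plot(x$fold, x$fold_change, type = "b", pch = 19,
                 xlab = "fold overexpression",
                 ylab = "capacity fold-change",
                 main = sprintf("Predicted capacity gain (%s scan)",
                                attr(x, "scan")), ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}
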