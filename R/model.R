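# Thiol-equivalent weight of each species: electrons (as 2e- = one thiol
# pair = 2 equivalents, GSH = 1) stored in the reduced species.  ERO_r1
# carries one reduced regulatory pair, the activated states two; ERO_act_red
# additionally carries a reduced active site.
THIOL_EQUIV <- c(O2 = 0, H2O2 = 0, GSH = 1, GSSG = 0, DTT_red = 2,
                 DTT_ox = 0, PDI_ox = 0, PDI_mix = 1, PDI_red = 2,
                 ERO_rr = 0, ERO_r1 = 2, ERO_act_ox = 4, ERO_act_red = 6)

constants_to_parms <- function(k, diffusion, gsh_activation = FALSE) {
  c(as.numeric(k[OPF_RATE_NAMES]), as.numeric(isTRUE(diffusion)),
    as.numeric(isTRUE(gsh_activation)))
}

#' Mass-action derivatives of the redox network
#'
#' Evaluates the right-hand side of the reaction network at one instant:
#' the two sequential activation steps of Ero1p (reduction of its regulatory
#' disulfides by reduced Pdi1p), the Pdi1p/Ero1p active-site exchange, the
#' terminal single-step reaction of reduced Ero1p with O2 producing H2O2,
#' the two identical-rate glutathione steps reducing oxidized Pdi1p through
#' the glutathionylated intermediate, the DTT calibration branch (DTT
#' reduces any Ero1p disulfide), and first-order O2 exchange between the
#' open electrode cell and the environment.
#'
#' This is the reference R implementation; [opf_simulate()] integrates an
#' identical compiled version for speed.
#'
#' @param state named numeric vector over [OPF_SPECIES] (uM); all >= 0.
#' @param k an [opf_constants] object (or named vector of the same names).
#' @param diffusion include the electrode-cell O2 exchange term?
#' @param gsh_activation use glutathione instead of reduced Pdi1p as the
#'   reductant of the Ero1p regulatory disulfides.
#' @return Named numeric vector of time derivatives (uM/s).
#' @examples
#' s <- opf_state(PDI_ox = 5, GSH = 40000)
#' opf_derivatives(s, opf_constants(), diffusion = FALSE)
#' @export
opf_derivatives <- function(state, k, diffusion = TRUE,
                            gsh_activation = FALSE) {
  stopifnot(all(OPF_SPECIES %in% names(state)))
  state <- state[OPF_SPECIES]
  if (any(state < 0))
    stop("negative input concentration: ",
         paste(names(state)[state < 0], collapse = ", "), call. = FALSE)
  k <- as_opf_constants(k)
  va1 <- k[["ka1"]] * (if (gsh_activation) state[["GSH"]] else
                       state[["PDI_red"]]) * state[["ERO_rr"]]
  va2 <- k[["ka2"]] * (if (gsh_activation) state[["GSH"]] else
                       state[["PDI_red"]]) * state[["ERO_r1"]]
  vr2 <- k[["kox"]] * state[["PDI_red"]] * state[["ERO_act_ox"]]
  vr1 <- k[["k1"]] * state[["ERO_act_red"]] * state[["O2"]]
  vg1 <- k[["kg"]] * state[["PDI_ox"]] * state[["GSH"]]
  vg2 <- k[["kg"]] * state[["PDI_mix"]] * state[["GSH"]]
  vd1 <- k[["kdtt"]] * state[["DTT_red"]] * state[["ERO_rr"]]
  vd2 <- k[["kdtt"]] * state[["DTT_red"]] * state[["ERO_r1"]]
  vd3 <- k[["kdtt"]] * state[["DTT_red"]] * state[["ERO_act_ox"]]
  d <- stats::setNames(numeric(length(OPF_SPECIES)), OPF_SPECIES)
  d["O2"] <- -vr1 + if (diffusion)
    k[["kdiff"]] * (k[["o2_sat"]] - state[["O2"]]) else 0
  d["H2O2"] <- vr1
  d["GSH"] <- -vg1 - vg2 - if (gsh_activation) 2 * (va1 + va2) else 0
  d["GSSG"] <- vg2 + if (gsh_activation) va1 + va2 else 0
  d["DTT_red"] <- -(vd1 + vd2 + vd3)
  d["DTT_ox"] <- vd1 + vd2 + vd3
  if (gsh_activation) {
    d["PDI_ox"] <- vr2 - vg1
    d["PDI_red"] <- vg2 - vr2
  } else {
    d["PDI_ox"] <- va1 + va2 + vr2 - vg1
    d["PDI_red"] <- vg2 - va1 - va2 - vr2
  }
  d["PDI_mix"] <- vg1 - vg2
  d["ERO_rr"] <- -va1 - vd1
  d["ERO_r1"] <- va1 + vd1 - va2 - vd2
  d["ERO_act_ox"] <- va2 + vd2 - vr2 + vr1 - vd3
  d["ERO_act_red"] <- vr2 + vd3 - vr1
  d
}

#' @rdname opf_derivatives
#' @param ... named species concentrations (uM); unnamed species default 0.
#' @export
opf_state <- function(...) {
  s <- stats::setNames(numeric(length(OPF_SPECIES)), OPF_SPECIES)
  args <- c(...)
  if (length(args)) {
    bad <- setdiff(names(args), OPF_SPECIES)
    if (length(bad))
      stop("unknown species: ", paste(bad, collapse = ", "), call. = FALSE)
    s[names(args)] <- args
  }
  s
}

#' Integrate the redox network over an assay
#'
#' Simulates one oxygen-consumption experiment with a stiff-capable adaptive
#' integrator (`deSolve::lsoda`, compiled right-hand side).  Injection events
#' are handled by stopping the integration at the event time, incrementing
#' the injected species and restarting -- never by event interpolation.
#'
#' @param conditions an [opf_conditions] object.
#' @param k an [opf_constants] object.
#' @param gsh_activation see [opf_derivatives()].
#' @param rtol,atol solver tolerances (relative; absolute in uM).
#' @param times optional output time grid (s) overriding the conditions'
#'   regular sampling; must start at 0 and lie within the run duration.
#'   Used to evaluate the model directly on a measured trace's grid.
#' @return An object of class `opf_trajectory`: a data.frame with `time_s`
#'   and one column per species, carrying the conditions, constants and
#'   solver settings as attributes.
#' @examples
#' cond <- opf_conditions(ero = 1, duration = 300,
#'                        injections = data.frame(time_s = 100,
#'                          species = "dtt", amount_uM = 10000))
#' traj <- opf_simulate(cond, opf_constants())
#' head(traj)
#' @export
opf_simulate <- function(conditions, k = opf_constants(),
                         gsh_activation = FALSE, rtol = 1e-8, atol = 1e-10,
                         times = NULL) {
  stopifnot(inherits(conditions, "opf_conditions"))
  k <- as_opf_constants(k)
  y <- conditions$init
  if (is.na(y[["O2"]])) y[["O2"]] <- k[["o2_sat"]]
  parms <- constants_to_parms(k, conditions$diffusion, gsh_activation)
  if (is.null(times)) {
    grid <- seq(0, conditions$duration, by = conditions$interval)
    if (grid[length(grid)] < conditions$duration)
      grid <- c(grid, conditions$duration)
  } else {
    grid <- sort(unique(as.numeric(times)))
    if (grid[1] != 0 || grid[length(grid)] > conditions$duration)
      stop("`times` must start at 0 and stay within the run duration",
           call. = FALSE)
  }
  t_end <- grid[length(grid)]
  inj <- conditions$injections
  breaks <- sort(unique(inj$time_s[inj$time_s > 0 & inj$time_s < t_end]))
  seg_bounds <- c(0, breaks, t_end)

  # injections at t = 0 are just initial-state increments
  at0 <- inj$time_s == 0
  if (any(at0))
    for (i in which(at0))
      y[inj$species[i]] <- y[inj$species[i]] + inj$amount_uM[i]

  rows <- NULL
  for (s in seq_len(length(seg_bounds) - 1)) {
    t0 <- seg_bounds[s]; t1 <- seg_bounds[s + 1]
    tt <- unique(c(t0, grid[grid > t0 & grid < t1], t1))
    out <- deSolve::ode(y = y, times = tt, func = "opfkin_derivs",
                        parms = parms, dllname = "opfkin",
                        initfunc = "opfkin_init", method = "lsoda",
                        rtol = rtol, atol = atol, maxsteps = 100000)
    if (any(!is.finite(out)))
      stop(sprintf(
        "ODE solver failed; last good time %g s", max(tt[stats::complete.cases(out)])),
        call. = FALSE)
    y <- out[nrow(out), -1]
    # small negative excursions within solver tolerance are zeroed
    neg <- y < 0
    if (any(y[neg] < -1e3 * atol))
      stop("ODE solver produced negative concentrations beyond tolerance",
           call. = FALSE)
    y[neg] <- 0
    keep <- out[, 1] %in% grid & !(out[, 1] == t1 & t1 < t_end)
    rows <- rbind(rows, out[keep, , drop = FALSE])
    for (i in which(inj$time_s == t1 & t1 < t_end))
      y[inj$species[i]] <- y[inj$species[i]] + inj$amount_uM[i]
  }
  traj <- as.data.frame(rows)
  names(traj) <- c("time_s", OPF_SPECIES)
  traj[traj < 0 & traj > -1e3 * atol] <- 0
  rownames(traj) <- NULL
  structure(traj, class = c("opf_trajectory", "data.frame"),
            conditions = conditions, constants = k,
            solver = list(method = "lsoda", rtol = rtol, atol = atol,
                          gsh_activation = gsh_activation))
}

#' Conservation bookkeeping over a trajectory
#'
#' Checks four ledgers that the chemistry fixes.  The electron ledger sums
#' the thiol equivalents stored in every reduced species (GSH and the
#' glutathionylated Pdi1p intermediate count 1, every reduced disulfide
#' pair counts 2, including the regulatory pairs implied by the Ero1p
#' activation states) and credits 2 equivalents per accumulated H2O2.  The
#' three moiety ledgers track total glutathione (GSH + PDI_mix + 2 GSSG),
#' total Pdi1p and total Ero1p.  After debiting injected material, all
#' four must be constant in time; a correct trajectory deviates only at
#' solver-tolerance level, a corrupted one does not.
#'
#' @param traj an `opf_trajectory` from [opf_simulate()].
#' @return Maximum absolute ledger deviation over the trajectory (uM;
#'   thiol equivalents for the electron ledger).
#' @export
electron_balance <- function(traj) {
  if (!inherits(traj, "opf_trajectory"))
    stop("electron_balance() needs an opf_trajectory", call. = FALSE)
  missing <- setdiff(OPF_SPECIES, names(traj))
  if (length(missing))
    stop("trajectory lacks species: ", paste(missing, collapse = ", "),
         call. = FALSE)
  m <- as.matrix(traj[OPF_SPECIES])
  electrons <- THIOL_EQUIV[OPF_SPECIES]
  electrons[["H2O2"]] <- 2
  gs_moiety <- stats::setNames(numeric(length(OPF_SPECIES)), OPF_SPECIES)
  gs_moiety[c("GSH", "PDI_mix")] <- 1; gs_moiety[["GSSG"]] <- 2
  pdi_pool <- stats::setNames(OPF_SPECIES %in%
                                c("PDI_ox", "PDI_mix", "PDI_red") + 0,
                              OPF_SPECIES)
  ero_pool <- stats::setNames(OPF_SPECIES %in%
                                c("ERO_rr", "ERO_r1", "ERO_act_ox",
                                  "ERO_act_red") + 0, OPF_SPECIES)
  inj <- attr(traj, "conditions")$injections
  dev <- vapply(list(electrons, gs_moiety, pdi_pool, ero_pool),
                function(w) {
    ledger <- drop(m %*% w)
    if (NROW(inj)) {
      for (i in seq_len(nrow(inj))) {
        wi <- w[[inj$species[i]]]
        if (wi != 0)
          ledger <- ledger - ifelse(traj$time_s >= inj$time_s[i],
                                    wi * inj$amount_uM[i], 0)
      }
    }
    max(abs(ledger - ledger[1]))
  }, numeric(1))
  max(dev)
}

#' @export
print.opf_trajectory <- function(x, ...) {
  cond <- attr(x, "conditions")
  cat(sprintf("Simulated redox trajectory: %d time points over %g s\n",
              nrow(x), cond$duration))
  cat(sprintf("  O2: %.3g -> %.3g uM\n", x$O2[1], x$O2[nrow(x)]))
  invisible(x)
}

# Extract the O2 trace of a trajectory.
#' @rdname opf_simulate
#' @param traj an `opf_trajectory`.
#' @export
trajectory_trace <- function(traj) {
  stopifnot(inherits(traj, "opf_trajectory"))
  opf_trace(traj$time_s, traj$O2)
}
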