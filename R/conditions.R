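# Friendly injection aliases: which state species an injected reagent enters.
INJECT_ALIASES <- c(pdi = "PDI_ox", ero = "ERO_rr", gsh = "GSH",
                    dtt = "DTT_red", o2 = "O2")

#' Assay conditions for a simulated oxygen-consumption run
#'
#' Describes one Clarke-electrode experiment: the initial concentrations, any
#' injection events (reagents added mid-run, e.g. Ero1p added after a 100-s
#' baseline), the duration, the output sampling interval and whether oxygen
#' exchange with the environment is modelled.
#'
#' Initial redox states follow the preparation of the purified proteins:
#' Pdi1p starts fully oxidized (`PDI_ox`), Ero1p starts with both regulatory
#' disulfides intact (`ERO_rr`, the homogeneously oxidized prep) and
#' glutathione fully reduced.  Pass a full named `state` vector to override.
#'
#' @param pdi,ero,gsh,dtt initial concentrations (uM) of Pdi1p, Ero1p,
#'   glutathione and DTT.  Note 40 mM GSH enters as 40000 uM.
#' @param o2 initial O2 (uM); defaults to `o2_sat` at run time when `NA`.
#' @param injections a data.frame with columns `time_s`, `species`,
#'   `amount_uM`.  `species` may be a state name or one of the aliases
#'   `"pdi"`, `"ero"`, `"gsh"`, `"dtt"`, `"o2"`.
#' @param duration total run length (s).
#' @param interval output sampling interval (s).
#' @param diffusion logical; model O2 exchange between the open cell and the
#'   environment?
#' @param state optional full named initial state (uM) overriding the scalar
#'   shortcuts; names must be among [OPF_SPECIES].
#' @return An object of class `opf_conditions`.
#' @examples
#' # the reference GSH-driven assay: Ero1p injected after the 100-s baseline
#' opf_conditions(pdi = 5, gsh = 40000,
#'                injections = data.frame(time_s = 100, species = "ero",
#'                                        amount_uM = 1))
#' @export
opf_conditions <- function(pdi = 0, ero = 0, gsh = 0, dtt = 0, o2 = NA,
                           injections = NULL, duration = 900, interval = 1,
                           diffusion = TRUE, state = NULL) {
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  if (interval <= 0) stop("sampling interval must be > 0", call. = FALSE)
  init <- stats::setNames(numeric(length(OPF_SPECIES)), OPF_SPECIES)
  init["O2"] <- o2
  init["GSH"] <- gsh
  init["DTT_red"] <- dtt
  init["PDI_ox"] <- pdi
  init["ERO_rr"] <- ero
  if (!is.null(state)) {
    bad <- setdiff(names(state), OPF_SPECIES)
    if (length(bad))
      stop("unknown species in `state`: ", paste(bad, collapse = ", "),
           call. = FALSE)
    init[names(state)] <- state
  }
  if (any(init < 0, na.rm = TRUE))
    stop("initial concentrations must be >= 0", call. = FALSE)
  inj <- normalise_injections(injections, duration)
  structure(list(init = init, injections = inj, duration = duration,
                 interval = interval, diffusion = isTRUE(diffusion)),
            class = "opf_conditions")
}

normalise_injections <- function(injections, duration) {
  if (is.null(injections) || NROW(injections) == 0)
    return(data.frame(time_s = numeric(0), species = character(0),
                      amount_uM = numeric(0)))
  stopifnot(is.data.frame(injections),
            all(c("time_s", "species", "amount_uM") %in% names(injections)))
  inj <- injections[c("time_s", "species", "amount_uM")]
  inj$species <- as.character(inj$species)
  alias <- inj$species %in% names(INJECT_ALIASES)
  inj$species[alias] <- INJECT_ALIASES[inj$species[alias]]
  bad <- setdiff(inj$species, OPF_SPECIES)
  if (length(bad))
    stop("unknown injected species: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(inj$time_s < 0 | inj$time_s > duration))
    stop("injection times must lie within [0, duration]", call. = FALSE)
  if (any(inj$amount_uM < 0))
    stop("injected amounts must be >= 0", call. = FALSE)
  inj[order(inj$time_s), , drop = FALSE]
}

#' @export
print.opf_conditions <- function(x, ...) {
  cat("Oxygen-consumption assay conditions\n")
  nz <- x$init[x$init != 0 | names(x$init) == "O2"]
  cat("  initial (uM):",
      paste(sprintf("%s = %s", names(nz), signif(nz, 4)), collapse = ", "),
      "\n")
  if (nrow(x$injections)) {
    for (i in seq_len(nrow(x$injections)))
      cat(sprintf("  inject at %g s: %s + %g uM\n", x$injections$time_s[i],
                  x$injections$species[i], x$injections$amount_uM[i]))
  }
  cat(sprintf("  duration %g s, sampled every %g s, O2 diffusion %s\n",
              x$duration, x$interval, if (x$diffusion) "on" else "off"))
  invisible(x)
}

# Total amount of one protein pool across all its states plus pending
# injections; used for conservation checks and overexpression scans.
conditions_total <- function(cond, what = c("pdi", "ero")) {
  what <- match.arg(what)
  states <- if (what == "pdi") c("PDI_ox", "PDI_mix", "PDI_red")
            else c("ERO_rr", "ERO_r1", "ERO_act_ox", "ERO_act_red")
  sum(cond$init[states]) +
    sum(cond$injections$amount_uM[cond$injections$species %in% states])
}
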