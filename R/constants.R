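# Species ordering shared with src/opfkin.c -- do not reorder.
OPF_SPECIES <- c("O2", "H2O2", "GSH", "GSSG", "DTT_red", "DTT_ox",
                 "PDI_ox", "PDI_mix", "PDI_red",
                 "ERO_rr", "ERO_r1", "ERO_act_ox", "ERO_act_red")

OPF_RATE_NAMES <- c("k1", "kox", "ka1", "ka2", "kg", "kdtt", "kdiff", "o2_sat")

#' Rate constants of the oxidative protein folding network
#'
#' Bundles the kinetic parameters of the reaction network together with a
#' fixed/free mask used by the fitting protocol.  All second-order constants
#' are in 1/(uM s); `kdiff` is a first-order electrode-cell oxygen exchange
#' rate in 1/s and `o2_sat` the air-saturation oxygen level in uM.
#'
#' The defaults are the package's reference parameterisation, calibrated once
#' against the published in vitro observables of the yeast Pdi1p/Ero1p system
#' (maximal per-Ero1p rate of 0.8 uM O2/s at 10 mM DTT, a saturating maximal
#' rate of ~1.5 uM/s, and the predicted 1.4-fold capacity gain on 10x Pdi1p
#' overexpression).  See the package vignette for the calibration procedure.
#'
#' @param k1 Ero1p(red) + O2 -> Ero1p(ox) + H2O2, the terminal oxygen
#'   reaction.  Experimentally determined (DTT-driven assays) and therefore
#'   fixed, never fitted.
#' @param kox exchange between reduced Pdi1p and activated, oxidized Ero1p.
#' @param ka1,ka2 the two sequential reductions of Ero1p regulatory
#'   disulfides that activate the enzyme (reductant: reduced Pdi1p).
#' @param kg both steps of the two-step glutathione reduction of oxidized
#'   Pdi1p; the two chemically similar steps share one rate.
#' @param kdtt reduction of any Ero1p disulfide by DTT (calibration branch).
#' @param kdiff first-order O2 exchange between the open Clarke cell and the
#'   environment (1/s).
#' @param o2_sat air-saturation O2 concentration (uM; ~258 uM for water near
#'   25 C).
#' @param fixed character vector naming the constants held fixed during
#'   fitting.  `k1` and `kdiff` are experimentally calibrated and fixed by
#'   default, as are `kdtt` and `o2_sat`.
#' @return An object of class `opf_constants`: a named numeric vector with a
#'   `fixed` attribute (logical mask).
#' @examples
#' k <- opf_constants()
#' k[["k1"]]
#' fixed_mask(k)
#' @export
opf_constants <- function(k1 = 0.005814,
                          kox = 1.41,
                          ka1 = 0.02,
                          ka2 = 0.02,
                          kg = 0.001,
                          kdtt = 1.82e-4,
                          kdiff = 0.002,
                          o2_sat = 258,
                          fixed = c("k1", "kdtt", "kdiff", "o2_sat")) {
  k <- c(k1 = k1, kox = kox, ka1 = ka1, ka2 = ka2, kg = kg,
         kdtt = kdtt, kdiff = kdiff, o2_sat = o2_sat)
  if (any(!is.finite(k)) || any(k < 0))
    stop("all rate constants must be finite and >= 0", call. = FALSE)
  bad <- setdiff(fixed, OPF_RATE_NAMES)
  if (length(bad))
    stop("unknown constant name(s) in `fixed`: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(k, fixed = OPF_RATE_NAMES %in% fixed, class = "opf_constants")
}

#' @rdname opf_constants
#' @param k an `opf_constants` object.
#' @export
fixed_mask <- function(k) {
  stopifnot(inherits(k, "opf_constants"))
  stats::setNames(attr(k, "fixed"), names(k))
}

#' @rdname opf_constants
#' @export
free_names <- function(k) names(k)[!fixed_mask(k)]

as_opf_constants <- function(x, template = opf_constants()) {
  if (inherits(x, "opf_constants")) return(x)
  stopifnot(is.numeric(x), !is.null(names(x)))
  k <- unclass(template)
  k[names(x)] <- x
  structure(k, fixed = attr(template, "fixed"), class = "opf_constants")
}

#' @export
print.opf_constants <- function(x, ...) {
  cat("Rate constants of the oxidative protein folding network\n")
  df <- data.frame(
    value = as.numeric(x),
    unit = c(rep("1/(uM s)", 6), "1/s", "uM"),
    fitting = ifelse(attr(x, "fixed"), "fixed", "free"),
    row.names = names(x)
  )
  print(df, ...)
  invisible(x)
}
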