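# Run code with a temporary, seeded RNG state; the caller's stream is
# untouched.  seed = NULL leaves the RNG alone (still restores nothing).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Electrode-noise specification
#'
#' Additive iid Gaussian noise on the O2 readings, with an optional slow
#' linear drift, emulating Clarke-electrode acquisition noise.
#'
#' @param sd Gaussian standard deviation (uM).
#' @param drift linear drift (uM/s) added to the readings.
#' @param seed integer seed; `NULL` uses (and advances) the current RNG.
#' @export
noise_spec <- function(sd = 1.0, drift = 0, seed = NULL) {
  if (sd < 0) stop("noise sd must be >= 0", call. = FALSE)
  structure(list(sd = sd, drift = drift, seed = seed), class = "opf_noise")
}

#' Generate a synthetic electrode trace
#'
#' Simulates the assay under `conditions` with the ground-truth constants
#' `k_true`, samples the O2 column at the conditions' interval and adds
#' seeded noise and drift.  Covers ordinary GSH/DTT assays as well as
#' dithionite depletion/recovery runs (start O2 near 0, no enzymes,
#' diffusion on) -- everything is expressed through `conditions`.
#'
#' @param k_true ground-truth [opf_constants].
#' @param conditions an [opf_conditions] object.
#' @param noise a [noise_spec()].
#' @return An [opf_trace] with provenance metadata.
#' @examples
#' tr <- generate_trace(opf_constants(), recovery_conditions(duration = 300),
#'                      noise_spec(sd = 0, seed = 1))
#' @export
generate_trace <- function(k_true = opf_constants(),
                           conditions = opf_conditions(),
                           noise = noise_spec()) {
  traj <- opf_simulate(conditions, k_true)
  o2 <- traj$O2
  if (noise$sd > 0)
    o2 <- o2 + with_seed(noise$seed, stats::rnorm(length(o2), 0, noise$sd))
  if (noise$drift != 0) o2 <- o2 + noise$drift * traj$time_s
  opf_trace(traj$time_s, o2,
            meta = list(conditions = conditions, noise = noise))
}

#' Canonical assay conditions
#'
#' Convenience constructors for the three experiment families the pipeline
#' consumes: the GSH-driven coupled assay (reagents equilibrated for a 100-s
#' baseline, Ero1p injected at 100 s), the Pdi1p-free DTT-driven Ero1p assay
#' (Ero1p equilibrated, DTT injected at 100 s), and the dithionite
#' depletion/recovery run used to calibrate the electrode-cell O2 exchange
#' (O2 starts near zero, no enzymes, diffusion on).
#'
#' @param pdi,ero,gsh,dtt concentrations in uM (`dtt_mM` in mM).
#' @param duration,interval run length and sampling interval (s).
#' @param injection_time_s time of the starting injection (s).
#' @export
gsh_assay_conditions <- function(pdi, ero = 1, gsh = 40000, duration = 900,
                                 interval = 1, injection_time_s = 100) {
  opf_conditions(pdi = pdi, gsh = gsh, duration = duration,
                 interval = interval,
                 injections = data.frame(time_s = injection_time_s,
                                         species = "ero", amount_uM = ero))
}

#' @rdname gsh_assay_conditions
#' @export
dtt_assay_conditions <- function(ero = 1, dtt_mM = 10, duration = 600,
                                 interval = 1, injection_time_s = 100) {
  opf_conditions(ero = ero, duration = duration, interval = interval,
                 injections = data.frame(time_s = injection_time_s,
                                         species = "dtt",
                                         amount_uM = dtt_mM * 1000))
}

#' @rdname gsh_assay_conditions
#' @export
recovery_conditions <- function(duration = 1200, interval = 1) {
  opf_conditions(o2 = 0, duration = duration, interval = interval,
                 diffusion = TRUE)
}

#' Generate a titration series of synthetic assays
#'
#' One (conditions, trace) pair per grid point, sharing a series id.  The
#' default grids follow the in vitro titrations: Pdi1p in
#' \{1, 2.5, 5, 10, 15, 20\} uM at 1 uM Ero1p and 40 mM GSH; Ero1p in
#' \{0.25, 0.5, 1, 2\} uM at 5 uM Pdi1p; DTT in \{1, 5, 10, 20\} mM at 1 uM
#' Ero1p.  In the GSH designs Ero1p is injected at 100 s; in the DTT design
#' DTT is.
#'
#' @param k_true ground-truth [opf_constants].
#' @param design one of `"pdi_scan"`, `"ero_scan"`, `"dtt_scan"`.
#' @param noise a [noise_spec()]; member traces use `seed`, `seed + 1`, ...
#' @param grid optional numeric grid overriding the default (uM; mM for DTT).
#' @param ... passed to the conditions constructor (e.g. `duration`).
#' @return An object of class `opf_experiments`: a list of
#'   `list(conditions, trace)` with a `series` attribute.
#' @export
generate_titration_series <- function(k_true = opf_constants(),
                                      design = c("pdi_scan", "ero_scan",
                                                 "dtt_scan"),
                                      noise = noise_spec(), grid = NULL, ...) {
  design <- match.arg(design)
  if (!is.null(grid) && length(grid) == 0)
    stop("empty titration grid", call. = FALSE)
  grid <- if (!is.null(grid)) grid else switch(design,
    pdi_scan = c(1, 2.5, 5, 10, 15, 20),
    ero_scan = c(0.25, 0.5, 1, 2),
    dtt_scan = c(1, 5, 10, 20))
  pairs <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    cond <- switch(design,
      pdi_scan = gsh_assay_conditions(pdi = grid[i], ...),
      ero_scan = gsh_assay_conditions(pdi = 5, ero = grid[i], ...),
      dtt_scan = dtt_assay_conditions(ero = 1, dtt_mM = grid[i], ...))
    ns <- noise
    if (!is.null(ns$seed)) ns$seed <- ns$seed + (i - 1L)
    tr <- generate_trace(k_true, cond, ns)
    attr(tr, "meta")$series <- design
    attr(tr, "meta")$level <- grid[i]
    pairs[[i]] <- list(conditions = cond, trace = tr)
  }
  opf_experiments(pairs, series = design)
}

#' @rdname generate_titration_series
#' @param pairs list of `list(conditions, trace)` pairs.
#' @param series series identifier.
#' @export
opf_experiments <- function(pairs, series = "series") {
  if (!length(pairs)) stop("at least one experiment required", call. = FALSE)
  ok <- vapply(pairs, function(p)
    inherits(p$conditions, "opf_conditions") && inherits(p$trace, "opf_trace"),
    logical(1))
  if (!all(ok))
    stop("each experiment must pair opf_conditions with an opf_trace",
         call. = FALSE)
  structure(pairs, class = "opf_experiments", series = series)
}

#' @export
print.opf_experiments <- function(x, ...) {
  cat(sprintf("Experiment set '%s': %d traces\n", attr(x, "series"),
              length(x)))
  invisible(x)
}

#' Synthetic-proteome generator configuration
#'
#' Distributional knobs for ER/secretory-proteome tables: log-normal
#' abundances (molecules/cell), Poisson cysteine counts, log-normal
#' half-lives (min).  The defaults describe roughly 4000 proteins routed
#' through the secretory pathway with median abundance 1000 molecules/cell,
#' a mean of ~5 cysteines and median half-life 300 min, sized so the
#' resulting proteome-wide disulfide demand lands at the order of magnitude
#' estimated for growing yeast.  They are documented modelling choices, not
#' measured biology.
#'
#' @param n number of proteins.
#' @param abundance_scale median abundance (molecules/cell); abundances are
#'   `abundance_scale * exp(N(0, abundance_sdlog))`.
#' @param abundance_sdlog log-scale sd of abundances.
#' @param cys_lambda Poisson mean cysteine count.
#' @param half_life_scale median half-life (min).
#' @param half_life_sdlog log-scale sd of half-lives.
#' @param seed integer seed.
#' @export
proteome_config <- function(n = 4000, abundance_scale = 1000,
                            abundance_sdlog = 1.5, cys_lambda = 5,
                            half_life_scale = 300, half_life_sdlog = 0.8,
                            seed = NULL) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (abundance_scale <= 0 || half_life_scale <= 0 || cys_lambda < 0 ||
      abundance_sdlog < 0 || half_life_sdlog < 0)
    stop("invalid distribution parameters", call. = FALSE)
  structure(list(n = as.integer(n), abundance_scale = abundance_scale,
                 abundance_sdlog = abundance_sdlog, cys_lambda = cys_lambda,
                 half_life_scale = half_life_scale,
                 half_life_sdlog = half_life_sdlog, seed = seed),
            class = "opf_proteome_config")
}

#' Generate a synthetic proteome table
#'
#' Samples a per-protein table of abundance, cysteine count and degradation
#' rate (derived from sampled half-lives via ln 2), the input of the
#' proteome-wide disulfide-demand calculation.
#'
#' @param cfg a [proteome_config()].
#' @return A data.frame with columns `protein_id`, `abundance`, `n_cys`,
#'   `deg_rate_per_min`.
#' @export
generate_proteome <- function(cfg = proteome_config()) {
  stopifnot(inherits(cfg, "opf_proteome_config"))
  with_seed(cfg$seed, {
    abundance <- cfg$abundance_scale *
      exp(stats::rnorm(cfg$n, 0, cfg$abundance_sdlog))
    n_cys <- stats::rpois(cfg$n, cfg$cys_lambda)
    half_life <- cfg$half_life_scale *
      exp(stats::rnorm(cfg$n, 0, cfg$half_life_sdlog))
    data.frame(protein_id = sprintf("P%04d", seq_len(cfg$n)),
               abundance = abundance, n_cys = n_cys,
               deg_rate_per_min = log(2) / half_life)
  })
}
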