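#' Oxygen-electrode traces
#'
#' A trace is the primary readout of the Clarke-electrode assay: dissolved
#' O2 (uM) against time (s).  `opf_trace()` validates and constructs one.
#'
#' @param time_s strictly increasing times (s); at least two points.
#' @param o2_uM finite O2 readings (uM).
#' @param meta optional named list of metadata (conditions id, replicate id,
#'   comment lines from file headers ...).
#' @return An object of class `opf_trace` (a data.frame `time_s`, `o2_uM`).
#' @examples
#' tr <- opf_trace(0:10, 258 - 0.5 * (0:10))
#' max_consumption_rate(tr, window_s = 5, baseline_s = 0)
#' @export
opf_trace <- function(time_s, o2_uM, meta = list()) {
  time_s <- as.numeric(time_s); o2_uM <- as.numeric(o2_uM)
  if (length(time_s) != length(o2_uM))
    stop("time and O2 vectors differ in length", call. = FALSE)
  if (length(time_s) < 2)
    stop("a trace needs at least 2 points", call. = FALSE)
  if (any(diff(time_s) <= 0))
    stop("time must be strictly increasing", call. = FALSE)
  if (any(!is.finite(o2_uM)))
    stop("O2 readings must be finite", call. = FALSE)
  structure(data.frame(time_s = time_s, o2_uM = o2_uM),
            class = c("opf_trace", "data.frame"), meta = meta)
}

#' @export
print.opf_trace <- function(x, ...) {
  cat(sprintf("O2 trace: %d points, t in [%g, %g] s, O2 in [%.4g, %.4g] uM\n",
              nrow(x), x$time_s[1], x$time_s[nrow(x)],
              min(x$o2_uM), max(x$o2_uM)))
  invisible(x)
}

#' Remove the baseline-stabilisation segment of a trace
#'
#' Electrode runs begin with a stabilisation period (100 s by default)
#' before the reaction is started by injection; analysis is done on the
#' trace with that baseline removed and time re-zeroed at the cut.
#'
#' @param trace an [opf_trace].
#' @param baseline_s baseline duration to drop (s).
#' @return The sub-trace with `time_s >= baseline_s`, times re-zeroed.
#' @export
strip_baseline <- function(trace, baseline_s = 100) {
  stopifnot(inherits(trace, "opf_trace"))
  if (baseline_s < 0) stop("baseline_s must be >= 0", call. = FALSE)
  keep <- trace$time_s >= baseline_s
  if (sum(keep) < 2)
    stop(sprintf("trace (span %g s) does not extend beyond the %g-s baseline",
                 trace$time_s[nrow(trace)], baseline_s), call. = FALSE)
  opf_trace(trace$time_s[keep] - baseline_s, trace$o2_uM[keep],
            meta = attr(trace, "meta"))
}

#' Windowed oxygen-consumption rate
#'
#' The instantaneous consumption rate of an electrode trace, estimated as
#' minus the least-squares slope of O2 against time in a sliding window
#' (default width 10 s, advancing one sample at a time).  Positive values
#' mean O2 is falling.
#'
#' @param trace an [opf_trace].
#' @param window_s window width (s).
#' @return A data.frame of class `opf_rate_series` with `time_s` (window
#'   centre) and `rate_uM_s`.
#' @export
windowed_rate <- function(trace, window_s = 10) {
  stopifnot(inherits(trace, "opf_trace"))
  if (window_s <= 0) stop("window_s must be > 0", call. = FALSE)
  t <- trace$time_s; o2 <- trace$o2_uM; n <- length(t)
  if (t[n] - t[1] < window_s)
    stop(sprintf("trace span (%g s) is shorter than the window (%g s)",
                 t[n] - t[1], window_s), call. = FALSE)
  starts <- which(t <= t[n] - window_s)
  centre <- rate <- numeric(length(starts))
  j <- 1L
  for (idx in seq_along(starts)) {
    i <- starts[idx]
    if (j < i) j <- i
    while (j < n && t[j + 1] <= t[i] + window_s) j <- j + 1L
    if (j == i) { rate[idx] <- NA; centre[idx] <- t[i]; next }
    tw <- t[i:j]; ow <- o2[i:j]
    tc <- tw - mean(tw)
    rate[idx] <- -sum(tc * ow) / sum(tc * tc)
    centre[idx] <- mean(tw)
  }
  ok <- is.finite(rate)
  structure(data.frame(time_s = centre[ok], rate_uM_s = rate[ok]),
            class = c("opf_rate_series", "data.frame"))
}

#' Maximum windowed oxygen-consumption rate
#'
#' The headline statistic of a titration experiment: the largest windowed
#' consumption rate of the baseline-stripped trace.
#'
#' @inheritParams windowed_rate
#' @inheritParams strip_baseline
#' @return Maximum consumption rate (uM/s).
#' @export
max_consumption_rate <- function(trace, window_s = 10, baseline_s = 100) {
  rs <- windowed_rate(strip_baseline(trace, baseline_s), window_s)
  max(rs$rate_uM_s)
}
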