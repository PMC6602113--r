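# Independent fixed-step classical Runge-Kutta (RK4) integrator over the
# exported R derivatives.  Deliberately naive: no adaptivity, no compiled
# code, injections applied by hand -- a brute-force cross-check for the
# production solver.
rk4_simulate <- function(conditions, k, dt = 0.01) {
  k <- opfkin:::as_opf_constants(k)
  y <- conditions$init
  if (is.na(y[["O2"]])) y[["O2"]] <- k[["o2_sat"]]
  inj <- conditions$injections
  for (i in which(inj$time_s == 0))
    y[inj$species[i]] <- y[inj$species[i]] + inj$amount_uM[i]
  grid <- seq(0, conditions$duration, by = conditions$interval)
  events <- sort(unique(c(grid, inj$time_s, conditions$duration)))
  out <- matrix(NA_real_, nrow = length(grid), ncol = length(y) + 1)
  rowi <- 1L
  t <- 0
  record <- function(t, y, rowi) {
    out[rowi, ] <<- c(t, y)
    rowi + 1L
  }
  rowi <- record(0, y, rowi)
  f <- function(y) opf_derivatives(pmax(y, 0), k,
                                   diffusion = conditions$diffusion)
  for (ev in events[events > 0]) {
    while (t < ev - 1e-12) {
      h <- min(dt, ev - t)
      k1 <- f(y)
      k2 <- f(y + h / 2 * k1)
      k3 <- f(y + h / 2 * k2)
      k4 <- f(y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      y <- pmax(y, 0)
      t <- t + h
    }
    for (i in which(abs(inj$time_s - ev) < 1e-12 & inj$time_s > 0 &
                    inj$time_s < conditions$duration))
      y[inj$species[i]] <- y[inj$species[i]] + inj$amount_uM[i]
    if (any(abs(grid - ev) < 1e-12))
      rowi <- record(ev, y, rowi)
  }
  colnames(out) <- c("time_s", names(y))
  as.data.frame(out)
}

# Ground truth used across the tests: the package defaults.
k_default <- opf_constants()
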