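test_that("rmsd matches hand arithmetic", {
  a <- opf_trace(c(0, 1), c(10, 10))
  expect_equal(rmsd(a, a), 0)
  b <- opf_trace(c(0, 1), c(13, 13))
  expect_equal(rmsd(a, b), 3)
  d <- opf_trace(c(0, 1), c(11, 13))  # diffs (1, 3) -> sqrt(5)
  expect_equal(rmsd(a, d), sqrt(5))
  expect_error(rmsd(a, opf_trace(c(0, 2), c(1, 2))), "grid")
})

test_that("diffusion calibration recovers kdiff from recovery traces", {
  k <- opf_constants(kdiff = 0.01)
  tr <- generate_trace(k, recovery_conditions(duration = 600),
                       noise_spec(sd = 0))
  cf <- coef(calibrate_diffusion(tr))
  expect_equal(cf[["kdiff"]], 0.01, tolerance = 1e-6)
  expect_equal(cf[["o2_sat"]], k[["o2_sat"]], tolerance = 1e-6)

  flat <- opf_trace(0:100, rep(258, 101))
  expect_error(calibrate_diffusion(flat), "no recovery")
  falling <- opf_trace(0:100, 258 - (0:100))
  expect_error(calibrate_diffusion(falling), "no recovery")
})

test_that("diffusion calibration is robust to electrode noise", {
  k <- opf_constants(kdiff = 0.01)
  cond <- recovery_conditions(duration = 600, interval = 1)
  clean <- opf_simulate(cond, k)$O2
  errs <- vapply(1:100, function(s) {
    tr <- generate_trace(k, cond, noise_spec(sd = 1, seed = s))
    abs(coef(calibrate_diffusion(tr))[["kdiff"]] - 0.01) / 0.01
  }, numeric(1))
  expect_true(all(errs < 0.05))
})

test_that("DTT calibration recovers k1 and kdtt from a titration series", {
  k_true <- opf_constants(k1 = 0.005, kdtt = 2.2e-4)
  exps <- generate_titration_series(k_true, "dtt_scan", noise_spec(sd = 0),
                                    duration = 500, interval = 2)
  cal <- calibrate_ero1_dtt(exps)
  expect_equal(cal$k1, 0.005, tolerance = 0.01)
  expect_equal(cal$kdtt, 2.2e-4, tolerance = 0.01)
  expect_lt(cal$avg_rmsd, 0.05)
})

test_that("DTT calibration rejects inapplicable experiment sets", {
  zero_dtt <- generate_titration_series(k_default, "dtt_scan",
                                        noise_spec(sd = 0), grid = c(0, 0),
                                        duration = 200, interval = 5)
  expect_error(calibrate_ero1_dtt(zero_dtt), "no signal")

  gsh_exps <- generate_titration_series(k_default, "pdi_scan",
                                        noise_spec(sd = 0), grid = c(5),
                                        duration = 200, interval = 5)
  expect_error(calibrate_ero1_dtt(gsh_exps), "Ero1p and DTT only")
})

test_that("repeated fitting recovers the identifiable constants", {
  exps <- generate_titration_series(k_default, "pdi_scan", noise_spec(sd = 0),
                                    grid = c(1, 5, 15), duration = 300,
                                    interval = 2)
  fit <- opf_fit(exps, n_repeats = 3, seed = 11,
                 control = list(pop = 16, maxgen = 60, patience = 30,
                                max_eval = 2000))
  best <- coef(fit)
  for (nm in c("kox", "ka1", "ka2"))
    expect_lt(abs(best[[nm]] - k_default[[nm]]) / k_default[[nm]], 0.05)
  # fixed constants pass through untouched in every repeat
  for (res in fit$results)
    expect_identical(
      unclass(res$constants)[c("k1", "kdtt", "kdiff", "o2_sat")],
      unclass(k_default)[c("k1", "kdtt", "kdiff", "o2_sat")])
  # rank order: the first repeat has the lowest objective
  ssqs <- vapply(fit$results, `[[`, numeric(1), "ssq")
  expect_true(all(ssqs[1] <= ssqs))
  rmsds <- vapply(fit$results, `[[`, numeric(1), "avg_rmsd")
  expect_true(!is.unsorted(rmsds))
  # average RMSD is the mean of the per-experiment RMSDs
  for (res in fit$results)
    expect_equal(res$avg_rmsd, mean(res$per_rmsd))
})

test_that("fitting is deterministic under a fixed master seed", {
  exps <- generate_titration_series(k_default, "pdi_scan", noise_spec(sd = 0),
                                    grid = c(5), duration = 200, interval = 5)
  ctl <- list(pop = 8, maxgen = 8, patience = 5, max_eval = 100,
              polish = FALSE)
  f1 <- opf_fit(exps, n_repeats = 2, seed = 3, control = ctl)
  f2 <- opf_fit(exps, n_repeats = 2, seed = 3, control = ctl)
  expect_identical(f1$par_matrix, f2$par_matrix)
  expect_identical(vapply(f1$results, `[[`, numeric(1), "avg_rmsd"),
                   vapply(f2$results, `[[`, numeric(1), "avg_rmsd"))
})

test_that("fit accessors and report are coherent", {
  exps <- generate_titration_series(k_default, "pdi_scan", noise_spec(sd = 0),
                                    grid = c(5), duration = 200, interval = 5)
  fit <- opf_fit(exps, n_repeats = 2, seed = 5,
                 control = list(pop = 8, maxgen = 10, patience = 5,
                                max_eval = 150, polish = FALSE))
  preds <- predict(fit)
  expect_length(preds, length(exps))
  expect_equal(preds[[1]]$time_s, exps[[1]]$trace$time_s)
  res <- residuals(fit)
  expect_equal(sqrt(mean(res[[1]]$residual_uM^2)),
               fit$results[[1]]$per_rmsd[1], tolerance = 1e-10)
  rep_df <- fit_report(fit)
  expect_equal(nrow(rep_df), 2)
  expect_true(all(c("rank", "kox", "avg_rmsd") %in% names(rep_df)))
  expect_true(!is.unsorted(rep_df$avg_rmsd))
  sims <- simulate(fit, nsim = 1, seed = 2, noise = noise_spec(sd = 0.5))
  expect_length(sims[[1]], length(exps))
})
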