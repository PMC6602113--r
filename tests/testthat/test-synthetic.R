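test_that("noise-free generated traces equal the simulated trajectory", {
  cond <- dtt_assay_conditions(duration = 200, interval = 2)
  tr <- generate_trace(k_default, cond, noise_spec(sd = 0))
  traj <- opf_simulate(cond, k_default)
  expect_identical(tr$o2_uM, traj$O2)
  expect_identical(tr$time_s, traj$time_s)
})

test_that("trace generation is seed-deterministic and leaves the RNG alone", {
  cond <- recovery_conditions(duration = 120, interval = 1)
  t1 <- generate_trace(k_default, cond, noise_spec(sd = 1, seed = 42))
  set.seed(777)
  probe <- runif(1)
  t2 <- generate_trace(k_default, cond, noise_spec(sd = 1, seed = 42))
  expect_identical(t1$o2_uM, t2$o2_uM)
  # the global stream is untouched by the generator's internal seeding
  set.seed(777)
  expect_identical(runif(1), probe)
})

test_that("generated noise has the requested magnitude and drift", {
  cond <- recovery_conditions(duration = 5000, interval = 1)
  clean <- opf_simulate(cond, k_default)$O2
  noisy <- generate_trace(k_default, cond, noise_spec(sd = 2, seed = 9))
  resid <- noisy$o2_uM - clean
  expect_lt(abs(sd(resid) - 2) / 2, 0.1)

  drifted <- generate_trace(k_default, cond,
                            noise_spec(sd = 0, drift = 0.01))
  expect_equal(drifted$o2_uM - clean, 0.01 * noisy$time_s)
})

test_that("titration designs carry the documented fixed concentrations", {
  exps <- generate_titration_series(k_default, "pdi_scan", noise_spec(sd = 0),
                                    grid = c(1, 5), duration = 150,
                                    interval = 5)
  for (ex in exps) {
    expect_equal(ex$conditions$init[["GSH"]], 40000)
    inj <- ex$conditions$injections
    expect_equal(inj$species, "ERO_rr")
    expect_equal(inj$time_s, 100)
    expect_equal(inj$amount_uM, 1)
  }
  expect_equal(vapply(exps, function(e) e$conditions$init[["PDI_ox"]],
                      numeric(1)), c(1, 5))

  dtt <- generate_titration_series(k_default, "dtt_scan", noise_spec(sd = 0),
                                   grid = c(5, 10), duration = 150,
                                   interval = 5)
  for (ex in dtt) expect_equal(ex$conditions$init[["ERO_rr"]], 1)
  expect_equal(vapply(dtt, function(e) e$conditions$injections$amount_uM,
                      numeric(1)), c(5000, 10000))

  expect_error(generate_titration_series(k_default, "pdi_scan",
                                         grid = numeric(0)), "empty")
})

test_that("noise-free titration max rates rise with the scanned enzyme", {
  exps <- generate_titration_series(k_default, "pdi_scan", noise_spec(sd = 0),
                                    grid = c(1, 5, 15), duration = 500,
                                    interval = 2)
  rates <- vapply(exps, function(ex) max_consumption_rate(ex$trace),
                  numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("titration series are seed-deterministic", {
  e1 <- generate_titration_series(k_default, "ero_scan",
                                  noise_spec(sd = 1, seed = 5),
                                  grid = c(0.5, 1), duration = 150,
                                  interval = 5)
  e2 <- generate_titration_series(k_default, "ero_scan",
                                  noise_spec(sd = 1, seed = 5),
                                  grid = c(0.5, 1), duration = 150,
                                  interval = 5)
  for (i in seq_along(e1))
    expect_identical(e1[[i]]$trace$o2_uM, e2[[i]]$trace$o2_uM)
  # members use distinct sub-seeds, so their noise differs
  expect_false(identical(e1[[1]]$trace$o2_uM - mean(e1[[1]]$trace$o2_uM),
                         e1[[2]]$trace$o2_uM - mean(e1[[2]]$trace$o2_uM)))
})

test_that("synthetic proteomes satisfy the table invariants", {
  cfg <- proteome_config(n = 10000, seed = 21)
  p1 <- generate_proteome(cfg)
  p2 <- generate_proteome(cfg)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 10000)
  expect_true(all(p1$abundance > 0))
  expect_true(all(p1$n_cys >= 0 & p1$n_cys %% 1 == 0))
  expect_true(all(p1$deg_rate_per_min > 0))
})

test_that("abundance scale propagates linearly into the demand sum", {
  a <- generate_proteome(proteome_config(n = 500, abundance_scale = 1000,
                                         seed = 8))
  b <- generate_proteome(proteome_config(n = 500, abundance_scale = 2000,
                                         seed = 8))
  expect_equal(b$abundance, 2 * a$abundance)
  expect_identical(b$n_cys, a$n_cys)
  expect_equal(k_cys(b, 120)$total, 2 * k_cys(a, 120)$total)
})
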