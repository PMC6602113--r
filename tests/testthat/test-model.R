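test_that("air-saturated, enzyme-free state is an equilibrium", {
  s <- opf_state(O2 = k_default[["o2_sat"]])
  d <- opf_derivatives(s, k_default, diffusion = TRUE)
  expect_identical(unname(d), rep(0, length(d)))
})

test_that("derivatives follow the mass-action law (hand evaluation)", {
  s <- opf_state(PDI_ox = 5, GSH = 40000, O2 = 258)
  d <- opf_derivatives(s, k_default, diffusion = FALSE)
  kg <- k_default[["kg"]]
  expect_equal(d[["PDI_mix"]], kg * 5 * 40000)
  expect_equal(d[["GSH"]], -kg * 5 * 40000)
  expect_equal(unname(d[c("ERO_rr", "ERO_r1", "ERO_act_ox", "ERO_act_red")]),
               rep(0, 4))
})

test_that("derivatives conserve the enzyme pools and glutathione moieties", {
  set.seed(42)
  for (i in 1:50) {
    s <- opf_state()
    s[] <- stats::runif(length(s), 0, 100)
    for (gact in c(FALSE, TRUE)) {
      d <- opf_derivatives(s, k_default, diffusion = FALSE,
                           gsh_activation = gact)
      # zero up to floating-point cancellation in the summed rates
      expect_lt(abs(sum(d[c("PDI_ox", "PDI_mix", "PDI_red")])), 1e-8)
      expect_lt(abs(sum(d[c("ERO_rr", "ERO_r1", "ERO_act_ox",
                            "ERO_act_red")])), 1e-8)
      # glutathione moieties: GSH + PDI_mix + 2 GSSG
      expect_lt(abs(d[["GSH"]] + d[["PDI_mix"]] + 2 * d[["GSSG"]]), 1e-8)
    }
  }
})

test_that("negative concentrations are rejected", {
  s <- opf_state(O2 = 258)
  s[["GSH"]] <- -1
  expect_error(opf_derivatives(s, k_default), "negative")
})

test_that("without reductant the O2 reading stays at saturation", {
  cond <- opf_conditions(pdi = 5, gsh = 0, duration = 300, diffusion = TRUE)
  traj <- opf_simulate(cond, k_default)
  expect_lt(max(abs(traj$O2 - k_default[["o2_sat"]])), 1e-6)
})

test_that("simulated assays conserve enzyme totals at every output point", {
  cond <- gsh_assay_conditions(pdi = 5, ero = 1, duration = 600)
  traj <- opf_simulate(cond, k_default)
  pdi_tot <- rowSums(traj[c("PDI_ox", "PDI_mix", "PDI_red")])
  ero_tot <- rowSums(traj[c("ERO_rr", "ERO_r1", "ERO_act_ox",
                            "ERO_act_red")])
  expect_lt(max(abs(pdi_tot - 5)) / 5, 1e-9)
  # Ero1p appears at the 100-s injection and is conserved afterwards
  expect_true(all(ero_tot[traj$time_s < 100] == 0))
  post <- ero_tot[traj$time_s >= 100]
  expect_lt(max(abs(post - 1)), 1e-9)
  gs_tot <- traj$GSH + traj$PDI_mix + 2 * traj$GSSG
  expect_lt(max(abs(gs_tot - gs_tot[1])) / gs_tot[1], 1e-9)
})

test_that("with diffusion off and reductant present O2 never increases", {
  cond <- opf_conditions(pdi = 5, ero = 1, gsh = 40000, duration = 400,
                         diffusion = FALSE)
  traj <- opf_simulate(cond, k_default)
  expect_true(all(diff(traj$O2) <= 1e-10))
})

test_that("adaptive solution matches a fixed-step RK4 oracle", {
  # GSH-driven instance, 60 s, no injection
  cond <- opf_conditions(pdi = 5, ero = 1, gsh = 40000, duration = 60,
                         interval = 5, diffusion = TRUE)
  traj <- opf_simulate(cond, k_default)
  ora <- rk4_simulate(cond, k_default, dt = 0.01)
  for (sp in c("O2", "GSH", "PDI_red", "ERO_act_ox", "H2O2")) {
    scale <- max(abs(ora[[sp]]), 1e-3)
    expect_lt(max(abs(traj[[sp]] - ora[[sp]])) / scale, 1e-6)
  }
  # DTT instance with a mid-run injection exercises the restart logic
  cond2 <- opf_conditions(ero = 1, duration = 60, interval = 5,
                          injections = data.frame(time_s = 20,
                                                  species = "dtt",
                                                  amount_uM = 10000))
  traj2 <- opf_simulate(cond2, k_default)
  ora2 <- rk4_simulate(cond2, k_default, dt = 0.01)
  for (sp in c("O2", "DTT_red", "ERO_act_red", "H2O2")) {
    scale <- max(abs(ora2[[sp]]), 1e-3)
    expect_lt(max(abs(traj2[[sp]] - ora2[[sp]])) / scale, 1e-6)
  }
})

test_that("the reference assay shows lag, a single rate maximum, then decline", {
  cond <- gsh_assay_conditions(pdi = 5, ero = 1)
  tr <- trajectory_trace(opf_simulate(cond, k_default))
  rs <- windowed_rate(strip_baseline(tr, 100), 10)
  imax <- which.max(rs$rate_uM_s)
  expect_gt(imax, 5)                       # lag: the maximum is not immediate
  expect_lt(imax, nrow(rs))                # and not at the end
  expect_lt(rs$rate_uM_s[nrow(rs)], 0.1 * max(rs$rate_uM_s))  # decline
  # rise before the peak, fall after it (unimodal up to solver wiggle)
  expect_true(all(diff(rs$rate_uM_s[1:imax]) > -1e-6))
  expect_true(all(diff(rs$rate_uM_s[imax:nrow(rs)]) < 1e-6))
})

test_that("maximum rate increases with either enzyme", {
  rate_at <- function(pdi, ero)
    max_consumption_rate(trajectory_trace(opf_simulate(
      gsh_assay_conditions(pdi = pdi, ero = ero, duration = 600,
                           interval = 2), k_default)))
  pdi_rates <- vapply(c(1, 5, 15), rate_at, numeric(1), ero = 1)
  expect_true(all(diff(pdi_rates) > 0))
  ero_rates <- vapply(c(0.25, 1, 2), function(e) rate_at(5, e), numeric(1))
  expect_true(all(diff(ero_rates) > 0))
})

test_that("removing the activation bottleneck shortens the lag", {
  time_to_max <- function(k) {
    tr <- trajectory_trace(opf_simulate(
      gsh_assay_conditions(pdi = 5, ero = 1, duration = 600, interval = 1), k))
    rs <- windowed_rate(strip_baseline(tr, 100), 10)
    rs$time_s[which.max(rs$rate_uM_s)]
  }
  slow <- time_to_max(k_default)
  fast <- time_to_max(opf_constants(ka1 = 50, ka2 = 50))
  expect_lt(fast, slow)
})

test_that("electron ledger balances for simulated runs and flags corruption", {
  cond <- gsh_assay_conditions(pdi = 5, ero = 1, duration = 400)
  traj <- opf_simulate(cond, k_default)
  expect_lt(electron_balance(traj), 1e-6 * 40000)

  corrupted <- traj
  corrupted$GSSG[200] <- corrupted$GSSG[200] + 1
  expect_gt(electron_balance(corrupted), 1)
})

test_that("electron ledger at the end of a DTT assay matches hand arithmetic", {
  cond <- opf_conditions(ero = 1, dtt = 2000, duration = 120, interval = 10,
                         diffusion = FALSE)
  traj <- opf_simulate(cond, k_default)
  last <- traj[nrow(traj), ]
  # every O2 consumed took two electrons (appears as H2O2); the remaining
  # reduced equivalents sit in DTT and the Ero1p states
  stored <- 2 * last$DTT_red + 2 * last$ERO_r1 + 4 * last$ERO_act_ox +
    6 * last$ERO_act_red + 2 * last$PDI_red + last$PDI_mix + last$GSH
  initial <- 2 * 2000
  expect_equal(stored + 2 * last$H2O2, initial, tolerance = 1e-8)
  expect_lt(electron_balance(traj), 1e-6 * 2000)
})

test_that("trajectories with diffusion off never leak oxygen accounting", {
  # O2 consumed equals H2O2 produced in a closed cell
  cond <- opf_conditions(ero = 1, dtt = 5000, duration = 300,
                         diffusion = FALSE)
  traj <- opf_simulate(cond, k_default)
  expect_equal(traj$O2[1] - traj$O2, traj$H2O2 - traj$H2O2[1],
               tolerance = 1e-8)
})

test_that("simulation errors carry context for invalid setups", {
  expect_error(opf_conditions(duration = -5), "duration")
  expect_error(opf_conditions(pdi = -1), ">= 0")
  expect_error(opf_conditions(injections = data.frame(
    time_s = 999, species = "ero", amount_uM = 1), duration = 500),
    "within")
})
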