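test_that("grid scan records metrics per cell and survives degenerate pairs", {
  crit <- validity_criteria(min_final_population = 5, t_end_days = 150)
  scan <- grid_scan_growth(kv_values = c(0, 0.05), c0_values = c(1, 16),
                           criteria = crit)
  expect_equal(nrow(scan$grid), 4)
  expect_true(all(c("final_population", "n_populated", "valid", "reason")
                  %in% names(scan$grid)))
  # k_V = 0: zero capacity forever, never a valid tumor
  expect_false(any(scan$grid$valid[scan$grid$k_v == 0]))
  # deterministic model: repeating the scan is bitwise-identical
  scan2 <- grid_scan_growth(kv_values = c(0, 0.05), c0_values = c(1, 16),
                            criteria = crit)
  expect_identical(scan$grid, scan2$grid)
})

test_that("run selection is argmin over valid cells with deterministic ties", {
  fake_scan <- function(df) {
    structure(list(grid = df), class = "scan_result")
  }
  one <- fake_scan(data.frame(k_v = 0.1, c0_pct = 16, final_population = 2e7,
                              n_populated = 10, valid = TRUE, reason = ""))
  expect_equal(select_valid_run(one)$k_v, 0.1)
  two <- fake_scan(data.frame(k_v = c(0.1, 0.2), c0_pct = c(16, 16),
                              final_population = c(5e7, 2e7),
                              n_populated = 10, valid = TRUE, reason = ""))
  expect_equal(select_valid_run(two)$final_population, 2e7)
  tie <- fake_scan(data.frame(k_v = c(0.2, 0.1), c0_pct = c(16, 8),
                              final_population = 2e7,
                              n_populated = 10, valid = TRUE, reason = ""))
  expect_equal(select_valid_run(tie)$k_v, 0.1)
  none <- fake_scan(data.frame(k_v = 0.1, c0_pct = 16, final_population = 10,
                               n_populated = 2, valid = FALSE, reason = "x"))
  sel <- select_valid_run(none)
  expect_false(sel$valid)
  expect_match(sel$message, "no valid tumor")
})

test_that("sensitivity sweeps validate names and degenerate to plain runs", {
  expect_error(sensitivity_sweep("banana", 1), "k_V, C_0, phi_or_psi")
  sw <- sensitivity_sweep("k_V", 0.05, config = short_config(120))
  expect_equal(length(sw$runs), 1L)
  plain <- simulate_growth(update_config(short_config(120), k_v = 0.05))
  expect_identical(sw$runs[[1]]$P, plain$P)
})

test_that("half-life sweep families are ordered pointwise", {
  traj <- simulate_growth(short_config(150))
  sw <- sensitivity_sweep("t_half", c(0.64, 6.4, 64, 640),
                          config = short_config(150), growth_traj = traj)
  expect_equal(sw$mode, "shedding")
  for (j in 1:3) {
    expect_true(all(sw$runs[[j + 1]]$nonEC$q - sw$runs[[j]]$nonEC$q >= -1e-9))
    expect_true(all(sw$runs[[j + 1]]$EC$q - sw$runs[[j]]$EC$q >= -1e-9))
  }
})

test_that("per-compartment decomposition is exact and normalized", {
  traj <- simulate_growth(short_config(400))
  shed <- simulate_shedding(traj, default_proteins()[[1]])
  dec <- per_compartment_decomposition(traj, shed)
  for (tt in c(0, 100, 400)) {
    rows <- dec[dec$t_day == tt, ]
    expect_equal(sum(rows$P), sum(traj$P[tt + 1, ]), tolerance = 1e-12)
    expect_equal(sum(rows$u), sum(shed$u[tt + 1, ]), tolerance = 1e-12)
    if (sum(rows$P) > 0) expect_equal(sum(rows$P_share), 1, tolerance = 1e-12)
    if (sum(rows$D_inst) > 0) expect_equal(sum(rows$D_share), 1,
                                           tolerance = 1e-12)
  }
  # the innermost, best-oxygenated compartment dominates early growth
  early <- dec[dec$t_day == 50, ]
  expect_gt(early$P_share[early$comp == 1], 0.5)
  # distal compartments contribute disproportionately to death
  late <- dec[dec$t_day == 400, ]
  expect_gt(late$D_share[late$comp == 10], late$P_share[late$comp == 10])
  # misaligned time axes are rejected
  shed_short <- simulate_shedding(simulate_growth(short_config(100)),
                                  default_proteins()[[1]])
  expect_error(per_compartment_decomposition(traj, shed_short), "aligned")
})

test_that("scan envelopes equal the brute-force pointwise extremes", {
  traj <- simulate_growth(short_config(150))
  ec_ref <- protein_params("EC_ref", ec = 1, phi = 4.5e-4,
                           t_half_days = 6.4, u_h = 456)
  psi_g <- c(0.01, 1)
  th_g <- c(0.64, 6.4)
  uh_g <- c(4.56, 456)
  scan <- protein_scan_envelopes(psi_g, uh_g, th_g, traj, ec_ref)
  probe <- round(seq(1, length(traj$t), length.out = 10))
  for (a in seq_along(uh_g)) {
    qs <- sapply(seq_len(4), function(j) {
      combo <- expand.grid(psi = psi_g, t_half = th_g)[j, ]
      pp <- protein_params(ec = 0, psi = combo$psi,
                           t_half_days = combo$t_half, u_h = uh_g[a])
      simulate_shedding(traj, pp)$q
    })
    env <- scan$envelopes[[a]]
    expect_equal(env$q_min[probe], apply(qs[probe, ], 1, min),
                 tolerance = 1e-12)
    expect_equal(env$q_max[probe], apply(qs[probe, ], 1, max),
                 tolerance = 1e-12)
    expect_true(env$min_is_corner)
    expect_true(env$max_is_corner)
  }
})

test_that("a single-point scan grid collapses min and max", {
  traj <- simulate_growth(short_config(80))
  ec_ref <- protein_params("EC_ref", ec = 1, phi = 4.5e-4, u_h = 456)
  scan <- protein_scan_envelopes(1, 456, 6.4, traj, ec_ref)
  env <- scan$envelopes[[1]]
  expect_equal(env$q_min, env$q_max)
})

test_that("boosted non-EC parameters overtake the EC reference", {
  # xenograft comparison: no healthy influx on either protein
  traj <- simulate_growth(short_config(400))
  ec_ref <- protein_params("EC_ref", ec = 1, phi = 4.5e-4,
                           t_half_days = 6.4, u_h = 0)
  scan <- protein_scan_envelopes(psi_values = c(1.423e-2, 4.5e2),
                                 uh_values = 0,
                                 thalf_values = c(0.64, 640),
                                 traj = traj, ec_reference = ec_ref)
  env <- scan$envelopes[[1]]
  expect_false(is.na(env$crossover_day))
  nt <- length(traj$t)
  expect_gt(env$q_max[nt], scan$ec_reference_q[nt])
})
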