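test_that("elimination rate follows the half-life relation", {
  expect_equal(elimination_rate(6.4), log(2) / 6.4)
  expect_equal(elimination_rate(6.4), 0.10830, tolerance = 1e-4)
  expect_equal(elimination_rate(1e12), 0, tolerance = 1e-10)
  expect_error(elimination_rate(0), "positive")
  expect_error(elimination_rate(-3), "positive")
})

test_that("short half-lives trigger the stability contract", {
  pp <- protein_params(ec = 0, psi = 1, t_half_days = 0.64, u_h = 0, q0 = 0)
  expect_gt(pp$k_e, 1)  # ~1.083/day: unstable at dt = 1 without splitting
  expect_error(step_plasma(10, 0, pp, substep = FALSE), "unstable")
  expect_identical(plasma_substeps(elimination_rate(6.4)), 1L)
  expect_identical(plasma_substeps(elimination_rate(0.64)), 3L)
  # sub-stepped update stays nonnegative and decays toward the fixed point
  q <- 1000
  for (i in 1:50) q <- step_plasma(q, 5, pp)
  expect_gte(q, 0)
  expect_equal(q, 5 / pp$k_e, tolerance = 1e-3)
})

test_that("compartment outflux separates EC and non-EC sources", {
  rt <- list(w = 0.4472)
  ec <- protein_params(ec = 1, phi = 4.5e-4, u_h = 0, q0 = 0)
  nonec <- protein_params(ec = 0, psi = 4.5e-4, u_h = 0, q0 = 0)
  expect_equal(compartment_outflux(1000, 0, rt, ec), 0.2012, tolerance = 1e-3)
  expect_equal(compartment_outflux(1000, 100, rt, nonec), 0.02012,
               tolerance = 1e-3)
  expect_equal(compartment_outflux(c(1e5, 1e5), c(0, 0),
                                   list(w = c(0.4, 0.1)), nonec), c(0, 0))
})

test_that("plasma recurrence has the influx fixed point", {
  pp <- protein_params(ec = 1, phi = 0, t_half_days = 6.4, u_h = 456)
  k_e <- elimination_rate(6.4)
  expect_equal(step_plasma(0, 0, pp), 456)
  q_star <- 456 / k_e
  expect_equal(q_star, 4210, tolerance = 1e-3)
  expect_equal(step_plasma(q_star, 0, pp), q_star, tolerance = 1e-12)
  q_star2 <- (120 + 456) / k_e
  expect_equal(step_plasma(q_star2, 120, pp), q_star2, tolerance = 1e-12)
})

test_that("plasma mass converges geometrically to the fixed point", {
  pp <- protein_params(ec = 1, phi = 0, t_half_days = 6.4, u_h = 456, q0 = 0)
  k_e <- pp$k_e
  q_star <- 456 / k_e
  q <- 0
  for (t in 1:60) {
    q <- step_plasma(q, 0, pp)
    # closed-form geometric series oracle
    expect_equal(q - q_star, (1 - k_e)^t * (0 - q_star), tolerance = 1e-10)
  }
})

test_that("a tumor-free system stays at the healthy baseline", {
  rt <- default_rates()
  traj <- fake_trajectory(P = matrix(0, 50, 10), D_inst = matrix(0, 50, 10),
                          rates = rt)
  pp <- protein_params(ec = 1, phi = 4.5e-4, t_half_days = 6.4, u_h = 456)
  shed <- simulate_shedding(traj, pp)
  expect_equal(shed$q, rep(456 / pp$k_e, 50), tolerance = 1e-12)
})

test_that("non-EC plasma excess is identically zero before the first death", {
  rt <- default_rates()
  nt <- 40
  D <- matrix(0, nt, 10)
  D[22:nt, 1] <- 50  # deaths start on day 21
  P <- matrix(1e4, nt, 10)
  traj <- fake_trajectory(P = P, D_inst = D, rates = rt)
  pp <- protein_params(ec = 0, psi = 4.5e-4, t_half_days = 6.4, u_h = 456)
  shed <- simulate_shedding(traj, pp)
  baseline <- 456 / pp$k_e
  expect_equal(shed$q[1:22], rep(baseline, 22), tolerance = 1e-12)
  expect_true(all(shed$q[23:nt] > baseline))
})

test_that("xenograft EC shedding matches an independent hand-rolled recurrence", {
  cfg <- make_fixture_config("xenograft_no_uh")
  traj <- simulate_growth(cfg, t_end = 100)
  pp <- cfg$proteins[[1]]
  expect_identical(pp$u_h, 0)
  expect_identical(pp$q0, 0)
  shed <- simulate_shedding(traj, pp)
  # oracle: direct evaluation of the difference equation from raw matrices
  w <- traj$rates$w
  q_ref <- numeric(101)
  for (t in 1:100) {
    u_tot <- sum(w * pp$phi * traj$P[t, ])
    q_ref[t + 1] <- u_tot + pp$u_h + (1 - pp$k_e) * q_ref[t]
  }
  expect_equal(shed$q, q_ref, tolerance = 1e-12)
  expect_true(all(shed$q[-1] > 0))
})

test_that("plasma mass is linear in the shedding rate", {
  traj <- simulate_growth(short_config(150))
  mk <- function(phi) protein_params(ec = 1, phi = phi, t_half_days = 6.4,
                                     u_h = 456)
  q0 <- simulate_shedding(traj, mk(0))$q
  q1 <- simulate_shedding(traj, mk(4.5e-4))$q
  q2 <- simulate_shedding(traj, mk(9e-4))$q
  expect_equal(q2 - q0, 2 * (q1 - q0), tolerance = 1e-8)
})

test_that("plasma mass is monotone in half-life, shedding rate and influx", {
  traj <- simulate_growth(short_config(150))
  q_at <- function(t_half = 6.4, psi = 4.5e-4, u_h = 456) {
    pp <- protein_params(ec = 0, psi = psi, t_half_days = t_half, u_h = u_h,
                         q0 = 0)
    simulate_shedding(traj, pp)$q
  }
  fam_th <- lapply(c(0.64, 6.4, 64, 640), function(x) q_at(t_half = x))
  fam_psi <- lapply(c(1e-4, 1e-2, 1), function(x) q_at(psi = x))
  fam_uh <- lapply(c(4.56, 456, 45600), function(x) q_at(u_h = x))
  for (fam in list(fam_th, fam_psi, fam_uh)) {
    for (j in seq_len(length(fam) - 1)) {
      expect_true(all(fam[[j + 1]] - fam[[j]] >= -1e-9))
    }
  }
})

test_that("EC dominates non-EC while viable shedding outpaces necrotic release", {
  traj <- simulate_growth(short_config(200))
  ec <- protein_params(ec = 1, phi = 4.5e-4, t_half_days = 6.4, u_h = 456)
  nonec <- protein_params(ec = 0, psi = 4.5e-4, t_half_days = 6.4, u_h = 456)
  s_ec <- simulate_shedding(traj, ec)
  s_ne <- simulate_shedding(traj, nonec)
  # early tumors: P*phi exceeds D*psi compartmentwise, so EC mass leads
  expect_true(all(s_ec$u >= s_ne$u))
  expect_true(all(s_ec$q >= s_ne$q))
})

test_that("batch evaluation reuses one growth trajectory for many proteins", {
  traj <- simulate_growth(short_config(100))
  out <- simulate_shedding_batch(traj, default_proteins())
  expect_named(out, c("EC_baseline", "nonEC_baseline"))
  expect_equal(out$EC_baseline$q,
               simulate_shedding(traj, default_proteins()[[1]])$q)
})
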