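# The auxiliary-region coupling: propensities, SSA primitives, enactments,
# and the event-driven hybrid loop

test_that("jump rate is D / h_a^2", {
  expect_equal(jump_rate(0.0025, 0.05), 1)
  expect_equal(jump_rate(0.025, 0.05), 10)
  expect_equal(jump_rate(0, 0.05), 0) # sealed interface
  expect_error(jump_rate(0.0025, 0), "positive")
})

test_that("propensities follow the jump rates with the N_PA < 1 clamp", {
  st <- interface_state(0, 0.05, D = 0.0025) # d = 1
  st$n_pa <- 0.7; st$n_ba <- 0L
  p <- propensities(st)
  expect_equal(p$alpha_P, 0) # clamp: withdrawing a particle would go negative
  st$n_pa <- 12.5; st$n_ba <- 13L
  p <- propensities(st)
  expect_equal(p$alpha_P, 12.5)
  expect_equal(p$alpha_B, 13)
  expect_equal(p$alpha0, 25.5)
  st$n_pa <- -1
  expect_error(propensities(st), "negative")
})

test_that("second-order auxiliary reactions use the combinatorial propensity", {
  net <- reaction_network(
    channels = list(list(name = "2A->0", reactants = c(A = 2L),
                         products = integer(0), rate = 0.01)),
    compartment_size = 0.05)
  st <- interface_state(0, 0.05, D = 0.0025)
  st$n_pa <- 0; st$n_ba <- 5L
  p <- propensities(st, net)
  expect_equal(unname(p$alpha_r["2A->0"]), 10 * 0.01 / 0.05) # g = 5*4/2
  st$n_ba <- 1L # below the stoichiometric requirement
  expect_equal(unname(propensities(st, net)$alpha_r["2A->0"]), 0)
})

test_that("waiting times are exponential with rate alpha0", {
  expect_equal(sample_waiting_time(2, u = 1), 0)
  expect_equal(sample_waiting_time(2, u = exp(-1)), 0.5)
  expect_identical(sample_waiting_time(0), Inf)
  set.seed(20)
  taus <- vapply(runif(1e5), function(u) sample_waiting_time(1, u), numeric(1))
  expect_lt(abs(mean(taus) - 1), 3 / sqrt(1e5))
})

test_that("event selection inverts the cumulative propensities", {
  st <- interface_state(0, 0.05, D = 0.0025)
  st$n_pa <- 5; st$n_ba <- 0L
  p <- propensities(st)
  expect_equal(select_event(p, u2 = 0.99)$type, "jump_P_to_B")
  st$n_pa <- 1; st$n_ba <- 3L
  p <- propensities(st)
  set.seed(21)
  draws <- replicate(1e5, select_event(p)$type)
  frac <- mean(draws == "jump_P_to_B")
  expect_lt(abs(frac - 0.25), 3 * sqrt(0.25 * 0.75 / 1e5))
  st$n_pa <- 0; st$n_ba <- 0L
  expect_error(select_event(propensities(st)), "positive")
})

test_that("jump enactments conserve mass and move exactly one particle", {
  set.seed(22)
  f <- pde_field(-1, 0, 0.01, values = 250)
  e <- particle_ensemble(runif(10, 0, 0.05), 0, 1)
  st <- interface_state(0, 0.05, D = 0.0025, field = f, ensemble = e)
  total0 <- sum(f$values) * f$h_p + nrow(e$pos)
  out <- enact_jump_P_to_B(f, e, st)
  st1 <- update_counts(st, out$field, out$ensemble)
  expect_equal(st1$n_pa, st$n_pa - 1, tolerance = 1e-12)
  expect_equal(st1$n_ba, st$n_ba + 1L)
  expect_equal(sum(out$field$values) * f$h_p + nrow(out$ensemble$pos), total0,
               tolerance = 1e-12)
  out2 <- enact_jump_B_to_P(f, e, st)
  st2 <- update_counts(st, out2$field, out2$ensemble)
  expect_equal(st2$n_ba, st$n_ba - 1L)
  # density in the PDE auxiliary region rises by exactly 1/h_a
  expect_equal(out2$field$values[96:100] - f$values[96:100], rep(20, 5))
  expect_equal(sum(out2$field$values) * f$h_p + nrow(out2$ensemble$pos),
               total0, tolerance = 1e-12)
})

test_that("P -> B placements are uniform over the Brownian auxiliary region", {
  set.seed(23)
  f <- pde_field(-1, 0, 0.01, values = 1e6)
  e <- particle_ensemble(numeric(0), 0, 1)
  st <- interface_state(0, 0.05, D = 0.0025, field = f, ensemble = e)
  xs <- replicate(1e4, enact_jump_P_to_B(f, e, st)$ensemble$pos[1, 1])
  expect_gt(ks.test(xs / 0.05, "punif")$p.value, 0.01)
})

test_that("B -> P removal picks uniformly among auxiliary particles", {
  set.seed(24)
  f <- pde_field(-1, 0, 0.01, values = 250)
  e <- particle_ensemble(c(0.01, 0.02, 0.03, 0.5), 0, 1)
  st <- interface_state(0, 0.05, D = 0.0025, field = f, ensemble = e)
  kept <- replicate(1e4, {
    out <- enact_jump_B_to_P(f, e, st)
    setdiff(c(0.01, 0.02, 0.03), out$ensemble$pos[, 1])
  })
  freq <- table(factor(kept, levels = c(0.01, 0.02, 0.03))) / 1e4
  expect_true(all(abs(freq - 1 / 3) < 3 * sqrt((1 / 3) * (2 / 3) / 1e4)))
  # the particle outside the auxiliary region is never removed
  expect_false(0.5 %in% kept)
})

test_that("auxiliary reactions act only on particles in the region", {
  ch <- list(name = "2A->0", reactants = c(A = 2L), products = integer(0),
             rate = 0.01)
  e <- particle_ensemble(c(0.01, 0.03, 0.7), 0, 1)
  st <- interface_state(0, 0.05, D = 0.0025)
  set.seed(25)
  out <- enact_aux_reaction(e, st, ch)
  expect_equal(nrow(out$pos), 1L)
  expect_equal(out$pos[1, 1], 0.7) # the outsider survives
  expect_error(enact_aux_reaction(out, st, ch), "insufficient")
  # a pure birth channel places its product uniformly in the region
  birth <- list(name = "0->A", reactants = integer(0), products = c(A = 1L),
                rate = 0.5)
  set.seed(26)
  xs <- replicate(5000, enact_aux_reaction(
    particle_ensemble(numeric(0), 0, 1), st, birth)$pos[1, 1])
  expect_true(all(xs >= 0 & xs < 0.05))
  expect_gt(ks.test(xs / 0.05, "punif")$p.value, 0.01)
})

test_that("a short hybrid run conserves mass exactly and keeps ledger coherence", {
  cfg <- make_test_problem("tp1", t_end = 10, snapshot_times = seq(0, 10, 2))
  set.seed(27)
  tr <- run_hybrid(cfg)
  expect_true(all(abs(tr$total_mass - 500) / 500 < 1e-9))
  expect_lt(tr$ledger$max_drift, 1e-12)
  expect_equal(tr$ledger$final_mass, tr$ledger$expected_mass,
               tolerance = 1e-12)
})

test_that("a sealed interface (D = 0) freezes both regime totals", {
  cfg <- make_test_problem("tp1", D = 0, t_end = 2,
                           snapshot_times = seq(0, 2, 1))
  set.seed(28)
  tr <- run_hybrid(cfg)
  expect_true(all(tr$pde_mass == tr$pde_mass[1]))
  expect_true(all(tr$n_b == tr$n_b[1]))
  expect_equal(tr$ledger$jumps_pb + tr$ledger$jumps_bp, 0)
})

test_that("with both updates disabled the hybrid is the two-box jump process", {
  # short distributional check; the full 1e5-realization comparison against
  # the closed-form mean lives in the acceptance suite
  tb <- make_two_box(nu0 = 10, mu_P = 8, d = 1, t_end = 1, dt = 0.5)
  mp <- vapply(1:4000, function(s) {
    set.seed(s)
    run_hybrid(tb, record_particles = FALSE)$npa[3]
  }, numeric(1))
  m <- two_box_mean(10, 8, 1, 1)
  expect_lt(abs(mean(mp) - m), 3 * sd(mp) / sqrt(4000))
  # occupancies stay integer: jumps move exactly one particle at a time
  expect_true(all(mp == round(mp)))
})

test_that("identical seeds give bit-identical trajectories", {
  cfg <- make_test_problem("tp1", t_end = 5, snapshot_times = c(0, 5))
  set.seed(29); a <- run_hybrid(cfg)
  set.seed(29); b <- run_hybrid(cfg)
  expect_identical(a$pde, b$pde)
  expect_identical(a$particles, b$particles)
  expect_identical(a$ledger, b$ledger)
})
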