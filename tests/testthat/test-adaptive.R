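# Adaptive interface: thresholds, conversions, conservation

make_tp4_like_field <- function(dens = 20, iface = 2, h_p = 0.1) {
  pde_field(0, iface, h_p, values = dens)
}

test_that("thresholds must satisfy beta_u > beta_l", {
  expect_error(adaptive_config(4, 4), "beta_u > beta_l")
  cfgok <- adaptive_config(4, 9.5)
  expect_equal(cfgok$beta_l, 4)
  expect_equal(cfgok$beta_u, 9.5)
})

test_that("occupancies between the thresholds leave the interface in place", {
  f <- make_tp4_like_field(dens = 10, iface = 2)     # N_PA = 10*0.5 = 5
  e <- particle_ensemble(seq(2.01, 2.48, length.out = 8), 2, 10) # N_BA = 8
  st <- interface_state(2, 0.5, D = 0.2)
  out <- check_and_move(f, e, st, adaptive_config(4, 9.5), domain = c(0, 10))
  expect_equal(out$moved, 0L)
  expect_equal(out$state$iface, 2)
})

test_that("a depleted PDE auxiliary region moves the interface left by h_a", {
  f <- make_tp4_like_field(dens = 6.4, iface = 2)    # N_PA = 3.2 < 4
  e <- particle_ensemble(seq(2.01, 2.48, length.out = 5), 2, 10)
  st <- interface_state(2, 0.5, D = 0.2)
  set.seed(31)
  out <- check_and_move(f, e, st, adaptive_config(4, 9.5), domain = c(0, 10))
  expect_equal(out$moved, -1L)
  expect_equal(out$state$iface, 1.5)
  expect_equal(out$field$x1, 1.5)
  # total mass conserved exactly for this realization
  before <- sum(f$values) * f$h_p + nrow(e$pos)
  after <- sum(out$field$values) * out$field$h_p + nrow(out$ensemble$pos)
  expect_equal(after, before, tolerance = 1e-12)
})

test_that("an overfull Brownian auxiliary region moves the interface right by h_a", {
  f <- make_tp4_like_field(dens = 20, iface = 2)
  e <- particle_ensemble(seq(2.01, 2.49, length.out = 10), 2, 10) # N_BA = 10
  st <- interface_state(2, 0.5, D = 0.2)
  out <- check_and_move(f, e, st, adaptive_config(4, 9.5), domain = c(0, 10))
  expect_equal(out$moved, 1L)
  expect_equal(out$state$iface, 2.5)
  # converted slab carries density N_BA / h_a = 20
  expect_equal(tail(out$field$values, 5), rep(20, 5))
  expect_equal(nrow(out$ensemble$pos), 0L)
})

test_that("pde_to_particles realizes floor-plus-Bernoulli counts, unbiased", {
  f <- make_tp4_like_field(dens = 6.8, iface = 2)    # N_PA = 3.4
  st <- interface_state(2, 0.5, D = 0.2)
  set.seed(32)
  ns <- replicate(1e4, pde_to_particles(f, st)$n)
  expect_true(all(ns %in% c(3, 4)))
  expect_lt(abs(mean(ns) - 3.4), 3 * sd(ns) / sqrt(1e4))
  # integer pseudo-particle count converts exactly, rescale factor 1
  f5 <- make_tp4_like_field(dens = 10, iface = 2)    # N_PA = 5.0
  out5 <- pde_to_particles(f5, st)
  expect_equal(out5$n, 5)
  expect_equal(out5$factor, 1)
  # per-realization conservation through the rescale
  set.seed(33)
  for (i in 1:5) {
    out <- pde_to_particles(f, st)
    after <- sum(out$field$values) * 0.1 + out$n
    expect_equal(after, sum(f$values) * 0.1, tolerance = 1e-12)
  }
  # new particles live in the outgoing slab (the new Brownian aux region)
  expect_true(all(out5$new_particles[, 1] >= 1.5 &
                    out5$new_particles[, 1] < 2))
})

test_that("particles_to_pde lays down N_BA / h_a and tolerates an empty region", {
  f <- make_tp4_like_field(dens = 20, iface = 2)
  e <- particle_ensemble(c(seq(2.01, 2.49, length.out = 7), 5), 2, 10)
  st <- interface_state(2, 0.5, D = 0.2)
  out <- particles_to_pde(f, e, st)
  expect_equal(out$n, 7)
  expect_equal(tail(out$field$values, 5), rep(14, 5)) # 7 / 0.5
  expect_equal(nrow(out$ensemble$pos), 1L)
  before <- sum(f$values) * 0.1 + nrow(e$pos)
  after <- sum(out$field$values) * 0.1 + nrow(out$ensemble$pos)
  expect_equal(after, before, tolerance = 1e-12)
  # empty region: a valid zero-density slab
  e0 <- particle_ensemble(5, 2, 10)
  out0 <- particles_to_pde(f, e0, st)
  expect_equal(out0$n, 0)
  expect_equal(tail(out0$field$values, 5), rep(0, 5))
})

test_that("moves that would shrink a subdomain below h_a are suppressed", {
  f <- pde_field(0, 0.5, 0.1, values = 2) # N_PA = 1 < beta_l, but I - h_a = 0
  e <- particle_ensemble(0.7, 0.5, 10)
  st <- interface_state(0.5, 0.5, D = 0.2)
  expect_warning(
    out <- check_and_move(f, e, st, adaptive_config(4, 9.5),
                          domain = c(0, 10)),
    "suppressed")
  expect_equal(out$moved, 0L)
  f2 <- pde_field(0, 9.5, 0.1, values = 20)
  e2 <- particle_ensemble(seq(9.51, 9.99, length.out = 11), 9.5, 10)
  st2 <- interface_state(9.5, 0.5, D = 0.2)
  expect_warning(
    out2 <- check_and_move(f2, e2, st2, adaptive_config(4, 9.5),
                           domain = c(0, 10)),
    "suppressed")
  expect_equal(out2$moved, 0L)
})

test_that("grid alignment survives adaptive moves in a full hybrid run", {
  cfg <- make_test_problem("tp4")
  set.seed(34)
  tr <- run_hybrid(cfg)
  # interface always on the h_a lattice
  expect_true(all(abs(tr$iface / cfg$h_a - round(tr$iface / cfg$h_a)) < 1e-9))
  # PDE cell count always a whole number of auxiliary regions
  naux <- round(cfg$h_a / cfg$h_p)
  lens <- vapply(tr$pde, length, integer(1))
  expect_true(all(lens %% naux == 0))
  # every move conserved mass exactly
  expect_lt(tr$ledger$max_drift, 1e-12)
})
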