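# Brownian regime: diffusion, reflection, counting, microscopic reactions

test_that("zero diffusivity leaves the ensemble unchanged", {
  set.seed(1)
  e <- particle_ensemble(runif(50), 0, 1)
  expect_identical(bd_diffuse(e, dt = 0.02, D = 0)$pos, e$pos)
})

test_that("displacement variance matches 2*D*dt", {
  set.seed(2)
  n <- 1e5; D <- 0.0025; dt <- 0.02
  e <- particle_ensemble(rep(0, n), -1e6, 1e6) # effectively unconstrained
  d <- bd_diffuse(e, dt, D)$pos[, 1]
  v <- var(d)
  se <- sqrt(2 / (n - 1)) * 2 * D * dt
  expect_lt(abs(v - 2 * D * dt), 3 * se)
  expect_lt(abs(mean(d)), 3 * sqrt(2 * D * dt / n))
})

test_that("mirror reflection folds positions back into the domain", {
  expect_equal(auxregion:::reflect_fold(1.05, 0, 1), 0.95)
  expect_equal(auxregion:::reflect_fold(-0.3, 0, 1), 0.3)
  expect_equal(auxregion:::reflect_fold(2.4, 0, 1), 0.4) # double fold
  set.seed(3)
  e <- particle_ensemble(runif(200), 0, 1)
  suppressWarnings(f <- bd_diffuse(e, dt = 5, D = 0.25)) # huge steps
  expect_true(all(f$pos >= 0 & f$pos <= 1))
  expect_equal(nrow(f$pos), 200L)
})

test_that("reflection preserves the uniform distribution as stationary", {
  set.seed(4)
  e <- particle_ensemble(runif(2000), 0, 1)
  for (i in 1:1000) e <- bd_diffuse(e, dt = 0.02, D = 0.0025)
  counts <- tabulate(findInterval(e$pos[, 1], seq(0, 1, 0.1),
                                  rightmost.closed = TRUE), nbins = 10)
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.01)
})

test_that("count_in uses the half-open convention", {
  e <- particle_ensemble(c(0.01, 0.04, 0.06), 0, 1)
  expect_equal(count_in(e, c(0, 0.05)), 2)
  expect_equal(count_in(e, c(0, 1)), 3)
  expect_equal(count_in(e, c(0.06, 0.5)), 1) # lower edge included
  e0 <- particle_ensemble(numeric(0), 0, 1)
  expect_equal(count_in(e0, c(0, 1)), 0)
})

test_that("first-order decay removes the exact per-step fraction", {
  set.seed(5)
  e <- particle_ensemble(runif(1000), 0, 1)
  expect_identical(first_order_decay(e, mu = 0, dt = 0.02)$pos, e$pos)
  # binomial check over 1e6 particle-steps at the morphogen rate
  mu <- 0.001; dt <- 0.02
  p <- -expm1(-mu * dt)
  n <- 1e6
  big <- particle_ensemble(runif(n), 0, 1)
  removed <- n - nrow(first_order_decay(big, mu, dt)$pos)
  expect_lt(abs(removed / n - p), 3 * sqrt(p * (1 - p) / n))
  # mu*dt = 50: everything goes
  expect_equal(nrow(first_order_decay(e, mu = 2500, dt = 0.02)$pos), 0L)
})

test_that("zeroth-order birth is a single Bernoulli event with the right rate", {
  e <- particle_ensemble(matrix(numeric(0), ncol = 3),
                         c(0.5, 0, 0), c(10, 2, 2)) # V_B = 38 at I0 = 0.5
  expect_identical(nrow(zeroth_order_birth(e, kappa2 = 0, dt = 0.01)$pos), 0L)
  set.seed(6)
  p_birth <- 0.5 * 0.01 * 38 # tp4 rates at the initial Brownian volume: 0.19
  nstep <- 1e4
  births <- 0
  for (i in seq_len(nstep)) {
    out <- zeroth_order_birth(e, kappa2 = 0.5, dt = 0.01)
    births <- births + nrow(out$pos)
  }
  expect_lt(abs(births / nstep - p_birth),
            3 * sqrt(p_birth * (1 - p_birth) / nstep))
  # birth positions uniform per axis
  set.seed(7)
  pos <- t(replicate(3000, {
    repeat {
      out <- zeroth_order_birth(e, kappa2 = 0.5, dt = 0.01)
      if (nrow(out$pos)) return(out$pos[1, ])
    }
  }))
  expect_gt(ks.test((pos[, 1] - 0.5) / 9.5, "punif")$p.value, 0.01)
  expect_gt(ks.test(pos[, 2] / 2, "punif")$p.value, 0.01)
  expect_gt(ks.test(pos[, 3] / 2, "punif")$p.value, 0.01)
  # configuration error when the per-step probability reaches 1
  expect_error(zeroth_order_birth(e, kappa2 = 0.5, dt = 10), ">= 1")
})

test_that("lambda-rho pairs react only when close, outside the exclusion slab", {
  # far apart: nothing happens
  e <- particle_ensemble(cbind(c(0.1, 5, 9), 1, 1), c(0, 0, 0), c(10, 2, 2))
  expect_equal(nrow(lambda_rho_step(e, rho = 0.1, P_lambda = 1)$pos), 3L)
  # a close pair outside the exclusion reacts with P_lambda = 1
  e2 <- particle_ensemble(cbind(c(5.00, 5.04), 1, 1), c(0, 0, 0), c(10, 2, 2))
  out <- lambda_rho_step(e2, rho = 0.1, P_lambda = 1,
                         exclusion = c(0.5, 1.0))
  expect_equal(nrow(out$pos), 0L)
  expect_equal(attr(out, "n_pairs_reacted"), 1)
  # the same pair wholly inside the exclusion slab is untouched
  e3 <- particle_ensemble(cbind(c(0.60, 0.64), 1, 1), c(0, 0, 0), c(10, 2, 2))
  out3 <- lambda_rho_step(e3, rho = 0.1, P_lambda = 1,
                          exclusion = c(0.5, 1.0))
  expect_equal(nrow(out3$pos), 2L)
  # P_lambda = 0 never reacts
  expect_equal(nrow(lambda_rho_step(e2, rho = 0.1, P_lambda = 0)$pos), 2L)
  # each particle reacts at most once: three mutually close particles
  # leave exactly one survivor
  set.seed(8)
  e4 <- particle_ensemble(cbind(c(5.00, 5.01, 5.02), 1, 1),
                          c(0, 0, 0), c(10, 2, 2))
  out4 <- lambda_rho_step(e4, rho = 0.1, P_lambda = 1)
  expect_equal(nrow(out4$pos), 1L)
  # a radius at or above h_a triggers the safety warning
  expect_warning(lambda_rho_step(e2, rho = 0.6, P_lambda = 0, warn_ha = 0.5),
                 "h_a")
})

test_that("lambda-rho calibration is monotone and hits the macroscopic rate", {
  expect_equal(compute_P_lambda(0, 0.1, 0.2, 0.01), 0)
  p_ref <- compute_P_lambda(0.01, 0.1, 0.2, 0.01)
  expect_gt(p_ref, 0)
  expect_lt(p_ref, 1)
  expect_gt(compute_P_lambda(0.02, 0.1, 0.2, 0.01), p_ref)  # up in kappa1
  expect_lt(compute_P_lambda(0.01, 0.15, 0.2, 0.01), p_ref) # down in rho
  # naive well-mixed limit is a lower bound (depletion needs a larger P)
  expect_gt(p_ref, 0.01 * 0.01 / (4 / 3 * pi * 0.1^3) * 0.99)
  # an unreachable rate fails to bracket
  expect_error(compute_P_lambda(10, 0.05, 0.2, 0.001), "bracket")
})

test_that("calibrated lambda-rho reproduces the well-mixed mean decay of 2A -> 0", {
  # closed 10 x 2 x 2 box, kappa1 = 0.01, 200 particles; the reference is
  # the mean birth-death equation dn/dt = -kappa1 * phi * n(n-1) / V with
  # phi the exact reflective-wall pair-volume fraction of the box
  k1 <- 0.01; rho <- 0.1; D <- 0.2; dt <- 0.01; V <- 40
  pl <- compute_P_lambda(k1, rho, D, dt)
  phi <- box_pair_volume_fraction(10, 2, 2, rho)
  cfg <- sim_config(x0 = 0, x1 = 10, iface = 0.5, h_a = 0.5, h_p = 0.1,
                    dt = dt, t_end = 5, D = D, N = 200,
                    ic = list(type = "uniform"), kappa1 = k1, rho = rho,
                    P_lambda = pl, dim = 3, Ly = 2, Lz = 2,
                    snapshot_times = seq(0, 5, 1))
  S <- 200
  counts <- vapply(seq_len(S), function(s) {
    set.seed(s)
    run_microscopic(cfg, record_particles = FALSE)$n_b
  }, numeric(6))
  emp <- rowMeans(counts)
  se <- apply(counts, 1, sd) / sqrt(S)
  # integrate the mean equation
  tt <- seq(0, 5, 1)
  ode <- numeric(6); ode[1] <- 200
  cur <- 200; h <- 1e-3
  for (j in 2:6) {
    for (i in seq_len(1000)) cur <- cur + h * (-k1 * phi * cur * (cur - 1) / V)
    ode[j] <- cur
  }
  z <- (emp[-1] - ode[-1]) / se[-1]
  expect_true(all(abs(z) < 3))
})

test_that("diffusion is exchangeable over particle labels", {
  set.seed(9)
  x <- runif(2000)
  e1 <- particle_ensemble(x, 0, 1)
  e2 <- particle_ensemble(rev(x), 0, 1)
  set.seed(10); a <- bd_diffuse(e1, 0.02, 0.0025)$pos[, 1]
  set.seed(11); b <- bd_diffuse(e2, 0.02, 0.0025)$pos[, 1]
  expect_gt(stats::ks.test(a, b)$p.value, 0.01)
})
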