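# Ground-truth oracles the hybrid is validated against.

#' Mean-field diffusion solution (cosine series)
#'
#' Analytic solution of `dp/dt = D d2p/dx2` with zero-flux boundaries on
#' `domain`, for three canonical initial profiles: `uniform` mass `N`
#' everywhere, `left_step` (all mass uniform left of `step_at`), and `ramp`
#' (density decreasing linearly to zero at the right end).  The cosine
#' series is truncated once the tail bound drops below `tol`.
#'
#' @param x positions at which to evaluate.
#' @param t time (`>= 0`, scalar).
#' @param N total particle number.
#' @param D diffusion coefficient.
#' @param ic one of `"uniform"`, `"left_step"`, `"ramp"`.
#' @param domain length-2 vector `(a, b)`.
#' @param step_at split point of the `left_step` profile (default: midpoint
#'   `0` of the standard `(-1, 1)` domain, i.e. the interface).
#' @param tol series truncation tolerance.
#' @return densities `p(x, t)` (particles per unit length).
#' @export
meanfield_diffusion <- function(x, t, N = 500, D = 0.0025,
                                ic = c("uniform", "left_step", "ramp"),
                                domain = c(-1, 1), step_at = 0,
                                tol = 1e-10) {
  ic <- match.arg(ic)
  a <- domain[1]; b <- domain[2]; L <- b - a
  stopifnot(t >= 0, L > 0)
  xi <- x - a
  if (ic == "uniform") return(rep(N / L, length(x)))
  if (t == 0) {          # return the exact initial profile
    p0 <- switch(ic,
      left_step = ifelse(x < step_at, N / (step_at - a), 0),
      ramp = (2 * N / L) * (1 - xi / L))
    return(p0)
  }
  p <- rep(N / L, length(x))
  xc <- step_at - a
  m <- 1
  repeat {
    A <- switch(ic,
      left_step = (2 * N / (xc * m * pi)) * sin(m * pi * xc / L),
      ramp = 2 * (2 * N / L) * (1 - (-1)^m) / (m * pi)^2)
    decay <- exp(-D * (m * pi / L)^2 * t)
    p <- p + A * cos(m * pi * xi / L) * decay
    # remaining-tail bound: coefficients are O(1/m), decay is Gaussian in m
    if (abs(A) * decay < tol && m > 10) break
    m <- m + 1
    if (m > 1e5) break
  }
  p
}

#' Mean-field morphogen-gradient solution (fine-grid reference)
#'
#' Numerical solution of the whole-domain analogue of the morphogen model:
#' `dc/dt = D d2c/dx2 - mu c` with prescribed influx `D * lambda` at the
#' left boundary (`dc/dx = -lambda`), zero flux at the right, from a uniform
#' initial condition with total mass `N`.  Solved by Crank-Nicolson on a
#' fine grid; returns a function-like object evaluable on `(x, t)` via
#' linear interpolation in `x` at the stored output times.
#'
#' @param t_out times at which profiles are required (sorted, `>= 0`).
#' @param lambda boundary production parameter (influx rate `D * lambda`).
#' @param mu degradation rate.
#' @param D diffusion coefficient.
#' @param N initial total mass.
#' @param domain length-2 vector.
#' @param h reference grid spacing.
#' @param dt_ref reference time step.
#' @return list with `x` (cell centres), `t`, `profiles` (matrix, one
#'   column per output time) and an interpolator `density(x, t)`.
#' @export
meanfield_morphogen <- function(t_out, lambda = 400, mu = 0.001, D = 0.0025,
                                N = 500, domain = c(-1, 1), h = 1e-3,
                                dt_ref = 0.01) {
  t_out <- sort(unique(t_out))
  L <- domain[2] - domain[1]
  n <- as.integer(round(L / h))
  xc <- domain[1] + (seq_len(n) - 0.5) * h
  c_now <- rep(N / L, n)
  profiles <- matrix(NA_real_, n, length(t_out))
  t_now <- 0
  src_flux <- c(D * lambda / h, rep(0, n - 1L))
  for (j in seq_along(t_out)) {
    nsteps <- round((t_out[j] - t_now) / dt_ref)
    if (nsteps > 0) {
      for (s in seq_len(nsteps)) {
        src <- src_flux - mu * c_now
        c_now <- cpp_theta_solve(c_now, h, dt_ref, D, 0.5, src)
      }
      t_now <- t_now + nsteps * dt_ref
    }
    profiles[, j] <- c_now
  }
  density <- function(x, t) {
    j <- which.min(abs(t_out - t))
    approx(xc, profiles[, j], xout = x, rule = 2)$y
  }
  list(x = xc, t = t_out, profiles = profiles, density = density)
}

#' Reduce the 3-D second-order system to its closed 1-D PDE
#'
#' For the reaction pair `2A -> 0` (rate `kappa1`) and `0 -> A` (rate
#' `kappa2`), Poisson moment closure (`Var(A) = E[A]`) closes the mean
#' equation into `dc/dt = kappa2 - kappa1 c^2`; folding a translationally
#' invariant cuboid over its cross-section `L_y x L_z` gives the reduced
#' reaction operator for the 1-D density `C(x, t)` (particles per unit
#' length): `f(C) = kappa2 L_y L_z - kappa1 C^2 / (L_y L_z)`.
#'
#' @param kappa1 bimolecular annihilation rate (volume/time).
#' @param kappa2 production rate (1/volume/time).
#' @param Ly,Lz cross-section side lengths.
#' @return list with the reduced reaction operator `f`, and the well-mixed
#'   fixed point `fixed_point = L_y L_z sqrt(kappa2 / kappa1)` (reduced
#'   density units).
#' @export
moment_closure_reduce <- function(kappa1, kappa2, Ly, Lz) {
  stopifnot(Ly > 0, Lz > 0, kappa1 >= 0, kappa2 >= 0)
  A <- Ly * Lz
  list(
    f = function(C) kappa2 * A - kappa1 * C^2 / A,
    fixed_point = if (kappa1 > 0) A * sqrt(kappa2 / kappa1) else Inf,
    area = A)
}

#' Pair-volume fraction of a reflective box
#'
#' In a closed box, particles near a wall see part of their reaction sphere
#' cut off, so the well-mixed bimolecular rate is reduced by the exact
#' geometric factor
#' `phi = Pr(|x - y| < rho) / ((4/3) pi rho^3 / V)` for `x`, `y` uniform in
#' the box.  Closed form (valid for `rho` smaller than every side):
#' `F = (4 pi/3) rho^3 V - (pi/2) rho^4 (sum of face-pair areas) +
#' (8/15) rho^5 (sum of sides) - rho^6 / 6`, and `phi = F / ((4 pi/3) rho^3
#' V)`.  Used when validating the lambda-rho calibration against the
#' well-mixed mean equation in a bounded geometry.
#'
#' @param Lx,Ly,Lz box side lengths.
#' @param rho reaction radius (`< min(Lx, Ly, Lz)`).
#' @return the rate reduction factor `phi` in `(0, 1]`.
#' @export
box_pair_volume_fraction <- function(Lx, Ly, Lz, rho) {
  stopifnot(rho > 0, rho < min(Lx, Ly, Lz))
  V <- Lx * Ly * Lz
  Fv <- (4 * pi / 3) * rho^3 * V -
    (pi / 2) * rho^4 * (Lx * Ly + Lx * Lz + Ly * Lz) +
    (8 / 15) * rho^5 * (Lx + Ly + Lz) - rho^6 / 6
  Fv / ((4 * pi / 3) * rho^3 * V)
}

#' Mean occupancy of the two-compartment jump process
#'
#' Closed-form mean of the PDE-side auxiliary occupancy for the isolated
#' two-box jump process (both synchronous updates disabled): with `nu0`
#' particles in total, `mu_P` initially on the PDE side, and jump rate `d`
#' each way, `M_P(t) = (nu0 - (nu0 - 2 mu_P) exp(-2 d t)) / 2`.
#'
#' @param nu0 total particle count (conserved).
#' @param mu_P initial PDE-side count (`0 <= mu_P <= nu0`).
#' @param d jump rate.
#' @param t time(s), `>= 0`.
#' @return mean occupancy `M_P(t)`.
#' @export
two_box_mean <- function(nu0, mu_P, d, t) {
  stopifnot(all(t >= 0), mu_P >= 0, mu_P <= nu0)
  0.5 * (nu0 - (nu0 - 2 * mu_P) * exp(-2 * d * t))
}

#' Degenerate two-box configuration
#'
#' Builds a configuration in which both synchronous updates are disabled so
#' the hybrid reduces to the textbook two-compartment jump process: `mu_P`
#' pseudo-particles in the PDE auxiliary region, `nu0 - mu_P` particles in
#' the Brownian auxiliary region, jump rate `d` each way.
#'
#' @inheritParams two_box_mean
#' @param t_end final time.
#' @param dt snapshot spacing (no dynamics happen at updates).
#' @param h_a auxiliary width (the jump rate is realized as `D = d h_a^2`).
#' @return a `sim_config`.
#' @export
make_two_box <- function(nu0 = 10, mu_P = 8, d = 1, t_end = 2, dt = 0.25,
                         h_a = 0.05) {
  stopifnot(mu_P == round(mu_P), nu0 == round(nu0))
  sim_config(
    x0 = -0.2, x1 = 0.2, iface = 0, h_a = h_a, h_p = h_a, dt = dt,
    t_end = t_end, D = d * h_a^2, N = nu0,
    ic = list(type = "two_box", mu_P = mu_P),
    snapshot_times = seq(0, t_end, by = dt),
    pde_on = FALSE, bd_on = FALSE)
}
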