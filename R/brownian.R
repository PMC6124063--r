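# Individual-based regime: Brownian position updates with reflective
# boundaries, region counting and microscopic reactions.

#' Particle ensemble in the Brownian subdomain
#'
#' Holds explicit particle positions: a numeric vector for 1-D problems or a
#' 3-column matrix `(x, y, z)` for the cuboid geometry.  All positions must
#' lie inside the closed domain; Brownian updates re-impose this by mirror
#' reflection.
#'
#' @param positions numeric vector (1-D) or `n x 3` matrix (3-D).
#' @param lower,upper domain bounds per coordinate.
#' @return an object of class `particle_ensemble`.
#' @export
particle_ensemble <- function(positions, lower, upper) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 1L)
  positions <- as.matrix(positions)
  d <- ncol(positions)
  stopifnot(d %in% c(1L, 3L), length(lower) == d, length(upper) == d,
            all(upper > lower))
  if (nrow(positions) > 0L) {
    for (j in seq_len(d))
      if (any(positions[, j] < lower[j] | positions[, j] > upper[j]))
        stop("particle positions must lie inside the closed domain")
  }
  structure(list(pos = positions, lower = as.numeric(lower),
                 upper = as.numeric(upper), dim = d),
            class = "particle_ensemble")
}

#' @export
print.particle_ensemble <- function(x, ...) {
  cat(sprintf("<particle_ensemble> %d particle(s) in %d-D domain [%s] x [%s]\n",
              nrow(x$pos), x$dim,
              paste(signif(x$lower, 4), collapse = ", "),
              paste(signif(x$upper, 4), collapse = ", ")))
  invisible(x)
}

# mirror-fold x into [lo, hi] (vectorized; terminates for any displacement)
reflect_fold <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

#' Brownian update with reflective boundaries
#'
#' Adds `sqrt(2 D dt) * xi` to every coordinate, `xi ~ N(0, 1)` i.i.d., then
#' mirror-reflects (repeatedly, if necessary) any position that left the
#' domain.  A warning is raised if any single displacement exceeded the
#' domain width, which indicates a physically too-large `dt`.
#'
#' @param ensemble a [particle_ensemble()].
#' @param dt time step.
#' @param D diffusion coefficient (`>= 0`).
#' @return the updated ensemble.
#' @export
bd_diffuse <- function(ensemble, dt, D) {
  stopifnot(inherits(ensemble, "particle_ensemble"), dt > 0, D >= 0)
  n <- nrow(ensemble$pos)
  if (n == 0L || D == 0) return(ensemble)
  s <- sqrt(2 * D * dt)
  for (j in seq_len(ensemble$dim)) {
    disp <- s * rnorm(n)
    if (any(abs(disp) > ensemble$upper[j] - ensemble$lower[j]))
      warning("displacement exceeded the domain width; dt is too large for this D")
    ensemble$pos[, j] <- reflect_fold(ensemble$pos[, j] + disp,
                                      ensemble$lower[j], ensemble$upper[j])
  }
  ensemble
}

#' Count particles with x-coordinate in a half-open region
#'
#' Uses the half-open convention `[lo, hi)` throughout, so a particle
#' sitting exactly on the interface belongs to the Brownian auxiliary
#' region.
#'
#' @inheritParams bd_diffuse
#' @param region length-2 vector `(lo, hi)`.
#' @return integer count.
#' @export
count_in <- function(ensemble, region) {
  stopifnot(length(region) == 2L)
  x <- ensemble$pos[, 1]
  sum(x >= region[1] & x < region[2])
}

#' First-order decay enacted per particle per step
#'
#' Each particle is removed independently with the exact per-step
#' probability `1 - exp(-mu * dt)` (rather than the `O(mu dt)` approximation
#' `mu * dt`).
#'
#' @inheritParams bd_diffuse
#' @param mu decay rate (`>= 0`).
#' @return the updated ensemble.
#' @export
first_order_decay <- function(ensemble, mu, dt) {
  stopifnot(mu >= 0, dt > 0)
  n <- nrow(ensemble$pos)
  if (n == 0L || mu == 0) return(ensemble)
  keep <- runif(n) >= -expm1(-mu * dt)
  ensemble$pos <- ensemble$pos[keep, , drop = FALSE]
  ensemble
}

#' Zeroth-order birth: at most one particle per step
#'
#' With probability `kappa2 * dt * V_B` (which must be below 1) exactly one
#' particle is added uniformly at random in the domain.
#'
#' @inheritParams bd_diffuse
#' @param kappa2 production rate per unit volume per unit time.
#' @return the updated ensemble.
#' @export
zeroth_order_birth <- function(ensemble, kappa2, dt) {
  stopifnot(kappa2 >= 0, dt > 0)
  if (kappa2 == 0) return(ensemble)
  V <- prod(ensemble$upper - ensemble$lower)
  p <- kappa2 * dt * V
  if (p >= 1)
    stop("kappa2 * dt * V_B = ", signif(p, 4),
         " >= 1; choose a smaller dt so at most one birth can occur per step")
  if (runif(1) < p) {
    newp <- ensemble$lower + runif(ensemble$dim) *
      (ensemble$upper - ensemble$lower)
    ensemble$pos <- rbind(ensemble$pos, newp)
  }
  ensemble
}

#' One lambda-rho bimolecular step (2A -> 0)
#'
#' Every unordered pair closer than the reaction radius `rho`, with at least
#' one member outside the exclusion slab (the Brownian auxiliary region,
#' whose pairs are enacted by the compartment SSA instead), reacts with
#' probability `P_lambda`; both reactants are removed.  Pairs are processed
#' in randomized order and each particle reacts at most once per step.
#'
#' @inheritParams bd_diffuse
#' @param rho reaction radius.  A warning is raised if `rho >= h_a` would be
#'   violated; pass `h_a` via `warn_ha` to enable the check.
#' @param P_lambda per-step pair reaction probability, see
#'   [compute_P_lambda()].
#' @param exclusion optional `(lo, hi)` x-interval whose wholly-interior
#'   pairs are skipped; `NULL` disables the exclusion.
#' @param warn_ha optional auxiliary-region width for the `rho < h_a` sanity
#'   warning.
#' @return the updated ensemble, with attribute `n_pairs_reacted`.
#' @export
lambda_rho_step <- function(ensemble, rho, P_lambda, exclusion = NULL,
                            warn_ha = NULL) {
  stopifnot(rho > 0, P_lambda >= 0, P_lambda <= 1)
  if (!is.null(warn_ha) && rho >= warn_ha)
    warning("reaction radius rho >= auxiliary width h_a; ",
            "the interface exclusion is no longer safe")
  use_excl <- !is.null(exclusion)
  ex <- if (use_excl) as.numeric(exclusion) else c(0, 0)
  res <- cpp_lambda_rho(ensemble$pos, rho, P_lambda, use_excl, ex[1], ex[2])
  ensemble$pos <- res$pos
  attr(ensemble, "n_pairs_reacted") <- res$n_pairs_reacted
  ensemble
}

#' Calibrate the lambda-rho per-step reaction probability
#'
#' Inverts the rate--radius relation of the time-stepped lambda-rho scheme:
#' finds the `P_lambda` for which a well-mixed `2A -> 0` system reproduces
#' the macroscopic rate constant `kappa1` (volume/time units).  The
#' effective rate for a candidate `P_lambda` is computed deterministically
#' from the stationary pair-correlation function of the scheme, obtained by
#' iterating the exact radial transition kernel of the 3-D Gaussian relative
#' displacement (standard deviation `sqrt(4 D dt)` per axis) to a fixed
#' point; reaction depletes the correlation inside `rho`, so the effective
#' rate falls below the naive `P_lambda * (4/3) pi rho^3 / dt` once steps
#' are short compared with the radius.
#'
#' @param kappa1 target macroscopic bimolecular rate (volume/time).
#' @param rho reaction radius.
#' @param D diffusion coefficient of each reactant.
#' @param dt simulation time step.
#' @param dr radial grid resolution for the kernel iteration.
#' @param tol relative convergence tolerance of the calibration.
#' @return the per-step pair reaction probability in `[0, 1]`.
#' @export
compute_P_lambda <- function(kappa1, rho, D, dt, dr = rho / 150,
                             tol = 1e-4) {
  if (kappa1 == 0) return(0)
  stopifnot(kappa1 > 0, rho > 0, D > 0, dt > 0)
  key <- paste(kappa1, rho, D, dt, dr, tol, sep = "|")
  hit <- .calibration_cache[[key]]
  if (!is.null(hit)) return(hit)
  s <- sqrt(4 * D * dt)                     # relative-coordinate step sd
  rmax <- rho + 8 * s
  r <- seq(dr / 2, rmax, by = dr)
  n <- length(r)
  # radial kernel: destination r_i given source r_j, times dr
  K <- outer(r, r, function(ri, rj) {
    ri / (rj * s * sqrt(2 * pi)) *
      (exp(-(rj - ri)^2 / (2 * s^2)) - exp(-(rj + ri)^2 / (2 * s^2))) * dr
  })
  # far-field inflow chosen so that the uniform state (g = 1, m = r^2) is
  # exactly stationary under the truncated kernel
  m_unif <- r^2
  far <- pmax(m_unif - as.numeric(K %*% m_unif), 0)
  inside <- r < rho
  kappa_eff <- function(P) {
    m <- m_unif
    for (it in 1:5000) {
      m_new <- as.numeric(K %*% m) + far     # diffuse
      flux <- 4 * pi * sum(m_new[inside]) * dr * P
      m_new[inside] <- m_new[inside] * (1 - P)  # react
      if (max(abs(m_new - m)) < 1e-12 * max(m_unif)) {
        m <- m_new
        break
      }
      m <- m_new
    }
    m_diff <- as.numeric(K %*% m) + far
    P * 4 * pi * sum(m_diff[inside]) * dr / dt
  }
  hi <- kappa_eff(1)
  if (hi < kappa1)
    stop("lambda-rho calibration failed to bracket: even P_lambda = 1 gives ",
         "kappa_eff = ", signif(hi, 4), " < kappa1 = ", kappa1,
         "; increase rho or dt")
  root <- uniroot(function(P) kappa_eff(P) - kappa1, c(1e-12, 1),
                  tol = tol * kappa1 * dt)$root
  .calibration_cache[[key]] <- root
  root
}

# calibration results are deterministic in their arguments; memoize them
.calibration_cache <- new.env(parent = emptyenv())
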