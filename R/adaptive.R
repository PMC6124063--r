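# Threshold-driven interface relocation: move one auxiliary width towards
# whichever regime's auxiliary occupancy breaches its threshold, converting
# the mass representation while conserving mass exactly per realization.

#' Adaptive-interface thresholds
#'
#' The interface moves towards the PDE subdomain when the PDE auxiliary
#' occupancy drops below `beta_l`, and towards the Brownian subdomain when
#' the Brownian auxiliary occupancy exceeds `beta_u`.  Requiring
#' `beta_u > beta_l` provides hysteresis that prevents the interface from
#' oscillating rapidly between two positions.
#'
#' @param beta_l lower threshold (particles).
#' @param beta_u upper threshold (particles), `> beta_l`.
#' @return an object of class `adaptive_config`.
#' @export
adaptive_config <- function(beta_l, beta_u) {
  if (!(beta_u > beta_l))
    stop("adaptive thresholds require beta_u > beta_l")
  structure(list(beta_l = beta_l, beta_u = beta_u), class = "adaptive_config")
}

#' Convert the PDE auxiliary region into particles
#'
#' Creates `floor(N_PA)` particles plus one extra with probability
#' `N_PA mod 1` (so the expected number equals `N_PA`), each placed
#' uniformly over the outgoing PDE auxiliary slab, which becomes the new
#' Brownian auxiliary region.  The auxiliary cells are removed from the grid
#' and the remaining PDE densities are multiplied by
#' `(M_rest + N_PA - n) / M_rest`, so total mass is conserved exactly for
#' every realization, not just in expectation.
#'
#' @param field a [pde_field()] whose rightmost `h_a/h_p` cells form the PDE
#'   auxiliary region.
#' @param state an [interface_state()].
#' @param ensemble_dim 1 or 3; transverse coordinates of new particles are
#'   uniform over `cross_section` when 3.
#' @param cross_section length-2 vector `(L_y, L_z)` for 3-D placements.
#' @return list with the shrunk `field`, a matrix `new_particles`, the
#'   realized particle count `n`, and the rescale `factor` applied.
#' @export
pde_to_particles <- function(field, state, ensemble_dim = 1L,
                             cross_section = c(1, 1)) {
  n_pa <- region_mass(field, state$omega_pa)
  n_new <- floor(n_pa) + (runif(1) < (n_pa %% 1))
  naux <- as.integer(round(state$h_a / field$h_p))
  kept <- field$values[seq_len(field$n - naux)]
  new_field <- pde_field(field$x0, field$x1 - state$h_a, field$h_p,
                         values = kept, theta = field$theta,
                         left_flux = field$left_flux)
  m_rest <- sum(kept) * field$h_p
  factor <- 1
  if (m_rest > 0) {
    factor <- (m_rest + n_pa - n_new) / m_rest
    new_field$values <- new_field$values * factor
    if (abs(factor - 1) > 0.1)
      warning(sprintf("PDE rescale factor %.3f deviates from 1 by more than 10%%",
                      factor))
  } else if (n_pa != n_new) {
    warning("remaining PDE mass is zero; conversion discrepancy of ",
            signif(n_pa - n_new, 4), " particles cannot be absorbed")
  }
  new_particles <- if (n_new > 0) {
    cbind(state$omega_pa[1] + runif(n_new) * state$h_a,
          if (ensemble_dim == 3L)
            cbind(runif(n_new) * cross_section[1],
                  runif(n_new) * cross_section[2]))
  } else {
    matrix(numeric(0), ncol = ensemble_dim)
  }
  list(field = new_field, new_particles = new_particles, n = n_new,
       factor = factor)
}

#' Convert the Brownian auxiliary region into PDE mass
#'
#' Deletes every particle in the Brownian auxiliary region and extends the
#' PDE grid over that slab with the uniform density `N_BA / h_a` (reduced,
#' i.e. already folded over the cross-section in 3-D), conserving mass
#' exactly.
#'
#' @inheritParams pde_to_particles
#' @param ensemble a [particle_ensemble()].
#' @return list with the extended `field` and thinned `ensemble`, plus the
#'   converted count `n`.
#' @export
particles_to_pde <- function(field, ensemble, state) {
  x <- ensemble$pos[, 1]
  idx <- which(x >= state$omega_ba[1] & x < state$omega_ba[2])
  n_ba <- length(idx)
  naux <- as.integer(round(state$h_a / field$h_p))
  new_field <- pde_field(field$x0, field$x1 + state$h_a, field$h_p,
                         values = c(field$values, rep(n_ba / state$h_a, naux)),
                         theta = field$theta, left_flux = field$left_flux)
  if (n_ba > 0) ensemble$pos <- ensemble$pos[-idx, , drop = FALSE]
  list(field = new_field, ensemble = ensemble, n = n_ba)
}

#' Threshold check and (at most one) interface move
#'
#' Called once per synchronous update, after the PDE/Brownian step.  If
#' `N_PA < beta_l` the interface moves one auxiliary width towards the PDE
#' subdomain (converting the PDE auxiliary region into particles); else if
#' `N_BA > beta_u` it moves one width towards the Brownian subdomain
#' (converting particles into PDE mass); occupancies between the thresholds
#' leave the interface untouched.  A move that would shrink either
#' subdomain below one auxiliary width is suppressed with a warning.
#'
#' @param field a [pde_field()] ending at the interface.
#' @param ensemble a [particle_ensemble()] starting at the interface.
#' @param state an [interface_state()].
#' @param cfg an [adaptive_config()].
#' @param domain length-2 vector with the full domain `(x0, x1)`.
#' @return list with possibly-updated `field`, `ensemble`, `state` and a
#'   `moved` flag (`-1` left, `0` none, `+1` right).
#' @export
check_and_move <- function(field, ensemble, state, cfg,
                           domain = c(field$x0, ensemble$upper[1])) {
  stopifnot(inherits(cfg, "adaptive_config"))
  state <- update_counts(state, field, ensemble)
  moved <- 0L
  if (state$n_pa < cfg$beta_l) {
    if (state$iface - state$h_a - domain[1] < state$h_a - 1e-12) {
      warning("interface move towards the PDE subdomain suppressed: ",
              "it would shrink the PDE subdomain below h_a")
    } else {
      conv <- pde_to_particles(field, state, ensemble$dim,
                               cross_section = ensemble$upper[-1])
      field <- conv$field
      ensemble$lower[1] <- state$iface - state$h_a
      ensemble$pos <- rbind(conv$new_particles, ensemble$pos)
      state <- interface_state(state$iface - state$h_a, state$h_a,
                               state$d * state$h_a^2)
      moved <- -1L
    }
  } else if (state$n_ba > cfg$beta_u) {
    if (domain[2] - (state$iface + state$h_a) < state$h_a - 1e-12) {
      warning("interface move towards the Brownian subdomain suppressed: ",
              "it would shrink the Brownian subdomain below h_a")
    } else {
      conv <- particles_to_pde(field, ensemble, state)
      field <- conv$field
      ensemble <- conv$ensemble
      ensemble$lower[1] <- state$iface + state$h_a
      state <- interface_state(state$iface + state$h_a, state$h_a,
                               state$d * state$h_a^2)
      moved <- 1L
    }
  }
  state <- update_counts(state, field, ensemble)
  list(field = field, ensemble = ensemble, state = state, moved = moved)
}
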