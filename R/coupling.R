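# The auxiliary-region coupling proper: interface bookkeeping, propensities,
# SSA primitives and the event-driven hybrid loop.

#' Jump rate between the two auxiliary regions
#'
#' The auxiliary regions form a two-compartment jump process; each particle
#' (or pseudo-particle) hops across the interface at rate `d = D / h_a^2`,
#' the standard compartment-based discretization of diffusion at compartment
#' size `h_a`.
#'
#' @param D macroscopic diffusion coefficient.
#' @param h_a auxiliary-region width (`> 0`).
#' @return the per-particle jump rate (1/time).
#' @export
jump_rate <- function(D, h_a) {
  if (h_a <= 0) stop("auxiliary-region width h_a must be positive")
  D / h_a^2
}

#' Interface state: auxiliary intervals, jump rates and occupancies
#'
#' The PDE auxiliary region is `[I - h_a, I)` and the Brownian auxiliary
#' region `[I, I + h_a)`.  Occupancies are always *recomputed* from the
#' current field/ensemble (never cached across mutations): `N_PA` is the
#' real-valued pseudo-particle count [region_mass()] over the PDE auxiliary
#' region and `N_BA` the integer [count_in()] over the Brownian one.
#'
#' @param iface interface position `I`.
#' @param h_a auxiliary width.
#' @param D diffusion coefficient(s) per species.
#' @param field optional [pde_field()] from which to compute `N_PA`.
#' @param ensemble optional [particle_ensemble()] from which to compute
#'   `N_BA`.
#' @return an object of class `interface_state` with elements `iface`,
#'   `h_a`, `d`, `omega_pa`, `omega_ba`, `n_pa`, `n_ba`.
#' @export
interface_state <- function(iface, h_a, D, field = NULL, ensemble = NULL) {
  st <- structure(
    list(iface = iface, h_a = h_a, d = jump_rate(D, h_a),
         omega_pa = c(iface - h_a, iface), omega_ba = c(iface, iface + h_a),
         n_pa = NA_real_, n_ba = NA_integer_),
    class = "interface_state")
  update_counts(st, field, ensemble)
}

#' Recompute auxiliary-region occupancies
#' @param state an [interface_state()].
#' @inheritParams interface_state
#' @return the state with fresh `n_pa` / `n_ba`.
#' @export
update_counts <- function(state, field = NULL, ensemble = NULL) {
  if (!is.null(field)) state$n_pa <- region_mass(field, state$omega_pa)
  if (!is.null(ensemble)) state$n_ba <- count_in(ensemble, state$omega_ba)
  state
}

#' @export
print.interface_state <- function(x, ...) {
  cat(sprintf("<interface_state> I = %g, h_a = %g, d = %g\n",
              x$iface, x$h_a, x$d))
  cat(sprintf("  N_PA = %s, N_BA = %s\n", format(x$n_pa), format(x$n_ba)))
  invisible(x)
}

#' Reaction network for the auxiliary-region SSA
#'
#' Channels are given as lists with elements `reactants` and `products`
#' (named integer stoichiometries), `rate` (`kappa_r`, in the macroscopic
#' convention where the compartment propensity is
#' `g_r(N) * kappa_r * volume^(1 - order)`), and optionally `name`.  The
#' combinatorial factor `g_r(N)` is `prod(choose(N_s, nu_s))` over reactant
#' species, which vanishes whenever any reactant count is below its
#' stoichiometric requirement.
#'
#' @param channels list of channel descriptions.
#' @param compartment_size the auxiliary compartment's physical size:
#'   `h_a` in 1-D, `h_a * L_y * L_z` for the cuboid geometry.
#' @return an object of class `reaction_network`.
#' @export
reaction_network <- function(channels = list(), compartment_size = 1) {
  channels <- lapply(seq_along(channels), function(i) {
    ch <- channels[[i]]
    stopifnot(is.numeric(ch$rate), ch$rate >= 0)
    ch$reactants <- ch$reactants %||% integer(0)
    ch$products <- ch$products %||% integer(0)
    ch$order <- sum(ch$reactants)
    ch$name <- ch$name %||% paste0("r", i)
    ch
  })
  structure(list(channels = channels, compartment_size = compartment_size),
            class = "reaction_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

g_combinations <- function(reactants, counts) {
  if (length(reactants) == 0L) return(1)
  out <- 1
  for (sp in names(reactants)) {
    n <- if (sp %in% names(counts)) counts[[sp]] else 0
    out <- out * choose(n, reactants[[sp]])
  }
  out
}

#' Propensities of all interfacial jumps and auxiliary reactions
#'
#' For each species `k`: `alpha_P^k = d_k N_PA^k`, clamped to zero whenever
#' `N_PA^k < 1` (removing a whole particle's worth of mass would otherwise
#' drive the density negative), and `alpha_B^k = d_k N_BA^k`.  For each
#' reaction channel whose reactant set lies wholly in the Brownian auxiliary
#' region, `alpha_r = g_r(N_BA) kappa_r V^(1 - nu)` with `V` the
#' compartment size.  Counts may be named vectors for multi-species
#' networks; occupancies must have been freshly recomputed.
#'
#' @param state an [interface_state()] with current `n_pa`, `n_ba` (scalars
#'   or named per-species vectors).
#' @param net optional [reaction_network()].
#' @return an object of class `propensity_set` with per-species `alpha_P`,
#'   `alpha_B`, per-channel `alpha_r`, and totals `alpha_P0`, `alpha_B0`,
#'   `alpha0`.
#' @export
propensities <- function(state, net = NULL) {
  n_pa <- state$n_pa
  n_ba <- state$n_ba
  if (any(is.na(n_pa)) || any(is.na(n_ba)))
    stop("occupancies have not been computed; call update_counts() first")
  if (any(n_pa < 0) || any(n_ba < 0))
    stop("internal-consistency fault: negative auxiliary-region count")
  alpha_P <- ifelse(n_pa < 1, 0, state$d * n_pa)
  alpha_B <- state$d * n_ba
  alpha_r <- numeric(0)
  if (!is.null(net) && length(net$channels)) {
    counts <- n_ba
    if (is.null(names(counts)) && length(counts) == 1L)
      names(counts) <- "A"
    alpha_r <- vapply(net$channels, function(ch) {
      g_combinations(ch$reactants, counts) * ch$rate *
        net$compartment_size^(1 - ch$order)
    }, numeric(1))
    names(alpha_r) <- vapply(net$channels, `[[`, character(1), "name")
  }
  structure(list(alpha_P = alpha_P, alpha_B = alpha_B, alpha_r = alpha_r,
                 alpha_P0 = sum(alpha_P), alpha_B0 = sum(alpha_B),
                 alpha0 = sum(alpha_P) + sum(alpha_B) + sum(alpha_r)),
            class = "propensity_set")
}

#' Exponential waiting time of the SSA
#'
#' Transforms a uniform draw into the time to the next event,
#' `tau = ln(1/u) / alpha0`.  A zero total propensity returns `Inf` (no
#' event before the next synchronous update).
#'
#' @param alpha0 total propensity (`>= 0`).
#' @param u uniform(0,1) variate; drawn internally if omitted.
#' @return waiting time `tau`.
#' @export
sample_waiting_time <- function(alpha0, u = runif(1)) {
  stopifnot(alpha0 >= 0)
  if (alpha0 == 0) return(Inf)
  log(1 / u) / alpha0
}

#' Select the next SSA event by cumulative-sum inversion
#'
#' Events are enumerated in a fixed order -- PDE-to-Brownian jumps by
#' species, Brownian-to-PDE jumps by species, then reaction channels in
#' network order -- so trajectories are bit-reproducible under a fixed seed.
#'
#' @param props a [propensities()] result with `alpha0 > 0`.
#' @param u2 uniform(0,1) variate; drawn internally if omitted.
#' @return a list with `type` (`"jump_P_to_B"`, `"jump_B_to_P"` or
#'   `"reaction"`) and `index` (species or channel index).
#' @export
select_event <- function(props, u2 = runif(1)) {
  if (props$alpha0 <= 0)
    stop("select_event requires a positive total propensity")
  w <- c(props$alpha_P, props$alpha_B, props$alpha_r)
  types <- c(rep("jump_P_to_B", length(props$alpha_P)),
             rep("jump_B_to_P", length(props$alpha_B)),
             rep("reaction", length(props$alpha_r)))
  idx <- c(seq_along(props$alpha_P), seq_along(props$alpha_B),
           seq_along(props$alpha_r))
  k <- findInterval(u2 * props$alpha0, cumsum(w), left.open = TRUE) + 1L
  k <- min(k, length(w))
  list(type = types[k], index = idx[k])
}

#' Enact a pseudo-particle jump from the PDE to the Brownian regime
#'
#' Removes one particle's worth of mass uniformly from the PDE auxiliary
#' region and initializes one particle uniformly at random in the Brownian
#' auxiliary region (for 3-D ensembles, the transverse coordinates are
#' uniform over the cross-section).  Mass is conserved exactly.
#'
#' @param field a [pde_field()].
#' @param ensemble a [particle_ensemble()].
#' @param state an [interface_state()] with `n_pa >= 1`.
#' @return list with updated `field` and `ensemble`.
#' @export
enact_jump_P_to_B <- function(field, ensemble, state) {
  if (!is.na(state$n_pa) && state$n_pa < 1)
    stop("jump P->B requires N_PA >= 1 (propensity clamp violated)")
  field <- deposit_uniform(field, state$omega_pa, -1)
  newp <- c(state$omega_ba[1] + runif(1) * state$h_a,
            if (ensemble$dim == 3L)
              ensemble$lower[2:3] + runif(2) *
                (ensemble$upper[2:3] - ensemble$lower[2:3]))
  ensemble$pos <- rbind(ensemble$pos, newp)
  list(field = field, ensemble = ensemble)
}

#' Enact a particle jump from the Brownian to the PDE regime
#'
#' Deletes one particle chosen uniformly at random from the Brownian
#' auxiliary region and adds one particle's worth of mass uniformly over the
#' PDE auxiliary region (density increment `1/h_a`).
#'
#' @inheritParams enact_jump_P_to_B
#' @return list with updated `field` and `ensemble`.
#' @export
enact_jump_B_to_P <- function(field, ensemble, state) {
  x <- ensemble$pos[, 1]
  idx <- which(x >= state$omega_ba[1] & x < state$omega_ba[2])
  if (length(idx) == 0L)
    stop("internal fault: B->P jump with no particles in the auxiliary region")
  kill <- idx[sample.int(length(idx), 1L)]
  ensemble$pos <- ensemble$pos[-kill, , drop = FALSE]
  field <- deposit_uniform(field, state$omega_pa, +1)
  list(field = field, ensemble = ensemble)
}

#' Enact a compartment-based reaction inside the Brownian auxiliary region
#'
#' Reactant particles are chosen uniformly at random among those in the
#' Brownian auxiliary region and removed; product particles are placed
#' uniformly at random throughout the region.  Particles outside the region
#' are untouched.
#'
#' @inheritParams enact_jump_P_to_B
#' @param channel a channel description (see [reaction_network()]).
#' @return the updated ensemble.
#' @export
enact_aux_reaction <- function(ensemble, state, channel) {
  n_react <- sum(channel$reactants)
  x <- ensemble$pos[, 1]
  idx <- which(x >= state$omega_ba[1] & x < state$omega_ba[2])
  if (length(idx) < n_react)
    stop("internal fault: insufficient reactants in the auxiliary region")
  if (n_react > 0L) {
    kill <- idx[sample.int(length(idx), n_react)]
    ensemble$pos <- ensemble$pos[-kill, , drop = FALSE]
  }
  n_prod <- sum(channel$products)
  if (n_prod > 0L) {
    for (i in seq_len(n_prod)) {
      newp <- c(state$omega_ba[1] + runif(1) * state$h_a,
                if (ensemble$dim == 3L)
                  ensemble$lower[2:3] + runif(2) *
                    (ensemble$upper[2:3] - ensemble$lower[2:3]))
      ensemble$pos <- rbind(ensemble$pos, newp)
    }
  }
  ensemble
}

#' Run one hybrid trajectory
#'
#' Executes the event-driven hybrid loop: between consecutive synchronous
#' updates (every `dt`), interfacial jumps and auxiliary-region reactions
#' are enacted by the Gillespie SSA; at each update time the PDE advances by
#' one theta step, the particles by one Brownian step plus microscopic
#' reactions, and (optionally) the adaptive-interface check runs.  After
#' every synchronous update the stale putative event time is discarded and
#' redrawn, which is statistically consistent by the memorylessness of the
#' exponential.  An event falling exactly on an update time is processed
#' before the update.
#'
#' @param config a simulation configuration from [make_test_problem()],
#'   [sim_config()] or [make_two_box()].
#' @param record_particles keep full particle positions at snapshots
#'   (otherwise only counts and the PDE field are stored).
#' @return an object of class `hybrid_trajectory`: snapshot times, PDE
#'   fields, particle positions, interface positions, auxiliary occupancies,
#'   masses, and the event/mass ledger.
#' @export
run_hybrid <- function(config, record_particles = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  init <- build_initial_state(config)
  cfg <- engine_config(config, init, micro_only = FALSE,
                       record_particles = record_particles)
  raw <- cpp_run_hybrid(cfg)
  new_trajectory(raw, config, mode = "hybrid")
}

#' Run one fully microscopic (Brownian-only) trajectory
#'
#' The whole domain is simulated with Brownian dynamics: lambda-rho pair
#' reactions everywhere (no interface exclusion), zeroth-order births with
#' probability `kappa2 * dt * V`, and first-order decay.  Used as the
#' ground-truth arm for second-order systems, where moment closure makes
#' the mean-field PDE inexact.
#'
#' @inheritParams run_hybrid
#' @return a `hybrid_trajectory` (with an empty PDE part).
#' @export
run_microscopic <- function(config, record_particles = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  init <- build_initial_state(config, micro_only = TRUE)
  cfg <- engine_config(config, init, micro_only = TRUE,
                       record_particles = record_particles)
  raw <- cpp_run_hybrid(cfg)
  new_trajectory(raw, config, mode = "microscopic")
}

new_trajectory <- function(raw, config, mode) {
  structure(
    list(t = raw$t, iface = raw$iface, npa = raw$npa, nba = raw$nba,
         pde_mass = raw$pde_mass, total_mass = raw$total_mass,
         n_b = raw$n_b, pde = raw$pde, particles = raw$particles,
         ledger = raw$ledger, x0 = raw$x0, hp = raw$hp, ha = raw$ha,
         dim = raw$dim, config = config, mode = mode),
    class = "hybrid_trajectory")
}

#' @export
print.hybrid_trajectory <- function(x, ...) {
  led <- x$ledger
  cat(sprintf("<hybrid_trajectory> (%s) %d snapshot(s), t in [%g, %g]\n",
              x$mode, length(x$t), min(x$t), max(x$t)))
  cat(sprintf("  final mass %.6g (PDE %.6g + %d particles); max ledger drift %.3g\n",
              led$final_mass, tail(x$pde_mass, 1), tail(x$n_b, 1),
              led$max_drift))
  cat(sprintf("  events: %d P->B, %d B->P, %d aux reactions, %d micro pairs, %d births, %d decays\n",
              led$jumps_pb, led$jumps_bp, led$aux_reactions, led$micro_pairs,
              led$births, led$bd_decay))
  if (led$clamps > 0)
    cat(sprintf("  note: N_PA < 1 propensity clamp activated %d time(s)\n",
                led$clamps))
  if (led$moves_left + led$moves_right > 0)
    cat(sprintf("  adaptive interface: %d move(s) left, %d right, %d suppressed\n",
                led$moves_left, led$moves_right, led$moves_suppressed))
  invisible(x)
}

#' @export
summary.hybrid_trajectory <- function(object, ...) {
  data.frame(t = object$t, iface = object$iface, n_pa = object$npa,
             n_ba = object$nba, pde_mass = object$pde_mass,
             n_particles = object$n_b, total_mass = object$total_mass)
}

#' Plot a trajectory snapshot: PDE density plus binned particle density
#' @param x a `hybrid_trajectory`.
#' @param snapshot index of the snapshot to draw (default: last).
#' @param ... passed to `plot.default`.
#' @export
plot.hybrid_trajectory <- function(x, snapshot = length(x$t), ...) {
  cfg <- x$config
  prof <- bin_trajectory(x, snapshot)
  xm <- (prof$edges[-1] + prof$edges[-length(prof$edges)]) / 2
  plot.default(xm, prof$density, type = "h", lwd = 6, col = "goldenrod",
               xlab = "x", ylab = "density",
               main = sprintf("t = %g (%s)", x$t[snapshot], x$mode), ...)
  if (length(x$pde[[snapshot]])) {
    cc <- x$x0 + (seq_along(x$pde[[snapshot]]) - 0.5) * x$hp
    lines(cc, x$pde[[snapshot]] / ifelse(x$dim == 3, cfg$Ly * cfg$Lz, 1),
          col = "forestgreen", lwd = 2)
  }
  abline(v = x$iface[snapshot], col = "red")
  invisible(x)
}

# bin one snapshot of a trajectory onto the common h_a mesh:
# PDE contribution by exact cell integral, particles by counting
bin_trajectory <- function(traj, snapshot) {
  cfg <- traj$config
  edges <- seq(cfg$x0, cfg$x1, by = traj$ha)
  L <- length(edges) - 1L
  mass <- numeric(L)
  vals <- traj$pde[[snapshot]]
  if (length(vals)) {
    cells_per_bin <- as.integer(round(traj$ha / traj$hp))
    nfull <- length(vals) %/% cells_per_bin
    for (b in seq_len(nfull)) {
      idx <- ((b - 1L) * cells_per_bin + 1L):(b * cells_per_bin)
      mass[b] <- mass[b] + sum(vals[idx]) * traj$hp
    }
  }
  P <- traj$particles[[snapshot]]
  if (!is.null(P) && nrow(P)) {
    bi <- pmin(pmax(floor((P[, 1] - cfg$x0) / traj$ha), 0), L - 1) + 1L
    tab <- tabulate(bi, nbins = L)
    mass <- mass + tab
  }
  list(edges = edges, mass = mass, density = mass / traj$ha)
}
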