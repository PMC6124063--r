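# Reproducible experiment definitions: canonical test-problem configurations,
# initial-state construction, and repeated seeded runs.

#' Simulation configuration
#'
#' Collects every parameter of a hybrid (or fully microscopic) run.  For
#' 1-D problems the domain is `(x0, x1)` with a point interface; for the
#' cuboid geometry (`dim = 3`) the domain is `(x0, x1) x (0, Ly) x (0, Lz)`
#' with a planar interface and the PDE is the translationally invariant 1-D
#' reduction in the density `C(x, t)` (particles per unit length).
#'
#' @param x0,x1 domain end points along the interface normal.
#' @param iface initial interface position, `x0 < iface < x1`, aligned to
#'   the PDE grid.
#' @param h_a auxiliary-region width; must be an integer multiple of `h_p`.
#' @param h_p PDE grid spacing.
#' @param dt synchronous update time step for both PDE and Brownian
#'   regimes.
#' @param t_end final time (an integer multiple of `dt`).
#' @param D diffusion coefficient.
#' @param N total initial particle number.
#' @param ic initial-condition description: `list(type = "uniform" | "pde_only" |
#'   "ramp" | "two_box" | "custom", ...)`.
#' @param theta PDE time-stepping weight.
#' @param mu first-order decay rate (0 = none).
#' @param lambda_flux left-boundary production parameter (influx rate
#'   `D * lambda_flux`; 0 = zero-flux).
#' @param kappa1 bimolecular `2A -> 0` rate (volume/time; 0 = none).
#' @param kappa2 zeroth-order production rate (1/volume/time; 0 = none).
#' @param rho lambda-rho reaction radius.
#' @param P_lambda per-step pair reaction probability; `NULL` means
#'   calibrate from `kappa1` via [compute_P_lambda()].
#' @param dim 1 or 3.
#' @param Ly,Lz cross-section side lengths (3-D only).
#' @param adaptive logical; enable the threshold-driven interface.
#' @param beta_l,beta_u adaptive thresholds (see [adaptive_config()]).
#' @param snapshot_times times at which state is recorded (rounded to the
#'   update grid).
#' @param pde_on,bd_on disable the synchronous PDE / Brownian updates
#'   (used by the degenerate two-box mode).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(x0, x1, iface, h_a, h_p, dt, t_end, D, N,
                       ic = list(type = "uniform"), theta = 0.51, mu = 0,
                       lambda_flux = 0, kappa1 = 0, kappa2 = 0, rho = 0,
                       P_lambda = NULL, dim = 1L, Ly = 1, Lz = 1,
                       adaptive = FALSE, beta_l = 0, beta_u = Inf,
                       snapshot_times = NULL, pde_on = TRUE, bd_on = TRUE) {
  stopifnot(x0 < iface, iface < x1, h_a > 0, h_p > 0, dt > 0, t_end >= dt,
            D >= 0, theta >= 0, theta <= 1)
  if (abs(h_a / h_p - round(h_a / h_p)) > 1e-8)
    stop("h_a must be an integer multiple of h_p")
  if (abs((iface - x0) / h_p - round((iface - x0) / h_p)) > 1e-6)
    stop("the interface must lie on a PDE grid line")
  if (adaptive && !(beta_u > beta_l))
    stop("adaptive thresholds require beta_u > beta_l")
  V <- (x1 - x0) * (if (dim == 3) Ly * Lz else 1)
  if (kappa2 > 0 && kappa2 * dt * V >= 1)
    stop("kappa2 * dt * V = ", signif(kappa2 * dt * V, 4),
         " >= 1; the zeroth-order channel needs a smaller dt")
  if (kappa1 > 0 && is.null(P_lambda) && rho > 0)
    P_lambda <- compute_P_lambda(kappa1, rho, D, dt)
  if (is.null(snapshot_times)) snapshot_times <- c(0, t_end)
  structure(
    list(x0 = x0, x1 = x1, iface = iface, h_a = h_a, h_p = h_p, dt = dt,
         t_end = t_end, D = D, N = N, ic = ic, theta = theta, mu = mu,
         lambda_flux = lambda_flux, kappa1 = kappa1, kappa2 = kappa2,
         rho = rho, P_lambda = P_lambda %||% 0, dim = as.integer(dim),
         Ly = Ly, Lz = Lz, adaptive = adaptive, beta_l = beta_l,
         beta_u = beta_u, snapshot_times = snapshot_times, pde_on = pde_on,
         bd_on = bd_on),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d-D domain (%g, %g), interface %g, h_a = %g, h_p = %g\n",
              x$dim, x$x0, x$x1, x$iface, x$h_a, x$h_p))
  cat(sprintf("  dt = %g, T = %g, D = %g, N = %g, IC '%s'\n",
              x$dt, x$t_end, x$D, x$N, x$ic$type))
  rx <- c(if (x$mu > 0) sprintf("decay mu=%g", x$mu),
          if (x$lambda_flux != 0) sprintf("influx D*lambda=%g", x$D * x$lambda_flux),
          if (x$kappa1 > 0) sprintf("2A->0 kappa1=%g (rho=%g, P_lambda=%.4g)",
                                    x$kappa1, x$rho, x$P_lambda),
          if (x$kappa2 > 0) sprintf("0->A kappa2=%g", x$kappa2))
  if (length(rx)) cat("  reactions:", paste(rx, collapse = "; "), "\n")
  if (x$adaptive)
    cat(sprintf("  adaptive interface: beta_l = %g, beta_u = %g\n",
                x$beta_l, x$beta_u))
  invisible(x)
}

#' Canonical test-problem configurations
#'
#' Returns the full printed parameter set of one of the four canonical test
#' problems:
#'
#' * `tp1` -- equilibrium maintenance: pure diffusion on `(-1, 1)`,
#'   interface at 0, `dt = 0.02`, `h_a = 0.05`, `D = 0.0025`, `N = 500`
#'   initialized uniformly, `T = 100`.
#' * `tp2` -- interfacial flux stress test: as `tp1` but `D = 0.025`,
#'   `dt = 0.005` and all mass initially uniform in the PDE subdomain.
#' * `tp3` -- morphogen gradient: as `tp1` plus boundary production
#'   `lambda = 400` at `x = -1` and degradation `mu = 0.001`.
#' * `tp4` -- second-order system in a `10 x 2 x 2` cuboid: `2A -> 0`
#'   (`kappa1 = 0.01`) and `0 -> A` (`kappa2 = 0.5`) with the lambda-rho
#'   radius `rho = 0.1`, `D = 0.2`, `dt = 0.01`, `h_p = 0.1`, `h_a = 0.5`,
#'   `N = 200` on a linear ramp vanishing at `x1`, `T = 5`, adaptive
#'   interface starting at `I_0 = 0.5` with thresholds `beta_u = 9.5`,
#'   `beta_l = 4`.
#'
#' @param id one of `"tp1"`, `"tp2"`, `"tp3"`, `"tp4"`.
#' @param ... overrides applied after the canonical values (any
#'   [sim_config()] argument).
#' @return a `sim_config`.
#' @export
make_test_problem <- function(id = c("tp1", "tp2", "tp3", "tp4"), ...) {
  id <- match.arg(id)
  base <- switch(id,
    tp1 = list(x0 = -1, x1 = 1, iface = 0, h_a = 0.05, h_p = 0.01,
               dt = 0.02, t_end = 100, D = 0.0025, N = 500,
               ic = list(type = "uniform"),
               snapshot_times = seq(0, 100, by = 5)),
    tp2 = list(x0 = -1, x1 = 1, iface = 0, h_a = 0.05, h_p = 0.01,
               dt = 0.005, t_end = 100, D = 0.025, N = 500,
               ic = list(type = "pde_only"),
               snapshot_times = seq(0, 100, by = 5)),
    tp3 = list(x0 = -1, x1 = 1, iface = 0, h_a = 0.05, h_p = 0.01,
               dt = 0.02, t_end = 100, D = 0.0025, N = 500,
               ic = list(type = "uniform"), lambda_flux = 400, mu = 0.001,
               snapshot_times = seq(0, 100, by = 5)),
    tp4 = list(x0 = 0, x1 = 10, iface = 0.5, h_a = 0.5, h_p = 0.1,
               dt = 0.01, t_end = 5, D = 0.2, N = 200,
               ic = list(type = "ramp"), kappa1 = 0.01, kappa2 = 0.5,
               rho = 0.1, dim = 3L, Ly = 2, Lz = 2, adaptive = TRUE,
               beta_l = 4, beta_u = 9.5,
               snapshot_times = seq(0, 5, by = 0.25)))
  over <- list(...)
  base[names(over)] <- over
  do.call(sim_config, base)
}

# Build the initial PDE cell values and particle positions for a config.
# Deterministic mass split: the PDE subdomain receives exactly the integral
# of the initial profile over it; the particle count is that integral's
# floor plus a Bernoulli on its fractional part (exact when integer).
build_initial_state <- function(config, micro_only = FALSE) {
  cfg <- config
  area <- if (cfg$dim == 3) cfg$Ly * cfg$Lz else 1
  n_p <- as.integer(round((cfg$iface - cfg$x0) / cfg$h_p))
  xc <- cfg$x0 + (seq_len(n_p) - 0.5) * cfg$h_p
  Lx <- cfg$x1 - cfg$x0
  sample_count <- function(mass) {
    n <- floor(mass)
    if (runif(1) < mass - n) n <- n + 1
    as.integer(n)
  }
  unif_yz <- function(n) {
    if (cfg$dim == 3) cbind(runif(n) * cfg$Ly, runif(n) * cfg$Lz) else NULL
  }
  if (micro_only) {
    pos <- switch(cfg$ic$type,
      uniform = cfg$x0 + runif(cfg$N) * Lx,
      pde_only = cfg$x0 + runif(cfg$N) * (cfg$iface - cfg$x0),
      ramp = ramp_sample(cfg$N, cfg$x0, cfg$x1, cfg$x0),
      stop("unsupported IC for a microscopic run: ", cfg$ic$type))
    return(list(pde = numeric(0), bd = cbind(pos, unif_yz(length(pos)))))
  }
  switch(cfg$ic$type,
    uniform = {
      dens <- cfg$N / Lx                     # reduced density
      pde <- rep(dens, n_p)
      n_bd <- sample_count(dens * (cfg$x1 - cfg$iface))
      bd <- cfg$iface + runif(n_bd) * (cfg$x1 - cfg$iface)
      list(pde = pde, bd = cbind(bd, unif_yz(n_bd)))
    },
    pde_only = {
      dens <- cfg$N / (cfg$iface - cfg$x0)
      list(pde = rep(dens, n_p),
           bd = cbind(numeric(0), unif_yz(0L)))
    },
    ramp = {
      c0 <- 2 * cfg$N / Lx                   # reduced density at x0
      pde <- c0 * (1 - (xc - cfg$x0) / Lx)   # midpoint-exact for a ramp
      m_bd <- cfg$N - sum(pde) * cfg$h_p
      n_bd <- sample_count(m_bd)
      bd <- ramp_sample(n_bd, cfg$iface, cfg$x1, cfg$x0)
      list(pde = pde, bd = cbind(bd, unif_yz(n_bd)))
    },
    two_box = {
      mu_P <- cfg$ic$mu_P
      pde <- rep(0, n_p)
      naux <- as.integer(round(cfg$h_a / cfg$h_p))
      pde[(n_p - naux + 1L):n_p] <- mu_P / cfg$h_a
      n_bd <- cfg$N - mu_P
      bd <- cfg$iface + runif(n_bd) * cfg$h_a
      list(pde = pde, bd = cbind(bd, unif_yz(n_bd)))
    },
    custom = {
      list(pde = cfg$ic$pde, bd = as.matrix(cfg$ic$bd))
    },
    stop("unknown IC type: ", cfg$ic$type))
}

# inverse-CDF sampling from the linear ramp vanishing at x1, restricted to
# (lo, x1); `origin` is where the ramp has its maximum (the full-domain x0)
ramp_sample <- function(n, lo, x1, origin) {
  if (n == 0L) return(numeric(0))
  L <- x1 - origin
  cdf <- function(x) {
    z <- x - origin
    z - z^2 / (2 * L)
  }
  u <- cdf(lo) + runif(n) * (cdf(x1) - cdf(lo))
  origin + L - L * sqrt(1 - 2 * u / L)
}

engine_config <- function(config, init, micro_only, record_particles) {
  cfg <- config
  snap_steps <- sort(unique(as.integer(round(cfg$snapshot_times / cfg$dt))))
  nsteps <- as.integer(round(cfg$t_end / cfg$dt))
  snap_steps <- snap_steps[snap_steps >= 0L & snap_steps <= nsteps]
  bd <- init$bd
  if (is.null(dim(bd))) bd <- matrix(bd, ncol = 1L)
  if (ncol(bd) == 0L) bd <- matrix(numeric(0), ncol = cfg$dim)
  list(x0 = cfg$x0, x1 = cfg$x1, iface = cfg$iface, ha = cfg$h_a,
       hp = cfg$h_p, dt = cfg$dt, theta = cfg$theta, dim = cfg$dim,
       Ly = cfg$Ly, Lz = cfg$Lz, D = cfg$D, mu = cfg$mu,
       lambda_flux = cfg$lambda_flux, kappa1 = cfg$kappa1,
       kappa2 = cfg$kappa2, rho = cfg$rho, P_lambda = cfg$P_lambda,
       pde_on = cfg$pde_on && !micro_only, bd_on = cfg$bd_on || micro_only,
       ssa_on = !micro_only, micro_only = micro_only,
       adaptive = cfg$adaptive && !micro_only, beta_l = cfg$beta_l,
       beta_u = cfg$beta_u, pde_init = init$pde, bd_init = bd,
       nsteps = nsteps, snap_steps = snap_steps,
       record_particles = record_particles)
}

#' Run repeated seeded simulations and aggregate them
#'
#' Executes `S` repeats of the requested mode, seeding repeat `s` with
#' `base_seed + s` so every repeat is independently reproducible, and
#' reduces each trajectory to the quantities the error toolkit needs:
#' per-snapshot binned densities on the common `h_a` mesh (PDE contribution
#' by exact cell integral, particles by counting), region masses and
#' counts, the last-slab count, interface positions and the mass ledger.
#'
#' @param config a [sim_config()].
#' @param mode `"hybrid"` or `"microscopic"`.
#' @param S number of repeats (`>= 1`).
#' @param base_seed integer; repeat `s` uses seed `base_seed + s`.
#' @param out_dir optional directory: writes `binned_density.csv`,
#'   `summary.csv` and `manifest.json` (requires the jsonlite package for
#'   the manifest).
#' @return an object of class `arm_experiment` with elements `t`,
#'   `bin_edges`, `density` (array `S x T x L`), `n_P`, `n_B`, `slab`,
#'   `iface`, `total_mass` (matrices `S x T`), `ledgers`, `config`, `mode`,
#'   `S`, `base_seed`.
#' @export
run_experiment <- function(config, mode = c("hybrid", "microscopic"), S = 1,
                           base_seed = 1, out_dir = NULL) {
  mode <- match.arg(mode)
  stopifnot(S >= 1)
  cfg <- config
  edges <- seq(cfg$x0, cfg$x1, by = cfg$h_a)
  L <- length(edges) - 1L
  snap_steps <- sort(unique(as.integer(round(cfg$snapshot_times / cfg$dt))))
  snap_steps <- snap_steps[snap_steps >= 0 &
                             snap_steps <= round(cfg$t_end / cfg$dt)]
  TT <- length(snap_steps)
  density <- array(NA_real_, c(S, TT, L))
  n_P <- n_B <- slab <- ifc <- total <- matrix(NA_real_, S, TT)
  ledgers <- vector("list", S)
  cells_per_bin <- as.integer(round(cfg$h_a / cfg$h_p))
  tvec <- NULL
  for (s in seq_len(S)) {
    set.seed(base_seed + s)
    traj <- if (mode == "hybrid") run_hybrid(cfg, record_particles = TRUE)
            else run_microscopic(cfg, record_particles = TRUE)
    if (is.null(tvec)) tvec <- traj$t
    for (j in seq_len(TT)) {
      mass <- numeric(L)
      vals <- traj$pde[[j]]
      if (length(vals)) {
        nfull <- length(vals) %/% cells_per_bin
        if (nfull > 0) {
          mm <- matrix(vals[seq_len(nfull * cells_per_bin)], cells_per_bin)
          mass[seq_len(nfull)] <- colSums(mm) * cfg$h_p
        }
      }
      P <- traj$particles[[j]]
      if (!is.null(P) && nrow(P)) {
        bi <- pmin(pmax(floor((P[, 1] - cfg$x0) / cfg$h_a), 0), L - 1) + 1L
        mass <- mass + tabulate(bi, nbins = L)
      }
      density[s, j, ] <- mass / cfg$h_a
      n_P[s, j] <- traj$pde_mass[j]
      n_B[s, j] <- traj$n_b[j]
      slab[s, j] <- mass[L]
      ifc[s, j] <- traj$iface[j]
      total[s, j] <- traj$total_mass[j]
    }
    ledgers[[s]] <- traj$ledger
  }
  out <- structure(
    list(t = tvec, bin_edges = edges, density = density, n_P = n_P,
         n_B = n_B, slab = slab, iface = ifc, total_mass = total,
         ledgers = ledgers, config = cfg, mode = mode, S = S,
         base_seed = base_seed),
    class = "arm_experiment")
  if (!is.null(out_dir)) write_experiment(out, out_dir)
  out
}

#' @export
print.arm_experiment <- function(x, ...) {
  cat(sprintf("<arm_experiment> %s, S = %d repeats, %d snapshots, %d bins of width %g\n",
              x$mode, x$S, length(x$t), length(x$bin_edges) - 1L,
              x$config$h_a))
  drift <- max(vapply(x$ledgers, `[[`, numeric(1), "max_drift"))
  cat(sprintf("  final mean mass %.4f; max ledger drift over repeats %.3g\n",
              mean(x$total_mass[, ncol(x$total_mass)]), drift))
  invisible(x)
}

# long-format CSV serialization plus a JSON manifest for reproducibility
write_experiment <- function(exp, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  L <- length(exp$bin_edges) - 1L
  dens <- data.frame(
    repeat_ = rep(seq_len(exp$S), times = length(exp$t) * L),
    t = rep(rep(exp$t, each = exp$S), times = L),
    bin = rep(seq_len(L), each = exp$S * length(exp$t)),
    density = as.vector(exp$density))
  write.csv(dens, file.path(out_dir, "binned_density.csv"),
            row.names = FALSE)
  summ <- data.frame(
    repeat_ = rep(seq_len(exp$S), times = length(exp$t)),
    t = rep(exp$t, each = exp$S),
    n_P = as.vector(exp$n_P), n_B = as.vector(exp$n_B),
    slab = as.vector(exp$slab), iface = as.vector(exp$iface),
    total_mass = as.vector(exp$total_mass))
  write.csv(summ, file.path(out_dir, "summary.csv"), row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    manifest <- list(mode = exp$mode, S = exp$S, base_seed = exp$base_seed,
                     config = unclass(exp$config),
                     package_version = as.character(utils::packageVersion("auxregion")),
                     written = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(out_dir)
}
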