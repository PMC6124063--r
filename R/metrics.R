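# Error instrumentation: histogram distance error, region relative errors,
# last-slab relative error, binned variance, and the dt--h_a robustness sweep.

#' Histogram distance error (HDE)
#'
#' Half the L1 distance between the two histograms after normalizing each
#' to unit total: 0 means identical normalized profiles, 1 means disjoint
#' supports.  Symmetric and invariant under separate rescaling of either
#' histogram.
#'
#' @param hist_a,hist_b nonnegative histograms on a common mesh, with
#'   positive totals.
#' @return the HDE in `[0, 1]`.
#' @export
hde <- function(hist_a, hist_b) {
  stopifnot(length(hist_a) == length(hist_b))
  if (any(hist_a < 0) || any(hist_b < 0))
    stop("histograms must be nonnegative")
  sa <- sum(hist_a); sb <- sum(hist_b)
  if (sa <= 0 || sb <= 0)
    stop("histograms must have positive totals")
  0.5 * sum(abs(hist_a / sa - hist_b / sb))
}

# integrate a reference density function over each bin (fine midpoint rule)
bin_reference <- function(reference, edges, t, subdivisions = 50L) {
  L <- length(edges) - 1L
  vapply(seq_len(L), function(b) {
    xs <- seq(edges[b], edges[b + 1], length.out = subdivisions + 1L)
    xm <- (xs[-1] + xs[-length(xs)]) / 2
    mean(reference(xm, t)) * (edges[b + 1] - edges[b])
  }, numeric(1))
}

#' Region-count relative errors against a mean-field reference
#'
#' Compares the repeat-averaged particle content of the PDE region
#' (`N_HP`, the mean PDE integral) and the Brownian region (`N_HB`, the
#' mean particle count) of a hybrid experiment to the reference integrals
#' `N_MP`, `N_MB` over the same regions, reporting the relative errors
#' `(N_HP - N_MP)/N_MP` and `(N_HB - N_MB)/N_MB` per snapshot.  Ratios with
#' a zero reference are reported as `NA` (undefined), never infinite.
#'
#' @param exp an [run_experiment()] result (hybrid mode).
#' @param reference a function `reference(x, t)` giving the mean-field
#'   density.
#' @return a data frame with columns `t`, `n_hp`, `n_mp`, `n_hb`, `n_mb`,
#'   `rel_P`, `rel_B`, plus standard errors `se_P`, `se_B` of the hybrid
#'   means.
#' @export
region_relative_errors <- function(exp, reference) {
  stopifnot(inherits(exp, "arm_experiment"))
  cfg <- exp$config
  tt <- exp$t
  fine <- seq(cfg$x0, cfg$iface, length.out = 2001L)
  finem <- (fine[-1] + fine[-length(fine)]) / 2
  fine_b <- seq(cfg$iface, cfg$x1, length.out = 2001L)
  finem_b <- (fine_b[-1] + fine_b[-length(fine_b)]) / 2
  hx <- diff(fine)[1]; hxb <- diff(fine_b)[1]
  n_mp <- vapply(tt, function(t) sum(reference(finem, t)) * hx, numeric(1))
  n_mb <- vapply(tt, function(t) sum(reference(finem_b, t)) * hxb, numeric(1))
  n_hp <- colMeans(exp$n_P)
  n_hb <- colMeans(exp$n_B)
  se_P <- apply(exp$n_P, 2, sd) / sqrt(exp$S)
  se_B <- apply(exp$n_B, 2, sd) / sqrt(exp$S)
  data.frame(
    t = tt, n_hp = n_hp, n_mp = n_mp, n_hb = n_hb, n_mb = n_mb,
    rel_P = ifelse(n_mp > 0, (n_hp - n_mp) / n_mp, NA_real_),
    rel_B = ifelse(n_mb > 0, (n_hb - n_mb) / n_mb, NA_real_),
    se_P = se_P, se_B = se_B)
}

#' Last-slab relative error between two experiment arms
#'
#' `E_Rel(t) = (N_M(t) - N_H(t)) / N_M(t)` where `N_H`, `N_M` are the
#' repeat-averaged particle contents of the slab `(x1 - h_a, x1)` (times
#' the full cross-section) in the hybrid and reference (typically fully
#' microscopic) arms.  Undefined (`NA`) wherever the reference slab is
#' empty.
#'
#' @param exp_hybrid,exp_micro [run_experiment()] results on identical
#'   snapshot grids.
#' @return data frame with columns `t`, `n_h`, `n_m`, `e_rel`.
#' @export
last_slab_error <- function(exp_hybrid, exp_micro) {
  stopifnot(inherits(exp_hybrid, "arm_experiment"),
            inherits(exp_micro, "arm_experiment"),
            isTRUE(all.equal(exp_hybrid$t, exp_micro$t)))
  n_h <- colMeans(exp_hybrid$slab)
  n_m <- colMeans(exp_micro$slab)
  data.frame(t = exp_hybrid$t, n_h = n_h, n_m = n_m,
             e_rel = ifelse(n_m > 0, (n_m - n_h) / n_m, NA_real_))
}

#' Across-repeat variance of the binned density
#'
#' For each bin of the common `h_a` mesh, the variance over repeats of the
#' bin density (bin mass divided by `h_a`; the PDE contribution is the
#' exact cell integral, the Brownian contribution the particle count).  The
#' accompanying reference is the binomial sampling variance of a fully
#' Brownian simulation at equilibrium, `N q (1 - q) / h_a^2` with
#' `q = h_a / |domain|`.
#'
#' @param exp an [run_experiment()] result.
#' @param snapshot snapshot index (default: last).
#' @return data frame with `bin`, `x_mid`, `variance`, `binomial_ref`.
#' @export
binned_variance <- function(exp, snapshot = length(exp$t)) {
  stopifnot(inherits(exp, "arm_experiment"), exp$S >= 2)
  cfg <- exp$config
  v <- apply(exp$density[, snapshot, , drop = FALSE], 3, var)
  q <- cfg$h_a / (cfg$x1 - cfg$x0)
  data.frame(
    bin = seq_along(v),
    x_mid = (exp$bin_edges[-1] + exp$bin_edges[-length(exp$bin_edges)]) / 2,
    variance = v,
    binomial_ref = cfg$N * q * (1 - q) / cfg$h_a^2)
}

#' Robustness sweep over the free parameters dt and h_a
#'
#' For every pair on the `dt_list` x `ha_list` grid, runs `S` hybrid
#' repeats of the pure-diffusion flux problem (all mass initially uniform
#' in the PDE subdomain of `(-1, 1)`) to time `T` and records the HDE of
#' the repeat-averaged binned profile against the analytic series solution,
#' together with the stability diagnostic `D dt / h_a^2` (the accuracy of
#' the coupling degrades once the two auxiliary regions equilibrate
#' between synchronous updates, i.e. once this ratio is large).
#'
#' @param dt_list,ha_list grids of time steps and auxiliary widths; every
#'   `h_a` must be an integer multiple of `h_p`.
#' @param D diffusion coefficient.
#' @param T final time (integer multiple of every `dt`).
#' @param S repeats per cell.
#' @param N particle number.
#' @param h_p PDE grid spacing.
#' @param base_seed seed offset; cell `(i, j)` repeats use seeds derived
#'   from it.
#' @return data frame with `dt`, `ha`, `D_dt_over_ha2`, `hde` (of the mean
#'   profile), `hde_rep_mean`, `hde_rep_sd`.
#' @export
robustness_sweep <- function(dt_list, ha_list, D = 0.05, T = 10, S = 20,
                             N = 500, h_p = 0.01, base_seed = 1) {
  grid <- expand.grid(dt = dt_list, ha = ha_list)
  res <- lapply(seq_len(nrow(grid)), function(g) {
    dt <- grid$dt[g]; ha <- grid$ha[g]
    cfg <- sim_config(x0 = -1, x1 = 1, iface = 0, h_a = ha, h_p = h_p,
                      dt = dt, t_end = T, D = D, N = N,
                      ic = list(type = "pde_only"),
                      snapshot_times = c(0, T))
    exp <- run_experiment(cfg, "hybrid", S = S,
                          base_seed = base_seed + 1000L * g)
    edges <- exp$bin_edges
    ref_mass <- bin_reference(
      function(x, t) meanfield_diffusion(x, t, N = N, D = D,
                                         ic = "left_step"),
      edges, T)
    mean_mass <- apply(exp$density[, length(exp$t), , drop = FALSE], 3,
                       mean) * ha
    h_cell <- hde(mean_mass, ref_mass)
    per_rep <- vapply(seq_len(S), function(s)
      hde(exp$density[s, length(exp$t), ] * ha, ref_mass), numeric(1))
    data.frame(dt = dt, ha = ha, D_dt_over_ha2 = D * dt / ha^2,
               hde = h_cell, hde_rep_mean = mean(per_rep),
               hde_rep_sd = sd(per_rep))
  })
  do.call(rbind, res)
}
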