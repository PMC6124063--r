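# Deterministic continuum regime: theta-method finite differences on a
# cell-centred grid with conservative ghost-cell boundaries.

#' Gridded continuum density field
#'
#' Represents the PDE subdomain as a cell-centred grid of piecewise-constant
#' densities (units: particles per unit length).  The grid spans
#' `(x0, x1)` with spacing `h_p`; cell `i` is centred at
#' `x0 + (i - 1/2) h_p`.  Mass is the cell sum times `h_p`, so zero-flux
#' stepping conserves mass exactly by construction.
#'
#' @param x0,x1 domain end points, `x1 > x0`; the width must be an integer
#'   multiple of `h_p`.
#' @param h_p grid spacing (length).
#' @param values densities per cell, either a single number (recycled) or a
#'   vector of length `(x1 - x0)/h_p`.
#' @param theta time-stepping weight in `[0, 1]`; `0.51` by default (slightly
#'   implicit of Crank-Nicolson, damping the spurious oscillations that
#'   `theta = 0.5` produces on step-function data).
#' @param left_flux prescribed density gradient `lambda` at the left
#'   boundary, giving influx rate `D * lambda`; `0` means zero flux.  The
#'   right boundary is always zero flux.
#' @return an object of class `pde_field`.
#' @export
pde_field <- function(x0, x1, h_p, values = 0, theta = 0.51, left_flux = 0) {
  stopifnot(x1 > x0, h_p > 0, theta >= 0, theta <= 1)
  n <- (x1 - x0) / h_p
  if (abs(n - round(n)) > 1e-8)
    stop("domain width must be an integer multiple of h_p")
  n <- as.integer(round(n))
  if (length(values) == 1L) values <- rep(as.numeric(values), n)
  if (length(values) != n)
    stop("length(values) must equal the number of grid cells (", n, ")")
  structure(
    list(x0 = x0, x1 = x1, h_p = h_p, n = n, values = as.numeric(values),
         theta = theta, left_flux = left_flux),
    class = "pde_field")
}

#' @export
print.pde_field <- function(x, ...) {
  cat(sprintf("<pde_field> %d cells on (%g, %g), h_p = %g, theta = %g\n",
              x$n, x$x0, x$x1, x$h_p, x$theta))
  cat(sprintf("  total mass %.6g; left boundary: %s\n",
              sum(x$values) * x$h_p,
              if (x$left_flux != 0)
                sprintf("prescribed flux (lambda = %g)", x$left_flux)
              else "zero flux"))
  invisible(x)
}

#' Cell centres of a field's grid
#' @param field a [pde_field()].
#' @return numeric vector of cell-centre coordinates.
#' @export
cell_centers <- function(field) {
  field$x0 + (seq_len(field$n) - 0.5) * field$h_p
}

# indices of the cells exactly tiling `interval`; error if misaligned
cells_in_interval <- function(field, interval) {
  stopifnot(length(interval) == 2L, interval[2] > interval[1])
  i0 <- (interval[1] - field$x0) / field$h_p
  i1 <- (interval[2] - field$x0) / field$h_p
  tol <- 1e-6
  if (abs(i0 - round(i0)) > tol || abs(i1 - round(i1)) > tol)
    stop("interval (", interval[1], ", ", interval[2],
         ") is not aligned to whole grid cells")
  i0 <- as.integer(round(i0)); i1 <- as.integer(round(i1))
  if (i0 < 0L || i1 > field$n)
    stop("interval extends outside the PDE subdomain")
  seq.int(i0 + 1L, i1)
}

#' One theta-method update of the diffusion--reaction PDE
#'
#' Advances `dc/dt = D d2c/dx2 + f(c)` by one step of the one-parameter
#' theta family (explicit Euler at `theta = 0`, Crank-Nicolson at `0.5`,
#' implicit Euler at `1`).  Diffusion uses a conservative ghost-cell
#' discretization, so with zero-flux boundaries and `f = 0` the discrete
#' mass is conserved to rounding error; the reaction term is evaluated
#' explicitly at the old state so that the linear tridiagonal solve is
#' retained.  A prescribed-flux left boundary injects mass at exactly
#' `D * left_flux` per unit time.
#'
#' @param field a [pde_field()].
#' @param dt time step (`> 0`).
#' @param D diffusion coefficient.
#' @param reaction optional reaction operator: a function mapping the vector
#'   of cell densities to their local rates of change (e.g. `function(c) -mu
#'   * c`).
#' @return the updated `pde_field`.
#' @export
theta_step <- function(field, dt, D, reaction = NULL) {
  stopifnot(inherits(field, "pde_field"), dt > 0, D >= 0)
  src <- rep(0, field$n)
  if (!is.null(reaction)) {
    src <- as.numeric(reaction(field$values))
    if (length(src) == 1L) src <- rep(src, field$n)
    if (length(src) != field$n)
      stop("reaction operator must return a scalar or one rate per cell")
  }
  if (field$left_flux != 0)
    src[1] <- src[1] + D * field$left_flux / field$h_p
  new_values <- cpp_theta_solve(field$values, field$h_p, dt, D, field$theta,
                                src)
  if (any(!is.finite(new_values)))
    stop("numerical failure: non-finite densities after theta step")
  neg <- new_values < -1e-9 * max(abs(new_values), 1)
  if (any(neg))
    warning(sprintf("negative density in %d cell(s) after theta step (min %.3g)",
                    sum(neg), min(new_values)))
  field$values <- new_values
  field
}

#' Mass of the field over a cell-aligned interval
#'
#' Integrates the piecewise-constant density over `interval` by the exact
#' cell sum (midpoint rule, exact for this representation).  This is the
#' "pseudo-particle" count when `interval` is the PDE auxiliary region.
#'
#' @param field a [pde_field()].
#' @param interval length-2 vector `(lo, hi)` aligned to whole grid cells.
#' @return mass (particle count, real-valued, `>= 0` for nonnegative fields).
#' @export
region_mass <- function(field, interval) {
  idx <- cells_in_interval(field, interval)
  sum(field$values[idx]) * field$h_p
}

#' Deposit (or withdraw) mass uniformly over a cell-aligned interval
#'
#' Changes every cell in `interval` by `amount / width(interval)` so that
#' [region_mass()] changes by exactly `amount`; cells outside are untouched.
#' Withdrawals that drive cells negative are logged as a warning rather than
#' clipped, since clipping would break mass conservation.
#'
#' @inheritParams region_mass
#' @param amount signed particle count to add (`+`) or remove (`-`).
#' @return the updated `pde_field`.
#' @export
deposit_uniform <- function(field, interval, amount) {
  idx <- cells_in_interval(field, interval)
  width <- interval[2] - interval[1]
  field$values[idx] <- field$values[idx] + amount / width
  neg <- which(field$values[idx] < 0)
  if (amount < 0 && length(neg))
    warning(sprintf("deposit_uniform drove %d cell(s) negative (first: cell %d)",
                    length(neg), idx[neg[1]]))
  field
}

#' Dense matrix-exponential reference for the discrete heat equation
#'
#' Independent oracle for the theta stepper: evolves the same cell-centred
#' zero-flux Laplacian exactly in time via an eigendecomposition, i.e.
#' computes `expm(t D L) c0`.  Used to isolate the time-discretization error
#' of [theta_step()].
#'
#' @param values initial cell densities.
#' @param h_p grid spacing.
#' @param D diffusion coefficient.
#' @param t time at which to evaluate.
#' @return cell densities at time `t`.
#' @export
heat_expm_ref <- function(values, h_p, D, t) {
  n <- length(values)
  L <- diag(-2, n)
  L[cbind(1:(n - 1), 2:n)] <- 1
  L[cbind(2:n, 1:(n - 1))] <- 1
  L[1, 1] <- -1
  L[n, n] <- -1
  L <- L * D / h_p^2
  e <- eigen(L, symmetric = TRUE)
  as.numeric(e$vectors %*% (exp(t * e$values) * crossprod(e$vectors, values)))
}
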