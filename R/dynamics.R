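# Samplers and thermostatted dynamics on generic potentials.  A potential is
# a list(energy = function(x), forces = function(x)) over coordinate
# matrices; masses are unity, time is in reduced units.

#' Langevin (BAOAB) propagation at constant temperature
#'
#' @param potential list with `energy(x)` and `forces(x)`.
#' @param x0 starting coordinates (n x 3 matrix).
#' @param n_steps number of steps.
#' @param dt timestep (reduced units).
#' @param kT thermal energy (kJ/mol).
#' @param friction friction coefficient (1/time).
#' @param v0 optional starting velocities (default Maxwell-Boltzmann draw).
#' @param thin keep every `thin`-th frame (0 = final frame only).
#' @return list with `x` (final coordinates), `v` (final velocities) and
#'   `frames` (list of kept coordinate matrices, possibly empty).
#' @export
langevin_dynamics <- function(potential, x0, n_steps, dt = 0.01, kT = 2.5,
                              friction = 1.0, v0 = NULL, thin = 0) {
  x <- matrix(x0, ncol = 3)
  n <- nrow(x)
  v <- if (is.null(v0)) matrix(stats::rnorm(3 * n, sd = sqrt(kT)), n, 3)
       else matrix(v0, ncol = 3)
  f <- potential$forces(x)
  c1 <- exp(-friction * dt)
  c2 <- sqrt(kT * (1 - c1^2))
  frames <- list()
  for (s in seq_len(n_steps)) {
    v <- v + 0.5 * dt * f
    x <- x + 0.5 * dt * v
    v <- c1 * v + c2 * matrix(stats::rnorm(3 * n), n, 3)
    x <- x + 0.5 * dt * v
    f <- potential$forces(x)
    v <- v + 0.5 * dt * f
    if (thin > 0 && s %% thin == 0) frames[[length(frames) + 1L]] <- x
  }
  list(x = x, v = v, frames = frames)
}

#' Metropolis sampling of a potential at fixed temperature
#'
#' Random-walk Metropolis with single-atom Gaussian moves.
#'
#' @inheritParams langevin_dynamics
#' @param n_sweeps number of sweeps (one proposed move per atom each).
#' @param step proposal standard deviation (Angstrom).
#' @return as [langevin_dynamics()] (velocities are NULL).
#' @export
metropolis_sampling <- function(potential, x0, n_sweeps, step = 0.05,
                                kT = 2.5, thin = 0) {
  x <- matrix(x0, ncol = 3)
  n <- nrow(x)
  e <- potential$energy(x)
  frames <- list()
  for (s in seq_len(n_sweeps)) {
    for (a in seq_len(n)) {
      xp <- x
      xp[a, ] <- xp[a, ] + stats::rnorm(3, sd = step)
      ep <- potential$energy(xp)
      if (ep <= e || stats::runif(1) < exp(-(ep - e) / kT)) {
        x <- xp; e <- ep
      }
    }
    if (thin > 0 && s %% thin == 0) frames[[length(frames) + 1L]] <- x
  }
  list(x = x, v = NULL, frames = frames)
}
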