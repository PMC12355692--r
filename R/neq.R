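# Nonequilibrium switching between two potentials, bidirectional
# free-energy estimators (BAR, Jarzynski, Crooks intersection),
# thermodynamic-cycle assembly and uncertainty propagation.
# Units: kJ/mol; time in reduced units.

#' Nonequilibrium switching protocol
#'
#' @param n_start_structures start configurations drawn from the initial
#'   equilibrium ensemble (default 150).
#' @param n_steps switching steps; together with `dt` they set the switch
#'   duration (the defaults emulate a 10 ps switch in reduced time).
#' @param dt timestep.
#' @param relaxation_steps equilibration steps on the target surface
#'   between the forward and backward switches.
#' @param n_repeats independent repeats of the full procedure (default 6).
#' @param kT thermal energy (kJ/mol).
#' @param friction Langevin friction.
#' @param lambda_schedule monotone nondecreasing function on [0, 1] with
#'   lambda(0) = 0 and lambda(1) = 1 (default identity = linear schedule).
#' @param seed integer seed.
#' @return object of class `switching_protocol`.
#' @export
switching_protocol <- function(n_start_structures = 150, n_steps = 1000,
                               dt = 0.01, relaxation_steps = 1000,
                               n_repeats = 6, kT = 2.5, friction = 1.0,
                               lambda_schedule = identity, seed = 1) {
  stopifnot(abs(lambda_schedule(0)) < 1e-12,
            abs(lambda_schedule(1) - 1) < 1e-12)
  grid <- lambda_schedule(seq(0, 1, length.out = max(n_steps, 1) + 1))
  if (any(diff(grid) < -1e-12))
    stop("lambda schedule must be monotone nondecreasing")
  p <- list(n_start_structures = n_start_structures, n_steps = n_steps,
            dt = dt, relaxation_steps = relaxation_steps,
            n_repeats = n_repeats, kT = kT, friction = friction,
            lambda_schedule = lambda_schedule, seed = seed)
  class(p) <- "switching_protocol"
  p
}

mix_potential <- function(U_start, U_end, lam) {
  list(energy = function(x)
         (1 - lam) * U_start$energy(x) + lam * U_end$energy(x),
       forces = function(x)
         (1 - lam) * U_start$forces(x) + lam * U_end$forces(x))
}

#' Switch an ensemble from one potential to another, accumulating work
#'
#' For every start configuration the coupling parameter walks its schedule
#' from 0 to 1; at each increment the work picks up
#' `U_(lambda+dlambda)(x) - U_lambda(x)` and the system is then propagated
#' one Langevin step at the new fixed lambda.  A zero-step protocol reduces
#' to instantaneous perturbation, `W = U_end(x) - U_start(x)`.
#'
#' @param starts list of start coordinate matrices (drawn from the
#'   equilibrium of `U_start`).
#' @param U_start,U_end potentials: `list(energy(x), forces(x))`.
#' @param protocol a [switching_protocol()].
#' @param seed integer seed (default from the protocol).
#' @return list with `works` (kJ/mol, one per surviving trajectory),
#'   `final_configs`, `n_failed` (NaN-flagged and excluded trajectories).
#' @export
neq_switch <- function(starts, U_start, U_end, protocol, seed = NULL) {
  if (is.null(seed)) seed <- protocol$seed
  ns <- protocol$n_steps
  lam_grid <- protocol$lambda_schedule(seq(0, 1, length.out = ns + 1))
  with_seed(seed, {
    works <- numeric(0)
    finals <- list()
    n_failed <- 0L
    for (x0 in starts) {
      x <- matrix(x0, ncol = 3)
      v <- NULL
      W <- 0
      ok <- TRUE
      if (ns == 0) {
        W <- U_end$energy(x) - U_start$energy(x)
      } else {
        for (k in seq_len(ns)) {
          e_old <- (1 - lam_grid[k]) * U_start$energy(x) +
            lam_grid[k] * U_end$energy(x)
          e_new <- (1 - lam_grid[k + 1]) * U_start$energy(x) +
            lam_grid[k + 1] * U_end$energy(x)
          W <- W + (e_new - e_old)
          if (!is.finite(W)) { ok <- FALSE; break }
          pot <- mix_potential(U_start, U_end, lam_grid[k + 1])
          st <- langevin_dynamics(pot, x, 1, dt = protocol$dt,
                                  kT = protocol$kT,
                                  friction = protocol$friction, v0 = v)
          x <- st$x; v <- st$v
        }
      }
      if (ok && is.finite(W)) {
        works <- c(works, W)
        finals[[length(finals) + 1L]] <- x
      } else {
        n_failed <- n_failed + 1L
      }
    }
    if (n_failed > 0)
      warning(n_failed, " trajectories produced non-finite work and were ",
              "excluded")
    list(works = works, final_configs = finals, n_failed = n_failed)
  })
}

#' Importance-resample switched configurations toward the target ensemble
#'
#' Weights `w_i` proportional to `exp(-W_i / kT)` (normalized with a
#' log-sum-exp guard), drawn by systematic resampling under a fixed seed.
#' An effective sample size below 2 triggers a warning.
#'
#' @param configs list of configurations.
#' @param works switching works aligned with `configs` (kJ/mol).
#' @param kT thermal energy (kJ/mol).
#' @param seed integer seed.
#' @return list with `configs` (resampled), `weights` (normalized), `ess`.
#' @export
resample_to_target <- function(configs, works, kT, seed = 1) {
  stopifnot(length(configs) == length(works))
  lw <- -works / kT
  lw <- lw - max(lw)
  w <- exp(lw) / sum(exp(lw))
  ess <- 1 / sum(w^2)
  if (ess < 2)
    warning("weight collapse during resampling: ESS = ", format(ess))
  n <- length(w)
  res <- with_seed(seed, {
    u <- (stats::runif(1) + seq_len(n) - 1) / n
    cw <- cumsum(w)
    idx <- findInterval(u, cw) + 1L
    idx[idx > n] <- n
    idx
  })
  list(configs = configs[res], weights = w, ess = ess)
}

logmeanexp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

#' Free energy from bidirectional work samples
#'
#' `"bar"` solves the Bennett acceptance-ratio self-consistency to 1e-10
#' and reports the standard asymptotic error; `"jarzynski_forward"`
#' exponentially averages the forward works; `"crooks_fit"` locates the
#' crossing of the forward work density and the negated backward work
#' density.  Backward works `W_b` are the works measured along the reverse
#' (end to start) switches.
#'
#' @param W_f forward works (kJ/mol).
#' @param W_b backward works (kJ/mol; required for bar and crooks_fit).
#' @param method `"bar"`, `"jarzynski_forward"` or `"crooks_fit"`.
#' @param kT thermal energy (kJ/mol).
#' @return list with `delta_g` (kJ/mol), `se` (kJ/mol) and `method`.
#' @export
estimate_free_energy <- function(W_f, W_b = NULL,
                                 method = c("bar", "jarzynski_forward",
                                            "crooks_fit"),
                                 kT = 2.5) {
  method <- match.arg(method)
  if (length(W_f) == 0) stop("empty forward work set")
  beta <- 1 / kT
  if (method == "jarzynski_forward") {
    dg <- -kT * logmeanexp(-beta * W_f)
    z <- exp(-beta * (W_f - min(W_f)))
    se <- kT * stats::sd(z) / (mean(z) * sqrt(length(W_f)))
    return(list(delta_g = dg, se = se, method = method))
  }
  if (is.null(W_b) || length(W_b) == 0)
    stop(method, " requires backward works")
  if (method == "crooks_fit") {
    rev_w <- -W_b
    rng <- range(c(W_f, rev_w))
    grid <- seq(rng[1], rng[2], length.out = 512)
    df <- stats::density(W_f, from = rng[1], to = rng[2], n = 512)
    db <- stats::density(rev_w, from = rng[1], to = rng[2], n = 512)
    diffd <- df$y - db$y
    cross <- which(diffd[-1] * diffd[-length(diffd)] < 0)
    if (!length(cross))
      stop("forward and reversed-backward work densities do not cross")
    # pick the crossing with the highest local density (the overlap region)
    dens <- (df$y + db$y)[cross]
    k <- cross[which.max(dens)]
    x1 <- grid[k]; x2 <- grid[k + 1]
    y1 <- diffd[k]; y2 <- diffd[k + 1]
    dg <- x1 - y1 * (x2 - x1) / (y2 - y1)
    return(list(delta_g = dg, se = NA_real_, method = method))
  }
  # BAR
  nf <- length(W_f); nb <- length(W_b)
  M <- log(nf / nb)
  fermi <- function(x) 1 / (1 + exp(x))
  gfun <- function(dg)
    sum(fermi(M + beta * (W_f - dg))) -
      sum(fermi(-M + beta * (W_b + dg)))
  lo <- min(c(W_f, -W_b)) - 10 * kT
  hi <- max(c(W_f, -W_b)) + 10 * kT
  sol <- stats::uniroot(gfun, c(lo, hi), tol = 1e-10)
  dg <- sol$root
  se <- bar_variance(W_f, W_b, kT, dg)
  list(delta_g = dg, se = se, method = "bar")
}

#' Asymptotic standard error of the acceptance-ratio estimator
#'
#' Standard two-state asymptotic variance evaluated at the BAR solution
#' (computed internally when not supplied).
#'
#' @inheritParams estimate_free_energy
#' @param delta_g optional precomputed BAR estimate (kJ/mol).
#' @return standard error (kJ/mol).
#' @export
bar_variance <- function(W_f, W_b, kT = 2.5, delta_g = NULL) {
  if (length(W_f) < 2 || length(W_b) < 2)
    stop("at least 2 samples per direction are required")
  if (is.null(delta_g))
    delta_g <- estimate_free_energy(W_f, W_b, "bar", kT)$delta_g
  beta <- 1 / kT
  nf <- length(W_f); nb <- length(W_b)
  M <- log(nf / nb)
  fermi <- function(x) 1 / (1 + exp(x))
  ff <- fermi(M + beta * (W_f - delta_g))
  fb <- fermi(-M + beta * (W_b + delta_g))
  var_b <- mean(ff^2) / (nf * mean(ff)^2) - 1 / nf +
    mean(fb^2) / (nb * mean(fb)^2) - 1 / nb
  kT * sqrt(max(var_b, 0))
}

#' Combine end-state corrections through the thermodynamic cycle
#'
#' `dG_bind(i, j) = dG_MM_bind + dG_corr_LP[i] - dG_corr_LS[j]` over the
#' full repeat grid (n_repeats per end state gives an n x n grid), with the
#' grid mean and its standard deviation.
#'
#' @param dg_mm_bind the MM-level binding free energy (kJ/mol, input
#'   scalar).
#' @param corrections_lp per-repeat end-state corrections for the
#'   protein-ligand complex (kJ/mol).
#' @param corrections_ls per-repeat corrections for the solvated ligand
#'   (kJ/mol).
#' @return object of class `cycle_estimate`: `grid`, `mean`, `sigma`
#'   (standard deviation over the grid), `n_combinations`.
#' @export
combine_cycle <- function(dg_mm_bind, corrections_lp, corrections_ls) {
  if (!length(corrections_lp) || !length(corrections_ls))
    stop("corrections for both end states are required")
  grid <- outer(corrections_lp, -corrections_ls, `+`) + dg_mm_bind
  out <- list(grid = grid, mean = mean(grid), sigma = stats::sd(grid),
              n_combinations = length(grid),
              dg_mm_bind = dg_mm_bind,
              corrections_lp = corrections_lp,
              corrections_ls = corrections_ls)
  class(out) <- "cycle_estimate"
  out
}

#' @export
print.cycle_estimate <- function(x, ...) {
  cat("cycle_estimate:", x$n_combinations, "combinations; dG_bind =",
      format(x$mean, digits = 6), "+/-", format(x$sigma, digits = 4),
      "kJ/mol (grid sd)\n")
  invisible(x)
}

#' Total uncertainty of the corrected binding free energy
#'
#' `sqrt(d_LP^2 + d_LS^2 + (2 sigma)^2)`: the two end-state estimator
#' errors combined with twice the spread of the repeat-grid estimates.
#'
#' @param delta_mbar_lp,delta_mbar_ls end-state estimator standard errors
#'   (kJ/mol, nonnegative).
#' @param sigma_bind standard deviation over the cycle grid (kJ/mol,
#'   nonnegative).
#' @return total uncertainty (kJ/mol).
#' @export
propagate_uncertainty <- function(delta_mbar_lp, delta_mbar_ls,
                                  sigma_bind) {
  if (delta_mbar_lp < 0 || delta_mbar_ls < 0 || sigma_bind < 0)
    stop("uncertainty components must be nonnegative")
  sqrt(delta_mbar_lp^2 + delta_mbar_ls^2 + (2 * sigma_bind)^2)
}

#' Write work records to CSV / a cycle report to JSON
#'
#' @param works data frame with columns `repeat_id`, `direction`,
#'   `start_index`, `work_kJ_per_mol` (see [neq_switch()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_work_records <- function(works, path) {
  utils::write.csv(works, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_work_records
#' @param cycle a [combine_cycle()] result.
#' @param uncertainty list with `delta_mbar_lp`, `delta_mbar_ls` and the
#'   propagated total (see [propagate_uncertainty()]).
#' @export
write_cycle_report <- function(cycle, uncertainty, path) {
  payload <- list(dg_mm_bind = cycle$dg_mm_bind,
                  corrections_lp = cycle$corrections_lp,
                  corrections_ls = cycle$corrections_ls,
                  n_combinations = cycle$n_combinations,
                  dg_bind_mean = cycle$mean,
                  sigma_bind = cycle$sigma,
                  uncertainty = uncertainty)
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}
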