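#' Generate a labeled conformer set from the toy surface
#'
#' Samples the tier-0 surface at the configured temperature (Langevin with
#' burn-in and thinning, or Metropolis), then labels every conformer with
#' energies at all three tiers and analytic forces at tiers 0 and 1.
#' Tier-2 forces are withheld by default, reflecting the situation where the
#' highest tier provides energies only; `tier2_forces = TRUE` overrides this
#' for controlled experiments.  Deterministic under `seed`.
#'
#' @param cfg a [toy_pes_config()].
#' @param n number of conformers.
#' @param sampler `"langevin"` or `"metropolis"`.
#' @param seed integer seed.
#' @param burn_in equilibration steps/sweeps before collecting.
#' @param thin steps/sweeps between collected frames.
#' @param tier2_forces include analytic tier-2 forces (default FALSE).
#' @param energy_ceiling abort if a sampled energy exceeds this value
#'   (kJ/mol) above the starting energy; guards against divergence.
#' @return object of class `conformer_set`: list with `conformers` (each a
#'   list with `elements`, `coords`, `region`, `energies`, `forces`) and
#'   `config`.
#' @export
gen_conformers <- function(cfg, n, sampler = c("langevin", "metropolis"),
                           seed = 1, burn_in = 500, thin = 25,
                           tier2_forces = FALSE, energy_ceiling = 1e4) {
  sampler <- match.arg(sampler)
  pot <- toy_pes_potential(cfg, tier = 0)
  with_seed(seed, {
    e_start <- pot$energy(cfg$x0)
    if (sampler == "langevin") {
      eq <- langevin_dynamics(pot, cfg$x0, burn_in, kT = cfg$kT)
      run <- langevin_dynamics(pot, eq$x, n * thin, kT = cfg$kT,
                               v0 = eq$v, thin = thin)
    } else {
      eq <- metropolis_sampling(pot, cfg$x0, burn_in, kT = cfg$kT)
      run <- metropolis_sampling(pot, eq$x, n * thin, kT = cfg$kT,
                                 thin = thin)
    }
    frames <- run$frames[seq_len(n)]
    conformers <- lapply(frames, function(x) {
      e0 <- toy_pes_energy(cfg, x, 0, gradient = TRUE)
      e1 <- toy_pes_energy(cfg, x, 1, gradient = TRUE)
      if (e0$energy - e_start > energy_ceiling)
        stop("sampler diverged: energy ", format(e0$energy),
             " kJ/mol above ceiling")
      e2 <- toy_pes_energy(cfg, x, 2, gradient = tier2_forces)
      forces <- list(tier0 = e0$forces, tier1 = e1$forces)
      if (tier2_forces) forces$tier2 <- e2$forces
      list(elements = cfg$elements, coords = x, region = cfg$region,
           energies = c(tier0 = e0$energy, tier1 = e1$energy,
                        tier2 = e2$energy),
           forces = forces)
    })
    out <- list(conformers = conformers, config = cfg)
    class(out) <- "conformer_set"
    out
  })
}

#' @export
print.conformer_set <- function(x, ...) {
  cat("conformer_set:", length(x$conformers), "conformers,",
      x$config$n_atoms, "atoms (",
      sum(x$config$region == 1L), "QM )\n")
  invisible(x)
}

#' Tier-gap statistics of a labeled conformer set
#'
#' Sample means and standard deviations of the tier-1 minus tier-0 and
#' tier-2 minus tier-1 energy differences, plus the raw gap vectors for
#' histogramming.
#'
#' @param set a [gen_conformers()] result.
#' @return list with `mean_10`, `sd_10`, `mean_21`, `sd_21` (kJ/mol) and a
#'   data frame `gaps`.
#' @export
tier_gap_statistics <- function(set) {
  E <- t(vapply(set$conformers, function(cf) cf$energies, numeric(3)))
  if (anyNA(E)) stop("missing tier energy labels")
  g10 <- E[, "tier1"] - E[, "tier0"]
  g21 <- E[, "tier2"] - E[, "tier1"]
  list(mean_10 = mean(g10), sd_10 = stats::sd(g10),
       mean_21 = mean(g21), sd_21 = stats::sd(g21),
       gaps = data.frame(gap_10 = g10, gap_21 = g21))
}

#' Calibrate the tier-2 correction magnitude to a target spread
#'
#' The tier-2 correction scales linearly with its magnitude parameter, so
#' the standard deviation of the tier-2 minus tier-1 gap is proportional to
#' it; the calibration samples once at the current magnitude and rescales.
#'
#' @param cfg a [toy_pes_config()].
#' @param target_sd desired standard deviation of the tier-2 minus tier-1
#'   energy difference (kJ/mol).
#' @param n sample size for the calibration estimate.
#' @param seed integer seed.
#' @return the calibrated `toy_pes_config`.
#' @export
calibrate_tier2 <- function(cfg, target_sd, n = 200, seed = 99) {
  set <- gen_conformers(cfg, n, seed = seed)
  s <- tier_gap_statistics(set)$sd_21
  if (s <= 0) stop("tier-2 correction has zero spread; cannot calibrate")
  cfg$tier2_magnitude <- cfg$tier2_magnitude * target_sd / s
  cfg
}
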