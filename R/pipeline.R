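# Glue between the trained potential and the switching protocol: the
# ensemble exposed as a generic potential, and the full per-end-state
# correction procedure (forward switch, resampling, relaxation, backward
# switch, repeated).

#' Expose a trained ensemble as a generic potential
#'
#' Wraps [predict_hdnnp()] in the `list(energy, forces)` interface used by
#' the dynamics and switching drivers, with an optional constant offset
#' (e.g. the stoichiometric shift sum of the modelled system).  The last
#' evaluation is cached so an energy call followed by a force call at the
#' same coordinates costs one prediction.
#'
#' @param ensemble an `hdnnp_ensemble`.
#' @param elements element symbols of the system the potential will see.
#' @param offset constant added to every energy (kJ/mol).
#' @return list with `energy(x)` and `forces(x)`.
#' @export
hdnnp_potential <- function(ensemble, elements, offset = 0) {
  cache <- new.env(parent = emptyenv())
  cache$x <- NULL
  evaluate <- function(x, need_forces) {
    x <- matrix(x, ncol = 3)
    hit <- !is.null(cache$x) && identical(dim(cache$x), dim(x)) &&
      all(cache$x == x) && (!need_forces || !is.null(cache$forces))
    if (!hit) {
      p <- predict_hdnnp(ensemble, elements, x, forces = need_forces)
      cache$x <- x
      cache$energy <- p$energy + offset
      cache$forces <- p$forces
    }
    invisible(NULL)
  }
  list(energy = function(x) { evaluate(x, FALSE); cache$energy },
       forces = function(x) { evaluate(x, TRUE); cache$forces })
}

#' Per-end-state free-energy correction by bidirectional switching
#'
#' Runs the full protocol for one end state: start structures are drawn
#' (with a fresh seeded draw per repeat) from a pool sampled on the start
#' surface, switched forward, importance-resampled toward the target
#' surface, relaxed there, and switched back; each repeat yields a BAR
#' estimate.  The pooled works over all repeats give the end-state
#' estimator error.
#'
#' @param starts_pool list of equilibrium configurations of the start
#'   surface.
#' @param U_start,U_end potentials (`list(energy, forces)`).
#' @param protocol a [switching_protocol()].
#' @return list with `dg_per_repeat`, `se_pooled` (BAR asymptotic error on
#'   the pooled works), `works` (data frame of all work records),
#'   `n_failed`.
#' @export
end_state_correction <- function(starts_pool, U_start, U_end, protocol) {
  kT <- protocol$kT
  dg <- numeric(protocol$n_repeats)
  all_wf <- numeric(0); all_wb <- numeric(0)
  records <- list()
  n_failed <- 0L
  for (rep_i in seq_len(protocol$n_repeats)) {
    seed_r <- protocol$seed + 1000L * rep_i
    starts <- with_seed(seed_r, {
      idx <- sample(length(starts_pool), protocol$n_start_structures,
                    replace = length(starts_pool) <
                      protocol$n_start_structures)
      starts_pool[idx]
    })
    fwd <- neq_switch(starts, U_start, U_end, protocol, seed = seed_r + 1L)
    res <- resample_to_target(fwd$final_configs, fwd$works, kT,
                              seed = seed_r + 2L)
    relaxed <- with_seed(seed_r + 3L, {
      lapply(res$configs, function(x)
        langevin_dynamics(U_end, x, protocol$relaxation_steps,
                          dt = protocol$dt, kT = kT,
                          friction = protocol$friction)$x)
    })
    bwd <- neq_switch(relaxed, U_end, U_start, protocol, seed = seed_r + 4L)
    est <- estimate_free_energy(fwd$works, bwd$works, "bar", kT)
    dg[rep_i] <- est$delta_g
    all_wf <- c(all_wf, fwd$works); all_wb <- c(all_wb, bwd$works)
    n_failed <- n_failed + fwd$n_failed + bwd$n_failed
    records[[length(records) + 1L]] <- data.frame(
      repeat_id = rep_i,
      direction = rep(c("forward", "backward"),
                      c(length(fwd$works), length(bwd$works))),
      start_index = c(seq_along(fwd$works), seq_along(bwd$works)),
      work_kJ_per_mol = c(fwd$works, bwd$works))
  }
  list(dg_per_repeat = dg,
       se_pooled = bar_variance(all_wf, all_wb, kT),
       works = do.call(rbind, records),
       n_failed = n_failed)
}
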