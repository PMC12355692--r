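# Three-tier toy potential-energy surface:
#   tier 0 ("MM")      harmonic bonds + Lennard-Jones + fixed point charges
#                      (or pure site-tethered harmonic wells)
#   tier 1 ("QM/MM")   Morse-type anharmonic correction and charge rescaling
#                      on the tagged QM atoms
#   tier 2 ("QM/QM")   strictly local correction on the quantum-core atoms
# All terms depend on interatomic distances only, so analytic forces follow
# from dU/dr.  Units: kJ/mol, Angstrom; dynamics in reduced time with unit
# masses.

#' Configure the three-tier toy potential-energy surface
#'
#' Defines a linear chain of `n_atoms` atoms with harmonic bonds,
#' Lennard-Jones interactions between atoms at least three bonds apart and
#' fixed point charges.  Atoms in `qm_atoms` (the represented region Q) get
#' a Morse-type anharmonic bond correction and rescaled charges at tier 1;
#' atoms in `core_atoms` (a subset of Q) carry the strictly local tier-2
#' correction, a linear-plus-quadratic term in the core bond displacements
#' whose overall magnitude `tier2_magnitude` tunes the spread of the
#' tier-2 minus tier-1 energy-difference distribution.
#'
#' @param n_atoms chain length (default 12).
#' @param qm_atoms indices of the QM-region atoms (default 1:6).
#' @param core_atoms indices of the quantum-core atoms (default 1:3, must be
#'   a subset of `qm_atoms`).
#' @param kT thermal energy used by the samplers (kJ/mol; default 2.5,
#'   roughly room temperature).
#' @param bond_k harmonic bond force constant (kJ/mol/A^2).
#' @param bond_r0 equilibrium bond length (Angstrom).
#' @param lj_epsilon,lj_sigma Lennard-Jones parameters (kJ/mol, Angstrom).
#' @param charge magnitude of the alternating point charges (e).
#' @param tier1_magnitude scale of the tier-1 anharmonic correction.
#' @param tier2_magnitude scale of the tier-2 core correction; the default
#'   of 3.0 puts the tier-2 minus tier-1 spread near 10 kJ/mol at the
#'   default temperature.
#' @param harmonic_only if TRUE the tier-0 surface is a sum of site-tethered
#'   Cartesian harmonic wells only (closed-form equipartition:
#'   mean potential energy = 3 n_atoms kT / 2).
#' @return object of class `toy_pes_config`.
#' @export
toy_pes_config <- function(n_atoms = 12, qm_atoms = 1:6, core_atoms = 1:3,
                           kT = 2.5, bond_k = 300, bond_r0 = 1.5,
                           lj_epsilon = 0.4, lj_sigma = 3.0, charge = 0.15,
                           tier1_magnitude = 1.0, tier2_magnitude = 3.0,
                           harmonic_only = FALSE) {
  stopifnot(all(core_atoms %in% qm_atoms), all(qm_atoms <= n_atoms))
  elements <- rep(c("C", "O", "N", "C", "C", "H"), length.out = n_atoms)
  region <- integer(n_atoms)
  region[qm_atoms] <- 1L                      # Q
  region[setdiff(seq_len(n_atoms), qm_atoms)] <- 2L   # E'
  cfg <- list(n_atoms = n_atoms, qm_atoms = qm_atoms,
              core_atoms = core_atoms, elements = elements, region = region,
              kT = kT, bond_k = bond_k, bond_r0 = bond_r0,
              lj_epsilon = lj_epsilon, lj_sigma = lj_sigma,
              charges = charge * (-1)^(seq_len(n_atoms)),
              tier1_magnitude = tier1_magnitude,
              tier2_magnitude = tier2_magnitude,
              harmonic_only = harmonic_only,
              x0 = cbind(bond_r0 * (seq_len(n_atoms) - 1), 0, 0))
  class(cfg) <- "toy_pes_config"
  cfg
}

# pair lists ------------------------------------------------------------

pes_pairs <- function(cfg) {
  n <- cfg$n_atoms
  bonds <- cbind(seq_len(n - 1), seq(2, n))
  far <- which(outer(seq_len(n), seq_len(n),
                     function(i, j) j - i >= 3), arr.ind = TRUE)
  list(bonds = bonds, far = far[far[, 1] < far[, 2], , drop = FALSE])
}

# distance helper: returns r and unit vectors for a pair list
pair_geometry <- function(x, pairs) {
  dvec <- x[pairs[, 2], , drop = FALSE] - x[pairs[, 1], , drop = FALSE]
  r <- sqrt(rowSums(dvec^2))
  list(r = r, u = dvec / r)
}

# accumulate pairwise forces from the radial derivative dU/dr:
# with u the unit vector from atom i to atom j, F_i = +dU/dr * u and
# F_j = -dU/dr * u
add_pair_forces <- function(Fm, pairs, dU_dr, u) {
  for (k in seq_len(nrow(pairs))) {
    f <- dU_dr[k] * u[k, ]
    Fm[pairs[k, 1], ] <- Fm[pairs[k, 1], ] + f
    Fm[pairs[k, 2], ] <- Fm[pairs[k, 2], ] - f
  }
  Fm
}

#' Evaluate a tier of the toy potential-energy surface
#'
#' @param cfg a [toy_pes_config()].
#' @param x coordinate matrix (n_atoms x 3, Angstrom).
#' @param tier 0, 1 or 2 (cumulative: tier 2 = tier 0 + both corrections).
#' @param gradient if TRUE also return analytic forces.
#' @return list with `energy` (kJ/mol) and, if requested, `forces`
#'   (n_atoms x 3, kJ/mol/Angstrom).
#' @export
toy_pes_energy <- function(cfg, x, tier = 0, gradient = FALSE) {
  x <- matrix(x, ncol = 3)
  n <- cfg$n_atoms
  Fm <- matrix(0, n, 3)
  e <- 0
  if (cfg$harmonic_only) {
    dx <- x - cfg$x0
    e <- 0.5 * cfg$bond_k * sum(dx^2)
    if (gradient) Fm <- -cfg$bond_k * dx
  } else {
    pr <- pes_pairs(cfg)
    bg <- pair_geometry(x, pr$bonds)
    dr <- bg$r - cfg$bond_r0
    e <- e + 0.5 * cfg$bond_k * sum(dr^2)
    if (gradient)
      Fm <- add_pair_forces(Fm, pr$bonds, cfg$bond_k * dr, bg$u)
    if (nrow(pr$far)) {
      fg <- pair_geometry(x, pr$far)
      sr6 <- (cfg$lj_sigma / fg$r)^6
      e <- e + 4 * cfg$lj_epsilon * sum(sr6^2 - sr6)
      qq <- coulomb_constant() *
        cfg$charges[pr$far[, 1]] * cfg$charges[pr$far[, 2]]
      e <- e + sum(qq / fg$r)
      if (gradient) {
        dlj <- 4 * cfg$lj_epsilon * (-12 * sr6^2 + 6 * sr6) / fg$r
        dc <- -qq / fg$r^2
        Fm <- add_pair_forces(Fm, pr$far, dlj + dc, fg$u)
      }
    }
  }
  if (tier >= 1) {
    t1 <- tier1_correction(cfg, x, gradient)
    e <- e + t1$energy
    if (gradient) Fm <- Fm + t1$forces
  }
  if (tier >= 2) {
    t2 <- tier2_correction(cfg, x, gradient)
    e <- e + t2$energy
    if (gradient) Fm <- Fm + t2$forces
  }
  if (gradient) list(energy = e, forces = Fm) else list(energy = e)
}

# Morse-minus-harmonic on QM bonds plus charge rescaling on QM pairs
tier1_correction <- function(cfg, x, gradient = FALSE) {
  n <- cfg$n_atoms
  Fm <- matrix(0, n, 3)
  qm <- cfg$qm_atoms
  bonds <- cbind(seq_len(n - 1), seq(2, n))
  inQ <- bonds[, 1] %in% qm & bonds[, 2] %in% qm
  e <- 0
  if (any(inQ)) {
    bq <- bonds[inQ, , drop = FALSE]
    g <- pair_geometry(x, bq)
    dr <- g$r - cfg$bond_r0
    De <- cfg$tier1_magnitude * 40
    a <- sqrt(cfg$bond_k / (2 * De))
    em <- exp(-a * dr)
    e <- e + sum(De * (1 - em)^2 - 0.5 * cfg$bond_k * dr^2)
    if (gradient) {
      dU <- 2 * De * a * em * (1 - em) - cfg$bond_k * dr
      Fm <- add_pair_forces(Fm, bq, dU, g$u)
    }
  }
  # polarization-like charge rescaling: QM-QM far pairs get 10% stronger
  if (!cfg$harmonic_only) {
    pr <- pes_pairs(cfg)
    far <- pr$far
    both_q <- far[, 1] %in% qm & far[, 2] %in% qm
    if (any(both_q)) {
      fq <- far[both_q, , drop = FALSE]
      g <- pair_geometry(x, fq)
      dq <- 0.21 * cfg$tier1_magnitude   # (1.1^2 - 1) charge-product scale
      qq <- coulomb_constant() * dq *
        cfg$charges[fq[, 1]] * cfg$charges[fq[, 2]]
      e <- e + sum(qq / g$r)
      if (gradient)
        Fm <- add_pair_forces(Fm, fq, -qq / g$r^2, g$u)
    }
  }
  list(energy = e, forces = Fm)
}

# strictly local: linear + quadratic in the core bond displacements
tier2_correction <- function(cfg, x, gradient = FALSE) {
  n <- cfg$n_atoms
  Fm <- matrix(0, n, 3)
  core <- cfg$core_atoms
  bonds <- cbind(seq_len(n - 1), seq(2, n))
  inC <- bonds[, 1] %in% core & bonds[, 2] %in% core
  e <- 0
  if (any(inC)) {
    bc <- bonds[inC, , drop = FALSE]
    g <- pair_geometry(x, bc)
    dr <- g$r - cfg$bond_r0
    a_lin <- cfg$tier2_magnitude * 25     # kJ/mol per Angstrom
    b_quad <- cfg$tier2_magnitude * 15    # kJ/mol per Angstrom^2
    e <- sum(a_lin * dr + b_quad * dr^2)
    if (gradient) {
      dU <- a_lin + 2 * b_quad * dr
      Fm <- add_pair_forces(Fm, bc, dU, g$u)
    }
  }
  list(energy = e, forces = Fm)
}

#' Package a tier of the toy surface as a generic potential
#'
#' Returns the `list(energy = function(x), forces = function(x))` interface
#' consumed by the samplers and the nonequilibrium switching driver.
#'
#' @inheritParams toy_pes_energy
#' @return list of two closures.
#' @export
toy_pes_potential <- function(cfg, tier = 0) {
  force(tier)
  list(energy = function(x) toy_pes_energy(cfg, x, tier)$energy,
       forces = function(x) toy_pes_energy(cfg, x, tier,
                                           gradient = TRUE)$forces)
}
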