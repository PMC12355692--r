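# Energy ledger: assembling and disassembling QM/MM and QM/QM/MM totals,
# atomic references, element-dependent stoichiometric shifts, and the
# median-window structure filter.  Units: kJ/mol, Angstrom, elementary charge.

#' Coulomb constant in kJ/mol * Angstrom / e^2
#'
#' `N_A e^2 / (4 pi eps0)`, evaluated from the 2018 CODATA exact values of
#' the elementary charge and Avogadro constant and the recommended vacuum
#' permittivity.  Used by [pair_electrostatics()].
#'
#' @return scalar, approximately 1389.3545764.
#' @export
coulomb_constant <- function() {
  e <- 1.602176634e-19        # C (exact)
  na <- 6.02214076e23         # 1/mol (exact)
  eps0 <- 8.8541878128e-12    # F/m
  na * e^2 / (4 * pi * eps0) * 1e10 / 1000  # J*m -> kJ/mol*Angstrom
}

#' Pairwise QM-MM point-charge electrostatics
#'
#' `sum_{I in Q} sum_{A in E} k q_I q_A / |R_I - R_A|` over all pairs of QM
#' charges and MM charges, with `k` from [coulomb_constant()].
#'
#' @param q_qm,q_mm numeric charge vectors (e).
#' @param r_qm,r_mm coordinate matrices (n x 3, Angstrom).
#' @return scalar energy (kJ/mol).
#' @export
pair_electrostatics <- function(q_qm, r_qm, q_mm, r_mm) {
  r_qm <- matrix(as.numeric(r_qm), ncol = 3)
  r_mm <- matrix(as.numeric(r_mm), ncol = 3)
  stopifnot(length(q_qm) == nrow(r_qm), length(q_mm) == nrow(r_mm),
            all(is.finite(q_qm)), all(is.finite(q_mm)))
  if (length(q_qm) == 0 || length(q_mm) == 0) return(0)
  d2 <- outer(rowSums(r_qm^2), rowSums(r_mm^2), `+`) -
    2 * r_qm %*% t(r_mm)
  d <- sqrt(pmax(d2, 0))
  if (any(d < 1e-12))
    stop("coincident QM-MM pair (zero distance)")
  coulomb_constant() * sum(outer(q_qm, q_mm) / d)
}

#' Machine-learning energy target from a QM/MM calculation
#'
#' The quantity the potential actually learns: the QM energy plus the
#' difference between the embedded electrostatic interaction and the pure
#' point-charge pair sum, `E_ML = E_QM + E_elec_int - pair_sum`.
#'
#' @param e_qm QM energy (kJ/mol).
#' @param e_elec_int electrostatic QM-MM embedding interaction (kJ/mol).
#' @param pair_sum point-charge pair electrostatics (kJ/mol).
#' @return scalar `E_ML` (kJ/mol).
#' @export
ml_target_from_qmmm <- function(e_qm, e_elec_int, pair_sum) {
  e_qm + e_elec_int - pair_sum
}

#' Assemble the QM/MM total energy
#'
#' `E_QM/MM = E_ML + E_MM + E_LJ_int + pair_sum + sum_m n_m E_atomic_m`.
#' The atomic reference energies remove the large per-atom offset from the
#' learned quantity.
#'
#' @param e_ml learned energy component (kJ/mol).
#' @param e_mm MM energy (kJ/mol).
#' @param e_lj_int nonelectrostatic QM-MM interaction (kJ/mol).
#' @param pair_sum point-charge pair electrostatics (kJ/mol).
#' @param atomic_reference named numeric vector, element -> atomic reference
#'   energy (kJ/mol).
#' @param counts named integer vector, element -> number of QM atoms.
#' @return scalar total (kJ/mol).
#' @export
assemble_qmmm <- function(e_ml, e_mm = 0, e_lj_int = 0, pair_sum = 0,
                          atomic_reference = numeric(0),
                          counts = integer(0)) {
  missing_el <- setdiff(names(counts), names(atomic_reference))
  if (length(missing_el))
    stop("no atomic reference energy for element(s): ",
         paste(missing_el, collapse = ", "))
  atom_sum <- if (length(counts))
    sum(counts * atomic_reference[names(counts)]) else 0
  e_ml + e_mm + e_lj_int + pair_sum + atom_sum
}

#' Assemble the QM/QM/MM total energy
#'
#' Adds the learned tier correction and the element-dependent mean shifts to
#' the QM/MM assembly:
#' `E = E_ML + dE_ML + E_MM + E_LJ_int + pair_sum +
#'  sum_m n_m (E_atomic_m + shift_m)`.
#'
#' @inheritParams assemble_qmmm
#' @param delta_e_ml learned tier-correction energy (kJ/mol).
#' @param shifts a [fit_shifts()] table or a named numeric vector,
#'   element -> mean shift (kJ/mol).
#' @return scalar total (kJ/mol).
#' @export
assemble_qmqmmm <- function(e_ml, delta_e_ml = 0, e_mm = 0, e_lj_int = 0,
                            pair_sum = 0, atomic_reference = numeric(0),
                            counts = integer(0), shifts = numeric(0)) {
  if (inherits(shifts, "shift_table")) shifts <- shifts$shifts
  base <- assemble_qmmm(e_ml, e_mm, e_lj_int, pair_sum,
                        atomic_reference, counts)
  shift_sum <- if (length(counts) && length(shifts)) {
    sh <- shifts[names(counts)]
    sh[is.na(sh)] <- 0
    sum(counts * sh)
  } else 0
  base + delta_e_ml + shift_sum
}

#' Fit element-dependent stoichiometric shifts
#'
#' Least-squares fit of per-structure energy differences between two theory
#' tiers against the structures' element counts: solves `N s = dE` in the
#' minimum-norm least-squares sense (SVD pseudo-inverse), so rank-deficient
#' stoichiometries (elements in fixed ratio) return the minimum-norm
#' solution, flagged in the diagnostics.
#'
#' @param stoichiometry numeric matrix (structures x elements) of atom
#'   counts, with element names as column names.
#' @param delta_e numeric vector of per-structure energy differences
#'   (kJ/mol).
#' @return object of class `shift_table`: `shifts` (named vector, kJ/mol),
#'   `residual_rms`, `rank`, `rank_deficient`, `max_normal_residual`
#'   (max |N' r|, orthogonality of residuals to the column space).
#' @export
fit_shifts <- function(stoichiometry, delta_e) {
  N <- as.matrix(stoichiometry)
  if (nrow(N) == 0 || length(delta_e) == 0)
    stop("at least one structure is required to fit shifts")
  stopifnot(nrow(N) == length(delta_e))
  sv <- svd(N)
  tol <- max(dim(N)) * max(sv$d) * .Machine$double.eps
  keep <- sv$d > tol
  s <- sv$v[, keep, drop = FALSE] %*%
    (crossprod(sv$u[, keep, drop = FALSE], delta_e) / sv$d[keep])
  s <- drop(s)
  names(s) <- colnames(N)
  r <- delta_e - drop(N %*% s)
  out <- list(shifts = s,
              residual_rms = sqrt(mean(r^2)),
              rank = sum(keep),
              rank_deficient = sum(keep) < ncol(N),
              max_normal_residual = max(abs(crossprod(N, r))))
  class(out) <- "shift_table"
  out
}

#' @export
print.shift_table <- function(x, ...) {
  cat("shift_table (rank", x$rank,
      if (x$rank_deficient) "(deficient)" else "", "):\n")
  print(round(x$shifts, 6))
  cat("residual RMS:", format(x$residual_rms), "kJ/mol\n")
  invisible(x)
}

#' Filter structures by a window around the median energy
#'
#' Keeps a structure when its energy lies within `window` of the median of
#' the energy distribution (inclusive comparison; the median of an even
#' count is the midpoint of the central pair).  Idempotent with respect to
#' the original median and invariant under permutation of the input.
#'
#' @param energies numeric vector (kJ/mol).
#' @param window half-width of the acceptance window (kJ/mol, default 150).
#' @return logical mask, TRUE for structures to keep.
#' @export
filter_by_median_window <- function(energies, window = 150) {
  if (length(energies) == 0) stop("empty energy list")
  m <- stats::median(energies)
  abs(energies - m) <= window
}

#' Per-structure ledger records
#'
#' Builds a data frame itemizing every term of the two assemblies for a set
#' of structures, so the tier-difference identity
#' `E_QM/QM/MM - E_QM/MM = dE_ML + sum_m n_m shift_m` can be audited row by
#' row.  Use [utils::write.csv()] or [jsonlite::write_json()] to export.
#'
#' @param e_ml,delta_e_ml,e_mm,e_lj_int,pair_sum numeric vectors (kJ/mol).
#' @param stoichiometry matrix (structures x elements) of atom counts.
#' @param atomic_reference named vector of atomic reference energies.
#' @param shifts a [fit_shifts()] table or named vector.
#' @return data frame with one row per structure, including both totals and
#'   the tier difference.
#' @export
energy_breakdown <- function(e_ml, delta_e_ml, e_mm, e_lj_int, pair_sum,
                             stoichiometry, atomic_reference, shifts) {
  if (inherits(shifts, "shift_table")) shifts <- shifts$shifts
  N <- as.matrix(stoichiometry)
  n <- length(e_ml)
  atom_sum <- drop(N %*% atomic_reference[colnames(N)])
  shift_sum <- drop(N %*% shifts[colnames(N)])
  e_qmmm <- e_ml + e_mm + e_lj_int + pair_sum + atom_sum
  e_qmqmmm <- e_qmmm + delta_e_ml + shift_sum
  data.frame(e_ml = e_ml, delta_e_ml = delta_e_ml, e_mm = e_mm,
             e_lj_int = e_lj_int, pair_sum = pair_sum,
             atomic_sum = atom_sum, shift_sum = shift_sum,
             e_qmmm = e_qmmm, e_qmqmmm = e_qmqmmm,
             tier_difference = e_qmqmmm - e_qmmm)
}
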