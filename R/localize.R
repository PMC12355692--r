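#' Mulliken population of an orbital on a group of atoms
#'
#' Gross Mulliken population `sum_{mu in group} c_mu (S c)_mu` of a single
#' normalized orbital on the basis functions belonging to a set of atoms.
#' Populations over all atoms sum to one for a normalized orbital.
#'
#' @param orbital numeric coefficient vector, normalized so `c' S c = 1`.
#' @param atom_group integer vector of atom indices.
#' @param system a [model_system()].
#' @return scalar population fraction.
#' @export
mulliken_population <- function(orbital, atom_group, system) {
  S <- system$overlap
  nrm <- as.numeric(t(orbital) %*% S %*% orbital)
  if (abs(nrm - 1) > 1e-8)
    stop("orbital is not normalized: c'Sc = ", format(nrm))
  mask <- system$atom_group_of_basis %in% atom_group
  sum((orbital * as.numeric(S %*% orbital))[mask])
}

# per-atom gross populations for every column of c (no normalization check)
mulliken_per_atom <- function(c_occ, system) {
  S <- system$overlap
  SC <- S %*% c_occ
  gp <- c_occ * SC                         # basis x orbital
  n_atoms <- length(system$atom_labels)
  out <- matrix(0, n_atoms, ncol(c_occ))
  for (a in seq_len(n_atoms))
    out[a, ] <- colSums(gp[system$atom_group_of_basis == a, , drop = FALSE])
  out
}

pm_metric <- function(c_occ, system) sum(mulliken_per_atom(c_occ, system)^2)

#' Localize the occupied orbitals (Pipek-Mezey)
#'
#' Jacobi-sweep maximization of the Pipek-Mezey localization metric (the sum
#' of squared Mulliken atomic populations) over rotations within the occupied
#' space.  The occupied span, the density and the total mean-field energy are
#' invariant under such rotations.  Columns are ordered by the atom carrying
#' their largest population, and the sign of each column is fixed so its
#' largest-magnitude coefficient is positive.
#'
#' @param orbitals an `scf_result` or an occupied coefficient matrix.
#' @param system a [model_system()].
#' @param tol convergence threshold on the metric gain per sweep.
#' @param max_sweeps maximum number of Jacobi sweeps.
#' @return localized occupied coefficient matrix.
#' @export
localize_occupied <- function(orbitals, system, tol = 1e-10,
                              max_sweeps = 200) {
  C <- if (inherits(orbitals, "scf_result")) orbitals$c_occ
       else as.matrix(orbitals)
  n <- ncol(C)
  if (n <= 1L) return(fix_columns(C, system))
  S <- system$overlap
  n_atoms <- length(system$atom_labels)
  basis_of_atom <- lapply(seq_len(n_atoms),
                          function(a) which(system$atom_group_of_basis == a))
  metric0 <- pm_metric(C, system)
  metric_old <- metric0
  for (sweep in seq_len(max_sweeps)) {
    for (s in seq_len(n - 1)) for (t in seq(s + 1, n)) {
      SCs <- as.numeric(S %*% C[, s]); SCt <- as.numeric(S %*% C[, t])
      Ast <- 0; Bst <- 0
      for (a in seq_len(n_atoms)) {
        idx <- basis_of_atom[[a]]
        Qss <- sum(C[idx, s] * SCs[idx])
        Qtt <- sum(C[idx, t] * SCt[idx])
        Qst <- 0.5 * (sum(C[idx, s] * SCt[idx]) + sum(C[idx, t] * SCs[idx]))
        Ast <- Ast + Qst^2 - 0.25 * (Qss - Qtt)^2
        Bst <- Bst + Qst * (Qss - Qtt)
      }
      if (abs(Ast) < 1e-14 && abs(Bst) < 1e-14) next
      gamma <- 0.25 * atan2(Bst, -Ast)
      if (abs(gamma) < 1e-12) next
      cs <- cos(gamma); sn <- sin(gamma)
      new_s <- cs * C[, s] + sn * C[, t]
      new_t <- -sn * C[, s] + cs * C[, t]
      C[, s] <- new_s; C[, t] <- new_t
    }
    metric_new <- pm_metric(C, system)
    if (metric_new - metric_old < tol) break
    metric_old <- metric_new
  }
  if (pm_metric(C, system) < metric0 - 1e-8)
    stop("localization decreased the metric; rotation left the occupied space")
  fix_columns(C, system)
}

# deterministic column order (descending leading population, then atom index)
# and sign convention (largest-magnitude coefficient positive)
fix_columns <- function(C, system) {
  if (ncol(C) == 0L) return(C)
  pops <- mulliken_per_atom(C, system)
  lead_atom <- apply(pops, 2, which.max)
  lead_pop <- apply(pops, 2, max)
  ord <- order(lead_atom, -lead_pop)
  C <- C[, ord, drop = FALSE]
  for (j in seq_len(ncol(C))) {
    k <- which.max(abs(C[, j]))
    if (C[k, j] < 0) C[, j] <- -C[, j]
  }
  C
}
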