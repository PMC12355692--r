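#' Partition localized occupied orbitals into quantum cores and environment
#'
#' Applies the two-step assignment rule: an occupied orbital is assigned to
#' the low-level environment set (`"LL"`) if its Mulliken population on the
#' environment atoms (all atoms outside every quantum core) strictly exceeds
#' `env_threshold`; otherwise it is assigned to the quantum core on which it
#' has the largest population, with exact ties broken toward the
#' lowest-index core.
#'
#' @param localized localized occupied coefficient matrix (see
#'   [localize_occupied()]).
#' @param system a [model_system()].
#' @param core_atom_groups list of pairwise-disjoint integer vectors of atom
#'   indices, one per quantum core.
#' @param env_threshold environment-population threshold (default 0.4).
#' @param c_virt shared virtual coefficient matrix (from [run_scf()]).
#' @param epsilon_shift positive level shift of the projector, hartree
#'   (default 1.0).
#' @return an object of class `orbital_set_partition` with elements `c_occ`,
#'   `c_virt`, `assignment` (character vector: `"1"`, `"2"`, ... or `"LL"`),
#'   `core_atom_groups` and `epsilon_shift`.
#' @export
partition_orbitals <- function(localized, system, core_atom_groups,
                               env_threshold = 0.4, c_virt = NULL,
                               epsilon_shift = 1.0) {
  C <- as.matrix(localized)
  K <- length(core_atom_groups)
  if (K == 0) stop("at least one quantum core group is required")
  for (g in core_atom_groups)
    if (length(g) == 0) stop("empty core atom group")
  all_core <- unlist(core_atom_groups)
  if (anyDuplicated(all_core))
    stop("core atom groups must be pairwise disjoint")
  n_atoms <- length(system$atom_labels)
  env_atoms <- setdiff(seq_len(n_atoms), all_core)
  pops <- mulliken_per_atom(C, system)
  assignment <- character(ncol(C))
  for (i in seq_len(ncol(C))) {
    env_pop <- sum(pops[env_atoms, i])
    if (env_pop > env_threshold) {
      assignment[i] <- "LL"
    } else {
      core_pop <- vapply(core_atom_groups,
                         function(g) sum(pops[g, i]), numeric(1))
      assignment[i] <- as.character(which(core_pop == max(core_pop))[1L])
    }
  }
  obj <- list(c_occ = C, c_virt = c_virt, assignment = assignment,
              core_atom_groups = core_atom_groups,
              epsilon_shift = epsilon_shift)
  class(obj) <- "orbital_set_partition"
  obj
}

#' @export
print.orbital_set_partition <- function(x, ...) {
  tab <- table(x$assignment)
  cat("orbital_set_partition:", ncol(x$c_occ), "occupied orbitals ->",
      paste(sprintf("%s:%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n  eps_shift =", x$epsilon_shift, "hartree\n")
  invisible(x)
}

# AO density matrix (factor 2 for closed shell) of the orbitals in one set
set_density <- function(partition, label) {
  idx <- which(partition$assignment == label)
  nb <- nrow(partition$c_occ)
  if (length(idx) == 0) return(matrix(0, nb, nb))
  2 * tcrossprod(partition$c_occ[, idx, drop = FALSE])
}

partition_labels <- function(partition)
  unique(c(setdiff(unique(partition$assignment), "LL"), "LL"))

check_orthonormal <- function(partition, system, tol = 1e-8) {
  C <- cbind(partition$c_occ, partition$c_virt)
  dev <- max(abs(t(C) %*% system$overlap %*% C - diag(ncol(C))))
  if (dev > tol)
    stop("orbitals are not orthonormal (max deviation ", format(dev), ")")
  invisible(dev)
}
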