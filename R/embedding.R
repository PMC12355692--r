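#' Build the embedded one-electron Hamiltonian of a quantum core
#'
#' Assembles `h_eff = h_core + v_xc_nadd + v_C + p` for one quantum core:
#' the nonadditive exchange-correlation potential (difference of the XC
#' potential at the total and at the core density), the mean-field potential
#' of all electrons outside the core, and the level-shifted projector
#' enforcing orthogonality against every other occupied orbital set,
#' `p = -[P (f - eps) + (f - eps) P]` with `P` the occupied projector of the
#' other sets and `f` the embedded Fock operator of the core.
#'
#' @param system a [model_system()].
#' @param partition an [partition_orbitals()] result.
#' @param core_index integer index of the quantum core.
#' @param xc an [xc_model()].
#' @return an object of class `embedded_hamiltonian` with elements `h_eff`,
#'   `f_embedded`, `core_occ_indices`, `densities` (list with `core`,
#'   `other`, `ll`, `tot`), `core_index` and `epsilon_shift`.
#' @export
build_core_hamiltonian <- function(system, partition, core_index,
                                   xc = xc_model("hf")) {
  label <- as.character(core_index)
  idx <- which(partition$assignment == label)
  if (length(idx) == 0)
    stop("quantum core ", label, " has no occupied orbitals")
  S <- system$overlap
  D_I <- set_density(partition, label)
  D_tot <- 2 * tcrossprod(partition$c_occ)
  D_other <- D_tot - D_I
  D_LL <- set_density(partition, "LL")

  v_nadd <- xc_potential(xc, D_tot) - xc_potential(xc, D_I)
  v_C <- mean_field_operator(system, xc, D_other)
  f_HF <- system$h_core + coulomb_matrix(system$g_eri, D_I) -
    0.5 * exchange_matrix(system$g_eri, D_I)
  f_emb <- f_HF + v_nadd + v_C
  eps <- partition$epsilon_shift
  M <- S %*% (D_other / 2)                       # AO matrix of the projector
  fs <- f_emb - eps * S
  p <- -(M %*% fs + fs %*% t(M))
  p <- (p + t(p)) / 2
  h_eff <- system$h_core + v_nadd + v_C + p

  obj <- list(h_eff = h_eff, f_embedded = f_emb, projector = p,
              v_xc_nadd = v_nadd, v_coulomb = v_C,
              core_occ_indices = idx,
              densities = list(core = D_I, other = D_other,
                               ll = D_LL, tot = D_tot),
              core_index = core_index, epsilon_shift = eps)
  class(obj) <- "embedded_hamiltonian"
  obj
}

#' Energy of a quantum core
#'
#' Expectation value of the embedded core Hamiltonian (modified one-electron
#' part plus the bare two-electron interaction among the core electrons).
#' `solver = "determinant"` evaluates the single-determinant expectation over
#' the core's occupied orbitals without re-optimization; `solver = "fci"`
#' diagonalizes the full CI Hamiltonian in the space spanned by the core's
#' occupied orbitals plus the shared virtual space, and is therefore always
#' at or below the determinant energy.
#'
#' @param embedded an [build_core_hamiltonian()] result.
#' @param system a [model_system()].
#' @param partition the matching `orbital_set_partition`.
#' @param solver `"determinant"` or `"fci"`.
#' @param fci_orbital_cap maximum number of spatial orbitals in the FCI
#'   space; above the cap an error advises virtual truncation.
#' @param n_virt number of virtual orbitals to keep (default: all).
#' @return scalar core energy (hartree).
#' @export
core_energy <- function(embedded, system, partition,
                        solver = c("determinant", "fci"),
                        fci_orbital_cap = 12, n_virt = NULL) {
  solver <- match.arg(solver)
  D_I <- embedded$densities$core
  if (solver == "determinant") {
    e1 <- sum(D_I * embedded$h_eff)
    e2 <- 0.5 * sum(D_I * coulomb_matrix(system$g_eri, D_I)) -
      0.25 * sum(D_I * exchange_matrix(system$g_eri, D_I))
    return(e1 + e2)
  }
  C_core <- partition$c_occ[, embedded$core_occ_indices, drop = FALSE]
  C_virt <- partition$c_virt
  if (is.null(C_virt))
    stop("fci solver requires the shared virtual space in the partition")
  if (!is.null(n_virt))
    C_virt <- C_virt[, seq_len(min(n_virt, ncol(C_virt))), drop = FALSE]
  C_space <- cbind(C_core, C_virt)
  n_orb <- ncol(C_space)
  if (n_orb > fci_orbital_cap)
    stop("FCI space has ", n_orb, " orbitals, above the cap of ",
         fci_orbital_cap, "; truncate the virtual space via n_virt")
  h_mo <- t(C_space) %*% embedded$h_eff %*% C_space
  g_mo <- transform_eri(system$g_eri, C_space)
  n_el <- 2L * length(embedded$core_occ_indices)
  fci_ground_state(h_mo, g_mo, n_el)$energy
}

# 4-index transform of (pq|rs) into the column space of C
transform_eri <- function(g, C) {
  nb <- dim(g)[1]; m <- ncol(C)
  t1 <- array(t(C) %*% matrix(g, nb, nb^3), c(m, nb, nb, nb))
  t2 <- aperm(t1, c(2, 1, 3, 4))
  t2 <- array(t(C) %*% matrix(t2, nb, m * nb * nb), c(m, m, nb, nb))
  t3 <- aperm(t2, c(3, 1, 2, 4))
  t3 <- array(t(C) %*% matrix(t3, nb, m * m * nb), c(m, m, m, nb))
  t4 <- aperm(t3, c(4, 2, 3, 1))
  t4 <- array(t(C) %*% matrix(t4, nb, m^3), c(m, m, m, m))
  aperm(t4, c(2, 3, 4, 1))
}

#' Kohn-Sham energy of the low-level orbital set
#'
#' One-electron terms plus the intra-set mean-field two-electron energy and
#' the XC energy of the LL density.  Excludes nuclear repulsion (added once
#' when the total is assembled).  Returns 0 when no orbital is labeled
#' `"LL"`.
#'
#' @inheritParams build_core_hamiltonian
#' @return scalar energy (hartree).
#' @export
ll_energy <- function(system, partition, xc = xc_model("hf")) {
  D <- set_density(partition, "LL")
  if (max(abs(D)) == 0) return(0)
  scf_energy_of_density(system, xc, D) - system$e_nuclear
}

#' Rest-energy correction of the multi-orbital-set decomposition
#'
#' Collects the remaining contributions: the nonadditive XC energy
#' (`E_xc[rho_tot] - sum_A E_xc[rho_A]` over all orbital sets), minus the
#' expectation values of the nonadditive XC potentials already contained in
#' the embedded core Hamiltonians (evaluated with the mean-field densities),
#' minus the inter-core mean-field interaction counted twice through `v_C`.
#' In hf mode the first three groups vanish identically and the inter-core
#' term carries Coulomb plus exact exchange.
#'
#' @inheritParams build_core_hamiltonian
#' @return scalar with attribute `"breakdown"` itemizing the four terms.
#' @export
rest_energy <- function(system, partition, xc = xc_model("hf")) {
  labels <- partition_labels(partition)
  present <- labels[vapply(labels, function(l)
    any(partition$assignment == l), logical(1))]
  cores <- setdiff(present, "LL")
  D_tot <- 2 * tcrossprod(partition$c_occ)
  dens <- lapply(present, function(l) set_density(partition, l))
  names(dens) <- present

  e_xc_tot <- xc_energy(xc, D_tot)
  e_xc_sets <- sum(vapply(dens, function(D) xc_energy(xc, D), numeric(1)))
  e_nadd_expect <- 0
  for (l in cores) {
    v_nadd <- xc_potential(xc, D_tot) - xc_potential(xc, dens[[l]])
    e_nadd_expect <- e_nadd_expect + sum(dens[[l]] * v_nadd)
  }
  e_intercore <- 0
  if (length(cores) >= 2) {
    for (i in seq_len(length(cores) - 1)) for (j in seq(i + 1, length(cores)))
      e_intercore <- e_intercore +
        mean_field_interaction(system, xc, dens[[cores[i]]], dens[[cores[j]]])
  }
  out <- e_xc_tot - e_xc_sets - e_nadd_expect - e_intercore
  attr(out, "breakdown") <- list(
    e_xc_total = e_xc_tot, e_xc_sets = e_xc_sets,
    e_nadd_expectation = e_nadd_expect, e_intercore = e_intercore)
  out
}

#' Assemble the full multilevel embedding energy
#'
#' Runs every quantum core through [build_core_hamiltonian()] and
#' [core_energy()], adds the LL energy, the rest correction and the nuclear
#' repulsion to form the QM energy, and adds the supplied MM terms to form
#' the QM/QM/MM total.  Cores with no occupied orbitals contribute nothing.
#'
#' @inheritParams core_energy
#' @param xc an [xc_model()].
#' @param mm_terms list with scalars `e_mm`, `e_elec_int`, `e_lj_int`
#'   (kept in the same unit as the electronic terms; zero for pure-QM use).
#' @return an object of class `embedding_energies` with elements `e_core`
#'   (named vector), `e_ll`, `e_rest` (with breakdown attribute),
#'   `e_nuclear`, `e_qm`, `mm_terms` and `e_total`.
#' @export
embedding_total <- function(system, partition, xc = xc_model("hf"),
                            solver = c("determinant", "fci"),
                            mm_terms = list(e_mm = 0, e_elec_int = 0,
                                            e_lj_int = 0),
                            fci_orbital_cap = 12, n_virt = NULL) {
  solver <- match.arg(solver)
  check_orthonormal(partition, system)
  cores <- setdiff(partition_labels(partition), "LL")
  cores <- cores[vapply(cores, function(l)
    any(partition$assignment == l), logical(1))]
  e_core <- numeric(0)
  for (l in cores) {
    emb <- build_core_hamiltonian(system, partition, as.integer(l), xc)
    e_core[l] <- core_energy(emb, system, partition, solver,
                             fci_orbital_cap, n_virt)
  }
  e_ll <- ll_energy(system, partition, xc)
  e_rest <- rest_energy(system, partition, xc)
  e_qm <- sum(e_core) + e_ll + as.numeric(e_rest) + system$e_nuclear
  e_total <- e_qm + mm_terms$e_mm + mm_terms$e_elec_int + mm_terms$e_lj_int
  obj <- list(e_core = e_core, e_ll = e_ll, e_rest = e_rest,
              e_nuclear = system$e_nuclear, e_qm = e_qm,
              mm_terms = mm_terms, e_total = e_total, solver = solver,
              xc = xc$name)
  class(obj) <- "embedding_energies"
  obj
}

#' @export
print.embedding_energies <- function(x, ...) {
  cat("embedding_energies (xc =", x$xc, ", solver =", x$solver, ")\n")
  for (l in names(x$e_core))
    cat(sprintf("  E_QC[%s]   = %18.12f\n", l, x$e_core[[l]]))
  cat(sprintf("  E_LL      = %18.12f\n", x$e_ll))
  cat(sprintf("  E_rest    = %18.12f\n", as.numeric(x$e_rest)))
  cat(sprintf("  E_nuclear = %18.12f\n", x$e_nuclear))
  cat(sprintf("  E_QM      = %18.12f\n", x$e_qm))
  cat(sprintf("  E_total   = %18.12f\n", x$e_total))
  invisible(x)
}

#' Write an itemized JSON energy report
#'
#' @param energies an [embedding_total()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_embedding_report <- function(energies, path) {
  rb <- attr(energies$e_rest, "breakdown")
  payload <- list(
    xc = energies$xc, solver = energies$solver,
    e_core = as.list(energies$e_core), e_ll = energies$e_ll,
    e_rest = as.numeric(energies$e_rest), e_rest_breakdown = rb,
    e_nuclear = energies$e_nuclear, e_qm = energies$e_qm,
    mm_terms = energies$mm_terms, e_total = energies$e_total)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
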