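#' @keywords internal
coulomb_matrix <- function(g_eri, D) {
  nb <- nrow(D)
  matrix(matrix(g_eri, nb * nb, nb * nb) %*% as.numeric(D), nb, nb)
}

#' @keywords internal
exchange_matrix <- function(g_eri, D) {
  nb <- nrow(D)
  gk <- aperm(g_eri, c(1, 3, 2, 4))  # K_pq = sum_rs D_rs (pr|qs)
  matrix(matrix(gk, nb * nb, nb * nb) %*% as.numeric(D), nb, nb)
}

# Mean-field two-electron operator acting on a density: J[D] in toy-local
# mode, J[D] - K[D]/2 in hf mode (exact exchange carried here, not in E_xc).
mean_field_operator <- function(system, xc, D) {
  V <- coulomb_matrix(system$g_eri, D)
  if (xc$name == "hf") V <- V - 0.5 * exchange_matrix(system$g_eri, D)
  V
}

# Two-electron interaction energy of density A in the mean field of density B:
# tr(D_A (J[D_B] - K[D_B]/2)) at hf, tr(D_A J[D_B]) otherwise.
mean_field_interaction <- function(system, xc, D_A, D_B) {
  sum(D_A * mean_field_operator(system, xc, D_B))
}

scf_energy_of_density <- function(system, xc, D) {
  e1 <- sum(D * system$h_core)
  eJ <- 0.5 * sum(D * coulomb_matrix(system$g_eri, D))
  eX <- if (xc$name == "hf")
    -0.25 * sum(D * exchange_matrix(system$g_eri, D)) else xc_energy(xc, D)
  e1 + eJ + eX + system$e_nuclear
}

#' Converge the mean-field reference for a model system
#'
#' Restricted closed-shell self-consistent field with DIIS acceleration.  In
#' `"hf"` mode this is Hartree-Fock; in `"toy-local"` mode it is a Kohn-Sham
#' style calculation with the grid-free local functional of [xc_model()].
#' The converged occupied and virtual orbitals are the starting point for
#' orbital localization, partitioning and projection-based embedding.
#'
#' @param system a [model_system()].
#' @param xc an [xc_model()].
#' @param tol convergence threshold on the energy change (hartree).
#' @param max_iter maximum number of SCF iterations.
#' @param diis logical, use DIIS extrapolation of the Fock matrix.
#' @param level_shifts numeric vector of virtual-orbital level shifts
#'   (hartree) tried in order until the SCF converges; a shift moves the
#'   unoccupied orbitals up during the iterations without changing the
#'   converged stationary point.
#' @return an object of class `scf_result` with elements `energy` (hartree,
#'   includes nuclear repulsion), `c_occ`, `c_virt`, `orbital_energies`,
#'   `density` (AO density matrix, traces to n_electrons with the overlap),
#'   `n_occ`, `n_iter` and `energy_change`.
#' @export
run_scf <- function(system, xc = xc_model("hf"), tol = 1e-10,
                    max_iter = 200, diis = TRUE,
                    level_shifts = c(0, 0.5, 2)) {
  last_err <- NULL
  for (mu in level_shifts) {
    res <- tryCatch(
      run_scf_once(system, xc, tol, max_iter, diis, mu),
      error = function(e) e)
    if (!inherits(res, "error")) return(res)
    last_err <- res
  }
  # fixed-point iteration failed: minimize the energy directly over
  # occupied-virtual orbital rotations (always a valid determinant)
  res <- tryCatch(scf_direct_min(system, xc, tol), error = function(e) e)
  if (!inherits(res, "error")) return(res)
  stop(conditionMessage(last_err))
}

# orthogonal rotation exp(K) of an antisymmetric matrix via its normal form
expm_antisym <- function(K) {
  # scaling-and-squaring series (robust for these small matrices)
  n <- nrow(K)
  A <- K; s <- max(abs(A))
  j <- max(0L, ceiling(log2(max(s, 1e-300))) + 2L)
  A <- A / 2^j
  Q <- diag(n); term <- diag(n)
  for (k in 1:20) {
    term <- term %*% A / k
    Q <- Q + term
    if (max(abs(term)) < 1e-17) break
  }
  for (k in seq_len(j)) Q <- Q %*% Q
  Q
}

scf_direct_min <- function(system, xc, tol) {
  S <- system$overlap; h <- system$h_core
  nb <- nrow(h)
  n_occ <- system$n_electrons / 2L
  n_virt <- nb - n_occ
  es <- eigen(S, symmetric = TRUE)
  X <- es$vectors %*% diag(1 / sqrt(es$values), nb) %*% t(es$vectors)
  Fo <- t(X) %*% h %*% X
  eo <- eigen((Fo + t(Fo)) / 2, symmetric = TRUE)
  C <- X %*% eo$vectors[, rev(seq_len(nb)), drop = FALSE]
  energy_of_C <- function(C) {
    D <- 2 * tcrossprod(C[, seq_len(n_occ), drop = FALSE])
    scf_energy_of_density(system, xc, D)
  }
  if (n_occ == 0 || n_virt == 0) {
    return(scf_finalize(system, xc, C, n_occ, 0, 0))
  }
  rotate <- function(C, k) {
    K <- matrix(0, nb, nb)
    K[seq_len(n_occ), n_occ + seq_len(n_virt)] <- k
    K <- K - t(K)
    C %*% expm_antisym(K)
  }
  e_prev <- energy_of_C(C)
  for (outer in 1:60) {
    obj <- function(k) energy_of_C(rotate(C, matrix(k, n_occ, n_virt)))
    opt <- stats::optim(rep(0, n_occ * n_virt), obj, method = "BFGS",
                        control = list(reltol = 1e-16, maxit = 500))
    C <- rotate(C, matrix(opt$par, n_occ, n_virt))
    # re-orthonormalize against drift
    M <- t(C) %*% S %*% C
    C <- C %*% solve(chol(M))
    e_new <- energy_of_C(C)
    if (e_prev - e_new < tol) break
    e_prev <- e_new
  }
  scf_finalize(system, xc, C, n_occ, outer, e_new - e_prev)
}

# semicanonicalize (diagonalize F within the occupied and virtual blocks,
# leaving the determinant untouched) and package the result
scf_finalize <- function(system, xc, C, n_occ, n_iter, de) {
  nb <- ncol(C)
  D <- if (n_occ > 0)
    2 * tcrossprod(C[, seq_len(n_occ), drop = FALSE]) else matrix(0, nb, nb)
  F <- system$h_core + mean_field_operator(system, xc, D) +
    xc_potential(xc, D)
  Fmo <- t(C) %*% F %*% C
  eps <- numeric(nb)
  occ <- seq_len(n_occ); virt <- setdiff(seq_len(nb), occ)
  for (blk in list(occ, virt)) {
    if (length(blk) == 0) next
    eb <- eigen((Fmo[blk, blk] + t(Fmo[blk, blk])) / 2, symmetric = TRUE)
    ord <- rev(seq_along(blk))
    C[, blk] <- C[, blk, drop = FALSE] %*% eb$vectors[, ord, drop = FALSE]
    eps[blk] <- rev(eb$values)
  }
  D <- if (n_occ > 0)
    2 * tcrossprod(C[, occ, drop = FALSE]) else matrix(0, nb, nb)
  res <- list(energy = scf_energy_of_density(system, xc, D),
              c_occ = C[, occ, drop = FALSE],
              c_virt = C[, virt, drop = FALSE],
              orbital_energies = eps, density = D,
              n_occ = n_occ, n_iter = n_iter, energy_change = de)
  class(res) <- "scf_result"
  res
}

run_scf_once <- function(system, xc, tol, max_iter, diis, level_shift) {
  stopifnot(inherits(system, "model_system"), inherits(xc, "xc_model"))
  S <- system$overlap
  h <- system$h_core
  nb <- nrow(h)
  n_occ <- system$n_electrons / 2L
  es <- eigen(S, symmetric = TRUE)
  X <- es$vectors %*% diag(1 / sqrt(es$values), nb) %*% t(es$vectors)

  solve_fock <- function(F) {
    Fo <- t(X) %*% F %*% X
    eo <- eigen((Fo + t(Fo)) / 2, symmetric = TRUE)
    C <- X %*% eo$vectors[, rev(seq_len(nb)), drop = FALSE]
    eps <- rev(eo$values)
    list(C = C, eps = eps)
  }

  density_of <- function(C) {
    if (n_occ > 0) 2 * tcrossprod(C[, seq_len(n_occ), drop = FALSE])
    else matrix(0, nb, nb)
  }
  energy_of <- function(D) scf_energy_of_density(system, xc, D)

  # core guess
  sol <- solve_fock(h)
  C <- sol$C
  D <- density_of(C)
  e_old <- energy_of(D)
  fock_hist <- list(); err_hist <- list()
  de <- Inf

  shifted <- function(F, D) {
    if (level_shift == 0) F
    else F + level_shift * (S - S %*% (D / 2) %*% S)
  }

  for (it in seq_len(max_iter)) {
    F <- h + mean_field_operator(system, xc, D) + xc_potential(xc, D)
    err <- t(X) %*% (F %*% D %*% S - S %*% D %*% F) %*% X
    max_err <- max(abs(err))
    use_diis <- diis && max_err < 5e-2
    if (use_diis) {
      fock_hist[[length(fock_hist) + 1L]] <- F
      err_hist[[length(err_hist) + 1L]] <- err
      if (length(fock_hist) > 8) {
        fock_hist <- fock_hist[-1]; err_hist <- err_hist[-1]
      }
      m <- length(fock_hist)
      if (m >= 2) {
        B <- matrix(0, m + 1, m + 1)
        for (i in seq_len(m)) for (j in seq_len(m))
          B[i, j] <- sum(err_hist[[i]] * err_hist[[j]])
        sc <- max(abs(B[seq_len(m), seq_len(m)]), 1e-300)
        B[seq_len(m), seq_len(m)] <- B[seq_len(m), seq_len(m)] / sc
        B[m + 1, seq_len(m)] <- -1; B[seq_len(m), m + 1] <- -1
        rhs <- c(rep(0, m), -1)
        sv <- svd(B)
        keep <- sv$d > 1e-12 * max(sv$d)
        co <- (sv$v[, keep, drop = FALSE] %*%
               (crossprod(sv$u[, keep, drop = FALSE], rhs) /
                sv$d[keep]))[seq_len(m)]
        F <- Reduce(`+`, Map(function(f, w) w * f, fock_hist, co))
      }
      sol <- solve_fock(shifted(F, D))
      C <- sol$C
      D <- density_of(C)
    } else {
      # optimal-damping step: line search on D(lambda) = D + lambda (D_cand - D);
      # the energy is exactly quadratic in lambda for hf, so fit through three
      # points and take the minimizer (fall back to the best sampled point)
      fock_hist <- list(); err_hist <- list()
      sol <- solve_fock(shifted(F, D))
      D_cand <- density_of(sol$C)
      e0 <- e_old
      e_half <- energy_of(D + 0.5 * (D_cand - D))
      e1 <- energy_of(D_cand)
      b2 <- 2 * (e1 - 2 * e_half + e0)
      a1 <- e1 - e0 - b2 / 2
      lam <- if (b2 > 1e-14) max(min(-a1 / b2, 1), 0.05) else 1
      cand <- c(lam, 0.5, 1)
      evals <- c(energy_of(D + lam * (D_cand - D)), e_half, e1)
      lam <- cand[which.min(evals)]
      D <- D + lam * (D_cand - D)
      C <- sol$C
    }
    e_new <- energy_of(D)
    de <- e_new - e_old
    e_old <- e_new
    if (abs(de) < tol && max_err < 1e-6 && it >= 2) {
      # final canonical orbitals from the unshifted Fock operator
      D_final <- density_of(C)
      F_final <- h + mean_field_operator(system, xc, D_final) +
        xc_potential(xc, D_final)
      sol <- solve_fock(F_final)
      C <- sol$C
      D_final <- density_of(C)
      res <- list(energy = energy_of(D_final),
                  c_occ = C[, seq_len(n_occ), drop = FALSE],
                  c_virt = C[, setdiff(seq_len(nb), seq_len(n_occ)),
                             drop = FALSE],
                  orbital_energies = sol$eps, density = D_final,
                  n_occ = n_occ, n_iter = it, energy_change = de)
      class(res) <- "scf_result"
      return(res)
    }
  }
  stop("SCF did not converge in ", max_iter,
       " iterations; last energy change ", format(de), " hartree")
}

#' @export
print.scf_result <- function(x, ...) {
  cat("scf_result: E =", format(x$energy, digits = 12), "hartree (",
      x$n_iter, "iterations, dE =", format(x$energy_change), ")\n")
  invisible(x)
}
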