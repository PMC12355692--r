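# Independent oracles and shared fixtures for the test suite.

# --- brute-force Roothaan SCF oracle (plain fixed-point with damping),
#     written directly against the Roothaan equations, independent of the
#     package's solver internals
oracle_rhf <- function(h, g, S, n_el, e_nuc = 0, iter = 500, damp = 0.3) {
  nb <- nrow(h)
  n_occ <- n_el / 2
  es <- eigen(S, symmetric = TRUE)
  X <- es$vectors %*% diag(1 / sqrt(es$values), nb) %*% t(es$vectors)
  D <- matrix(0, nb, nb)
  for (it in seq_len(iter)) {
    J <- matrix(0, nb, nb); K <- matrix(0, nb, nb)
    for (p in 1:nb) for (q in 1:nb) for (r in 1:nb) for (s in 1:nb) {
      J[p, q] <- J[p, q] + D[r, s] * g[p, q, r, s]
      K[p, q] <- K[p, q] + D[r, s] * g[p, r, q, s]
    }
    F <- h + J - 0.5 * K
    Fo <- t(X) %*% F %*% X
    eo <- eigen((Fo + t(Fo)) / 2, symmetric = TRUE)
    C <- X %*% eo$vectors[, order(eo$values), drop = FALSE]
    Dn <- 2 * tcrossprod(C[, seq_len(n_occ), drop = FALSE])
    D <- damp * D + (1 - damp) * Dn
  }
  J <- matrix(0, nb, nb); K <- matrix(0, nb, nb)
  for (p in 1:nb) for (q in 1:nb) for (r in 1:nb) for (s in 1:nb) {
    J[p, q] <- J[p, q] + D[r, s] * g[p, q, r, s]
    K[p, q] <- K[p, q] + D[r, s] * g[p, r, q, s]
  }
  sum(D * h) + 0.5 * sum(D * J) - 0.25 * sum(D * K) + e_nuc
}

# --- explicit two-electron contraction by quadruple loop (tensor oracle)
oracle_coulomb <- function(g, D) {
  nb <- nrow(D)
  J <- matrix(0, nb, nb)
  for (p in 1:nb) for (q in 1:nb) for (r in 1:nb) for (s in 1:nb)
    J[p, q] <- J[p, q] + D[r, s] * g[p, q, r, s]
  J
}
oracle_exchange <- function(g, D) {
  nb <- nrow(D)
  K <- matrix(0, nb, nb)
  for (p in 1:nb) for (q in 1:nb) for (r in 1:nb) for (s in 1:nb)
    K[p, q] <- K[p, q] + D[r, s] * g[p, r, q, s]
  K
}

# --- hand-built symmetric 2-atom, 2-basis model (homo-diatomic analogue);
#     the MO cross integrals vanish by parity so the closed-shell doubles
#     CI matrix is exactly 2x2
symmetric_diatomic <- function(onsite = -1.1, hop = -0.45, s = 0.2,
                               u = 0.5) {
  h <- matrix(c(onsite, hop, hop, onsite), 2, 2)
  S <- matrix(c(1, s, s, 1), 2, 2)
  # separable symmetric two-electron tensor (pq|rs) = sum_k L^k_pq L^k_rs
  L1 <- matrix(c(1, 0.3, 0.3, 0.2), 2, 2)
  L2 <- L1[2:1, 2:1]
  g <- u * (array(outer(as.numeric(L1), as.numeric(L1)), rep(2, 4)) +
            array(outer(as.numeric(L2), as.numeric(L2)), rep(2, 4)))
  model_system(atom_labels = c("X", "X"), atom_group_of_basis = 1:2,
               n_electrons = 2, h_core = h, g_eri = g, overlap = S,
               e_nuclear = 0.5)
}

# --- cached small systems with converged SCF and localized orbitals
.cache <- new.env(parent = emptyenv())
embed_fixture <- function(seed, n_atoms = 4, basis_per_atom = 1,
                          n_electrons = 4, xc_name = "hf") {
  key <- paste(seed, n_atoms, basis_per_atom, n_electrons, xc_name,
               sep = "_")
  if (!is.null(.cache[[key]])) return(.cache[[key]])
  sys <- gen_model_system(n_atoms = n_atoms, basis_per_atom = basis_per_atom,
                          n_electrons = n_electrons, seed = seed)
  xc <- if (xc_name == "hf") xc_model("hf") else
    xc_model("toy-local", strength = 0.1)
  scf <- run_scf(sys, xc)
  loc <- localize_occupied(scf, sys)
  out <- list(sys = sys, xc = xc, scf = scf, loc = loc)
  .cache[[key]] <- out
  out
}

# enumerate all single-core and two-core atom groupings of n atoms
enumerate_core_groups <- function(n_atoms) {
  atoms <- seq_len(n_atoms)
  subsets <- unlist(lapply(seq_len(n_atoms - 1), function(k)
    utils::combn(atoms, k, simplify = FALSE)), recursive = FALSE)
  parts <- lapply(subsets, function(s) list(s))
  for (i in seq_along(subsets)) for (j in seq_along(subsets)) {
    if (i < j && !length(intersect(subsets[[i]], subsets[[j]])))
      parts[[length(parts) + 1L]] <- list(subsets[[i]], subsets[[j]])
  }
  parts
}

# --- small labeled conformer set, shared across MLP tests
mlp_fixture <- function() {
  if (!is.null(.cache$mlp)) return(.cache$mlp)
  cfg <- toy_pes_config()
  set <- gen_conformers(cfg, 80, seed = 11)
  dcfg <- descriptor_config()
  ens <- train_base(set, dcfg, n_members = 2, epochs = 120, seed = 5)
  .cache$mlp <- list(cfg = cfg, set = set, dcfg = dcfg, ens = ens)
  .cache$mlp
}

# --- 1-D harmonic potential embedded in the n x 3 coordinate convention
harmonic_1d <- function(k) {
  list(energy = function(x) 0.5 * k * x[1, 1]^2,
       forces = function(x) {
         f <- matrix(0, 1, 3); f[1, 1] <- -k * x[1, 1]; f
       })
}

harmonic_starts <- function(n, k, kT, seed) {
  set.seed(seed)
  lapply(stats::rnorm(n, sd = sqrt(kT / k)),
         function(z) matrix(c(z, 0, 0), 1, 3))
}
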