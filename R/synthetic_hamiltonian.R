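# Seeded generator for model electronic systems.

# evaluate code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a seeded model electronic system
#'
#' Builds a closed-shell model Hamiltonian on a chain or ring of atoms:
#' negative on-site energies and nearest-neighbour hoppings in the one-electron
#' matrix, an exponentially decaying symmetric positive-definite overlap, and
#' a two-electron tensor assembled as a sum of atom-centered separable terms
#' `g_pqrs = strength * sum_k L^k_pq L^k_rs` with localized symmetric factors
#' `L^k`, which guarantees the 8-fold permutational symmetry and a
#' positive-semidefinite Coulomb metric.  Optional external point charges
#' enter the one-electron matrix through a diagonal attraction term.
#' Deterministic under `seed`; the caller's RNG state is untouched.
#'
#' @param n_atoms number of atoms.
#' @param basis_per_atom basis functions per atom.
#' @param topology `"chain"` or `"ring"`.
#' @param n_electrons even electron count (default `n_atoms`, rounded down
#'   to even).
#' @param hopping_range,onsite_range numeric length-2 ranges (hartree).
#' @param interaction_strength prefactor of the two-electron tensor.
#' @param overlap_decay decay constant of the off-diagonal overlap; larger
#'   means closer to orthonormal.
#' @param point_charges optional data frame with columns `q`, `x`, `y`, `z`
#'   (e, bohr).
#' @param spacing interatomic spacing (bohr).
#' @param seed integer seed.
#' @return a [model_system()].
#' @export
gen_model_system <- function(n_atoms = 4, basis_per_atom = 1,
                             topology = c("chain", "ring"),
                             n_electrons = NULL,
                             hopping_range = c(-0.8, -0.3),
                             onsite_range = c(-1.5, -0.8),
                             interaction_strength = 0.4,
                             overlap_decay = 1.2,
                             point_charges = NULL,
                             spacing = 2.0, seed = 1) {
  topology <- match.arg(topology)
  if (is.null(n_electrons)) n_electrons <- n_atoms - (n_atoms %% 2)
  nb <- n_atoms * basis_per_atom
  with_seed(seed, {
    # atom positions
    pos <- if (topology == "chain") {
      cbind(spacing * (seq_len(n_atoms) - 1), 0, 0)
    } else {
      r <- spacing / (2 * sin(pi / n_atoms))
      th <- 2 * pi * (seq_len(n_atoms) - 1) / n_atoms
      cbind(r * cos(th), r * sin(th), 0)
    }
    atom_of_basis <- rep(seq_len(n_atoms), each = basis_per_atom)
    d_atom <- as.matrix(stats::dist(pos))
    d_basis <- d_atom[atom_of_basis, atom_of_basis]

    h <- matrix(0, nb, nb)
    # on-site ladder: jittered ramp with a guaranteed minimum gap so the
    # mean-field spectrum stays gapped at the Fermi level
    diag(h) <- mean(onsite_range) + 0.5 * (seq_len(nb) - 1) +
      stats::runif(nb, -0.15, 0.15)
    hop <- matrix(stats::runif(nb * nb, hopping_range[1], hopping_range[2]),
                  nb, nb)
    hop <- (hop + t(hop)) / 2
    neighbor <- d_basis > 0 & d_basis < 1.5 * spacing
    h[neighbor] <- hop[neighbor]
    same_atom <- d_basis == 0 & row(h) != col(h)
    h[same_atom] <- 0.1 * hop[same_atom]

    S <- exp(-overlap_decay * d_basis)
    dimnames(S) <- NULL
    S[same_atom] <- 0.05
    diag(S) <- 1
    for (trial in 1:20) {
      ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) > 0.05) break
      off <- S - diag(diag(S))
      S <- diag(diag(S)) + 0.5 * off
      warning("overlap not safely positive definite; shrinking off-diagonals")
    }

    alpha <- stats::runif(1, 0.4, 0.7)
    wts <- stats::runif(n_atoms, 0.8, 1.2)
    g <- array(0, rep(nb, 4))
    for (k in seq_len(n_atoms)) {
      dk <- d_atom[atom_of_basis, k]
      L <- exp(-alpha * (outer(dk, dk, `+`)))
      g <- g + interaction_strength * wts[k] *
        array(outer(as.numeric(L), as.numeric(L)), rep(nb, 4))
    }

    e_nuc <- sum(1 / d_atom[upper.tri(d_atom)])
    if (!is.null(point_charges)) {
      pc <- as.matrix(point_charges[, c("x", "y", "z")])
      for (ci in seq_len(nrow(point_charges))) {
        dc <- sqrt(colSums((t(pos) - pc[ci, ])^2))
        # electron attraction on the diagonal of h (electron charge -1)
        diag(h) <- diag(h) - point_charges$q[ci] / dc[atom_of_basis]
        e_nuc <- e_nuc + sum(point_charges$q[ci] * 1 / dc)
      }
    }
    model_system(atom_labels = rep("X", n_atoms),
                 atom_group_of_basis = atom_of_basis,
                 n_electrons = n_electrons,
                 h_core = h, g_eri = g, overlap = S, e_nuclear = e_nuc,
                 point_charges = point_charges, atom_positions = pos)
  })
}
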