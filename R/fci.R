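#' Full configuration interaction in a small orbital space
#'
#' Determinant-basis FCI for an even number of electrons in a set of
#' orthonormal spatial orbitals, using Slater-Condon rules over the Sz = 0
#' determinant sector (which contains the closed-shell singlet ground
#' state).  Integrals are in chemists' notation `(pq|rs)`.
#'
#' @param h_mo one-electron matrix in the orbital basis (may be an embedded
#'   core Hamiltonian).
#' @param g_mo rank-4 two-electron tensor `(pq|rs)` in the orbital basis.
#' @param n_el even number of electrons.
#' @param max_determinants guard on the determinant-space dimension.
#' @return list with `energy` (lowest eigenvalue, hartree) and
#'   `n_determinants`.
#' @export
fci_ground_state <- function(h_mo, g_mo, n_el, max_determinants = 4000) {
  n <- nrow(h_mo)
  if (n_el %% 2 != 0) stop("open-shell cores are not supported")
  na <- n_el / 2L
  if (na > n) stop("more electron pairs than orbitals")
  if (na == 0) return(list(energy = 0, n_determinants = 1L))
  strings <- utils::combn(n, na, simplify = FALSE)
  ns <- length(strings)
  ndet <- ns * ns
  if (ndet > max_determinants)
    stop("FCI determinant space (", ndet, ") exceeds cap (",
         max_determinants, ")")

  # spin-orbital helpers: alpha = 1..n, beta = n+1..2n
  sp <- function(i) ((i - 1L) %% n) + 1L
  same_spin <- function(i, j) (i > n) == (j > n)
  h_so <- function(i, j) if (same_spin(i, j)) h_mo[sp(i), sp(j)] else 0
  # antisymmetrized <ij||kl> over spin orbitals
  g_anti <- function(i, j, k, l) {
    d <- if (same_spin(i, k) && same_spin(j, l))
      g_mo[sp(i), sp(k), sp(j), sp(l)] else 0
    x <- if (same_spin(i, l) && same_spin(j, k))
      g_mo[sp(i), sp(l), sp(j), sp(k)] else 0
    d - x
  }

  occ_list <- vector("list", ndet)
  for (ia in seq_len(ns)) for (ib in seq_len(ns))
    occ_list[[(ia - 1L) * ns + ib]] <- c(strings[[ia]], strings[[ib]] + n)

  H <- matrix(0, ndet, ndet)
  for (I in seq_len(ndet)) {
    oI <- occ_list[[I]]
    # diagonal
    eI <- sum(vapply(oI, function(i) h_so(i, i), numeric(1)))
    for (a in seq_along(oI)) for (b in seq_along(oI))
      if (a < b) eI <- eI + g_anti(oI[a], oI[b], oI[a], oI[b])
    H[I, I] <- eI
    if (I == ndet) break
    for (J in seq(I + 1L, ndet)) {
      oJ <- occ_list[[J]]
      only_I <- setdiff(oI, oJ)
      deg <- length(only_I)
      if (deg > 2) next
      only_J <- setdiff(oJ, oI)
      common <- intersect(oI, oJ)
      sgn <- slater_sign(oI, oJ, only_I, only_J)
      if (deg == 1) {
        m <- only_I; p <- only_J
        v <- h_so(m, p)
        for (c in common) v <- v + g_anti(m, c, p, c)
        H[I, J] <- sgn * v
      } else {
        m <- sort(only_I); p <- sort(only_J)
        H[I, J] <- sgn * g_anti(m[1], m[2], p[1], p[2])
      }
      H[J, I] <- H[I, J]
    }
  }
  e <- eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values
  list(energy = min(e), n_determinants = ndet)
}

# permutation sign bringing two sorted spin-orbital lists to maximal
# coincidence (positions of the differing orbitals in each sorted list)
slater_sign <- function(oI, oJ, only_I, only_J) {
  sI <- sort(oI); sJ <- sort(oJ)
  pos <- c(match(sort(only_I), sI), match(sort(only_J), sJ))
  if (sum(pos) %% 2 == 0) 1 else -1
}
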