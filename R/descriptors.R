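# Atom-centered symmetry-function descriptors with element weighting and
# analytic Cartesian Jacobians.  Radial part:
#   G_rad(a; eta, mu) = sum_{j != a} w(Z_j) exp(-eta (r_aj - mu)^2) fc(r_aj)
# Angular part over pairs of neighbours j < k:
#   G_ang(a; zeta, lambda, eta) = 2^(1-zeta) sum_{j<k} w(Z_j) w(Z_k)
#       (1 + lambda cos theta_jak)^zeta
#       exp(-eta (r_aj^2 + r_ak^2)) fc(r_aj) fc(r_ak)
# with the cosine cutoff fc(r) = (cos(pi r / rc) + 1)/2 for r < rc, whose
# value and first derivative both vanish at rc.  The element weights make a
# single descriptor set embrace all elements.

#' Configure the atom-centered descriptors
#'
#' @param cutoff cutoff radius (Angstrom).
#' @param radial data frame with columns `eta` (1/A^2) and `mu` (Angstrom),
#'   one radial function per row.
#' @param angular data frame with columns `zeta`, `lambda` (+1/-1) and
#'   `eta` (1/A^2), one angular function per row.
#' @param element_weights named numeric vector mapping element symbols to
#'   weights; elements absent from the map are rejected at evaluation time.
#' @return object of class `descriptor_config`; its `dim` element is the
#'   descriptor dimension.
#' @export
descriptor_config <- function(cutoff = 5.0,
                              radial = data.frame(
                                eta = 4,
                                mu = c(1.0, 1.5, 2.0, 2.5, 3.5)),
                              angular = data.frame(
                                zeta = c(1, 1, 4, 4),
                                lambda = c(1, -1, 1, -1),
                                eta = 0.2),
                              element_weights = c(H = 0.125, C = 0.75,
                                                  N = 0.875, O = 1.0)) {
  stopifnot(cutoff > 0)
  cfg <- list(cutoff = cutoff, radial = radial, angular = angular,
              element_weights = element_weights,
              dim = nrow(radial) + nrow(angular))
  class(cfg) <- "descriptor_config"
  cfg
}

cutoff_fn <- function(r, rc) {
  out <- 0.5 * (cos(pi * r / rc) + 1)
  out[r >= rc] <- 0
  out
}

cutoff_fn_deriv <- function(r, rc) {
  out <- -0.5 * pi / rc * sin(pi * r / rc)
  out[r >= rc] <- 0
  out
}

#' Compute per-atom descriptors (and optionally their Jacobian)
#'
#' @param elements character vector of element symbols.
#' @param coords coordinate matrix (n x 3, Angstrom).
#' @param config a [descriptor_config()].
#' @param jacobian if TRUE also return `J`, an array
#'   `n_atoms x dim x (3 n_atoms)` with `J[a, k, c]` the derivative of
#'   descriptor `k` of atom `a` with respect to flattened coordinate `c`.
#' @return list with `G` (n_atoms x dim matrix) and optionally `J`.
#' @export
compute_features <- function(elements, coords, config, jacobian = FALSE) {
  x <- matrix(coords, ncol = 3)
  n <- nrow(x)
  if (n < 1) stop("at least one atom is required")
  missing_el <- setdiff(unique(elements), names(config$element_weights))
  if (length(missing_el))
    stop("no element weight for: ", paste(missing_el, collapse = ", "))
  w <- config$element_weights[elements]
  rc <- config$cutoff
  d2 <- as.matrix(stats::dist(x))
  if (any(d2[upper.tri(d2)] < 0.1))
    stop("two atoms closer than 0.1 Angstrom")
  nr <- nrow(config$radial); na <- nrow(config$angular)
  G <- matrix(0, n, nr + na)
  J <- if (jacobian) array(0, c(n, nr + na, 3 * n)) else NULL
  cidx <- function(atom) (atom - 1L) * 3L + 1:3

  for (a in seq_len(n)) {
    nb <- which(d2[a, ] < rc & seq_len(n) != a)
    if (!length(nb)) next
    rv <- x[nb, , drop = FALSE] - matrix(x[a, ], length(nb), 3, byrow = TRUE)
    r <- d2[a, nb]
    u <- rv / r
    fc <- cutoff_fn(r, rc); dfc <- cutoff_fn_deriv(r, rc)
    # radial: vectorized over the parameter set (rows: params, cols: nbrs)
    if (nr > 0) {
      eta_r <- config$radial$eta; mu_r <- config$radial$mu
      rmu <- outer(mu_r, r, function(m, rr) rr - m)     # r - mu
      gau <- exp(-eta_r * rmu^2)                        # eta recycles by row
      G[a, seq_len(nr)] <- as.numeric(gau %*% (w[nb] * fc))
      if (jacobian) {
        dterm <- sweep(gau, 2, w[nb] * dfc, `*`) -
          2 * eta_r * rmu * sweep(gau, 2, w[nb] * fc, `*`)
        for (jj in seq_along(nb)) {
          gr_block <- outer(dterm[, jj], u[jj, ])       # nr x 3
          J[a, seq_len(nr), cidx(nb[jj])] <-
            J[a, seq_len(nr), cidx(nb[jj])] + gr_block
          J[a, seq_len(nr), cidx(a)] <-
            J[a, seq_len(nr), cidx(a)] - gr_block
        }
      }
    }
    # angular
    if (na > 0 && length(nb) >= 2) {
      for (jj in seq_len(length(nb) - 1)) for (kk in seq(jj + 1, length(nb))) {
        j <- nb[jj]; k <- nb[kk]
        rj <- r[jj]; rk <- r[kk]
        uj <- u[jj, ]; uk <- u[kk, ]
        cth <- sum(uj * uk)
        # d cos / d x_j and d x_k (center gets minus the sum)
        dc_j <- (uk - cth * uj) / rj
        dc_k <- (uj - cth * uk) / rk
        wjk <- w[j] * w[k]
        # vectorized over the angular parameter set
        zeta <- config$angular$zeta; lam <- config$angular$lambda
        eta <- config$angular$eta
        base <- pmax(1 + lam * cth, 0)
        P <- 2^(1 - zeta) * base^zeta
        ex <- exp(-eta * (rj^2 + rk^2))
        R <- wjk * ex * fc[jj] * fc[kk]
        G[a, nr + seq_len(na)] <- G[a, nr + seq_len(na)] + P * R
        if (jacobian) {
          dP_dc <- 2^(1 - zeta) * zeta * lam *
            ifelse(base > 0, base^(zeta - 1), 0)
          dR_drj <- wjk * ex * (dfc[jj] * fc[kk] -
                                2 * eta * rj * fc[jj] * fc[kk])
          dR_drk <- wjk * ex * (fc[jj] * dfc[kk] -
                                2 * eta * rk * fc[jj] * fc[kk])
          grad_j <- outer(dP_dc * R, dc_j) + outer(P * dR_drj, uj)
          grad_k <- outer(dP_dc * R, dc_k) + outer(P * dR_drk, uk)
          ai <- nr + seq_len(na)
          J[a, ai, cidx(j)] <- J[a, ai, cidx(j)] + grad_j
          J[a, ai, cidx(k)] <- J[a, ai, cidx(k)] + grad_k
          J[a, ai, cidx(a)] <- J[a, ai, cidx(a)] - grad_j - grad_k
        }
      }
    }
  }
  if (jacobian) list(G = G, J = J) else list(G = G)
}
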