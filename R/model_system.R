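#' Construct a model electronic system
#'
#' A `model_system` is an integral-level description of a closed-shell toy
#' electronic system: one-electron core Hamiltonian (kinetic energy plus the
#' external potential of the nuclei and of any embedding point charges), the
#' two-electron repulsion tensor, the basis overlap matrix, the nuclear
#' repulsion constant and the electron count.  All quantities are in atomic
#' units (hartree, bohr).
#'
#' @param atom_labels character vector of element symbols, one per atom.
#' @param atom_group_of_basis integer vector mapping each basis function to the
#'   index of the atom it sits on.
#' @param n_electrons even integer, number of electrons (closed shell only).
#' @param h_core symmetric numeric matrix, one-electron integrals (hartree).
#' @param g_eri rank-4 numeric array of two-electron integrals in chemists'
#'   notation `(pq|rs)` with the usual 8-fold permutational symmetry (hartree).
#' @param overlap symmetric positive-definite overlap matrix.
#' @param e_nuclear scalar nuclear repulsion energy (hartree).
#' @param point_charges optional data frame with columns `q` (charge, e) and
#'   `x`, `y`, `z` (position, bohr) of external embedding charges whose
#'   attraction is already folded into `h_core`.
#' @param atom_positions optional numeric matrix (n_atoms x 3, bohr); needed
#'   only when point-charge interactions are rebuilt or inspected.
#' @return an object of class `model_system`.
#' @export
model_system <- function(atom_labels, atom_group_of_basis, n_electrons,
                         h_core, g_eri, overlap, e_nuclear = 0,
                         point_charges = NULL, atom_positions = NULL) {
  h_core <- as.matrix(h_core)
  overlap <- as.matrix(overlap)
  nb <- nrow(h_core)
  stopifnot(ncol(h_core) == nb, all(dim(overlap) == nb),
            length(atom_group_of_basis) == nb,
            length(dim(g_eri)) == 4, all(dim(g_eri) == nb))
  if (n_electrons %% 2 != 0)
    stop("only closed-shell systems are supported: n_electrons must be even")
  if (n_electrons > 2 * nb)
    stop("n_electrons exceeds twice the basis size")
  if (max(abs(h_core - t(h_core))) > 1e-10)
    stop("h_core must be symmetric")
  if (max(abs(overlap - t(overlap))) > 1e-10)
    stop("overlap must be symmetric")
  ev <- eigen(overlap, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("overlap must be positive definite (min eigenvalue ",
         format(min(ev)), ")")
  obj <- list(atom_labels = as.character(atom_labels),
              atom_group_of_basis = as.integer(atom_group_of_basis),
              n_electrons = as.integer(n_electrons),
              h_core = h_core, g_eri = g_eri, overlap = overlap,
              e_nuclear = as.numeric(e_nuclear),
              point_charges = point_charges,
              atom_positions = atom_positions)
  class(obj) <- "model_system"
  obj
}

#' @export
print.model_system <- function(x, ...) {
  cat("model_system:", length(x$atom_labels), "atoms,",
      nrow(x$h_core), "basis functions,", x$n_electrons, "electrons\n")
  cat("  e_nuclear =", format(x$e_nuclear), "hartree;",
      if (is.null(x$point_charges)) "no" else nrow(x$point_charges),
      "point charges\n")
  invisible(x)
}

#' Exchange-correlation model for the mean-field reference
#'
#' Two modes are supported.  `"hf"` is Hartree-Fock: the XC functional is
#' identically zero and exact exchange is carried by the mean-field
#' two-electron operator instead.  `"toy-local"` is a grid-free local model
#' defined directly on the basis representation of the density,
#' `E_xc[D] = -c * sum_p max(D_pp, 0)^gamma`, with the matching diagonal
#' potential `v_xc,pp = -c * gamma * max(D_pp, 0)^(gamma-1)`.  It provides a
#' nonzero nonadditive XC coupling without any quadrature machinery.
#'
#' @param name `"hf"` or `"toy-local"`.
#' @param strength positive prefactor `c` of the toy functional.
#' @param exponent exponent `gamma` of the toy functional (default 4/3).
#' @return an object of class `xc_model`.
#' @export
xc_model <- function(name = c("hf", "toy-local"), strength = 0.1,
                     exponent = 4 / 3) {
  name <- match.arg(name)
  obj <- list(name = name, strength = strength, exponent = exponent)
  class(obj) <- "xc_model"
  obj
}

xc_energy <- function(xc, D) {
  if (xc$name == "hf") return(0)
  d <- pmax(diag(D), 0)
  -xc$strength * sum(d^xc$exponent)
}

xc_potential <- function(xc, D) {
  n <- nrow(D)
  if (xc$name == "hf") return(matrix(0, n, n))
  d <- pmax(diag(D), 0)
  diag(-xc$strength * xc$exponent * d^(xc$exponent - 1), n)
}

#' Write / read the integral container
#'
#' Serializes a [model_system()] to a single JSON container holding the
#' datasets `h_core`, `g_eri`, `overlap`, the scalars `e_nuclear` and
#' `n_electrons`, the atom tables and any point charges.  Doubles are written
#' with 17 significant digits so that the round trip is exact.
#'
#' @param system a `model_system`.
#' @param path file path.
#' @return `write_model_system` returns `path` invisibly;
#'   `read_model_system` returns a `model_system`.
#' @export
write_model_system <- function(system, path) {
  payload <- list(
    format = "hiqem-integral-container-v1",
    atom_labels = system$atom_labels,
    atom_group_of_basis = system$atom_group_of_basis,
    n_electrons = system$n_electrons,
    n_basis = nrow(system$h_core),
    h_core = as.numeric(system$h_core),
    g_eri = as.numeric(system$g_eri),
    overlap = as.numeric(system$overlap),
    e_nuclear = system$e_nuclear)
  if (!is.null(system$point_charges))
    payload$point_charges <- system$point_charges
  if (!is.null(system$atom_positions))
    payload$atom_positions <- as.numeric(system$atom_positions)
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model_system
#' @export
read_model_system <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  nb <- p$n_basis
  model_system(
    atom_labels = p$atom_labels,
    atom_group_of_basis = p$atom_group_of_basis,
    n_electrons = p$n_electrons,
    h_core = matrix(p$h_core, nb, nb),
    g_eri = array(p$g_eri, rep(nb, 4)),
    overlap = matrix(p$overlap, nb, nb),
    e_nuclear = p$e_nuclear,
    point_charges = if (!is.null(p$point_charges))
      as.data.frame(p$point_charges) else NULL,
    atom_positions = if (!is.null(p$atom_positions))
      matrix(p$atom_positions, ncol = 3) else NULL)
}
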