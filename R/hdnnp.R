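# Ensemble high-dimensional neural-network potential.
#
# Each ensemble member holds one small feedforward network per element
# (descriptor -> 2 hidden tanh layers -> atomic energy); the molecular
# energy is the sum of atomic outputs.  Training is full batch with a
# per-weight adaptive step-size optimizer (Rprop family): every weight
# carries its own step size, grown when the gradient sign persists and
# shrunk when it flips.  The optimizer state survives from base training
# into transfer learning, where the input standardization and the first
# hidden layer are frozen.

#' Training configuration for the network potential
#'
#' @param hidden sizes of the two hidden layers.
#' @param lambda_force weight of the force term in the loss (dimensionless;
#'   the default puts the initial energy and force terms at a comparable
#'   order of magnitude on the toy surfaces).
#' @param step0 initial per-weight step size.
#' @param step_min,step_max bounds on the adaptive step sizes.
#' @param grow,shrink step-size adaptation factors.
#' @param grad_floor gradients below this magnitude are treated as zero
#'   (sign-based updates would otherwise amplify numerical noise).
#' @return object of class `hdnnp_config`.
#' @export
hdnnp_config <- function(hidden = c(25, 25), lambda_force = 0.01,
                         step0 = 0.01, step_min = 1e-7, step_max = 0.5,
                         grow = 1.2, shrink = 0.5, grad_floor = 1e-10) {
  cfg <- list(hidden = hidden, lambda_force = lambda_force, step0 = step0,
              step_min = step_min, step_max = step_max, grow = grow,
              shrink = shrink, grad_floor = grad_floor)
  class(cfg) <- "hdnnp_config"
  cfg
}

# ---------------------------------------------------------------------------
# dataset preparation: descriptors (and Jacobians when forces are used)

prepare_dataset <- function(set, dconfig, need_jacobian = FALSE) {
  confs <- lapply(set$conformers, function(cf) {
    ft <- compute_features(cf$elements, cf$coords, dconfig,
                           jacobian = need_jacobian)
    list(G = ft$G,
         Jmat = if (need_jacobian)
           matrix(ft$J, nrow(ft$G) * ncol(ft$G), 3 * nrow(ft$G)) else NULL,
         elements = cf$elements, n_atoms = nrow(ft$G))
  })
  list(confs = confs, dim = dconfig$dim,
       elements = sort(unique(unlist(lapply(confs, `[[`, "elements")))))
}

# stack atoms by element: returns, per element, the row indices into the
# (conformer, atom) flattened order
element_index <- function(prep) {
  el_all <- unlist(lapply(prep$confs, `[[`, "elements"))
  conf_of <- rep(seq_along(prep$confs),
                 vapply(prep$confs, `[[`, 0L, "n_atoms"))
  lapply(stats::setNames(prep$elements, prep$elements),
         function(e) which(el_all == e))
}

stack_features <- function(prep) {
  do.call(rbind, lapply(prep$confs, `[[`, "G"))
}

conf_of_atom <- function(prep) {
  rep(seq_along(prep$confs), vapply(prep$confs, `[[`, 0L, "n_atoms"))
}

# ---------------------------------------------------------------------------
# member initialization

init_params <- function(d, hidden, e_per_atom) {
  h1 <- hidden[1]; h2 <- hidden[2]
  list(W1 = matrix(stats::rnorm(h1 * d, sd = 1 / sqrt(d)), h1, d),
       b1 = numeric(h1),
       W2 = matrix(stats::rnorm(h2 * h1, sd = 1 / sqrt(h1)), h2, h1),
       b2 = numeric(h2),
       w3 = stats::rnorm(h2, sd = 0.1),
       b3 = e_per_atom)
}

zero_like <- function(p) lapply(p, function(x) x * 0)
const_like <- function(p, v) lapply(p, function(x) x * 0 + v)

# ---------------------------------------------------------------------------
# batched forward / backward over one element's atom block

forward_element <- function(par, X) {
  Z1 <- X %*% t(par$W1) + rep(par$b1, each = nrow(X))
  A1 <- tanh(Z1)
  Z2 <- A1 %*% t(par$W2) + rep(par$b2, each = nrow(X))
  A2 <- tanh(Z2)
  e_atom <- drop(A2 %*% par$w3) + par$b3
  list(A1 = A1, A2 = A2, e_atom = e_atom)
}

# gradient of sum_a s_a * E_a over the parameters
backward_element <- function(par, X, fw, s) {
  m <- nrow(X)
  d2 <- (1 - fw$A2^2) * (s %o% par$w3)      # m x h2
  d1 <- (d2 %*% par$W2) * (1 - fw$A1^2)     # m x h1
  list(W1 = t(d1) %*% X, b1 = colSums(d1),
       W2 = t(d2) %*% fw$A1, b2 = colSums(d2),
       w3 = colSums(fw$A2 * s), b3 = sum(s))
}

# per-atom gradient of the atomic energy w.r.t. the standardized input
input_gradient_element <- function(par, fw) {
  w3row <- matrix(par$w3, nrow(fw$A2), length(par$w3), byrow = TRUE)
  d2 <- (1 - fw$A2^2) * w3row
  d1 <- (d2 %*% par$W2) * (1 - fw$A1^2)
  d1 %*% par$W1                              # m x d
}

# gradient of sum_a v_a . dE_a/dg_a over the parameters (double backprop);
# V holds one row v_a per atom, in standardized input space
force_backward_element <- function(par, X, fw, V) {
  m <- nrow(X)
  s1 <- 1 - fw$A1^2; s2 <- 1 - fw$A2^2
  w3row <- matrix(par$w3, m, length(par$w3), byrow = TRUE)
  a1 <- V %*% t(par$W1)
  q1 <- s1 * a1
  t2 <- q1 %*% t(par$W2)
  r2 <- (w3row * t2) * (-2 * fw$A2 * s2)
  w3s2 <- w3row * s2
  c2 <- w3s2 %*% par$W2
  r1 <- (r2 %*% par$W2) * s1 + (c2 * a1) * (-2 * fw$A1 * s1)
  list(W1 = t(r1) %*% X + t(s1 * c2) %*% V,
       b1 = colSums(r1),
       W2 = t(r2) %*% fw$A1 + t(w3s2) %*% q1,
       b2 = colSums(r2),
       w3 = colSums(s2 * t2),
       b3 = 0)
}

# ---------------------------------------------------------------------------
# full-dataset evaluation for one member

member_predict_all <- function(member, prep, Xs_cache = NULL,
                               want_input_grad = FALSE) {
  Xall <- if (is.null(Xs_cache)) stack_features(prep) else Xs_cache
  idx <- element_index(prep)
  n_atoms_total <- nrow(Xall)
  e_atom <- numeric(n_atoms_total)
  dEdg_std <- if (want_input_grad)
    matrix(0, n_atoms_total, prep$dim) else NULL
  fws <- list()
  for (e in prep$elements) {
    rows <- idx[[e]]
    if (!length(rows)) next
    Xs <- sweep(sweep(Xall[rows, , drop = FALSE], 2,
                      member$std[[e]]$mean), 2, member$std[[e]]$sd, "/")
    fw <- forward_element(member$params[[e]], Xs)
    e_atom[rows] <- fw$e_atom
    if (want_input_grad)
      dEdg_std[rows, ] <- input_gradient_element(member$params[[e]], fw)
    fws[[e]] <- list(fw = fw, Xs = Xs, rows = rows)
  }
  co <- conf_of_atom(prep)
  energies <- as.numeric(rowsum(e_atom, co))
  list(energies = energies, e_atom = e_atom, dEdg_std = dEdg_std,
       fws = fws)
}

# forces for every conformer from the per-atom standardized input gradients
member_forces_all <- function(member, prep, dEdg_std) {
  co <- conf_of_atom(prep)
  sd_row <- matrix(0, nrow(dEdg_std), prep$dim)
  el_all <- unlist(lapply(prep$confs, `[[`, "elements"))
  for (e in prep$elements) {
    rows <- which(el_all == e)
    if (length(rows))
      sd_row[rows, ] <- matrix(member$std[[e]]$sd, length(rows),
                               prep$dim, byrow = TRUE)
  }
  dEdg_raw <- dEdg_std / sd_row
  out <- vector("list", length(prep$confs))
  start <- 0L
  for (ci in seq_along(prep$confs)) {
    n <- prep$confs[[ci]]$n_atoms
    rows <- start + seq_len(n)
    out[[ci]] <- -drop(t(prep$confs[[ci]]$Jmat) %*%
                       as.numeric(dEdg_raw[rows, , drop = FALSE]))
    start <- start + n
  }
  out
}

# ---------------------------------------------------------------------------
# optimizer: per-weight adaptive step sizes (Rprop family, iRprop- update)

rprop_update <- function(params, grads, state, cfg, frozen = NULL) {
  for (nm in names(params)) {
    if (!is.null(frozen) && nm %in% frozen) {
      state$prev_grad[[nm]] <- state$prev_grad[[nm]] * 0
      next
    }
    g <- grads[[nm]]
    g[abs(g) < cfg$grad_floor] <- 0   # numerically-zero gradients: no step
    sg <- sign(g)
    same <- sg * sign(state$prev_grad[[nm]])
    eta <- state$eta[[nm]]
    eta[same > 0] <- pmin(eta[same > 0] * cfg$grow, cfg$step_max)
    eta[same < 0] <- pmax(eta[same < 0] * cfg$shrink, cfg$step_min)
    g[same < 0] <- 0          # iRprop-: skip the update after a sign flip
    params[[nm]] <- params[[nm]] - sign(g) * eta
    state$eta[[nm]] <- eta
    state$prev_grad[[nm]] <- g
  }
  list(params = params, state = state)
}

# ---------------------------------------------------------------------------
# single-member training loop (shared by base training and transfer)

train_member <- function(member, prep, e_ref, f_ref, cfg, epochs,
                         train_idx, test_idx, use_forces, frozen = NULL) {
  n_atoms_c <- vapply(prep$confs, `[[`, 0L, "n_atoms")
  co <- conf_of_atom(prep)
  Xall <- stack_features(prep)
  atom_in_train <- co %in% train_idx
  history <- matrix(NA_real_, epochs, 2,
                    dimnames = list(NULL, c("train_rmse", "test_rmse")))
  for (ep in seq_len(epochs)) {
    pred <- member_predict_all(member, prep, Xall,
                               want_input_grad = use_forces)
    dE <- pred$energies - e_ref
    history[ep, 1] <- sqrt(mean((dE[train_idx] / n_atoms_c[train_idx])^2))
    history[ep, 2] <- if (length(test_idx))
      sqrt(mean((dE[test_idx] / n_atoms_c[test_idx])^2)) else NA_real_
    # energy-loss upstream scalar per atom
    s_atom <- (2 * dE[co] / n_atoms_c[co]^2 / length(train_idx)) *
      atom_in_train
    # optional force loss: residual weights and per-atom v vectors
    V_std <- NULL
    if (use_forces) {
      forces <- member_forces_all(member, prep, pred$dEdg_std)
      Vraw <- matrix(0, nrow(Xall), prep$dim)
      start <- 0L
      for (ci in train_idx) {
        n <- prep$confs[[ci]]$n_atoms
        rows_offset <- sum(n_atoms_c[seq_len(ci - 1L)])
        w_res <- 2 * cfg$lambda_force * (forces[[ci]] - f_ref[[ci]]) /
          (3 * n * length(train_idx))
        Vraw[rows_offset + seq_len(n), ] <-
          -matrix(prep$confs[[ci]]$Jmat %*% w_res, n, prep$dim)
        start <- start + n
      }
      # convert to standardized input space (divide by per-element sd)
      el_all <- unlist(lapply(prep$confs, `[[`, "elements"))
      V_std <- Vraw
      for (e in prep$elements) {
        rows <- which(el_all == e)
        if (length(rows))
          V_std[rows, ] <- sweep(Vraw[rows, , drop = FALSE], 2,
                                 member$std[[e]]$sd, "/")
      }
    }
    # accumulate gradients per element and update
    for (e in prep$elements) {
      blk <- pred$fws[[e]]
      if (is.null(blk)) next
      s <- s_atom[blk$rows]
      gr <- backward_element(member$params[[e]], blk$Xs, blk$fw, s)
      if (use_forces) {
        grf <- force_backward_element(member$params[[e]], blk$Xs, blk$fw,
                                      V_std[blk$rows, , drop = FALSE])
        gr <- Map(`+`, gr, grf)
      }
      upd <- rprop_update(member$params[[e]], gr, member$opt[[e]], cfg,
                          frozen)
      member$params[[e]] <- upd$params
      member$opt[[e]] <- upd$state
    }
  }
  member$history <- rbind(member$history, history)
  member
}

# ---------------------------------------------------------------------------

#' Train the base ensemble on energies and forces
#'
#' Trains an ensemble of atomic neural networks on a labeled conformer set
#' (one tier of energies plus matching forces).  Each member gets its own
#' random 90/10 train/test split, its own weight initialization and records
#' its per-epoch train/test energy RMSE.  Deterministic under `seed`.
#'
#' @param set a `conformer_set` with energy and force labels.
#' @param dconfig a [descriptor_config()].
#' @param energy_tier name of the energy label to learn (default
#'   `"tier1"`).
#' @param force_tier name of the force label (default same as
#'   `energy_tier`); set `use_forces = FALSE` to train on energies only.
#' @param n_members ensemble size (default 10).
#' @param epochs training epochs (full batch).
#' @param config an [hdnnp_config()].
#' @param train_fraction fraction of structures in each member's training
#'   split (default 0.9).
#' @param use_forces include the force term in the loss (default TRUE).
#' @param uncertainty_c ensemble uncertainty scaling factor (default 2).
#' @param seed integer seed.
#' @return object of class `hdnnp_ensemble`.
#' @export
train_base <- function(set, dconfig = descriptor_config(),
                       energy_tier = "tier1", force_tier = energy_tier,
                       n_members = 10, epochs = 300,
                       config = hdnnp_config(), train_fraction = 0.9,
                       use_forces = TRUE, uncertainty_c = 2, seed = 1) {
  e_ref <- vapply(set$conformers, function(cf) cf$energies[[energy_tier]],
                  numeric(1))
  f_ref <- NULL
  if (use_forces) {
    has_f <- vapply(set$conformers,
                    function(cf) !is.null(cf$forces[[force_tier]]),
                    logical(1))
    if (!all(has_f))
      stop("force labels '", force_tier, "' missing for some conformers; ",
           "train with use_forces = FALSE for energy-only mode")
    f_ref <- lapply(set$conformers,
                    function(cf) as.numeric(t(cf$forces[[force_tier]])))
  }
  prep <- prepare_dataset(set, dconfig, need_jacobian = use_forces)
  n_conf <- length(prep$confs)
  if (n_conf < 10) stop("at least 10 conformers are required")
  Xall <- stack_features(prep)
  el_all <- unlist(lapply(prep$confs, `[[`, "elements"))
  mean_e_per_atom <- mean(e_ref) / mean(vapply(prep$confs, `[[`, 0L,
                                               "n_atoms"))
  members <- vector("list", n_members)
  for (mi in seq_len(n_members)) {
    members[[mi]] <- with_seed(seed + 7919L * mi, {
      n_train <- max(1L, round(train_fraction * n_conf))
      train_idx <- sort(sample(n_conf, n_train))
      test_idx <- setdiff(seq_len(n_conf), train_idx)
      params <- list(); std <- list(); opt <- list()
      for (e in prep$elements) {
        rows <- which(el_all == e)
        mu <- colMeans(Xall[rows, , drop = FALSE])
        sdv <- apply(Xall[rows, , drop = FALSE], 2, stats::sd)
        sdv[sdv < 1e-10] <- 1
        std[[e]] <- list(mean = mu, sd = sdv)
        params[[e]] <- init_params(prep$dim, config$hidden, mean_e_per_atom)
        opt[[e]] <- list(eta = const_like(params[[e]], config$step0),
                         prev_grad = zero_like(params[[e]]))
      }
      member <- list(params = params, std = std, opt = opt,
                     split = list(train = train_idx, test = test_idx),
                     seed = seed + 7919L * mi, history = NULL)
      train_member(member, prep, e_ref, f_ref, config, epochs,
                   train_idx, test_idx, use_forces)
    })
  }
  ens <- list(members = members, elements = prep$elements,
              descriptor_config = dconfig, config = config,
              uncertainty_c = uncertainty_c, energy_tier = energy_tier,
              n_members = n_members, transfer_log = NULL)
  class(ens) <- "hdnnp_ensemble"
  ens
}

#' @export
print.hdnnp_ensemble <- function(x, ...) {
  cat("hdnnp_ensemble:", x$n_members, "members, elements:",
      paste(x$elements, collapse = ", "),
      "; c =", x$uncertainty_c, "\n")
  if (!is.null(x$members[[1]]$history)) {
    h <- x$members[[1]]$history
    cat("  member 1 final train/test RMSE per atom:",
        format(h[nrow(h), ], digits = 4), "kJ/mol\n")
  }
  invisible(x)
}

#' Transfer-learn the ensemble to a higher theory tier
#'
#' Continues training each member on new per-structure energy targets
#' (and optionally forces), with the input standardization and the first
#' hidden layer frozen and the per-weight optimizer state carried over from
#' the previous training stage.  Each member draws a fresh random
#' train/test split of the target data.
#'
#' @param ensemble a [train_base()] result.
#' @param set conformer set of target structures.
#' @param targets numeric vector of per-structure target energies (kJ/mol),
#'   e.g. tier-corrected learned energies after shift removal.
#' @param forces optional list of per-structure force matrices (or NULL for
#'   energy-only transfer, the default).
#' @param epochs transfer epochs (default 300).
#' @param train_fraction per-member training fraction (default 0.9).
#' @param seed integer seed for the member splits.
#' @return the refined `hdnnp_ensemble`.
#' @export
transfer_learn <- function(ensemble, set, targets, forces = NULL,
                           epochs = 300, train_fraction = 0.9, seed = 2) {
  if (length(targets) < 10)
    stop("transfer learning requires at least 10 target structures")
  use_forces <- !is.null(forces)
  prep <- prepare_dataset(set, ensemble$descriptor_config,
                          need_jacobian = use_forces)
  miss <- setdiff(prep$elements, ensemble$elements)
  if (length(miss))
    stop("element(s) outside the training alphabet: ",
         paste(miss, collapse = ", "))
  f_ref <- if (use_forces)
    lapply(forces, function(f) as.numeric(t(f))) else NULL
  n_conf <- length(prep$confs)
  frozen <- c("W1", "b1")
  for (mi in seq_along(ensemble$members)) {
    member <- ensemble$members[[mi]]
    ensemble$members[[mi]] <- with_seed(seed + 104729L * mi, {
      n_train <- max(1L, round(train_fraction * n_conf))
      train_idx <- sort(sample(n_conf, n_train))
      test_idx <- setdiff(seq_len(n_conf), train_idx)
      member$split <- list(train = train_idx, test = test_idx)
      train_member(member, prep, targets, f_ref, ensemble$config, epochs,
                   train_idx, test_idx, use_forces, frozen = frozen)
    })
  }
  ensemble$transfer_log <- c(ensemble$transfer_log,
                             list(list(epochs = epochs,
                                       train_fraction = train_fraction,
                                       use_forces = use_forces,
                                       seed = seed)))
  ensemble
}

#' Predict energy, forces and uncertainty for one conformer
#'
#' The ensemble energy is the member mean; the uncertainty is
#' `c * population standard deviation` across members; forces are the
#' negative analytic gradient of the mean energy (equal to the mean of the
#' member forces).
#'
#' @param ensemble an `hdnnp_ensemble`.
#' @param elements element symbols of the conformer.
#' @param coords coordinate matrix (n x 3, Angstrom).
#' @param forces compute forces (default TRUE).
#' @return list with `energy` (kJ/mol), `uncertainty` (kJ/mol), `forces`
#'   (n x 3 matrix, kJ/mol/Angstrom) and `member_energies`.
#' @export
predict_hdnnp <- function(ensemble, elements, coords, forces = TRUE) {
  miss <- setdiff(unique(elements), ensemble$elements)
  if (length(miss))
    stop("element(s) outside the training alphabet: ",
         paste(miss, collapse = ", "))
  set1 <- list(conformers = list(list(elements = elements,
                                      coords = matrix(coords, ncol = 3))))
  prep <- prepare_dataset(set1, ensemble$descriptor_config,
                          need_jacobian = forces)
  e_members <- numeric(length(ensemble$members))
  f_sum <- NULL
  for (mi in seq_along(ensemble$members)) {
    pred <- member_predict_all(ensemble$members[[mi]], prep,
                               want_input_grad = forces)
    e_members[mi] <- pred$energies[1]
    if (forces) {
      f <- member_forces_all(ensemble$members[[mi]], prep, pred$dEdg_std)[[1]]
      f_sum <- if (is.null(f_sum)) f else f_sum + f
    }
  }
  n_m <- length(e_members)
  pop_sd <- sqrt(mean((e_members - mean(e_members))^2))
  list(energy = mean(e_members),
       uncertainty = ensemble$uncertainty_c * pop_sd,
       forces = if (forces)
         matrix(f_sum / n_m, ncol = 3, byrow = TRUE) else NULL,
       member_energies = e_members)
}

#' Energy (and force) RMSE statistics of an ensemble on a labeled set
#'
#' Reports member-wise train/test RMSEs (mean and standard deviation over
#' members, using each member's own split) and the RMSE of the ensemble
#' mean prediction, optionally normalized by the number of QM atoms.
#'
#' @param ensemble an `hdnnp_ensemble`.
#' @param set a conformer set.
#' @param targets per-structure reference energies (kJ/mol).
#' @param forces_ref optional list of reference force matrices; when given,
#'   force RMSEs over all components are reported as well.
#' @param per_qm_atom normalize energy errors by the per-structure QM-atom
#'   count (region tag 1); default FALSE normalizes by nothing.
#' @return list of RMSE statistics (kJ/mol, or kJ/mol per QM atom).
#' @export
evaluate_rmse <- function(ensemble, set, targets, forces_ref = NULL,
                          per_qm_atom = FALSE) {
  if (!length(set$conformers)) stop("empty dataset")
  use_forces <- !is.null(forces_ref)
  prep <- prepare_dataset(set, ensemble$descriptor_config,
                          need_jacobian = use_forces)
  norm <- if (per_qm_atom)
    vapply(set$conformers, function(cf) sum(cf$region == 1L), numeric(1))
  else rep(1, length(set$conformers))
  member_rmse <- matrix(NA_real_, length(ensemble$members), 2,
                        dimnames = list(NULL, c("train", "test")))
  force_rmse_members <- numeric(length(ensemble$members))
  e_mat <- matrix(0, length(ensemble$members), length(prep$confs))
  f_mean <- NULL
  for (mi in seq_along(ensemble$members)) {
    member <- ensemble$members[[mi]]
    pred <- member_predict_all(member, prep, want_input_grad = use_forces)
    e_mat[mi, ] <- pred$energies
    err <- (pred$energies - targets) / norm
    tr <- member$split$train; te <- member$split$test
    tr <- tr[tr <= length(err)]; te <- te[te <= length(err)]
    member_rmse[mi, 1] <- sqrt(mean(err[tr]^2))
    member_rmse[mi, 2] <- if (length(te)) sqrt(mean(err[te]^2)) else NA
    if (use_forces) {
      f <- member_forces_all(member, prep, pred$dEdg_std)
      res <- unlist(Map(function(fp, fr) fp - as.numeric(t(fr)),
                        f, forces_ref))
      force_rmse_members[mi] <- sqrt(mean(res^2))
      f_mean <- if (is.null(f_mean)) f else Map(`+`, f_mean, f)
    }
  }
  ens_err <- (colMeans(e_mat) - targets) / norm
  out <- list(member_train_mean = mean(member_rmse[, 1]),
              member_train_sd = stats::sd(member_rmse[, 1]),
              member_test_mean = mean(member_rmse[, 2], na.rm = TRUE),
              member_test_sd = stats::sd(member_rmse[, 2]),
              ensemble_rmse = sqrt(mean(ens_err^2)),
              member_rmse = member_rmse)
  if (use_forces) {
    nm <- length(ensemble$members)
    # ensemble force RMSE from the mean member forces
    f_ens <- lapply(f_mean, function(f) f / nm)
    res <- unlist(Map(function(fp, fr) fp - as.numeric(t(fr)),
                      f_ens, forces_ref))
    out$force_rmse_member_mean <- mean(force_rmse_members)
    out$force_rmse_member_sd <- stats::sd(force_rmse_members)
    out$force_rmse_ensemble <- sqrt(mean(res^2))
  }
  out
}
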