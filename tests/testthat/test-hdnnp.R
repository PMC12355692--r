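test_that("training reduces the loss and the history is recorded", {
  fx <- mlp_fixture()
  h <- fx$ens$members[[1]]$history
  expect_lt(h[nrow(h), "train_rmse"], h[1, "train_rmse"])
  expect_equal(nrow(h), 120)
})

test_that("ensemble uncertainty follows the c * population-sd rule", {
  fx <- mlp_fixture()
  cf <- fx$set$conformers[[3]]
  p <- predict_hdnnp(fx$ens, cf$elements, cf$coords, forces = FALSE)
  e <- p$member_energies
  expect_equal(p$uncertainty, 2 * sqrt(mean((e - mean(e))^2)),
               tolerance = 1e-12)
  # two members at e +/- u give uncertainty 2u
  expect_equal(p$uncertainty, abs(e[1] - e[2]), tolerance = 1e-12)
  # weight-identical members give zero uncertainty
  ens_same <- fx$ens
  ens_same$members[[2]] <- ens_same$members[[1]]
  p0 <- predict_hdnnp(ens_same, cf$elements, cf$coords, forces = FALSE)
  expect_equal(p0$uncertainty, 0, tolerance = 1e-12)
})

test_that("predicted forces equal the negative finite-difference gradient", {
  fx <- mlp_fixture()
  cf <- fx$set$conformers[[7]]
  p <- predict_hdnnp(fx$ens, cf$elements, cf$coords)
  h <- 1e-4
  set.seed(4)
  worst <- 0
  for (probe in 1:6) {
    a <- sample(12, 1); d <- sample(3, 1)
    xp <- cf$coords; xp[a, d] <- xp[a, d] + h
    xm <- cf$coords; xm[a, d] <- xm[a, d] - h
    fd <- -(predict_hdnnp(fx$ens, cf$elements, xp, forces = FALSE)$energy -
            predict_hdnnp(fx$ens, cf$elements, xm, forces = FALSE)$energy) /
      (2 * h)
    worst <- max(worst, abs(p$forces[a, d] - fd) / max(abs(fd), 1e-6))
  }
  expect_lt(worst, 1e-4)
})

test_that("elements outside the alphabet are rejected at prediction", {
  fx <- mlp_fixture()
  cf <- fx$set$conformers[[1]]
  els <- cf$elements; els[1] <- "Xx"
  expect_error(predict_hdnnp(fx$ens, els, cf$coords), "alphabet")
})

test_that("force labels are required unless energy-only mode is chosen", {
  fx <- mlp_fixture()
  set2 <- fx$set
  for (i in seq_along(set2$conformers)) set2$conformers[[i]]$forces <- list()
  expect_error(train_base(set2, fx$dcfg, n_members = 1, epochs = 2),
               "energy-only")
  expect_s3_class(train_base(set2, fx$dcfg, n_members = 1, epochs = 2,
                             use_forces = FALSE, seed = 1),
                  "hdnnp_ensemble")
})

test_that("transfer learning freezes standardization and first layer
           bit-exactly over 300 epochs", {
  fx <- mlp_fixture()
  e2 <- vapply(fx$set$conformers, function(cf) cf$energies[["tier2"]],
               numeric(1))
  tr <- transfer_learn(fx$ens, fx$set, e2, epochs = 300, seed = 9)
  for (mi in seq_along(tr$members)) {
    for (e in tr$elements) {
      expect_identical(tr$members[[mi]]$std[[e]],
                       fx$ens$members[[mi]]$std[[e]])
      expect_identical(tr$members[[mi]]$params[[e]]$W1,
                       fx$ens$members[[mi]]$params[[e]]$W1)
      expect_identical(tr$members[[mi]]$params[[e]]$b1,
                       fx$ens$members[[mi]]$params[[e]]$b1)
    }
  }
  # and the transfer actually learned the new tier
  r_before <- evaluate_rmse(fx$ens, fx$set, e2)
  r_after <- evaluate_rmse(tr, fx$set, e2)
  expect_lt(r_after$ensemble_rmse, r_before$ensemble_rmse)
})

test_that("transfer on targets equal to the base predictions is a fixed
           point", {
  fx <- mlp_fixture()
  preds <- vapply(fx$set$conformers, function(cf)
    predict_hdnnp(fx$ens, cf$elements, cf$coords, forces = FALSE)$energy,
    numeric(1))
  # member-level fixed point: use a single-member ensemble so the targets
  # match that member's own predictions exactly
  ens1 <- fx$ens
  ens1$members <- ens1$members[1]
  ens1$n_members <- 1L
  p1 <- vapply(fx$set$conformers, function(cf)
    predict_hdnnp(ens1, cf$elements, cf$coords, forces = FALSE)$energy,
    numeric(1))
  r_pre <- evaluate_rmse(ens1, fx$set, p1)
  tr <- transfer_learn(ens1, fx$set, p1, epochs = 50, seed = 3)
  r_post <- evaluate_rmse(tr, fx$set, p1)
  expect_lt(abs(r_post$ensemble_rmse - r_pre$ensemble_rmse), 1e-8)
  for (e in tr$elements) {
    dmax <- max(abs(unlist(tr$members[[1]]$params[[e]]) -
                    unlist(ens1$members[[1]]$params[[e]])))
    expect_lt(dmax, 1e-6)
  }
})

test_that("transfer refuses tiny target sets", {
  fx <- mlp_fixture()
  expect_error(transfer_learn(fx$ens, fx$set, rnorm(5)), "at least 10")
})

test_that("RMSE evaluation matches its closed forms", {
  fx <- mlp_fixture()
  preds <- vapply(fx$set$conformers, function(cf)
    predict_hdnnp(fx$ens, cf$elements, cf$coords, forces = FALSE)$energy,
    numeric(1))
  r0 <- evaluate_rmse(fx$ens, fx$set, preds)
  expect_equal(r0$ensemble_rmse, 0, tolerance = 1e-12)
  # uniform offset delta on all references gives RMSE = delta
  r_off <- evaluate_rmse(fx$ens, fx$set, preds + 0.37)
  expect_equal(r_off$ensemble_rmse, 0.37, tolerance = 1e-10)
  # ensemble RMSE never exceeds the mean member RMSE (Jensen)
  e2 <- vapply(fx$set$conformers, function(cf) cf$energies[["tier2"]],
               numeric(1))
  r <- evaluate_rmse(fx$ens, fx$set, e2)
  member_full <- apply(r$member_rmse, 1, function(z) max(z, na.rm = TRUE))
  expect_lte(r$ensemble_rmse, mean(member_full) + 1e-10)
  expect_error(evaluate_rmse(fx$ens, list(conformers = list()), numeric(0)),
               "empty")
})

test_that("identical seeds give bit-identical ensembles", {
  cfg <- toy_pes_config(n_atoms = 6, qm_atoms = 1:4, core_atoms = 1:2)
  set <- gen_conformers(cfg, 20, seed = 2, burn_in = 100, thin = 5)
  a <- train_base(set, n_members = 2, epochs = 15, seed = 77)
  b <- train_base(set, n_members = 2, epochs = 15, seed = 77)
  expect_identical(a$members, b$members)
})

test_that("a student ensemble recovers a frozen random teacher network", {
  cfg <- toy_pes_config()
  set <- gen_conformers(cfg, 200, seed = 8)
  dcfg <- descriptor_config()
  prep <- hiqem:::prepare_dataset(set, dcfg, need_jacobian = TRUE)
  Xall <- hiqem:::stack_features(prep)
  el_all <- unlist(lapply(prep$confs, `[[`, "elements"))
  set.seed(77)
  std <- list(); params <- list()
  for (e in prep$elements) {
    rows <- which(el_all == e)
    mu <- colMeans(Xall[rows, , drop = FALSE])
    sdv <- apply(Xall[rows, , drop = FALSE], 2, sd); sdv[sdv < 1e-10] <- 1
    std[[e]] <- list(mean = mu, sd = sdv)
    p <- hiqem:::init_params(dcfg$dim, c(25, 25), 0)
    p$w3 <- p$w3 * 3
    params[[e]] <- p
  }
  teacher <- list(params = params, std = std)
  pr <- hiqem:::member_predict_all(teacher, prep, want_input_grad = TRUE)
  f_t <- hiqem:::member_forces_all(teacher, prep, pr$dEdg_std)
  for (i in seq_along(set$conformers)) {
    set$conformers[[i]]$energies["tier1"] <- pr$energies[i]
    set$conformers[[i]]$forces$tier1 <- matrix(f_t[[i]], ncol = 3,
                                               byrow = TRUE)
  }
  student <- train_base(set, dcfg, n_members = 2, epochs = 400, seed = 3)
  r <- evaluate_rmse(student, set, pr$energies)
  expect_lt(r$member_test_mean, 0.05 * sd(pr$energies))
})

test_that("a constant-energy zero-force dataset collapses the network to a
           constant", {
  set2 <- gen_conformers(toy_pes_config(n_atoms = 6, qm_atoms = 1:4,
                                        core_atoms = 1:2),
                         40, seed = 4, burn_in = 100, thin = 5)
  for (i in seq_along(set2$conformers)) {
    set2$conformers[[i]]$energies["tier1"] <- 7.5
    set2$conformers[[i]]$forces$tier1 <- matrix(0, 6, 3)
  }
  hc <- hdnnp_config(hidden = c(10, 10), step_min = 1e-12,
                     grad_floor = 1e-14)
  ce <- train_base(set2, descriptor_config(), n_members = 1, epochs = 5000,
                   config = hc, seed = 6, use_forces = FALSE,
                   train_fraction = 1)
  preds <- vapply(set2$conformers, function(cf)
    predict_hdnnp(ce, cf$elements, cf$coords, forces = FALSE)$energy,
    numeric(1))
  expect_lt(max(preds) - min(preds), 1e-6)
})

test_that("the model archive round-trips the ensemble exactly", {
  fx <- mlp_fixture()
  d <- tempfile()
  save_hdnnp(fx$ens, d)
  back <- load_hdnnp(d)
  cf <- fx$set$conformers[[2]]
  p1 <- predict_hdnnp(fx$ens, cf$elements, cf$coords)
  p2 <- predict_hdnnp(back, cf$elements, cf$coords)
  expect_identical(p1$energy, p2$energy)
  expect_identical(p1$forces, p2$forces)
  expect_identical(back$members[[1]]$split, fx$ens$members[[1]]$split)
})

test_that("the double-backprop force gradient matches finite differences", {
  cfg <- toy_pes_config(n_atoms = 6, qm_atoms = 1:4, core_atoms = 1:2)
  set <- gen_conformers(cfg, 12, seed = 2, burn_in = 100, thin = 5)
  dcfg <- descriptor_config()
  e_ref <- vapply(set$conformers, function(cf) cf$energies[["tier1"]],
                  numeric(1))
  f_ref <- lapply(set$conformers, function(cf) as.numeric(t(cf$forces$tier1)))
  prep <- hiqem:::prepare_dataset(set, dcfg, need_jacobian = TRUE)
  hcfg <- hdnnp_config(hidden = c(5, 4), lambda_force = 0.02)
  Xall <- hiqem:::stack_features(prep)
  el_all <- unlist(lapply(prep$confs, `[[`, "elements"))
  set.seed(3)
  params <- list(); std <- list()
  for (e in prep$elements) {
    rows <- which(el_all == e)
    mu <- colMeans(Xall[rows, , drop = FALSE])
    sdv <- apply(Xall[rows, , drop = FALSE], 2, sd); sdv[sdv < 1e-10] <- 1
    std[[e]] <- list(mean = mu, sd = sdv)
    params[[e]] <- hiqem:::init_params(prep$dim, hcfg$hidden, 0)
  }
  member <- list(params = params, std = std)
  nat <- vapply(prep$confs, `[[`, 0L, "n_atoms")
  co <- hiqem:::conf_of_atom(prep)
  loss_fn <- function(member) {
    pred <- hiqem:::member_predict_all(member, prep, want_input_grad = TRUE)
    dE <- pred$energies - e_ref
    lE <- mean((dE / nat)^2)
    fo <- hiqem:::member_forces_all(member, prep, pred$dEdg_std)
    lF <- mean(vapply(seq_along(fo), function(ci)
      hcfg$lambda_force * mean((fo[[ci]] - f_ref[[ci]])^2), numeric(1)))
    lE + lF
  }
  pred <- hiqem:::member_predict_all(member, prep, want_input_grad = TRUE)
  dE <- pred$energies - e_ref
  s_atom <- 2 * dE[co] / nat[co]^2 / length(prep$confs)
  fo <- hiqem:::member_forces_all(member, prep, pred$dEdg_std)
  Vraw <- matrix(0, nrow(Xall), prep$dim)
  for (ci in seq_along(prep$confs)) {
    n <- prep$confs[[ci]]$n_atoms
    off <- sum(nat[seq_len(ci - 1)])
    w_res <- 2 * hcfg$lambda_force * (fo[[ci]] - f_ref[[ci]]) /
      (3 * n * length(prep$confs))
    Vraw[off + seq_len(n), ] <-
      -matrix(prep$confs[[ci]]$Jmat %*% w_res, n, prep$dim)
  }
  e1 <- prep$elements[1]
  rows <- which(el_all == e1)
  V_std <- sweep(Vraw[rows, , drop = FALSE], 2, std[[e1]]$sd, "/")
  Xs <- sweep(sweep(Xall[rows, , drop = FALSE], 2, std[[e1]]$mean), 2,
              std[[e1]]$sd, "/")
  fw <- hiqem:::forward_element(params[[e1]], Xs)
  gr <- hiqem:::backward_element(params[[e1]], Xs, fw, s_atom[rows])
  grf <- hiqem:::force_backward_element(params[[e1]], Xs, fw, V_std)
  gtot <- Map(`+`, gr, grf)
  h <- 1e-6
  worst <- 0
  for (nm in names(gtot)) {
    for (i in seq_len(min(3, length(gtot[[nm]])))) {
      mp <- member; mp$params[[e1]][[nm]][i] <-
        mp$params[[e1]][[nm]][i] + h
      mm <- member; mm$params[[e1]][[nm]][i] <-
        mm$params[[e1]][[nm]][i] - h
      fdg <- (loss_fn(mp) - loss_fn(mm)) / (2 * h)
      worst <- max(worst, abs(fdg - gtot[[nm]][i]) / max(abs(fdg), 1e-8))
    }
  }
  expect_lt(worst, 1e-4)
})
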