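test_that("identical potentials give zero work and instantaneous switching
           reduces to perturbation", {
  U <- harmonic_1d(1)
  starts <- harmonic_starts(20, 1, 1, seed = 1)
  proto <- switching_protocol(n_steps = 25, dt = 0.02, kT = 1, seed = 2)
  w_same <- neq_switch(starts, U, U, proto)$works
  expect_lt(max(abs(w_same)), 1e-12)
  proto0 <- switching_protocol(n_steps = 0, kT = 1, seed = 2)
  UB <- harmonic_1d(4)
  w0 <- neq_switch(starts, U, UB, proto0)$works
  ref <- vapply(starts, function(x) UB$energy(x) - U$energy(x), numeric(1))
  expect_identical(w0, ref)
})

test_that("the lambda schedule must be a monotone bridge", {
  expect_error(switching_protocol(lambda_schedule = function(l) 1 - l))
  expect_error(switching_protocol(lambda_schedule = function(l)
    sin(4 * pi * l) * 0.5 + l), "monotone")
  p <- switching_protocol(lambda_schedule = function(l) l^2)
  expect_s3_class(p, "switching_protocol")
})

test_that("BAR, Jarzynski and Crooks agree on the harmonic switch and the
           second law holds", {
  kT <- 1
  proto <- switching_protocol(n_steps = 100, dt = 0.02, kT = kT, seed = 11)
  starts_f <- harmonic_starts(800, 1, kT, seed = 42)
  starts_b <- harmonic_starts(800, 4, kT, seed = 43)
  wf <- neq_switch(starts_f, harmonic_1d(1), harmonic_1d(4), proto,
                   seed = 1)$works
  wb <- neq_switch(starts_b, harmonic_1d(4), harmonic_1d(1), proto,
                   seed = 2)$works
  dF <- 0.5 * log(4)
  bar <- estimate_free_energy(wf, wb, "bar", kT)
  expect_lt(abs(bar$delta_g - dF), 3 * bar$se)
  se_f <- sd(wf) / sqrt(length(wf)); se_b <- sd(wb) / sqrt(length(wb))
  expect_gt(mean(wf), dF - 3 * se_f)
  expect_gt(mean(wb), -dF - 3 * se_b)
  jz <- estimate_free_energy(wf, method = "jarzynski_forward", kT = kT)
  expect_lt(abs(jz$delta_g - dF), 0.1)
  cr <- estimate_free_energy(wf, wb, "crooks_fit", kT)
  expect_lt(abs(cr$delta_g - bar$delta_g), 3 * bar$se + 0.05)
})

test_that("degenerate work sets recover their closed forms", {
  # all forward works +w, all backward works -w: BAR gives exactly w
  w <- 1.7
  bar <- estimate_free_energy(rep(w, 50), rep(-w, 50), "bar", kT = 2.5)
  expect_equal(bar$delta_g, w, tolerance = 1e-8)
  # zero-variance Jarzynski returns the mean work
  jz <- estimate_free_energy(rep(0.4, 30), method = "jarzynski_forward",
                             kT = 2.5)
  expect_equal(jz$delta_g, 0.4, tolerance = 1e-12)
  expect_error(estimate_free_energy(numeric(0)), "empty")
  expect_error(estimate_free_energy(rnorm(5), method = "bar"), "backward")
})

test_that("the asymptotic BAR error scales as 1/sqrt(n) and matches a
           bootstrap", {
  kT <- 1
  set.seed(5)
  wf <- rnorm(400, mean = 1.0, sd = 0.8)
  wb <- rnorm(400, mean = -0.3, sd = 0.8)
  se1 <- bar_variance(wf, wb, kT)
  se4 <- bar_variance(rep(wf, 4), rep(wb, 4), kT)
  expect_equal(se4, se1 / 2, tolerance = 0.01)
  dgs <- replicate(1000, {
    i <- sample(400, replace = TRUE); j <- sample(400, replace = TRUE)
    estimate_free_energy(wf[i], wb[j], "bar", kT)$delta_g
  })
  expect_lt(abs(se1 - sd(dgs)) / sd(dgs), 0.3)
  expect_error(bar_variance(1, c(1, 2)), "2 samples")
})

test_that("resampling weights follow the Boltzmann rule", {
  cfgs <- lapply(1:4, function(i) matrix(i, 1, 3))
  r <- resample_to_target(cfgs, rep(2.5, 4), kT = 2.5, seed = 1)
  expect_equal(r$weights, rep(0.25, 4))
  expect_equal(r$ess, 4)
  kT <- 2.5
  r2 <- resample_to_target(cfgs[1:2], c(0, kT * log(2)), kT, seed = 1)
  expect_equal(r2$weights[1] / r2$weights[2], 2, tolerance = 1e-12)
  expect_equal(sum(r2$weights), 1, tolerance = 1e-14)
  expect_warning(resample_to_target(cfgs, c(0, 500, 500, 500), kT = 2.5,
                                    seed = 1), "ESS")
})

test_that("a double-well start ensemble produces a two-component work
           distribution", {
  skip_if_not_installed("mclust")
  # two basins at +/-2; instantaneous switch to a harmonic centred at -2
  set.seed(21)
  z <- c(rnorm(150, -2, 0.3), rnorm(150, 2, 0.3))
  starts <- lapply(z, function(zi) matrix(c(zi, 0, 0), 1, 3))
  dw <- list(energy = function(x) 0.1 * (x[1, 1]^2 - 4)^2,
             forces = function(x) {
               f <- matrix(0, 1, 3)
               f[1, 1] <- -0.4 * x[1, 1] * (x[1, 1]^2 - 4); f
             })
  target <- list(energy = function(x) 0.5 * (x[1, 1] + 2)^2,
                 forces = function(x) {
                   f <- matrix(0, 1, 3); f[1, 1] <- -(x[1, 1] + 2); f
                 })
  w <- neq_switch(starts, dw, target,
                  switching_protocol(n_steps = 0, kT = 1), seed = 3)$works
  b <- mclust::mclustBIC(w, G = 1:2, verbose = FALSE)
  # the two-component model wins the BIC comparison
  expect_gt(max(b["2", ], na.rm = TRUE), max(b["1", ], na.rm = TRUE))
})

test_that("cycle combination counts the repeat grid and is antisymmetric in
           the end states", {
  cy0 <- combine_cycle(-35.3, rep(0, 6), rep(0, 6))
  expect_equal(cy0$n_combinations, 36)
  expect_equal(cy0$mean, -35.3)
  expect_equal(cy0$sigma, 0)
  lp <- c(1.0, 1.4); ls <- c(-0.2, 0.3)
  cy <- combine_cycle(-10, lp, ls)
  expect_equal(cy$n_combinations, 4)
  cy_swap <- combine_cycle(-10, ls, lp)
  expect_equal(cy$mean + 10, -(cy_swap$mean + 10), tolerance = 1e-12)
  expect_error(combine_cycle(-10, numeric(0), ls), "both end states")
})

test_that("uncertainty propagation is exact and monotone", {
  expect_equal(propagate_uncertainty(0, 0, 0), 0)
  expect_equal(propagate_uncertainty(0.3, 0.4, 0.45), sqrt(1.06),
               tolerance = 1e-14)
  expect_error(propagate_uncertainty(-0.1, 0, 0), "nonnegative")
  set.seed(2)
  g <- expand.grid(a = seq(0, 1, 0.25), b = seq(0, 1, 0.25),
                   s = seq(0, 1, 0.25))
  u <- mapply(propagate_uncertainty, g$a, g$b, g$s)
  for (col in c("a", "b", "s")) {
    gp <- g; gp[[col]] <- gp[[col]] + 0.1
    up <- mapply(propagate_uncertainty, gp$a, gp$b, gp$s)
    expect_true(all(up >= u))
  }
})

test_that("switching is deterministic under fixed seeds", {
  starts <- harmonic_starts(30, 1, 1, seed = 9)
  proto <- switching_protocol(n_steps = 30, dt = 0.02, kT = 1, seed = 4)
  a <- neq_switch(starts, harmonic_1d(1), harmonic_1d(4), proto)
  b <- neq_switch(starts, harmonic_1d(1), harmonic_1d(4), proto)
  expect_identical(a$works, b$works)
})

test_that("work records and the cycle report serialize faithfully", {
  works <- data.frame(repeat_id = 1L, direction = "forward",
                      start_index = 1:3,
                      work_kJ_per_mol = c(0.1, -0.2, 0.3))
  f <- tempfile(fileext = ".csv")
  write_work_records(works, f)
  expect_equal(utils::read.csv(f)$work_kJ_per_mol, works$work_kJ_per_mol)
  cy <- combine_cycle(-35.3, c(1, 2), c(0.5, 0.8))
  unc <- list(delta_mbar_lp = 0.3, delta_mbar_ls = 0.4,
              total = propagate_uncertainty(0.3, 0.4, cy$sigma))
  fj <- tempfile(fileext = ".json")
  write_cycle_report(cy, unc, fj)
  rep <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(rep$dg_bind_mean, cy$mean, tolerance = 1e-12)
  expect_equal(rep$uncertainty$total, unc$total, tolerance = 1e-12)
})

test_that("the BAR error shrinks as the switch is slowed", {
  kT <- 1
  ses <- numeric(0)
  for (ns in c(10, 100, 400)) {
    proto <- switching_protocol(n_steps = ns, dt = 0.02, kT = kT,
                                seed = 17)
    wf <- neq_switch(harmonic_starts(300, 1, kT, seed = 51),
                     harmonic_1d(1), harmonic_1d(4), proto, seed = 4)$works
    wb <- neq_switch(harmonic_starts(300, 4, kT, seed = 52),
                     harmonic_1d(4), harmonic_1d(1), proto, seed = 5)$works
    ses <- c(ses, estimate_free_energy(wf, wb, "bar", kT)$se)
  }
  expect_lt(ses[2], ses[1] * 1.1)
  expect_lt(ses[3], ses[2] * 1.1)
  expect_lt(ses[3], ses[1])
})
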