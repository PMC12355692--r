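test_that("a single all-occupied core with no LL set leaves h_core intact", {
  fx <- embed_fixture(2)
  # one core covering every atom: every occupied orbital lands in it
  p <- partition_orbitals(fx$loc, fx$sys,
                          list(seq_along(fx$sys$atom_labels)),
                          c_virt = fx$scf$c_virt)
  expect_true(all(p$assignment == "1"))
  emb <- build_core_hamiltonian(fx$sys, p, 1, fx$xc)
  expect_lt(max(abs(emb$h_eff - fx$sys$h_core)), 1e-10)
  expect_lt(max(abs(emb$v_xc_nadd)), 1e-12)
  expect_lt(max(abs(emb$projector)), 1e-10)
})

test_that("the nonadditive XC potential vanishes in hf mode", {
  fx <- embed_fixture(5)
  p <- partition_orbitals(fx$loc, fx$sys, list(1:2), c_virt = fx$scf$c_virt)
  for (lbl in setdiff(unique(p$assignment), "LL")) {
    emb <- build_core_hamiltonian(fx$sys, p, as.integer(lbl), fx$xc)
    expect_lt(max(abs(emb$v_xc_nadd)), 1e-14)
  }
})

test_that("the embedded mean-field potential matches explicit tensor
           contraction with the other sets' densities", {
  fx <- embed_fixture(6)
  sys <- fx$sys
  p <- partition_orbitals(fx$loc, sys, list(1:2, 3:4),
                          c_virt = fx$scf$c_virt)
  lbls <- setdiff(unique(p$assignment), "LL")
  expect_length(lbls, 2)
  emb <- build_core_hamiltonian(sys, p, as.integer(lbls[1]), fx$xc)
  D_I <- emb$densities$core
  D_other <- emb$densities$other
  J <- oracle_coulomb(sys$g_eri, D_other)
  K <- oracle_exchange(sys$g_eri, D_other)
  # hf mode: the mean field of the other sets is J - K/2
  expect_equal(sum(D_I * emb$v_coulomb), sum(D_I * (J - 0.5 * K)),
               tolerance = 1e-10)
})

test_that("embedded cores with no occupied orbitals are rejected", {
  fx <- embed_fixture(2)
  p <- partition_orbitals(fx$loc, fx$sys, list(1:2), c_virt = fx$scf$c_virt)
  p$assignment[] <- "LL"
  expect_error(build_core_hamiltonian(fx$sys, p, 1, fx$xc),
               "no occupied")
})

test_that("FCI core energy matches the analytic 2x2 CI eigenvalue", {
  sys <- symmetric_diatomic()
  xc <- xc_model("hf")
  scf <- run_scf(sys, xc)
  loc <- scf$c_occ   # single occupied orbital; nothing to localize
  p <- partition_orbitals(loc, sys, list(1:2), c_virt = scf$c_virt)
  emb <- build_core_hamiltonian(sys, p, 1, xc)
  e_fci <- core_energy(emb, sys, p, "fci")
  # independent construction: transform integrals by explicit loops and
  # build the closed-shell doubles CI matrix by hand
  C <- cbind(scf$c_occ, scf$c_virt)
  h_mo <- t(C) %*% emb$h_eff %*% C
  g_mo <- array(0, rep(2, 4))
  for (p1 in 1:2) for (q in 1:2) for (r in 1:2) for (s in 1:2) {
    acc <- 0
    for (mu in 1:2) for (nu in 1:2) for (la in 1:2) for (sg in 1:2)
      acc <- acc + C[mu, p1] * C[nu, q] * C[la, r] * C[sg, s] *
        sys$g_eri[mu, nu, la, sg]
    g_mo[p1, q, r, s] <- acc
  }
  # parity makes the singles couplings vanish for the homo-diatomic
  expect_lt(abs(h_mo[1, 2]), 1e-8)
  H2x2 <- matrix(c(2 * h_mo[1, 1] + g_mo[1, 1, 1, 1], g_mo[1, 2, 1, 2],
                   g_mo[1, 2, 1, 2], 2 * h_mo[2, 2] + g_mo[2, 2, 2, 2]),
                 2, 2)
  expect_equal(e_fci, min(eigen(H2x2, symmetric = TRUE)$values),
               tolerance = 1e-10)
})

test_that("FCI is variational against the determinant expectation", {
  for (s in c(3, 6, 10)) {
    fx <- embed_fixture(s)
    p <- partition_orbitals(fx$loc, fx$sys, list(1:2),
                            c_virt = fx$scf$c_virt)
    for (lbl in setdiff(unique(p$assignment), "LL")) {
      emb <- build_core_hamiltonian(fx$sys, p, as.integer(lbl), fx$xc)
      e_det <- core_energy(emb, fx$sys, p, "determinant")
      e_fci <- core_energy(emb, fx$sys, p, "fci")
      expect_lte(e_fci, e_det + 1e-12)
    }
  }
})

test_that("FCI with no virtual space equals the determinant expectation", {
  fx <- embed_fixture(2)
  p <- partition_orbitals(fx$loc, fx$sys,
                          list(seq_along(fx$sys$atom_labels)),
                          c_virt = fx$scf$c_virt)
  emb <- build_core_hamiltonian(fx$sys, p, 1, fx$xc)
  e_det <- core_energy(emb, fx$sys, p, "determinant")
  e_fci <- core_energy(emb, fx$sys, p, "fci", n_virt = 0)
  expect_equal(e_fci, e_det, tolerance = 1e-10)
})

test_that("oversized FCI spaces trigger the truncation advice", {
  fx <- embed_fixture(2)
  p <- partition_orbitals(fx$loc, fx$sys, list(1:2),
                          c_virt = fx$scf$c_virt)
  lbl <- setdiff(unique(p$assignment), "LL")[1]
  emb <- build_core_hamiltonian(fx$sys, p, as.integer(lbl), fx$xc)
  expect_error(core_energy(emb, fx$sys, p, "fci", fci_orbital_cap = 1),
               "truncate")
})

test_that("the LL energy reproduces the reference for an all-LL set and
           vanishes for an empty one", {
  fx <- embed_fixture(7)
  p <- partition_orbitals(fx$loc, fx$sys, list(1:2),
                          c_virt = fx$scf$c_virt)
  p_all <- p; p_all$assignment[] <- "LL"
  expect_equal(ll_energy(fx$sys, p_all, fx$xc) + fx$sys$e_nuclear,
               fx$scf$energy, tolerance = 1e-10)
  p_none <- p; p_none$assignment[] <- "1"
  expect_identical(ll_energy(fx$sys, p_none, fx$xc), 0)
})

test_that("a distant point charge shifts the LL energy like q*Q/R", {
  base <- function(R) {
    sys <- gen_model_system(n_atoms = 2, n_electrons = 2, seed = 12,
                            overlap_decay = 4,
                            point_charges = data.frame(q = 0.5, x = R,
                                                       y = 0, z = 0))
    xc <- xc_model("hf")
    scf <- run_scf(sys, xc)
    p <- partition_orbitals(scf$c_occ, sys, list(1), c_virt = scf$c_virt)
    p$assignment[] <- "LL"
    ll_energy(sys, p, xc)
  }
  sys0 <- gen_model_system(n_atoms = 2, n_electrons = 2, seed = 12,
                           overlap_decay = 4)
  xc <- xc_model("hf")
  scf0 <- run_scf(sys0, xc)
  p0 <- partition_orbitals(scf0$c_occ, sys0, list(1), c_virt = scf0$c_virt)
  p0$assignment[] <- "LL"
  e0 <- ll_energy(sys0, p0, xc)
  # electronic charge Q = -n_electrons; interaction with charge q at R
  for (R in c(50, 200)) {
    shift <- base(R) - e0
    expected <- 0.5 * (-2) / R
    expect_equal(shift / expected, 1, tolerance = 0.05)
  }
})

test_that("the rest energy reduces to the inter-core term at hf", {
  fx <- embed_fixture(6)
  p1 <- partition_orbitals(fx$loc, fx$sys,
                           list(seq_along(fx$sys$atom_labels)),
                           c_virt = fx$scf$c_virt)
  expect_equal(as.numeric(rest_energy(fx$sys, p1, fx$xc)), 0,
               tolerance = 1e-12)
  p2 <- partition_orbitals(fx$loc, fx$sys, list(1:2, 3:4),
                           c_virt = fx$scf$c_virt)
  lbls <- setdiff(unique(p2$assignment), "LL")
  expect_length(lbls, 2)
  D1 <- hiqem:::set_density(p2, lbls[1])
  D2 <- hiqem:::set_density(p2, lbls[2])
  J12 <- sum(D1 * oracle_coulomb(fx$sys$g_eri, D2))
  K12 <- sum(D1 * oracle_exchange(fx$sys$g_eri, D2))
  expect_equal(as.numeric(rest_energy(fx$sys, p2, fx$xc)),
               -(J12 - 0.5 * K12), tolerance = 1e-10)
  p_all <- p2; p_all$assignment[] <- "LL"
  expect_equal(as.numeric(rest_energy(fx$sys, p_all, fx$xc)), 0,
               tolerance = 1e-12)
})

test_that("the determinant-level decomposition is exact and shift-invariant
           for hf references", {
  for (s in c(4, 6, 11)) {
    fx <- embed_fixture(s)
    for (groups in list(list(1:2), list(1:2, 3:4), list(2:3))) {
      p <- partition_orbitals(fx$loc, fx$sys, groups,
                              c_virt = fx$scf$c_virt)
      tot <- embedding_total(fx$sys, p, fx$xc, "determinant")
      expect_equal(tot$e_qm, fx$scf$energy, tolerance = 1e-10)
      p$epsilon_shift <- 7.3
      tot2 <- embedding_total(fx$sys, p, fx$xc, "determinant")
      expect_equal(tot2$e_qm, tot$e_qm, tolerance = 1e-10)
    }
  }
})

test_that("MM terms enter the total additively", {
  fx <- embed_fixture(4)
  p <- partition_orbitals(fx$loc, fx$sys, list(1:2),
                          c_virt = fx$scf$c_virt)
  mm <- list(e_mm = 7, e_elec_int = -1.5, e_lj_int = 0.25)
  tot <- embedding_total(fx$sys, p, fx$xc, "determinant", mm_terms = mm)
  expect_equal(tot$e_total, tot$e_qm + 7 - 1.5 + 0.25, tolerance = 1e-12)
})

test_that("the JSON embedding report itemizes every term", {
  fx <- embed_fixture(4)
  p <- partition_orbitals(fx$loc, fx$sys, list(1:2),
                          c_virt = fx$scf$c_virt)
  tot <- embedding_total(fx$sys, p, fx$xc, "determinant")
  f <- tempfile(fileext = ".json")
  write_embedding_report(tot, f)
  rep <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(rep$e_qm, tot$e_qm, tolerance = 1e-12)
  expect_named(rep$e_rest_breakdown,
               c("e_xc_total", "e_xc_sets", "e_nadd_expectation",
                 "e_intercore"))
})
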