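# Restricted Kohn-Sham SCF host.

# Independent restricted Hartree-Fock oracle for two-electron diatomics in
# an s-only basis: closed-form s integrals (Boys F0 written directly via
# erf) and a plain fixed-point SCF loop. Shares no code with the package's
# integral engine or SCF driver.
rhf_oracle_h2 <- function(zeta, coef, R) {
  F0 <- function(T) ifelse(T < 1e-12, 1 - T / 3, 0.5 * sqrt(pi / T) *
                             (2 * stats::pnorm(sqrt(2 * T)) - 1))
  np <- length(zeta)
  A <- c(0, 0, 0); B <- c(0, 0, R)
  centers <- list(A, B)
  ov <- function(za, zb, RA, RB) {
    p <- za + zb
    (pi / p)^1.5 * exp(-za * zb / p * sum((RA - RB)^2))
  }
  kin <- function(za, zb, RA, RB) {
    p <- za + zb; mu <- za * zb / p; R2 <- sum((RA - RB)^2)
    mu * (3 - 2 * mu * R2) * ov(za, zb, RA, RB)
  }
  nuc <- function(za, zb, RA, RB, RC) {
    p <- za + zb; P <- (za * RA + zb * RB) / p
    -2 * pi / p * exp(-za * zb / p * sum((RA - RB)^2)) *
      F0(p * sum((P - RC)^2))
  }
  eri_s <- function(za, zb, zc, zd, RA, RB, RC, RD) {
    p <- za + zb; q <- zc + zd
    P <- (za * RA + zb * RB) / p; Q <- (zc * RC + zd * RD) / q
    2 * pi^2.5 / (p * q * sqrt(p + q)) *
      exp(-za * zb / p * sum((RA - RB)^2) - zc * zd / q * sum((RC - RD)^2)) *
      F0(p * q / (p + q) * sum((P - Q)^2))
  }
  # contracted 2x2 matrices over the two atom-centered s functions
  S <- Tm <- V <- matrix(0, 2, 2)
  ERI <- array(0, c(2, 2, 2, 2))
  for (m in 1:2) for (n in 1:2) {
    for (k in seq_len(np)) for (l in seq_len(np)) {
      cc <- coef[k] * coef[l]
      S[m, n] <- S[m, n] + cc * ov(zeta[k], zeta[l], centers[[m]], centers[[n]])
      Tm[m, n] <- Tm[m, n] + cc * kin(zeta[k], zeta[l], centers[[m]], centers[[n]])
      for (Ci in 1:2) {
        V[m, n] <- V[m, n] + cc * nuc(zeta[k], zeta[l], centers[[m]],
                                      centers[[n]], centers[[Ci]])
      }
    }
    for (s in 1:2) for (t in 1:2) {
      for (k in seq_len(np)) for (l in seq_len(np)) {
        for (u in seq_len(np)) for (v in seq_len(np)) {
          ERI[m, n, s, t] <- ERI[m, n, s, t] +
            coef[k] * coef[l] * coef[u] * coef[v] *
            eri_s(zeta[k], zeta[l], zeta[u], zeta[v], centers[[m]],
                  centers[[n]], centers[[s]], centers[[t]])
        }
      }
    }
  }
  H <- Tm + V
  se <- eigen(S, symmetric = TRUE)
  X <- se$vectors %*% diag(1 / sqrt(se$values)) %*% t(se$vectors)
  C <- X[, 1, drop = FALSE]
  for (it in 1:100) {
    P <- 2 * tcrossprod(C)
    Gm <- matrix(0, 2, 2)
    for (m in 1:2) for (n in 1:2) {
      Gm[m, n] <- sum(P * (ERI[m, n, , ] - 0.5 * ERI[m, , n, ]))
    }
    Fm <- H + Gm
    Fp <- t(X) %*% Fm %*% X
    ev <- eigen((Fp + t(Fp)) / 2, symmetric = TRUE)
    C <- (X %*% ev$vectors)[, which.min(ev$values), drop = FALSE]
  }
  P <- 2 * tcrossprod(C)
  Gm <- matrix(0, 2, 2)
  for (m in 1:2) for (n in 1:2) {
    Gm[m, n] <- sum(P * (ERI[m, n, , ] - 0.5 * ERI[m, , n, ]))
  }
  sum(P * H) + 0.5 * sum(P * Gm) + 1 / R
}

test_that("pure Hartree-Fock matches the independent RHF oracle", {
  fx <- fixture_objs("h2")
  hf <- functional_spec("hf", c_F = 1, alpha = 1, beta = 0,
                        correlation = "none")
  scf <- scf_for("h2", hf, options = list(coulomb = "exact"))
  sh <- fx$basis$shells[[1]]
  ref <- rhf_oracle_h2(sh$zeta, sh$coef[, 1], 1.4)
  expect_equal(scf$energy, ref, tolerance = 1e-8)
})

test_that("exact density representability gives exact fitted Coulomb energy", {
  # one normalized s orbital with exponent z: its density is the s Hermite
  # Gaussian with exponent 2z (up to normalization), so an auxiliary set
  # containing that function fits the density exactly
  mol <- molecule("H", matrix(0, 1, 3))
  z <- 0.75
  basis <- build_basis(mol, sprintf("H 0\nS 1 1.0\n %.10f 1.0\n****", z))
  aux <- build_aux_basis(mol, sprintf("H 0\nS 1 1.0\n %.10f 1.0\n****", 2 * z))
  tc <- three_center(basis, aux)
  G <- coulomb_metric(aux)
  P <- matrix(2, 1, 1)            # doubly occupied normalized orbital
  ft <- fit_density(P, tc, G)
  eri <- four_center(basis)
  exact <- 4 * eri[1, 1, 1, 1]
  expect_equal(ft$self_repulsion, exact, tolerance = 1e-10)
})

test_that("LDA total energy is invariant under rigid rotation", {
  scf <- scf_for("h2o", "lda")
  fx <- generate_fixture("h2o")
  R <- random_rotation(5)
  mol2 <- rotate_molecule(parse_xyz(fx$xyz), R)
  scf2 <- run_scf(mol2, build_basis(mol2, fx$basis),
                  build_aux_basis(mol2, fx$aux), functional_preset("lda"))
  expect_equal(scf2$energy, scf$energy, tolerance = 1e-8)
})

test_that("SCF energy descends monotonically once DIIS has engaged", {
  for (name in c("h2o", "lih")) {
    h <- scf_for(name, "lda")$history
    if (length(h) > 3L) {
      expect_true(all(diff(h[3:length(h)]) <= 1e-10))
    }
  }
})

test_that("virial-style sanity bound on all fixtures", {
  for (name in c("h2", "heh+", "lih", "h2o")) {
    scf <- scf_for(name, "lda")
    kin <- sum(scf$P * scf$cache$one_electron$T)
    ratio <- abs(kin / scf$energy)
    expect_gt(ratio, 0.5)
    expect_lt(ratio, 1.5)
  }
})

test_that("orthonormal MOs and Aufbau ordering", {
  scf <- scf_for("h2o", "lda")
  S <- scf$cache$one_electron$S
  expect_lt(max(abs(t(scf$C) %*% S %*% scf$C - diag(length(scf$eps)))), 1e-8)
  expect_true(all(diff(scf$eps) >= -1e-12))
})

test_that("odd electron count and degenerate HOMO are rejected", {
  fx <- generate_fixture("heh+")
  mol <- parse_xyz(fx$xyz, charge = 0L)  # 3 electrons
  expect_error(run_scf(mol, build_basis(mol, fx$basis),
                       build_aux_basis(mol, fx$aux),
                       functional_preset("lda")), "odd electron|closed-shell")

  # square H4 has a half-filled, exactly degenerate HOMO at Aufbau filling
  a <- 1.6
  mol4 <- molecule(rep("H", 4),
                   rbind(c(0, 0, 0), c(a, 0, 0), c(a, a, 0), c(0, a, 0)))
  fxh <- generate_fixture("h2")
  hf <- functional_spec("hf", c_F = 1, alpha = 1, beta = 0,
                        correlation = "none")
  expect_error(run_scf(mol4, build_basis(mol4, fxh$basis),
                       build_aux_basis(mol4, fxh$aux), hf),
               "degenerate HOMO")
})

test_that("checkpoint write/read round trip", {
  scf <- scf_for("h2", "lda")
  path <- tempfile(fileext = ".chk")
  write_checkpoint(scf, path)
  chk <- read_checkpoint(path)
  expect_equal(chk$C, scf$C, tolerance = 1e-12)
  expect_equal(chk$eps, scf$eps, tolerance = 1e-12)
  expect_identical(chk$nocc, scf$nocc)
  expect_s3_class(chk$functional, "functional_spec")
  unlink(path)
})
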