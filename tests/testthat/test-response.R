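# Response stage: M matrix, HDA shifts, matrix-free operator, Davidson,
# oscillator strengths, polarizability, dense full-exchange reference.

hyb_scf <- function() scf_for("h2o", "hyb25")

test_that("M matrix equals the naive MO-transformation path", {
  scf <- hyb_scf()
  M <- m_matrix(scf)
  M_naive <- hdatd:::m_matrix_naive(scf, scf$cache$tc)
  expect_lt(max(abs(M - M_naive)), 1e-12)
})

test_that("M matrix rows are invariant under MO sign flips and vanish for
           zero coefficient vectors", {
  scf <- hyb_scf()
  M <- m_matrix(scf)
  scf2 <- scf
  scf2$C[, 3] <- -scf2$C[, 3]
  M2 <- m_matrix(scf2)
  expect_lt(max(abs(M2 - M)), 1e-13)
  scf3 <- scf
  scf3$C[, 2] <- 0
  expect_identical(max(abs(m_matrix(scf3)[2, ])), 0)
})

test_that("HDA shifts match brute-force density fitting of (aa|ii)", {
  for (name in c("h2", "h2o")) {
    scf <- scf_for(name, "hyb25")
    fn <- scf$functional
    M <- m_matrix(scf)
    delta <- hda_shift(M, scf$cache$metric, fn, "gh", scf$nocc)
    # brute force: fit each MO pair density, contract through the metric
    G <- scf$cache$metric
    no <- scf$nocc; nv <- length(scf$eps) - no
    X <- vapply(seq_len(no + nv), function(p) {
      fit_density(tcrossprod(scf$C[, p]), scf$cache$tc, G)$x
    }, numeric(scf$cache$aux$n))
    ref <- matrix(0, nv, no)
    for (i in seq_len(no)) for (a in seq_len(nv)) {
      ref[a, i] <- fn$c_F * as.numeric(t(X[, no + a]) %*% G$G %*% X[, i])
    }
    expect_lt(max(abs(delta - ref)), 1e-10)
  }
})

test_that("range-separated shift with alpha = 1, beta = 0 equals the
           global-hybrid shift", {
  scf <- hyb_scf()
  M <- m_matrix(scf)
  fn_rs <- functional_spec("rs-as-gh", c_F = 0.25, alpha = 1, beta = 0)
  d_gh <- hda_shift(M, scf$cache$metric, scf$functional, "gh", scf$nocc)
  d_rs <- hda_shift(M, scf$cache$metric, fn_rs, "rs", scf$nocc)
  expect_lt(max(abs(d_gh - d_rs)), 1e-12)
})

test_that("matrix-free operator agrees with explicit dense assembly", {
  scf <- hyb_scf()
  O <- O_for("h2o_hyb25", scf)
  M <- m_matrix(scf)
  delta <- hda_shift(M, scf$cache$metric, scf$functional, "gh", scf$nocc)
  op <- response_op(scf$eps, scf$nocc, delta, mo_three_center(scf), O)

  Om <- dense_omega(op)
  set.seed(8)
  for (r in 1:5) {
    t <- rnorm(op$n)
    expect_lt(max(abs(op$apply_rpa(t) - Om %*% t)), 1e-10)
  }
  At <- dense_tda(op)
  t <- rnorm(op$n)
  expect_lt(max(abs(op$apply_tda(t) - At %*% t)), 1e-10)

  # operator symmetry through random vector pairs
  set.seed(9)
  for (r in 1:20) {
    u <- rnorm(op$n); v <- rnorm(op$n)
    expect_equal(sum(u * op$apply_rpa(v)), sum(v * op$apply_rpa(u)),
                 tolerance = 1e-10)
  }
})

test_that("zero shift reduces the operator to the pure TD-ADFT form", {
  scf <- scf_for("h2o", "lda")
  O <- O_for("h2o_lda", scf)
  B3 <- mo_three_center(scf)
  op0 <- response_op(scf$eps, scf$nocc, 0, B3, O)
  nv <- length(scf$eps) - scf$nocc
  Dm <- outer(scf$eps[scf$nocc + seq_len(nv)], scf$eps[seq_len(scf$nocc)], "-")
  expect_equal(op0$D, as.vector(Dm), tolerance = 0)
})

test_that("non-positive shifted diagonals raise an instability error
           naming the pairs", {
  scf <- hyb_scf()
  nv <- length(scf$eps) - scf$nocc
  bad <- matrix(10, nv, scf$nocc)  # absurdly large shift
  expect_error(response_op(scf$eps, scf$nocc, bad, mo_three_center(scf),
                           O_for("h2o_hyb25", scf)),
               "instability.*->")
})

test_that("two-level system reproduces the closed-form excitation energy", {
  for (name in c("h2", "heh+")) {
    scf <- scf_for(name, "hyb25")
    res <- cached(paste0("exc_", name, "_hyb25_s"),
                  excite(scf, n_roots = 1, approximation = "hda",
                         method = "dense"))
    O <- O_for(paste0(name, "_hyb25"), scf)
    M <- m_matrix(scf)
    delta <- hda_shift(M, scf$cache$metric, scf$functional, "gh", scf$nocc)
    B3 <- mo_three_center(scf)
    K <- as.numeric(B3 %*% O %*% t(B3))
    de <- scf$eps[2] - scf$eps[1] - delta[1, 1]
    omega_ref <- sqrt(de * (de + 4 * K))
    expect_equal(res$energy[1], omega_ref, tolerance = 1e-12)
  }
})

test_that("Davidson matches dense diagonalization and is deterministic", {
  scf <- hyb_scf()
  r1 <- excite(scf, n_roots = 10, approximation = "hda", method = "davidson")
  r2 <- excite(scf, n_roots = 10, approximation = "hda", method = "dense")
  expect_lt(max(abs(r1$energy_ev - r2$energy_ev)), 1e-8)
  r3 <- excite(scf, n_roots = 10, approximation = "hda", method = "davidson")
  expect_identical(r1$energy, r3$energy)
  expect_identical(r1$F, r3$F)
  expect_error(excite(scf, n_roots = 99), "exceeds")
})

test_that("oscillator strengths are non-negative, with symmetry-forbidden
           roots dark", {
  scf <- scf_for("h2", "lda", basis_level = "sv")
  nov <- (length(scf$eps) - scf$nocc) * scf$nocc
  res <- cached("exc_h2sv_lda", excite(scf, n_roots = nov, method = "dense"))
  expect_true(all(res$f >= 0))
  # centrosymmetric H2: gerade -> gerade roots carry zero dipole strength
  expect_lt(min(res$f), 1e-10)
  expect_gt(max(res$f), 1e-3)
})

test_that("excitation energies and oscillator strengths are rotation
           invariant", {
  scf <- scf_for("h2o", "lda")
  res <- cached("exc_h2o_lda_10", excite(scf, n_roots = 10, method = "dense"))
  fx <- generate_fixture("h2o")
  R <- random_rotation(17)
  mol2 <- rotate_molecule(parse_xyz(fx$xyz), R, shift = c(0.5, -2, 1))
  scf2 <- run_scf(mol2, build_basis(mol2, fx$basis),
                  build_aux_basis(mol2, fx$aux), functional_preset("lda"))
  res2 <- excite(scf2, n_roots = 10, method = "dense")
  expect_lt(max(abs(res$energy - res2$energy)) * 27.2114, 1e-8)
  expect_lt(max(abs(res$f - res2$f)), 1e-10)
})

test_that("dynamic polarizability: parity, static limit, pole bracketing", {
  scf <- scf_for("h2o", "lda")
  nov <- (length(scf$eps) - scf$nocc) * scf$nocc
  res <- cached("exc_h2o_lda_full",
                excite(scf, n_roots = nov, method = "dense"))
  wg <- c(0, 0.05, 0.21, 0.33)
  pol <- dynamic_polarizability(res, wg)
  pol_neg <- dynamic_polarizability(res, -wg)
  expect_equal(pol$alpha_bar, pol_neg$alpha_bar, tolerance = 1e-12)

  # static value against an independent sum-over-states evaluation
  static_ref <- mean(vapply(1:3, function(q) {
    sum(2 * res$tdip[q, ]^2 / res$energy)
  }, numeric(1)))
  expect_equal(pol$alpha_bar[1], static_ref, tolerance = 1e-10)

  # each dipole-allowed root is bracketed by a sign change within 1e-4 Ha
  bright <- which(res$f > 1e-8)
  for (I in bright) {
    w <- res$energy[I]
    below <- dynamic_polarizability(res, w - 1e-4)$alpha_bar
    above <- dynamic_polarizability(res, w + 1e-4)$alpha_bar
    expect_lt(sign(above) * sign(below), 0)
  }

  expect_warning(dynamic_polarizability(res, res$energy[1]), "pole")
})

test_that("dense reference restricted to diagonal exchange reproduces HDA", {
  scf <- hyb_scf()
  for (spin in c("singlet", "triplet")) {
    O <- O_for("h2o_hyb25", scf, spin)
    for (mode in c("rpa", "tda")) {
      hda <- excite(scf, n_roots = 10, mode = mode, spin = spin,
                    approximation = "hda", method = "dense")
      restr <- reference_full_hybrid(scf, scf$functional, O, mode = mode,
                                     spin = spin, hda_restrict = TRUE)
      expect_lt(max(abs(hda$energy_ev - restr$energy_ev[1:10])), 1e-10)
    }
  }
})

test_that("reference with c_F = 0 reproduces the pure spectrum", {
  scf <- scf_for("h2o", "lda")
  O <- O_for("h2o_lda", scf)
  pure <- excite(scf, n_roots = 10, method = "dense")
  orc <- reference_full_hybrid(scf, scf$functional, O, mode = "rpa",
                               spin = "singlet")
  expect_lt(max(abs(pure$energy_ev - orc$energy_ev[1:10])), 1e-10)
})

test_that("exact-exchange four-center reference runs and stays close to the
           fitted-exchange reference", {
  scf <- hyb_scf()
  O <- O_for("h2o_hyb25", scf)
  fit <- reference_full_hybrid(scf, scf$functional, O, exchange = "fitted")
  exa <- reference_full_hybrid(scf, scf$functional, O, exchange = "exact")
  expect_lt(max(abs(fit$energy_ev - exa$energy_ev)), 0.2)
})
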