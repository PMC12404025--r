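# Integral engine: Boys function, one-electron matrices, Coulomb metric,
# three- and four-center ERIs, checked against closed forms and the
# independent quadrature oracle (helper-oracle.R).

test_that("Boys function closed forms and quadrature agreement", {
  expect_equal(boys(0, 0)[1], 1, tolerance = 0)
  n <- 0:10
  expect_equal(boys(10, 0), 1 / (2 * n + 1), tolerance = 1e-15)

  for (tv in c(1, 7.5)) {
    ref <- vapply(c(0, 3), function(nn) {
      stats::integrate(function(t) t^(2 * nn) * exp(-tv * t^2), 0, 1,
                       rel.tol = 1e-13, abs.tol = 1e-15)$value
    }, numeric(1))
    expect_equal(boys(3, tv)[c(1, 4)], ref, tolerance = 1e-12)
  }
  expect_error(boys(-1, 1), "non-negative")
  expect_error(boys(2, -0.1), "non-negative")
})

test_that("one-electron matrices: symmetry, normalization, dipole shift", {
  fx <- fixture_objs("lih")
  oe <- one_electron(fx$basis)
  expect_equal(oe$S, t(oe$S), tolerance = 1e-13)
  expect_equal(oe$T, t(oe$T), tolerance = 1e-13)
  expect_equal(oe$V, t(oe$V), tolerance = 1e-13)
  expect_equal(diag(oe$S), rep(1, fx$basis$n_ao), tolerance = 1e-10)

  # origin translation by Q shifts dipole matrices by -Q * S
  Q <- c(0.3, -0.7, 1.1)
  oe2 <- one_electron(fx$basis, origin = Q)
  for (d in 1:3) {
    expect_equal(oe2$dipole[[d]], oe$dipole[[d]] - Q[d] * oe$S,
                 tolerance = 1e-12)
  }
})

test_that("overlap elements match the independent quadrature oracle", {
  fx <- fixture_objs("lih")
  oe <- one_electron(fx$basis)
  b <- fx$basis
  # s-s across centers and p-s mixed
  s_ss <- oracle_overlap(b$shells[[1]], b$shells[[4]], 1, 1)
  expect_equal(oe$S[b$offsets[1] + 1, b$offsets[4] + 1], s_ss,
               tolerance = 1e-12)
  s_ps <- oracle_overlap(b$shells[[3]], b$shells[[4]], 3, 1)
  expect_equal(oe$S[b$offsets[3] + 3, b$offsets[4] + 1], s_ps,
               tolerance = 1e-12)
})

test_that("Coulomb metric matches quadrature and satisfies operator limits", {
  fx <- fixture_objs("h2")
  aux <- fx$aux
  G <- coulomb_metric(aux)
  expect_equal(G$G, t(G$G), tolerance = 1e-13)
  expect_true(is.finite(G$cond) && G$cond > 1)

  # two s-type Hermite functions against the 6-d quadrature oracle
  i <- which(aux$center == 1 & rowSums(aux$k) == 0)[1]
  j <- which(aux$center == 2 & rowSums(aux$k) == 0)[2]
  ref <- aux$norm[i] * aux$norm[j] *
    oracle_metric(aux$k[i, ], aux$zeta[i], aux$C[i, ],
                  aux$k[j, ], aux$zeta[j], aux$C[j, ])
  expect_equal(G$G[i, j], ref, tolerance = 1e-8 * abs(ref))

  # attenuated operator limits: erf -> 1 and erf -> 0
  Ginf <- coulomb_metric(aux, op_cam(0, 1, 1e6))
  expect_lt(max(abs(Ginf$G - G$G)), 1e-8)
  G0 <- coulomb_metric(aux, op_cam(0.37, 0.5, 1e-12))
  expect_lt(max(abs(G0$G - 0.37 * G$G)), 1e-8)
  # exact omega = 0 limit: the erf part vanishes identically
  G00 <- coulomb_metric(aux, op_cam(0.37, 0.5, 0))
  expect_equal(G00$G, 0.37 * G$G, tolerance = 1e-14)

  # linear dependence diagnostics
  dup <- "H 0\nS 1 1.0\n 1.0 1.0\nS 1 1.0\n 1.0000000001 1.0\n****"
  aux_bad <- build_aux_basis(fx$molecule, dup)
  expect_error(coulomb_metric(aux_bad), "linearly dependent")
})

test_that("three-center ERIs: closed form, oracle, symmetry, invariance", {
  fx <- fixture_objs("h2")
  tc <- cached("tc_h2", three_center(fx$basis, fx$aux))
  aux <- fx$aux
  sh <- fx$basis$shells[[1]]

  # all-s closed form 2 pi^{5/2} / (zp zc sqrt(zp + zc)) kappa F0(T)
  i <- which(aux$center == 1 & rowSums(aux$k) == 0 & aux$zeta == 7.2)[1]
  ref <- 0
  for (k in 1:3) for (l in 1:3) {
    zp <- sh$zeta[k] + sh$zeta[l]
    ref <- ref + sh$coef[k, 1] * sh$coef[l, 1] *
      2 * pi^2.5 / (zp * 7.2 * sqrt(zp + 7.2)) * boys(0, 0)[1]
  }
  expect_equal(tc[1, 1, i], aux$norm[i] * ref, tolerance = 1e-13)

  # symmetry in the AO pair
  expect_equal(tc, aperm(tc, c(2, 1, 3)), tolerance = 1e-13)

  # translation invariance of the full tensor
  mol2 <- molecule(fx$molecule$symbols,
                   fx$molecule$coords +
                     matrix(c(1.1, -0.4, 2.3), 2, 3, byrow = TRUE))
  fx_t <- generate_fixture("h2")
  b2 <- build_basis(mol2, fx_t$basis)
  a2 <- build_aux_basis(mol2, fx_t$aux)
  tc2 <- three_center(b2, a2)
  expect_lt(max(abs(tc2 - tc)), 1e-12)
})

test_that("general-shell three-center ERIs match the quadrature oracle", {
  fx <- fixture_objs("lih")
  b <- fx$basis; aux <- fx$aux
  tc <- cached("tc_lih", three_center(b, aux))
  tca <- cached("tca_lih", three_center(b, aux, op_erf(0.4)))
  cases <- list(           # (shell1, comp1, shell2, comp2, aux row)
    list(3L, 1L, 4L, 1L, which(aux$center == 1 & rowSums(aux$k) == 2)[3]),
    list(3L, 3L, 3L, 2L, which(aux$center == 2 & rowSums(aux$k) == 1)[2]),
    list(1L, 1L, 4L, 1L, which(aux$center == 1 & rowSums(aux$k) == 2)[6])
  )
  for (cs in cases) {
    r <- b$offsets[cs[[1]]] + cs[[2]]
    c <- b$offsets[cs[[3]]] + cs[[4]]
    g <- cs[[5]]
    ref <- aux$norm[g] *
      oracle_three_center(b$shells[[cs[[1]]]], b$shells[[cs[[3]]]],
                          cs[[2]], cs[[4]], aux$k[g, ], aux$zeta[g],
                          aux$C[g, ])
    expect_equal(tc[r, c, g], ref, tolerance = 1e-7 * max(abs(ref), 1e-4))
    refa <- aux$norm[g] *
      oracle_three_center(b$shells[[cs[[1]]]], b$shells[[cs[[3]]]],
                          cs[[2]], cs[[4]], aux$k[g, ], aux$zeta[g],
                          aux$C[g, ], omega = 0.4)
    expect_equal(tca[r, c, g], refa, tolerance = 1e-7 * max(abs(refa), 1e-4))
  }
})

test_that("attenuated all-s three-center integrals interpolate monotonically", {
  fx <- fixture_objs("h2")
  aux <- fx$aux
  i <- which(aux$center == 2 & rowSums(aux$k) == 0 & aux$zeta == 1.8)[1]
  alpha <- 0.2; beta <- 0.7
  plain <- three_center(fx$basis, fx$aux)[1, 2, i]
  vals <- vapply(c(1e-3, 0.1, 0.5, 1, 3, 10, 1e3), function(w) {
    three_center(fx$basis, fx$aux, op_cam(alpha, beta, w))[1, 2, i]
  }, numeric(1))
  expect_true(all(diff(vals * sign(plain)) > -1e-12))
  expect_gt(vals[1] * sign(plain), alpha * abs(plain) - 1e-6)
  expect_lt(vals[7] * sign(plain), (alpha + beta) * abs(plain) + 1e-6)
})

test_that("four-center ERIs: permutation symmetry, Schwarz bound, oracle", {
  fx <- fixture_objs("h2")
  eri <- cached("eri_h2", four_center(fx$basis))
  n <- dim(eri)[1]
  expect_equal(eri, aperm(eri, c(2, 1, 3, 4)), tolerance = 1e-13)
  expect_equal(eri, aperm(eri, c(1, 2, 4, 3)), tolerance = 1e-13)
  expect_equal(eri, aperm(eri, c(3, 4, 1, 2)), tolerance = 1e-13)

  for (mu in 1:n) for (nu in 1:n) for (s in 1:n) for (t in 1:n) {
    expect_lte(abs(eri[mu, nu, s, t]),
               sqrt(eri[mu, nu, mu, nu]) * sqrt(eri[s, t, s, t]) + 1e-12)
  }

  # (11|11) against the quadrature oracle
  b <- fx$basis
  ref <- oracle_four_center(b$shells[[1]], b$shells[[1]], b$shells[[1]],
                            b$shells[[1]], 1, 1, 1, 1)
  expect_equal(eri[1, 1, 1, 1], ref, tolerance = 1e-11)

  # alpha = 1, beta = 0 attenuated operator equals the plain path exactly
  eri_cam <- four_center(fx$basis, op_cam(1, 0, 0.5))
  expect_equal(eri_cam, eri, tolerance = 1e-13)

  # size guard refuses large systems before computing
  alk <- load_fixture("linear_alkane(18)")
  expect_gt(alk$basis$n_ao, 120L)
  expect_error(four_center(alk$basis), "guarded")
})

test_that("p-shell four-center ERIs match the quadrature oracle", {
  fx <- fixture_objs("lih")
  b <- fx$basis
  eri <- cached("eri_lih", four_center(b))
  o <- b$offsets
  cases <- list(list(3L, 3L, 4L, 1L, 3L, 1L, 3L, 2L),
                list(2L, 1L, 3L, 3L, 4L, 1L, 4L, 1L))
  for (cs in cases) {
    ref <- oracle_four_center(b$shells[[cs[[1]]]], b$shells[[cs[[3]]]],
                              b$shells[[cs[[5]]]], b$shells[[cs[[7]]]],
                              cs[[2]], cs[[4]], cs[[6]], cs[[8]])
    got <- eri[o[cs[[1]]] + cs[[2]], o[cs[[3]]] + cs[[4]],
               o[cs[[5]]] + cs[[6]], o[cs[[7]]] + cs[[8]]]
    expect_equal(got, ref, tolerance = 1e-7 * max(abs(ref), 1e-4))
  }
})

test_that("variational density fitting bound and monotone improvement", {
  fx <- fixture_objs("h2")
  eri <- cached("eri_h2", four_center(fx$basis))
  tc <- cached("tc_h2", three_center(fx$basis, fx$aux))
  G <- coulomb_metric(fx$aux)
  n <- fx$basis$n_ao
  em <- matrix(eri, n * n, n * n)
  set.seed(42)
  for (r in 1:5) {
    A <- matrix(rnorm(n * n), n)
    P <- A + t(A)
    exact <- as.numeric(t(as.vector(P)) %*% em %*% as.vector(P))
    fitted <- fit_density(P, tc, G)$self_repulsion
    expect_lte(fitted, exact + 1e-10)
  }

  # extending the auxiliary set never increases the fitting residual
  base_z <- c(7.2, 1.8, 0.45)
  extras <- c(3.6, 0.9, 0.225, 14.4, 0.1125, 28.8, 5.1, 2.55, 1.275, 0.64)
  set.seed(7)
  A <- matrix(rnorm(n * n), n); P <- A + t(A)
  exact <- as.numeric(t(as.vector(P)) %*% em %*% as.vector(P))
  res_prev <- Inf
  zs <- base_z
  for (add in extras) {
    zs <- c(zs, add)
    txt <- paste0("H 0\n", paste(sprintf("S 1 1.0\n %.10f 1.0", sort(zs, TRUE)),
                                 collapse = "\n"), "\n****")
    auxn <- build_aux_basis(fx$molecule, txt)
    tcn <- three_center(fx$basis, auxn)
    Gn <- coulomb_metric(auxn)
    res <- exact - fit_density(P, tcn, Gn)$self_repulsion
    expect_gte(res, -1e-9)
    expect_lte(res, res_prev + 1e-9)
    res_prev <- res
  }
})
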