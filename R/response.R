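# Linear-response stage: MO-basis three-center integrals, HDA shift
# vectors, the matrix-free response operator, the Davidson eigensolver,
# oscillator strengths, dynamic polarizabilities and the dense full-hybrid
# reference (exact-exchange oracle) used to measure the HDA error.
#
# Pair convention: occupied i = 1..nocc, virtual a = 1..nvir (orbital
# nocc + a). Occupied-virtual quantities are stored as (nvir x nocc)
# matrices whose column-major vectorization gives the pair order
# (a fastest), matching the rows of the MO three-center matrix.

pair_labels <- function(nocc, nvir) {
  as.vector(outer(seq_len(nvir), seq_len(nocc),
                  function(a, i) sprintf("%d->%d", i, nocc + a)))
}

#' Occupied-virtual MO three-center integrals
#'
#' Contracts the AO three-center tensor with the occupied and virtual MO
#' coefficients: rows are (a,i) pairs, columns auxiliary functions.
#'
#' @param scf An `scf_result`.
#' @param tc AO three-center tensor (defaults to the SCF cache).
#' @return Matrix `(nvir * nocc) x n_aux`.
#' @export
mo_three_center <- function(scf, tc = scf$cache$tc) {
  no <- scf$nocc
  nv <- length(scf$eps) - no
  Co <- scf$C[, seq_len(no), drop = FALSE]
  Cv <- scf$C[, no + seq_len(nv), drop = FALSE]
  naux <- dim(tc)[3]
  out <- matrix(0, nv * no, naux)
  for (k in seq_len(naux)) {
    out[, k] <- as.vector(crossprod(Cv, tc[, , k] %*% Co))
  }
  out
}

# full MO-transformed three-center tensor <pq||k> (small systems)
mo_three_center_full <- function(C, tc) {
  n <- ncol(C)
  naux <- dim(tc)[3]
  out <- array(0, c(n, n, naux))
  for (k in seq_len(naux)) {
    out[, , k] <- crossprod(C, tc[, , k] %*% C)
  }
  out
}

#' Diagonal-pair MO integral matrix M
#'
#' `M[p, k] = <pp || k>`: the three-center ERI of the density of canonical
#' MO p against auxiliary function k. Computed by contracting the per-MO
#' pair densities `Q^p = c_p c_p'` into the shell-pair integral loop, so
#' the AO tensor is never stored or transformed; the result is identical in
#' value to the naive double MO transformation.
#'
#' @param scf An `scf_result`.
#' @param operator Two-electron operator descriptor.
#' @return Matrix `n_mo x n_aux` of class `m_matrix`.
#' @export
m_matrix <- function(scf, operator = op_plain()) {
  basis <- scf$cache$basis
  aux <- scf$cache$aux
  C <- scf$C
  np <- ncol(C)
  M <- matrix(0, np, aux$n)
  three_center_map(basis, aux, operator, function(rows, cols, blk, ncA, ncB) {
    # Q[p, (cb-1)*ncA + ca] = C[rows[ca], p] * C[cols[cb], p]
    Q <- matrix(0, np, ncA * ncB)
    for (cb in seq_len(ncB)) {
      Q[, (cb - 1L) * ncA + seq_len(ncA)] <-
        t(C[rows, , drop = FALSE] * rep(C[cols[cb], ], each = length(rows)))
    }
    fac <- if (identical(rows, cols)) 1 else 2
    M <<- M + fac * (Q %*% blk)
  })
  structure(M, class = c("m_matrix", "matrix"))
}

# reference path: naive double MO transformation of the stored tensor
m_matrix_naive <- function(scf, tc, operator_tc = NULL) {
  use <- if (is.null(operator_tc)) tc else operator_tc
  n <- dim(use)[1]
  tcm <- matrix(use, n * n, dim(use)[3])
  t(vapply(seq_len(ncol(scf$C)), function(p) {
    Pp <- tcrossprod(scf$C[, p])
    as.vector(crossprod(tcm, as.vector(Pp)))
  }, numeric(dim(use)[3])))
}

#' HDA shift vector
#'
#' Diagonal exact-exchange shifts `Delta_ai` of the hybrid diagonal
#' approximation. For a global hybrid,
#' `Delta_ai = c_F sum_kl M_ak G^-1_kl M_il`; the range-separated variant
#' adds the beta-weighted attenuated term with its own metric and M matrix.
#'
#' @param M Plain-operator [m_matrix()].
#' @param metric Plain-operator `coulomb_metric`.
#' @param functional A `functional_spec`.
#' @param variant `"gh"` (Eq. of the global hybrid, ignores alpha/beta) or
#'   `"rs"` (CAM-weighted plain + attenuated terms).
#' @param nocc Number of occupied MOs.
#' @param M_att,metric_att Attenuated-operator M matrix and metric
#'   (required for `"rs"` with `beta != 0`).
#' @return `nvir x nocc` matrix of shifts (hartree).
#' @export
hda_shift <- function(M, metric, functional, variant = c("gh", "rs"),
                      nocc, M_att = NULL, metric_att = NULL) {
  variant <- match.arg(variant)
  np <- nrow(M)
  occ <- seq_len(nocc)
  vir <- setdiff(seq_len(np), occ)
  fit_cross <- function(Mmat, met) {
    # (pp|qq)_fitted for p virtual, q occupied
    Mmat[vir, , drop = FALSE] %*%
      metric_solve(met, t(Mmat[occ, , drop = FALSE]))
  }
  if (variant == "gh") {
    D <- functional$c_F * fit_cross(M, metric)
  } else {
    D <- 0
    if (functional$alpha != 0) D <- D + functional$alpha * fit_cross(M, metric)
    if (functional$beta != 0) {
      if (is.null(M_att) || is.null(metric_att)) {
        stop("hda_shift: range-separated variant with beta != 0 needs M_att and metric_att")
      }
      D <- D + functional$beta * fit_cross(M_att, metric_att)
    }
    D <- functional$c_F * D
  }
  matrix(D, length(vir), nocc)
}

#' Matrix-free response operator
#'
#' Packages the orbital-energy differences (minus HDA shifts), the MO
#' three-center integrals and the auxiliary coupling matrix into an object
#' whose RPA action is
#' `Omega t = D^2 t + 4 sqrt(D) B (O (B' (sqrt(D) t)))`
#' and whose TDA action is `A t = D t + 2 B (O (B' t))`, computed without
#' ever assembling the dense matrix (cost per apply
#' `O(nocc * nvir * n_aux)`).
#'
#' @param eps Orbital energies (hartree).
#' @param nocc Occupied count.
#' @param delta HDA shift matrix (`nvir x nocc`), or 0 for a pure
#'   functional.
#' @param B3 MO three-center matrix from [mo_three_center()].
#' @param O Auxiliary coupling matrix ([o_matrix()]).
#' @return Object of class `response_op` with elements `apply_rpa`,
#'   `apply_tda`, `diag_rpa`, `diag_tda`, `D`, `n`.
#' @export
response_op <- function(eps, nocc, delta, B3, O) {
  nv <- length(eps) - nocc
  Dm <- outer(eps[nocc + seq_len(nv)], eps[seq_len(nocc)], "-") - delta
  D <- as.vector(Dm)
  if (any(D <= 0)) {
    bad <- which(D <= 0)
    lab <- pair_labels(nocc, nv)[bad]
    stop("response instability: non-positive shifted orbital-energy difference for pair(s) ",
         paste(lab, collapse = ", "))
  }
  sD <- sqrt(D)
  BO <- B3 %*% O
  cdiag <- rowSums(BO * B3)     # diagonal of B O B'
  structure(list(
    D = D, B3 = B3, O = O, nocc = nocc, nvir = nv, n = nv * nocc,
    apply_rpa = function(t) {
      u <- crossprod(B3, sD * t)
      D^2 * t + 4 * sD * as.vector(BO %*% u)
    },
    apply_tda = function(t) {
      u <- crossprod(B3, t)
      D * t + 2 * as.vector(BO %*% u)
    },
    diag_rpa = D^2 + 4 * D * cdiag,
    diag_tda = D + 2 * cdiag
  ), class = "response_op")
}

# Davidson eigensolver for a symmetric positive operator given matrix-free.
# Deterministic start: unit vectors on the n_roots smallest diagonal
# entries (ties broken by pair index).
davidson <- function(applyfn, diagvec, n_roots, tol = 1e-6,
                     max_subspace = NULL, max_iter = 200L) {
  n <- length(diagvec)
  n_roots <- min(n_roots, n)
  if (is.null(max_subspace)) max_subspace <- min(n, 12L * n_roots)
  max_subspace <- min(max(max_subspace, 2L * n_roots), n)
  ord <- order(diagvec, seq_len(n))
  V <- matrix(0, n, n_roots)
  V[cbind(ord[seq_len(n_roots)], seq_len(n_roots))] <- 1
  AV <- apply_cols(applyfn, V)
  repeat_count <- 0L
  repeat {
    H <- crossprod(V, AV)
    H <- (H + t(H)) / 2
    es <- eigen(H, symmetric = TRUE)
    k <- ncol(V)
    sel <- order(es$values)[seq_len(n_roots)]
    theta <- es$values[sel]
    Y <- es$vectors[, sel, drop = FALSE]
    X <- V %*% Y
    R <- AV %*% Y - X %*% diag(theta, n_roots)
    rn <- sqrt(colSums(R^2))
    if (all(rn < tol) || k >= n) {
      return(list(values = theta, vectors = X, residuals = rn,
                  iterations = repeat_count))
    }
    repeat_count <- repeat_count + 1L
    if (repeat_count > max_iter) {
      stop(sprintf("davidson: no convergence after %d iterations (max residual %.3e)",
                   max_iter, max(rn)))
    }
    if (k + n_roots > max_subspace) {
      # collapse restart onto the current Ritz vectors
      V <- X
      AV <- AV %*% Y
      H <- crossprod(V, AV)
    }
    added <- 0L
    for (j in seq_len(n_roots)) {
      if (rn[j] < tol) next
      denom <- diagvec - theta[j]
      denom[abs(denom) < 1e-10] <- 1e-10
      t_new <- R[, j] / denom
      # orthogonalize twice against the subspace
      for (pass in 1:2) {
        t_new <- t_new - V %*% crossprod(V, t_new)
      }
      nrm <- sqrt(sum(t_new^2))
      if (nrm > 1e-10) {
        V <- cbind(V, t_new / nrm)
        added <- added + 1L
      }
    }
    if (added == 0L) {
      return(list(values = theta, vectors = X, residuals = rn,
                  iterations = repeat_count))
    }
    newcols <- (ncol(V) - added + 1L):ncol(V)
    AV <- cbind(AV, apply_cols(applyfn, V[, newcols, drop = FALSE]))
  }
}

apply_cols <- function(applyfn, V) {
  out <- matrix(0, nrow(V), ncol(V))
  for (j in seq_len(ncol(V))) out[, j] <- applyfn(V[, j])
  out
}

#' Solve for excitation energies
#'
#' Lowest eigenpairs of the response eigenproblem: RPA mode diagonalizes
#' the symmetrized `Omega` operator (`omega = sqrt(eigenvalue)`), TDA mode
#' the `A` matrix (`omega = eigenvalue`). Davidson by default; `"dense"`
#' explicitly assembles the operator by application to unit vectors and
#' diagonalizes it (fixture-scale oracle and full-spectrum mode).
#'
#' @param op A [response_op()].
#' @param n_roots Number of roots (capped at the pair-space dimension).
#' @param mode `"rpa"` or `"tda"`.
#' @param method `"davidson"` or `"dense"`.
#' @param options List: `tol` (Davidson residual, 1e-6), `max_subspace`
#'   (12 * n_roots), `max_iter` (200).
#' @return Object of class `excitation_result` with fields `energy`
#'   (hartree, ascending), `energy_ev`, `F` (eigenvectors, columns), `D`,
#'   `mode`, `spin` (filled by callers), `n_pairs`.
#' @export
solve_excitations <- function(op, n_roots, mode = c("rpa", "tda"),
                              method = c("davidson", "dense"),
                              options = list()) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  opt <- utils::modifyList(list(tol = 1e-6, max_subspace = NULL,
                                max_iter = 200L), options)
  n <- op$n
  if (n_roots > n) stop("solve_excitations: n_roots exceeds the occupied-virtual space")
  applyfn <- if (mode == "rpa") op$apply_rpa else op$apply_tda
  diagvec <- if (mode == "rpa") op$diag_rpa else op$diag_tda
  if (method == "davidson") {
    sol <- davidson(applyfn, diagvec, n_roots, tol = opt$tol,
                    max_subspace = opt$max_subspace, max_iter = opt$max_iter)
    vals <- sol$values; vecs <- sol$vectors
  } else {
    Mfull <- apply_cols(applyfn, diag(n))
    es <- eigen((Mfull + t(Mfull)) / 2, symmetric = TRUE)
    sel <- order(es$values)[seq_len(n_roots)]
    vals <- es$values[sel]; vecs <- es$vectors[, sel, drop = FALSE]
  }
  if (any(vals < 0)) {
    stop("solve_excitations: negative eigenvalue (response instability)")
  }
  omega <- if (mode == "rpa") sqrt(vals) else vals
  ord <- order(omega)
  omega <- omega[ord]; vecs <- vecs[, ord, drop = FALSE]
  # fix eigenvector sign deterministically (largest element positive)
  for (j in seq_len(ncol(vecs))) {
    imax <- which.max(abs(vecs[, j]))
    if (vecs[imax, j] < 0) vecs[, j] <- -vecs[, j]
  }
  structure(list(energy = omega, energy_ev = omega * HARTREE2EV,
                 F = vecs, D = op$D, mode = mode, spin = NA_character_,
                 approximation = NA_character_, n_pairs = n,
                 nocc = op$nocc, nvir = op$nvir),
            class = "excitation_result")
}

#' @export
print.excitation_result <- function(x, ...) {
  cat(sprintf("excitation_result: %d roots (%s%s)\n", length(x$energy),
              toupper(x$mode),
              if (!is.na(x$spin)) paste0(", ", x$spin) else ""))
  f <- if (!is.null(x$f)) sprintf("%8.5f", x$f) else rep("      --", length(x$energy))
  lab <- pair_labels(x$nocc, x$nvir)
  for (I in seq_along(x$energy)) {
    dom <- which.max(abs(x$F[, I]))
    cat(sprintf("  %2d  %10.5f eV   f = %s   %s (%.2f)\n", I,
                x$energy_ev[I], f[I], lab[dom], x$F[dom, I]^2))
  }
  invisible(x)
}

#' Oscillator strengths
#'
#' Length-gauge oscillator strengths from the response eigenvectors. For
#' RPA the transition dipole is
#' `d_I = sum_ai mu_ai sqrt(2 D_ai / omega_I) F_ai`; for TDA
#' `d_I = sqrt(2) sum_ai mu_ai X_ai`. `f_I = (2/3) omega_I |d_I|^2`.
#'
#' @param exc An `excitation_result`.
#' @param mu_pairs `n_pairs x 3` matrix of occupied-virtual transition
#'   dipole integrals (see [mo_dipole_pairs()]).
#' @return The `excitation_result` with `f` (oscillator strengths) and
#'   `tdip` (`3 x n_roots` transition dipoles) added.
#' @export
oscillator_strengths <- function(exc, mu_pairs) {
  if (any(exc$energy <= 0)) stop("oscillator_strengths: non-positive excitation energy")
  nr <- length(exc$energy)
  tdip <- matrix(0, 3, nr)
  for (I in seq_len(nr)) {
    wgt <- if (exc$mode == "rpa") sqrt(2 * exc$D / exc$energy[I]) else sqrt(2)
    tdip[, I] <- crossprod(mu_pairs, wgt * exc$F[, I])
  }
  exc$tdip <- tdip
  exc$f <- (2 / 3) * exc$energy * colSums(tdip^2)
  exc
}

#' Occupied-virtual transition dipole integrals
#'
#' @param scf An `scf_result`.
#' @return `(nvir * nocc) x 3` matrix, rows in pair order.
#' @export
mo_dipole_pairs <- function(scf) {
  no <- scf$nocc
  nv <- length(scf$eps) - no
  Co <- scf$C[, seq_len(no), drop = FALSE]
  Cv <- scf$C[, no + seq_len(nv), drop = FALSE]
  out <- vapply(1:3, function(q) {
    as.vector(crossprod(Cv, scf$cache$one_electron$dipole[[q]] %*% Co))
  }, numeric(nv * no))
  matrix(out, nrow = nv * no, ncol = 3)
}

#' Average dynamic polarizability
#'
#' Sum-over-states polarizability
#' `alpha_qq(w) = sum_I 2 omega_I d_qI^2 / (omega_I^2 - w^2)`, averaged over
#' the three Cartesian components. Its poles coincide with the excitation
#' energies. Frequencies within 1e-8 hartree of a pole are skipped with a
#' warning.
#'
#' @param exc An `excitation_result` carrying transition dipoles (run
#'   [oscillator_strengths()] first), ideally the full spectrum.
#' @param omega_grid Frequencies (hartree).
#' @return Data frame with `omega` and `alpha_bar` (atomic units).
#' @export
dynamic_polarizability <- function(exc, omega_grid) {
  if (is.null(exc$tdip)) stop("dynamic_polarizability: run oscillator_strengths() first")
  keep <- vapply(omega_grid, function(wq) {
    all(abs(exc$energy - abs(wq)) > 1e-8)
  }, logical(1))
  if (!all(keep)) {
    warning(sprintf("%d frequency point(s) within 1e-8 of a pole skipped",
                    sum(!keep)))
  }
  wg <- omega_grid[keep]
  ab <- vapply(wg, function(wq) {
    sum(exc$tdip^2 * rep(2 * exc$energy / (exc$energy^2 - wq^2),
                         each = 3)) / 3
  }, numeric(1))
  data.frame(omega = wg, alpha_bar = ab)
}

#' Dense full-hybrid reference (exact-exchange oracle)
#'
#' Assembles the full (non-diagonal) hybrid response matrices
#' `A + B = D + 4 B O B' - c_F [K_abij + K_ajbi]` and
#' `A - B = D - c_F [K_abij - K_ajbi]` with every exchange element
#' included, and solves the symplectic eigenproblem
#' `(A-B)^{1/2} (A+B) (A-B)^{1/2} F = omega^2 F`. Exchange ERIs are
#' density-fitted through the metric (the same fitting the shifts use) by
#' default, or exact four-center MO ERIs on request. Setting
#' `hda_restrict = TRUE` keeps only the diagonal `(aa|ii)` elements, which
#' reproduces the HDA operator by construction.
#'
#' @param scf An `scf_result`.
#' @param functional A `functional_spec`.
#' @param O Auxiliary coupling matrix for the requested spin channel
#'   (singlet: Hartree + kernel; triplet: kernel only).
#' @param mode `"rpa"` or `"tda"`.
#' @param spin Spin channel label (coupling choice is carried by `O`).
#' @param exchange `"fitted"` or `"exact"`.
#' @param hda_restrict Zero all off-diagonal exchange elements.
#' @return An `excitation_result` with all roots.
#' @export
reference_full_hybrid <- function(scf, functional, O, mode = c("rpa", "tda"),
                                  spin = c("singlet", "triplet"),
                                  exchange = c("fitted", "exact"),
                                  hda_restrict = FALSE) {
  mode <- match.arg(mode)
  spin <- match.arg(spin)
  exchange <- match.arg(exchange)
  no <- scf$nocc
  nv <- length(scf$eps) - no
  n <- length(scf$eps)
  nov <- no * nv
  occ <- seq_len(no); vir <- no + seq_len(nv)
  Dvec <- as.vector(outer(scf$eps[vir], scf$eps[occ], "-"))

  # coupling term
  B3 <- mo_three_center(scf)
  coup <- B3 %*% O %*% t(B3)

  # MO ERIs (pq|rs) under an operator, fitted or exact
  mo_eri <- function(operator) {
    if (exchange == "fitted") {
      met <- coulomb_metric(scf$cache$aux, operator)
      tc_op <- if (operator$type == "plain") scf$cache$tc else
        three_center(scf$cache$basis, scf$cache$aux, operator)
      Tmo <- mo_three_center_full(scf$C, tc_op)
      U <- matrix(Tmo, n * n, dim(Tmo)[3])
      # fitted (pq|rs) = U G^-1 U' in this operator's own metric
      array(U %*% metric_solve(met, t(U)), c(n, n, n, n))
    } else {
      eri <- if (operator$type == "plain") {
        if (!is.null(scf$cache$eri_plain)) scf$cache$eri_plain
        else four_center(scf$cache$basis, op_plain())
      } else four_center(scf$cache$basis, operator)
      m <- matrix(eri, n * n, n * n)
      Cp <- kronecker(scf$C, scf$C)   # columns index (p,q) pairs
      array(crossprod(Cp, m %*% Cp), c(n, n, n, n))
    }
  }

  K_ab_ij <- matrix(0, nov, nov)   # (ab|ij)-type
  K_aj_bi <- matrix(0, nov, nov)   # (aj|bi)-type
  if (functional$c_F > 0) {
    ops <- list()
    if (functional$alpha != 0) ops <- c(ops, list(list(w = functional$alpha, op = op_plain())))
    if (functional$beta != 0) {
      ops <- c(ops, list(list(w = functional$beta, op = op_erf(functional$rs_omega))))
    }
    for (item in ops) {
      E4 <- mo_eri(item$op)
      for (i in seq_len(no)) for (a in seq_len(nv)) {
        ai <- (i - 1L) * nv + a
        for (j in seq_len(no)) for (b in seq_len(nv)) {
          bj <- (j - 1L) * nv + b
          K_ab_ij[ai, bj] <- K_ab_ij[ai, bj] +
            item$w * E4[no + a, no + b, i, j]
          K_aj_bi[ai, bj] <- K_aj_bi[ai, bj] +
            item$w * E4[no + a, j, no + b, i]
        }
      }
    }
    K_ab_ij <- functional$c_F * K_ab_ij
    K_aj_bi <- functional$c_F * K_aj_bi
    if (hda_restrict) {
      K_ab_ij <- diag(diag(K_ab_ij), nov)
      K_aj_bi <- matrix(0, nov, nov)
    }
  }

  if (mode == "tda") {
    A <- diag(Dvec, nov) + 2 * coup - K_ab_ij
    es <- eigen((A + t(A)) / 2, symmetric = TRUE)
    ord <- order(es$values)
    omega <- es$values[ord]
    vecs <- es$vectors[, ord, drop = FALSE]
    if (any(omega < 0)) stop("reference_full_hybrid: TDA instability (negative root)")
    Dfull <- Dvec
  } else {
    ApB <- diag(Dvec, nov) + 4 * coup - K_ab_ij - K_aj_bi
    AmB <- diag(Dvec, nov) - K_ab_ij + K_aj_bi
    esm <- eigen((AmB + t(AmB)) / 2, symmetric = TRUE)
    if (min(esm$values) <= 0) {
      stop("reference_full_hybrid: A - B not positive definite (instability)")
    }
    Sh <- esm$vectors %*% (sqrt(esm$values) * t(esm$vectors))
    Om <- Sh %*% ApB %*% Sh
    es <- eigen((Om + t(Om)) / 2, symmetric = TRUE)
    ord <- order(es$values)
    if (es$values[ord][1] < 0) stop("reference_full_hybrid: negative omega^2 (instability)")
    omega <- sqrt(pmax(es$values[ord], 0))
    vecs <- es$vectors[, ord, drop = FALSE]
    attr(vecs, "AmB_half") <- Sh
    Dfull <- Dvec
  }
  for (j in seq_len(ncol(vecs))) {
    imax <- which.max(abs(vecs[, j]))
    if (vecs[imax, j] < 0) vecs[, j] <- -vecs[, j]
  }
  res <- structure(list(energy = omega, energy_ev = omega * HARTREE2EV,
                        F = vecs, D = Dfull, mode = mode, spin = spin,
                        approximation = if (hda_restrict) "hda-restricted" else "oracle",
                        n_pairs = nov, nocc = no, nvir = nv),
                   class = "excitation_result")
  if (mode == "rpa") res$AmB_half <- attr(vecs, "AmB_half")
  res
}

#' Oscillator strengths for the dense reference
#'
#' Same length-gauge assignment as [oscillator_strengths()], with the full
#' `(A - B)^{1/2}` weighting instead of its diagonal approximation.
#'
#' @param exc Result of [reference_full_hybrid()] in RPA mode.
#' @param mu_pairs From [mo_dipole_pairs()].
#' @return `exc` with `f` and `tdip` added.
#' @export
oscillator_strengths_full <- function(exc, mu_pairs) {
  if (is.null(exc$AmB_half)) return(oscillator_strengths(exc, mu_pairs))
  nr <- length(exc$energy)
  tdip <- matrix(0, 3, nr)
  for (I in seq_len(nr)) {
    wvec <- sqrt(2 / exc$energy[I]) * (exc$AmB_half %*% exc$F[, I])
    tdip[, I] <- crossprod(mu_pairs, wvec)
  }
  exc$tdip <- tdip
  exc$f <- (2 / 3) * exc$energy * colSums(tdip^2)
  exc
}
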