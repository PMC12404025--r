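# Restricted Kohn-Sham SCF host with density-fitted Coulomb term, grid
# exchange-correlation and (optionally attenuated) Fock exchange from
# conventional four-center ERIs.

#' Variational density fitting
#'
#' Solves the Coulomb-metric least-squares problem for the auxiliary
#' expansion coefficients of an AO density: `x = G^-1 J` with
#' `J_k = sum_{mu nu} P_{mu nu} <mu nu || k>`.
#'
#' @param P AO density matrix.
#' @param tc Three-center tensor from [three_center()] (plain operator).
#' @param metric Plain-operator `coulomb_metric`.
#' @return List with coefficients `x`, the Coulomb vector `J` and the
#'   fitted self-repulsion `(rho_tilde | rho_tilde) = x' G x`.
#' @export
fit_density <- function(P, tc, metric) {
  n <- dim(tc)[1]
  tcm <- matrix(tc, n * n, dim(tc)[3])
  J <- as.vector(crossprod(tcm, as.vector(P)))
  x <- as.vector(metric_solve(metric, J))
  list(x = x, J = J, self_repulsion = sum(x * (metric$G %*% x)))
}

nuclear_repulsion <- function(mol) {
  n <- nrow(mol$coords)
  if (n < 2L) return(0)
  e <- 0
  for (i in 1:(n - 1L)) {
    for (j in (i + 1L):n) {
      e <- e + mol$Z[i] * mol$Z[j] / sqrt(sum((mol$coords[i, ] - mol$coords[j, ])^2))
    }
  }
  e
}

#' Restricted Kohn-Sham SCF
#'
#' Closed-shell SCF with the Fock operator
#' `T + V + J[fitted] + V_xc + Fock exchange`, where the Coulomb term uses
#' variational density fitting in the auxiliary set, the local
#' exchange-correlation part is the functional's short-range complement
#' evaluated on the molecular grid, and Fock exchange (fraction `c_F`,
#' CAM-split by `alpha`/`beta`) is built from conventional four-center
#' ERIs. DIIS-accelerated, core-Hamiltonian initial guess.
#'
#' @param mol A [molecule] (even electron count).
#' @param basis A `basis_set`.
#' @param aux An `aux_basis`.
#' @param functional A `functional_spec`.
#' @param grid A `molecular_grid`, or `NULL` to build one at
#'   `options$grid_level` (omitted entirely for pure Hartree-Fock, i.e.
#'   `c_F = 1`, `alpha = 1`, `beta = 0`, no correlation).
#' @param options List: `e_tol` (1e-8 Ha), `p_tol` (density RMS 1e-6),
#'   `diis_depth` (8), `max_iter` (200), `grid_level` ("default"),
#'   `coulomb` ("fitted" or "exact").
#' @return Object of class `scf_result`: MO coefficients `C`, orbital
#'   energies `eps` (hartree), occupied count `nocc`, total `energy`,
#'   fitting coefficients `x`, density `P`, convergence history, and a
#'   `cache` with the integral objects for reuse by the response stage.
#' @export
run_scf <- function(mol, basis, aux, functional, grid = NULL,
                    options = list()) {
  opt <- utils::modifyList(list(e_tol = 1e-8, p_tol = 1e-6, diis_depth = 8L,
                                max_iter = 200L, grid_level = "default",
                                coulomb = "fitted"), options)
  if (mol$n_electrons %% 2L != 0L) {
    stop("run_scf: odd electron count; only closed-shell systems are supported")
  }
  nocc <- mol$n_electrons %/% 2L
  n <- basis$n_ao
  if (nocc > n) stop("run_scf: more occupied orbitals than basis functions")

  oe <- one_electron(basis)
  H <- oe$T + oe$V
  metric <- coulomb_metric(aux, op_plain())
  tc <- three_center(basis, aux, op_plain())
  tcm <- matrix(tc, n * n, aux$n)

  pure_hf <- functional$c_F == 1 && functional$alpha == 1 &&
    functional$beta == 0 && functional$correlation == "none"
  need_xc <- !pure_hf
  if (need_xc && is.null(grid)) grid <- build_grid(mol, opt$grid_level)
  if (need_xc) {
    Phi <- eval_basis(basis, grid$points)
    w <- grid$weights
  }
  eri_p <- NULL; eri_b <- NULL
  if (functional$c_F > 0) {
    if (functional$alpha != 0 || opt$coulomb == "exact") {
      eri_p <- four_center(basis, op_plain())
    }
    if (functional$beta != 0) {
      eri_b <- four_center(basis, op_erf(functional$rs_omega))
    }
  } else if (opt$coulomb == "exact") {
    eri_p <- four_center(basis, op_plain())
  }

  # symmetric orthogonalizer
  se <- eigen(oe$S, symmetric = TRUE)
  if (min(se$values) < 1e-10) stop("run_scf: near-singular overlap matrix")
  X <- se$vectors %*% diag(1 / sqrt(se$values)) %*% t(se$vectors)

  exch_K <- function(P) {
    K <- 0
    if (functional$c_F > 0) {
      if (functional$alpha != 0) {
        K <- K + functional$alpha *
          apply(eri_p, c(1, 3), function(sl) sum(sl * P))
      }
      if (functional$beta != 0) {
        K <- K + functional$beta *
          apply(eri_b, c(1, 3), function(sl) sum(sl * P))
      }
      K <- functional$c_F * K
    }
    K
  }

  diag_fock <- function(F) {
    Fp <- t(X) %*% F %*% X
    ev <- eigen((Fp + t(Fp)) / 2, symmetric = TRUE)
    ord <- order(ev$values)        # ascending: Aufbau occupation
    C <- X %*% ev$vectors[, ord, drop = FALSE]
    list(C = C, eps = ev$values[ord])
  }

  check_aufbau <- function(eps) {
    if (nocc < n && abs(eps[nocc + 1L] - eps[nocc]) < 1e-8) {
      stop("run_scf: degenerate HOMO at Aufbau filling; fractional occupation unsupported")
    }
  }

  gs <- diag_fock(H)
  check_aufbau(gs$eps)
  C <- gs$C
  P <- 2 * tcrossprod(C[, seq_len(nocc), drop = FALSE])

  enuc <- nuclear_repulsion(mol)
  e_old <- Inf
  history <- numeric(0)
  diis_F <- list(); diis_E <- list()
  fit <- NULL; eps <- gs$eps
  converged <- FALSE
  dP <- Inf

  for (iter in seq_len(opt$max_iter)) {
    fit <- fit_density(P, tc, metric)
    if (opt$coulomb == "exact") {
      Jmat <- apply(eri_p, c(1, 2), function(sl) sum(sl * P))
      e_coul <- 0.5 * sum(P * Jmat)
    } else {
      Jmat <- matrix(tcm %*% fit$x, n, n)
      e_coul <- sum(fit$x * fit$J) - 0.5 * fit$self_repulsion
    }
    F <- H + Jmat
    e_xc <- 0
    if (need_xc) {
      rho <- rowSums((Phi %*% P) * Phi)
      ep <- xc_energy_potential(rho, functional)
      e_xc <- sum(w * ep$e)
      F <- F + crossprod(Phi, (w * ep$v) * Phi)
    }
    e_k <- 0
    if (functional$c_F > 0) {
      K <- exch_K(P)
      F <- F - 0.5 * K
      e_k <- -0.25 * sum(P * K)
    }
    energy <- sum(P * H) + e_coul + e_xc + e_k + enuc
    history <- c(history, energy)

    # DIIS on the orthonormal-basis commutator
    err <- t(X) %*% (F %*% P %*% oe$S - oe$S %*% P %*% F) %*% X
    diis_F[[length(diis_F) + 1L]] <- F
    diis_E[[length(diis_E) + 1L]] <- err
    if (length(diis_F) > opt$diis_depth) {
      diis_F <- diis_F[-1]; diis_E <- diis_E[-1]
    }
    m <- length(diis_F)
    Fuse <- F
    if (m >= 2L) {
      B <- matrix(0, m + 1L, m + 1L)
      for (i in seq_len(m)) for (j in seq_len(m)) {
        B[i, j] <- sum(diis_E[[i]] * diis_E[[j]])
      }
      B[m + 1L, seq_len(m)] <- -1; B[seq_len(m), m + 1L] <- -1
      rhs <- c(numeric(m), -1)
      cf <- tryCatch(solve(B, rhs)[seq_len(m)], error = function(e) NULL)
      if (!is.null(cf) && all(is.finite(cf))) {
        Fuse <- Reduce(`+`, Map(`*`, diis_F, cf))
      }
    }
    sol <- diag_fock(Fuse)
    C <- sol$C; eps <- sol$eps
    check_aufbau(eps)
    P_new <- 2 * tcrossprod(C[, seq_len(nocc), drop = FALSE])
    dP <- sqrt(mean((P_new - P)^2))
    dE <- abs(energy - e_old)
    P <- P_new
    e_old <- energy
    if (iter > 1L && dE < opt$e_tol && dP < opt$p_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop(sprintf("run_scf: no convergence in %d iterations (dE = %.3e, dP rms = %.3e)",
                 opt$max_iter, e_old - history[length(history) - 1L], dP))
  }
  fit <- fit_density(P, tc, metric)
  structure(list(
    C = C, eps = eps, nocc = nocc, energy = e_old, x = fit$x, P = P,
    functional = functional, history = history, iterations = iter,
    molecule = mol,
    cache = list(basis = basis, aux = aux, metric = metric, tc = tc,
                 one_electron = oe, grid = grid,
                 eri_plain = eri_p, eri_erf = eri_b)
  ), class = "scf_result")
}

#' @export
print.scf_result <- function(x, ...) {
  cat(sprintf("scf_result: E = %.10f Ha (%d iterations, functional %s)\n",
              x$energy, x$iterations, x$functional$name))
  cat(sprintf("  %d occupied / %d virtual MOs; HOMO %.6f, LUMO %s Ha\n",
              x$nocc, length(x$eps) - x$nocc, x$eps[x$nocc],
              if (length(x$eps) > x$nocc) sprintf("%.6f", x$eps[x$nocc + 1]) else "n/a"))
  invisible(x)
}

#' Write / read an SCF checkpoint
#'
#' Plain-text checkpoint of the SCF result (coefficients, energies,
#' occupation, fitting coefficients) so response runs can restart without
#' redoing the SCF. Stored as dput-formatted R data.
#'
#' @param scf An `scf_result`.
#' @param path File path.
#' @return `read_checkpoint` returns the stored list (without the integral
#'   cache; integrals are rebuilt on demand).
#' @export
write_checkpoint <- function(scf, path) {
  keep <- scf[c("C", "eps", "nocc", "energy", "x")]
  keep$functional <- unclass(scf$functional)
  dput(keep, file = path,
       control = c("keepInteger", "showAttributes", "digits17"))
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  obj <- dget(path)
  obj$functional <- structure(obj$functional, class = "functional_spec")
  obj
}
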