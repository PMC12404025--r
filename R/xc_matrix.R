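# Auxiliary-function kernel matrices <m|f|n> and the response coupling
# matrices O = G^-1 + G^-1 K G^-1 in auxiliary-function space.

#' Kernel matrix over auxiliary functions
#'
#' Quadrature of `<m| f |n> = sum_points w * m(r) * f(r) * n(r)` for a
#' pointwise kernel `f` evaluated on the grid. Points are processed in
#' batches to bound memory; the result is exactly symmetric by
#' construction (crossproducts of sign-split weighted values).
#'
#' @param aux An `aux_basis`.
#' @param grid A `molecular_grid`.
#' @param fvals Kernel values at the grid points (length `n_points`).
#' @param batch Points per evaluation batch.
#' @return Symmetric `n_aux x n_aux` matrix.
#' @export
kernel_matrix <- function(aux, grid, fvals, batch = 20000L) {
  n <- length(grid$weights)
  stopifnot(length(fvals) == n)
  K <- matrix(0, aux$n, aux$n)
  wf <- grid$weights * fvals
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    A <- eval_aux(aux, grid$points[idx, , drop = FALSE])
    w <- wf[idx]
    pos <- w > 0
    if (any(pos)) K <- K + crossprod(A[pos, , drop = FALSE] * sqrt(w[pos]))
    if (any(!pos)) K <- K - crossprod(A[!pos, , drop = FALSE] * sqrt(-w[!pos]))
  }
  K
}

#' Response coupling matrix in auxiliary space
#'
#' Builds `O = G^-1 + G^-1 K G^-1` (or the kernel-only variant without the
#' Hartree term, used for the triplet channel) from a Coulomb metric and an
#' exchange-correlation kernel matrix. The three spec variants differ only
#' in which kernel matrix `K` is supplied:
#' pure (`f_xc`), global hybrid (`f_xc - c_F f_x`) and range separated
#' (`f_x^SR + f_c`); use [o_matrix()] for the variant-aware front end.
#'
#' @param metric A `coulomb_metric` (plain operator).
#' @param K Kernel matrix from [kernel_matrix()], or `NULL` for a zero
#'   kernel.
#' @param hartree Include the `G^-1` Hartree term (FALSE for the triplet
#'   coupling).
#' @return Symmetric `n_aux x n_aux` matrix.
#' @export
build_O <- function(metric, K = NULL, hartree = TRUE) {
  Ginv_K_Ginv <- if (is.null(K)) 0 else {
    GK <- metric_solve(metric, K)          # G^-1 K
    t(metric_solve(metric, t(GK)))         # G^-1 K G^-1 (symmetric K)
  }
  O <- if (hartree) metric_solve(metric, diag(metric$n)) + Ginv_K_Ginv
       else Ginv_K_Ginv
  (O + t(O)) / 2
}

#' Variant-aware O matrix construction
#'
#' Evaluates the functional's response kernel at the fitted density on the
#' grid and assembles the coupling matrix. The `variant` must be consistent
#' with the functional: `"rs"` requires a positive `rs_omega`, `"gh"`
#' expects no range separation.
#'
#' @param variant `"pure"`, `"gh"` or `"rs"`.
#' @param metric Plain-operator `coulomb_metric`.
#' @param aux An `aux_basis`.
#' @param grid A `molecular_grid`.
#' @param rho_fit Fitted density values at the grid points.
#' @param functional A `functional_spec`.
#' @param spin `"singlet"` or `"triplet"` response channel.
#' @param rho_cut Density screening threshold: grid points where the fitted
#'   density falls below this value contribute nothing to the kernel
#'   matrix. The local kernel diverges as `rho^(-2/3)` (exchange) and
#'   `1/rho` (triplet correlation) for vanishing density, while the true
#'   integrand decays Gaussian-fast there; screening removes the
#'   numerically ill-defined tail points (the fitted density may even dip
#'   slightly negative far from the molecule).
#' @return Symmetric coupling matrix (Hartree term included for singlet,
#'   kernel-only for triplet).
#' @export
o_matrix <- function(variant = c("pure", "gh", "rs"), metric, aux, grid,
                     rho_fit, functional, spin = c("singlet", "triplet"),
                     rho_cut = 1e-8) {
  variant <- match.arg(variant)
  spin <- match.arg(spin)
  if (variant == "rs" && (functional$beta != 0 && functional$rs_omega <= 0)) {
    stop("o_matrix: range-separated variant requires rs_omega > 0")
  }
  if (variant == "pure" && functional$c_F != 0) {
    stop("o_matrix: pure variant requires c_F = 0")
  }
  if (variant == "gh" && (functional$beta != 0)) {
    stop("o_matrix: global-hybrid variant requires beta = 0; use variant 'rs'")
  }
  f <- numeric(length(rho_fit))
  sel <- rho_fit >= rho_cut
  f[sel] <- xc_kernel_values(rho_fit[sel], functional, spin = spin)
  K <- kernel_matrix(aux, grid, f)
  build_O(metric, K, hartree = (spin == "singlet"))
}
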