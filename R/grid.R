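# Becke-partitioned molecular quadrature grid.
#
# Radial: Gauss-Chebyshev (second kind) points mapped onto [0, Inf) with the
# Becke transformation r = R_m (1+x)/(1-x). Angular: a Gauss-Legendre
# (cos theta) x uniform (phi) product grid, exact for spherical harmonics up
# to degree min(2*n_theta - 1, n_phi - 1). Atomic grids are combined with
# Becke's fuzzy-cell partition (three smoothing iterations, no atomic size
# adjustment).

# midpoint radius (bohr) of the Becke radial map, loosely element dependent
.becke_rm <- function(Z) {
  rm <- c(0.8, 0.9, 1.8, 1.4, 1.3, 1.1, 0.9, 0.9, 0.9, 0.9)
  ifelse(Z <= length(rm), rm[Z], 1.4)
}

.GRID_LEVELS <- list(
  coarse  = list(nr = 35L, ntheta = 14L, nphi = 28L),
  default = list(nr = 60L, ntheta = 20L, nphi = 40L),
  fine    = list(nr = 90L, ntheta = 28L, nphi = 56L)
)

#' Build a molecular quadrature grid
#'
#' Atom-centered radial x angular grids with Becke partition weights. The
#' grid follows the atoms, so integrals computed on it are translation and
#' rotation invariant up to quadrature accuracy.
#'
#' @param mol A [molecule].
#' @param level One of `"coarse"`, `"default"`, `"fine"`.
#' @return Object of class `molecular_grid` with `points` (`n x 3`, bohr),
#'   `weights` (including the partition factor), `level` and the per-atom
#'   scheme descriptor.
#' @export
build_grid <- function(mol, level = "default") {
  level <- match.arg(level, names(.GRID_LEVELS))
  sc <- .GRID_LEVELS[[level]]
  natom <- nrow(mol$coords)

  # angular product grid on the unit sphere, attached to a deterministic
  # molecule-fixed frame so that quadrature (and everything downstream) is
  # exactly equivariant under rigid rotation of the molecule
  Fr <- molecular_frame(mol)
  gl <- pracma::gaussLegendre(sc$ntheta, -1, 1)
  phi <- 2 * pi * (seq_len(sc$nphi) - 0.5) / sc$nphi
  ct <- rep(gl$x, each = sc$nphi)
  st <- sqrt(pmax(0, 1 - ct^2))
  ang <- cbind(st * cos(phi), st * sin(phi), ct) %*% t(Fr)
  wang <- rep(gl$w, each = sc$nphi) * (2 * pi / sc$nphi)

  # radial Gauss-Chebyshev second kind
  i <- seq_len(sc$nr)
  x <- cos(i * pi / (sc$nr + 1))
  wgc <- pi / (sc$nr + 1) * sin(i * pi / (sc$nr + 1))^2

  pts <- list(); wts <- list(); atom_of <- list()
  for (ia in seq_len(natom)) {
    rm <- .becke_rm(mol$Z[ia])
    r <- rm * (1 + x) / (1 - x)
    drdx <- 2 * rm / (1 - x)^2
    wr <- wgc / sqrt(1 - x^2) * drdx * r^2
    keep <- r < 40        # beyond 40 bohr nothing contributes
    r <- r[keep]; wr <- wr[keep]
    p <- ang[rep(seq_len(nrow(ang)), times = length(r)), ] *
      rep(r, each = nrow(ang))
    p <- sweep(p, 2L, mol$coords[ia, ], "+")
    w <- rep(wr, each = nrow(ang)) * rep(wang, times = length(r))
    pts[[ia]] <- p
    wts[[ia]] <- w
    atom_of[[ia]] <- rep(ia, length(w))
  }
  points <- do.call(rbind, pts)
  weights <- unlist(wts)
  atom <- unlist(atom_of)

  if (natom > 1L) {
    weights <- weights * becke_partition(points, atom, mol$coords)
  }
  structure(list(points = points, weights = weights, atom = atom,
                 level = level, scheme = sc, molecule = mol),
            class = "molecular_grid")
}

# Deterministic molecule-fixed orthonormal frame: principal axes of the
# nuclear-charge-weighted second-moment tensor, ordered by eigenvalue,
# signs fixed by the largest-magnitude component, right-handed. For
# degenerate moments the axes within the degenerate subspace are only
# defined up to rotation; for linear molecules that ambiguity is a
# symmetry of the geometry and leaves all computed scalars unchanged.
molecular_frame <- function(mol) {
  w <- mol$Z
  c0 <- colSums(mol$coords * w) / sum(w)
  d <- sweep(mol$coords, 2L, c0)
  M <- crossprod(d * sqrt(w))
  es <- eigen((M + t(M)) / 2, symmetric = TRUE)
  Fr <- es$vectors
  for (j in 1:3) {
    i <- which.max(abs(Fr[, j]))
    if (Fr[i, j] < 0) Fr[, j] <- -Fr[, j]
  }
  if (det(Fr) < 0) Fr[, 3] <- -Fr[, 3]
  Fr
}

# Becke fuzzy-cell weights: for each grid point (owned by atom `atom`),
# the normalized cell function of its owner.
becke_partition <- function(points, atom, centers) {
  natom <- nrow(centers)
  n <- nrow(points)
  f3 <- function(mu) {
    for (it in 1:3) mu <- 1.5 * mu - 0.5 * mu^3
    mu
  }
  # distances of every point to every atom
  dist_at <- matrix(0, n, natom)
  for (a in seq_len(natom)) {
    d <- sweep(points, 2L, centers[a, ], "-")
    dist_at[, a] <- sqrt(rowSums(d * d))
  }
  Rab <- as.matrix(stats::dist(centers))
  cell <- matrix(1, n, natom)
  for (a in seq_len(natom)) {
    for (b in seq_len(natom)) {
      if (a == b) next
      mu <- (dist_at[, a] - dist_at[, b]) / Rab[a, b]
      cell[, a] <- cell[, a] * 0.5 * (1 - f3(mu))
    }
  }
  tot <- rowSums(cell)
  cell[cbind(seq_len(n), atom)] / tot
}

#' @export
print.molecular_grid <- function(x, ...) {
  cat(sprintf("molecular_grid: %d points (%s: %d radial x %d x %d angular per atom)\n",
              length(x$weights), x$level, x$scheme$nr, x$scheme$ntheta, x$scheme$nphi))
  invisible(x)
}

# physicists' Hermite polynomial values H_0..H_kmax at x (vectorized in x)
hermite_poly <- function(kmax, x) {
  out <- matrix(0, length(x), kmax + 1L)
  out[, 1] <- 1
  if (kmax >= 1L) out[, 2] <- 2 * x
  if (kmax >= 2L) {
    for (k in 2:kmax) {
      out[, k + 1L] <- 2 * x * out[, k] - 2 * (k - 1) * out[, k - 1L]
    }
  }
  out
}

#' Evaluate contracted basis functions on points
#'
#' @param basis A `basis_set`.
#' @param points Numeric `n x 3` matrix (bohr).
#' @return Matrix `n_points x n_ao`.
#' @export
eval_basis <- function(basis, points) {
  n <- nrow(points)
  out <- matrix(0, n, basis$n_ao)
  for (s in seq_along(basis$shells)) {
    sh <- basis$shells[[s]]
    d <- sweep(points, 2L, sh$A, "-")
    r2 <- rowSums(d * d)
    ncomp <- nrow(sh$comps)
    rad <- matrix(0, n, length(sh$zeta))
    for (k in seq_along(sh$zeta)) rad[, k] <- exp(-sh$zeta[k] * r2)
    for (c in seq_len(ncomp)) {
      l <- sh$comps[c, ]
      ang <- d[, 1]^l[1] * d[, 2]^l[2] * d[, 3]^l[3]
      out[, basis$offsets[s] + c] <- ang * (rad %*% sh$coef[, c])
    }
  }
  out
}

#' Evaluate primitive Hermite auxiliary functions on points
#'
#' A Hermite Gaussian of index k is the k-th derivative of the s Gaussian
#' with respect to its center; per direction it evaluates to
#' `zeta^{k/2} H_k(sqrt(zeta) u) exp(-zeta u^2)`.
#'
#' @param aux An `aux_basis`.
#' @param points Numeric `n x 3` matrix (bohr).
#' @return Matrix `n_points x n_aux`.
#' @export
eval_aux <- function(aux, points) {
  n <- nrow(points)
  out <- matrix(0, n, aux$n)
  groups <- aux_groups(aux)
  for (g in groups) {
    d <- sweep(points, 2L, g$C, "-")
    sz <- sqrt(g$zeta)
    e <- exp(-g$zeta * rowSums(d * d))
    H <- lapply(1:3, function(dir) hermite_poly(g$Lg, sz * d[, dir]))
    for (j in seq_len(nrow(g$k))) {
      kk <- g$k[j, ]
      out[, g$rows[j]] <- aux$norm[g$rows[j]] * g$zeta^(sum(kk) / 2) * e *
        H[[1]][, kk[1] + 1L] * H[[2]][, kk[2] + 1L] * H[[3]][, kk[3] + 1L]
    }
  }
  out
}
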