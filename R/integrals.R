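# Molecular integrals over contracted Cartesian Gaussians and primitive
# Hermite Gaussian auxiliary functions.
#
# Everything runs through the McMurchie-Davidson scheme: Cartesian products
# are expanded in Hermite Gaussians (E coefficients), Coulomb interactions
# between Hermite distributions reduce to Boys-function ladders (R
# integrals). The erf-attenuated operator reuses the plain machinery with a
# scaled effective exponent, and the CAM operator
# (alpha + beta erf(omega r))/r is the corresponding linear combination.

#' Two-electron operator constructors
#'
#' `op_plain()` is the bare Coulomb operator 1/r12. `op_erf(omega)` is the
#' long-range kernel erf(omega r12)/r12. `op_cam(alpha, beta, omega)` is the
#' Coulomb-attenuated combination (alpha + beta erf(omega r12))/r12.
#'
#' @param omega Range-separation parameter (bohr^-1), `omega >= 0`.
#' @param alpha,beta CAM mixing coefficients.
#' @return An operator descriptor used by the integral routines.
#' @export
op_plain <- function() structure(list(type = "plain"), class = "eri_operator")

#' @rdname op_plain
#' @export
op_erf <- function(omega) {
  if (omega < 0) stop("op_erf: omega must be >= 0")
  structure(list(type = "cam", alpha = 0, beta = 1, omega = omega),
            class = "eri_operator")
}

#' @rdname op_plain
#' @export
op_cam <- function(alpha, beta, omega) {
  if (omega < 0) stop("op_cam: omega must be >= 0")
  structure(list(type = "cam", alpha = alpha, beta = beta, omega = omega),
            class = "eri_operator")
}

# Hermite Coulomb R array for a given operator. rho is the reduced exponent
# of the two charge distributions, PC their center separation, pref the
# operator-independent prefactor. For the erf kernel the effective exponent
# is rho * s with s = omega^2/(rho + omega^2) and the value scales by
# sqrt(s); the CAM kernel is the linear combination of plain and erf parts.
coulomb_R <- function(Lmax, rho, PC, pref, op) {
  if (op$type == "plain") {
    return(hermite_R(Lmax, rho, PC, pref))
  }
  out <- 0
  if (op$alpha != 0) out <- out + op$alpha * hermite_R(Lmax, rho, PC, pref)
  if (op$beta != 0) {
    s <- op$omega^2 / (rho + op$omega^2)
    out <- out + op$beta * hermite_R(Lmax, rho * s, PC, pref * sqrt(s))
  }
  out
}

# --- shell-pair Hermite representation -------------------------------------
#
# For one pair of contracted shells, return per primitive pair the combined
# exponent p, product center P and the coefficient-weighted Hermite
# expansion W[(ca,cb), (t,u,v)] flattened over a full (Lt+1)^3 cube, so that
# any Coulomb integral of the pair density is W %*% vec(R-slice).
shellpair_hermite <- function(sha, shb) {
  La <- sha$L; Lb <- shb$L; Lt <- La + Lb
  compsA <- sha$comps; compsB <- shb$comps
  ncA <- nrow(compsA); ncB <- nrow(compsB)
  AB <- sha$A - shb$A
  dims <- Lt + 1L
  prs <- list()
  for (k in seq_along(sha$zeta)) {
    for (l in seq_along(shb$zeta)) {
      za <- sha$zeta[k]; zb <- shb$zeta[l]
      p <- za + zb
      P <- (za * sha$A + zb * shb$A) / p
      Ex <- md_E(La, Lb, za, zb, AB[1])
      Ey <- md_E(La, Lb, za, zb, AB[2])
      Ez <- md_E(La, Lb, za, zb, AB[3])
      W <- matrix(0, ncA * ncB, dims^3)
      for (ca in seq_len(ncA)) {
        for (cb in seq_len(ncB)) {
          la <- compsA[ca, ]; lb <- compsB[cb, ]
          cw <- sha$coef[k, ca] * shb$coef[l, cb]
          ex <- Ex[la[1] + 1L, lb[1] + 1L, seq_len(la[1] + lb[1] + 1L)]
          ey <- Ey[la[2] + 1L, lb[2] + 1L, seq_len(la[2] + lb[2] + 1L)]
          ez <- Ez[la[3] + 1L, lb[3] + 1L, seq_len(la[3] + lb[3] + 1L)]
          cube <- array(0, c(dims, dims, dims))
          cube[seq_along(ex), seq_along(ey), seq_along(ez)] <-
            outer(outer(ex, ey), ez)
          W[(cb - 1L) * ncA + ca, ] <- cw * as.vector(cube)
        }
      }
      prs[[length(prs) + 1L]] <- list(p = p, P = P, W = W)
    }
  }
  list(pairs = prs, Lt = Lt, ncA = ncA, ncB = ncB, dims = Lt + 1L)
}

# group auxiliary functions by (center, exponent); each group shares Boys
# ladders. Returns list of groups with C, zeta, rows (indices), k matrix.
aux_groups <- function(aux) {
  key <- paste(aux$center, format(aux$zeta, digits = 15))
  idx <- split(seq_len(aux$n), factor(key, levels = unique(key)))
  lapply(idx, function(rows) {
    list(rows = rows,
         C = aux$C[rows[1], ],
         zeta = aux$zeta[rows[1]],
         k = aux$k[rows, , drop = FALSE],
         Lg = max(rowSums(aux$k[rows, , drop = FALSE])))
  })
}

# linear index into a (d,d,d) cube for Hermite index rows (t,u,v) (0-based)
cube_index <- function(k, d) {
  1L + k[, 1] + d * k[, 2] + d * d * k[, 3]
}

#' One-electron integrals
#'
#' Overlap, kinetic-energy, nuclear-attraction and dipole-moment matrices
#' over the contracted Cartesian basis.
#'
#' @param basis A `basis_set` from [build_basis()].
#' @param origin Origin for the dipole matrices (bohr), default c(0,0,0).
#' @return List with symmetric matrices `S`, `T`, `V` and a list `dipole`
#'   of the three Cartesian moment matrices.
#' @export
one_electron <- function(basis, origin = c(0, 0, 0)) {
  n <- basis$n_ao
  mol <- basis$molecule
  S <- matrix(0, n, n); Tm <- matrix(0, n, n); V <- matrix(0, n, n)
  D <- list(matrix(0, n, n), matrix(0, n, n), matrix(0, n, n))
  ns <- length(basis$shells)
  for (s1 in seq_len(ns)) {
    for (s2 in s1:ns) {
      sha <- basis$shells[[s1]]; shb <- basis$shells[[s2]]
      La <- sha$L; Lb <- shb$L
      cA <- sha$comps; cB <- shb$comps
      ncA <- nrow(cA); ncB <- nrow(cB)
      AB <- sha$A - shb$A
      o1 <- basis$offsets[s1]; o2 <- basis$offsets[s2]
      Sblk <- matrix(0, ncA, ncB); Tblk <- matrix(0, ncA, ncB)
      Vblk <- matrix(0, ncA, ncB)
      Dblk <- list(Sblk, Sblk, Sblk)
      for (k in seq_along(sha$zeta)) {
        for (l in seq_along(shb$zeta)) {
          za <- sha$zeta[k]; zb <- shb$zeta[l]
          p <- za + zb
          P <- (za * sha$A + zb * shb$A) / p
          # E up to Lb+2 in j for the kinetic ladder
          E <- lapply(1:3, function(d) md_E(La, Lb + 2L, za, zb, AB[d]))
          sqp <- sqrt(pi / p)
          s1d <- function(d, i, j) E[[d]][i + 1L, j + 1L, 1L] * sqp
          m1d <- function(d, i, j) {
            (E[[d]][i + 1L, j + 1L, 2L] + (P[d] - origin[d]) *
               E[[d]][i + 1L, j + 1L, 1L]) * sqp
          }
          k1d <- function(d, i, j) {
            val <- -2 * zb^2 * s1d(d, i, j + 2L) +
              zb * (2 * j + 1) * s1d(d, i, j)
            if (j >= 2L) val <- val - 0.5 * j * (j - 1) * s1d(d, i, j - 2L)
            val
          }
          # nuclear attraction needs the Hermite expansion of the pair
          Lt <- La + Lb
          dims <- Lt + 1L
          Rsum <- 0
          for (ia in seq_len(ncA)) {
            for (ib in seq_len(ncB)) {
              la <- cA[ia, ]; lb <- cB[ib, ]
              cw <- sha$coef[k, ia] * shb$coef[l, ib]
              sx <- s1d(1, la[1], lb[1]); sy <- s1d(2, la[2], lb[2])
              sz <- s1d(3, la[3], lb[3])
              Sblk[ia, ib] <- Sblk[ia, ib] + cw * sx * sy * sz
              Tblk[ia, ib] <- Tblk[ia, ib] + cw *
                (k1d(1, la[1], lb[1]) * sy * sz +
                 sx * k1d(2, la[2], lb[2]) * sz +
                 sx * sy * k1d(3, la[3], lb[3]))
              Dblk[[1]][ia, ib] <- Dblk[[1]][ia, ib] + cw * m1d(1, la[1], lb[1]) * sy * sz
              Dblk[[2]][ia, ib] <- Dblk[[2]][ia, ib] + cw * sx * m1d(2, la[2], lb[2]) * sz
              Dblk[[3]][ia, ib] <- Dblk[[3]][ia, ib] + cw * sx * sy * m1d(3, la[3], lb[3])
            }
          }
          # nuclear attraction via Hermite cube per nucleus
          Wm <- matrix(0, ncA * ncB, dims^3)
          for (ia in seq_len(ncA)) {
            for (ib in seq_len(ncB)) {
              la <- cA[ia, ]; lb <- cB[ib, ]
              cw <- sha$coef[k, ia] * shb$coef[l, ib]
              ex <- E[[1]][la[1] + 1L, lb[1] + 1L, seq_len(la[1] + lb[1] + 1L)]
              ey <- E[[2]][la[2] + 1L, lb[2] + 1L, seq_len(la[2] + lb[2] + 1L)]
              ez <- E[[3]][la[3] + 1L, lb[3] + 1L, seq_len(la[3] + lb[3] + 1L)]
              cube <- array(0, c(dims, dims, dims))
              cube[seq_along(ex), seq_along(ey), seq_along(ez)] <-
                outer(outer(ex, ey), ez)
              Wm[(ib - 1L) * ncA + ia, ] <- cw * as.vector(cube)
            }
          }
          for (ia2 in seq_len(nrow(mol$coords))) {
            R <- hermite_R(Lt, p, P - mol$coords[ia2, ], 2 * pi / p)
            contrib <- Wm %*% as.vector(R)
            Vblk <- Vblk - mol$Z[ia2] * matrix(contrib, ncA, ncB)
          }
        }
      }
      rows <- o1 + seq_len(ncA); cols <- o2 + seq_len(ncB)
      S[rows, cols] <- Sblk; Tm[rows, cols] <- Tblk; V[rows, cols] <- Vblk
      S[cols, rows] <- t(Sblk); Tm[cols, rows] <- t(Tblk); V[cols, rows] <- t(Vblk)
      for (d in 1:3) {
        D[[d]][rows, cols] <- Dblk[[d]]
        D[[d]][cols, rows] <- t(Dblk[[d]])
      }
    }
  }
  list(S = S, T = Tm, V = V, dipole = D)
}

#' Coulomb metric over auxiliary functions
#'
#' Two-center Coulomb matrix `G` of the primitive Hermite Gaussian auxiliary
#' set under the plain or attenuated operator. The plain metric is checked
#' for positive definiteness (variational density fitting requires it).
#'
#' @param aux An `aux_basis` from [build_aux_basis()].
#' @param operator An operator from [op_plain()], [op_erf()] or [op_cam()].
#' @return Object of class `coulomb_metric`: the matrix `G`, its Cholesky
#'   factor (plain operator), condition number estimate and operator tag.
#' @export
coulomb_metric <- function(aux, operator = op_plain()) {
  groups <- aux_groups(aux)
  n <- aux$n
  G <- matrix(0, n, n)
  ng <- length(groups)
  for (g1 in seq_len(ng)) {
    for (g2 in g1:ng) {
      a <- groups[[g1]]; b <- groups[[g2]]
      z1 <- a$zeta; z2 <- b$zeta
      rho <- z1 * z2 / (z1 + z2)
      pref <- 2 * pi^2.5 / (z1 * z2 * sqrt(z1 + z2))
      Lmax <- a$Lg + b$Lg
      R <- coulomb_R(Lmax, rho, a$C - b$C, pref, operator)
      d <- Lmax + 1L
      # value(kA, kB) = (-1)^{|kB|} R[kA + kB]
      for (i in seq_len(nrow(a$k))) {
        kA <- a$k[i, ]
        kB <- b$k
        idx <- cube_index(sweep(kB, 2L, kA, "+"), d)
        G[a$rows[i], b$rows] <- (-1)^rowSums(kB) * R[idx]
      }
      G[b$rows, a$rows] <- t(G[a$rows, b$rows, drop = FALSE])
    }
  }
  G <- G * outer(aux$norm, aux$norm)
  G <- (G + t(G)) / 2
  chol_G <- NULL
  eig_G <- NULL
  es <- eigen(G, symmetric = TRUE)
  kappa <- es$values[1] / es$values[n]
  if (operator$type == "plain") {
    chol_G <- tryCatch(chol(G), error = function(e) NULL)
    if (is.null(chol_G) || es$values[n] <= 0) {
      worst <- order(abs(es$vectors[, n]), decreasing = TRUE)[1:min(3L, n)]
      stop("linearly dependent auxiliary set; offending functions (rows): ",
           paste(worst, collapse = ", "))
    }
  } else {
    # Attenuated metrics are intrinsically ill-conditioned: the smooth
    # long-range kernel nearly annihilates high-index Hermite functions.
    # Solves go through a truncated eigendecomposition (relative threshold
    # 1e-12), the standard regularization for density-fitting metrics.
    eig_G <- es
  }
  structure(list(G = G, chol = chol_G, eig = eig_G, cond = kappa,
                 operator = operator, n = n),
            class = "coulomb_metric")
}

#' @export
print.coulomb_metric <- function(x, ...) {
  cat(sprintf("coulomb_metric: %d x %d (%s operator), condition number %.3g\n",
              x$n, x$n, x$operator$type, x$cond))
  invisible(x)
}

# solve G x = b: Cholesky for the plain metric, truncated-eigenvalue
# pseudo-solve for attenuated metrics (see coulomb_metric)
metric_solve <- function(metric, b, rel_tol = 1e-12) {
  if (!is.null(metric$chol)) {
    backsolve(metric$chol, forwardsolve(t(metric$chol), b))
  } else {
    ev <- metric$eig$values
    keep <- abs(ev) > rel_tol * max(abs(ev))
    V <- metric$eig$vectors[, keep, drop = FALSE]
    V %*% (crossprod(V, b) / ev[keep])
  }
}

#' Three-center electron repulsion integrals
#'
#' Computes the tensor `<mu nu || kbar>` of contracted AO pairs against
#' primitive Hermite Gaussian auxiliary functions for the plain or
#' attenuated Coulomb operator. Contraction is performed after the vertical
#' recursion; the `(-1)^{|kbar|}` phase of the two-center Hermite expansion
#' is applied to the assembled integrals.
#'
#' @param basis A `basis_set`.
#' @param aux An `aux_basis`.
#' @param operator Two-electron operator descriptor.
#' @return Numeric array `n_ao x n_ao x n_aux`, symmetric in the first two
#'   indices.
#' @export
three_center <- function(basis, aux, operator = op_plain()) {
  n <- basis$n_ao
  out <- array(0, c(n, n, aux$n))
  three_center_map(basis, aux, operator, function(rows, cols, blk, ncA, ncB) {
    for (j in seq_len(aux$n)) {
      m <- matrix(blk[, j], ncA, ncB)
      out[rows, cols, j] <<- m
      out[cols, rows, j] <<- t(m)
    }
  })
  out
}

# Shell-pair-driven three-center ERI engine. Calls
# `accum(rows, cols, blk, ncA, ncB)` once per canonical shell pair with the
# contracted integral block `blk` ((ncA*ncB) x n_aux, component pairs
# flattened column-major). Used both to materialize the full tensor and to
# contract MO pair densities on the fly without storing it.
three_center_map <- function(basis, aux, operator, accum) {
  groups <- aux_groups(aux)
  ns <- length(basis$shells)
  for (s1 in seq_len(ns)) {
    for (s2 in s1:ns) {
      sha <- basis$shells[[s1]]; shb <- basis$shells[[s2]]
      sp <- shellpair_hermite(sha, shb)
      o1 <- basis$offsets[s1]; o2 <- basis$offsets[s2]
      blk <- matrix(0, sp$ncA * sp$ncB, aux$n)
      for (pr in sp$pairs) {
        for (g in groups) {
          zc <- g$zeta
          rho <- pr$p * zc / (pr$p + zc)
          pref <- 2 * pi^2.5 / (pr$p * zc * sqrt(pr$p + zc))
          Lmax <- sp$Lt + g$Lg
          R <- coulomb_R(Lmax, rho, pr$P - g$C, pref, operator)
          # columns: R cube shifted by each Hermite index, with phase
          Rcols <- matrix(0, sp$dims^3, nrow(g$k))
          for (j in seq_len(nrow(g$k))) {
            kk <- g$k[j, ]
            sub <- R[kk[1] + seq_len(sp$dims), kk[2] + seq_len(sp$dims),
                     kk[3] + seq_len(sp$dims)]
            Rcols[, j] <- (-1)^sum(kk) * as.vector(sub)
          }
          blk[, g$rows] <- blk[, g$rows] + pr$W %*% Rcols
        }
      }
      blk <- blk * rep(aux$norm, each = nrow(blk))
      rows <- o1 + seq_len(sp$ncA); cols <- o2 + seq_len(sp$ncB)
      accum(rows, cols, blk, sp$ncA, sp$ncB)
    }
  }
  invisible(NULL)
}

#' Four-center electron repulsion integrals
#'
#' Conventional AO ERIs `(mu nu | sigma tau)` with full 8-fold permutation
#' symmetry, for the plain or attenuated operator. Intended for the SCF
#' exchange term and as the exact-exchange oracle; guarded to small systems.
#'
#' @param basis A `basis_set` (at most 120 AOs).
#' @param operator Two-electron operator descriptor.
#' @return Numeric 4-d array `n_ao^4`.
#' @export
four_center <- function(basis, operator = op_plain()) {
  n <- basis$n_ao
  if (n > 120L) stop("four_center is guarded to <= 120 basis functions (got ", n, ")")
  ns <- length(basis$shells)
  sps <- vector("list", ns * ns)
  pair_of <- function(s1, s2) shellpair_hermite(basis$shells[[s1]], basis$shells[[s2]])
  out <- array(0, c(n, n, n, n))
  # canonical shell pair list
  plist <- list()
  for (s1 in seq_len(ns)) for (s2 in s1:ns) {
    plist[[length(plist) + 1L]] <- list(s1 = s1, s2 = s2, sp = pair_of(s1, s2))
  }
  np <- length(plist)
  for (ip in seq_len(np)) {
    for (jp in ip:np) {
      P1 <- plist[[ip]]; P2 <- plist[[jp]]
      spA <- P1$sp; spB <- P2$sp
      d1 <- spA$dims; d2 <- spB$dims
      Lmax <- spA$Lt + spB$Lt
      dd <- Lmax + 1L
      acc <- matrix(0, spA$ncA * spA$ncB, spB$ncA * spB$ncB)
      # phase (-1)^{t'+u'+v'} over the second cube
      ks <- as.matrix(expand.grid(t = 0:(d2 - 1L), u = 0:(d2 - 1L), v = 0:(d2 - 1L)))
      ks <- ks[order(ks[, 3], ks[, 2], ks[, 1]), , drop = FALSE]  # column-major vec order
      phase <- (-1)^(ks[, 1] + ks[, 2] + ks[, 3])
      for (pa in spA$pairs) {
        for (pb in spB$pairs) {
          rho <- pa$p * pb$p / (pa$p + pb$p)
          pref <- 2 * pi^2.5 / (pa$p * pb$p * sqrt(pa$p + pb$p))
          R <- coulomb_R(Lmax, rho, pa$P - pb$P, pref, operator)
          # Rmat[(tuv), (t'u'v')] = phase' * R[t+t', u+u', v+v']
          Rmat <- matrix(0, d1^3, d2^3)
          for (j in seq_len(d2^3)) {
            kk <- ks[j, ]
            sub <- R[kk[1] + seq_len(d1), kk[2] + seq_len(d1), kk[3] + seq_len(d1)]
            Rmat[, j] <- phase[j] * as.vector(sub)
          }
          acc <- acc + pa$W %*% Rmat %*% t(pb$W)
        }
      }
      rA <- basis$offsets[P1$s1] + seq_len(spA$ncA)
      cA <- basis$offsets[P1$s2] + seq_len(spA$ncB)
      rB <- basis$offsets[P2$s1] + seq_len(spB$ncA)
      cB <- basis$offsets[P2$s2] + seq_len(spB$ncB)
      for (i2 in seq_along(rB)) {
        for (j2 in seq_along(cB)) {
          m <- matrix(acc[, (j2 - 1L) * spB$ncA + i2], spA$ncA, spA$ncB)
          mu <- rB[i2]; nu <- cB[j2]
          out[rA, cA, mu, nu] <- m
          out[cA, rA, mu, nu] <- t(m)
          out[rA, cA, nu, mu] <- m
          out[cA, rA, nu, mu] <- t(m)
          out[mu, nu, rA, cA] <- m
          out[nu, mu, rA, cA] <- m
          out[mu, nu, cA, rA] <- t(m)
          out[nu, mu, cA, rA] <- t(m)
        }
      }
    }
  }
  out
}

#' Analytic overlap matrix of the auxiliary set
#'
#' Closed-form overlaps of primitive Hermite Gaussian functions, used as the
#' reference for grid quadrature checks.
#'
#' @param aux An `aux_basis`.
#' @return Symmetric `n_aux x n_aux` matrix.
#' @export
aux_overlap <- function(aux) {
  n <- aux$n
  S <- matrix(0, n, n)
  # 1-d ladder h_t(D) = (d/dD)^t exp(-mu D^2)
  hladder <- function(tmax, mu, D) {
    h <- numeric(tmax + 1L)
    h[1] <- exp(-mu * D * D)
    if (tmax >= 1L) h[2] <- -2 * mu * D * h[1]
    if (tmax >= 2L) {
      for (t in 2:tmax) {
        h[t + 1L] <- -2 * mu * (D * h[t] + (t - 1) * h[t - 1L])
      }
    }
    h
  }
  for (i in seq_len(n)) {
    for (j in i:n) {
      z1 <- aux$zeta[i]; z2 <- aux$zeta[j]
      p <- z1 + z2; mu <- z1 * z2 / p
      D <- aux$C[i, ] - aux$C[j, ]
      k1 <- aux$k[i, ]; k2 <- aux$k[j, ]
      val <- (pi / p)^1.5 * (-1)^sum(k2)
      for (dir in 1:3) {
        t <- k1[dir] + k2[dir]
        val <- val * hladder(t, mu, D[dir])[t + 1L]
      }
      val <- val * aux$norm[i] * aux$norm[j]
      S[i, j] <- val
      S[j, i] <- val
    }
  }
  S
}
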