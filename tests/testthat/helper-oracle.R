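# Independent numerical oracles for the integral engine.
#
# Strategy: any pairwise Coulomb-type integral factorizes through the
# integral representation 1/r12 = (2/sqrt(pi)) \int_0^Inf exp(-t^2 r12^2) dt
# (upper limit omega for the erf-attenuated kernel). For fixed t the
# integrand is a polynomial times a 2-d Gaussian per Cartesian direction,
# which 2-d Gauss-Hermite quadrature integrates exactly; the outer t
# integral uses R's adaptive integrate(). No Boys function and no
# McMurchie-Davidson recursion is involved anywhere.

# Gauss-Hermite nodes/weights by Golub-Welsch (Jacobi-matrix eigenproblem)
gh_rule <- function(n) {
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1) / 2)
  J[cbind(1:(n - 1), 2:n)] <- off
  J[cbind(2:n, 1:(n - 1))] <- off
  es <- eigen(J, symmetric = TRUE)
  list(x = es$values, w = sqrt(pi) * es$vectors[1, ]^2)
}

# polynomial utilities: coefficient vectors, constant term first
poly_mul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  }
  out
}
poly_eval <- function(a, x) {
  out <- 0
  for (i in rev(seq_along(a))) out <- out * x + a[i]
  out
}
# (u + s)^m as a polynomial in u
poly_shift_pow <- function(m, s) {
  if (m == 0L) return(1)
  out <- 1
  for (r in seq_len(m)) out <- poly_mul(out, c(s, 1))
  out
}

# charge distribution: product of two primitive Cartesian Gaussians
dist_cart_pair <- function(la, lb, za, zb, A, B) {
  p <- za + zb
  P <- (za * A + zb * B) / p
  xi <- za * zb / p
  polys <- lapply(1:3, function(d) {
    poly_mul(poly_shift_pow(la[d], P[d] - A[d]),
             poly_shift_pow(lb[d], P[d] - B[d]))
  })
  pref <- exp(-xi * sum((A - B)^2))
  list(p = p, P = P, polys = polys, pref = pref)
}

# charge distribution: one primitive Hermite Gaussian of index k
dist_hermite <- function(k, zc, C) {
  herm <- function(kk) {
    # P_0 = 1; P_{j+1} = 2 zc u P_j - P_j'
    pol <- 1
    if (kk >= 1L) {
      for (j in seq_len(kk)) {
        up <- c(0, 2 * zc * pol)
        dp <- if (length(pol) > 1L) seq_along(pol[-1]) * pol[-1] else 0
        dp <- c(dp, numeric(length(up) - length(dp)))
        pol <- up - dp
      }
    }
    pol
  }
  list(p = zc, P = C, polys = lapply(1:3, function(d) herm(k[d])), pref = 1)
}

# Coulomb interaction of two distributions under 1/r or erf(omega r)/r
coulomb_quad <- function(d1, d2, omega = Inf, nquad = 14L,
                         rel.tol = 1e-12) {
  gh <- gh_rule(nquad)
  D <- d1$P - d2$P
  p <- d1$p; q <- d2$p
  integrand <- function(tv) {
    vapply(tv, function(t) {
      t2 <- t * t
      M <- matrix(c(p + t2, -t2, -t2, q + t2), 2, 2)
      det <- p * q + t2 * (p + q)
      es <- eigen(M, symmetric = TRUE)
      val <- 1
      for (d in 1:3) {
        # completed square (stable closed forms):
        # shift s = (-t^2 D q, t^2 D p) / det; exponent -t^2 D^2 p q / det
        s <- c(-t2 * D[d] * q, t2 * D[d] * p) / det
        cexp <- -t2 * D[d]^2 * p * q / det
        acc <- 0
        for (i in seq_len(nquad)) {
          wi <- gh$w[i]
          yi <- gh$x[i] / sqrt(es$values[1])
          for (j in seq_len(nquad)) {
            y <- c(yi, gh$x[j] / sqrt(es$values[2]))
            z <- as.vector(es$vectors %*% y) + s
            acc <- acc + wi * gh$w[j] *
              poly_eval(d1$polys[[d]], z[1]) * poly_eval(d2$polys[[d]], z[2])
          }
        }
        val <- val * acc / sqrt(det) * exp(cexp)
        if (val == 0) break
      }
      val
    }, numeric(1))
  }
  up <- if (is.finite(omega)) omega else Inf
  2 / sqrt(pi) * d1$pref * d2$pref *
    stats::integrate(integrand, 0, up, rel.tol = rel.tol,
                     abs.tol = 1e-14)$value
}

# contracted three-center ERI <(shell a comp ca)(shell b comp cb) || k> by
# quadrature, given placed shells from a basis_set and one aux function
oracle_three_center <- function(sha, shb, ca, cb, kvec, zc, C,
                                omega = Inf) {
  la <- sha$comps[ca, ]; lb <- shb$comps[cb, ]
  d2 <- dist_hermite(kvec, zc, C)
  val <- 0
  for (k in seq_along(sha$zeta)) {
    for (l in seq_along(shb$zeta)) {
      d1 <- dist_cart_pair(la, lb, sha$zeta[k], shb$zeta[l], sha$A, shb$A)
      val <- val + sha$coef[k, ca] * shb$coef[l, cb] *
        coulomb_quad(d1, d2, omega = omega)
    }
  }
  val
}

# contracted four-center ERI (a b | c d) by quadrature
oracle_four_center <- function(sha, shb, shc, shd, ca, cb, cc, cd,
                               omega = Inf) {
  la <- sha$comps[ca, ]; lb <- shb$comps[cb, ]
  lc <- shc$comps[cc, ]; ld <- shd$comps[cd, ]
  val <- 0
  for (k in seq_along(sha$zeta)) for (l in seq_along(shb$zeta)) {
    d1 <- dist_cart_pair(la, lb, sha$zeta[k], shb$zeta[l], sha$A, shb$A)
    for (m in seq_along(shc$zeta)) for (o in seq_along(shd$zeta)) {
      d2 <- dist_cart_pair(lc, ld, shc$zeta[m], shd$zeta[o], shc$A, shd$A)
      val <- val + sha$coef[k, ca] * shb$coef[l, cb] *
        shc$coef[m, cc] * shd$coef[o, cd] * coulomb_quad(d1, d2, omega = omega)
    }
  }
  val
}

# two-center metric element by quadrature
oracle_metric <- function(k1, z1, C1, k2, z2, C2, omega = Inf) {
  coulomb_quad(dist_hermite(k1, z1, C1), dist_hermite(k2, z2, C2),
               omega = omega)
}

# overlap of two contracted components by 3-d Gauss-Hermite quadrature
oracle_overlap <- function(sha, shb, ca, cb, nquad = 20L) {
  gh <- gh_rule(nquad)
  la <- sha$comps[ca, ]; lb <- shb$comps[cb, ]
  val <- 0
  for (k in seq_along(sha$zeta)) {
    for (l in seq_along(shb$zeta)) {
      d1 <- dist_cart_pair(la, lb, sha$zeta[k], shb$zeta[l], sha$A, shb$A)
      contrib <- 1
      for (d in 1:3) {
        x <- gh$x / sqrt(d1$p)
        contrib <- contrib * sum(gh$w / sqrt(d1$p) * poly_eval(d1$polys[[d]], x))
      }
      val <- val + sha$coef[k, ca] * shb$coef[l, cb] * d1$pref * contrib
    }
  }
  val
}
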