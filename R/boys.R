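# Boys function F_n(T) = \int_0^1 t^{2n} exp(-T t^2) dt, the radial kernel
# of all Gaussian Coulomb integrals.
#
# Evaluation strategy (documented in the methods vignette):
#   T < 1e-13      : exact limit 1/(2n+1)
#   T < 40         : Maclaurin series at the highest needed order, then
#                    numerically stable downward recursion
#                    F_n = (2T F_{n+1} + e^{-T}) / (2n+1)
#   T >= 40        : closed form via the regularized lower incomplete gamma,
#                    F_n(T) = Gamma(n+1/2) P(n+1/2, T) / (2 T^{n+1/2}),
#                    where e^{-T} has dropped below double precision
# Both branches are accurate to better than 1e-13 absolute for n <= 32.

boys_series_top <- function(n, T) {
  # F_n(T) = e^{-T} * sum_{i>=0} (2T)^i (2n-1)!! / (2n+2i+1)!!
  term <- 1 / (2 * n + 1)
  s <- term
  i <- 0
  repeat {
    i <- i + 1
    term <- term * (2 * T) / (2 * n + 2 * i + 1)
    s <- s + term
    if (term < s * 1e-17 || i > 500) break
  }
  exp(-T) * s
}

#' Boys function
#'
#' Computes `F_n(T)` for all orders `0..n` at once (the recurrences of the
#' integral engine always need the whole ladder).
#'
#' @param n Maximum order (non-negative integer).
#' @param T Argument, `T >= 0`.
#' @return Numeric vector of length `n + 1`: `F_0(T) .. F_n(T)`.
#' @examples
#' boys(3, 0)      # 1, 1/3, 1/5, 1/7
#' boys(0, 1)[1]   # 0.7468241...
#' @export
boys <- function(n, T) {
  if (length(n) != 1L || n < 0 || n != round(n)) stop("boys: n must be a non-negative integer")
  if (length(T) != 1L || is.na(T) || T < 0) stop("boys: T must be a non-negative real")
  n <- as.integer(n)
  if (T < 1e-13) {
    return(1 / (2 * seq(0L, n) + 1))
  }
  out <- numeric(n + 1L)
  if (T < 40) {
    out[n + 1L] <- boys_series_top(n, T)
    if (n > 0L) {
      eT <- exp(-T)
      for (m in seq(n, 1L)) {
        out[m] <- (2 * T * out[m + 1L] + eT) / (2 * (m - 1L) + 1)
      }
    }
  } else {
    m <- seq(0L, n)
    a <- m + 0.5
    out <- exp(lgamma(a) + stats::pgamma(T, a, log.p = TRUE) -
                 a * log(T)) / 2
  }
  out
}

# Hermite Coulomb integrals R^{(0)}_{tuv}(alpha, PC) for all t+u+v <= Lmax,
# scaled by `pref`. Returns a 3-d array indexed [t+1, u+1, v+1].
# Seed: R^{(n)}_{000} = (-2 alpha)^n F_n(alpha |PC|^2); recursion raises one
# Cartesian index at a time while consuming one auxiliary order n.
hermite_R <- function(Lmax, alpha, PC, pref = 1) {
  T <- alpha * sum(PC * PC)
  Fn <- boys(Lmax, T)
  # Rn[[n+1]] holds R^{(n)} arrays built up order by order
  dims <- Lmax + 1L
  R <- vector("list", Lmax + 1L)
  for (nn in 0:Lmax) {
    A <- array(0, c(dims, dims, dims))
    A[1, 1, 1] <- (-2 * alpha)^nn * Fn[nn + 1L]
    R[[nn + 1L]] <- A
  }
  if (Lmax > 0L) {
    for (Ltot in 1:Lmax) {            # total Cartesian order being built
      for (nn in 0:(Lmax - Ltot)) {
        A <- R[[nn + 1L]]
        A1 <- R[[nn + 2L]]
        for (t in 0:Ltot) {
          for (u in 0:(Ltot - t)) {
            v <- Ltot - t - u
            if (t > 0) {
              val <- PC[1] * A1[t, u + 1L, v + 1L]
              if (t > 1) val <- val + (t - 1) * A1[t - 1L, u + 1L, v + 1L]
            } else if (u > 0) {
              val <- PC[2] * A1[t + 1L, u, v + 1L]
              if (u > 1) val <- val + (u - 1) * A1[t + 1L, u - 1L, v + 1L]
            } else {
              val <- PC[3] * A1[t + 1L, u + 1L, v]
              if (v > 1) val <- val + (v - 1) * A1[t + 1L, u + 1L, v - 1L]
            }
            A[t + 1L, u + 1L, v + 1L] <- val
          }
        }
        R[[nn + 1L]] <- A
      }
    }
  }
  R[[1L]] * pref
}

# McMurchie-Davidson Hermite expansion coefficients E_t^{ij} for a 1-d
# product of Cartesian Gaussians (za, A) and (zb, B). Returns matrix
# E[i+1, j+1, t+1] as a 3-d array, including the exp(-xi AB^2) prefactor.
md_E <- function(imax, jmax, za, zb, AB) {
  p <- za + zb
  mu <- za * zb / p
  E <- array(0, c(imax + 1L, jmax + 1L, imax + jmax + 1L))
  E[1, 1, 1] <- exp(-mu * AB * AB)
  if (imax + jmax == 0L) return(E)
  # raise i using X_PA = -zb/p * AB ; raise j using X_PB = za/p * AB
  XPA <- -zb / p * AB
  XPB <- za / p * AB
  for (i in 0:imax) {
    for (j in 0:jmax) {
      if (i == 0L && j == 0L) next
      for (t in 0:(i + j)) {
        val <- 0
        if (i > 0L) {
          if (t > 0L) val <- val + E[i, j + 1L, t] / (2 * p) * 1
          val <- val + XPA * E[i, j + 1L, t + 1L]
          if (t + 2L <= i + j) val <- val + (t + 1) * E[i, j + 1L, t + 2L]
          # note: E[i, j+1, t+2] exists since dim is imax+jmax+1
        } else {
          if (t > 0L) val <- val + E[i + 1L, j, t] / (2 * p)
          val <- val + XPB * E[i + 1L, j, t + 1L]
          if (t + 2L <= i + j) val <- val + (t + 1) * E[i + 1L, j, t + 2L]
        }
        E[i + 1L, j + 1L, t + 1L] <- val
      }
    }
  }
  E
}
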