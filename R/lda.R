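# Local density approximation: Dirac exchange, its erf-attenuated
# short-range variant, and VWN5 correlation, together with the first and
# second density derivatives needed for the SCF potential and the response
# kernels.

.CX <- 0.75 * (3 / pi)^(1 / 3)   # Dirac exchange constant

# density floor: response kernels diverge as rho -> 0
.RHO_FLOOR <- 1e-14

clamp_rho <- function(rho) {
  if (any(rho < -1e-8)) warning("negative density beyond numerical floor")
  pmax(rho, .RHO_FLOOR)
}

# --- Dirac exchange --------------------------------------------------------

lda_ex_energy <- function(rho) -.CX * rho^(4 / 3)
lda_ex_potential <- function(rho) -(4 / 3) * .CX * rho^(1 / 3)
lda_ex_kernel <- function(rho) -(4 / 9) * .CX * rho^(-2 / 3)

# --- short-range (attenuated) Dirac exchange -------------------------------
#
# Energy density of LDA exchange with the CAM complement removed:
#   e_x^SR = e_x^LDA(rho) * [1 - alpha - beta * Fatt(a)],
#   a = rs_omega / (2 k_F), k_F = (3 pi^2 rho)^{1/3},
#   Fatt(a) = (8/3) a [sqrt(pi) erf(1/(2a)) + 2a(b - c)],
#   b = exp(-1/(4a^2)) - 1,  c = 2a^2 b + 1/2.
# Fatt runs from 0 (a -> 0, no attenuation) to 1 (a -> Inf).

sr_attenuation <- function(a) {
  out <- numeric(length(a))
  tiny <- a < 1e-8
  out[tiny] <- (8 / 3) * sqrt(pi) * a[tiny]
  aa <- a[!tiny]
  if (length(aa)) {
    b <- expm1(-1 / (4 * aa^2))
    bc <- b * (1 - 2 * aa^2) - 0.5          # = b - c
    out[!tiny] <- (8 / 3) * aa * (sqrt(pi) * erf(1 / (2 * aa)) + 2 * aa * bc)
  }
  pmin(out, 1)
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Short-range exchange energy density
#'
#' Attenuated LDA exchange energy per unit volume: the part of local
#' exchange that remains after the Fock-exchange fractions
#' `alpha + beta erf(rs_omega r)` have been removed. Its second density
#' derivative is the short-range exchange kernel of the range-separated
#' response coupling.
#'
#' @param rho Density values (clamped at a 1e-14 floor).
#' @param Fx GGA enhancement factor (1 for the LDA host).
#' @param alpha,beta CAM coefficients (including any global `c_F` factor).
#' @param rs_omega Range-separation parameter, `>= 0`.
#' @return Energy density values (hartree / bohr^3).
#' @export
sr_exchange_energy_density <- function(rho, Fx = 1, alpha = 0, beta = 0,
                                       rs_omega = 0) {
  if (rs_omega < 0) stop("sr_exchange_energy_density: rs_omega must be >= 0")
  rho <- clamp_rho(rho)
  if (beta == 0 || rs_omega == 0) {
    return(lda_ex_energy(rho) * Fx * (1 - alpha))
  }
  a <- rs_omega * sqrt(Fx) / (2 * (3 * pi^2 * rho)^(1 / 3))
  lda_ex_energy(rho) * Fx * (1 - alpha - beta * sr_attenuation(a))
}

# second density derivative of the beta term of e_x^SR by Richardson
# finite differences (the (1 - alpha) part is analytic)
sr_exchange_kernel <- function(rho, alpha = 0, beta = 0, rs_omega = 0) {
  rho <- clamp_rho(rho)
  out <- (1 - alpha) * lda_ex_kernel(rho)
  if (beta != 0 && rs_omega > 0) {
    g <- function(r) {
      a <- rs_omega / (2 * (3 * pi^2 * r)^(1 / 3))
      lda_ex_energy(r) * sr_attenuation(a)
    }
    d2 <- function(h) (g(rho + h) - 2 * g(rho) + g(rho - h)) / h^2
    h <- 1e-2 * rho
    out <- out - beta * (4 * d2(h / 2) - d2(h)) / 3
  }
  out
}

# --- VWN5 correlation ------------------------------------------------------

# Pade-type interpolation G(x = sqrt(rs)); returns value and d/dx
.vwn_G <- function(x, A, x0, b, c) {
  X <- x^2 + b * x + c
  X0 <- x0^2 + b * x0 + c
  Q <- sqrt(4 * c - b^2)
  atanQ <- atan(Q / (2 * x + b))
  val <- A * (log(x^2 / X) + 2 * b / Q * atanQ -
                b * x0 / X0 * (log((x - x0)^2 / X) +
                                 2 * (b + 2 * x0) / Q * atanQ))
  den <- (2 * x + b)^2 + Q^2
  dval <- A * (2 / x - (2 * x + b) / X - 4 * b / den -
                 b * x0 / X0 * (2 / (x - x0) - (2 * x + b) / X -
                                  4 * (b + 2 * x0) / den))
  list(val = val, dval = dval)
}

.VWN_PARA <- list(A = 0.0310907, x0 = -0.10498, b = 3.72744, c = 12.9352)
.VWN_STIFF <- list(A = -1 / (6 * pi^2), x0 = -0.0047584, b = 1.13107, c = 13.0045)

vwn_rs <- function(rho) (3 / (4 * pi * rho))^(1 / 3)

# paramagnetic correlation energy per particle and its rs derivative
vwn_ec <- function(rho) {
  x <- sqrt(vwn_rs(rho))
  g <- .vwn_G(x, .VWN_PARA$A, .VWN_PARA$x0, .VWN_PARA$b, .VWN_PARA$c)
  list(ec = g$val, dec_drs = g$dval / (2 * x))
}

vwn_ec_energy <- function(rho) rho * vwn_ec(rho)$ec

vwn_ec_potential <- function(rho) {
  e <- vwn_ec(rho)
  rs <- vwn_rs(rho)
  e$ec - rs / 3 * e$dec_drs
}

# f_c = d v_c / d rho by Richardson central differences of the analytic v_c
vwn_ec_kernel <- function(rho) {
  d1 <- function(h) (vwn_ec_potential(rho + h) - vwn_ec_potential(rho - h)) / (2 * h)
  h <- 1e-3 * rho
  (4 * d1(h / 2) - d1(h)) / 3
}

# spin stiffness alpha_c(rs); triplet correlation kernel is alpha_c / rho
vwn_spin_stiffness <- function(rho) {
  x <- sqrt(vwn_rs(rho))
  .vwn_G(x, .VWN_STIFF$A, .VWN_STIFF$x0, .VWN_STIFF$b, .VWN_STIFF$c)$val
}

# --- assembled kernels -----------------------------------------------------

#' Local exchange-correlation kernel values
#'
#' Second density derivative of the local exchange(-correlation) energy
#' density, evaluated pointwise at the (fitted) density. The exchange part
#' is analytic Dirac exchange; VWN5 correlation uses Richardson-extrapolated
#' central differences of the analytic potential.
#'
#' @param rho Density values (floored at 1e-14).
#' @param correlation `"vwn"` or `"none"`.
#' @return Kernel values `f_xc(rho)`.
#' @examples
#' lda_kernel_values(1, correlation = "none")  # -(4/9) C_x
#' @export
lda_kernel_values <- function(rho, correlation = c("vwn", "none")) {
  correlation <- match.arg(correlation)
  rho <- clamp_rho(rho)
  f <- lda_ex_kernel(rho)
  if (correlation == "vwn") f <- f + vwn_ec_kernel(rho)
  f
}

# response-kernel values for a functional / spin channel; the exchange part
# is the short-range kernel with effective CAM fractions c_F*alpha and
# c_F*beta, which covers pure (c_F = 0), global-hybrid (alpha = 1) and
# range-separated cases in one expression.
xc_kernel_values <- function(rho, functional,
                             spin = c("singlet", "triplet")) {
  spin <- match.arg(spin)
  rho <- clamp_rho(rho)
  f <- sr_exchange_kernel(rho,
                          alpha = functional$c_F * functional$alpha,
                          beta = functional$c_F * functional$beta,
                          rs_omega = functional$rs_omega)
  if (functional$correlation == "vwn") {
    f <- f + if (spin == "singlet") vwn_ec_kernel(rho)
             else vwn_spin_stiffness(rho) / rho
  }
  f
}

# SCF-side local exchange-correlation energy density and potential for a
# functional (complementary to its Fock exchange fractions)
xc_energy_potential <- function(rho, functional) {
  rho <- clamp_rho(rho)
  a <- functional$c_F * functional$alpha
  b <- functional$c_F * functional$beta
  e <- sr_exchange_energy_density(rho, 1, a, b, functional$rs_omega)
  if (b == 0 || functional$rs_omega == 0) {
    v <- (1 - a) * lda_ex_potential(rho)
  } else {
    g <- function(r) sr_exchange_energy_density(r, 1, a, b, functional$rs_omega)
    h <- 1e-3 * rho
    d1 <- function(hh) (g(rho + hh) - g(rho - hh)) / (2 * hh)
    v <- (4 * d1(h / 2) - d1(h)) / 3
  }
  if (functional$correlation == "vwn") {
    e <- e + vwn_ec_energy(rho)
    v <- v + vwn_ec_potential(rho)
  }
  list(e = e, v = v)
}
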