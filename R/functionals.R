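# Functional specification: Fock-exchange mixing c_F, CAM coefficients
# (alpha, beta) and range-separation parameter rs_omega, on top of an LDA
# (Dirac exchange + VWN5 correlation) host.
#
# Conventions: the exact-exchange operator is
#   c_F * (alpha / r12 + beta * erf(rs_omega r12) / r12)
# so a global hybrid is (alpha = 1, beta = 0) with 0 < c_F < 1, and CAM-type
# range-separated hybrids use c_F = 1 with (alpha, beta) carrying the
# short/long-range fractions. Inverse range separation (short-range Fock
# exchange, HSE-type) is expressed with beta < 0 behind an explicit flag.

#' Functional specification
#'
#' @param name Label for printing.
#' @param c_F Global Fock-exchange mixing coefficient in `[0, 1]`.
#' @param alpha,beta CAM coefficients; without `inverse`, both in `[0, 1]`
#'   with `alpha + beta <= 1`.
#' @param rs_omega Range-separation parameter (bohr^-1), `>= 0`.
#' @param correlation `"vwn"` (VWN5) or `"none"`.
#' @param inverse Logical; permits `beta < 0` (short-range Fock exchange,
#'   inverse range separation).
#' @return An object of class `functional_spec`.
#' @examples
#' functional_spec("half-and-half", c_F = 0.5)
#' @export
functional_spec <- function(name = "custom", c_F = 0, alpha = 1, beta = 0,
                            rs_omega = 0, correlation = c("vwn", "none"),
                            inverse = FALSE) {
  correlation <- match.arg(correlation)
  if (c_F < 0 || c_F > 1) stop("functional_spec: c_F must lie in [0, 1]")
  if (rs_omega < 0) stop("functional_spec: rs_omega must be >= 0")
  if (alpha < 0 || alpha > 1) stop("functional_spec: alpha must lie in [0, 1]")
  if (!inverse) {
    if (beta < 0 || beta > 1) stop("functional_spec: beta must lie in [0, 1]")
    if (alpha + beta < 0 || alpha + beta > 1) {
      stop("functional_spec: alpha + beta must lie in [0, 1]")
    }
  } else {
    if (beta > 0) stop("functional_spec: inverse range separation expects beta <= 0")
    if (alpha + beta < 0) stop("functional_spec: alpha + beta must be >= 0")
  }
  if (beta != 0 && rs_omega <= 0) {
    stop("functional_spec: beta != 0 requires a positive rs_omega")
  }
  structure(list(name = name, c_F = c_F, alpha = alpha, beta = beta,
                 rs_omega = rs_omega, correlation = correlation,
                 inverse = inverse),
            class = "functional_spec")
}

#' Built-in functional presets
#'
#' Exchange-mixing parameters taken from the original functional
#' publications; the local part of every preset is the LDA host (Dirac
#' exchange + VWN5 correlation).
#'
#' * `"lda"` - pure local functional, no Fock exchange.
#' * `"hyb25"` - PBE0-type global hybrid, `c_F = 0.25`.
#' * `"hyb20"` - B3LYP-type mixing, `c_F = 0.20`.
#' * `"cam"` - CAM-B3LYP-type, `alpha = 0.19`, `beta = 0.46`,
#'   `rs_omega = 0.33`.
#' * `"lc"` - long-range corrected, `alpha = 0`, `beta = 1`,
#'   `rs_omega = 0.47`.
#' * `"hse"` - HSE-type inverse range separation, `alpha = 0.25`,
#'   `beta = -0.25`, `rs_omega = 0.11`.
#'
#' @param name Preset name.
#' @return A [functional_spec()].
#' @export
functional_preset <- function(name) {
  switch(tolower(name),
    "lda"   = functional_spec("lda", c_F = 0),
    "hyb25" = functional_spec("hyb25", c_F = 0.25),
    "hyb20" = functional_spec("hyb20", c_F = 0.20),
    "cam"   = functional_spec("cam", c_F = 1, alpha = 0.19, beta = 0.46,
                              rs_omega = 0.33),
    "lc"    = functional_spec("lc", c_F = 1, alpha = 0, beta = 1,
                              rs_omega = 0.47),
    "hse"   = functional_spec("hse", c_F = 1, alpha = 0.25, beta = -0.25,
                              rs_omega = 0.11, inverse = TRUE),
    stop("unknown functional preset: ", name)
  )
}

#' @export
print.functional_spec <- function(x, ...) {
  cat(sprintf(
    "functional_spec '%s': c_F = %.3f, alpha = %.3f, beta = %.3f, rs_omega = %.3f, correlation = %s%s\n",
    x$name, x$c_F, x$alpha, x$beta, x$rs_omega, x$correlation,
    if (x$inverse) " (inverse RS)" else ""))
  invisible(x)
}

# TRUE when the functional needs erf-attenuated integrals
uses_attenuation <- function(fn) fn$c_F != 0 && fn$beta != 0
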