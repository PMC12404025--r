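# Physical constants and element data. Atomic units internally everywhere;
# geometry is read in Angstrom, excitation energies are reported in eV.

#' Unit conversion constants
#'
#' `ANG2BOHR` converts Angstrom to bohr (CODATA); `HARTREE2EV` converts
#' hartree to electron volt.
#'
#' @name units
#' @keywords internal
NULL

ANG2BOHR <- 1.8897261254578281
HARTREE2EV <- 27.211386245988

# Elements supported by the parser (H..Kr is plenty for the fixture suite).
.ELEMENTS <- c(
  "H", "He",
  "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar",
  "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr"
)

#' Atomic number of an element symbol
#' @param symbol Element symbol, e.g. "O" (case-sensitive standard form).
#' @return Integer atomic number.
#' @keywords internal
element_Z <- function(symbol) {
  z <- match(symbol, .ELEMENTS)
  if (anyNA(z)) {
    stop("unknown element symbol: ", paste(symbol[is.na(z)], collapse = ", "))
  }
  z
}

#' @keywords internal
element_symbol <- function(Z) {
  if (any(Z < 1L | Z > length(.ELEMENTS))) stop("atomic number out of range")
  .ELEMENTS[Z]
}

# double factorial (2n-1)!! with (-1)!! = 1
dfact2 <- function(n) {
  vapply(n, function(k) {
    if (k <= 0L) return(1)
    prod(seq(k, 1, by = -2))
  }, numeric(1))
}
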