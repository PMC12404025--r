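#' Molecular geometry container
#'
#' A `molecule` holds element symbols, atomic numbers and Cartesian positions
#' in bohr, together with the total charge. Only closed-shell (even electron
#' count) systems are supported downstream.
#'
#' @param symbols Character vector of element symbols.
#' @param coords Numeric matrix `n_atoms x 3`, positions in bohr.
#' @param charge Integer total charge.
#' @return An object of class `molecule` with fields `symbols`, `Z`,
#'   `coords` (bohr), `charge` and `n_electrons`.
#' @examples
#' mol <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1.4)))
#' mol$n_electrons
#' @export
molecule <- function(symbols, coords, charge = 0L) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(coords) != length(symbols) || ncol(coords) != 3L) {
    stop("coords must be an n_atoms x 3 matrix matching symbols")
  }
  Z <- element_Z(symbols)
  n_el <- sum(Z) - as.integer(charge)
  if (n_el <= 0L) stop("non-positive electron count")
  if (nrow(coords) > 1L) {
    d <- as.matrix(stats::dist(coords))
    if (any(d[upper.tri(d)] < 1e-8)) stop("coincident atomic centers")
  }
  structure(
    list(symbols = symbols, Z = Z, coords = coords,
         charge = as.integer(charge), n_electrons = n_el),
    class = "molecule"
  )
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("molecule: %d atoms, charge %+d, %d electrons\n",
              nrow(x$coords), x$charge, x$n_electrons))
  ang <- x$coords / ANG2BOHR
  for (i in seq_along(x$symbols)) {
    cat(sprintf("  %-2s % 12.7f % 12.7f % 12.7f\n",
                x$symbols[i], ang[i, 1], ang[i, 2], ang[i, 3]))
  }
  invisible(x)
}

#' Parse an XYZ-format geometry
#'
#' Standard XYZ text: an atom-count line, a comment line, then one
#' `element x y z` line per atom with coordinates in Angstrom. Coordinates
#' are converted to bohr.
#'
#' @param text XYZ file content as a single string or character vector of
#'   lines.
#' @param charge Total molecular charge (XYZ carries no charge field).
#' @return A [molecule].
#' @examples
#' parse_xyz("2\nhydrogen\nH 0 0 0\nH 0 0 0.74")
#' @export
parse_xyz <- function(text, charge = 0L) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- sub("\\s+$", "", lines)
  if (length(lines) < 1L) stop("XYZ parse error: empty input")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1L) stop("XYZ parse error line 1: bad atom count")
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n) {
    stop(sprintf("XYZ parse error: declared %d atoms but found %d atom lines",
                 n, length(body)))
  }
  symbols <- character(n)
  coords <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(tok) < 4L) stop(sprintf("XYZ parse error line %d: expected 'El x y z'", i + 2L))
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(xyz)) stop(sprintf("XYZ parse error line %d: non-numeric coordinate", i + 2L))
    symbols[i] <- tok[1]
    coords[i, ] <- xyz
  }
  z <- match(symbols, .ELEMENTS)
  if (anyNA(z)) {
    bad <- which(is.na(z))[1]
    stop(sprintf("XYZ parse error line %d: unknown element symbol '%s'",
                 bad + 2L, symbols[bad]))
  }
  molecule(symbols, coords * ANG2BOHR, charge = charge)
}

#' Write a molecule as XYZ text
#'
#' Inverse of [parse_xyz()] (coordinates emitted in Angstrom).
#'
#' @param mol A [molecule].
#' @param comment Comment line content.
#' @return A single XYZ-format string.
#' @export
write_xyz <- function(mol, comment = "") {
  ang <- mol$coords / ANG2BOHR
  body <- vapply(seq_along(mol$symbols), function(i) {
    sprintf("%-2s % 18.12f % 18.12f % 18.12f", mol$symbols[i],
            ang[i, 1], ang[i, 2], ang[i, 3])
  }, character(1))
  paste(c(length(mol$symbols), comment, body), collapse = "\n")
}
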