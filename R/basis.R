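# Orbital and auxiliary basis handling.
#
# Orbital basis functions are contracted Cartesian Gaussians; auxiliary
# functions are primitive Hermite Gaussians (derivatives of an s Gaussian
# with respect to its center), the natural expansion set for the fitted
# density. Everything is kept in a stable, documented ordering so that
# integral tensors, MO coefficients and fitting coefficients stay aligned.

# Cartesian components of angular momentum L in canonical order
# (p: x,y,z; d: xx,xy,xz,yy,yz,zz).
cart_components <- function(L) {
  out <- matrix(0L, 0L, 3L)
  for (lx in seq(L, 0L)) {
    for (ly in seq(L - lx, 0L)) {
      out <- rbind(out, c(lx, ly, L - lx - ly))
    }
  }
  out
}

.SHELL_LETTERS <- c("S", "P", "D", "F", "G")

shell_L <- function(letter) {
  L <- match(toupper(letter), .SHELL_LETTERS) - 1L
  if (is.na(L)) stop("unsupported shell type: ", letter)
  L
}

# primitive normalization constant for Cartesian component l = (lx,ly,lz)
prim_norm <- function(zeta, l) {
  L <- sum(l)
  (2 * zeta / pi)^0.75 * (4 * zeta)^(L / 2) /
    sqrt(dfact2(2 * l[1] - 1) * dfact2(2 * l[2] - 1) * dfact2(2 * l[3] - 1))
}

# same-center overlap of two primitive Cartesian Gaussians with equal l
prim_self_overlap <- function(za, zb, l) {
  p <- za + zb
  prod(dfact2(2 * l - 1)) / (2 * p)^sum(l) * (pi / p)^1.5
}

# Build the per-component contraction coefficient matrix (nprim x ncomp)
# such that every contracted Cartesian function has unit self-overlap.
normalize_shell <- function(zeta, d, comps) {
  nprim <- length(zeta)
  ncomp <- nrow(comps)
  coef <- matrix(0, nprim, ncomp)
  for (c in seq_len(ncomp)) {
    l <- comps[c, ]
    ck <- d * vapply(zeta, prim_norm, numeric(1), l = l)
    s <- 0
    for (k in seq_len(nprim)) {
      for (m in seq_len(nprim)) {
        s <- s + ck[k] * ck[m] * prim_self_overlap(zeta[k], zeta[m], l)
      }
    }
    coef[, c] <- ck / sqrt(s)
  }
  coef
}

.num <- function(x) {
  v <- suppressWarnings(as.numeric(gsub("[DdEe]", "e", x)))
  v
}

# Split Gaussian94 text into per-element blocks (terminated by ****).
g94_blocks <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  blocks <- list()
  cur <- character(0)
  for (ln in lines) {
    if (startsWith(ln, "****")) {
      if (length(cur)) {
        el <- strsplit(cur[1], "\\s+")[[1]][1]
        blocks[[el]] <- cur[-1]
      }
      cur <- character(0)
    } else {
      cur <- c(cur, ln)
    }
  }
  if (length(cur)) {
    el <- strsplit(cur[1], "\\s+")[[1]][1]
    blocks[[el]] <- cur[-1]
  }
  blocks
}

#' Parse a Gaussian94-format orbital basis for one element
#'
#' Reads the element's block from a Gaussian94-dialect basis-set text
#' (element header line, then per shell a `L nprim scale` line followed by
#' exponent/coefficient rows; blocks separated by `****`). `SP` shells are
#' split into separate S and P shells. Contraction coefficients are returned
#' already scaled so that every contracted Cartesian function has unit
#' self-overlap.
#'
#' @param text Basis-set file content (string or lines).
#' @param element Element symbol to extract.
#' @return List of contracted shells; each shell has `L`, `zeta`
#'   (exponents), `d` (raw contraction coefficients), `coef`
#'   (normalized per-component coefficients, `nprim x ncomp`) and `comps`
#'   (Cartesian component exponents).
#' @export
parse_basis <- function(text, element) {
  blocks <- g94_blocks(text)
  blk <- blocks[[element]]
  if (is.null(blk)) stop("element ", element, " not found in basis text")
  shells <- list()
  i <- 1L
  while (i <= length(blk)) {
    hdr <- strsplit(blk[i], "\\s+")[[1]]
    type <- toupper(hdr[1])
    nprim <- suppressWarnings(as.integer(hdr[2]))
    if (is.na(nprim) || nprim < 1L) stop("basis parse error: bad shell header '", blk[i], "'")
    rows <- blk[(i + 1L):(i + nprim)]
    if (length(rows) < nprim || any(is.na(rows))) stop("basis parse error: truncated shell block")
    tab <- t(vapply(rows, function(r) {
      v <- .num(strsplit(r, "\\s+")[[1]])
      if (anyNA(v)) stop("basis parse error: non-numeric exponent/coefficient in '", r, "'")
      v
    }, numeric(if (type == "SP") 3L else 2L)))
    tab <- unname(tab)
    zeta <- tab[, 1]
    if (any(zeta <= 0)) stop("basis parse error: non-positive exponent")
    if (type == "SP") {
      shells <- c(shells,
                  list(list(L = 0L, zeta = zeta, d = tab[, 2]),
                       list(L = 1L, zeta = zeta, d = tab[, 3])))
    } else {
      shells <- c(shells, list(list(L = shell_L(type), zeta = zeta, d = tab[, 2])))
    }
    i <- i + nprim + 1L
  }
  lapply(shells, function(sh) {
    comps <- cart_components(sh$L)
    sh$comps <- comps
    sh$coef <- normalize_shell(sh$zeta, sh$d, comps)
    sh
  })
}

#' Attach an orbital basis to a molecule
#'
#' Parses the basis text for each element present and instantiates one copy
#' of its shells per atom, in atom input order. The resulting atomic-orbital
#' ordering is: atoms in input order, shells in file order, Cartesian
#' components in canonical order.
#'
#' @param mol A [molecule].
#' @param basis_text Gaussian94 basis-set text covering every element in
#'   `mol`.
#' @return A `basis_set` object: list of placed shells (each with `center`,
#'   `A` position, normalized coefficients) plus `n_ao` and an `ao` table.
#' @export
build_basis <- function(mol, basis_text) {
  per_el <- list()
  shells <- list()
  ao_center <- integer(0)
  ao_l <- matrix(0L, 0L, 3L)
  for (ia in seq_along(mol$symbols)) {
    el <- mol$symbols[ia]
    if (is.null(per_el[[el]])) per_el[[el]] <- parse_basis(basis_text, el)
    for (sh in per_el[[el]]) {
      sh$center <- ia
      sh$A <- mol$coords[ia, ]
      shells[[length(shells) + 1L]] <- sh
      ao_center <- c(ao_center, rep(ia, nrow(sh$comps)))
      ao_l <- rbind(ao_l, sh$comps)
    }
  }
  offs <- integer(length(shells))
  n <- 0L
  for (s in seq_along(shells)) {
    offs[s] <- n
    n <- n + nrow(shells[[s]]$comps)
  }
  structure(list(shells = shells, offsets = offs, n_ao = n,
                 ao_center = ao_center, ao_l = ao_l, molecule = mol),
            class = "basis_set")
}

#' @export
print.basis_set <- function(x, ...) {
  cat(sprintf("basis_set: %d shells, %d Cartesian AOs on %d atoms\n",
              length(x$shells), x$n_ao, nrow(x$molecule$coords)))
  invisible(x)
}

# Coulomb self-energy <k || k> of one primitive Hermite Gaussian
aux_self_energy <- function(zeta, k) {
  rho <- zeta / 2
  pref <- 2 * pi^2.5 / (zeta^2 * sqrt(2 * zeta))
  R <- hermite_R(2L * sum(k), rho, c(0, 0, 0), pref)
  (-1)^sum(k) * R[2 * k[1] + 1L, 2 * k[2] + 1L, 2 * k[3] + 1L]
}

# all Hermite indices with |k| <= L, in ascending lexicographic (kx,ky,kz)
hermite_indices <- function(L) {
  g <- expand.grid(kz = 0:L, ky = 0:L, kx = 0:L)
  g <- g[g$kx + g$ky + g$kz <= L, c("kx", "ky", "kz")]
  g <- g[order(g$kx, g$ky, g$kz), ]
  as.matrix(g)
}

#' Parse a Gaussian94-format auxiliary basis for one element
#'
#' Auxiliary sets are primitive: every shell must have contraction depth 1.
#' A shell of angular momentum L expands into all primitive Hermite Gaussian
#' functions with total Hermite index |k| <= L on that exponent (an `S`
#' shell gives 1 function, a `D` shell the full spd set of 10).
#'
#' @param text Auxiliary basis text (Gaussian94 dialect).
#' @param element Element symbol to extract.
#' @return List with one entry per exponent: `zeta` and integer matrix `k`
#'   of Hermite indices.
#' @export
parse_aux_basis <- function(text, element) {
  blocks <- g94_blocks(text)
  blk <- blocks[[element]]
  if (is.null(blk)) stop("element ", element, " not found in auxiliary basis text")
  sets <- list()
  i <- 1L
  while (i <= length(blk)) {
    hdr <- strsplit(blk[i], "\\s+")[[1]]
    L <- shell_L(hdr[1])
    nprim <- suppressWarnings(as.integer(hdr[2]))
    if (is.na(nprim)) stop("auxiliary basis parse error: bad shell header '", blk[i], "'")
    if (nprim != 1L) {
      stop("auxiliary sets are primitive: contraction depth ", nprim, " not allowed")
    }
    v <- .num(strsplit(blk[i + 1L], "\\s+")[[1]])
    if (anyNA(v[1]) || v[1] <= 0) stop("auxiliary basis parse error: bad exponent row")
    sets[[length(sets) + 1L]] <- list(zeta = v[1], k = hermite_indices(L), L = L)
    i <- i + 2L
  }
  sets
}

#' Attach an auxiliary basis to a molecule
#'
#' Instantiates the element auxiliary sets on every atom and flattens them
#' into individual primitive Hermite Gaussian functions with the
#' deterministic ordering: center (atom input order), then exponent
#' descending, then lexicographic Hermite index. Duplicate
#' (center, exponent, index) triples are rejected.
#'
#' @param mol A [molecule].
#' @param aux_text Gaussian94-dialect auxiliary basis text.
#' @return An `aux_basis` object with vectors `center`, `zeta`, `norm`
#'   (unit-Coulomb-self-energy scaling), integer matrix `k` (`n x 3`),
#'   position matrix `C` and size `n`.
#' @export
build_aux_basis <- function(mol, aux_text) {
  per_el <- list()
  center <- integer(0); zeta <- numeric(0); kmat <- matrix(0L, 0L, 3L)
  for (ia in seq_along(mol$symbols)) {
    el <- mol$symbols[ia]
    if (is.null(per_el[[el]])) per_el[[el]] <- parse_aux_basis(aux_text, el)
    sets <- per_el[[el]]
    zs <- vapply(sets, `[[`, numeric(1), "zeta")
    for (s in order(-zs)) {
      kk <- sets[[s]]$k
      center <- c(center, rep(ia, nrow(kk)))
      zeta <- c(zeta, rep(sets[[s]]$zeta, nrow(kk)))
      kmat <- rbind(kmat, kk)
    }
  }
  key <- paste(center, format(zeta, digits = 15), kmat[, 1], kmat[, 2], kmat[, 3])
  if (anyDuplicated(key)) {
    stop("duplicate auxiliary function (center, exponent, Hermite index)")
  }
  # scale every function to unit Coulomb self-energy: keeps the fitted
  # physics identical while bounding the metric's dynamic range
  norm <- vapply(seq_along(zeta), function(i) {
    1 / sqrt(aux_self_energy(zeta[i], kmat[i, ]))
  }, numeric(1))
  structure(list(center = center, zeta = zeta, k = kmat, norm = norm,
                 C = mol$coords[center, , drop = FALSE],
                 n = length(zeta), molecule = mol),
            class = "aux_basis")
}

#' @export
print.aux_basis <- function(x, ...) {
  cat(sprintf("aux_basis: %d primitive Hermite Gaussian functions on %d atoms\n",
              x$n, nrow(x$molecule$coords)))
  invisible(x)
}

#' Serialize an element auxiliary set back to Gaussian94 text
#'
#' Inverse of [parse_aux_basis()]: each exponent is written as one primitive
#' shell whose letter encodes the maximum Hermite index it expands to.
#'
#' @param sets Result of [parse_aux_basis()].
#' @param element Element symbol for the block header.
#' @return Gaussian94-dialect text.
#' @export
write_aux_basis <- function(sets, element) {
  out <- c(paste(element, "0"))
  for (s in sets) {
    out <- c(out,
             sprintf("%s   1   1.00", .SHELL_LETTERS[s$L + 1L]),
             sprintf("      %.10E   1.0", s$zeta))
  }
  paste(c(out, "****"), collapse = "\n")
}

#' Serialize element orbital shells back to Gaussian94 text
#'
#' Inverse of [parse_basis()] up to SP recombination (split S and P shells
#' are written separately, which re-parses identically).
#'
#' @param shells Result of [parse_basis()].
#' @param element Element symbol for the block header.
#' @return Gaussian94-dialect text.
#' @export
write_basis <- function(shells, element) {
  out <- c(paste(element, "0"))
  for (sh in shells) {
    out <- c(out, sprintf("%s   %d   1.00", .SHELL_LETTERS[sh$L + 1L], length(sh$zeta)))
    out <- c(out, sprintf("      %.10E   % .10E", sh$zeta, sh$d))
  }
  paste(c(out, "****"), collapse = "\n")
}
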