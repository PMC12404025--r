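# Built-in fixture molecules with embedded minimal basis and even-tempered
# auxiliary sets. Everything is generated in code: no downloads, no binary
# data. The alkane series provides a size ladder for scaling-shape checks.

.STO3G <- "
H 0
S   3   1.00
      3.42525091          0.15432897
      0.62391373          0.53532814
      0.16885540          0.44463454
****
He 0
S   3   1.00
      6.36242139          0.15432897
      1.15892300          0.53532814
      0.31364979          0.44463454
****
Li 0
S   3   1.00
     16.11957500          0.15432897
      2.93620070          0.53532814
      0.79465050          0.44463454
SP   3   1.00
      0.63628970         -0.09996723          0.15591627
      0.14786010          0.39951283          0.60768372
      0.04808870          0.70011547          0.39195739
****
C 0
S   3   1.00
     71.61683700          0.15432897
     13.04509600          0.53532814
      3.53051220          0.44463454
SP   3   1.00
      2.94124940         -0.09996723          0.15591627
      0.68348310          0.39951283          0.60768372
      0.22228990          0.70011547          0.39195739
****
O 0
S   3   1.00
    130.70932000          0.15432897
     23.80886100          0.53532814
      6.44360830          0.44463454
SP   3   1.00
      5.03315130         -0.09996723          0.15591627
      1.16959610          0.39951283          0.60768372
      0.38038900          0.70011547          0.39195739
****
"

.SV631G <- "
H 0
S   3   1.00
     18.7311370          0.03349460
      2.8253937          0.23472695
      0.6401217          0.81375733
S   1   1.00
      0.1612778          1.0000000
****
He 0
S   3   1.00
     38.4216340          0.0237660
      5.7780300          0.1546790
      1.2417740          0.4696300
S   1   1.00
      0.2979640          1.0000000
****
Li 0
S   6   1.00
    642.4189200          0.0021426
     96.7985150          0.0162089
     22.0911210          0.0773156
      6.2010703          0.2457860
      1.9351177          0.4701890
      0.6367358          0.3454708
SP   3   1.00
      2.3249184         -0.0350917          0.0089415
      0.6324306         -0.1912328          0.1410095
      0.0790534          1.0839878          0.9453637
SP   1   1.00
      0.0359620          1.0000000          1.0000000
****
C 0
S   6   1.00
   3047.5249000          0.0018347
    457.3695100          0.0140373
    103.9486900          0.0688426
     29.2101550          0.2321844
      9.2866630          0.4679413
      3.1639270          0.3623120
SP   3   1.00
      7.8682724         -0.1193324          0.0689991
      1.8812885         -0.1608542          0.3164240
      0.5442493          1.1434564          0.7443083
SP   1   1.00
      0.1687144          1.0000000          1.0000000
****
O 0
S   6   1.00
   5484.6717000          0.0018311
    825.2349500          0.0139501
    188.0469600          0.0684451
     52.9645000          0.2327143
     16.8975700          0.4701930
      5.7996353          0.3585209
SP   3   1.00
     15.5396160         -0.1107775          0.0708743
      3.5999336         -0.1480263          0.3397528
      1.0137618          1.1307670          0.7271586
SP   1   1.00
      0.2700058          1.0000000          1.0000000
****
"

# even-tempered auxiliary sets: tight s exponents plus spd sets (a D shell
# in the auxiliary dialect expands to the full |k| <= 2 Hermite set)
# one spd set per element: a second spd set makes the metric nearly
# singular (the trace of the Hermite d block re-spans the s ladder)
.AUX_SETS <- list(
  H  = list(s = c(7.2, 1.8, 0.45), spd = 1.0),
  He = list(s = c(14.4, 3.6, 0.9), spd = 1.6),
  Li = list(s = c(28.8, 7.2, 1.8, 0.45, 0.1125), spd = 0.35),
  C  = list(s = c(108, 27, 6.75, 1.69, 0.42), spd = 0.9),
  O  = list(s = c(200, 50, 12.5, 3.1, 0.8), spd = 1.6)
)

aux_text_for <- function(elements) {
  paste(vapply(unique(elements), function(el) {
    st <- .AUX_SETS[[el]]
    if (is.null(st)) stop("no auxiliary set for element ", el)
    lines <- c(paste(el, "0"))
    for (z in st$s) {
      lines <- c(lines, "S   1   1.00", sprintf("      %.8f   1.0", z))
    }
    for (z in st$spd) {
      lines <- c(lines, "D   1   1.00", sprintf("      %.8f   1.0", z))
    }
    paste(c(lines, "****"), collapse = "\n")
  }, character(1)), collapse = "\n")
}

# all-trans alkane C_n H_{2n+2} from tetrahedral geometry
alkane_geometry <- function(n) {
  dcc <- 1.54; dch <- 1.09
  th <- 109.47 * pi / 180
  sx <- dcc * sin(th / 2); sz <- dcc * cos(th / 2)
  C <- t(vapply(seq_len(n), function(i) {
    c((i - 1) * sx, 0, (i %% 2) * sz)
  }, numeric(3)))
  syms <- rep("C", n)
  H <- NULL
  unit <- function(v) v / sqrt(sum(v * v))
  for (i in seq_len(n)) {
    nb <- list()
    if (i > 1) nb <- c(nb, list(unit(C[i - 1, ] - C[i, ])))
    if (i < n) nb <- c(nb, list(unit(C[i + 1, ] - C[i, ])))
    if (length(nb) == 2L) {
      b <- unit(-(nb[[1]] + nb[[2]]))
      p <- unit(pracma::cross(nb[[1]], nb[[2]]))
      d <- th / 2
      H <- rbind(H,
                 C[i, ] + dch * (b * cos(d) + p * sin(d)),
                 C[i, ] + dch * (b * cos(d) - p * sin(d)))
    } else {
      a <- if (n == 1L) c(1, 0, 0) else nb[[1]]
      # three H at tetrahedral angle from the single C-C bond
      e1 <- unit(if (abs(a[3]) < 0.9) pracma::cross(a, c(0, 0, 1))
                 else pracma::cross(a, c(0, 1, 0)))
      e2 <- unit(pracma::cross(a, e1))
      ct <- cos(pi - th); st <- sin(pi - th)
      for (ph in c(0, 2 * pi / 3, 4 * pi / 3)) {
        dir <- a * ct + st * (e1 * cos(ph) + e2 * sin(ph))
        H <- rbind(H, C[i, ] + dch * dir)
      }
      if (n == 1L) {
        H <- rbind(H, C[i, ] + dch * a)  # methane: fourth H along axis
      }
    }
  }
  list(symbols = c(syms, rep("H", nrow(H))), coords = rbind(C, H))
}

#' Generate a fixture molecule with basis and auxiliary sets
#'
#' Emits a self-consistent (geometry, orbital basis, auxiliary basis)
#' triple as plain text, either returned or written to `dir`. Available
#' fixtures: `"h2"` (R = 1.4 bohr), `"heh+"` (charge +1), `"lih"`,
#' `"h2o"`, and `"linear_alkane(n)"` (all-trans C_n H_{2n+2}, the scaling
#' ladder). Orbital basis is the minimal STO-3G set; auxiliary sets are
#' even-tempered s/spd Hermite sets.
#'
#' @param name Fixture name (e.g. `"h2o"` or `"linear_alkane(4)"`).
#' @param dir Optional directory; when given, writes `<name>.xyz`,
#'   `<name>.basis`, `<name>.aux`.
#' @param basis_level `"minimal"` (STO-3G) or `"sv"` (6-31G split valence;
#'   the larger virtual space matters for structural comparisons between
#'   HDA and the full-exchange reference).
#' @return List with `xyz`, `basis`, `aux` (text), `charge` and `name`.
#' @examples
#' fx <- generate_fixture("h2")
#' cat(fx$xyz)
#' @export
generate_fixture <- function(name, dir = NULL,
                             basis_level = c("minimal", "sv")) {
  basis_level <- match.arg(basis_level)
  charge <- 0L
  alk <- regmatches(name, regexec("^linear_alkane\\((\\d+)\\)$", name))[[1]]
  if (length(alk) == 2L) {
    geo <- alkane_geometry(as.integer(alk[2]))
    mol <- molecule(geo$symbols, geo$coords * ANG2BOHR)
  } else {
    geo <- switch(tolower(name),
      "h2" = list(symbols = c("H", "H"),
                  coords = rbind(c(0, 0, 0), c(0, 0, 1.4))),
      "heh+" = {
        charge <- 1L
        list(symbols = c("He", "H"),
             coords = rbind(c(0, 0, 0), c(0, 0, 1.4632)))
      },
      "lih" = list(symbols = c("Li", "H"),
                   coords = rbind(c(0, 0, 0), c(0, 0, 3.014))),
      "h2o" = {
        r <- 0.9572 * ANG2BOHR
        a <- 104.52 * pi / 180
        list(symbols = c("O", "H", "H"),
             coords = rbind(c(0, 0, 0),
                            c(r * sin(a / 2), 0, r * cos(a / 2)),
                            c(-r * sin(a / 2), 0, r * cos(a / 2))))
      },
      stop("unknown fixture name: ", name)
    )
    mol <- molecule(geo$symbols, geo$coords, charge = charge)
  }
  els <- unique(mol$symbols)
  fx <- list(name = name,
             xyz = write_xyz(mol, comment = paste("fixture", name)),
             basis = if (basis_level == "sv") .SV631G else .STO3G,
             aux = aux_text_for(els),
             charge = charge)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    safe <- gsub("[^a-z0-9_]+", "_", tolower(name))
    writeLines(fx$xyz, file.path(dir, paste0(safe, ".xyz")))
    writeLines(fx$basis, file.path(dir, paste0(safe, ".basis")))
    writeLines(fx$aux, file.path(dir, paste0(safe, ".aux")))
  }
  fx
}

#' Instantiate a fixture as package objects
#'
#' Convenience wrapper: parse the fixture triple into a molecule, basis set
#' and auxiliary basis ready for [run_scf()].
#'
#' @param name Fixture name as in [generate_fixture()].
#' @param basis_level `"minimal"` or `"sv"`.
#' @return List with `molecule`, `basis`, `aux`.
#' @export
load_fixture <- function(name, basis_level = "minimal") {
  fx <- generate_fixture(name, basis_level = basis_level)
  mol <- parse_xyz(fx$xyz, charge = fx$charge)
  list(molecule = mol,
       basis = build_basis(mol, fx$basis),
       aux = build_aux_basis(mol, fx$aux))
}
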