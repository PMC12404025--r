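# Shared lazily-computed objects: SCF runs and coupling matrices are
# expensive, so test files share them through this memoizing cache.

.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .test_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .test_cache)
  }
  get(key, envir = .test_cache, inherits = FALSE)
}

fixture_objs <- function(name, basis_level = "minimal") {
  cached(paste0("fx_", name, "_", basis_level),
         load_fixture(name, basis_level = basis_level))
}

scf_for <- function(name, functional = "lda", basis_level = "minimal",
                    options = list()) {
  fname <- if (is.character(functional)) functional else functional$name
  key <- paste0("scf_", name, "_", fname, "_", basis_level, "_",
                paste(names(options), unlist(options), collapse = "_"))
  cached(key, {
    fx <- fixture_objs(name, basis_level)
    fn <- if (is.character(functional)) functional_preset(functional)
          else functional
    run_scf(fx$molecule, fx$basis, fx$aux, fn, options = options)
  })
}

O_for <- function(scf_key_name, scf, spin = "singlet") {
  key <- paste0("O_", scf_key_name, "_", spin)
  cached(key, {
    grid <- scf$cache$grid
    if (is.null(grid)) grid <- build_grid(scf$molecule, "default")
    rho_fit <- hdatd:::fitted_density_values(scf, grid)
    fn <- scf$functional
    variant <- if (fn$c_F == 0) "pure" else if (fn$beta == 0) "gh" else "rs"
    o_matrix(variant, scf$cache$metric, scf$cache$aux, grid, rho_fit, fn,
             spin = spin)
  })
}

# deterministic random rotation matrix
random_rotation <- function(seed) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(9), 3)))
}

rotate_molecule <- function(mol, R, shift = c(0, 0, 0)) {
  molecule(mol$symbols, mol$coords %*% t(R) +
             matrix(shift, nrow(mol$coords), 3, byrow = TRUE),
           charge = mol$charge)
}

# dense response matrix assembled directly from the formula pieces
# (independent of the operator's apply functions)
dense_omega <- function(op) {
  coup <- op$B3 %*% op$O %*% t(op$B3)
  diag(op$D^2, op$n) + 4 * outer(sqrt(op$D), sqrt(op$D)) * coup
}
dense_tda <- function(op) {
  diag(op$D, op$n) + 2 * op$B3 %*% op$O %*% t(op$B3)
}
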