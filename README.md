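# hdatd — density-fitted TD-DFT response with the hybrid diagonal approximation

`hdatd` computes vertical singlet and triplet excitation energies,
oscillator strengths and dynamic polarizabilities of closed-shell molecules
with linear-response TD-DFT built on **auxiliary density fitting**
(TD-ADFT), for pure, global-hybrid and range-separated-hybrid functionals.
It is aimed at method developers who want a compact, fully inspectable
implementation of the **hybrid diagonal approximation (HDA)** — the trick
that lets hybrid functionals ride on the index-aligned, matrix-free
eigenproblem structure of pure-functional TD-ADFT — together with the
oracles needed to measure exactly what the approximation does.

## The method in brief

For a pure functional the RPA response eigenproblem is
`Ω F = ω² F` with

```
Ω_ai,bj = (ε_a − ε_i)² δ_ab δ_ij
        + 4 (ε_a − ε_i)^{1/2} Σ_kl ⟨ai‖k⟩ O_kl ⟨l‖bj⟩ (ε_b − ε_j)^{1/2}
```

where `i,j` are occupied and `a,b` virtual canonical MOs, `k,l` primitive
Hermite Gaussian auxiliary functions, `⟨ai‖k⟩` three-center Coulomb ERIs,
and `O = G⁻¹ + G⁻¹⟨f_xc[ρ̃]⟩G⁻¹` couples through the inverse Coulomb metric
`G` and the XC kernel evaluated at the fitted density `ρ̃`. Because the ERI
indices stay aligned with the excitation-vector indices, `Ω` is applied
matrix-free at `O(N_occ·N_virt·N_aux)` cost per Davidson iteration.

Exact (Fock) exchange destroys that alignment. The HDA keeps only the
*diagonal* exchange elements, folded into orbital-energy shifts

```
Δ_ai = c_F Σ_kl M_ak G⁻¹_kl M_il ,   M_pk = ⟨pp‖k⟩ ,
```

so every `ε_a − ε_i` above becomes `ε_a − ε_i − Δ_ai` (with `O` adjusted for
the reduced local-exchange fraction) and the eigenproblem keeps its pure
form. Range-separated hybrids use the CAM operator
`(α + β·erf(ω_rs·r))/r`: the shift gains an `α`-weighted plain and a
`β`-weighted attenuated term, each with its own metric, and the local
kernel becomes the short-range exchange complement. A dense four-center
reference mode (`approximation = "oracle"`) solves the *full* hybrid
response problem and serves as the yardstick for the HDA error.

Everything underneath is self-contained: McMurchie–Davidson Gaussian
integrals (plain and erf-attenuated, two- to four-center), Boys function,
restricted Kohn–Sham SCF with density-fitted Coulomb term and exact
exchange, Becke-partitioned XC quadrature grids, LDA/VWN5 kernels with
analytic derivatives, and a Davidson eigensolver.

## Worked example

Ten-line HDA calculation on the built-in water fixture (STO-3G orbital
basis, even-tempered Hermite auxiliary set, PBE0-type mixing `c_F = 0.25`
on the LDA host):

```r
library(hdatd)
cfg <- run_config(fixture = "h2o", functional = "hyb25", n_roots = 6)
res <- run_pipeline(cfg)
print(res$scf)
print(res$excitations)
```

```
scf_result: E = -74.9603799713 Ha (7 iterations, functional hyb25)
  5 occupied / 2 virtual MOs; HOMO -0.161220, LUMO 0.375459 Ha
excitation_result: 6 roots (RPA, singlet)
   1    11.93108 eV   f =  0.00252   5->6 (1.00)
   2    14.21482 eV   f =  0.00000   5->7 (1.00)
   3    14.54796 eV   f =  0.05826   4->6 (0.96)
   4    17.76861 eV   f =  0.04266   4->7 (0.82)
   5    21.84179 eV   f =  0.90699   3->6 (0.82)
   6    26.71063 eV   f =  0.38337   3->7 (0.87)
```

Each row is one vertical singlet excitation: energy in eV, length-gauge
oscillator strength, and the dominant occupied→virtual pair with its
weight. Root 2 is dipole-forbidden by symmetry (`f ≈ 0`); root 5 is the
strong valence transition. For the same system `functional = "lda"` gives
the pure-functional spectrum (first root 11.50 eV) — the upward shift is
the diagonal exact-exchange correction, here `Δ_HOMO-LUMO ≈ 0.147 Ha`
acting through the square-root structure of `Ω`, not additively.

`excite(scf, ..., approximation = "oracle")` repeats the calculation with
every off-diagonal exchange element included; `spin = "triplet"` switches
to the kernel-only triplet coupling. `write_results_tsv()` and
`broadened_spectrum()` export the table and a Gaussian-broadened spectrum.
A command-line driver with `run`, `scf`, `excite`, `fixtures` and
`spectrum` subcommands is installed as `exec/hdatd`.

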