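---
title: "Hybrid diagonal approximation in density-fitted TD-DFT: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid diagonal approximation in density-fitted TD-DFT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, which
approximations it makes, and why the numerical machinery is built the way
it is. It states no measured numbers; every quantitative claim about the
implementation is asserted by the test suite or recomputed by
`scripts/acceptance.R`.

## 1. The response model

`hdatd` solves closed-shell linear-response TD-DFT in the Casida/RPA form
`ΩF = ω²F` on top of an auxiliary-density-fitted ground state. The
super-matrix elements for a pure (LDA-type) functional are

$$\Omega_{ai,bj} = (\varepsilon_a-\varepsilon_i)^2\,\delta_{ab}\delta_{ij}
 + 4(\varepsilon_a-\varepsilon_i)^{1/2}
 \sum_{\bar k\bar l}\langle ai\|\bar k\rangle\,O_{\bar k\bar l}\,
 \langle\bar l\|bj\rangle\,(\varepsilon_b-\varepsilon_j)^{1/2},$$

with occupied MOs $i,j$, virtual MOs $a,b$, primitive Hermite Gaussian
auxiliary functions $\bar k,\bar l$, the Coulomb operator $\|$, and

$$O = G^{-1} + G^{-1}\,\langle \bar m|f_{xc}[\tilde\rho]|\bar n\rangle\,G^{-1},$$

where $G_{\bar k\bar l}=\langle\bar k\|\bar l\rangle$ is the Coulomb metric
of the auxiliary set and $f_{xc}$ is evaluated at the *fitted* density
$\tilde\rho=\sum_{\bar k}x_{\bar k}\bar k(\vec r)$. The decisive structural
property is index alignment: the three-center ERIs carry exactly the
occupied–virtual index pattern of the excitation vector, so `Ω` is applied
matrix-free at $O(N_{occ}N_{virt}N_{aux})$ cost per Davidson iteration
(`response_op()`), and the dense matrix is never formed on the solution
path.

### The hybrid diagonal approximation

Fock exchange contributes $-c_F(ab|ij)$-type and $-c_F(aj|bi)$-type
elements whose indices do *not* align with the excitation vector. The HDA
retains only the diagonal $(aa|ii)$ elements, recast as orbital-energy
shifts

$$\Delta_{ai} = c_F \sum_{\bar k\bar l} M_{a\bar k}\,G^{-1}_{\bar k\bar l}\,
M_{i\bar l},\qquad M_{p\bar k}=\langle pp\|\bar k\rangle,$$

so that every $\varepsilon_a-\varepsilon_i$ in `Ω` becomes
$\varepsilon_a-\varepsilon_i-\Delta_{ai}$ while the coupling kernel loses
the exchanged local fraction,
$f_{xc}\to f_{xc}-c_F f_x$ for a global hybrid. The `M` matrix is built by
contracting per-MO pair densities $Q^p_{\mu\nu}=c_{\mu p}c_{\nu p}$ into
the shell-pair integral loop (`m_matrix()`), never materializing or
transforming the three-center tensor; the test suite pins this path to the
naive double MO transformation at 1e-12.

Range-separated hybrids split the operator as
$(\alpha+\beta\,\mathrm{erf}(\omega_{rs} r))/r$. The shift becomes
$\Delta^{RS}_{ai}=c_F(\alpha\,M G^{-1} M + \beta\,\bar M\bar G^{-1}\bar M)$
with attenuated integrals $\bar M$ and metric $\bar G$, and the local
kernel becomes the short-range exchange complement (Section 4). The global
hybrid is the exact special case $\alpha=1,\beta=0$; inverse range
separation (HSE-type, short-range Fock exchange) is expressed as
$\beta<0$ behind an explicit `inverse` flag. The convention throughout is
that `c_F` multiplies the whole exchange operator and $(\alpha,\beta)$
partition it, so CAM-type presets use `c_F = 1`.

### The exact-exchange reference

`reference_full_hybrid()` assembles the dense $(A\pm B)$ matrices with
*every* exchange element and solves
$(A-B)^{1/2}(A+B)(A-B)^{1/2}F=\omega^2 F$. Exchange ERIs are
density-fitted through the same metric as the shifts (the form the
response equations are written in), with an optional exact four-center
mode as a cross-check. Setting `hda_restrict = TRUE` zeroes all
off-diagonal exchange and reproduces the HDA operator identically — the
HDA is by construction the diagonal restriction of this reference, and the
acceptance suite asserts the reduction at 1e-10 eV.

### Spin channels and TDA

The paper-level theory prints only singlet RPA equations. Two completions
were needed and are deliberate design choices:

* **Triplet channel.** The Hartree term drops and the coupling matrix is
  kernel-only, $O_T=G^{-1}\langle f^T_{xc}\rangle G^{-1}$, with the
  standard closed-shell spin-flip LDA kernel: the exchange part equals the
  singlet exchange kernel (Dirac exchange is spin-scaling), the
  correlation part is the VWN5 spin stiffness $\alpha_c(r_s)/\rho$. The
  exchange shifts $\Delta_{ai}$ are spin-independent and retained
  unchanged, mirroring full TD-HF where the $(ab|ij)$ exchange terms are
  identical in both channels.
* **TDA.** `mode = "tda"` diagonalizes
  $A = (\varepsilon_a-\varepsilon_i-\Delta_{ai})\delta\delta + 2\,B_3 O
  B_3^T$ — the shift on the diagonal, singlet coupling factor 2 (versus 4
  in $A+B$). This is the natural diagonal restriction of the full TDA
  matrix and reduces exactly to it for one-pair systems.

Oscillator strengths use the length gauge,
$f_I=\tfrac23\,\omega_I|\vec d_I|^2$ with
$\vec d_I=\sum_{ai}\vec\mu_{ai}\sqrt{2(\varepsilon_a-\varepsilon_i-\Delta_{ai})/\omega_I}\,F_{ai}$
(the diagonal $(A-B)^{1/2}$ weighting; the dense reference uses the full
matrix square root). The average dynamic polarizability is the
sum-over-states expression
$\bar\alpha(\omega)=\tfrac13\sum_q\sum_I 2\omega_I d_{qI}^2/(\omega_I^2-\omega^2)$,
whose poles coincide with the excitation energies; the acceptance suite
verifies the sign change across every dipole-allowed root within a
$10^{-4}$ hartree bracket.

## 2. Ground-state host

The SCF is a conventional restricted Kohn–Sham loop hosting the fitted
machinery: Fock matrix $T+V+J[\tilde\rho]+V_{xc}+$ Fock exchange, with

* variational density fitting $x=G^{-1}J$ (Coulomb metric least squares),
  Coulomb energy $x^TJ-\tfrac12 x^TGx$;
* grid XC from the *orbital* density (the response kernel, by contrast,
  is evaluated at the fitted density — faithful to the ADFT response
  equations even though the SCF host is conventional; at fixture scale the
  difference is far below the approximation being studied);
* exact four-center Fock exchange with CAM splitting
  $c_F(\alpha K^{plain} + \beta K^{erf})$. Using exact rather than fitted
  exchange in the SCF isolates the HDA as the only response-side
  approximation;
* DIIS (depth 8) on the orthonormal-basis commutator $FPS-SPF$,
  core-Hamiltonian guess, convergence at $10^{-8}$ Ha energy and $10^{-6}$
  density RMS, 200-iteration cap. A degenerate HOMO at Aufbau filling
  (checked at the guess and every iteration, threshold $10^{-8}$ Ha) is a
  hard error: fractional occupation is unsupported.

`options$coulomb = "exact"` replaces the fitted Coulomb matrix by the
four-center one; with `c_F = 1`, no correlation and exact Coulomb the loop
is plain restricted Hartree–Fock, which the tests pin against an
independently coded closed-form RHF oracle at $10^{-8}$ Ha.

## 3. Integral engine

All integrals run through McMurchie–Davidson recurrences: Cartesian pair
densities are expanded in Hermite Gaussians ($E$ coefficients), Coulomb
interactions of Hermite distributions reduce to Boys-function ladders
($R$ integrals), and the auxiliary functions *are* primitive Hermite
Gaussians, so the three-center basic integral is the
$2\pi^{5/2}/(\zeta_p\zeta_{\bar c}\sqrt{\zeta_p+\zeta_{\bar c}})\,
\kappa_{AB}F_n(T)$ seed with the $(-1)^{|\bar k|}$ two-center expansion
phase; contraction happens after the recursion. The erf-attenuated
operator reuses the identical machinery with effective exponent
$\rho\,s$, $s=\omega^2/(\rho+\omega^2)$, and prefactor $\sqrt s$; the CAM
operator is the linear combination. Only the near-field (exact) pathway is
implemented — asymptotic far-field expansions are a large-system speed
optimization with no accuracy content at this scale.

The Boys function uses three regimes: the exact $1/(2n+1)$ limit at
$T<10^{-13}$; a Maclaurin series at the top order with downward recursion
below for $T<40$; and the closed incomplete-gamma form
$F_n(T)=\Gamma(n+\tfrac12)P(n+\tfrac12,T)/(2T^{n+1/2})$ (where $e^{-T}$ is
below double precision) beyond. Accuracy is pinned at $10^{-12}$ against
adaptive quadrature over an $(n,T)$ lattice up to $n=16$, $T=300$.

Independence of the oracles matters: the test-suite reference integrals
come from a quadrature scheme that shares nothing with the engine — the
$1/r_{12}=\frac{2}{\sqrt\pi}\int_0^\infty e^{-t^2r_{12}^2}dt$
representation (upper limit $\omega$ for the erf kernel), with the inner
6-d integral factorized per Cartesian direction and evaluated *exactly* by
2-d Gauss–Hermite quadrature, and the outer $t$ integral by adaptive
quadrature. No Boys function, no recursion.

### Numerical conditioning choices

Two conditioning issues shaped the auxiliary-basis handling:

* **Normalization.** Auxiliary functions are scaled to unit Coulomb
  self-energy at build time. This is a pure rescaling (fitting results are
  invariant) but bounds the metric's dynamic range; with raw primitives
  the diagonal spans six orders of magnitude and $G^{-1}$ amplifies
  response-operator roundoff past the $10^{-10}$ symmetry tolerance the
  tests demand.
* **Attenuated metrics.** The long-range kernel
  $\mathrm{erf}(\omega r)/r$ is smooth, so it nearly annihilates
  high-index Hermite functions and $\bar G$ is intrinsically
  ill-conditioned. Solves against non-plain metrics use a
  truncated-eigenvalue pseudo-inverse (relative threshold $10^{-12}$).
  The plain metric must be genuinely positive definite; a Cholesky
  failure raises a linear-dependence error naming the offending
  functions.

## 4. Exchange-correlation kernels

The local host is Dirac exchange plus VWN5 correlation. Analytic pieces:
$f_x=-\tfrac49 C_x\rho^{-2/3}$, the VWN5 $\varepsilon_c$ and $v_c$ from
the Padé parametrization, and the spin-stiffness $\alpha_c(r_s)$ for the
triplet kernel. Second derivatives that are unwieldy in closed form —
$f_c=\partial v_c/\partial\rho$ and the $\beta$-dependent part of the
short-range exchange kernel — use Richardson-extrapolated central
differences with relative steps ($10^{-3}\rho$ and $10^{-2}\rho$), pinned
against finite differences of the analytic potentials at $10^{-6}$.

The short-range exchange energy density is the standard attenuated-LDA
form

$$e_x^{SR}(\rho)=e_x^{LDA}(\rho)\Big[1-\alpha-\beta\Big(\tfrac83 a\big(
\sqrt\pi\,\mathrm{erf}(\tfrac1{2a})+2a(b-c)\big)\Big)\Big],\quad
a=\frac{\omega_{rs}}{2(3\pi^2\rho)^{1/3}},$$

with $b=e^{-1/(4a^2)}-1$ and $c=2a^2b+\tfrac12$ — algebraically identical
to the $(2a-4a^3)e^{-1/(4a^2)}-3a+4a^3$ attenuation function of the
range-separation literature. `expm1` keeps the large-$a$ cancellation at
machine precision. The three analytic limits are asserted:
$\alpha{=}1,\beta{=}0$ gives identically zero;
$\omega_{rs}\to0$ gives $(1-\alpha)\,e_x^{LDA}$;
$\omega_{rs}\to\infty$ gives $(1-\alpha-\beta)\,e_x^{LDA}$. The energy
limits are tested at the stand-ins $10^{-6}/10^4$ over densities
$\rho\in[0.5,8]$ a.u. (below $\rho\approx0.5$ the $O(\omega)$ residual of
the $\omega\to0$ limit exceeds $10^{-6}$ relative — an analytic property,
not an implementation artifact). For the *metric* limits the residual
scales as $O(\omega)$ times the squared spatial integral of an s-type
auxiliary function, so those limits are tested at $10^{-12}/10^{6}$,
where the bound is attainable, plus exact equality at $\omega=0$.

Kernel matrices $\langle\bar m|f|\bar n\rangle$ are grid sums, assembled
as sign-split crossproducts so symmetry is exact by construction, with
density screening at $\tilde\rho<10^{-8}$: the LDA kernel diverges as
$\rho^{-2/3}$ (and $1/\rho$ for the triplet correlation) while the true
integrand vanishes Gaussian-fast, and the *fitted* density even dips
slightly negative in the far tails, so the ill-defined tail points are
excluded rather than clamped into the quadrature.

## 5. Quadrature grid

Atom-centered grids: Gauss–Chebyshev (second kind) radial points under the
Becke map $r=R_m(1+x)/(1-x)$ with loosely element-dependent $R_m$, a
Gauss–Legendre($\cos\theta$) × uniform($\varphi$) angular product grid,
and Becke fuzzy-cell partitioning (three smoothing iterations, no size
adjustment). Levels: coarse $35\times14\times28$, default
$60\times20\times40$, fine $90\times28\times56$ (radial × θ × φ per atom).
The product grid replaces the Lebedev tables that molecular codes usually
embed: at these molecule sizes the accuracy target (single-Gaussian
normalization at $10^{-8}$, kernel-matrix Cauchy convergence below
$10^{-5}$ between default and fine) is met without carrying large node
tables, at the cost of more angular points per degree.

The angular grid is attached to a **deterministic molecule-fixed frame**
(principal axes of the nuclear-charge-weighted second-moment tensor,
eigenvalue-ordered, signs fixed by largest component, right-handed), which
makes every grid integral exactly equivariant under rigid rotation — a
lab-fixed grid is rotation invariant only to quadrature accuracy, which is
orders of magnitude short of the $10^{-8}$ invariance contract. For
degenerate principal moments the in-subspace axes are arbitrary; for
linear molecules that ambiguity is itself a symmetry of the geometry and
leaves all scalars unchanged, while for spherical tops (not among the
fixtures) invariance degrades to quadrature accuracy.

## 6. Fixtures: what they emulate, what they do not

`generate_fixture()` emits self-consistent geometry/basis/auxiliary
triples entirely in code: H₂ (R = 1.4 bohr), HeH⁺, LiH, H₂O, and all-trans
linear alkanes CₙH₂ₙ₊₂ as a size ladder. Orbital bases are STO-3G
(`basis_level = "minimal"`) or 6-31G (`"sv"`); auxiliary sets are
even-tempered, one s ladder plus **one** spd Hermite set per element — a
second spd set makes the metric numerically singular, because the trace of
the Hermite d block re-spans the s ladder. Exponent ranges were chosen
once for sane fitting and metric condition numbers ($\lesssim10^6$) and
are not tuned thereafter.

These fixtures exercise every code path (contracted s/p shells, Hermite
s/p/d auxiliaries, charged species, both spin channels, both response
modes, CAM attenuation) but they are *toy systems*: minimal/split-valence
bases, no diffuse functions, tiny virtual spaces, no Rydberg or
charge-transfer states, and auxiliary sets far smaller than production
fitting sets. Passing tests therefore demonstrate correctness of the
implemented equations and the structural properties of the HDA — not
production accuracy of excitation energies against experiment.

One structural finding deserves emphasis: the qualitative behavior of the
HDA error depends on the virtual-space size. With minimal-basis water
(two virtuals) the singlet HDA-vs-reference deviation *exceeds* the
triplet one, dominated by the dropped $(ai|ai)$ diagonal of the
$B$-exchange; with split-valence fixtures the expected ordering — singlet
deviations at or below triplet deviations — is restored across molecules,
functionals and both RPA/TDA. The structural acceptance check therefore
runs on the split-valence suite (H₂, LiH, H₂O × `hyb25`, `cam` × RPA,
TDA; lowest ≤ 10 roots), sizes chosen so the whole suite completes in a
few minutes on one core.

## 7. Solver numerics

* **Davidson**: deterministic start on the `n_roots` smallest diagonal
  entries (ties broken by pair index), residual tolerance $10^{-6}$,
  subspace cap $12\,n_{roots}$ with collapse restart onto the Ritz
  vectors, double Gram–Schmidt orthogonalization, diagonal
  preconditioner. On fixture-sized pair spaces the subspace legitimately
  reaches the full dimension, at which point the result is exact;
  equality with dense diagonalization is asserted at $10^{-8}$ eV.
* **Eigenvector sign**: fixed by making the largest-magnitude component
  positive, so repeated runs are bitwise identical.
* **Instabilities**: any non-positive shifted diagonal
  $\varepsilon_a-\varepsilon_i-\Delta_{ai}\le0$ aborts with the offending
  pairs listed; a non-positive-definite $A-B$ or negative $\omega^2$ in
  the dense reference raises an instability error rather than returning
  complex roots.
* **Units**: hartree internally; reported eV via
  1 Ha = 27.211386245988 eV; geometry input Å with
  1 Å = 1.8897261254578281 bohr.

## 8. Known limitations

* LDA (Dirac + VWN5) local host only; GGA enhancement factors enter the
  formulas (`Fx`) but no GGA kernels are implemented. Cartesian Gaussians
  throughout, so d-shell counts differ from spherical-harmonic codes.
* Closed-shell systems only; fractional occupation and open shells are
  hard errors, not approximations.
* The triplet HDA construction is a standard completion, not a derived
  result; the full-exchange reference is the arbiter of its quality, and
  the tests only assert the *relative* singlet/triplet structure.
* Four-center ERIs (SCF exchange, oracle mode) are guarded to ≤ 120 basis
  functions; the matrix-free HDA path itself has no such guard but has
  only been exercised at fixture scale.
* The sum-over-states polarizability needs the full spectrum and is
  therefore a dense-mode, fixture-scale tool.
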