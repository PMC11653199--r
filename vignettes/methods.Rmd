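---
title: "Hybrid variational-quantum surface hopping: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid variational-quantum surface hopping: models, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`vqehop` couples a variational-quantum electronic-structure engine to a
fewest-switches surface-hopping (FSSH) driver. This vignette documents
the model, the conventions the implementation pins down, the places
where the design was genuinely open and what was decided, and what the
shipped fixtures do and do not demonstrate.

## Electronic structure

The active-space electronic Hamiltonian at nuclear configuration $R$ is

$$\hat H(R) = \sum_{rs} h_{rs}(R)\, a_r^\dagger a_s
 + \tfrac12 \sum_{pqrs} g_{pqrs}(R)\, a_p^\dagger a_q^\dagger a_s a_r
 + E_{\mathrm{core}}(R),$$

with spin orbitals interleaved (α of spatial orbital $p$ on qubit $2p$,
β on $2p+1$). The interleaved ordering is a choice — it keeps the paired
double excitations of the ansatz local on the qubit register. The
constant $E_{\mathrm{core}}$ carries nuclear repulsion plus any frozen
core; because it is differentiated along with everything else, state
gradients are complete expectation values of one derivative operator.

The Jordan–Wigner transformation maps ladder operators to Pauli strings
with Z parity chains. Pauli words are stored in symplectic (x, z) bit
masks; operators up to 60 qubits are supported for counting and
grouping, while statevector work is limited to what dense amplitudes
allow (≤ 20 qubits, in practice ≤ 12 for the dense oracles). Qubit
Hamiltonian coefficients are pruned below $10^{-12}$; this stabilizes
term counting, which matters because the package reports measurement
statistics.

### Measurement grouping conventions

Two counters are deliberately exported, because the phrase "native
Pauli bases" is used loosely in the literature:

* `count_pauli_strings()` — the number of distinct Pauli words,
  including the identity/constant term. This is the count of
  measurement circuits when every string is measured in its own basis,
  and it is the convention under which the canonical H2/STO-3G
  Hamiltonian has 15 strings and the symmetry-blocked
  (4 electron, 3 orbital) π/σ/π\* ethylene-like Hamiltonian has exactly
  34.
* `count_native_pauli_bases()` — greedy qubit-wise wildcard merging
  (two words share a basis iff on every qubit their factors agree or
  one is identity). The same two Hamiltonians give 5 and 9.

`group_commuting_cliques()` partitions the words into *fully* commuting
cliques by greedy first-fit over words sorted by Pauli weight
(descending, ties lexicographic). The ordering is part of the
algorithm's definition: it is seedless and deterministic, gives 2
cliques for H2, 3 for the (4e, 3o) Hamiltonian (provably optimal there:
a 2-coloring of its anticommutation graph does not exist), and 497 for
the structural full-6-31G Hamiltonian described next.

### The ethylene-like structural Hamiltonians

No self-consistent-field engine is part of this package (a deliberate
non-goal; integrals come from pluggable providers). The shipped
ethylene fixtures therefore encode *symmetry structure* rather than ab
initio numbers, and are labelled synthetic. The point they support is
that Pauli-string counts are invariants of which integrals the orbital
symmetries allow, not of the integral values:

* `ethylene_4e3o_synthetic_integrals()` — the π, σ and π\* orbitals of
  planar ethylene belong to three distinct D2h irreps, so the
  one-electron matrix is diagonal and only Coulomb/exchange-type
  two-electron integrals survive. Any generic values with that sparsity
  yield 34 Pauli strings on 6 qubits.
* `ethylene_631g_structural_hamiltonian()` — the full 6-31G orbital
  space of ethylene has symmetry-adapted function counts
  7 a_g, 7 b_1u, 4 b_2u, 4 b_3g, 2 b_3u, 2 b_2g; freezing the two
  carbon-1s core MOs leaves 24 orbitals (48 qubits) with multiset
  {6, 6, 4, 4, 2, 2}. Generic coefficients on the symmetry-allowed
  integrals give exactly 73 089 Pauli strings, grouped into 497
  commuting cliques. Building the operator takes ~20 s and the clique
  grouping ~3–4 min on one core; both are exercised in the validation
  suite at exactly this size.

## The variational solvers

The k-UpCCGSD ansatz applies, per layer, all spin-adapted generalized
singles over spatial pairs $p<q$ and all paired doubles
$(p\alpha,p\beta)\to(q\alpha,q\beta)$; $k$ layers are concatenated (6
parameters per layer for 3 spatial orbitals). Each generator's
Jordan–Wigner image has mutually commuting Pauli terms, so realizing
the exponential as one rotation per term in a pinned lexicographic
order is a convention, not a Trotter error. The reference is the
closed-shell determinant; particle number, $S_z$ and total spin are
conserved at every angle, which is why deflation never needs spin
penalties but also why only singlet states are reachable.

VQE/VQD minimize with BFGS (`stats::optim`), iteration cap 500,
gradient tolerance $10^{-6}$, using *analytic* gradients from an
adjoint (reverse-sweep) differentiation of the rotation circuit — cost
and gradient together cost about three state preparations. The VQD
cost adds $\sum_j \lambda_j |\langle\Psi(\theta)|\Psi_j\rangle|^2$;
overlaps are evaluated directly on statevectors, which is
mathematically identical to the projector form used on hardware.

Two practical behaviors are worth recording:

* **Cold starts sit on a stationary point.** At $\theta=0$ the state is
  the Hartree–Fock reference; by Brillouin's theorem the energy
  gradient along every single excitation vanishes, and the deflation
  penalty's gradient vanishes there too. Plain gradient descent from a
  cold start therefore often converges to the (deflated) ground state
  and flags a collapse. `vqd()` answers with a small deterministic
  multistart (perturbed starting vectors tried in a fixed order until
  one converges orthogonally). Warm starts along a trajectory — the
  production mode — do not need it.
* **The penalty weight must exceed the target gap.** The default
  $\lambda = |E_{\mathrm{gs}}|$ (the customary heuristic) is valid for
  bound states with negative total energy. H2/STO-3G's third singlet
  lies at +0.48 hartree, above what $\lambda = 1.14$ can enforce, so
  the three-state tests pass an explicit $\lambda = 2.5$. The model
  fixtures carry a constant core shift of −2 hartree for the same
  reason: it makes their total energies bound-molecule-like without
  touching forces, couplings or dynamics.

Per-state ansatz depth is configurable (`ansatz_policy`): `"uniform"`
(default, one ansatz for all states — adequate for the 2- and
3-orbital spaces used here) or `"grow"` (state $m$ gets $m$ layers with
the lower layers frozen at warm-start values). The published angle
counts for state-specific extended ansätze do not fully determine the
freezing pattern, so both readings are exposed rather than asserting
either.

## Properties

Gradients use only the Hellmann–Feynman term,
$\langle\Psi_m|\partial\hat H/\partial R_{I\xi}|\Psi_m\rangle$, with
the Hamiltonian derivative from 0.001-Å central differences; Pulay
terms are neglected by design (their neglect is validated against
central differences of the *energy* in the test suite, which agree to
5×10⁻⁵ hartree/bohr on the fixtures). Approximate nonadiabatic
couplings divide the off-diagonal derivative matrix element by the
energy gap; the convention is $d_{ml} =
\langle\Psi_m|\partial\hat H/\partial R|\Psi_l\rangle/(E_l-E_m)$,
antisymmetric under $m\leftrightarrow l$. Gaps below $10^{-6}$ hartree
are floored and flagged rather than amplified — safe here because the
dynamics never consumes raw NACs (local diabatization does the
propagation); the vectors are diagnostics. Oscillator strengths use the
length gauge, $f = \tfrac23|\Delta E|\,|\mu|^2$ in atomic units.

## Cross-step overlaps and local diabatization

Each converged state is exported as a CI-type expansion (determinant
strings, amplitudes above $10^{-6}$, the geometry's MO matrix).
Determinant-pair overlaps factorize over spin blocks into determinants
of occupied submatrices of the provider's MO cross-overlap matrix, and
are cached by occupation-string pair across the state matrix — the
dominant cost control at larger active spaces.

The propagation per nuclear step: Löwdin-orthogonalize the overlap
matrix ($T = S(S^TS)^{-1/2}$, computed from the SVD polar factor), flip
columns so $\operatorname{diag}(T)\ge 0$ (the global phase of each
state between steps is otherwise undefined), set $H(t)=\mathrm{diag}
(E_t)$ and $H(t+\Delta t) = T\,\mathrm{diag}(E_{t+\Delta t})\,T^T$,
interpolate $H$ linearly across the electronic substeps, and advance
the diabatic coefficients with the exponential midpoint rule (exact
for piecewise-constant $H$). A smallest singular value of $S$ below
$10^{-6}$ raises an explicit trivial-crossing error naming the state
— the configured response is to rerun with a smaller nuclear step, not
to regularize silently. Against an independent NAC-based TDSE
integration on the analytic model, the LD populations converge with
observed order ≥ 2 in the step size and agree to $10^{-4}$ at fine
steps.

## Hopping, decoherence, bookkeeping

The fewest-switches literature in the local-diabatization setting does
not pin one formula; the choice here (documented as this package's
principal formula-level decision) apportions the active state's net
population loss over the step among targets by the propagator flux
$|P_{lm}|^2$, clamped at zero. This retains the fewest-switches
essence — the total hop probability equals the fractional population
loss, so ensemble hop statistics match the population flux — and gives
exactly zero hops for diagonal propagators or non-decreasing active
population. Hops rescale velocities along the nuclear momentum so
total energy is conserved to $10^{-10}$ hartree; energetically
forbidden hops are frustrated with velocities unchanged (no reversal).
The energy-based decoherence correction damps inactive amplitudes with
$\tau = (1/|\Delta E|)(1 + C/E_{\mathrm{kin}})$, $C = 0.1$ a.u.;
vanishing kinetic energy suppresses the decay (the $\tau\to\infty$
limit), and degenerate pairs do not decohere.

Defaults mirror small-imine practice: 0.5 fs nuclear and 0.02 fs
electronic steps, 150 fs maximum, early stop after 20 fs of continuous
ground-state dwell (10 fs for the faster ethylene-like runs), and a
0.2 eV total-energy drift threshold for discarding a trajectory (the
discard rule is standard; the threshold value is this package's
choice, as published work rarely prints one). Trajectory RNG is
counter-based (base seed + trajectory index), so ensembles are
reproducible and extendable.

## Initial conditions

Hessians are built fully numerically from ground-state energies
(3-point diagonal, 4-point mixed central differences, displacement
0.01 bohr — energies rather than gradients because the variational
energies are the cheapest robust quantity, and the displacement is a
stability choice). Normal modes come from the mass-weighted Hessian
with translations and rotations projected out. Wigner sampling draws
mass-weighted $(Q, P)$ per mode from the $v=0$ Gaussians
($\sigma_Q^2 = \hbar/2\omega$, $\sigma_P^2 = \hbar\omega/2$); no
rotational sampling is imposed. Ensemble spectra place a Gaussian of
area $f$ at each vertical excitation (FWHM 0.1 eV by default — a
display choice); initial states are selected by acceptance-rejection
with probability $f/p_{\mathrm{norm}}$ inside the excitation window,
with $p_{\mathrm{norm}}$ defaulting to 1.01× the largest in-window
strength.

## Kinetics and outcome analysis

Populations are fractions of trajectories per active state;
early-terminated trajectories are held at their final (ground) state,
matching the early-stop protocol (a flag switches to dropping them
from the denominator instead). The delayed-exponential model is
$P(t)=1$ for $t\le t_0$, $e^{-(t-t_0)/\tau_1}$ after, lifetime
$\tau_1+t_0$; the two-step irreversible model uses
$P_{S_2}=e^{-t/\tau_2}$ and the standard A→B→C intermediate closed
form with its equal-rate limit $t\,e^{-t/\tau}/\tau$ handled
analytically. Fits are unweighted least squares on the grid. Dihedrals
follow the IUPAC right-hand sign convention and are folded to
[0°, 180°] for cis/trans classification; the quantum yield counts
ground-state trajectories with folded dihedral ≤ 50° as reactant,
≥ 125° as photoisomerized, leaves the band between unassigned and out
of the denominator, and reports the binomial standard deviation
$\sqrt{\Phi(1-\Phi)/n}$.

## What the fixtures emulate — and what they do not

The analytic avoided crossing (`make_avoided_crossing`: linear diabats,
Gaussian coupling) and its bound sibling (`make_bound_crossing`:
harmonic wells, vertical excitation 0.15 hartree, crossing at
$R = 3$ bohr) supply closed-form surfaces, couplings and eigenvector
frames, and double as 2-electron/2-orbital fermionic providers whose
two lowest singlets reproduce the model exactly (closed-shell
determinants as diabats, exchange integral as coupling, open-shell
states pushed up by a large inter-orbital Coulomb term). Every stage —
FCIDUMP I/O, JW, VQE/VQD, gradients, CI overlaps, LD-FSSH, Hessians,
Wigner, kinetics — runs end-to-end on them in seconds to minutes.

What passing on these fixtures shows: the algebra, the propagators,
the conservation laws, the estimators and their couplings are correct
against independent oracles (dense diagonalization, permutation-sum
overlaps, NAC-based TDSE, closed-form kinetics). What it does not
show: behavior on real polyatomic surfaces — orbital-rotation
discontinuities of small active spaces, trivial crossings in dense
state manifolds, anharmonicity beyond the harmonic Wigner picture.
Those require an ab initio provider implementing the
`electronic_structure_provider` contract (integrals, MO coefficients,
cross-geometry MO overlaps, dipole integrals); none ships with this
package.

## Problem sizes used in the validation suite

Dense oracles run at 4–6 qubits; the structural measurement-grouping
study at 48 qubits (73 089 strings); model-driver FSSH ensembles at
120 trajectories × ~110 fs against an independent NAC-FSSH reference;
the VQE/VQD-driven trajectory at 60–160 steps of 0.5 fs; Wigner moment
checks at 10⁴ samples; kinetic-fit recoveries at the published
ensemble sizes (141 and 85 trajectories) with 20 000-trajectory runs
for the law-of-large-numbers checks. These sizes were chosen so the
whole suite documents the method at desk scale.
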