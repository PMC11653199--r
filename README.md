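# vqehop

Surface-hopping nonadiabatic molecular dynamics with a variational-quantum
electronic-structure engine, in R.

## The problem

Photochemistry — *cis–trans* isomerization of imines, ultrafast internal
conversion of ethylene — is governed by nuclear motion across several
coupled electronic surfaces. Mixed quantum–classical methods treat the
nuclei as classical trajectories on one adiabatic potential energy surface
at a time, with stochastic "hops" between surfaces mimicking the electronic
population flux (Tully's fewest-switches surface hopping, FSSH). The
bottleneck is the electronic structure that must be solved at every time
step. `vqehop` implements the hybrid quantum–classical variant of this
workflow: the electronic states come from statevector simulation of the
variational quantum eigensolver (VQE) for the ground state and
penalty-based variational quantum deflation (VQD) for excited states,

- E₀ = min_θ ⟨Ψ(θ)|Ĥ|Ψ(θ)⟩,   Eₘ from min_θ ⟨Ĥ⟩ + Σ_{l<m} λ_l |⟨Ψ(θ)|Ψ_l⟩|²,

with the active-space Hamiltonian Ĥ(R) = Σ h_rs a†_r a_s + ½ Σ g_pqrs
a†_p a†_q a_s a_r + E_core(R) mapped to qubits by the Jordan–Wigner
transformation and the trial state built from the k-UpCCGSD ansatz
(generalized singles plus paired doubles, k layers). From the converged
states the package forms Hellmann–Feynman gradients ⟨Ψₘ|∂Ĥ/∂R|Ψₘ⟩ via
0.001-Å central differences of the Hamiltonian, approximate nonadiabatic
couplings ⟨Ψₘ|∂Ĥ/∂R|Ψ_l⟩/(E_l−Eₘ), transition dipoles and oscillator
strengths, and CI-type determinant expansions whose cross-time-step
overlap matrix S_ml = ⟨ψₘ(t)|ψ_l(t+Δt)⟩ drives the local-diabatization
propagation of the electronic coefficients (Löwdin-orthogonalized T,
linearly interpolated diabatic H, exponential-midpoint substeps). The
nuclear side is velocity Verlet with fewest-switches hops, exact-energy
velocity rescaling along the momentum, and the Granucci–Persico
energy-based decoherence correction (C = 0.1 a.u.). Initial conditions
come from fully numerical Hessians, harmonic Wigner sampling of the
ground vibrational state, nuclear-ensemble absorption spectra and
oscillator-strength-weighted state selection; analysis tools cover
population kinetics (delayed-exponential and two-step sequential fits),
hopping-geometry statistics and photoisomerization quantum yields.

Everything runs against pluggable electronic-structure providers. Two
analytic providers ship with the package — a 1-D avoided crossing and its
exact 2-electron/2-orbital fermionic embedding — so the entire pipeline,
from FCIDUMP to population fits, is exercisable on a laptop with no
external quantum-chemistry code. Measurement-grouping tools
(`count_pauli_strings`, `count_native_pauli_bases`,
`group_commuting_cliques`) analyze how many distinct measurement settings
a hardware run of the same Hamiltonians would need.

## Worked example

A photoexcitation cartoon: harmonic ground well, displaced excited well,
Gaussian coupling at the curve crossing — solved by the full
VQE/VQD + FSSH machinery through its fermionic embedding.

```r
library(vqehop)

model  <- make_bound_crossing()           # two-state model, crossing at R = 3
prov   <- two_level_provider(model)       # 2e/2o fermionic embedding, 4 qubits
aspace <- active_space(2, 2)
ansatz <- build_kupccgsd(4, 2, k = 1)

# electronic structure at the Franck-Condon point
H  <- build_qubit_hamiltonian(prov, two_level_geometry(0), aspace)
ss <- solve_state_set(H, n_states = 2, ansatz)
ss
#> <electronic_state_set: 2 states>
#>   S0  E = -2.0000000000 hartree (1 iterations)
#>   S1  E = -1.8500000000 hartree (13 iterations)

# one surface-hopping trajectory starting on S1
drv <- vqe_sh_driver(prov, aspace, n_states = 2, ansatz)
cfg <- sh_config(n_states = 2, dt_nuclear = 0.5, dt_electronic = 0.02,
                 max_time = 80, ground_state_dwell = 15, seed = 5)
tr <- run_trajectory(list(geometry = two_level_geometry(0),
                          velocities = matrix(0, 2, 3), state = 2L),
                     drv, cfg)
tr
#> <trajectory: 62 steps, final state S0, 1 hops (0 frustrated),
#>  drift 4.98e-04 hartree, ground_dwell>
```

The S0/S1 vertical gap at the start is 0.150 hartree (the model's
`e_vert`); the trajectory slides down the upper surface, hops to the
ground state near the avoided crossing at 16 fs (rescaling the
velocities so total energy is conserved exactly), and is stopped by the
15-fs ground-state dwell rule with a total-energy drift of 5e-4 hartree.

Measurement grouping on the shipped ethylene-like (4e, 3o) active-space
Hamiltonian:

```r
ints <- read_fcidump(system.file("extdata",
        "ethylene_4e3o_631g_synthetic.fcidump", package = "vqehop"))
H <- jordan_wigner(second_quantized_hamiltonian(ints))
count_pauli_strings(H)            # 34 native Pauli bases
length(group_commuting_cliques(H))  # 3 commuting cliques
```

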