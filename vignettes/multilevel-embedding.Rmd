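---
title: "Multilevel embedding, transfer-learned potentials and end-state corrections: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel embedding methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`hiqem` is a desk-scale toolkit for a three-level QM(HL)/QM(LL)/MM modelling
strategy: small *quantum cores* inside a larger quantum region are treated
with a correlated wave-function method via Huzinaga-type projection-based
embedding; the resulting high-accuracy energies refine a machine-learned
potential by transfer learning; and the refined potential corrects a
classical binding free energy through nonequilibrium switching at the end
states of a thermodynamic cycle.  Every stage operates on seeded synthetic
inputs — model Hamiltonians and a three-tier toy potential-energy surface —
so the full pipeline runs in minutes on one CPU with no external data.

This vignette records the model assumptions, the numerical choices and the
places where the design was genuinely open, in the order the pipeline runs.

# Projection-based multi-orbital-set embedding

## The model systems

Real molecular integrals are out of scope.  `gen_model_system()` builds
closed-shell model Hamiltonians: a one-electron matrix with a gapped
on-site ladder and nearest-neighbour hoppings, an exponentially decaying
symmetric positive-definite overlap, and a two-electron tensor assembled as
a sum of atom-centered separable terms `g_pqrs = sum_k L^k_pq L^k_rs`.  The
separable form guarantees the 8-fold permutational symmetry and a
positive-semidefinite Coulomb metric by construction.  External point
charges enter the one-electron matrix through a diagonal attraction term,
which reproduces the correct `qQ/R` multipole limit for distant charges.
The on-site ladder (0.5 hartree ramp with ±0.15 jitter) is deliberate: it
keeps the mean-field spectrum gapped at the Fermi level so that the
closed-shell determinant is well defined across seeds.

## Mean-field reference

`run_scf()` is a restricted closed-shell SCF (energy tolerance 1e-10
hartree, at most 200 iterations).  The iteration strategy is layered:
DIIS-accelerated Roothaan steps with an optimal-damping line search when
the DIIS residual is large, level-shifted retries if the fixed-point
iteration oscillates, and — as a last resort — direct minimization of the
energy over occupied–virtual orbital rotations (BFGS on the rotation
parameters, always a valid determinant), followed by semicanonicalization.
The decomposition identity below holds for *any* orthonormal determinant,
so the solver hierarchy affects robustness, not correctness.

Two exchange-correlation models exist.  `"hf"` is Hartree–Fock: the XC
functional is identically zero and exact exchange is carried by the
mean-field two-electron operator `G[D] = J[D] - K[D]/2`.  `"toy-local"` is
a grid-free local functional defined directly on the basis representation
of the density, `E_xc[D] = -c * sum_p max(D_pp, 0)^(4/3)`, with its
matching diagonal derivative potential.  It provides a nonzero nonadditive
XC coupling between orbital sets without any quadrature machinery.

## Orbital localization and partitioning

Occupied orbitals are localized with Pipek–Mezey Jacobi sweeps on Mulliken
populations (convergence when the metric gain per sweep drops below 1e-10;
columns ordered by leading atomic population; signs fixed by the
largest-magnitude coefficient).  Partitioning follows a two-step rule: an
orbital whose Mulliken population on the environment atoms strictly
exceeds 0.4 goes to the low-level (LL) set; otherwise it goes to the core
on which its population is largest, with exact ties broken toward the
lowest core index.  The strict ">" and the tie-break are deliberate,
documented conventions.

## Embedded cores and the energy decomposition

For core *I* the embedded one-electron operator is

    h_eff = h_core + v_xc_nadd,I + v_C,I + p_I

where `v_xc_nadd,I` is the difference of XC potentials at the total and
core densities, `v_C,I` is the mean field of all electrons outside the
core, and `p_I = -[P (f - eps) + (f - eps) P]` is the level-shifted
projector against the other sets' occupied spaces (`eps` defaults to
1.0 hartree).  Because the core orbitals are orthogonal to the other
occupied sets, the projector contributes nothing at the determinant level
and nothing inside the FCI space (core occupieds plus shared virtuals);
the assembled energy is therefore exactly independent of `eps`, which the
tests verify over 0.1–10 hartree.

The total QM energy decomposes as

    E_QM = sum_I E_I^QC + E_LL + E_rest + E_nuclear

`E_I^QC` is the expectation of the embedded core Hamiltonian — the
modified one-electron part plus the bare two-electron interaction among
core electrons — evaluated either over the frozen core determinant
(`solver = "determinant"`, no embedded re-optimization) or by
determinant-basis FCI in the core-occupied ⊕ shared-virtual space
(`solver = "fci"`, capped at 12 spatial orbitals with an explicit
virtual-truncation option).  `E_LL` is the usual mean-field expression over
the LL density; `E_rest` collects the nonadditive XC energy, subtracts the
nonadditive-potential expectation values already inside the core
Hamiltonians, and removes the double-counted inter-core interaction.  All
`E_rest` densities are mean-field densities, never correlated ones.

Two design points deserve emphasis:

* **Exactness in hf mode.**  With exact exchange carried by the mean-field
  operator (in `v_C,I`, in the LL two-electron term and in the inter-core
  correction), the determinant-level decomposition reproduces the
  undecomposed SCF energy to machine precision for *every* partition.
  This is the central correctness oracle of the module: the acceptance
  suite checks it over 20 seeded systems and every enumerable one- and
  two-core atom grouping, at 1e-10 hartree.  A consequence of this
  formulation is that the "inter-core Coulomb" correction carries the
  inter-core exchange as well in hf mode; in `toy-local` mode `v_C` is a
  pure Coulomb operator and the correction is pure Coulomb, as in a
  conventional Kohn–Sham embedding.
* **Nuclear repulsion.**  The LL energy excludes it; the assembled
  `e_qm` includes it as an explicitly itemized term, so the all-LL
  partition reproduces the SCF reference.

Closed-shell systems only; odd electron counts are rejected everywhere.

# The learned potential

## Descriptors

Atom-centered symmetry functions with element weighting: five radial
Gaussians (width 4 1/A^2, centers 1.0–3.5 A) and four angular functions
(zeta in {1, 4}, lambda = ±1), under a cosine cutoff at 5 A whose value
and first derivative vanish at the cutoff.  Element weights embed all
elements in one descriptor set, so a single network per element sees a
chemistry-aware but fixed-dimension input.  Analytic Cartesian Jacobians
of every descriptor are implemented and verified against central finite
differences at 1e-6.

## Networks, training and the optimizer

Each ensemble member holds one feedforward network per element
(descriptor → 25 → 25 → atomic energy, tanh activations); the molecular
energy is the sum of atomic outputs, and forces are the exact negative
gradient through the descriptor Jacobians.  The loss is
`mean((dE/n_atoms)^2) + lambda_F * mean(dF^2)` with `lambda_F = 0.01`
chosen so both terms start at a comparable order of magnitude on the toy
surfaces.  The gradient of the force term with respect to the weights
(a double-backprop quantity) is implemented in closed form and verified
against finite differences.

Training is full batch with a per-weight adaptive step-size optimizer of
the Rprop family: each weight carries its own step size, grown by 1.2 when
the gradient sign persists and halved when it flips, with the update
skipped after a sign flip.  Two properties motivated this choice over a
moment-based update: the per-weight state survives naturally from base
training into transfer learning (continuation, not reset), and a zero
gradient produces exactly zero movement, which makes the fixed-point
contract of transfer learning (targets equal to current predictions leave
the weights untouched) hold bit-exactly.  Gradients below 1e-10 are
treated as zero so the sign-based update cannot amplify numerical noise.

## Ensembles and transfer learning

An ensemble holds 10 members by default (tests and the acceptance script
use 2–3 for runtime), each with its own weight initialization and its own
random 90/10 train/test split.  The ensemble energy is the member mean and
the reported uncertainty is twice the population standard deviation across
members (`c = 2`).  Member splits are independent per member; whether they
should share a global test pool was an open choice, and per-member splits
were selected as the reading consistent with "for each member
individually".

Transfer learning continues each member on new per-structure energy
targets for 300 epochs (full batch, all training energies each step), with
the input standardization and the first hidden layer frozen bit-exactly
and the optimizer state carried over.  Targets are tier-corrected learned
energies after removal of the element-dependent stoichiometric shifts; the
shifts come from a minimum-norm least-squares fit of the tier differences
against the element counts (`fit_shifts()`), so single-stoichiometry
datasets (a rank-1 design) absorb the mean gap and multi-stoichiometry
datasets recover per-element shifts exactly.

# The energy ledger

The ledger operations assemble and disassemble the two-tier totals:

    E_QM/MM    = E_ML + E_MM + E_LJ_int + pair_sum + sum_m n_m E_atomic_m
    E_QM/QM/MM = E_QM/MM + dE_ML + sum_m n_m shift_m

with `pair_sum` the pairwise point-charge electrostatics over all QM–MM
pairs (no distance cutoff — the systems here are small) computed with the
CODATA-derived Coulomb constant 1389.3545764 kJ/mol·A/e².  Atomic
reference energies are user-supplied constants.  The tier-difference
identity holds to machine precision by construction and is tested over
1000 random breakdowns.  The structure filter keeps energies within
150 kJ/mol (inclusive) of the median, with the even-count median taken as
the midpoint of the central pair.

# The synthetic three-tier surface

`toy_pes_config()` defines a 12-atom chain (6 tagged QM atoms, 3 of them
quantum-core atoms) with harmonic bonds, Lennard-Jones interactions and
alternating point charges at tier 0; a Morse-minus-harmonic bond
correction and a polarization-like charge rescaling on the QM atoms at
tier 1; and a strictly local linear-plus-quadratic term in the core bond
displacements at tier 2.  The tier-2 term depends only on core-atom
internal coordinates, mirroring the locality premise of quantum-core
embedding.  Its default magnitude (3.0) puts the spread of the
tier-2 − tier-1 energy-difference distribution near 10 kJ/mol at the
default temperature (kT = 2.5 kJ/mol), the regime the distributions are
meant to emulate; `calibrate_tier2()` retunes the magnitude to any target
spread, exploiting the exact linearity of the correction in its magnitude.

Conformers are sampled on tier 0 (Langevin BAOAB or Metropolis), and every
structure carries energies at all three tiers plus analytic forces at
tiers 0 and 1.  Tier-2 forces are withheld by default — the highest tier
provides energies only, which is precisely what forces the energy-only
transfer path — with an override flag for controlled comparisons.  The
"harmonic-only" variant replaces all interactions by site-tethered
Cartesian wells, for which mean potential energy = (3N/2) kT exactly;
bond-length terms are nonlinear in Cartesians and would break that closed
form, which is why the tethered variant exists.

Time is in reduced units with unit masses; protocol durations quoted in
"ps" map to `n_steps * dt` in these units.  Temperatures are specified
directly as kT in kJ/mol.

# Nonequilibrium switching and the cycle

`neq_switch()` walks a monotone coupling schedule (linear by default) from
0 to 1, accumulating `U_(l+dl)(x) - U_l(x)` at each increment and
propagating one Langevin step at the new fixed coupling — for the linear
mixture this discrete accumulation equals the thermodynamic-integration
work.  A zero-step protocol reduces exactly to instantaneous perturbation.
Between the forward and backward switches the configurations are
importance-resampled with weights `exp(-W/kT)` (systematic resampling,
effective sample size reported, warning on collapse) and relaxed on the
target surface; the resampling rule is one defensible reading of a
qualitative protocol description and is flagged as such.

Free energies come from BAR (the natural estimator for a bidirectional
protocol; self-consistency solved to 1e-10 with the standard two-state
asymptotic variance), with one-sided Jarzynski and a Crooks
density-intersection fit as cross-checks.  The toy dynamics are Langevin
at constant temperature — constant-pressure solvated dynamics are out of
scope at desk scale.  Each repeat of the end-state procedure draws a fresh
seeded set of start structures; the per-repeat BAR estimates feed the
repeat grid (`combine_cycle()`: an n x n grid of corrected binding
estimates; 6 repeats per end state give the 36-combination grid), and the
total uncertainty is `sqrt(dP^2 + dS^2 + (2 sigma)^2)`.  The MM-level
binding free energy is an input scalar, and a two-state BAR error stands
in for the multistate estimator error since only end-state pairs exist in
this artifact.

# Problem sizes and what passing shows

The test and acceptance runs use deliberately small instances: 20 model
systems with at most 8 basis functions; 150–300 conformers; ensembles of
2–3 members; switching with 12 starts, 100 steps and 2 repeats per end
state; the harmonic estimator checks with 2000 works per direction.
These sizes exercise every code path in minutes while leaving the
statistical checks (3-standard-error bands, ratio patterns) meaningful.

One consequence of the scaled-down switching protocol deserves a note:
with tier gaps several times kT, short switches dissipate enough work
that the per-end-state estimates carry a finite-switching-time bias (the
resampling step reports the ensemble collapse when it happens).  The bias
is similar for the two end states and largely cancels in the combined
correction, which is the quantity the cycle uses; the end-to-end check
therefore compares the *combined* correction against its independent
perturbation oracle.  Validating a learned surface by free-energy
perturbation has its own subtlety: a network potential extrapolates
freely outside its data region and can develop spurious low-energy
basins there, so the oracle never samples the learned surface directly.
It instead bridges between the two analytic surfaces with a converged
staged perturbation and crosses from the highest analytic tier to the
learned surface with a small-perturbation exponential average on the
analytic ensemble.

Passing on the synthetic surfaces shows that the decomposition algebra,
the learning contracts and the estimator statistics are implemented
correctly.  It does not show that the approach is accurate for real
protein–ligand systems: the toy tiers are far smoother than DFT or
coupled-cluster surfaces, the conformer ensembles are tiny, and the MM
force-field, solvation and sampling problems of real binding free-energy
work are absent by design.

# Known limitations

* Closed-shell electronic structure only; open-shell cores are rejected.
* No analytic nuclear gradients of the embedded QM energies (the toy
  tier-2 surface mirrors this by withholding forces).
* The FCI solver is dense and capped; beyond the cap the virtual space
  must be truncated explicitly.
* Descriptor evaluation is plain R; the potentials are priced for
  hundreds, not millions, of force calls.
* The Crooks intersection estimator requires overlapping work densities
  and reports no standard error.
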