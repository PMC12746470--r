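---
title: "Learning one-electron reduced density matrices as a surrogate for SCF electronic structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning one-electron reduced density matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A closed-shell mean-field calculation is, operationally, a map from the
external electron–nuclear potential to a converged one-electron reduced
density matrix (1-RDM),

$$ v(\mathbf r) = -\sum_I \frac{Z_I}{|\mathbf r - \mathbf R_I|}
\quad\longrightarrow\quad
\gamma(\mathbf r, \mathbf r') = \sum_i n_i\,\phi_i(\mathbf r)\phi_i(\mathbf r'), $$

with aufbau occupations $n_i \in \{0, 2\}$ for a spin-compensated system.
Density-matrix functional theory guarantees the functional dependence
$\hat\gamma[\hat v]$, so the expensive SCF iteration can be replaced by a
regression. In a Gaussian-type-orbital basis both operators become symmetric
$M\times M$ matrices; `rdmlearn` flattens them to vectors of length
$M(M+1)/2$ (upper triangle, row-major, off-diagonals once) and learns

$$ \hat\gamma[\hat v] = \sum_{i=1}^{n} \hat\beta_i\, K(\hat v_i, \hat v), $$

kernel ridge regression with matrix-shaped weights $\hat\beta_i$ obtained
from one linear solve $(K + \alpha I)B = Y$. Supported kernels are the
linear, Gaussian (RBF) and polynomial kernels with the conventional defaults
$\Gamma = 1/N_\text{features}$ (recomputed per data set), $d = 3$, $c = 0$.
Cross-validated searches over kernel kind, $\alpha$ and $\Gamma$
consistently select **RBF with $\alpha = 0$** and a $\Gamma$ for which the
default is within a factor of two of optimal — $\alpha = 0$ means exact
interpolation of the training densities, which is appropriate because the
SCF labels are essentially noise-free.

Three model flavors are assembled by `model_stack()`:

1. `gamma` — properties evaluated directly from the purified predicted
   1-RDM;
2. `gamma+delta_gamma` — an affine refinement of the predicted density
   (ordinary least squares, minimum-norm via SVD when rank-deficient) is
   applied before property evaluation;
3. `delta_properties` — energies and forces come from affine maps off the
   purified density; no Fock build is performed, and the density remains
   available.

## N-representability

Raw KRR output is symmetric but not a valid fermionic 1-RDM. `purify()`
transforms to the Löwdin-orthogonalized basis, diagonalizes once, occupies
the $N/2$ largest-occupation natural orbitals with 2 and the rest with 0,
and back-transforms. The result satisfies $\mathrm{Tr}[\gamma S] = N$ (to
1e-10) and $\gamma S \gamma = 2\gamma$ (to 1e-8) by construction, and the
map is idempotent. Ties at the aufbau boundary (degenerate occupations
within 1e-10) are broken by the deterministic eigenvector ordering and
logged. Enforcing N-representability is not cosmetic: it is required for
stable dynamics, because the energy functional is only variational over
N-representable densities.

## Forces for nonvariational densities

For a converged density, forces are the Hellmann–Feynman term plus Pulay
corrections carried by the energy-weighted density
$\hat\rho_\varepsilon = \sum_i \varepsilon_i n_i |\phi_i\rangle\langle\phi_i|$.
A predicted density is *not* variational, and using the converged-case
formula leaves an inconsistency between the surrogate energy surface and
its forces that destabilizes NVE dynamics within a fraction of a
picosecond.

`compute_forces(mode = "corrected")` evaluates the exact total derivative
of the surrogate energy,

$$ F_I \;=\; F_I^{\text{frozen}}[\gamma]
\;-\; \mathrm{Tr}\!\left[ f[\gamma]\, \frac{\partial \gamma}{\partial R_I} \right], $$

where $F^{\text{frozen}}$ is the gradient at frozen AO density (no
orbital-response term) and $f = \delta E/\delta\gamma$ is the Fock matrix of
the predicted density. Splitting $f = f' + \delta f$ — with $f'$ the part of
$f$ block-diagonal in the occupied/virtual decomposition of $\gamma$'s
natural orbitals — shows the structure: the $f'$ contraction reproduces the
standard $\rho_\varepsilon$ Pulay force at convergence (orthonormality
response), and the occupied–virtual coupling $\delta f$, which vanishes by
the Brillouin condition whenever $[f, \gamma] = 0$, is the nonvariational
correction. For an aufbau-purified density the natural orbitals are only
defined up to rotations inside the occupied and virtual subspaces, so the
"diagonal part of $f$ in the natural-orbital basis" is implemented as this
unique block-diagonal projection (`fock_prime()`); any other reading makes
$f'$ depend on an arbitrary gauge.

We evaluate the contraction $\mathrm{Tr}[f\,\partial\gamma]$ *unsplit*
rather than adding a $\delta f$ term on top of the
$\rho_\varepsilon$-based baseline. The two assemblies agree at convergence,
but off convergence only the unsplit form is exactly consistent with the
energy: on a deliberately sparse water model at 500 K displacements it
matches central differences of the surrogate energy to 1.1e-6 Ha/Å
(uncorrected: 3.4e-3) and reduces the force RMSE against the engine from
1.8e-3 to 1.5e-4 Ha/Å — the order-of-magnitude gain that separates stable
from unstable NVE trajectories. The package therefore treats energy–force
consistency as the defining property of the corrected mode; the
$\delta f \to 0$ variational limit is asserted separately (the residual and
its force contribution decay monotonically to < 1e-7 along a scan
$\gamma_t = \mathcal P[(1-t)\gamma_\text{pred} + t\,\gamma_\text{SCF}]$).

$\partial\gamma/\partial R_I$ is obtained by central finite differences of
the full align–predict–purify pipeline (default step 5e-4 Å; the
correction-vanishing residual is pure $O(h^2)$ truncation, measured
4.4e-6/1.15e-6/3.8e-7/1.6e-7 Ha/Å at h = 2e-3/1e-3/5e-4/2e-4, so the
default sits where truncation is below the 1e-6 Ha/Å bar). An analytic
mode differentiates the kernel expansion directly (RBF:
$\partial K_i/\partial v = -2\Gamma(v - v_i)K_i$) composed with the
analytic $\partial\hat v/\partial R_I$ integrals and the response of the
alignment frame (obtained by differencing the closed-form Kabsch map, which
involves no integral or kernel evaluations); it is available for the raw
prediction, where it agrees with finite differences to ~1e-6, and not for
the purified one, whose eigensolver is not smoothly differentiable at
occupation crossings. The linear-response route to $\delta f$ through the
four-index kernel is intentionally not implemented.

## Frames

GTO matrices are not invariant under rigid motions, so every geometry —
training and prediction — is Kabsch-aligned (mass-weighted) to the model's
reference geometry before $\hat v$ is built, and predicted densities are
rotated back to the lab frame through the block-orthogonal AO rotation
(s blocks trivial, p blocks the Cartesian rotation). The AO rotation is
validated against engine recomputation at rotated geometries. Atom ordering
must be fixed across a data set; permutational symmetry is out of scope.

## Training data: a stated world

`sample_normal_mode_geometries()` draws mass-weighted normal-coordinate
displacements $q_i \sim \mathcal N(0,\ k_BT/\omega_i^2)$ — the classical
harmonic-oscillator variance, proportionality constant 1, which reproduces
classical equipartition at the target temperature (300 K default, matching
the temperature of the dynamics the surrogate is meant to drive). Modes
softer than 50 cm⁻¹ (large-amplitude torsions, where the harmonic σ
diverges) are drawn uniformly within the amplitude the floor frequency
would give. Sampling is seeded end-to-end; growing a training set derives
its draws from the base seed so that growth in any increments yields
identical records.

The generator emulates a thermal vibrational ensemble around one (or, via
explicit symmetry images, several) minima. It does not emulate: anharmonic
tails beyond the Gaussian envelope, mode–mode correlation, conformational
transitions it is not told about, or bond-breaking. A green test therefore
establishes accuracy for thermally accessible, near-equilibrium
configuration space at the stated temperature — exactly the regime NVE
dynamics at that temperature explores — and nothing beyond it.

Reference (test) data follow the dynamics protocol: velocity-Verlet NVE at
0.5 fs with Maxwell–Boltzmann initial momenta at 300 K, 2 ps total, 100
equally spaced frames from the last 1 ps; all parameters scale down for
desk-sized runs.

## The engine behind the adapter

No external quantum-chemistry engine is assumed. A self-contained
restricted Hartree–Fock implementation (McMurchie–Davidson Cartesian
Gaussian integrals in C++: overlap, kinetic, nuclear attraction, dipole,
two-electron integrals with 8-fold packed storage, analytic derivative
integrals for forces and for $\partial\hat v/\partial R_I$; DIIS-accelerated
SCF converged to 1e-9 Ha) supplies every label. STO-3G (generated from the
published Slater-fit expansion) and 6-31G parameter tables ship for H, C,
N and O — the elements of every bundled molecule. The engine reproduces
textbook oracle values (H₂/STO-3G at 1.4 a₀: −1.116714 Ha; H₂O/STO-3G:
−74.9630 Ha; H₂O/6-31G: −75.9840 Ha) and its analytic forces match central
differences to ~1e-8 Ha/Å. Density-functional exchange–correlation is not
implemented (it would need a quadrature grid); the learning machinery is
engine-agnostic — the regression never sees anything but matrices — so HF
plays the role the hybrid functional played in the original protocol, and
absolute numbers tied to a specific functional (e.g. the biphenyl
equilibrium dihedral) are expected to differ and are flagged as such in the
acceptance tests.

## Numerical choices

- **RBF distances** are computed after subtracting a reference feature row:
  raw potential features carry a large common offset
  ($\|v\|^2 \sim 10^4$ vs squared distances $\sim 1$), and the textbook
  expansion loses ~8 digits to cancellation — enough to put a visible noise
  floor under $\alpha = 0$ interpolation and to break finite-difference
  density derivatives.
- **$\alpha = 0$ solves** use Cholesky with escalating diagonal jitter
  (1e-12 → 1e-8, scaled by the mean kernel diagonal), logged when engaged;
  duplicate feature rows are rejected with guidance.
- **Hessians** are finite differences of analytic gradients (central by
  default, forward for the larger acceptance molecules), mass-weighted,
  with rigid translations/rotations projected out; linear molecules are
  detected by a null rotation generator.
- **Tie-breaks**: natural orbitals use a deterministic sign convention
  (first significant component positive); aufbau boundary ties warn.
- **Serialization** uses JSON with 17 significant digits, which round-trips
  doubles exactly; archives are versioned and refuse mismatched basis
  metadata.
- **Units**: hartree atomic units internally; geometry I/O in Å; forces in
  Ha/Å; MD in Å, fs, amu.

## Scaled-down acceptance protocols

The original study's headline scales (cc-pVTZ water, 15k-geometry
B3LYP/6-31G* biphenyl sets, picosecond biphenyl AIMD) are beyond this
package's compute budget and engine. The acceptance tests keep each
criterion's *threshold* and scale the *protocol*: water at HF/6-31G with the
27-sample budget (held-out energy RMSE must still beat 1e-6 Ha); the
benzene learning curve at HF/STO-3G (chemical accuracy by 50 structures);
methanol torsion with training sampled around each of the three relaxed
conformer minima — with fixed atom ordering these are distinct points in
feature space, and sampling rigidly rotated non-minima instead degrades the
barrier prediction by an order of magnitude (scan RMSE must stay at the
1e-3 kcal/mol order); correction-vanishing and paired corrected-vs-
uncorrected force comparisons on methanol at 500 K displacements; and a
0.2 ps methanol NVE with the drift bound kept at 1e-4 Ha/ps plus pointwise
decoherence ordering against the engine trajectory. The biphenyl
equilibrium-dihedral criterion is asserted unweakened against the published
38.49° and is expected to fail under the HF/STO-3G engine (rigid-scan
minimum near 44°): an honest record of the engine substitution's limit, not
a defect of the learning method.

## Known limitations

- Closed-shell systems only; no pseudopotentials, no periodic boundaries.
- Basis sets limited to STO-3G/6-31G for H/C/N/O; no d shells, hence AO
  rotations cover s/p blocks.
- Finite-difference $\partial\gamma/\partial R$ costs $6N$ pipeline
  evaluations per force call; fine for the bundled molecule sizes, the
  dominant cost for larger ones.
- The Kabsch frame makes the learned map exactly invariant under rigid
  motions of the *whole* molecule, but alignment-frame response enters
  force evaluation only through the finite-difference pipeline; symmetric
  tests (energy–force consistency) bound the residual at ~1e-6 Ha/Å for
  the bundled systems.
- KRR stores all training features; prediction is $O(n)$ kernel
  evaluations — by design (that is what makes training trivial), but memory
  grows linearly in $n \cdot M^2$.
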