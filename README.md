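# rdmlearn

Machine-learned one-electron reduced density matrices (1-RDMs) as a
surrogate for self-consistent-field electronic structure, in R.

## The problem

A mean-field electronic-structure calculation maps a molecular geometry to a
converged one-electron reduced density matrix γ̂, from which the energy,
forces and every one-electron property follow. The self-consistent-field
(SCF) iteration that produces γ̂ dominates the cost of ab initio molecular
dynamics (AIMD). Reduced-density-matrix functional theory guarantees that γ̂
is a functional of the external (electron–nuclear Coulomb) potential v̂
alone, so the map can be *learned*:

- **γ-learning** — kernel ridge regression of the map v̂ → γ̂ with
  matrix-shaped weights:
  γ̂[v̂] = Σᵢ β̂ᵢ K(v̂ᵢ, v̂), with K ∈ {LIN, RBF, POL},
  defaults Γ = 1/N_features, d = 3, c = 0, and ridge α (α = 0, exact
  interpolation, performs best);
- **N-representability purification** — a single diagonalization of the
  predicted γ̂ followed by aufbau occupations (the N/2 highest natural
  orbitals get occupation 2, the rest 0), so Tr[γ̂S] = N and γ̂Sγ̂ = 2γ̂
  hold exactly;
- **δ-learning** — affine (linear-regression) maps from the predicted γ̂ to
  refined densities or directly to energies and forces;
- **corrected forces** — predicted densities are not variational, so
  Hellmann–Feynman + Pulay forces alone are inconsistent with the surrogate
  energy surface. The package evaluates
  F_I = F_I[frozen γ̂] − Tr[ f̂[γ̂] · ∂γ̂/∂R_I ],
  whose f̂′/δf̂ split reproduces the standard energy-weighted-density force
  at convergence while the occupied–virtual coupling δf̂ = f̂ − f̂′ carries
  the nonvariational correction (it vanishes when [f̂, γ̂] = 0). This
  restores energy–force consistency to ~10⁻⁶ Ha/Å and cuts the force error
  by roughly an order of magnitude, which is what keeps NVE dynamics stable;
- **normal-mode training sets** — geometries are sampled around a relaxed
  minimum with per-mode variance k_BT/ω² (300 K default), avoiding
  reference AIMD entirely;
- **NVE dynamics** — velocity-Verlet with any force provider (reference
  engine or surrogate), with energy-drift and trajectory-decoherence
  diagnostics.

Everything is driven by a built-in, deterministic restricted Hartree–Fock
engine (McMurchie–Davidson Gaussian integrals in C++ with analytic nuclear
gradients; STO-3G and 6-31G bases for H/C/N/O), exposed through a narrow
adapter so the learning stack never sees engine internals.

## Worked example

```r
library(rdmlearn)

m   <- method_spec("HF", "6-31G")
eq  <- read_xyz(system.file("extdata", "water_hf_631g.xyz",
                            package = "rdmlearn"))   # relaxed water
modes <- hessian_normal_modes(eq, m)
ts  <- make_training_set(eq, modes, sampler_config(300, 27, seed = 11), m)
gm  <- fit_gamma(ts, kernel_spec("RBF", alpha = 0))
stack <- model_stack(gm)

held <- sample_normal_mode_geometries(eq, modes,
                                      sampler_config(300, 20, seed = 99))
tts  <- build_training_set(held, eq, m)
pred <- sapply(seq_along(held), function(i)
  predict_full(stack, tts$geometries[[i]])$energy)
sqrt(mean((pred - tts$energies)^2))
#> [1] 2.77496e-09
```

27 thermally sampled water geometries suffice for a held-out total-energy
RMSE of **2.8 × 10⁻⁹ Ha** — far below both SCF-threshold accuracy (10⁻⁶ Ha)
and chemical accuracy (1 kcal/mol ≈ 1.6 × 10⁻³ Ha). The same stack yields
purified densities (`predict_full(...)$gamma`), dipoles and kinetic energies
(`one_electron_property`), HOMO–LUMO gaps (`homo_lumo_gap`), corrected
forces (`compute_forces`) and NVE trajectories (`run_nve` with
`ml_force_provider`).

A command-line workflow covers the same pipeline:

```sh
Rscript -e 'rdmlearn::rdm_cli()' gen-train --molecule water --basis STO-3G \
        --n 30 --seed 1 --out ts.json
Rscript -e 'rdmlearn::rdm_cli()' fit     --training ts.json --kernel RBF --alpha 0 --out model.json
Rscript -e 'rdmlearn::rdm_cli()' eval    --model model.json --test ts.json --out eval.tsv
Rscript -e 'rdmlearn::rdm_cli()' md      --model model.json --xyz water.xyz --steps 400 --out traj.xyz
```

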