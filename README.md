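# nbens — nanobody paratope ensembles, enhanced sampling, and NMR cross-validation

`nbens` is an R toolkit for the computational side of validating simulated
conformational ensembles of nanobody (V<sub>H</sub>H) antigen-binding loops
against solution NMR data. It is aimed at structural-bioinformatics users
who have (or simulate) loop ensembles and want to confront them with the
two workhorse NMR observables:

* **NOE distance upper limits** — cross-relaxation intensity scales as
  r⁻⁶ in the interproton distance, so an ensemble predicts
  r_eff = ⟨r⁻⁶⟩⁻¹ᐟ⁶ per restraint, compared against CYANA-style `.upl`
  upper limits (violation = max(0, r_eff − U));
* **Lipari–Szabo order parameters** —
  S² = (3/2) Σ_ab ⟨μ_a μ_b⟩² − 1/2 for backbone amide N–H unit vectors,
  1 = rigid, 0 = disordered, computed both from the second moment and from
  the plateau of C(t) = ⟨P₂(μ(0)·μ(t))⟩.

Around these sit the analysis stack used for loop-ensemble work: torsion
(sin, cos) featurization with time-lagged independent component analysis
(tICA, generalized eigenproblem C_τ v = λ C₀ v on symmetrized estimators),
free-energy surfaces ΔG = −k_BT ln(n/n_max) over the two slowest
components, average-linkage RMSD clustering with a cutoff criterion, a
well-tempered (bias-exchange) metadynamics engine on toy Langevin systems
(Gaussian height 10 kJ/mol, width 0.3, pace 1000 steps, bias factor 10,
300 K), and flat-bottom distance restraints with exponential-memory time
averaging (τ = 100 ps). Synthetic generators with analytic ground truth
(diffusion in a cone, two-state torsion loops, double-well particles,
fluctuating bead chains) make the whole pipeline testable offline.

See `vignettes/nanobody-ensembles.Rmd` for the models, parameter choices,
and design notes.

## Worked example

```r
library(nbens)

## a metastable two-state loop, analyzed by tICA + free-energy surface
loop <- gen_two_state_loop(n_residues = 3,
  state_centers = rbind(c(-60, 120, -40), c(60, -120, 140)),
  hop_probability = 0.02, angular_noise_sd = 15,
  n_frames = 20000, seed = 42)
feats <- featurize(loop$traj)
model <- tica_fit(feats, lag = 5)
model
#> <tica_model> 6 features, lag 5 (5 frames); leading eigenvalues: 0.8101, 0.0137, 0.01227
proj <- tica_transform(model, feats, n_components = 2)
fes <- free_energy_surface(proj, bins = 40, temperature = 300)
```

The leading eigenvalue (0.81 at lag 5) is the slow hopping mode; the gap
to the rest (≈ 0.01) says only one slow process exists, exactly as
constructed. Thresholding tIC1 recovers the generator's hidden state
labels with < 5 % error (tested in `test-acceptance.R`).

```r
## order parameters against the cone-model closed form
cone <- gen_cone_vectors(semi_angle = 60, n_frames = 50000,
                         frame_correlation = 0.9, seed = 42)
s2_second_moment(cone$traj)
#> cone S2: truth 0.1406 | second moment 0.1420 | plateau 0.1429
```

Both estimators sit within sampling error of the analytic
S² = [cos θ₀ (1 + cos θ₀)/2]² = 0.1406 for θ₀ = 60°.

```r
## well-tempered metadynamics recovering a 10 kJ/mol double-well barrier
meta <- run_wt_metad(list(kind = "double_well", barrier_height = 10),
                     n_steps = 5e5, height0 = 10, width = 0.3,
                     pace = 1000, bias_factor = 10, seed = 42)
fe <- estimate_free_energy(meta$bias, seq(-1.5, 1.5, length.out = 61))
#> metadynamics: 500 hills; barrier estimate 11.8 kJ/mol (true 10.0)
```

The recovered well region is accurate to < 1 k_BT (the acceptance
criterion); the barrier-top estimate runs slightly high because the
0.3-wide hills smooth the narrow barrier — see the vignette's numerical
notes.

## Command line

A thin CLI wraps the same functions (installed to `exec/nbens`):

```sh
nbens synth cone --semi-angle 60 --frames 10000 --seed 1 --out cone
nbens restraints --upl restraints.upl
nbens metad --height 10 --width 0.3 --pace 1000 --biasfactor 10 \
            --steps 200000 --seed 1 --out dw
nbens report --ensemble ensemble.pdb --reference xray.pdb \
             --upl restraints.upl --range 3:113 --out table1.tsv
```

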