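---
title: "Characterizing nanobody paratope ensembles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing nanobody paratope ensembles: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbens)
```

## The problem this package addresses

The antigen-binding surface (paratope) of a nanobody — the single variable
domain of a camelid heavy-chain-only antibody — is formed by three
hypervariable CDR loops. A single crystal structure does not capture how
these loops move in solution, yet loop dynamics (above all of CDR3) largely
determine antigen recognition. Solution NMR constrains the same physics from
the experimental side: NOE cross-relaxation intensities scale as
$r^{-6}$ in the interproton distance and yield distance upper limits, and
$^{15}$N relaxation yields Lipari–Szabo order parameters $S^2$ that grade
backbone rigidity between 1 (rigid) and 0 (disordered).

`nbens` implements the computational half of a cross-validation between
simulated loop ensembles and such NMR observables, on a desk scale:

* reading/writing multi-model PDB ensembles and CYANA-style `.upl`
  upper-limit restraint files, with Kabsch superposition and backbone
  torsion primitives (`structure_io`);
* torsion $(\sin,\cos)$ featurization, time-lagged independent component
  analysis (tICA), free-energy surfaces over the two slowest components,
  and average-linkage RMSD clustering (`cv_landscape`);
* a well-tempered (optionally bias-exchange) metadynamics engine on toy
  Langevin systems (`metadynamics`);
* NOE effective distances with $r^{-6}$ time/ensemble averaging, violation
  reports, and two $S^2$ estimators (`nmr_observables`);
* flat-bottom upper-limit restraints with exponential-memory time
  averaging, driving a toy bead-chain Langevin integrator
  (`restrained_dynamics`);
* ensemble refinement statistics: precision RMSD, accuracy to a reference
  structure, Ramachandran classification, violation counts
  (`ensemble_stats`);
* synthetic generators with analytically known ground truth
  (`synthetic_data`), which make every stage testable offline.

All-atom force-field MD, NOE peak assignment, and relaxation model fitting
are explicitly out of scope: the package analyses trajectories and
ensembles, it does not produce protein ones.

## Models and estimators

### NOE effective distances

For a restraint between proton groups $A$ and $B$ the instantaneous
effective distance at frame $t$ is the $r^{-6}$ average over all
inter-group pairs,
$r_t = \big(\tfrac{1}{|A||B|}\sum_{a,b} r_{ab}^{-6}\big)^{-1/6}$
(the pseudoatom convention), and the reported distance is the weighted
time average $r_\mathrm{eff} = (\sum_t w_t r_t^{-6} / \sum_t w_t)^{-1/6}$.
Convexity of $x \mapsto x^{-6}$ gives the invariant
$\min_t r_t \le r_\mathrm{eff} \le \mathrm{mean}_t\, r_t$, which the test
suite checks on a thousand generated trajectories. Upper limits parsed
from `.upl` files (e.g. 5 or 7 Å for methyl NOEs, 2.5 Å for H-bond
restraints) are used as-is; no additional pseudoatom corrections are
applied, because the group averaging already carries the multiplicity.

Because published refinement tables are ambiguous about what counts as one
violation, `violation_report()` exposes both conventions — ensemble-averaged
$r_\mathrm{eff}$ above the limit, and violated-in-any-model — and
`table1_report()` prints them side by side.

### Order parameters

Two estimators of $S^2$ are provided and cross-checked against each other:

* **second moment**: $S^2 = \tfrac{3}{2}\sum_{ab}\langle\mu_a\mu_b\rangle^2
  - \tfrac12$ over all frames;
* **correlation plateau**: $C(t) = \langle P_2(\mu(0)\cdot\mu(t))\rangle$
  averaged over time origins (FFT-accelerated through the six unique
  products $\mu_a\mu_b$), with $S^2$ the mean of $C$ over the final 20 % of
  lags up to half the trajectory. A plateau whose fitted slope exceeds
  $10^{-3}$ per lag is flagged as non-converged (never silently dropped).

Both are invariant under global rotations. Before computing backbone
amide vectors, `nh_vectors()` superposes every frame onto the reference
topology over framework backbone atoms, so $S^2$ reports internal motion
only — the standard choice when the source trajectory retains global
tumbling.

The diffusion-in-a-cone generator supplies the analytic control: uniform
orientations on a cap of semi-angle $\theta_0$ have
$S^2 = [\cos\theta_0(1+\cos\theta_0)/2]^2$. The acceptance suite requires
both estimators to recover this closed form within 0.03 at $10^5$ frames
for $\theta_0 \in \{20^\circ, 40^\circ, 60^\circ, 80^\circ\}$.

### tICA and free-energy surfaces

Backbone torsions are embedded as $(\sin\psi,\cos\psi)$ pairs (wrap-safe),
and tICA solves $C_\tau v = \lambda C_0 v$ with the *symmetrized*
(reversible) estimators — the paper-independent standard for equilibrium
trajectories, chosen because it guarantees a real spectrum. $C_0$ gets an
$\epsilon I$ ridge ($\epsilon = 10^{-6}$ by default; sine/cosine features
are routinely rank-deficient). Components have unit $C_0$-norm and a fixed
sign (largest-magnitude loading positive), so results are deterministic.
Combined coordinate systems across several trajectories are fit on
concatenated features with lagged pairs formed within each trajectory only.
The protocol's production lag is 10 ns; for toy data the lag is stated in
the trajectory's own time units and must simply exceed one frame.

The free-energy surface over $(\mathrm{tIC1}, \mathrm{tIC2})$ is
$\Delta G = -k_BT\,\ln(n_\mathrm{bin}/n_\mathrm{max})$, so the global
minimum is exactly 0 and only relative depths are meaningful (the source
figures are relative too). Empty bins are `NA` ("unsampled"), never
infinities. When frames come from a biased run and a bias record is
supplied, weights $\propto e^{+V_\mathrm{bias}/k_BT}$ reweight the
histogram; unweighted analysis of biased data is a caller decision, not a
silent default.

### Well-tempered metadynamics

The engine runs on 1-D toy Langevin systems (double well, harmonic) with
the particle position as the collective variable; the production-scale
protein CV — a linear combination of $\sin/\cos$ of loop $\psi$ torsions —
is available as `collective_variable()`/`eval_cv()` for analysis.
Deposits follow the protocol parameters: Gaussian height 10.0 kJ/mol,
width 0.3, deposition every 1000 steps, bias factor $\gamma = 10$, 300 K.
The deposited height at step $t$ is
$h_0\, e^{-V(s_t)/k_B\Delta T}$ with $\Delta T = (\gamma-1)T$ (deposit-time
bias, the PLUMED convention), and the free-energy estimate is
$\hat F = -\tfrac{\gamma}{\gamma-1}V + \mathrm{const}$, anchored at
$\min \hat F = 0$. Angular CVs evaluate Gaussians on minimum-image
distances. Bias exchange is nearest-neighbor Metropolis on the two
replicas' bias energies at both configurations.

Numerical stability note: the overdamped Euler update is stable only where
$U'' < 2\gamma/\mathrm{d}t$. Biased runs climb the steep quartic walls
further than unbiased ones, so `run_wt_metad()` defaults to
$\gamma = 5\,\mathrm{ps}^{-1}$ (versus 1 ps$^{-1}$ for the unbiased
generator), keeping the instability threshold outside the thermally plus
bias-accessible region. The hill-width smoothing of $\hat F$ is real:
curvature estimates of a well are only unbiased when
$k w^2 / k_B T \ll 1$, which the test for harmonic-curvature recovery
respects by using $w = 0.1$.

### Time-averaged restraints

Flat-bottom upper-limit restraints are half-harmonic:
$E = \tfrac{k}{2}(r-U)^2$ for $r > U$, zero otherwise, continuous at the
limit. In time-averaged mode the driving distance is the exponential
memory $\bar r = m^{-1/p}$,
$m \leftarrow m\,e^{-\mathrm{d}t/\tau} + r^{-p}(1 - e^{-\mathrm{d}t/\tau})$,
with $\tau = 100$ ps (the protocol value) and $p = 3$ by default (the
common MD-engine default; the protocol does not state the exponent, and
$p \in \{1,3,6\}$ is configurable). The restraint force is computed from
$\bar r$ but applied along the current pair vector *without* the formal
$(\bar r/r)^{p+1}$ correction factor — a deliberate stability choice on
toys, documented as a divergence from engine-exact behavior. Two exact
properties pin the memory down: constant input is a fixed point
($\bar r \to r$), and the update is independent of how $\mathrm{d}t$ is
partitioned. As $\tau \to 0$ the dynamics reduces to instantaneous
restraints (verified to $10^{-6}$ on matched-seed trajectories). The
bead-chain integrator is BAOAB Langevin; with $\gamma = 0$ it is plain
velocity Verlet, whose bounded energy drift is a standing test.

### Ensemble statistics

Precision is the mean RMSD of models to their iteratively superposed mean
(the convention most NMR refinement tables report); a pairwise-mean variant
sits behind a flag because deposited tables rarely say which they use.
Accuracy is the Cα RMSD of the ensemble mean to a reference after Kabsch
superposition over the residue-index intersection, minus an explicit
exclusion list for flexible termini.

The Ramachandran classifier uses a four-class 10°×10° map
(core/allowed/generous/disallowed) shipped as inspectable text under
`inst/extdata/`. **The map is a synthetic approximation**: rectangular
core regions for the β, right-handed α and left-handed α basins, dilated
on the torus for the allowed and generous classes, with a point-symmetrized
variant for glycine and a φ-restricted variant for proline. It reproduces
the canonical assignments (α: $(-60,-45)$, β: $(-120,130)$ are core) but is
*not* the empirical PROCHECK grid, which is not redistributable here;
percentages from real ensembles will differ from published tables
accordingly. Van der Waals close contacts use heavy-atom radii with a
0.4 Å allowance and are likewise labeled approximate.

## The synthetic world, and what a green test establishes

Every generator carries its ground truth with the data (no constants
buried in tests) and is exactly reproducible from one explicit seed, with
independent streams per call:

* **cone vectors** — uniform on a spherical cap with a keep-probability
  Markov correlation; marginally exactly uniform, so the closed-form
  $S^2$ holds at every correlation level;
* **two-state torsion loop** — symmetric Markov hopping between two loop
  conformations plus wrapped Gaussian noise; stationary occupancy 0.5/0.5
  by symmetry, labels returned for tICA/clustering validation;
* **double-well Langevin particle** — overdamped dynamics in
  $U = h((x/a)^2-1)^2$; in 1-D the free energy *is* the potential, giving
  an analytic target for metadynamics recovery;
* **toy bead chain** — Gaussian-perturbed linear chain that also emits the
  exact distance of every pair in every frame, the oracle for $r^{-6}$
  averaging.

Defaults reflect the stated protocol where one exists (300 K, metadynamics
hill parameters, $\tau = 100$ ps) and otherwise plain physical choices
(bond length 3.8 Å — a Cα virtual bond; fluctuation SD 0.3 Å — sub-bond
thermal noise; hop probabilities and noise SDs sized so states are
well-separated but overlapping in single torsions).

A green suite establishes that the estimators implement their definitions
correctly and recover analytic ground truth in regimes where that truth is
known. It does **not** establish force-field accuracy, convergence of real
protein sampling, assignment correctness of real NOE data, or agreement
with any deposited ensemble — those require the accession-based inputs
(an NMR ensemble, a crystal reference, a BMRB restraint list) that this
offline build deliberately treats as optional extensions.

## Resolved design questions

* *"All six CDR loops"* in the source protocol (a nanobody has three) is
  treated as protocol text reused from a paired-domain workflow; loop
  residue ranges are therefore always user configuration, never
  hard-coded.
* Transition-timescale estimation from the free-energy landscape is
  excluded: the method is cited without equations in the source, and
  guessing a formula would be worse than omitting it.
* CYANA's exact pseudoatom-correction and violation-counting conventions
  are not published in the source; the package picks the physically
  motivated $r^{-6}$ group averaging and reports both violation-counting
  conventions rather than choosing silently.
* The spec's numeric acceptance-target list is empty (all quantitative
  published values require network downloads), so the acceptance report
  emits an empty JSON object and the seven property-based criteria carry
  acceptance; see `tests/testthat/test-acceptance.R`.

## Known limitations

Toy dynamics only (no force fields, solvent, or constraints); 1-D
metadynamics CVs; the Euler/BAOAB integrators require the documented
step-size limits; the Ramachandran map is approximate; `.upl` parsing
covers the standard 7-column dialect and the common pseudoatom codes, not
every CYANA extension; mmCIF and binary trajectory formats are out of
scope.
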