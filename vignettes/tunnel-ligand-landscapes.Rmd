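---
title: "Free-energy landscapes of ligand motion in tunnel-shaped protein cavities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-energy landscapes of ligand motion in tunnel-shaped protein cavities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tunnelscape)
```

## The problem

Lipid transfer proteins (LTPs) and many related carriers enclose their
ligand in a tunnel-like hydrophobic cavity with two openings. How the
lipid moves along that tunnel — and how different head-in versus
head-out poses (orientations A and B) differ energetically — is a
question about a one-dimensional slow coordinate buried in a
3N-dimensional system. `tunnelscape` implements a protocol for exactly
this situation:

1. derive a **diffusion axis** from pocket-occupancy maps accumulated
   over a trajectory;
2. define two **collective variables** in a roto-translational frame
   fixed to the rigid core of the protein: CV1, the displacement of the
   ligand tail centroid along the axis, and CV2, its displacement in
   the orthogonal plane;
3. explore CV1 with **well-tempered metadynamics** confined by harmonic
   walls, and reconstruct the free-energy profile with its basins and
   barriers;
4. run the auxiliary analyses used to interpret the landscape:
   contact-covariance residue clustering, configurational entropy by
   the PCA-histogram method, assembly of binding free energies, and
   cavity-volume/CV correlation.

The package operates at desk scale: the metadynamics engine integrates
analytic model potentials rather than coupling to an all-atom MD code,
and synthetic generators supply every input with known ground truth.
The all-atom stages of the original protocol (force-field MD, docking,
continuum-electrostatics enthalpies, pocket detection itself) are out
of scope; their *outputs* — trajectories, pocket grids, enthalpy
tables, cavity-volume series — are this package's inputs.

## Diffusion axis from pocket grids

Pocket-mapping tools emit a volumetric map of pocket frequency: for
each voxel, the fraction of trajectory frames in which it belonged to a
detected pocket. `read_dx_grid()` reads the common OpenDX text dialect;
`threshold_points()` keeps every voxel whose frequency is *strictly*
above a cutoff (default 0.2, the conventional choice) as a point cloud
in world coordinates; `diffusion_axes()` performs an eigendecomposition
of the coordinate covariance. The leading eigenvector — the direction
of greatest cavity extent — is the diffusion axis.

Choices worth knowing:

* The covariance uses the unbiased (n − 1) denominator; the variances
  are descriptive, so this only affects reporting.
* Eigenvector sign is fixed by making each axis's largest-magnitude
  component positive, so results are identical across eigensolvers.
* Adjacent eigenvalues within 1% of each other (or clouds of fewer
  than 4 points) set a `degenerate` flag and a warning rather than an
  error: the protocol still runs, but the axis direction is not
  uniquely determined by the data.
* Points are unweighted by default. Whether thresholded voxels should
  be weighted by their frequency before the decomposition is not
  settled; a `weights` argument exposes the frequency-weighted variant,
  but the unweighted form is the default because the threshold already
  encodes the confidence judgment.

```{r axis-example}
grid <- make_pocket_grid(axis = c(1, 0, 0), half_lengths = c(8, 3, 2),
                         noise_level = 0.1, seed = 1)
cloud <- threshold_points(grid, 0.2)
diffusion_axes(cloud)
```

## Collective variables in a fitted frame

Raw ligand coordinates mix internal motion with the protein's global
diffusion and tumbling. The CVs are therefore computed in the
roto-translational frame that minimizes the RMSD between each frame's
*fit atoms* and a reference structure (optimal rigid superposition via
the Kabsch algorithm, proper rotations only). Fit atoms are the
alpha-carbons whose RMSF falls strictly below a threshold — on a
helical protein this keeps the helices and discards loops and termini.
The default threshold of 1.0 Å is deliberate: fluctuations below
roughly an angstrom characterize secondary-structure cores, and the
synthetic scaffold is built so this value reproduces the intended
helix/loop split.

After superposition, the displacement `d` of the ligand-tail centroid
from its reference position decomposes into

* `cv1 = d · u` (signed, along the diffusion axis `u`), and
* `cv2 = |d − (d · u) u|` (non-negative, radial).

The tail centroid is the *unweighted* centroid of the selected carbons
(equal carbon masses make this identical to their center of mass), and
the bulky aromatic head group is excluded from the selection by
construction — its internal torsions would contaminate a centroid that
is meant to track translation along the tunnel. The origin is the CV
value of the reference frame itself, so the reference evaluates to
(0, 0) exactly.

RMSF is computed after a *single* alignment pass onto the first frame
(on the requested atoms). An iterated superposition/RMSF cycle would
converge to a slightly different atom set on real data; with a clearly
bimodal fluctuation spectrum the two agree, and the single pass is
deterministic and cheap. This is a documented divergence risk for
borderline thresholds.

## Well-tempered metadynamics engine

The engine explores one degree of freedom (CV1) of an analytic model
potential with overdamped (Brownian) Langevin dynamics,

```
s <- s - (D / kB T) * grad(U + V_bias + V_walls) * dt + sqrt(2 D dt) * eta
```

and deposits a Gaussian hill on CV1 every `tauG` of simulated time with
the tempered height `h = H exp(-V_bias(s) / kB deltaT)`. Defaults are
the published study parameters: `H = 0.1` kcal/mol, width
`delta = 0.05` Å, bias temperature `deltaT = 4500` K, `tauG = 1000` fs,
system temperature 298 K, with `kB = 1.987204e-3` kcal/(mol K). The
bias temperature controls the exploration/convergence trade-off: hill
heights decay as the bias accumulates, and in the long-time limit the
bias compensates the fraction `deltaT / (T + deltaT)` of the free
energy, so `reconstruct_fes()` applies the scale factor
`(T + deltaT) / deltaT` and shifts the minimum to zero. As `H -> 0`
(or `deltaT -> 0`) plain unbiased dynamics are recovered — a property
the test suite checks against the Boltzmann variance of a harmonic
well.

Harmonic walls are half-harmonic: zero inside `[s_lo, s_hi]` and
`(K/2)(s − bound)²` outside, with `K = 40` kcal/(mol Å²) as published.
The published parameter table pairs the longitudinal range
[−20, 12.5] Å with CV2 and [0, 9] Å with CV1, while the accompanying
text describes sampling "from −20 to +12.5 Å" along CV1; the text's
reading is adopted (longitudinal wall on CV1, radial upper wall at
9 Å on CV2 — CV2 ≥ 0 needs no lower bound), and the assignment is
configurable since the table is ambiguous. The exact functional forms
of the original appendix are not available in the source text; the
standard well-tempered and half-harmonic forms above are used and
documented as such.

Numerical choices:

* **Integrator.** Euler–Maruyama with `dt = 0.1` fs and diffusion
  coefficient `D = 0.1` Å²/fs by default. For a curvature `k` the
  scheme requires `(D k / kB T) dt < 2` for stability and inflates the
  stationary variance by `1/(1 − θ dt/2)`; at the defaults and the
  curvatures of the toy potentials this bias is below 1%. A sanity
  bound aborts with a diagnostic if the coordinate diverges.
* **Bias bookkeeping.** The user-facing `bias_energy()` is exact hill
  summation, and free-energy reconstruction always uses it. Inside the
  integrator, summing thousands of hills at every step is prohibitive,
  so the engine accumulates hills on a fine grid (spacing `delta/8`)
  storing both the energy and its analytic derivative at each node and
  interpolating with a cubic Hermite — the engine-path evaluation
  agrees with exact summation to better than 1e-6 kcal/mol, which the
  test suite asserts.
* **Reproducibility.** The engine uses a dedicated mt19937_64 stream
  keyed by the user seed with an implementation-independent Box–Muller
  transform; identical seeds give bit-identical hills logs, and the
  seed is recorded in the log header.
* **Deposition timing.** `tauG` counts *simulated time* (fs), not
  steps, so results with different `dt` remain comparable.

```{r wtmeta-example}
pot <- make_double_well(barrier = 5, minima = c(-2, 2))
res <- run_wt_metadynamics(pot, wt_params(), n_steps = 2e6, dt = 0.1,
                           seed = 42)
res$hills
```

## Reading the landscape

`reconstruct_fes()` evaluates the scaled, shifted bias on a regular
CV1 grid; `find_basins()` locates local minima, the saddles between
them, and prunes basins whose depth relative to their lowest adjacent
saddle is below `min_depth` (persistence pruning). Labels are assigned
by energy rank — 0 for the deepest basin, matching the convention of
naming the deepest basins of each landscape first.

Two analysis parameters matter when the curve comes from a finite
metadynamics run:

* **Smoothing.** Deposited hills of width `delta` leave ripple on the
  reconstructed curve at the sub-hill-width scale; features narrower
  than a few hill widths are deposition noise, not landscape. A
  moving-average window of 7 grid points (0.35 Å at the default 0.05 Å
  grid, i.e. seven hill widths) suppresses the ripple while shifting a
  5 kcal/mol barrier estimate by well under 0.1 kcal/mol; this is the
  window used in the package's own validation. The default is no
  smoothing, appropriate for analytic or already-smooth curves.
* **`min_depth`** separates genuine metastability from residual noise;
  1 kcal/mol (≈ 1.7 kB T at 298 K) is used in the validation runs.

The convergence diagnostic is `deposition_profile()`: total hill
height deposited per time window. A converged well-tempered run adds
almost nothing late — in the validation runs the final tenth of the
run deposits less than a tenth of the energy of the first tenth.

The remaining descriptive analyses follow their literal definitions:
`radius_of_gyration_mean()` is the *mean* distance of the
alpha-carbons to their centroid — a linear spread measure, deliberately
distinct from the conventional RMS radius, which is available as
`radius_of_gyration_rms()` (the mean-distance form is never larger, by
Jensen's inequality); `count_contacts()` counts atom pairs strictly
closer than a 4.5 Å heavy-atom cutoff (configurable; the cutoff is a
convention, not a published value); `volume_cv_correlation()` reports
the Pearson correlation between a cavity-volume series and CV1,
per orientation — the expected signature is a clear correlation whose
sign flips between the two ligand orientations, with zero-variance
input flagged rather than propagated as NaN.

## Contact map and residue clustering

For each frame, the minimum atom–atom distance from every protein
residue to each of the three ligand parts (head, tail, bridge) is
passed through a logistic transform spanning (−1, 1):
`f(d) = 2/(1 + exp((d − d0)/lam)) − 1`, with midpoint `d0 = 4.5` Å and
steepness `lam = 1` Å by default — the typical heavy-atom contact
scale; the transform saturates for intimate contacts and far-away
residues while remaining steep in the first-shell region. The
covariance of these channels over time feeds average-linkage
agglomerative clustering with distance `1 − cov/max|cov|`, a
scale-invariant and deterministic choice (the aggregation convention —
minimum distance per residue/part pair, and residues assigned the
cluster of their strongest part channel by maximum absolute
covariance — is a documented choice; the source protocol does not
specify either). Validation uses synthetic series with known block
structure, which the clustering must recover exactly; reproducing
specific residue lists from the original 100-ns all-atom trajectories
is explicitly *not* a desk-scale claim.

## Binding thermodynamics

`gibbs_combine()` assembles ΔG = ΔH − TΔS at a stated temperature;
enthalpies are inputs (in the original protocol they come from an
external MM–PBSA tool, which is not reimplemented).
`fold_change()` converts a ΔΔG into an affinity ratio,
`exp(ΔΔG/RT)`. The package ships the published six-row ligand table as
a plain-text fixture; `check_thermo_table()` recomputes ΔG for every
row and flags disagreements beyond 0.01 kcal/mol (printed-value
rounding). One row — phytosphingosine, orientation A — prints a
positive entropy term inconsistent with its ΔG unless the sign is read
as negative; the checker flags it rather than asserting it, and the
flagged row becomes consistent under the sign correction. For the
natural ligand the recomputed orientation gap (−7.27 vs
−11.15 kcal/mol) corresponds to a ≈ 7 × 10² affinity ratio at 298 K;
since the published claim is "~600-fold", the package's checks treat
600 as a lower bound rather than a two-sided target.

`pca_histogram_entropy()` estimates configurational entropy: frames
are superposed, Cartesian deviations decomposed by PCA, each retained
component histogrammed independently, and the discrete Shannon
entropies summed, `S = −kB Σ p ln p`. Defaults are 10 components and
30 bins. Two caveats are inherent to the method and documented rather
than hidden: discrete Shannon entropy depends on the binning (so only
comparisons at fixed binning are meaningful — the output records it),
and summing marginal entropies ignores correlations between
components beyond the linear ones PCA removes.

## Synthetic systems: what they do and do not establish

The generators exist so that every stage has an input with known
ground truth:

* `make_double_well()` / `make_tunnel_potential()` — quartic axial
  profiles scaled to an exact barrier, optionally with harmonic radial
  confinement; the analytic profile is the oracle for free-energy
  recovery.
* `make_toy_complex_trajectory()` — a rigid pseudo-alpha-carbon
  scaffold (four helical arcs around a tunnel, echoing the four-helix
  LTP fold, plus mobile terminal loops that the RMSF filter must
  reject) and a three-part ligand whose tail follows a scripted CV1
  course; per-frame random global roto-translations exercise the
  fitting machinery (the first frame stays in the canonical pose,
  since it defines the reference frame and the axis coordinates), and
  the emitted ground truth is the pre-transformation course.
* `make_pocket_grid()` — voxel frequencies high inside an ellipsoid
  elongated along a declared axis, with sub-threshold background
  noise.

All generators are deterministic under a fixed seed and restore the
global RNG state. What passing tests on these systems establish is
that the *machinery* is correct: axes are recovered from clouds with
known anisotropy, CVs invert scripted motion exactly and ignore rigid
motion, the sampler obeys Boltzmann statistics without bias and
recovers known barriers with it. What they do not establish is
anything about real proteins: the toys have no explicit solvent, no
anharmonic protein response, no coupling between cavity breathing and
ligand position, and their noise is Gaussian and uncorrelated. Claims
about a real LTP require the all-atom inputs this package consumes but
does not produce.

## Validation problem sizes

The package's own validation (test suite and acceptance script) uses:
three independent well-tempered runs of 2 × 10⁸ fs simulated time
(2 × 10⁹ steps at `dt = 0.1` fs, ≈ 2 × 10⁵ hills each) on the
5 kcal/mol double well, chosen so that the deposition profile is well
into its decaying regime (final/first window ratio ≈ 0.075); a 10⁶-step
unbiased run for the Boltzmann-variance check; and synthetic grids,
trajectories, and contact series of a few hundred elements each. At
these sizes the recovered barrier sits within 0.2 kcal/mol of truth
per seed and the three-seed mean within 0.1.

## Known limitations

* The metadynamics engine is one-dimensional in its biased coordinate
  (CV1) by design, matching the protocol it implements; 2D landscapes
  on (CV1, CV2) and funnel-style restraints are out of scope.
* Trajectory I/O covers multi-model PDB and XYZ text formats; binary
  trajectory formats would slot in behind the same `trajectory()`
  contract but are not included.
* No periodic-boundary handling: inputs are assumed whole and
  unwrapped.
* The Euler–Maruyama discretization bias, while small at the defaults,
  grows linearly in `dt`; halve `dt` when in doubt and compare.
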