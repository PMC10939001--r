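---
title: "Global structure search for flexible adsorbates: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global structure search for flexible adsorbates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Finding the global-minimum structure of a flexible molecule adsorbed on a
metal surface is a nested search: the molecule's internal conformation
(hydroxyl rotations, glycosidic torsions, pyranose ring flips) and its
rigid-body placement on the surface (two in-plane translations, height,
three orientation angles) each span a rugged landscape, and every energy
evaluation with an electronic-structure engine is expensive. `surfbo`
implements an accelerated workflow built around four ideas:

1. **Reduced coordinates.** The search never runs in Cartesian space.
   A conformer search for beta-d-xylopyranose is six-dimensional (four
   hydroxyl torsions plus two ring-flip coordinates); for
   1,4-beta-d-xylotetraose it is sixteen-dimensional (ten hydroxyls plus
   phi/psi for three glycosidic linkages). Adding reduced ring flips for
   all four rings would give twenty-four dimensions, and a full
   one-coordinate-per-ring-atom treatment of a single ring would give ten
   for xylose — `count_dimensions()` does this arithmetic from the
   molecule's annotations.
2. **A Gaussian-process surrogate, refined actively.** A GP is fit to all
   evaluated configurations; a lower-confidence-bound acquisition picks
   the next configuration; the surrogate's local minima are harvested at
   the end and only those few structures are relaxed with the expensive
   engine.
3. **Data economy.** The (111) surface symmetry multiplies every
   adsorption observation sixfold at no cost; an energy transformation
   caps unphysical contacts and compresses the high-energy tail so the GP
   spends its capacity on the chemically relevant region; duplicate
   minima are removed by Kabsch RMSD.
4. **Recycling the data.** Every backend evaluation is exportable as a
   training frame (energies + forces) for a machine-learned potential. A
   lightweight descriptor-regression potential is included and can drive
   a second, nearly free search pass; an external equivariant-network
   potential can be plugged in through the same calculator contract.

# Geometry conventions

**Slabs.** `build_slab()` constructs an orthogonal fcc(111) slab with
`nx * ny` atoms per layer and ABC stacking; the orthogonal surface search
cell has dimensions `a = a_fcc/sqrt(2)` and `b = a_fcc*sqrt(3)/sqrt(2)`
(2.568 and 4.448 Angstrom for Cu with `a_fcc = 3.632` Angstrom). Note the
accounting: a "6 x 8 x 4" slab holds 6 x 8 = 48 atoms per layer, 192 in
total, so xylose (20 atoms) on it makes a 212-atom system and
xylotetraose (71 atoms) on 14 x 16 x 4 makes 967. The bottom layers are
frozen to mimic bulk; the vacuum (default 60 Angstrom) is split evenly
above and below. The stacking is chosen so the *top* layer has an atom at
the xy origin: the 3-fold rotation axis used by symmetry augmentation
passes through it.

**Angles.** All angular variables are in degrees. The rigid-body
orientation applies `R = Rz(gamma) Ry(beta) Rz(alpha)` about the
adsorbate's geometric center; `gamma` is deliberately the *outer* z
rotation so that a global rotation about the surface normal — the C3
symmetry operation — simply adds 120 degrees to it. Heights (`tz`,
bounds 3 to 12 Angstrom by default) are measured from the mean z of the
top substrate layer to the adsorbate's geometric center.

**Ring flips.** The two most prominent pyranose conformers (the 4C1 and
1C4 chairs) are connected by a two-coordinate reduced parametrization:
the opposing ring torsions O5-C1-C2-C3 and C3-C4-C5-O5 are driven to
target values and the ring is rebuilt by natural-extension chain
construction, with closure restored by damped Gauss-Newton adjustment of
the free torsions and (softly penalized) placement angles to a closure
gap below 1e-4 Angstrom. Substituents ride along on per-ring-atom local
frames anchored exactly at each ring atom, so bond lengths are preserved
to machine precision. If closure fails, the realization is flagged and
the point enters the dataset at the cap energy — the same treatment as a
hard contact.

# The energy transformation

Configurations with any interatomic distance below 0.5 Angstrom skip the
backend entirely and are booked at a fixed 5.0 eV — a placeholder on the
Pauli-repulsive wall. Relative energies above 1.0 eV are compressed to
`1 + log(E)` (natural logarithm, so the map is continuous at the
threshold); energies at or below 1 eV pass through unchanged. The GP
therefore sees a landscape bounded above, and its lengthscales are set by
the low-energy physics rather than by the repulsive wall. The reference
zero is the energy of the relaxed isolated building blocks (conformer +
clean slab) and is fixed for the whole run.

# The surrogate and the acquisition

The kernel is a product over dimensions: squared-exponential components
for bounded variables and standard periodic components
(`exp(-2 sin^2(pi d / p) / l^2)`) for periodic ones, times a signal
variance, plus a small noise variance. Hyperparameters maximize the log
marginal likelihood with analytic gradients from several bounded
multistarts. Linear solves use Cholesky factorization with jitter
escalation (1e-10 to 1e-4 of the diagonal scale) and two steps of
iterative refinement, which keeps interpolation accurate even at the tiny
noise levels appropriate to deterministic backends.

The acquisition is a lower confidence bound, `mean - kappa * sd`. The
default `kappa` follows the growing GP-UCB schedule
`sqrt(2 log(t^(D/2+2) pi^2 / 0.3))` rather than a constant: with a fixed
`kappa` the exploration bonus is bounded by `kappa` times the signal
standard deviation, and once one deep basin has been found the search
provably never leaves it on landscapes whose basin depth exceeds that
bonus — we observed exactly this failure (the deepest well missed
entirely) on three-well test landscapes. The growing schedule restores
asymptotic coverage; a fixed numeric `kappa` remains available.

A run terminates when the argmin of the posterior mean has not moved (per
dimension, by more than 1% of its range) for 100 consecutive iterations,
or at the iteration budget. After termination a short verification phase
evaluates any harvested surrogate minimum that lacks a nearby sample —
within the same evaluation budget — and refits. This mirrors the
workflow's own discipline of checking predicted minima against the
expensive engine, and it is what makes the surrogate's energies at
*shallow* minima trustworthy: without it we measured ~11% energy error at
the shallowest of three planted wells, with it well under 1%.

# Symmetry augmentation and deduplication

Each sampled adsorption observation is expanded by the group
{identity, centring translation (a/2, b/2)} x {C3^0, C3^1, C3^2 about the
atop axis at the origin}: six images at general positions, with
coincident images collapsed. Images act on `(tx, ty)` and add 120 degrees
to `gamma`; energies are copied. The packaged toy surface backend is
*exactly* invariant under this group by construction (see below), so
augmented labels are exact for it; for a real engine on a relaxed slab
they are exact up to the slab's deviation from the ideal surface.

Augmentation has a flip side: the surrogate's minima come in symmetry
orbits. `deduplicate()` therefore accepts an `images_fn`; for adsorption
minima the RMSD to a kept minimum is the minimum over that minimum's
symmetry images, so each orbit keeps one representative. RMSDs for
adsorbate+slab systems are computed by superposing the full system (the
shared slab pins the frame) and reporting the RMSD over adsorbate atoms
(`adsorption_rmsd()`); plain `kabsch_rmsd()` over all atoms would dilute
a 1-Angstrom adsorbate displacement by the hundreds of identical slab
atoms. The dedup threshold defaults to 0.3 Angstrom, which separates
distinct relaxed basins at the RMSD scale this workflow produces
(realized-to-relaxed displacements of roughly 0.1-0.6 Angstrom).

# The toy backends

The packaged backends stand in for an electronic-structure engine so the
entire workflow runs on a desk machine. They are deliberately simple and
physically shaped, not fits to any reference data:

- **Intramolecular**: Lennard-Jones interactions between atoms at least
  four bonds apart (Lorentz-Berthelot mixing over per-element parameters)
  plus a directional O-H...O hydrogen-bond well
  (`-eps * cos^4(theta) * exp(-(r - r0)^2 / 2w^2)`). Forces are analytic
  and the energy is exactly invariant under rigid motion.
- **Surface**: pairwise adsorbate-substrate Morse terms with a C1
  polynomial switch at 3.5 Angstrom, evaluated from the actual slab atoms
  under minimum image. Because the substrate field derives from the
  atomistic geometry, every symmetry of the periodic slab is an exact
  symmetry of the energy — the augmentation-exactness tests hold to
  1e-9 eV with no tuning. The short interaction range also places this
  backend inside the representational class of the packaged surrogate
  potential (a pair potential within the same cutoff), which is what
  makes the workflow-closure test below meaningful. A consequence worth
  knowing: the fcc- and hcp-type hollow sites are exactly degenerate,
  because the subsurface layer that distinguishes them lies beyond the
  interaction range. Tests that compare global minima treat the tied
  orbits as equivalent.

What the toy backends do *not* emulate: electronic charge transfer,
image-charge screening, surface relaxation under the adsorbate,
anharmonic coupling between conformer and surface degrees of freedom
beyond simple sterics. A passing workflow on the toy backends therefore
demonstrates the correctness of the search machinery — augmentation,
transformation, surrogate, harvesting, deduplication, relaxation,
training-data round trip — not the chemical accuracy of any particular
engine.

# Relaxation

`relax()` is a line-search-free BFGS with a per-atom step cap (0.2
Angstrom), energy backtracking (so the energy is non-increasing over
accepted steps), a relative curvature guard on the inverse-Hessian
update, and an adaptive steepest-descent scale for regions with no usable
curvature (for example beyond a pair potential's inflection point, where
the Hessian is indefinite). Convergence is declared when every force
component on every free atom is below `fmax` (default 0.01 eV/Angstrom;
a looser 0.03 is customary for surrogate-potential exploration runs).
Frozen atoms and, with `fix_substrate = TRUE`, all substrate atoms are
held exactly. The reported step count is the number of force evaluations
after the first, which includes backtracking evaluations — an honest
measure of backend work.

# The surrogate potential

`mlip_train()` fits per-atom energy contributions that are linear in
Gaussian-smeared radial distribution features per neighbour-element
channel (cutoff 3.5 Angstrom, C1 switching), with per-element offsets,
by ridge regression on a joint objective in which the mean energy loss
and the mean force loss enter 1:1. Forces are analytic, the model is
size-consistent by construction, and training reports train/validation
mean absolute errors on a seeded 90/10 frame split. This is intentionally
the simplest member of the MLIP family — a pair potential in disguise —
because the package's claim is about the *workflow contract* (search data
in, usable calculator out, second pass closes on the same global
minimum), not about matching the accuracy of equivariant message-passing
networks, which plug in through `calculator_new()` if available.

The workflow-closure property, checked end to end in the test suite: a
potential trained only on first-pass search data from the toy backend,
used as the backend of a second search pass, yields a deduplicated global
minimum in the same symmetry-resolved Kabsch cluster (RMSD below 0.3
Angstrom) as the toy backend's own, with the degenerate hollow orbits
treated as tied.

# Numerical choices and problem sizes

- GP noise default 1e-6 eV^2 in searches (backends are deterministic);
  jitter escalation only on factorization failure.
- Acquisition minimization: `20 * D` low-discrepancy starts of bounded
  L-BFGS driven by analytic gradients of the posterior; minima harvesting
  `100 * D` starts, greedy clustering at 5% of each variable's range,
  capped at the 20 lowest representatives (sparse high-dimensional
  surrogates exhibit many shallow micro-basins; only the lowest few are
  ever relaxed); periodic variables compared with wrap-around.
- Stall rule: argmin displacement below 1% of range per dimension for 100
  consecutive iterations, matching the convention of comparing the
  predicted *structure*, not its energy.
- Planted-landscape oracle: three Gaussian wells (depths 1.0/0.8/0.6 eV,
  width 0.8 Angstrom, minimum separation 2.5 Angstrom) in a cell twice
  the Cu(111) search cell, periodized exactly; the search budget in the
  recovery test is 150 evaluations (5 initial + 145), a realistic
  desk-scale analogue of a few hundred engine calls.
- Closure test: single-probe adsorption over a 4 x 4 x 2 slab, 3-D
  search space, 45 evaluations per pass with sixfold augmentation.
  These sizes were chosen so the full suite exercises every claim in a
  few minutes on one core while leaving the algorithms' asymptotics
  untouched.

# Known limitations

- The ring-closure solver handles chair-to-chair paths of a single
  six-membered ring; fused or larger rings are out of scope.
- Ring flips of the oligosaccharide (the 24-dimensional space) are
  counted and realizable, but the packaged search workflows exercise the
  6-D and 16-D spaces.
- The toy surface has no fcc/hcp asymmetry (degenerate hollows) and no
  substrate relaxation; the augmentation-exactness guarantee would soften
  on a relaxed slab from a real engine.
- `augment_symmetry()` applies rotations about the ideal atop axis to
  *every* observation (a valid symmetry of the infinite ideal slab), not
  only to observations at high-symmetry points; the rotation block can be
  disabled per run.
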