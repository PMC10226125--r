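---
title: "Methods: end-state MMPBSA rescoring with Monte-Carlo geometry"
author: "mmpbsar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: end-state MMPBSA rescoring with Monte-Carlo geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmpbsar)
```

## The model

In the single-trajectory end-state formalism the binding free energy of a
protein–ligand (P–L) complex is assembled from ensemble-averaged
differences (complex − protein − ligand, same frames for all three
species, so bonded terms cancel):

$$\Delta G = \Delta E_\mathrm{vdW} +
             \frac{\Delta E_\mathrm{ele}}{\varepsilon_\mathrm{ele}} +
             \frac{\Delta G_\mathrm{PB}}{\varepsilon_\mathrm{pb}} +
             \Delta G_\mathrm{np} - T\Delta S .$$

`mmpbsar` takes the decomposed terms as *inputs* (per-frame or
pre-averaged tables, `read_terms_table()` / `average_deltas()`): it never
runs MD or a Poisson–Boltzmann solver. What it adds is everything
downstream: the nonpolar models, the empirical re-weightings, the
dielectric handling, geometry replacement, fitting and evaluation.

The nonpolar term is modelled as

- one-term: $\gamma\,\Delta\mathrm{SASA} + b$ (or $\Delta$SAV),
- two-term (cavity + dispersion): $\gamma\,\Delta\mathrm{SAV} + b +
  \Delta E_\mathrm{disp}$, with the dispersion coefficient fixed at 1,
- scaled particle theory (SPT): $\gamma\,\Delta\mathrm{SASA} +
  p\,\Delta\mathrm{SAV} + b$, which captures the crossover between
  volume-dominated (small cavity) and area-dominated (large cavity)
  repulsive solvation.

When the dispersion energy is an exactly linear function of the volume the
two-term model collapses algebraically onto SPT with transformed
coefficients; the test suite asserts this identity rather than treating the
two models as independent.

Fully empirical re-weightings are provided as the `pbsa_e` regime
($\alpha_1 \Delta E_\mathrm{vdW} + \alpha_2(\Delta E_\mathrm{ele} +
\Delta G_\mathrm{PB}) + \alpha_3\,\gamma\,\Delta\mathrm{SASA} +
\alpha_4 N_\mathrm{rot}$, with the rotatable-bond count as an entropy
surrogate) and the five-coefficient `pbsa_ex`. Because the published
layouts of such equations are ambiguous in places, the coefficient-to-term
mapping of `pbsa_e` and `ani_pbsae` is data (`term_map` in
`model_spec()`), not code: reinterpretation costs a configuration change,
never an edit.

The `ani_*` regimes replace the two gas-phase MM terms with a scaled
single-point interaction energy $a\,\Delta E_\mathrm{sp}$, where
$\Delta E_\mathrm{sp} = \langle E(PL) - E(P) - E(L)\rangle$ is evaluated on
identical geometries (no relaxation — the single-trajectory convention) by
any `energy_provider()`. A machine-learned potential is one such provider;
the bundled mock pairwise potentials satisfy the same contract
(determinism, permutation and rigid-motion invariance, asserted by
`check_provider()`) and make the whole path testable offline, since the
cross-fragment interaction of a pairwise potential is independently
computable by brute-force pair summation. Conformational entropy beyond
the $N_\mathrm{rot}$ surrogate is deliberately out of scope: the estimator
family sets $-T\Delta S = 0$ elsewhere.

### Two-valued interior dielectric

The interior (solute) dielectric constant enters twice — in the P–L
Coulombic term and in the polar solvation term — and there is no physical
reason the same effective value should correct both: the binding pocket of
a neutral ligand is typically apolar while the solvent-exposed surface is
not. `dielectric_pair(eps_ele, eps_pb)` decouples them; the single-valued
convention is the diagonal. Rescaling is algebraic division of terms
computed at $\varepsilon_\mathrm{int} = 1$. That is exact for the
Coulombic term and an *approximation* for the PB term (a true dielectric
change would re-solve the PB equation); it is the same shortcut used when
reproducing published decomposed data, and it is documented as such.
`scan_dielectrics()` grids over pairs, reports the full metric table, and
breaks ties toward the lexicographically smaller pair so results are
reproducible.

## Monte-Carlo geometry

A probe of radius $r_p$ is *probe-centered accessible* at $y$ iff
$|y - a_i| \ge r_i + r_p$ for every atom $i$.

- **ASA**: per-atom stratified sampling — equal numbers of points drawn
  uniformly on each probe-inflated sphere; a point is accessible iff it
  lies outside every other inflated sphere; the estimate is
  $\sum_i 4\pi (r_i + r_p)^2 \hat p_i$ with binomial per-atom variances
  combined into the standard error. Stratification keeps the variance
  bookkeeping exact; spheres with no intersecting neighbour contribute
  their closed-form area with zero variance.
- **PCAV**: the volume of the accessible locus inside the sampling cell
  (uniform cell sampling); the *molecular* volume is cell volume minus
  pore volume, which cancels the cell dependence.
- **POAV**: additionally counts every point outside the vdW spheres lying
  within $r_p$ of an accessible probe center, i.e. it removes the
  probe-radius shell PCAV over-counts. Membership of a border point $x$
  (outside vdW, clearance $< r_p$) is equivalent to
  $\max_{y \in B(x, r_p)} g(y) \ge r_p$, where
  $g(y) = \min_i (|y-a_i| - r_i)$ is the vdW clearance. The maximum is
  located by analytic escape candidates (radially away from the nearest
  atom — exact for a single body and convex pockets; along the bisector of
  the two nearest atoms — the seam geometry), 32 quasi-random starts in
  the ball, and a projected supergradient ascent of $g$ over the ball from
  the best start (diminishing cyclic steps, since $g$ is a nonsmooth min).
  The candidate stage alone misclassifies deep seam regions; the ascent is
  what makes the estimator agree with the exact oracle at the percent
  level on heavily overlapping clusters. Because acceptance of a point
  requires an explicitly verified probe center, false positives are
  impossible; residual error is a (small) false-negative bias in
  pathological necks.

Pore volumes include interior voids: no reachability or percolation
analysis is performed, matching the pore-subtraction construction the
volumes feed (and stated here because porous-material codes differ on
this).

The three volume classifications share one sample, so the ordering
$V_\mathrm{vdW} \le V_\mathrm{POAV} \le V_\mathrm{PCAV}$ holds exactly for
every seed, not just in expectation.

**RNG.** Reproducibility is per-substream: Mersenne–Twister streams are
seeded by a splitmix-style mix of (seed, atom index), so estimates are
bit-identical for a fixed (structure, probe, seed) and independent of atom
iteration order; sampling is done in structure-local coordinates, making
rigid translation (cell moved along) a no-op.

### The lattice oracle

`grid_oracle()` is the deterministic validation reference: voxel-center
inclusion counting for the volumes and fixed Fibonacci-sphere quadrature
for the area. For POAV it is *exact on the lattice* rather than sharing
the Monte-Carlo candidate logic: since $g$ is 1-Lipschitz, every
accessible voxel center $y$ certifies a continuously accessible ball of
radius $g(y) - r_p$, so $x$ is occupiable iff $|x - y| \le g(y)$ for some
accessible voxel — an additively weighted squared distance transform
(parabola envelope with vertical offsets $-g^2$), computed with the
separable Felzenszwalb–Huttenlocher algorithm in C++. The far-field
clearance is initialised to $r_p + 2\,\mathrm{res}$, a guaranteed lower
bound outside the per-atom boxes, because the weighted transform is only
valid if $g$ never overestimates the true clearance. The oracle refuses
resolutions so coarse that an atom contains fewer than 10 lattice points.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `probe_radius` | 1.4 | Å | water-sized probe, the SASA convention |
| `n_samples` | 1e5 | — | ~0.5% relative error on typical cluster volumes; scale as $1/\sqrt{n}$ |
| cell padding | 5 + probe | Å | keeps every inflated sphere strictly inside the cell |
| radii table | Bondi (1964) | Å | the de-facto standard set for SASA codes; swappable via `radii_table(path)` |
| `grid_oracle` resolution | 0.05 | Å | sub-percent volume error on Å-scale solutes |
| one-term presets | γ=0.00542/b=0.92, γ=0.005/b=0, γ=0.0072/b=0 | kcal/mol/Å² | the classic PB/GB parameterisations |
| dispersion preset | γ=0.0378, b=−0.5692 | kcal/mol/Å³ | the standard cavity coefficients of the two-term model |

Radii and probe radius are conventions, not fitted quantities: upstream
tools rarely document theirs, so both are explicit arguments and the
defaults are flagged here rather than buried.

## Fitting and evaluation

Every estimator is affine in its coefficients; `fit()` exploits this by
building the design matrix from scores at unit coefficient vectors and
solving ordinary least squares on $\Delta G_\mathrm{pred} -
\Delta G_\mathrm{exp}$ (QR, with rank-deficiency reported as a
singular-design error naming the collinear coefficients — feeding
identical area and volume columns is the canonical way to trigger it).
Least squares is the default objective because published tables report
both coefficients and unsigned errors; direct Pearson maximisation is
available (`objective = "pearson"`, Nelder–Mead seeded at the OLS
solution) and coincides with OLS up to affine scale when nothing is
pinned. In `pbsa_e` the internal surface-tension factor γ multiplies
$\alpha_3$, so the product is not identifiable; γ is pinned (default
0.0072) unless supplied. Per-coefficient standard errors are classical
OLS; frame-level standard errors are carried through `average_deltas()`
but not used to weight fits. Dielectric scans rescale without refitting by
default — the coefficients are part of the model under test — and
`refit = TRUE` refits at every grid point when the question is instead
"how good could each pair be made".

Metrics: predictive index (pairwise rank agreement weighted by
experimental affinity differences; ties in predictions contribute 0, ties
in experiment carry zero weight), Pearson and Spearman correlation
(average ranks for ties), and the MUE family — raw MUE, MUEtr after
removing the mean signed error, MUEsc after least-squares affine mapping
of predictions onto experiment. PI, both correlations and MUEsc are
invariant under positive-affine transforms of the predictions and MUEtr
under shifts; the suite asserts these invariances on random fixtures
because they are what make the metrics comparable across estimators with
different natural scales.

## Synthetic data: what it emulates and what it does not

`gen_study()` draws per-complex delta terms from independent normals
(defaults: ΔE_vdW −50±10, ΔE_ele −30±15, ΔG_PB 45±15 kcal/mol, ΔSASA
−750±150 Å², chosen once as plausible magnitudes for drug-like
protein–ligand complexes; area/volume differences of a few hundred units
with matching signs are what end-state decompositions of such complexes
produce). ΔSAV is drawn as ΔSASA plus a normal offset (SD 80) because the
two differences track each other in real data — correlated enough to be
realistic, not collinear enough to break the SPT design. Experimental
affinities are the chosen regime's formula at the true coefficients and
true dielectric pair plus Gaussian noise (default SD 1 kcal/mol, the scale
of good experimental binding data; the default study size of 54 complexes
matches a typical curated fitting set). Per-frame tables add zero-sum
jitter, so frame averaging recovers the drawn deltas at machine precision
— averaging tests are exact, not statistical.

`gen_cluster()` grows connected unions of overlapping spheres (radii
uniform in 1.2–2.0 Å, center separation 0.8 of the radius sum), the
geometry fixtures whose surface and volume the lattice oracle can compute.

What passing these tests shows: the estimators, fitting, scanning and
geometry machinery are internally correct and recover known ground truth.
What it does **not** show: real decomposed terms are not independent
normals (vdW and area differences correlate strongly), real dispersion is
only approximately linear in volume, the PB ε-division is not a PB
re-solve, proteins are not 20-sphere clusters, and charged ligands are
outside the estimators' domain of validity. Performance claims on real
systems require real trajectories and are out of scope.

## Numerical choices and degenerate inputs

- Problem sizes in the shipped tests: $10^5$ samples for single-sphere
  references, $5\times10^5$ for cluster/oracle agreement at 0.05 Å
  resolution, 200 replicates of 54 complexes for bias checks — sizes at
  which the statistical bands (3 standard errors, 1%) are meaningful while
  the suite stays quick to run.
- Degenerate inputs fail as classed conditions, not silent NAs: empty
  structures, unknown elements without fallback, cells that do not contain
  an inflated atom, incomplete PL/P/L triples, missing terms or
  coefficients (named), all-equal experimental values (PI weights vanish),
  zero-variance predictions (MUEsc slope), rank-deficient designs, empty
  or sub-unity dielectric grids.
- Scan ties break toward the smaller (ε_ele, ε_pb) lexicographically;
  Spearman ties use average ranks.
- Altloc records keep the first location; models beyond the first are
  ignored; hydrogens are used if present and never added — geometry
  estimators must not silently alter their input.
- CLI outputs are written atomically (write-then-rename) with a
  provenance sidecar (version, seed, flat config and its hash) and contain
  no timestamps, so identical seed + config gives byte-identical files.

## Known limitations

- The POAV Monte-Carlo membership test is a local optimisation; a probe
  pocket reachable only through a path longer than $r_p$ from the sampled
  point could in principle be missed (bias toward larger POAV molecular
  volume). The oracle does not share this approximation.
- ε-division approximates PB rescaling; coefficients fitted at one ε pair
  absorb part of that approximation.
- No bootstrap or cross-validation beyond a single labelled train/test
  split; no regularised fitting.
- `N_rot` is read, not computed; rotatable-bond perception from chemical
  structure is upstream's job.
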