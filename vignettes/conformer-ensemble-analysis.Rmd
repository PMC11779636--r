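---
title: "Characterizing conformer ensembles with saxsemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing conformer ensembles with saxsemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saxsemble)
```

## The problem

Large structured RNAs such as bacterial RNase P RNA are not single
structures: in solution they sample a broad conformational space built from
a conformationally invariant core and flexible peripheral elements that
swing with amplitudes of tens of Angstrom. Single-particle imaging can
deliver a discrete ensemble of coarse-grained conformers (one bead per
residue), and small-angle X-ray scattering (SAXS) independently reports the
population-weighted average over the whole solution ensemble. saxsemble
implements the analysis layer that connects the two:

1. **Forward scattering.** Each conformer's theoretical profile is computed
   with the Debye equation over bead pairs,
   $I(q) = \sum_{i}\sum_{j} f(q)^2 \,\mathrm{sinc}(q\,d_{ij})$,
   with unit point form factors by default. This is a deliberate
   coarse-grained model: it has no hydration shell or excluded-volume term,
   so absolute $\chi^2$ values against curves back-calculated by
   atomistic tools will differ even when compositions agree.
2. **Ensemble fitting.** The experimental curve is modelled as
   $I_\mathrm{Total}(q) = \sum_i \nu_i I_i(q)$ with volume fractions
   $\nu_i \ge 0$, $\sum_i \nu_i = 1$, and a single global scale that absorbs
   units. Fit quality is the reduced $\chi^2$ against the experimental
   errors.
3. **Ensemble decomposition.** Iterative superposition with
   ellipsoid-volume pruning finds the invariant core; PCA of the
   $3N$-dimensional coordinate covariance decomposes the motions; a
   movement-similarity matrix maps correlated motions; per-residue r.m.s.f.
   is compared with crystallographic B factors.
4. **Sequence vs conformation.** Per-column sequence conservation (SCS)
   from a multiple alignment is correlated with the 3D conformation
   conservation score (3DCS), defined as one minus the min–max-normalised
   per-residue r.m.s.f., and residues conserved in sequence but mobile in
   space (or vice versa) are flagged.

## Volume-fraction fitting

`fit_volume_fractions()` solves the constrained least-squares problem
exactly rather than with an iterative box-constrained optimizer. The
observation is that the parameterisation (fractions $\nu$ on the simplex,
free positive scale $c$) is a bijection onto nonnegative coefficient
vectors $a_i = c\,\nu_i$: Lawson–Hanson nonnegative least squares on the
error-weighted design matrix returns the optimal $a$, from which
$\nu_i = a_i/\sum a$ and $c = \sum a$. The result is deterministic, has no
convergence parameters, and the optimum is global.

Two practical caveats are surfaced in the fit object:

* **Identifiability.** Conformers of similar shape have nearly
  proportional profiles; the design matrix can be numerically
  rank-deficient, in which case the *split* between degenerate candidates
  is arbitrary even though their *sum* is well determined. The fit carries
  an `identifiable` flag (singular-value test) so downstream code can
  aggregate fractions at class level, which is also the scientifically
  meaningful quantity.
* **Error model.** When the experimental curve has no `sigma` column, a
  1% multiplicative error floor is assumed — the typical noise regime of a
  bench SAXS instrument — which keeps the reduced $\chi^2$ scale-free.

`classify_by_cosine()` assigns conformers to class representatives by the
cosine distance of raw intensity vectors over the shared $q$ grid
(threshold 0.1 by default). Cosine distance is invariant to per-profile
positive scaling, so theoretical and experimental curves on arbitrary
scales compare directly; ties are broken by reference order and recorded.
The randomized combination study (`combination_chi2_study()`) draws $k$
members per class without replacement (classes smaller than $k$ contribute
all members), refits, and summarises $\chi^2$ by mean, s.d. and minimum per
$k$ — the standard demonstration that fits improve with ensemble size. The
genetic-algorithm selector (`ga_subensemble_select()`) uses tournament
selection (size 2), single-point crossover, per-gene mutation at rate
$1/\text{pool}$, elitism, and a singleton-seeded initial population, which
guarantees the returned $\chi^2$ never exceeds the best single conformer's.
These operator choices are pragmatic defaults, not tuned quantities.

## Invariant core and motion decomposition

`find_invariant_core()` alternates superposition on the current residue set
with per-residue ellipsoid volumes
$v_i = \tfrac{4}{3}\pi\sqrt{\lambda_1\lambda_2\lambda_3}$, where the
$\lambda$ are eigenvalues of residue $i$'s $3\times3$ positional covariance
across members, and removes the residue with the largest volume. With the
default cutoff the iteration stops when every remaining residue's volume is
at or below 150 Å³; with `volume_cutoff = "auto"` the full pruning
trajectory is computed and cut at the valley of the 3-point-smoothed first
difference of total volume versus remaining count — i.e. at the start of
the flat tail, favouring the largest core with stationary volume.

Two properties of this family of algorithms are worth knowing:

* **Lever-arm absorption.** When very few flexible residues remain in the
  superposition set and they sit far from the rigid body, the Kabsch fit
  can rotate to chase their fluctuations, collapsing their apparent
  variance perpendicular to the lever. A lone flexible residue on a long
  rod can therefore survive any sensible volume cutoff. This is inherent
  to superposition-based core detection, not specific to this
  implementation.
* **Curve-like motion.** The ellipsoid volume is a *geometric* mean of
  variances, so motion confined to a low-dimensional manifold (e.g. a pure
  hinge arc with little jitter) yields small volumes even when amplitudes
  are large. Real data, with per-residue noise in all directions, does not
  trigger this; pathological noise-free fixtures can.

`ensemble_pca()` eigendecomposes the covariance of member coordinates after
superposition (by default on the invariant core, which is also the
recommended reference). Components are ordered by eigenvalue; each
eigenvector's largest-magnitude coefficient is made positive so reports
are reproducible across platforms; numerically null components (beyond
$M-1$) are dropped. Per-residue amplitudes are
$\sqrt{\lambda_k}\,\lVert v_{k,i}\rVert$, whose squares sum to
$\lambda_k$. `interpolate_pc_trajectory()` sweeps the mean structure
linearly between the minimum and maximum observed projections — a spatial
interpolation with no temporal meaning. `movement_similarity_matrix()` is
the standard dynamic cross-correlation of positional deviations,
$\langle \Delta r_i\cdot\Delta r_j\rangle /
\sqrt{\langle|\Delta r_i|^2\rangle\langle|\Delta r_j|^2\rangle} \in [-1,1]$;
residues with zero fluctuation are flagged and given zero off-diagonal
entries rather than dividing by zero. Clustering in PC space is
hierarchical (average linkage, Euclidean) on the leading projections,
deterministic by construction; `n_components_for_variance()` picks the
component count covering a target variance fraction (70% by default).

## Conservation scores

The sequence conservation score substitutes a transparent information
measure for heavyweight evolutionary-rate models: per column,
$1 - H/\log_2 4$ over {A, C, G, U} with gaps excluded from the entropy but
penalised through occupancy weighting, then min–max rescaled to $[0,1]$
across residues. It preserves the ordering semantics (conserved columns
high, variable columns low) while being deterministic and dependency-free.
Covariation and secondary-structure terms are documented extension points,
not scored. The 3DCS is $1 - $ normalised r.m.s.f., so it inherits
invariance to affine rescaling of the fluctuations. `correlate_and_flag()`
reports the Pearson correlation between the two, flags residues in the
upper quartile of one score and lower quartile of the other (quartiles are
the default because no principled numeric cutoff exists for "high but
low"), and recomputes the correlation without them. Because squaring the
scores has been proposed as an alternative scale, the squared-score
correlation is reported alongside the raw one rather than choosing one
interpretation.

## What the synthetic generators emulate

`generate_hinge_ensemble()` builds a two-domain coarse-grained molecule:
a rigid core ball and a peripheral arm that pivots about an attachment
residue. Defaults are set to the study scale this package is exercised at:
400 residues, a 140-residue arm, three classes with fold angles
(90°, 69°, 0°) calibrated so class mean radii of gyration sit near 46.5,
51 and 58 Å (compact, intermediate, extended), class counts 32/119/7, and
modest per-member angle spread (4°) and arm jitter (2 Å). The hinge angle
is the fold away from the fully extended radial pose, so 0° is the most
open class. Straight-chain arms (`arm_shape = "straight"`, bead spacing
5.9 Å) expose exact tip-displacement geometry for validation; the default
coil arms emulate a globular domain.

What the generator does **not** emulate: RNA backbone geometry, base
pairing, sequence-specific structure, Mg²⁺ electrostatics, or experimental
noise sources beyond multiplicative Gaussian noise on mixture curves.
Passing recovery tests on these ensembles therefore demonstrates that the
estimators are correct and well calibrated on data satisfying their
assumptions — not that real imaging-derived ensembles are free of model
error. `generate_coupled_msa()` ties per-column substitution probability to
a flexibility profile; its `coupling` argument is the signed strength of
the conservation–flexibility coupling, with $-1$ the biologically typical
regime (flexible residues variable, hence sequence conservation tracking
conformational conservation) and planted invariant columns at the most
flexible residues emulating conserved-but-mobile functional elements.

## Numerical choices and problem sizes

* Default $q$ grid: 101 linear points over 0.006–0.45 Å⁻¹; model curves
  are interpolated linearly onto the experimental grid and never
  extrapolated (fits clip to the overlap).
* Guinier fitting iterates the window until $qR_g \le 1.3$ is
  self-consistent; at least 5 points are required, a nonnegative slope is
  reported as non-Guinier behaviour. For spheres the Guinier
  approximation has a known positive bias (~1.5% at $qR_g\le1.3$), so
  sub-1% accuracy needs the conservative $qR_g \le 0.9$ window.
* $P(r)$ bins are pinned to $d_\mathrm{max}$ (final partial bin), padded
  with zero bins, and renormalised to trapezoid integral 1.
* Superposition requires 3 non-collinear points; reflections are excluded
  by the determinant correction; re-superposition is idempotent to
  numerical precision.
* The test suite and the acceptance script run at reduced problem sizes
  chosen to exercise every code path at the study's physical scale:
  400-residue representatives for fraction recovery (100 noisy repeats),
  a 36-member labelled pool for the 500-round combination study,
  50-member/60-residue ensembles across 10 seeds for core recovery, and
  100-sequence/400-column alignments for the conservation closure.

## Limitations

* Point-scatterer profiles are not comparable in absolute $\chi^2$ to
  hydration-shell models; compositions and relative comparisons are.
* The GA is a compact stand-in for full ensemble-optimization machinery;
  it has no $R_g$-distribution priors or flexibility metrics.
* SCS has no phylogenetic correction: deep, biased alignments will weight
  clades unevenly.
* Single-structure ensembles, all-gap reference rows, constant r.m.s.f.
  vectors and zero-fluctuation residues are handled as documented errors
  or flagged degeneracies, not silently.
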