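# saxsemble

Conformer-ensemble characterization for flexible biomolecules: SAXS
volume-fraction fitting, invariant-core and principal-component
decomposition, and sequence-vs-conformational conservation analysis.

## The problem

Large structured RNAs (the motivating case is bacterial RNase P RNA, a
~400-nt two-domain ribozyme) sample broad conformational spaces: a rigid
catalytic core plus peripheral elements that swing by tens of Angstrom.
Single-particle methods can produce a discrete ensemble of coarse-grained
conformers — one bead per residue — while solution SAXS measures the
population average over all of them. This package implements the analysis
connecting the two views:

- **Forward scattering** by the Debye equation over bead pairs,
  `I(q) = sum_ij f(q)^2 sinc(q d_ij)`, plus standard SAXS analytics
  (Guinier Rg, P(r), dimensionless Kratky, reduced chi-squared).
- **Volume-fraction ensemble fitting**:
  `I_total(q) = sum_i nu_i I_i(q)` with `nu_i >= 0`, `sum nu_i = 1` and one
  global scale, solved exactly by nonnegative least squares on the
  error-weighted design; plus cosine-distance conformer classification
  (threshold 0.1), a randomized combination chi-squared study,
  genetic-algorithm subensemble selection, and titration-series population
  tracking.
- **Ensemble decomposition**: iterative invariant-core search by
  ellipsoid-volume pruning (`v = 4/3 pi sqrt(l1 l2 l3)` from each residue's
  positional covariance, 150 A^3 default cutoff), coordinate-covariance
  PCA with per-residue amplitudes and min-to-max motion trajectories, the
  movement similarity matrix (dynamic cross-correlation of positional
  deviations), PC-space clustering, and r.m.s.f. vs B-factor correlation.
- **Conservation**: per-column sequence conservation (entropy/occupancy
  score, SCS) from Stockholm or FASTA alignments, the 3D conformation
  conservation score `3DCS = 1 - normalized r.m.s.f.`, their Pearson
  correlation, and flagging of anticorrelated (sequence-conserved but
  mobile) residues.
- **Synthetic data generators** with known ground truth — multi-class
  two-domain hinge ensembles at the study scale (class Rg near 46.5 / 51 /
  58 A), noisy mixture curves, single-mode ensembles, and alignments whose
  conservation is coupled to flexibility — so every estimator is validated
  by parameter recovery.

Everything is tidyverse-shaped: profiles and result tables are tibbles,
fitted objects have `tidy()`/`glance()` and `autoplot()` methods, and the
full pipeline runs from one `analysis_config()` via `run_full_analysis()`.

## Worked example

Three class representatives (compact / intermediate / extended), a noisy
18/76/6 mixture of their theoretical curves, and the fit that recovers it:

```r
library(saxsemble)

gen <- generate_hinge_ensemble(hinge_ensemble_spec(
  class_counts = c(1L, 1L, 1L),
  class_params = data.frame(hinge_mean_deg = c(90, 69, 0),
                            hinge_sd_deg = 0, arm_jitter_sd = 0),
  seed = 3
))
sapply(gen$ensemble$members, rg_from_coordinates)
#>     S001     S002     S003
#> 46.86139 50.97500 57.65329

profiles <- ensemble_profiles(gen$ensemble)
mix <- synthesize_mixture_profile(profiles, c(0.18, 0.76, 0.06),
                                  noise_fraction = 0.01, seed = 11)
fit <- fit_volume_fractions(profiles, mix)
fit
#> <volume_fraction_fit> 3 candidates, chi2 = 0.8182
#>   S002: 75.5%
#>   S001: 19.1%
#>   S003: 5.4%
glance(fit)
#> # A tibble: 1 x 5
#>    chi2 scale n_candidates n_points identifiable
#>   <dbl> <dbl>        <int>    <int> <lgl>
#> 1 0.818 0.999            3      101 TRUE
```

The recovered fractions (19.1 / 75.5 / 5.4%) match the generating truth
(18 / 76 / 6%) within the noise level, and the reduced chi-squared near 1
says the fit is consistent with the 1% error bars.

Invariant core and motion decomposition on a 50-member hinge ensemble
(rigid residues 1–30, flexible arm 31–60 with 12 degrees of hinge spread
and 5 A jitter):

```r
spec <- hinge_ensemble_spec(
  n_residues = 60L, core_range = c(1L, 30L),
  arm_definitions = list(list(residues = c(31L, 60L), attachment = 30L)),
  class_params = data.frame(hinge_mean_deg = 45, hinge_sd_deg = 12,
                            arm_jitter_sd = 5),
  class_counts = 50L, arm_shape = "coil",
  core_radius = 30, arm_radius = 12, arm_offset = 20, seed = 8
)
gen <- generate_hinge_ensemble(spec)

core <- find_invariant_core(gen$ensemble, volume_cutoff = 150)
core
#> <core_result> 30 core residues (cutoff 150 A^3)

pca <- ensemble_pca(gen$ensemble, superpose_subset = core$core_residues)
tidy(pca)[1:3, ]
#> # A tibble: 3 x 4
#>   component eigenvalue variance_fraction cumulative_variance
#>       <int>      <dbl>             <dbl>               <dbl>
#> 1         1       673.            0.226                0.226
#> 2         2       135.            0.0455               0.272
#> 3         3       131.            0.0440               0.316

rmsf <- per_residue_rmsf(gen$ensemble, superpose_subset = core$core_residues)
round(c(core = mean(rmsf[1:30]), arm = mean(rmsf[31:60])), 2)
#> core  arm
#> 0.00 9.83
```

The search recovers exactly the 30 rigid residues; PC1 carries the hinge
motion and the arm fluctuates by ~10 A r.m.s.f. while the core does not
move. `autoplot()` methods draw the fit overlay, the volume pruning curve,
PC projections, the AMSM heat map and the SCS/3DCS scatter;
`run_full_analysis()` + `write_report()` run all stages from one config
and emit JSON/TSV/PDB outputs.

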