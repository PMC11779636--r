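# Shared fixtures built in code at test time.

# small random bead cloud
toy_conformer <- function(n = 10, id = "toy", seed = 1, scale = 10,
                          bfactors = NULL) {
  coords <- withr::with_seed(seed, matrix(stats::rnorm(3 * n) * scale, ncol = 3))
  conformer(id, seq_len(n), coords, bfactors = bfactors)
}

# rigid transform: rotation about an arbitrary axis plus a translation
rigid_transform <- function(coords, angle = 0.8, axis = c(1, 2, 3),
                            shift = c(5, -3, 2)) {
  a <- axis / sqrt(sum(axis^2))
  kx <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  rot <- diag(3) + sin(angle) * kx + (1 - cos(angle)) * (kx %*% kx)
  sweep(coords %*% rot, 2, shift, `+`)
}

apply_rigid <- function(cf, ...) {
  cf$coords <- rigid_transform(cf$coords, ...)
  cf
}

# three well-separated single-member classes at the study's geometry scale
# (hinge angles spanning compact -> extended); representatives for mixture
# fitting tests
class_representatives <- function(seed = 3) {
  spec <- hinge_ensemble_spec(
    class_counts = c(1L, 1L, 1L),
    class_params = data.frame(
      hinge_mean_deg = c(90, 69, 0),
      hinge_sd_deg = 0, arm_jitter_sd = 0
    ),
    seed = seed
  )
  generate_hinge_ensemble(spec)
}

# rigid-core + jittered-blob ensemble used for core-recovery tests: two
# compact domains of comparable extent so superposition cannot absorb the
# flexible domain's variance
rigid_flexible_spec <- function(seed, n_members = 50L, jitter = 5) {
  hinge_ensemble_spec(
    n_residues = 60L, core_range = c(1L, 30L),
    arm_definitions = list(list(residues = c(31L, 60L), attachment = 30L)),
    class_params = data.frame(
      hinge_mean_deg = 0, hinge_sd_deg = 0, arm_jitter_sd = jitter
    ),
    class_counts = n_members, arm_shape = "coil",
    core_radius = 30, arm_radius = 12, arm_offset = 20, seed = seed
  )
}

# labelled multi-member pool for combination-study and GA tests
labelled_pool <- function(per_class = 12L, seed = 21) {
  spec <- hinge_ensemble_spec(
    n_residues = 120L, core_range = c(1L, 80L),
    arm_definitions = list(list(residues = c(81L, 120L), attachment = 80L)),
    class_params = data.frame(
      hinge_mean_deg = c(90, 60, 0),
      hinge_sd_deg = 3, arm_jitter_sd = 1.5
    ),
    class_counts = rep(as.integer(per_class), 3),
    arm_shape = "coil", core_radius = 26, arm_radius = 15, arm_offset = 22,
    seed = seed
  )
  gen <- generate_hinge_ensemble(spec)
  profiles <- ensemble_profiles(gen$ensemble)
  labels <- stats::setNames(gen$truth$labels$class, gen$truth$labels$id)
  list(gen = gen, profiles = profiles, labels = labels)
}
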