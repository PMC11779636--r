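# Deterministic quasi-uniform points filling a ball: Fibonacci directions
# with cube-root radial spacing. Used to lay out compact "domains" of beads.
ball_spiral <- function(n, radius) {
  k <- seq_len(n)
  z <- 1 - 2 * (k - 0.5) / n
  theta <- pi * (1 + sqrt(5)) * k
  s <- sqrt(pmax(1 - z^2, 0))
  dir <- cbind(s * cos(theta), s * sin(theta), z)
  r <- radius * (k / n)^(1 / 3)
  dir * r
}

# Rodrigues rotation matrix about a unit axis
rotation_about_axis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  kx <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * kx + (1 - cos(angle)) * (kx %*% kx)
}

unit_perpendicular <- function(v) {
  ref <- if (abs(v[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  w <- c(
    v[2] * ref[3] - v[3] * ref[2],
    v[3] * ref[1] - v[1] * ref[3],
    v[1] * ref[2] - v[2] * ref[1]
  )
  w / sqrt(sum(w^2))
}

#' Specification for a synthetic two-domain hinge ensemble
#'
#' Describes a coarse-grained molecule with a rigid core domain and one or
#' more peripheral arms that pivot about attachment residues, emulating a
#' large structured RNA whose substrate-specificity domain swings relative to
#' the catalytic domain. The defaults emulate the study conditions this
#' package is exercised under: 400 residues, one 140-residue arm, three
#' conformer classes whose fold angles put the class mean radii of gyration
#' at roughly 58, 51 and 46.5 Angstrom (extended, intermediate, compact) with
#' class counts 7/119/32 out of 158 members.
#'
#' The hinge angle is the fold angle of the arm away from the fully extended
#' (radial) pose: 0 degrees is maximally open, larger angles fold the arm
#' against the core and reduce Rg.
#'
#' @param n_residues Total residue count.
#' @param core_range Integer pair, the residue interval of the rigid core.
#' @param arm_definitions List of arms, each
#'   `list(residues = c(lo, hi), attachment = <core residue>)`.
#' @param class_params Data frame with one row per class and columns
#'   `hinge_mean_deg`, `hinge_sd_deg`, `arm_jitter_sd` (Angstrom).
#' @param class_counts Integer member count per class.
#' @param bead_spacing Bead spacing for straight arms (Angstrom).
#' @param arm_shape `"coil"` (compact globular arm) or `"straight"` (linear
#'   chain of `bead_spacing`-spaced beads, length = spacing x residues).
#' @param core_radius,arm_radius Ball radii of the coil domains (Angstrom).
#' @param arm_offset Distance from the attachment residue to a coil arm's
#'   centre (Angstrom).
#' @param seed Integer RNG seed.
#' @return A `hinge_ensemble_spec` list.
#' @export
hinge_ensemble_spec <- function(n_residues = 400L,
                                core_range = c(1L, 260L),
                                arm_definitions = list(
                                  list(
                                    residues = c(261L, 400L),
                                    attachment = 260L
                                  )
                                ),
                                class_params = data.frame(
                                  hinge_mean_deg = c(90, 69, 0),
                                  hinge_sd_deg = c(4, 4, 4),
                                  arm_jitter_sd = c(2, 2, 2)
                                ),
                                class_counts = c(32L, 119L, 7L),
                                bead_spacing = 5.9,
                                arm_shape = c("coil", "straight"),
                                core_radius = 38.7,
                                arm_radius = 31,
                                arm_offset = 68,
                                seed = 1L) {
  arm_shape <- match.arg(arm_shape)
  all_res <- seq_len(n_residues)
  arm_res <- lapply(arm_definitions, function(a) {
    seq(a$residues[1], a$residues[2])
  })
  taken <- unlist(arm_res)
  if (anyDuplicated(taken)) stop("arm intervals overlap")
  if (any(!taken %in% all_res)) stop("arm interval outside 1..n_residues")
  core <- setdiff(all_res, taken)
  if (length(core) < 3L) stop("core must keep at least 3 residues")
  for (a in arm_definitions) {
    if (!a$attachment %in% core) stop("attachment residue must be in the core")
  }
  if (any(core_range < 1L | core_range > n_residues)) {
    stop("core_range outside 1..n_residues")
  }
  if (any(class_counts < 0L)) stop("class_counts must be nonnegative")
  if (any(class_params$hinge_sd_deg < 0) || any(class_params$arm_jitter_sd < 0)) {
    stop("spread parameters must be nonnegative")
  }
  if (nrow(class_params) != length(class_counts)) {
    stop("one class_params row per class count")
  }
  structure(
    list(
      n_residues = as.integer(n_residues), core_range = as.integer(core_range),
      arm_definitions = arm_definitions, class_params = class_params,
      class_counts = as.integer(class_counts), bead_spacing = bead_spacing,
      arm_shape = arm_shape, core_radius = core_radius,
      arm_radius = arm_radius, arm_offset = arm_offset,
      core_residues = core, seed = as.integer(seed)
    ),
    class = "hinge_ensemble_spec"
  )
}

#' Generate a multi-class two-domain hinge ensemble with known ground truth
#'
#' Core beads are identical across members; each arm is rotated rigidly about
#' its attachment residue by a class-specific fold angle plus per-member
#' Gaussian angle spread, then per-member Gaussian jitter is added to the arm
#' beads. Reproducible from the spec's seed.
#'
#' @param spec A [hinge_ensemble_spec].
#' @return List with `ensemble` (a [conformer_ensemble]) and `truth`
#'   containing `labels` (tibble `id`, `class`, `hinge_deg`), `core_residues`
#'   and the spec.
#' @export
generate_hinge_ensemble <- function(spec) {
  stopifnot(inherits(spec, "hinge_ensemble_spec"))
  n <- spec$n_residues
  core <- spec$core_residues
  core_xyz <- ball_spiral(length(core), spec$core_radius)
  base <- matrix(NA_real_, n, 3)
  base[core, ] <- core_xyz
  arm_geom <- lapply(spec$arm_definitions, function(a) {
    res <- seq(a$residues[1], a$residues[2])
    p_a <- base[a$attachment, ]
    d0 <- p_a / sqrt(sum(p_a^2))
    offsets <- if (spec$arm_shape == "straight") {
      outer(seq_along(res) * spec$bead_spacing, d0)
    } else {
      sweep(ball_spiral(length(res), spec$arm_radius), 2,
        spec$arm_offset * d0, `+`
      )
    }
    list(res = res, p_a = p_a, axis = unit_perpendicular(d0), offsets = offsets)
  })
  m_total <- sum(spec$class_counts)
  if (m_total < 2L) stop("need at least 2 members in total")
  class_of <- rep(seq_along(spec$class_counts), spec$class_counts)
  members <- vector("list", m_total)
  hinge_deg <- numeric(m_total)
  withr::with_seed(spec$seed, {
    for (m in seq_len(m_total)) {
      cl <- class_of[m]
      pars <- spec$class_params[cl, ]
      theta <- stats::rnorm(1, pars$hinge_mean_deg, pars$hinge_sd_deg)
      hinge_deg[m] <- theta
      coords <- base
      for (g in arm_geom) {
        rot <- rotation_about_axis(g$axis, theta * pi / 180)
        arm_xyz <- sweep(g$offsets %*% t(rot), 2, g$p_a, `+`)
        if (pars$arm_jitter_sd > 0) {
          arm_xyz <- arm_xyz + matrix(
            stats::rnorm(length(arm_xyz), 0, pars$arm_jitter_sd),
            ncol = 3
          )
        }
        coords[g$res, ] <- arm_xyz
      }
      members[[m]] <- conformer(sprintf("S%03d", m), seq_len(n), coords)
    }
  })
  list(
    ensemble = conformer_ensemble(members),
    truth = list(
      labels = tibble::tibble(
        id = sprintf("S%03d", seq_len(m_total)),
        class = paste0("C", class_of),
        hinge_deg = hinge_deg
      ),
      core_residues = core,
      spec = spec
    )
  )
}

#' Synthesize a noisy mixture SAXS curve with known volume fractions
#'
#' Computes I(q) = sum_i fraction_i I_i(q) on the common q grid and applies
#' multiplicative Gaussian noise of relative standard deviation
#' `noise_fraction`; the returned `sigma` column carries the true noise
#' level. This is the forward model whose inverse the volume-fraction fit
#' recovers.
#'
#' @param component_profiles List of profiles on a common q grid.
#' @param fractions Nonnegative fractions summing to 1 (tolerance 1e-9).
#' @param noise_fraction Relative noise level (default 0.01).
#' @param seed Integer RNG seed.
#' @return A [scattering_profile] with `sigma`.
#' @export
synthesize_mixture_profile <- function(component_profiles, fractions,
                                       noise_fraction = 0.01, seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (any(fractions < 0)) stop("fractions must be nonnegative")
  q <- component_profiles[[1]]$q
  for (p in component_profiles[-1]) {
    if (!isTRUE(all.equal(p$q, q))) stop("profiles must share one q grid")
  }
  imix <- Reduce(
    `+`,
    Map(function(p, f) f * p$intensity, component_profiles, fractions)
  )
  noisy <- if (noise_fraction > 0) {
    withr::with_seed(
      seed,
      imix * (1 + stats::rnorm(length(imix), 0, noise_fraction))
    )
  } else {
    imix
  }
  scattering_profile(q, noisy,
    sigma = pmax(noise_fraction * abs(imix), 1e-12),
    label = "mixture"
  )
}

#' Generate a single-mode ensemble for testing PCA recovery
#'
#' Member m = base + amplitude_m x mode (reshaped N x 3) + isotropic Gaussian
#' jitter; with zero jitter the ensemble is exactly rank 1 along `mode`.
#'
#' @param base A [conformer].
#' @param mode_vector Numeric vector of length 3N (x1, y1, z1, x2, ...).
#' @param amplitudes Numeric vector of per-member amplitudes.
#' @param jitter Isotropic per-coordinate Gaussian s.d. (Angstrom).
#' @param seed Integer RNG seed.
#' @return A [conformer_ensemble].
#' @export
generate_mode_ensemble <- function(base, mode_vector, amplitudes, jitter = 0,
                                   seed = 1L) {
  stopifnot(inherits(base, "conformer"))
  n <- n_residues(base)
  if (length(mode_vector) != 3L * n) stop("mode vector must have length 3N")
  mode_mat <- matrix(mode_vector, ncol = 3, byrow = TRUE)
  members <- withr::with_seed(seed, {
    lapply(seq_along(amplitudes), function(m) {
      coords <- base$coords + amplitudes[m] * mode_mat
      if (jitter > 0) {
        coords <- coords + matrix(stats::rnorm(3 * n, 0, jitter), ncol = 3)
      }
      conformer(sprintf("m%03d", m), base$residue_numbers, coords)
    })
  })
  conformer_ensemble(members)
}

#' Generate a multiple alignment whose conservation tracks flexibility
#'
#' Builds an ungapped RNA alignment over a reference sequence in which each
#' column's substitution probability is tied to the per-residue flexibility
#' profile. `coupling` is the sign and strength of the coupling between
#' sequence conservation and flexibility: `coupling = -1` makes flexible
#' residues maximally variable (the biologically typical regime, giving a
#' strongly positive correlation between sequence conservation and the
#' conformational conservation score, which is itself 1 minus normalised
#' r.m.s.f.), `coupling = +1` makes flexible residues conserved, and 0
#' decouples the two. Optionally plants invariant ("anticorrelated") columns
#' at the most flexible residues to emulate sequence-conserved but mobile
#' functional elements.
#'
#' @param flex_profile Per-residue flexibility (for example r.m.s.f.,
#'   Angstrom), length N.
#' @param n_sequences Number of rows (>= 2).
#' @param coupling Real in \[-1, 1\].
#' @param n_planted Number of invariant columns planted at the most flexible
#'   residues (default 0).
#' @param base_substitution Mean substitution probability at `coupling = 0`.
#' @param seed Integer RNG seed.
#' @return List with `msa` (an [msa] object), and `truth` (tibble `residue`,
#'   `substitution_prob`, `planted`).
#' @export
generate_coupled_msa <- function(flex_profile, n_sequences = 100L,
                                 coupling = -1, n_planted = 0L,
                                 base_substitution = 0.4, seed = 1L) {
  if (coupling < -1 || coupling > 1) stop("`coupling` must be in [-1, 1]")
  if (n_sequences < 2L) stop("need at least 2 sequences")
  n <- length(flex_profile)
  rng <- range(flex_profile)
  fn <- if (diff(rng) == 0) {
    rep(0.5, n)
  } else {
    (flex_profile - rng[1]) / diff(rng)
  }
  ramp <- if (coupling < 0) fn else if (coupling > 0) 1 - fn else rep(0.5, n)
  p_sub <- abs(coupling) * (0.02 + 0.78 * ramp) +
    (1 - abs(coupling)) * base_substitution
  planted <- rep(FALSE, n)
  if (n_planted > 0L) {
    idx <- order(flex_profile, decreasing = TRUE)[seq_len(n_planted)]
    p_sub[idx] <- 0
    planted[idx] <- TRUE
  }
  alphabet <- c("A", "C", "G", "U")
  rows <- withr::with_seed(seed, {
    ref <- sample(alphabet, n, replace = TRUE)
    mat <- matrix(rep(ref, each = n_sequences), nrow = n_sequences)
    for (j in seq_len(n)) {
      if (p_sub[j] == 0) next
      hit <- which(stats::runif(n_sequences - 1L) < p_sub[j]) + 1L
      if (length(hit)) {
        mat[hit, j] <- vapply(
          mat[hit, j],
          function(b) sample(setdiff(alphabet, b), 1L),
          character(1)
        )
      }
    }
    rownames(mat) <- c("reference", sprintf("seq%03d", seq_len(n_sequences - 1L)))
    mat
  })
  list(
    msa = msa(rows),
    truth = tibble::tibble(
      residue = seq_len(n), substitution_prob = p_sub, planted = planted
    )
  )
}
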