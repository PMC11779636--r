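#' Superpose all ensemble members onto their mean structure
#'
#' Iterative mean-structure superposition over a residue subset: members are
#' first fitted to the reference member, then repeatedly to the running mean
#' until the mean converges. This removes global rigid-body motion so that
#' fluctuation statistics (r.m.s.f., PCA, movement correlations) measure
#' internal motion only.
#'
#' @param ensemble A [conformer_ensemble].
#' @param subset Residue numbers used for the fit (default all); typically
#'   the invariant core.
#' @param max_iter,tol Convergence controls on the mean structure (Angstrom).
#' @return A [conformer_ensemble] with transformed coordinates.
#' @export
superpose_ensemble <- function(ensemble, subset = NULL, max_iter = 10L,
                               tol = 1e-8) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  members <- ensemble$members
  ref <- members[[ensemble$reference_index]]
  members <- lapply(members, function(m) {
    kabsch_superpose(m, ref, subset)$conformer
  })
  mean_cf <- ref
  for (it in seq_len(max_iter)) {
    xyz <- ensemble_xyz(conformer_ensemble(members,
      reference_index = ensemble$reference_index
    ))
    mean_cf$coords <- matrix(colMeans(xyz), ncol = 3, byrow = TRUE)
    new_members <- lapply(members, function(m) {
      kabsch_superpose(m, mean_cf, subset)$conformer
    })
    shift <- max(vapply(
      seq_along(members),
      function(i) max(abs(new_members[[i]]$coords - members[[i]]$coords)),
      numeric(1)
    ))
    members <- new_members
    if (shift < tol) break
  }
  conformer_ensemble(members, reference_index = ensemble$reference_index)
}

#' Per-residue root-mean-square fluctuation
#'
#' rmsf_i = sqrt(mean over members of |r_i - <r_i>|^2) after superposition on
#' `superpose_subset` (internal superposition can be disabled when the
#' ensemble is already fitted).
#'
#' @param ensemble A [conformer_ensemble].
#' @param superpose_subset Residue numbers for the superposition fit
#'   (default all residues).
#' @param superpose Perform the superposition internally (default TRUE).
#' @return Named numeric vector (Angstrom), names = residue numbers.
#' @export
per_residue_rmsf <- function(ensemble, superpose_subset = NULL,
                             superpose = TRUE) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  if (superpose) ensemble <- superpose_ensemble(ensemble, superpose_subset)
  xyz <- ensemble_xyz(ensemble)
  dev <- sweep(xyz, 2, colMeans(xyz))
  n <- ncol(xyz) / 3L
  msf <- vapply(seq_len(n), function(i) {
    cols <- (3L * (i - 1L) + 1L):(3L * i)
    mean(rowSums(dev[, cols, drop = FALSE]^2))
  }, numeric(1))
  stats::setNames(sqrt(msf), ensemble$members[[1L]]$residue_numbers)
}

# Per-residue ellipsoid volumes over the members of a superposed ensemble:
# v_i = 4/3 pi sqrt(l1 l2 l3) with l* the eigenvalues of residue i's 3x3
# positional covariance across members.
residue_ellipsoid_volumes <- function(xyz) {
  n <- ncol(xyz) / 3L
  dev <- sweep(xyz, 2, colMeans(xyz))
  vapply(seq_len(n), function(i) {
    cols <- (3L * (i - 1L) + 1L):(3L * i)
    cv <- crossprod(dev[, cols, drop = FALSE]) / (nrow(xyz) - 1L)
    ev <- pmax(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, 0)
    4 / 3 * pi * sqrt(prod(ev))
  }, numeric(1))
}

#' Iterative invariant-core search by ellipsoid-volume pruning
#'
#' Repeatedly superposes all members on the current residue set, computes for
#' each remaining residue the volume of the ellipsoid covering the variance
#' of its X, Y, Z coordinates across members (v = 4/3 pi sqrt(l1 l2 l3) from
#' the eigenvalues of the 3x3 positional covariance), and removes the residue
#' with the largest volume. With a numeric `volume_cutoff` (Angstrom^3) the
#' iteration stops once every remaining residue's volume is at or below the
#' cutoff; with `volume_cutoff = "auto"` the full pruning trajectory is
#' computed and the core is cut at the valley of the first difference of
#' total ellipsoid volume versus remaining residue count (smoothed over 3
#' points), i.e. at the start of the flat tail of the volume curve.
#'
#' @param ensemble A [conformer_ensemble] with at least 3 members.
#' @param volume_cutoff Positive number (Angstrom^3, default 150) or
#'   `"auto"`.
#' @param min_core Smallest admissible core size (default 3).
#' @return Object of class `core_result`: `core_residues`, `volume_cutoff`,
#'   and `iterations`, a tibble with one row per pruning step
#'   (`step`, `removed_residue`, `remaining`, `max_volume`, `total_volume`;
#'   step 0 is the state before any removal).
#' @export
find_invariant_core <- function(ensemble, volume_cutoff = 150,
                                min_core = 3L) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  if (length(ensemble$members) < 3L) stop("need at least 3 members")
  auto <- identical(volume_cutoff, "auto")
  if (!auto && (!is.numeric(volume_cutoff) || volume_cutoff <= 0)) {
    stop("`volume_cutoff` must be positive or \"auto\"")
  }
  res_all <- ensemble$members[[1L]]$residue_numbers
  current <- res_all
  steps <- list()
  step <- 0L
  repeat {
    fitted <- superpose_ensemble(ensemble, subset = current)
    xyz <- ensemble_xyz(fitted)
    idx <- match(current, res_all)
    cols <- as.vector(t(outer(idx, 1:3, function(i, k) 3L * (i - 1L) + k)))
    vols <- residue_ellipsoid_volumes(xyz[, cols, drop = FALSE])
    steps[[step + 1L]] <- tibble::tibble(
      step = step,
      removed_residue = NA_integer_,
      remaining = length(current),
      max_volume = max(vols),
      total_volume = sum(vols)
    )
    if (!auto && max(vols) <= volume_cutoff) break
    if (length(current) - 1L < min_core) {
      if (auto) break
      stop(
        "core would shrink below ", min_core,
        " residues before reaching the volume cutoff"
      )
    }
    worst <- current[which.max(vols)]
    current <- setdiff(current, worst)
    step <- step + 1L
    # each row records the state before a removal plus the residue removed
    # right after it; the final row keeps NA (nothing removed)
    steps[[step]]$removed_residue <- worst
  }
  iterations <- dplyr::bind_rows(steps)
  if (auto) {
    drop <- -diff(iterations$total_volume)
    sm <- stats::filter(drop, rep(1 / 3, 3), sides = 2)
    sm[is.na(sm)] <- drop[is.na(sm)]
    floor_level <- min(sm)
    span <- max(sm) - floor_level
    valley <- which(sm <= floor_level + 0.01 * span)[1L]
    core <- res_all
    if (valley > 1L) {
      core <- setdiff(core, iterations$removed_residue[seq_len(valley - 1L)])
    }
    cutoff <- iterations$max_volume[valley]
  } else {
    core <- current
    cutoff <- volume_cutoff
  }
  structure(
    list(
      core_residues = core, volume_cutoff = cutoff,
      iterations = iterations, auto = auto
    ),
    class = "core_result"
  )
}

#' @export
print.core_result <- function(x, ...) {
  cat("<core_result> ", length(x$core_residues), " core residues (cutoff ",
    signif(x$volume_cutoff, 4), " A^3",
    if (x$auto) ", automatic" else "", ")\n",
    sep = ""
  )
  invisible(x)
}

#' Principal component analysis of a conformer ensemble
#'
#' Eigendecomposition of the 3N x 3N coordinate covariance across members
#' after superposition on `superpose_subset` (typically the invariant core).
#' Components are ordered by decreasing eigenvalue; each eigenvector's
#' largest-magnitude coefficient is made positive for reproducible reports.
#'
#' @param ensemble A [conformer_ensemble].
#' @param superpose_subset Residue numbers for the superposition fit.
#' @param superpose Superpose internally (default TRUE).
#' @return Object of class `ensemble_pca`: `mean_coords` (N x 3),
#'   `eigenvalues` (Angstrom^2, descending), `eigenvectors` (3N x k,
#'   orthonormal columns), `projections` (M x k), `variance_fractions`,
#'   `cumulative_variance`, `residue_numbers`, `member_ids`.
#' @export
ensemble_pca <- function(ensemble, superpose_subset = NULL,
                         superpose = TRUE) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  if (superpose) ensemble <- superpose_ensemble(ensemble, superpose_subset)
  xyz <- ensemble_xyz(ensemble)
  if (nrow(xyz) < 2L) stop("PCA needs at least 2 members")
  pc <- stats::prcomp(xyz, center = TRUE, scale. = FALSE)
  # drop numerically-null components (at most M - 1 can carry variance)
  k <- max(sum(pc$sdev > pc$sdev[1L] * 1e-8), 1L)
  vecs <- pc$rotation[, seq_len(k), drop = FALSE]
  proj <- pc$x[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    v <- vecs[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  vecs <- sweep(vecs, 2, flip, `*`)
  proj <- sweep(proj, 2, flip, `*`)
  lambda <- pc$sdev[seq_len(k)]^2
  total_var <- sum(pc$sdev^2)
  structure(
    list(
      mean_coords = matrix(pc$center, ncol = 3, byrow = TRUE),
      eigenvalues = lambda,
      eigenvectors = vecs,
      projections = proj,
      variance_fractions = lambda / total_var,
      cumulative_variance = cumsum(lambda / total_var),
      total_variance = total_var,
      residue_numbers = ensemble$members[[1L]]$residue_numbers,
      member_ids = ensemble_ids(ensemble)
    ),
    class = "ensemble_pca"
  )
}

#' @export
print.ensemble_pca <- function(x, ...) {
  k <- min(5L, length(x$eigenvalues))
  cat("<ensemble_pca> ", length(x$member_ids), " members, ",
    length(x$residue_numbers), " residues\n  top ", k,
    " PCs cover ", round(100 * x$cumulative_variance[k]),
    "% of the variance\n",
    sep = ""
  )
  invisible(x)
}

#' Number of components covering a variance fraction
#'
#' @param pca An [ensemble_pca].
#' @param fraction Target cumulative variance fraction (default 0.7).
#' @return Integer component count.
#' @export
n_components_for_variance <- function(pca, fraction = 0.7) {
  which(pca$cumulative_variance >= fraction)[1L]
}

#' Per-residue motion amplitude of a principal component
#'
#' amplitude_i = sqrt(eigenvalue) x norm of residue i's three eigenvector
#' coefficients; the squared amplitudes sum to the component's eigenvalue.
#'
#' @param pca An [ensemble_pca].
#' @param component Component index.
#' @return Named numeric vector (Angstrom), names = residue numbers.
#' @export
per_residue_pc_amplitude <- function(pca, component) {
  if (component < 1L || component > length(pca$eigenvalues)) {
    stop("component out of range")
  }
  v <- matrix(pca$eigenvectors[, component], ncol = 3, byrow = TRUE)
  stats::setNames(
    sqrt(pca$eigenvalues[component]) * sqrt(rowSums(v^2)),
    pca$residue_numbers
  )
}

#' Interpolate a principal-component motion trajectory
#'
#' Frames are the mean structure displaced along one component, with the
#' projection sweeping linearly from the minimum to the maximum observed
#' member projection; useful for visualising a motion mode as a multi-model
#' PDB (see [write_conformer()]).
#'
#' @param pca An [ensemble_pca].
#' @param component Component index.
#' @param n_frames Number of frames (>= 2, default 20).
#' @return A [conformer_ensemble] of frames `frame001`, `frame002`, ...
#' @export
interpolate_pc_trajectory <- function(pca, component, n_frames = 20L) {
  if (n_frames < 2L) stop("need at least 2 frames")
  if (component < 1L || component > length(pca$eigenvalues)) {
    stop("component out of range")
  }
  pr <- pca$projections[, component]
  ts <- seq(min(pr), max(pr), length.out = n_frames)
  v <- matrix(pca$eigenvectors[, component], ncol = 3, byrow = TRUE)
  members <- lapply(seq_len(n_frames), function(f) {
    conformer(
      sprintf("frame%03d", f), pca$residue_numbers,
      pca$mean_coords + ts[f] * v
    )
  })
  conformer_ensemble(members)
}

#' Atomic movement similarity matrix (AMSM)
#'
#' Pairwise correlation of residue motions across the ensemble: entry (i, j)
#' is <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>) with dr the deviation from
#' the mean position after superposition -- the standard dynamic
#' cross-correlation of positional deviations, in \[-1, 1\], unit diagonal.
#' Residues with zero fluctuation get 0 off-diagonal (flagged).
#'
#' @param ensemble A [conformer_ensemble].
#' @param superpose_subset Residue numbers for the superposition fit.
#' @param superpose Superpose internally (default TRUE).
#' @return Object of class `amsm`: `values` (N x N, dimnames = residue
#'   numbers), `residue_numbers`, `zero_fluctuation` (residue numbers).
#' @export
movement_similarity_matrix <- function(ensemble, superpose_subset = NULL,
                                       superpose = TRUE) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  if (superpose) ensemble <- superpose_ensemble(ensemble, superpose_subset)
  xyz <- ensemble_xyz(ensemble)
  dev <- sweep(xyz, 2, colMeans(xyz))
  n <- ncol(xyz) / 3L
  m <- nrow(xyz)
  # inner products <dr_i . dr_j> as a sum over the x, y, z block covariances
  blocks <- lapply(1:3, function(k) {
    cols <- seq(k, by = 3L, length.out = n)
    crossprod(dev[, cols, drop = FALSE]) / m
  })
  cij <- Reduce(`+`, blocks)
  msf <- diag(cij)
  zero <- msf <= 0
  denom <- sqrt(outer(pmax(msf, 1e-300), pmax(msf, 1e-300)))
  values <- cij / denom
  values[zero, ] <- 0
  values[, zero] <- 0
  diag(values) <- 1
  res <- ensemble$members[[1L]]$residue_numbers
  dimnames(values) <- list(res, res)
  structure(
    list(
      values = values, residue_numbers = res,
      zero_fluctuation = res[zero]
    ),
    class = "amsm"
  )
}

#' @export
print.amsm <- function(x, ...) {
  cat("<amsm> ", nrow(x$values), " x ", ncol(x$values), " residues\n",
    sep = ""
  )
  invisible(x)
}

#' Cluster ensemble members in principal-component space
#'
#' Hierarchical clustering (average linkage, Euclidean distance) of the
#' member projections onto the leading components; deterministic. Choose
#' `n_components` to cover a target variance fraction with
#' [n_components_for_variance()].
#'
#' @param pca An [ensemble_pca].
#' @param n_components Number of leading components to use.
#' @param n_clusters Number of clusters (<= number of members).
#' @return Named integer vector of cluster labels per member.
#' @export
cluster_pc_space <- function(pca, n_components, n_clusters) {
  m <- nrow(pca$projections)
  if (n_clusters > m) stop("more clusters than members")
  n_components <- min(n_components, ncol(pca$projections))
  d <- stats::dist(pca$projections[, seq_len(n_components), drop = FALSE])
  hc <- stats::hclust(d, method = "average")
  stats::setNames(stats::cutree(hc, k = n_clusters), pca$member_ids)
}

#' Correlation between r.m.s.f. and crystallographic B factor
#'
#' Pearson correlation of the min-max normalised vectors (normalisation does
#' not change r; it is performed for plotting parity with conventional
#' r.m.s.f./B-factor overlays). Residues lacking B factors (NA) are masked.
#'
#' @param rmsf Numeric vector of per-residue r.m.s.f.
#' @param bfactors Numeric vector of the same length; NAs masked.
#' @return List with `r`, `n` and `data` (tibble `rmsf_norm`, `bfactor_norm`).
#' @export
rmsf_bfactor_correlation <- function(rmsf, bfactors) {
  if (length(rmsf) != length(bfactors)) stop("length mismatch")
  keep <- !is.na(rmsf) & !is.na(bfactors)
  x <- rmsf[keep]
  y <- bfactors[keep]
  if (length(x) < 3L) stop("need at least 3 residues with B factors")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant vector: correlation undefined")
  }
  norm01 <- function(v) (v - min(v)) / (max(v) - min(v))
  tibble_out <- tibble::tibble(
    rmsf_norm = norm01(x), bfactor_norm = norm01(y)
  )
  list(
    r = stats::cor(tibble_out$rmsf_norm, tibble_out$bfactor_norm),
    n = length(x), data = tibble_out
  )
}
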