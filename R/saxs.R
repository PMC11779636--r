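#' Scattering profiles
#'
#' A scattering profile is a tibble with columns `q` (momentum transfer,
#' 1/Angstrom, strictly increasing and nonnegative), `intensity` (arbitrary
#' units) and optionally `sigma` (positive experimental errors, same units as
#' `intensity`). All SAXS functions accept any data frame with these columns.
#'
#' @param q Strictly increasing nonnegative numeric vector (1/Angstrom).
#' @param intensity Numeric vector, same length as `q`.
#' @param sigma Optional positive numeric vector of errors.
#' @param label Optional text label stored in the `label` attribute.
#' @return A tibble of class `scattering_profile`.
#' @export
scattering_profile <- function(q, intensity, sigma = NULL, label = NULL) {
  q <- as.numeric(q)
  intensity <- as.numeric(intensity)
  if (length(q) != length(intensity)) stop("`q`/`intensity` length mismatch")
  if (any(q < 0)) stop("`q` must be nonnegative")
  if (is.unsorted(q, strictly = TRUE)) stop("`q` must be strictly increasing")
  out <- tibble::tibble(q = q, intensity = intensity)
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q)) stop("`sigma` length mismatch")
    if (any(!is.finite(sigma) | sigma <= 0)) stop("`sigma` must be positive")
    out$sigma <- sigma
  }
  class(out) <- c("scattering_profile", class(out))
  attr(out, "label") <- label
  out
}

#' Default momentum-transfer grid
#'
#' 101 linearly spaced points over 0.006-0.45 1/Angstrom, the working range of
#' a bench SAXS instrument for a particle of this size.
#'
#' @param q_min,q_max Range in 1/Angstrom.
#' @param n Number of points.
#' @return Numeric vector.
#' @export
default_q_grid <- function(q_min = 0.006, q_max = 0.45, n = 101L) {
  seq(q_min, q_max, length.out = n)
}

#' Read/write SAXS curves in 3-column text format
#'
#' Whitespace-delimited columns `q I [sigma]` with `#` comment lines, the de
#' facto .dat dialect of ATSAS-family tools; 2-column files (no errors) are
#' accepted.
#'
#' @param path File path.
#' @param label Optional label; defaults to the file base name.
#' @return `read_saxs()` returns a [scattering_profile].
#' @export
read_saxs <- function(path, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dat <- utils::read.table(path, comment.char = "#", header = FALSE)
  if (ncol(dat) < 2L) stop("expected at least 2 columns (q, intensity)")
  scattering_profile(
    q = dat[[1]], intensity = dat[[2]],
    sigma = if (ncol(dat) >= 3L) dat[[3]] else NULL,
    label = if (is.null(label)) sub("\\.[^.]*$", "", basename(path)) else label
  )
}

#' @rdname read_saxs
#' @param profile Data frame with columns `q`, `intensity` and optionally
#'   `sigma`.
#' @export
write_saxs <- function(profile, path) {
  has_sigma <- "sigma" %in% names(profile)
  header <- paste0("# q[1/A] I(q)", if (has_sigma) " sigma" else "")
  body <- if (has_sigma) {
    sprintf("%.8g %.10g %.10g", profile$q, profile$intensity, profile$sigma)
  } else {
    sprintf("%.8g %.10g", profile$q, profile$intensity)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Theoretical scattering profile by the Debye equation
#'
#' Computes I(q) = sum_ij f(q)^2 sinc(q d_ij) over all bead pairs of a
#' coarse-grained conformer (sinc(0) = 1), with unit point form factors by
#' default, so I(0) = N^2. An optional Gaussian bead form factor
#' f(q) = exp(-(q w)^2 / 2) smears each bead over a width `w`.
#'
#' @param conformer A [conformer].
#' @param q_grid Momentum-transfer grid (1/Angstrom); default
#'   [default_q_grid()].
#' @param form_factor_width Gaussian bead width w in Angstrom; 0 (default)
#'   gives unit point scatterers.
#' @return A [scattering_profile] labelled with the conformer id.
#' @export
debye_profile <- function(conformer, q_grid = default_q_grid(),
                          form_factor_width = 0) {
  stopifnot(inherits(conformer, "conformer"))
  if (!all(is.finite(conformer$coords))) stop("non-finite coordinates")
  n <- n_residues(conformer)
  d <- as.numeric(stats::dist(conformer$coords))
  intens <- vapply(q_grid, function(q) {
    if (q == 0 || length(d) == 0L) {
      n + 2 * length(d)
    } else {
      qd <- q * d
      n + 2 * sum(sin(qd) / qd)
    }
  }, numeric(1))
  if (form_factor_width > 0) {
    intens <- intens * exp(-(q_grid * form_factor_width)^2)
  }
  scattering_profile(q_grid, intens, label = conformer$id)
}

#' Theoretical profiles for every member of an ensemble
#'
#' @param ensemble A [conformer_ensemble].
#' @inheritParams debye_profile
#' @return Named list of [scattering_profile]s, one per member.
#' @export
ensemble_profiles <- function(ensemble, q_grid = default_q_grid(),
                              form_factor_width = 0) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  lapply(ensemble$members, debye_profile,
    q_grid = q_grid,
    form_factor_width = form_factor_width
  )
}

#' Radius of gyration from coordinates
#'
#' Root-mean-square distance of beads from their centroid, uniform weights.
#'
#' @param conformer A [conformer].
#' @return Rg in Angstrom.
#' @export
rg_from_coordinates <- function(conformer) {
  stopifnot(inherits(conformer, "conformer"))
  x <- conformer$coords
  if (nrow(x) < 2L) stop("need at least 2 beads")
  sqrt(mean(rowSums(sweep(x, 2, colMeans(x))^2)))
}

#' Guinier fit of the low-q region
#'
#' Weighted linear regression of ln I on q^2 over a low-q window, iterated
#' until the window q.Rg <= `qrg_max` is self-consistent with the fitted Rg.
#' Rg = sqrt(-3 slope), I0 = exp(intercept). Weights are 1/sigma_lnI^2 when
#' the profile carries errors (propagated as sigma/I), else uniform.
#'
#' @param profile Data frame with `q`, `intensity` and optionally `sigma`.
#' @param qrg_max Upper bound of q.Rg defining the Guinier window
#'   (default 1.3, the conventional limit for globular particles).
#' @param max_iter Maximum window iterations.
#' @return List with `rg`, `i0`, `window` (logical vector over input points),
#'   `n_points`, `qrg_range`.
#' @export
guinier_fit <- function(profile, qrg_max = 1.3, max_iter = 50L) {
  q <- profile$q
  intens <- profile$intensity
  sig <- profile[["sigma"]]
  keep <- intens > 0 & q > 0
  window <- keep
  rg <- NA_real_
  for (iter in seq_len(max_iter)) {
    if (sum(window) < 5L) stop("fewer than 5 points in the Guinier window")
    x <- q[window]^2
    y <- log(intens[window])
    w <- if (is.null(sig)) {
      rep(1, sum(window))
    } else {
      (intens[window] / sig[window])^2
    }
    fit <- stats::lm.wfit(cbind(1, x), y, w)
    slope <- fit$coefficients[2]
    if (slope >= 0) stop("non-Guinier behaviour: nonnegative Guinier slope")
    rg_new <- sqrt(-3 * slope)
    new_window <- keep & (q * rg_new <= qrg_max)
    if (identical(new_window, window)) {
      rg <- rg_new
      break
    }
    window <- new_window
    rg <- rg_new
  }
  x <- q[window]^2
  y <- log(intens[window])
  w <- if (is.null(sig)) {
    rep(1, sum(window))
  } else {
    (intens[window] / sig[window])^2
  }
  fit <- stats::lm.wfit(cbind(1, x), y, w)
  rg <- sqrt(-3 * fit$coefficients[[2]])
  list(
    rg = rg, i0 = exp(fit$coefficients[[1]]), window = window,
    n_points = sum(window), qrg_range = range(q[window] * rg)
  )
}

#' Pair-distance distribution P(r) of a conformer
#'
#' Normalised histogram of all inter-bead distances on bins of width
#' `bin_width` from 0 to just past the maximum distance; the returned density
#' integrates to 1 by the trapezoid rule over the bin centres, and is 0
#' beyond `dmax`.
#'
#' @param conformer A [conformer].
#' @param bin_width Bin width in Angstrom (default 2).
#' @return List with `distribution` (tibble `r`, `p`) and `dmax` (Angstrom).
#' @export
distance_distribution <- function(conformer, bin_width = 2) {
  stopifnot(inherits(conformer, "conformer"))
  if (bin_width <= 0) stop("`bin_width` must be positive")
  d <- as.numeric(stats::dist(conformer$coords))
  if (length(d) == 0L) stop("need at least 2 beads")
  dmax <- max(d)
  # last break pinned to dmax (final bin may be partial) so that no density
  # sits beyond the maximum distance
  breaks <- unique(c(seq(0, dmax, by = bin_width), dmax))
  h <- graphics::hist(d, breaks = breaks, include.lowest = TRUE, plot = FALSE)
  widths <- diff(breaks)
  p <- h$counts / (length(d) * widths)
  r <- h$mids
  # pad with a zero bin on each side, then renormalise by the trapezoid rule
  r <- c(r[1] - widths[1], r, dmax + bin_width)
  p <- c(0, p, 0)
  integral <- sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
  p <- p / integral
  list(distribution = tibble::tibble(r = r, p = p), dmax = dmax)
}

#' Rg from a pair-distance distribution
#'
#' sqrt(integral of r^2 P(r) dr / 2), trapezoid rule; agrees with
#' [rg_from_coordinates()] up to binning error.
#'
#' @param dd Result of [distance_distribution()].
#' @return Rg in Angstrom.
#' @export
rg_from_pr <- function(dd) {
  r <- dd$distribution$r
  p <- dd$distribution$p
  f <- r^2 * p
  sqrt(sum(diff(r) * (utils::head(f, -1) + utils::tail(f, -1)) / 2) / 2)
}

#' Dimensionless Kratky transform
#'
#' Returns the curve ((qRg), (qRg)^2 I(q)/I0) on the input q support. For an
#' ideal globular (Guinier-like) particle the curve peaks at
#' (sqrt(3), 3/e); extended particles do not return to baseline at qRg > 3.
#'
#' @param profile Data frame with `q` and `intensity`.
#' @param rg Radius of gyration (Angstrom), positive.
#' @param i0 Forward intensity I(0), positive.
#' @return Tibble with columns `qrg` and `kratky`.
#' @export
dimensionless_kratky <- function(profile, rg, i0) {
  if (rg <= 0 || i0 <= 0) stop("`rg` and `i0` must be positive")
  qrg <- profile$q * rg
  tibble::tibble(qrg = qrg, kratky = qrg^2 * profile$intensity / i0)
}

# Default experimental error model when sigma is absent: 1% of intensity,
# floored away from zero; keeps chi^2 scale-free in the bench-SAXS noise
# regime.
default_sigma <- function(intensity) {
  pmax(0.01 * abs(intensity), 1e-12)
}

# Linear interpolation of a model profile onto target q values; extrapolation
# is forbidden, so callers must clip to the overlap first.
interp_profile <- function(profile, q_target) {
  stats::approx(profile$q, profile$intensity, xout = q_target, rule = 1)$y
}

#' Reduced chi-squared between two scattering curves
#'
#' chi2 = 1/(K-1) sum_k ((I_exp - c I_model) / sigma_k)^2 over the K points of
#' the common q support, with `c` the closed-form weighted least-squares scale
#' when `fit_scale` is TRUE, else 1. The model is linearly interpolated onto
#' the experimental grid; points outside the model's q range are dropped
#' (no extrapolation). Missing experimental errors default to 1% of intensity.
#'
#' @param experimental,model Data frames with `q`, `intensity`, optionally
#'   `sigma` (experimental only).
#' @param fit_scale Fit the global scale factor (default TRUE).
#' @return List with `chi2`, `scale` and `n_points`.
#' @export
reduced_chi2 <- function(experimental, model, fit_scale = TRUE) {
  keep <- experimental$q >= min(model$q) & experimental$q <= max(model$q)
  if (sum(keep) < 2L) stop("fewer than 2 common q points")
  q <- experimental$q[keep]
  i_exp <- experimental$intensity[keep]
  sig <- experimental[["sigma"]]
  sig <- if (is.null(sig)) default_sigma(i_exp) else sig[keep]
  i_mod <- interp_profile(model, q)
  scale <- if (fit_scale) {
    sum(i_exp * i_mod / sig^2) / sum(i_mod^2 / sig^2)
  } else {
    1
  }
  chi2 <- sum(((i_exp - scale * i_mod) / sig)^2) / (length(q) - 1L)
  list(chi2 = chi2, scale = scale, n_points = length(q))
}
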