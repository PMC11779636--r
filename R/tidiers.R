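#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a volume-fraction fit
#'
#' @param x A `volume_fraction_fit`.
#' @param ... Unused.
#' @return Tibble with one row per candidate: `id`, `nu`, `percent`.
#' @export
tidy.volume_fraction_fit <- function(x, ...) {
  tibble::tibble(id = x$member_ids, nu = x$nu, percent = 100 * x$nu)
}

#' @rdname tidy.volume_fraction_fit
#' @return `glance()` returns a one-row tibble with `chi2`, `scale`,
#'   `n_candidates`, `n_points`, `identifiable`.
#' @export
glance.volume_fraction_fit <- function(x, ...) {
  tibble::tibble(
    chi2 = x$chi2, scale = x$scale,
    n_candidates = length(x$member_ids),
    n_points = x$n_points, identifiable = x$identifiable
  )
}

#' Tidy an ensemble PCA
#'
#' @param x An `ensemble_pca`.
#' @param ... Unused.
#' @return Tibble with `component`, `eigenvalue`, `variance_fraction`,
#'   `cumulative_variance`.
#' @export
tidy.ensemble_pca <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    variance_fraction = x$variance_fractions,
    cumulative_variance = x$cumulative_variance
  )
}

#' @rdname tidy.ensemble_pca
#' @export
glance.ensemble_pca <- function(x, ...) {
  tibble::tibble(
    n_members = length(x$member_ids),
    n_residues = length(x$residue_numbers),
    total_variance = x$total_variance,
    n_components_70 = n_components_for_variance(x, 0.7)
  )
}

#' Tidy a class assignment
#'
#' @param x A `class_assignment`.
#' @param ... Unused.
#' @return The assignment tibble (`id`, `label`, `distance`, `tie`).
#' @export
tidy.class_assignment <- function(x, ...) x$assignments

#' Tidy an invariant-core result
#'
#' @param x A `core_result`.
#' @param ... Unused.
#' @return The pruning-trajectory tibble.
#' @export
tidy.core_result <- function(x, ...) x$iterations

#' @rdname tidy.core_result
#' @export
glance.core_result <- function(x, ...) {
  tibble::tibble(
    n_core = length(x$core_residues),
    volume_cutoff = x$volume_cutoff,
    n_pruned = sum(!is.na(x$iterations$removed_residue)),
    automatic_cutoff = x$auto
  )
}

#' Tidy a combination chi-squared study
#'
#' @param x A `combination_study`.
#' @param ... Unused.
#' @return The per-k summary tibble (`k`, `mean`, `sd`, `min`, `rounds`).
#' @export
tidy.combination_study <- function(x, ...) x$summary

#' Tidy a conservation correlation
#'
#' @param x A `conservation_correlation`.
#' @param ... Unused.
#' @return The per-residue table with flags.
#' @export
tidy.conservation_correlation <- function(x, ...) x$table

#' @rdname tidy.conservation_correlation
#' @export
glance.conservation_correlation <- function(x, ...) {
  tibble::tibble(
    r_all = x$r_all,
    r_excluding_flagged = x$r_excluding_flagged,
    r_all_squared = x$r_all_squared,
    n_flagged = length(x$flagged_high_scs_low_3dcs) +
      length(x$flagged_low_scs_high_3dcs)
  )
}

#' Plot scattering profiles
#'
#' Log-intensity versus q for one or several profiles.
#'
#' @param profiles A profile data frame or (named) list of them.
#' @return A ggplot.
#' @export
plot_profiles <- function(profiles) {
  if (inherits(profiles, "data.frame")) profiles <- list(profiles)
  ids <- profile_ids(profiles)
  df <- purrr::map2_dfr(profiles, ids, function(p, nm) {
    tibble::tibble(q = p$q, intensity = p$intensity, profile = nm)
  })
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$q, y = .data$intensity,
    colour = .data$profile
  )) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = expression(q ~ (ring(A)^-1)), y = "I(q) (a.u., log scale)"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.volume_fraction_fit <- function(object, experimental = NULL, ...) {
  df <- tibble::tibble(
    q = object$fitted_total$q,
    intensity = object$scale * object$fitted_total$intensity,
    curve = "fitted I_total"
  )
  if (!is.null(experimental)) {
    df <- dplyr::bind_rows(
      df,
      tibble::tibble(
        q = experimental$q, intensity = experimental$intensity,
        curve = "experimental"
      )
    )
  }
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$q, y = .data$intensity,
    colour = .data$curve
  )) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = expression(q ~ (ring(A)^-1)), y = "I(q) (a.u., log scale)",
      subtitle = sprintf("reduced chi^2 = %.3g", object$chi2)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ensemble_pca <- function(object, components = c(1L, 2L),
                                  labels = NULL, ...) {
  df <- tibble::tibble(
    x = object$projections[, components[1]],
    y = object$projections[, components[2]],
    id = object$member_ids
  )
  if (!is.null(labels)) df$label <- labels[df$id]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::labs(
      x = sprintf(
        "PC%d (%.0f%%)", components[1],
        100 * object$variance_fractions[components[1]]
      ),
      y = sprintf(
        "PC%d (%.0f%%)", components[2],
        100 * object$variance_fractions[components[2]]
      )
    ) +
    ggplot2::theme_minimal()
  if (is.null(labels)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$label))
  }
}

#' @export
autoplot.core_result <- function(object, ...) {
  ggplot2::ggplot(object$iterations, ggplot2::aes(
    x = .data$remaining,
    y = .data$total_volume
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(
      x = "residues remaining",
      y = expression("total ellipsoid volume" ~ (ring(A)^3))
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.amsm <- function(object, ...) {
  df <- tibble::as_tibble(object$values, rownames = "residue_i")
  df <- tidyr::pivot_longer(df, -"residue_i",
    names_to = "residue_j", values_to = "correlation"
  )
  df$residue_i <- as.integer(df$residue_i)
  df$residue_j <- as.integer(df$residue_j)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$residue_i, y = .data$residue_j,
    fill = .data$correlation
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(
      low = "darkblue", mid = "white",
      high = "red", limits = c(-1, 1)
    ) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "residue", y = "residue") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.conservation_correlation <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(
    x = .data$scs, y = .data$threeDCS,
    colour = .data$flag
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = "sequence conservation score",
      y = "3D conformation conservation score",
      subtitle = sprintf(
        "Pearson r = %.2f (all), %.2f (excluding anticorrelated)",
        object$r_all, object$r_excluding_flagged
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-residue conservation scores along the sequence
#'
#' SCS and 3DCS versus residue number, the standard overlay for spotting
#' regions that are sequence-conserved but conformationally mobile (and vice
#' versa).
#'
#' @param table Tibble with `residue_number`, `scs`, `threeDCS`.
#' @return A ggplot.
#' @export
plot_conservation_tracks <- function(table) {
  df <- tidyr::pivot_longer(
    table[, c("residue_number", "scs", "threeDCS")],
    -"residue_number",
    names_to = "score", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$residue_number, y = .data$value,
    colour = .data$score
  )) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(
      values = c(scs = "darkorange", threeDCS = "steelblue"),
      labels = c(scs = "SCS", threeDCS = "3DCS")
    ) +
    ggplot2::labs(x = "residue", y = "score", colour = NULL) +
    ggplot2::theme_minimal()
}
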