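# Build the common q grid and sigma-weighted design for a set of candidate
# profiles against one experimental curve. Model curves are interpolated
# linearly onto the experimental grid, clipped to the overlap of all supports.
build_design <- function(candidate_profiles, experimental) {
  stopifnot(length(candidate_profiles) >= 1L)
  q_lo <- max(vapply(candidate_profiles, function(p) min(p$q), numeric(1)))
  q_hi <- min(vapply(candidate_profiles, function(p) max(p$q), numeric(1)))
  keep <- experimental$q >= q_lo & experimental$q <= q_hi
  if (sum(keep) < 2L) stop("no usable q overlap between curves")
  q <- experimental$q[keep]
  i_exp <- experimental$intensity[keep]
  sig <- experimental[["sigma"]]
  sig <- if (is.null(sig)) default_sigma(i_exp) else sig[keep]
  design <- vapply(
    candidate_profiles, interp_profile,
    numeric(length(q)), q_target = q
  )
  design <- matrix(design, nrow = length(q))
  list(q = q, i_exp = i_exp, sigma = sig, design = design)
}

profile_ids <- function(profiles) {
  ids <- names(profiles)
  if (is.null(ids) || any(!nzchar(ids))) {
    lab <- vapply(profiles, function(p) {
      l <- attr(p, "label")
      if (is.null(l)) "" else as.character(l)
    }, character(1))
    ids <- ifelse(nzchar(lab), lab, sprintf("profile_%d", seq_along(profiles)))
  }
  make.unique(ids)
}

#' Fit an experimental SAXS curve as a volume-fraction mixture
#'
#' Models the experimental intensity as a linear combination of candidate
#' conformer profiles, I_total(q) = sum_i nu_i I_i(q), with volume fractions
#' nu_i >= 0 summing to 1 and one global scale absorbing units. The bounded
#' weighted least-squares problem is solved exactly by Lawson-Hanson
#' nonnegative least squares on the error-weighted design (every feasible
#' fraction/scale pair corresponds to one nonnegative coefficient vector), so
#' the fit is deterministic. The goodness of fit is the reduced chi-squared
#' against the experimental errors (1% of intensity when absent).
#'
#' @param candidate_profiles Named list of profiles (data frames with `q`,
#'   `intensity`), e.g. from [ensemble_profiles()].
#' @param experimental Data frame with `q`, `intensity`, optionally `sigma`.
#' @return An object of class `volume_fraction_fit` with fields `member_ids`,
#'   `nu` (fractions summing to 1), `scale`, `chi2`, `fitted_total`
#'   (a [scattering_profile]) and `identifiable` (FALSE when the candidate
#'   profiles are numerically rank-deficient, so the split between
#'   degenerate candidates is arbitrary even though their sum is not).
#' @export
fit_volume_fractions <- function(candidate_profiles, experimental) {
  if (inherits(candidate_profiles, "data.frame")) {
    candidate_profiles <- list(candidate_profiles)
  }
  ids <- profile_ids(candidate_profiles)
  dz <- build_design(candidate_profiles, experimental)
  a_mat <- dz$design / dz$sigma
  b <- dz$i_exp / dz$sigma
  sv <- svd(a_mat, nu = 0, nv = 0)$d
  identifiable <- sv[length(sv)] > max(sv) * max(dim(a_mat)) * 1e-12
  coef <- if (ncol(a_mat) == 1L) {
    max(sum(a_mat * b) / sum(a_mat^2), 0)
  } else {
    pracma::lsqnonneg(a_mat, b)$x
  }
  total <- sum(coef)
  if (total <= 0) stop("degenerate fit: all mixture coefficients are zero")
  nu <- coef / total
  i_tot <- as.numeric(dz$design %*% nu)
  chi2 <- sum(((dz$i_exp - total * i_tot) / dz$sigma)^2) / (length(dz$q) - 1L)
  structure(
    list(
      member_ids = ids, nu = as.numeric(nu), scale = total, chi2 = chi2,
      fitted_total = scattering_profile(dz$q, i_tot, label = "I_total"),
      identifiable = identifiable, n_points = length(dz$q)
    ),
    class = "volume_fraction_fit"
  )
}

#' @export
print.volume_fraction_fit <- function(x, ...) {
  cat("<volume_fraction_fit> ", length(x$member_ids), " candidates, chi2 = ",
    signif(x$chi2, 4), if (!x$identifiable) " (non-identifiable split)",
    "\n",
    sep = ""
  )
  top <- order(x$nu, decreasing = TRUE)
  top <- top[x$nu[top] > 0.005]
  for (i in top) {
    cat(sprintf("  %s: %.1f%%\n", x$member_ids[i], 100 * x$nu[i]))
  }
  invisible(x)
}

cosine_distance <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero-norm intensity vector")
  1 - sum(a * b) / (na * nb)
}

#' Classify conformer profiles against reference profiles by cosine distance
#'
#' Assigns each candidate to the nearest reference by cosine distance
#' (1 - cosine similarity of the raw intensity vectors over the common q
#' grid) when that distance is at or below `threshold`, else "unassigned".
#' Cosine distance is invariant to per-profile positive scaling, so profiles
#' on arbitrary intensity scales compare directly. Nearest-reference ties are
#' broken by reference order (recorded in the output).
#'
#' @param candidate_profiles,reference_profiles Named lists of profiles; the
#'   reference names become class labels.
#' @param threshold Maximum cosine distance for assignment (default 0.1).
#' @return An object of class `class_assignment`: tibble `assignments`
#'   (`id`, `label`, `distance`, `tie`), matrix `distances` (candidates x
#'   references) and `threshold`.
#' @export
classify_by_cosine <- function(candidate_profiles, reference_profiles,
                               threshold = 0.1) {
  cand_ids <- profile_ids(candidate_profiles)
  ref_ids <- profile_ids(reference_profiles)
  # common grid: overlap of every support, sampled at the first reference's q
  q_lo <- max(vapply(
    c(candidate_profiles, reference_profiles),
    function(p) min(p$q), numeric(1)
  ))
  q_hi <- min(vapply(
    c(candidate_profiles, reference_profiles),
    function(p) max(p$q), numeric(1)
  ))
  q <- reference_profiles[[1]]$q
  q <- q[q >= q_lo & q <= q_hi]
  if (length(q) < 2L) stop("no usable q overlap between curves")
  cand <- vapply(candidate_profiles, interp_profile, numeric(length(q)),
    q_target = q
  )
  refs <- vapply(reference_profiles, interp_profile, numeric(length(q)),
    q_target = q
  )
  cand <- matrix(cand, nrow = length(q))
  refs <- matrix(refs, nrow = length(q))
  dmat <- matrix(NA_real_, ncol(cand), ncol(refs),
    dimnames = list(cand_ids, ref_ids)
  )
  for (i in seq_len(ncol(cand))) {
    for (j in seq_len(ncol(refs))) {
      dmat[i, j] <- cosine_distance(cand[, i], refs[, j])
    }
  }
  best <- apply(dmat, 1, which.min)
  dist_min <- dmat[cbind(seq_len(nrow(dmat)), best)]
  tie <- apply(dmat, 1, function(d) sum(abs(d - min(d)) < 1e-12) > 1L)
  label <- ifelse(dist_min <= threshold, ref_ids[best], "unassigned")
  structure(
    list(
      assignments = tibble::tibble(
        id = cand_ids, label = label,
        distance = dist_min, tie = tie
      ),
      distances = dmat, threshold = threshold
    ),
    class = "class_assignment"
  )
}

#' @export
print.class_assignment <- function(x, ...) {
  tab <- table(x$assignments$label)
  cat("<class_assignment> threshold ", x$threshold, ": ",
    paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Randomised combination chi-squared study
#'
#' For each per-class draw size k, repeatedly samples k conformers from each
#' class (uniformly, without replacement; classes smaller than k contribute
#' all members), fits the experimental curve with the drawn subset via
#' [fit_volume_fractions()], and records the reduced chi-squared. Summaries
#' (mean, s.d., minimum) per k quantify how fit quality improves with
#' ensemble size. Fully reproducible from `seed`.
#'
#' @param profiles Named list of candidate profiles.
#' @param labels Named character vector (or a `class_assignment`) giving each
#'   profile's class; "unassigned" profiles are ignored.
#' @param experimental Data frame with `q`, `intensity`, optionally `sigma`.
#' @param counts_per_class Integer vector of per-class draw sizes
#'   (default `c(1, 2, 3, 5, 10, 20, 50)`).
#' @param rounds Random draws per k (default 10000).
#' @param seed Integer RNG seed.
#' @return Object of class `combination_study`: tibble `samples`
#'   (`k`, `round`, `chi2`), tibble `summary` (`k`, `mean`, `sd`, `min`,
#'   `rounds`).
#' @export
combination_chi2_study <- function(profiles, labels, experimental,
                                   counts_per_class = c(1, 2, 3, 5, 10, 20, 50),
                                   rounds = 10000L, seed = 1L) {
  if (inherits(labels, "class_assignment")) {
    lab <- labels$assignments$label
    names(lab) <- labels$assignments$id
    labels <- lab
  }
  ids <- profile_ids(profiles)
  names(profiles) <- ids
  labels <- labels[ids]
  classes <- sort(unique(labels[!is.na(labels) & labels != "unassigned"]))
  if (length(classes) == 0L) stop("no assigned classes")
  members <- lapply(classes, function(cl) ids[!is.na(labels) & labels == cl])
  if (any(lengths(members) == 0L)) stop("empty class")
  if (rounds < 1L) stop("`rounds` must be >= 1")
  samples <- withr::with_seed(seed, {
    purrr::map_dfr(counts_per_class, function(k) {
      chi2 <- vapply(seq_len(rounds), function(r) {
        picked <- unlist(lapply(members, function(m) {
          if (length(m) <= k) m else sample(m, k)
        }))
        fit_volume_fractions(profiles[picked], experimental)$chi2
      }, numeric(1))
      tibble::tibble(k = k, round = seq_len(rounds), chi2 = chi2)
    })
  })
  summary <- dplyr::summarise(
    dplyr::group_by(samples, .data$k),
    mean = mean(.data$chi2), sd = stats::sd(.data$chi2),
    min = min(.data$chi2), rounds = dplyr::n(), .groups = "drop"
  )
  structure(
    list(samples = samples, summary = summary, seed = seed,
         classes = classes),
    class = "combination_study"
  )
}

#' @export
print.combination_study <- function(x, ...) {
  cat("<combination_study> ", length(x$classes), " classes\n", sep = "")
  print(x$summary)
  invisible(x)
}

# enforce subensemble size bounds by random add/remove
repair_chromosome <- function(chrom, min_size, max_size) {
  n_on <- sum(chrom)
  if (n_on > max_size) {
    drop <- sample(which(chrom), n_on - max_size)
    chrom[drop] <- FALSE
  } else if (n_on < min_size) {
    add <- sample(which(!chrom), min_size - n_on)
    chrom[add] <- TRUE
  }
  chrom
}

#' Genetic-algorithm subensemble selection
#'
#' A simplified genetic algorithm in the spirit of ensemble-optimisation
#' SAXS tools: chromosomes are conformer subsets, scored by the
#' [fit_volume_fractions()] reduced chi-squared against the experimental
#' curve, evolved by tournament selection (size 2), single-point crossover
#' and per-gene mutation at rate 1/pool size, with elitism. The initial
#' population contains every singleton, so the returned chi-squared is never
#' worse than the best single candidate. Seeded and reproducible.
#'
#' @param pool_profiles Named list of candidate profiles (>= 2).
#' @param experimental Data frame with `q`, `intensity`, optionally `sigma`.
#' @param generations Number of generations (default 100).
#' @param ensembles_per_generation Population size (default 50).
#' @param max_per_ensemble Maximum conformers per subensemble (default 50).
#' @param min_per_ensemble Minimum conformers per subensemble (default 1).
#' @param rg Optional named numeric vector of per-conformer radii of
#'   gyration; when given, the Rg values of the selected subensemble are
#'   returned as its Rg distribution.
#' @param seed Integer RNG seed.
#' @return Object of class `ga_selection`: `selected_ids`, `chi2`, `fit`
#'   (the final `volume_fraction_fit`), `rg_selected`, `history` (best
#'   chi-squared per generation).
#' @export
ga_subensemble_select <- function(pool_profiles, experimental,
                                  generations = 100L,
                                  ensembles_per_generation = 50L,
                                  max_per_ensemble = 50L,
                                  min_per_ensemble = 1L,
                                  rg = NULL, seed = 1L) {
  ids <- profile_ids(pool_profiles)
  names(pool_profiles) <- ids
  n_pool <- length(pool_profiles)
  if (n_pool < 2L) stop("pool must contain at least 2 profiles")
  if (generations < 1L || ensembles_per_generation < 2L) {
    stop("GA parameters must be positive (population >= 2)")
  }
  max_per_ensemble <- min(max_per_ensemble, n_pool)
  score <- function(chrom) {
    fit_volume_fractions(pool_profiles[chrom], experimental)$chi2
  }
  res <- withr::with_seed(seed, {
    pop <- lapply(seq_len(ensembles_per_generation), function(i) {
      chrom <- rep(FALSE, n_pool)
      if (i <= n_pool) {
        chrom[i] <- TRUE # singleton seeding
      } else {
        chrom[sample(n_pool, sample(min_per_ensemble:max_per_ensemble, 1))] <-
          TRUE
      }
      chrom
    })
    fitness <- vapply(pop, score, numeric(1))
    history <- numeric(generations)
    for (g in seq_len(generations)) {
      elite <- which.min(fitness)
      new_pop <- list(pop[[elite]])
      while (length(new_pop) < ensembles_per_generation) {
        pick <- function() {
          cand <- sample(ensembles_per_generation, 2L)
          pop[[cand[which.min(fitness[cand])]]]
        }
        p1 <- pick()
        p2 <- pick()
        cut <- sample(n_pool - 1L, 1L)
        child <- c(p1[seq_len(cut)], p2[seq(cut + 1L, n_pool)])
        flip <- stats::runif(n_pool) < 1 / n_pool
        child[flip] <- !child[flip]
        child <- repair_chromosome(child, min_per_ensemble, max_per_ensemble)
        new_pop[[length(new_pop) + 1L]] <- child
      }
      pop <- new_pop
      fitness <- vapply(pop, score, numeric(1))
      history[g] <- min(fitness)
    }
    best <- pop[[which.min(fitness)]]
    list(best = best, chi2 = min(fitness), history = history)
  })
  selected <- ids[res$best]
  structure(
    list(
      selected_ids = selected, chi2 = res$chi2,
      fit = fit_volume_fractions(pool_profiles[res$best], experimental),
      rg_selected = if (is.null(rg)) NULL else unname(rg[selected]),
      history = res$history, seed = seed
    ),
    class = "ga_selection"
  )
}

#' @export
print.ga_selection <- function(x, ...) {
  cat("<ga_selection> ", length(x$selected_ids), " conformers, chi2 = ",
    signif(x$chi2, 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' Class populations along a titration series
#'
#' Fits each experimental curve of a series (for example, SAXS recorded at
#' increasing Mg2+ concentrations) against the class reference profiles with
#' [fit_volume_fractions()], returning per-condition class populations that
#' sum to 1.
#'
#' @param experimental_series Named list of experimental profiles, one per
#'   condition.
#' @param reference_profiles Named list of class reference profiles.
#' @return Tibble with columns `condition`, `chi2` and one population column
#'   per reference class.
#' @export
titration_population_series <- function(experimental_series,
                                        reference_profiles) {
  cond <- profile_ids(experimental_series)
  ref_ids <- profile_ids(reference_profiles)
  rows <- purrr::map2_dfr(experimental_series, cond, function(exp_p, nm) {
    fit <- fit_volume_fractions(reference_profiles, exp_p)
    pops <- stats::setNames(as.list(fit$nu), ref_ids)
    tibble::tibble(condition = nm, chi2 = fit$chi2, !!!pops)
  })
  rows
}
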