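test_that("volume-fraction fit recovers pure and mixed compositions", {
  gen <- class_representatives()
  profs <- ensemble_profiles(gen$ensemble)

  # experimental curve equal to one candidate: that candidate gets it all
  pure <- fit_volume_fractions(profs, profs[[1]])
  expect_equal(pure$nu, c(1, 0, 0), tolerance = 1e-8)
  expect_lt(pure$chi2, 1e-12)
  expect_true(pure$identifiable)
  expect_equal(sum(pure$nu), 1, tolerance = 1e-9)

  # 18/76/6 mixture with 1% noise: each fraction within 0.03
  truth <- c(0.18, 0.76, 0.06)
  mix <- synthesize_mixture_profile(profs, truth, 0.01, seed = 11)
  fit <- fit_volume_fractions(profs, mix)
  expect_lt(max(abs(fit$nu - truth)), 0.03)
  expect_equal(sum(fit$nu), 1, tolerance = 1e-9)
})

test_that("duplicate candidates are flagged non-identifiable but sum correctly", {
  gen <- class_representatives()
  profs <- ensemble_profiles(gen$ensemble)
  truth <- c(0.18, 0.76, 0.06)
  mix <- synthesize_mixture_profile(profs, truth, 0.01, seed = 11)

  dup <- c(profs, profs[1])
  names(dup)[4] <- "dup_of_1"
  fit <- fit_volume_fractions(dup, mix)
  expect_false(fit$identifiable)
  expect_lt(abs(fit$nu[1] + fit$nu[4] - truth[1]), 0.03)

  # pseudoinverse oracle for the summed composition: project the mixture on
  # the 3 distinct profiles (the duplicated pair spans the same column space)
  a <- vapply(profs, function(p) p$intensity / mix$sigma, numeric(nrow(mix)))
  b <- mix$intensity / mix$sigma
  ls <- as.numeric(MASS::ginv(a) %*% b)
  expect_equal(fit$nu[2:3], (ls / sum(ls))[2:3], tolerance = 0.01)
})

test_that("fraction recovery is accurate over repeated noisy simulations", {
  gen <- class_representatives()
  profs <- ensemble_profiles(gen$ensemble)
  truth <- c(0.18, 0.76, 0.06)
  errs <- vapply(1:100, function(s) {
    mix <- synthesize_mixture_profile(profs, truth, 0.01, seed = s)
    abs(fit_volume_fractions(profs, mix)$nu - truth)
  }, numeric(3))
  expect_lt(mean(errs), 0.02)
  expect_lt(max(errs), 0.05)
})

test_that("adding the true components never worsens the fit", {
  pool <- labelled_pool()
  truth_ids <- c("S001", "S013", "S025")
  mix <- synthesize_mixture_profile(
    pool$profiles[truth_ids], c(0.3, 0.5, 0.2), 0.01,
    seed = 5
  )
  others <- setdiff(names(pool$profiles), truth_ids)[1:6]
  chi2_without <- fit_volume_fractions(pool$profiles[others], mix)$chi2
  chi2_with <- fit_volume_fractions(
    pool$profiles[c(others, truth_ids)], mix
  )$chi2
  expect_lte(chi2_with, chi2_without + 1e-9)
})

test_that("cosine classification is scale-invariant and thresholds correctly", {
  gen <- class_representatives()
  profs <- ensemble_profiles(gen$ensemble)

  cl <- classify_by_cosine(profs, profs, threshold = 0.1)
  expect_equal(cl$assignments$label, names(profs))
  expect_equal(cl$assignments$distance, rep(0, 3), tolerance = 1e-12)

  # positive rescaling leaves assignment and distance unchanged
  scaled <- lapply(profs, function(p) {
    scattering_profile(p$q, 3.7 * p$intensity)
  })
  names(scaled) <- names(profs)
  cl2 <- classify_by_cosine(scaled, profs, threshold = 0.1)
  expect_equal(cl2$assignments$label, names(profs))
  expect_lt(max(cl2$assignments$distance), 1e-12)

  # a vector orthogonalised against every reference has cosine distance 1
  # to all of them, far beyond the threshold
  q <- profs[[1]]$q
  ref_mat <- vapply(profs, function(p) p$intensity, numeric(length(q)))
  v <- withr::with_seed(3, stats::rnorm(length(q))^2 + 1)
  v_orth <- v - qr.fitted(qr(ref_mat), v)
  far <- list(far = scattering_profile(q, v_orth))
  out <- classify_by_cosine(far, profs, threshold = 0.1)
  expect_identical(out$assignments$label, "unassigned")
  expect_equal(unname(out$distances[1, ]), rep(1, 3), tolerance = 1e-8)

  # zero-norm candidate errors out
  zero <- list(z = scattering_profile(q, rep(0, length(q))))
  expect_error(classify_by_cosine(zero, profs), "zero-norm")
})

test_that("combination study is seeded, reproducible and reduces to single fits", {
  pool <- labelled_pool(per_class = 4L)
  mix <- synthesize_mixture_profile(
    pool$profiles[c("S001", "S005", "S009")], c(0.2, 0.7, 0.1), 0.01,
    seed = 8
  )

  a <- combination_chi2_study(pool$profiles, pool$labels, mix,
    counts_per_class = c(1, 2), rounds = 5, seed = 42
  )
  b <- combination_chi2_study(pool$profiles, pool$labels, mix,
    counts_per_class = c(1, 2), rounds = 5, seed = 42
  )
  expect_identical(a$samples, b$samples)

  # one profile per class: every round equals the direct 3-candidate fit
  single <- pool$profiles[c("S001", "S005", "S009")]
  single_labels <- stats::setNames(c("C1", "C2", "C3"), names(single))
  st <- combination_chi2_study(single, single_labels, mix,
    counts_per_class = 1, rounds = 3, seed = 1
  )
  direct <- fit_volume_fractions(single, mix)$chi2
  expect_equal(st$summary$min, direct, tolerance = 1e-12)
  expect_equal(st$summary$mean, direct, tolerance = 1e-12)

  # k = full class size: min chi2 equals the all-members fit
  full <- combination_chi2_study(pool$profiles, pool$labels, mix,
    counts_per_class = 4, rounds = 3, seed = 2
  )
  all_fit <- fit_volume_fractions(pool$profiles, mix)$chi2
  expect_equal(full$summary$min, all_fit, tolerance = 1e-12)
})

test_that("mean combination chi2 is non-increasing in the draw size", {
  pool <- labelled_pool(per_class = 12L)
  mix <- synthesize_mixture_profile(
    pool$profiles[c("S002", "S018", "S030")], c(0.25, 0.6, 0.15), 0.01,
    seed = 4
  )
  st <- combination_chi2_study(pool$profiles, pool$labels, mix,
    counts_per_class = c(1, 3, 10), rounds = 100, seed = 7
  )
  means <- st$summary$mean[order(st$summary$k)]
  # non-increasing within Monte-Carlo error
  expect_true(all(diff(means) <= 0.05 * means[-length(means)]))
  expect_true(all(st$summary$min <= st$summary$mean))
  expect_true(all(st$summary$sd >= 0))
})

test_that("the GA finds planted subensembles and is reproducible", {
  pool <- labelled_pool(per_class = 7L)
  profs <- pool$profiles

  # one pool member equals the experimental curve: GA should find it
  hit <- ga_subensemble_select(profs, profs[["S010"]],
    generations = 15, ensembles_per_generation = 20,
    max_per_ensemble = 5, seed = 1
  )
  expect_lt(hit$chi2, 1e-10)
  expect_true("S010" %in% hit$selected_ids)

  # same seed, same selection; different seed may differ
  hit2 <- ga_subensemble_select(profs, profs[["S010"]],
    generations = 15, ensembles_per_generation = 20,
    max_per_ensemble = 5, seed = 1
  )
  expect_identical(hit$selected_ids, hit2$selected_ids)
  expect_identical(hit$history, hit2$history)

  # GA never does worse than the best singleton
  mix <- synthesize_mixture_profile(
    profs[c("S003", "S017")], c(0.55, 0.45), 0.01,
    seed = 3
  )
  singles <- vapply(
    profs, function(p) fit_volume_fractions(list(p), mix)$chi2,
    numeric(1)
  )
  ga <- ga_subensemble_select(profs, mix,
    generations = 20, ensembles_per_generation = 20,
    max_per_ensemble = 6, rg = stats::setNames(
      vapply(pool$gen$ensemble$members, rg_from_coordinates, numeric(1)),
      names(profs)
    ), seed = 9
  )
  expect_lte(ga$chi2, min(singles))
  expect_length(ga$rg_selected, length(ga$selected_ids))
})

test_that("the GA recovers hidden two-component mixtures across seeds", {
  pool <- labelled_pool(per_class = 7L) # 21-profile pool
  profs <- pool$profiles
  truth_ids <- c("S002", "S016") # one compact, one extended
  found <- vapply(1:20, function(s) {
    mix <- synthesize_mixture_profile(profs[truth_ids], c(0.6, 0.4), 0.01,
      seed = 100 + s
    )
    ga <- ga_subensemble_select(profs, mix,
      generations = 25, ensembles_per_generation = 24,
      max_per_ensemble = 4, seed = s
    )
    all(truth_ids %in% ga$selected_ids)
  }, logical(1))
  expect_gte(mean(found), 0.9)
})

test_that("titration series tracks monotone population shifts", {
  gen <- class_representatives()
  refs <- ensemble_profiles(gen$ensemble)

  # single condition equal to reference 1
  one <- titration_population_series(list(c0 = refs[[1]]), refs)
  expect_equal(unlist(one[1, names(refs)]), c(S001 = 1, S002 = 0, S003 = 0),
    tolerance = 1e-8
  )

  # series interpolating from extended-rich to compact-rich mixtures
  fracs <- list(
    c(0.10, 0.20, 0.70), c(0.30, 0.30, 0.40),
    c(0.55, 0.30, 0.15), c(0.80, 0.15, 0.05)
  )
  series <- lapply(seq_along(fracs), function(i) {
    synthesize_mixture_profile(refs, fracs[[i]], 0.005, seed = i)
  })
  names(series) <- sprintf("mg_%d", seq_along(series))
  tab <- titration_population_series(series, refs)
  expect_equal(rowSums(tab[, names(refs)]), rep(1, 4),
    tolerance = 1e-9, ignore_attr = TRUE
  )
  expect_true(all(diff(tab$S001) > 0)) # compact class grows monotonically
})
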