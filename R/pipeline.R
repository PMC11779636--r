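#' Analysis configuration
#'
#' Assembles (or reads from a JSON file) the configuration driving
#' [run_full_analysis()]. Only the stages whose inputs are present are run,
#' so a partial configuration runs a partial pipeline.
#'
#' @param ensemble_dir Directory of conformer PDB files.
#' @param experimental_saxs Path to an experimental SAXS curve (3-column
#'   text), or a named character vector of paths for a titration series.
#' @param alignment Path to a multiple alignment (Stockholm or FASTA).
#' @param alignment_reference Sequence id mapping alignment columns to the
#'   structure's residue numbers.
#' @param reference_structure Path to a PDB file carrying per-residue B
#'   factors for the r.m.s.f. comparison.
#' @param atom_name Bead atom name (default `"P"`).
#' @param q_min,q_max,q_points Theoretical q grid settings.
#' @param cosine_threshold Classification threshold (default 0.1).
#' @param core_volume_cutoff Ellipsoid-volume cutoff in Angstrom^3, or
#'   `"auto"` (default 150).
#' @param reference_ids Member ids used as class references for
#'   classification; default the members of the best volume-fraction fit
#'   with fractions above 5%.
#' @param combination_counts Per-class draw sizes for the combination study.
#' @param combination_rounds Random draws per count (default 10000; lower it
#'   for quick looks).
#' @param flag_quantile Quantile for conservation flagging (default 0.25).
#' @param seed Integer seed for every stochastic stage.
#' @param out_dir Output directory for [write_report()].
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(ensemble_dir = NULL,
                            experimental_saxs = NULL,
                            alignment = NULL,
                            alignment_reference = NULL,
                            reference_structure = NULL,
                            atom_name = "P",
                            q_min = 0.006, q_max = 0.45, q_points = 101L,
                            cosine_threshold = 0.1,
                            core_volume_cutoff = 150,
                            reference_ids = NULL,
                            combination_counts = c(1, 2, 3, 5, 10, 20, 50),
                            combination_rounds = 10000L,
                            flag_quantile = 0.25,
                            seed = 1L,
                            out_dir = NULL) {
  cfg <- list(
    ensemble_dir = ensemble_dir, experimental_saxs = experimental_saxs,
    alignment = alignment, alignment_reference = alignment_reference,
    reference_structure = reference_structure, atom_name = atom_name,
    q_min = q_min, q_max = q_max, q_points = as.integer(q_points),
    cosine_threshold = cosine_threshold,
    core_volume_cutoff = core_volume_cutoff,
    reference_ids = reference_ids,
    combination_counts = combination_counts,
    combination_rounds = as.integer(combination_rounds),
    flag_quantile = flag_quantile,
    seed = as.integer(seed), out_dir = out_dir
  )
  class(cfg) <- "analysis_config"
  cfg
}

#' @rdname analysis_config
#' @param path JSON file holding configuration fields.
#' @export
read_analysis_config <- function(path) {
  fields <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(analysis_config, fields)
}

run_stage <- function(report, name, expr) {
  res <- tryCatch(
    list(status = "ok", value = expr),
    error = function(e) {
      list(status = "failed", value = NULL, message = conditionMessage(e))
    }
  )
  report$stages[[name]] <- res[names(res) != "value"]
  report$results[[name]] <- res$value
  report
}

skip_stage <- function(report, name, why) {
  report$stages[[name]] <- list(status = "skipped", message = why)
  report
}

#' Run the full conformer-ensemble analysis
#'
#' Orchestrates the pipeline: load ensemble, back-calculate member profiles,
#' volume-fraction fit and classification against an experimental curve,
#' randomized combination study, invariant core, PCA (core-superposed) with
#' clustering, movement similarity matrix, r.m.s.f./B-factor comparison, and
#' the sequence-vs-conformational conservation analysis. Stages whose inputs
#' are missing are marked "skipped"; stage failures are recorded with the
#' stage name and downstream stages that do not depend on them still run.
#' Every report carries provenance (configuration hash, seed, package
#' version), and results are byte-identical for identical configurations and
#' seeds.
#'
#' @param config An [analysis_config] (or path to its JSON form).
#' @return An `analysis_report`: list with `stages` (status per stage),
#'   `results` (per-stage objects) and `provenance`.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- read_analysis_config(config)
  stopifnot(inherits(config, "analysis_config"))
  report <- structure(
    list(
      stages = list(), results = list(),
      provenance = list(
        config = unclass(config),
        config_hash = rlang::hash(unclass(config)),
        seed = config[["seed"]],
        package_version = as.character(utils::packageVersion("saxsemble"))
      )
    ),
    class = "analysis_report"
  )

  if (is.null(config[["ensemble_dir"]])) {
    return(skip_stage(report, "ensemble", "no ensemble directory configured"))
  }
  report <- run_stage(
    report, "ensemble",
    load_ensemble(config[["ensemble_dir"]], atom_name = config[["atom_name"]])
  )
  ens <- report$results$ensemble
  if (is.null(ens)) {
    return(report)
  }

  q_grid <- seq(config[["q_min"]], config[["q_max"]], length.out = config[["q_points"]])
  report <- run_stage(report, "profiles", ensemble_profiles(ens, q_grid))
  profiles <- report$results$profiles

  rg_tbl <- tibble::tibble(
    id = ensemble_ids(ens),
    rg = vapply(ens$members, rg_from_coordinates, numeric(1))
  )
  report$results$rg <- rg_tbl

  # SAXS-vs-experiment stages
  exp_paths <- config[["experimental_saxs"]]
  if (is.null(exp_paths) || is.null(profiles)) {
    report <- skip_stage(report, "fit", "no experimental SAXS curve")
    report <- skip_stage(report, "classify", "no experimental SAXS curve")
    report <- skip_stage(report, "combination_study", "no experimental SAXS curve")
  } else {
    first_exp <- read_saxs(exp_paths[[1]])
    report <- run_stage(
      report, "fit",
      fit_volume_fractions(profiles, first_exp)
    )
    fit <- report$results$fit
    ref_ids <- config[["reference_ids"]]
    if (is.null(ref_ids) && !is.null(fit)) {
      ref_ids <- fit$member_ids[fit$nu > 0.05]
    }
    if (is.null(ref_ids) || length(ref_ids) == 0L) {
      report <- skip_stage(report, "classify", "no reference conformers")
      report <- skip_stage(report, "combination_study", "no class labels")
    } else {
      report <- run_stage(
        report, "classify",
        classify_by_cosine(profiles, profiles[ref_ids],
          threshold = config[["cosine_threshold"]]
        )
      )
      cl <- report$results$classify
      if (is.null(cl)) {
        report <- skip_stage(report, "combination_study", "classification failed")
      } else {
        report <- run_stage(
          report, "combination_study",
          combination_chi2_study(profiles, cl, first_exp,
            counts_per_class = config[["combination_counts"]],
            rounds = config[["combination_rounds"]],
            seed = config[["seed"]]
          )
        )
      }
      if (length(exp_paths) > 1L && !is.null(cl)) {
        series <- lapply(exp_paths, read_saxs)
        names(series) <- names(exp_paths) %||% basename(unlist(exp_paths))
        report <- run_stage(
          report, "titration",
          titration_population_series(series, profiles[ref_ids])
        )
      }
    }
  }

  # ensemble-geometry stages
  report <- run_stage(
    report, "core",
    find_invariant_core(ens, volume_cutoff = config[["core_volume_cutoff"]])
  )
  core_res <- report$results$core$core_residues
  report <- run_stage(
    report, "rmsf",
    per_residue_rmsf(ens, superpose_subset = core_res)
  )
  report <- run_stage(
    report, "pca",
    ensemble_pca(ens, superpose_subset = core_res)
  )
  pca <- report$results$pca
  if (!is.null(pca)) {
    k <- n_components_for_variance(pca, 0.7)
    report <- run_stage(
      report, "pc_clusters",
      cluster_pc_space(pca, n_components = k, n_clusters = min(3L, nrow(pca$projections)))
    )
  }
  report <- run_stage(
    report, "amsm",
    movement_similarity_matrix(ens, superpose_subset = core_res)
  )

  # B-factor comparison
  if (is.null(config[["reference_structure"]]) || is.null(report$results$rmsf)) {
    report <- skip_stage(report, "bfactor", "no reference structure with B factors")
  } else {
    report <- run_stage(report, "bfactor", {
      ref <- read_conformer(config[["reference_structure"]],
        atom_name = config[["atom_name"]]
      )
      if (is.null(ref$bfactors)) stop("reference structure carries no B factors")
      rmsf <- report$results$rmsf
      shared <- intersect(
        as.integer(names(rmsf)),
        ref$residue_numbers
      )
      rmsf_bfactor_correlation(
        rmsf[as.character(shared)],
        ref$bfactors[match(shared, ref$residue_numbers)]
      )
    })
  }

  # conservation
  if (is.null(config[["alignment"]]) || is.null(report$results$rmsf)) {
    report <- skip_stage(report, "conservation", "no alignment configured")
  } else {
    report <- run_stage(report, "conservation", {
      aln <- read_alignment(config[["alignment"]])
      mapping <- if (is.null(config[["alignment_reference"]])) {
        NULL
      } else {
        map_columns_to_reference(aln, config[["alignment_reference"]])
      }
      scs <- sequence_conservation_score(aln, mapping)
      rmsf <- report$results$rmsf
      tab <- conservation_table(scs, rmsf,
        residue_numbers = as.integer(names(rmsf)),
        core_residues = core_res
      )
      correlate_and_flag(tab, flag_quantile = config[["flag_quantile"]])
    })
  }
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report> config ", substr(x$provenance$config_hash, 1, 8),
    ", seed ", x$provenance$seed, "\n",
    sep = ""
  )
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(
      "  ", formatC(nm, width = 18, flag = "-"), st$status,
      if (!is.null(st$message)) paste0(" (", st$message, ")") else "", "\n"
    )
  }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits a versioned JSON summary (`summary.json`, with provenance, stage
#' statuses, volume fractions, chi-squared values and correlations), TSV
#' tables (per-residue r.m.s.f./amplitudes, conservation table, AMSM and
#' pairwise matrices, PCA variance table) and multi-model PDB trajectories of
#' the leading principal components, all re-readable by the package's own
#' readers.
#'
#' @param report An `analysis_report` from [run_full_analysis()].
#' @param out_dir Output directory (created if needed); defaults to the
#'   configuration's `out_dir`.
#' @param n_trajectories Number of PC trajectories to write (default 2).
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(report, out_dir = NULL, n_trajectories = 2L) {
  stopifnot(inherits(report, "analysis_report"))
  if (length(report$results) == 0L) stop("empty report: no stage produced output")
  out_dir <- out_dir %||% report$provenance$config[["out_dir"]]
  if (is.null(out_dir)) stop("no output directory given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit <- function(path) {
    written <<- c(written, path)
    path
  }

  summary <- list(
    schema_version = "1.0",
    provenance = report$provenance[c("config_hash", "seed", "package_version")],
    stages = report$stages
  )
  res <- report$results
  if (!is.null(res$fit)) {
    summary$fit <- list(
      member_ids = res$fit$member_ids, nu = res$fit$nu,
      scale = res$fit$scale, chi2 = res$fit$chi2,
      identifiable = res$fit$identifiable
    )
  }
  if (!is.null(res$classify)) {
    summary$class_counts <- as.list(table(res$classify$assignments$label))
  }
  if (!is.null(res$core)) {
    summary$core <- list(
      n_core = length(res$core$core_residues),
      core_residues = res$core$core_residues,
      volume_cutoff = res$core$volume_cutoff
    )
  }
  if (!is.null(res$pca)) {
    summary$pca <- list(
      eigenvalues = res$pca$eigenvalues,
      cumulative_variance = res$pca$cumulative_variance
    )
  }
  if (!is.null(res$bfactor)) summary$rmsf_bfactor_r <- res$bfactor$r
  if (!is.null(res$conservation)) {
    summary$conservation <- list(
      r_all = res$conservation$r_all,
      r_excluding_flagged = res$conservation$r_excluding_flagged
    )
  }
  jsonlite::write_json(summary, emit(file.path(out_dir, "summary.json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  write_tsv_file <- function(df, name) {
    readr::write_tsv(df, emit(file.path(out_dir, name)))
  }
  if (!is.null(res$rg)) write_tsv_file(res$rg, "rg.tsv")
  if (!is.null(res$rmsf)) {
    write_tsv_file(
      tibble::tibble(
        residue_number = as.integer(names(res$rmsf)),
        rmsf = as.numeric(res$rmsf)
      ),
      "rmsf.tsv"
    )
  }
  if (!is.null(res$fit)) write_tsv_file(generics::tidy(res$fit), "fit.tsv")
  if (!is.null(res$classify)) {
    write_tsv_file(res$classify$assignments, "classes.tsv")
  }
  if (!is.null(res$combination_study)) {
    write_tsv_file(res$combination_study$summary, "combination_study.tsv")
  }
  if (!is.null(res$titration)) write_tsv_file(res$titration, "titration.tsv")
  if (!is.null(res$core)) {
    write_tsv_file(res$core$iterations, "core_iterations.tsv")
  }
  if (!is.null(res$pca)) {
    write_tsv_file(generics::tidy(res$pca), "pca_variance.tsv")
    amp <- purrr::map_dfr(
      seq_len(min(5L, length(res$pca$eigenvalues))),
      function(k) {
        tibble::tibble(
          component = k,
          residue_number = res$pca$residue_numbers,
          amplitude = as.numeric(per_residue_pc_amplitude(res$pca, k))
        )
      }
    )
    write_tsv_file(amp, "pc_amplitudes.tsv")
  }
  if (!is.null(res$amsm)) {
    amsm_df <- tibble::as_tibble(res$amsm$values, rownames = "residue_number")
    write_tsv_file(amsm_df, "amsm.tsv")
  }
  if (!is.null(res$conservation)) {
    write_tsv_file(res$conservation$table, "conservation.tsv")
  }
  if (!is.null(res$pca) && n_trajectories > 0L) {
    for (k in seq_len(min(n_trajectories, length(res$pca$eigenvalues)))) {
      tr <- interpolate_pc_trajectory(res$pca, k, n_frames = 20L)
      write_conformer(tr, emit(file.path(out_dir, sprintf("pc%d_trajectory.pdb", k))))
    }
  }
  invisible(written)
}
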