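#' End-to-end pipeline configuration
#'
#' Bundles every stage setting of the generate - profile - compare - model
#' pipeline. All randomness flows from the single `seed`: the generator,
#' each contrast's bootstrap, and the model sweeps receive seeds derived from
#' it, so re-running the same config reproduces every number exactly.
#'
#' @param cohort A [cohort_config()] (the synthetic cohort to generate), or
#'   `NULL` when `labels_csv`/`profiles_csv` point at existing inputs.
#' @param labels_csv,profiles_csv Optional paths to precomputed inputs; used
#'   only when `cohort` is `NULL`.
#' @param projection `"truth"` or `"skeleton"` (see [cohort_profiles()]).
#' @param fwhm Gaussian FWHM for the profiles (mm).
#' @param spacing Profile position spacing (mm).
#' @param contrasts Contrasts to analyse.
#' @param sides Sides to analyse.
#' @param model_positions Axis positions at which prognostic models are
#'   fitted (default: every 2 mm interior position).
#' @param q_level FDR level for the position-wise tests.
#' @param n_boot Bootstrap resamples for all reported CIs.
#' @param inner,nlambda,lambda_min_ratio Model settings, see
#'   [nested_loocv_elastic_net()].
#' @param seed Master seed.
#' @param out_dir Output directory for the report bundle.
#' @return A `run_config` list.
#' @export
run_config <- function(cohort = cohort_config(), labels_csv = NULL,
                       profiles_csv = NULL,
                       projection = c("truth", "skeleton"),
                       fwhm = 1.5, spacing = 0.5,
                       contrasts = c("sham_tbi", "tbi_epilepsy", "ci"),
                       sides = c("ipsi", "contra"),
                       model_positions = NULL, q_level = 0.05,
                       n_boot = 10000, inner = "loo", nlambda = 100,
                       lambda_min_ratio = 1e-4, seed = 1,
                       out_dir = tempfile("hippoaxis_run_")) {
  projection <- match.arg(projection)
  if (is.null(cohort)) {
    if (is.null(labels_csv) || is.null(profiles_csv)) {
      stop("either a cohort config or labels_csv + profiles_csv is required")
    }
    if (!file.exists(labels_csv)) stop("label file not found: ", labels_csv)
    if (!file.exists(profiles_csv)) {
      stop("profile file not found: ", profiles_csv)
    }
  }
  structure(list(cohort = cohort, labels_csv = labels_csv,
                 profiles_csv = profiles_csv, projection = projection,
                 fwhm = fwhm, spacing = spacing, contrasts = contrasts,
                 sides = sides, model_positions = model_positions,
                 q_level = q_level, n_boot = n_boot, inner = inner,
                 nlambda = nlambda, lambda_min_ratio = lambda_min_ratio,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Scalar stage settings map directly onto [run_config()] arguments; a
#' `cohort:` block maps onto [cohort_config()] (grid given as `shape` and
#' `vox_mm`). Effects, baselines and noise defaults are used as-is unless
#' overridden.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- NULL
  if (!is.null(y$cohort)) {
    cc <- y$cohort
    grid <- if (!is.null(cc$shape)) {
      voxel_grid(cc$shape, if (!is.null(cc$vox_mm)) cc$vox_mm
                 else c(0.2, 0.2, 0.5))
    } else voxel_grid(c(90, 90, 24))
    args <- cc[names(cc) %in% c("n_sham", "n_tbi", "epilepsy_prev", "ci_prev",
                                "axis_len", "geometry_jitter", "seed")]
    cohort <- do.call(cohort_config, c(args, list(grid = grid)))
  }
  args <- y[names(y) %in% c("labels_csv", "profiles_csv", "projection",
                            "fwhm", "spacing", "contrasts", "sides",
                            "model_positions", "q_level", "n_boot", "inner",
                            "nlambda", "lambda_min_ratio", "seed", "out_dir")]
  do.call(run_config, c(list(cohort = cohort), args))
}

#' Run the full analysis pipeline
#'
#' generate (or load) - profile - compare - model, writing a report bundle:
#' `labels.csv`, `profiles.csv`, `volumes.csv`, per-contrast
#' `stats_<contrast>.csv` (position-wise tests) and
#' `auc_curve_<contrast>.csv` (model sweep), `coef_importance_<contrast>.csv`,
#' and `provenance.json` (config echo, seeds, package version). Any stage
#' failure aborts with that stage's message after writing a partial-results
#' manifest.
#'
#' @param config A [run_config()].
#' @param verbose Print stage progress.
#' @return Invisibly, a list with `labels`, `profiles`, `volumes`, `stats`,
#'   `models` and `out_dir`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(...)
  manifest <- character(0)
  note <- function(f) {
    manifest <<- c(manifest, f)
    writeLines(manifest, file.path(config$out_dir, "MANIFEST"))
  }

  if (!is.null(config$cohort)) {
    say("stage 1/4: generating synthetic cohort")
    cohort <- generate_cohort(config$cohort)
    labels <- cohort_labels(cohort)
    volumes <- cohort_volumes(cohort)
    say("stage 2/4: profiling along the septotemporal axis (",
        config$projection, " projection)")
    profiles <- cohort_profiles(cohort, projection = config$projection,
                                spacing = config$spacing, fwhm = config$fwhm)
  } else {
    say("stage 1-2/4: loading labels and profiles")
    labels <- read_labels_csv(config$labels_csv)
    profiles <- read_profiles_csv(config$profiles_csv)
    volumes <- NULL
  }
  write_labels_csv(labels, file.path(config$out_dir, "labels.csv"))
  note("labels.csv")
  write_profiles_csv(profiles, file.path(config$out_dir, "profiles.csv"))
  note("profiles.csv")
  if (!is.null(volumes)) {
    utils::write.csv(volumes, file.path(config$out_dir, "volumes.csv"),
                     row.names = FALSE)
    note("volumes.csv")
  }

  positions <- sort(unique(profiles$position_mm))
  model_pos <- config$model_positions
  if (is.null(model_pos)) {
    interior <- positions[positions >= 1 & positions <= max(positions) - 1]
    model_pos <- interior[seq(1, length(interior), length.out =
                                min(6, length(interior)))]
  }

  stats_out <- list(); models_out <- list()
  ci_seed_base <- config$seed + 1000L
  for (k in seq_along(config$contrasts)) {
    ct <- config$contrasts[k]
    say("stage 3/4: position-wise comparison (", ct, ")")
    sg <- profile_group_comparison(profiles, labels, ct,
                                   q_level = config$q_level)
    utils::write.csv(sg, file.path(config$out_dir,
                                   paste0("stats_", ct, ".csv")),
                     row.names = FALSE)
    note(paste0("stats_", ct, ".csv"))
    stats_out[[ct]] <- sg
    say("stage 4/4: prognostic models (", ct, ")")
    sw <- position_sweep(profiles, labels, ct, model_pos,
                         sides = config$sides, n_boot = config$n_boot,
                         seed = ci_seed_base + 100L * k,
                         inner = config$inner, nlambda = config$nlambda,
                         lambda_min_ratio = config$lambda_min_ratio)
    utils::write.csv(sw$summary,
                     file.path(config$out_dir,
                               paste0("auc_curve_", ct, ".csv")),
                     row.names = FALSE)
    note(paste0("auc_curve_", ct, ".csv"))
    imp <- coefficient_importance(sw$results, k = 5)
    utils::write.csv(imp, file.path(config$out_dir,
                                    paste0("coef_importance_", ct, ".csv")),
                     row.names = FALSE)
    note(paste0("coef_importance_", ct, ".csv"))
    if (!is.null(volumes)) {
      vres <- volume_model(volumes, labels, contrast = ct,
                           inner = config$inner, nlambda = config$nlambda,
                           lambda_min_ratio = config$lambda_min_ratio)
      vci <- model_auc_with_ci(vres, n_boot = config$n_boot,
                               seed = ci_seed_base + 100L * k + 99L)
      sw$volume <- vci
    }
    models_out[[ct]] <- sw
  }

  prov <- list(
    package = "hippoaxis",
    version = as.character(utils::packageVersion("hippoaxis")),
    seed = config$seed,
    projection = config$projection,
    fwhm = config$fwhm, spacing = config$spacing,
    contrasts = config$contrasts, model_positions = model_pos,
    n_boot = config$n_boot, inner = config$inner,
    cohort = if (!is.null(config$cohort)) {
      c(config$cohort[c("n_sham", "n_tbi", "epilepsy_prev", "ci_prev",
                        "axis_len", "geometry_jitter", "seed")],
        list(shape = config$cohort$grid$shape,
             vox_mm = config$cohort$grid$vox_mm))
    }
  )
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  note("provenance.json")
  invisible(list(labels = labels, profiles = profiles, volumes = volumes,
                 stats = stats_out, models = models_out,
                 out_dir = config$out_dir))
}
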