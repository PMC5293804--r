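#' Pipeline run configuration
#'
#' Bundles generator, segmentation and inference settings for a full
#' simulate -> extract -> QC -> inference run. The segmentation variant
#' defaults to the one matching the generator's sampling rate
#' (displacement rule at 60 Hz, velocity rule at 200 Hz); an explicit
#' mismatching choice is accepted with a warning.
#'
#' @param generator A [generator_config()].
#' @param segmentation A [segmentation_config()] or `NULL` for the
#'   rate-matched default.
#' @param parameters Kinematic parameters to analyze.
#' @param alpha,correction,alpha_fixed,sided Passed to
#'   [planned_ttests()].
#' @param bayes Compute JZS Bayes factors.
#' @param bf_samples Monte Carlo draws for [jzs_bf_anova()].
#' @param min_valid_fraction Participant-exclusion boundary.
#' @param seed Master seed of the run.
#' @return An object of class `run_config`.
#' @export
run_config <- function(generator = generator_preset("exp1_italian"),
                       segmentation = NULL,
                       parameters = c("reach_time_ms", "t_vpeak_ms",
                                      "pct_t_vpeak", "vpeak_mm_s"),
                       alpha = 0.05, correction = "bonferroni",
                       alpha_fixed = 0.01, sided = "one",
                       bayes = TRUE, bf_samples = 10000L,
                       min_valid_fraction = 0.5, seed = 1L) {
  stopifnot(inherits(generator, "generator_config"))
  expected <- default_variant(generator$sampling_rate_hz)
  if (is.null(segmentation)) {
    segmentation <- segmentation_config(expected)
  } else {
    stopifnot(inherits(segmentation, "segmentation_config"))
    if (!identical(segmentation$variant, expected)) {
      warning("segmentation variant ", segmentation$variant,
              " does not match the ", generator$sampling_rate_hz,
              " Hz sampling-rate default (", expected, ")", call. = FALSE)
    }
  }
  if (segmentation$filter_cutoff_hz >= generator$sampling_rate_hz / 2) {
    stop("filter cutoff must be below the Nyquist frequency", call. = FALSE)
  }
  structure(list(generator = generator, segmentation = segmentation,
                 parameters = parameters, alpha = alpha,
                 correction = correction, alpha_fixed = alpha_fixed,
                 sided = sided, bayes = bayes,
                 bf_samples = as.integer(bf_samples),
                 min_valid_fraction = min_valid_fraction,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the complete simulation and analysis pipeline
#'
#' Simulates an experiment, writes the trajectory CSV, extracts the
#' per-trial kinematic parameters, applies trial rejection and
#' participant exclusion, computes subject condition means and the
#' inference tables, and writes everything (plus a JSON run manifest
#' recording configuration, seed and package version) into `out_dir`.
#' Identical configuration and seed reproduce identical outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @param write_trajectories Write the (large) trajectory CSV; the
#'   derived tables are always written.
#' @return A list with `params` (per-trial table), `report`
#'   (inference tables), `exclusions` (participant report) and
#'   `manifest`, invisibly.
#' @export
run_pipeline <- function(config, out_dir, write_trajectories = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "simulate"
  result <- tryCatch({
    ds <- simulate_experiment(config$generator, seed = config$seed)
    if (write_trajectories) {
      write_dataset(ds, file.path(out_dir, "trajectories.csv"))
    }
    stage <- "extract"
    params <- process_dataset(ds, config$segmentation)
    stage <- "qc"
    params <- apply_qc(params)
    write_trial_params(params, file.path(out_dir, "trial_params.tsv"))
    flt <- filter_participants(params, config$min_valid_fraction)
    utils::write.table(flt$report, file.path(out_dir, "exclusions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
    stage <- "analyze"
    cm <- condition_means(flt$params)
    parameters <- intersect(config$parameters, unique(cm$parameter))
    report <- summarize_results(cm, parameters = parameters,
                                bayes = config$bayes,
                                bf_samples = config$bf_samples,
                                seed = config$seed,
                                alpha = config$alpha,
                                correction = config$correction,
                                alpha_fixed = config$alpha_fixed,
                                sided = config$sided)
    stage <- "report"
    write_results(report, out_dir)
    manifest <- run_manifest(config)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    list(params = params, report = report, exclusions = flt$report,
         manifest = manifest, condition_means = cm)
  }, error = function(e) {
    writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline failed at stage `", stage, "`: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

run_manifest <- function(config) {
  gen <- config$generator
  list(
    package = "reachgrasp",
    version = as.character(utils::packageVersion("reachgrasp")),
    seed = config$seed,
    generator = gen[setdiff(names(gen), "condition_means")],
    condition_means = gen$condition_means,
    segmentation = unclass(config$segmentation),
    inference = config[c("parameters", "alpha", "correction", "alpha_fixed",
                         "sided", "bayes", "bf_samples", "min_valid_fraction")]
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' The file mirrors the [run_config()] structure: top-level keys
#' `generator` (with optional `preset`), `segmentation`, inference
#' options and `seed`. Any omitted key keeps its default.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  gen_args <- y$generator
  preset <- gen_args$preset
  gen_args$preset <- NULL
  if (!is.null(gen_args$condition_means)) {
    gen_args$condition_means <- as.data.frame(
      do.call(rbind, lapply(gen_args$condition_means, as.data.frame)))
  }
  generator <- if (!is.null(preset)) {
    do.call(generator_preset, c(list(name = preset), gen_args))
  } else {
    do.call(generator_config, gen_args %||% list())
  }
  seg <- if (!is.null(y$segmentation)) {
    do.call(segmentation_config, y$segmentation)
  } else {
    NULL
  }
  opts <- y[setdiff(names(y), c("generator", "segmentation"))]
  do.call(run_config, c(list(generator = generator, segmentation = seg), opts))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
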