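#' Load and validate a person table from CSV
#'
#' Reads a header CSV with empty fields as missing, recodes through the
#' codebook (unmapped values become missing and are counted in the recode
#' log) and checks that every codebook variable is present.
#'
#' @param path CSV path.
#' @param cb a [codebook()].
#' @return a harmonized person table; attributes `recode_log` and `n_read`.
#' @export
load_person_table <- function(path, cb) {
  raw <- utils::read.csv(path, colClasses = "character", na.strings = "",
                         check.names = FALSE)
  out <- recode_table(raw, cb)
  if ("true_prob" %in% names(out)) {
    out$true_prob <- as.numeric(out$true_prob)
  }
  attr(out, "n_read") <- nrow(raw)
  out
}

#' Default end-to-end run configuration
#'
#' The synthetic benchmark: default population, census-like reference
#' (5% sample, 95% response), 5.5% volunteer selection, the default
#' association batch, and a 10-fold CV penalized probit.
#'
#' @param seed master seed.
#' @param n_population synthetic population size.
#' @param output_dir optional directory for artifacts.
#' @param loo also run the leave-one-out robustness refits (slow).
#' @return a named list understood by [run_pipeline()].
#' @export
default_run_config <- function(seed = 1L, n_population = 500000L,
                               output_dir = NULL, loo = FALSE) {
  list(mode = "synthetic", seed = seed, n_population = n_population,
       sampling_fraction = 0.05, response_rate = 0.95,
       target_rate = 0.055,
       codebook = default_codebook(),
       selection = default_selection_spec(seed = seed),
       associations = default_associations(),
       model = list(folds = 10L, n_lambda = 20L, cv_tol = 1e-3,
                    tol = 1e-6),
       missingness = NULL, loo = loo, output_dir = output_dir)
}

#' Run the full volunteer-bias pipeline
#'
#' Orchestrates simulate (or load) -> harmonize -> impute -> fit ->
#' weight -> associate -> diagnose with a single configuration and master
#' seed. In `"synthetic"` mode the population, reference sample and
#' volunteer cohort are generated with a known selection mechanism so the
#' run also reports oracle-weight results; in `"files"` mode `cohort_path`
#' and `reference_path` name CSV person tables.
#'
#' @param config list as produced by [default_run_config()] (YAML paths are
#'   accepted for the `codebook` entry). Required entries: `mode`, `seed`,
#'   `codebook`, `associations`; synthetic mode adds `n_population`,
#'   `sampling_fraction`, `response_rate` and a [selection_spec()];
#'   file mode adds `cohort_path`/`reference_path`.
#' @return list of class `pipeline_run`: the fitted `participation_model`,
#'   `comparison` (association table under estimated weights),
#'   `comparison_oracle` (synthetic mode only), `ess`, `robustness`
#'   (when requested), generated tables, timings, and the manifest.
#' @export
run_pipeline <- function(config) {
  t_all <- proc.time()[["elapsed"]]
  stopifnot(is.list(config), !is.null(config$mode), !is.null(config$seed))
  cb <- config$codebook
  if (is.character(cb)) cb <- read_codebook(cb)
  stopifnot(inherits(cb, "codebook"))
  seed <- as.integer(config$seed)
  timings <- c()
  tick <- function(stage, t0) {
    timings[stage] <<- round(proc.time()[["elapsed"]] - t0, 2)
  }

  if (identical(config$mode, "synthetic")) {
    t0 <- proc.time()[["elapsed"]]
    pspec <- population_spec(
      config$n_population %||% 500000L,
      config$variables %||% .default_variables(),
      # the default latent correlation only matches the default variables;
      # custom variable sets without an explicit correlation get identity
      latent_correlation = config$latent_correlation %||%
        (if (is.null(config$variables)) .default_latent_correlation()),
      seed = seed)
    pop <- generate_population(pspec)
    pop <- filter_eligible(pop, cb)
    tick("simulate_population", t0)

    t0 <- proc.time()[["elapsed"]]
    reference <- draw_reference_sample(
      pop, config$sampling_fraction %||% 0.05,
      config$response_rate %||% 0.95, seed = seed)
    sel <- config$selection %||% default_selection_spec(seed = seed)
    sel$seed <- seed
    cohort <- draw_volunteers(pop, sel, cb)
    tick("draw_samples", t0)
  } else if (identical(config$mode, "files")) {
    t0 <- proc.time()[["elapsed"]]
    cohort <- load_person_table(config$cohort_path, cb)
    reference <- load_person_table(config$reference_path, cb)
    cohort <- filter_eligible(cohort, cb)
    reference <- filter_eligible(reference, cb)
    cohort$source <- "cohort"; reference$source <- "reference"
    pop <- NULL
    tick("load_tables", t0)
  } else {
    stop("unknown mode: ", config$mode)
  }

  if (!is.null(config$missingness)) {
    cohort <- inject_missingness(cohort, unlist(config$missingness),
                                 seed = seed)
  }

  t0 <- proc.time()[["elapsed"]]
  model_cfg <- config$model %||% list()
  model <- participation_model(
    cohort, reference, cb,
    vars = config$model_vars,
    folds = model_cfg$folds %||% 10L, seed = seed,
    cv_tol = model_cfg$cv_tol %||% 1e-3,
    tol = model_cfg$tol %||% 1e-6,
    lambdas = model_cfg$lambdas)
  tick("fit_participation_model", t0)

  t0 <- proc.time()[["elapsed"]]
  associations <- config$associations %||% default_associations()
  comparison <- estimate_associations(associations, cohort, reference,
                                      weights(model), cb)
  ess <- ess_report(weights(model), comparison)
  comparison_oracle <- NULL
  if ("true_prob" %in% names(cohort)) {
    comparison_oracle <- estimate_associations(
      associations, cohort, reference, oracle_weights(cohort), cb)
  }
  tick("associations", t0)

  robustness <- NULL
  if (isTRUE(config$loo)) {
    t0 <- proc.time()[["elapsed"]]
    done <- impute_exact_match(cohort, model$vars, seed = seed)
    robustness <- leave_one_out_robustness(
      done$table, reference, cb, associations, comparison,
      vars = model$vars, folds = model_cfg$folds %||% 10L, seed = seed,
      cv_tol = model_cfg$cv_tol %||% 1e-3)
    tick("leave_one_out", t0)
  }

  timings["total"] <- round(proc.time()[["elapsed"]] - t_all, 2)
  manifest <- list(
    mode = config$mode, seed = seed,
    n_cohort = model$n_cohort, n_reference = model$n_reference,
    n_population = if (!is.null(pop)) nrow(pop),
    realized_participation_rate = if (!is.null(pop))
      attr(cohort, "realized_rate"),
    chosen_lambda = model$fit$chosen_lambda,
    n_selected = model$fit$n_selected,
    n_design_columns = length(model$design_cols),
    n_excluded = length(model$excluded_ids),
    kish_ess = ess$kish_ess, kish_fraction = ess$kish_fraction,
    mean_bias_reduction = mean_bias_reduction(comparison),
    timings = as.list(timings))

  run <- structure(list(model = model, comparison = comparison,
                        comparison_oracle = comparison_oracle,
                        ess = ess, robustness = robustness,
                        cohort = cohort, reference = reference,
                        codebook = cb, associations = associations,
                        manifest = manifest, timings = timings),
                   class = "pipeline_run")
  if (!is.null(config$output_dir)) {
    write_run_artifacts(run, config$output_dir)
  }
  run
}

#' Write the artifact set of a pipeline run
#'
#' weights CSV (+ JSON provenance), long and wide association CSVs, ESS
#' JSON, robustness JSON when present, a machine-readable manifest and a
#' human-readable report.
#'
#' @param run a `pipeline_run`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_run_artifacts <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_weights(weights(run$model), file.path(dir, "weights.csv"),
                provenance = list(
                  chosen_lambda = run$model$fit$chosen_lambda,
                  n_selected = run$model$fit$n_selected,
                  n_clipped = run$model$n_clipped %||% 0L,
                  seed = run$manifest$seed))
  association_long(run$comparison, file.path(dir, "associations.csv"))
  utils::write.csv(as.data.frame(run$comparison),
                   file.path(dir, "comparison.csv"), row.names = FALSE,
                   na = "")
  jsonlite::write_json(
    list(n_cohort = run$ess$n_cohort, kish_ess = run$ess$kish_ess,
         kish_fraction = run$ess$kish_fraction,
         mean_regression_ess = run$ess$mean_regression_ess,
         per_association = run$ess$per_association),
    file.path(dir, "ess.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows", pretty = TRUE)
  if (!is.null(run$robustness)) {
    jsonlite::write_json(
      list(mean_bias_reduction_full =
             run$robustness$mean_bias_reduction_full,
           mean_bias_reduction_reduced =
             run$robustness$mean_bias_reduction_reduced,
           per_association = run$robustness$per_association),
      file.path(dir, "robustness.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows", pretty = TRUE)
  }
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(utils::capture.output(write_report(run)),
             file.path(dir, "report.txt"))
  invisible(dir)
}

#' Human-readable run report
#'
#' @param run a `pipeline_run` (or a directory containing `manifest.json`
#'   written by [write_run_artifacts()], in which case the stored manifest
#'   is summarized).
#' @return the run, invisibly; the report is printed.
#' @export
write_report <- function(run) {
  if (is.character(run)) {
    man <- jsonlite::read_json(file.path(run, "manifest.json"),
                               simplifyVector = TRUE)
    cat("Pipeline run (from manifest)\n")
    for (k in setdiff(names(man), "timings")) {
      cat(sprintf("  %s: %s\n", k, paste(format(man[[k]]), collapse = " ")))
    }
    return(invisible(run))
  }
  stopifnot(inherits(run, "pipeline_run"))
  m <- run$manifest
  cat("== Volunteer-bias pipeline run ==\n")
  cat(sprintf("mode: %s, master seed: %d\n", m$mode, m$seed))
  if (!is.null(m$n_population)) {
    cat(sprintf("population: %d eligible persons; realized participation rate %.4f\n",
                m$n_population, m$realized_participation_rate))
  }
  cat(sprintf("cohort n = %d, reference n = %d, excluded (no donor) = %d\n",
              m$n_cohort, m$n_reference, m$n_excluded))
  cat(sprintf("participation model: lambda = %.6g, %d of %d columns selected\n",
              m$chosen_lambda, m$n_selected, m$n_design_columns))
  cat(sprintf("Kish ESS: %.0f (%.3f of cohort)\n", m$kish_ess,
              m$kish_fraction))
  cat(sprintf("mean regression ESS: %.0f\n", run$ess$mean_regression_ess))
  cat(sprintf("mean bias reduction (estimated weights): %.3f over %d associations\n",
              mean_bias_reduction(run$comparison), nrow(run$comparison)))
  if (!is.null(run$comparison_oracle)) {
    cat(sprintf("mean bias reduction (oracle weights):    %.3f\n",
                mean_bias_reduction(run$comparison_oracle)))
  }
  if (!is.null(run$robustness)) {
    cat(sprintf("leave-one-out mean bias reduction: %.3f (full %.3f)\n",
                run$robustness$mean_bias_reduction_reduced,
                run$robustness$mean_bias_reduction_full))
  }
  und <- sum(is.na(run$comparison$bias_reduction))
  if (und) cat(sprintf("associations with undefined bias reduction: %d\n", und))
  cat("timings (s):", paste(names(run$timings), unname(run$timings),
                            sep = "=", collapse = ", "), "\n")
  invisible(run)
}

#' @export
print.pipeline_run <- function(x, ...) write_report(x)
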