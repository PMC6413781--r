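#' Configure an end-to-end pigmentation analysis run
#'
#' Collects everything [run_pipeline()] needs: either a [cohort_truth()] to
#' simulate inputs from, or paths to existing input files; scoring
#' parameters; the longitudinal model specification; and the visit at which
#' change from baseline is summarised.
#'
#' @param output_dir Run directory (created by [run_pipeline()]).
#' @param seed Integer seed for all stochastic stages.
#' @param simulate If `TRUE` (default) inputs are generated from `truth` and
#'   written under `output_dir/inputs`; if `FALSE`, `inputs` paths are used.
#' @param truth A [cohort_truth()]; defaults to the standard 5-participant
#'   design with the given `seed`.
#' @param inputs Named list of paths (`images_dir`, `geometry`, `grades`,
#'   `spectra`, `hair`, `acuity`) used when `simulate = FALSE`.
#' @param scoring Named list of [semiquant_score()] parameters
#'   (`blur_sigma`, `disk_radius`, `scale_reference`).
#' @param random Random-effect structure for the longitudinal fits.
#' @param target_visit Visit month for the change-from-baseline summaries.
#' @param stages Stages to run after input acquisition.
#'
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir, seed = 1L, simulate = TRUE,
                            truth = cohort_truth(seed = seed),
                            inputs = list(),
                            scoring = list(scale_reference = 1000),
                            random = c("intercept_slope", "intercept"),
                            target_visit = 12,
                            stages = c("score", "panel", "icc", "correlation",
                                       "reflectometry", "hair",
                                       "longitudinal")) {
  random <- match.arg(random)
  stages <- match.arg(stages, several.ok = TRUE)
  if (!is.numeric(seed) || length(seed) != 1L)
    stop("invalid `seed`: must be a single integer", call. = FALSE)
  if (!simulate) {
    need <- c(
      if ("score" %in% stages) c("images_dir", "geometry"),
      if (any(c("panel", "icc", "correlation") %in% stages)) "grades",
      if ("reflectometry" %in% stages) "spectra",
      if ("hair" %in% stages) "hair",
      if ("longitudinal" %in% stages) "acuity"
    )
    for (field in unique(need)) {
      if (is.null(inputs[[field]]))
        stop("invalid config: `inputs$", field,
             "` is required when simulate = FALSE", call. = FALSE)
      if (!file.exists(inputs[[field]]))
        stop("invalid config: `inputs$", field, "` does not exist: ",
             inputs[[field]], call. = FALSE)
    }
  }
  structure(
    list(output_dir = output_dir, seed = as.integer(seed),
         simulate = isTRUE(simulate), truth = truth, inputs = inputs,
         scoring = scoring, random = random, target_visit = target_visit,
         stages = stages),
    class = "pipeline_config"
  )
}

#' Run the full pigmentation analysis pipeline
#'
#' Executes, in order: input acquisition (synthetic generation or reading),
#' semiquantitative image scoring, grader-panel aggregation, per-visit
#' intergrader ICCs, the panel-vs-image Spearman correlation, reflectometry
#' M-index summaries, hair marker change summaries, and the longitudinal
#' mixed-model fits for the panel score, the semiquantitative score, letters
#' read and each reflectometry site.  Every stage writes a CSV under
#' `output_dir/outputs`; a manifest and a log complete the run.  All
#' randomness derives from the configured seed, so rerunning an unchanged
#' configuration reproduces every CSV byte for byte.
#'
#' A longitudinal fit that fails to converge even with the random-intercept
#' fallback is recorded (with `converged = FALSE`) rather than aborting the
#' run; structural errors in any stage abort with the stage name.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the run directory, the per-stage output
#'   paths and the consolidated metrics table.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop("`config` must be a `pipeline_config`", call. = FALSE)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  outdir <- file.path(config$output_dir, "outputs")
  dir.create(outdir, showWarnings = FALSE)
  log_lines <- character(0)
  t0 <- proc.time()[["elapsed"]]
  log_msg <- function(level, ...) {
    line <- sprintf("[%s] %7.2fs %s", level,
                    proc.time()[["elapsed"]] - t0, paste0(...))
    log_lines <<- c(log_lines, line)
    message(line)
  }
  run_stage <- function(name, expr) {
    log_msg("INFO", "stage ", name, " started")
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    log_msg("INFO", "stage ", name, " done")
    res
  }
  outputs <- list()
  metrics <- data.frame(metric = character(0), value = numeric(0))

  # --- inputs ---------------------------------------------------------
  if (config$simulate) {
    inp <- file.path(config$output_dir, "inputs")
    bundle <- run_stage("simulate", {
      b <- generate_cohort(config$truth)
      write_bundle(b, inp)
      b
    })
    images_dir <- file.path(inp, "images")
    geometry <- read_geometry(file.path(inp, "geometry.csv"))
    grades <- bundle$grades
    spectra <- bundle$spectra
    hair <- bundle$hair
    acuity <- bundle$acuity
  } else {
    images_dir <- config$inputs$images_dir
    geometry <- if (!is.null(config$inputs$geometry))
      read_geometry(config$inputs$geometry)
    grades <- if (!is.null(config$inputs$grades))
      read_grades(config$inputs$grades)
    spectra <- if (!is.null(config$inputs$spectra))
      read_spectra(config$inputs$spectra)
    hair <- if (!is.null(config$inputs$hair))
      read.csv(config$inputs$hair, stringsAsFactors = FALSE)
    acuity <- if (!is.null(config$inputs$acuity))
      read.csv(config$inputs$acuity, stringsAsFactors = FALSE)
  }

  semiquant <- NULL
  if ("score" %in% config$stages) {
    scored <- run_stage("score", {
      imgs <- read_ti_images(images_dir, geometry)
      do.call(score_image_set, c(list(imgs), config$scoring))
    })
    write_table(scored$image_scores, file.path(outdir, "image_scores.csv"))
    write_table(scored$eye_visit_scores,
                file.path(outdir, "semiquant_scores.csv"))
    outputs$image_scores <- file.path(outdir, "image_scores.csv")
    outputs$semiquant_scores <- file.path(outdir, "semiquant_scores.csv")
    semiquant <- scored$eye_visit_scores
  }

  panel <- NULL
  if ("panel" %in% config$stages) {
    panel <- run_stage("panel", panel_scores(grades))
    write_table(panel, file.path(outdir, "panel_scores.csv"))
    outputs$panel_scores <- file.path(outdir, "panel_scores.csv")
  }

  if ("icc" %in% config$stages) {
    icc <- run_stage("icc", icc_by_visit(grades))
    write_table(icc, file.path(outdir, "icc.csv"))
    outputs$icc <- file.path(outdir, "icc.csv")
    metrics <- rbind(metrics, data.frame(metric = "icc_min",
                                         value = min(icc$icc)))
  }

  if ("correlation" %in% config$stages && !is.null(panel) &&
      !is.null(semiquant)) {
    rho <- run_stage("correlation", method_correlation(panel, semiquant))
    metrics <- rbind(metrics,
                     data.frame(metric = "spearman_panel_vs_semiquant",
                                value = rho))
  }

  mindex <- NULL
  if ("reflectometry" %in% config$stages && !is.null(spectra)) {
    mindex <- run_stage("reflectometry", summarize_site(spectra))
    write_table(mindex, file.path(outdir, "mindex.csv"))
    outputs$mindex <- file.path(outdir, "mindex.csv")
  }

  if ("hair" %in% config$stages && !is.null(hair)) {
    hc <- run_stage("hair",
                    marker_change_summary(hair, config$target_visit))
    write_table(hc$summary, file.path(outdir, "hair_changes.csv"))
    outputs$hair_changes <- file.path(outdir, "hair_changes.csv")
  }

  if ("longitudinal" %in% config$stages) {
    fits <- run_stage("longitudinal", {
      specs <- list()
      if (!is.null(panel))
        specs$ti_panel <- data.frame(
          participant = panel$participant, eye = panel$eye,
          visit_month = panel$visit_month, value = panel$mean_score)
      if (!is.null(semiquant))
        specs$ti_semiquant <- data.frame(
          participant = semiquant$participant, eye = semiquant$eye,
          visit_month = semiquant$visit_month, value = semiquant$mean_score)
      if (!is.null(acuity))
        specs$letters <- data.frame(
          participant = acuity$participant, eye = acuity$eye,
          visit_month = acuity$visit_month, value = acuity$letters)
      if (!is.null(mindex))
        for (s in unique(mindex$site))
          specs[[paste0("m_index_", s)]] <- data.frame(
            participant = mindex$participant[mindex$site == s],
            visit_month = mindex$visit_month[mindex$site == s],
            value = mindex$m_index[mindex$site == s])

      rows <- list()
      changes <- list()
      for (nm in names(specs)) {
        ds <- specs[[nm]]
        fit <- tryCatch(fit_longitudinal(ds, random = config$random),
                        error = function(e) e)
        if (inherits(fit, "error")) {
          log_msg("WARN", "fit for ", nm, " failed: ",
                  conditionMessage(fit))
          rows[[nm]] <- data.frame(outcome = nm, visit_month = NA_real_,
                                   estimate = NA_real_, ci_low = NA_real_,
                                   ci_high = NA_real_, p = NA_real_,
                                   label = NA_character_,
                                   fallback_applied = NA, converged = FALSE)
        } else {
          if (fit$fallback_applied)
            log_msg("WARN", "fit for ", nm,
                    ": intercept-only fallback applied")
          rows[[nm]] <- data.frame(outcome = nm, fit$estimates[
            , c("visit_month", "estimate", "ci_low", "ci_high", "p", "label")],
            fallback_applied = fit$fallback_applied, converged = TRUE)
        }
        cb <- tryCatch(change_from_baseline(ds, config$target_visit),
                       error = function(e) NULL)
        if (!is.null(cb))
          changes[[nm]] <- cbind(outcome = nm, cb$summary)
      }
      list(fits = do.call(rbind, rows), changes = do.call(rbind, changes))
    })
    rownames(fits$fits) <- rownames(fits$changes) <- NULL
    write_table(fits$fits, file.path(outdir, "longitudinal_fits.csv"))
    write_table(fits$changes, file.path(outdir, "change_summaries.csv"))
    outputs$longitudinal_fits <- file.path(outdir, "longitudinal_fits.csv")
    outputs$change_summaries <- file.path(outdir, "change_summaries.csv")
  }

  if (nrow(metrics)) {
    write_table(metrics, file.path(outdir, "metrics.csv"))
    outputs$metrics <- file.path(outdir, "metrics.csv")
  }

  cfg_dump <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config_as_list(config), cfg_dump)
  manifest <- list(
    outputs = lapply(outputs, function(p)
      file.path("outputs", basename(p))),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_dump)),
    package_version = as.character(packageVersion("melaquant"))
  )
  yaml::write_yaml(manifest, file.path(config$output_dir, "manifest.yaml"))
  unlink(cfg_dump)
  writeLines(log_lines, file.path(config$output_dir, "pipeline.log"))

  invisible(list(dir = config$output_dir, outputs = outputs,
                 metrics = metrics))
}

config_as_list <- function(config) {
  cl <- unclass(config)
  cl$truth <- truth_as_list(cl$truth)
  cl
}
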