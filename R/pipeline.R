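#' @include AllClasses.R synthetic-cohort.R fitting.R population-stats.R
NULL

#' Run the full analysis pipeline on a synthetic cohort
#'
#' End-to-end composition of the package stages: generate (or accept) a
#' cohort, simulate and extract features, optionally fit conductances by
#' grid search, and compute the population statistics (per-bird volumes,
#' pairwise distances, MANOVA, song-similarity correlation, and -- when the
#' cohort carries its true conductances -- a parameter-recovery summary).
#' Deterministic for a fixed config: rerunning writes byte-identical
#' reports.
#'
#' @param config list (or \code{\link{cohortConfig}}) with the cohort
#'   settings; extra pipeline fields: \code{fit} (logical: run the grid
#'   search; default FALSE), \code{gridPointsPerAxis} (desk grid
#'   resolution), \code{outDir} (write report files there).
#' @param cohort optionally a pre-built BirdCohort (config then only
#'   supplies pipeline options).
#' @return List of class "hvcxReport": cohort, features, fits (or NULL),
#'   volumes, distances, manova, similarity analysis, recovery summary.
#' @export
runPipeline <- function(config, cohort = NULL) {
  t0 <- proc.time()[["elapsed"]]
  log_i <- function(fmt, ...) message(sprintf("[%6.1fs] %s",
    proc.time()[["elapsed"]] - t0, sprintf(fmt, ...)))
  opts <- config
  if (is.null(cohort)) {
    cc <- if (inherits(config, "cohortConfig")) config
          else do.call(cohortConfig, config[intersect(names(config),
                       names(formals(cohortConfig)))])
    if (!isTRUE(cc$simulateTraces)) cc$simulateTraces <- TRUE
    log_i("generating %s cohort: %d birds x %d neurons",
          cc$preset, cc$nBirds, cc$neuronsPerBird)
    cohort <- generateCohort(cc)
  }
  tab <- cohort@conductances
  nm <- conductanceNames()

  # features
  features <- NULL
  if (length(cohort@traces)) {
    log_i("extracting features for %d neurons", nrow(tab))
    fl <- lapply(tab$neuron_id, function(id) {
      trs <- cohort@traces[[id]]
      extractFeatures(trs[["+100"]], trs[["-140"]])
    })
    names(fl) <- tab$neuron_id
    features <- featuresTable(fl, birdIds = tab$bird_id)
  }

  # fits
  fits <- NULL
  if (isTRUE(opts$fit %||% FALSE)) {
    grid <- deskGrid(opts$gridPointsPerAxis %||% 5)
    log_i("grid search (%d candidates per neuron)", gridSize(grid))
    params <- referenceParameters(
      if (cohort@config$preset == "juvenile") "juvenile" else "adult")
    rows <- lapply(tab$neuron_id, function(id) {
      trs <- cohort@traces[[id]]
      fit <- gridSearch(trs[["+100"]], trs[["-140"]], grid, params,
                        neuronId = id)
      data.frame(neuron_id = id,
                 bird_id = tab$bird_id[tab$neuron_id == id],
                 t(conductances(fit)), error = fit@error,
                 disregarded_count = fit@disregarded,
                 stringsAsFactors = FALSE)
    })
    fits <- do.call(rbind, rows)
  }

  # population statistics on the conductance table (true values unless fits
  # were computed; the recovery section compares the two)
  stat_tab <- fits %||% tab
  log_i("population statistics")
  volumes <- birdVolumes(stat_tab)
  dist_e <- conductanceDistances(stat_tab, "euclidean")
  dist_m <- conductanceDistances(stat_tab, "mahalanobis")
  mano <- NULL
  if (!is.null(features)) {
    cv <- manovaCovariates(features)
    if (length(unique(cv$birds)) >= 2 && nrow(cv$covariates) > 8)
      mano <- tryCatch(birdManova(cv$covariates, cv$birds),
                       error = function(e) NULL)
  }
  simil <- songSimilarity(cohort)
  simcor <- if (!is.null(simil))
    similarityDistanceCorrelation(simil, dist_e, mode = "both") else NULL

  recovery <- NULL
  if (!is.null(fits)) {
    err <- abs(as.matrix(fits[, nm]) - as.matrix(tab[, nm]))
    step <- matrix(rep((deskGrid(opts$gridPointsPerAxis %||% 5)@step)[nm],
                       each = nrow(err)), nrow(err))
    recovery <- list(
      max_abs_error = apply(err, 2, max),
      within_one_step = mean(apply(err <= step + 1e-9, 1, all)))
  }

  report <- list(cohort = cohort, features = features, fits = fits,
                 volumes = volumes,
                 distances = list(euclidean = dist_e, mahalanobis = dist_m),
                 manova = mano, similarity = simcor, recovery = recovery,
                 config = if (inherits(opts, "cohortConfig")) unclass(opts)
                          else opts)
  class(report) <- "hvcxReport"
  out_dir <- opts$outDir %||% NULL
  if (!is.null(out_dir)) writeReport(report, out_dir)
  log_i("done")
  report
}

#' Write a pipeline report to disk
#'
#' Emits \code{report.json} (machine-readable: volumes, distances, MANOVA,
#' correlation, recovery, config snapshot and its hash), \code{report.md}
#' (human-readable summary) and the features/fits CSVs next to them.
#'
#' @param report an "hvcxReport" from \code{\link{runPipeline}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the JSON path.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- report$config
  # hash over the scientific configuration only, not output locations
  cfg_json <- jsonlite::toJSON(cfg[setdiff(names(cfg), "outDir")],
                               auto_unbox = TRUE, digits = NA,
                               null = "null", force = TRUE)
  cfg_hash <- sum(utf8ToInt(as.character(cfg_json)) *
                  (seq_along(utf8ToInt(as.character(cfg_json))) %% 97 + 1))
  body <- list(
    config = cfg, config_hash = cfg_hash,
    volumes = report$volumes,
    distances_euclidean = report$distances$euclidean,
    distances_mahalanobis = report$distances$mahalanobis,
    manova = if (!is.null(report$manova)) unclass(report$manova),
    similarity = report$similarity,
    recovery = report$recovery
  )
  jpath <- file.path(dir, "report.json")
  jsonlite::write_json(body, jpath, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  md <- c("# Cohort analysis report", "",
          sprintf("- preset: %s (%d birds, %d neurons/bird, seed %d)",
                  cfg$preset %||% "custom", cfg$nBirds %||% NA,
                  cfg$neuronsPerBird %||% NA, cfg$seed %||% NA),
          sprintf("- config hash: %s", cfg_hash), "",
          "## Per-bird volumes", "",
          paste0("    ", utils::capture.output(print(report$volumes))))
  if (!is.null(report$manova))
    md <- c(md, "", "## MANOVA",
            sprintf("Wilks lambda = %.4g, F(%g, %.1f) = %.3g, p = %.3g",
                    report$manova$lambda, report$manova$df1,
                    report$manova$df2, report$manova$F, report$manova$p))
  if (!is.null(report$similarity))
    md <- c(md, "", "## Song similarity vs conductance distance",
            sprintf("pooled R = %.3f (p = %.3g, n = %d)",
                    report$similarity$pooled$R, report$similarity$pooled$p,
                    report$similarity$pooled$n))
  if (!is.null(report$recovery))
    md <- c(md, "", "## Parameter recovery",
            sprintf("fraction of neurons within one grid step on every axis: %.3f",
                    report$recovery$within_one_step))
  writeLines(md, file.path(dir, "report.md"))
  if (!is.null(report$features))
    write.csv(report$features, file.path(dir, "features.csv"),
              row.names = FALSE)
  if (!is.null(report$fits))
    writeFitsCsv(report$fits, file.path(dir, "fits.csv"))
  invisible(jpath)
}

#' @export
print.hvcxReport <- function(x, ...) {
  cat("hvcx pipeline report\n")
  cat(sprintf("  cohort: %d neurons, %d birds\n",
              nrow(x$cohort@conductances), nrow(x$cohort@centroids)))
  if (!is.null(x$fits)) cat(sprintf("  fitted: %d neurons\n", nrow(x$fits)))
  if (!is.null(x$recovery))
    cat(sprintf("  recovery within one grid step: %.2f\n",
                x$recovery$within_one_step))
  if (!is.null(x$manova))
    cat(sprintf("  MANOVA p = %.3g\n", x$manova$p))
  invisible(x)
}
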