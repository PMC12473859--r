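#' Default run configuration
#'
#' Assembles the validated defaults of the full analysis run: synthetic
#' demo input, confidence threshold 0.3 with a 5-frame interpolation cap,
#' pooled 95th-percentile displacement filtering, angular directional
#' shift, standard SPPB cut points, Pearson plus Spearman correlation, sex
#' stratification on, and no multiplicity correction.
#'
#' @param outDir Output directory for the report bundle.
#' @param seed Master seed.
#' @param ... Overrides for any field: `inputDir` (read a written cohort
#'   instead of simulating), `synth` (list of [synthCohortConfig()]
#'   overrides), `minScore`, `maxGap`, `percentile`, `scope`, `mode`,
#'   `cutpoints`, `methods`, `stratify`, `adjust`.
#' @return Named list of class `RunConfig`.
#' @export
defaultRunConfig <- function(outDir = tempfile("comgait_run"), seed = 1L,
                             ...) {
  cfg <- list(inputDir = NULL, synth = list(), outDir = outDir,
              seed = as.integer(seed), minScore = 0.3, maxGap = 5L,
              percentile = 95, scope = "pooled", mode = "angular",
              cutpoints = sppbCutpoints(),
              methods = c("pearson", "spearman"), stratify = TRUE,
              adjust = "none")
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$percentile > 0, cfg$percentile < 100,
            cfg$scope %in% c("pooled", "per_participant"),
            cfg$mode %in% c("angular", "horizontal"),
            all(cfg$methods %in% c("pearson", "spearman")),
            cfg$adjust %in% c("none", "BH"))
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a run configuration from YAML or JSON
#'
#' @param path Path to a YAML or JSON file whose top-level keys are
#'   fields of [defaultRunConfig()].
#' @return A `RunConfig`.
#' @export
readRunConfig <- function(path) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path) else yaml::read_yaml(path)
  if (!is.null(obj$cutpoints)) obj$cutpoints <- as.data.frame(obj$cutpoints)
  do.call(defaultRunConfig, obj)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage [", name, "]: ", conditionMessage(e), call. = FALSE))
}

.readCohortDir <- function(dir) {
  poseFiles <- list.files(file.path(dir, "poses"), full.names = TRUE,
                          pattern = "\\.(json|csv)$")
  if (!length(poseFiles)) stop("no pose files under ", dir, "/poses")
  poses <- lapply(poseFiles, readPoseSequence)
  names(poses) <- vapply(poses, participantId, character(1))
  list(poses = poses,
       bodyComp = readBodyComp(file.path(dir, "body_comp.csv")),
       walkTrials = utils::read.csv(file.path(dir, "walk_trials.csv"),
                                    stringsAsFactors = FALSE))
}

#' Run the full analysis pipeline
#'
#' Orchestrates ingest, repair, feature extraction, displacement
#' filtering, walk scoring, indicator validation and the statistical
#' battery, and writes a report bundle to `config$outDir`: per-participant
#' feature and confidence tables, the threshold report, walk scores,
#' indicator summaries and sarcopenia flags, the normality screen,
#' correlation tables (report-formatted CSV plus machine-readable JSON),
#' the per-indicator regression table, per-sex stratified tables, the
#' walking-path density histogram, a structured per-stage run log and a
#' manifest with the seed, the config and content checksums. The same
#' config and seed reproduce the bundle byte for byte.
#'
#' @param config A `RunConfig` from [defaultRunConfig()] or
#'   [readRunConfig()].
#' @return Invisibly, the report bundle as a named list of tables.
#' @export
runPipeline <- function(config = defaultRunConfig()) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  logLines <- character(0)
  note <- function(...) logLines <<- c(logLines, sprintf(...))

  data <- .stage("ingest", {
    if (!is.null(config$inputDir)) .readCohortDir(config$inputDir)
    else {
      synthArgs <- config$synth
      if (is.null(synthArgs$seed)) synthArgs$seed <- config$seed
      synthCfg <- do.call(synthCohortConfig, synthArgs)
      co <- generateCohort(synthCfg)
      list(poses = co$poses, bodyComp = co$bodyComp,
           walkTrials = co$walkTrials, truth = co$truth)
    }
  })
  note("ingest: %d participants, %d pose frames total",
       length(data$poses),
       sum(vapply(data$poses, nFrames, integer(1))))

  repaired <- .stage("repair", lapply(data$poses, interpolateMissing,
                                      minScore = config$minScore,
                                      maxGap = config$maxGap))
  nRep <- sum(vapply(repaired, function(r)
    sum(r$log$action == "repaired"), numeric(1)))
  nDrop <- sum(vapply(repaired, function(r)
    sum(r$log$action == "dropped"), numeric(1)))
  note("repair: %d keypoint-frames repaired, %d dropped (min_score %.2f, max_gap %d)",
       nRep, nDrop, config$minScore, config$maxGap)

  confidence <- .stage("confidence",
    do.call(rbind, lapply(data$poses, summarizeConfidence)))
  rownames(confidence) <- NULL

  com <- .stage("com", lapply(repaired, function(r)
    computeCoM(r$sequence)))
  dynList <- .stage("dynamics", lapply(com, computeDynamics))
  note("dynamics: %d frame pairs before filtering",
       sum(vapply(dynList, nrow, integer(1))))

  filt <- .stage("filter", filterDynamics(dynList,
                                          percentile = config$percentile,
                                          scope = config$scope))
  rep1 <- filt$reports[[1]]
  note("filter: percentile %s, scope %s, removed %d of %d frame pairs (%.2f%%)",
       format(config$percentile), config$scope,
       sum(vapply(filt$reports, function(r) r@nRemoved, integer(1))),
       sum(vapply(filt$reports, function(r) r@nTotal, integer(1))),
       100 * sum(vapply(filt$reports, function(r) r@nRemoved,
                        integer(1))) /
         sum(vapply(filt$reports, function(r) r@nTotal, integer(1))))

  thr <- if (config$scope == "pooled") rep1@threshold else NA_real_
  features <- .stage("features", featureTable(lapply(filt$dynamics,
    aggregateFeatures, mode = config$mode, filterThreshold = thr)))
  altMode <- setdiff(c("angular", "horizontal"), config$mode)
  altFeatures <- featureTable(lapply(filt$dynamics, aggregateFeatures,
                                     mode = altMode,
                                     filterThreshold = thr))
  note("features: mode %s; alternative %s-mode cohort mean shift %.4f",
       config$mode, altMode, mean(altFeatures$mean_directional_shift))
  rownames(features) <- NULL

  scores <- .stage("scores", scoreWalk(data$walkTrials,
                                       cutpoints = config$cutpoints))
  body <- data$bodyComp
  indSummary <- .stage("indicators", describeIndicators(body))
  sarco <- data.frame(participant_id = body$participant_id,
                      sex = body$sex, SMI = body$SMI,
                      risk = flagSarcopeniaRisk(body$sex, body$SMI),
                      stringsAsFactors = FALSE)
  note("indicators: %d records, %d flagged at sarcopenia risk",
       nrow(body), sum(sarco$risk == "at_risk"))

  merged <- merge(merge(features, body, by = "participant_id"),
                  scores, by = "participant_id")
  normality <- .stage("normality", shapiroScreen(merged,
    variables = intersect(c(setdiff(bodyCompColumns()$column,
                                    c("participant_id", "sex")),
                            "mean_directional_shift"), names(merged))))
  failed <- normality$variable[!is.na(normality$conforms) &
                               !normality$conforms]
  note("normality: %d of %d variables conform (non-normal: %s)",
       sum(normality$conforms, na.rm = TRUE), nrow(normality),
       if (length(failed)) paste(failed, collapse = ", ") else "none")

  corTables <- list()
  for (mth in config$methods) {
    cells <- .stage(paste0("correlation_", mth),
      correlationMatrix(features, body, scores, method = mth,
                        adjust = config$adjust))
    cells$non_normal_annotation <- cells$x %in% failed
    corTables[[mth]] <- cells
  }

  regression <- .stage("regression",
    regressionTable(merged, yvar = "mean_directional_shift"))

  stratified <- if (isTRUE(config$stratify))
    .stage("stratified",
      suppressWarnings(stratifiedAnalysis(features, body, scores)))
  else NULL

  density <- .stage("density", pathDensity(com, bins = 50L))

  # --- write the bundle -------------------------------------------------
  out <- function(...) file.path(config$outDir, ...)
  wcsv <- function(df, name) utils::write.csv(df, out(name),
                                              row.names = FALSE)
  wcsv(features, "features.csv")
  wcsv(confidence, "confidence.csv")
  wcsv(do.call(rbind, lapply(filt$reports, as.data.frame)),
       "threshold_report.csv")
  wcsv(scores, "walk_scores.csv")
  wcsv(indSummary, "indicator_summary.csv")
  wcsv(sarco, "sarcopenia.csv")
  wcsv(normality, "normality.csv")
  for (mth in names(corTables)) {
    wcsv(formatCorrelationTable(corTables[[mth]]),
         paste0("correlation_", mth, ".csv"))
    jsonlite::write_json(corTables[[mth]],
                         out(paste0("correlation_cells_", mth, ".json")),
                         digits = NA, dataframe = "rows")
  }
  wcsv(regression, "regression.csv")
  jsonlite::write_json(regression, out("regression.json"), digits = NA,
                       dataframe = "rows")
  if (!is.null(stratified)) {
    for (lv in names(stratified)) {
      wcsv(stratified[[lv]]$cells,
           paste0("correlation_", lv, ".csv"))
    }
    wcsv(do.call(rbind, lapply(stratified, `[[`, "summary")),
         "stratified_summary.csv")
  }
  jsonlite::write_json(list(counts = density$counts,
                            xbreaks = density$xbreaks,
                            ybreaks = density$ybreaks, n = density$n),
                       out("path_density.json"), digits = NA)
  writeLines(logLines, out("run_log.txt"))

  files <- sort(setdiff(list.files(config$outDir), "run_manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("comgait")),
    seed = config$seed,
    config = config[setdiff(names(config), c("outDir", "cutpoints"))],
    cutpoints = config$cutpoints,
    checksums = as.list(stats::setNames(
      unname(tools::md5sum(file.path(config$outDir, files))), files)))
  jsonlite::write_json(manifest, out("run_manifest.json"), digits = NA,
                       auto_unbox = TRUE, force = TRUE)

  invisible(list(features = features, confidence = confidence,
                 thresholdReports = filt$reports, scores = scores,
                 bodyComp = body, indicatorSummary = indSummary,
                 sarcopenia = sarco, normality = normality,
                 correlations = corTables, regression = regression,
                 stratified = stratified, density = density,
                 log = logLines,
                 truth = if (!is.null(data$truth)) data$truth else NULL))
}
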