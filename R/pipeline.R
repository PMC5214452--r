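# Orchestration: exams -> FTV tables -> AUC surfaces -> report tables.
# The imaging and cohort stages are decoupled through the long FTV table,
# so the statistics are fully testable without images.

#' Imaging stage: sweep the grid over a set of exams
#'
#' Computes enhancement maps for each examination and evaluates FTV at
#' every threshold grid cell, producing the long FTV table (one row per
#' patient x timepoint x cell).  An exam whose phases disagree in shape
#' or spacing is reported and skipped; the run continues and the missing
#' timepoint propagates as missing downstream.
#'
#' @param exams list of [DceExam-class] objects.
#' @param rois named list of [RoiBox-class], keyed
#'   `"<patientId>/tp<timepoint>"`, or a single box applied to all exams.
#' @param grid threshold grid from [thresholdGrid()].
#' @param minVoxels,neighborhood connectivity constraint parameters.
#' @return data.frame: patient_id, timepoint, pe_t, ser_t, n_voxels,
#'   ftv_cc.
#' @export
runImagingStage <- function(exams, rois, grid = thresholdGrid(),
                            minVoxels = 5L, neighborhood = 26L) {
  rows <- list()
  for (exam in exams) {
    key <- sprintf("%s/tp%d", exam@patientId, exam@timepoint)
    roi <- if (is(rois, "RoiBox")) rois else rois[[key]]
    if (is.null(roi)) {
      warning("no ROI for ", key, "; exam skipped")
      next
    }
    res <- tryCatch({
      maps <- enhancementMaps(exam)
      sw <- ftvSweep(maps, roi, grid, minVoxels, neighborhood)
      cbind(patient_id = exam@patientId, timepoint = exam@timepoint, sw)
    }, error = function(e) {
      warning("exam ", key, " failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  if (!length(rows))
    return(data.frame(patient_id = character(0), timepoint = integer(0),
                      pe_t = numeric(0), ser_t = numeric(0),
                      n_voxels = integer(0), ftv_cc = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Analysis stage: surfaces, optimal thresholds and report tables
#'
#' For every predictor x subgroup combination with both outcome classes
#' present: the AUC surface and its optimum; a maximum-AUC summary with
#' DeLong intervals; and, for the focal predictor, diagnostic-performance
#' and group-comparison tables at the default versus the optimized
#' thresholds (optimal cutoff with exact binomial intervals for
#' sensitivity and specificity; medians with IQR, Hodges-Lehmann
#' difference with rank-inverted interval, likelihood-ratio p and odds
#' ratio per 10 points of percent FTV change).
#'
#' @param cohort an [FtvCohort-class].
#' @param predictors predictors to map.
#' @param subgroups subgroups to analyze ("full" plus the subtype labels).
#' @param focalPredictor predictor used for the report tables.
#' @param defaultPe,defaultSer the default threshold pair.
#' @param orScale predictor units per odds-ratio step.
#' @return list of class "FtvAnalysis": `surfaces` (named list of
#'   [AucSurface-class]), `maxAuc` (data.frame), `diagnostics`
#'   (data.frame), `comparison` (data.frame).
#' @export
runAnalysisStage <- function(cohort,
                             predictors = c("ftv1", "ftv2", "ftv3", "ftv4",
                                            "dftv2", "dftv3", "dftv4"),
                             subgroups = c("full",
                                           unique(stats::na.omit(
                                             subtypes(cohort)))),
                             focalPredictor = "dftv3",
                             defaultPe = 70, defaultSer = 0,
                             orScale = 10) {
  surfaces <- list()
  maxAuc <- list()
  for (sg in subgroups) {
    for (pr in predictors) {
      surf <- tryCatch(aucSurface(cohort, pr, sg), error = function(e) {
        warning("surface ", pr, " / ", sg, " skipped: ",
                conditionMessage(e))
        NULL
      })
      if (is.null(surf)) next
      surfaces[[paste(pr, sg, sep = "/")]] <- surf
      opt <- selectOptimal(surf)
      ci <- predictorCellCI(cohort, pr, sg, opt$pe_t, opt$ser_t)
      maxAuc[[length(maxAuc) + 1L]] <- data.frame(
        predictor = pr, subgroup = sg, pe_t = opt$pe_t,
        ser_t = opt$ser_t, auc = opt$auc,
        auc_low = ci[1], auc_high = ci[2])
    }
  }
  diagnostics <- list()
  comparison <- list()
  for (sg in subgroups) {
    key <- paste(focalPredictor, sg, sep = "/")
    if (is.null(surfaces[[key]])) next
    opt <- selectOptimal(surfaces[[key]])
    for (setting in list(c(defaultPe, defaultSer),
                         c(opt$pe_t, opt$ser_t))) {
      lab <- if (setting[1] == defaultPe && setting[2] == defaultSer)
        "default" else "optimized"
      d <- cellData(cohort, focalPredictor, sg, setting[1], setting[2])
      if (is.null(d)) next
      roc <- rocAuc(d$values, ifelse(d$case, "case", "control"))
      cut <- optimalCutoff(roc)
      sensCI <- clopperPearson(round(cut$sens * roc$nCase), roc$nCase)
      specCI <- clopperPearson(round(cut$spec * roc$nControl),
                               roc$nControl)
      diagnostics[[length(diagnostics) + 1L]] <- data.frame(
        subgroup = sg, setting = lab, pe_t = setting[1],
        ser_t = setting[2], cutoff = cut$cutoff,
        sens = cut$sens, sens_low = sensCI[1], sens_high = sensCI[2],
        spec = cut$spec, spec_low = specCI[1], spec_high = specCI[2])
      gi <- groupSummary(d$values[!d$case])   # pCR (controls)
      gn <- groupSummary(d$values[d$case])    # non-pCR (cases)
      md <- medianDifferenceCI(d$values[!d$case], d$values[d$case])
      lr <- logisticLrtOr(d$values, d$case, scale = orScale)
      comparison[[length(comparison) + 1L]] <- data.frame(
        subgroup = sg, setting = lab, pe_t = setting[1],
        ser_t = setting[2],
        pcr_median = gi$median, pcr_q1 = gi$q1, pcr_q3 = gi$q3,
        nonpcr_median = gn$median, nonpcr_q1 = gn$q1, nonpcr_q3 = gn$q3,
        diff = md$estimate, diff_low = md$low, diff_high = md$high,
        p_lrt = lr$p, or = lr$or, or_low = lr$orLow, or_high = lr$orHigh,
        separated = lr$separated)
    }
  }
  structure(list(surfaces = surfaces,
                 maxAuc = do.call(rbind, maxAuc),
                 diagnostics = do.call(rbind, diagnostics),
                 comparison = do.call(rbind, comparison)),
            class = "FtvAnalysis")
}

# Predictor values and case flags of one subgroup at one grid cell,
# excluding patients with an undefined percent change there.
cellData <- function(cohort, predictor, subgroup, pe_t, ser_t) {
  rd <- SummarizedExperiment::rowData(cohort)
  i <- which(rd$pe_t == pe_t & rd$ser_t == ser_t)
  if (length(i) != 1L)
    stop(sprintf("threshold pair (%g, %g) is not on the grid", pe_t, ser_t))
  cols <- subgroupColumns(cohort, subgroup)
  v <- predictorMatrix(cohort, predictor)[i, cols]
  case <- !pcrStatus(cohort)[cols]
  ok <- !is.na(v)
  if (!any(case[ok]) || all(case[ok])) return(NULL)
  list(values = v[ok], case = case[ok])
}

predictorCellCI <- function(cohort, predictor, subgroup, pe_t, ser_t) {
  d <- cellData(cohort, predictor, subgroup, pe_t, ser_t)
  if (is.null(d) || sum(d$case) < 2 || sum(!d$case) < 2)
    return(c(NA_real_, NA_real_))
  aucCI(rocAuc(d$values, ifelse(d$case, "case", "control")))
}

#' Write analysis outputs to CSV
#'
#' Emits the long surface table, the maximum-AUC summary and the two
#' report tables into a directory; rerunning with the same inputs
#' produces byte-identical files.
#'
#' @param analysis an "FtvAnalysis" from [runAnalysisStage()].
#' @param dir output directory (created if needed).
#' @return the output paths, invisibly.
#' @export
writeAnalysisOutputs <- function(analysis, dir) {
  stopifnot(inherits(analysis, "FtvAnalysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("auc_surfaces.csv", "max_auc.csv",
                            "diagnostics.csv", "comparison.csv"))
  utils::write.csv(aucSurfaceTable(analysis$surfaces), paths[1],
                   row.names = FALSE)
  utils::write.csv(analysis$maxAuc, paths[2], row.names = FALSE)
  utils::write.csv(analysis$diagnostics, paths[3], row.names = FALSE)
  utils::write.csv(analysis$comparison, paths[4], row.names = FALSE)
  invisible(paths)
}
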