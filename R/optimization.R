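# AUC surfaces over the threshold grid and optimal-threshold selection.

subgroupColumns <- function(cohort, subgroup) {
  if (subgroup == "full") return(seq_len(ncol(cohort)))
  s <- subtypes(cohort)
  which(!is.na(s) & s == subgroup)
}

# Fast Mann-Whitney AUC used cell-wise (NA values excluded pairwise).
cellAuc <- function(v, case) {
  ok <- !is.na(v)
  v <- v[ok]; case <- case[ok]
  n1 <- sum(case); n0 <- sum(!case)
  if (n1 == 0L || n0 == 0L)
    return(c(NA_real_, n1, n0))
  r <- rank(v)
  c((sum(r[case]) - n1 * (n1 + 1) / 2) / (n1 * n0), n1, n0)
}

#' AUC surface of one predictor in one subgroup
#'
#' For every (PE threshold, SER threshold) grid cell, the AUC of the
#' predictor for discriminating non-pCR (cases) from pCR (controls).
#' Patients with an undefined percent change (zero baseline FTV) are
#' excluded cell-wise; a cell that loses a whole outcome class this way is
#' set to NA (missing, not 0.5).  The maximizing cell (smallest-threshold
#' tie-break, ties reported via message) is recorded in the object.
#'
#' @param cohort an [FtvCohort-class].
#' @param predictor one of "ftv1".."ftv4", "dftv2".."dftv4".
#' @param subgroup "full" or a subtype label present in the cohort.
#' @return An [AucSurface-class].
#' @examples
#' coh <- generateCohort(syntheticCohortSpec(seed = 3))
#' aucSurface(coh, "dftv3", "HER2+")
#' @export
aucSurface <- function(cohort, predictor = "dftv3", subgroup = "full") {
  stopifnot(is(cohort, "FtvCohort"))
  cols <- subgroupColumns(cohort, subgroup)
  if (!length(cols)) stop("no patients in subgroup '", subgroup, "'")
  case <- !pcrStatus(cohort)[cols]          # non-pCR are the cases
  if (!any(case) || all(case))
    stop("subgroup '", subgroup,
         "' has a single outcome class; AUC is undefined")
  vals <- predictorMatrix(cohort, predictor)[, cols, drop = FALSE]
  pe <- peThresholds(cohort)
  ser <- serThresholds(cohort)
  rd <- SummarizedExperiment::rowData(cohort)
  auc <- matrix(NA_real_, length(pe), length(ser),
                dimnames = list(pe, ser))
  nCa <- nCo <- matrix(0L, length(pe), length(ser),
                       dimnames = list(pe, ser))
  for (i in seq_len(nrow(vals))) {
    r <- cellAuc(vals[i, ], case)
    pi <- match(rd$pe_t[i], pe); si <- match(rd$ser_t[i], ser)
    auc[pi, si] <- r[1]
    nCa[pi, si] <- as.integer(r[2]); nCo[pi, si] <- as.integer(r[3])
  }
  opt <- pickOptimum(auc, pe, ser)
  new("AucSurface", predictor = predictor, subgroup = subgroup,
      auc = auc, nCases = nCa, nControls = nCo,
      peGrid = pe, serGrid = ser,
      optimum = c(opt$pe_t, opt$ser_t, opt$auc))
}

pickOptimum <- function(auc, pe, ser) {
  if (all(is.na(auc))) stop("AUC surface is entirely missing")
  mx <- max(auc, na.rm = TRUE)
  hits <- which(!is.na(auc) & auc == mx, arr.ind = TRUE)
  if (nrow(hits) > 1L) {
    # smallest PE threshold wins, then smallest SER threshold
    hits <- hits[order(pe[hits[, 1]], ser[hits[, 2]]), , drop = FALSE]
    message(sprintf("AUC tie across %d cells; selected PEt=%g%%, SERt=%g",
                    nrow(hits), pe[hits[1, 1]], ser[hits[1, 2]]))
  }
  list(pe_t = pe[hits[1, 1]], ser_t = ser[hits[1, 2]], auc = mx)
}

#' Optimal thresholds of an AUC surface
#'
#' The grid cell with maximal AUC; ties are broken by the smallest PE
#' threshold, then the smallest SER threshold (larger, more stable
#' volumes are preferred at equal discrimination).
#'
#' @param surface an [AucSurface-class].
#' @return list: `pe_t`, `ser_t`, `auc`.
#' @export
selectOptimal <- function(surface) {
  stopifnot(is(surface, "AucSurface"))
  list(pe_t = surface@optimum[1], ser_t = surface@optimum[2],
       auc = surface@optimum[3])
}

#' Long-format export of AUC surfaces
#'
#' @param surfaces an [AucSurface-class] or a list of them.
#' @return data.frame: predictor, subgroup, pe_t, ser_t, auc, n_cases,
#'   n_controls.
#' @export
aucSurfaceTable <- function(surfaces) {
  if (is(surfaces, "AucSurface")) surfaces <- list(surfaces)
  do.call(rbind, lapply(surfaces, function(s) {
    data.frame(predictor = s@predictor, subgroup = s@subgroup,
               pe_t = rep(s@peGrid, times = length(s@serGrid)),
               ser_t = rep(s@serGrid, each = length(s@peGrid)),
               auc = as.vector(s@auc),
               n_cases = as.vector(s@nCases),
               n_controls = as.vector(s@nControls))
  }))
}

snapToGrid <- function(x, levels) levels[which.min(abs(levels - x))]

#' Planted-optimum recovery experiment
#'
#' Generates replicate synthetic cohorts and checks, per subtype, whether
#' the grid-search argmax of the predictor's AUC surface falls inside the
#' planted optimal threshold region (within `slackSteps` grid steps), and
#' whether the AUC at the planted representative pair exceeds the AUC at
#' the default thresholds (70%, 0).  Replicates where a subgroup has fewer
#' than two patients in either outcome class are redrawn with an offset
#' seed (the surface is undefined there).
#'
#' @param nReps number of replicate cohorts.
#' @param seed base seed; replicate r uses `seed + r`.
#' @param predictor predictor to optimize (default "dftv3", the
#'   inter-regimen percent change).
#' @param spec function(seed) returning a [syntheticCohortSpec()]; the
#'   default uses the standard cohort.
#' @param slackSteps tolerance around the planted region, in grid steps.
#' @return data.frame with one row per replicate x subtype: `recovered`
#'   (argmax within the slackened planted region), `aucPlanted`,
#'   `aucDefault`, the argmax cell and its AUC.
#' @export
thresholdRecoveryExperiment <- function(nReps = 20L, seed = 1L,
                                        predictor = "dftv3",
                                        spec = function(s)
                                          syntheticCohortSpec(seed = s),
                                        slackSteps = 1L) {
  out <- list()
  for (r in seq_len(nReps)) {
    s <- seed + r
    repeat {
      coh <- generateCohort(spec(s))
      cd <- SummarizedExperiment::colData(coh)
      ok <- all(vapply(unique(cd$subtype[!is.na(cd$subtype)]),
                       function(g) {
                         p <- cd$pcr[!is.na(cd$subtype) & cd$subtype == g]
                         sum(p) >= 2 && sum(!p) >= 2
                       }, logical(1)))
      if (ok) break
      s <- s + 104729L   # degenerate draw: redraw under an offset seed
    }
    gt <- groundTruth(coh)
    pe <- peThresholds(coh); ser <- serThresholds(coh)
    peStep <- min(diff(sort(pe))); serStep <- min(diff(sort(ser)))
    for (g in names(gt$planted)) {
      surf <- aucSurface(coh, predictor, g)
      opt <- selectOptimal(surf)
      pl <- gt$planted[[g]]
      recovered <-
        opt$pe_t >= pl$pe[1] - slackSteps * peStep &
        opt$pe_t <= pl$pe[2] + slackSteps * peStep &
        opt$ser_t >= pl$ser[1] - slackSteps * serStep &
        opt$ser_t <= pl$ser[2] + slackSteps * serStep
      pePl <- snapToGrid(pl$pair[1], pe)
      serPl <- snapToGrid(pl$pair[2], ser)
      aucAt <- function(p, s)
        surf@auc[match(p, surf@peGrid), match(s, surf@serGrid)]
      out[[length(out) + 1L]] <- data.frame(
        rep = r, subtype = g, recovered = recovered,
        pe_opt = opt$pe_t, ser_opt = opt$ser_t, auc_opt = opt$auc,
        aucPlanted = aucAt(pePl, serPl),
        aucDefault = aucAt(snapToGrid(70, pe), snapToGrid(0, ser)))
    }
  }
  do.call(rbind, out)
}
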