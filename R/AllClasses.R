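#' @import methods
#' @importFrom stats pnorm pchisq rnorm rbinom runif quantile median
#'   binom.test fisher.test wilcox.test glm logLik coef vcov qnorm
#'   binomial setNames
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' DceExam: one DCE-MRI examination (three acquisition phases)
#'
#' Container for the three signal-intensity volumes of a single dynamic
#' contrast-enhanced MRI examination: pre-contrast (S0), early post-contrast
#' (S1) and late post-contrast (S2), together with voxel geometry, the MRI
#' timepoint within the neoadjuvant treatment course (1 = baseline,
#' 2 = early treatment, 3 = inter-regimen, 4 = pre-surgery) and a patient
#' identifier.
#'
#' @slot s0,s1,s2 3D numeric arrays of identical dimension (arbitrary
#'   signal units).
#' @slot spacing numeric(3), voxel spacing in mm along each axis.
#' @slot timepoint integer in 1..4.
#' @slot patientId character scalar.
#' @export
setClass("DceExam",
  representation(
    s0 = "array", s1 = "array", s2 = "array",
    spacing = "numeric", timepoint = "integer", patientId = "character"
  )
)

setValidity("DceExam", function(object) {
  msg <- character()
  d0 <- dim(object@s0)
  if (length(d0) != 3L) msg <- c(msg, "phase volumes must be 3D arrays")
  if (!identical(d0, dim(object@s1)) || !identical(d0, dim(object@s2)))
    msg <- c(msg, "S0, S1 and S2 must have identical dimensions")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive numbers (mm)")
  if (length(object@timepoint) != 1L || is.na(object@timepoint) ||
      object@timepoint < 1L || object@timepoint > 4L)
    msg <- c(msg, "timepoint must be a single integer in 1..4")
  if (length(object@patientId) != 1L || is.na(object@patientId))
    msg <- c(msg, "patientId must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a DceExam
#'
#' @param s0,s1,s2 3D numeric arrays (same dimensions): pre-contrast, early
#'   post-contrast and late post-contrast signal.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param timepoint MRI timepoint, integer 1..4.
#' @param patientId patient identifier.
#' @return A [DceExam-class] object.
#' @examples
#' a <- array(100, c(4, 4, 2))
#' ex <- DceExam(a, a * 2, a * 1.5, spacing = c(1, 1, 2.5),
#'               timepoint = 1, patientId = "P1")
#' @export
DceExam <- function(s0, s1, s2, spacing, timepoint = 1L, patientId = "anon") {
  new("DceExam", s0 = s0, s1 = s1, s2 = s2,
      spacing = as.numeric(spacing), timepoint = as.integer(timepoint),
      patientId = as.character(patientId))
}

setMethod("show", "DceExam", function(object) {
  d <- dim(object@s0)
  cat(sprintf(
    "DceExam '%s' timepoint %d: %d x %d x %d voxels @ %.2f x %.2f x %.2f mm\n",
    object@patientId, object@timepoint, d[1], d[2], d[3],
    object@spacing[1], object@spacing[2], object@spacing[3]))
})

#' EnhancementMaps: voxelwise PE and SER with validity mask
#'
#' Voxelwise percent enhancement (PE, in percent) and signal enhancement
#' ratio (SER, dimensionless) maps derived from a [DceExam-class], plus a
#' logical mask of voxels where both are computable tissue (above the
#' automatic background threshold, non-degenerate enhancement).
#'
#' @slot pe 3D numeric array, percent enhancement.
#' @slot ser 3D numeric array, signal enhancement ratio.
#' @slot valid 3D logical array; PE and SER are finite wherever TRUE.
#' @slot spacing numeric(3) voxel spacing in mm (carried from the exam).
#' @export
setClass("EnhancementMaps",
  representation(pe = "array", ser = "array", valid = "array",
                 spacing = "numeric")
)

setValidity("EnhancementMaps", function(object) {
  msg <- character()
  d <- dim(object@pe)
  if (length(d) != 3L) msg <- c(msg, "maps must be 3D")
  if (!identical(d, dim(object@ser)) || !identical(d, dim(object@valid)))
    msg <- c(msg, "pe, ser and valid must share dimensions")
  if (!is.logical(object@valid)) msg <- c(msg, "valid must be logical")
  v <- object@valid
  if (is.logical(v) && identical(d, dim(object@pe)) &&
      (any(!is.finite(object@pe[v])) || any(!is.finite(object@ser[v]))))
    msg <- c(msg, "pe and ser must be finite wherever valid is TRUE")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive numbers")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EnhancementMaps", function(object) {
  d <- dim(object@pe)
  cat(sprintf("EnhancementMaps: %d x %d x %d voxels, %d (%.1f%%) valid\n",
              d[1], d[2], d[3], sum(object@valid),
              100 * mean(object@valid)))
})

#' RoiBox: axis-aligned 3D region of interest
#'
#' A rectangular box in voxel coordinates, stored 0-based and half-open
#' (`lo` inclusive, `hi` exclusive) so that it composes directly with array
#' slicing.
#'
#' @slot lo integer(3), inclusive lower corner (0-based).
#' @slot hi integer(3), exclusive upper corner.
#' @export
setClass("RoiBox", representation(lo = "integer", hi = "integer"))

setValidity("RoiBox", function(object) {
  msg <- character()
  if (length(object@lo) != 3L || length(object@hi) != 3L)
    msg <- c(msg, "lo and hi must have length 3")
  else {
    if (any(object@lo < 0L)) msg <- c(msg, "lo must be non-negative")
    if (any(object@hi <= object@lo))
      msg <- c(msg, "hi must exceed lo on every axis")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a RoiBox
#'
#' @param lo integer(3) inclusive lower corner, 0-based voxel indices.
#' @param hi integer(3) exclusive upper corner.
#' @return A [RoiBox-class].
#' @examples
#' RoiBox(c(0, 0, 0), c(10, 10, 4))
#' @export
RoiBox <- function(lo, hi) new("RoiBox", lo = as.integer(lo), hi = as.integer(hi))

setMethod("show", "RoiBox", function(object) {
  cat(sprintf("RoiBox [%s) x [%s) x [%s)\n",
              paste(object@lo[1], object@hi[1], sep = ", "),
              paste(object@lo[2], object@hi[2], sep = ", "),
              paste(object@lo[3], object@hi[3], sep = ", ")))
})

#' AucSurface: AUC over the PE/SER threshold grid
#'
#' The AUC of one FTV-derived predictor of pathologic complete response,
#' evaluated at every (PE threshold, SER threshold) grid cell for one
#' patient subgroup, with per-cell case/control counts after exclusions and
#' the maximizing cell.
#'
#' @slot predictor one of "ftv1".."ftv4", "dftv2".."dftv4".
#' @slot subgroup one of "full", "HR+/HER2-", "HER2+", "TNBC".
#' @slot auc numeric matrix (PE levels x SER levels); NA where a class was
#'   lost to exclusions.
#' @slot nCases,nControls integer matrices of the same shape.
#' @slot peGrid,serGrid numeric vectors of the grid levels.
#' @slot optimum numeric(3): optimal pe_t, ser_t and the maximal AUC
#'   (smallest-threshold tie-break).
#' @export
setClass("AucSurface",
  representation(predictor = "character", subgroup = "character",
                 auc = "matrix", nCases = "matrix", nControls = "matrix",
                 peGrid = "numeric", serGrid = "numeric",
                 optimum = "numeric")
)

setValidity("AucSurface", function(object) {
  msg <- character()
  d <- dim(object@auc)
  if (!identical(d, c(length(object@peGrid), length(object@serGrid))))
    msg <- c(msg, "auc matrix must be peGrid x serGrid")
  if (!identical(dim(object@nCases), d) || !identical(dim(object@nControls), d))
    msg <- c(msg, "count matrices must match the auc matrix")
  a <- object@auc[!is.na(object@auc)]
  if (length(a) && (min(a) < 0 || max(a) > 1))
    msg <- c(msg, "AUC values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AucSurface", function(object) {
  cat(sprintf(
    "AucSurface %s / %s: %d x %d grid, max AUC %.3f at PEt=%g%%, SERt=%g\n",
    object@predictor, object@subgroup,
    length(object@peGrid), length(object@serGrid),
    object@optimum[3], object@optimum[1], object@optimum[2]))
})

#' FtvCohort: per-patient FTV over the threshold grid
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' whose rows are (PE threshold, SER threshold) grid cells (rowData columns
#' `pe_t`, `ser_t`) and whose columns are patients (colData columns
#' `patient_id`, `hr`, `her2`, `subtype`, `pcr`).  Assays `ftv1`..`ftv4`
#' hold FTV in cubic centimetres at the four MRI timepoints.
#'
#' @export
setClass("FtvCohort", contains = "SummarizedExperiment")

setValidity("FtvCohort", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("ftv1", "ftv2", "ftv3", "ftv4") %in% an))
    msg <- c(msg, "assays ftv1..ftv4 are required")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("pe_t", "ser_t") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain pe_t and ser_t")
  cd <- SummarizedExperiment::colData(object)
  need <- c("patient_id", "subtype", "pcr")
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, "colData must contain patient_id, subtype and pcr")
  else if (!is.logical(cd$pcr)) msg <- c(msg, "pcr must be logical")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FtvCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("FtvCohort: %d grid cells x %d patients (%d pCR / %d non-pCR)\n",
              nrow(object), ncol(object), sum(cd$pcr), sum(!cd$pcr)))
  tab <- table(cd$subtype, useNA = "ifany")
  cat("  subtypes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})
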