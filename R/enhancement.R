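# Voxelwise enhancement maps: PE, SER, automatic background masking and
# MIP-box regions of interest.

# SER assigned to strong-washout voxels whose late-phase signal has returned
# to (or below) baseline: keeps them includable at any SER threshold <= 2.
SER_CAP <- 10

#' Otsu threshold of an intensity volume
#'
#' Histogram-based threshold maximizing the between-class variance, used to
#' separate background (air, suppressed fat) from enhancing tissue on the
#' pre-contrast volume.
#'
#' @param x numeric array or vector of intensities.
#' @param nbins number of histogram bins.
#' @return The threshold value, or `NA` when the input is constant (no
#'   threshold exists; a warning is raised).
#' @examples
#' otsuThreshold(c(rep(10, 50), rep(1000, 50)))
#' @export
otsuThreshold <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (!is.finite(diff(rng)) || diff(rng) == 0) {
    warning("constant volume: no background threshold exists")
    return(NA_real_)
  }
  edges <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, edges, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins)
  mids <- (edges[-1L] + edges[-(nbins + 1L)]) / 2
  w <- cumsum(h)
  m <- cumsum(h * mids)
  tot <- w[nbins]
  mu <- m[nbins]
  # between-class variance for a cut after bin k:
  # (tot m_k - mu w_k)^2 / (w_k (tot - w_k)), maximized over k
  wk <- w[-nbins]
  bc <- (tot * m[-nbins] - mu * wk)^2 / (wk * (tot - wk))
  bc[!is.finite(bc)] <- -Inf
  k <- which.max(bc)
  edges[k + 1L]
}

#' Background/fat mask from the pre-contrast volume
#'
#' TRUE where tissue: the pre-contrast signal exceeds an automatically
#' determined (Otsu) intensity threshold.  Air and suppressed fat fall
#' below it.  A constant volume yields an all-TRUE mask with a warning.
#'
#' @param s0 3D numeric array, pre-contrast signal.
#' @return 3D logical array.
#' @export
backgroundMask <- function(s0) {
  thr <- otsuThreshold(s0)
  if (is.na(thr)) return(array(TRUE, dim(s0)))
  array(s0 > thr, dim(s0))
}

#' Percent enhancement map
#'
#' PE = 100 (S1 - S0) / S0 at every voxel above the background threshold.
#' Degenerate voxels (background, S0 at or below the automatic threshold)
#' are returned as NA; use [enhancementMaps()] for the joint valid mask.
#'
#' @param exam a [DceExam-class].
#' @return 3D numeric array of percent enhancement.
#' @export
computePE <- function(exam) {
  stopifnot(is(exam, "DceExam"))
  m <- backgroundMask(exam@s0)
  pe <- array(NA_real_, dim(exam@s0))
  pe[m] <- 100 * (exam@s1[m] - exam@s0[m]) / exam@s0[m]
  pe
}

#' Signal enhancement ratio map
#'
#' SER = (S1 - S0) / (S2 - S0).  When the denominator is at or below a
#' small epsilon (1e-6 of the S0 dynamic range) while the numerator is
#' positive -- strong washout, late signal back at baseline -- the voxel is
#' assigned the cap value 10 so it stays includable at any SER threshold
#' up to 2.  When numerator and denominator are both degenerate the voxel
#' is NA (invalid).
#'
#' @param exam a [DceExam-class].
#' @return 3D numeric array of SER values.
#' @export
computeSER <- function(exam) {
  stopifnot(is(exam, "DceExam"))
  eps <- 1e-6 * diff(range(exam@s0))
  num <- exam@s1 - exam@s0
  den <- exam@s2 - exam@s0
  ser <- array(NA_real_, dim(exam@s0))
  ok <- den > eps
  ser[ok] <- num[ok] / den[ok]
  capped <- !ok & num > eps
  ser[capped] <- SER_CAP
  ser
}

#' Compute PE/SER maps with validity mask
#'
#' Runs the background mask, PE and SER computations for one examination
#' and combines them into an [EnhancementMaps-class].  A voxel is valid
#' when it is above the background threshold and its enhancement is
#' non-degenerate (not both numerator and denominator at baseline).
#'
#' @param exam a [DceExam-class].
#' @return An [EnhancementMaps-class].
#' @examples
#' a <- array(c(5, 100), c(4, 4, 2))
#' ex <- DceExam(a, a * 2, a * 1.5, c(1, 1, 1))
#' maps <- enhancementMaps(ex)
#' @export
enhancementMaps <- function(exam) {
  stopifnot(is(exam, "DceExam"))
  tissue <- backgroundMask(exam@s0)
  eps <- 1e-6 * diff(range(exam@s0))
  num <- exam@s1 - exam@s0
  den <- exam@s2 - exam@s0
  valid <- tissue & !(num <= eps & den <= eps)
  pe <- array(NA_real_, dim(exam@s0))
  pe[valid] <- 100 * num[valid] / exam@s0[valid]
  ser <- array(NA_real_, dim(exam@s0))
  ok <- valid & den > eps
  ser[ok] <- num[ok] / den[ok]
  capped <- valid & den <= eps
  ser[capped] <- SER_CAP
  new("EnhancementMaps", pe = pe, ser = ser, valid = valid,
      spacing = exam@spacing)
}

#' Maximum intensity projection
#'
#' Projects a volume (by default the early post-contrast phase, on which
#' ROI boxes are drawn) along one axis, taking the per-ray maximum.
#'
#' @param vol 3D numeric array.
#' @param axis projection axis (1, 2 or 3).
#' @return 2D matrix over the two remaining axes, in ascending axis order.
#' @export
mipImage <- function(vol, axis) {
  stopifnot(length(dim(vol)) == 3L, axis %in% 1:3)
  apply(vol, setdiff(1:3, axis), max)
}

#' A rectangular box drawn on a maximum intensity projection
#'
#' @param axis the projection axis (1..3) the box was drawn on.
#' @param lo,hi integer(2): inclusive/exclusive corners (0-based) in the
#'   projected plane, whose axes are the remaining volume axes in
#'   ascending order.
#' @return A list of class "mipBox".
#' @export
mipBox <- function(axis, lo, hi) {
  axis <- as.integer(axis)
  lo <- as.integer(lo); hi <- as.integer(hi)
  stopifnot(axis %in% 1:3, length(lo) == 2L, length(hi) == 2L,
            all(lo >= 0L), all(hi > lo))
  structure(list(axis = axis, lo = lo, hi = hi), class = "mipBox")
}

#' 3D ROI from two orthogonal MIP boxes
#'
#' Back-projects two rectangles drawn on orthogonal maximum intensity
#' projections into the axis-aligned 3D box consistent with both.  Each
#' volume axis takes its extent from whichever rectangle constrains it;
#' the axis seen by both rectangles uses the intersection of the two
#' ranges.
#'
#' @param boxA,boxB [mipBox()] objects with distinct projection axes.
#' @param dim optional integer(3) grid dimensions for bounds checking.
#' @return A [RoiBox-class].
#' @examples
#' a <- mipBox(1, lo = c(2, 0), hi = c(8, 4))   # constrains axes 2 and 3
#' b <- mipBox(3, lo = c(1, 2), hi = c(6, 8))   # constrains axes 1 and 2
#' roiFromMipBoxes(a, b)
#' @export
roiFromMipBoxes <- function(boxA, boxB, dim = NULL) {
  stopifnot(inherits(boxA, "mipBox"), inherits(boxB, "mipBox"))
  if (boxA$axis == boxB$axis)
    stop("the two MIP boxes must be drawn on different projection axes")
  lo <- rep(NA_integer_, 3L)
  hi <- rep(NA_integer_, 3L)
  for (box in list(boxA, boxB)) {
    plane <- setdiff(1:3, box$axis)
    for (k in 1:2) {
      ax <- plane[k]
      lo[ax] <- if (is.na(lo[ax])) box$lo[k] else max(lo[ax], box$lo[k])
      hi[ax] <- if (is.na(hi[ax])) box$hi[k] else min(hi[ax], box$hi[k])
    }
  }
  if (any(hi <= lo))
    stop("MIP boxes do not intersect on their shared axis")
  if (!is.null(dim) && any(hi > dim))
    stop("ROI box exceeds the volume bounds")
  RoiBox(lo, hi)
}

#' Write / read ROI sidecar files
#'
#' ROI boxes travel alongside the imaging as a small JSON sidecar with
#' fields patient, timepoint, lo and hi (0-based, half-open voxel indices).
#'
#' @param roi a [RoiBox-class].
#' @param patient,timepoint identifiers stored with the box.
#' @param path file path.
#' @return `readRoiSidecar` returns a list with elements `patient`,
#'   `timepoint` and `roi` (a [RoiBox-class]).
#' @export
writeRoiSidecar <- function(roi, patient, timepoint, path) {
  stopifnot(is(roi, "RoiBox"))
  jsonlite::write_json(
    list(patient = patient, timepoint = timepoint,
         lo = roi@lo, hi = roi@hi),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeRoiSidecar
#' @export
readRoiSidecar <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(patient = x$patient, timepoint = x$timepoint,
       roi = RoiBox(x$lo, x$hi))
}
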