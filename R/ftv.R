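# Functional tumor volume under a (PE_t, SER_t) threshold pair, with the
# connected-component constraint, and percent-change trajectories.

#' The PE/SER threshold grid
#'
#' Ordered grid of threshold pairs swept by the optimization: PE threshold
#' from 30% to 200% in steps of 10% and SER threshold from 0 to 2 in steps
#' of 0.2 (198 pairs), row-major with PE outermost.
#'
#' @param pe,ser numeric vectors of grid levels (defaults are the standard
#'   sweep ranges).
#' @return data.frame with columns `pe_t` and `ser_t`.
#' @examples
#' g <- thresholdGrid()
#' nrow(g)      # 198
#' g[1, ]       # PEt 30, SERt 0
#' @export
thresholdGrid <- function(pe = seq(30, 200, by = 10),
                          ser = seq(0, 2, by = 0.2)) {
  # round away sequence arithmetic fuzz so grid levels compare exactly
  pe <- round(pe, 10)
  ser <- round(ser, 10)
  stopifnot(all(pe > 0), all(ser >= 0))
  data.frame(pe_t = rep(pe, each = length(ser)),
             ser_t = rep(ser, times = length(pe)))
}

roiMask <- function(roi, dim) {
  m <- array(FALSE, dim)
  m[(roi@lo[1] + 1L):roi@hi[1],
    (roi@lo[2] + 1L):roi@hi[2],
    (roi@lo[3] + 1L):roi@hi[3]] <- TRUE
  m
}

#' Enhancing-tissue mask at a PE threshold
#'
#' TRUE exactly where a voxel lies inside the ROI, is valid, and its
#' percent enhancement meets the threshold (PE >= pe_t).
#'
#' @param maps an [EnhancementMaps-class].
#' @param roi a [RoiBox-class].
#' @param pe_t PE threshold in percent.
#' @return 3D logical array.
#' @export
peMask <- function(maps, roi, pe_t) {
  stopifnot(is(maps, "EnhancementMaps"), is(roi, "RoiBox"))
  d <- dim(maps@pe)
  if (any(roi@hi > d)) stop("ROI box exceeds the map bounds")
  m <- roiMask(roi, d) & maps@valid
  m[m] <- maps@pe[m] >= pe_t
  m
}

neighborOffsets <- function(neighborhood) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  keep <- switch(as.character(neighborhood),
    "6"  = rowSums(abs(off)) == 1,
    "18" = rowSums(abs(off)) <= 2,
    "26" = rep(TRUE, nrow(off)),
    stop("neighborhood must be 6, 18 or 26"))
  off[keep, , drop = FALSE]
}

#' Minimum-cluster-size connectivity filter
#'
#' Keeps exactly the voxels belonging to connected components of at least
#' `minVoxels` voxels under the chosen 3D neighborhood, eliminating
#' isolated enhancing voxels.  The output mask is a subset of the input.
#'
#' @param mask 3D logical array.
#' @param minVoxels minimum component size to retain (>= 1).
#' @param neighborhood 6, 18 or 26 (face, face+edge, full adjacency).
#' @return 3D logical array.
#' @examples
#' m <- array(FALSE, c(8, 8, 1)); m[1:5, 1, 1] <- TRUE; m[8, 8, 1] <- TRUE
#' sum(connectivityFilter(m, minVoxels = 5))  # the isolated voxel is gone
#' @export
connectivityFilter <- function(mask, minVoxels = 5L, neighborhood = 26L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L, minVoxels >= 1L)
  if (minVoxels == 1L || !any(mask)) return(mask)
  d <- dim(mask)
  idx <- which(mask)
  co <- arrayInd(idx, d)
  key <- (co[, 1] - 1) + (co[, 2] - 1) * d[1] + (co[, 3] - 1) * d[1] * d[2]
  off <- neighborOffsets(neighborhood)
  # each unordered neighbor pair once
  off <- off[off[, 3] > 0 | (off[, 3] == 0 & off[, 2] > 0) |
             (off[, 3] == 0 & off[, 2] == 0 & off[, 1] > 0), , drop = FALSE]
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(off))) {
    nb <- co + rep(off[r, ], each = nrow(co))
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
          nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    nkey <- (nb[ok, 1] - 1) + (nb[ok, 2] - 1) * d[1] +
            (nb[ok, 3] - 1) * d[1] * d[2]
    j <- match(nkey, key)
    hit <- !is.na(j)
    from <- c(from, which(ok)[hit])
    to <- c(to, j[hit])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to))
  comp <- igraph::components(g)
  keep <- comp$csize[comp$membership] >= minVoxels
  out <- array(FALSE, d)
  out[idx[keep]] <- TRUE
  out
}

#' Functional tumor volume at one threshold pair
#'
#' Applies the measurement pipeline in its canonical order: PE threshold
#' inside the ROI, then the connectivity test, then the SER threshold
#' (SER >= ser_t) on the surviving mask.  The SER cut does not retrigger
#' the connectivity test.  FTV is the surviving voxel count times the
#' voxel volume, in cubic centimetres.
#'
#' @param maps an [EnhancementMaps-class].
#' @param roi a [RoiBox-class].
#' @param pe_t,ser_t the threshold pair (percent; dimensionless).
#' @param minVoxels,neighborhood connectivity constraint parameters.
#' @param patientId,timepoint identifiers carried into the result.
#' @return A list of class "FtvMeasurement": `patient_id`, `timepoint`,
#'   `pe_t`, `ser_t`, `n_voxels`, `ftv_cc`.
#' @export
computeFTV <- function(maps, roi, pe_t = 70, ser_t = 0,
                       minVoxels = 5L, neighborhood = 26L,
                       patientId = "anon", timepoint = 1L) {
  m <- peMask(maps, roi, pe_t)
  m <- connectivityFilter(m, minVoxels, neighborhood)
  m[m] <- maps@ser[m] >= ser_t
  n <- sum(m)
  structure(
    list(patient_id = patientId, timepoint = as.integer(timepoint),
         pe_t = pe_t, ser_t = ser_t, n_voxels = n,
         ftv_cc = n * prod(maps@spacing) / 1000),
    class = "FtvMeasurement")
}

#' FTV sweep over the whole threshold grid for one exam
#'
#' Evaluates [computeFTV()] at every grid cell, sharing the PE mask and
#' connectivity filtering across SER levels (the connectivity test depends
#' only on the PE threshold).
#'
#' @inheritParams computeFTV
#' @param grid data.frame from [thresholdGrid()].
#' @return `grid` with columns `n_voxels` and `ftv_cc` appended.
#' @export
ftvSweep <- function(maps, roi, grid = thresholdGrid(),
                     minVoxels = 5L, neighborhood = 26L) {
  voxcc <- prod(maps@spacing) / 1000
  n <- integer(nrow(grid))
  for (pe in unique(grid$pe_t)) {
    rows <- which(grid$pe_t == pe)
    m <- connectivityFilter(peMask(maps, roi, pe), minVoxels, neighborhood)
    serv <- sort(maps@ser[m])
    # voxels with SER >= s, via one sorted vector per PE level
    n[rows] <- length(serv) -
      findInterval(grid$ser_t[rows], serv, left.open = TRUE)
  }
  cbind(grid, n_voxels = n, ftv_cc = n * voxcc)
}

#' Percent change in FTV relative to baseline
#'
#' dFTV_n = 100 (FTV_n - FTV_1) / FTV_1 for n in 2..4.  Patients with
#' FTV_1 = 0 have no defined percent change and are excluded from dFTV
#' analyses (`defined = FALSE`).
#'
#' @param ftvN,ftv1 "FtvMeasurement" results for timepoint n and baseline,
#'   same patient and same thresholds.
#' @return A list of class "DeltaFtv": `patient_id`, `timepoint`, `value`
#'   (percent, NA when undefined), `defined`.
#' @examples
#' m1 <- structure(list(patient_id = "P", timepoint = 1L, pe_t = 70,
#'                      ser_t = 0, n_voxels = 531L, ftv_cc = 5.31),
#'                 class = "FtvMeasurement")
#' m2 <- m1; m2$timepoint <- 2L; m2$ftv_cc <- 5.13
#' deltaFtv(m2, m1)$value   # -3.39
#' @export
deltaFtv <- function(ftvN, ftv1) {
  stopifnot(inherits(ftvN, "FtvMeasurement"), inherits(ftv1, "FtvMeasurement"))
  if (ftvN$patient_id != ftv1$patient_id)
    stop("percent change requires measurements from the same patient")
  if (ftv1$timepoint != 1L)
    stop("the reference measurement must be baseline (timepoint 1)")
  if (ftvN$pe_t != ftv1$pe_t || ftvN$ser_t != ftv1$ser_t)
    stop("percent change requires identical thresholds at both timepoints")
  defined <- ftv1$ftv_cc > 0
  structure(
    list(patient_id = ftvN$patient_id, timepoint = ftvN$timepoint,
         value = if (defined)
           100 * (ftvN$ftv_cc - ftv1$ftv_cc) / ftv1$ftv_cc else NA_real_,
         defined = defined),
    class = "DeltaFtv")
}
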