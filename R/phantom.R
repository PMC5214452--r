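# Synthetic three-phase DCE phantoms with known voxelwise kinetics.
#
# The generator inverts the enhancement definitions: after drawing a voxel's
# (PE, SER) it synthesizes S1 = S0 (1 + PE/100) and S2 = S0 + (S1 - S0)/SER,
# so the analysis maps recover the drawn values exactly at zero noise.

#' A kinetic compartment of tumor voxels
#'
#' One mixture component of voxelwise contrast kinetics: a fraction of the
#' tumor's voxels whose PE (percent) and SER (dimensionless) are drawn from
#' independent normals truncated to positive values.  Typical compartments
#' mirror the classic SER color bins: washout (SER well above 1), plateau
#' (SER near 1) and persistent enhancement (SER below 1).
#'
#' @param label compartment name.
#' @param fraction proportion of tumor voxels in \[0, 1\].
#' @param peMean,peSd PE distribution parameters, percent.
#' @param serMean,serSd SER distribution parameters, dimensionless.
#' @return A list of class "KineticCompartment".
#' @export
kineticCompartment <- function(label, fraction, peMean, peSd, serMean, serSd) {
  stopifnot(fraction >= 0, fraction <= 1, peSd >= 0, serSd >= 0)
  structure(list(label = label, fraction = fraction,
                 peMean = peMean, peSd = peSd,
                 serMean = serMean, serSd = serSd),
            class = "KineticCompartment")
}

defaultCompartments <- function() {
  list(
    kineticCompartment("washout",    0.55, peMean = 180, peSd = 30,
                       serMean = 1.6, serSd = 0.20),
    kineticCompartment("plateau",    0.30, peMean = 140, peSd = 30,
                       serMean = 1.0, serSd = 0.10),
    kineticCompartment("persistent", 0.15, peMean = 100, peSd = 25,
                       serMean = 0.6, serSd = 0.10))
}

#' Specification of a DCE phantom
#'
#' Geometry and intensity model of a synthetic breast examination: an air
#' background, a suppressed-fat shell, an enhancing parenchyma ellipsoid
#' (background parenchymal enhancement) and an ellipsoidal tumor whose
#' voxels follow the compartment kinetics.  The tumor volume is analytic
#' (axis-aligned ellipsoid), so FTV has a closed form for cross-checks.
#'
#' @param gridShape integer(3) voxel counts per axis.
#' @param spacingMm numeric(3) voxel spacing in mm.
#' @param tumorCenter voxel coordinates of the tumor center (1-based,
#'   defaults to the grid center).
#' @param tumorRadiiMm numeric(3) tumor semi-axes in mm.
#' @param compartments list of [kineticCompartment()]; fractions must sum
#'   to 1.
#' @param bpeLevel mean parenchymal PE in percent.
#' @param fatIntensity,airIntensity pre-contrast signal of suppressed fat
#'   and air (arbitrary units; air must be darker than fat).
#' @param tissueS0 pre-contrast signal of parenchyma and tumor.
#' @param parenchymaRadiiMm,outerRadiiMm semi-axes of the parenchyma
#'   ellipsoid and of the outer (fat) ellipsoid; defaults scale with the
#'   field of view.
#' @param noiseSd additive Gaussian noise SD applied to each phase.
#' @param seed integer RNG seed; generation is bit-reproducible given
#'   (spec, seed).
#' @return A list of class "PhantomSpec".
#' @examples
#' spec <- phantomSpec(gridShape = c(32, 32, 16), noiseSd = 0)
#' @export
phantomSpec <- function(gridShape = c(64, 64, 32),
                        spacingMm = c(1, 1, 2.5),
                        tumorCenter = NULL,
                        tumorRadiiMm = c(12, 12, 12),
                        compartments = defaultCompartments(),
                        bpeLevel = 40,
                        fatIntensity = 60,
                        airIntensity = 5,
                        tissueS0 = 300,
                        parenchymaRadiiMm = NULL,
                        outerRadiiMm = NULL,
                        noiseSd = 5,
                        seed = 1L) {
  gridShape <- as.integer(gridShape)
  stopifnot(length(gridShape) == 3L, all(gridShape >= 4L),
            length(spacingMm) == 3L, all(spacingMm > 0),
            noiseSd >= 0, airIntensity < fatIntensity,
            all(tumorRadiiMm > 0))
  fr <- vapply(compartments, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-8)
    stop("compartment fractions must sum to 1")
  fov <- gridShape * spacingMm
  if (is.null(tumorCenter)) tumorCenter <- (gridShape + 1) / 2
  if (is.null(parenchymaRadiiMm)) parenchymaRadiiMm <- 0.30 * fov
  if (is.null(outerRadiiMm)) outerRadiiMm <- 0.45 * fov
  # the tumor must fit inside the grid
  cmm <- (tumorCenter - 0.5) * spacingMm
  if (any(cmm - tumorRadiiMm < 0) || any(cmm + tumorRadiiMm > fov))
    stop("tumor radii exceed the grid")
  structure(list(gridShape = gridShape, spacingMm = spacingMm,
                 tumorCenter = tumorCenter, tumorRadiiMm = tumorRadiiMm,
                 compartments = compartments, bpeLevel = bpeLevel,
                 fatIntensity = fatIntensity, airIntensity = airIntensity,
                 tissueS0 = tissueS0,
                 parenchymaRadiiMm = parenchymaRadiiMm,
                 outerRadiiMm = outerRadiiMm,
                 noiseSd = noiseSd, seed = as.integer(seed)),
            class = "PhantomSpec")
}

# TRUE inside the axis-aligned ellipsoid (center in voxel coords, radii mm).
ellipsoidMask <- function(gridShape, spacingMm, center, radiiMm) {
  ax <- lapply(1:3, function(a)
    (((seq_len(gridShape[a]) - center[a]) * spacingMm[a]) / radiiMm[a])^2)
  d2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  d2 <= 1
}

# Parenchymal kinetics: persistent enhancement at the BPE level.
parenchymaCompartment <- function(spec) {
  kineticCompartment("parenchyma", 1,
                     peMean = spec$bpeLevel, peSd = 0.25 * spec$bpeLevel,
                     serMean = 0.55, serSd = 0.12)
}

#' Generate one synthetic DCE examination
#'
#' Renders the phantom at one MRI timepoint.  `responseFraction` scales the
#' tumor volume at this timepoint (1 = baseline size, 0 = tumor resolved);
#' radii scale with its cube root.  Tumor and parenchyma voxels draw
#' (PE, SER) from their compartments, the three phases are synthesized by
#' inverting the PE/SER definitions, and Gaussian noise is added to each
#' phase.
#'
#' @param spec a [phantomSpec()].
#' @param timepoint MRI timepoint 1..4.
#' @param responseFraction tumor volume fraction remaining, in \[0, 1\].
#' @param patientId identifier stored in the exam.
#' @return A list with elements `exam` (a [DceExam-class]) and `truth`
#'   (class "PhantomTruth"): drawn PE/SER values at tumor and parenchyma
#'   voxels, voxel index sets, compartment assignments and the spec --
#'   everything needed for closed-form FTV cross-checks via
#'   [ftvClosedForm()].
#' @examples
#' g <- generatePhantomExam(phantomSpec(gridShape = c(24, 24, 12),
#'                                      tumorRadiiMm = c(6, 6, 6),
#'                                      noiseSd = 0))
#' @export
generatePhantomExam <- function(spec, timepoint = 1L, responseFraction = 1,
                                patientId = "phantom") {
  stopifnot(inherits(spec, "PhantomSpec"),
            responseFraction >= 0, responseFraction <= 1)
  timepoint <- as.integer(timepoint)
  stopifnot(timepoint >= 1L, timepoint <= 4L)
  withSeed(spec$seed + 7919L * timepoint, {
    d <- spec$gridShape
    n <- prod(d)
    outer_m <- ellipsoidMask(d, spec$spacingMm, (d + 1) / 2,
                             spec$outerRadiiMm)
    paren_m <- ellipsoidMask(d, spec$spacingMm, (d + 1) / 2,
                             spec$parenchymaRadiiMm)
    radii <- spec$tumorRadiiMm * responseFraction^(1 / 3)
    tumor_m <- if (responseFraction > 0)
      ellipsoidMask(d, spec$spacingMm, spec$tumorCenter, radii)
    else array(FALSE, d)
    fat_m <- outer_m & !paren_m
    air_m <- !outer_m
    paren_only <- paren_m & !tumor_m

    s0 <- array(0, d)
    s0[air_m] <- spec$airIntensity
    s0[fat_m] <- spec$fatIntensity
    s0[paren_m] <- spec$tissueS0
    pe <- array(0, d)          # drawn PE; 0 = non-enhancing
    ser <- array(NA_real_, d)  # drawn SER; NA = non-enhancing
    compartment <- array(NA_integer_, d)

    drawKinetics <- function(idx, comps) {
      if (!length(idx)) return(integer(0))
      fr <- vapply(comps, `[[`, numeric(1), "fraction")
      k <- sample.int(length(comps), length(idx), replace = TRUE, prob = fr)
      for (j in seq_along(comps)) {
        sel <- idx[k == j]
        if (!length(sel)) next
        pe[sel] <<- rtruncnorm0(length(sel), comps[[j]]$peMean,
                                comps[[j]]$peSd)
        ser[sel] <<- rtruncnorm0(length(sel), comps[[j]]$serMean,
                                 comps[[j]]$serSd)
      }
      k
    }
    pidx <- which(paren_only)
    drawKinetics(pidx, list(parenchymaCompartment(spec)))
    tidx <- which(tumor_m)
    tcomp <- drawKinetics(tidx, spec$compartments)
    compartment[tidx] <- tcomp

    enh <- which(!is.na(ser))
    s1 <- s0
    s2 <- s0
    s1[enh] <- s0[enh] * (1 + pe[enh] / 100)
    s2[enh] <- s0[enh] + (s1[enh] - s0[enh]) / ser[enh]
    if (spec$noiseSd > 0) {
      s0 <- s0 + array(rnorm(n, 0, spec$noiseSd), d)
      s1 <- s1 + array(rnorm(n, 0, spec$noiseSd), d)
      s2 <- s2 + array(rnorm(n, 0, spec$noiseSd), d)
    }
    exam <- DceExam(s0, s1, s2, spec$spacingMm, timepoint, patientId)
    truth <- structure(
      list(spec = spec, timepoint = timepoint,
           responseFraction = responseFraction,
           tumorIdx = tidx, tumorCompartment = tcomp,
           parenchymaIdx = pidx,
           peDrawn = pe, serDrawn = ser,
           tumorMask = tumor_m, parenchymaMask = paren_only),
      class = "PhantomTruth")
    list(exam = exam, truth = truth)
  })
}

#' Closed-form expected FTV of a rendered phantom
#'
#' Expected FTV inside an ROI at thresholds (pe_t, ser_t), from the
#' generative model: for each compartment, (voxels of that compartment in
#' the ROI) x P(PE >= pe_t) x P(SER >= ser_t) under its truncated-normal
#' kinetics, summed over tumor compartments and parenchyma, times the
#' voxel volume.  The connectivity constraint is not part of the closed
#' form; compare against voxel counts obtained with `minVoxels = 1`.
#'
#' @param truth "PhantomTruth" from [generatePhantomExam()].
#' @param roi a [RoiBox-class].
#' @param pe_t,ser_t thresholds.
#' @return A list: `ftv_cc` (expectation), `var_cc2` (binomial variance of
#'   the voxel-counted FTV, in cc^2), `n_expected`.
#' @export
ftvClosedForm <- function(truth, roi, pe_t, ser_t) {
  stopifnot(inherits(truth, "PhantomTruth"), is(roi, "RoiBox"))
  spec <- truth$spec
  inroi <- roiMask(roi, spec$gridShape)
  voxcc <- prod(spec$spacingMm) / 1000
  mu <- 0
  v <- 0
  addComp <- function(nvox, comp) {
    p <- truncnormTail(pe_t, comp$peMean, comp$peSd) *
         truncnormTail(ser_t, comp$serMean, comp$serSd)
    mu <<- mu + nvox * p
    v <<- v + nvox * p * (1 - p)
  }
  for (j in seq_along(spec$compartments)) {
    nvox <- sum(inroi[truth$tumorIdx][truth$tumorCompartment == j])
    addComp(nvox, spec$compartments[[j]])
  }
  addComp(sum(inroi[truth$parenchymaIdx]), parenchymaCompartment(spec))
  list(ftv_cc = mu * voxcc, var_cc2 = v * voxcc^2, n_expected = mu)
}

#' Tight ROI around the phantom tumor
#'
#' Bounding box of the ground-truth tumor mask, expanded by a margin --
#' the programmatic stand-in for the manually drawn MIP boxes.
#'
#' @param truth "PhantomTruth".
#' @param marginVoxels margin added on every side.
#' @return A [RoiBox-class].
#' @export
tumorRoi <- function(truth, marginVoxels = 2L) {
  stopifnot(inherits(truth, "PhantomTruth"))
  d <- truth$spec$gridShape
  if (!length(truth$tumorIdx))
    return(RoiBox(c(0, 0, 0), d))
  co <- arrayInd(truth$tumorIdx, d)
  lo <- pmax(apply(co, 2, min) - 1L - marginVoxels, 0L)
  hi <- pmin(apply(co, 2, max) + marginVoxels, d)
  RoiBox(lo, hi)
}

#' Write / read a DceExam as NIfTI
#'
#' One file per phase (`<patient>_tp<k>_s0.nii.gz` etc.), with the voxel
#' spacing carried in the NIfTI header.
#'
#' @param exam a [DceExam-class].
#' @param dir output directory (created if needed).
#' @return `writeDceExam` returns the three file paths invisibly;
#'   `readDceExam` returns a [DceExam-class].
#' @export
writeDceExam <- function(exam, dir) {
  stopifnot(is(exam, "DceExam"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- file.path(dir, sprintf("%s_tp%d", exam@patientId, exam@timepoint))
  paths <- paste0(stem, "_s", 0:2, ".nii.gz")
  vols <- list(exam@s0, exam@s1, exam@s2)
  for (i in 1:3) {
    im <- RNifti::asNifti(vols[[i]])
    RNifti::pixdim(im) <- exam@spacing
    RNifti::writeNifti(im, paths[i])
  }
  invisible(paths)
}

#' @rdname writeDceExam
#' @param patientId,timepoint identifiers naming the files to read.
#' @export
readDceExam <- function(dir, patientId, timepoint) {
  stem <- file.path(dir, sprintf("%s_tp%d", patientId, timepoint))
  paths <- paste0(stem, "_s", 0:2, ".nii.gz")
  if (!all(file.exists(paths)))
    stop("missing phase volume(s): ", paste(paths[!file.exists(paths)],
                                            collapse = ", "))
  vols <- lapply(paths, RNifti::readNifti)
  spacing <- RNifti::pixdim(vols[[1]])[1:3]
  DceExam(array(as.numeric(vols[[1]]), dim(vols[[1]])),
          array(as.numeric(vols[[2]]), dim(vols[[2]])),
          array(as.numeric(vols[[3]]), dim(vols[[3]])),
          spacing, timepoint, patientId)
}
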