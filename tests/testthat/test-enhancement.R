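# PE/SER maps, background masking and MIP-box ROIs.

makeExam <- function(s0, s1, s2, spacing = c(1, 1, 1)) {
  DceExam(s0, s1, s2, spacing, timepoint = 1, patientId = "T")
}

test_that("PE and SER follow their defining formulas on tissue voxels", {
  d <- c(4, 4, 2)
  s0 <- array(rep(c(5, 100), each = 16), d)   # air slab + tissue slab
  s1 <- s0; s2 <- s0
  tissue <- s0 == 100
  s1[tissue] <- 200
  s2[tissue] <- 150
  maps <- enhancementMaps(makeExam(s0, s1, s2))
  expect_true(all(maps@valid[tissue]))
  expect_equal(unique(maps@pe[tissue]), 100)
  expect_equal(unique(maps@ser[tissue]), 2)
  # air voxels are invalid and excluded
  expect_false(any(maps@valid[!tissue]))
  # standalone PE map: no enhancement means PE = 0
  s1b <- s0
  pe <- computePE(makeExam(s0, s1b, s2))
  expect_equal(unique(pe[tissue]), 0)
})

test_that("SER capping keeps strong-washout voxels includable", {
  d <- c(4, 4, 2)
  s0 <- array(rep(c(5, 100), each = 16), d)
  tissue <- s0 == 100
  s1 <- s0; s2 <- s0
  s1[tissue] <- 180
  s2[tissue] <- 100     # late signal back at baseline: denominator zero
  maps <- enhancementMaps(makeExam(s0, s1, s2))
  expect_true(all(maps@valid[tissue]))
  expect_equal(unique(maps@ser[tissue]), 10)
  # cap exceeds any SER threshold on the standard grid
  expect_true(all(unique(maps@ser[tissue]) >= 2))
})

test_that("PE and SER are invariant under global intensity rescaling", {
  set.seed(41)
  d <- c(6, 6, 3)
  s0 <- array(rep(c(8, 300), prod(d) / 2) + runif(prod(d), 0, 4), d)
  s1 <- s0 * (1 + runif(prod(d), 0, 2))
  s2 <- s0 + (s1 - s0) / runif(prod(d), 0.3, 2.5)
  m1 <- enhancementMaps(makeExam(s0, s1, s2))
  for (c in c(0.25, 7)) {
    m2 <- enhancementMaps(makeExam(c * s0, c * s1, c * s2))
    expect_equal(m2@valid, m1@valid)
    expect_equal(m2@pe[m2@valid], m1@pe[m1@valid], tolerance = 1e-12)
    expect_equal(m2@ser[m2@valid], m1@ser[m1@valid], tolerance = 1e-12)
  }
})

test_that("automatic background threshold matches exhaustive Otsu", {
  # bimodal toy: mask must select exactly the bright half
  x <- array(rep(c(10, 1000), each = 32), c(4, 4, 4))
  thr <- otsuThreshold(x)
  expect_gt(thr, 10)
  expect_lt(thr, 1000)
  expect_equal(backgroundMask(x), array(x == 1000, dim(x)))

  # single tissue voxel among air
  y <- array(10, c(4, 4, 4)); y[2, 3, 1] <- 1000
  m <- backgroundMask(y)
  expect_true(m[2, 3, 1])
  expect_equal(sum(m), 1L)

  # random two-population volumes agree with the brute-force oracle mask
  set.seed(11)
  for (i in 1:5) {
    v <- array(c(rnorm(40, 10, 2), rnorm(24, 800, 50)), c(4, 4, 4))
    expect_equal(backgroundMask(v), bruteOtsuMask(v))
  }
})

test_that("constant volume yields an all-true mask with a warning", {
  x <- array(7, c(3, 3, 2))
  expect_warning(m <- backgroundMask(x), "constant")
  expect_true(all(m))
})

test_that("valid mask never includes sub-threshold voxels", {
  set.seed(12)
  g <- generatePhantomExam(smallPhantom(seed = 12, noiseSd = 8))
  maps <- enhancementMaps(g$exam)
  thr <- otsuThreshold(g$exam@s0)
  expect_false(any(maps@valid[g$exam@s0 <= thr]))
})

test_that("MIP boxes back-project to the correct 3D box", {
  d <- c(8, 7, 6)
  set.seed(13)
  vol <- array(runif(prod(d)), d)
  for (i in 1:20) {
    axes <- sample(1:3, 2)
    pick <- function(v) v[sample.int(length(v), 1)]
    rand2 <- function(ax) {
      pl <- setdiff(1:3, ax)
      lo <- c(pick(0:(d[pl[1]] - 1)), pick(0:(d[pl[2]] - 1)))
      hi <- c(pick((lo[1] + 1):d[pl[1]]), pick((lo[2] + 1):d[pl[2]]))
      mipBox(ax, lo, hi)
    }
    a <- rand2(axes[1]); b <- rand2(axes[2])
    inBox <- function(box, co) {
      pl <- setdiff(1:3, box$axis)
      co[, pl[1]] >= box$lo[1] + 1 & co[, pl[1]] <= box$hi[1] &
        co[, pl[2]] >= box$lo[2] + 1 & co[, pl[2]] <= box$hi[2]
    }
    co <- arrayInd(seq_len(prod(d)), d)
    hit <- inBox(a, co) & inBox(b, co)
    if (!any(hit)) {
      expect_error(roiFromMipBoxes(a, b, d), "intersect")
    } else {
      roi <- roiFromMipBoxes(a, b, d)
      bb_lo <- apply(co[hit, , drop = FALSE], 2, min) - 1L
      bb_hi <- apply(co[hit, , drop = FALSE], 2, max)
      expect_equal(unname(roi@lo), unname(bb_lo))
      expect_equal(unname(roi@hi), unname(bb_hi))
    }
  }
})

test_that("full-image rectangles give the whole volume; errors are raised", {
  d <- c(8, 7, 6)
  a <- mipBox(1, c(0, 0), d[2:3])
  b <- mipBox(3, c(0, 0), d[1:2])
  roi <- roiFromMipBoxes(a, b, d)
  expect_equal(roi@lo, c(0L, 0L, 0L))
  expect_equal(roi@hi, as.integer(d))
  expect_error(roiFromMipBoxes(a, mipBox(1, c(0, 0), c(2, 2))),
               "different projection axes")
  # disjoint ranges on the shared axis (axis 2 here)
  a2 <- mipBox(1, c(0, 0), c(3, 6))    # axis 2 in [0, 3)
  b2 <- mipBox(3, c(0, 4), c(8, 7))    # axis 2 in [4, 7)
  expect_error(roiFromMipBoxes(a2, b2, d), "intersect")
})

test_that("ROI sidecars round-trip through JSON", {
  roi <- RoiBox(c(1, 2, 0), c(5, 6, 3))
  p <- tempfile(fileext = ".json")
  writeRoiSidecar(roi, "P1", 2, p)
  back <- readRoiSidecar(p)
  expect_equal(back$patient, "P1")
  expect_equal(back$timepoint, 2L)
  expect_equal(back$roi@lo, roi@lo)
  expect_equal(back$roi@hi, roi@hi)
})
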