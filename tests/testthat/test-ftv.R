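# FTV measurement: threshold grid, PE masking, connectivity, volumes,
# percent change.

test_that("the threshold grid spans the standard sweep in order", {
  g <- thresholdGrid()
  expect_equal(nrow(g), 198L)
  expect_equal(unlist(g[1, ]), c(pe_t = 30, ser_t = 0))
  expect_equal(unlist(g[nrow(g), ]), c(pe_t = 200, ser_t = 2))
  expect_equal(length(unique(g$pe_t)), 18L)
  expect_equal(length(unique(g$ser_t)), 11L)
})

test_that("peMask selects exactly the in-ROI voxels at the threshold", {
  pe <- array(0, c(4, 4, 1))
  hot <- rbind(c(1, 1, 1), c(2, 3, 1), c(3, 3, 1), c(4, 2, 1), c(2, 1, 1))
  pe[hot] <- c(70, 80, 90, 100, 71)
  pe[1, 4, 1] <- 69.9   # just below
  maps <- toyMaps(pe)
  m <- peMask(maps, RoiBox(c(0, 0, 0), c(4, 4, 1)), 70)
  expect_equal(sum(m), 5L)
  expect_true(all(m[hot]))
  # threshold above every value: empty
  expect_equal(sum(peMask(maps, RoiBox(c(0, 0, 0), c(4, 4, 1)), 200)), 0L)
  # ROI restriction and uniform pass
  pe2 <- array(100, c(4, 4, 1))
  m2 <- peMask(toyMaps(pe2), RoiBox(c(1, 1, 0), c(3, 3, 1)), 70)
  expect_equal(sum(m2), 4L)
  # invalid voxels never pass
  v <- array(TRUE, c(4, 4, 1)); v[2, 3, 1] <- FALSE
  m3 <- peMask(toyMaps(pe, valid = v), RoiBox(c(0, 0, 0), c(4, 4, 1)), 70)
  expect_false(m3[2, 3, 1])
  expect_equal(sum(m3), 4L)
})

test_that("connectivity filter drops small components and keeps large ones", {
  m <- array(FALSE, c(8, 8, 2))
  m[2:6, 2, 1] <- TRUE          # straight run of 5, face-adjacent
  m[8, 8, 2] <- TRUE            # isolated voxel
  f <- connectivityFilter(m, minVoxels = 5, neighborhood = 6)
  expect_equal(sum(f), 5L)
  expect_true(all(f[2:6, 2, 1]))
  expect_false(f[8, 8, 2])
  # single isolated voxel, minVoxels = 5: empty
  m1 <- array(FALSE, c(4, 4, 1)); m1[2, 2, 1] <- TRUE
  expect_equal(sum(connectivityFilter(m1, 5, 26)), 0L)
})

test_that("corner-touching voxels connect under 26- but not 6-adjacency", {
  m <- array(FALSE, c(4, 4, 4))
  m[2, 2, 2] <- TRUE
  m[3, 3, 3] <- TRUE            # corner neighbor
  expect_equal(sum(connectivityFilter(m, 2, 26)), 2L)   # one component
  expect_equal(sum(connectivityFilter(m, 2, 6)), 0L)    # two singletons
  expect_equal(sum(connectivityFilter(m, 2, 18)), 0L)   # corners excluded
  # edge-touching voxels connect under 18 but not 6
  m2 <- array(FALSE, c(4, 4, 4))
  m2[2, 2, 2] <- TRUE
  m2[3, 3, 2] <- TRUE
  expect_equal(sum(connectivityFilter(m2, 2, 18)), 2L)
  expect_equal(sum(connectivityFilter(m2, 2, 6)), 0L)
})

test_that("connectivity filter equals brute-force flood fill", {
  set.seed(21)
  for (i in 1:20) {
    d <- sample(3:10, 3, replace = TRUE)
    m <- randomMask(d, runif(1, 0.15, 0.55))
    nb <- sample(c(6, 18, 26), 1)
    mv <- sample(1:6, 1)
    expect_identical(connectivityFilter(m, mv, nb),
                     bruteFloodFilter(m, mv, nb))
  }
})

test_that("output of the connectivity filter is a subset of its input", {
  set.seed(22)
  for (i in 1:10) {
    m <- randomMask(c(8, 8, 4), 0.4)
    f <- connectivityFilter(m, 3, 26)
    expect_false(any(f & !m))
  }
})

test_that("computeFTV applies PE, connectivity then SER, in that order", {
  # two clusters (12 and 3 voxels); min size 5 removes the small one;
  # half of the large cluster passes the SER threshold
  d <- c(8, 8, 4)
  pe <- array(0, d)
  ser <- array(0, d)
  big <- as.matrix(expand.grid(2:4, 2:3, 2:3))       # 12 voxels, connected
  small <- rbind(c(7, 7, 1), c(7, 8, 1), c(8, 7, 1)) # 3 voxels
  pe[big] <- 100
  pe[small] <- 100
  ser[big] <- rep(c(1.5, 0.5), 6)                    # 6 of 12 at SER 1.5
  maps <- toyMaps(pe, ser, spacing = c(1, 1, 2.5))
  f <- computeFTV(maps, RoiBox(c(0, 0, 0), d), pe_t = 70, ser_t = 1.0,
                  minVoxels = 5)
  expect_equal(f$n_voxels, 6L)
  expect_equal(f$ftv_cc, 6 * 2.5 / 1000)
  # ser_t = 0 keeps the whole surviving component
  f0 <- computeFTV(maps, RoiBox(c(0, 0, 0), d), 70, 0, minVoxels = 5)
  expect_equal(f0$n_voxels, 12L)
  # 10 voxels at 1 x 1 x 2.5 mm = 0.025 cc
  pe10 <- array(0, c(5, 5, 2)); pe10[1:5, 1:2, 1] <- 100
  f10 <- computeFTV(toyMaps(pe10, array(1, dim(pe10)),
                            spacing = c(1, 1, 2.5)),
                    RoiBox(c(0, 0, 0), c(5, 5, 2)), 70, 0, minVoxels = 5)
  expect_equal(f10$n_voxels, 10L)
  expect_equal(f10$ftv_cc, 0.025)
  # empty mask: zero volume
  fe <- computeFTV(maps, RoiBox(c(0, 0, 0), d), 300, 0)
  expect_equal(fe$ftv_cc, 0)
})

test_that("grid sweep equals cell-by-cell computeFTV", {
  g <- generatePhantomExam(smallPhantom(seed = 23, noiseSd = 4))
  maps <- enhancementMaps(g$exam)
  roi <- tumorRoi(g$truth)
  grid <- thresholdGrid(pe = c(40, 90, 150), ser = c(0, 0.8, 1.6))
  sw <- ftvSweep(maps, roi, grid, minVoxels = 5)
  for (i in seq_len(nrow(grid))) {
    f <- computeFTV(maps, roi, grid$pe_t[i], grid$ser_t[i], minVoxels = 5)
    expect_equal(sw$n_voxels[i], f$n_voxels)
    expect_equal(sw$ftv_cc[i], f$ftv_cc)
  }
})

test_that("FTV is non-increasing in both thresholds on a random phantom", {
  g <- generatePhantomExam(smallPhantom(seed = 24, noiseSd = 6))
  maps <- enhancementMaps(g$exam)
  sw <- ftvSweep(maps, tumorRoi(g$truth))
  m <- matrix(sw$ftv_cc, nrow = 11)   # ser varies fastest within a PE level
  expect_true(all(diff(m) <= 0))                  # along SER
  expect_true(all(t(diff(t(m))) <= 0))            # along PE
})

test_that("percent FTV change follows the baseline-relative formula", {
  mk <- function(tp, cc, pe = 70, ser = 0, id = "P") {
    structure(list(patient_id = id, timepoint = as.integer(tp), pe_t = pe,
                   ser_t = ser, n_voxels = NA_integer_, ftv_cc = cc),
              class = "FtvMeasurement")
  }
  d <- deltaFtv(mk(2, 5.13), mk(1, 5.31))
  expect_true(d$defined)
  expect_equal(d$value, 100 * (5.13 - 5.31) / 5.31)
  expect_equal(round(d$value, 1), -3.4)
  # complete response: -100%
  expect_equal(deltaFtv(mk(3, 0), mk(1, 2))$value, -100)
  # zero baseline: undefined, excluded
  d0 <- deltaFtv(mk(2, 1), mk(1, 0))
  expect_false(d0$defined)
  expect_true(is.na(d0$value))
  # guards
  expect_error(deltaFtv(mk(2, 1, id = "A"), mk(1, 1, id = "B")), "patient")
  expect_error(deltaFtv(mk(2, 1, pe = 130), mk(1, 1, pe = 70)),
               "thresholds")
  expect_error(deltaFtv(mk(3, 1), mk(2, 1)), "baseline")
})
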