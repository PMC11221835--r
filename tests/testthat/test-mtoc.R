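cfg <- analysisConfig()
px <- 0.325

test_that("percentile normalization is an affine clip-and-rescale", {
  # constant image -> all zeros (degenerate convention)
  expect_equal(normalizeIntensity(matrix(5, 8, 8)), matrix(0, 8, 8))

  # two-level image with 0/100 percentiles -> exact endpoints
  m <- matrix(c(10, 100), 4, 4)
  n <- normalizeIntensity(m, c(0, 1))
  expect_equal(sort(unique(as.vector(n))), c(0, 1))

  # random raster vs elementwise brute-force oracle
  set.seed(11)
  r <- matrix(rexp(900, 1 / 50), 30, 30)
  pcts <- c(0.05, 0.95)
  q <- quantile(r, pcts, names = FALSE)
  oracle <- (pmin(pmax(r, q[1]), q[2]) - q[1]) / (q[2] - q[1])
  expect_equal(normalizeIntensity(r, pcts), oracle, tolerance = 1e-12)
  # monotone on unclipped pixels
  un <- r > q[1] & r < q[2]
  expect_identical(order(r[un]), order(normalizeIntensity(r, pcts)[un]))
})

test_that("rolling-ball background subtraction removes flat background, keeps spots", {
  # flat image -> all zeros
  expect_equal(subtractBackground(matrix(50, 32, 32), 5, px),
               matrix(0, 32, 32))

  # single impulse on zero background, radius >> 1 px: preserved within 1%
  # (against a brute-force grayscale-opening oracle)
  img <- matrix(0, 21, 21); img[11, 11] <- 100
  got <- subtractBackground(img, 5, 1)  # radius 5 px
  oracle <- pmax(img - greyOpeningOracle(img, 5), 0)
  expect_equal(got, oracle, tolerance = 1e-8)
  expect_gt(got[11, 11], 99)

  # output never negative for random nonnegative input
  set.seed(3)
  r <- matrix(rexp(400, 1 / 30), 20, 20)
  expect_true(all(subtractBackground(r, 3, 1) >= 0))

  expect_error(subtractBackground(matrix(1, 8, 8), 0.1, 1), "at least one pixel")
})

test_that("MTOC detection finds the brightest spot per cell", {
  dims <- c(80, 80)
  cellLab <- matrix(1L, dims[1], dims[2])
  cells <- LabelMask(cellLab, "cell")

  # single spot at (40, 40) on zero background
  tub <- spotMat(dims, c(40, 40), 1.5, 1000)
  mt <- detectMtoc(tub, cells, cfg, px, preprocess = FALSE)
  expect_true(mt$detected)
  expect_lt(sqrt((mt$row - 40)^2 + (mt$col - 40)^2), 1)

  # two spots with integrated intensities 200 vs 100: the brighter wins;
  # oracle = weighted centroid of the brighter blob's own pixels
  tub2 <- matrix(0, dims[1], dims[2])
  tub2[20, 20] <- 100; tub2[20, 21] <- 100   # integrated 200
  tub2[60, 60] <- 100                         # integrated 100
  mt2 <- detectMtoc(tub2, cells, cfg, px, preprocess = FALSE)
  expect_equal(c(mt2$row, mt2$col), c(20, 20.5), tolerance = 1e-9)

  # all-zero tubulin -> not detected
  mt3 <- detectMtoc(matrix(0, dims[1], dims[2]), cells, cfg, px,
                    preprocess = FALSE)
  expect_false(mt3$detected)

  # empty cell mask -> empty result
  none <- LabelMask(matrix(0L, 8, 8), "cell")
  expect_equal(nrow(detectMtoc(matrix(1, 8, 8), none, cfg, px)), 0L)
})

test_that("detection is deterministic and positions stay inside their cells", {
  g <- generateField(syntheticCellSpec(seed = 21L))
  tub <- getChannel(g$field, "tubulin")
  nuclei <- segmentNuclei(getChannel(g$field, "nuclear"), cfg, px)
  cells <- segmentCells(nuclei, tub + getChannel(g$field, "lysosome"), cfg, px)
  a <- detectMtoc(tub, cells, cfg, px)
  b <- detectMtoc(tub, cells, cfg, px)
  expect_identical(a, b)
  lab <- labels(cells)
  for (i in which(a$detected))
    expect_equal(lab[round(a$row[i]), round(a$col[i])], a$cell_label[i])
})

test_that("median MTOC localization error is below one pixel on noisy fields", {
  errs <- c()
  for (s in 1:13) {  # 13 fields x 8 cells > 100 cells, photon + read noise on
    g <- generateField(syntheticCellSpec(seed = 400L + s))
    sc <- scoreField(g$field, cfg, returnMasks = TRUE)
    lab <- labels(attr(sc, "cells"))
    tr <- g$truth$cells
    for (i in seq_len(nrow(tr))) {
      k <- lab[round(tr$row[i]), round(tr$col[i])]
      j <- which(sc$cell_label == k)
      if (length(j) == 1L && !is.na(sc$mtoc_row[j]))
        errs <- c(errs, sqrt((sc$mtoc_row[j] - tr$mtoc_row[i])^2 +
                               (sc$mtoc_col[j] - tr$mtoc_col[i])^2))
    }
  }
  expect_gte(length(errs), 100L)
  expect_lt(median(errs), 1)
})
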