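cfg <- analysisConfig()
px <- 0.325

test_that("circle masks agree with a per-pixel distance oracle", {
  set.seed(13)
  for (i in 1:25) {
    dims <- c(sample(20:60, 1), sample(20:60, 1))
    ce <- c(runif(1, 1, dims[1]), runif(1, 1, dims[2]))
    diam <- runif(1, 0.5, 15) * px
    got <- circleMask(ce, diam, px, dims)
    oracle <- circleOracle(ce, diam / 2 / px, dims)
    if (!any(oracle))  # degenerate tiny circle keeps the centre pixel
      oracle[round(ce[1]), round(ce[2])] <- TRUE
    expect_identical(got, oracle)
  }
})

test_that("circle mask geometry: discretized area, corner clipping, degenerate cases", {
  # area close to the analytic disc area (radius 20 px)
  m <- circleMask(c(50, 50), 40 * px, px, c(100, 100))
  expect_lt(abs(sum(m) - pi * 20^2), 0.05 * pi * 20^2)

  # centre at the image corner: a quarter disc
  q <- circleMask(c(1, 1), 40 * px, px, c(100, 100))
  expect_lt(abs(sum(q) / sum(m) - 0.25), 0.05)

  # diameter below the pixel spacing: just the centre pixel
  tiny <- circleMask(c(10, 10), 0.2 * px, px, c(20, 20))
  expect_equal(sum(tiny), 1L)
  expect_true(tiny[10, 10])

  # centre outside the image: empty with a warning
  expect_warning(out <- circleMask(c(-5, 10), 7, px, c(20, 20)), "outside")
  expect_false(any(out))
})

test_that("clustering ratio matches brute-force pixel sums and its identities", {
  dims <- c(64, 64)
  cell <- diskMat(dims, c(32, 32), 28)
  mtoc <- list(cell_label = 1L, row = 32, col = 32, detected = TRUE)

  # all intensity inside the circle -> ratio 1
  lys1 <- spotMat(dims, c(32, 32), 1.2, 100) * circleMask(c(32, 32), 7, px, dims)
  m1 <- clusteringRatio(lys1, cell, mtoc, cfg, px)
  expect_equal(m1$raw_ratio, 1.0, tolerance = 1e-12)

  # uniform intensity -> exact area identity
  lysU <- matrix(3, dims[1], dims[2])
  mU <- clusteringRatio(lysU, cell, mtoc, cfg, px)
  circ <- circleMask(c(32, 32), 7, px, dims)
  expect_equal(mU$raw_ratio, sum(circ & cell) / sum(cell), tolerance = 1e-9)

  # two puncta of equal integrated intensity, one in, one out -> 0.5
  lys2 <- matrix(0, dims[1], dims[2])
  lys2[32, 34] <- 250   # inside the 7 um circle
  lys2[32, 55] <- 250   # outside, still in the cell
  m2 <- clusteringRatio(lys2, cell, mtoc, cfg, px)
  expect_equal(m2$raw_ratio, 0.5, tolerance = 1e-12)

  # scale invariance
  m2b <- clusteringRatio(lys2 * 37.5, cell, mtoc, cfg, px)
  expect_equal(m2b$raw_ratio, m2$raw_ratio, tolerance = 1e-12)

  # random instances vs independent masked-sum oracle
  set.seed(29)
  for (i in 1:100) {
    lys <- matrix(rexp(prod(dims), 1 / 20), dims[1], dims[2])
    ce <- c(runif(1, 20, 44), runif(1, 20, 44))
    mt <- list(cell_label = 1L, row = ce[1], col = ce[2], detected = TRUE)
    got <- clusteringRatio(lys, cell, mt, cfg, px)
    oracle <- sum(lys[circleOracle(ce, 3.5 / px, dims) & cell]) / sum(lys[cell])
    expect_equal(got$raw_ratio, oracle, tolerance = 1e-12)
  }
})

test_that("moving a punctum into the circle never decreases the ratio", {
  dims <- c(64, 64)
  cell <- diskMat(dims, c(32, 32), 28)
  mtoc <- list(cell_label = 1L, row = 32, col = 32, detected = TRUE)
  set.seed(31)
  for (i in 1:20) {
    base <- matrix(rexp(prod(dims), 1 / 5), dims[1], dims[2])
    outPos <- c(sample(10:54, 1), sample(50:58, 1))  # outside circle
    lysOut <- base; lysOut[outPos[1], outPos[2]] <- lysOut[outPos[1], outPos[2]] + 500
    lysIn <- base; lysIn[32, 30] <- lysIn[32, 30] + 500
    rOut <- clusteringRatio(lysOut, cell, mtoc, cfg, px)$raw_ratio
    rIn <- clusteringRatio(lysIn, cell, mtoc, cfg, px)$raw_ratio
    expect_gte(rIn, rOut)
  }
})

test_that("excluded cells carry their reasons", {
  dims <- c(32, 32)
  cell <- diskMat(dims, c(16, 16), 12)
  noMtoc <- list(cell_label = 1L, row = NA_real_, col = NA_real_, detected = FALSE)
  m <- clusteringRatio(matrix(1, dims[1], dims[2]), cell, noMtoc, cfg, px)
  expect_true(m$excluded)
  expect_match(m$reason, "no MTOC")

  mt <- list(cell_label = 1L, row = 16, col = 16, detected = TRUE)
  m2 <- clusteringRatio(matrix(0, dims[1], dims[2]), cell, mt, cfg, px)
  expect_true(m2$excluded)
  expect_match(m2$reason, "empty lysosome signal")
})

test_that("control normalization follows the stat-and-divide contract", {
  expect_equal(clusteringValue(c(0.3, 0.4), c(0.3, 0.4)), 1.0)
  expect_equal(clusteringValue(0.33, 0.30), 1.1)

  set.seed(17)
  control <- runif(200, 0.1, 0.5)
  for (stat in c("mean", "median")) {
    fn <- if (stat == "mean") mean else median
    for (i in 1:50) {
      treated <- runif(sample(3:40, 1), 0.1, 0.8)
      expect_equal(clusteringValue(treated, control, stat),
                   fn(treated) / fn(control), tolerance = 1e-12)
    }
  }
  expect_warning(v <- clusteringValue(numeric(), c(0.3)), "no measurements")
  expect_true(is.na(v))
  expect_error(clusteringValue(0.3, numeric()), "control group is empty")
  expect_error(clusteringValue(0.3, c(0, 0)), "positive")
})

test_that("peripheral-lysosome cell percentages match planted placement", {
  lab <- matrix(0L, 64, 128)
  lab[diskMat(c(64, 128), c(32, 32), 24)] <- 1L
  lab[diskMat(c(64, 128), c(32, 96), 24)] <- 2L
  cells <- LabelMask(lab, "cell")
  central <- centralRegion(cells, 0.5)
  cen <- labels(central)

  lysCentral <- matrix(0, 64, 128)
  lysCentral[cen > 0L] <- 10
  expect_equal(peripheralCellFraction(lysCentral, cells, central)$percentage, 0)

  lysPeri <- matrix(0, 64, 128)
  lysPeri[lab > 0L & cen == 0L] <- 10
  expect_equal(peripheralCellFraction(lysPeri, cells, central)$percentage, 100)

  # mixed: cell 1 peripheral, cell 2 central -> 50% and per-cell flags exact
  mix <- matrix(0, 64, 128)
  mix[lab == 1L & cen == 0L] <- 10
  mix[lab == 2L & cen == 2L] <- 10
  got <- peripheralCellFraction(mix, cells, central)
  expect_equal(got$percentage, 50)
  expect_identical(got$cells$peripheral, c(TRUE, FALSE))

  expect_error(peripheralCellFraction(matrix(0, 64, 128), cells, central),
               "no cells")
})

test_that("aggregate colocalization scores masked lysosome intensity", {
  dims <- c(64, 64)
  lab <- matrix(0L, dims[1], dims[2])
  lab[diskMat(dims, c(32, 32), 28)] <- 1L
  cells <- LabelMask(lab, "cell")

  agg <- matrix(0, dims[1], dims[2])
  agg[diskMat(dims, c(28, 28), 6)] <- 80  # one aggregate blob

  # lysosome zero inside the aggregate -> zero score
  lys0 <- matrix(0, dims[1], dims[2])
  lys0[50, 50] <- 100
  s0 <- aggregateColocalization(lys0, agg, cells, cfg)
  expect_equal(s0$lysosome_intensity_in_aggregate, 0)

  # punctum half-inside the aggregate: sum equals the brute-force masked sum
  lys <- spotMat(dims, c(28, 34), 1.5, 300)
  s <- aggregateColocalization(lys, agg, cells, cfg)
  thr <- 0  # aggregate is binary 0/80; any data-driven threshold sits between
  mask <- agg > 40 & lab == 1L
  expect_equal(s$lysosome_intensity_in_aggregate, sum(lys[mask]),
               tolerance = 1e-9)
  expect_equal(s$mean_intensity_in_aggregate,
               sum(lys[mask]) / sum(mask), tolerance = 1e-9)

  # no aggregate anywhere -> valid all-zero record
  sNone <- aggregateColocalization(lys, matrix(0, dims[1], dims[2]), cells, cfg)
  expect_equal(sNone$aggregate_area_px, 0L)
  expect_equal(sNone$lysosome_intensity_in_aggregate, 0)
})

test_that("pixels-above-threshold fraction equals direct counting", {
  expect_equal(fractionAboveThreshold(matrix(1, 10, 10), 2), 0)
  expect_equal(fractionAboveThreshold(matrix(3, 10, 10), 2), 1)
  set.seed(5)
  for (i in 1:100) {
    r <- matrix(rnorm(64, 10, 4), 8, 8)
    thr <- runif(1, 0, 20)
    cnt <- 0L
    for (v in as.vector(r)) if (v > thr) cnt <- cnt + 1L
    expect_identical(fractionAboveThreshold(r, thr), cnt / 64)
  }
  expect_error(fractionAboveThreshold(matrix(numeric(), 0, 0), 1), "non-empty")
})
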