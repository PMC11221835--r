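test_that("field generation is a pure function of spec and seed", {
  s <- syntheticCellSpec(seed = 77L)
  a <- generateField(s); b <- generateField(s)
  expect_identical(a$field@channels, b$field@channels)
  expect_identical(a$truth$cells, b$truth$cells)
  expect_identical(a$truth$puncta, b$truth$puncta)
  c <- generateField(syntheticCellSpec(seed = 78L))
  expect_false(identical(a$field@channels, c$field@channels))
})

test_that("planted geometry is self-consistent", {
  g <- generateField(syntheticCellSpec(clusteredFraction = 1, seed = 4L))
  tr <- g$truth
  ccr <- 3.5 / 0.325
  for (k in seq_len(nrow(tr$cells))) {
    p <- tr$puncta[tr$puncta$cell_label == k, ]
    d <- sqrt((p$row - tr$cells$mtoc_row[k])^2 +
                (p$col - tr$cells$mtoc_col[k])^2)
    # kappa = 1: every punctum centre within the circle radius of the MTOC
    expect_true(all(d <= ccr))
    # stored in-circle flags recompute from positions
    expect_identical(p$in_circle, d <= ccr)
  }
  # all puncta sit inside their own cell mask
  lab <- labels(tr$cellMask)
  expect_true(all(lab[cbind(round(tr$puncta$row), round(tr$puncta$col))] ==
                    tr$puncta$cell_label))
})

test_that("in-circle intensity fraction matches the binomial expectation", {
  # kappa = 0.5, many puncta, noise off: fraction within 3 binomial SEs of
  # kappa + (1 - kappa) * a
  fr <- c(); expd <- c(); n <- 0L
  for (s in 1:6) {
    g <- generateField(syntheticCellSpec(clusteredFraction = 0.5,
                                         nPuncta = 200L, photonNoise = FALSE,
                                         readNoiseSd = 0, seed = 50L + s))
    tr <- g$truth$cells
    fr <- c(fr, tr$in_circle_intensity_fraction)
    expd <- c(expd, 0.5 + 0.5 * tr$a_fraction)
    n <- n + sum(tr$n_puncta)
  }
  p <- mean(expd)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(fr) - p), 3 * se)
})

test_that("generation fails cleanly when cells cannot fit", {
  expect_error(generateField(syntheticCellSpec(imageSize = c(64L, 64L),
                                               nCells = 4L)),
               "larger image")
})

test_that("screen tables plant recoverable hits", {
  # zero planted hits, zero noise: all fold changes exactly 1
  z <- generateScreenTable(50, 0, controlNoiseSd = 0, seed = 1L)
  expect_true(all(z$table$fold_change == 1))
  expect_equal(nrow(callHits(z$table, 1.1)$hits), 0L)

  s <- generateScreenTable(300, 20, hitMargin = 0.05, controlNoiseSd = 0.01,
                           seed = 2L)
  hits <- callHits(s$table, 1.1)$hits
  expect_setequal(hits$compound_id,
                  s$truth$compound_id[s$truth$is_hit])

  # determinism
  expect_identical(s$table,
                   generateScreenTable(300, 20, hitMargin = 0.05,
                                       controlNoiseSd = 0.01, seed = 2L)$table)

  expect_error(generateScreenTable(10, 5, hitMargin = 0), "infeasible")
  expect_error(generateScreenTable(10, 11), "exceed")
})

test_that("flow event generation plants exact gate categories and the ratio median", {
  allDead <- generateFlowEvents(500, deadFraction = 1, seed = 3L)
  expect_warning(
    g <- gateEvents(allDead$events, allDead$truth$dapi_max,
                    allDead$truth$rfp_min),
    "no events pass")
  expect_equal(unname(g$counts["kept"]), 0L)

  sim <- generateFlowEvents(10000, ratioMedian = 2.0, seed = 4L)
  g2 <- gateEvents(sim$events, sim$truth$dapi_max, sim$truth$rfp_min)
  med <- rfpGfpRatio(g2$events, "median")$value
  # order-statistic standard error of the sample median of a lognormal
  n <- nrow(g2$events)
  seMed <- 1 / (2 * sqrt(n) * dlnorm(2, log(2), 0.4))
  expect_lt(abs(med - 2.0), 3 * seMed)

  expect_identical(sim$events,
                   generateFlowEvents(10000, ratioMedian = 2.0, seed = 4L)$events)
})
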