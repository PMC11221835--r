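test_that("hit calling is strict at the threshold and matches a brute-force filter", {
  tab <- data.frame(compound_id = c("a", "b", "c"),
                    fold_change = c(1.15, 1.10, 0.95))
  got <- callHits(tab, 1.1)
  expect_identical(got$hits$compound_id, "a")  # 1.10 is not "over" 1.1

  expect_equal(nrow(callHits(tab[0, ], 1.1)$hits), 0L)

  set.seed(23)
  big <- data.frame(compound_id = sprintf("c%04d", 1:1000),
                    fold_change = rnorm(1000, 1, 0.15))
  got <- callHits(big, 1.1)
  oracle <- big[big$fold_change > 1.1, ]
  expect_setequal(got$hits$compound_id, oracle$compound_id)
  # sorted by descending fold change
  expect_identical(got$hits$fold_change, sort(got$hits$fold_change,
                                              decreasing = TRUE))
  # invariant to row order
  perm <- big[sample(nrow(big)), ]
  expect_identical(callHits(perm, 1.1)$hits, got$hits)
})

test_that("non-finite fold changes are excluded with a reason, never dropped silently", {
  tab <- data.frame(compound_id = c("a", "b", "c"),
                    fold_change = c(1.5, NaN, NA))
  got <- callHits(tab, 1.1)
  expect_identical(got$hits$compound_id, "a")
  expect_setequal(got$excluded$compound_id, c("b", "c"))
  expect_true(all(grepl("non-finite", got$excluded$reason)))
  expect_error(callHits(tab, -1), "positive")
})

test_that("autofluorescence exclusion removes exactly the flagged compounds", {
  hits <- data.frame(compound_id = sprintf("h%02d", 1:15),
                     fold_change = seq(2, 1.2, length.out = 15))
  flagged <- sprintf("h%02d", c(2, 5, 8, 11, 14))
  got <- excludeAutofluorescent(hits, flagged)
  expect_equal(nrow(got$kept), 10L)
  expect_false(any(got$kept$compound_id %in% flagged))
  expect_identical(got$excluded$compound_id, flagged)

  expect_identical(excludeAutofluorescent(hits, character())$kept, hits)
  expect_equal(nrow(excludeAutofluorescent(hits, hits$compound_id)$kept), 0L)
  expect_error(excludeAutofluorescent(hits, "zz"), "unknown compound")
})

test_that("the cascade chains planted counts and stays internally consistent", {
  cfg <- analysisConfig()
  prim <- generateScreenTable(100, 12, seed = 31L)
  primHits <- callHits(prim$table, 1.1)$hits
  sec <- generateScreenTable(nrow(primHits), 4, seed = 32L,
                             compoundIds = primHits$compound_id,
                             stage = "secondary")
  secPass <- sec$truth$compound_id[sec$truth$is_hit]
  ledger <- runCascade(prim$table, sec$table, flags = secPass[1L], config = cfg)

  st <- stages(ledger)
  expect_equal(vapply(st, `[[`, integer(1), "output"), c(12L, 4L, 3L))
  # chained-count invariant
  for (i in 2:length(st))
    expect_equal(st[[i]]$input, st[[i - 1L]]$output)
  expect_equal(length(finalCandidates(ledger)), 3L)

  # all compounds below threshold -> zero at every stage
  flat <- data.frame(compound_id = c("a", "b"), fold_change = c(1.0, 1.05))
  led0 <- runCascade(flat, flat[0, ], config = cfg)
  expect_true(all(vapply(stages(led0), `[[`, integer(1), "output") == 0L))

  # secondary with a compound absent from primary hits -> consistency error
  badSec <- data.frame(compound_id = c(primHits$compound_id, "ghost"),
                       fold_change = 1.2)
  expect_error(runCascade(prim$table, badSec, config = cfg), "absent")
})

test_that("manual confirmation is recorded as an annotation stage", {
  prim <- data.frame(compound_id = c("a", "b", "c", "d"),
                     fold_change = c(1.5, 1.4, 1.3, 1.0))
  sec <- data.frame(compound_id = c("a", "b", "c"),
                    fold_change = c(1.5, 1.3, 1.2))
  led <- runCascade(prim, sec, flags = "c", manualConfirmed = "a")
  st <- stages(led)
  expect_equal(length(st), 4L)
  expect_identical(finalCandidates(led), "a")
  expect_error(runCascade(prim, sec, flags = "c", manualConfirmed = "zz"),
               "not in the remaining hits")
})

test_that("ledgers serialize to JSON with their stage records", {
  prim <- data.frame(compound_id = c("a", "b"), fold_change = c(1.5, 1.0))
  sec <- data.frame(compound_id = "a", fold_change = 1.4)
  led <- runCascade(prim, sec)
  f <- tempfile(fileext = ".json")
  writeCascadeLedger(led, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(length(back$stages$stage), 3L)
  expect_equal(back$stages$output, c(1L, 1L, 1L))
})
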