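# Dual plate-layout robustness: partitioning, comparison, combination and
# the disagreement filter.

test_that("source-plate split is a disjoint cover keeping controls local", {
  set.seed(10)
  for (i in 1:5) {
    nPlates <- sample(2:5, 1)
    rec <- makeRecords(runif(95 * nPlates),
                       sourcePlate = rep(sprintf("SP%d", seq_len(nPlates)),
                                         each = 95))
    groups <- splitBySourcePlate(rec)
    expect_length(groups, nPlates)
    expect_equal(sum(vapply(groups, nrow, integer(1))), nrow(rec))
    expect_equal(sort(unlist(lapply(groups, `[[`, "sample_id"),
                             use.names = FALSE)),
                 sort(rec$sample_id))
    for (g in groups) expect_length(unique(g$source_plate_id), 1L)
  }
  bad <- makeRecords(runif(3)); bad$source_plate_id[2] <- ""
  expect_error(splitBySourcePlate(bad), class = "polyfp_validation_error")
})

test_that("layout comparison counts disagreements over shared calls", {
  a <- makeScoreMatrix(matrix(rep(2L, 100), 50, 2), layout = "single")
  expect_equal(compareLayoutCalls(a, a)$disagreement_fraction, c(0, 0))

  v <- matrix(2L, 50, 2)
  w <- v; w[1, 1] <- 3L; w[2, 1] <- 1L   # two cells differ by 1
  cmp <- compareLayoutCalls(makeScoreMatrix(v, layout = "single"),
                            makeScoreMatrix(w, layout = "original"))
  expect_equal(cmp$n_both_called, c(50, 50))
  expect_equal(cmp$disagreement_fraction, c(2 / 50, 0))
  expect_equal(cmp$diff_1, c(2, 0))
  expect_equal(sum(cmp[1, c("diff_1", "diff_2", "diff_3", "diff_4")]),
               cmp$n_disagree[1])

  # no shared calls: undefined disagreement
  x <- matrix(c(1L, NA), 2, 1); y <- matrix(c(NA, 1L), 2, 1)
  cmp <- compareLayoutCalls(makeScoreMatrix(x), makeScoreMatrix(y))
  expect_equal(cmp$n_both_called, 0)
  expect_true(is.na(cmp$disagreement_fraction))

  expect_error(
    compareLayoutCalls(a, makeScoreMatrix(matrix(1L, 2, 2))),
    class = "polyfp_usage_error")
})

test_that("combination takes the unique call, agrees, or higher posterior", {
  s <- makeScoreMatrix(rbind(c(2L, NA), c(2L, 1L), c(NA, NA)),
                       posteriors = rbind(c(0.97, NA), c(0.96, 0.99),
                                          c(NA, NA)), layout = "single")
  o <- makeScoreMatrix(rbind(c(NA, 4L), c(3L, 1L), c(NA, NA)),
                       posteriors = rbind(c(NA, 0.98), c(0.99, 0.97),
                                          c(NA, NA)), layout = "original")
  res <- combineLayoutCalls(s, o)
  cm <- scores(res$combined)
  expect_equal(cm[1, ], c(mk01 = 2L, mk02 = 4L))  # single-source cells
  expect_equal(cm[2, 2], 1L)                       # agreeing cell
  expect_equal(cm[2, 1], 3L)                       # conflict: 0.99 > 0.96
  expect_true(all(is.na(cm[3, ])))                 # called in neither
  expect_equal(nrow(res$conflicts), 1L)
  expect_equal(res$conflicts$chosen, 3L)
  expect_identical(layoutTag(res$combined), "combined")
})

test_that("combining a matrix with itself is the identity", {
  set.seed(11)
  v <- matrix(sample(c(0:4, NA), 60, replace = TRUE), 12, 5)
  m <- makeScoreMatrix(v, posteriors = matrix(runif(60, 0.95, 1), 12, 5))
  res <- combineLayoutCalls(m, m)
  expect_identical(scores(res$combined), scores(m))
  expect_equal(nrow(res$conflicts), 0L)
})

test_that("combined call rate dominates both inputs on dropout runs", {
  for (dropout in c(0, 0.02, 0.1)) {
    tr <- generateTruthPanel(nAccessions = 190, nMarkers = 3,
                             seed = 20 + round(100 * dropout),
                             dropoutRate = dropout)
    rec <- simulateFluorescence(tr)
    single <- callDosageMatrix(rec, layout = "single")$matrix
    orig <- callDosageMatrix(rec, layout = "original")$matrix
    cmp <- compareLayoutCalls(single, orig)
    expect_true(all(cmp$call_rate_combined >=
                    pmax(cmp$call_rate_single, cmp$call_rate_original)))
  }
})

test_that("zero-noise simulations show no cross-layout disagreement", {
  tr <- generateTruthPanel(nAccessions = 190, nMarkers = 3, seed = 30,
                           clusterScale = 1e-4, dropoutRate = 0)
  rec <- simulateFluorescence(tr)
  single <- callDosageMatrix(rec, layout = "single")$matrix
  orig <- callDosageMatrix(rec, layout = "original")$matrix
  cmp <- compareLayoutCalls(single, orig)
  expect_true(all(cmp$n_disagree == 0))
})

test_that("robustness filter excludes markers strictly above threshold", {
  cmp <- data.frame(marker_id = c("a", "b", "c"),
                    disagreement_fraction = c(0.136, 0.060, 0.100))
  r <- markerRobustnessFilter(cmp)
  expect_identical(r$excluded, "a")
  expect_identical(r$retained, c("b", "c"))   # exactly 10% is retained
  expect_error(markerRobustnessFilter(cmp[0, ]),
               class = "polyfp_validation_error")
})

test_that("robust subset keeps complete, fully agreeing accessions", {
  s <- makeScoreMatrix(rbind(c(1L, 2L), c(1L, NA), c(1L, 2L)),
                       accessions = c("ok", "hasNA", "differs"))
  o <- makeScoreMatrix(rbind(c(1L, 2L), c(1L, 2L), c(1L, 3L)),
                       accessions = c("ok", "hasNA", "differs"))
  expect_identical(robustSubset(s, o), "ok")
})
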