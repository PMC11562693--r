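# Mixture-model dosage calling: signal transform, EM fit, posterior
# calling, call rate and plate-repeat flagging.

test_that("signal transform is the allele-B fraction with NA at zero total", {
  expect_equal(transformSignal(1000, 0), 0)
  expect_equal(transformSignal(0, 1000), 1)
  expect_equal(transformSignal(500, 500), 0.5)
  expect_true(is.na(transformSignal(0, 0)))
  expect_error(transformSignal(-1, 5), class = "polyfp_validation_error")
  # strictly monotone in signal B at fixed signal A
  b <- seq(0, 2000, by = 50)
  expect_true(all(diff(transformSignal(rep(700, length(b)), b)) > 0))
})

test_that("EM recovers well-separated cluster locations", {
  set.seed(1)
  cl <- clusteredRatios(rep(100, 5))
  fit <- fitDosageMixture(makeRecords(cl$ratios))
  expect_true(fit@converged)
  expect_lt(max(abs(fit@locations - seq(0.1, 0.9, 0.2))), 0.01)
  expect_equal(sum(fit@weights), 1, tolerance = 1e-9)
  calls <- callDosages(fit, makeRecords(cl$ratios))
  expect_gt(mean(calls$dosage == cl$truth, na.rm = TRUE), 0.99)
})

test_that("a single tight cluster concentrates onto one component", {
  set.seed(2)
  fit <- fitDosageMixture(makeRecords(rnorm(300, 0.5, 0.02)))
  expect_true(fit@converged)
  expect_gte(max(fit@weights), 0.95)
})

test_that("parameter recovery holds across seeds", {
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    cl <- clusteredRatios(rep(100, 5))
    fit <- fitDosageMixture(makeRecords(cl$ratios))
    median(abs(fit@locations - seq(0.1, 0.9, 0.2)))
  }, numeric(1))
  expect_lt(median(errs), 0.02)
})

test_that("too few usable records is a fit error", {
  expect_error(fitDosageMixture(makeRecords(c(0.1, 0.5, 0.9))),
               class = "polyfp_fit_error")
  # controls and zero-signal wells do not count as usable
  rec <- makeRecords(rep(0.5, 6))
  rec$is_negative_control[1:2] <- TRUE
  rec$signal_a[3:4] <- 0; rec$signal_b[3:4] <- 0
  expect_error(fitDosageMixture(rec), class = "polyfp_fit_error")
})

test_that("posterior threshold rule assigns or withholds dosage", {
  fit <- new("DosageMixtureFit", markerId = "M1", unitId = "AP1",
             locations = seq(0.1, 0.9, 0.2), scales = rep(0.05, 5),
             weights = rep(0.2, 5), logLik = 0, converged = TRUE,
             nSamples = 100L)
  rec <- makeRecords(c(0.1, 0.2))   # on-cluster vs between clusters
  calls <- callDosages(fit, rec)
  expect_gte(calls$posterior[1], 0.95)
  expect_equal(calls$dosage[1], 0L)
  expect_lt(calls$posterior[2], 0.95)
  expect_true(is.na(calls$dosage[2]))
  # unprocessable well: missing call, NA posterior
  rec0 <- makeRecords(0.5); rec0$signal_a <- 0; rec0$signal_b <- 0
  c0 <- callDosages(fit, rec0)
  expect_true(is.na(c0$dosage) && is.na(c0$posterior))
  # wrong marker is a usage error
  recX <- makeRecords(0.5, marker = "M2")
  expect_error(callDosages(fit, recX), class = "polyfp_usage_error")
})

test_that("posteriors match a direct Bayes-rule oracle", {
  fit <- new("DosageMixtureFit", markerId = "M1", unitId = "AP1",
             locations = c(0.08, 0.31, 0.52, 0.69, 0.91),
             scales = c(0.02, 0.03, 0.025, 0.02, 0.03),
             weights = c(0.1, 0.3, 0.2, 0.25, 0.15),
             logLik = 0, converged = TRUE, nSamples = 30L)
  set.seed(42)
  ratios <- runif(30)
  post <- classPosteriors(fit, ratios)
  # independent direct computation: weights x normal densities, normalized
  oracle <- t(vapply(ratios, function(r) {
    d <- fit@weights * dnorm(r, fit@locations, fit@scales)
    d / sum(d)
  }, numeric(5)))
  expect_lt(max(abs(post - oracle)), 1e-9)
  expect_equal(rowSums(post), rep(1, 30), tolerance = 1e-9)
})

test_that("assigned dosage is non-decreasing in the transformed ratio", {
  set.seed(3)
  cl <- clusteredRatios(rep(80, 5))
  rec <- makeRecords(sort(cl$ratios))
  fit <- fitDosageMixture(rec)
  d <- callDosages(fit, rec)$dosage
  expect_true(all(diff(d[!is.na(d)]) >= 0))
})

test_that("fitting and calling are deterministic", {
  set.seed(4)
  cl <- clusteredRatios(rep(50, 5))
  rec <- makeRecords(cl$ratios)
  f1 <- fitDosageMixture(rec); f2 <- fitDosageMixture(rec)
  expect_identical(f1@locations, f2@locations)
  expect_identical(callDosages(f1, rec), callDosages(f2, rec))
})

test_that("call rate excludes negative controls", {
  calls <- data.frame(dosage = c(rep(1L, 90), rep(NA, 5), NA),
                      is_negative_control = c(rep(FALSE, 95), TRUE))
  expect_equal(callRate(calls), 90 / 95)
  expect_equal(callRate(data.frame(dosage = rep(NA_integer_, 4),
                                   is_negative_control = FALSE)), 0)
  expect_error(callRate(data.frame(dosage = 1L,
                                   is_negative_control = TRUE)),
               class = "polyfp_validation_error")
})

test_that("plates are flagged for repeat only above 20% missing", {
  calls <- data.frame(
    dosage = c(rep(NA, 25), rep(1L, 75),    # 25% missing
               rep(NA, 20), rep(1L, 80),    # exactly 20%
               rep(1L, 100)),               # 0%
    source_plate_id = rep(c("P25", "P20", "P00"), each = 100),
    is_negative_control = FALSE)
  expect_identical(flagPlatesForRepeat(calls), "P25")
})

test_that("fit reports serialize every marker/unit with its call rate", {
  set.seed(5)
  tr <- generateTruthPanel(nAccessions = 95, nMarkers = 2, seed = 55)
  rec <- simulateFluorescence(tr)
  res <- callDosageMatrix(rec, layout = "original")
  f <- withr::local_tempfile(fileext = ".json")
  writeFitReport(res, f)
  rep <- jsonlite::read_json(f)
  expect_length(rep, length(res$fits))
  expect_true(all(vapply(rep, function(x) length(x$locations) == 5,
                         logical(1))))
  expect_true(all(vapply(rep, function(x)
    x$call_rate >= 0 && x$call_rate <= 1, logical(1))))
})
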