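# Amplicon haplotype analysis: read filters, discrimination summaries,
# dosage assignment, combination tables and concordance.

test_that("read filters apply their thresholds strictly", {
  ht <- makeHaplotypeTable(rbind(
    g_low   = c(60L, 39L, 0L),     # 99 reads: removed
    g_keep  = c(60L, 40L, 0L),     # 100 reads: kept
    g_edge  = c(900L, 100L, 0L),   # exactly 10%: retained
    g_below = c(901L, 99L, 0L)))   # 9.9%: zeroed
  f <- filterReadTable(ht)
  cm <- readCounts(f)
  expect_false("g_low" %in% rownames(cm))
  expect_true(all(c("g_keep", "g_edge", "g_below") %in% rownames(cm)))
  expect_equal(cm["g_edge", "H2"], 100L)
  expect_equal(cm["g_below", "H2"], 0L)
  expect_false("H3" %in% colnames(cm))        # empty haplotype dropped
  expect_false("H3" %in% names(haplotypeSequences(f)))
})

test_that("filtering is idempotent", {
  set.seed(14)
  for (i in 1:5) {
    cm <- matrix(rpois(60, 80), 10, 6)
    ht <- makeHaplotypeTable(cm)
    f1 <- filterReadTable(ht)
    f2 <- filterReadTable(f1)
    expect_identical(readCounts(f2), readCounts(f1))
    expect_identical(as.character(haplotypeSequences(f2)),
                     as.character(haplotypeSequences(f1)))
  }
})

test_that("haplotype dosages sum to the ploidy with largest-remainder", {
  expect_equal(haplotypeDosages(c(H1 = 1000)), c(H1 = 4L))
  expect_equal(haplotypeDosages(c(H1 = 500, H2 = 500)), c(H1 = 2L, H2 = 2L))
  expect_equal(haplotypeDosages(c(H1 = 750, H2 = 250)), c(H1 = 3L, H2 = 1L))
  # every retained haplotype gets at least one copy
  expect_equal(haplotypeDosages(c(H1 = 700, H2 = 100, H3 = 100, H4 = 100)),
               c(H1 = 1L, H2 = 1L, H3 = 1L, H4 = 1L))
  # more retained haplotypes than ploidy: flagged (NULL)
  expect_null(haplotypeDosages(c(H1 = 30, H2 = 30, H3 = 20, H4 = 10,
                                 H5 = 10)))
  # conservation property over random counts
  set.seed(15)
  for (i in 1:50) {
    k <- sample(1:4, 1)
    d <- haplotypeDosages(setNames(rpois(k, 200) + 1, paste0("H", 1:k)))
    expect_equal(sum(d), 4L)
    expect_true(all(d >= 1L))
  }
})

test_that("amplicon summary counts sites, haplotypes and multisets", {
  seqs <- c(H1 = "ACGTACGTAC", H2 = "ACGAACGTAC",   # col 4 differs
            H3 = "ACGAAGGTAC", H4 = "ACGAAGGT-C")   # cols 6 and 9
  cm <- rbind(
    g01 = c(1000L, 0L, 0L, 0L),  g02 = c(500L, 500L, 0L, 0L),
    g03 = c(750L, 250L, 0L, 0L), g04 = c(0L, 0L, 1000L, 0L),
    g05 = c(0L, 250L, 250L, 500L), g06 = c(250L, 250L, 250L, 250L),
    g07 = c(1000L, 0L, 0L, 0L),  g08 = c(500L, 500L, 0L, 0L),
    g09 = c(0L, 0L, 1000L, 0L),  g10 = c(250L, 250L, 250L, 250L))
  ht <- makeHaplotypeTable(cm, seqs = seqs)
  s <- summarizeAmplicon(ht)
  expect_equal(s$n_polymorphic_sites, 3L)   # gap column counts as a symbol
  expect_equal(s$n_haplotypes, 4L)
  expect_equal(s$n_genotypes_retained, 10L)
  expect_equal(s$n_distinguishable_genotypes, 6L)

  mono <- makeHaplotypeTable(matrix(c(500L, 600L), 2, 1),
                             seqs = c(H1 = "ACGT"))
  sm <- summarizeAmplicon(mono)
  expect_equal(sm$n_polymorphic_sites, 0L)
  expect_equal(sm$n_haplotypes, 1L)
  expect_equal(sm$n_distinguishable_genotypes, 1L)
})

test_that("pairwise combination table equals joint-profile enumeration", {
  # marker A splits {1,2} | {3,4}; marker B splits {1,3} | {2,4}
  cmA <- rbind(g1 = c(1000L, 0L), g2 = c(1000L, 0L),
               g3 = c(0L, 1000L), g4 = c(0L, 1000L))
  cmB <- rbind(g1 = c(1000L, 0L), g2 = c(0L, 1000L),
               g3 = c(1000L, 0L), g4 = c(0L, 1000L))
  tabs <- list(A = makeHaplotypeTable(cmA, marker = "A"),
               B = makeHaplotypeTable(cmB, marker = "B"))
  pc <- pairwiseCombinationTable(tabs)
  expect_equal(diag(pc), c(A = 2L, B = 2L))
  expect_equal(pc["A", "B"], 4L)
  expect_equal(pc, t(pc))

  # duplicate marker paired with itself adds nothing
  pc2 <- pairwiseCombinationTable(list(makeHaplotypeTable(cmA, marker = "A"),
                                       makeHaplotypeTable(cmA, marker = "A2")))
  expect_equal(pc2[1, 2], pc2[1, 1])

  # randomized fixtures against a brute-force oracle, plus bounds
  set.seed(16)
  for (i in 1:5) {
    n <- 20
    mk <- function(id) {
      d <- t(vapply(seq_len(n), function(g) {
        k <- sample(1:3, 1)
        v <- rep(0L, 3)
        v[sample(1:3, k)] <- as.integer(diff(c(0, sort(sample(1:3, k - 1)),
                                               4)))
        v
      }, integer(3)))
      rownames(d) <- sprintf("g%02d", 1:n)
      colnames(d) <- paste0("H", 1:3)
      simulateAmpliconReads(d, depth = 5000, seed = 100 + i,
                            markerId = id)
    }
    tabs <- list(mk("m1"), mk("m2"))
    pc <- pairwiseCombinationTable(tabs)
    lab <- lapply(tabs, polyfp:::.dosageMultisets)
    oracle <- length(unique(paste(lab[[1]], lab[[2]], sep = "|")))
    expect_equal(pc[1, 2], oracle)
    expect_gte(pc[1, 2], max(diag(pc)))
    expect_lte(pc[1, 2], min(n, prod(diag(pc))))
  }
  expect_error(pairwiseCombinationTable(tabs[1]),
               class = "polyfp_usage_error")
})

test_that("concordance report mirrors per-source unscored counts", {
  a <- makeScoreMatrix(rbind(c(1L, 2L), c(1L, NA), c(3L, 2L), c(NA, 2L),
                             c(1L, 1L)))
  expect_equal(concordanceWithReference(a, a)$agreement, 1)

  r <- makeScoreMatrix(rbind(c(1L, 2L), c(1L, 3L), c(2L, 2L), c(1L, NA),
                             c(1L, 1L)))
  res <- concordanceWithReference(a, r)
  # shared scored cells: (1,1),(3,1),(5,1),(1,2),(3,2),(5,2) minus NAs
  pm <- res$perMarker
  expect_equal(pm$n_identical, c(3L, 3L))
  expect_equal(pm$n_differing, c(1L, 0L))
  expect_equal(pm$n_unscored_total, c(1L, 2L))
  expect_equal(pm$n_unscored_amplicon, c(1L, 1L))
  expect_equal(pm$n_unscored_reference, c(0L, 1L))
  expect_equal(res$agreement, 6 / 7)
})
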