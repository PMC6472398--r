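# Transcriptome-level aggregation, bootstrap CIs, coverage trend,
# robustness and consistency.

mkResults <- function(deltas, size = 28L, frame = 0L) {
  n <- length(deltas)
  data.frame(gene_id = sprintf("g%03d", seq_len(n)),
             size = rep(size, n), frame = rep(frame, n),
             delta_prime = deltas,
             delta_second = rep(NA_integer_, n), T_prime = rep(10, n),
             T_second = rep(5, n), coverage = rep(2, n),
             secondary_applied = rep(FALSE, n),
             status = rep("informative", n))
}

test_that("aggregation applies the unique-fraction and min-genes rules", {
  th <- selectionThresholds()
  # 72 of 100 genes at 15 -> unique
  res <- mkResults(c(rep(15L, 72), rep(18L, 28)))
  row <- offsetRows(aggregateOffsets(res, th, sizeRange = 28L, B = 100,
                                     seed = 1))
  r <- row[row$frame == 0, ]
  expect_equal(r$status, "unique")
  expect_equal(r$primary, 15)
  expect_equal(r$fraction, 0.72)
  expect_equal(r$n_genes, 100L)

  # 47% at 15, 30% at 18 -> ambiguous with both offsets
  res2 <- mkResults(c(rep(15L, 47), rep(18L, 30), rep(12L, 23)))
  r2 <- offsetRows(aggregateOffsets(res2, th, sizeRange = 28L, B = 100,
                                    seed = 1))
  r2 <- r2[r2$frame == 0, ]
  expect_equal(r2$status, "ambiguous")
  expect_equal(r2$primary, 15)
  expect_equal(r2$secondary, 18)

  # 9 genes, all at 15 -> insufficient
  res3 <- mkResults(rep(15L, 9))
  r3 <- offsetRows(aggregateOffsets(res3, th, sizeRange = 28L, B = 100,
                                    seed = 1))
  expect_equal(r3$status[r3$frame == 0], "insufficient")

  # empty input -> insufficient, not an error
  r4 <- offsetRows(aggregateOffsets(mkResults(integer(0)), th,
                                    sizeRange = 28L, B = 100, seed = 1))
  expect_equal(r4$status, rep("insufficient", 3))
})

test_that("aggregation is permutation-invariant in gene order", {
  res <- mkResults(c(rep(15L, 40), rep(18L, 20)))
  set.seed(5)
  resPerm <- res[sample(nrow(res)), ]
  a <- offsetRows(aggregateOffsets(res, sizeRange = 28L, B = 100, seed = 2))
  b <- offsetRows(aggregateOffsets(resPerm, sizeRange = 28L, B = 100,
                                   seed = 2))
  expect_equal(a, b)
})

test_that("raising the unique fraction can only demote unique calls", {
  set.seed(11)
  for (i in 1:20) {
    frac <- sample(50:100, 1)
    res <- mkResults(c(rep(15L, frac), rep(18L, 100 - frac)))
    s70 <- offsetRows(aggregateOffsets(res, selectionThresholds(
      uniqueFraction = 0.7), sizeRange = 28L, B = 50, seed = 3))
    s80 <- offsetRows(aggregateOffsets(res, selectionThresholds(
      uniqueFraction = 0.8), sizeRange = 28L, B = 50, seed = 3))
    u70 <- s70$status[s70$frame == 0] == "unique"
    u80 <- s80$status[s80$frame == 0] == "unique"
    expect_true(!u80 || u70)  # unique at 80% implies unique at 70%
  }
})

test_that("bootstrap CI behaves on degenerate and binomial samples", {
  expect_equal(bootstrapFractionCI(rep(1, 20), B = 200, seed = 1), c(1, 1))
  expect_error(bootstrapFractionCI(c(1, 0), B = 0), "at least 1")

  # 70/100 sample: percentile interval agrees with the normal approximation
  x <- c(rep(1, 70), rep(0, 30))
  ci <- bootstrapFractionCI(x, B = 2000, seed = 42)
  se <- sqrt(0.7 * 0.3 / 100)
  expect_true(ci[1] < 0.7 && ci[2] > 0.7)
  expect_equal(ci[1], 0.7 - 1.96 * se, tolerance = 0.25)
  expect_equal(ci[2], 0.7 + 1.96 * se, tolerance = 0.25)

  # two genes (1, 0): the four equiprobable resamples give lo 0, hi 1
  ci2 <- bootstrapFractionCI(c(1, 0), B = 4000, seed = 7)
  expect_equal(unname(ci2), c(0, 1))

  # CI contains the point estimate
  set.seed(8)
  for (i in 1:10) {
    x <- rbinom(50, 1, runif(1, 0.2, 0.8))
    ci <- bootstrapFractionCI(x, B = 300, seed = i)
    expect_true(ci[1] <= mean(x) && mean(x) <= ci[2])
  }

  # reproducible under a fixed seed, and the ambient RNG is untouched
  set.seed(99); before <- .Random.seed
  c1 <- bootstrapFractionCI(c(1, 1, 0, 0, 1), B = 100, seed = 5)
  expect_identical(.Random.seed, before)
  expect_identical(c1, bootstrapFractionCI(c(1, 1, 0, 0, 1), B = 100,
                                           seed = 5))
})

test_that("coverage trend resolves rising fractions and rejects flat ones", {
  set.seed(21)
  # construct per-gene data whose modal fraction rises with coverage
  n <- 400
  coverage <- rep(c(1, 2, 5, 10, 20), length.out = n)
  # fraction at 15 rises from ~60% (low coverage kept) to ~85%
  p <- 0.55 + 0.017 * coverage
  delta <- ifelse(runif(n) < p, 15L, 18L)
  tr <- coverageTrend(coverage, delta, thresholdGrid = c(1, 2, 5, 10, 20))
  expect_true(tr$slope > 0)
  expect_lt(tr$p_value, 0.05)
  expect_true(tr$resolved)
  expect_equal(tr$resolved_offset, 15)

  # constant 50/50 split never resolves
  delta2 <- rep(c(15L, 18L), n / 2)
  tr2 <- coverageTrend(coverage, delta2, thresholdGrid = c(1, 2, 5, 10, 20))
  expect_false(tr2$resolved)

  # cutoffs retaining fewer than 10 genes are dropped from the regression
  cov3 <- c(rep(1, 50), rep(60, 8))
  delta3 <- rep(15L, 58)
  tr3 <- coverageTrend(cov3, delta3, thresholdGrid = c(1, 2, 50))
  expect_false(50 %in% tr3$thresholds)

  # fewer than two surviving cutoffs: no regression, unresolved
  tr4 <- coverageTrend(rep(1, 12), rep(15L, 12), thresholdGrid = c(1, 50))
  expect_false(tr4$resolved)
  expect_true(is.na(tr4$p_value))
})

test_that("robustness scan labels stable and threshold-sensitive calls", {
  # 19 of 20 genes at 15 (95%): unique under every variation -> R
  prR <- plantedProfileSet(20, c(rep(15L, 19), 18L))
  labR <- robustnessScan(prR, sizeRange = 28L)
  expect_equal(labR$label[labR$size == 28 & labR$frame == 0], "R")
  # 18 of 25 at 15 (72%): unique at 70%, ambiguous at 80% -> S
  prS <- plantedProfileSet(25, c(rep(15L, 18), rep(18L, 7)))
  labS <- robustnessScan(prS, sizeRange = 28L)
  expect_equal(labS$label[labS$size == 28 & labS$frame == 0], "S")
  # combinations without a baseline unique call are unlabeled
  expect_true(all(is.na(labR$label[labR$frame != 0])))
})

test_that("consistency fractions count matching modal offsets", {
  mkTab <- function(primary, status = "unique") {
    OffsetTable(data.frame(size = 28L, frame = 0:2, status = status,
                           primary = primary,
                           secondary = if (status[1] == "ambiguous") 12
                                       else NA_real_))
  }
  ref <- mkTab(c(15, 15, 18))
  tabs <- list(mkTab(c(15, 15, 18)), mkTab(c(15, 18, 18)),
               mkTab(c(15, 15, 18)), mkTab(c(18, 15, 18)))
  cc <- consistencyCheck(ref, tabs)
  expect_equal(cc$consistency[cc$frame == 0], 0.75)
  expect_equal(cc$consistency[cc$frame == 2], 1.0)
  expect_false(cc$discard[cc$frame == 0])
  expect_equal(cc$consistency[cc$frame == 1], 0.75)
  # a dataset's modal offset counts even when its call is ambiguous
  tabs2 <- list(mkTab(c(15, 15, 18), status = "ambiguous"))
  cc2 <- suppressWarnings(consistencyCheck(ref, tabs2))
  expect_equal(cc2$consistency[cc2$frame == 0], 1)
  # ambiguous reference rows are skipped
  refAmb <- OffsetTable(data.frame(size = 28L, frame = 0:2,
                                   status = "ambiguous", primary = 15,
                                   secondary = 18))
  cc3 <- consistencyCheck(refAmb, tabs)
  expect_true(all(is.na(cc3$consistency)))
})
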