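# Per-gene integer-programming optimization: objective, constraints,
# secondary criteria, filtering.

test_that("shifted codon counts place reads in the right codons", {
  # upstream read shifted into codon 1
  expect_equal(shiftedCodonCounts(list(pos = -14L, count = 5), 30L, 15L, 33L),
               c(5, rep(0, 9)))
  # unshifted read at j = 4 belongs to codon 2
  expect_equal(shiftedCodonCounts(list(pos = 4L, count = 2), 30L, 0L, 20L),
               c(0, 2, rep(0, 8)))
  # all-zero track stays all-zero
  expect_equal(shiftedCodonCounts(list(pos = integer(), count = numeric()),
                                  30L, 6L, 28L),
               rep(0, 10))
  # shifting beyond N_C drops reads instead of wrapping
  expect_equal(sum(shiftedCodonCounts(list(pos = 29L, count = 3), 30L, 6L,
                                      28L)), 0)
})

test_that("objective counts reads shifted into the window [4, N_C]", {
  track <- list(pos = c(-14L, 1L, 10L), count = c(5, 2, 3))
  expect_equal(objectiveScore(track, 30L, 15L, 33L)$T, 5)
  expect_equal(objectiveScore(track, 30L, 18L, 33L)$T, 10)
  expect_equal(objectiveScore(list(pos = integer(), count = numeric()),
                              30L, 9L, 30L)$T, 0)
})

test_that("offset constraints are enforced", {
  track <- list(pos = 4L, count = 1)
  expect_error(objectiveScore(track, 30L, 14L, 33L), "multiple of 3")
  expect_error(objectiveScore(track, 30L, 36L, 33L), "multiple of 3")
  expect_error(shiftedCodonCounts(track, 30L, -3L, 33L), "multiple of 3")
})

test_that("secondary criteria choose the biologically plausible candidate", {
  # candidate A: empty start codon, second > third -> passes
  a <- c(0, 10, 4, 6, 5, 5, 5, 5, 5, 5)
  # candidate B: loaded start codon -> fails
  b <- c(5, 2, 8, 6, 5, 5, 5, 5, 5, 5)
  sel <- applySecondaryCriteria(a, b, 18L, 15L)
  expect_equal(sel$delta, 18L)
  expect_true(sel$passPrime); expect_false(sel$passSecond)
  # B as prime candidate: A still wins even though B had max T
  sel2 <- applySecondaryCriteria(b, a, 15L, 18L)
  expect_equal(sel2$delta, 18L)
  # both fail -> keep the max-T candidate
  sel3 <- applySecondaryCriteria(b, b, 15L, 18L)
  expect_equal(sel3$delta, 15L)
  expect_error(applySecondaryCriteria(a, b[1:5], 18L, 15L), "length")
})

test_that("closeness rule gates the secondary criteria", {
  pass <- c(0, 10, 4, 6)
  failv <- c(5, 2, 8, 6)
  # difference above the per-codon average: scores decide alone
  sel <- selectOffset(15L, 18L, 100, 50, 7.85, pass, failv)
  expect_false(sel$secondaryApplied)
  expect_equal(sel$delta, 15L)
  # difference below the average: criteria arbitrate
  sel2 <- selectOffset(18L, 15L, 222, 215, 7.85, pass, failv)
  expect_true(sel2$secondaryApplied)
  expect_equal(sel2$delta, 18L)
})

test_that("per-gene optimization scans the feasible set exhaustively", {
  track <- list(pos = c(-14L, 1L, 10L), count = c(5, 2, 3))
  r <- optimizeGeneOffset(track, 30L, 33L, 0L)
  expect_equal(r$delta_prime, 18L)
  expect_equal(r$T_prime, 10)
  expect_equal(r$status, "informative")
  # runner-up confirmed by the independent oracle's enumeration
  expect_equal(bruteOptimize(track, 30L, 33L)$delta, 18L)
  expect_equal(r$delta_second, 21L)
  expect_equal(r$T_second, 7)

  # all-zero track is uninformative, not an error
  r0 <- optimizeGeneOffset(list(pos = integer(), count = numeric()),
                           30L, 28L, 0L)
  expect_equal(r0$status, "uninformative")
  expect_true(is.na(r0$delta_prime))

  # reads only in the window at Delta = 0 and unreachable otherwise
  trackZero <- list(pos = c(6L, 9L), count = c(4, 4))
  rz <- optimizeGeneOffset(trackZero, 9L, 3L, 2L)
  expect_equal(rz$delta_prime, 0L)
})

test_that("optimization is deterministic", {
  set.seed(42)
  tr <- randomTrack(60L, 30L)
  r1 <- optimizeGeneOffset(tr, 60L, 30L, 0L)
  r2 <- optimizeGeneOffset(tr, 60L, 30L, 0L)
  expect_identical(r1, r2)
})

test_that("optimization agrees with the brute-force oracle on random tracks", {
  set.seed(101)
  nAgree <- 0L
  n <- 400L
  for (i in seq_len(n)) {
    ncCds <- sample(c(30L, 45L, 60L), 1)
    S <- sample(20:35, 1)
    tr <- randomTrack(ncCds, S, nSpikes = sample(2:10, 1))
    mine <- optimizeGeneOffset(tr, ncCds, S, 0L)
    oracle <- bruteOptimize(tr, ncCds, S)
    same <- identical(oracle$status, mine$status) &&
      (oracle$status == "uninformative" ||
         oracle$delta == mine$delta_prime)
    if (same) nAgree <- nAgree + 1L
  }
  expect_equal(nAgree, n)
})

test_that("objective never exceeds the track total and shifting conserves reads", {
  set.seed(7)
  for (i in 1:50) {
    ncCds <- 60L; S <- sample(20:35, 1)
    tr <- randomTrack(ncCds, S)
    total <- sum(tr$count)
    for (d in seq(0, S, by = 3)) {
      sc <- objectiveScore(tr, ncCds, d, S)
      expect_lte(sc$T, total)
      codons <- shiftedCodonCounts(tr, ncCds, d, S)
      shifted <- tr$pos + d
      outside <- sum(tr$count[shifted < 1 | shifted > ncCds])
      expect_equal(sum(codons) + outside, total)
    }
  }
})

test_that("gene filter applies the coverage and multimapping rules", {
  # 150 reads on 100 codons -> 1.5 > 1 -> pass
  track <- list(pos = as.integer(seq(-27, 272, by = 2)), count = rep(1, 150))
  expect_true(passesGeneFilter(track, 300L, 28L, 0))
  # identical coverage but 2% multimapped -> fail
  expect_false(passesGeneFilter(track, 300L, 28L, 0.02))
  # zero reads -> fail
  expect_false(passesGeneFilter(list(pos = integer(), count = numeric()),
                                300L, 28L, 0))
  # reads upstream of the filter window do not count
  far <- list(pos = rep(-35L, 3), count = rep(200, 3))
  expect_false(passesGeneFilter(far, 300L, 28L, 0))
})

test_that("detection produces 3 slots per size per gene with statuses", {
  pr <- plantedProfileSet(3, c(15, 15, 18))
  res <- detectOffsets(pr, sizeRange = 20:35)
  expect_equal(nrow(res), 3 * 48)
  expect_equal(sort(unique(res$size)), 20:35)
  # the planted combination is informative with the planted offsets
  sub <- res[res$size == 28 & res$frame == 0, ]
  expect_equal(sub$status, rep("informative", 3))
  expect_equal(sort(sub$delta_prime), c(15L, 15L, 18L))
  # untouched combinations are filtered, not guessed
  expect_true(all(res$status[res$size == 22] == "filtered"))
})

test_that("3'-anchored tracks shift toward the 5' end", {
  # reads anchored at the 3' end, true offset 12 toward 5': x - 12 in window;
  # the second codon is initiation-enriched so the secondary criteria can
  # break the tie between offsets that both keep every read in the window
  k <- 2:19
  a <- 3L * k - 2L
  x3 <- a + 12L                       # 3' ends sit 12 nt downstream of A-site
  track <- list(pos = as.integer(x3),
                count = c(5, rep(2, length(x3) - 1L)))
  r <- optimizeGeneOffset(track, 60L, 28L, 0L, anchor = "three_prime")
  expect_equal(r$delta_prime, 12L)
})
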