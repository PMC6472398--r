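# A-site profile construction, baselines, normalization, metagene.

asiteFixture <- function(rows, nCodons = 20L, ids = NULL) {
  ids <- ids %||% unique(rows$gene_id)
  genes <- GeneModelSet(ids, 3L * nCodons)
  RiboProfileSet(rows, genes)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("offset application moves reads to the right codon", {
  pr <- asiteFixture(data.frame(gene_id = "g1", size = 28, frame = 0,
                                pos = 1, count = 4))
  tab <- OffsetTable(data.frame(size = 28L, frame = 0:2, status = "unique",
                                primary = 15))
  as <- buildAsiteProfile(pr, tab, dropFlagged = list())
  v <- asiteValues(as)[["g1"]]
  expect_equal(v[6], 4)               # (1 + 15) = 16 -> codon 6
  expect_equal(sum(v), 4)
})

test_that("ambiguous and flagged combinations are excluded", {
  rows <- rbind(
    data.frame(gene_id = "g1", size = 32, frame = 0, pos = 1, count = 5),
    data.frame(gene_id = "g1", size = 27, frame = 1, pos = 2, count = 7),
    data.frame(gene_id = "g1", size = 28, frame = 0, pos = 4, count = 2))
  pr <- asiteFixture(rows)
  tab <- OffsetTable(data.frame(
    size = c(32L, 27L, 28L), frame = c(0L, 1L, 0L),
    status = c("ambiguous", "unique", "unique"),
    primary = c(18, 15, 15), secondary = c(15, NA, NA)))
  as <- buildAsiteProfile(pr, tab, dropAmbiguous = TRUE)
  # ambiguous (32,0) dropped, flagged (27,1) dropped; only (28,0) remains
  expect_equal(sum(asiteValues(as)[["g1"]]), 2)
  # keeping ambiguous combinations restores their reads
  as2 <- buildAsiteProfile(pr, tab, dropAmbiguous = FALSE,
                           dropFlagged = list())
  expect_equal(sum(asiteValues(as2)[["g1"]]), 14)
  # a fully dropped profile is all zeros, not an error
  as3 <- buildAsiteProfile(pr, OffsetTable(data.frame(
    size = 20L, frame = 0:2, status = "insufficient", primary = NA_real_)))
  expect_equal(sum(asiteValues(as3)[["g1"]]), 0)
})

test_that("the P-site profile is the A-site shifted one codon 5'-ward", {
  set.seed(31)
  rows <- data.frame(gene_id = "g1", size = 28, frame = 0,
                     pos = seq(4, 40, by = 3), count = rpois(13, 5) + 1)
  pr <- asiteFixture(rows)
  tab <- OffsetTable(data.frame(size = 28L, frame = 0L, status = "unique",
                                primary = 15))
  a <- asiteValues(buildAsiteProfile(pr, tab, dropFlagged = list()))[["g1"]]
  p <- asiteValues(buildAsiteProfile(pr, tab, dropFlagged = list(),
                                     site = "P"))[["g1"]]
  expect_equal(p[1:19], a[2:20])
})

test_that("baseline tables match the literature rules", {
  h <- offsetRows(baselineOffsetTable("hussmann_frame"))
  expect_equal(h$primary[h$size == 28 & h$frame == 1], 14)
  expect_equal(h$primary[h$size == 30 & h$frame == 1], 17)
  expect_equal(h$status[h$size == 27 & h$frame == 0], "insufficient")
  i <- offsetRows(baselineOffsetTable("ingolia_mesc"))
  expect_equal(i$primary[i$size == 31], rep(16, 3))
  expect_equal(i$primary[i$size == 34], rep(17, 3))
  c15 <- offsetRows(baselineOffsetTable("const15"))
  expect_equal(unique(c15$primary[c15$status == "unique"]), 15)
  expect_equal(sort(unique(c15$size[c15$status == "unique"])), 27:30)
  w <- offsetRows(baselineOffsetTable("const15_wide"))
  expect_equal(sort(unique(w$size[w$status == "unique"])), 25:35)
  expect_error(baselineOffsetTable("nope"))
})

test_that("center-weighted density spreads reads over the trimmed span", {
  pr <- asiteFixture(data.frame(gene_id = "g1", size = 28, frame = 0,
                                pos = 1, count = 1))
  cw <- centerWeightedProfile(pr)
  v <- asiteValues(cw)[["g1"]]
  # 28 - 22 = 6 central nucleotides (12..17), 1/6 each -> codons 4,5,6
  expect_equal(sum(v) + attr(cw, "outside_mass"), 1, tolerance = 1e-9)
  expect_equal(v[4], 1 / 6, tolerance = 1e-9)
  expect_equal(v[5], 3 / 6, tolerance = 1e-9)
  expect_equal(v[6], 2 / 6, tolerance = 1e-9)
  # 23-nt reads contribute nothing
  pr23 <- asiteFixture(data.frame(gene_id = "g1", size = 23, frame = 0,
                                  pos = 1, count = 5))
  expect_equal(sum(asiteValues(centerWeightedProfile(pr23))[["g1"]]), 0)
  # per-read mass conservation on random fixtures
  set.seed(32)
  rows <- data.frame(gene_id = "g1", size = sample(24:35, 30, TRUE),
                     frame = 0, pos = 0, count = sample(1:4, 30, TRUE))
  rows$pos <- sample(seq(1, 30, by = 3), 30, TRUE)
  rows$frame <- (rows$pos - 1) %% 3
  prR <- asiteFixture(rows, nCodons = 40L)
  cwR <- centerWeightedProfile(prR)
  expect_equal(sum(asiteValues(cwR)[["g1"]]) + attr(cwR, "outside_mass"),
               sum(rows$count), tolerance = 1e-9)
})

test_that("normalized density has unit mean and is scale invariant", {
  expect_equal(normalizedDensity(c(2, 0, 4)), c(1, 0, 2))
  expect_error(normalizedDensity(c(0, 0, 0)), "all-zero")
  set.seed(33)
  v <- rpois(50, 3)
  v[1] <- v[1] + 1
  expect_equal(mean(normalizedDensity(v)), 1)
  expect_equal(normalizedDensity(v * 7), normalizedDensity(v))
})

test_that("metagene aligns and averages normalized densities", {
  genes <- GeneModelSet(c("g1", "g2", "g3"), c(60L, 60L, 30L))
  mk <- function(n, pause = NULL) {
    v <- rep(2, n)
    if (!is.null(pause)) v[pause] <- 10
    v
  }
  vals <- list(g1 = mk(20), g2 = mk(20), g3 = mk(10))
  as <- new("AsiteProfileSet", values = vals, method = "toy", genes = genes)
  mg <- metageneDensity(as, "start", windowCodons = 15L)
  expect_equal(mg$mean_density, rep(1, 15))
  expect_equal(mg$n_genes[1:10], rep(3L, 10))
  expect_equal(mg$n_genes[11:15], rep(2L, 15)[1:5])  # short gene truncated

  # a shared pause at codon 7 peaks at position 7
  vals2 <- list(g1 = mk(20, 7), g2 = mk(20, 7))
  as2 <- new("AsiteProfileSet", values = vals2, method = "toy",
             genes = genes)
  mg2 <- metageneDensity(as2, "start", windowCodons = 12L)
  expect_equal(which.max(mg2$mean_density), 7L)

  # stop alignment puts position 0 on the stop codon
  mg3 <- metageneDensity(as, "stop", windowCodons = 15L)
  expect_equal(mg3$position[length(mg3$position)], 0L)
  expect_equal(mg3$mean_density, rep(1, 15))
})
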