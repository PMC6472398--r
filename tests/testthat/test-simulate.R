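# Synthetic Ribo-Seq generator: Gillespie occupancies, (S, F) event
# distribution, read emission, truth-table comparison.

test_that("uniform elongation yields uniform occupancy over visited codons", {
  genes <- GeneModelSet("gU", 3L * 60L)
  occ <- simulateOccupancies(genes, stepsPerCodon = 2000L, seed = 1)[["gU"]]
  expect_equal(occ[1], 0L)            # A-site never sits on the start codon
  visited <- occ[-1]
  expect_gt(sum(visited), 2000)
  chi <- suppressWarnings(chisq.test(visited))
  expect_gt(chi$p.value, 0.01)
})

test_that("occupancy is inversely proportional to the elongation rate", {
  genes <- GeneModelSet("gR", 9L)      # 3 codons
  rates <- list(gR = c(1, 1, 2))       # codon 3 twice as fast as codon 2
  occ <- simulateOccupancies(genes, elongationRates = rates,
                             stepsPerCodon = 60000L, seed = 2)[["gR"]]
  ratio <- occ[2] / occ[3]
  se <- ratio * sqrt(1 / occ[2] + 1 / occ[3])
  expect_lt(abs(ratio - 2), 3 * se + 0.2)
})

test_that("the simulator is reproducible and validates inputs", {
  genes <- GeneModelSet("gS", 45L)
  o1 <- simulateOccupancies(genes, seed = 7)
  o2 <- simulateOccupancies(genes, seed = 7)
  expect_identical(o1, o2)
  expect_error(riboAsite:::gillespie_occupancy(1L, 1, 1, 100L, 10L, 5L),
               "at least 2 codons")
  expect_error(riboAsite:::gillespie_occupancy(3L, c(1, 1, 0), 1, 100L,
                                               10L, 5L), "positive")
})

test_that("occupancy normalization hits the target exactly", {
  occ <- c(3, 0, 5, 2)
  norm <- normalizeOccupancy(occ, 100L)
  expect_equal(sum(norm), 100L)
  expect_equal(norm[2], 0L)
  expect_equal(norm, c(30L, 0L, 50L, 20L))
  # largest-remainder handles awkward proportions
  norm2 <- normalizeOccupancy(c(1, 1, 1), 100L)
  expect_equal(sum(norm2), 100L)
  expect_true(all(abs(norm2 - 100 / 3) < 1))
  expect_equal(normalizeOccupancy(c(0, 0), 0L), integer(2))
  expect_error(normalizeOccupancy(c(0, 0), 5L), "all-zero")
})

test_that("the (S, F) distribution is a shifted truncated Poisson", {
  d <- buildSFDistribution(8)
  pmf <- sfPmf(d)
  expect_length(pmf, 48L)
  expect_equal(sum(pmf), 1, tolerance = 1e-12)
  # maximal at (28, 0); for integer lambda the event one step left ties
  expect_equal(pmf[["28_0"]], max(pmf))
  # direct factorial-formula oracle for the modal event
  mass <- sum(exp(-8) * 8^(0:31) / factorial(0:31))
  expect_equal(pmf[["28_0"]], (exp(-8) * 8^8 / factorial(8)) / mass,
               tolerance = 1e-12)
  # alternative modes relocate the peak
  d24 <- buildSFDistribution(8, modeSF = c(24L, 0L))
  expect_equal(names(which.max(sfPmf(d24))), "23_2")  # exact tie at 24_0
  expect_equal(sfPmf(d24)[["24_0"]], max(sfPmf(d24)))
  expect_error(buildSFDistribution(0), "lam > 0")
})

test_that("read emission follows the offsets and conserves reads", {
  genes <- GeneModelSet("gE", 60L, upstream_pad = 40L)
  occ <- list(gE = c(0L, rep(0L, 18), 100L))  # all reads on codon 20...
  # lam tiny: essentially all mass at the mode event (28, 0)
  d <- buildSFDistribution(1e-9)
  sch <- offsetScheme("const15")
  gen <- generateProfiles(occ, genes, d, sch, seed = 3)
  dt <- profileCounts(gen$profiles)
  expect_equal(sum(dt$count) + gen$spilled, 100)
  main <- dt[dt$size == 28 & dt$frame == 0, ]
  # A-site codon 20 starts at a = 58; 5' end at 58 - 15 = 43
  expect_equal(main$pos, 43L)
  expect_gte(main$count, 99)

  # zero occupancy -> empty profiles
  gen0 <- generateProfiles(list(gE = integer(20)), genes, d, sch, seed = 3)
  expect_equal(nrow(profileCounts(gen0$profiles)), 0L)
})

test_that("reads below the upstream pad spill and are counted", {
  genes <- GeneModelSet("gP", 60L, upstream_pad = 5L)
  occ <- list(gP = c(0L, 50L, rep(0L, 18)))   # codon 2, a = 4
  d <- buildSFDistribution(1e-9)              # (28, 0), offset 15
  gen <- generateProfiles(occ, genes, d, offsetScheme("const15"), seed = 4)
  # x = 4 - 15 = -11 < 1 - 5: every modal-event read spills
  expect_gt(gen$spilled, 45)
  expect_equal(sum(profileCounts(gen$profiles)$count) + gen$spilled, 50)
})

test_that("emitted (S, F) frequencies converge to the event pmf", {
  genes <- GeneModelSet("gF", 3L * 200L, upstream_pad = 40L)
  occ <- list(gF = c(0L, rep(2500L, 199L)))   # half a million reads
  d <- buildSFDistribution(8)
  gen <- generateProfiles(occ, genes, d, offsetScheme("const18"), seed = 5)
  dt <- profileCounts(gen$profiles)
  emp <- tapply(dt$count, paste(dt$size, dt$frame, sep = "_"), sum)
  tot <- sum(emp) + gen$spilled
  pmf <- sfPmf(d)
  empFull <- stats::setNames(rep(0, 48), names(pmf))
  empFull[names(emp)] <- emp / tot
  tv <- sum(abs(empFull - pmf)) / 2
  expect_lt(tv, 0.01)
})

test_that("whole-generator runs are seed-deterministic", {
  s1 <- simulateRiboseq(nGenes = 4, lengthRange = c(50, 60),
                        medianReadsPerCodon = 10, seed = 12)
  s2 <- simulateRiboseq(nGenes = 4, lengthRange = c(50, 60),
                        medianReadsPerCodon = 10, seed = 12)
  expect_equal(profileCounts(s1$profiles), profileCounts(s2$profiles))
  s3 <- simulateRiboseq(nGenes = 4, lengthRange = c(50, 60),
                        medianReadsPerCodon = 10, seed = 13)
  expect_false(isTRUE(all.equal(profileCounts(s1$profiles),
                                profileCounts(s3$profiles))))
})

test_that("offset schemes define the documented ground truths", {
  rows15 <- offsetRows(offsetScheme("const15"))
  expect_true(all(rows15$primary == 15) && nrow(rows15) == 48)
  rowsSplit <- offsetRows(offsetScheme("split12_18"))
  expect_true(all(rowsSplit$primary[rowsSplit$size <= 27] == 12))
  expect_true(all(rowsSplit$primary[rowsSplit$size >= 28] == 18))
  # custom tables pass through
  tab <- readOffsetTable(system.file("extdata", "scerevisiae_offsets.tsv",
                                     package = "riboAsite"))
  expect_identical(offsetScheme("table", table = tab), tab)
})

test_that("offset-table comparison counts unique, correct recoveries", {
  truth <- offsetScheme("const15")
  expect_equal(compareOffsetTables(truth, truth)$fraction_all, 1)
  # degrade 3 of 48 combos -> 45/48
  rows <- offsetRows(truth)
  rows$n_genes <- 50L
  rows$status[1:3] <- "ambiguous"
  rows$secondary[1:3] <- 18
  degraded <- OffsetTable(rows)
  cmp <- compareOffsetTables(truth, degraded)
  expect_equal(cmp$fraction_all, 45 / 48)
  expect_equal(cmp$n_covered, 48L)
})
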