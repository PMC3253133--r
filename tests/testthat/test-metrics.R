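test_that("Diff is the total-variation distance on matched compositions", {
  expect_equal(diffScore(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(diffScore(c(1, 0), c(0, 1)), 1)
  expect_equal(diffScore(c(0.7, 0.3), c(0.5, 0.5)), 0.2)
  expect_equal(diffScore(c(a = 0.7, b = 0.3), c(b = 0.3, a = 0.7)), 0)  # name matching
  expect_error(diffScore(c(0.5, 0.5), c(1, 0, 0)), "mismatched")
  expect_error(diffScore(c(a = 1, b = 0), c(a = 1, c = 0)), "mismatched")
})

test_that("Diff is a metric on the simplex", {
  set.seed(42)
  for (i in 1:1000) {
    K <- sample(2:5, 1)
    draw <- function() { x <- stats::rexp(K); x / sum(x) }
    a <- draw(); b <- draw(); c <- draw()
    dab <- diffScore(a, b); dbc <- diffScore(b, c); dac <- diffScore(a, c)
    expect_gte(dab, 0); expect_lte(dab, 1)
    expect_equal(dab, diffScore(b, a))
    expect_lte(dac, dab + dbc + 1e-12)
  }
  expect_identical(diffScore(c(0.2, 0.8), c(0.2, 0.8)), 0)
})

test_that("dominant isoform selection is deterministic under ties", {
  g <- makeToyGene(c(50L, 30L, 40L), list(c(1L, 2L), c(1L, 3L), c(2L, 3L)))
  expect_equal(dominantIsoform(c(iso1 = 0.2, iso2 = 0.5, iso3 = 0.3), g), "iso2")
  # tie on theta: longer isoform wins (iso2 L=90 vs iso3 L=70)
  expect_equal(dominantIsoform(c(iso1 = 0.2, iso2 = 0.4, iso3 = 0.4), g), "iso2")
  # full tie on theta and length: lexicographic id
  g2 <- makeToyGene(c(50L, 30L, 30L), list(c(1L, 2L), c(1L, 3L)))
  expect_equal(dominantIsoform(c(iso1 = 0.5, iso2 = 0.5), g2), "iso1")
})

test_that("structural differences between dominants classify by aspect", {
  # skipped internal block only: Alternative Exon with weight 1
  gA <- toyGenePreset("geneA")
  w <- classifyStructuralDifference(gA, "iso1", "iso2")
  expect_equal(unname(w["Alternative Exon"]), 1)
  expect_equal(sum(w), 1)
  # internal boundary change: extra block contiguous with a shared one
  gE <- makeToyGene(c(40L, 20L, 40L), list(c(1L, 2L, 3L), c(1L, 3L)),
                    gaps = c(0L, 50L))
  wE <- classifyStructuralDifference(gE, 1, 2)
  expect_equal(unname(wE["Extended Exon"]), 1)
  # longer terminal 3' block (contiguous extension): Overlapping 3' UTR
  g3 <- makeToyGene(c(50L, 30L, 20L), list(c(1L, 2L), c(1L, 2L, 3L)),
                    gaps = c(50L, 0L))
  w3 <- classifyStructuralDifference(g3, 1, 2)
  expect_equal(unname(w3["Overlapping 3' UTR"]), 1)
  # distinct 5' starts plus a skipped internal block: 0.5 / 0.5
  g5 <- makeToyGene(c(30L, 30L, 25L, 40L, 30L),
                    list(c(1L, 3L, 4L, 5L), c(2L, 3L, 5L)))
  w5 <- classifyStructuralDifference(g5, 1, 2)
  expect_equal(unname(w5["Distinct 5' UTR"]), 0.5)
  expect_equal(unname(w5["Alternative Exon"]), 0.5)
  expect_equal(sum(w5), 1)
  # one-sided extra 5' block: Overlapping 5' UTR
  gO <- makeToyGene(c(30L, 40L, 40L), list(c(1L, 2L, 3L), c(2L, 3L)))
  expect_equal(unname(classifyStructuralDifference(gO, 1, 2)["Overlapping 5' UTR"]), 1)
  # minus strand: 5' and 3' swap genomic sides
  gM <- makeToyGene(c(30L, 40L, 40L), list(c(1L, 2L, 3L), c(2L, 3L)), strand = "-")
  expect_equal(unname(classifyStructuralDifference(gM, 1, 2)["Overlapping 3' UTR"]), 1)
  expect_error(classifyStructuralDifference(gA, "iso1", "iso1"), "identical")
  # weights always sum to 1 on random gene pairs
  for (seed in 1:10) {
    g <- randomToyGene(seed)
    keys <- vapply(g@isoforms, paste, character(1), collapse = ",")
    pick <- which(!duplicated(keys))
    if (length(pick) < 2L) next
    wr <- classifyStructuralDifference(g, pick[1L], pick[2L])
    expect_equal(sum(wr), 1, info = paste("seed", seed))
    expect_true(all(wr >= 0))
  }
})

test_that("perturbing the isoform set moves L_avg in the expected direction", {
  g <- makeToyGene(c(40L, 30L, 30L, 40L),
                   list(c(1L, 2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 3L)))
  m <- shotgunMethod("s", 10L)
  r <- simulateReads(g, c(0.6, 0.25, 0.15), m, 5000L, seed = 5)
  dropDom <- perturbationAnalysis(g, list(m), r, "drop_dominant")
  dropMin <- perturbationAnalysis(g, list(m), r, "drop_minor")
  addDum <- perturbationAnalysis(g, list(m), r, "add_dummy")
  expect_lt(dropDom$deltaLAvg, 0)
  expect_lt(dropMin$deltaLAvg, 0)
  expect_gt(abs(dropDom$deltaLAvg), abs(dropMin$deltaLAvg))
  expect_lt(addDum$deltaTheta, 0.01)
  # dropping a zero-abundance isoform leaves L_avg unchanged
  g0 <- toyGenePreset("geneA")
  r0 <- simulateReads(g0, c(1, 0), m, 2000L, seed = 6)
  pa0 <- perturbationAnalysis(g0, list(m), r0, "drop_minor")
  expect_lt(abs(pa0$deltaLAvg), 1e-9)
  expect_error(perturbationAnalysis(simpleShotgunGene(), list(m),
                                    simulateReads(simpleShotgunGene(), 1, m, 10L, seed = 1),
                                    "drop_minor"), "K >= 2")
})

test_that("transcriptome complexity is expression-weighted entropy in bits", {
  # single-isoform genes carry no isoform diversity
  expect_equal(transcriptomeComplexity(list(1, 1, 1)), 0)
  # uniform over 4 isoforms: 2 bits
  expect_equal(transcriptomeComplexity(list(rep(0.25, 4))), 2)
  # weighted mean over three genes, by hand
  th <- list(c(0.5, 0.5), c(1, 0), rep(1 / 4, 4))
  wts <- c(2, 1, 1)
  expect_equal(transcriptomeComplexity(th, wts), (2 * 1 + 1 * 0 + 1 * 2) / 4)
  expect_error(transcriptomeComplexity(th, c(0, 0, 0)), "zero")
})
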