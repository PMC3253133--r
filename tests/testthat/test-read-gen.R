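test_that("compatibility is junction-exact and strand/chromosome aware", {
  g <- toyGenePreset("geneA")   # blocks [0,60) [110,140) [190,250), iso1=(1,2,3), iso2=(1,3)
  m <- shotgunMethod("s", 10L)
  # intra-block read: compatible with both isoforms containing block 1
  expect_equal(isCompatible(g, m, rbind(c(5L, 15L)), 1), 1L)
  expect_equal(isCompatible(g, m, rbind(c(5L, 15L)), 2), 1L)
  # read spanning the 1|2 junction: iso2 lacks block 2
  j12 <- rbind(c(55L, 60L), c(110L, 115L))
  expect_equal(isCompatible(g, m, j12, 1), 1L)
  expect_equal(isCompatible(g, m, j12, 2), 0L)
  # read spanning the 1|3 junction: iso1 has block 2 in between
  j13 <- rbind(c(55L, 60L), c(190L, 195L))
  expect_equal(isCompatible(g, m, j13, 1), 0L)
  expect_equal(isCompatible(g, m, j13, 2), 1L)
  # junction-inexact read (gap not at a block boundary) matches nothing
  expect_equal(isCompatible(g, m, rbind(c(54L, 59L), c(110L, 115L)), 1), 0L)
})

test_that("paired-end compatibility applies the fragment-length window", {
  # skipped 150 nt exon: mates 300 apart on the long isoform, 150 on the short
  g <- makeToyGene(c(150L, 150L, 150L), list(c(1L, 2L, 3L), c(1L, 3L)))
  mate1 <- rbind(c(50L, 100L))          # tx [50,100) on both isoforms
  mate2 <- rbind(c(400L, 450L))         # first 50 nt of block 3
  tight <- pairedEndMethod("pe", 50L, 300, 0.1)
  loose <- pairedEndMethod("pe", 50L, 300, 1.5)
  expect_equal(isCompatible(g, tight, mate1, 1, mate2), 1L)
  expect_equal(isCompatible(g, tight, mate1, 2, mate2), 0L)
  expect_equal(isCompatible(g, loose, mate1, 1, mate2), 1L)
  expect_equal(isCompatible(g, loose, mate1, 2, mate2), 1L)
})

test_that("generation probabilities normalize over each isoform's read space", {
  g100 <- simpleShotgunGene(100L)
  m25 <- shotgunMethod("s", 25L)
  expect_equal(gValue(g100, m25, rbind(c(40L, 65L)), 1), 1 / 76)

  geoms <- function(g) isomix:::.isoGeom(g)
  sumG <- function(g, method, k, lens) {
    gm <- geoms(g)
    tot <- 0
    for (l in lens) {
      L <- gm[[k]]$L
      if (L < l) next
      for (p in 0:(L - l)) {
        b <- isomix:::.txToGenomicBlocks(g, gm, k, p, l)
        tot <- tot + gValue(g, method, b, k)
      }
    }
    tot
  }
  g <- toyGenePreset("geneA")
  for (k in 1:2) {
    expect_equal(sumG(g, shotgunMethod("s", 10L), k, 10L), 1)
    mix <- lengthMixtureMethod("mix", c(5L, 12L), c(0.3, 0.7))
    expect_equal(sumG(g, mix, k, c(5L, 12L)), 1)
    set.seed(k)
    prof <- stats::runif(100); prof <- prof / sum(prof)
    expect_equal(sumG(g, biasedMethod("b", 10L, prof), k, 10L), 1)
  }
  # paired-end: sum over all (start, fragment) placements
  pe <- pairedEndMethod("pe", 15L, 60, 0.2)
  gm <- geoms(g)
  for (k in 1:2) {
    L <- gm[[k]]$L
    tot <- 0
    for (d in isomix:::.validFragLengths(pe, L)) {
      for (p in 0:(L - d)) {
        b1 <- isomix:::.txToGenomicBlocks(g, gm, k, p, 15L)
        b2 <- isomix:::.txToGenomicBlocks(g, gm, k, p + d - 15L, 15L)
        tot <- tot + gValue(g, pe, b1, k, b2)
      }
    }
    expect_equal(tot, 1)
  }
})

test_that("degenerate families reduce to fixed shotgun", {
  g <- toyGenePreset("geneB")
  fixed <- shotgunMethod("f", 12L)
  single <- lengthMixtureMethod("m", 12L, 1)
  uniformBias <- biasedMethod("u", 12L, rep(0.01, 100))
  gm <- isomix:::.isoGeom(g)
  for (k in 1:2) {
    for (p in c(0L, 33L, 57L)) {
      b <- isomix:::.txToGenomicBlocks(g, gm, k, p, 12L)
      gf <- gValue(g, fixed, b, k)
      expect_identical(gValue(g, single, b, k), gf)
      expect_equal(gValue(g, uniformBias, b, k), gf)
    }
  }
  # gValue is zero whenever compatibility is zero
  j <- rbind(c(55L, 60L), c(110L, 116L))   # junction 1|2 of geneB
  expect_equal(isCompatible(g, fixed, j, 2), 0L)
  expect_identical(gValue(g, fixed, j, 2), 0)
})

test_that("empirical bias profiles aggregate per-transcript start signal", {
  g1 <- simpleShotgunGene(200L)
  m <- shotgunMethod("s", 20L)
  # all reads at the transcript start: all mass in bin 0
  rs <- readSet("s", replicate(50, rbind(c(0L, 20L)), simplify = FALSE),
                chrom = "chrT", strand = "+")
  prof <- buildBiasProfile(rs, list(g1))
  expect_equal(prof[1], 1)
  expect_equal(sum(prof), 1, tolerance = 1e-12)
  # uniform simulated reads over many transcripts recover the uniform
  # start-position law (exact expectation accounts for the l-1 trailing
  # positions where no read can start)
  L <- 1000L; l <- 10L; nTx <- 30L; nPerTx <- 400L
  genes <- lapply(seq_len(nTx), function(i)
    makeToyGene(L, list(1L), geneId = paste0("u", i)))
  m10 <- shotgunMethod("s", l)
  reads <- do.call(combineReadSets, lapply(seq_along(genes), function(i)
    simulateReads(genes[[i]], 1, m10, nPerTx, seed = i)))
  prof2 <- buildBiasProfile(reads, genes)
  expect_equal(sum(prof2), 1, tolerance = 1e-12)
  expected <- tabulate(floor(100 * (0:(L - l)) / L) + 1L, 100) / (L - l + 1L)
  mcSd <- sqrt(max(expected) * (1 - max(expected)) / nPerTx / nTx)
  expect_lt(max(abs(prof2 - expected)), 4 * mcSd)
  expect_error(buildBiasProfile(rs, list(toyGenePreset("geneA"))), "single-isoform")
})

test_that("SAM and TSV alignment dialects parse to identical block structure", {
  sam <- c(
    "@HD\tVN:1.6",
    "@SQ\tSN:chrT\tLN:1000",
    # junction read: 5M across block end, 50N intron, 5M
    "r1\t0\tchrT\t56\t60\t5M50N5M\t*\t0\t0\tAAAAAAAAAA\t*",
    # soft-clipped intra-block read
    "r2\t0\tchrT\t11\t60\t3S10M\t*\t0\t0\tAAAAAAAAAAAAA\t*",
    # secondary alignment: skipped
    "r3\t256\tchrT\t11\t60\t10M\t*\t0\t0\tAAAAAAAAAA\t*",
    # unmapped: skipped
    "r4\t4\t*\t0\t0\t*\t*\t0\t0\tAAAA\t*",
    # paired-end mates
    "p1\t99\tchrT\t11\t60\t15M\t=\t61\t65\tAAAAAAAAAAAAAAA\t*",
    "p1\t147\tchrT\t61\t60\t15M\t=\t11\t-65\tAAAAAAAAAAAAAAA\t*")
  samPath <- withr::local_tempfile(fileext = ".sam")
  writeLines(sam, samPath)
  rs <- readAlignmentsSAM(samPath, "short")
  expect_equal(length(rs), 3L)
  r1 <- which(rs@readId == "r1")
  expect_equal(unname(rs@blocks[[r1]]), rbind(c(55L, 60L), c(110L, 115L)))
  r2 <- which(rs@readId == "r2")
  expect_equal(unname(rs@blocks[[r2]]), rbind(c(10L, 20L)))
  p1 <- which(rs@readId == "p1")
  expect_false(is.null(rs@mateBlocks[[p1]]))
  expect_equal(unname(rs@mateBlocks[[p1]]), rbind(c(60L, 75L)))

  tsvPath <- withr::local_tempfile(fileext = ".tsv")
  writeAlignmentsTSV(rs, tsvPath, header = "round trip")
  rs2 <- readAlignmentsTSV(tsvPath)
  expect_equal(length(rs2), length(rs))
  for (i in seq_len(length(rs)))
    expect_equal(unname(rs2@blocks[[i]]), unname(rs@blocks[[i]]))
  expect_equal(is.null(rs2@mateBlocks[[p1]]), FALSE)
})

test_that("reads compatible with no isoform are dropped and counted", {
  g <- toyGenePreset("geneA")
  m <- shotgunMethod("s", 10L)
  good <- simulateReads(g, c(0.5, 0.5), m, 50L, seed = 1)
  stray <- readSet("s", list(rbind(c(500L, 510L))), chrom = "chrT", strand = "+")
  est <- emFit(g, list(m), combineReadSets(good, stray))
  expect_equal(est@nReadsDropped, 1L)
  expect_equal(est@nReadsUsed, 50L)
})
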