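test_that("exon blocks form the minimal boundary partition", {
  # single transcript: no splitting needed
  g <- buildExonBlocks(list(rbind(c(0L, 100L), c(200L, 300L))))
  expect_equal(unname(cbind(g@blockStarts, g@blockEnds)),
               rbind(c(0L, 100L), c(200L, 300L)))
  expect_equal(isoformLengths(g), 200)

  # shared 5' exon, different 3' exon starts
  ex <- list(rbind(c(0L, 100L), c(200L, 300L)), rbind(c(0L, 100L), c(250L, 300L)))
  g2 <- buildExonBlocks(ex)
  expect_equal(unname(cbind(g2@blockStarts, g2@blockEnds)),
               rbind(c(0L, 100L), c(200L, 250L), c(250L, 300L)))
  expect_equal(isoformLengths(g2), c(200, 150))
  expect_equal(unname(cbind(g2@blockStarts, g2@blockEnds)),
               unname(oracleBlocks(ex)))

  # idempotence: identical transcripts share one block set
  g3 <- buildExonBlocks(list(rbind(c(0L, 50L)), rbind(c(0L, 50L))))
  expect_equal(length(g3@blockStarts), 1L)
  expect_equal(nIsoforms(g3), 2L)
  expect_identical(g3@isoforms[[1L]], g3@isoforms[[2L]])

  expect_error(buildExonBlocks(list(matrix(integer(0), 0, 2))), "empty transcript")
  expect_error(buildExonBlocks(list(rbind(c(0L, 10L))), strand = c("+", "-")),
               "opposite strands")
})

test_that("partition conserves exonic bases and transcript lengths", {
  for (seed in 1:10) {
    set.seed(seed)
    nTx <- sample(2:4, 1)
    exonSets <- lapply(seq_len(nTx), function(i) {
      n <- sample(1:4, 1)
      s <- integer(n); e <- integer(n)
      cur <- sample(0:50, 1)
      for (j in seq_len(n)) {
        s[j] <- cur + sample(0:30, 1)
        e[j] <- s[j] + sample(10:40, 1)
        cur <- e[j]
      }
      cbind(s, e)
    })
    g <- buildExonBlocks(exonSets)
    unionBp <- length(unique(unlist(lapply(exonSets, function(m)
      unlist(lapply(seq_len(nrow(m)), function(r) m[r, 1]:(m[r, 2] - 1)))))))
    expect_equal(sum(blockLengths(g)), unionBp)
    expect_equal(isoformLengths(g),
                 vapply(exonSets, function(m) sum(m[, 2] - m[, 1]), numeric(1)))
  }
})

test_that("transcripts cluster by transitive exonic overlap per strand", {
  tx <- function(id, exons, strand = "+", chrom = "chr1")
    list(txId = id, chrom = chrom, strand = strand, exons = exons)
  # 1 bp overlap joins; same intervals on opposite strands stay apart
  cl <- clusterTranscripts(list(tx("a", rbind(c(0L, 100L))),
                                tx("b", rbind(c(99L, 200L)))))
  expect_length(cl, 1L)
  cl2 <- clusterTranscripts(list(tx("a", rbind(c(0L, 100L))),
                                 tx("b", rbind(c(0L, 100L)), strand = "-")))
  expect_length(cl2, 2L)
  # touching (0 bp shared) does not join
  cl3 <- clusterTranscripts(list(tx("a", rbind(c(0L, 100L))),
                                 tx("b", rbind(c(100L, 200L)))))
  expect_length(cl3, 2L)
  # chain A-B, B-C with A and C disjoint: one cluster by transitivity
  cl4 <- clusterTranscripts(list(tx("A", rbind(c(0L, 100L))),
                                 tx("B", rbind(c(50L, 150L))),
                                 tx("C", rbind(c(120L, 220L)))))
  expect_length(cl4, 1L)
  expect_equal(nIsoforms(cl4[[1L]]), 3L)
  expect_identical(clusterTranscripts(list()), list())
})

test_that("isoform enumeration matches a DFS-independent path count", {
  # linear chain: one path; diamond: two
  lin <- makeToyGene(c(20L, 20L, 20L), list(c(1L, 2L, 3L)))
  expect_length(enumerateIsoforms(lin), 1L)
  dia <- makeToyGene(c(20L, 20L, 20L), list(c(1L, 2L, 3L), c(1L, 3L)))
  expect_length(enumerateIsoforms(dia), 2L)
  for (seed in 1:12) {
    g <- randomToyGene(seed)
    paths <- enumerateIsoforms(g, maxPaths = 10000L)
    expect_equal(length(paths), oraclePathCount(g@isoforms, length(g@blockStarts)),
                 info = paste("seed", seed))
    # known isoforms always included
    keys <- vapply(paths, paste, character(1), collapse = ",")
    expect_true(all(vapply(g@isoforms, paste, character(1), collapse = ",") %in% keys))
  }
  expect_error(enumerateIsoforms(dia, maxPaths = 1L), "geneId|toy|paths")
})

test_that("junction signatures identify equivalent reads", {
  g <- toyGenePreset("geneA")   # blocks 60/30/60, isoforms (1,2,3) and (1,3)
  s5 <- junctionSignature(g, 1, 55, 65)   # spans junction at 60
  s6 <- junctionSignature(g, 1, 56, 66)
  expect_identical(s5, s6)
  inBlock <- junctionSignature(g, 1, 10, 20)
  expect_length(inBlock$junctions, 0L)
  expect_equal(inBlock$blocks, 1L)
  two <- junctionSignature(g, 1, 55, 95)  # spans both junctions of iso1
  expect_equal(length(two$junctions), 2L)
  expect_false(identical(s5$junctions, two$junctions))
  expect_error(junctionSignature(g, 1, -1, 10), "range")
  expect_error(junctionSignature(g, 1, 140, 160), "range")
})

test_that("minus-strand transcript coordinates run 5' to 3'", {
  gp <- makeToyGene(c(30L, 20L), list(c(1L, 2L)), strand = "+")
  gm <- makeToyGene(c(30L, 20L), list(c(1L, 2L)), strand = "-")
  geomsP <- isomix:::.isoGeom(gp)
  geomsM <- isomix:::.isoGeom(gm)
  expect_equal(geomsM[[1]]$L, 50L)
  # on the minus strand the transcript starts at the genomically last block
  expect_equal(geomsM[[1]]$ids, c(2L, 1L))
  bP <- isomix:::.txToGenomicBlocks(gp, geomsP, 1L, 0L, 5L)
  bM <- isomix:::.txToGenomicBlocks(gm, geomsM, 1L, 0L, 5L)
  expect_equal(unname(bP), cbind(0L, 5L))
  expect_equal(unname(bM), cbind(95L, 100L))   # block 2 is [80,100)
  # round trip through projection recovers the transcript interval
  expect_equal(isomix:::.projectGenomicRead(gm, geomsM, 1L, bM), c(0, 5))
  junc <- isomix:::.txToGenomicBlocks(gm, geomsM, 1L, 15L, 10L)
  expect_equal(isomix:::.projectGenomicRead(gm, geomsM, 1L, junc), c(15, 25))
})
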