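# Shared fixtures and independent oracles used across the suite.

# Random toy gene: 3-8 blocks of 10-50 nt, 2-5 isoforms as random block
# subsets.  Deterministic given the seed.
randomToyGene <- function(seed, minIso = 2L, maxIso = 5L) {
  set.seed(seed)
  nb <- sample(3:8, 1L)
  lens <- sample(10:50, nb, replace = TRUE)
  K <- sample(minIso:maxIso, 1L)
  paths <- lapply(seq_len(K), function(i) {
    repeat {
      sel <- which(stats::runif(nb) < 0.6)
      if (length(sel) >= 1L) return(sort(sel))
    }
  })
  makeToyGene(lens, paths, geneId = paste0("rnd", seed))
}

# Fully distinguishable two-isoform gene: disjoint blocks, no shared read.
distinctGene <- function(len1 = 60L, len2 = 60L) {
  makeToyGene(c(len1, len2), list(1L, 2L), geneId = "distinct")
}

# Expected FIM by direct enumeration over the DISTINCT read space:
# J = sum_r f(r | theta) M(r).  Reads are enumerated as genomic block
# content (merging identical reads across isoforms) and their G values are
# obtained through the external-alignment projection route, independent of
# the transcript-space chain machinery the algorithms use.
oracleExpectedFIM <- function(gene, method, theta) {
  geoms <- isomix:::.isoGeom(gene)
  K <- length(geoms)
  lens <- if (method@family == "length_mixture") method@lengthDist$l else method@readLength
  seen <- new.env(parent = emptyenv())
  for (l in lens) {
    for (k in seq_len(K)) {
      L <- geoms[[k]]$L
      if (L < l) next
      for (p in 0:(L - l)) {
        b <- isomix:::.txToGenomicBlocks(gene, geoms, k, p, l)
        seen[[paste(b, collapse = ",")]] <- b
      }
    }
  }
  J <- matrix(0, K - 1L, K - 1L)
  for (key in ls(seen)) {
    b <- seen[[key]]
    g <- vapply(seq_len(K), function(j) gValue(gene, method, b, j), numeric(1))
    f <- sum(theta * g)
    if (f <= 0) next
    d <- (g[-K] - g[K]) / f
    J <- J + f * outer(d, d)
  }
  J
}

# Number of START->END paths in the splicing graph, by dynamic programming
# over the (acyclic, index-ordered) block graph.
oraclePathCount <- function(paths, nBlocks) {
  starts <- unique(vapply(paths, function(p) p[1L], integer(1)))
  ends <- unique(vapply(paths, function(p) p[length(p)], integer(1)))
  succ <- lapply(seq_len(nBlocks), function(b) integer(0))
  for (p in paths) {
    if (length(p) > 1L) for (i in seq_len(length(p) - 1L))
      succ[[p[i]]] <- union(succ[[p[i]]], p[i + 1L])
  }
  ways <- rep(NA_real_, nBlocks)
  count <- function(b) {
    if (!is.na(ways[b])) return(ways[b])
    w <- as.numeric(b %in% ends) + sum(vapply(succ[[b]], count, numeric(1)))
    ways[b] <<- w
    w
  }
  sum(vapply(sort(starts), count, numeric(1)))
}

# Minimal-partition oracle: per-base scan over covered positions, cutting at
# every annotated exon boundary.
oracleBlocks <- function(exonSets) {
  allEx <- do.call(rbind, exonSets)
  pos <- sort(unique(unlist(lapply(seq_len(nrow(allEx)), function(i)
    allEx[i, 1L]:(allEx[i, 2L] - 1L)))))
  cuts <- sort(unique(c(allEx[, 1L], allEx[, 2L])))
  grp <- cumsum(c(TRUE, diff(pos) > 1L | pos[-1L] %in% cuts))
  t(vapply(split(pos, grp), function(p) c(min(p), max(p) + 1L), integer(2)))
}

# any block appearing in >= 2 isoforms with room for an intra-block read
hasSharedLongBlock <- function(gene, l) {
  bl <- blockLengths(gene)
  cnt <- table(unlist(gene@isoforms))
  any(bl[as.integer(names(cnt)[cnt >= 2L])] >= l)
}

simpleShotgunGene <- function(L = 100L) makeToyGene(L, list(1L), geneId = "single")
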