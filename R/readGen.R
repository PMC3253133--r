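#' Sampling-method constructors
#'
#' Build [SamplingMethod-class] objects for each supported read-generation
#' family.  `shotgunMethod()` is the fixed-length uniform model: an isoform
#' of length `L` has `L - l + 1` equiprobable read placements.
#' `lengthMixtureMethod()` mixes several fixed lengths with probabilities
#' `P(l)`; `pairedEndMethod()` draws a fragment uniformly among placements
#' whose length `d` satisfies `|d - mu| <= delta * mu`; `biasedMethod()`
#' weights start positions by a 100-bin positional profile.
#'
#' @param id method identifier, matched against read annotations.
#' @param readLength read (or mate) length in nt.
#' @param lengths,probs mixture read lengths and their probabilities
#'   (must sum to 1).
#' @param insertMean,insertTol fragment-length mean `mu` (nt) and tolerated
#'   fractional deviation `delta >= 0`.
#' @param biasProfile 100 non-negative bin weights summing to 1 (5'-anchored
#'   relative transcript position).
#' @param costPerBase sequencing cost per base for [readsForBudget()].
#' @return a [SamplingMethod-class].
#' @name samplingMethods
NULL

#' @rdname samplingMethods
#' @export
shotgunMethod <- function(id, readLength, costPerBase = 1) {
  new("SamplingMethod", id = id, family = "fixed_shotgun",
      readLength = as.integer(readLength),
      lengthDist = data.frame(l = as.integer(readLength), p = 1),
      insertMean = NA_real_, insertTol = NA_real_,
      biasProfile = numeric(0), costPerBase = costPerBase)
}

#' @rdname samplingMethods
#' @export
lengthMixtureMethod <- function(id, lengths, probs, costPerBase = 1) {
  new("SamplingMethod", id = id, family = "length_mixture",
      readLength = as.integer(round(sum(lengths * probs))),
      lengthDist = data.frame(l = as.integer(lengths), p = as.numeric(probs)),
      insertMean = NA_real_, insertTol = NA_real_,
      biasProfile = numeric(0), costPerBase = costPerBase)
}

#' @rdname samplingMethods
#' @export
pairedEndMethod <- function(id, readLength, insertMean, insertTol, costPerBase = 1) {
  new("SamplingMethod", id = id, family = "paired_end",
      readLength = as.integer(readLength),
      lengthDist = data.frame(l = as.integer(readLength), p = 1),
      insertMean = as.numeric(insertMean), insertTol = as.numeric(insertTol),
      biasProfile = numeric(0), costPerBase = costPerBase)
}

#' @rdname samplingMethods
#' @export
biasedMethod <- function(id, readLength, biasProfile, costPerBase = 1) {
  new("SamplingMethod", id = id, family = "empirical_bias",
      readLength = as.integer(readLength),
      lengthDist = data.frame(l = as.integer(readLength), p = 1),
      insertMean = NA_real_, insertTol = NA_real_,
      biasProfile = as.numeric(biasProfile), costPerBase = costPerBase)
}

#' Mean sequenced bases per read
#'
#' Fixed-length families return `l`, mixtures return `sum(l * P(l))`, and
#' paired-end returns `2 * l` (both mates are sequenced; the unsequenced
#' insert gap costs nothing).  Used to convert budgets into read counts.
#'
#' @param method a [SamplingMethod-class].
#' @return mean number of sequenced bases per read (pair).
#' @export
meanReadLength <- function(method) {
  switch(method@family,
    paired_end = 2 * method@readLength,
    length_mixture = sum(method@lengthDist$l * method@lengthDist$p),
    as.numeric(method@readLength))
}

# smallest transcript length a method can sample from
.minSampleLength <- function(method) {
  switch(method@family,
    paired_end = max(method@readLength,
                     ceiling(method@insertMean * (1 - method@insertTol))),
    length_mixture = min(method@lengthDist$l),
    as.integer(method@readLength))
}

# Integer fragment lengths admitted by the paired-end delta-window.
.validFragLengths <- function(method, L) {
  mu <- method@insertMean; delta <- method@insertTol
  dmin <- max(method@readLength, ceiling(mu - delta * mu - 1e-9))
  dmax <- min(L, floor(mu + delta * mu + 1e-9))
  if (dmax < dmin) integer(0) else dmin:dmax
}

# Per-isoform normalizers for a method: for empirical_bias the sum of bin
# weights over valid starts (per mixture length); for paired_end the count
# of valid (start, fragment-length) placements.
.methodNorms <- function(gene, geoms, method) {
  K <- length(geoms)
  if (method@family == "empirical_bias") {
    l <- method@readLength
    W <- vapply(geoms, function(g) {
      if (g$L < l) return(0)
      p <- 0:(g$L - l)
      sum(method@biasProfile[pmin(floor(100 * p / g$L), 99) + 1L])
    }, numeric(1))
    list(W = W)
  } else if (method@family == "paired_end") {
    V <- vapply(geoms, function(g) {
      ds <- .validFragLengths(method, g$L)
      if (length(ds) == 0L) 0 else sum(g$L - ds + 1L)
    }, numeric(1))
    list(V = V)
  } else list()
}

# G vector across all isoforms for a single-end read of length `l` occupying
# genomic block chain `gIds` at intra-chain offset `offset`.
.gVecSingle <- function(gene, geoms, method, norms, gIds, offset, l, lprob = NULL) {
  starts <- .chainTxStarts(gene, geoms, gIds)
  K <- length(geoms)
  out <- numeric(K)
  if (is.null(lprob)) {
    lprob <- if (method@family == "length_mixture") {
      i <- match(l, method@lengthDist$l)
      if (is.na(i)) return(out)
      method@lengthDist$p[i]
    } else 1
  }
  for (j in seq_len(K)) {
    if (is.na(starts[j])) next
    L <- geoms[[j]]$L
    if (L < l) next
    out[j] <- if (method@family == "empirical_bias") {
      if (norms$W[j] <= 0) 0 else {
        p <- starts[j] + offset
        lprob * method@biasProfile[min(floor(100 * p / L), 99) + 1L] / norms$W[j]
      }
    } else lprob / (L - l + 1)
  }
  out
}

# G vector for a paired-end read: mate chains/offsets in transcript space.
.gVecPaired <- function(gene, geoms, method, norms, gIds1, off1, gIds2, off2) {
  l <- method@readLength
  s1 <- .chainTxStarts(gene, geoms, gIds1)
  s2 <- .chainTxStarts(gene, geoms, gIds2)
  K <- length(geoms)
  out <- numeric(K)
  mu <- method@insertMean; delta <- method@insertTol
  for (j in seq_len(K)) {
    if (is.na(s1[j]) || is.na(s2[j]) || norms$V[j] <= 0) next
    p1 <- s1[j] + off1
    d <- (s2[j] + off2 + l) - p1
    if (d < l || d > geoms[[j]]$L) next
    if (abs(d - mu) > delta * mu + 1e-9) next
    out[j] <- 1 / norms$V[j]
  }
  out
}

#' Read-isoform compatibility and generation probability
#'
#' `isCompatible()` is the indicator that a read's alignment blocks are an
#' exact, junction-consistent contiguous projection of the isoform's exon
#' chain; for paired-end reads the implied fragment length `d` on the
#' isoform must additionally satisfy `|d - mu| <= delta * mu`.  `gValue()`
#' is the probability that the method generates this read from the isoform
#' (0 whenever incompatible).
#'
#' @param gene a [GeneModel-class].
#' @param method a [SamplingMethod-class].
#' @param blocks two-column matrix of genomic alignment blocks (0-based
#'   half-open), sorted.
#' @param isoform isoform index or id.
#' @param mateBlocks optional mate alignment blocks for paired-end reads.
#' @return `isCompatible()`: 0 or 1; `gValue()`: a probability.
#' @examples
#' g <- makeToyGene(c(50, 50), list(c(1, 2), 1))
#' m <- shotgunMethod("short", 10)
#' isCompatible(g, m, rbind(c(45, 50), c(100, 105)), 1)  # junction read
#' isCompatible(g, m, rbind(c(45, 50), c(100, 105)), 2)  # isoform lacks it
#' @export
isCompatible <- function(gene, method, blocks, isoform, mateBlocks = NULL) {
  as.integer(gValue(gene, method, blocks, isoform, mateBlocks) > 0)
}

#' @rdname isCompatible
#' @export
gValue <- function(gene, method, blocks, isoform, mateBlocks = NULL) {
  if (is.character(isoform)) isoform <- match(isoform, gene@isoformIds)
  geoms <- .isoGeom(gene)
  norms <- .methodNorms(gene, geoms, method)
  g <- .gVecGenomic(gene, geoms, method, norms, blocks, mateBlocks)
  g[isoform]
}

# G vector for an externally aligned read given genomic blocks.
.gVecGenomic <- function(gene, geoms, method, norms, blocks, mateBlocks = NULL) {
  K <- length(geoms)
  out <- numeric(K)
  if (method@family == "paired_end") {
    if (is.null(mateBlocks)) return(out)
    l <- method@readLength
    mu <- method@insertMean; delta <- method@insertTol
    for (j in seq_len(K)) {
      pq1 <- .projectGenomicRead(gene, geoms, j, blocks)
      pq2 <- .projectGenomicRead(gene, geoms, j, mateBlocks)
      if (is.null(pq1) || is.null(pq2) || norms$V[j] <= 0) next
      d <- max(pq1[2L], pq2[2L]) - min(pq1[1L], pq2[1L])
      if (abs(d - mu) > delta * mu + 1e-9) next
      out[j] <- 1 / norms$V[j]
    }
  } else {
    l <- sum(blocks[, 2L] - blocks[, 1L])
    lprob <- if (method@family == "length_mixture") {
      i <- match(l, method@lengthDist$l)
      if (is.na(i)) return(out) else method@lengthDist$p[i]
    } else if (l != method@readLength) return(out) else 1
    for (j in seq_len(K)) {
      pq <- .projectGenomicRead(gene, geoms, j, blocks)
      if (is.null(pq)) next
      L <- geoms[[j]]$L
      if (L < l) next
      out[j] <- if (method@family == "empirical_bias") {
        if (norms$W[j] <= 0) 0 else
          lprob * method@biasProfile[min(floor(100 * pq[1L] / L), 99) + 1L] / norms$W[j]
      } else lprob / (L - l + 1)
    }
  }
  out
}

#' Read-generation probability matrix for a read set
#'
#' Computes the `N x K` matrix `G[i, j] = G_m(r_i | I_j)` of generation
#' probabilities of each read under each isoform, the quantity the EM fit
#' and the observed Fisher information are built from.  Reads simulated by
#' [simulateReads()] carry their transcript-space placement and use a fast
#' lookup; external reads are projected from their genomic blocks (both
#' routes give identical values).  Reads on the wrong chromosome or strand
#' get an all-zero row.
#'
#' @param gene a [GeneModel-class].
#' @param methods list of [SamplingMethod-class] objects (named by id, or
#'   names are taken from the ids).
#' @param reads a [ReadSet-class].
#' @return numeric matrix with one row per read, one column per isoform.
#' @export
gMatrix <- function(gene, methods, reads) {
  methods <- .namedMethods(methods)
  geoms <- .isoGeom(gene)
  K <- length(geoms)
  n <- length(reads)
  out <- matrix(0, n, K, dimnames = list(NULL, gene@isoformIds))
  if (n == 0L) return(out)
  bad <- setdiff(unique(reads@methodId), names(methods))
  if (length(bad))
    stop("reads reference undefined method id(s): ", paste(bad, collapse = ", "))
  normsByMethod <- lapply(methods, function(m) .methodNorms(gene, geoms, m))
  usable <- reads@chrom == gene@chrom &
    (!reads@strand %in% c("+", "-") | reads@strand == gene@strand)
  # identical placements/contents share one G evaluation
  fast <- usable & !is.na(reads@srcIso)
  keys <- rep(NA_character_, n)
  keys[fast] <- paste(reads@methodId[fast], reads@srcIso[fast], reads@txStart[fast],
                      reads@readLen[fast], reads@fragLen[fast])
  slow <- which(usable & !fast)
  keys[slow] <- paste(reads@methodId[slow],
                      vapply(slow, function(i) paste(
                        .blocksKey(reads@blocks[[i]]),
                        .blocksKey(reads@mateBlocks[[i]]), sep = "|"), character(1)))
  grp <- split(seq_len(n)[!is.na(keys)], keys[!is.na(keys)])
  for (idx in grp) {
    i <- idx[1L]
    m <- methods[[reads@methodId[i]]]
    norms <- normsByMethod[[reads@methodId[i]]]
    k <- reads@srcIso[i]
    g <- if (!is.na(k)) {
      p <- reads@txStart[i]
      if (m@family == "paired_end") {
        l <- m@readLength
        d <- reads@fragLen[i]
        c1 <- .readChainTx(geoms[[k]], p, l)
        c2 <- .readChainTx(geoms[[k]], p + d - l, l)
        .gVecPaired(gene, geoms, m, norms, c1$gIds, c1$offset, c2$gIds, c2$offset)
      } else {
        ch <- .readChainTx(geoms[[k]], p, reads@readLen[i])
        .gVecSingle(gene, geoms, m, norms, ch$gIds, ch$offset, reads@readLen[i])
      }
    } else {
      .gVecGenomic(gene, geoms, m, norms, reads@blocks[[i]], reads@mateBlocks[[i]])
    }
    out[idx, ] <- rep(g, each = length(idx))
  }
  out
}

.blocksKey <- function(b) if (is.null(b)) "" else paste(b, collapse = ",")

.namedMethods <- function(methods) {
  if (is(methods, "SamplingMethod")) methods <- list(methods)
  names(methods) <- vapply(methods, function(m) m@id, character(1))
  methods
}

#' Construct a ReadSet
#'
#' @param methodId character vector of sampling-method ids, one per read.
#' @param blocks list of two-column genomic block matrices (0-based
#'   half-open).
#' @param mateBlocks optional list of mate block matrices (`NULL` entries
#'   for single-end reads).
#' @param chrom,strand per-read chromosome and strand (`"*"` = unstranded);
#'   recycled if scalar.
#' @param readId optional read names.
#' @return a [ReadSet-class].
#' @export
readSet <- function(methodId, blocks, mateBlocks = NULL, chrom = "chr",
                    strand = "*", readId = NULL) {
  n <- length(blocks)
  if (is.null(mateBlocks)) mateBlocks <- vector("list", n)
  if (is.null(readId)) readId <- sprintf("read%d", seq_len(n))
  new("ReadSet", readId = readId, methodId = rep_len(methodId, n),
      chrom = rep_len(chrom, n), strand = rep_len(strand, n),
      blocks = lapply(blocks, function(b) {
        m <- as.matrix(b); storage.mode(m) <- "integer"; m
      }),
      mateBlocks = lapply(mateBlocks, function(b) {
        if (is.null(b)) NULL else { m <- as.matrix(b); storage.mode(m) <- "integer"; m }
      }),
      srcIso = rep(NA_integer_, n), txStart = rep(NA_integer_, n),
      readLen = vapply(blocks, function(b) {
        m <- as.matrix(b); as.integer(sum(m[, 2L] - m[, 1L]))
      }, integer(1)),
      fragLen = rep(NA_integer_, n))
}

#' Subset a ReadSet
#' @param x a [ReadSet-class].
#' @param i index vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "ReadSet", function(x, i, j, ..., drop = FALSE) {
  new("ReadSet", readId = x@readId[i], methodId = x@methodId[i],
      chrom = x@chrom[i], strand = x@strand[i], blocks = x@blocks[i],
      mateBlocks = x@mateBlocks[i], srcIso = x@srcIso[i],
      txStart = x@txStart[i], readLen = x@readLen[i], fragLen = x@fragLen[i])
})

#' Aggregate an empirical 100-bin positional bias profile
#'
#' Estimates the start-position bias of a sequencing protocol from genes
#' with a single annotated isoform (where read assignment is unambiguous).
#' Each usable transcript's first-base signal is binned into 100
#' relative-position bins and normalized to sum 1, then profiles are
#' averaged across transcripts, so deeply sequenced genes do not dominate.
#'
#' @param reads a [ReadSet-class] (single-end reads).
#' @param genes list of [GeneModel-class] objects; only genes with exactly
#'   one isoform contribute.
#' @return numeric vector of 100 non-negative weights summing to 1, usable
#'   as `biasProfile` in [biasedMethod()].
#' @export
buildBiasProfile <- function(reads, genes) {
  profiles <- list()
  for (gene in genes) {
    if (nIsoforms(gene) != 1L) next
    geoms <- .isoGeom(gene)
    L <- geoms[[1L]]$L
    counts <- numeric(100)
    for (i in seq_len(length(reads))) {
      if (reads@chrom[i] != gene@chrom) next
      if (reads@strand[i] %in% c("+", "-") && reads@strand[i] != gene@strand) next
      pq <- if (!is.na(reads@srcIso[i])) c(reads@txStart[i], NA) else
        .projectGenomicRead(gene, geoms, 1L, reads@blocks[[i]])
      if (is.null(pq)) next
      bin <- min(floor(100 * pq[1L] / L), 99) + 1L
      counts[bin] <- counts[bin] + 1
    }
    if (sum(counts) > 0) profiles[[length(profiles) + 1L]] <- counts / sum(counts)
  }
  if (length(profiles) == 0L)
    stop("no single-isoform gene with assignable reads; cannot build bias profile")
  prof <- Reduce(`+`, profiles) / length(profiles)
  prof / sum(prof)
}
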