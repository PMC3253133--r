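# Internal transcript-space geometry shared by the read model, the EM fit
# and the Fisher-information algorithms.  All coordinates are 0-based
# half-open; transcript coordinates always run 5'->3' (reversed relative to
# the genome on the minus strand) because positional-bias profiles are
# anchored at the 5' end.

# Per-isoform geometry: block ids in transcript order, their lengths,
# cumulative transcript starts (length n+1, first element 0) and total
# transcript length L.
.isoGeom <- function(gene) {
  bl <- gene@blockEnds - gene@blockStarts
  lapply(gene@isoforms, function(path) {
    ids <- if (gene@strand == "-") rev(path) else path
    lens <- bl[ids]
    cum <- c(0L, cumsum(lens))
    list(ids = ids, lens = lens, cum = cum, L = cum[length(cum)])
  })
}

# Block chain (genomic-order block ids) and intra-chain offset for a read
# occupying transcript interval [p, p+len) of isoform k.
.readChainTx <- function(geom_k, p, len) {
  cum <- geom_k$cum
  first <- findInterval(p, cum)
  last <- findInterval(p + len - 1L, cum)
  txIds <- geom_k$ids[first:last]
  list(gIds = sort(txIds), offset = p - cum[first])
}

# Transcript start position of a genomic block chain in every isoform.
# `gIds` is a strictly increasing vector of block indices that must occur as
# a consecutive run of the isoform's path (in genomic order).  Returns a
# numeric vector with NA where the chain is absent.  The offset of a read
# within a chain is strand-consistent: it is measured from the chain's
# 5'-most transcript position, so position p_j = chainStart_j + offset.
.chainTxStarts <- function(gene, geoms, gIds) {
  K <- length(gene@isoforms)
  out <- rep(NA_real_, K)
  n <- length(gIds)
  for (j in seq_len(K)) {
    path <- gene@isoforms[[j]]
    m <- match(gIds[1L], path)
    if (is.na(m) || m + n - 1L > length(path)) next
    if (!identical(path[m:(m + n - 1L)], gIds)) next
    # transcript index of the chain's 5'-most block
    txIdx <- if (gene@strand == "-") length(path) - (m + n - 1L) + 1L else m
    out[j] <- geoms[[j]]$cum[txIdx]
  }
  out
}

# Project a read given as genomic alignment blocks onto isoform k.
# Returns c(p, q) in transcript coordinates when the read is a junction-exact
# contiguous sub-path projection of the isoform, else NULL.
.projectGenomicRead <- function(gene, geoms, k, blocks) {
  bs <- gene@blockStarts; be <- gene@blockEnds
  path <- gene@isoforms[[k]]
  nb <- nrow(blocks)
  seqIds <- integer(0)
  # expand each aligned block into the gene blocks it covers; inside one
  # aligned block consecutive gene blocks must be genomically contiguous
  for (r in seq_len(nb)) {
    s <- blocks[r, 1L]; e <- blocks[r, 2L]
    i <- findInterval(s, bs)
    if (i < 1L || s >= be[i]) return(NULL)
    j <- findInterval(e - 1L, bs)
    if (j < 1L || (e - 1L) >= be[j]) return(NULL)
    if (j > i && any(be[i:(j - 1L)] != bs[(i + 1L):j])) return(NULL)
    # junction exactness across the N gap between aligned blocks
    if (r > 1L && s != bs[i]) return(NULL)
    if (r < nb && e != be[j]) return(NULL)
    seqIds <- c(seqIds, i:j)
  }
  m <- match(seqIds[1L], path)
  n <- length(seqIds)
  if (is.na(m) || m + n - 1L > length(path)) return(NULL)
  if (!identical(path[m:(m + n - 1L)], seqIds)) return(NULL)
  width <- sum(blocks[, 2L] - blocks[, 1L])
  if (gene@strand == "+") {
    p <- geoms[[k]]$cum[m] + (blocks[1L, 1L] - bs[seqIds[1L]])
  } else {
    txIdx <- length(path) - (m + n - 1L) + 1L
    p <- geoms[[k]]$cum[txIdx] + (be[seqIds[n]] - blocks[nb, 2L])
  }
  p <- unname(p)
  c(p, p + width)
}

# Genomic alignment blocks (two-column matrix) for transcript interval
# [p, p+len) of isoform k; adjacent gene blocks that are genomically
# contiguous are merged, so the result matches an aligner's M/N structure.
.txToGenomicBlocks <- function(gene, geoms, k, p, len) {
  geom <- geoms[[k]]
  cum <- geom$cum
  first <- findInterval(p, cum)
  last <- findInterval(p + len - 1L, cum)
  idx <- geom$ids[first:last]          # transcript order
  bs <- gene@blockStarts[idx]; be <- gene@blockEnds[idx]
  offL <- p - cum[first]               # trim at transcript 5' end
  offR <- cum[last + 1L] - (p + len)   # trim at transcript 3' end
  if (gene@strand == "+") {
    bs[1L] <- bs[1L] + offL
    be[length(be)] <- be[length(be)] - offR
  } else {
    be[1L] <- be[1L] - offL
    bs[length(bs)] <- bs[length(bs)] + offR
  }
  o <- order(bs)
  bs <- bs[o]; be <- be[o]
  # merge genomically contiguous pieces
  if (length(bs) > 1L) {
    keep <- c(TRUE, bs[-1L] != be[-length(be)])
    grp <- cumsum(keep)
    bs <- as.integer(tapply(bs, grp, min))
    be <- as.integer(tapply(be, grp, max))
  }
  cbind(start = bs, end = be)
}

.chainKey <- function(gIds, len) paste(paste(gIds, collapse = ","), len, sep = "|")
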