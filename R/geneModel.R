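#' Construct a GeneModel from exon blocks and isoform paths
#'
#' Low-level constructor; most users will obtain `GeneModel` objects from
#' [buildExonBlocks()], [clusterTranscripts()], [importAnnotation()] or
#' [makeToyGene()].
#'
#' @param geneId gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param blockStarts,blockEnds integer block boundaries, 0-based half-open,
#'   sorted and non-overlapping.
#' @param isoforms list of strictly increasing block-index vectors.
#' @param isoformIds optional isoform identifiers (default `iso1`, `iso2`, ...).
#' @return a [GeneModel-class] object.
#' @export
newGeneModel <- function(geneId, chrom, strand, blockStarts, blockEnds,
                         isoforms, isoformIds = NULL) {
  if (is.null(isoformIds))
    isoformIds <- paste0("iso", seq_along(isoforms))
  new("GeneModel", geneId = as.character(geneId), chrom = as.character(chrom),
      strand = as.character(strand), blockStarts = as.integer(blockStarts),
      blockEnds = as.integer(blockEnds),
      isoforms = lapply(isoforms, as.integer),
      isoformIds = as.character(isoformIds))
}

#' Build the minimal exon-block partition for a set of transcripts
#'
#' Splits the union of all input exons at every annotated exon boundary, so
#' that the resulting blocks (the splicing-graph nodes) are pairwise
#' non-overlapping and every input exon is an exact concatenation of blocks.
#' Each transcript is then re-expressed as a path over block indices.
#'
#' @param transcripts list of per-transcript exon tables: two-column
#'   matrices or data.frames of `(start, end)` in 0-based half-open genomic
#'   coordinates, sorted and non-overlapping within a transcript.
#' @param geneId,chrom identifiers carried into the result.
#' @param strand a single strand, or a per-transcript vector; transcripts on
#'   opposite strands are rejected (cluster per strand first).
#' @param txIds optional transcript identifiers.
#' @return a [GeneModel-class] whose isoform lengths equal the input
#'   transcripts' summed exon lengths.
#' @examples
#' g <- buildExonBlocks(list(rbind(c(0, 100), c(200, 300)),
#'                           rbind(c(0, 100), c(250, 300))))
#' blockLengths(g)     # 100 50 50
#' isoformLengths(g)   # 200 150
#' @export
buildExonBlocks <- function(transcripts, geneId = "gene", chrom = "chr",
                            strand = "+", txIds = NULL) {
  if (length(transcripts) == 0L) stop("no transcripts given")
  strand <- unique(strand)
  if (length(strand) != 1L)
    stop("transcripts on opposite strands in one gene cluster; cluster per strand")
  exonMats <- lapply(transcripts, function(x) {
    m <- as.matrix(x)[, 1:2, drop = FALSE]
    storage.mode(m) <- "integer"
    if (nrow(m) == 0L) stop("empty transcript (no exons)")
    if (any(m[, 1L] >= m[, 2L])) stop("exon must satisfy start < end")
    if (nrow(m) > 1L && any(m[-1L, 1L] < m[-nrow(m), 2L]))
      stop("exons within a transcript must be sorted and non-overlapping")
    m
  })
  allEx <- do.call(rbind, exonMats)
  bounds <- sort(unique(c(allEx[, 1L], allEx[, 2L])))
  candS <- bounds[-length(bounds)]
  candE <- bounds[-1L]
  # keep only segments covered by at least one exon
  covered <- vapply(seq_along(candS), function(i)
    any(allEx[, 1L] <= candS[i] & allEx[, 2L] >= candE[i]), logical(1))
  bs <- candS[covered]; be <- candE[covered]
  paths <- lapply(exonMats, function(m) {
    idx <- unlist(lapply(seq_len(nrow(m)), function(r) {
      which(bs >= m[r, 1L] & be <= m[r, 2L])
    }))
    stopifnot(sum(be[idx] - bs[idx]) == sum(m[, 2L] - m[, 1L]))
    idx
  })
  newGeneModel(geneId, chrom, strand, bs, be, paths, txIds)
}

#' Cluster transcripts into genes by exonic overlap
#'
#' Transcripts sharing at least one base of exonic overlap on the same
#' strand are placed in one cluster (transitive closure); each cluster
#' becomes one [GeneModel-class] via [buildExonBlocks()].
#'
#' @param transcripts list of transcript records, each a list with elements
#'   `txId`, `chrom`, `strand` and `exons` (two-column matrix, 0-based
#'   half-open), and optionally `geneId` (annotation hint used to name the
#'   cluster when unambiguous).
#' @return list of [GeneModel-class] objects (empty input gives an empty
#'   list).
#' @export
clusterTranscripts <- function(transcripts) {
  if (length(transcripts) == 0L) return(list())
  key <- vapply(transcripts, function(t) paste(t$chrom, t$strand), character(1))
  out <- list()
  cl <- 0L
  for (grpKey in unique(key)) {
    grp <- transcripts[key == grpKey]
    # merge all exon intervals that overlap by >= 1 bp
    allEx <- do.call(rbind, lapply(seq_along(grp), function(i)
      cbind(grp[[i]]$exons[, 1:2, drop = FALSE], i)))
    o <- order(allEx[, 1L], allEx[, 2L])
    allEx <- allEx[o, , drop = FALSE]
    mergedId <- integer(nrow(allEx))
    curEnd <- -Inf; cur <- 0L
    for (r in seq_len(nrow(allEx))) {
      if (allEx[r, 1L] >= curEnd) cur <- cur + 1L      # touching does not overlap
      mergedId[r] <- cur
      curEnd <- max(curEnd, allEx[r, 2L])
    }
    # union-find over merged intervals, joined through transcripts
    parent <- seq_len(max(mergedId))
    findRoot <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
    txIvs <- split(mergedId, allEx[, 3L])
    for (ivs in txIvs) {
      r0 <- findRoot(ivs[1L])
      for (iv in ivs[-1L]) parent[findRoot(iv)] <- r0
    }
    txRoot <- vapply(txIvs, function(ivs) findRoot(ivs[1L]), integer(1))
    txOrder <- as.integer(names(txIvs))
    for (root in unique(txRoot)) {
      members <- txOrder[txRoot == root]
      cl <- cl + 1L
      hints <- unique(unlist(lapply(grp[members], function(t) t$geneId)))
      gid <- if (length(hints) == 1L && !is.null(hints)) hints else sprintf("cluster_%d", cl)
      out[[length(out) + 1L]] <- buildExonBlocks(
        lapply(grp[members], function(t) t$exons),
        geneId = gid, chrom = grp[[members[1L]]]$chrom,
        strand = grp[[members[1L]]]$strand,
        txIds = vapply(grp[members], function(t) t$txId, character(1)))
    }
  }
  out
}

#' Enumerate candidate isoforms as splicing-graph paths
#'
#' Builds the directed splicing graph whose edges are the consecutive block
#' pairs observed in any known isoform (plus START and END nodes attached to
#' each isoform's first and last block), and enumerates all START-to-END
#' paths.  Known isoforms are always among the enumerated paths.
#'
#' @param gene a [GeneModel-class].
#' @param maxPaths overflow guard: more than this many paths raises an error
#'   naming the gene, so combinatorial blowups fail loudly.
#' @return named list of strictly increasing block-index vectors; known
#'   isoforms keep their ids, novel paths are named `path_<i>`.
#' @export
enumerateIsoforms <- function(gene, maxPaths = 1000L) {
  paths <- gene@isoforms
  starts <- unique(vapply(paths, function(p) p[1L], integer(1)))
  ends <- unique(vapply(paths, function(p) p[length(p)], integer(1)))
  edges <- unique(do.call(rbind, lapply(paths, function(p) {
    if (length(p) < 2L) NULL else cbind(p[-length(p)], p[-1L])
  })))
  if (is.null(edges)) edges <- matrix(integer(0), ncol = 2L)
  adj <- split(edges[, 2L], factor(edges[, 1L], levels = seq_along(gene@blockStarts)))
  found <- list()
  dfs <- function(node, acc) {
    if (node %in% ends) {
      found[[length(found) + 1L]] <<- acc
      if (length(found) > maxPaths)
        stop(sprintf("gene '%s': more than %d splicing-graph paths", gene@geneId, maxPaths))
    }
    for (nxt in adj[[node]]) dfs(nxt, c(acc, nxt))
  }
  for (s in sort(starts)) dfs(s, s)
  knownKeys <- vapply(paths, paste, character(1), collapse = ",")
  keys <- vapply(found, paste, character(1), collapse = ",")
  stopifnot(all(knownKeys %in% keys))
  nm <- character(length(found))
  nm[match(knownKeys, keys)] <- gene@isoformIds
  novel <- which(nm == "")
  nm[novel] <- paste0("path_", seq_along(novel))
  names(found) <- nm
  found
}

#' Replace the isoform set of a gene model
#'
#' @param gene a [GeneModel-class].
#' @param paths named list of block-index paths (e.g. from
#'   [enumerateIsoforms()], or a subset of the current isoforms).
#' @return a new [GeneModel-class] over the same blocks.
#' @export
withIsoforms <- function(gene, paths) {
  newGeneModel(gene@geneId, gene@chrom, gene@strand, gene@blockStarts,
               gene@blockEnds, unname(paths),
               if (is.null(names(paths))) NULL else names(paths))
}

#' Junction signature of a transcript-space read
#'
#' The ordered set of exon-junction positions strictly inside the read's
#' transcript interval `[p, q)`, together with the identity of the run of
#' connected exon blocks the read overlaps.  Two fixed-length uniform
#' shotgun reads with equal signatures are equivalent partial samples: they
#' have identical generation probabilities with respect to every isoform,
#' so one per-read Fisher-information evaluation stands for both.
#'
#' @param gene a [GeneModel-class].
#' @param isoform isoform index (or id) within `gene`.
#' @param p,q transcript coordinates, `0 <= p < q <= L`.
#' @return list with `blocks` (block ids of the connected-exon run, in
#'   transcript order) and `junctions` (transcript positions of the covered
#'   junctions; empty for an intra-block read).
#' @export
junctionSignature <- function(gene, isoform, p, q) {
  if (is.character(isoform)) isoform <- match(isoform, gene@isoformIds)
  geoms <- .isoGeom(gene)
  geom <- geoms[[isoform]]
  if (p < 0 || q <= p || q > geom$L) stop("read coordinates out of transcript range")
  cum <- geom$cum
  first <- findInterval(p, cum)
  last <- findInterval(q - 1, cum)
  juncs <- if (last > first) cum[(first + 1L):last] else integer(0)
  list(blocks = geom$ids[first:last], junctions = as.integer(juncs))
}
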