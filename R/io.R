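#' Import transcript annotation and build gene models
#'
#' Reads GTF/GFF3 (exon features grouped by transcript) or BED12 (block
#' fields) annotation via rtracklayer, converts to 0-based half-open
#' coordinates and clusters transcripts into genes with
#' [clusterTranscripts()].
#'
#' @param path annotation file.
#' @param format `"auto"` (from the extension), `"gtf"`, `"gff3"` or
#'   `"bed"`.
#' @return list of [GeneModel-class] objects.
#' @export
importAnnotation <- function(path, format = c("auto", "gtf", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext, gtf = "gtf", gff = "gff3", gff3 = "gff3", bed = "bed",
                     stop("cannot guess annotation format from extension: ", path))
  }
  if (format %in% c("gtf", "gff3")) .checkGtfLines(path, format)
  gr <- rtracklayer::import(path, format = format)
  txs <- list()
  if (format == "bed") {
    for (i in seq_along(gr)) {
      blocks <- gr$blocks[[i]]
      s <- GenomicRanges::start(gr)[i] - 1L   # to 0-based
      exons <- cbind(s + IRanges::start(blocks) - 1L, s + IRanges::end(blocks))
      txs[[length(txs) + 1L]] <- list(
        txId = if (!is.null(gr$name)) gr$name[i] else sprintf("tx%d", i),
        geneId = NULL,
        chrom = as.character(GenomicRanges::seqnames(gr)[i]),
        strand = as.character(GenomicRanges::strand(gr)[i]),
        exons = exons)
    }
  } else {
    ex <- gr[gr$type == "exon"]
    if (length(ex) == 0L) stop("annotation contains no exon features")
    txId <- if (!is.null(ex$transcript_id)) as.character(ex$transcript_id)
            else if (!is.null(ex$Parent)) as.character(unlist(ex$Parent))
            else stop("exon features carry neither transcript_id nor Parent")
    geneId <- if (!is.null(ex$gene_id)) as.character(ex$gene_id) else rep(NA_character_, length(ex))
    for (id in unique(txId)) {
      sel <- which(txId == id)
      o <- sel[order(GenomicRanges::start(ex)[sel])]
      exons <- cbind(GenomicRanges::start(ex)[o] - 1L, GenomicRanges::end(ex)[o])
      gid <- unique(geneId[sel])
      txs[[length(txs) + 1L]] <- list(
        txId = id,
        geneId = if (length(gid) == 1L && !is.na(gid)) gid else NULL,
        chrom = as.character(GenomicRanges::seqnames(ex)[o[1L]]),
        strand = as.character(GenomicRanges::strand(ex)[o[1L]]),
        exons = exons)
    }
  }
  clusterTranscripts(txs)
}

# cheap structural validation so a malformed line is reported by number
.checkGtfLines <- function(path, format) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#")) next
    nf <- length(strsplit(ln, "\t", fixed = TRUE)[[1L]])
    if (nf < 8L)
      stop(sprintf("malformed %s record at line %d of %s (%d fields)",
                   toupper(format), i, path, nf))
  }
  invisible(TRUE)
}

#' Write gene clusters as BED for inspection
#'
#' One BED6 line per gene cluster spanning its exon blocks.
#'
#' @param genes list of [GeneModel-class] objects.
#' @param path output file.
#' @export
writeClustersBED <- function(genes, path) {
  lines <- vapply(genes, function(g) {
    sprintf("%s\t%d\t%d\t%s\t%d\t%s", g@chrom, min(g@blockStarts),
            max(g@blockEnds), g@geneId, nIsoforms(g), g@strand)
  }, character(1))
  writeLines(lines, path)
}

#' Read aligned reads from the tab-delimited alignment dialect
#'
#' A simple plain-text alignment format: columns `read_id`, `method_id`,
#' `chrom`, `strand`, `blocks` and optionally `mate_blocks`, where a block
#' list is comma-separated `start-end` pairs in 0-based half-open genomic
#' coordinates (e.g. `100-125,200-210` for a junction read).
#'
#' @param path input file (`#` lines are comments).
#' @return a [ReadSet-class].
#' @export
readAlignmentsTSV <- function(path) {
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("read_id", "method_id", "chrom", "strand", "blocks")
  if (!all(need %in% names(df)))
    stop("alignment TSV must have columns: ", paste(need, collapse = ", "))
  parse1 <- function(s) {
    if (is.na(s) || s == "") return(NULL)
    parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1L]], "-", fixed = TRUE)
    m <- do.call(rbind, lapply(parts, as.integer))
    colnames(m) <- c("start", "end")
    m
  }
  blocks <- lapply(df$blocks, parse1)
  mates <- if ("mate_blocks" %in% names(df)) lapply(df$mate_blocks, parse1)
           else vector("list", nrow(df))
  readSet(methodId = df$method_id, blocks = blocks, mateBlocks = mates,
          chrom = df$chrom, strand = df$strand, readId = df$read_id)
}

#' Write a ReadSet in the tab-delimited alignment dialect
#' @param reads a [ReadSet-class].
#' @param path output file.
#' @param header optional comment lines (written with a leading `#`).
#' @export
writeAlignmentsTSV <- function(reads, path, header = character(0)) {
  fmt <- function(b) if (is.null(b)) "" else
    paste(sprintf("%d-%d", b[, 1L], b[, 2L]), collapse = ",")
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  writeLines(paste("read_id", "method_id", "chrom", "strand", "blocks",
                   "mate_blocks", sep = "\t"), con)
  for (i in seq_len(length(reads))) {
    writeLines(paste(reads@readId[i], reads@methodId[i], reads@chrom[i],
                     reads@strand[i], fmt(reads@blocks[[i]]),
                     fmt(reads@mateBlocks[[i]]), sep = "\t"), con)
  }
  invisible(path)
}

#' Read aligned reads from SAM or BAM
#'
#' Keeps primary alignments only (unmapped, secondary and supplementary
#' records are skipped).  CIGAR is converted to genomic blocks: `M`, `=`,
#' `X` and `D` consume the reference within a block, `N` splits blocks at
#' junctions, `I`, `S`, `H` and `P` consume none.  Mates of a paired read
#' are joined by query name.  Text SAM is parsed directly; `.bam` files
#' require the Rsamtools package.
#'
#' @param path SAM (text) or BAM file.
#' @param methodId sampling-method id to assign to these reads.
#' @return a [ReadSet-class] (strand is recorded as `"*"`: alignment
#'   orientation does not identify the transcript strand in unstranded
#'   protocols).
#' @export
readAlignmentsSAM <- function(path, methodId) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    if (!requireNamespace("Rsamtools", quietly = TRUE))
      stop("reading BAM requires the Rsamtools package")
    b <- Rsamtools::scanBam(path, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "cigar")))[[1L]]
    rec <- data.frame(qname = b$qname, flag = b$flag,
                      rname = as.character(b$rname), pos = b$pos,
                      cigar = b$cigar, stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!startsWith(lines, "@") & lines != ""]
    f <- strsplit(lines, "\t", fixed = TRUE)
    rec <- data.frame(
      qname = vapply(f, `[`, character(1), 1L),
      flag = as.integer(vapply(f, `[`, character(1), 2L)),
      rname = vapply(f, `[`, character(1), 3L),
      pos = as.integer(vapply(f, `[`, character(1), 4L)),
      cigar = vapply(f, `[`, character(1), 6L),
      stringsAsFactors = FALSE)
  }
  keep <- !is.na(rec$pos) &
    bitwAnd(rec$flag, 0x4) == 0L &      # mapped
    bitwAnd(rec$flag, 0x100) == 0L &    # primary
    bitwAnd(rec$flag, 0x800) == 0L      # not supplementary
  rec <- rec[keep, , drop = FALSE]
  rec$blocks <- lapply(seq_len(nrow(rec)), function(i)
    .cigarToBlocks(rec$cigar[i], rec$pos[i] - 1L))
  paired <- bitwAnd(rec$flag, 0x1) != 0L
  out <- list()
  for (i in which(!paired)) {
    out[[length(out) + 1L]] <- list(id = rec$qname[i], chrom = rec$rname[i],
                                    b = rec$blocks[[i]], m = NULL)
  }
  if (any(paired)) {
    pr <- rec[paired, , drop = FALSE]
    for (qn in unique(pr$qname)) {
      sel <- which(pr$qname == qn)
      if (length(sel) != 2L) next    # orphan mate: skip
      o <- sel[order(vapply(sel, function(s) pr$pos[s], integer(1)))]
      out[[length(out) + 1L]] <- list(id = qn, chrom = pr$rname[o[1L]],
                                      b = pr$blocks[[o[1L]]], m = pr$blocks[[o[2L]]])
    }
  }
  readSet(methodId = methodId,
          blocks = lapply(out, `[[`, "b"),
          mateBlocks = lapply(out, `[[`, "m"),
          chrom = vapply(out, `[[`, character(1), "chrom"),
          strand = "*",
          readId = vapply(out, `[[`, character(1), "id"))
}

# CIGAR string to genomic blocks starting at 0-based `pos0`.
.cigarToBlocks <- function(cigar, pos0) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  if (length(ops) == 0L) stop("unparsable CIGAR: ", cigar)
  starts <- integer(0); ends <- integer(0)
  cur <- pos0; blockStart <- pos0; open <- FALSE
  for (op in ops) {
    n <- as.integer(sub("[MIDNSHP=X]$", "", op))
    code <- substr(op, nchar(op), nchar(op))
    if (code %in% c("M", "=", "X", "D")) {
      if (!open) { blockStart <- cur; open <- TRUE }
      cur <- cur + n
    } else if (code == "N") {
      if (open) { starts <- c(starts, blockStart); ends <- c(ends, cur); open <- FALSE }
      cur <- cur + n
    }
    # I, S, H, P consume no reference
  }
  if (open) { starts <- c(starts, blockStart); ends <- c(ends, cur) }
  cbind(start = starts, end = ends)
}

#' Concatenate read sets
#' @param ... [ReadSet-class] objects.
#' @return a single [ReadSet-class].
#' @export
combineReadSets <- function(...) {
  rs <- list(...)
  new("ReadSet",
      readId = unlist(lapply(rs, function(r) r@readId)),
      methodId = unlist(lapply(rs, function(r) r@methodId)),
      chrom = unlist(lapply(rs, function(r) r@chrom)),
      strand = unlist(lapply(rs, function(r) r@strand)),
      blocks = do.call(c, lapply(rs, function(r) r@blocks)),
      mateBlocks = do.call(c, lapply(rs, function(r) r@mateBlocks)),
      srcIso = unlist(lapply(rs, function(r) r@srcIso)),
      txStart = unlist(lapply(rs, function(r) r@txStart)),
      readLen = unlist(lapply(rs, function(r) r@readLen)),
      fragLen = unlist(lapply(rs, function(r) r@fragLen)))
}
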