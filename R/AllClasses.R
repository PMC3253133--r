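#' @import methods
#' @importFrom stats rmultinom runif var setNames cor
#' @importFrom utils head tail read.delim write.table
NULL

#' GeneModel: a splicing graph and its isoforms
#'
#' A `GeneModel` holds the non-overlapping exon blocks of one gene cluster
#' (the nodes of its splicing graph) together with the known isoforms, each
#' an ordered path over those blocks.  Blocks use 0-based half-open genomic
#' coordinates and are sorted and pairwise disjoint; every annotated exon of
#' an input transcript is an exact concatenation of blocks.
#'
#' @slot geneId single gene/cluster identifier.
#' @slot chrom single chromosome name.
#' @slot strand `"+"` or `"-"`.
#' @slot blockStarts,blockEnds integer vectors of block boundaries
#'   (0-based half-open), sorted, non-overlapping.
#' @slot isoforms list of strictly increasing integer vectors of block
#'   indices (genomic order; for minus-strand genes the transcript runs
#'   through the same indices in reverse).
#' @slot isoformIds character vector of isoform identifiers.
#'
#' @seealso [buildExonBlocks()], [makeToyGene()], [isoformLengths()]
#' @export
setClass("GeneModel", slots = c(
  geneId = "character",
  chrom = "character",
  strand = "character",
  blockStarts = "integer",
  blockEnds = "integer",
  isoforms = "list",
  isoformIds = "character"
))

setValidity("GeneModel", function(object) {
  msg <- character()
  s <- object@blockStarts; e <- object@blockEnds
  if (length(s) != length(e)) msg <- c(msg, "blockStarts/blockEnds length mismatch")
  if (length(s) == 0L) msg <- c(msg, "gene must have at least one exon block")
  if (any(s >= e)) msg <- c(msg, "blocks must satisfy start < end")
  if (length(s) > 1L && any(e[-length(e)] > s[-1L]))
    msg <- c(msg, "blocks must be sorted and non-overlapping")
  if (!object@strand %in% c("+", "-")) msg <- c(msg, "strand must be '+' or '-'")
  if (length(object@isoforms) < 1L) msg <- c(msg, "gene must have at least one isoform (K >= 1)")
  if (length(object@isoforms) != length(object@isoformIds))
    msg <- c(msg, "isoforms/isoformIds length mismatch")
  for (p in object@isoforms) {
    if (length(p) == 0L || any(p < 1L) || any(p > length(s)) ||
        (length(p) > 1L && any(diff(p) <= 0L))) {
      msg <- c(msg, "each isoform must be a non-empty strictly increasing block-index path")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' SamplingMethod: a read-generation model for one sequencing technology
#'
#' Describes how one sequencing technology turns an isoform into a read
#' (a partial sample): the read-length model, the per-base cost used in
#' budget sweeps, and family-specific parameters.  Families:
#'
#' * `fixed_shotgun` — fixed read length `l`; a transcript of length `L`
#'   yields `L - l + 1` equiprobable start positions.
#' * `length_mixture` — a finite mixture of fixed-length shotgun models
#'   with length probabilities `P(l)`.
#' * `paired_end` — two mates of fixed length whose implied fragment
#'   length `d` on an isoform must satisfy `|d - mu| <= delta * mu`;
#'   generation is uniform over valid (start, fragment-length) placements.
#' * `empirical_bias` — fixed read length with start-position probability
#'   proportional to a 100-bin positional profile along the transcript
#'   (5'-anchored), normalized over valid starts.
#'
#' @slot id method identifier (matches read annotations).
#' @slot family one of the four families above.
#' @slot readLength read (or mate) length in nt.
#' @slot lengthDist data.frame with columns `l`, `p` (length mixture only).
#' @slot insertMean,insertTol paired-end fragment-length mean `mu` (nt) and
#'   tolerated fractional deviation `delta`.
#' @slot biasProfile 100 non-negative bin weights summing to 1.
#' @slot costPerBase sequencing cost per base, used by [readsForBudget()].
#'
#' @seealso [shotgunMethod()], [lengthMixtureMethod()], [pairedEndMethod()],
#'   [biasedMethod()]
#' @export
setClass("SamplingMethod", slots = c(
  id = "character",
  family = "character",
  readLength = "integer",
  lengthDist = "data.frame",
  insertMean = "numeric",
  insertTol = "numeric",
  biasProfile = "numeric",
  costPerBase = "numeric"
))

setValidity("SamplingMethod", function(object) {
  msg <- character()
  fam <- object@family
  if (!fam %in% c("fixed_shotgun", "length_mixture", "paired_end", "empirical_bias"))
    msg <- c(msg, "unknown sampling-method family")
  if (fam %in% c("fixed_shotgun", "paired_end", "empirical_bias")) {
    if (length(object@readLength) != 1L || object@readLength < 1L)
      msg <- c(msg, "readLength must be a single integer >= 1")
  }
  if (fam == "length_mixture") {
    ld <- object@lengthDist
    if (!all(c("l", "p") %in% names(ld)) || nrow(ld) < 1L)
      msg <- c(msg, "lengthDist must have columns l, p")
    else {
      if (any(ld$l < 1L)) msg <- c(msg, "mixture lengths must be >= 1")
      if (abs(sum(ld$p) - 1) > 1e-12) msg <- c(msg, "length probabilities must sum to 1")
    }
  }
  if (fam == "paired_end") {
    if (length(object@insertMean) != 1L || object@insertMean <= 0)
      msg <- c(msg, "insertMean must be positive")
    if (length(object@insertTol) != 1L || object@insertTol < 0)
      msg <- c(msg, "insertTol (delta) must be >= 0")
  }
  if (fam == "empirical_bias") {
    b <- object@biasProfile
    if (length(b) != 100L || any(b < 0) || abs(sum(b) - 1) > 1e-12)
      msg <- c(msg, "biasProfile must be 100 non-negative weights summing to 1")
  }
  if (object@costPerBase <= 0) msg <- c(msg, "costPerBase must be positive")
  if (length(msg)) msg else TRUE
})

#' ReadSet: a collection of aligned partial samples
#'
#' Reads are stored as genomic alignment blocks (0-based half-open, sorted,
#' non-overlapping) plus the id of the sampling method that produced them.
#' Paired-end reads carry a second mate block list.  Reads produced by the
#' simulator additionally record their source isoform and transcript-space
#' placement, which downstream code uses as a fast path when computing
#' read-generation probabilities (results are identical to projecting the
#' genomic blocks).
#'
#' @slot readId character read names.
#' @slot methodId character sampling-method id per read.
#' @slot chrom,strand per-read chromosome and strand.
#' @slot blocks list of two-column integer matrices (start, end).
#' @slot mateBlocks list of mate matrices, or `NULL` entries for single-end.
#' @slot srcIso,txStart,readLen,fragLen integer simulator annotations
#'   (`NA` for external reads).
#' @export
setClass("ReadSet", slots = c(
  readId = "character",
  methodId = "character",
  chrom = "character",
  strand = "character",
  blocks = "list",
  mateBlocks = "list",
  srcIso = "integer",
  txStart = "integer",
  readLen = "integer",
  fragLen = "integer"
))

setValidity("ReadSet", function(object) {
  n <- length(object@methodId)
  lens <- c(length(object@readId), length(object@chrom), length(object@strand),
            length(object@blocks), length(object@mateBlocks), length(object@srcIso),
            length(object@txStart), length(object@readLen), length(object@fragLen))
  if (any(lens != n)) return("all ReadSet slots must have equal length")
  TRUE
})

#' ThetaEstimate: EM maximum-likelihood isoform abundances for one gene
#'
#' @slot theta named numeric vector of relative abundances (sums to 1).
#' @slot loglik maximized total log-likelihood (natural log).
#' @slot loglikTrace per-iteration log-likelihood values (monotone
#'   non-decreasing, the EM guarantee).
#' @slot lAvg per-read average maximized log-likelihood, `loglik / N`.
#' @slot nIter number of EM iterations run.
#' @slot converged whether the log-likelihood change fell below tolerance.
#' @slot nReadsUsed,nReadsDropped reads entering the likelihood and reads
#'   discarded because they were compatible with no isoform.
#' @slot expectedReads posterior expected read count per isoform.
#' @slot rpkm,geneRpkm per-isoform RPKM and their sum (NA until [rpkm()]
#'   is called with a library size).
#' @export
setClass("ThetaEstimate", slots = c(
  theta = "numeric",
  loglik = "numeric",
  loglikTrace = "numeric",
  lAvg = "numeric",
  nIter = "integer",
  converged = "logical",
  nReadsUsed = "integer",
  nReadsDropped = "integer",
  expectedReads = "numeric",
  rpkm = "numeric",
  geneRpkm = "numeric"
))

setValidity("ThetaEstimate", function(object) {
  th <- object@theta
  if (any(th < 0)) return("theta must be non-negative")
  if (abs(sum(th) - 1) > 1e-10) return("theta must sum to 1")
  TRUE
})

#' FIMResult: expected Fisher information for one gene and method mix
#'
#' The matrix is over the K-1 free abundance parameters (the last isoform
#' is the dependent one, `theta_K = 1 - sum(theta_[1..K-1])`).
#'
#' @slot J symmetric positive semi-definite `(K-1) x (K-1)` matrix.
#' @slot algorithm `"bruteforce"`, `"equivalence"` or `"cross_isoform"`.
#' @slot evals number of single-read FIM evaluations performed.
#' @slot unidentifiable logical per free parameter: `TRUE` where the
#'   diagonal information is (numerically) zero.
#' @export
setClass("FIMResult", slots = c(
  J = "matrix",
  algorithm = "character",
  evals = "integer",
  unidentifiable = "logical"
))

setValidity("FIMResult", function(object) {
  J <- object@J
  if (nrow(J) != ncol(J)) return("J must be square")
  if (nrow(J) > 0L && max(abs(J - t(J))) > 1e-8) return("J must be symmetric")
  TRUE
})
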