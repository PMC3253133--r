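#' @include AllClasses.R
NULL

#' Accessors for isomix classes
#'
#' Small accessor generics so user code never reaches into slots:
#' `geneId()` returns the gene identifier, `nIsoforms()` the number of
#' isoforms K, `isoformIds()` their names, `blockLengths()` the exon-block
#' lengths, `isoformLengths()` the summed transcript lengths, `theta()` the
#' abundance vector, `logLik2()` the maximized log-likelihood, `lAvg()` the
#' per-read average log-likelihood, `fimMatrix()` the expected Fisher
#' information matrix and `fimEvals()` the per-read FIM evaluation count.
#'
#' @param object an isomix object.
#' @return the accessed component; see each method.
#' @name accessors
#' @aliases geneId nIsoforms isoformIds blockLengths isoformLengths theta
#'   lAvg fimMatrix fimEvals
NULL

#' @rdname accessors
#' @export
setGeneric("geneId", function(object) standardGeneric("geneId"))
#' @rdname accessors
#' @export
setGeneric("nIsoforms", function(object) standardGeneric("nIsoforms"))
#' @rdname accessors
#' @export
setGeneric("isoformIds", function(object) standardGeneric("isoformIds"))
#' @rdname accessors
#' @export
setGeneric("blockLengths", function(object) standardGeneric("blockLengths"))
#' @rdname accessors
#' @export
setGeneric("isoformLengths", function(object) standardGeneric("isoformLengths"))
#' @rdname accessors
#' @export
setGeneric("theta", function(object) standardGeneric("theta"))
#' @rdname accessors
#' @export
setGeneric("lAvg", function(object) standardGeneric("lAvg"))
#' @rdname accessors
#' @export
setGeneric("fimMatrix", function(object) standardGeneric("fimMatrix"))
#' @rdname accessors
#' @export
setGeneric("fimEvals", function(object) standardGeneric("fimEvals"))

#' @rdname accessors
setMethod("geneId", "GeneModel", function(object) object@geneId)
#' @rdname accessors
setMethod("nIsoforms", "GeneModel", function(object) length(object@isoforms))
#' @rdname accessors
setMethod("isoformIds", "GeneModel", function(object) object@isoformIds)
#' @rdname accessors
setMethod("blockLengths", "GeneModel",
          function(object) object@blockEnds - object@blockStarts)
#' @rdname accessors
setMethod("isoformLengths", "GeneModel", function(object) {
  bl <- blockLengths(object)
  vapply(object@isoforms, function(p) sum(bl[p]), numeric(1))
})
#' @rdname accessors
setMethod("theta", "ThetaEstimate", function(object) object@theta)
#' @rdname accessors
setMethod("lAvg", "ThetaEstimate", function(object) object@lAvg)
#' @rdname accessors
setMethod("fimMatrix", "FIMResult", function(object) object@J)
#' @rdname accessors
setMethod("fimEvals", "FIMResult", function(object) object@evals)

setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel '%s' (%s:%s) with %d exon blocks, K = %d isoforms\n",
              object@geneId, object@chrom, object@strand,
              length(object@blockStarts), nIsoforms(object)))
  L <- isoformLengths(object)
  for (j in seq_along(object@isoforms)) {
    cat(sprintf("  %s: blocks [%s], L = %d nt\n", object@isoformIds[j],
                paste(object@isoforms[[j]], collapse = ","), L[j]))
  }
  invisible(object)
})

setMethod("show", "SamplingMethod", function(object) {
  cat(sprintf("SamplingMethod '%s' (%s)", object@id, object@family))
  extra <- switch(object@family,
    fixed_shotgun = sprintf("l = %d nt", object@readLength),
    length_mixture = sprintf("lengths {%s}",
      paste(sprintf("%d:%.3g", object@lengthDist$l, object@lengthDist$p), collapse = ", ")),
    paired_end = sprintf("mates %d nt, mu = %g, delta = %g",
      object@readLength, object@insertMean, object@insertTol),
    empirical_bias = sprintf("l = %d nt, 100-bin positional profile", object@readLength))
  cat(": ", extra, sprintf(", cost %g/base\n", object@costPerBase), sep = "")
  invisible(object)
})

setMethod("show", "ReadSet", function(object) {
  n <- length(object@methodId)
  paired <- sum(!vapply(object@mateBlocks, is.null, logical(1)))
  cat(sprintf("ReadSet with %d reads (%d paired-end) from method(s): %s\n",
              n, paired, paste(unique(object@methodId), collapse = ", ")))
  invisible(object)
})

setMethod("length", "ReadSet", function(x) length(x@methodId))

setMethod("show", "ThetaEstimate", function(object) {
  cat(sprintf("ThetaEstimate (K = %d, %d reads, %d dropped): %s after %d EM iterations\n",
              length(object@theta), object@nReadsUsed, object@nReadsDropped,
              if (object@converged) "converged" else "NOT converged", object@nIter))
  print(round(object@theta, 6))
  cat(sprintf("  loglik = %.6g, L_avg = %.6g\n", object@loglik, object@lAvg))
  invisible(object)
})

setMethod("show", "FIMResult", function(object) {
  cat(sprintf("FIMResult (%s): %d x %d expected FIM, %d per-read FIM evaluations\n",
              object@algorithm, nrow(object@J), ncol(object@J), object@evals))
  if (any(object@unidentifiable))
    cat("  unidentifiable free parameters:",
        paste(which(object@unidentifiable), collapse = ", "), "\n")
  invisible(object)
})
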