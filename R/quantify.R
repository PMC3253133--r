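#' EM steps for the partial-sample mixture likelihood
#'
#' The likelihood of the reads given abundances `theta` is
#' `prod_i sum_j theta_j G_m(r_i | I_j)`; introducing the hidden isoform
#' assignment of each read gives the classic EM updates.  `eStep()` computes
#' the posterior assignment weights
#' `w[i, j] = theta_j G[i, j] / sum_j' theta_j' G[i, j']`
#' and `mStep()` the new abundances `theta_j = mean_i w[i, j]`.
#'
#' @param gmat read-generation probability matrix from [gMatrix()]
#'   (one row per read or per collapsed read class).
#' @param theta current abundance vector (non-negative, sums to 1).
#' @param w posterior weight matrix from `eStep()` (rows sum to 1).
#' @param counts multiplicity of each row (default 1), for collapsed
#'   read classes.
#' @return `eStep()`: the weight matrix; `mStep()`: the updated theta.
#' @export
eStep <- function(gmat, theta) {
  num <- sweep(gmat, 2L, theta, `*`)
  den <- rowSums(num)
  if (any(den <= 0))
    stop("read with zero likelihood under all isoforms; filter incompatible reads first")
  num / den
}

#' @rdname eStep
#' @export
mStep <- function(w, counts = 1) {
  n <- sum(rep_len(counts, nrow(w)))
  if (n == 0) stop("no reads")
  th <- colSums(w * rep_len(counts, nrow(w))) / n
  th / sum(th)
}

#' Maximum-likelihood isoform abundances by expectation maximization
#'
#' Alternates [eStep()]/[mStep()] from a uniform start until the absolute
#' log-likelihood change falls below `tol` or `maxIter` is reached.  The
#' log-likelihood is guaranteed non-decreasing across iterations and its
#' full trace is kept in the result.  Reads compatible with no isoform
#' (all-zero rows of the G matrix) are excluded from the likelihood and
#' counted as dropped.  Identical G rows are collapsed to weighted classes
#' internally, which changes nothing numerically but makes large simulated
#' read sets cheap.
#'
#' @param gene a [GeneModel-class].
#' @param methods list of [SamplingMethod-class] objects.
#' @param reads a [ReadSet-class], or `NULL` if `gmat` is supplied.
#' @param gmat optional precomputed [gMatrix()] result.
#' @param init optional starting abundances (default uniform `1/K`).
#' @param tol absolute log-likelihood convergence tolerance.
#' @param maxIter iteration cap.
#' @return a [ThetaEstimate-class]; `theta` values below 1e-12 are floored
#'   to 0 on output (and the vector renormalized), `lAvg` is
#'   `loglik / N` in natural log.
#' @examples
#' g <- toyGenePreset("geneA")
#' m <- shotgunMethod("short", 10)
#' r <- simulateReads(g, c(0.7, 0.3), m, 2000, seed = 1)
#' emFit(g, list(m), r)
#' @export
emFit <- function(gene, methods, reads = NULL, gmat = NULL, init = NULL,
                  tol = 1e-8, maxIter = 1000L) {
  if (is.null(gmat)) {
    if (is.null(reads)) stop("supply reads or a precomputed gmat")
    gmat <- gMatrix(gene, methods, reads)
  }
  K <- ncol(gmat)
  keep <- rowSums(gmat) > 0
  nDropped <- sum(!keep)
  gmat <- gmat[keep, , drop = FALSE]
  N <- nrow(gmat)
  if (N == 0L) stop(sprintf("gene '%s': no reads compatible with any isoform", gene@geneId))
  # collapse identical rows into weighted read classes
  key <- do.call(paste, c(as.data.frame(gmat), sep = "\r"))
  first <- !duplicated(key)
  cnt <- as.vector(table(factor(key, levels = key[first])))
  gU <- gmat[first, , drop = FALSE]
  if (K == 1L) {
    ll <- sum(cnt * log(gU[, 1L]))
    return(new("ThetaEstimate",
               theta = stats::setNames(1, colnames(gmat)), loglik = ll,
               loglikTrace = ll, lAvg = ll / N, nIter = 0L, converged = TRUE,
               nReadsUsed = as.integer(N), nReadsDropped = as.integer(nDropped),
               expectedReads = stats::setNames(as.numeric(N), colnames(gmat)),
               rpkm = NA_real_, geneRpkm = NA_real_))
  }
  th <- if (is.null(init)) rep(1 / K, K) else init / sum(init)
  trace <- numeric(0)
  llPrev <- -Inf
  converged <- FALSE
  iter <- 0L
  w <- NULL
  repeat {
    num <- sweep(gU, 2L, th, `*`)
    den <- rowSums(num)
    if (any(den <= 0))
      stop("read with zero likelihood under all isoforms; filter incompatible reads first")
    ll <- sum(cnt * log(den))
    trace <- c(trace, ll)
    if (is.finite(llPrev) && abs(ll - llPrev) < tol) { converged <- TRUE; break }
    if (iter >= maxIter) break
    llPrev <- ll
    w <- num / den
    th <- colSums(w * cnt) / N
    th <- th / sum(th)
    iter <- iter + 1L
  }
  w <- sweep(gU, 2L, th, `*`)
  w <- w / rowSums(w)
  nExp <- colSums(w * cnt)
  thOut <- th
  thOut[thOut < 1e-12] <- 0
  thOut <- thOut / sum(thOut)
  new("ThetaEstimate",
      theta = stats::setNames(thOut, colnames(gmat)),
      loglik = trace[length(trace)], loglikTrace = trace,
      lAvg = trace[length(trace)] / N, nIter = iter, converged = converged,
      nReadsUsed = as.integer(N), nReadsDropped = as.integer(nDropped),
      expectedReads = stats::setNames(nExp, colnames(gmat)),
      rpkm = NA_real_, geneRpkm = NA_real_)
}

#' Reads per kilobase of transcript per million mapped reads
#'
#' Converts the posterior expected read counts of a fit into per-isoform
#' RPKM values: `RPKM_j = n_j / (L_j / 1e3) / (total / 1e6)`.  The gene
#' RPKM is the sum of its isoforms' RPKMs.
#'
#' @param estimate a [ThetaEstimate-class] from [emFit()].
#' @param gene the [GeneModel-class] it was fitted on.
#' @param totalMappedReads library size (mapped reads in the experiment).
#' @return the estimate with `rpkm` and `geneRpkm` slots filled.
#' @export
rpkm <- function(estimate, gene, totalMappedReads) {
  if (totalMappedReads <= 0) stop("totalMappedReads must be positive")
  L <- isoformLengths(gene)
  if (any(L <= 0)) stop("zero-length isoform")
  r <- estimate@expectedReads / (L / 1e3) / (totalMappedReads / 1e6)
  estimate@rpkm <- stats::setNames(r, gene@isoformIds)
  estimate@geneRpkm <- sum(r)
  estimate
}
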