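# Expected Fisher information over the K-1 free abundance parameters.
# theta_K (the dependent isoform, by default the last) is 1 - sum of the
# others, so the score of a single read r with generation probabilities
# G_j = G_m(r | I_j) is (G_a - G_K) / f(r | theta) for free parameter a,
# with f = sum_j theta_j G_j, and the per-read FIM is the score outer
# product M(r)_{ab} = (G_a - G_K)(G_b - G_K) / f^2.

# clamp near-boundary abundances inside FIM evaluation to avoid division
# blow-ups; raw theta is never modified elsewhere
.clampTheta <- function(theta, floor = 1e-6) pmax(theta, floor)

#' Per-read (observed) Fisher information matrix
#'
#' The score outer product of a single read for the multinomial-mixture
#' likelihood with the last abundance treated as the dependent parameter:
#' element `(a, b)` is `(G_a - G_K)(G_b - G_K) / f^2` with
#' `f = sum_j theta_j G_j`.  The matrix is symmetric and rank at most 1;
#' a read with identical generation probability under every isoform
#' contributes a zero matrix (it carries no information about theta).
#'
#' @param gvalues numeric vector of per-isoform generation probabilities
#'   `G_m(r | I_j)` for one read (e.g. a row of [gMatrix()]).
#' @param theta abundance vector (clamped at 1e-6 away from the boundary
#'   inside the evaluation).
#' @return `(K-1) x (K-1)` matrix.
#' @export
observedFIM <- function(gvalues, theta) {
  K <- length(gvalues)
  stopifnot(length(theta) == K)
  theta <- .clampTheta(theta)
  f <- sum(theta * gvalues)
  if (f <= 0) stop("read has zero likelihood; it should have been filtered")
  d <- (gvalues[-K] - gvalues[K]) / f
  outer(d, d)
}

#' Expected Fisher information matrix of a single read from one method
#'
#' Computes `J_m = sum_k theta_k sum_r G_m(r | I_k) M(r)` — the expectation
#' of the per-read FIM over the method's read distribution — by one of
#' three exact algorithms:
#'
#' * `bruteforce`: enumerates every read placement of every
#'   isoform; `sum_k (L_k - l + 1)` per-read FIM evaluations for a
#'   fixed-length method.
#' * `equivalence`: groups each isoform's placements into
#'   equivalent sample sets — reads covering the same junction run have
#'   identical G under every isoform — and evaluates one representative per
#'   class, scaled by the class multiplicity.  For a step-function
#'   positional-bias model, classes are additionally split at bias-bin
#'   boundaries of every compatible isoform so the G vector stays constant
#'   within a class.  Supported for single-end families only.
#' * `cross_isoform`: as `equivalence`, but classes whose read
#'   content (genomic block chain and offset range) was already evaluated
#'   in another isoform reuse the stored per-read FIM instead of
#'   recomputing it.
#'
#' All three return the same matrix to floating-point accuracy; only the
#' evaluation counts differ.  Paired-end methods use `bruteforce`
#' regardless (the equivalence machinery covers single-end families).
#'
#' @param gene a [GeneModel-class].
#' @param method a [SamplingMethod-class].
#' @param theta abundance vector of length K.
#' @param algorithm which algorithm to run.
#' @return a [FIMResult-class] over the `K - 1` free parameters.
#' @examples
#' g <- toyGenePreset("geneA")
#' f1 <- expectedFIM(g, shotgunMethod("s", 10), c(0.7, 0.3), "bruteforce")
#' f3 <- expectedFIM(g, shotgunMethod("s", 10), c(0.7, 0.3), "cross_isoform")
#' all.equal(fimMatrix(f1), fimMatrix(f3))
#' fimEvals(f3) < fimEvals(f1)
#' @export
expectedFIM <- function(gene, method, theta,
                        algorithm = c("cross_isoform", "equivalence", "bruteforce")) {
  algorithm <- match.arg(algorithm)
  K <- nIsoforms(gene)
  stopifnot(length(theta) == K)
  if (K == 1L)
    return(new("FIMResult", J = matrix(numeric(0), 0L, 0L), algorithm = algorithm,
               evals = 0L, unidentifiable = logical(0)))
  geoms <- .isoGeom(gene)
  if (method@family == "paired_end") {
    if (algorithm != "bruteforce")
      algorithm <- "bruteforce"   # equivalence classes cover single-end families
    res <- .fimBrutePaired(gene, geoms, method, theta)
  } else if (algorithm == "bruteforce") {
    res <- .fimBruteSingle(gene, geoms, method, theta)
  } else {
    res <- .fimEquivalence(gene, geoms, method, theta,
                           cross = algorithm == "cross_isoform")
  }
  J <- (res$J + t(res$J)) / 2
  new("FIMResult", J = J, algorithm = algorithm, evals = as.integer(res$evals),
      unidentifiable = diag(J) < 1e-12)
}

# mixture lengths with probabilities (degenerate for fixed-length families)
.mixtureLengths <- function(method) {
  if (method@family == "length_mixture") method@lengthDist
  else data.frame(l = method@readLength, p = 1)
}

# Brute-force route, single-end: enumerate every (isoform, start, length).
.fimBruteSingle <- function(gene, geoms, method, theta) {
  K <- length(geoms)
  thetaC <- .clampTheta(theta)
  J <- matrix(0, K - 1L, K - 1L)
  evals <- 0L
  ld <- .mixtureLengths(method)
  chainMemo <- new.env(parent = emptyenv())
  anyRead <- FALSE
  for (li in seq_len(nrow(ld))) {
    l <- ld$l[li]; lp <- ld$p[li]
    for (k in seq_len(K)) {
      L <- geoms[[k]]$L
      if (L < l) next
      anyRead <- TRUE
      for (p in 0:(L - l)) {
        ch <- .readChainTx(geoms[[k]], p, l)
        ck <- .chainKey(ch$gIds, 0L)
        starts <- chainMemo[[ck]]
        if (is.null(starts)) {
          starts <- .chainTxStarts(gene, geoms, ch$gIds)
          chainMemo[[ck]] <- starts
        }
        g <- .gFromStarts(gene, geoms, method, starts, ch$offset, l, lp)
        f <- sum(thetaC * g)
        d <- (g[-K] - g[K]) / f
        J <- J + (thetaC[k] * g[k]) * outer(d, d)
        evals <- evals + 1L
      }
    }
  }
  if (!anyRead) warning(sprintf("gene '%s': every isoform is shorter than the read length",
                                gene@geneId))
  list(J = J, evals = evals)
}

# G vector given precomputed chain transcript starts per isoform.
.gFromStarts <- function(gene, geoms, method, starts, offset, l, lp) {
  K <- length(geoms)
  g <- numeric(K)
  if (method@family == "empirical_bias") {
    norms <- .biasNormsCached(gene, geoms, method)
    for (j in seq_len(K)) {
      if (is.na(starts[j]) || geoms[[j]]$L < l || norms[j] <= 0) next
      p <- starts[j] + offset
      Lj <- geoms[[j]]$L
      g[j] <- lp * method@biasProfile[min(floor(100 * p / Lj), 99) + 1L] / norms[j]
    }
  } else {
    for (j in seq_len(K)) {
      if (is.na(starts[j]) || geoms[[j]]$L < l) next
      g[j] <- lp / (geoms[[j]]$L - l + 1)
    }
  }
  g
}

# per-gene cache of bias normalizers would buy little here; recompute cheaply
.biasNormsCached <- function(gene, geoms, method) {
  l <- method@readLength
  vapply(geoms, function(gm) {
    if (gm$L < l) return(0)
    p <- 0:(gm$L - l)
    sum(method@biasProfile[pmin(floor(100 * p / gm$L), 99) + 1L])
  }, numeric(1))
}

# Brute-force route, paired-end: enumerate every (isoform, start, fragment length).
.fimBrutePaired <- function(gene, geoms, method, theta) {
  K <- length(geoms)
  thetaC <- .clampTheta(theta)
  J <- matrix(0, K - 1L, K - 1L)
  evals <- 0L
  l <- method@readLength
  norms <- .methodNorms(gene, geoms, method)
  anyRead <- FALSE
  for (k in seq_len(K)) {
    L <- geoms[[k]]$L
    ds <- .validFragLengths(method, L)
    if (length(ds) == 0L) next
    anyRead <- TRUE
    for (d in ds) {
      for (p in 0:(L - d)) {
        c1 <- .readChainTx(geoms[[k]], p, l)
        c2 <- .readChainTx(geoms[[k]], p + d - l, l)
        g <- .gVecPaired(gene, geoms, method, norms, c1$gIds, c1$offset,
                         c2$gIds, c2$offset)
        f <- sum(thetaC * g)
        dd <- (g[-K] - g[K]) / f
        J <- J + (thetaC[k] * g[k]) * outer(dd, dd)
        evals <- evals + 1L
      }
    }
  }
  if (!anyRead) warning(sprintf("gene '%s': no isoform admits a valid fragment length",
                                gene@geneId))
  list(J = J, evals = evals)
}

# Equivalence classes of start positions for isoform k at read length l:
# runs of p with the same covered-junction set, optionally refined at
# bias-bin cutpoints of every compatible isoform.  Each class records its
# representative start, multiplicity, genomic block chain and the intra-
# chain offset range (intrinsic to the chain, hence shared by the identical
# read set in any other isoform containing the chain).
.isoClasses <- function(gene, geoms, k, l, method) {
  geom <- geoms[[k]]
  L <- geom$L
  if (L < l) return(list())
  p <- 0:(L - l)
  cj <- geom$cum[-c(1L, length(geom$cum))]   # interior junction positions
  loJ <- findInterval(p, cj)
  hiJ <- findInterval(p + l - 1L, cj)
  sig <- paste(loJ, hiJ)
  if (method@family == "empirical_bias") {
    # refine by the bias bin of the read start in every compatible isoform
    chainCache <- new.env(parent = emptyenv())
    binSig <- character(length(p))
    for (i in seq_along(p)) {
      ch <- .readChainTx(geom, p[i], l)
      ck <- .chainKey(ch$gIds, 0L)
      starts <- chainCache[[ck]]
      if (is.null(starts)) {
        starts <- .chainTxStarts(gene, geoms, ch$gIds)
        chainCache[[ck]] <- starts
      }
      bins <- vapply(seq_along(starts), function(j) {
        if (is.na(starts[j])) return(-1L)
        as.integer(min(floor(100 * (starts[j] + ch$offset) / geoms[[j]]$L), 99))
      }, integer(1))
      binSig[i] <- paste(bins, collapse = ",")
    }
    sig <- paste(sig, binSig)
  }
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  startsIdx <- ends - r$lengths + 1L
  lapply(seq_along(r$lengths), function(ci) {
    repP <- p[startsIdx[ci]]
    ch <- .readChainTx(geom, repP, l)
    list(repP = repP, mult = r$lengths[ci], gIds = ch$gIds,
         offLo = ch$offset, offHi = ch$offset + r$lengths[ci] - 1L)
  })
}

# Equivalence-class route, optionally with the cross-isoform ledger.
.fimEquivalence <- function(gene, geoms, method, theta, cross = FALSE) {
  K <- length(geoms)
  thetaC <- .clampTheta(theta)
  J <- matrix(0, K - 1L, K - 1L)
  evals <- 0L
  ld <- .mixtureLengths(method)
  cache <- new.env(parent = emptyenv())   # cross-isoform ledger: read content -> (g, M)
  anyRead <- FALSE
  for (li in seq_len(nrow(ld))) {
    l <- ld$l[li]; lp <- ld$p[li]
    for (k in seq_len(K)) {
      classes <- .isoClasses(gene, geoms, k, l, method)
      if (length(classes) > 0L) anyRead <- TRUE
      for (cls in classes) {
        key <- paste(.chainKey(cls$gIds, l), cls$offLo, cls$offHi)
        hit <- if (cross) cache[[key]] else NULL
        if (is.null(hit)) {
          starts <- .chainTxStarts(gene, geoms, cls$gIds)
          g <- .gFromStarts(gene, geoms, method, starts, cls$offLo, l, lp)
          f <- sum(thetaC * g)
          d <- (g[-K] - g[K]) / f
          M <- outer(d, d)
          evals <- evals + 1L
          hit <- list(g = g, M = M)
          if (cross) cache[[key]] <- hit
        }
        J <- J + (thetaC[k] * hit$g[k] * cls$mult) * hit$M
      }
    }
  }
  if (!anyRead) warning(sprintf("gene '%s': every isoform is shorter than the read length",
                                gene@geneId))
  list(J = J, evals = evals)
}

#' Combine per-method Fisher information across an experiment
#'
#' The expected FIM of a whole experiment is the read-count-weighted sum of
#' the per-method single-read FIMs: `I_total = sum_m N_m J_m`.
#'
#' @param fims list of [FIMResult-class] objects of equal dimension.
#' @param nReads numeric vector of read counts `N_m`, one per method.
#' @return a [FIMResult-class] (algorithm `"combined"`; evaluation counts
#'   summed).
#' @export
combineMethods <- function(fims, nReads) {
  stopifnot(length(fims) == length(nReads))
  dims <- vapply(fims, function(f) nrow(f@J), integer(1))
  if (length(unique(dims)) != 1L)
    stop("FIM dimension mismatch across methods")
  J <- Reduce(`+`, Map(function(f, n) n * f@J, fims, nReads))
  J <- (J + t(J)) / 2
  new("FIMResult", J = J, algorithm = "combined",
      evals = sum(vapply(fims, function(f) f@evals, integer(1))),
      unidentifiable = diag(J) < 1e-12)
}

#' Average-variance heuristic from the Fisher information diagonal
#'
#' A single-number estimate of the mean variance of the abundance MLE:
#' the mean of the reciprocal diagonal entries of the total expected FIM
#' over the `K - 1` free parameters.  It avoids inverting the matrix and
#' reduces to the scalar Cramer-Rao bound `1 / I` when `K = 2`.
#' Parameters with (numerically) zero information are flagged
#' unidentifiable and excluded from the average with a warning; if every
#' parameter is unidentifiable the heuristic is `Inf`.
#'
#' @param fim a [FIMResult-class] or a plain FIM matrix (e.g. from
#'   [combineMethods()]).
#' @return scalar average-variance estimate.
#' @export
avgVarianceHeuristic <- function(fim) {
  J <- if (is(fim, "FIMResult")) fim@J else fim
  if (nrow(J) == 0L) return(NA_real_)
  d <- diag(J)
  bad <- d < 1e-12
  if (all(bad)) {
    warning("all free parameters unidentifiable (zero Fisher information)")
    return(Inf)
  }
  if (any(bad))
    warning(sprintf("%d unidentifiable free parameter(s) excluded from the average",
                    sum(bad)))
  mean(1 / d[!bad])
}

#' Cramer-Rao covariance estimate
#'
#' The inverse of the total expected Fisher information, evaluated at the
#' abundance estimate, bounds (and asymptotically matches) the covariance
#' of the maximum-likelihood estimator over the free parameters.
#'
#' @param fim a [FIMResult-class] or FIM matrix.
#' @param maxCondition condition-number guard; a numerically singular
#'   matrix raises an error recommending [avgVarianceHeuristic()].
#' @return symmetric `(K-1) x (K-1)` covariance matrix.
#' @export
covarianceEstimate <- function(fim, maxCondition = 1e12) {
  J <- if (is(fim, "FIMResult")) fim@J else fim
  if (nrow(J) == 0L) return(J)
  if (rcond(J) < 1 / maxCondition)
    stop("Fisher information numerically singular; use avgVarianceHeuristic() instead")
  S <- solve(J)
  (S + t(S)) / 2
}

#' Heuristic averaged over every choice of dependent isoform
#'
#' The free-parameter convention drops one isoform (the last) as dependent;
#' the average-variance heuristic depends weakly on that choice.  This
#' convenience recomputes the combined FIM with each isoform in turn as the
#' dependent one (by rotating the isoform order) and returns the mean of
#' the per-pivot heuristics.
#'
#' @param gene a [GeneModel-class].
#' @param methods list of [SamplingMethod-class] objects.
#' @param nReads read count per method.
#' @param theta abundance vector.
#' @param algorithm passed to [expectedFIM()].
#' @return scalar mean heuristic over the K pivot choices.
#' @export
pivotAveragedVariance <- function(gene, methods, nReads, theta,
                                  algorithm = "cross_isoform") {
  methods <- .namedMethods(methods)
  K <- nIsoforms(gene)
  vals <- vapply(seq_len(K), function(pivot) {
    perm <- c(setdiff(seq_len(K), pivot), pivot)
    g2 <- withIsoforms(gene, stats::setNames(gene@isoforms[perm], gene@isoformIds[perm]))
    fims <- lapply(methods, function(m) expectedFIM(g2, m, theta[perm], algorithm))
    avgVarianceHeuristic(combineMethods(fims, nReads))
  }, numeric(1))
  mean(vals)
}
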