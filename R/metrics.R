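#' Isoform-composition difference between two conditions
#'
#' Total-variation distance between a gene's abundance vectors in two
#' conditions: `Diff = 0.5 * sum_j |theta_a[j] - theta_b[j]|`.  Ranges from
#' 0 (identical composition) to 1 (disjoint support, a complete switch);
#' symmetric, and a metric on the simplex.
#'
#' @param thetaA,thetaB abundance vectors over the same isoform set; when
#'   both are named, `thetaB` is matched to `thetaA`'s names.
#' @return scalar in `[0, 1]`.
#' @examples
#' diffScore(c(0.7, 0.3), c(0.5, 0.5))  # 0.2
#' @export
diffScore <- function(thetaA, thetaB) {
  if (length(thetaA) != length(thetaB))
    stop("mismatched isoform sets")
  if (!is.null(names(thetaA)) && !is.null(names(thetaB))) {
    if (!setequal(names(thetaA), names(thetaB))) stop("mismatched isoform sets")
    thetaB <- thetaB[names(thetaA)]
  }
  0.5 * sum(abs(thetaA - thetaB))
}

#' Dominant isoform of an estimate
#'
#' The isoform with the highest estimated abundance; ties are broken by
#' longer transcript, then lexicographically by id, so the call is
#' deterministic.
#'
#' @param estimate a [ThetaEstimate-class] (or plain named theta vector).
#' @param gene the corresponding [GeneModel-class].
#' @return isoform id (character).
#' @export
dominantIsoform <- function(estimate, gene) {
  th <- if (is(estimate, "ThetaEstimate")) theta(estimate) else estimate
  L <- isoformLengths(gene)
  ids <- gene@isoformIds
  o <- order(-th, -L, ids)
  ids[o[1L]]
}

#' Classify the structural difference between two dominant isoforms
#'
#' Rule-based comparison of two exon-block paths of the same gene, in
#' transcript (5' to 3') orientation.  Differences are split into aspects:
#'
#' * a 5'-end aspect when the paths begin with unshared blocks —
#'   `Distinct 5' UTR` when both do, `Overlapping 5' UTR` when only one
#'   does (one isoform is a 5' truncation/extension of the other);
#' * one internal aspect per maximal run of unshared internal blocks —
#'   `Extended Exon` when the run is genomically contiguous with a
#'   flanking shared block (an exon-boundary change), `Alternative Exon`
#'   otherwise (a discrete exon present in one isoform only);
#' * a 3'-end aspect, symmetric to the 5' one.
#'
#' When the isoforms differ in several aspects the unit weight is split
#' equally among them (two aspects get 0.5 each), which is why aggregated
#' category counts over many genes can be half-integers.
#'
#' @param gene a [GeneModel-class].
#' @param dominantA,dominantB isoform ids or indices; must differ.
#' @return named numeric vector of weights over the six categories
#'   (`Overlapping 5' UTR`, `Distinct 5' UTR`, `Alternative Exon`,
#'   `Extended Exon`, `Overlapping 3' UTR`, `Distinct 3' UTR`), summing
#'   to 1.
#' @export
classifyStructuralDifference <- function(gene, dominantA, dominantB) {
  if (is.character(dominantA)) dominantA <- match(dominantA, gene@isoformIds)
  if (is.character(dominantB)) dominantB <- match(dominantB, gene@isoformIds)
  cats <- c("Overlapping 5' UTR", "Distinct 5' UTR", "Alternative Exon",
            "Extended Exon", "Overlapping 3' UTR", "Distinct 3' UTR")
  w <- stats::setNames(numeric(6), cats)
  a <- gene@isoforms[[dominantA]]; b <- gene@isoforms[[dominantB]]
  if (gene@strand == "-") { a <- rev(a); b <- rev(b) }   # transcript order
  if (identical(a, b)) stop("dominant isoforms are identical; nothing to classify")
  shared <- intersect(a, b)
  lead <- function(p) { i <- 0L; while (i < length(p) && !(p[i + 1L] %in% shared)) i <- i + 1L; i }
  trail <- function(p) lead(rev(p))
  la <- lead(a); lb <- lead(b)
  ta <- trail(a); tb <- trail(b)
  if (length(shared) == 0L) {
    # no block in common: the two ends differ and there is no internal run
    w["Distinct 5' UTR"] <- 0.5; w["Distinct 3' UTR"] <- 0.5
    return(w)
  }
  tally <- stats::setNames(numeric(6), cats)
  if (la > 0L || lb > 0L)
    tally[if (la > 0L && lb > 0L) "Distinct 5' UTR" else "Overlapping 5' UTR"] <-
      tally[if (la > 0L && lb > 0L) "Distinct 5' UTR" else "Overlapping 5' UTR"] + 1
  if (ta > 0L || tb > 0L)
    tally[if (ta > 0L && tb > 0L) "Distinct 3' UTR" else "Overlapping 3' UTR"] <-
      tally[if (ta > 0L && tb > 0L) "Distinct 3' UTR" else "Overlapping 3' UTR"] + 1
  # internal unshared runs in either path
  for (p in list(a, b)) {
    core <- p[(lead(p) + 1L):(length(p) - trail(p))]
    inRun <- FALSE; runBlocks <- integer(0); runs <- list()
    for (i in seq_along(core)) {
      if (!(core[i] %in% shared)) {
        inRun <- TRUE; runBlocks <- c(runBlocks, core[i])
      } else if (inRun) {
        runs[[length(runs) + 1L]] <- runBlocks
        inRun <- FALSE; runBlocks <- integer(0)
      }
    }
    for (run in runs) {
      contiguous <- any(vapply(run, function(blk) {
        i <- match(blk, p)
        nb <- c(if (i > 1L) p[i - 1L], if (i < length(p)) p[i + 1L])
        nb <- nb[nb %in% shared]
        any(vapply(nb, function(n2) {
          gene@blockEnds[min(blk, n2)] == gene@blockStarts[max(blk, n2)]
        }, logical(1)))
      }, logical(1)))
      cat <- if (contiguous) "Extended Exon" else "Alternative Exon"
      tally[cat] <- tally[cat] + 1
    }
  }
  if (sum(tally) == 0) stop("paths differ but no aspect detected (unexpected)")
  tally / sum(tally)
}

#' Effect of perturbing the isoform set on the fit
#'
#' Refits the reads after modifying the gene's isoform set and reports how
#' the per-read average maximized log-likelihood (`L_avg`) and the retained
#' abundances move.  Removing the dominant isoform degrades `L_avg` the
#' most; adding a dissimilar "dummy" splicing-graph path barely changes
#' either, which is what makes `L_avg` useful for ranking candidate
#' isoform sets.
#'
#' @param gene a [GeneModel-class].
#' @param methods list of [SamplingMethod-class] objects.
#' @param reads a [ReadSet-class].
#' @param mode `"drop_dominant"` (remove the highest-theta isoform),
#'   `"drop_minor"` (remove the lowest-theta isoform) or `"add_dummy"`
#'   (add the enumerated splicing-graph path, not already in the set,
#'   sharing the fewest blocks with the dominant isoform).
#' @param tol,maxIter passed to [emFit()].
#' @return list with `base` and `modified` [ThetaEstimate-class] objects,
#'   `deltaLAvg` (modified minus base) and `deltaTheta` (largest absolute
#'   change among retained isoforms).
#' @export
perturbationAnalysis <- function(gene, methods, reads,
                                 mode = c("drop_dominant", "drop_minor", "add_dummy"),
                                 tol = 1e-8, maxIter = 1000L) {
  mode <- match.arg(mode)
  K <- nIsoforms(gene)
  base <- emFit(gene, methods, reads, tol = tol, maxIter = maxIter)
  th <- theta(base)
  L <- isoformLengths(gene)
  ids <- gene@isoformIds
  if (mode %in% c("drop_dominant", "drop_minor")) {
    if (K < 2L) stop("dropping an isoform requires K >= 2")
    drop <- if (mode == "drop_dominant") order(-th, -L, ids)[1L] else order(th, L, ids)[1L]
    keep <- setdiff(seq_len(K), drop)
    g2 <- withIsoforms(gene, stats::setNames(gene@isoforms[keep], ids[keep]))
  } else {
    paths <- enumerateIsoforms(gene)
    knownKeys <- vapply(gene@isoforms, paste, character(1), collapse = ",")
    novel <- paths[!vapply(paths, paste, character(1), collapse = ",") %in% knownKeys]
    if (length(novel) == 0L)
      stop("splicing graph admits no path outside the current isoform set")
    dom <- match(dominantIsoform(base, gene), ids)
    overlap <- vapply(novel, function(p) length(intersect(p, gene@isoforms[[dom]])), integer(1))
    dummy <- novel[[order(overlap)[1L]]]
    g2 <- withIsoforms(gene, c(stats::setNames(gene@isoforms, ids), list(dummy = dummy)))
  }
  mod <- emFit(g2, methods, .stripSimAnnotations(reads), tol = tol, maxIter = maxIter)
  retained <- intersect(ids, g2@isoformIds)
  list(base = base, modified = mod,
       deltaLAvg = lAvg(mod) - lAvg(base),
       deltaTheta = max(abs(theta(mod)[retained] - th[retained])))
}

# Simulator annotations index into the original gene's isoform list; drop
# them so a modified gene is handled through genomic-block projection.
.stripSimAnnotations <- function(reads) {
  n <- length(reads)
  reads@srcIso <- rep(NA_integer_, n)
  reads@txStart <- rep(NA_integer_, n)
  reads@fragLen <- reads@fragLen   # fragment length still describes the read pair
  reads
}

#' Entropy-based transcriptome complexity
#'
#' Summarizes isoform-level diversity of a whole experiment: each gene
#' contributes the Shannon entropy of its isoform composition,
#' `H_g = -sum_j theta_j log2 theta_j` (with `0 log 0 = 0`), and genes are
#' averaged with expression weights, so the result is the expected number
#' of bits needed to describe which isoform a random transcript molecule
#' comes from.
#'
#' @param thetas list of per-gene abundance vectors (or
#'   [ThetaEstimate-class] objects).
#' @param weights non-negative per-gene expression weights (e.g. gene
#'   RPKM); must not all be zero.
#' @return scalar complexity in bits.
#' @export
transcriptomeComplexity <- function(thetas, weights = rep(1, length(thetas))) {
  stopifnot(length(thetas) == length(weights), all(weights >= 0))
  if (sum(weights) == 0) stop("all expression weights are zero")
  H <- vapply(thetas, function(th) {
    if (is(th, "ThetaEstimate")) th <- theta(th)
    th <- th[th > 0]
    -sum(th * log2(th))
  }, numeric(1))
  sum(weights * H) / sum(weights)
}
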