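# Seed plumbing: every stochastic entry point takes one seed; per-trial
# streams are derived from it by a counter scheme so trials are independent
# and insensitive to evaluation order.
.streamSeed <- function(master, counter) {
  as.integer((as.numeric(master) %% 2147483647 * 48271 + counter * 9973) %% 2147483647)
}

.withSeed <- function(seed, fun) {
  if (is.null(seed)) return(fun())
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  fun()
}

#' Construct a toy gene from block lengths and isoform paths
#'
#' Deterministic fixture builder for simulation studies: blocks of the
#' given lengths are laid on a synthetic chromosome, separated by fixed
#' intron gaps (a gap of 0 makes two blocks genomically contiguous, which
#' is how extended-exon structures are written).
#'
#' @param blockLengths integer block lengths (nt).
#' @param isoforms list of strictly increasing block-index paths.
#' @param gaps intron length(s) between consecutive blocks (scalar or
#'   vector of length `length(blockLengths) - 1`).
#' @param geneId,chrom,strand,origin placement of the gene.
#' @return a [GeneModel-class].
#' @export
makeToyGene <- function(blockLengths, isoforms, gaps = 50L, geneId = "toy",
                        chrom = "chrT", strand = "+", origin = 0L) {
  n <- length(blockLengths)
  gaps <- rep_len(as.integer(gaps), max(n - 1L, 0L))
  starts <- origin + c(0L, cumsum(as.integer(blockLengths[-n]) + gaps))
  ends <- starts + as.integer(blockLengths)
  newGeneModel(geneId, chrom, strand, starts, ends, isoforms)
}

#' Preset two-isoform toy genes
#'
#' Three simplified gene structures used throughout the simulation studies,
#' each with two isoforms: `geneA` has a skipped internal exon (blocks
#' 60/30/60 nt), `geneB` alternative 3' terminal exons (60 then 40 vs
#' 50 nt), and `geneC` a structure dominated by shared sequence with only a
#' tiny 8 nt distinguishing exon (80/8/80 nt), which makes its isoforms
#' hard to tell apart.
#'
#' @param name `"geneA"`, `"geneB"` or `"geneC"`.
#' @return a [GeneModel-class] with `K = 2`.
#' @export
toyGenePreset <- function(name = c("geneA", "geneB", "geneC")) {
  name <- match.arg(name)
  switch(name,
    geneA = makeToyGene(c(60L, 30L, 60L), list(c(1L, 2L, 3L), c(1L, 3L)),
                        geneId = "geneA"),
    geneB = makeToyGene(c(60L, 40L, 50L), list(c(1L, 2L), c(1L, 3L)),
                        geneId = "geneB"),
    geneC = makeToyGene(c(80L, 8L, 80L), list(c(1L, 2L, 3L), c(1L, 3L)),
                        geneId = "geneC"))
}

#' Simulate reads from a gene under known abundances
#'
#' Follows the two-step generative model: each read first draws its source
#' isoform proportionally to `theta` (not length-weighted), then its
#' placement from the method's read-generation function G.  Isoforms too
#' short for the method are excluded (with a warning if they carry
#' positive abundance) and the draw renormalized over the rest.
#'
#' @param gene a [GeneModel-class].
#' @param theta true relative abundances (sums to 1).
#' @param method a [SamplingMethod-class].
#' @param N number of reads.
#' @param seed optional integer seed; identical seeds reproduce the read
#'   set exactly.
#' @return a [ReadSet-class] with genomic alignment blocks and
#'   transcript-space annotations (`srcIso`, `txStart`, `readLen`,
#'   `fragLen`).
#' @export
simulateReads <- function(gene, theta, method, N, seed = NULL) {
  stopifnot(abs(sum(theta) - 1) < 1e-8, N >= 0)
  .withSeed(seed, function() .simulateReadsImpl(gene, theta, method, N))
}

.simulateReadsImpl <- function(gene, theta, method, N) {
  geoms <- .isoGeom(gene)
  K <- length(geoms)
  valid <- vapply(seq_len(K), function(k) {
    L <- geoms[[k]]$L
    if (method@family == "paired_end") length(.validFragLengths(method, L)) > 0
    else L >= .minSampleLength(method)
  }, logical(1))
  if (!any(valid)) stop("no isoform long enough for this sampling method")
  if (any(theta[!valid] > 0))
    warning("isoform(s) too short for the method carry positive abundance; redrawing from the rest")
  thEff <- theta * valid
  thEff <- thEff / sum(thEff)
  ks <- if (N > 0) sample.int(K, N, replace = TRUE, prob = thEff) else integer(0)
  txStart <- integer(N); readLen <- integer(N); fragLen <- rep(NA_integer_, N)
  for (k in unique(ks)) {
    idx <- which(ks == k)
    L <- geoms[[k]]$L
    if (method@family == "fixed_shotgun") {
      l <- method@readLength
      readLen[idx] <- l
      txStart[idx] <- sample.int(L - l + 1L, length(idx), replace = TRUE) - 1L
    } else if (method@family == "length_mixture") {
      ls <- sample(method@lengthDist$l, length(idx), replace = TRUE,
                   prob = method@lengthDist$p)
      bad <- ls > L
      while (any(bad)) {   # reject lengths that do not fit this isoform
        ls[bad] <- sample(method@lengthDist$l, sum(bad), replace = TRUE,
                          prob = method@lengthDist$p)
        bad <- ls > L
      }
      readLen[idx] <- ls
      txStart[idx] <- vapply(ls, function(l)
        sample.int(L - l + 1L, 1L) - 1L, integer(1))
    } else if (method@family == "empirical_bias") {
      l <- method@readLength
      readLen[idx] <- l
      p <- 0:(L - l)
      w <- method@biasProfile[pmin(floor(100 * p / L), 99) + 1L]
      txStart[idx] <- sample(p, length(idx), replace = TRUE, prob = w)
    } else {  # paired_end: uniform over valid (start, fragment) placements
      l <- method@readLength
      ds <- .validFragLengths(method, L)
      wd <- L - ds + 1L
      d <- ds[sample.int(length(ds), length(idx), replace = TRUE, prob = wd)]
      readLen[idx] <- l
      fragLen[idx] <- d
      txStart[idx] <- vapply(d, function(dd)
        sample.int(L - dd + 1L, 1L) - 1L, integer(1))
    }
  }
  # genomic alignment blocks (memoized by placement; placements repeat a lot)
  memo <- new.env(parent = emptyenv())
  blocks <- vector("list", N); mateBlocks <- vector("list", N)
  for (i in seq_len(N)) {
    k <- ks[i]; p <- txStart[i]; l <- readLen[i]; d <- fragLen[i]
    key <- paste(k, p, l, d)
    hit <- memo[[key]]
    if (is.null(hit)) {
      if (is.na(d)) {
        hit <- list(b = .txToGenomicBlocks(gene, geoms, k, p, l), m = NULL)
      } else {
        hit <- list(b = .txToGenomicBlocks(gene, geoms, k, p, l),
                    m = .txToGenomicBlocks(gene, geoms, k, p + d - l, l))
      }
      memo[[key]] <- hit
    }
    blocks[[i]] <- hit$b; mateBlocks[i] <- list(hit$m)
  }
  new("ReadSet",
      readId = sprintf("sim%d", seq_len(N)),
      methodId = rep(method@id, N),
      chrom = rep(gene@chrom, N), strand = rep(gene@strand, N),
      blocks = blocks, mateBlocks = mateBlocks,
      srcIso = as.integer(ks), txStart = txStart,
      readLen = readLen, fragLen = fragLen)
}

#' Reads affordable under a budget share
#'
#' `N_m = floor(fraction * totalBudget / (costPerBase * meanReadLength))`,
#' the number of reads method `m` can produce when assigned the given share
#' of the experiment's budget.
#'
#' @param method a [SamplingMethod-class].
#' @param fraction budget share in `[0, 1]`.
#' @param totalBudget total experiment budget (currency units matching
#'   `costPerBase`).
#' @return integer read count.
#' @export
readsForBudget <- function(method, fraction, totalBudget) {
  ml <- meanReadLength(method)
  if (ml <= 0) stop("method has zero mean read length")
  as.integer(floor(fraction * totalBudget / (method@costPerBase * ml)))
}

#' Brute-force resampling variance of the abundance MLE
#'
#' The direct Monte-Carlo estimator of quantification variance: simulate
#' `trials` independent read sets under the true abundances, fit each by
#' [emFit()], and return the across-trial variance of the estimated
#' abundances averaged over isoforms.  This is the quantity the Fisher
#' information heuristic approximates at a tiny fraction of the cost.
#'
#' @param gene a [GeneModel-class].
#' @param theta true abundances.
#' @param methods list of [SamplingMethod-class] objects.
#' @param nReads read count per method (recycled if scalar).
#' @param trials number of resampling trials (>= 2).
#' @param seed master seed; per-trial streams are derived from it.
#' @param tol,maxIter passed to [emFit()].
#' @return list with `avgVarSim` (mean over isoforms of the across-trial
#'   variance of theta-hat) and `thetaMat` (trials x K matrix of
#'   estimates).
#' @export
resamplingVariance <- function(gene, theta, methods, nReads, trials = 200L,
                               seed = 1L, tol = 1e-8, maxIter = 1000L) {
  stopifnot(trials >= 2L)
  methods <- .namedMethods(methods)
  nReads <- rep_len(nReads, length(methods))
  K <- nIsoforms(gene)
  thetaMat <- matrix(NA_real_, trials, K, dimnames = list(NULL, gene@isoformIds))
  for (t in seq_len(trials)) {
    gms <- list()
    for (m in seq_along(methods)) {
      if (nReads[m] == 0L) next
      r <- simulateReads(gene, theta, methods[[m]], nReads[m],
                         seed = .streamSeed(seed, (t - 1L) * 100L + m))
      gms[[length(gms) + 1L]] <- gMatrix(gene, methods, r)
    }
    if (length(gms) == 0L) { warning(sprintf("trial %d has zero reads; skipped", t)); next }
    est <- emFit(gene, methods, gmat = do.call(rbind, gms), tol = tol, maxIter = maxIter)
    thetaMat[t, ] <- theta(est)
  }
  ok <- stats::complete.cases(thetaMat)
  list(avgVarSim = mean(apply(thetaMat[ok, , drop = FALSE], 2L, stats::var)),
       thetaMat = thetaMat)
}

#' Sweep budget splits between sequencing methods
#'
#' For each budget split, converts budget shares into per-method read
#' counts, combines the per-method single-read FIMs with those counts and
#' evaluates the average-variance heuristic; optionally also runs the
#' brute-force resampling estimator for comparison.  This reproduces the
#' design question: how should a fixed budget be divided among sequencing
#' technologies to quantify a gene's isoforms most precisely?
#'
#' @param gene a [GeneModel-class].
#' @param theta true abundances.
#' @param design list with `methods` (list of [SamplingMethod-class]),
#'   `totalBudget`, `fractions` (list of per-method budget-share vectors,
#'   each summing to 1), `trials`, `seed`, and optionally
#'   `simulate = FALSE` to skip the resampling arm and `algorithm` for
#'   [expectedFIM()].
#' @return data.frame with one row per split: the shares, per-method read
#'   counts, `avgVarEst` (FIM heuristic) and `avgVarSim` (resampling; NA
#'   when skipped).
#' @export
costSweep <- function(gene, theta, design) {
  stopifnot(!is.null(design$methods), length(design$fractions) > 0)
  methods <- .namedMethods(design$methods)
  algorithm <- if (is.null(design$algorithm)) "cross_isoform" else design$algorithm
  doSim <- !identical(design$simulate, FALSE)
  trials <- if (is.null(design$trials)) 200L else design$trials
  seed <- if (is.null(design$seed)) 1L else design$seed
  fims <- lapply(methods, function(m) expectedFIM(gene, m, theta, algorithm))
  rows <- lapply(seq_along(design$fractions), function(s) {
    fr <- design$fractions[[s]]
    stopifnot(length(fr) == length(methods), abs(sum(fr) - 1) < 1e-8)
    N <- vapply(seq_along(methods), function(m)
      readsForBudget(methods[[m]], fr[m], design$totalBudget), integer(1))
    est <- suppressWarnings(avgVarianceHeuristic(combineMethods(fims, N)))
    sim <- NA_real_
    if (doSim) {
      sim <- resamplingVariance(gene, theta, methods, N, trials = trials,
                                seed = .streamSeed(seed, s))$avgVarSim
    }
    out <- data.frame(split = s, avgVarEst = est, avgVarSim = sim)
    for (m in seq_along(methods)) {
      out[[paste0("frac_", names(methods)[m])]] <- fr[m]
      out[[paste0("n_", names(methods)[m])]] <- N[m]
    }
    out
  })
  do.call(rbind, rows)
}
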