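test_that("per-read FIM has the closed score-outer-product form", {
  # uninformative read: equal G under both isoforms
  expect_equal(observedFIM(c(0.01, 0.01), c(0.4, 0.6)), matrix(0, 1, 1))
  # K=2, read unique to isoform 1: scalar 1/theta1^2
  th <- c(0.3, 0.7)
  expect_equal(observedFIM(c(0.05, 0), th)[1, 1], 1 / 0.3^2)
  # symmetric, rank <= 1
  g4 <- c(0.04, 0.01, 0, 0.02)
  th4 <- c(0.4, 0.3, 0.2, 0.1)
  M <- observedFIM(g4, th4)
  expect_equal(M, t(M))
  expect_lte(qr(M)$rank, 1L)
  expect_error(observedFIM(c(0, 0), c(0.5, 0.5)), "zero likelihood")
})

test_that("brute-force expected FIM equals the distinct-read enumeration", {
  th <- c(0.55, 0.45)
  g <- toyGenePreset("geneA")
  m <- shotgunMethod("s", 8L)
  f <- expectedFIM(g, m, th, "bruteforce")
  expect_equal(fimMatrix(f), oracleExpectedFIM(g, m, th), tolerance = 1e-12)
  expect_equal(fimEvals(f), sum(pmax(isoformLengths(g) - 8 + 1, 0)))
  # length mixture and positional bias, random genes
  for (seed in c(3, 4)) {
    gr <- randomToyGene(seed)
    thr <- rep(1 / nIsoforms(gr), nIsoforms(gr))
    mix <- lengthMixtureMethod("mix", c(5L, 12L), c(0.4, 0.6))
    expect_equal(fimMatrix(expectedFIM(gr, mix, thr, "bruteforce")),
                 oracleExpectedFIM(gr, mix, thr), tolerance = 1e-12)
    set.seed(seed)
    prof <- stats::runif(100); prof <- prof / sum(prof)
    mb <- biasedMethod("b", 6L, prof)
    expect_equal(fimMatrix(expectedFIM(gr, mb, thr, "bruteforce")),
                 oracleExpectedFIM(gr, mb, thr), tolerance = 1e-12)
  }
  # K = 1: no free parameter
  expect_equal(dim(fimMatrix(expectedFIM(simpleShotgunGene(), m, 1))), c(0L, 0L))
  # identical isoforms: nothing distinguishes them
  gid <- makeToyGene(c(40L, 40L), list(c(1L, 2L), c(1L, 2L)))
  expect_equal(fimMatrix(expectedFIM(gid, m, c(0.5, 0.5), "bruteforce")),
               matrix(0, 1, 1))
  expect_true(all(expectedFIM(gid, m, c(0.5, 0.5), "bruteforce")@unidentifiable))
})

test_that("equivalence classes conserve multiplicity and match junction signatures", {
  g <- toyGenePreset("geneA")
  geoms <- isomix:::.isoGeom(g)
  m <- shotgunMethod("s", 10L)
  for (k in 1:2) {
    cls <- isomix:::.isoClasses(g, geoms, k, 10L, m)
    expect_equal(sum(vapply(cls, `[[`, numeric(1), "mult")),
                 geoms[[k]]$L - 10 + 1)
    # within a class, every read has the junction signature of the representative
    for (cl in cls) {
      sigRep <- junctionSignature(g, k, cl$repP, cl$repP + 10L)
      pLast <- cl$repP + cl$mult - 1L
      expect_identical(junctionSignature(g, k, pLast, pLast + 10L), sigRep)
    }
  }
  # single-block isoform: exactly one class of multiplicity L - l + 1
  g1 <- simpleShotgunGene(100L)
  cls1 <- isomix:::.isoClasses(g1, isomix:::.isoGeom(g1), 1L, 25L, m)
  expect_length(cls1, 1L)
  expect_equal(cls1[[1L]]$mult, 76)
})

test_that("all three algorithms agree on random genes with monotone eval counts", {
  for (seed in 1:20) {
    g <- randomToyGene(seed)
    K <- nIsoforms(g)
    set.seed(seed + 1000)
    th <- as.vector(stats::rgamma(K, 2)); th <- th / sum(th)
    l <- sample(c(5L, 8L, 12L), 1L)
    m <- shotgunMethod("s", l)
    f1 <- suppressWarnings(expectedFIM(g, m, th, "bruteforce"))
    f2 <- suppressWarnings(expectedFIM(g, m, th, "equivalence"))
    f3 <- suppressWarnings(expectedFIM(g, m, th, "cross_isoform"))
    expect_lt(max(abs(fimMatrix(f2) - fimMatrix(f1))), 1e-10)
    expect_lt(max(abs(fimMatrix(f3) - fimMatrix(f1))), 1e-10)
    expect_lte(fimEvals(f3), fimEvals(f2))
    expect_lte(fimEvals(f2), fimEvals(f1))
    if (hasSharedLongBlock(g, l))
      expect_lt(fimEvals(f3), fimEvals(f2))
    # PSD
    if (nrow(fimMatrix(f1)) > 0)
      expect_gte(min(eigen(fimMatrix(f1), symmetric = TRUE)$values), -1e-9)
  }
})

test_that("cross-isoform reuse changes counts only where reads are shared", {
  m <- shotgunMethod("s", 10L)
  th <- c(0.5, 0.5)
  # no shared blocks: the cross-isoform ledger saves nothing
  gd <- distinctGene()
  f2 <- expectedFIM(gd, m, th, "equivalence")
  f3 <- expectedFIM(gd, m, th, "cross_isoform")
  expect_equal(fimEvals(f3), fimEvals(f2))
  # long shared constitutive blocks: shared classes computed once
  gs <- toyGenePreset("geneC")
  expect_lt(fimEvals(expectedFIM(gs, m, th, "cross_isoform")),
            fimEvals(expectedFIM(gs, m, th, "equivalence")))
})

test_that("step-function bias profiles stay exact under the class machinery", {
  for (seed in c(2, 5, 9)) {
    g <- randomToyGene(seed)
    K <- nIsoforms(g)
    th <- rep(1 / K, K)
    set.seed(seed)
    prof <- stats::runif(100)^2; prof <- prof / sum(prof)
    mb <- biasedMethod("b", 7L, prof)
    f1 <- expectedFIM(g, mb, th, "bruteforce")
    f2 <- expectedFIM(g, mb, th, "equivalence")
    f3 <- expectedFIM(g, mb, th, "cross_isoform")
    expect_lt(max(abs(fimMatrix(f2) - fimMatrix(f1))), 1e-10)
    expect_lt(max(abs(fimMatrix(f3) - fimMatrix(f1))), 1e-10)
    expect_lte(fimEvals(f3), fimEvals(f2))
    expect_lte(fimEvals(f2), fimEvals(f1))
  }
})

test_that("method combination is the read-count weighted sum", {
  g <- toyGenePreset("geneB")
  th <- c(0.6, 0.4)
  mA <- shotgunMethod("a", 8L)
  mB <- shotgunMethod("b", 15L)
  fA <- expectedFIM(g, mA, th)
  fB <- expectedFIM(g, mB, th)
  tot <- combineMethods(list(fA, fB), c(100, 50))
  expect_equal(fimMatrix(tot), 100 * fimMatrix(fA) + 50 * fimMatrix(fB))
  # single method, N = 1: identity
  expect_equal(fimMatrix(combineMethods(list(fA), 1)), fimMatrix(fA))
  # doubling every N doubles the information and halves the variance
  tot2 <- combineMethods(list(fA, fB), c(200, 100))
  expect_equal(fimMatrix(tot2), 2 * fimMatrix(tot))
  expect_equal(avgVarianceHeuristic(tot2), avgVarianceHeuristic(tot) / 2)
  f3 <- expectedFIM(makeToyGene(c(30L, 30L, 30L),
                                list(c(1L, 2L, 3L), c(1L, 3L), c(2L, 3L))),
                    mA, c(0.5, 0.3, 0.2))
  expect_error(combineMethods(list(fA, f3), c(1, 1)), "dimension")
})

test_that("variance heuristic averages reciprocal diagonal information", {
  # K=2 fully distinguishable: avgVar = theta1 * theta2 / N exactly
  gd <- distinctGene()
  m <- shotgunMethod("s", 10L)
  th <- c(0.7, 0.3)
  f <- expectedFIM(gd, m, th)
  expect_equal(avgVarianceHeuristic(combineMethods(list(f), 1000)),
               0.7 * 0.3 / 1000, tolerance = 1e-9)
  # K=3 toy matrix: mean of reciprocal diagonal
  J <- matrix(c(4, 1, 1, 2), 2, 2)
  expect_equal(avgVarianceHeuristic(J), mean(c(1 / 4, 1 / 2)))
  # identical isoforms: unidentifiable
  gid <- makeToyGene(c(40L, 40L), list(c(1L, 2L), c(1L, 2L)))
  fid <- expectedFIM(gid, m, c(0.5, 0.5))
  expect_warning(v <- avgVarianceHeuristic(fid), "unidentifiable")
  expect_identical(v, Inf)
})

test_that("covariance estimate inverts the information matrix", {
  J <- matrix(c(5, 1, 1, 3), 2, 2)
  S <- covarianceEstimate(J)
  expect_equal(S, matrix(c(3, -1, -1, 5), 2, 2) / 14)
  expect_equal(S, t(S))
  expect_gte(min(eigen(S, symmetric = TRUE)$values), 0)
  # 1-D case matches the scalar Cramer-Rao bound
  gd <- distinctGene()
  f <- expectedFIM(gd, shotgunMethod("s", 10L), c(0.6, 0.4))
  expect_equal(covarianceEstimate(combineMethods(list(f), 500))[1, 1],
               avgVarianceHeuristic(combineMethods(list(f), 500)))
  expect_error(covarianceEstimate(matrix(c(1, 1, 1, 1), 2, 2)), "singular")
})

test_that("pivot choice has only a weak effect on the heuristic", {
  g <- makeToyGene(c(40L, 25L, 40L), list(c(1L, 2L, 3L), c(1L, 3L), c(2L, 3L)))
  th <- c(0.5, 0.3, 0.2)
  m <- shotgunMethod("s", 10L)
  pv <- pivotAveragedVariance(g, list(m), 1000, th)
  direct <- avgVarianceHeuristic(combineMethods(list(expectedFIM(g, m, th)), 1000))
  expect_gt(pv, 0)
  expect_lt(abs(log(pv / direct)), log(5))   # same order of magnitude
})
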