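---
title: "Isoform quantification and Fisher-information variance estimation with isomix"
author: "isomix authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isoform quantification and Fisher-information variance estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomix)
```

# The statistical model

A gene is represented by its splicing graph: a set of non-overlapping exon
blocks (the graph nodes) such that every annotated exon is an exact
concatenation of blocks, and each isoform $I_1, \dots, I_K$ is a path over
those blocks.  The quantity of interest is the vector of relative isoform
abundances $\Theta = (\theta_1, \dots, \theta_K)$, $\sum_j \theta_j = 1$.

Sequencing is modelled as *partial sampling*: a read from sampling method
$m$ arises in two steps — an isoform is drawn with probability $\theta_j$,
then a read is drawn from that isoform according to the method's
read-generation function $G_m(r \mid I_j)$.  $G$ is pluggable; the package
ships four families:

* **fixed-length shotgun** — a transcript of length $L$ has $L - l + 1$
  equiprobable start positions for reads of length $l$;
* **length mixture** — a finite mixture of fixed lengths with weights
  $P(l)$, so $G(r) = P(l_r)\,/\,(L - l_r + 1)$;
* **paired-end** — two mates of fixed length; a placement is valid when the
  implied fragment length $d$ on the isoform satisfies
  $|d - \mu| \le \delta \mu$, and generation is uniform over valid
  (start, fragment-length) placements, normalized per isoform.  The model
  specifies only the compatibility window; uniformity over placements is
  the minimal density assumption consistent with the shotgun family;
* **empirical positional bias** — a step function: each transcript is
  divided into 100 equal bins, the start-position probability is
  proportional to the bin weight, normalized over valid starts.  Profiles
  are estimated from single-isoform genes (unambiguous assignment) with
  [buildBiasProfile()], each transcript's signal normalized before
  averaging so deep genes do not dominate.

A read is *compatible* with an isoform when its alignment blocks are an
exact, junction-consistent projection of the isoform's exon chain (plus the
fragment-length window for pairs).  All transcript coordinates run 5' to 3'
— on the minus strand the transcript starts at the genomically last block —
because bias profiles are anchored at the 5' end.

# Maximum likelihood by EM

The likelihood of a read set is $\prod_i \sum_j \theta_j G(r_i \mid I_j)$,
with reads from all methods entering the same product.  Introducing hidden
read-to-isoform assignments gives the EM updates implemented in
`eStep()`/`mStep()`: posterior weights
$w_{ij} \propto \theta_j G(r_i \mid I_j)$ and the update
$\theta_j \leftarrow \frac{1}{N}\sum_i w_{ij}$.  When every read is
compatible with exactly one isoform this reduces to counting read
fractions, which is the classical full-observation estimator.

Numerical choices in `emFit()`:

* initialization is uniform, $\theta_j = 1/K$ — the likelihood is
  well-behaved from a uniform start and the fit is reproducible;
* convergence is an absolute log-likelihood change below `tol = 1e-8`
  with `maxIter = 1000`; desk-scale genes converge in tens of iterations
  and the log-likelihood trace is kept so monotonicity is verifiable;
* reads compatible with no isoform are dropped from the likelihood and
  counted (`nReadsDropped`), which keeps the objective well-defined;
* abundances below $10^{-12}$ are floored to zero on output only;
* identical rows of the G matrix are collapsed to weighted classes — a
  pure implementation detail with no numerical effect.

The per-read average maximized log-likelihood $L_{avg} = \log L / N$
(natural log; the base is a convention we fix and document) scores how well
an isoform *set* explains the reads and is used to rank candidate sets in
`perturbationAnalysis()`.

# Quantification variance from Fisher information

The stability of $\hat\Theta$ over resampled read sets is its variance,
estimated directly by `resamplingVariance()`: simulate $T$ read sets, fit
each, average the per-isoform across-trial variances.  This brute-force
estimator is the reference but is far too slow for genome-scale use, which
is the reason for the Fisher-information route.

With $\theta_K = 1 - \sum_{a<K}\theta_a$ treated as dependent, the score of
a read with generation probabilities $G_j$ is
$(G_a - G_K)/f$, $f = \sum_j \theta_j G_j$, so the per-read (observed) FIM
is the rank-one outer product implemented in `observedFIM()`.  The expected
FIM of one read from method $m$ is

$$J_m = \sum_k \theta_k \sum_r G_m(r \mid I_k)\, M(r),$$

and an experiment with $N_m$ reads per method has
$I_{total} = \sum_m N_m J_m$ (`combineMethods()`).  The Cramér–Rao bound
$\mathrm{Cov}(\hat\Theta) \succeq I_{total}^{-1}$ is evaluated at
$\hat\Theta$ by `covarianceEstimate()`.

As a single-number summary we use the **average-variance heuristic**: the
mean of the reciprocal diagonal entries of $I_{total}$ over the $K-1$ free
parameters.  It avoids the matrix inverse (which can be numerically
unstable for near-unidentifiable genes) and reduces to the scalar bound
$1/I$ when $K = 2$; these two properties pin the form down among the simple
candidates, and we document it as our chosen definition.  Its weak
dependence on which isoform is the dependent one can be averaged away with
`pivotAveragedVariance()`.  Free parameters with (numerically) zero
information are reported unidentifiable and excluded with a warning.
Abundances below $10^{-6}$ are clamped to $10^{-6}$ inside FIM evaluation
to avoid division blow-ups; reported abundances are never modified.

## Exact fast algorithms

`expectedFIM()` offers three routes that return the same matrix:

1. **bruteforce** enumerates every read placement of every isoform —
   $\sum_k (L_k - l + 1)$ per-read FIM evaluations for fixed length $l$.
2. **equivalence** exploits that two fixed-length uniform reads covering
   the same junction run of an isoform have identical generation
   probabilities under *every* isoform, hence the same per-read FIM: start
   positions are grouped into equivalence classes by covered-junction run
   and one representative is evaluated per class, scaled by the class
   multiplicity.  For the step-function bias family the classes are
   additionally split at bias-bin boundaries of every compatible isoform,
   which keeps the G vector exactly constant within a class; this is why
   the machinery applies to any piecewise-constant $G$ but not to
   continuous densities.
3. **cross_isoform** adds a ledger across isoforms: a class whose read
   content (genomic block chain and intra-chain offset range) was already
   evaluated in another isoform reuses the stored per-read FIM.  The class
   offset range is intrinsic to the chain, so identical read sets in
   different isoforms produce identical keys.

Evaluation counts satisfy cross ≤ equivalence ≤ bruteforce, strictly on
genes with shared blocks; the test suite checks elementwise agreement to
$10^{-10}$ on randomized genes.  Paired-end methods always use the
brute-force enumeration over (start, fragment-length) placements: the
junction-run argument assumes contiguous single-end reads, and a
paired-end read is only approximately a long read with its gap filled.

# Synthetic data and study conditions

The generator (`makeToyGene()`, `simulateReads()`) implements the model's
own two-step process — isoform by $\Theta$ (not length-weighted), then
placement by $G$ — so MLE recovery is unbiased under the generating model,
and every stochastic entry point takes one seed from which per-trial
streams are derived by a counter scheme (trials are order-insensitive).

Preset genes mirror the three canonical two-isoform structures: `geneA`
(skipped 30 nt internal exon between 60 nt flanks), `geneB` (alternative
3' terminal exons), `geneC` (80/8/80 nt — nearly indistinguishable
isoforms).  The problem sizes used throughout the tests and the acceptance
script are chosen as desk-scale study conditions: $N = 20{,}000$ reads for
EM recovery (recovering $\theta = (0.7, 0.3)$ to $\pm 0.02$),
$N = 1{,}000$ with $T = 500$ trials for the variance comparisons, and
budget sweeps over five splits between a 10 nt single-end method (cost
1/base) and a 15 nt-mate paired-end method ($\mu = 60$, $\delta = 0.1$,
cost 0.5/base) with a total budget of 20,000 currency units, i.e. roughly
100–1900 reads per method and split (about 100–200x coverage of the toy
genes).  The budget is set so every split sits in the asymptotic regime
where the MLE variance approaches the Cramér–Rao bound; at much lower
coverage (tens of reads) the finite-sample variance sits visibly above the
bound and rank comparisons between near-equal splits become Monte-Carlo
ties.  Per-base costs are configuration inputs with no claim of matching
any published price list.

What the simulations do *not* emulate: sequence-composition (hexamer/GC)
bias, base-call errors, alignment ambiguity between genes, library
duplicates, and length-weighted isoform choice.  Passing tests therefore
demonstrate correctness of the estimators under the stated generative
model, not robustness to those real-data artifacts; the empirical-bias
family is the hook through which measured positional effects enter.

# Downstream statistics

* `diffScore()` — the difference between a gene's compositions in two
  conditions is the total-variation distance
  $\tfrac12 \sum_j |\theta^A_j - \theta^B_j|$: symmetric, a metric, 0 for
  identical compositions and 1 for disjoint support.  We deliberately do
  not divide by the isoform count: total variation is already bounded in
  $[0, 1]$ regardless of $K$, which keeps scores comparable across genes.
  Histograms over genes should be restricted to genes whose gene-level
  RPKM (sum of isoform RPKMs) passes a threshold in both conditions
  (`runDiff(..., rpkmThreshold = )`), since low-coverage compositions are
  noise-dominated.
* `classifyStructuralDifference()` — rule-based comparison of the two
  dominant isoforms' block paths into six categories (overlapping/distinct
  5' UTR, alternative/extended exon, overlapping/distinct 3' UTR); when a
  pair differs in several aspects the unit weight is split equally, which
  is how aggregated category counts become half-integers.  Calls are made
  from exon-block structure alone: a one-sided terminal difference is
  "overlapping", a two-sided one "distinct", and an internal run of
  unshared blocks is "extended" when genomically contiguous with a shared
  flanking block, else "alternative".  We do not restrict the comparison
  to CDS-annotated UTR blocks even when the annotation carries CDS
  features — structure-only calls keep the operation applicable to
  annotations without CDS and to the synthetic genes; with CDS-aware
  annotations the 5'/3' categories should be read as "terminal-end"
  differences.
* `transcriptomeComplexity()` — the expression-weighted mean of per-gene
  Shannon entropies $-\sum_j \theta_j \log_2 \theta_j$, in bits: the
  expected number of bits needed to name which isoform a random transcript
  molecule of a gene uses.  The weighted-mean form is our chosen
  definition; weights are typically gene RPKM.
* Dominant isoforms are the abundance argmax with deterministic
  tie-breaking (longer transcript, then lexicographic id).
* In `perturbationAnalysis()` the "dummy" isoform is chosen
  deterministically as the enumerated splicing-graph path outside the
  current set sharing the fewest blocks with the dominant isoform.

# Known limitations

* Reads are assigned to genes by chromosomal overlap with one gene model
  at a time; multi-gene ambiguity is not modelled.
* Continuous (non-step) generation densities are supported by the EM and
  the brute-force FIM but not by the equivalence-class algorithms, which
  raise an explicit error rather than approximate.
* Strand-unassigned reads (`*`) are matched to either strand; strand
  inference for unstranded protocols is out of scope.
* The average-variance heuristic is a diagonal summary: it ignores
  covariances between free parameters and should be read as an
  order-of-magnitude precision estimate, which is exactly how the budget
  sweep uses it (ranking, not calibration).

# A worked example

```{r example}
gene <- toyGenePreset("geneA")
method <- shotgunMethod("short", 10, costPerBase = 1)
reads <- simulateReads(gene, c(0.7, 0.3), method, 5000, seed = 1)
fit <- emFit(gene, list(method), reads)
theta(fit)

fim <- expectedFIM(gene, method, theta(fit), "cross_isoform")
avgVarianceHeuristic(combineMethods(list(fim), length(reads)))
fimEvals(fim)
```
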