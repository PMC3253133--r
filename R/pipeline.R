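#' Load a run configuration
#'
#' Configurations are YAML (or equivalent R lists) with fields:
#' `annotation` (path, optionally `annotation_format`), `alignments`
#' (mapping of method id to file path; `.sam`/`.bam` or the TSV dialect),
#' `methods` (list of method definitions: `id`, `family`, and the family's
#' parameters `read_length`, `lengths`/`probs`, `insert_mean`/`insert_tol`,
#' `bias_profile` path or 100 numbers, `cost_per_base`), `em`
#' (`tol`, `max_iter`), `fim` (`algorithm`), `rpkm_threshold`,
#' `total_mapped_reads`, `seed` and `outdir`.
#'
#' @param x path to a YAML file, or a list already in memory.
#' @return validated config list.
#' @export
loadConfig <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  if (!is.null(cfg$alignments) && !is.null(cfg$methods)) {
    ids <- vapply(cfg$methods, function(m) m$id, character(1))
    bad <- setdiff(names(cfg$alignments), ids)
    if (length(bad))
      stop("alignments reference undefined method id(s): ", paste(bad, collapse = ", "))
  }
  cfg
}

# method definition list -> SamplingMethod
.methodFromConfig <- function(def) {
  cost <- if (is.null(def$cost_per_base)) 1 else def$cost_per_base
  switch(def$family,
    fixed_shotgun = shotgunMethod(def$id, def$read_length, cost),
    length_mixture = lengthMixtureMethod(def$id, unlist(def$lengths),
                                         unlist(def$probs), cost),
    paired_end = pairedEndMethod(def$id, def$read_length, def$insert_mean,
                                 def$insert_tol, cost),
    empirical_bias = {
      prof <- if (is.character(def$bias_profile))
        scan(def$bias_profile, quiet = TRUE) else unlist(def$bias_profile)
      biasedMethod(def$id, def$read_length, prof, cost)
    },
    stop("unknown method family: ", def$family))
}

.configMethods <- function(cfg) .namedMethods(lapply(cfg$methods, .methodFromConfig))

.configHash <- function(cfg) {
  s <- paste(deparse(cfg), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1)) %% .Machine$integer.max)
}

.loadAlignments <- function(cfg) {
  rs <- lapply(names(cfg$alignments), function(mid) {
    path <- cfg$alignments[[mid]]
    if (grepl("\\.(sam|bam)$", path, ignore.case = TRUE))
      readAlignmentsSAM(path, mid)
    else readAlignmentsTSV(path)
  })
  do.call(combineReadSets, rs)
}

# reads whose span overlaps the gene's block span on the same chromosome
.readsForGene <- function(reads, gene) {
  lo <- min(gene@blockStarts); hi <- max(gene@blockEnds)
  sel <- which(reads@chrom == gene@chrom &
               vapply(seq_len(length(reads)), function(i) {
                 b <- reads@blocks[[i]]
                 b[1L, 1L] < hi && b[nrow(b), 2L] > lo
               }, logical(1)))
  reads[sel]
}

.floatFmt <- function(x, full = FALSE) {
  ifelse(is.na(x), "NA", formatC(x, digits = if (full) 17L else 6L, format = "g"))
}

#' Quantify isoform abundances for every gene in a configuration
#'
#' Clusters the annotation into genes, collects each gene's overlapping
#' reads, fits abundances by [emFit()] and writes one TSV row per isoform
#' with columns `gene_id`, `isoform_id`, `theta`, `rpkm`,
#' `n_expected_reads`, `l_avg`, `n_iter`, `converged`.  Genes without
#' usable reads get `NA` rows flagged in the log; dropped-read counts are
#' reported per gene.
#'
#' @param config a config list or YAML path (see [loadConfig()]).
#' @param out output TSV path (default `<outdir>/quant.tsv`).
#' @param fullPrecision write floats at full precision instead of 6
#'   significant digits.
#' @return (invisibly) the result data.frame.
#' @export
runQuant <- function(config, out = NULL, fullPrecision = FALSE) {
  cfg <- loadConfig(config)
  genes <- importAnnotation(cfg$annotation,
                            if (is.null(cfg$annotation_format)) "auto" else cfg$annotation_format)
  methods <- .configMethods(cfg)
  reads <- .loadAlignments(cfg)
  tol <- if (is.null(cfg$em$tol)) 1e-8 else cfg$em$tol
  maxIter <- if (is.null(cfg$em$max_iter)) 1000L else as.integer(cfg$em$max_iter)
  total <- if (is.null(cfg$total_mapped_reads)) length(reads) else cfg$total_mapped_reads
  rows <- list()
  for (gene in genes) {
    gr <- .readsForGene(reads, gene)
    est <- NULL
    if (length(gr) > 0L)
      est <- tryCatch(emFit(gene, methods, gr, tol = tol, maxIter = maxIter),
                      error = function(e) NULL)
    if (is.null(est)) {
      message(sprintf("gene %s: no compatible reads; writing NA row", geneId(gene)))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = geneId(gene), isoform_id = isoformIds(gene), theta = NA_real_,
        rpkm = NA_real_, n_expected_reads = NA_real_, l_avg = NA_real_,
        n_iter = NA_integer_, converged = NA, stringsAsFactors = FALSE)
      next
    }
    est <- rpkm(est, gene, total)
    if (est@nReadsDropped > 0L)
      message(sprintf("gene %s: dropped %d read(s) compatible with no isoform",
                      geneId(gene), est@nReadsDropped))
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = geneId(gene), isoform_id = isoformIds(gene),
      theta = theta(est), rpkm = est@rpkm,
      n_expected_reads = est@expectedReads, l_avg = lAvg(est),
      n_iter = est@nIter, converged = est@converged, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  if (is.null(out)) out <- file.path(if (is.null(cfg$outdir)) "." else cfg$outdir, "quant.tsv")
  .writeReport(df, out, cfg, c("theta", "rpkm", "n_expected_reads", "l_avg"), fullPrecision)
  invisible(df)
}

.writeReport <- function(df, out, cfg, floatCols, fullPrecision = FALSE) {
  dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
  for (cn in intersect(floatCols, names(df))) df[[cn]] <- .floatFmt(df[[cn]], fullPrecision)
  con <- file(out, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s seed=%s", .configHash(cfg),
                     if (is.null(cfg$seed)) "NA" else cfg$seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Per-gene Fisher-information variance report
#'
#' For every gene, evaluates the expected FIM at the fitted (or supplied)
#' abundances with the requested algorithm(s) and writes `gene_id`, `K`,
#' `algorithm`, `avg_var_est`, `n_unidentifiable` and `per_read_fim_evals`.
#' Single-isoform genes have no free parameter and get an `NA` row.
#'
#' @param config a config list or YAML path.
#' @param quant data.frame from [runQuant()] (or path to its TSV); supplies
#'   theta.  Required.
#' @param algorithms character vector of algorithms to run.
#' @param out output TSV path.
#' @return (invisibly) the result data.frame.
#' @export
runFim <- function(config, quant, algorithms = "cross_isoform", out = NULL) {
  cfg <- loadConfig(config)
  if (is.character(quant)) quant <- readReportTSV(quant)
  if (is.null(quant)) stop("runFim needs the quantification result (theta)")
  genes <- importAnnotation(cfg$annotation,
                            if (is.null(cfg$annotation_format)) "auto" else cfg$annotation_format)
  methods <- .configMethods(cfg)
  nByMethod <- table(.loadAlignments(cfg)@methodId)
  rows <- list()
  for (gene in genes) {
    sel <- quant[quant$gene_id == geneId(gene), , drop = FALSE]
    th <- sel$theta[match(isoformIds(gene), sel$isoform_id)]
    K <- nIsoforms(gene)
    for (alg in algorithms) {
      if (K < 2L || anyNA(th)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = geneId(gene), K = K, algorithm = alg, avg_var_est = NA_real_,
          n_unidentifiable = NA_integer_, per_read_fim_evals = NA_integer_,
          stringsAsFactors = FALSE)
        next
      }
      fims <- lapply(methods, function(m) expectedFIM(gene, m, th, alg))
      N <- as.numeric(nByMethod[names(methods)])
      N[is.na(N)] <- 0
      tot <- combineMethods(fims, N)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = geneId(gene), K = K, algorithm = alg,
        avg_var_est = suppressWarnings(avgVarianceHeuristic(tot)),
        n_unidentifiable = sum(tot@unidentifiable),
        per_read_fim_evals = fimEvals(tot), stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  if (is.null(out)) out <- file.path(if (is.null(cfg$outdir)) "." else cfg$outdir, "fim.tsv")
  .writeReport(df, out, cfg, "avg_var_est")
  invisible(df)
}

#' Simulate reads from a configuration
#'
#' Expects `simulate` fields in the config: `gene` (a [toyGenePreset()]
#' name, or `blocks` + `isoforms`), `theta`, `n_reads` per method, and the
#' global `seed`.  Writes the reads in the TSV alignment dialect plus a
#' truth file with the generating abundances.
#'
#' @param config config list or YAML path.
#' @param out output TSV path for reads.
#' @return (invisibly) the simulated [ReadSet-class].
#' @export
runSimulate <- function(config, out = NULL) {
  cfg <- loadConfig(config)
  sim <- cfg$simulate
  gene <- if (!is.null(sim$gene$preset)) toyGenePreset(sim$gene$preset)
          else makeToyGene(unlist(sim$gene$blocks), lapply(sim$gene$isoforms, unlist))
  methods <- .configMethods(cfg)
  theta <- unlist(sim$theta)
  nReads <- rep_len(unlist(sim$n_reads), length(methods))
  seed <- if (is.null(cfg$seed)) 1L else cfg$seed
  rs <- lapply(seq_along(methods), function(m)
    simulateReads(gene, theta, methods[[m]], nReads[m], seed = .streamSeed(seed, m)))
  reads <- do.call(combineReadSets, rs)
  if (is.null(out)) out <- file.path(if (is.null(cfg$outdir)) "." else cfg$outdir, "sim_reads.tsv")
  dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
  writeAlignmentsTSV(reads, out, header = sprintf("config_hash=%s seed=%s truth_theta=%s",
    .configHash(cfg), seed, paste(theta, collapse = ",")))
  invisible(reads)
}

#' Run a budget-split sweep from a configuration
#'
#' Expects `sweep` fields: `gene` (preset or blocks/isoforms), `theta`,
#' `total_budget`, `fractions` (list of per-method shares), `trials`, and
#' optionally `simulate: false`.
#'
#' @param config config list or YAML path.
#' @param out output TSV path.
#' @return (invisibly) the [costSweep()] data.frame.
#' @export
runSweep <- function(config, out = NULL) {
  cfg <- loadConfig(config)
  sw <- cfg$sweep
  gene <- if (!is.null(sw$gene$preset)) toyGenePreset(sw$gene$preset)
          else makeToyGene(unlist(sw$gene$blocks), lapply(sw$gene$isoforms, unlist))
  design <- list(methods = .configMethods(cfg), totalBudget = sw$total_budget,
                 fractions = lapply(sw$fractions, unlist),
                 trials = sw$trials, seed = cfg$seed, simulate = sw$simulate,
                 algorithm = cfg$fim$algorithm)
  df <- costSweep(gene, unlist(sw$theta), design)
  if (is.null(out)) out <- file.path(if (is.null(cfg$outdir)) "." else cfg$outdir, "sweep.tsv")
  .writeReport(df, out, cfg, c("avgVarEst", "avgVarSim"))
  invisible(df)
}

#' Compare isoform composition between two quantified conditions
#'
#' Joins two [runQuant()] outputs by gene and isoform, computes the Diff
#' score for genes whose gene-level RPKM reaches `rpkmThreshold` in both
#' conditions, identifies the dominant isoforms and (when `genes` models
#' are supplied) classifies the structural difference between differing
#' dominants.
#'
#' @param quantA,quantB data.frames from [runQuant()] (or TSV paths).
#' @param genes optional list of [GeneModel-class] for structural calls.
#' @param rpkmThreshold minimum gene RPKM in both conditions (default 1).
#' @param out optional output TSV path.
#' @return data.frame with `gene_id`, `diff`, `dominant_a`, `dominant_b`
#'   and one weight column per structural category.
#' @export
runDiff <- function(quantA, quantB, genes = NULL, rpkmThreshold = 1, out = NULL) {
  if (is.character(quantA)) quantA <- readReportTSV(quantA)
  if (is.character(quantB)) quantB <- readReportTSV(quantB)
  geneIdx <- if (is.null(genes)) NULL else
    stats::setNames(seq_along(genes), vapply(genes, geneId, character(1)))
  cats <- c("Overlapping 5' UTR", "Distinct 5' UTR", "Alternative Exon",
            "Extended Exon", "Overlapping 3' UTR", "Distinct 3' UTR")
  rows <- list()
  for (gid in intersect(unique(quantA$gene_id), unique(quantB$gene_id))) {
    a <- quantA[quantA$gene_id == gid, , drop = FALSE]
    b <- quantB[quantB$gene_id == gid, , drop = FALSE]
    if (anyNA(a$theta) || anyNA(b$theta)) next
    if (!setequal(a$isoform_id, b$isoform_id)) next
    b <- b[match(a$isoform_id, b$isoform_id), , drop = FALSE]
    if (sum(a$rpkm) < rpkmThreshold || sum(b$rpkm) < rpkmThreshold) next
    thA <- stats::setNames(a$theta, a$isoform_id)
    thB <- stats::setNames(b$theta, b$isoform_id)
    d <- diffScore(thA, thB)
    g <- if (!is.null(geneIdx) && gid %in% names(geneIdx)) genes[[geneIdx[[gid]]]] else NULL
    domFrom <- function(th) {
      if (is.null(g)) names(th)[order(-th, names(th))[1L]] else dominantIsoform(th, g)
    }
    domA <- domFrom(thA); domB <- domFrom(thB)
    w <- stats::setNames(rep(NA_real_, 6), cats)
    if (!is.null(g) && domA != domB)
      w <- classifyStructuralDifference(g, domA, domB)
    row <- data.frame(gene_id = gid, diff = d, dominant_a = domA,
                      dominant_b = domB, stringsAsFactors = FALSE)
    for (cn in cats) row[[cn]] <- w[[cn]]
    rows[[length(rows) + 1L]] <- row
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(data.frame(matrix(ncol = 10, nrow = 0)),
                    c("gene_id", "diff", "dominant_a", "dominant_b", cats))
  rownames(df) <- NULL
  if (!is.null(out)) .writeReport(df, out, list(), c("diff", cats))
  df
}

#' Read a report TSV written by the pipeline
#'
#' Parses the `#`-prefixed header and returns the table with numeric
#' columns restored, so outputs round-trip losslessly into their domain
#' types.
#'
#' @param path a TSV written by [runQuant()], [runFim()] or [runSweep()].
#' @return data.frame.
#' @export
readReportTSV <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
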