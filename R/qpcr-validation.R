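# Efficiency-corrected relative quantification of qPCR data and
# cross-platform agreement with array fold changes.

#' @importFrom stats lm coef cor.test
NULL

#' Amplification efficiency from a standard curve
#'
#' Least-squares slope `m` of Cp against log10 of the relative template
#' input; the per-cycle amplification factor is `E = 10^(-1/m)`. A
#' perfect assay doubles per cycle: slope -3.3219 on the log10 axis
#' gives E = 2.
#'
#' @param points data.frame with `log2_dilution` (0, -1, -2, ... for
#'   two-fold serial dilutions) and `cp`. Duplicates welcome.
#' @param minSlope smallest absolute slope regarded as amplification.
#' @return estimated efficiency E (amplification factor per cycle).
#' @examples
#' d <- data.frame(log2_dilution = 0:-4, cp = 20 + (0:4))
#' efficiencyFromCurve(d)  # exactly 2
#' @export
efficiencyFromCurve <- function(points, minSlope = 0.5) {
  stopifnot(all(c("log2_dilution", "cp") %in% names(points)))
  if (length(unique(points$log2_dilution)) < 3L)
    stop("standard curve needs >= 3 distinct dilution points")
  log10input <- points$log2_dilution * log10(2)
  m <- unname(coef(lm(points$cp ~ log10input))[2])
  if (!is.finite(m) || abs(m) < minSlope)
    stop("assay is non-amplifying (|slope| = ", signif(abs(m), 3), ")")
  10^(-1 / m)
}

#' Efficiency-corrected calibrator-relative expression
#'
#' For each sample and target gene, duplicates are averaged and the
#' ratio is
#' `E_target^(Cp_cal,target - Cp_sample,target) /
#'  E_ref^(Cp_cal,ref - Cp_sample,ref)`,
#' i.e. target quantity relative to the calibrator, normalized to the
#' reference gene. With all efficiencies forced to 2 this reduces to the
#' classical 2^-ddCp form.
#'
#' @param cp data.frame `sample`, `gene`, `replicate`, `cp`.
#' @param efficiencies named per-gene amplification factors (must cover
#'   targets and the reference); use `assumePerfect = TRUE` to force 2.
#' @param referenceGene stably expressed normalizer assay.
#' @param calibrator sample against which quantities are expressed.
#' @param assumePerfect ignore `efficiencies` and use E = 2 throughout.
#' @return matrix of ratios, genes (excluding the reference) x samples.
#' @export
relativeExpression <- function(cp, efficiencies,
                               referenceGene = "MDH",
                               calibrator,
                               assumePerfect = FALSE) {
  stopifnot(all(c("sample", "gene", "cp") %in% names(cp)))
  if (!calibrator %in% cp$sample) stop("calibrator sample missing")
  if (!referenceGene %in% cp$gene) stop("reference gene missing")
  mcp <- tapply(cp$cp, list(cp$gene, cp$sample), mean)
  genes <- setdiff(rownames(mcp), referenceGene)
  if (assumePerfect)
    efficiencies <- stats::setNames(rep(2, nrow(mcp)), rownames(mcp))
  need <- c(genes, referenceGene)
  if (!all(need %in% names(efficiencies)))
    stop("efficiencies missing for: ",
         paste(setdiff(need, names(efficiencies)), collapse = ", "))
  if (anyNA(mcp[, calibrator]))
    stop("calibrator lacks Cp for some genes")
  samples <- colnames(mcp)
  et <- efficiencies[genes]
  er <- efficiencies[referenceGene]
  num <- et^(mcp[genes, calibrator] - mcp[genes, samples, drop = FALSE])
  den <- er^(mcp[referenceGene, calibrator] - mcp[referenceGene, samples])
  out <- sweep(num, 2, den, `/`)
  rownames(out) <- genes
  out
}

#' Reference-gene stability on the array
#'
#' Percentage coefficient of variation of each probe's normalized
#' intensity across all arrays: `100 * sd / mean`.
#'
#' @param dataset a normalized [ExpressionDataset-class].
#' @param transcriptId reference transcript (its probes are evaluated).
#' @param sample use the sample (n-1) standard deviation (default) or
#'   the population form.
#' @return named CV% per probe.
#' @export
referenceStability <- function(dataset, transcriptId, sample = TRUE) {
  pid <- probeInfo(dataset)
  pid <- pid$probe_id[pid$transcript_id == transcriptId]
  if (!length(pid)) stop("no probes for transcript ", transcriptId)
  m <- intensities(dataset)[pid, , drop = FALSE]
  mu <- rowMeans(m)
  if (any(mu == 0)) stop("zero mean intensity; CV undefined")
  s <- apply(m, 1, stats::sd)
  if (!sample) s <- s * sqrt((ncol(m) - 1) / ncol(m))
  stats::setNames(100 * s / mu, pid)
}

#' Spearman agreement between qPCR and array expression
#'
#' Rank correlation (average ranks for ties, two-sided p) between qPCR
#' relative quantities and array intensities, per gene and probe, plus a
#' pooled test over all matched points (each gene contributes its
#' qPCR/array pairs; the array value is the mean over the gene's
#' probes).
#'
#' @param qpcr genes x samples matrix of relative quantities.
#' @param dataset a normalized [ExpressionDataset-class] sharing sample
#'   names with `qpcr`.
#' @return list: `perProbe` (data.frame `gene`, `probe_id`, `rho`,
#'   `p_value`) and `pooled` (list `rho`, `p_value`, `n`); the pooled
#'   test requires >= 5 matched points.
#' @export
crossplatformAgreement <- function(qpcr, dataset) {
  stopifnot(is(dataset, "ExpressionDataset"))
  samples <- intersect(colnames(qpcr), colnames(dataset))
  if (length(samples) < 3L) stop("need >= 3 shared samples")
  pinfo <- probeInfo(dataset)
  x <- intensities(dataset)[, samples, drop = FALSE]
  rows <- list(); pooled_q <- numeric(); pooled_a <- numeric()
  for (g in rownames(qpcr)) {
    pid <- pinfo$probe_id[pinfo$transcript_id == g]
    if (!length(pid)) next
    qv <- qpcr[g, samples]
    for (p in pid) {
      ct <- suppressWarnings(
        cor.test(qv, x[p, ], method = "spearman", exact = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, probe_id = p, rho = unname(ct$estimate),
        p_value = ct$p.value, stringsAsFactors = FALSE)
    }
    pooled_q <- c(pooled_q, rank(qv))
    pooled_a <- c(pooled_a, rank(colMeans(x[pid, , drop = FALSE])))
  }
  if (length(pooled_q) < 5L) stop("pooled test needs >= 5 points")
  pct <- suppressWarnings(
    cor.test(pooled_q, pooled_a, method = "spearman", exact = FALSE))
  list(perProbe = .rbindRows(rows),
       pooled = list(rho = unname(pct$estimate), p_value = pct$p.value,
                     n = length(pooled_q)))
}
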