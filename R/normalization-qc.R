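# One-colour normalisation with spike-in-guided method selection, and the
# platform's three quality-control surfaces: flag-based hybridisation
# success, probe-pair concordance, and replicate correlation.

#' @importFrom limma normalizeQuantiles normalizeCyclicLoess
#' @importFrom stats sd cor median quantile
NULL

.getMatrix <- function(x) {
  if (is(x, "ExpressionDataset")) intensities(x) else as.matrix(x)
}

.putMatrix <- function(x, m) {
  if (is(x, "ExpressionDataset")) { intensities(x) <- m; x } else m
}

#' Quantile-normalize intensity columns
#'
#' Every column is mapped onto the per-rank means across columns: sorted
#' values become identical in all samples while within-column ranks are
#' preserved (ties averaged). Idempotent, and it exactly undoes any
#' monotone per-array distortion of arrays sharing a common intensity
#' distribution.
#'
#' @param x positive intensity matrix (probes x samples) or an
#'   [ExpressionDataset-class].
#' @return same type as `x`, quantile normalized. Requires >= 2 samples.
#' @examples
#' quantileNormalize(cbind(a = c(1, 3, 5), b = c(2, 4, 6)))
#' @export
quantileNormalize <- function(x) {
  m <- .getMatrix(x)
  if (ncol(m) < 2L) stop("quantile normalization needs >= 2 samples")
  out <- normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  .putMatrix(x, out)
}

#' Cyclic-loess normalization (pairwise, the rejected comparator)
#'
#' @param x as in [quantileNormalize()]; normalisation runs on the log2
#'   scale and is mapped back to linear intensities.
#' @param span loess span.
#' @param iterations number of cycles.
#' @export
cyclicLoessNormalize <- function(x, span = 0.4, iterations = 3L) {
  m <- .getMatrix(x)
  out <- 2^normalizeCyclicLoess(log2(m), span = span,
                                iterations = iterations,
                                method = "pairs")
  dimnames(out) <- dimnames(m)
  .putMatrix(x, out)
}

#' Median-scaling normalization
#'
#' Columns are rescaled so all sample medians equal the grand median.
#' @param x as in [quantileNormalize()].
#' @export
medianScaleNormalize <- function(x) {
  m <- .getMatrix(x)
  med <- apply(m, 2, median)
  out <- sweep(m, 2, median(m) / med, `*`)
  dimnames(out) <- dimnames(m)
  .putMatrix(x, out)
}

NORMALIZATION_METHODS <- c("quantile", "cyclic-loess", "median-scale",
                           "none")

#' Apply a named normalization method
#'
#' @param x intensity matrix or [ExpressionDataset-class].
#' @param method one of `"quantile"`, `"cyclic-loess"`,
#'   `"median-scale"`, `"none"`.
#' @export
normalizeIntensities <- function(x, method = NORMALIZATION_METHODS) {
  method <- match.arg(method)
  switch(method,
         quantile = quantileNormalize(x),
         `cyclic-loess` = cyclicLoessNormalize(x),
         `median-scale` = medianScaleNormalize(x),
         none = x)
}

#' Spike-in flatness of a normalization method
#'
#' After normalization the exogenous spike-in controls, present at fixed
#' concentration in every sample, should be uniform across arrays. The
#' score is the mean coefficient of variation (sd/mean) of the spike-in
#' rows; lower is flatter.
#'
#' @param dataset an [ExpressionDataset-class] with spike-in rows.
#' @param method normalization method to score.
#' @return mean CV across spike-in rows (zero-mean rows excluded).
#' @export
spikeFlatness <- function(dataset, method = "quantile") {
  stopifnot(is(dataset, "ExpressionDataset"))
  if (ncol(dataset) < 2L)
    stop("spike flatness is undefined for a single sample")
  sp <- spikeProbes(dataset)
  if (!length(sp)) stop("dataset has no spike-in rows")
  m <- intensities(normalizeIntensities(dataset, method))[sp, ,
                                                          drop = FALSE]
  mu <- rowMeans(m)
  keep <- mu != 0
  cv <- apply(m[keep, , drop = FALSE], 1, sd) / mu[keep]
  mean(cv)
}

#' Choose the normalization with the flattest spike-ins
#'
#' @param dataset an [ExpressionDataset-class].
#' @param methods candidate methods.
#' @return list with `best` (method name) and `scores` (named mean spike
#'   CV per method).
#' @export
selectNormalization <- function(dataset,
                                methods = NORMALIZATION_METHODS) {
  scores <- vapply(methods, function(m) spikeFlatness(dataset, m),
                   numeric(1))
  list(best = methods[which.min(scores)], scores = scores)
}

#' Flag-based hybridization success
#'
#' A probe hybridized successfully in an experiment when its detection
#' flag is 1. Counts successes per probe over all provided experiments;
#' "detected in at least half" uses a ceiling convention:
#' count >= ceiling(n_experiments * minFraction).
#'
#' @param flags binary matrix (probes x experiments) or an
#'   [ExpressionDataset-class].
#' @param minFraction detection fraction defining routine success.
#' @return list: `perProbe` (data.frame `probe_id`, `n_detected`,
#'   `fraction`), `nNeverDetected`, `nDetectedAtLeastHalf`,
#'   `fractionAtLeastHalf`.
#' @export
hybridizationSuccess <- function(flags, minFraction = 0.5) {
  fl <- if (is(flags, "ExpressionDataset")) detectionFlags(flags)
        else as.matrix(flags)
  stopifnot(all(fl %in% c(0, 1)))
  n <- ncol(fl)
  cnt <- rowSums(fl)
  thr <- ceiling(n * minFraction)
  ids <- rownames(fl)
  if (is.null(ids)) ids <- sprintf("probe%05d", seq_len(nrow(fl)))
  list(perProbe = data.frame(probe_id = ids, n_detected = cnt,
                             fraction = cnt / n,
                             stringsAsFactors = FALSE, row.names = NULL),
       nNeverDetected = sum(cnt == 0),
       nDetectedAtLeastHalf = sum(cnt >= thr),
       fractionAtLeastHalf = mean(cnt >= thr))
}

#' Probe-pair concordance
#'
#' For transcripts carrying exactly two probes, the per-sample fold
#' change between the pair is max(I1, I2) / min(I1, I2) on raw
#' normalized intensities (>= 1 by construction). Reports the fraction of
#' transcript/sample fold changes strictly below 2, per-sample
#' fractions, and the per-transcript Pearson correlation of Probe_1 vs
#' Probe_2 across samples.
#'
#' @param dataset an [ExpressionDataset-class] (normalized).
#' @return list: `fc` (transcripts x samples matrix), `fractionBelow2`
#'   (overall), `fractionBelow2PerSample`, `probeCorrelation` (named per
#'   transcript), `nTranscripts`. Single-probe transcripts are skipped.
#' @export
probePairConcordance <- function(dataset) {
  stopifnot(is(dataset, "ExpressionDataset"))
  pi_ <- probeInfo(dataset)
  pi_ <- pi_[!pi_$is_spike, , drop = FALSE]
  two <- names(which(table(pi_$transcript_id) == 2L))
  if (!length(two)) stop("no transcript has exactly two probes")
  m <- intensities(dataset)
  p1 <- pi_$probe_id[pi_$probe_index == 1L][
    match(two, pi_$transcript_id[pi_$probe_index == 1L])]
  p2 <- pi_$probe_id[pi_$probe_index == 2L][
    match(two, pi_$transcript_id[pi_$probe_index == 2L])]
  a <- m[p1, , drop = FALSE]
  b <- m[p2, , drop = FALSE]
  fc <- pmax(a, b) / pmin(a, b)
  rownames(fc) <- two
  r <- vapply(seq_along(two), function(i)
    suppressWarnings(cor(a[i, ], b[i, ])), numeric(1))
  names(r) <- two
  list(fc = fc,
       fractionBelow2 = mean(fc < 2),
       fractionBelow2PerSample = colMeans(fc < 2),
       probeCorrelation = r,
       nTranscripts = length(two))
}

#' Pairwise Pearson correlation over samples
#'
#' @param dataset an [ExpressionDataset-class] or intensity matrix.
#' @param log2Scale correlate log2 intensities (default) or linear.
#' @return symmetric correlation matrix with unit diagonal; constant
#'   samples give `NA` entries.
#' @export
replicateCorrelation <- function(dataset, log2Scale = TRUE) {
  m <- .getMatrix(dataset)
  if (ncol(m) < 2L) stop("need >= 2 samples")
  if (log2Scale) m <- log2(m)
  suppressWarnings(r <- cor(m))
  diag(r) <- 1
  r
}
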