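# Synthetic-data generator: transcript catalogues with planted
# sense/antisense pairs, probe-level intensity matrices with planted
# differential expression, homology-hit tables, EST fragmentations, GO
# maps and qPCR Cp tables -- all with recorded ground truth.

#' @importFrom Biostrings DNAStringSet reverseComplement writeXStringSet
#' @importFrom stats rnorm runif rbinom setNames
NULL

.randomSeq <- function(len, gc = 0.45) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

.revcomp <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

#' Simulate a transcript catalogue with planted antisense pairs
#'
#' Generates `nTranscripts` sequences of 200-3000 nt. For each planted
#' sense/antisense pair, both members derive from one shared reference
#' locus: the sense member is a sub-region of the locus and the antisense
#' member is the reverse complement of an overlapping sub-region, so the
#' emitted homology-hit table shows the two queries matching the same
#' subject on opposite strands. All other transcripts hit (at most) their
#' own private subject on the plus strand.
#'
#' @param config a [SimulationConfig-class].
#' @param hitRate probability that a non-pair transcript has a
#'   reference-species hit at all.
#' @return list with `transcripts` (named [Biostrings::DNAStringSet]),
#'   `hits` (BLAST tabular data.frame, 12 outfmt-6-style columns; minus
#'   strand encoded as `sstart > send`), and `truth`
#'   ([GroundTruth-class]).
#' @examples
#' sim <- simulateTranscriptome(SimulationConfig(seed = 1, nTranscripts = 20,
#'                                               nAntisensePairs = 2,
#'                                               nDeGenes = 5))
#' length(sim$transcripts)
#' @export
simulateTranscriptome <- function(config, hitRate = 0.7) {
  validObject(config)
  set.seed(config@seed)
  n <- config@nTranscripts
  npair <- config@nAntisensePairs
  ids <- sprintf("DLSIM%05d", seq_len(n))

  seqs <- character(n)
  hit_rows <- list()
  pair_df <- data.frame(sense_id = character(), antisense_id = character(),
                        subject_id = character(),
                        stringsAsFactors = FALSE)

  # planted pairs occupy the first 2*npair slots
  if (npair > 0) {
    for (p in seq_len(npair)) {
      locus_len <- sample(900:1600, 1)
      locus <- .randomSeq(locus_len)
      subject <- sprintf("ENSGACT%06d", p)
      s_end <- sample(600:(locus_len - 100), 1)
      a_start <- sample(200:(s_end - 100), 1)
      sense <- substr(locus, 1, s_end)
      anti <- .revcomp(substr(locus, a_start, locus_len))
      i_s <- 2L * p - 1L
      i_a <- 2L * p
      seqs[i_s] <- sense
      seqs[i_a] <- anti
      pair_df <- rbind(pair_df, data.frame(
        sense_id = ids[i_s], antisense_id = ids[i_a], subject_id = subject,
        stringsAsFactors = FALSE))
      ev <- 10^-runif(2, 30, 120)
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        qseqid = ids[i_s], sseqid = subject,
        pident = round(runif(1, 88, 99), 2), length = s_end,
        mismatch = 0L, gapopen = 0L,
        qstart = 1L, qend = s_end, sstart = 1L, send = s_end,
        evalue = ev[1], bitscore = round(s_end * 1.8),
        stringsAsFactors = FALSE)
      alen <- locus_len - a_start + 1L
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        qseqid = ids[i_a], sseqid = subject,
        pident = round(runif(1, 88, 99), 2), length = alen,
        mismatch = 0L, gapopen = 0L,
        qstart = 1L, qend = alen, sstart = locus_len, send = a_start,
        evalue = ev[2], bitscore = round(alen * 1.8),
        stringsAsFactors = FALSE)
    }
  }

  for (i in seq((2L * npair) + 1L, length.out = n - 2L * npair)) {
    len <- sample(200:3000, 1)
    seqs[i] <- .randomSeq(len)
    if (runif(1) < hitRate) {
      subject <- sprintf("ENSGACT%06d", 1000L + i)
      hlen <- sample(150:min(len, 800), 1)
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        qseqid = ids[i], sseqid = subject,
        pident = round(runif(1, 85, 99), 2), length = hlen,
        mismatch = sample(0:10, 1), gapopen = 0L,
        qstart = 1L, qend = hlen, sstart = 1L, send = hlen,
        evalue = 10^-runif(1, 20, 100), bitscore = round(hlen * 1.7),
        stringsAsFactors = FALSE)
    }
  }

  de_ids <- sample(ids, config@nDeGenes)
  lfc <- runif(config@nDeGenes,
               min(config@deLog2fcRange), max(config@deLog2fcRange))

  transcripts <- DNAStringSet(setNames(seqs, ids))
  truth <- new("GroundTruth",
    deTranscripts = data.frame(transcript_id = de_ids, log2fc = lfc,
                               stringsAsFactors = FALSE),
    antisensePairs = pair_df,
    clusterMembership = data.frame(est_id = character(),
                                   transcript_id = character(),
                                   stringsAsFactors = FALSE),
    qpcrEfficiencies = numeric())
  list(transcripts = transcripts,
       hits = .rbindRows(hit_rows),
       truth = truth)
}

#' Fragment transcripts into overlapping ESTs with known memberships
#'
#' Each transcript is cut into a tiling path of fragments with overlaps
#' comfortably above the clustering acceptance floor, so single-linkage
#' clustering at the default thresholds recovers the per-transcript
#' memberships exactly. A fraction of fragments is emitted
#' reverse-complemented, emulating orientation errors in 5'-sequenced
#' clone libraries.
#'
#' @param transcripts named [Biostrings::DNAStringSet].
#' @param seed RNG seed.
#' @param fragLen target fragment length (nt).
#' @param overlap overlap between successive fragments (nt), must exceed
#'   the clustering `minOverlap` to make the tiling recoverable.
#' @param revcompRate fraction of fragments emitted on the opposite
#'   strand.
#' @return list with `ests` (named `DNAStringSet`) and `membership`
#'   (data.frame `est_id`, `transcript_id`).
#' @export
simulateEsts <- function(transcripts, seed = 1L, fragLen = 300L,
                         overlap = 80L, revcompRate = 0.1) {
  stopifnot(overlap < fragLen)
  set.seed(seed)
  out <- character(0)
  memb <- list()
  for (tid in names(transcripts)) {
    s <- as.character(transcripts[[tid]])
    L <- nchar(s)
    step <- fragLen - overlap
    starts <- seq(1L, max(1L, L - overlap), by = step)
    for (k in seq_along(starts)) {
      frag <- substr(s, starts[k], min(L, starts[k] + fragLen - 1L))
      if (nchar(frag) < overlap) next
      eid <- sprintf("%s.e%02d", tid, k)
      if (runif(1) < revcompRate) frag <- .revcomp(frag)
      out[eid] <- frag
      memb[[length(memb) + 1L]] <- data.frame(
        est_id = eid, transcript_id = tid, stringsAsFactors = FALSE)
    }
  }
  list(ests = DNAStringSet(out),
       membership = .rbindRows(memb))
}

#' Simulate a flagged one-colour intensity matrix
#'
#' Intensity model (log2 scale): transcript baseline ~
#' Normal(`intensityLocation`, `intensityScale`); both probes of a
#' transcript share that baseline plus a fixed probe-affinity offset and
#' independent per-spot noise (`probeNoiseSd`). Planted DE transcripts are
#' shifted by their planted log2 fold change in the `deformed` condition;
#' planted antisense members sit `log2(senseAntisenseRatio)` below their
#' sense partner. Spike-in rows share a condition-independent signal.
#' Each array is distorted by an affine map on the log2 scale (strength
#' `arrayDistortion`), which quantile normalisation can undo. Detection
#' flags are Bernoulli(1 - `flagMissingnessRate`), forced to 0 where the
#' linear intensity falls below a detection floor.
#'
#' @param config a [SimulationConfig-class].
#' @param probes data.frame with `probe_id`, `transcript_id`,
#'   `probe_index` (e.g. from [designProbes()]).
#' @param truth optional [GroundTruth-class] carrying planted DE effects
#'   and antisense pairs; when `NULL` no effects are planted.
#' @param detectionFloor linear-scale intensity below which a spot is
#'   always flagged 0.
#' @param probeAffinitySd sd of the fixed per-probe affinity offset
#'   (log2 scale) separating the two probes of a transcript.
#' @return an [ExpressionDataset-class].
#' @export
simulateExpression <- function(config, probes, truth = NULL,
                               detectionFloor = 32,
                               probeAffinitySd = 0.3) {
  validObject(config)
  stopifnot(all(c("probe_id", "transcript_id", "probe_index") %in%
                  names(probes)))
  set.seed(config@seed + 1L)

  tids <- unique(probes$transcript_id)
  base <- setNames(rnorm(length(tids), config@intensityLocation,
                         config@intensityScale), tids)
  if (!is.null(truth) && nrow(antisenseTruth(truth)) > 0) {
    ap <- antisenseTruth(truth)
    keep <- ap$sense_id %in% tids & ap$antisense_id %in% tids
    ap <- ap[keep, , drop = FALSE]
    base[ap$antisense_id] <- base[ap$sense_id] -
      log2(config@senseAntisenseRatio)
  }
  lfc <- setNames(rep(0, length(tids)), tids)
  if (!is.null(truth) && nrow(deTruth(truth)) > 0) {
    de <- deTruth(truth)
    de <- de[de$transcript_id %in% tids, , drop = FALSE]
    lfc[de$transcript_id] <- de$log2fc
  }

  cond <- config@conditions
  sample_cond <- rep(cond$name, cond$n_replicates)
  sample_rep <- unlist(lapply(cond$n_replicates, seq_len))
  snames <- sprintf("58d_%s%d",
                    toupper(substr(sample_cond, 1, 1)), sample_rep)
  nsamp <- length(snames)
  # planted effect applies to every condition after the first (reference)
  eff_on <- sample_cond != cond$name[1]

  probe_aff <- rnorm(nrow(probes), 0, probeAffinitySd)
  nspike <- config@nSpikeins
  spike_ids <- sprintf("SPIKE%02d", seq_len(nspike))
  spike_level <- seq(8, 14, length.out = max(nspike, 2))[seq_len(nspike)]

  nprobe <- nrow(probes) + nspike
  log2x <- matrix(0, nprobe, nsamp)
  for (j in seq_len(nsamp)) {
    mu <- base[probes$transcript_id] + probe_aff +
      if (eff_on[j]) lfc[probes$transcript_id] else 0
    sig <- c(mu + rnorm(nrow(probes), 0, config@probeNoiseSd),
             spike_level + rnorm(nspike, 0, config@probeNoiseSd / 2))
    a <- 1 + config@arrayDistortion * runif(1, -0.15, 0.15)
    b <- config@arrayDistortion * runif(1, -1, 1)
    log2x[, j] <- a * sig + b
  }
  x <- 2^log2x
  flags <- matrix(rbinom(length(x), 1L, 1 - config@flagMissingnessRate),
                  nrow(x), ncol(x))
  flags[x < detectionFloor] <- 0L

  probeData <- rbind(
    data.frame(probe_id = probes$probe_id,
               transcript_id = probes$transcript_id,
               probe_index = probes$probe_index,
               is_spike = FALSE, stringsAsFactors = FALSE),
    data.frame(probe_id = spike_ids, transcript_id = spike_ids,
               probe_index = 0L, is_spike = TRUE,
               stringsAsFactors = FALSE))
  dimnames(x) <- dimnames(flags) <- list(probeData$probe_id, snames)
  sampleData <- data.frame(stage = "58", condition = sample_cond,
                           replicate = sample_rep, row.names = snames,
                           stringsAsFactors = FALSE)
  ExpressionDataset(x, flags, probeData, sampleData)
}

#' Simulate qPCR Cp tables and standard-curve dilution series
#'
#' Cp values follow `Cp = intercept - log_E(quantity) + noise`, with `E`
#' the per-assay amplification factor. The reference gene's quantity is 1
#' in every sample (condition-independent); all quantities are expressed
#' relative to the calibrator sample, whose quantity is 1 for every gene.
#' The dilution series amplifies two-fold serial dilutions of the
#' calibrator cDNA.
#'
#' @param quantities genes x samples matrix of planted relative quantities
#'   (calibrator column = 1). Row and column names required.
#' @param referenceGene id of the stably expressed reference assay
#'   (quantity forced to 1 everywhere).
#' @param calibrator sample id used as the standard-curve template.
#' @param efficiencies named per-gene amplification factors; drawn
#'   uniformly from [1.8, 2] when `NULL`.
#' @param noiseSd Cp measurement noise (cycles).
#' @param nDilutions number of two-fold dilution steps (>= 5).
#' @param nDuplicates technical replicates per well.
#' @param seed RNG seed.
#' @return list with `cp` (data.frame `sample`, `gene`, `replicate`,
#'   `cp`), `dilution` (data.frame `gene`, `log2_dilution`, `replicate`,
#'   `cp`) and `efficiencies` (named numeric, the planted truth).
#' @export
simulateQpcr <- function(quantities, referenceGene = "MDH",
                         calibrator = colnames(quantities)[1],
                         efficiencies = NULL, noiseSd = 0.1,
                         nDilutions = 5L, nDuplicates = 2L, seed = 1L) {
  stopifnot(nDilutions >= 5L, calibrator %in% colnames(quantities))
  set.seed(seed)
  genes <- rownames(quantities)
  if (!referenceGene %in% genes) {
    quantities <- rbind(quantities,
                        matrix(1, 1, ncol(quantities),
                               dimnames = list(referenceGene, NULL)))
    genes <- rownames(quantities)
  }
  quantities[referenceGene, ] <- 1
  if (is.null(efficiencies))
    efficiencies <- setNames(runif(length(genes), 1.8, 2.0), genes)
  intercepts <- setNames(runif(length(genes), 18, 24), genes)

  cp <- expand.grid(sample = colnames(quantities), gene = genes,
                    replicate = seq_len(nDuplicates),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cp$cp <- intercepts[cp$gene] -
    log(quantities[cbind(cp$gene, cp$sample)]) / log(efficiencies[cp$gene]) +
    rnorm(nrow(cp), 0, noiseSd)

  dil <- expand.grid(gene = genes, step = seq_len(nDilutions) - 1L,
                     replicate = seq_len(nDuplicates),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  dil$log2_dilution <- -dil$step
  dil$cp <- intercepts[dil$gene] -
    log(2^dil$log2_dilution) / log(efficiencies[dil$gene]) +
    rnorm(nrow(dil), 0, noiseSd)
  dil$step <- NULL

  list(cp = cp, dilution = dil, efficiencies = efficiencies,
       calibrator = calibrator, referenceGene = referenceGene)
}

#' Simulate a transcript-to-GO map with a slim roll-up
#'
#' @param transcriptIds character vector of catalogue ids.
#' @param nTerms number of distinct GO term ids to draw from.
#' @param nSlim number of slim classes.
#' @param termsPerTranscript mean number of terms per annotated
#'   transcript.
#' @param annotatedFraction fraction of transcripts receiving any term.
#' @param seed RNG seed.
#' @return list with `goMap` (data.frame `transcript_id`, `go_id`,
#'   `namespace`) and `slimMap` (data.frame `go_id`, `slim_id`,
#'   `namespace`; many-to-many).
#' @export
simulateGoMap <- function(transcriptIds, nTerms = 30L, nSlim = 6L,
                          termsPerTranscript = 2, annotatedFraction = 0.6,
                          seed = 1L) {
  set.seed(seed)
  ns <- c("BP", "CC", "MF")
  terms <- sprintf("GO:%07d", seq_len(nTerms))
  term_ns <- sample(ns, nTerms, replace = TRUE)
  slims <- sprintf("GOSLIM:%03d", seq_len(nSlim))
  slim_rows <- do.call(rbind, lapply(seq_len(nTerms), function(i) {
    k <- sample(1:2, 1)
    data.frame(go_id = terms[i], slim_id = sample(slims, k),
               namespace = term_ns[i], stringsAsFactors = FALSE)
  }))
  annotated <- transcriptIds[runif(length(transcriptIds)) <
                               annotatedFraction]
  go_rows <- do.call(rbind, lapply(annotated, function(id) {
    k <- max(1L, rpois(1, termsPerTranscript))
    idx <- sample(nTerms, min(k, nTerms))
    data.frame(transcript_id = id, go_id = terms[idx],
               namespace = term_ns[idx], stringsAsFactors = FALSE)
  }))
  if (is.null(go_rows))
    go_rows <- data.frame(transcript_id = character(), go_id = character(),
                          namespace = character(), stringsAsFactors = FALSE)
  list(goMap = go_rows, slimMap = slim_rows)
}

#' @importFrom stats rpois
NULL

#' Write a simulation to disk in plain-text interchange formats
#'
#' FASTA for sequences, TSV for probes, intensity/flag matrices, sample
#' metadata, hit tables and ground truth.
#'
#' @param sim result of [simulateTranscriptome()].
#' @param dataset optional [ExpressionDataset-class] to write alongside.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
writeSimulation <- function(sim, dataset = NULL, dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character()
  w <- function(obj, name, rn = FALSE) {
    f <- file.path(dir, name)
    utils::write.table(obj, f, sep = "\t", quote = FALSE,
                       row.names = rn, col.names = TRUE)
    files <<- c(files, f)
  }
  fa <- file.path(dir, "transcripts.fasta")
  writeXStringSet(sim$transcripts, fa)
  files <- c(files, fa)
  w(sim$hits, "hits.tsv")
  w(deTruth(sim$truth), "truth_de.tsv")
  w(antisenseTruth(sim$truth), "truth_antisense_pairs.tsv")
  if (!is.null(dataset)) {
    w(as.data.frame(intensities(dataset)), "intensities.tsv", rn = TRUE)
    w(as.data.frame(detectionFlags(dataset)), "flags.tsv", rn = TRUE)
    w(sampleInfo(dataset), "samples.tsv", rn = TRUE)
    w(probeInfo(dataset), "probes.tsv")
  }
  invisible(files)
}
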