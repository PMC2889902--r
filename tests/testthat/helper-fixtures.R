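# Shared fixture builders: probe tables, ground truths and expression
# datasets assembled in code at test time.

mkProbeTable <- function(n) {
  data.frame(
    probe_id = c(sprintf("T%04d_1", seq_len(n)),
                 sprintf("T%04d_2", seq_len(n))),
    transcript_id = rep(sprintf("T%04d", seq_len(n)), 2),
    probe_index = rep(1:2, each = n),
    stringsAsFactors = FALSE)
}

mkDeTruth <- function(ids, lfc) {
  new("GroundTruth",
      deTranscripts = data.frame(transcript_id = ids, log2fc = lfc,
                                 stringsAsFactors = FALSE),
      antisensePairs = data.frame(sense_id = character(),
                                  antisense_id = character(),
                                  subject_id = character(),
                                  stringsAsFactors = FALSE),
      clusterMembership = data.frame(est_id = character(),
                                     transcript_id = character(),
                                     stringsAsFactors = FALSE),
      qpcrEfficiencies = numeric())
}

# minimal two-condition dataset from an explicit log2 matrix
mkDataset <- function(log2x, condition, flags = NULL,
                      probe_index = NULL, stage = "58") {
  x <- 2^log2x
  n <- nrow(x)
  if (is.null(rownames(x))) rownames(x) <- sprintf("P%03d_1", seq_len(n))
  if (is.null(flags)) flags <- matrix(1L, n, ncol(x))
  dimnames(flags) <- dimnames(x)
  if (is.null(colnames(x)))
    colnames(x) <- colnames(flags) <- sprintf("s%02d", seq_len(ncol(x)))
  pid <- rownames(x)
  probeData <- data.frame(
    probe_id = pid,
    transcript_id = sub("_[0-9]+$", "", pid),
    probe_index = if (is.null(probe_index))
      as.integer(sub("^.*_", "", pid)) else probe_index,
    is_spike = grepl("^SPIKE", pid),
    stringsAsFactors = FALSE)
  sampleData <- data.frame(stage = stage, condition = condition,
                           replicate = as.integer(stats::ave(
                             seq_along(condition), condition,
                             FUN = seq_along)),
                           row.names = colnames(x),
                           stringsAsFactors = FALSE)
  ExpressionDataset(x, flags, probeData, sampleData)
}

randomSeqChr <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
        collapse = "")
}

revcompChr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
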