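# Two non-overlapping 60mer probes per transcript, as near as possible to
# the 3' end, with composition and cross-hybridisation screens. The
# composition thresholds are this package's own, configurable stand-ins
# for a vendor probe-design service; the contract (two disjoint
# 3'-proximal 60mers, single probe when only one window passes) is the
# platform's.

PROBE_LENGTH <- 60L
CROSSHYB_K <- 15L

#' Build a cross-hybridisation index over a transcript catalogue
#'
#' Returns the set of 15-mers occurring in two or more distinct
#' transcripts. A candidate window's cross-hybridisation penalty is the
#' number of its 15-mers found in this shared set (a 15-mer private to the
#' window's own transcript cannot cross-hybridise).
#'
#' @param transcripts named character vector or
#'   [Biostrings::DNAStringSet].
#' @return character vector of shared 15-mers.
#' @export
buildCrossHybIndex <- function(transcripts) {
  seqs <- .asCharSet(transcripts)
  per <- lapply(seqs, .kmerSet, k = CROSSHYB_K)
  tab <- table(unlist(per, use.names = FALSE))
  names(tab)[tab >= 2L]
}

.maskPolyA <- function(s, minRun = 10L) {
  m <- regexpr(sprintf("A{%d,}$", minRun), s)
  if (m[1] > 0) substr(s, 1L, m[1] - 1L) else s
}

.maxHomopolymer <- function(s) {
  runs <- rle(strsplit(s, "")[[1]])
  max(runs$lengths)
}

#' Enumerate and score candidate 60-nt probe windows
#'
#' All 60-nt windows of the (poly-A-masked) transcript are scored:
#' GC fraction must lie in `gcBounds`, no homopolymer run of
#' `maxHomopolymer` or more, no ambiguous base, and a
#' cross-hybridisation penalty counting 15-mers shared with other
#' transcripts in the catalogue. Windows are ranked passing-first, then
#' by 3' proximity.
#'
#' @param seq transcript sequence (assumed sense strand).
#' @param crossHybIndex shared 15-mer set from [buildCrossHybIndex()];
#'   `NULL` skips the screen (penalty 0).
#' @param gcBounds inclusive GC-fraction bounds.
#' @param maxHomopolymer shortest disallowed homopolymer run.
#' @param maskPolyA mask a trailing poly-A run (>= 10 A) before
#'   enumeration.
#' @return data.frame with `start` (0-based), `seq`, `gc`,
#'   `max_homopolymer`, `n_count`, `cross_hyb`, `pass`; ordered 3'-most
#'   first within passing, then failing windows. Errors if the usable
#'   sequence is shorter than 60 nt.
#' @export
enumerateWindows <- function(seq, crossHybIndex = NULL,
                             gcBounds = c(0.35, 0.60),
                             maxHomopolymer = 8L, maskPolyA = TRUE) {
  s <- toupper(as.character(seq))
  if (maskPolyA) s <- .maskPolyA(s)
  L <- nchar(s)
  if (L < PROBE_LENGTH)
    stop("no probe possible: usable sequence shorter than ",
         PROBE_LENGTH, " nt")
  starts <- 0:(L - PROBE_LENGTH)
  win <- substring(s, starts + 1L, starts + PROBE_LENGTH)
  gc <- vapply(win, function(w) {
    v <- strsplit(w, "")[[1]]
    mean(v %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
  hp <- vapply(win, .maxHomopolymer, integer(1), USE.NAMES = FALSE)
  nc <- vapply(win, function(w)
    sum(strsplit(w, "")[[1]] == "N"), integer(1), USE.NAMES = FALSE)
  xh <- if (is.null(crossHybIndex)) rep(0L, length(win)) else
    vapply(win, function(w)
      sum(.kmerSet(w, CROSSHYB_K) %in% crossHybIndex), integer(1),
      USE.NAMES = FALSE)
  pass <- gc >= gcBounds[1] & gc <= gcBounds[2] &
    hp < maxHomopolymer & nc == 0L & xh == 0L
  out <- data.frame(start = starts, seq = win, gc = gc,
                    max_homopolymer = hp, n_count = nc,
                    cross_hyb = xh, pass = pass,
                    stringsAsFactors = FALSE)
  out[order(!out$pass, -out$start), , drop = FALSE]
}

#' Select the two most 3'-proximal disjoint passing probe windows
#'
#' Probe `_1` is the passing window nearest the 3' end; probe `_2` is the
#' most 3'-proximal passing window whose 60-nt span does not overlap
#' `_1`. If only one passing window exists a single probe is emitted; if
#' none, `NULL`. No passing disjoint pair can have both windows strictly
#' more 3' than the emitted pair.
#'
#' @param seq transcript sequence.
#' @param transcriptId id used to form `probe_id` = `<id>_1` / `<id>_2`.
#' @param ... passed to [enumerateWindows()].
#' @return data.frame with 0, 1 or 2 rows (`probe_id`, `transcript_id`,
#'   `probe_index`, `start`, `seq`, `gc`, `cross_hyb`), or `NULL` when no
#'   window passes.
#' @export
selectProbePair <- function(seq, transcriptId = "probe", ...) {
  wins <- tryCatch(enumerateWindows(seq, ...),
                   error = function(e) NULL)
  if (is.null(wins)) return(NULL)
  p <- wins[wins$pass, , drop = FALSE]
  if (!nrow(p)) return(NULL)
  one <- p[1L, , drop = FALSE]            # most 3'-proximal
  two <- p[p$start + PROBE_LENGTH <= one$start, , drop = FALSE]
  sel <- if (nrow(two)) rbind(one, two[1L, ]) else one
  data.frame(probe_id = sprintf("%s_%d", transcriptId,
                                seq_len(nrow(sel))),
             transcript_id = transcriptId,
             probe_index = seq_len(nrow(sel)),
             start = sel$start, seq = sel$seq, gc = sel$gc,
             cross_hyb = sel$cross_hyb, stringsAsFactors = FALSE)
}

#' Design probes for a whole catalogue
#'
#' Applies [selectProbePair()] to every transcript, screening
#' cross-hybridisation against the full catalogue. Transcripts for which
#' no window passes are reported in the `failed` attribute.
#'
#' @param transcripts named character vector or
#'   [Biostrings::DNAStringSet].
#' @param crossHyb apply the shared-15-mer screen across the catalogue.
#' @param ... passed to [enumerateWindows()].
#' @return data.frame of probes (columns as in [selectProbePair()]), with
#'   attribute `failed` listing transcripts without any passing window.
#' @export
designProbes <- function(transcripts, crossHyb = TRUE, ...) {
  seqs <- .asCharSet(transcripts)
  idx <- if (crossHyb) buildCrossHybIndex(seqs) else NULL
  res <- lapply(names(seqs), function(id)
    selectProbePair(seqs[[id]], id, crossHybIndex = idx, ...))
  failed <- names(seqs)[vapply(res, is.null, logical(1))]
  out <- .rbindRows(res)
  if (is.null(out))
    out <- data.frame(probe_id = character(), transcript_id = character(),
                      probe_index = integer(), start = integer(),
                      seq = character(), gc = numeric(),
                      cross_hyb = integer(), stringsAsFactors = FALSE)
  attr(out, "failed") <- failed
  out
}
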