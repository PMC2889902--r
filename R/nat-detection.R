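# Natural antisense transcript inference: orientation classification of
# queries against multi-species strand-annotated hit tables, pairing of
# opposite-strand queries sharing a reference subject, and sense vs
# antisense expression comparison.

#' Classify transcript orientation against reference transcriptomes
#'
#' For each query, the best hit per species (minimum e-value, ties by
#' maximum bit score) carries a strand sign. A query with hits is
#' `sense-consistent` when every hit species agrees on the plus strand,
#' `antisense-consistent` when every one agrees on minus, otherwise
#' `discordant`. The high-confidence tier requires a hit in *all*
#' species of `allSpecies`, all antisense. With `useAllHits = TRUE`,
#' consistency is judged across every hit passing the cutoff rather than
#' best hits only.
#'
#' @param hits data.frame with BLAST tabular columns plus `species` and
#'   `strand_sign` (see [hitStrand()]).
#' @param allSpecies the full reference panel (default: the five teleost
#'   transcriptomes).
#' @param cutoff strict e-value cutoff.
#' @param useAllHits judge consistency over all passing hits instead of
#'   per-species best hits.
#' @return data.frame `transcript_id`, `n_species_hit`, `class`,
#'   `high_confidence`; attribute `tierCounts` = named counts
#'   (`opposite_ge1`: queries whose hits include >= 1 opposite-strand
#'   species; `consistent_antisense`: antisense-consistent over all hit
#'   species; `all_species_antisense`: high-confidence tier).
#' @export
classifyOrientation <- function(hits,
                                allSpecies = c("gasAcu", "oryLat",
                                               "danRer", "tetNig",
                                               "takRub"),
                                cutoff = 1e-5, useAllHits = FALSE) {
  stopifnot(!is.null(hits$species), !is.null(hits$strand_sign))
  h <- hits[hits$evalue < cutoff, , drop = FALSE]
  per_query <- split(h, h$qseqid)
  rows <- lapply(names(per_query), function(q) {
    hq <- per_query[[q]]
    strands <- if (useAllHits) {
      tapply(hq$strand_sign, hq$species, function(x) unique(x),
             simplify = FALSE)
    } else {
      lapply(split(hq, hq$species), function(g)
        g$strand_sign[.bestHitIdx(g$evalue, g$bitscore, g$sseqid)])
    }
    flat <- unlist(strands)
    nsp <- length(strands)
    cls <- if (all(flat == 1)) "sense-consistent"
           else if (all(flat == -1)) "antisense-consistent"
           else "discordant"
    data.frame(transcript_id = q, n_species_hit = nsp, class = cls,
               high_confidence = cls == "antisense-consistent" &&
                 all(allSpecies %in% names(strands)),
               any_opposite = any(flat == -1),
               stringsAsFactors = FALSE)
  })
  out <- .rbindRows(rows)
  if (is.null(out))
    out <- data.frame(transcript_id = character(),
                      n_species_hit = integer(), class = character(),
                      high_confidence = logical(), any_opposite = logical(),
                      stringsAsFactors = FALSE)
  attr(out, "tierCounts") <- c(
    opposite_ge1 = sum(out$any_opposite),
    consistent_antisense = sum(out$class == "antisense-consistent"),
    all_species_antisense = sum(out$high_confidence))
  out
}

#' Pair sense and antisense queries sharing a reference subject
#'
#' Each query is assigned to its best subject (minimum e-value, ties by
#' bit score then subject id). For every subject attracting both
#' plus-strand and minus-strand queries, the lowest-e-value query of each
#' strand forms a pair; every query belongs to at most one pair.
#'
#' @param hits strand-annotated hit table against one reference species.
#' @param cutoff strict e-value cutoff.
#' @return data.frame `sense_id`, `antisense_id`, `subject_id`.
#' @export
pairSenseAntisense <- function(hits, cutoff = 1e-5) {
  stopifnot(!is.null(hits$strand_sign))
  h <- hits[hits$evalue < cutoff, , drop = FALSE]
  best <- bestHits(h)
  rows <- lapply(split(best, best$sseqid), function(g) {
    plus <- g[g$strand_sign == 1, , drop = FALSE]
    minus <- g[g$strand_sign == -1, , drop = FALSE]
    if (!nrow(plus) || !nrow(minus)) return(NULL)
    ip <- .bestHitIdx(plus$evalue, plus$bitscore, plus$qseqid)
    im <- .bestHitIdx(minus$evalue, minus$bitscore, minus$qseqid)
    data.frame(sense_id = plus$qseqid[ip],
               antisense_id = minus$qseqid[im],
               subject_id = g$sseqid[1], stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- .rbindRows(rows)
  if (is.null(out))
    out <- data.frame(sense_id = character(), antisense_id = character(),
                      subject_id = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$subject_id), , drop = FALSE]
}

#' Compare expression of sense/antisense pairs
#'
#' A pair member's expression is the mean of its probes' normalized
#' intensities over the selected samples. Members whose probe flags are
#' missing in at least `maxMissingFraction` of the probe/sample cells are
#' excluded; pairs with an excluded member are dropped (and reported).
#'
#' @param pairs data.frame from [pairSenseAntisense()].
#' @param dataset a normalized [ExpressionDataset-class].
#' @param maxMissingFraction exclusion threshold (inclusive, default
#'   0.5).
#' @param stage restrict to samples of this stage (default: all
#'   samples).
#' @return data.frame `sense_id`, `antisense_id`, `ratio`
#'   (sense/antisense mean intensity), `sense_dominant`; attributes
#'   `senseDominantFraction` and `dropped` (pair indices lost to the
#'   missingness filter).
#' @export
comparePairExpression <- function(pairs, dataset,
                                  maxMissingFraction = 0.5,
                                  stage = NULL) {
  stopifnot(is(dataset, "ExpressionDataset"))
  si <- sampleInfo(dataset)
  j <- if (is.null(stage)) seq_len(nrow(si)) else
    which(si$stage == stage)
  if (!length(j)) stop("no samples for stage ", stage)
  pinfo <- probeInfo(dataset)
  x <- intensities(dataset)[, j, drop = FALSE]
  fl <- detectionFlags(dataset)[, j, drop = FALSE]
  member_stats <- function(tid) {
    pid <- pinfo$probe_id[pinfo$transcript_id == tid]
    if (!length(pid)) return(NULL)
    list(mean = mean(x[pid, , drop = FALSE]),
         missing = mean(fl[pid, , drop = FALSE] == 0))
  }
  keep <- logical(nrow(pairs))
  ratio <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    s <- member_stats(pairs$sense_id[i])
    a <- member_stats(pairs$antisense_id[i])
    ok <- !is.null(s) && !is.null(a) &&
      s$missing < maxMissingFraction && a$missing < maxMissingFraction
    keep[i] <- ok
    ratio[i] <- if (ok) s$mean / a$mean else NA_real_
  }
  out <- data.frame(sense_id = pairs$sense_id[keep],
                    antisense_id = pairs$antisense_id[keep],
                    ratio = ratio[keep],
                    sense_dominant = ratio[keep] > 1,
                    stringsAsFactors = FALSE)
  attr(out, "senseDominantFraction") <-
    if (nrow(out)) mean(out$sense_dominant) else NA_real_
  attr(out, "dropped") <- which(!keep)
  out
}
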