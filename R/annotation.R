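# Homology-based annotation: BLAST tabular ingestion with strand signs,
# e-value-threshold annotation status, GO slim roll-ups, and
# model-organism identifier mapping by direct or stickleback-bridged
# routes.

BLAST_COLUMNS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                   "gapopen", "qstart", "qend", "sstart", "send",
                   "evalue", "bitscore")

#' Read a BLAST tabular (outfmt-6-style) hit file
#'
#' Twelve standard columns; a 13th column, when present, is taken as the
#' query frame of a translated search. Malformed rows raise an error
#' naming the line.
#'
#' @param file path to a tab-separated hit table without header.
#' @return data.frame with standard column names plus `strand_sign`
#'   (+1/-1): the query-frame sign for translated hits, otherwise the
#'   sign of `send - sstart`.
#' @export
readBlastTab <- function(file) {
  raw <- utils::read.table(file, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           quote = "")
  if (ncol(raw) < 12L)
    stop("expected >= 12 BLAST tabular columns, found ", ncol(raw))
  names(raw)[1:12] <- BLAST_COLUMNS
  if (ncol(raw) >= 13L) names(raw)[13] <- "qframe"
  num <- c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
           "sstart", "send", "evalue", "bitscore")
  for (cn in num) {
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    bad <- which(is.na(v) & !is.na(raw[[cn]]))
    if (length(bad))
      stop("malformed value in column '", cn, "' at line ", bad[1])
    raw[[cn]] <- v
  }
  raw$strand_sign <- hitStrand(raw)
  raw
}

#' Strand sign of homology hits
#'
#' For nucleotide-vs-nucleotide hits the strand is encoded in the subject
#' coordinate order (`sstart > send` means minus); translated searches
#' carry it in the query frame sign.
#'
#' @param hits data.frame with `sstart`/`send` and optionally `qframe`.
#' @return integer vector of +1/-1.
#' @export
hitStrand <- function(hits) {
  if (!is.null(hits$qframe))
    ifelse(hits$qframe < 0, -1L, 1L)
  else
    ifelse(hits$send < hits$sstart, -1L, 1L)
}

# best hit within a group: min e-value, ties by max bit score, then
# lexicographic subject id -- deterministic under row permutation
.bestHitIdx <- function(evalue, bitscore, sseqid) {
  order(evalue, -bitscore, sseqid)[1]
}

#' Best hit per query (deterministic tie-breaking)
#'
#' @param hits data.frame of hits (BLAST tabular columns).
#' @param by grouping column(s), default `"qseqid"`.
#' @return data.frame with one row per group: the minimum-e-value hit,
#'   ties broken by maximum bit score then lexicographic subject id.
#' @export
bestHits <- function(hits, by = "qseqid") {
  if (!nrow(hits)) return(hits)
  key <- interaction(hits[by], drop = TRUE)
  idx <- unlist(lapply(split(seq_len(nrow(hits)), key), function(i)
    i[.bestHitIdx(hits$evalue[i], hits$bitscore[i], hits$sseqid[i])]))
  out <- hits[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign annotation status from protein and nucleotide hit tables
#'
#' A transcript is `protein-annotated` if any protein-database hit has
#' e-value strictly below `proteinCutoff` (default 1e-3);
#' otherwise `nucleotide-only` if any nucleotide-database hit falls
#' strictly below `nucleotideCutoff` (default 1e-5); otherwise
#' `unannotated`. Best hits are reported with deterministic tie-breaking.
#'
#' @param hits data.frame of hits with a `db` column naming the database
#'   each row was searched against.
#' @param transcriptIds full catalogue; transcripts without hits are
#'   reported as unannotated. Defaults to the queries present.
#' @param proteinDbs,nucleotideDbs database tags of each search class.
#' @param proteinCutoff,nucleotideCutoff strict e-value cutoffs.
#' @return data.frame per transcript: `transcript_id`, `status`,
#'   `protein_subject`, `protein_evalue`, `nucleotide_subject`,
#'   `nucleotide_evalue`.
#' @export
assignAnnotation <- function(hits,
                             transcriptIds = unique(hits$qseqid),
                             proteinDbs = c("nr", "SwissProt", "TrEMBL"),
                             nucleotideDbs = c("nt", "gasAcu", "oryLat",
                                               "danRer", "tetNig",
                                               "takRub"),
                             proteinCutoff = 1e-3,
                             nucleotideCutoff = 1e-5) {
  stopifnot(!is.null(hits$db))
  prot <- hits[hits$db %in% proteinDbs & hits$evalue < proteinCutoff, ,
               drop = FALSE]
  nuc <- hits[hits$db %in% nucleotideDbs & hits$evalue < nucleotideCutoff, ,
              drop = FALSE]
  bp <- bestHits(prot)
  bn <- bestHits(nuc)
  out <- data.frame(transcript_id = transcriptIds,
                    stringsAsFactors = FALSE)
  out$protein_subject <- bp$sseqid[match(out$transcript_id, bp$qseqid)]
  out$protein_evalue <- bp$evalue[match(out$transcript_id, bp$qseqid)]
  out$nucleotide_subject <- bn$sseqid[match(out$transcript_id, bn$qseqid)]
  out$nucleotide_evalue <- bn$evalue[match(out$transcript_id, bn$qseqid)]
  out$status <- ifelse(!is.na(out$protein_subject), "protein-annotated",
                ifelse(!is.na(out$nucleotide_subject), "nucleotide-only",
                       "unannotated"))
  out
}

#' Per-database membership (Venn) counts for protein annotation
#'
#' @param hits data.frame with `db` column.
#' @param dbs database tags to cross-tabulate.
#' @param cutoff strict e-value cutoff.
#' @return table of counts over the 2^k membership patterns; pattern
#'   names join the member databases with `&` (empty pattern = queries in
#'   `hits` passing in no listed db).
#' @export
proteinVennCounts <- function(hits, dbs = c("nr", "SwissProt", "TrEMBL"),
                              cutoff = 1e-3) {
  qs <- unique(hits$qseqid)
  memb <- vapply(dbs, function(d)
    qs %in% hits$qseqid[hits$db == d & hits$evalue < cutoff],
    logical(length(qs)))
  if (is.null(dim(memb))) memb <- matrix(memb, nrow = length(qs))
  pat <- apply(memb, 1, function(r) paste(dbs[r], collapse = "&"))
  lev <- c("", unlist(lapply(seq_along(dbs), function(k)
    apply(utils::combn(dbs, k), 2, paste, collapse = "&"))))
  table(factor(pat, levels = lev))
}

#' Roll GO annotations up to slim classes
#'
#' Joins a transcript-to-term map with a (many-to-many) term-to-slim map
#' and counts, per namespace, the distinct slim classes hit and the
#' number of annotations rolling up to each. Terms absent from the slim
#' map are reported as unmapped.
#'
#' @param goMap data.frame `transcript_id`, `go_id`, `namespace`.
#' @param slimMap data.frame `go_id`, `slim_id`, `namespace`.
#' @return list: `classCounts` (data.frame `namespace`, `slim_id`,
#'   `count` of distinct transcript-term annotations), `nClasses` (named
#'   integer per namespace), `transcriptsPerNamespace` (named integer:
#'   transcripts with >= 1 mapped term), `unmapped` (character of term
#'   ids not in the slim map).
#' @export
rollupGoSlim <- function(goMap, slimMap) {
  if (!nrow(goMap))
    return(list(classCounts = data.frame(namespace = character(),
                                         slim_id = character(),
                                         count = integer()),
                nClasses = integer(), transcriptsPerNamespace = integer(),
                unmapped = character()))
  unmapped <- setdiff(unique(goMap$go_id), unique(slimMap$go_id))
  j <- merge(goMap, slimMap[c("go_id", "slim_id")], by = "go_id")
  j <- unique(j[c("transcript_id", "go_id", "namespace", "slim_id")])
  agg <- stats::aggregate(
    list(count = j$go_id),
    by = list(namespace = j$namespace, slim_id = j$slim_id), FUN = length)
  agg <- agg[order(agg$namespace, agg$slim_id), , drop = FALSE]
  rownames(agg) <- NULL
  ncl <- tapply(agg$slim_id, agg$namespace, function(x)
    length(unique(x)))
  tpn <- tapply(j$transcript_id, j$namespace, function(x)
    length(unique(x)))
  list(classCounts = agg,
       nClasses = c(ncl),
       transcriptsPerNamespace = c(tpn),
       unmapped = unmapped)
}

MODEL_ID_ROUTES <- c("direct-human", "via-stickleback-human",
                     "direct-zebrafish", "via-stickleback-zebrafish")

#' Map transcripts to model-organism identifiers
#'
#' Direct routes take the best hit of each query against the target
#' species. Bridged routes compose the best hit of each query against the
#' stickleback with the best hit of that stickleback sequence against the
#' target species.
#'
#' @param route one of `"direct-human"`, `"via-stickleback-human"`,
#'   `"direct-zebrafish"`, `"via-stickleback-zebrafish"`.
#' @param directHits hit table query -> target species (direct routes).
#' @param queryToStickleback hit table query -> stickleback (bridged
#'   routes).
#' @param sticklebackToTarget hit table stickleback -> target species
#'   (bridged routes).
#' @param cutoff strict e-value cutoff applied to every table.
#' @return data.frame `transcript_id`, `route`, `model_id` (one best id
#'   per transcript), with attribute `summary` = c(raw, unique) counts
#'   (total mappings vs distinct model ids).
#' @export
mapToModelIds <- function(route, directHits = NULL,
                          queryToStickleback = NULL,
                          sticklebackToTarget = NULL,
                          cutoff = 1e-5) {
  route <- match.arg(route, MODEL_ID_ROUTES)
  direct <- route %in% c("direct-human", "direct-zebrafish")
  if (direct) {
    if (is.null(directHits)) stop("route '", route,
                                  "' needs 'directHits'")
    b <- bestHits(directHits[directHits$evalue < cutoff, , drop = FALSE])
    out <- data.frame(transcript_id = b$qseqid, route = route,
                      model_id = b$sseqid, stringsAsFactors = FALSE)
  } else {
    if (is.null(queryToStickleback) || is.null(sticklebackToTarget))
      stop("route '", route, "' needs 'queryToStickleback' and ",
           "'sticklebackToTarget'")
    b1 <- bestHits(queryToStickleback[
      queryToStickleback$evalue < cutoff, , drop = FALSE])
    b2 <- bestHits(sticklebackToTarget[
      sticklebackToTarget$evalue < cutoff, , drop = FALSE])
    mid <- b2$sseqid[match(b1$sseqid, b2$qseqid)]
    keep <- !is.na(mid)
    out <- data.frame(transcript_id = b1$qseqid[keep], route = route,
                      model_id = mid[keep], stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "summary") <- c(raw = nrow(out),
                            unique = length(unique(out$model_id)))
  out
}
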