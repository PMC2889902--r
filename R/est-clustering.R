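# EST clustering into unique transcripts: shared-k-mer candidate screen,
# end-free overlap alignment against the 40 bp / 90% identity acceptance
# rule, single-linkage closure, and a majority-vote consensus over the
# pairwise-overlap layout.

#' @importFrom Biostrings DNAString DNAStringSet pairwiseAlignment
#'   nucleotideSubstitutionMatrix nmatch alignedPattern alignedSubject
#'   pattern subject score
#' @importFrom BiocGenerics start end width
NULL

.kmerSet <- function(s, k) {
  L <- nchar(s)
  if (L < k) return(character(0))
  unique(substring(s, seq_len(L - k + 1L), k:L))
}

#' Candidate EST pairs by exact shared k-mers
#'
#' Deterministic screen standing in for a BLAST candidate search: two
#' sequences are candidates if they share at least one exact k-mer in
#' either relative orientation. Any pair with a >= `k` bp exact-matching
#' stretch shares a k-mer, so for overlaps at >= 90% identity and
#' moderate k the screen returns a superset of the pairs the acceptance
#' rule can admit.
#'
#' @param seqs named character vector or [Biostrings::DNAStringSet].
#' @param k k-mer size (>= 8; default 16).
#' @return data.frame with columns `id1`, `id2`, one row per unordered
#'   candidate pair (ids in input order).
#' @examples
#' findCandidatePairs(c(a = "ACGTACGTACGTACGTACGT",
#'                      b = "ACGTACGTACGTACGTACGT"), k = 16)
#' @export
findCandidatePairs <- function(seqs, k = 16L) {
  stopifnot(k >= 8L)
  seqs <- .asCharSet(seqs)
  n <- length(seqs)
  if (n < 2L)
    return(data.frame(id1 = character(), id2 = character(),
                      stringsAsFactors = FALSE))
  ids <- names(seqs)
  fwd <- lapply(seqs, .kmerSet, k = k)
  rev <- lapply(seqs, function(s) .kmerSet(.revcomp(s), k))
  # index: k-mer -> indices of sequences containing it (forward strand)
  idx <- split(rep(seq_len(n), lengths(fwd)), unlist(fwd))
  hit <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (km in fwd[[i]]) {
      j <- idx[[km]]
      if (!is.null(j)) hit[i, j] <- TRUE
    }
    for (km in rev[[i]]) {
      j <- idx[[km]]
      if (!is.null(j)) hit[i, j] <- TRUE
    }
  }
  hit <- hit | t(hit)
  w <- which(hit & upper.tri(hit), arr.ind = TRUE)
  data.frame(id1 = ids[w[, 1]], id2 = ids[w[, 2]],
             stringsAsFactors = FALSE)
}

.asCharSet <- function(seqs) {
  if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("seq%04d", seq_along(seqs))
  toupper(seqs)
}

# Best end-free (overlap) alignment of b against a in one fixed
# orientation. Scoring: match +1, mismatch -1, gap opening 2, extension 1.
# Identity denominator = aligned columns including gaps.
.overlapAlign <- function(a, b) {
  m <- nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  aln <- pairwiseAlignment(DNAString(a), DNAString(b), type = "overlap",
                           substitutionMatrix = m,
                           gapOpening = 2, gapExtension = 1)
  cols <- nchar(as.character(alignedPattern(aln)))
  list(score = score(aln),
       columns = cols,
       matches = nmatch(aln),
       identity = if (cols > 0) nmatch(aln) / cols else 0,
       startA = start(pattern(aln)),
       startB = start(subject(aln)))
}

#' Test two ESTs against the cluster-acceptance rule
#'
#' Computes the best end-free overlap alignment between the two sequences
#' (both relative orientations when `considerRevcomp` is `TRUE`, keeping
#' the higher-scoring one) and accepts if the aligned overlap spans at
#' least `minOverlap` columns with identity (matches / aligned columns,
#' gaps included) of at least `minIdentity`. Both thresholds are
#' inclusive.
#'
#' @param a,b sequences (character or `DNAString`-coercible).
#' @param minOverlap minimum aligned overlap (bp, default 40).
#' @param minIdentity minimum identity fraction over the overlap
#'   (default 0.90).
#' @param considerRevcomp also try `b` reverse-complemented.
#' @return list with `accept`, `overlapLen`, `identity`, `orientation`
#'   (`"+"` or `"-"`), `score`, and the alignment offsets `startA`,
#'   `startB` (1-based positions where the overlap begins in each
#'   oriented sequence).
#' @examples
#' s <- paste(rep("ACGT", 30), collapse = "")
#' overlapCheck(s, s)$accept
#' @export
overlapCheck <- function(a, b, minOverlap = 40L, minIdentity = 0.90,
                         considerRevcomp = TRUE) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  best <- c(.overlapAlign(a, b), orientation = "+")
  if (considerRevcomp) {
    alt <- c(.overlapAlign(a, .revcomp(b)), orientation = "-")
    if (alt$score > best$score) best <- alt
  }
  list(accept = best$columns >= minOverlap &&
         best$identity >= minIdentity,
       overlapLen = best$columns,
       identity = best$identity,
       orientation = best$orientation,
       score = best$score,
       startA = best$startA,
       startB = best$startB)
}

# union-find with path compression
.ufFind <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Cluster ESTs into unique transcripts
#'
#' Single-linkage transitive closure over all candidate pairs accepted by
#' [overlapCheck()]: sequences sharing a chain of >= `minOverlap` bp,
#' >= `minIdentity` overlaps end up in one cluster. Each cluster gets a
#' majority-vote consensus over the pairwise-overlap layout (columns tied
#' between bases keep the base of the earliest-placed member); singletons
#' pass through unchanged.
#'
#' @param seqs named character vector or [Biostrings::DNAStringSet].
#' @param minOverlap,minIdentity acceptance thresholds, see
#'   [overlapCheck()].
#' @param k k-mer size for the candidate screen.
#' @return list with `membership` (data.frame `est_id`, `cluster_id`),
#'   `consensus` (named [Biostrings::DNAStringSet], one per cluster) and
#'   `evidence` (data.frame of accepted pairwise overlaps: `id1`, `id2`,
#'   `overlap_len`, `identity`, `orientation`).
#' @export
clusterEsts <- function(seqs, minOverlap = 40L, minIdentity = 0.90,
                        k = 16L) {
  seqs <- .asCharSet(seqs)
  ids <- names(seqs)
  n <- length(seqs)
  cand <- findCandidatePairs(seqs, k = k)
  parent <- seq_len(n)
  ev <- list()
  if (nrow(cand)) {
    for (r in seq_len(nrow(cand))) {
      i <- match(cand$id1[r], ids); j <- match(cand$id2[r], ids)
      chk <- overlapCheck(seqs[[i]], seqs[[j]], minOverlap, minIdentity)
      if (chk$accept) {
        ev[[length(ev) + 1L]] <- data.frame(
          id1 = ids[i], id2 = ids[j], overlap_len = chk$overlapLen,
          identity = chk$identity, orientation = chk$orientation,
          stringsAsFactors = FALSE)
        ri <- .ufFind(parent, i); rj <- .ufFind(parent, j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_len(n), function(i) .ufFind(parent, i), integer(1))
  cl <- match(root, sort(unique(root)))
  membership <- data.frame(est_id = ids,
                           cluster_id = sprintf("CL%04d", cl),
                           stringsAsFactors = FALSE)
  cons <- vapply(sort(unique(membership$cluster_id)), function(cid) {
    mem <- membership$est_id[membership$cluster_id == cid]
    .consensus(seqs[mem], minOverlap, minIdentity)
  }, character(1))
  list(membership = membership,
       consensus = DNAStringSet(cons),
       evidence = if (length(ev)) .rbindRows(ev)
       else data.frame(id1 = character(), id2 = character(),
                       overlap_len = numeric(), identity = numeric(),
                       orientation = character(), stringsAsFactors = FALSE))
}

# Majority-vote consensus: members are placed on a common coordinate
# system by breadth-first traversal of accepted overlaps starting from
# the longest member; per-column votes, ties keep the earliest-placed
# member's base. Indels within overlaps are ignored when computing
# offsets, adequate for the near-identical overlaps the acceptance rule
# admits.
.consensus <- function(members, minOverlap, minIdentity) {
  if (length(members) == 1L) return(unname(members[[1]]))
  ids <- names(members)
  seed <- ids[which.max(nchar(members))]
  placed <- list()
  placed[[seed]] <- list(offset = 0L, seq = members[[seed]])
  queue <- seed
  remaining <- setdiff(ids, seed)
  while (length(remaining) && length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (id in remaining) {
      chk <- overlapCheck(placed[[cur]]$seq, members[[id]],
                          minOverlap, minIdentity)
      if (!chk$accept) next
      s <- if (chk$orientation == "-") .revcomp(members[[id]])
           else members[[id]]
      off <- placed[[cur]]$offset + chk$startA - chk$startB
      placed[[id]] <- list(offset = off, seq = s)
      queue <- c(queue, id)
    }
    remaining <- setdiff(remaining, names(placed))
  }
  # members unreachable by accepted overlaps (possible when linkage came
  # through since-reoriented chains) are appended untouched downstream of
  # the layout; in practice single-linkage closure makes this rare
  for (id in remaining)
    placed[[id]] <- list(offset = max(vapply(placed, function(p)
      p$offset + nchar(p$seq), numeric(1))), seq = members[[id]])
  minoff <- min(vapply(placed, `[[`, numeric(1), "offset"))
  width <- max(vapply(placed, function(p)
    p$offset - minoff + nchar(p$seq), numeric(1)))
  votes <- matrix(0L, 5L, width,
                  dimnames = list(c("A", "C", "G", "T", "N"), NULL))
  first <- rep(NA_character_, width)
  for (p in placed) {
    chars <- strsplit(p$seq, "")[[1]]
    pos <- p$offset - minoff + seq_along(chars)
    for (kk in seq_along(chars)) {
      b <- chars[kk]
      if (!b %in% rownames(votes)) b <- "N"
      votes[b, pos[kk]] <- votes[b, pos[kk]] + 1L
      if (is.na(first[pos[kk]])) first[pos[kk]] <- b
    }
  }
  out <- vapply(seq_len(width), function(cc) {
    v <- votes[, cc]
    if (all(v == 0L)) return("N")
    top <- names(v)[v == max(v)]
    if (length(top) == 1L) top else {
      if (first[cc] %in% top) first[cc] else top[1]
    }
  }, character(1))
  paste(out, collapse = "")
}
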