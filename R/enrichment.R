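# GO over-representation of a gene list against a custom array
# background: one-sided hypergeometric (Fisher) tests with an optional
# EASE offset, fold enrichment, gene-count floors and multiple-testing
# correction.

#' @importFrom stats phyper p.adjust
NULL

#' Per-term 2x2 contingency counts
#'
#' Tallies, for every annotation term, how many list and background genes
#' carry it. The background is the full array universe and includes the
#' list; a list gene missing from the background violates the contract
#' and errors. Terms with a list count below `minGeneCount` are dropped.
#'
#' @param geneList character vector of significant gene ids.
#' @param background character vector of array-background gene ids
#'   (superset of `geneList`).
#' @param gene2term data.frame `gene_id`, `term_id` (one row per
#'   annotation).
#' @param minGeneCount minimum list count for a term to be tested
#'   (default 4).
#' @return data.frame `term_id`, `list_count`, `list_total`, `bg_count`,
#'   `bg_total`.
#' @export
termTable <- function(geneList, background, gene2term,
                      minGeneCount = 4L) {
  geneList <- unique(geneList)
  background <- unique(background)
  if (!all(geneList %in% background))
    stop("gene list must be a subset of the background")
  g2t <- unique(gene2term[gene2term$gene_id %in% background,
                          c("gene_id", "term_id")])
  bg_count <- table(g2t$term_id)
  list_count <- table(g2t$term_id[g2t$gene_id %in% geneList])
  terms <- names(bg_count)
  lc <- as.integer(list_count[terms])
  lc[is.na(lc)] <- 0L
  out <- data.frame(term_id = terms,
                    list_count = lc,
                    list_total = length(geneList),
                    bg_count = as.integer(bg_count),
                    bg_total = length(background),
                    stringsAsFactors = FALSE)
  out <- out[out$list_count >= minGeneCount, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One-sided hypergeometric p-value with an EASE offset
#'
#' Upper-tail probability of drawing at least `list_count` term-positive
#' genes when `list_total` genes are sampled from a background of
#' `bg_total` genes of which `bg_count` carry the term. With
#' `easeOffset = 1` the list-with-term cell is first reduced by one
#' (floored at zero), giving the conservative EASE score; the EASE
#' p-value is never smaller than the Fisher p-value.
#'
#' @param listCount,listTotal,bgCount,bgTotal 2x2 margins (vectorized).
#' @param easeOffset 0 for Fisher, 1 for EASE.
#' @return p-value(s) in \[0, 1\]; degenerate margins give 1.
#' @export
easeFisher <- function(listCount, listTotal, bgCount, bgTotal,
                       easeOffset = 0L) {
  stopifnot(all(listCount >= 0), all(bgCount >= 0),
            all(listCount <= listTotal), all(bgCount <= bgTotal))
  k <- pmax(listCount - easeOffset, 0)
  p <- phyper(k - 1, bgCount, bgTotal - bgCount, listTotal,
              lower.tail = FALSE)
  pmin(1, pmax(p, 0))
}

#' Fold enrichment of a term in the list over the background
#'
#' `(list_count / list_total) / (bg_count / bg_total)`.
#'
#' @inheritParams easeFisher
#' @return fold enrichment; `NA` when the background count is zero.
#' @export
foldEnrichment <- function(listCount, listTotal, bgCount, bgTotal) {
  ifelse(bgCount == 0, NA_real_,
         (listCount / listTotal) / (bgCount / bgTotal))
}

#' Multiple-testing correction for enrichment p-values
#'
#' @param p p-values.
#' @param method `"none"` (raw p, the GOStat-style report), `"BH"`
#'   (Benjamini-Hochberg step-up), or `"david-fdr"` (BH reported as a
#'   percentage, mirroring the DAVID FDR column).
#' @return adjusted values.
#' @export
correctMultiple <- function(p, method = c("none", "BH", "david-fdr")) {
  method <- match.arg(method)
  switch(method,
         none = p,
         BH = p.adjust(p, "BH"),
         `david-fdr` = 100 * p.adjust(p, "BH"))
}

#' GO over-representation analysis against a custom background
#'
#' The `"gostat"` style reports the raw one-sided Fisher p-value with a
#' minimum gene count of 3; the `"david"` style uses the EASE offset of
#' 1, a minimum gene count of 4, and adds a BH-based FDR column in
#' percent. Optionally, annotations are propagated to ancestor terms
#' before counting (a gene annotated to a term counts for all its
#' ancestors).
#'
#' @param geneList,background,gene2term see [termTable()].
#' @param style `"david"` or `"gostat"`.
#' @param ancestors optional data.frame `term_id`, `ancestor_id` used to
#'   propagate annotations upward.
#' @param minGeneCount override of the style's gene-count floor.
#' @param threshold significance threshold on the reported p-value.
#' @return data.frame `term_id`, `count`, `percent`, `p_value`,
#'   `fold_enrichment`, `fdr`, `significant`, stable-sorted by p-value.
#' @export
goEnrichment <- function(geneList, background, gene2term,
                         style = c("david", "gostat"),
                         ancestors = NULL, minGeneCount = NULL,
                         threshold = 0.05) {
  style <- match.arg(style)
  if (!is.null(ancestors)) {
    extra <- merge(gene2term, ancestors, by = "term_id")
    extra <- data.frame(gene_id = extra$gene_id,
                        term_id = extra$ancestor_id,
                        stringsAsFactors = FALSE)
    gene2term <- unique(rbind(gene2term[c("gene_id", "term_id")], extra))
  }
  mgc <- if (!is.null(minGeneCount)) minGeneCount
         else if (style == "david") 4L else 3L
  tt <- termTable(geneList, background, gene2term, minGeneCount = mgc)
  offset <- if (style == "david") 1L else 0L
  p <- easeFisher(tt$list_count, tt$list_total, tt$bg_count,
                  tt$bg_total, easeOffset = offset)
  out <- data.frame(term_id = tt$term_id,
                    count = tt$list_count,
                    percent = 100 * tt$list_count / tt$list_total,
                    p_value = p,
                    fold_enrichment = foldEnrichment(
                      tt$list_count, tt$list_total, tt$bg_count,
                      tt$bg_total),
                    fdr = correctMultiple(
                      p, if (style == "david") "david-fdr" else "none"),
                    stringsAsFactors = FALSE)
  out$significant <- out$p_value <= threshold
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}
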