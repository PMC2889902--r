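mkHit <- function(q, s, db, e, bit = 100, sstart = 1, send = 100) {
  data.frame(qseqid = q, sseqid = s, db = db, evalue = e, bitscore = bit,
             sstart = sstart, send = send, stringsAsFactors = FALSE)
}

test_that("annotation status follows the protein-first threshold logic", {
  hits <- rbind(mkHit("q1", "sp1", "SwissProt", 1e-5),
                mkHit("q1", "nt1", "nt", 1e-20))
  ann <- assignAnnotation(hits)
  expect_equal(ann$status, "protein-annotated")
  expect_equal(ann$protein_subject, "sp1")

  # nucleotide hit at e = 1e-4 fails the strict 1e-5 cutoff
  ann2 <- assignAnnotation(mkHit("q1", "nt1", "nt", 1e-4))
  expect_equal(ann2$status, "unannotated")
  # and at 1e-6 it passes
  ann3 <- assignAnnotation(mkHit("q1", "nt1", "nt", 1e-6))
  expect_equal(ann3$status, "nucleotide-only")
  # protein cutoff is strict too: e exactly 1e-3 is not significant
  ann4 <- assignAnnotation(mkHit("q1", "p1", "nr", 1e-3))
  expect_equal(ann4$status, "unannotated")
})

test_that("status counts partition the catalogue and respect monotonicity", {
  hits <- rbind(mkHit("q1", "p1", "nr", 1e-10),
                mkHit("q2", "n1", "nt", 1e-10),
                mkHit("q3", "p2", "nr", 1e-2))
  ids <- c("q1", "q2", "q3", "q4")
  ann <- assignAnnotation(hits, transcriptIds = ids)
  expect_equal(sum(table(ann$status)), length(ids))
  expect_equal(as.integer(table(ann$status)[c("protein-annotated",
                                              "nucleotide-only",
                                              "unannotated")]),
               c(1L, 1L, 2L))
  # loosening the cutoff can only add annotations
  loose <- assignAnnotation(hits, transcriptIds = ids,
                            proteinCutoff = 1e-1)
  expect_gte(sum(loose$status == "protein-annotated"),
             sum(ann$status == "protein-annotated"))
})

test_that("best hits and annotations are invariant to row order", {
  hits <- rbind(mkHit("q1", "b", "nr", 1e-10, bit = 50),
                mkHit("q1", "a", "nr", 1e-10, bit = 50),
                mkHit("q1", "c", "nr", 1e-10, bit = 80))
  for (perm in list(1:3, 3:1, c(2, 3, 1))) {
    b <- bestHits(hits[perm, ])
    expect_equal(b$sseqid, "c")  # max bit score wins at equal e-value
  }
  tie <- hits[1:2, ]             # equal e and bit: lexicographic subject
  expect_equal(bestHits(tie[2:1, ])$sseqid, "a")
})

test_that("protein Venn membership counts match exhaustive set algebra", {
  hits <- rbind(mkHit("q1", "x", "nr", 1e-9),
                mkHit("q2", "x", "nr", 1e-9),
                mkHit("q2", "y", "SwissProt", 1e-9),
                mkHit("q3", "z", "TrEMBL", 1e-2))  # fails cutoff
  vc <- proteinVennCounts(hits)
  expect_equal(as.integer(vc["nr"]), 1L)
  expect_equal(as.integer(vc["nr&SwissProt"]), 1L)
  expect_equal(as.integer(vc[names(vc) == ""]), 1L)
  expect_equal(as.integer(sum(vc)), 3L)
})

test_that("GO slim roll-up counts classes per namespace correctly", {
  expect_equal(nrow(rollupGoSlim(
    data.frame(transcript_id = character(), go_id = character(),
               namespace = character()),
    data.frame(go_id = "GO:1", slim_id = "S1",
               namespace = "BP"))$classCounts), 0)

  goMap <- data.frame(transcript_id = c("t1", "t2"),
                      go_id = c("GO:1", "GO:2"),
                      namespace = "BP", stringsAsFactors = FALSE)
  slimMap <- data.frame(go_id = c("GO:1", "GO:2"), slim_id = "S1",
                        namespace = "BP", stringsAsFactors = FALSE)
  r <- rollupGoSlim(goMap, slimMap)
  expect_equal(r$nClasses[["BP"]], 1L)
  expect_equal(r$classCounts$count, 2L)

  # unmapped terms are reported, not silently dropped
  goMap2 <- rbind(goMap, data.frame(transcript_id = "t3",
                                    go_id = "GO:9", namespace = "MF"))
  r2 <- rollupGoSlim(goMap2, slimMap)
  expect_equal(r2$unmapped, "GO:9")
})

test_that("slim roll-up equals brute-force path enumeration on a toy map", {
  set.seed(31)
  terms <- sprintf("GO:%02d", 1:10)
  slims <- sprintf("S%d", 1:4)
  slimMap <- do.call(rbind, lapply(terms, function(tm)
    data.frame(go_id = tm, slim_id = sample(slims, sample(1:2, 1)),
               namespace = "BP", stringsAsFactors = FALSE)))
  goMap <- data.frame(transcript_id = sample(sprintf("t%d", 1:6), 15,
                                             replace = TRUE),
                      go_id = sample(terms, 15, replace = TRUE),
                      namespace = "BP", stringsAsFactors = FALSE)
  r <- rollupGoSlim(goMap, slimMap)
  # brute force: enumerate every (annotation row, slim ancestor) path
  ann <- unique(goMap)
  brute <- new.env()
  for (i in seq_len(nrow(ann))) {
    for (s in slimMap$slim_id[slimMap$go_id == ann$go_id[i]]) {
      key <- s
      cur <- mget(key, brute, ifnotfound = list(character(0)))[[1]]
      assign(key, unique(c(cur, paste(ann$transcript_id[i],
                                      ann$go_id[i]))), brute)
    }
  }
  for (i in seq_len(nrow(r$classCounts))) {
    s <- r$classCounts$slim_id[i]
    expect_equal(r$classCounts$count[i], length(get(s, brute)))
  }
})

test_that("model-id mapping composes routes and reports unique counts", {
  q2s <- mkHit(c("q1", "q2"), c("s1", "s1"), "gasAcu", c(1e-20, 1e-10))
  s2h <- mkHit("s1", "h9", "human", 1e-30)
  m <- mapToModelIds("via-stickleback-human",
                     queryToStickleback = q2s,
                     sticklebackToTarget = s2h)
  expect_equal(m$model_id, c("h9", "h9"))
  expect_equal(unname(attr(m, "summary")), c(2L, 1L))

  direct <- mapToModelIds("direct-human", directHits = s2h)
  expect_equal(direct$model_id, "h9")
  expect_error(mapToModelIds("via-stickleback-human",
                             queryToStickleback = q2s), "needs")
})

test_that("all four mapping routes equal a brute-force join oracle", {
  set.seed(32)
  qs <- sprintf("q%d", 1:5)
  q2h <- do.call(rbind, lapply(qs, function(q)
    mkHit(q, sample(sprintf("h%d", 1:3), 2), "human",
          10^-runif(2, 4, 30))))
  q2s <- do.call(rbind, lapply(qs, function(q)
    mkHit(q, sample(sprintf("s%d", 1:3), 2), "gasAcu",
          10^-runif(2, 4, 30))))
  s2h <- do.call(rbind, lapply(sprintf("s%d", 1:3), function(s)
    mkHit(s, sample(sprintf("h%d", 1:4), 2), "human",
          10^-runif(2, 4, 30))))
  bestOf <- function(h, q) {
    hh <- h[h$qseqid == q & h$evalue < 1e-5, , drop = FALSE]
    if (!nrow(hh)) return(NA_character_)
    hh <- hh[order(hh$evalue, -hh$bitscore, hh$sseqid), ]
    hh$sseqid[1]
  }
  d <- mapToModelIds("direct-human", directHits = q2h)
  for (q in qs) {
    want <- bestOf(q2h, q)
    got <- d$model_id[d$transcript_id == q]
    if (is.na(want)) expect_length(got, 0) else expect_equal(got, want)
  }
  v <- mapToModelIds("via-stickleback-human", queryToStickleback = q2s,
                     sticklebackToTarget = s2h)
  for (q in qs) {
    s <- bestOf(q2s, q)
    want <- if (is.na(s)) NA_character_ else bestOf(s2h, s)
    got <- v$model_id[v$transcript_id == q]
    if (is.na(want)) expect_length(got, 0) else expect_equal(got, want)
  }
})

test_that("BLAST tabular files parse with strand signs and line errors", {
  f <- tempfile(fileext = ".tsv")
  rows <- c("q1\ts1\t98.5\t100\t1\t0\t1\t100\t200\t101\t1e-30\t180",
            "q2\ts2\t95.0\t80\t4\t0\t1\t80\t50\t129\t1e-10\t120")
  writeLines(rows, f)
  h <- readBlastTab(f)
  expect_equal(h$strand_sign, c(-1L, 1L))
  writeLines(c(rows, "q3\ts3\tbad\t1\t1\t0\t1\t2\t3\t4\t1e-5\t10"), f)
  expect_error(readBlastTab(f), "line 3")
  # a 13th column is used as the translated-search frame
  writeLines(paste0(rows, c("\t-2", "\t3")), f)
  h2 <- readBlastTab(f)
  expect_equal(h2$strand_sign, c(-1L, 1L))
})
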