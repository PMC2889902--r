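mkSpHit <- function(q, species, strand, e = 1e-20, s = NULL, bit = 100) {
  data.frame(qseqid = q, sseqid = if (is.null(s)) paste0("sub_", species)
             else s, species = species, strand_sign = strand, evalue = e,
             bitscore = bit, stringsAsFactors = FALSE)
}

FIVE <- c("gasAcu", "oryLat", "danRer", "tetNig", "takRub")

test_that("orientation classes and the high-confidence tier", {
  hits <- do.call(rbind, lapply(FIVE, function(sp)
    mkSpHit("q1", sp, -1L)))
  oc <- classifyOrientation(hits)
  expect_equal(oc$class, "antisense-consistent")
  expect_true(oc$high_confidence)
  expect_equal(oc$n_species_hit, 5)

  # mixed strands across species are discordant, never high confidence
  oc2 <- classifyOrientation(rbind(mkSpHit("q1", "gasAcu", -1L),
                                   mkSpHit("q1", "danRer", 1L)))
  expect_equal(oc2$class, "discordant")
  expect_false(oc2$high_confidence)

  # antisense in fewer than all species: consistent but not high tier
  oc3 <- classifyOrientation(rbind(mkSpHit("q1", "gasAcu", -1L),
                                   mkSpHit("q1", "danRer", -1L)))
  expect_equal(oc3$class, "antisense-consistent")
  expect_false(oc3$high_confidence)

  # hits at the cutoff are excluded (strict inequality)
  oc4 <- classifyOrientation(mkSpHit("q1", "gasAcu", -1L, e = 1e-5))
  expect_equal(nrow(oc4), 0)
})

test_that("tier counts equal exhaustive classification of a toy table", {
  set.seed(61)
  rows <- list()
  truth <- list()
  for (i in 1:20) {
    q <- sprintf("q%02d", i)
    nsp <- sample(1:5, 1)
    sps <- sample(FIVE, nsp)
    strands <- sample(c(-1L, 1L), nsp, replace = TRUE)
    truth[[q]] <- strands
    rows[[i]] <- do.call(rbind, Map(function(sp, st)
      mkSpHit(q, sp, st), sps, strands))
  }
  oc <- classifyOrientation(do.call(rbind, rows))
  tiers <- attr(oc, "tierCounts")
  brute_any <- sum(vapply(truth, function(s) any(s == -1), logical(1)))
  brute_cons <- sum(vapply(truth, function(s) all(s == -1), logical(1)))
  brute_all5 <- sum(vapply(truth, function(s)
    length(s) == 5 && all(s == -1), logical(1)))
  expect_equal(unname(tiers["opposite_ge1"]), brute_any)
  expect_equal(unname(tiers["consistent_antisense"]), brute_cons)
  expect_equal(unname(tiers["all_species_antisense"]), brute_all5)
  # tier monotonicity
  expect_lte(tiers["all_species_antisense"],
             tiers["consistent_antisense"])
  expect_lte(tiers["consistent_antisense"], tiers["opposite_ge1"])
})

test_that("flipping every strand swaps sense and antisense classes", {
  set.seed(62)
  hits <- rbind(mkSpHit("q1", "gasAcu", 1L), mkSpHit("q1", "danRer", 1L),
                mkSpHit("q2", "gasAcu", -1L),
                mkSpHit("q3", "gasAcu", -1L), mkSpHit("q3", "oryLat", 1L))
  oc <- classifyOrientation(hits)
  flipped <- hits
  flipped$strand_sign <- -flipped$strand_sign
  ocf <- classifyOrientation(flipped)
  map <- c(`sense-consistent` = "antisense-consistent",
           `antisense-consistent` = "sense-consistent",
           discordant = "discordant")
  expect_equal(ocf$class, unname(map[oc$class]))
})

test_that("sense/antisense pairing picks best opposite-strand queries per subject", {
  hits <- rbind(mkSpHit("A", "gasAcu", 1L, e = 1e-30, s = "S"),
                mkSpHit("B", "gasAcu", -1L, e = 1e-25, s = "S"),
                mkSpHit("C", "gasAcu", -1L, e = 1e-10, s = "S"),
                mkSpHit("D", "gasAcu", 1L, e = 1e-40, s = "S2"))
  p <- pairSenseAntisense(hits)
  expect_equal(nrow(p), 1)   # S2 has no minus-strand query
  expect_equal(p$sense_id, "A")
  expect_equal(p$antisense_id, "B")   # lower e-value than C

  # deterministic under row permutation
  for (perm in list(4:1, c(2, 4, 1, 3))) {
    p2 <- pairSenseAntisense(hits[perm, ])
    expect_equal(p2, p)
  }
})

test_that("planted pairs are recovered exactly from the simulated hit table", {
  cfg <- SimulationConfig(seed = 8, nTranscripts = 40,
                          nAntisensePairs = 5, nDeGenes = 0)
  sim <- simulateTranscriptome(cfg)
  h <- sim$hits
  h$strand_sign <- hitStrand(h)
  pairs <- pairSenseAntisense(h)
  truth <- antisenseTruth(sim$truth)
  expect_equal(nrow(pairs), nrow(truth))
  got <- pairs[order(pairs$subject_id), ]
  want <- truth[order(truth$subject_id), ]
  expect_equal(got$sense_id, want$sense_id)
  expect_equal(got$antisense_id, want$antisense_id)
})

test_that("pair expression comparison filters members and summarizes dominance", {
  x <- log2(rbind(S1_1 = rep(200, 6), S1_2 = rep(200, 6),
                  A1_1 = rep(50, 6), A1_2 = rep(50, 6),
                  S2_1 = rep(100, 6), S2_2 = rep(100, 6),
                  A2_1 = rep(100, 6), A2_2 = rep(100, 6)))
  fl <- matrix(1L, 8, 6, dimnames = list(rownames(x), NULL))
  fl["A2_1", 1:3] <- 0L   # half missing for one probe
  fl["A2_2", 1:3] <- 0L
  ds <- mkDataset(x, condition = rep(c("normal", "deformed"), each = 3),
                  flags = fl)
  pairs <- data.frame(sense_id = c("S1", "S2"),
                      antisense_id = c("A1", "A2"),
                      subject_id = c("L1", "L2"),
                      stringsAsFactors = FALSE)
  pe <- comparePairExpression(pairs, ds)
  # the A2 member is missing in exactly 50% of cells: excluded
  expect_equal(nrow(pe), 1)
  expect_equal(attr(pe, "dropped"), 2L)
  expect_equal(pe$ratio, 4)
  expect_true(pe$sense_dominant)
})

test_that("planted 5:1 pairs are sense-dominant throughout at low noise", {
  cfg <- SimulationConfig(seed = 10, nTranscripts = 30,
                          nAntisensePairs = 6, nDeGenes = 0,
                          probeNoiseSd = 0.05, flagMissingnessRate = 0,
                          senseAntisenseRatio = 5,
                          intensityLocation = 12, intensityScale = 1)
  sim <- simulateTranscriptome(cfg)
  probes <- data.frame(
    probe_id = c(paste0(names(sim$transcripts), "_1"),
                 paste0(names(sim$transcripts), "_2")),
    transcript_id = rep(names(sim$transcripts), 2),
    probe_index = rep(1:2, each = length(sim$transcripts)),
    stringsAsFactors = FALSE)
  ds <- simulateExpression(cfg, probes, sim$truth)
  ds <- quantileNormalize(ds)
  h <- sim$hits
  h$strand_sign <- hitStrand(h)
  pairs <- pairSenseAntisense(h)
  pe <- comparePairExpression(pairs, ds)
  expect_equal(attr(pe, "senseDominantFraction"), 1)
  expect_equal(nrow(pe), 6)
})
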