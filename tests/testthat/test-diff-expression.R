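test_that("missing-value filter removes probes with >2 missing per condition", {
  fl <- rbind(p1_1 = c(1, 1, 1, 1, 0, 0, 0, 1),  # 3 missing in deformed
              p2_1 = c(0, 0, 1, 1, 1, 1, 0, 0),  # 2 and 2: retained
              p3_1 = rep(1, 8),
              p4_1 = c(0, 0, 0, 0, 1, 1, 1, 1))  # 4 missing in normal
  x <- matrix(10, 4, 8, dimnames = dimnames(fl))
  ds <- mkDataset(x, condition = rep(c("normal", "deformed"), each = 4),
                  flags = fl)
  res <- missingValueFilter(ds)
  expect_setequal(res$removed, c("p1_1", "p4_1"))
  expect_equal(nrow(res$dataset), 2)
  # an all-detected dataset loses nothing
  ds2 <- mkDataset(x, condition = rep(c("normal", "deformed"), each = 4))
  expect_length(missingValueFilter(ds2)$removed, 0)
})

test_that("imputation fills missing cells with within-condition means", {
  x <- log2(rbind(p1_1 = c(8, 10, 12, 100, 20, 20, 20, 20)))
  fl <- rbind(p1_1 = c(1, 1, 1, 0, 1, 1, 1, 1))
  ds <- mkDataset(x, condition = rep(c("normal", "deformed"), each = 4),
                  flags = fl)
  imp <- imputeMissing(ds)
  got <- log2(intensities(imp))["p1_1", 4]
  expect_equal(unname(got), mean(log2(c(8, 10, 12))))
})

test_that("the d statistic matches the pooled-standard-error formula", {
  # group means 2 and 5, within-group squared deviations summing to 2
  # in each group, n1 = n2 = 3: s = sqrt((2+2)*(1/3+1/3)/4) = 0.8165,
  # d = (2 - 5)/s = -3.674 with s0 = 0
  g1 <- c(2, 3, 1)    # mean 2, ss 2
  g2 <- c(5, 6, 4)    # mean 5, ss 2
  x <- rbind(p1_1 = c(g2, g1),
             p2_1 = c(9, 10, 11, 9.5, 10, 10.5),
             p3_1 = c(7, 8, 9, 8, 9, 7))
  ds <- mkDataset(x, condition = rep(c("normal", "deformed"), each = 3))
  res <- samTwoClass(ds, s0 = 0, seed = 1)
  d1 <- samProbes(res)$d[samProbes(res)$probe_id == "p1_1"]
  s <- sqrt((2 + 2) * (1 / 3 + 1 / 3) / 4)
  expect_equal(s, 0.8165, tolerance = 1e-4)
  expect_equal(d1, -3 / s, tolerance = 1e-10)
  expect_equal(d1, -3.674, tolerance = 1e-3)
})

test_that("equal group means with no noise give d = 0 and no calls", {
  x <- matrix(rep(c(8, 9, 10, 11), each = 8), 4, 8, byrow = TRUE)
  rownames(x) <- sprintf("p%d_1", 1:4)
  ds <- mkDataset(x, condition = rep(c("normal", "deformed"), each = 4))
  res <- samTwoClass(ds, s0 = 1, seed = 1)
  expect_true(all(samProbes(res)$d == 0))
  expect_equal(sum(samProbes(res)$significant), 0)
})

test_that("swapping class labels negates d and preserves the call count", {
  set.seed(51)
  n <- 120
  x <- matrix(rnorm(n * 8, 10, 1), n, 8)
  x[1:10, 5:8] <- x[1:10, 5:8] + 3
  rownames(x) <- sprintf("p%03d_1", 1:n)
  dsA <- mkDataset(x, condition = rep(c("normal", "deformed"), each = 4))
  # same data with the two replicate blocks swapped under the labels
  dsB <- mkDataset(x[, c(5:8, 1:4)],
                   condition = rep(c("normal", "deformed"), each = 4))
  rA <- samTwoClass(dsA, seed = 5)
  rB <- samTwoClass(dsB, seed = 5)
  expect_equal(samProbes(rA)$d, -samProbes(rB)$d, tolerance = 1e-12)
  expect_equal(sum(samProbes(rA)$significant),
               sum(samProbes(rB)$significant))
})

test_that("fold changes follow both reported conventions", {
  x <- cbind(a = c(100, 400, 64), b = c(100, 400, 64),
             c = c(25, 400, 8), d = c(25, 400, 8))
  fc <- foldChange(x, g2 = c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(fc$ratio, c(0.25, 1, 0.125))
  expect_equal(fc$signed, c(-4, 1, -8))
  # the printed ratio 0.08 corresponds to a signed value of -12.5
  expect_equal(signedFoldChange(0.08), -12.5)
  expect_equal(signedFoldChange(1), 1)
  # non-positive means are flagged undefined
  x2 <- cbind(a = c(0, 1), b = c(2, 1))
  fc2 <- foldChange(x2, c(FALSE, TRUE))
  expect_true(is.na(fc2$ratio[1]))
  expect_equal(fc2$undefined, 1L)
})

test_that("probe calls aggregate to transcripts with conserved counts", {
  probeMap <- mkProbeTable(4)
  sig <- data.frame(probe_id = c("T0001_1", "T0001_2", "T0002_1",
                                 "T0003_2"),
                    signed_fc = c(-4, -3, -2.5, -6),
                    stringsAsFactors = FALSE)
  # T0002's partner was filtered out before testing
  removed <- "T0002_2"
  probeMap <- probeMap[probeMap$probe_id != "T0002_2", ]
  agg <- aggregateToTranscripts(sig, probeMap, removedProbes = removed)
  expect_equal(nrow(agg), 3)
  cat_of <- setNames(agg$category, agg$transcript_id)
  expect_equal(unname(cat_of["T0001"]), "both-probe")
  expect_equal(unname(cat_of["T0002"]), "single-probe-filtered")
  expect_equal(unname(cat_of["T0003"]), "single-probe-ns")
  # conservation: 2 * n_both + n_single = n significant probes
  expect_equal(2 * sum(agg$category == "both-probe") +
                 sum(agg$category != "both-probe"), nrow(sig))
  expect_equal(unname(agg$best_fc[agg$transcript_id == "T0001"]), -4)
  # an orphan probe id is a mapping error
  expect_error(aggregateToTranscripts(
    data.frame(probe_id = "ZZZ_1", signed_fc = 1), probeMap),
    "not in probe map")
})

test_that("aggregation bookkeeping matches exhaustive enumeration on a toy call set", {
  probeMap <- mkProbeTable(6)
  sig_ids <- c("T0001_1", "T0001_2", "T0002_1", "T0004_2", "T0005_1",
               "T0006_2")
  sig <- data.frame(probe_id = sig_ids, signed_fc = -seq_along(sig_ids),
                    stringsAsFactors = FALSE)
  agg <- aggregateToTranscripts(sig, probeMap)
  # brute force: count significant probes per transcript
  brute <- table(sub("_[0-9]+$", "", sig_ids))
  expect_setequal(agg$transcript_id, names(brute))
  for (t in names(brute))
    expect_equal(agg$n_sig_probes[agg$transcript_id == t],
                 unname(brute[t]))
  expect_equal(sum(agg$n_sig_probes), length(sig_ids))
})

test_that("the tissue-dilution model reproduces the worked examples", {
  expect_equal(dilutionAdjustedFc(1 / 10, 10), 1.9)
  expect_equal(dilutionAdjustedFc(1 / 30, 10), 1.3)
  expect_equal(dilutionAdjustedFc(1, 7.3), 7.3)   # f = 1 identity
  expect_error(dilutionAdjustedFc(0, 10))
  expect_error(dilutionAdjustedFc(0.5, -1))
})

test_that("SAM controls false calls on null data and recovers planted effects", {
  # small-scale version of the calibration experiments (the acceptance
  # suite runs them at full size)
  nullcalls <- vapply(1:5, function(s) {
    cfg <- SimulationConfig(seed = s, nTranscripts = 300,
                            nAntisensePairs = 0, nDeGenes = 0,
                            probeNoiseSd = 0.25)
    ds <- simulateExpression(cfg, mkProbeTable(300))
    ds <- imputeMissing(missingValueFilter(quantileNormalize(ds))$dataset)
    sum(samProbes(samTwoClass(ds, seed = s))$significant)
  }, numeric(1))
  expect_lte(median(nullcalls), 1)

  cfg <- SimulationConfig(seed = 9, nTranscripts = 400,
                          nAntisensePairs = 0, nDeGenes = 20,
                          probeNoiseSd = 0.25, intensityLocation = 11,
                          intensityScale = 1, arrayDistortion = 0)
  set.seed(99)
  ids <- sample(sprintf("T%04d", 1:400), 20)
  truth <- mkDeTruth(ids, runif(20, 2, 4) * sample(c(-1, 1), 20,
                                                   replace = TRUE))
  ds <- simulateExpression(cfg, mkProbeTable(400), truth)
  ds <- imputeMissing(missingValueFilter(ds)$dataset)
  res <- samTwoClass(ds, seed = 9)
  sig <- samProbes(res)$probe_id[samProbes(res)$significant]
  planted <- c(paste0(ids, "_1"), paste0(ids, "_2"))
  expect_gte(mean(planted %in% sig), 0.9)
  expect_lte(mean(!(sig %in% planted)), 0.1)
})
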