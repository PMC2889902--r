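# Independent oracles: a dynamic-programming ends-free aligner (Gotoh
# affine gaps, score only), a union-find brute-force clusterer, and a
# closed-form hypergeometric tail sum. These deliberately avoid the code
# paths they check.

# ends-free (overlap) alignment score; match +1, mismatch -1, gap of
# length L costs open + L * ext
oracleOverlapScore <- function(a, b, match = 1, mismatch = -1,
                               open = 2, ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes b)
  M[1, ] <- 0; M[, 1] <- 0         # free leading gaps
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (av[i - 1] == bv[j - 1]) match else mismatch
      M[i, j] <- s + max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                         Iy[i - 1, j - 1])
      Ix[i, j] <- max(M[i - 1, j] - (open + ext), Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - (open + ext), Iy[i, j - 1] - ext)
    }
  }
  best <- max(M[n + 1, ], Ix[n + 1, ], Iy[n + 1, ],
              M[, m + 1], Ix[, m + 1], Iy[, m + 1])
  best
}

# brute-force clustering: every pair tested with overlapCheck (no
# candidate screen), single linkage by union-find
oracleCluster <- function(seqs, minOverlap = 40L, minIdentity = 0.90) {
  ids <- names(seqs)
  n <- length(seqs)
  parent <- seq_len(n)
  findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      chk <- overlapCheck(seqs[[i]], seqs[[j]], minOverlap, minIdentity)
      if (chk$accept) {
        ri <- findRoot(i); rj <- findRoot(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_len(n), findRoot, integer(1))
  split(ids, root)
}

# upper-tail hypergeometric sum from first principles (choose algebra)
oracleHyperTail <- function(k, K, N, n) {
  js <- seq(max(0, n + K - N), min(n, K))
  probs <- choose(K, js) * choose(N - K, n - js) / choose(N, n)
  sum(probs[js >= k])
}

# canonical form of a clustering for comparison: sorted members, sorted
canonicalClusters <- function(members) {
  unname(sort(vapply(members, function(m)
    paste(sort(m), collapse = "+"), character(1))))
}
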