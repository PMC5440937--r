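test_that("pairTable counts dinucleotides with consistent marginals", {
  aln <- MotifAlignment(c("AA", "AA", "TT", "TT"))
  t <- pairTable(aln, 1, 2)
  c16 <- counts16(t)
  expect_length(c16, 16)
  expect_equal(unname(c16["AA"]), 2)
  expect_equal(unname(c16["TT"]), 2)
  expect_equal(sum(c16), 4)

  # marginals reproduce the raw single-position counts
  aln2 <- simulateAlignment(L = 6, N = 75, seed = 17)
  cm <- buildCounts(aln2, pseudocounts = rep(0, 4))
  t2 <- pairTable(aln2, 2, 5)
  expect_equal(unname(rowSums(t2@counts)), unname(cm@counts[2, ]))
  expect_equal(unname(colSums(t2@counts)), unname(cm@counts[5, ]))

  # canonical orientation and argument checks
  t3 <- pairTable(aln2, 5, 2)
  expect_equal(t3@counts, t2@counts)
  expect_error(pairTable(aln2, 3, 3), "distinct")
  expect_error(pairTable(aln2, 1, 7), "range")
})

test_that("chi2 Q matches the brute-force oracle and its stated distribution", {
  aln <- MotifAlignment(c("AA", "AA", "TT", "TT"))
  r <- chi2Q(pairTable(aln, 1, 2))
  expect_equal(r$Q, 4)
  expect_equal(r$df, 15)
  expect_equal(r$p, pchisq(4, 15, lower.tail = FALSE))

  # independent pair with counts exactly proportional to marginal products
  ind <- MotifAlignment(c("AA", "AC", "CA", "CC"))
  expect_equal(chi2Q(pairTable(ind, 1, 2))$Q, 0)

  # fully conserved pair: one nonzero marginal each, Q = 0, p = 1
  cons <- chi2Q(pairTable(MotifAlignment(c("AG", "AG", "AG")), 1, 2))
  expect_equal(cons$Q, 0)
  expect_equal(cons$p, 1)

  # randomized alignments against the oracle and stats::chisq.test
  set.seed(8)
  for (rep in 1:15) {
    seqs <- vapply(1:30, function(i) {
      paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE), collapse = "")
    }, "")
    t <- pairTable(MotifAlignment(seqs), 1, 3)
    expect_equal(chi2Q(t)$Q, oracle_chi2(seqs, 1, 3), tolerance = 1e-9)
    ct <- suppressWarnings(stats::chisq.test(t@counts[rowSums(t@counts) > 0,
                                                      colSums(t@counts) > 0,
                                                      drop = FALSE],
                                             correct = FALSE))
    expect_equal(chi2Q(t)$Q, unname(ct$statistic), tolerance = 1e-9)
  }

  # the marginal df option
  expect_equal(chi2Q(pairTable(aln, 1, 2), df = "marginal")$df, 9)
})

test_that("mutual information matches the oracle and known closed forms", {
  two <- MotifAlignment(c("AA", "AA", "TT", "TT"))
  expect_equal(mutualInformation(pairTable(two, 1, 2)), 1)

  four <- MotifAlignment(c("AA", "CC", "GG", "TT"))
  expect_equal(mutualInformation(pairTable(four, 1, 2)), 2)

  ind <- MotifAlignment(c("AA", "AC", "CA", "CC"))
  expect_equal(mutualInformation(pairTable(ind, 1, 2)), 0)

  set.seed(12)
  for (rep in 1:15) {
    seqs <- vapply(1:25, function(i) {
      paste(sample(c("A", "C", "G", "T"), 2, replace = TRUE), collapse = "")
    }, "")
    expect_equal(mutualInformation(pairTable(MotifAlignment(seqs), 1, 2)),
                 oracle_mi(seqs, 1, 2), tolerance = 1e-9)
  }
})

test_that("Q and MI agree with the oracles on all tiny two-letter alignments", {
  for (n in c(1, 3, 6)) {
    for (seqs in enumerate_two_letter_alignments(n)) {
      t <- pairTable(MotifAlignment(seqs), 1, 2)
      expect_equal(chi2Q(t)$Q, oracle_chi2(seqs, 1, 2), tolerance = 1e-9)
      expect_equal(mutualInformation(t), oracle_mi(seqs, 1, 2), tolerance = 1e-9)
    }
  }
})

test_that("MI and Q invariances: symmetry, reordering, relabeling, entropy bound", {
  aln <- simulateAlignment(L = 4, N = 60, dependentPairs = list(c(1, 3, 0.3)),
                           seed = 23)
  t_ij <- pairTable(aln, 1, 3)
  t_ji <- pairTable(aln, 3, 1)
  expect_equal(mutualInformation(t_ij), mutualInformation(t_ji))
  expect_equal(chi2Q(t_ij)$Q, chi2Q(t_ji)$Q)

  # sequence reordering
  perm <- MotifAlignment(rev(unname(sequences(aln))))
  expect_equal(chi2Q(pairTable(perm, 1, 3))$Q, chi2Q(t_ij)$Q)

  # consistent nucleotide relabeling at both positions (A<->G, C<->T)
  relab <- chartr("ACGT", "GTAC", unname(sequences(aln)))
  tr <- pairTable(MotifAlignment(relab), 1, 3)
  expect_equal(chi2Q(tr)$Q, chi2Q(t_ij)$Q, tolerance = 1e-9)
  expect_equal(mutualInformation(tr), mutualInformation(t_ij), tolerance = 1e-9)

  # MI bounded by the smaller marginal entropy; both statistics non-negative
  cm <- buildCounts(aln, pseudocounts = rep(0, 4))
  for (j in 2:4) {
    t <- pairTable(aln, 1, j)
    mi <- mutualInformation(t)
    expect_gte(mi, 0)
    hi <- oracle_entropy(positionFrequencies(cm, 1))
    hj <- oracle_entropy(positionFrequencies(cm, j))
    expect_lte(mi, min(hi, hj) + 1e-9)
    expect_gte(chi2Q(t)$Q, 0)
  }
})

test_that("permutation null is seeded, reproducible, and degenerate when conserved", {
  aln <- simulateAlignment(L = 4, N = 50, seed = 3)
  n1 <- nullSummary(aln, 1, 2, B = 200, seed = 77)
  n2 <- nullSummary(aln, 1, 2, B = 200, seed = 77)
  expect_equal(n1@mean, n2@mean)
  expect_equal(n1@stdev, n2@stdev)
  n3 <- nullSummary(aln, 1, 2, B = 200, seed = 78)
  expect_false(isTRUE(all.equal(n1@mean, n3@mean)))

  cons <- MotifAlignment(rep("AG", 30))
  nc <- nullSummary(cons, 1, 2, B = 50, seed = 1)
  expect_equal(nc@mean, 0)
  expect_equal(nc@stdev, 0)
  expect_error(nullSummary(aln, 1, 2, B = 0), "B")
})

test_that("observed MI of an independent pair sits within the null spread", {
  # for independent columns the observed MI is itself a draw from the null
  hits <- 0
  for (s in 1:25) {
    aln <- simulateAlignment(L = 2, N = 100, seed = 1000 + s)
    mi <- mutualInformation(pairTable(aln, 1, 2))
    ns <- nullSummary(aln, 1, 2, B = 200, seed = s)
    if (abs(mi - ns@mean) <= 3 * ns@stdev) hits <- hits + 1
  }
  expect_gte(hits, 24)
})

test_that("Chebyshev bound follows p <= 1/K^2 with degenerate-null conventions", {
  ns <- new("NullSummary", mean = 0.1, stdev = 0.05, B = 1000L, seed = 1L)
  expect_equal(chebyshevBound(0.1, ns)$p_bound, 1)           # K = 0
  expect_equal(chebyshevBound(0.2, ns)$p_bound, 0.25)        # K = 2
  expect_equal(chebyshevBound(0.6, ns)$p_bound, 0.01)        # K = 10
  expect_equal(chebyshevBound(0.05, ns)$p_bound, 1)          # below the mean
  expect_equal(chebyshevBound(0.12, ns)$p_bound, 1)          # K < 1 caps at 1

  deg <- new("NullSummary", mean = 0, stdev = 0, B = 50L, seed = 1L)
  expect_equal(chebyshevBound(0.5, deg)$p_bound, 0)
  expect_equal(chebyshevBound(0, deg)$p_bound, 1)
})

test_that("buildLinks enumerates all pairs and carries the right significance", {
  aln <- simulateAlignment(L = 4, N = 40, seed = 5)
  lk <- buildLinks(aln, metric = "chi2")
  expect_equal(nrow(lk), 6)
  expect_true(all(lk$source < lk$target))
  for (r in seq_len(nrow(lk))) {
    t <- pairTable(aln, lk$source[r], lk$target[r])
    expect_equal(lk$statistic[r], chi2Q(t)$Q, tolerance = 1e-12)
    expect_equal(lk$p_value[r], chi2Q(t)$p, tolerance = 1e-12)
  }

  lkm <- buildLinks(aln, metric = "mi", B = 50, seed = 2)
  expect_equal(nrow(lkm), 6)
  for (r in seq_len(nrow(lkm))) {
    expect_equal(lkm$statistic[r],
                 mutualInformation(pairTable(aln, lkm$source[r], lkm$target[r])),
                 tolerance = 1e-12)
  }
  expect_true(all(lkm$p_value >= 0 & lkm$p_value <= 1))

  # B = 0 skips the null; determinism under a fixed seed
  lk0 <- buildLinks(aln, metric = "mi", B = 0)
  expect_true(all(is.na(lk0$p_value)))
  expect_identical(buildLinks(aln, metric = "mi", B = 30, seed = 9),
                   buildLinks(aln, metric = "mi", B = 30, seed = 9))

  # Bonferroni multiplies by the number of pairs, capped at 1
  lkb <- buildLinks(aln, metric = "chi2", bonferroni = TRUE)
  expect_equal(lkb$p_value, pmin(1, lk$p_value * 6))
})

test_that("an injected dependent pair carries the maximum statistic under both metrics", {
  aln <- simulateAlignment(L = 10, N = 150, dependentPairs = list(c(3, 8, 0.1)),
                           seed = 99)
  for (m in c("chi2", "mi")) {
    lk <- buildLinks(aln, metric = m, B = 0)
    top <- lk[which.max(lk$statistic), ]
    expect_equal(c(top$source, top$target), c(3, 8))
  }
})

test_that("metric suitability: conserved pairs kill MI, variable dependent pairs boost it", {
  # two near-invariant positions: co-occurrence persists but MI -> 0
  cons <- MotifAlignment(c(rep("AG", 99), "CT"))
  miCons <- mutualInformation(pairTable(cons, 1, 2))
  # two uniform, highly variable, perfectly coupled positions: MI large
  varSeqs <- paste0(rep(c("A", "C", "G", "T"), 25), rep(c("A", "C", "G", "T"), 25))
  miVar <- mutualInformation(pairTable(MotifAlignment(varSeqs), 1, 2))
  expect_lt(miCons, 0.1)
  expect_gt(miVar, 1.9)
})

test_that("links export to a TSV with the per-pair schema", {
  aln <- simulateAlignment(L = 4, N = 30, seed = 6)
  lk <- buildLinks(aln, metric = "chi2")
  f <- tempfile(fileext = ".tsv")
  writeLinksTsv(lk, f)
  back <- read.delim(f)
  expect_equal(names(back), c("i", "j", "metric", "statistic", "p_value"))
  expect_equal(nrow(back), 6)
  expect_equal(back$statistic, lk$statistic, tolerance = 1e-6)
})
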