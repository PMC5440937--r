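# Independent brute-force oracles and fixture builders. These never call
# package internals: statistics are computed straight from the textbook
# formulas on character matrices, so they can cross-check the package.

# character matrix (N x L) from sequences
oracle_char_matrix <- function(seqs) {
  t(vapply(strsplit(seqs, ""), identity, character(nchar(seqs[1]))))
}

# chi-square Q: sum over all 16 dinucleotide cells of (O-E)^2/E with
# E = N * p_i(a) * p_j(b); zero-expectation cells skipped
oracle_chi2 <- function(seqs, i, j) {
  m <- oracle_char_matrix(seqs)
  m[m == "U"] <- "T"
  n <- nrow(m)
  q <- 0
  for (a in c("A", "C", "G", "T")) {
    for (b in c("A", "C", "G", "T")) {
      o <- sum(m[, i] == a & m[, j] == b)
      e <- n * (sum(m[, i] == a) / n) * (sum(m[, j] == b) / n)
      if (e > 0) q <- q + (o - e)^2 / e
    }
  }
  q
}

# mutual information in bits, 0 log 0 terms dropped
oracle_mi <- function(seqs, i, j) {
  m <- oracle_char_matrix(seqs)
  m[m == "U"] <- "T"
  n <- nrow(m)
  mi <- 0
  for (a in c("A", "C", "G", "T")) {
    for (b in c("A", "C", "G", "T")) {
      pxy <- sum(m[, i] == a & m[, j] == b) / n
      px <- sum(m[, i] == a) / n
      py <- sum(m[, j] == b) / n
      if (pxy > 0) mi <- mi + pxy * log2(pxy / (px * py))
    }
  }
  mi
}

# Shannon entropy (bits) of a frequency vector
oracle_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

write_temp_fasta <- function(seqs, ids = paste0("s", seq_along(seqs)),
                             width = NULL) {
  f <- tempfile(fileext = ".fa")
  lines <- character(0)
  for (k in seq_along(seqs)) {
    s <- seqs[k]
    body <- if (is.null(width)) s else {
      starts <- seq(1, nchar(s), by = width)
      vapply(starts, function(a) substr(s, a, min(a + width - 1, nchar(s))), "")
    }
    lines <- c(lines, paste0(">", ids[k]), body)
  }
  writeLines(lines, f)
  f
}

# every alignment of n sequences, length 2, over a two-letter alphabet
# (sequence space AA, AT, TA, TT), as a list of character vectors
enumerate_two_letter_alignments <- function(n) {
  space <- c("AA", "AT", "TA", "TT")
  grid <- do.call(expand.grid, rep(list(seq_len(4)), n))
  lapply(seq_len(nrow(grid)), function(r) space[as.integer(grid[r, ])])
}

# a small valid graph for render/filter tests
toy_graph <- function(L = 5, nlinks = 3, seed = 11) {
  aln <- simulateAlignment(L = L, N = 40, seed = seed)
  g <- buildMotifGraph(aln, metric = "chi2", B = 0)
  lk <- motifLinks(g)
  g@links <- lk[seq_len(min(nlinks, nrow(lk))), , drop = FALSE]
  g
}
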