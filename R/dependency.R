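# Pairwise intra-motif dependency: dinucleotide tables, the chi-square Q
# statistic, mutual information, a column-permutation null and the Chebyshev
# significance bound; produces the link half of a MotifGraph.
#
# Pair tables always use raw counts — pseudocounts are never added here, so
# the chi-square calibration stays meaningful.

#' Dinucleotide contingency table for a position pair
#'
#' Counts the 16 dinucleotide combinations observed at positions `i` and
#' `j` across all sequences. All 16 categories are always represented
#' (zeros allowed); the table's marginals equal the raw single-position
#' nucleotide counts.
#'
#' @param aln a [MotifAlignment-class].
#' @param i,j distinct 1-based positions; stored canonically as `i < j`.
#' @return a [PairTable-class]; see [counts16()] for the flat
#'   AA, AC, ..., TT vector.
#' @export
#' @examples
#' counts16(pairTable(MotifAlignment(c("AA", "AA", "TT", "TT")), 1, 2))
pairTable <- function(aln, i, j) {
  stopifnot(is(aln, "MotifAlignment"))
  i <- as.integer(i); j <- as.integer(j)
  L <- motifLength(aln)
  if (i == j) stop("pairTable requires two distinct positions (i != j)")
  if (min(i, j) < 1L || max(i, j) > L) stop("position out of range")
  if (i > j) { tmp <- i; i <- j; j <- tmp }
  enc <- .encodeAlignment(aln@sequences)
  .pairTableEnc(enc, i, j)
}

.pairTableEnc <- function(enc, i, j) {
  cnt <- tabulate((enc[, i] - 1L) * 4L + enc[, j], nbins = 16L)
  new("PairTable",
    i = i, j = j,
    counts = matrix(as.integer(cnt), nrow = 4L, ncol = 4L, byrow = TRUE),
    n = nrow(enc)
  )
}

#' Chi-square Q statistic for a position pair
#'
#' `Q = sum_k (O_k - E_k)^2 / E_k` over the m = 16 dinucleotide cells, with
#' expected counts under independence `E_k = N p_i(a) p_j(b)` from the
#' pair's own marginal frequencies. Cells with zero expectation contribute
#' zero (routine when positions are conserved). The significance is the
#' upper tail of the chi-square distribution with `m - 1 = 15` degrees of
#' freedom by default; `df = "marginal"` uses the classical
#' `(4-1)(4-1) = 9` for estimated marginals instead.
#'
#' @param t a [PairTable-class].
#' @param df `"categories"` (m - 1 = 15, default) or `"marginal"` (9).
#' @return list with `Q`, `df` and upper-tail `p`.
#' @export
#' @examples
#' chi2Q(pairTable(MotifAlignment(c("AA", "AA", "TT", "TT")), 1, 2))$Q  # 4
chi2Q <- function(t, df = c("categories", "marginal")) {
  stopifnot(is(t, "PairTable"))
  df <- match.arg(df)
  O <- t@counts
  n <- t@n
  ri <- rowSums(O) / n
  cj <- colSums(O) / n
  E <- n * outer(ri, cj)
  nz <- E > 0
  Q <- sum((O[nz] - E[nz])^2 / E[nz])
  dfv <- if (df == "categories") 15L else 9L
  list(Q = Q, df = dfv, p = stats::pchisq(Q, df = dfv, lower.tail = FALSE))
}

#' Mutual information of a position pair (bits)
#'
#' `I(X;Y) = sum_x sum_y p(x,y) log2( p(x,y) / (p(x) p(y)) )` over raw
#' joint and marginal dinucleotide frequencies; `0 log 0` terms contribute
#' zero. Symmetric, non-negative, and bounded by the smaller marginal
#' entropy.
#'
#' @param t a [PairTable-class].
#' @return mutual information in bits.
#' @export
#' @examples
#' mutualInformation(pairTable(MotifAlignment(c("AA", "AA", "TT", "TT")), 1, 2))  # 1
mutualInformation <- function(t) {
  stopifnot(is(t, "PairTable"))
  .miFromJoint(t@counts / t@n)
}

.miFromJoint <- function(p) {
  px <- rowSums(p)
  py <- colSums(p)
  e <- outer(px, py)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / e[nz]))
}

.miEnc <- function(xi, xj) {
  p <- tabulate((xi - 1L) * 4L + xj, nbins = 16L) / length(xi)
  .miFromJoint(matrix(p, nrow = 4L, byrow = TRUE))
}

#' Permutation null distribution of mutual information
#'
#' Estimates the mutual information expected for positions `i`, `j` under
#' the random background model: column `j` is independently permuted across
#' sequences `B` times (both marginal compositions are preserved exactly,
#' the association is destroyed) and the MI recomputed each time. The
#' result is reproducible under a fixed seed.
#'
#' @param aln a [MotifAlignment-class].
#' @param i,j distinct positions.
#' @param B number of permutations (default 1000).
#' @param seed RNG seed (default 1).
#' @return a [NullSummary-class] with mean and standard deviation in bits.
#' @export
nullSummary <- function(aln, i, j, B = 1000L, seed = 1L) {
  stopifnot(is(aln, "MotifAlignment"))
  if (B < 1L) stop("B must be >= 1")
  enc <- .encodeAlignment(aln@sequences)
  xi <- enc[, as.integer(i)]
  xj <- enc[, as.integer(j)]
  mis <- .withSeed(seed, {
    vapply(seq_len(B), function(b) .miEnc(xi, sample(xj)), numeric(1))
  })
  new("NullSummary",
    mean = mean(mis),
    stdev = if (B > 1L) stats::sd(mis) else 0,
    B = as.integer(B), seed = as.integer(seed)
  )
}

#' Chebyshev significance bound for an observed mutual information
#'
#' If the observed MI sits `K` null standard deviations above the null
#' mean, Chebyshev's inequality bounds the tail probability by `1/K^2`
#' regardless of the null's shape: `p_bound = min(1, 1/K^2)` for `K > 0`,
#' and 1 otherwise. A degenerate null (`stdev = 0`, e.g. fully conserved
#' positions) gives `p_bound = 0` when the observation exceeds the null
#' mean and 1 when it does not.
#'
#' @param mi observed mutual information (bits).
#' @param null a [NullSummary-class].
#' @return list with `K` (stdev multiples) and `p_bound`.
#' @export
#' @examples
#' ns <- new("NullSummary", mean = 0.1, stdev = 0.05, B = 1000L, seed = 1L)
#' chebyshevBound(0.2, ns)$p_bound  # K = 2 -> 0.25
chebyshevBound <- function(mi, null) {
  stopifnot(is(null, "NullSummary"))
  if (null@stdev > 0) {
    K <- (mi - null@mean) / null@stdev
    p <- if (K > 0) min(1, 1 / K^2) else 1
  } else {
    K <- if (mi > null@mean) Inf else 0
    p <- if (mi > null@mean) 0 else 1
  }
  list(K = K, p_bound = p)
}

#' Compute dependency links for all position pairs
#'
#' Evaluates every unordered position pair `(i < j)` of the alignment —
#' `L(L-1)/2` links before any filtering — with the chosen metric. For
#' `metric = "chi2"` the statistic is the Q score and the p-value its
#' chi-square upper tail; for `metric = "mi"` the statistic is the mutual
#' information in bits and the p-value the Chebyshev bound against a
#' per-pair permutation null of `B` shuffles (`B = 0` skips the null and
#' leaves `p_value = NA`, useful when only the ranking matters). The link
#' `value` (drawn as ribbon width) is the raw statistic.
#'
#' @param aln a [MotifAlignment-class].
#' @param metric `"chi2"` (default) or `"mi"`.
#' @param B permutations per pair for the MI null (default 1000).
#' @param seed RNG seed for the permutation null.
#' @param df chi-square degrees of freedom rule, see [chi2Q()].
#' @param bonferroni if TRUE, p-values are Bonferroni-adjusted over the
#'   `L(L-1)/2` pairs (no correction by default).
#' @return data.frame of links: `source`, `target`, `value`, `statistic`,
#'   `p_value`, `metric`.
#' @export
#' @examples
#' aln <- simulateAlignment(L = 4, N = 50, seed = 7)
#' nrow(buildLinks(aln, metric = "chi2"))  # 6 pairs
buildLinks <- function(aln, metric = c("chi2", "mi"), B = 1000L, seed = 1L,
                       df = c("categories", "marginal"), bonferroni = FALSE) {
  stopifnot(is(aln, "MotifAlignment"))
  metric <- match.arg(metric)
  df <- match.arg(df)
  enc <- .encodeAlignment(aln@sequences)
  L <- ncol(enc)
  pairs <- utils::combn(L, 2L)
  nPairs <- ncol(pairs)

  compute <- function() {
    rows <- vector("list", nPairs)
    for (k in seq_len(nPairs)) {
      i <- pairs[1L, k]; j <- pairs[2L, k]
      t <- .pairTableEnc(enc, i, j)
      if (metric == "chi2") {
        r <- chi2Q(t, df = df)
        rows[[k]] <- c(i, j, r$Q, r$Q, r$p)
      } else {
        mi <- mutualInformation(t)
        p <- NA_real_
        if (B >= 1L) {
          mis <- vapply(seq_len(B), function(b) .miEnc(enc[, i], sample(enc[, j])),
                        numeric(1))
          ns <- new("NullSummary",
            mean = mean(mis), stdev = if (B > 1L) stats::sd(mis) else 0,
            B = as.integer(B), seed = as.integer(seed)
          )
          p <- chebyshevBound(mi, ns)$p_bound
        }
        rows[[k]] <- c(i, j, mi, mi, p)
      }
    }
    rows
  }
  rows <- if (metric == "mi" && B >= 1L) .withSeed(seed, compute()) else compute()

  m <- do.call(rbind, rows)
  links <- data.frame(
    source = as.integer(m[, 1L]), target = as.integer(m[, 2L]),
    value = m[, 3L], statistic = m[, 4L], p_value = m[, 5L],
    metric = metric, stringsAsFactors = FALSE
  )
  if (bonferroni) {
    links$p_value <- pmin(1, links$p_value * nPairs)
  }
  links
}

#' Write a link table to TSV
#'
#' Plain tab-separated export of per-pair results with columns `i`, `j`,
#' `metric`, `statistic`, `p_value`.
#'
#' @param links a link data.frame (from [buildLinks()]) or a
#'   [MotifGraph-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeLinksTsv <- function(links, path) {
  if (is(links, "MotifGraph")) links <- motifLinks(links)
  out <- data.frame(
    i = links$source, j = links$target, metric = links$metric,
    statistic = links$statistic, p_value = links$p_value,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
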