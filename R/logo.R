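# Position-specific composition: counts, frequencies and WebLogo-style
# information content; produces the node half of a MotifGraph.

#' Count nucleotides per position, with pseudocounts
#'
#' Tabulates the nucleotide at every motif position across all sequences
#' and adds the per-nucleotide pseudocounts, so every frequency downstream
#' is strictly positive even in small alignments. The default pseudocount
#' is 0.25 per nucleotide.
#'
#' @param aln a [MotifAlignment-class].
#' @param pseudocounts four non-negative values (A,C,G,T order).
#' @param background background frequencies (A,C,G,T); default uniform.
#' @return a [MotifCounts-class] (L x 4 matrix, A,C,G,T columns; U in RNA
#'   alignments is counted as T, the alphabet is remembered for display).
#' @export
#' @examples
#' buildCounts(MotifAlignment(c("AA", "AA")), pseudocounts = rep(0, 4))@counts
buildCounts <- function(aln, pseudocounts = rep(0.25, 4L),
                        background = rep(0.25, 4L)) {
  stopifnot(is(aln, "MotifAlignment"))
  pseudocounts <- as.numeric(pseudocounts)
  if (length(pseudocounts) != 4L || any(pseudocounts < 0)) {
    stop("pseudocounts must be 4 non-negative values")
  }
  enc <- .encodeAlignment(aln@sequences)
  L <- ncol(enc)
  counts <- t(vapply(seq_len(L), function(i) tabulate(enc[, i], nbins = 4L),
                     numeric(4L)))
  colnames(counts) <- .ACGT
  new("MotifCounts",
    counts = sweep(counts, 2L, pseudocounts, "+"),
    nSequences = nrow(enc),
    pseudocounts = pseudocounts,
    background = as.numeric(background) / sum(background),
    alphabet = aln@alphabet
  )
}

#' Per-position nucleotide frequencies
#'
#' The pseudocounted count row of position `i` normalized to sum to 1.
#'
#' @param cm a [MotifCounts-class].
#' @param i 1-based position.
#' @return named numeric of 4 frequencies (A,C,G,T).
#' @export
positionFrequencies <- function(cm, i) {
  stopifnot(is(cm, "MotifCounts"))
  i <- as.integer(i)
  if (i < 1L || i > motifLength(cm)) stop("position out of range: ", i)
  row <- cm@counts[i, ]
  .named4(row / sum(row))
}

#' WebLogo-style information content of one position
#'
#' The stack height in bits: `R_i = log2(4) - (H_i + e_n)` where `H_i` is
#' the Shannon entropy (bits) of position `i`'s nucleotide frequencies and
#' `e_n = 3 / (2 ln(2) N)` is the small-sample correction for a 4-letter
#' alphabet; the result is clamped to `[0, 2]`. With `correction = FALSE`
#' the height is plain `2 - H_i`.
#'
#' @param cm a [MotifCounts-class].
#' @param i 1-based position.
#' @param correction apply the small-sample correction (default TRUE).
#' @return information content in bits, in `[0, 2]`.
#' @export
#' @examples
#' cm <- buildCounts(MotifAlignment(c("AC", "AC", "AG", "AT")),
#'                   pseudocounts = rep(0, 4))
#' informationContent(cm, 1, correction = FALSE)  # conserved: 2 bits
informationContent <- function(cm, i, correction = TRUE) {
  p <- positionFrequencies(cm, i)
  h <- -sum(ifelse(p > 0, p * log2(p), 0))
  en <- if (correction) 3 / (2 * log(2) * cm@nSequences) else 0
  min(2, max(0, 2 - (h + en)))
}

#' Build the node list of a motif graph
#'
#' One node per position: `index` (1-based), `label` (the decimal position
#' by default), `bit` from [informationContent()], and the four nucleotides
#' with their frequencies sorted ascending by frequency (alphabetical
#' tie-break). RNA alignments display U in place of T.
#'
#' @param cm a [MotifCounts-class].
#' @param correction passed to [informationContent()].
#' @param labels optional character vector of per-position labels.
#' @return list of node entries suitable for a [MotifGraph-class].
#' @export
buildNodes <- function(cm, correction = TRUE, labels = NULL) {
  stopifnot(is(cm, "MotifCounts"))
  L <- motifLength(cm)
  if (is.null(labels)) labels <- as.character(seq_len(L))
  stopifnot(length(labels) == L)
  letters4 <- if (identical(cm@alphabet, "RNA")) c("A", "C", "G", "U") else .ACGT
  lapply(seq_len(L), function(i) {
    p <- as.numeric(positionFrequencies(cm, i))
    o <- order(p, letters4)
    list(
      index = i,
      label = labels[i],
      bit = informationContent(cm, i, correction = correction),
      base = letters4[o],
      freq = p[o]
    )
  })
}
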