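#' Accessors for motifRing classes
#'
#' Small accessor generics shared across the package's classes:
#' `nSequences()` (number of aligned instances), `motifLength()` (positions),
#' `alphabet()`, `sequences()`, `motifId()`, `background()`, `pseudocounts()`,
#' `motifNodes()` (nodes as a data.frame, one row per position),
#' `motifLinks()` (links as a data.frame), and `counts16()` (the 16
#' dinucleotide counts of a [PairTable-class] in AA, AC, AG, AT, CA, ..., TT
#' order).
#'
#' @param x a MotifAlignment, MotifCounts, PairTable or MotifGraph object.
#' @return the requested component; see details per class.
#' @name accessors
#' @aliases nSequences motifLength alphabet sequences motifId background
#'   pseudocounts motifNodes motifLinks counts16
#' @examples
#' aln <- MotifAlignment(c("ACGT", "ACGT", "ACTT"))
#' nSequences(aln)
#' motifLength(aln)
NULL

#' Construct a MotifAlignment from sequences in memory
#'
#' Validating constructor used by [readFasta()] and [simulateAlignment()];
#' also convenient for tests and small examples. Sequences are uppercased;
#' the alphabet is auto-detected (RNA when U occurs and T does not).
#'
#' @param sequences character vector of equal-length gap-free sequences.
#' @param ids optional per-sequence identifiers; defaults to `seq_1`, ...
#' @param alphabet `"auto"`, `"dna"` or `"rna"`.
#' @param nExcluded number of input records excluded upstream (bookkeeping).
#' @return a [MotifAlignment-class] object.
#' @export
#' @examples
#' MotifAlignment(c("ACGU", "ACGU"), alphabet = "rna")
MotifAlignment <- function(sequences, ids = NULL, alphabet = c("auto", "dna", "rna"),
                           nExcluded = 0L) {
  alphabet <- match.arg(alphabet)
  sequences <- toupper(as.character(sequences))
  if (is.null(ids)) ids <- paste0("seq_", seq_along(sequences))
  if (alphabet == "auto") {
    hasU <- any(grepl("U", sequences, fixed = TRUE))
    hasT <- any(grepl("T", sequences, fixed = TRUE))
    alphabet <- if (hasU && !hasT) "rna" else "dna"
  }
  new("MotifAlignment",
    sequences = sequences, ids = as.character(ids),
    alphabet = toupper(alphabet), nExcluded = as.integer(nExcluded)
  )
}

#' @rdname accessors
#' @export
setMethod("nSequences", "MotifAlignment", function(x) length(x@sequences))

#' @rdname accessors
#' @export
setMethod("nSequences", "MotifCounts", function(x) x@nSequences)

#' @rdname accessors
#' @export
setMethod("motifLength", "MotifAlignment", function(x) nchar(x@sequences[1L]))

#' @rdname accessors
#' @export
setMethod("motifLength", "MotifCounts", function(x) nrow(x@counts))

#' @rdname accessors
#' @export
setMethod("motifLength", "MotifGraph", function(x) length(x@nodes))

#' @rdname accessors
#' @export
setMethod("alphabet", "MotifAlignment", function(x) x@alphabet)

#' @rdname accessors
#' @export
setMethod("alphabet", "MotifCounts", function(x) x@alphabet)

#' @rdname accessors
#' @export
setMethod("alphabet", "MotifGraph", function(x) x@alphabet)

#' @rdname accessors
#' @export
setMethod("sequences", "MotifAlignment", function(x) {
  stats::setNames(x@sequences, x@ids)
})

#' @rdname accessors
#' @export
setMethod("motifId", "MotifGraph", function(x) x@id)

#' @rdname accessors
#' @export
setMethod("background", "MotifCounts", function(x) .named4(x@background))

#' @rdname accessors
#' @export
setMethod("background", "MotifGraph", function(x) .named4(x@background))

#' @rdname accessors
#' @export
setMethod("pseudocounts", "MotifCounts", function(x) .named4(x@pseudocounts))

#' @rdname accessors
#' @export
setMethod("pseudocounts", "MotifGraph", function(x) .named4(x@pseudocounts))

#' @rdname accessors
#' @export
setMethod("motifNodes", "MotifGraph", function(x) {
  do.call(rbind, lapply(x@nodes, function(nd) {
    data.frame(
      index = as.integer(nd$index), label = as.character(nd$label),
      bit = as.numeric(nd$bit),
      base = paste(nd$base, collapse = ""),
      freq = I(list(as.numeric(nd$freq))),
      stringsAsFactors = FALSE
    )
  }))
})

#' @rdname accessors
#' @export
setMethod("motifLinks", "MotifGraph", function(x) x@links)

#' @rdname accessors
#' @export
setMethod("counts16", "PairTable", function(x) {
  # row-major: first letter is the nucleotide at position i
  v <- as.vector(t(x@counts))
  names(v) <- as.vector(t(outer(.ACGT, .ACGT, paste0)))
  v
})

setMethod("show", "MotifAlignment", function(object) {
  cat(sprintf(
    "MotifAlignment: %d sequences x %d positions (%s)\n",
    nSequences(object), motifLength(object), object@alphabet
  ))
  if (object@nExcluded > 0L) {
    cat(sprintf("  %d input sequence(s) excluded (gaps/ambiguity)\n", object@nExcluded))
  }
  k <- min(3L, nSequences(object))
  for (i in seq_len(k)) {
    s <- object@sequences[i]
    if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
    cat(sprintf("  %s  %s\n", object@ids[i], s))
  }
  if (nSequences(object) > k) cat(sprintf("  ... and %d more\n", nSequences(object) - k))
})

setMethod("show", "MotifCounts", function(object) {
  cat(sprintf(
    "MotifCounts: %d positions, N = %g, pseudocounts = (%s)\n",
    motifLength(object), object@nSequences,
    paste(format(object@pseudocounts), collapse = ", ")
  ))
})

setMethod("show", "PairTable", function(object) {
  cat(sprintf("PairTable: positions %d-%d, N = %d\n", object@i, object@j, object@n))
  m <- object@counts
  dimnames(m) <- list(.ACGT, .ACGT)
  print(m)
})

setMethod("show", "NullSummary", function(object) {
  cat(sprintf(
    "NullSummary: mean = %.6g bits, stdev = %.6g bits (B = %d, seed = %d)\n",
    object@mean, object@stdev, object@B, object@seed
  ))
})

setMethod("show", "MotifGraph", function(object) {
  cat(sprintf(
    "MotifGraph '%s': %d nodes, %d links (%s)\n",
    object@id, motifLength(object), nrow(object@links), object@alphabet
  ))
  bits <- vapply(object@nodes, function(nd) nd$bit, numeric(1))
  cat(sprintf("  information content: %.3f-%.3f bits\n", min(bits), max(bits)))
  if (nrow(object@links)) {
    cat(sprintf(
      "  link metric(s): %s; max statistic %.4g\n",
      paste(unique(object@links$metric), collapse = ","),
      max(object@links$statistic)
    ))
  }
})
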