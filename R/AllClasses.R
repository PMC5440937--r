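#' @import methods
NULL

#' MotifAlignment: equal-length, gap-free nucleotide sequences
#'
#' Container for the aligned motif instances a circular logo is built from.
#' All sequences have identical length and contain only A, C, G, T (DNA) or
#' A, C, G, U (RNA) after uppercasing; sequences with gaps or ambiguity codes
#' are excluded at read time (see [readFasta()]). The original spelling (U
#' vs T) is preserved; statistics unify U with T internally.
#'
#' @slot sequences character vector of aligned sequences, one per instance.
#' @slot ids per-sequence identifiers (FASTA headers or generated).
#' @slot alphabet `"DNA"` or `"RNA"`.
#' @slot nExcluded number of input sequences dropped for gaps/ambiguity.
#'
#' @seealso [readFasta()], [simulateAlignment()], [buildCounts()]
#' @exportClass MotifAlignment
setClass("MotifAlignment",
  representation(
    sequences = "character",
    ids = "character",
    alphabet = "character",
    nExcluded = "integer"
  ),
  prototype(alphabet = "DNA", nExcluded = 0L)
)

setValidity("MotifAlignment", function(object) {
  msg <- character(0)
  n <- length(object@sequences)
  if (n < 1L) msg <- c(msg, "alignment must contain at least one sequence")
  if (n >= 1L) {
    lens <- nchar(object@sequences)
    if (length(unique(lens)) != 1L) {
      msg <- c(msg, "sequences must all have the same length")
    } else if (lens[1L] < 2L) {
      msg <- c(msg, "alignment must be at least 2 positions long")
    }
    ok <- switch(object@alphabet,
      DNA = grepl("^[ACGT]+$", object@sequences),
      RNA = grepl("^[ACGU]+$", object@sequences),
      NA
    )
    if (anyNA(ok)) {
      msg <- c(msg, "alphabet must be 'DNA' or 'RNA'")
    } else if (!all(ok)) {
      msg <- c(msg, "sequences contain characters outside the declared alphabet")
    }
  }
  if (length(object@ids) != n) msg <- c(msg, "ids must match sequences in length")
  if (length(msg)) msg else TRUE
})

#' MotifCounts: per-position nucleotide counts
#'
#' An L x 4 matrix of per-position nucleotide counts (columns A, C, G, T)
#' with pseudocounts already added, plus the background distribution. Every
#' row sums to `N + sum(pseudocounts)`. Pseudocounts keep all frequencies
#' strictly positive so small alignments never divide by zero.
#'
#' @slot counts numeric L x 4 matrix (A,C,G,T columns), pseudocounts included.
#' @slot nSequences number of sequences counted.
#' @slot pseudocounts the four per-nucleotide pseudocounts (A,C,G,T).
#' @slot background background nucleotide frequencies (A,C,G,T), summing to 1.
#' @slot alphabet `"DNA"` or `"RNA"` (controls U vs T display labels).
#'
#' @seealso [buildCounts()], [informationContent()], [buildNodes()]
#' @exportClass MotifCounts
setClass("MotifCounts",
  representation(
    counts = "matrix",
    nSequences = "numeric",
    pseudocounts = "numeric",
    background = "numeric",
    alphabet = "character"
  ),
  prototype(alphabet = "DNA")
)

setValidity("MotifCounts", function(object) {
  msg <- character(0)
  if (ncol(object@counts) != 4L) msg <- c(msg, "counts must have 4 columns (A,C,G,T)")
  if (nrow(object@counts) < 2L) msg <- c(msg, "motif must have at least 2 positions")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (object@nSequences < 1) msg <- c(msg, "nSequences must be >= 1")
  if (length(object@pseudocounts) != 4L || any(object@pseudocounts < 0)) {
    msg <- c(msg, "pseudocounts must be 4 non-negative values")
  }
  if (length(object@background) != 4L || any(object@background < 0) ||
      abs(sum(object@background) - 1) > 1e-9) {
    msg <- c(msg, "background must be 4 non-negative frequencies summing to 1")
  }
  expected <- object@nSequences + sum(object@pseudocounts)
  if (ncol(object@counts) == 4L &&
      any(abs(rowSums(object@counts) - expected) > 1e-6 * max(1, expected))) {
    msg <- c(msg, "every count row must sum to N + sum(pseudocounts)")
  }
  if (length(msg)) msg else TRUE
})

#' PairTable: dinucleotide contingency table for one position pair
#'
#' Exact dinucleotide counts for positions `i < j` of an alignment, held as
#' a 4 x 4 matrix (rows: nucleotide at `i`; columns: nucleotide at `j`; both
#' in A,C,G,T order). All 16 categories are always represented, zeros
#' allowed; marginals reproduce the raw single-position counts. Pseudocounts
#' are never added to pair tables.
#'
#' @slot i,j the two 1-based positions, `i < j`.
#' @slot counts integer 4 x 4 dinucleotide count matrix.
#' @slot n total number of sequences (equals `sum(counts)`).
#'
#' @seealso [pairTable()], [chi2Q()], [mutualInformation()]
#' @exportClass PairTable
setClass("PairTable",
  representation(i = "integer", j = "integer", counts = "matrix", n = "integer")
)

setValidity("PairTable", function(object) {
  msg <- character(0)
  if (!identical(dim(object@counts), c(4L, 4L))) {
    msg <- c(msg, "counts must be a 4 x 4 matrix")
  }
  if (object@i >= object@j) msg <- c(msg, "requires i < j")
  if (sum(object@counts) != object@n) msg <- c(msg, "counts must sum to n")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' NullSummary: permutation null distribution of mutual information
#'
#' Mean and standard deviation of the mutual information of a position pair
#' under `B` random shufflings of one column (both marginal compositions are
#' preserved exactly; the association is destroyed). Feeds the Chebyshev
#' significance bound.
#'
#' @slot mean expected MI (bits) under shuffling.
#' @slot stdev standard deviation of MI under shuffling.
#' @slot B number of permutations.
#' @slot seed RNG seed used.
#'
#' @seealso [nullSummary()], [chebyshevBound()]
#' @exportClass NullSummary
setClass("NullSummary",
  representation(mean = "numeric", stdev = "numeric", B = "integer", seed = "integer")
)

setValidity("NullSummary", function(object) {
  msg <- character(0)
  if (object@stdev < 0) msg <- c(msg, "stdev must be >= 0")
  if (object@B < 1L) msg <- c(msg, "B must be >= 1")
  if (length(msg)) msg else TRUE
})

#' MotifGraph: a motif with nodes (stacks) and links (dependencies)
#'
#' The full graph representation of a motif: one node per position carrying
#' its information content and ascending-sorted nucleotide frequencies, and
#' one link per retained position pair carrying the dependency strength. The
#' on-disk JSON form of this object is the package's exchange format (see
#' [writeJsonGraph()]).
#'
#' @slot id motif name.
#' @slot background background frequencies, internal A,C,G,T order, sum 1.
#' @slot pseudocounts per-nucleotide pseudocounts, internal A,C,G,T order.
#' @slot nodes list of per-position entries, each a list with `index`
#'   (1-based, ascending), `label`, `bit` (information content, 0..2),
#'   `base` (4 nucleotide symbols) and `freq` (4 frequencies, ascending,
#'   sum 1, aligned with `base`).
#' @slot links data.frame with columns `source`, `target`, `value`,
#'   `statistic`, `p_value`, `metric`; `source < target` always.
#' @slot alphabet `"DNA"` or `"RNA"`.
#'
#' @seealso [buildMotifGraph()], [readJsonGraph()], [renderSvg()]
#' @exportClass MotifGraph
setClass("MotifGraph",
  representation(
    id = "character",
    background = "numeric",
    pseudocounts = "numeric",
    nodes = "list",
    links = "data.frame",
    alphabet = "character"
  ),
  prototype(alphabet = "DNA")
)

.emptyLinks <- function() {
  data.frame(
    source = integer(0), target = integer(0), value = numeric(0),
    statistic = numeric(0), p_value = numeric(0), metric = character(0),
    stringsAsFactors = FALSE
  )
}

setValidity("MotifGraph", function(object) {
  msg <- character(0)
  if (length(object@background) != 4L || any(object@background < 0) ||
      abs(sum(object@background) - 1) > 1e-9) {
    msg <- c(msg, "background must be 4 non-negative frequencies summing to 1")
  }
  if (length(object@pseudocounts) != 4L || any(object@pseudocounts < 0)) {
    msg <- c(msg, "pseudocounts must be 4 non-negative values")
  }
  L <- length(object@nodes)
  if (L < 1L) msg <- c(msg, "graph must contain at least one node")
  idx <- vapply(object@nodes, function(nd) as.integer(nd$index), integer(1))
  if (L >= 1L && !identical(idx, seq_len(L))) {
    msg <- c(msg, "node indexes must be 1..L, unique, ascending")
  }
  for (nd in object@nodes) {
    if (length(nd$base) != 4L || length(nd$freq) != 4L) {
      msg <- c(msg, sprintf("node %s: base/freq must have 4 entries", nd$index))
      break
    }
    if (is.unsorted(nd$freq)) {
      msg <- c(msg, sprintf("node %s: freq must be sorted ascending", nd$index))
      break
    }
    if (abs(sum(nd$freq) - 1) > 1e-9) {
      msg <- c(msg, sprintf("node %s: freq must sum to 1", nd$index))
      break
    }
    if (is.na(nd$bit) || nd$bit < -1e-12) {
      msg <- c(msg, sprintf("node %s: bit must be >= 0", nd$index))
      break
    }
  }
  lk <- object@links
  need <- c("source", "target", "value", "statistic", "p_value", "metric")
  if (!all(need %in% names(lk))) {
    msg <- c(msg, "links must have columns source,target,value,statistic,p_value,metric")
  } else if (nrow(lk)) {
    if (any(lk$source >= lk$target)) msg <- c(msg, "links require source < target")
    if (any(lk$source < 1L) || any(lk$target > L)) {
      msg <- c(msg, "link endpoints must be valid node indexes")
    }
    if (any(lk$value < 0, na.rm = TRUE)) msg <- c(msg, "link values must be >= 0")
    pv <- lk$p_value
    if (any(!is.na(pv) & (pv < 0 | pv > 1))) {
      msg <- c(msg, "link p_value must lie in [0,1]")
    }
  }
  if (length(msg)) msg else TRUE
})
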