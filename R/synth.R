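# Synthetic alignments with controlled conservation and injected pairwise
# dependencies, plus the fragment-construction recipes used when assembling
# composite splice-site motifs and flank-extended binding sites.

#' Simulate an aligned set of motif instances
#'
#' Draws `N` sequences of length `L`. Independent positions are sampled
#' from `profile` (per-position nucleotide frequencies). For every entry of
#' `dependentPairs`, position `j` copies position `i`'s letter with
#' probability `1 - epsilon` and otherwise redraws from the profile — the
#' simplest mechanism giving tunable mutual information between a pair
#' (`epsilon = 0`: perfect copy, MI of a uniform pair approaches 2 bits;
#' `epsilon = 1`: independence, MI approaches 0).
#'
#' @param L motif length.
#' @param N number of sequences.
#' @param profile either a single vector of 4 frequencies (A,C,G,T) used at
#'   every position, or an L x 4 matrix of per-position frequencies.
#'   Default uniform.
#' @param dependentPairs list of `c(i, j, epsilon)` triples; the positions
#'   used must not overlap between pairs.
#' @param seed RNG seed; the same seed reproduces the same alignment.
#' @param alphabet `"dna"` or `"rna"`.
#' @return a [MotifAlignment-class].
#' @export
#' @examples
#' aln <- simulateAlignment(L = 8, N = 100,
#'   dependentPairs = list(c(2, 6, 0.1)), seed = 42)
#' mutualInformation(pairTable(aln, 2, 6))
simulateAlignment <- function(L, N, profile = rep(0.25, 4L),
                              dependentPairs = list(), seed = 1L,
                              alphabet = c("dna", "rna")) {
  alphabet <- match.arg(alphabet)
  stopifnot(.isCount(L), L >= 2, .isCount(N), N >= 1)
  if (is.null(dim(profile))) {
    if (length(profile) != 4L) stop("profile vector must have 4 frequencies (A,C,G,T)")
    profile <- matrix(as.numeric(profile), nrow = L, ncol = 4L, byrow = TRUE)
  }
  stopifnot(nrow(profile) == L, ncol(profile) == 4L, all(profile >= 0))
  profile <- profile / rowSums(profile)

  used <- integer(0)
  for (dp in dependentPairs) {
    stopifnot(length(dp) == 3L)
    i <- as.integer(dp[1L]); j <- as.integer(dp[2L]); eps <- dp[3L]
    if (i == j || min(i, j) < 1L || max(i, j) > L) {
      stop("dependent pair positions must be distinct and within 1..L")
    }
    if (eps < 0 || eps > 1) stop("copy error epsilon must be in [0, 1]")
    if (any(c(i, j) %in% used)) stop("dependent pairs must not share positions")
    used <- c(used, i, j)
  }

  enc <- .withSeed(seed, {
    m <- matrix(0L, nrow = N, ncol = L)
    for (p in seq_len(L)) {
      m[, p] <- sample.int(4L, N, replace = TRUE, prob = profile[p, ])
    }
    for (dp in dependentPairs) {
      i <- as.integer(dp[1L]); j <- as.integer(dp[2L]); eps <- dp[3L]
      copy <- stats::runif(N) < (1 - eps)
      m[copy, j] <- m[copy, i]
    }
    m
  })
  letters4 <- if (alphabet == "rna") c("A", "C", "G", "U") else .ACGT
  seqs <- apply(enc, 1L, function(r) paste(letters4[r], collapse = ""))
  MotifAlignment(seqs, ids = sprintf("sim_%04d", seq_len(N)), alphabet = alphabet)
}

#' Assemble a composite splice-motif fragment
#'
#' Concatenates a 5' donor-site segment (16 bases: 6 exonic + 10 intronic),
#' a branch-point segment (21 bases: the branch-point nucleotide with 10
#' bases of flank either side) and a 3' acceptor-site segment (16 bases:
#' 10 intronic + 6 exonic) in that order, yielding the 53-base fragment
#' used to study dependencies among the three splicing elements.
#'
#' @param donor 16-base donor-site string.
#' @param branch 21-base branch-point string.
#' @param acceptor 16-base acceptor-site string.
#' @return a 53-base string `donor | branch | acceptor`.
#' @export
#' @examples
#' nchar(concatSpliceFragment(strrep("A", 16), strrep("C", 21), strrep("G", 16)))
concatSpliceFragment <- function(donor, branch, acceptor) {
  stopifnot(is.character(donor), is.character(branch), is.character(acceptor))
  if (nchar(donor) != 16L) stop("donor segment must be exactly 16 bases, got ", nchar(donor))
  if (nchar(branch) != 21L) stop("branch-point segment must be exactly 21 bases, got ", nchar(branch))
  if (nchar(acceptor) != 16L) stop("acceptor segment must be exactly 16 bases, got ", nchar(acceptor))
  paste0(donor, branch, acceptor)
}

#' Extend a binding site with flanking sequence
#'
#' Concatenates `up`, `core` and `down`. With 20-base flanks around a
#' 25-base binding site this yields the 65-nucleotide windows used to
#' contrast within-motif dependencies against the background dependency
#' level of the flanks.
#'
#' @param core binding-site string.
#' @param up upstream flank (may be empty).
#' @param down downstream flank (may be empty).
#' @return the extended string `up | core | down`.
#' @export
#' @examples
#' nchar(extendSite(strrep("A", 25), strrep("C", 20), strrep("G", 20)))  # 65
extendSite <- function(core, up = "", down = "") {
  stopifnot(is.character(core), is.character(up), is.character(down))
  paste0(up, core, down)
}
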