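#' Read an aligned FASTA file of motif instances
#'
#' Reads a multi-record FASTA file (wrapped or unwrapped) and validates it as
#' a motif alignment. Sequences containing gap characters (`-`, `.`) or
#' ambiguity codes are excluded with a diagnostic message reporting the
#' count, mirroring the usual preprocessing of structured-RNA seed
#' alignments; `strict = TRUE` turns an exclusion into an error instead.
#' Because the dependency statistics lose power on small samples, a warning
#' is emitted when fewer than 25 sequences survive — at least 25 aligned
#' instances are recommended.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"auto"` (default), `"dna"` or `"rna"`. Auto-detection
#'   declares RNA when U occurs and T does not. U and T are preserved as
#'   read; statistics unify them internally.
#' @param strict if TRUE, gap/ambiguity characters raise an error rather
#'   than excluding the offending sequence.
#' @return a [MotifAlignment-class].
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "ACGTACGT", ">b", "ACGTTCGT"), fa)
#' readFasta(fa)
readFasta <- function(path, alphabet = c("auto", "dna", "rna"), strict = FALSE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("cannot parse FASTA file '", path, "': ", conditionMessage(e))
  )
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(set))
  ids <- names(set)
  if (is.null(ids)) ids <- paste0("seq_", seq_along(seqs))
  ids <- sub("\\s.*$", "", ids)

  clean <- grepl("^[ACGTU]+$", seqs)
  nExcluded <- sum(!clean)
  if (nExcluded > 0L) {
    if (strict) {
      stop(nExcluded, " sequence(s) contain gaps or ambiguity codes (strict mode)")
    }
    message(nExcluded, " sequence(s) excluded for gaps or ambiguity codes")
    seqs <- seqs[clean]
    ids <- ids[clean]
  }
  if (length(seqs) == 0L) stop("no sequences remain after exclusions: ", path)
  if (length(unique(nchar(seqs))) != 1L) {
    stop("sequences are not aligned: unequal lengths after exclusions")
  }
  aln <- MotifAlignment(seqs, ids = ids, alphabet = alphabet, nExcluded = nExcluded)
  if (nSequences(aln) < 25L) {
    warning("alignment has only ", nSequences(aln),
            " sequences; dependency estimates are unreliable below 25")
  }
  aln
}

#' Write a MotifAlignment to FASTA
#'
#' @param aln a [MotifAlignment-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(aln, path) {
  stopifnot(is(aln, "MotifAlignment"))
  set <- Biostrings::BStringSet(stats::setNames(aln@sequences, aln@ids))
  Biostrings::writeXStringSet(set, filepath = path, width = 80L)
  invisible(path)
}
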