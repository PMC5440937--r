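# Internal helpers shared across modules.

# Internal nucleotide order everywhere in memory; the on-disk JSON order
# (A,T,C,G) is honored only at the serialization boundary.
.ACGT <- c("A", "C", "G", "T")

# index maps between internal A,C,G,T and on-disk A,T,C,G
.TO_DISK <- c(1L, 4L, 2L, 3L)   # internal[TO_DISK] -> A,T,C,G
.FROM_DISK <- c(1L, 3L, 4L, 2L) # disk[FROM_DISK]   -> A,C,G,T

.named4 <- function(x) {
  x <- as.numeric(x)
  stopifnot(length(x) == 4L)
  names(x) <- .ACGT
  x
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream (restores .Random.seed on exit).
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Sequences as an integer matrix (N x L) over 1..4 = A,C,G,T; U counts as T.
.encodeAlignment <- function(sequences) {
  n <- length(sequences)
  l <- nchar(sequences[1L])
  chars <- matrix(unlist(strsplit(sequences, "", fixed = TRUE), use.names = FALSE),
                  nrow = n, ncol = l, byrow = TRUE)
  chars[chars == "U"] <- "T"
  m <- match(chars, .ACGT)
  if (anyNA(m)) {
    stop("alignment contains characters outside the nucleotide alphabet")
  }
  matrix(m, nrow = n, ncol = l)
}

.isCount <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
}

# format numbers for SVG output: fixed 4 decimals, trailing zeros kept,
# so re-rendering is byte-identical
.fmt <- function(x) sprintf("%.4f", x)
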