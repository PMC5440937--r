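#' Convert a JASPAR, MEME or TRANSFAC matrix file to MotifCounts
#'
#' Parses a count-matrix motif file and returns a [MotifCounts-class] with
#' the requested pseudocounts applied. JASPAR files carry per-position
#' counts in four nucleotide rows (`A [ 4 19 0 ... ]`); MEME minimal files
#' carry a letter-probability matrix whose rows are scaled by the stated
#' `nsites` to recover counts (nsites defaults to 20 when absent, the MEME
#' convention); TRANSFAC files carry numbered count rows in A, C, G, T
#' column order. Only the first motif of a multi-motif file is read.
#'
#' Matrix formats carry no dependency information, so a graph built from a
#' converted matrix always has an empty link list (see [countsToGraph()]).
#'
#' @param path path to the matrix file.
#' @param dialect `"jaspar"`, `"meme"` or `"transfac"`.
#' @param pseudocounts four per-nucleotide pseudocounts (A,C,G,T), default
#'   0.25 each.
#' @param background background frequencies (A,C,G,T), default uniform.
#' @return a [MotifCounts-class]; its `nSequences` is the (rounded) number
#'   of sites underlying the matrix.
#' @export
#' @examples
#' f <- tempfile(fileext = ".jaspar")
#' writeLines(c(
#'   ">MA0000.1 demo",
#'   "A [ 4  0 19  0 ]", "C [ 6  1  0 20 ]",
#'   "G [ 5 19  1  0 ]", "T [ 5  0  0  0 ]"
#' ), f)
#' convertMatrix(f, "jaspar")
convertMatrix <- function(path, dialect = c("jaspar", "meme", "transfac"),
                          pseudocounts = rep(0.25, 4L),
                          background = rep(0.25, 4L)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("matrix file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  parsed <- switch(dialect,
    jaspar = .parseJaspar(lines),
    meme = .parseMeme(lines),
    transfac = .parseTransfac(lines)
  )
  raw <- parsed$counts  # L x 4, A,C,G,T columns, no pseudocounts
  if (nrow(raw) < 2L) stop("matrix must have at least 2 positions")
  n <- max(1, round(max(rowSums(raw))))
  cm <- new("MotifCounts",
    counts = sweep(raw, 2L, as.numeric(pseudocounts), "+"),
    nSequences = n,
    pseudocounts = as.numeric(pseudocounts),
    background = as.numeric(background) / sum(background),
    alphabet = "DNA"
  )
  attr(cm, "motifName") <- parsed$name
  cm
}

.parseJaspar <- function(lines) {
  name <- "motif"
  hdr <- grep("^>", lines)
  if (length(hdr)) name <- sub("^>\\s*", "", lines[hdr[1L]])
  rows <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([ACGTacgt])\\s*[\\[|:]?\\s*([-0-9. eE]+)\\]?\\s*$", ln))[[1L]]
    if (length(m) == 3L) {
      vals <- as.numeric(strsplit(trimws(m[3L]), "\\s+")[[1L]])
      rows[[toupper(m[2L])]] <- vals
    }
  }
  if (!all(.ACGT %in% names(rows))) {
    missing <- setdiff(.ACGT, names(rows))
    stop("JASPAR parse error: missing count row(s) for ", paste(missing, collapse = ", "))
  }
  w <- unique(lengths(rows[.ACGT]))
  if (length(w) != 1L) stop("JASPAR parse error: nucleotide rows have unequal widths")
  counts <- cbind(A = rows$A, C = rows$C, G = rows$G, T = rows$T)
  if (any(counts < 0) || anyNA(counts)) stop("JASPAR parse error: invalid count values")
  list(counts = counts, name = name)
}

.parseMeme <- function(lines) {
  name <- "motif"
  mo <- grep("^MOTIF\\b", lines)
  if (length(mo)) name <- trimws(sub("^MOTIF\\s*", "", lines[mo[1L]]))
  lp <- grep("^letter-probability matrix", lines)
  if (!length(lp)) {
    stop("MEME parse error: no 'letter-probability matrix' line found")
  }
  hdr <- lines[lp[1L]]
  getNum <- function(key, default) {
    m <- regmatches(hdr, regexec(paste0(key, "\\s*=\\s*([0-9.eE+-]+)"), hdr))[[1L]]
    if (length(m) == 2L) as.numeric(m[2L]) else default
  }
  w <- getNum("w", NA)
  nsites <- getNum("nsites", 20)
  alength <- getNum("alength", 4)
  if (!is.na(alength) && alength != 4) {
    stop("MEME parse error: alength must be 4 for nucleotide motifs")
  }
  rows <- list()
  for (ln in lines[-seq_len(lp[1L])]) {
    t <- trimws(ln)
    if (t == "") { if (length(rows)) break else next }
    if (grepl("^[0-9.eE+\\s-]+$", t, perl = TRUE)) {
      vals <- as.numeric(strsplit(t, "\\s+")[[1L]])
      if (length(vals) != 4L || anyNA(vals)) {
        stop("MEME parse error: probability row at line ",
             lp[1L] + length(rows) + 1L, " does not have 4 numeric fields")
      }
      rows[[length(rows) + 1L]] <- vals
    } else break
  }
  if (!length(rows)) stop("MEME parse error: no probability rows follow the header")
  if (!is.na(w) && length(rows) != w) {
    stop("MEME parse error: header states w=", w, " but ", length(rows), " rows found")
  }
  probs <- do.call(rbind, rows)  # MEME column order is A C G T
  colnames(probs) <- .ACGT
  list(counts = probs * nsites, name = name)
}

.parseTransfac <- function(lines) {
  name <- "motif"
  id <- grep("^(ID|NA)\\s+", lines)
  if (length(id)) name <- trimws(sub("^(ID|NA)\\s+", "", lines[id[1L]]))
  rows <- list()
  for (k in seq_along(lines)) {
    t <- trimws(lines[k])
    if (grepl("^[0-9]{2}\\s", t)) {
      f <- strsplit(t, "\\s+")[[1L]]
      if (length(f) < 5L) stop("TRANSFAC parse error at line ", k, ": expected 4 count columns")
      vals <- suppressWarnings(as.numeric(f[2:5]))
      if (anyNA(vals)) stop("TRANSFAC parse error at line ", k, ": non-numeric count")
      rows[[length(rows) + 1L]] <- vals
    }
  }
  if (!length(rows)) stop("TRANSFAC parse error: no numbered count rows (P0 block) found")
  counts <- do.call(rbind, rows)  # TRANSFAC column order is A C G T
  colnames(counts) <- .ACGT
  list(counts = counts, name = name)
}

#' Build a link-free MotifGraph from a count matrix
#'
#' Matrix motif formats (JASPAR, MEME, TRANSFAC) describe each position
#' independently, so the resulting graph carries nodes only: per-position
#' frequencies and information content, and an empty link list.
#'
#' @param cm a [MotifCounts-class], typically from [convertMatrix()].
#' @param id motif name; defaults to the name parsed from the matrix file.
#' @param correction apply the small-sample entropy correction (see
#'   [informationContent()]).
#' @return a [MotifGraph-class] with `nrow(motifLinks(.)) == 0`.
#' @export
countsToGraph <- function(cm, id = NULL, correction = TRUE) {
  stopifnot(is(cm, "MotifCounts"))
  if (is.null(id)) {
    id <- attr(cm, "motifName")
    if (is.null(id)) id <- "motif"
  }
  new("MotifGraph",
    id = as.character(id),
    background = cm@background,
    pseudocounts = cm@pseudocounts,
    nodes = buildNodes(cm, correction = correction),
    links = .emptyLinks(),
    alphabet = cm@alphabet
  )
}
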