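# JSON-Graph serialization. On disk, "background" and "pseudocounts" are in
# A,T,C,G order; nodes carry index/label/bit/base/freq with base and freq
# co-sorted ascending by frequency; links carry source/target/value.

#' Read a motif from a JSON-Graph file
#'
#' Parses and validates the JSON-Graph motif exchange format. The document
#' is a single object with keywords `id`, `background`, `pseudocounts`,
#' `nodes` and `links`. `background` and `pseudocounts` are arrays of four
#' values in A, T, C, G order; when either is missing it defaults to 0.25
#' per nucleotide (equal frequencies). Each node object carries `index`
#' (anticlockwise drawing order, 1-based), `label`, `bit` (information
#' content), and the four nucleotides in `base` sorted incrementally by
#' their frequencies in `freq`. Each link carries `source`, `target` and
#' `value` (dependency strength; drawn as ribbon width).
#'
#' Frequency vectors are accepted when they sum to 1 within 1e-5 (files
#' typically store rounded floats) and renormalized exactly.
#'
#' @param path path to a JSON-Graph file.
#' @return a [MotifGraph-class].
#' @export
#' @examples
#' g <- buildMotifGraph(MotifAlignment(c("ACGT", "ACGT", "ACTT")), B = 10)
#' f <- tempfile(fileext = ".json")
#' writeJsonGraph(g, f)
#' readJsonGraph(f)
readJsonGraph <- function(path) {
  if (!file.exists(path)) stop("JSON-Graph file not found: ", path)
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("malformed JSON in '", path, "': ", conditionMessage(e))
  )
  if (!is.list(doc)) stop("JSON-Graph schema error: top level must be an object")
  if (is.null(doc$nodes)) stop("JSON-Graph schema error: missing keyword 'nodes'")

  id <- if (is.null(doc$id)) "motif" else as.character(doc$id)

  bgDisk <- if (is.null(doc$background)) rep(0.25, 4L) else as.numeric(unlist(doc$background))
  psDisk <- if (is.null(doc$pseudocounts)) rep(0.25, 4L) else as.numeric(unlist(doc$pseudocounts))
  if (length(bgDisk) != 4L) stop("JSON-Graph schema error: 'background' must have 4 entries")
  if (length(psDisk) != 4L) stop("JSON-Graph schema error: 'pseudocounts' must have 4 entries")
  if (abs(sum(bgDisk) - 1) > 1e-5 || any(bgDisk < 0)) {
    stop("JSON-Graph schema error: 'background' must be non-negative and sum to 1")
  }
  bg <- bgDisk[.FROM_DISK]
  bg <- bg / sum(bg)
  ps <- psDisk[.FROM_DISK]

  nodes <- lapply(doc$nodes, function(nd) {
    for (k in c("index", "bit", "base", "freq")) {
      if (is.null(nd[[k]])) stop("JSON-Graph schema error: node missing keyword '", k, "'")
    }
    base <- toupper(as.character(unlist(nd$base)))
    freq <- as.numeric(unlist(nd$freq))
    if (length(base) != 4L || length(freq) != 4L) {
      stop("JSON-Graph schema error: 'base'/'freq' must have 4 entries")
    }
    if (abs(sum(freq) - 1) > 1e-5 || any(freq < 0)) {
      stop("JSON-Graph schema error: 'freq' must be non-negative and sum to 1")
    }
    freq <- freq / sum(freq)
    o <- order(freq, base)
    list(
      index = as.integer(nd$index),
      label = if (is.null(nd$label)) as.character(nd$index) else as.character(nd$label),
      bit = as.numeric(nd$bit),
      base = base[o], freq = freq[o]
    )
  })
  nodes <- nodes[order(vapply(nodes, `[[`, integer(1), "index"))]
  L <- length(nodes)
  idx <- vapply(nodes, `[[`, integer(1), "index")
  if (!identical(idx, seq_len(L))) {
    stop("JSON-Graph schema error: node 'index' values must be 1..", L)
  }

  links <- .emptyLinks()
  if (!is.null(doc$links) && length(doc$links)) {
    rows <- lapply(doc$links, function(lk) {
      for (k in c("source", "target", "value")) {
        if (is.null(lk[[k]])) stop("JSON-Graph schema error: link missing keyword '", k, "'")
      }
      s <- as.integer(lk$source); t <- as.integer(lk$target)
      if (s == t) stop("JSON-Graph schema error: link 'source' equals 'target'")
      if (min(s, t) < 1L || max(s, t) > L) {
        stop("JSON-Graph schema error: link endpoint ", max(s, t),
             " is not a valid node index (L = ", L, ")")
      }
      data.frame(
        source = min(s, t), target = max(s, t),
        value = as.numeric(lk$value), statistic = as.numeric(lk$value),
        p_value = NA_real_, metric = NA_character_, stringsAsFactors = FALSE
      )
    })
    links <- do.call(rbind, rows)
  }

  hasU <- any(vapply(nodes, function(nd) "U" %in% nd$base, logical(1)))
  new("MotifGraph",
    id = id, background = bg, pseudocounts = ps, nodes = nodes,
    links = links, alphabet = if (hasU) "RNA" else "DNA"
  )
}

#' Write a motif to a JSON-Graph file
#'
#' Serializes a validated [MotifGraph-class] using exactly the schema
#' keywords (`id`, `background`, `pseudocounts`, `nodes` with
#' `index`/`label`/`bit`/`base`/`freq`, `links` with
#' `source`/`target`/`value`). `background` and `pseudocounts` are emitted
#' in A, T, C, G order; nodes in ascending index order with `freq` ascending
#' and `base` co-sorted. Floats are written with 6 significant digits, so a
#' write/read round-trip agrees within 1e-6.
#'
#' @param graph a valid [MotifGraph-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeJsonGraph <- function(graph, path) {
  stopifnot(is(graph, "MotifGraph"))
  validObject(graph)  # refuse to serialize invariant-violating graphs
  doc <- list(
    id = jsonlite::unbox(graph@id),
    background = graph@background[.TO_DISK],
    pseudocounts = graph@pseudocounts[.TO_DISK],
    nodes = lapply(graph@nodes, function(nd) {
      list(
        index = jsonlite::unbox(as.integer(nd$index)),
        label = jsonlite::unbox(as.character(nd$label)),
        bit = jsonlite::unbox(as.numeric(nd$bit)),
        base = as.character(nd$base),
        freq = as.numeric(nd$freq)
      )
    }),
    links = lapply(seq_len(nrow(graph@links)), function(r) {
      list(
        source = jsonlite::unbox(as.integer(graph@links$source[r])),
        target = jsonlite::unbox(as.integer(graph@links$target[r])),
        value = jsonlite::unbox(as.numeric(graph@links$value[r]))
      )
    })
  )
  json <- jsonlite::toJSON(doc, digits = I(6), pretty = TRUE, na = "null")
  writeLines(json, path)
  invisible(path)
}
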