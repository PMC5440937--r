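# End-to-end pipeline: alignment -> MotifGraph, and the command-style
# wrappers behind the Rscript front end (inst/scripts/motifring.R).

#' Build a full motif graph from an alignment
#'
#' The FASTA-to-graph pipeline in one call: per-position counts with
#' pseudocounts, WebLogo-style stack heights, dependency links for every
#' position pair under the chosen metric, and optional significance /
#' percentile filtering.
#'
#' @param aln a [MotifAlignment-class].
#' @param id motif name stored in the graph.
#' @param metric `"chi2"` (default) or `"mi"`; see [buildLinks()].
#' @param pseudocounts,background four values each (A,C,G,T order);
#'   defaults 0.25 per nucleotide.
#' @param correction apply the small-sample information-content correction.
#' @param B permutations for the MI null (0 skips significance).
#' @param seed RNG seed for the permutation null.
#' @param alpha if non-NULL, retain only links with `p_value <= alpha`.
#' @param percentile if non-NULL, drop links below this lower value
#'   quantile (e.g. 0.33).
#' @param df chi-square degrees-of-freedom rule, see [chi2Q()].
#' @param bonferroni Bonferroni-adjust p-values over all pairs.
#' @return a [MotifGraph-class].
#' @export
#' @examples
#' aln <- simulateAlignment(L = 6, N = 60, dependentPairs = list(c(2, 5, 0.1)),
#'                          seed = 3)
#' g <- buildMotifGraph(aln, metric = "mi", B = 100, alpha = 0.05)
#' motifLinks(g)
buildMotifGraph <- function(aln, id = "motif", metric = c("chi2", "mi"),
                            pseudocounts = rep(0.25, 4L),
                            background = rep(0.25, 4L),
                            correction = TRUE, B = 1000L, seed = 1L,
                            alpha = NULL, percentile = NULL,
                            df = c("categories", "marginal"),
                            bonferroni = FALSE) {
  stopifnot(is(aln, "MotifAlignment"))
  metric <- match.arg(metric)
  df <- match.arg(df)
  cm <- buildCounts(aln, pseudocounts = pseudocounts, background = background)
  links <- buildLinks(aln, metric = metric, B = B, seed = seed, df = df,
                      bonferroni = bonferroni)
  if (!is.null(alpha)) links <- filterPvalue(links, alpha)
  if (!is.null(percentile) && percentile > 0) links <- filterPercentile(links, percentile)
  rownames(links) <- NULL
  new("MotifGraph",
    id = as.character(id),
    background = cm@background,
    pseudocounts = cm@pseudocounts,
    nodes = buildNodes(cm, correction = correction),
    links = links,
    alphabet = aln@alphabet
  )
}

#' Command wrappers: build, draw, convert, simulate
#'
#' Thin, file-to-file entry points used by the `motifring.R` command-line
#' script (under `system.file("scripts", package = "motifRing")`); each is
#' an ordinary function so the whole pipeline is scriptable from R too.
#'
#' * `cmdBuild()`: aligned FASTA in, JSON-Graph out (low-sample warnings go
#'   to the diagnostic stream, results only to the file).
#' * `cmdDraw()`: JSON-Graph in, SVG out, with optional p-value, lower
#'   percentile and focus-node link filters applied before rendering.
#' * `cmdConvert()`: JASPAR/MEME/TRANSFAC matrix in, link-free JSON-Graph
#'   out.
#' * `cmdSimulate()`: synthetic FASTA fixture out.
#'
#' @param fasta,graph,matrix,out input and output file paths.
#' @param id motif name (default: the input file's base name).
#' @param metric,alpha,percentile,B,seed,pseudocounts,background,correction,
#'   df,bonferroni see [buildMotifGraph()].
#' @param dialect matrix dialect for `cmdConvert`, see [convertMatrix()].
#' @param focusNode if non-NULL, draw only links touching this node.
#' @param spec a [layoutSpec()] for drawing.
#' @param L,N,profile,dependentPairs simulation parameters, see
#'   [simulateAlignment()].
#' @return the output path, invisibly.
#' @name commands
NULL

#' @rdname commands
#' @export
cmdBuild <- function(fasta, out, id = NULL, metric = c("chi2", "mi"),
                     alpha = NULL, percentile = NULL, B = 1000L, seed = 1L,
                     pseudocounts = rep(0.25, 4L), background = rep(0.25, 4L),
                     correction = TRUE, df = c("categories", "marginal"),
                     bonferroni = FALSE) {
  metric <- match.arg(metric)
  df <- match.arg(df)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(fasta))
  aln <- readFasta(fasta)
  g <- buildMotifGraph(aln, id = id, metric = metric,
                       pseudocounts = pseudocounts, background = background,
                       correction = correction, B = B, seed = seed,
                       alpha = alpha, percentile = percentile, df = df,
                       bonferroni = bonferroni)
  writeJsonGraph(g, out)
  invisible(out)
}

#' @rdname commands
#' @export
cmdDraw <- function(graph, out, alpha = NULL, percentile = NULL,
                    focusNode = NULL, spec = layoutSpec()) {
  g <- readJsonGraph(graph)
  if (!is.null(alpha)) g <- filterPvalue(g, alpha)
  if (!is.null(percentile) && percentile > 0) g <- filterPercentile(g, percentile)
  if (!is.null(focusNode)) g <- linksOfNode(g, focusNode)
  renderSvg(g, path = out, spec = spec)
  invisible(out)
}

#' @rdname commands
#' @export
cmdConvert <- function(matrix, out, dialect = c("jaspar", "meme", "transfac"),
                       id = NULL, pseudocounts = rep(0.25, 4L),
                       background = rep(0.25, 4L), correction = TRUE) {
  dialect <- match.arg(dialect)
  cm <- convertMatrix(matrix, dialect = dialect, pseudocounts = pseudocounts,
                      background = background)
  g <- countsToGraph(cm, id = id, correction = correction)
  writeJsonGraph(g, out)
  invisible(out)
}

#' @rdname commands
#' @export
cmdSimulate <- function(out, L = 20L, N = 200L, profile = rep(0.25, 4L),
                        dependentPairs = list(), seed = 1L) {
  aln <- simulateAlignment(L = L, N = N, profile = profile,
                           dependentPairs = dependentPairs, seed = seed)
  writeFasta(aln, out)
  invisible(out)
}
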