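# Circular SVG rendering: one sector per position arranged anticlockwise,
# a radially scaled letter stack per sector, and one chord ribbon per link
# with stroke width proportional to the dependency strength. Output is
# deterministic: identical inputs give byte-identical SVG.

#' Layout parameters for the circular logo
#'
#' @param radiusInner radius (user units) where dependency ribbons attach.
#' @param radiusOuter radius where letter stacks begin; must exceed
#'   `radiusInner`.
#' @param startAngle angle (degrees, mathematical convention: 0 = east,
#'   increasing anticlockwise) where the sector of node 1 begins.
#' @param gapAngle angular gap (degrees) between adjacent sectors.
#' @param bitScale radial length per bit of information content; a fully
#'   conserved stack (2 bits) extends `2 * bitScale` beyond `radiusOuter`.
#' @param ribbonWidthRange min and max ribbon stroke widths; link values
#'   are mapped affinely onto this range.
#' @param margin blank border around the drawing.
#' @param colors named vector of per-nucleotide fill colors.
#' @return a `LayoutSpec` list for [layoutSectors()] and [renderSvg()].
#' @export
layoutSpec <- function(radiusInner = 150, radiusOuter = 160, startAngle = 90,
                       gapAngle = 0.5, bitScale = 45,
                       ribbonWidthRange = c(0.6, 8), margin = 30,
                       colors = c(A = "#109648", C = "#255C99", G = "#F7B32B",
                                  T = "#D62839", U = "#D62839")) {
  stopifnot(radiusInner < radiusOuter, gapAngle >= 0,
            length(ribbonWidthRange) == 2L,
            ribbonWidthRange[1L] <= ribbonWidthRange[2L])
  structure(
    list(
      radiusInner = radiusInner, radiusOuter = radiusOuter,
      startAngle = startAngle, direction = "anticlockwise",
      gapAngle = gapAngle, bitScale = bitScale,
      ribbonWidthRange = ribbonWidthRange, margin = margin, colors = colors
    ),
    class = "LayoutSpec"
  )
}

#' Angular sector of every node
#'
#' Divides the full circle into `L` equal sectors separated by
#' `spec$gapAngle`: node 1 begins at `spec$startAngle` and successive
#' indexes proceed anticlockwise. `L * (sectorAngle + gapAngle)` is exactly
#' 360 degrees.
#'
#' @param graph a [MotifGraph-class].
#' @param spec a [layoutSpec()].
#' @return data.frame with `index`, `start`, `end`, `mid` (degrees); `end`
#'   and `mid` are greater than `start` (anticlockwise sweep).
#' @export
#' @examples
#' g <- buildMotifGraph(simulateAlignment(L = 4, N = 30, seed = 1), B = 0)
#' layoutSectors(g, layoutSpec(gapAngle = 0, startAngle = 0))
layoutSectors <- function(graph, spec = layoutSpec()) {
  stopifnot(is(graph, "MotifGraph"))
  L <- motifLength(graph)
  if (L == 0L) stop("cannot lay out an empty graph")
  slot <- 360 / L
  sector <- slot - spec$gapAngle
  if (sector <= 0) stop("gapAngle too large for ", L, " sectors")
  start <- spec$startAngle + (seq_len(L) - 1L) * slot
  data.frame(
    index = seq_len(L),
    start = start,
    end = start + sector,
    mid = start + sector / 2
  )
}

# polar (deg, math convention) to SVG coords; y axis points down on screen,
# so anticlockwise on screen means increasing math angle here
.polar <- function(cx, cy, r, deg) {
  th <- deg * pi / 180
  c(x = cx + r * cos(th), y = cy - r * sin(th))
}

.svgArcPath <- function(cx, cy, r, a0, a1) {
  p0 <- .polar(cx, cy, r, a0)
  p1 <- .polar(cx, cy, r, a1)
  large <- if (abs(a1 - a0) > 180) 1L else 0L
  # sweep 0 = anticlockwise on screen with y-down coordinates
  sprintf(
    "M %s %s A %s %s 0 %d 0 %s %s",
    .fmt(p0["x"]), .fmt(p0["y"]), .fmt(r), .fmt(r), large,
    .fmt(p1["x"]), .fmt(p1["y"])
  )
}

#' Render a motif graph as a circular logo in SVG
#'
#' Draws one letter stack per node (anticlockwise from `spec$startAngle`)
#' and one ribbon per link. Within a stack, letters are stacked radially in
#' ascending frequency order so the most frequent nucleotide sits
#' outermost; each letter's radial extent is its frequency share of the
#' node's information content times `spec$bitScale`, so the whole stack
#' spans `bit * bitScale`. Ribbons are quadratic chords between sector
#' midpoints at `radiusInner`, with stroke width affine in the link value
#' over `spec$ribbonWidthRange`. The output is well-formed SVG 1.1 and
#' byte-identical across repeated renders of the same input.
#'
#' @param graph a [MotifGraph-class].
#' @param path output file; `NULL` returns the SVG text without writing.
#' @param spec a [layoutSpec()].
#' @return the SVG document as a character scalar, invisibly when written.
#' @export
#' @examples
#' g <- buildMotifGraph(simulateAlignment(L = 6, N = 40, seed = 2), B = 0)
#' svg <- renderSvg(g)
#' substr(svg, 1, 60)
renderSvg <- function(graph, path = NULL, spec = layoutSpec()) {
  stopifnot(is(graph, "MotifGraph"))
  validObject(graph)
  sectors <- layoutSectors(graph, spec)
  size <- 2 * (spec$radiusOuter + 2 * spec$bitScale + spec$margin)
  cx <- size / 2
  cy <- size / 2
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(
      '<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%s" height="%s" viewBox="0 0 %s %s">',
      .fmt(size), .fmt(size), .fmt(size), .fmt(size)
    ),
    sprintf('<title>%s</title>', graph@id)
  )

  # ribbons under the stacks
  lk <- graph@links
  if (nrow(lk)) {
    v <- lk$value
    wmin <- spec$ribbonWidthRange[1L]
    wmax <- spec$ribbonWidthRange[2L]
    widths <- if (max(v) > min(v)) {
      wmin + (v - min(v)) / (max(v) - min(v)) * (wmax - wmin)
    } else {
      rep((wmin + wmax) / 2, length(v))
    }
    out <- c(out, '<g class="ribbons">')
    for (r in seq_len(nrow(lk))) {
      a <- sectors$mid[match(lk$source[r], sectors$index)]
      b <- sectors$mid[match(lk$target[r], sectors$index)]
      p0 <- .polar(cx, cy, spec$radiusInner, a)
      p1 <- .polar(cx, cy, spec$radiusInner, b)
      out <- c(out, sprintf(
        '<path class="ribbon" d="M %s %s Q %s %s %s %s" fill="none" stroke="#7a7a7a" stroke-opacity="0.55" stroke-width="%s"/>',
        .fmt(p0["x"]), .fmt(p0["y"]), .fmt(cx), .fmt(cy),
        .fmt(p1["x"]), .fmt(p1["y"]), .fmt(widths[r])
      ))
    }
    out <- c(out, '</g>')
  }

  # baseline circle between ribbon zone and stacks
  out <- c(out, sprintf(
    '<circle cx="%s" cy="%s" r="%s" fill="none" stroke="#c8c8c8" stroke-width="0.75"/>',
    .fmt(cx), .fmt(cy), .fmt(spec$radiusOuter)
  ))

  fontSize <- 10  # nominal; letters are rescaled to their radial extent
  for (k in seq_len(motifLength(graph))) {
    nd <- graph@nodes[[k]]
    mid <- sectors$mid[k]
    sectorSpan <- sectors$end[k] - sectors$start[k]
    # sector arc width at the stack base limits the letter's tangential size
    tangential <- 2 * spec$radiusOuter * sin(min(sectorSpan, 90) * pi / 360)
    out <- c(out, sprintf('<g class="stack" data-index="%d">', nd$index))
    r0 <- spec$radiusOuter
    for (b in seq_len(4L)) {   # ascending frequency: most frequent outermost
      extent <- nd$freq[b] * nd$bit * spec$bitScale
      if (extent <= 1e-9) next
      base <- nd$base[b]
      col <- spec$colors[[base]]
      if (is.null(col)) col <- "#444444"
      pos <- .polar(cx, cy, r0, mid)
      rot <- 90 - mid  # letter top points radially outward
      sx <- min(1.6, tangential / fontSize)
      sy <- extent / fontSize
      out <- c(out, sprintf(
        '<text class="letter" x="0" y="0" font-family="monospace" font-weight="bold" font-size="%s" fill="%s" text-anchor="middle" transform="translate(%s,%s) rotate(%s) scale(%s,%s)">%s</text>',
        .fmt(fontSize), col, .fmt(pos["x"]), .fmt(pos["y"]), .fmt(rot),
        .fmt(sx), .fmt(sy), base
      ))
      r0 <- r0 + extent
    }
    # position label just inside the baseline
    lab <- .polar(cx, cy, spec$radiusInner - 8, mid)
    out <- c(out, sprintf(
      '<text class="index-label" x="%s" y="%s" font-family="sans-serif" font-size="6" fill="#555555" text-anchor="middle">%s</text>',
      .fmt(lab["x"]), .fmt(lab["y"]), nd$label
    ), '</g>')
  }
  out <- c(out, '</svg>')
  svg <- paste(out, collapse = "\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(paste0(svg, "\n")), con)
    return(invisible(svg))
  }
  svg
}
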