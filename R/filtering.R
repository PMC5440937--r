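# Link filtering: significance threshold, lower-percentile removal and
# node restriction. Each filter accepts either a link data.frame or a whole
# MotifGraph (returning the same kind), is idempotent, and commutes with
# the others on fixed inputs.

.applyLinkFilter <- function(x, f) {
  if (is(x, "MotifGraph")) {
    x@links <- f(x@links)
    rownames(x@links) <- NULL
    return(x)
  }
  out <- f(x)
  rownames(out) <- NULL
  out
}

#' Filter links by significance
#'
#' Retains exactly the links with `p_value <= alpha`, preserving order.
#' Links whose p-value is `NA` (no null computed) are dropped.
#'
#' @param links a link data.frame or [MotifGraph-class].
#' @param alpha significance threshold in (0, 1].
#' @return the filtered links, same type as the input.
#' @export
filterPvalue <- function(links, alpha) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha <= 1)
  .applyLinkFilter(links, function(lk) lk[!is.na(lk$p_value) & lk$p_value <= alpha, , drop = FALSE])
}

#' Filter out the weakest links by value percentile
#'
#' Drops links whose `value` is strictly below the `lowerFraction` quantile
#' of all link values (linear-interpolation quantile); ties at the cutoff
#' are retained. `lowerFraction = 0.33` reproduces the "filter out the
#' lower 33% of links" rule used when drawing structured-RNA logos.
#'
#' @param links a link data.frame or [MotifGraph-class].
#' @param lowerFraction proportion in [0, 1) of weakest links to remove.
#' @return the filtered links, same type as the input.
#' @export
#' @examples
#' lk <- data.frame(source = 1, target = 2:101, value = 1:100,
#'                  statistic = 1:100, p_value = 0.5, metric = "mi")
#' nrow(filterPercentile(lk, 0.33))  # 67
filterPercentile <- function(links, lowerFraction) {
  stopifnot(is.numeric(lowerFraction), length(lowerFraction) == 1L,
            lowerFraction >= 0, lowerFraction < 1)
  .applyLinkFilter(links, function(lk) {
    if (nrow(lk) == 0L || lowerFraction == 0) return(lk)
    cut <- stats::quantile(lk$value, probs = lowerFraction, type = 7, names = FALSE)
    lk[lk$value >= cut, , drop = FALSE]
  })
}

#' Restrict links to those touching one node
#'
#' Keeps the links whose source or target equals `index` — the
#' non-interactive equivalent of clicking a stack to isolate its
#' dependencies.
#'
#' @param links a link data.frame or [MotifGraph-class].
#' @param index a node index.
#' @return the filtered links, same type as the input.
#' @export
linksOfNode <- function(links, index) {
  index <- as.integer(index)
  stopifnot(length(index) == 1L, index >= 1L)
  .applyLinkFilter(links, function(lk) lk[lk$source == index | lk$target == index, , drop = FALSE])
}
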