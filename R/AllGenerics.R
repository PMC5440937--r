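#' @rdname accessors
#' @export
setGeneric("nSequences", function(x) standardGeneric("nSequences"))

#' @rdname accessors
#' @export
setGeneric("motifLength", function(x) standardGeneric("motifLength"))

#' @rdname accessors
#' @export
setGeneric("alphabet", function(x) standardGeneric("alphabet"))

#' @rdname accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname accessors
#' @export
setGeneric("motifId", function(x) standardGeneric("motifId"))

#' @rdname accessors
#' @export
setGeneric("background", function(x) standardGeneric("background"))

#' @rdname accessors
#' @export
setGeneric("pseudocounts", function(x) standardGeneric("pseudocounts"))

#' @rdname accessors
#' @export
setGeneric("motifNodes", function(x) standardGeneric("motifNodes"))

#' @rdname accessors
#' @export
setGeneric("motifLinks", function(x) standardGeneric("motifLinks"))

#' @rdname accessors
#' @export
setGeneric("counts16", function(x) standardGeneric("counts16"))
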