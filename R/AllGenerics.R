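#' @rdname accessors
#' @export
setGeneric("assocWeights", function(x) standardGeneric("assocWeights"))

#' @rdname accessors
#' @export
setGeneric("unitLabels", function(x) standardGeneric("unitLabels"))

#' @rdname accessors
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' @rdname accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname accessors
#' @export
setGeneric("networkLevel", function(x) standardGeneric("networkLevel"))

#' @rdname accessors
#' @export
setGeneric("stateMatrix", function(x) standardGeneric("stateMatrix"))

#' @rdname accessors
#' @export
setGeneric("scanTimes", function(x) standardGeneric("scanTimes"))

#' @rdname accessors
#' @export
setGeneric("scanDays", function(x) standardGeneric("scanDays"))

#' @rdname accessors
#' @export
setGeneric("restingCounts", function(x) standardGeneric("restingCounts"))

#' @rdname accessors
#' @export
setGeneric("modelScores", function(x) standardGeneric("modelScores"))

#' @rdname accessors
#' @export
setGeneric("testResults", function(x) standardGeneric("testResults"))
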