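#' Accessors for herdsync objects
#'
#' Small accessor functions for the package's S4 containers; use these
#' instead of reaching into slots.
#'
#' @param x an object of the documented class.
#' @return The slot contents: matrices, character vectors or numeric
#'   vectors as documented per accessor.
#' @name accessors
NULL

#' @rdname accessors
setMethod("assocWeights", "AssociationNetwork", function(x) x@weights)

#' @rdname accessors
setMethod("unitLabels", "AssociationNetwork", function(x) x@unitOf)

#' @rdname accessors
setMethod("unitLabels", "Society", function(x) x@unitOf)

#' @rdname accessors
setMethod("individualIds", "AssociationNetwork", function(x) rownames(x@weights))

#' @rdname accessors
setMethod("individualIds", "Society", function(x) x@ids)

#' @rdname accessors
setMethod("individualIds", "StateMatrix", function(x) x@ids)

#' @rdname accessors
setMethod("isNormalized", "AssociationNetwork", function(x) x@normalized)

#' @rdname accessors
setMethod("networkLevel", "AssociationNetwork", function(x) x@level)

#' @rdname accessors
setMethod("stateMatrix", "StateMatrix", function(x) x@states)

#' @rdname accessors
setMethod("stateMatrix", "SimResult", function(x) x@stateMatrix)

#' @rdname accessors
setMethod("scanTimes", "StateMatrix", function(x) x@times)

#' @rdname accessors
setMethod("scanDays", "StateMatrix", function(x) x@day)

#' @rdname accessors
setMethod("restingCounts", "StateMatrix", function(x)
  as.integer(rowSums(x@states == 1L, na.rm = TRUE)))

#' @rdname accessors
setMethod("modelScores", "EvalReport", function(x) x@scores)

#' @rdname accessors
setMethod("testResults", "EvalReport", function(x) x@results)

setMethod("show", "SocietyConfig", function(object) {
  cat("SocietyConfig:", object@nIndividuals, "individuals in",
      object@nUnits, "units\n")
  cat(sprintf("  spread %.2g m within units, %.3g m between units\n",
              object@intraUnitSpread, object@interUnitScale))
  cat(sprintf("  %d day(s) of %d min, scans every %d min (%d scans/day), seed %d\n",
              object@nDays, object@dayLength, object@scanInterval,
              object@dayLength %/% object@scanInterval, object@seed))
})

setMethod("show", "Society", function(object) {
  cat("Society:", length(object@ids), "individuals in",
      length(unique(object@unitOf)), "units\n")
})

setMethod("show", "DistanceHistogram", function(object) {
  cat(sprintf("DistanceHistogram: %d bins of width %.3g m, %d distances, max edge %.3g m\n",
              length(object@counts), object@binWidth, sum(object@counts),
              max(object@edges)))
})

setMethod("show", "ThresholdResult", function(object) {
  cat(sprintf("ThresholdResult: threshold %.3g m (nadir bin %d), peaks at bins %d and %d, p2 = %.3g m\n",
              object@threshold, object@nadirBin, object@firstPeakBin,
              object@secondPeakBin, object@p2))
})

setMethod("show", "AssociationNetwork", function(object) {
  n <- nrow(object@weights)
  cat(sprintf("AssociationNetwork: %d individuals, %d units, level '%s'%s\n",
              n, length(unique(object@unitOf)), object@level,
              if (object@normalized) ", row-normalized (row sums = N)" else ""))
})

setMethod("show", "StateMatrix", function(object) {
  cat(sprintf("StateMatrix: %d scans x %d individuals over %d day(s)\n",
              nrow(object@states), ncol(object@states),
              length(unique(object@day))))
})

setMethod("show", "ModelParams", function(object) {
  cat("ModelParams (destination-state indexed):\n")
  cat(sprintf("  -> resting: lambda %.3g /min, C %.3g, refractory %g min\n",
              object@lambdaR, object@cR, object@t01R))
  cat(sprintf("  -> moving : lambda %.3g /min, C %.3g, refractory %g min\n",
              object@lambdaM, object@cM, object@t01M))
  cat(sprintf("  N = %d, initial resting fraction %.2g, dt = %g min\n",
              object@nAgents, object@initRestingFraction, object@dt))
})

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec '%s' (level %s, %s)%s\n", object@name, object@level,
              if (object@proportional) "proportional" else "absolute",
              if (object@social) ", requires a network" else ""))
})

setMethod("show", "SimResult", function(object) {
  cat(sprintf("SimResult: %d scans, %d agents, seed %d%s\n",
              nrow(object@stateMatrix@states), ncol(object@stateMatrix@states),
              object@seed,
              if (nrow(object@trace)) ", per-minute trace kept" else ""))
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport (null model:", object@null, ")\n")
  wide <- tryCatch(evalReportTable(object), error = function(e) NULL)
  if (!is.null(wide)) print(wide, digits = 3, row.names = FALSE)
})
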