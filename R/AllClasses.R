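#' @import methods
NULL

#' Configuration of a synthetic multilevel society
#'
#' Describes the society and the scan-sampling design that the synthetic
#' generator emulates: a herd of \code{nIndividuals} horses partitioned into
#' \code{nUnits} harem-like units, observed by positional scans every
#' \code{scanInterval} minutes over a \code{dayLength}-minute day for
#' \code{nDays} days.
#'
#' @slot nUnits integer, number of social units in the herd.
#' @slot nIndividuals integer, total herd size (unit sizes are adjusted to
#'   hit this total exactly).
#' @slot unitSizeMean numeric, mean of the truncated-Poisson unit-size draw.
#' @slot intraUnitSpread numeric, metres; SD of member offsets around the
#'   unit centre.
#' @slot interUnitScale numeric, metres; characteristic inter-unit distance.
#'   The pooled inter-unit distance distribution peaks near this value.
#' @slot dayLength integer, minutes of observation per day.
#' @slot scanInterval integer, minutes between scans; must divide
#'   \code{dayLength}.
#' @slot nDays integer, number of observation days.
#' @slot seed integer, master seed; all randomness in the generator flows
#'   from it through derived child seeds.
#' @exportClass SocietyConfig
setClass("SocietyConfig",
  slots = c(
    nUnits = "integer", nIndividuals = "integer", unitSizeMean = "numeric",
    intraUnitSpread = "numeric", interUnitScale = "numeric",
    dayLength = "integer", scanInterval = "integer", nDays = "integer",
    seed = "integer"
  )
)

setValidity("SocietyConfig", function(object) {
  msg <- character()
  counts <- c(
    nUnits = object@nUnits, nIndividuals = object@nIndividuals,
    dayLength = object@dayLength, scanInterval = object@scanInterval,
    nDays = object@nDays
  )
  if (any(is.na(counts)) || any(counts < 1L))
    msg <- c(msg, "all counts (nUnits, nIndividuals, dayLength, scanInterval, nDays) must be >= 1")
  if (!is.na(object@nIndividuals) && !is.na(object@nUnits) &&
      object@nIndividuals < object@nUnits)
    msg <- c(msg, "nIndividuals must be >= nUnits (every unit has at least one member)")
  if (object@unitSizeMean <= 0 || object@intraUnitSpread <= 0 ||
      object@interUnitScale <= 0)
    msg <- c(msg, "unitSizeMean, intraUnitSpread and interUnitScale must be > 0")
  if (!any(is.na(counts)) && object@dayLength %% object@scanInterval != 0L)
    msg <- c(msg, "scanInterval must divide dayLength")
  if (is.na(object@seed))
    msg <- c(msg, "seed must be a finite integer")
  if (length(msg)) msg else TRUE
})

#' A synthetic society: individuals and their unit membership
#'
#' @slot ids character, ordered individual identifiers (unique).
#' @slot unitOf named character, unit label per individual (names = ids).
#' @exportClass Society
setClass("Society", slots = c(ids = "character", unitOf = "character"))

setValidity("Society", function(object) {
  msg <- character()
  if (anyDuplicated(object@ids)) msg <- c(msg, "individual ids must be unique")
  if (!identical(names(object@unitOf), object@ids))
    msg <- c(msg, "unitOf must be named by ids, in the same order")
  if (anyNA(object@unitOf)) msg <- c(msg, "every individual needs a unit label")
  if (length(msg)) msg else TRUE
})

#' Histogram of inter-individual distances
#'
#' Bins are anchored at zero with edges k * binWidth (k = 0, 1, 2, ...), so
#' bin k spans ((k-1) * binWidth, k * binWidth].
#'
#' @slot binWidth numeric, metres.
#' @slot counts integer, per-bin counts.
#' @slot edges numeric, bin edges in metres; length = length(counts) + 1.
#' @exportClass DistanceHistogram
setClass("DistanceHistogram",
  slots = c(binWidth = "numeric", counts = "integer", edges = "numeric")
)

setValidity("DistanceHistogram", function(object) {
  msg <- character()
  if (object@binWidth <= 0) msg <- c(msg, "binWidth must be > 0")
  if (length(object@edges) != length(object@counts) + 1L)
    msg <- c(msg, "edges must have length(counts) + 1 entries")
  if (any(object@counts < 0L)) msg <- c(msg, "counts must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Nadir threshold extracted from a bimodal distance histogram
#'
#' @slot threshold numeric, metres; upper edge of the nadir bin, used as the
#'   association cut-off.
#' @slot firstPeakBin,secondPeakBin,nadirBin integer, 1-based bin indices.
#' @slot p2 numeric, metres; upper edge of the second peak bin (used by the
#'   isolated-individual rescue rule).
#' @exportClass ThresholdResult
setClass("ThresholdResult",
  slots = c(
    threshold = "numeric", firstPeakBin = "integer",
    secondPeakBin = "integer", nadirBin = "integer", p2 = "numeric"
  )
)

setValidity("ThresholdResult", function(object) {
  msg <- character()
  if (!(object@firstPeakBin < object@nadirBin &&
        object@nadirBin < object@secondPeakBin))
    msg <- c(msg, "need firstPeakBin < nadirBin < secondPeakBin")
  if (!(object@threshold > 0 && object@threshold < object@p2))
    msg <- c(msg, "need 0 < threshold < p2")
  if (length(msg)) msg else TRUE
})

#' Association network between individuals
#'
#' Square nonnegative weight matrix with zero diagonal. Row i holds the
#' influence weights a_ik of every other individual k on i. After
#' normalization each row's off-diagonal sum equals N, i.e. the average
#' weight is 1. A unit-level network zeroes all inter-unit weights and is
#' not re-normalized.
#'
#' @slot weights numeric matrix, N x N, dimnames = ids.
#' @slot unitOf named character, unit label per individual.
#' @slot normalized logical flag.
#' @slot level character, "herd" or "unit".
#' @exportClass AssociationNetwork
setClass("AssociationNetwork",
  slots = c(
    weights = "matrix", unitOf = "character", normalized = "logical",
    level = "character"
  )
)

setValidity("AssociationNetwork", function(object) {
  msg <- character()
  w <- object@weights
  if (nrow(w) != ncol(w)) msg <- c(msg, "weights must be square")
  if (is.null(rownames(w)) || !identical(rownames(w), colnames(w)))
    msg <- c(msg, "weights must carry identical row and column names (ids)")
  if (any(w < 0)) msg <- c(msg, "weights must be nonnegative")
  if (any(diag(w) != 0)) msg <- c(msg, "diagonal must be zero")
  if (!identical(names(object@unitOf), rownames(w)))
    msg <- c(msg, "unitOf must be named by the ids, in matrix order")
  if (!object@level %in% c("herd", "unit"))
    msg <- c(msg, "level must be 'herd' or 'unit'")
  if (isTRUE(object@normalized) && object@level == "herd" && nrow(w) > 1) {
    if (any(abs(rowSums(w) - nrow(w)) > 1e-9))
      msg <- c(msg, "normalized herd network rows must sum to N (tol 1e-9)")
  }
  if (object@level == "unit" && nrow(w) > 1) {
    diffUnit <- outer(object@unitOf, object@unitOf, "!=")
    if (any(w[diffUnit] != 0))
      msg <- c(msg, "unit-level network must have zero inter-unit weights")
  }
  if (length(msg)) msg else TRUE
})

#' Binary behavioural state record at scan resolution
#'
#' Rows are scans (possibly across several days), columns are individuals.
#' States are coded 1 = resting, 0 = moving, NA = not observed in that scan.
#'
#' @slot states integer matrix, scans x N with values 0/1/NA.
#' @slot times numeric, minutes within the day, strictly increasing within
#'   each day.
#' @slot day integer, day label per scan.
#' @slot ids character, individual identifiers (column names of states).
#' @exportClass StateMatrix
setClass("StateMatrix",
  slots = c(
    states = "matrix", times = "numeric", day = "integer", ids = "character"
  )
)

setValidity("StateMatrix", function(object) {
  msg <- character()
  s <- object@states
  if (length(object@times) != nrow(s) || length(object@day) != nrow(s))
    msg <- c(msg, "times and day must have one entry per scan row")
  if (length(object@ids) != ncol(s))
    msg <- c(msg, "ids must have one entry per column")
  vals <- s[!is.na(s)]
  if (length(vals) && !all(vals %in% c(0L, 1L)))
    msg <- c(msg, "states must be 0, 1 or NA")
  for (d in unique(object@day)) {
    td <- object@times[object@day == d]
    if (length(td) > 1 && any(diff(td) <= 0)) {
      msg <- c(msg, sprintf("times must be strictly increasing within day %s", d))
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Parameters of the mimetic state-change model
#'
#' All rate-like parameters are per-minute probabilities and all times are
#' minutes. Parameters are indexed by the destination state: the "R" member
#' governs transitions into resting (used by moving agents) and the "M"
#' member transitions into moving (used by resting agents). With the field
#' estimates, a resting agent is therefore subject to the 25-minute
#' refractory cap and a moving agent to the 50-minute one.
#'
#' @slot lambdaR,lambdaM numeric, baseline per-minute probability of an
#'   individual starting to rest / to move (lambda_s = Psi1_s / N).
#' @slot cR,cM numeric, mimetic coefficients (per individual already in the
#'   destination state, or per unit of network weight in the social models).
#' @slot t01R,t01M numeric, minutes; refractory periods Delta-T01 for the
#'   destination state; on expiry the agent switches deterministically.
#' @slot nAgents integer, herd size N.
#' @slot initRestingFraction numeric in [0, 1], fraction resting at the
#'   start of a simulated day.
#' @slot dt numeric, minutes per simulation step.
#' @exportClass ModelParams
setClass("ModelParams",
  slots = c(
    lambdaR = "numeric", lambdaM = "numeric", cR = "numeric", cM = "numeric",
    t01R = "numeric", t01M = "numeric", nAgents = "integer",
    initRestingFraction = "numeric", dt = "numeric"
  )
)

setValidity("ModelParams", function(object) {
  msg <- character()
  probs <- c(object@lambdaR, object@lambdaM)
  if (any(probs < 0 | probs > 1))
    msg <- c(msg, "lambdaR and lambdaM must be probabilities in [0, 1]")
  if (object@cR < 0 || object@cM < 0)
    msg <- c(msg, "mimetic coefficients must be >= 0")
  if (object@t01R <= 0 || object@t01M <= 0)
    msg <- c(msg, "refractory periods must be > 0")
  if (object@nAgents < 1L) msg <- c(msg, "nAgents must be >= 1")
  if (object@initRestingFraction < 0 || object@initRestingFraction > 1)
    msg <- c(msg, "initRestingFraction must lie in [0, 1]")
  if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
  if (length(msg)) msg else TRUE
})

#' Which synchronization hypothesis to simulate
#'
#' The seven hypotheses: "independent" (null), "anonymous_abs",
#' "anonymous_prop", "unit_abs", "unit_prop", "herd_abs", "herd_prop".
#' Social hypotheses (unit/herd) require an \linkS4class{AssociationNetwork}
#' of the matching level.
#'
#' @slot name character, one of the seven model names.
#' @slot social logical, does the model read the association network.
#' @slot proportional logical, proportional (ratio) versus absolute drive.
#' @slot level character, "none", "anonymous", "unit" or "herd".
#' @exportClass ModelSpec
setClass("ModelSpec",
  slots = c(
    name = "character", social = "logical", proportional = "logical",
    level = "character"
  )
)

setValidity("ModelSpec", function(object) {
  if (!object@name %in% modelNames())
    return(sprintf("unknown model '%s'; valid models: %s",
                   object@name, paste(modelNames(), collapse = ", ")))
  TRUE
})

#' Result of one simulated day
#'
#' @slot stateMatrix \linkS4class{StateMatrix} at scan resolution.
#' @slot restingPerMinute numeric, number of resting agents after each
#'   one-minute step.
#' @slot trace integer matrix, steps x N per-minute states (only filled when
#'   the day was run with \code{recordTrace = TRUE}; otherwise 0 x 0).
#' @slot seed integer, the seed the day was run with.
#' @exportClass SimResult
setClass("SimResult",
  slots = c(
    stateMatrix = "StateMatrix", restingPerMinute = "numeric",
    trace = "matrix", seed = "integer"
  )
)

#' Model-comparison report
#'
#' Per-model results of the four evaluation tests (two K-S tests on the
#' per-window state-change counts, a K-S test on intra-unit synchronization
#' rates, and a Mantel test on the dyadic synchronization-rate matrix),
#' plus the 0-1 score: the fraction of tests on which the model strictly
#' beats the independent null (lower D, higher r).
#'
#' @slot results data.frame with columns model, test, statistic, p, better.
#' @slot scores named numeric, score per model.
#' @slot null character, name of the null model.
#' @exportClass EvalReport
setClass("EvalReport",
  slots = c(results = "data.frame", scores = "numeric", null = "character")
)

setValidity("EvalReport", function(object) {
  need <- c("model", "test", "statistic", "p", "better")
  if (!all(need %in% names(object@results)))
    return(paste("results must have columns:", paste(need, collapse = ", ")))
  ok <- object@scores[!is.na(object@scores)]
  if (length(ok) && any(ok < 0 | ok > 1))
    return("scores must lie in [0, 1]")
  TRUE
})
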