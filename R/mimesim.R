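#' Names of the seven synchronization hypotheses
#'
#' @return Character vector: "independent" (null model), "anonymous_abs",
#'   "anonymous_prop", "unit_abs", "unit_prop", "herd_abs", "herd_prop".
#' @export
modelNames <- function() {
  c("independent", "anonymous_abs", "anonymous_prop",
    "unit_abs", "unit_prop", "herd_abs", "herd_prop")
}

#' Construct a model specification
#'
#' @param name one of \code{\link{modelNames}()}.
#' @return A \linkS4class{ModelSpec}.
#' @export
#' @examples
#' modelSpec("herd_abs")
modelSpec <- function(name) {
  if (!is.character(name) || length(name) != 1L || !name %in% modelNames())
    stop(sprintf("unknown model '%s'; valid models: %s",
                 paste(name, collapse = ","),
                 paste(modelNames(), collapse = ", ")), call. = FALSE)
  level <- switch(name,
    independent = "none",
    anonymous_abs = , anonymous_prop = "anonymous",
    unit_abs = , unit_prop = "unit",
    herd_abs = , herd_prop = "herd")
  new("ModelSpec", name = name, social = level %in% c("unit", "herd"),
      proportional = grepl("_prop$", name), level = level)
}

asModelSpec <- function(spec) {
  if (is(spec, "ModelSpec")) spec else modelSpec(spec)
}

#' Construct model parameters
#'
#' Defaults are the field estimates for the study herd, indexed by
#' destination state: entering resting has baseline rate
#' \code{lambdaR = 0.02/123} per minute (herd-level rate Psi1 = 0.02),
#' mimetic coefficient 0.426 and refractory period 50 min; entering moving
#' has \code{lambdaM = 0.04/123}, coefficient 0.796 and refractory 25 min.
#' A herd of N = 123 starts each day with 30\% of agents resting.
#'
#' @param lambdaR,lambdaM baseline per-minute probabilities lambda_s of one
#'   individual starting to rest / move (Psi1_s / N).
#' @param cR,cM mimetic coefficients.
#' @param t01R,t01M refractory periods in minutes.
#' @param nAgents herd size N.
#' @param initRestingFraction fraction resting at the start of a day.
#' @param dt minutes per simulation step.
#' @return A \linkS4class{ModelParams}.
#' @export
#' @examples
#' modelParams()
#' modelParams(nAgents = 20)
modelParams <- function(lambdaR = 0.02 / 123, lambdaM = 0.04 / 123,
                        cR = 0.426, cM = 0.796, t01R = 50, t01M = 25,
                        nAgents = 123, initRestingFraction = 0.3, dt = 1) {
  p <- new("ModelParams",
    lambdaR = lambdaR, lambdaM = lambdaM, cR = cR, cM = cM,
    t01R = t01R, t01M = t01M, nAgents = as.integer(nAgents),
    initRestingFraction = initRestingFraction, dt = dt)
  validObject(p)
  p
}

# Destination-state parameter lookup for agents currently in `state`.
.destParams <- function(state, params) {
  resting <- state == "resting"
  list(
    lambda = ifelse(resting, params@lambdaM, params@lambdaR),
    C = ifelse(resting, params@cM, params@cR),
    t01 = ifelse(resting, params@t01M, params@t01R)
  )
}

#' Per-minute probability of an agent changing state
#'
#' Implements the refractory-capped mimetic rule. Writing s for the
#' destination state (the opposite of the agent's current state), the
#' probability is 1 once the time since the agent's last change reaches the
#' refractory period Delta-T01(s); before that it is
#' \code{min(1 / (t01 - dtSince), drive)}, clipped to [0, 1], where the
#' drive term depends on the hypothesis:
#' \itemize{
#'   \item independent: \code{lambda_s};
#'   \item anonymous absolute: \code{lambda_s + C * nDest};
#'   \item anonymous proportional: \code{lambda_s + C * nDest / nCur};
#'   \item social absolute: \code{lambda_s + C * wDest} with
#'     \code{wDest = sum of network weights a_ik over individuals k already
#'     in s};
#'   \item social proportional: \code{lambda_s + C * wDest / wCur}.
#' }
#' A zero proportional denominator makes the drive unbounded, so the
#' refractory cap term alone applies.
#'
#' All arguments are vectorized over agents.
#'
#' @param state "resting" or "moving" (current state of the agent).
#' @param dtSince minutes since the agent's last state change (>= 0).
#' @param spec a \linkS4class{ModelSpec} or model name.
#' @param params a \linkS4class{ModelParams}.
#' @param nDest,nCur counts of individuals in the destination / current
#'   state (anonymous models).
#' @param wDest,wCur the agent's summed network weights towards individuals
#'   in the destination / current state (social models).
#' @return Numeric vector of per-minute probabilities in [0, 1].
#' @export
#' @examples
#' # a moving agent 20 min after its last change, 10 herd members resting
#' transitionProbability("moving", 20, "anonymous_abs",
#'                       modelParams(), nDest = 10)
transitionProbability <- function(state, dtSince, spec, params,
                                  nDest = NULL, nCur = NULL,
                                  wDest = NULL, wCur = NULL) {
  spec <- asModelSpec(spec)
  stopifnot(is(params, "ModelParams"))
  if (any(dtSince < 0)) stop("dtSince must be >= 0")
  if (!all(state %in% c("resting", "moving")))
    stop("state must be 'resting' or 'moving'")
  dp <- .destParams(state, params)
  # mimetic term C * x, with C = 0 always killing the term (even when the
  # proportional denominator is zero and x is unbounded)
  mimetic <- function(C, x) ifelse(C == 0, 0, C * x)
  drive <- if (spec@level == "none") {
    dp$lambda
  } else if (spec@level == "anonymous") {
    if (is.null(nDest)) stop("anonymous models need nDest")
    if (spec@proportional) {
      if (is.null(nCur)) stop("proportional anonymous model needs nCur")
      dp$lambda + mimetic(dp$C, ifelse(nCur == 0, Inf, nDest / nCur))
    } else dp$lambda + mimetic(dp$C, nDest)
  } else {
    if (is.null(wDest)) stop("social models need wDest")
    if (spec@proportional) {
      if (is.null(wCur)) stop("proportional social models need wCur")
      dp$lambda + mimetic(dp$C, ifelse(wCur == 0, Inf, wDest / wCur))
    } else dp$lambda + mimetic(dp$C, wDest)
  }
  cap <- 1 / (dp$t01 - dtSince)
  psi <- ifelse(dtSince >= dp$t01, 1, pmin(cap, drive))
  pmin(pmax(psi, 0), 1)
}

# Vectorized per-step probabilities for a whole herd.
# resting: logical vector; dtSince: minutes since last change; W: weight
# matrix (rows = focal agent) for social specs, NULL otherwise.
.stepProbabilities <- function(resting, dtSince, spec, params, W = NULL) {
  n <- length(resting)
  state <- ifelse(resting, "resting", "moving")
  nR <- sum(resting)
  nM <- n - nR
  nDest <- ifelse(resting, nM, nR)
  nCur <- ifelse(resting, nR, nM)
  wDest <- wCur <- NULL
  if (spec@social) {
    wToResting <- as.vector(W %*% as.numeric(resting))
    wToMoving <- as.vector(W %*% as.numeric(!resting))
    wDest <- ifelse(resting, wToMoving, wToResting)
    wCur <- ifelse(resting, wToResting, wToMoving)
  }
  transitionProbability(state, dtSince, spec, params,
                        nDest = nDest, nCur = nCur,
                        wDest = wDest, wCur = wCur)
}

#' Simulate one day of herd state dynamics
#'
#' Runs the stochastic multi-agent model in one-minute steps over a
#' 540-minute day (both configurable). Updates are synchronous: all
#' transition probabilities are computed from the state at the start of a
#' step, then each agent performs an independent Bernoulli draw. At t = 0,
#' \code{round(initRestingFraction * N)} agents (the field average is 30\%,
#' so 37 of 123) are resting, chosen uniformly, and each agent's time since
#' its last state change is drawn uniformly on [0, t01(destination)) to
#' avoid an artificial mass switch when the refractory period first
#' expires. States are recorded every \code{scanInterval} minutes, giving
#' 18 scans for the default day.
#'
#' @param spec a \linkS4class{ModelSpec} or model name.
#' @param params a \linkS4class{ModelParams}.
#' @param network an \linkS4class{AssociationNetwork}; required by the
#'   social models, ignored otherwise.
#' @param seed integer seed for the day.
#' @param dayLength,scanInterval minutes.
#' @param recordTrace keep the full per-minute states x agents trace.
#' @return A \linkS4class{SimResult}.
#' @export
#' @examples
#' res <- runDay("anonymous_abs", modelParams(nAgents = 30), seed = 1)
#' stateMatrix(res)
runDay <- function(spec, params, network = NULL, seed = 1,
                   dayLength = 540, scanInterval = 30,
                   recordTrace = FALSE) {
  spec <- asModelSpec(spec)
  stopifnot(is(params, "ModelParams"))
  n <- params@nAgents
  W <- NULL
  ids <- sprintf("ind%03d", seq_len(n))
  if (spec@social) {
    if (is.null(network)) stop(sprintf("model '%s' requires a network", spec@name))
    W <- assocWeights(network)
    if (nrow(W) != n)
      stop(sprintf("network has %d individuals but params@nAgents = %d",
                   nrow(W), n))
    if (spec@level == "unit" && networkLevel(network) != "unit")
      stop("unit-level models need a unit-level network (see unitSubnetwork)")
    ids <- rownames(W)
  }
  nSteps <- as.integer(round(dayLength / params@dt))
  every <- as.integer(round(scanInterval / params@dt))
  scanSteps <- seq(every, nSteps, by = every)
  withSeed(seed, {
    resting <- logical(n)
    resting[sample.int(n, round(params@initRestingFraction * n))] <- TRUE
    t01dest <- ifelse(resting, params@t01M, params@t01R)
    dtSince <- runif(n, 0, t01dest)
    scanStates <- matrix(NA_integer_, length(scanSteps), n,
                         dimnames = list(NULL, ids))
    trace <- if (recordTrace)
      matrix(NA_integer_, nSteps, n, dimnames = list(NULL, ids))
    else matrix(integer(0), 0, 0)
    restingPerMinute <- numeric(nSteps)
    scanRow <- 0L
    for (step in seq_len(nSteps)) {
      psi <- .stepProbabilities(resting, dtSince, spec, params, W)
      switch <- runif(n) < psi
      resting <- xor(resting, switch)
      dtSince <- ifelse(switch, 0, dtSince + params@dt)
      restingPerMinute[step] <- sum(resting)
      if (recordTrace) trace[step, ] <- as.integer(resting)
      if (step %in% scanSteps) {
        scanRow <- scanRow + 1L
        scanStates[scanRow, ] <- as.integer(resting)
      }
    }
    sm <- new("StateMatrix", states = scanStates,
              times = scanSteps * params@dt,
              day = rep(1L, length(scanSteps)), ids = ids)
    new("SimResult", stateMatrix = sm, restingPerMinute = restingPerMinute,
        trace = trace, seed = as.integer(seed))
  })
}

#' Run independent replicate days of the simulator
#'
#' Replicate seeds are derived deterministically from the master seed, so
#' the list of results is order-stable and reproducible.
#'
#' @inheritParams runDay
#' @param nReps number of replicate days.
#' @param seed master seed.
#' @return A list of \linkS4class{SimResult} objects, length \code{nReps}.
#' @export
runReplicates <- function(spec, params, network = NULL, nReps = 100,
                          seed = 1, dayLength = 540, scanInterval = 30,
                          recordTrace = FALSE) {
  nReps <- assertCount(nReps, "nReps")
  seeds <- childSeeds(seed, nReps)
  lapply(seeds, function(s)
    runDay(spec, params, network = network, seed = s,
           dayLength = dayLength, scanInterval = scanInterval,
           recordTrace = recordTrace))
}
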