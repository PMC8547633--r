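#' Build a StateMatrix from a long scan table
#'
#' @param scans scan table with a filled \code{state} column
#'   ("resting"/"moving"; NA for unobserved).
#' @return A \linkS4class{StateMatrix} with rows ordered by (day, time) and
#'   columns by sorted individual id.
#' @export
stateMatrixFromScans <- function(scans) {
  scans <- validateScanTable(scans, requireState = TRUE)
  ids <- sort(unique(scans$individual_id))
  key <- paste(scans$day, scans$time_min, sep = "@")
  scanKey <- unique(data.frame(day = scans$day, time = scans$time_min,
                               key = key, stringsAsFactors = FALSE))
  scanKey <- scanKey[order(scanKey$day, scanKey$time), ]
  states <- matrix(NA_integer_, nrow(scanKey), length(ids),
                   dimnames = list(scanKey$key, ids))
  states[cbind(match(key, scanKey$key), match(scans$individual_id, ids))] <-
    ifelse(scans$state == "resting", 1L, 0L)
  new("StateMatrix", states = states, times = as.numeric(scanKey$time),
      day = as.integer(scanKey$day), ids = ids)
}

#' Dyadic synchronization-rate matrix
#'
#' For each dyad, the proportion of scans (in which both individuals were
#' observed) where the two were in the same behavioural state. Dyads never
#' co-observed are NA; the diagonal is NA.
#'
#' @param sm a \linkS4class{StateMatrix}.
#' @return Symmetric numeric matrix in [0, 1] with NA for never-co-observed
#'   dyads.
#' @export
syncRateMatrix <- function(sm) {
  stopifnot(is(sm, "StateMatrix"))
  x <- sm@states
  p <- !is.na(x)
  r <- (x == 1L) & p
  m <- (x == 0L) & p
  same <- crossprod(r) + crossprod(m)
  both <- crossprod(p)
  rate <- ifelse(both > 0, same / pmax(both, 1), NA_real_)
  diag(rate) <- NA_real_
  dimnames(rate) <- list(sm@ids, sm@ids)
  rate
}

# Maximal strictly monotone runs of a numeric sequence; returns a
# data.frame(start, end, direction) with direction +1 (increasing) or -1.
.monotoneRuns <- function(counts) {
  n <- length(counts)
  runs <- data.frame(start = integer(), end = integer(), direction = integer())
  if (n < 2L) return(runs)
  sgn <- sign(diff(counts))
  i <- 1L
  while (i <= n - 1L) {
    if (sgn[i] == 0) { i <- i + 1L; next }
    j <- i
    while (j < n - 1L && sgn[j + 1L] == sgn[i]) j <- j + 1L
    runs <- rbind(runs, data.frame(start = i, end = j + 1L,
                                   direction = sgn[i]))
    i <- j + 1L
  }
  runs
}

#' Detect collective synchronization phases
#'
#' A phase is a maximal strictly monotone run of the per-scan resting count
#' within one day: decreasing runs are resting-to-moving phases
#' (\code{"r_to_m"}, destination moving), increasing runs are
#' moving-to-resting phases (\code{"m_to_r"}, destination resting). The
#' day's first and last scan-to-scan changes are discounted (a run is
#' clipped off them and dropped if nothing remains), because a change seen
#' at the edge of the observation day cannot be attributed to a complete
#' phase. Runs must involve at least \code{minJoiners} individuals changing
#' per retained scan-to-scan step.
#'
#' @param sm a \linkS4class{StateMatrix}.
#' @param minJoiners minimum per-step count change for a run to count.
#' @return data.frame with columns \code{kind} ("r_to_m"/"m_to_r"),
#'   \code{destination} ("moving"/"resting"), \code{day}, \code{startScan},
#'   \code{endScan} (row indices into \code{sm}), \code{startTime},
#'   \code{endTime} (minutes).
#' @export
detectPhases <- function(sm, minJoiners = 1) {
  stopifnot(is(sm, "StateMatrix"))
  out <- list()
  rows <- seq_len(nrow(sm@states))
  for (d in unique(sm@day)) {
    sel <- rows[sm@day == d]
    counts <- as.numeric(rowSums(sm@states[sel, , drop = FALSE] == 1L,
                                 na.rm = TRUE))
    nd <- length(sel)
    runs <- .monotoneRuns(counts)
    if (!nrow(runs)) next
    # discount the day's first and last transitions
    runs$start <- pmax(runs$start, 2L)
    runs$end <- pmin(runs$end, nd - 1L)
    runs <- runs[runs$end > runs$start, , drop = FALSE]
    if (!nrow(runs)) next
    steps <- function(r) abs(diff(counts[r["start"]:r["end"]]))
    ok <- apply(runs, 1L, function(r) all(steps(r) >= minJoiners))
    runs <- runs[ok, , drop = FALSE]
    if (!nrow(runs)) next
    out[[length(out) + 1L]] <- data.frame(
      kind = ifelse(runs$direction < 0, "r_to_m", "m_to_r"),
      destination = ifelse(runs$direction < 0, "moving", "resting"),
      day = d,
      startScan = sel[runs$start], endScan = sel[runs$end],
      startTime = sm@times[sel[runs$start]],
      endTime = sm@times[sel[runs$end]],
      stringsAsFactors = FALSE
    )
  }
  if (!length(out))
    return(data.frame(kind = character(), destination = character(),
                      day = integer(), startScan = integer(),
                      endScan = integer(), startTime = numeric(),
                      endTime = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Per-phase joiner events: for each scan-to-scan step of the phase, the
# individuals switching to the destination state. Returns a data.frame
# (phase, window, count) plus imputed joiner times.
.phaseJoiners <- function(sm, phases, window) {
  if (!nrow(phases)) return(NULL)
  interval <- stats::median(unlist(lapply(split(sm@times, sm@day), diff)))
  if (!length(interval) || !is.finite(interval))
    stop("cannot infer the scan interval from a single-scan record")
  if (window %% interval != 0)
    stop(sprintf("window (%g min) must be a multiple of the scan interval (%g min)",
                 window, interval))
  res <- vector("list", nrow(phases))
  for (ph in seq_len(nrow(phases))) {
    p <- phases[ph, ]
    destVal <- if (p$destination == "resting") 1L else 0L
    scans <- p$startScan:p$endScan
    joiners <- integer(0); jtimes <- numeric(0); jwin <- integer(0)
    for (k in seq_len(length(scans) - 1L)) {
      before <- sm@states[scans[k], ]
      after <- sm@states[scans[k + 1L], ]
      switched <- !is.na(before) & !is.na(after) &
        before != destVal & after == destVal
      nj <- sum(switched)
      stepStart <- sm@times[scans[k]]
      win <- floor((stepStart - p$startTime) / window) + 1L
      joiners <- c(joiners, nj)
      if (nj > 0) {
        jtimes <- c(jtimes, stepStart + seq_len(nj) * (interval / nj))
        jwin <- c(jwin, rep(win, nj))
      }
    }
    nWin <- max(1L, ceiling((p$endTime - p$startTime) / window))
    winCount <- integer(nWin)
    stepWin <- floor((sm@times[scans[-length(scans)]] - p$startTime) / window) + 1L
    for (k in seq_along(joiners))
      winCount[stepWin[k]] <- winCount[stepWin[k]] + joiners[k]
    res[[ph]] <- list(phase = ph, kind = p$kind,
                      destination = p$destination,
                      windowCounts = winCount, joinerTimes = jtimes)
  }
  res
}

#' Per-window state-change counts after a phase start
#'
#' For each detected phase, counts the individuals switching to the phase's
#' destination state in each successive \code{window}-minute window from
#' the phase start (0-30, 30-60, ... minute windows).
#'
#' @param sm the \linkS4class{StateMatrix} the phases were detected in.
#' @param phases output of \code{\link{detectPhases}}.
#' @param window window length in minutes; must be a multiple of the scan
#'   interval.
#' @return data.frame with columns \code{kind}, \code{destination},
#'   \code{phase}, \code{window} (1-based index), \code{count}.
#' @export
deltaN <- function(sm, phases, window = 30) {
  pj <- .phaseJoiners(sm, phases, window)
  if (is.null(pj))
    return(data.frame(kind = character(), destination = character(),
                      phase = integer(), window = integer(),
                      count = integer()))
  do.call(rbind, lapply(pj, function(p)
    data.frame(kind = p$kind, destination = p$destination, phase = p$phase,
               window = seq_along(p$windowCounts), count = p$windowCounts,
               stringsAsFactors = FALSE)))
}

#' Latencies between consecutive phases (refractory samples)
#'
#' For consecutive phases within a day, the minutes between the end of one
#' phase and the start of the next, labelled by the later phase's
#' destination state. These are the samples the refractory period
#' Delta-T01 is estimated from.
#'
#' @inheritParams deltaN
#' @return data.frame with columns \code{kind} ("phase_start"),
#'   \code{destination}, \code{value} (minutes).
#' @export
phaseStartLatencies <- function(sm, phases) {
  out <- data.frame(kind = character(), destination = character(),
                    value = numeric())
  if (nrow(phases) < 2L) return(out)
  for (d in unique(phases$day)) {
    pd <- phases[phases$day == d, , drop = FALSE]
    pd <- pd[order(pd$startTime), , drop = FALSE]
    if (nrow(pd) < 2L) next
    lat <- pd$startTime[-1L] - pd$endTime[-nrow(pd)]
    out <- rbind(out, data.frame(kind = "phase_start",
                                 destination = pd$destination[-1L],
                                 value = lat, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Latencies between consecutive joiners within a phase
#'
#' Scan sampling only brackets a joiner's switch to within one scan
#' interval, so the k individuals switching within the same interval are
#' imputed evenly spaced times (interval / k apart). Gaps between
#' consecutive imputed joiner times -- within and across intervals of the
#' same phase -- form the samples the mimetic coefficient C is estimated
#' from (C = 1 / mean gap).
#'
#' @inheritParams deltaN
#' @return data.frame with columns \code{kind} ("joiner"),
#'   \code{destination}, \code{value} (minutes).
#' @export
joinerLatencies <- function(sm, phases, window = 30) {
  pj <- .phaseJoiners(sm, phases, window)
  out <- data.frame(kind = character(), destination = character(),
                    value = numeric())
  if (is.null(pj)) return(out)
  for (p in pj) {
    if (length(p$joinerTimes) < 2L) next
    out <- rbind(out, data.frame(kind = "joiner",
                                 destination = p$destination,
                                 value = diff(p$joinerTimes),
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
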