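# Shared fixtures and brute-force oracles, built in code at test time.

# Small two-unit scan table with hand-set geometry.
toyScanTable <- function() {
  # unit A: a1,a2 close together; unit B: b1,b2 50 m away
  rows <- expand.grid(scan = 1:3, id = c("a1", "a2", "b1", "b2"),
                      stringsAsFactors = FALSE)
  base <- c(a1 = 0, a2 = 1.5, b1 = 50, b2 = 51.5)
  data.frame(
    day = 1L, scan_id = paste0("s", rows$scan), time_min = rows$scan * 30,
    individual_id = rows$id, x_m = base[rows$id], y_m = 0,
    state = "moving", stringsAsFactors = FALSE
  )
}

# StateMatrix from a plain scans x individuals 0/1 matrix.
toyStateMatrix <- function(states, interval = 30, day = NULL) {
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  if (is.null(day)) day <- rep(1L, nrow(states))
  day <- as.integer(day)
  times <- stats::ave(seq_len(nrow(states)), day, FUN = seq_along) * interval
  ids <- sprintf("i%02d", seq_len(ncol(states)))
  colnames(states) <- ids
  new("StateMatrix", states = states, times = as.numeric(times),
      day = day, ids = ids)
}

# StateMatrix whose per-scan resting counts follow `counts` (one column per
# individual switched deterministically); used for phase-detection tests.
stateMatrixFromCounts <- function(counts, n = max(counts) + 1L, day = NULL) {
  states <- t(vapply(counts, function(k) c(rep(1L, k), rep(0L, n - k)),
                     integer(n)))
  toyStateMatrix(states, day = day)
}

# Brute-force two-sample K-S statistic: sup over all sample points of the
# ECDF difference.
bruteKS <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(p) mean(x <= p) - mean(y <= p), numeric(1))))
}

# Brute-force SRI recount straight from the definition.
bruteSRI <- function(assocs, id1, id2) {
  x <- yEither <- 0
  for (a in assocs) {
    p1 <- isTRUE(a$present[id1]); p2 <- isTRUE(a$present[id2])
    if (p1 || p2) yEither <- yEither + 1
    if (p1 && p2 && a$edges[id1, id2] == 1) x <- x + 1
  }
  if (yEither == 0) 0 else x / yEither
}

# Exhaustive monotone-run oracle: every maximal strictly monotone interval,
# then the day-edge clipping rule, by direct enumeration.
bruteMonotoneRuns <- function(counts) {
  n <- length(counts)
  isMono <- function(i, j, s) all(sign(diff(counts[i:j])) == s)
  out <- NULL
  for (s in c(-1, 1)) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (!isMono(i, j, s)) next
    maximal <- (i == 1L || !isMono(i - 1L, j, s)) &&
               (j == n || !isMono(i, j + 1L, s))
    if (!maximal) next
    ci <- max(i, 2L); cj <- min(j, n - 1L)
    if (cj > ci) out <- rbind(out, data.frame(start = ci, end = cj,
                                              direction = s))
  }
  if (is.null(out)) return(data.frame(start = integer(), end = integer(),
                                      direction = integer()))
  out[order(out$start), , drop = FALSE]
}

# All permutations of 1..n for the exhaustive Mantel oracle.
allPermsOracle <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in allPermsOracle(n - 1L))
    for (pos in 0:(n - 1L)) out[[length(out) + 1L]] <- append(p, n, pos)
  out
}

# One cached desk-scale model-recovery experiment per master seed, shared
# between the acceptance tests that look at scores and at sync separation.
recoveryCache <- new.env(parent = emptyenv())
recoveryRun <- function(masterSeed) {
  key <- as.character(masterSeed)
  if (is.null(recoveryCache[[key]])) {
    recoveryCache[[key]] <- runPipeline(
      config = societyConfig(nDays = 4, seed = masterSeed),
      truthModel = "herd_abs", nReps = 20, nPerm = 199, seed = masterSeed)
  }
  recoveryCache[[key]]
}
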