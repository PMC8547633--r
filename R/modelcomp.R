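#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs; the p-value
#' comes from the asymptotic two-sample K-S distribution (ties tolerated,
#' which makes the p approximate -- the model comparison only ranks the D
#' statistics).
#'
#' @param x,y numeric samples (non-empty).
#' @return List with \code{D} and \code{p}.
#' @export
#' @examples
#' ksTwoSample(c(1, 2, 3), c(2, 3, 4))  # D = 1/3
ksTwoSample <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  res <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(D = unname(res$statistic), p = res$p.value)
}

# All permutations of 1..n (n small), as a list.
.allPermutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- .allPermutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) for (pos in seq_len(n)) {
    k <- k + 1L
    out[[k]] <- append(p, n, after = pos - 1L)
  }
  out
}

#' Mantel test between two square similarity matrices
#'
#' Pearson correlation of the strictly-upper-triangle entries, with
#' significance from simultaneous row/column permutations of the second
#' matrix (one-sided, upper: p = (1 + number of permuted r >= observed r)
#' / (1 + nPerm)). NA dyads are excluded pairwise. With
#' \code{exact = TRUE} all n! permutations are enumerated instead and p is
#' the exact fraction of permutations (identity included) with r >= the
#' observed r.
#'
#' @param m1,m2 symmetric numeric matrices of identical shape and id order.
#' @param nPerm number of random permutations.
#' @param seed integer seed making the permutation draw reproducible.
#' @param exact enumerate all permutations (only feasible for tiny n).
#' @return List with \code{r}, \code{p} and \code{nPerm} used.
#' @export
mantelTest <- function(m1, m2, nPerm = 9999, seed = 1, exact = FALSE) {
  if (!is.matrix(m1) || !is.matrix(m2) || !all(dim(m1) == dim(m2)) ||
      nrow(m1) != ncol(m1))
    stop("m1 and m2 must be square matrices of identical shape")
  n <- nrow(m1)
  ut <- which(upper.tri(m1), arr.ind = TRUE)
  v1 <- m1[ut]
  corPair <- function(a, b) {
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3L || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0)
      return(NA_real_)
    stats::cor(a[ok], b[ok])
  }
  rObs <- corPair(v1, m2[ut])
  if (is.na(rObs)) stop("Mantel correlation undefined (constant or too-sparse matrices)")
  permuted <- function(p) m2[cbind(p[ut[, 1]], p[ut[, 2]])]
  if (exact) {
    perms <- .allPermutations(n)
    rs <- vapply(perms, function(p) corPair(v1, permuted(p)), numeric(1))
    p <- mean(rs >= rObs - 1e-12, na.rm = TRUE)
    return(list(r = rObs, p = p, nPerm = length(perms)))
  }
  rs <- withSeed(seed, vapply(seq_len(nPerm), function(k)
    corPair(v1, permuted(sample.int(n))), numeric(1)))
  p <- (1 + sum(rs >= rObs - 1e-12, na.rm = TRUE)) / (1 + nPerm)
  list(r = rObs, p = p, nPerm = nPerm)
}

# Pooled delta-n counts of one destination state over a list of phase sets.
.pooledDeltaN <- function(stateMats, kind, window = 30) {
  unlist(lapply(stateMats, function(sm) {
    phases <- detectPhases(sm)
    dn <- deltaN(sm, phases, window = window)
    dn$count[dn$kind == kind & dn$count > 0]
  }), use.names = FALSE)
}

# Intra-/inter-unit dyadic sync-rate values of one StateMatrix.
.syncByLevel <- function(sm, unitOf) {
  rate <- syncRateMatrix(sm)
  ids <- rownames(rate)
  same <- outer(unitOf[ids], unitOf[ids], "==")
  ut <- upper.tri(rate)
  list(intra = rate[ut & same][is.finite(rate[ut & same])],
       inter = rate[ut & !same][is.finite(rate[ut & !same])],
       matrix = rate)
}

#' Evaluate one simulated model against observed data
#'
#' Computes the four tests the model ranking is built on: (1) K-S between
#' pooled simulated and observed per-window state-change counts towards
#' moving (Delta-n_m, resting-to-moving phases); (2) the same towards
#' resting (Delta-n_r); (3) K-S between pooled simulated and observed
#' intra-unit dyadic synchronization rates; (4) Mantel correlation between
#' the across-replicate mean simulated synchronization-rate matrix and the
#' observed one. A Delta-n test with no phases on either side is reported
#' as NA.
#'
#' @param sims list of \linkS4class{SimResult} (or StateMatrix) replicates.
#' @param observed the observed \linkS4class{StateMatrix}.
#' @param unitOf named character of unit labels.
#' @param nPerm Mantel permutations.
#' @param seed seed for the Mantel permutation draw.
#' @param window Delta-n window length in minutes.
#' @return data.frame with columns \code{test}, \code{statistic}, \code{p}.
#' @export
evaluateModel <- function(sims, observed, unitOf, nPerm = 9999, seed = 1,
                          window = 30) {
  stopifnot(is(observed, "StateMatrix"))
  simMats <- lapply(sims, function(s) if (is(s, "SimResult")) stateMatrix(s) else s)
  if (any(vapply(simMats, function(m) ncol(m@states), 0L) !=
          ncol(observed@states)))
    stop("simulated and observed data must share the same individuals")
  ks <- function(simVals, obsVals) {
    if (!length(simVals) || !length(obsVals))
      return(list(D = NA_real_, p = NA_real_))
    ksTwoSample(simVals, obsVals)
  }
  obsPhases <- detectPhases(observed)
  obsDn <- deltaN(observed, obsPhases, window = window)
  ks1 <- ks(.pooledDeltaN(simMats, "r_to_m", window),
            obsDn$count[obsDn$kind == "r_to_m" & obsDn$count > 0])
  ks2 <- ks(.pooledDeltaN(simMats, "m_to_r", window),
            obsDn$count[obsDn$kind == "m_to_r" & obsDn$count > 0])
  obsSync <- .syncByLevel(observed, unitOf)
  simSync <- lapply(simMats, .syncByLevel, unitOf = unitOf)
  ks3 <- ks(unlist(lapply(simSync, `[[`, "intra")), obsSync$intra)
  meanSim <- Reduce(`+`, lapply(simSync, function(s) {
    m <- s$matrix; m[is.na(m)] <- 0; m
  })) / length(simSync)
  nOk <- Reduce(`+`, lapply(simSync, function(s) !is.na(s$matrix)))
  meanSim <- ifelse(nOk > 0, meanSim * length(simSync) / pmax(nOk, 1), NA_real_)
  mt <- mantelTest(obsSync$matrix, meanSim, nPerm = nPerm, seed = seed)
  data.frame(
    test = c("ks_delta_n_m", "ks_delta_n_r", "ks_sync_intra", "mantel_sync"),
    statistic = c(ks1$D, ks2$D, ks3$D, mt$r),
    p = c(ks1$p, ks2$p, ks3$p, mt$p),
    stringsAsFactors = FALSE
  )
}

#' Score models against the independent null
#'
#' A model beats the null on a K-S test by a strictly lower D and on the
#' Mantel test by a strictly higher r; ties are not better. The score is
#' the fraction of the four tests the model wins; tests missing (NA) on
#' either side are excluded from the denominator with a warning.
#'
#' @param reports named list of \code{\link{evaluateModel}} data.frames,
#'   one per model.
#' @param nullModel name of the null model inside \code{reports}.
#' @return An \linkS4class{EvalReport}.
#' @export
scoreModels <- function(reports, nullModel = "independent") {
  if (!nullModel %in% names(reports))
    stop("null model '", nullModel, "' not found in reports")
  null <- reports[[nullModel]]
  rows <- list(); scores <- numeric(0)
  for (model in names(reports)) {
    rep <- reports[[model]]
    better <- logical(nrow(rep))
    usable <- logical(nrow(rep))
    for (i in seq_len(nrow(rep))) {
      s <- rep$statistic[i]; s0 <- null$statistic[null$test == rep$test[i]]
      usable[i] <- is.finite(s) && length(s0) == 1L && is.finite(s0)
      if (!usable[i]) { better[i] <- NA; next }
      better[i] <- if (rep$test[i] == "mantel_sync") s > s0 else s < s0
    }
    if (!all(usable))
      warning(sprintf("model '%s': %d of %d tests missing; excluded from its score",
                      model, sum(!usable), length(usable)))
    scores[model] <- if (any(usable)) sum(better[usable]) / sum(usable)
                     else NA_real_
    rows[[model]] <- cbind(model = model, rep, better = better)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  new("EvalReport", results = res, scores = scores, null = nullModel)
}

#' Wide Table of an EvalReport
#'
#' One row per model with each test's statistic, p and win flag, plus the
#' score -- the layout the model ranking is usually read in.
#'
#' @param report an \linkS4class{EvalReport}.
#' @return data.frame, one row per model.
#' @export
evalReportTable <- function(report) {
  stopifnot(is(report, "EvalReport"))
  res <- report@results
  models <- unique(res$model)
  tests <- unique(res$test)
  out <- data.frame(model = models, stringsAsFactors = FALSE)
  for (tn in tests) {
    sub <- res[res$test == tn, ]
    i <- match(models, sub$model)
    out[[paste0(tn, "_stat")]] <- sub$statistic[i]
    out[[paste0(tn, "_p")]] <- sub$p[i]
    out[[paste0(tn, "_eval")]] <- ifelse(is.na(sub$better[i]), "",
                                         ifelse(sub$better[i], "+", "-"))
  }
  out$score <- unname(report@scores[models])
  out
}

#' Run the full synchronization-analysis pipeline
#'
#' Orchestrates the whole analysis: obtain observed scan data (either
#' supplied or synthesized under a ground-truth model), build the
#' proximity network from the scan positions, score the observed state
#' record, simulate every candidate model, evaluate each against the
#' observed data and score them against the independent null.
#'
#' When \code{scans} is NULL a synthetic observed data set is generated
#' from \code{config}: a society, its scan positions, the network derived
#' from those positions, and ground-truth states simulated under
#' \code{truthModel} -- a model-recovery experiment.
#'
#' @param scans optional observed scan table (with states) or path to its
#'   CSV.
#' @param unitOf optional named character of unit labels (or path to a
#'   unit CSV); required with \code{scans}.
#' @param config a \linkS4class{SocietyConfig} for the synthetic branch.
#' @param truthModel ground-truth model name for the synthetic branch.
#' @param params a \linkS4class{ModelParams} (nAgents adjusted to the
#'   data).
#' @param models character vector of model names to simulate and rank.
#' @param nReps replicate simulated days per model.
#' @param nPerm Mantel permutations.
#' @param seed master seed for simulation replicates and permutations.
#' @param estimateParams re-estimate refractory/mimetic parameters from the
#'   observed states before simulating (otherwise \code{params} is used as
#'   given).
#' @param outDir optional directory; when given, the report table (TSV),
#'   the report JSON and a run log with every seed and parameter are
#'   written there.
#' @return List of class \code{"herdsyncRun"}: \code{report}
#'   (\linkS4class{EvalReport}), \code{network}, \code{observed}
#'   (StateMatrix), \code{observedSync} (intra/inter rate samples),
#'   \code{simSync} (per-model pooled intra/inter rate samples),
#'   \code{params}, \code{seeds}.
#' @export
runPipeline <- function(scans = NULL, unitOf = NULL,
                        config = societyConfig(), truthModel = "herd_abs",
                        params = modelParams(), models = modelNames(),
                        nReps = 100, nPerm = 9999, seed = 1,
                        estimateParams = FALSE, outDir = NULL) {
  models <- vapply(models, function(m) asModelSpec(m)@name, "")
  if (!"independent" %in% models) models <- c("independent", models)
  if (is.null(scans)) {
    society <- generateSociety(config)
    positions <- generateScanPositions(society, config)
    unitOf <- unitLabels(society)
    fit <- buildNetwork(positions, unitOf = unitOf)
    params@nAgents <- length(individualIds(society))
    validObject(params)
    observed <- generateStateSeries(fit$network, truthModel, params, config)
  } else {
    if (is.character(scans)) scans <- readScanTable(scans)
    if (is.character(unitOf)) unitOf <- readUnitTable(unitOf)
    if (is.null(unitOf)) stop("observed scans need unit labels (unitOf)")
    scans <- validateScanTable(scans, requireState = TRUE)
    fit <- buildNetwork(scans, unitOf = unitOf)
    observed <- stateMatrixFromScans(scans)
    params@nAgents <- length(individualIds(observed))
    validObject(params)
  }
  if (estimateParams)
    params <- estimateParamsFromStates(observed, params@nAgents, params)
  herdNet <- fit$network
  unitNet <- unitSubnetwork(herdNet)
  seeds <- childSeeds(seed, length(models) + 1L)
  names(seeds) <- c(models, "mantel")
  reports <- list(); simSync <- list()
  scanInterval <- as.integer(round(stats::median(
    unlist(lapply(split(observed@times, observed@day), diff)))))
  dayLength <- max(observed@times)
  for (model in models) {
    spec <- modelSpec(model)
    net <- if (!spec@social) NULL
           else if (spec@level == "unit") unitNet else herdNet
    sims <- runReplicates(spec, params, network = net, nReps = nReps,
                          seed = seeds[[model]], dayLength = dayLength,
                          scanInterval = scanInterval)
    reports[[model]] <- evaluateModel(sims, observed, unitOf, nPerm = nPerm,
                                      seed = seeds[["mantel"]])
    sync <- lapply(sims, function(s) .syncByLevel(stateMatrix(s), unitOf))
    simSync[[model]] <- list(
      intra = unlist(lapply(sync, `[[`, "intra")),
      inter = unlist(lapply(sync, `[[`, "inter"))
    )
  }
  report <- scoreModels(reports, nullModel = "independent")
  obsSync <- .syncByLevel(observed, unitOf)
  run <- structure(list(
    report = report, network = herdNet, threshold = fit$threshold,
    observed = observed,
    observedSync = obsSync[c("intra", "inter")],
    simSync = simSync, params = params, seeds = seeds,
    networkSummary = fit$summary
  ), class = "herdsyncRun")
  if (!is.null(outDir)) writePipelineArtifacts(run, outDir, nReps, nPerm)
  run
}

writePipelineArtifacts <- function(run, outDir, nReps, nPerm) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  tab <- evalReportTable(run$report)
  utils::write.table(tab, file.path(outDir, "report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  p <- run$params
  jsonlite::write_json(
    list(scores = as.list(run$report@scores),
         results = run$report@results,
         networkSummary = run$networkSummary,
         params = list(lambdaR = p@lambdaR, lambdaM = p@lambdaM,
                       cR = p@cR, cM = p@cM, t01R = p@t01R, t01M = p@t01M,
                       nAgents = p@nAgents,
                       initRestingFraction = p@initRestingFraction),
         seeds = as.list(run$seeds), nReps = nReps, nPerm = nPerm),
    file.path(outDir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(NULL)
}

#' @export
print.herdsyncRun <- function(x, ...) {
  cat("herdsync pipeline run\n")
  show(x$network)
  cat(sprintf("observed: %d scans; intra-unit sync %.3f, inter-unit %.3f\n",
              nrow(x$observed@states), mean(x$observedSync$intra),
              mean(x$observedSync$inter)))
  show(x$report)
  invisible(x)
}
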