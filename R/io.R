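# Readers and writers for the package's plain-text interchange formats:
# scan CSV, unit CSV, network TSV (+ JSON sidecar) and params JSON.

scanTableColumns <- c("day", "scan_id", "time_min", "individual_id",
                      "x_m", "y_m")

validateScanTable <- function(scans, requireState = TRUE) {
  stopifnot(is.data.frame(scans))
  need <- scanTableColumns
  if (requireState) need <- c(need, "state")
  miss <- setdiff(need, names(scans))
  if (length(miss))
    stop("scan table is missing column(s): ", paste(miss, collapse = ", "))
  if (requireState) {
    st <- scans$state[!is.na(scans$state)]
    if (length(st) && !all(st %in% c("resting", "moving")))
      stop("state must be 'resting' or 'moving' (or NA)")
    if (!length(st))
      stop("scan table has no recorded states")
  }
  scans
}

#' Read and write scan tables
#'
#' The scan CSV holds one row per (scan, individual): \code{day},
#' \code{scan_id}, \code{time_min}, \code{individual_id}, \code{x_m},
#' \code{y_m} and \code{state} ("resting"/"moving", possibly NA).
#'
#' @param path CSV file path.
#' @param requireState insist on a filled state column.
#' @return \code{readScanTable}: the scan table data.frame.
#' @export
readScanTable <- function(path, requireState = FALSE) {
  scans <- utils::read.csv(path, stringsAsFactors = FALSE)
  validateScanTable(scans, requireState = requireState)
}

#' @rdname readScanTable
#' @param scans a scan table data.frame.
#' @export
writeScanTable <- function(scans, path) {
  validateScanTable(scans, requireState = FALSE)
  utils::write.csv(scans, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a unit-membership table
#'
#' @param path CSV with columns \code{individual_id}, \code{unit_id}.
#' @return Named character vector: unit label per individual id.
#' @export
readUnitTable <- function(path) {
  u <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("individual_id", "unit_id") %in% names(u)))
    stop("unit table needs columns individual_id and unit_id")
  stats::setNames(as.character(u$unit_id), u$individual_id)
}

#' Read and write association networks
#'
#' The network is stored as a TSV square matrix with an \code{id} column
#' and ids as the remaining headers, plus a JSON sidecar
#' (\code{<file>.json}) carrying the unit labels, normalization flag,
#' level, and any extra metadata (threshold, bin width, density).
#'
#' @param net an \linkS4class{AssociationNetwork}.
#' @param path TSV file path.
#' @param meta optional named list of extra metadata for the sidecar.
#' @return \code{readNetwork}: an \linkS4class{AssociationNetwork};
#'   \code{writeNetwork}: the path, invisibly.
#' @export
writeNetwork <- function(net, path, meta = list()) {
  stopifnot(is(net, "AssociationNetwork"))
  w <- assocWeights(net)
  df <- data.frame(id = rownames(w), w, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- c(list(unitOf = as.list(net@unitOf), normalized = net@normalized,
                 level = net@level), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeNetwork
#' @export
readNetwork <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df$id
  w <- as.matrix(df[, -1, drop = FALSE])
  rownames(w) <- ids
  storage.mode(w) <- "double"
  sidePath <- paste0(path, ".json")
  if (!file.exists(sidePath))
    stop("network sidecar not found: ", sidePath)
  side <- jsonlite::read_json(sidePath, simplifyVector = TRUE)
  new("AssociationNetwork", weights = w,
      unitOf = stats::setNames(as.character(unlist(side$unitOf)),
                               names(side$unitOf))[ids],
      normalized = isTRUE(side$normalized),
      level = side$level %||% "herd")
}

#' Read and write model parameters as JSON
#'
#' @param params a \linkS4class{ModelParams}.
#' @param path JSON file path.
#' @param model optional model name recorded alongside the parameters.
#' @param seed optional generating seed recorded alongside the parameters.
#' @return \code{readModelParams}: a list with \code{params}
#'   (\linkS4class{ModelParams}), \code{model} and \code{seed} (NULL when
#'   absent); \code{writeModelParams}: the path, invisibly.
#' @export
writeModelParams <- function(params, path, model = NULL, seed = NULL) {
  stopifnot(is(params, "ModelParams"))
  x <- list(
    lambda_r = params@lambdaR, lambda_m = params@lambdaM,
    c_r = params@cR, c_m = params@cM,
    t01_r = params@t01R, t01_m = params@t01M,
    n_agents = params@nAgents,
    init_resting_fraction = params@initRestingFraction,
    dt = params@dt
  )
  if (!is.null(model)) x$model <- model
  if (!is.null(seed)) x$seed <- seed
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeModelParams
#' @export
readModelParams <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- modelParams(
    lambdaR = x$lambda_r, lambdaM = x$lambda_m, cR = x$c_r, cM = x$c_m,
    t01R = x$t01_r, t01M = x$t01_m, nAgents = x$n_agents,
    initRestingFraction = x$init_resting_fraction, dt = x$dt
  )
  list(params = params, model = x$model, seed = x$seed)
}
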