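#' Create a synthetic-society configuration
#'
#' Defaults emulate the field system the package targets: a herd of 123
#' horses in 23 harem-like units, scanned every 30 minutes over a 540-minute
#' (9-hour) day. Unit members stay within roughly a metre of their unit
#' centre while unit centres are spread so the pooled inter-individual
#' distance distribution is bimodal with an intra-unit mode of 1-2 m and an
#' inter-unit mode near 50 m.
#'
#' @param nUnits number of units.
#' @param nIndividuals total herd size; unit sizes are adjusted to hit this
#'   total exactly.
#' @param unitSizeMean mean unit size for the truncated-Poisson draw;
#'   defaults to \code{nIndividuals / nUnits}.
#' @param intraUnitSpread metres, SD of member offsets around the unit centre.
#' @param interUnitScale metres, characteristic inter-unit distance (the
#'   inter-unit distance mode of the pooled histogram).
#' @param dayLength minutes of observation per day.
#' @param scanInterval minutes between scans; must divide \code{dayLength}.
#' @param nDays number of observation days.
#' @param seed master seed for every random draw in the generator.
#' @return A \linkS4class{SocietyConfig}.
#' @export
#' @examples
#' societyConfig()
#' societyConfig(nUnits = 1, nIndividuals = 1)
societyConfig <- function(nUnits = 23, nIndividuals = 123,
                          unitSizeMean = nIndividuals / nUnits,
                          intraUnitSpread = 1, interUnitScale = 50,
                          dayLength = 540, scanInterval = 30, nDays = 8,
                          seed = 1) {
  cfg <- try(new("SocietyConfig",
    nUnits = as.integer(nUnits), nIndividuals = as.integer(nIndividuals),
    unitSizeMean = as.numeric(unitSizeMean),
    intraUnitSpread = as.numeric(intraUnitSpread),
    interUnitScale = as.numeric(interUnitScale),
    dayLength = as.integer(dayLength), scanInterval = as.integer(scanInterval),
    nDays = as.integer(nDays), seed = as.integer(seed)
  ), silent = TRUE)
  if (inherits(cfg, "try-error"))
    stop("invalid society configuration: ", attr(cfg, "condition")$message,
         call. = FALSE)
  cfg
}

# One child seed per generator stage, so society structure, positions and
# state series are driven by independent streams of the same master seed.
.opSeed <- function(config, op = c("society", "positions", "states")) {
  op <- match.arg(op)
  childSeeds(config@seed, 3L)[match(op, c("society", "positions", "states"))]
}

#' Generate the individuals and units of a synthetic society
#'
#' Unit sizes are drawn from a Poisson distribution truncated at 1 around
#' \code{unitSizeMean} and then adjusted by single-member moves until the
#' total equals \code{nIndividuals}.
#'
#' @param config a \linkS4class{SocietyConfig}.
#' @return A \linkS4class{Society}.
#' @export
#' @examples
#' soc <- generateSociety(societyConfig())
#' length(individualIds(soc))         # 123
#' length(unique(unitLabels(soc)))    # 23
generateSociety <- function(config) {
  stopifnot(is(config, "SocietyConfig"))
  validObject(config)
  withSeed(.opSeed(config, "society"), {
    k <- config@nUnits
    sizes <- rpois(k, max(config@unitSizeMean - 1, 0)) + 1L
    total <- config@nIndividuals
    while (sum(sizes) < total) {
      i <- sample.int(k, 1L)
      sizes[i] <- sizes[i] + 1L
    }
    while (sum(sizes) > total) {
      eligible <- which(sizes > 1L)
      i <- eligible[sample.int(length(eligible), 1L)]
      sizes[i] <- sizes[i] - 1L
    }
    ids <- sprintf("ind%03d", seq_len(total))
    units <- rep(sprintf("unit%02d", seq_len(k)), times = sizes)
    new("Society", ids = ids, unitOf = stats::setNames(units, ids))
  })
}

#' Generate scan positions for a synthetic society
#'
#' For every scan each unit receives a fresh centre drawn from an isotropic
#' bivariate normal with per-axis SD \code{interUnitScale / sqrt(2)} (so
#' inter-unit distances follow a Rayleigh-like distribution whose mode is
#' \code{interUnitScale}), and members are placed around their centre with
#' per-axis SD \code{intraUnitSpread}. Units therefore drift between scans
#' and occasionally pass close to one another, while remaining internally
#' cohesive -- the pooled distance histogram is strongly bimodal.
#'
#' @param society a \linkS4class{Society}.
#' @param config the \linkS4class{SocietyConfig} used to generate it.
#' @return A scan table: \code{data.frame} with columns \code{day},
#'   \code{scan_id}, \code{time_min}, \code{individual_id}, \code{x_m},
#'   \code{y_m} and \code{state} (NA here; filled by
#'   \code{\link{generateStateSeries}} / \code{\link{makeFixtureDataset}}).
#' @export
generateScanPositions <- function(society, config) {
  stopifnot(is(society, "Society"), is(config, "SocietyConfig"))
  if (!length(society@ids)) stop("society is empty")
  validObject(society); validObject(config)
  nScans <- config@dayLength %/% config@scanInterval
  n <- length(society@ids)
  unitIdx <- match(society@unitOf, unique(society@unitOf))
  withSeed(.opSeed(config, "positions"), {
    out <- vector("list", config@nDays * nScans)
    r <- 0L
    for (d in seq_len(config@nDays)) {
      for (s in seq_len(nScans)) {
        r <- r + 1L
        centres <- matrix(rnorm(config@nUnits * 2,
                                sd = config@interUnitScale / sqrt(2)),
                          ncol = 2)
        offs <- matrix(rnorm(n * 2, sd = config@intraUnitSpread), ncol = 2)
        out[[r]] <- data.frame(
          day = d,
          scan_id = sprintf("d%02d_s%02d", d, s),
          time_min = s * config@scanInterval,
          individual_id = society@ids,
          x_m = centres[unitIdx, 1] + offs[, 1],
          y_m = centres[unitIdx, 2] + offs[, 2],
          state = NA_character_,
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, out)
  })
}

#' Generate a ground-truth state series under a named model
#'
#' Runs the stochastic simulator for \code{nDays} independent days under the
#' given hypothesis and stacks the scan-resolution records, providing the
#' "observed" data of a model-recovery experiment.
#'
#' @param network an \linkS4class{AssociationNetwork} (required by the
#'   social models; its ids define the agents).
#' @param spec a \linkS4class{ModelSpec} or model name.
#' @param params a \linkS4class{ModelParams}.
#' @param config a \linkS4class{SocietyConfig} (day length, scan interval,
#'   number of days, seed).
#' @return A \linkS4class{StateMatrix} with
#'   \code{nDays * dayLength / scanInterval} scan rows.
#' @export
generateStateSeries <- function(network, spec, params, config) {
  stopifnot(is(config, "SocietyConfig"))
  spec <- asModelSpec(spec)
  if (!is.null(network) && params@nAgents != nrow(assocWeights(network)))
    stop("network size does not match params@nAgents")
  seeds <- childSeeds(.opSeed(config, "states"), config@nDays)
  days <- lapply(seq_len(config@nDays), function(d) {
    res <- runDay(spec, params, network = network, seed = seeds[d],
                  dayLength = config@dayLength,
                  scanInterval = config@scanInterval)
    sm <- stateMatrix(res)
    sm@day <- rep(as.integer(d), nrow(sm@states))
    sm
  })
  do.call(rbindStateMatrices, days)
}

# Stack StateMatrix objects sharing the same individuals.
rbindStateMatrices <- function(...) {
  parts <- list(...)
  ids <- parts[[1]]@ids
  for (p in parts) stopifnot(identical(p@ids, ids))
  new("StateMatrix",
      states = do.call(rbind, lapply(parts, function(p) p@states)),
      times = unlist(lapply(parts, function(p) p@times)),
      day = unlist(lapply(parts, function(p) p@day)),
      ids = ids)
}

#' Write a complete synthetic fixture data set
#'
#' Generates a society, its scan positions, the proximity network derived
#' from those positions, and a ground-truth state series simulated under
#' \code{spec}, then writes three plain-text files into \code{outDir}:
#' \code{scans.csv} (scan table with states), \code{units.csv}
#' (individual-to-unit map) and \code{params.json} (the generating
#' parameters). The files round-trip through \code{\link{readScanTable}},
#' \code{\link{readUnitTable}} and \code{\link{readModelParams}}.
#'
#' @param config a \linkS4class{SocietyConfig}.
#' @param spec model name or \linkS4class{ModelSpec} used for the
#'   ground-truth states.
#' @param params a \linkS4class{ModelParams}; \code{nAgents} is overridden
#'   by the society size.
#' @param outDir output directory (created if missing).
#' @return Invisibly, a named character vector of the three file paths.
#' @export
makeFixtureDataset <- function(config, spec = "herd_abs",
                               params = modelParams(), outDir) {
  if (missing(outDir) || !is.character(outDir) || length(outDir) != 1L ||
      !nzchar(outDir))
    stop("'outDir' must be a non-empty directory path")
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("could not create output directory: ", outDir)
  spec <- asModelSpec(spec)
  society <- generateSociety(config)
  scans <- generateScanPositions(society, config)
  params@nAgents <- length(society@ids)
  validObject(params)
  fit <- buildNetwork(scans, unitOf = unitLabels(society))
  sm <- generateStateSeries(fit$network, spec, params, config)
  key <- paste(scans$day, scans$time_min, sep = "@")
  rowOf <- match(key, paste(sm@day, sm@times, sep = "@"))
  colOf <- match(scans$individual_id, sm@ids)
  scans$state <- c("moving", "resting")[sm@states[cbind(rowOf, colOf)] + 1L]
  paths <- c(
    scans = file.path(outDir, "scans.csv"),
    units = file.path(outDir, "units.csv"),
    params = file.path(outDir, "params.json")
  )
  writeScanTable(scans, paths[["scans"]])
  utils::write.csv(
    data.frame(individual_id = society@ids,
               unit_id = unname(society@unitOf)),
    paths[["units"]], row.names = FALSE, quote = FALSE)
  writeModelParams(params, paths[["params"]], model = spec@name,
                   seed = config@seed)
  invisible(paths)
}
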