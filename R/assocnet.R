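#' Pairwise Euclidean distances within one scan
#'
#' @param scanRows data.frame with columns \code{individual_id}, \code{x_m},
#'   \code{y_m} for the individuals present in a single scan.
#' @return data.frame with columns \code{id1}, \code{id2}, \code{distance}
#'   (metres), one row per unordered pair; empty when fewer than two
#'   individuals are present.
#' @export
#' @examples
#' pairwiseDistances(data.frame(individual_id = c("a", "b"),
#'                              x_m = c(0, 3), y_m = c(0, 4)))  # 5 m
pairwiseDistances <- function(scanRows) {
  stopifnot(all(c("individual_id", "x_m", "y_m") %in% names(scanRows)))
  n <- nrow(scanRows)
  if (n < 2L)
    return(data.frame(id1 = character(), id2 = character(),
                      distance = numeric()))
  if (any(!is.finite(scanRows$x_m)) || any(!is.finite(scanRows$y_m)))
    stop("coordinates must be finite")
  d <- as.matrix(dist(scanRows[, c("x_m", "y_m")]))
  pair <- which(upper.tri(d), arr.ind = TRUE)
  data.frame(id1 = scanRows$individual_id[pair[, 1]],
             id2 = scanRows$individual_id[pair[, 2]],
             distance = d[pair])
}

#' Data-driven histogram bin width for the distance distribution
#'
#' Direct plug-in bandwidth selection (Wand's rule, via
#' \code{KernSmooth::dpih}), the standard data-driven choice for histogram
#' bin widths. The result is scale-equivariant: multiplying all distances
#' by a constant multiplies the width by the same constant. Supply your own
#' width to \code{\link{buildDistanceHistogram}} to override it.
#'
#' @param distances numeric vector of at least 10 distances.
#' @return Bin width in metres.
#' @export
chooseBinWidth <- function(distances) {
  distances <- distances[is.finite(distances)]
  if (length(distances) < 10L)
    stop("need at least 10 distances for plug-in bin-width selection; ",
         "pass an explicit binWidth instead")
  if (stats::sd(distances) == 0)
    stop("distances have zero variance; pass an explicit binWidth instead")
  KernSmooth::dpih(distances)
}

#' Build the inter-individual distance histogram
#'
#' Bins are anchored at zero with edges at integer multiples of
#' \code{binWidth}, so with the study's width of 0.92 m the 12th bin spans
#' 10.12-11.04 m (printed 10.1-11.0) and the 55th bin ends at 50.6 m.
#'
#' @param distances numeric vector of distances (metres, >= 0).
#' @param binWidth bin width in metres; defaults to
#'   \code{\link{chooseBinWidth}}.
#' @return A \linkS4class{DistanceHistogram}.
#' @export
buildDistanceHistogram <- function(distances, binWidth = NULL) {
  distances <- distances[is.finite(distances)]
  if (!length(distances)) stop("no distances to bin")
  if (any(distances < 0)) stop("distances must be >= 0")
  if (is.null(binWidth)) binWidth <- chooseBinWidth(distances)
  if (binWidth <= 0) stop("binWidth must be > 0")
  nBins <- max(1L, ceiling(max(distances) / binWidth))
  edges <- seq(0, by = binWidth, length.out = nBins + 1L)
  # bin k spans ((k-1) w, k w]; a distance of exactly 0 falls in bin 1
  bin <- pmax(ceiling(distances / binWidth), 1L)
  counts <- tabulate(bin, nbins = nBins)
  new("DistanceHistogram", binWidth = binWidth,
      counts = as.integer(counts), edges = edges)
}

#' Find the nadir threshold of a bimodal distance histogram
#'
#' The two peaks are the two highest strict local maxima of the bin counts
#' (in ascending-distance order); the nadir is the minimum-count bin
#' strictly between them, ties broken towards the smaller distance. The
#' association threshold is the upper edge of the nadir bin and \code{p2}
#' the upper edge of the second peak bin.
#'
#' @param hist a \linkS4class{DistanceHistogram}.
#' @return A \linkS4class{ThresholdResult}.
#' @export
findThreshold <- function(hist) {
  stopifnot(is(hist, "DistanceHistogram"))
  counts <- as.numeric(hist@counts)
  n <- length(counts)
  if (n < 3L) stop("no nadir found: histogram has fewer than 3 bins")
  inner <- 2:(n - 1L)
  isMax <- counts[inner] > counts[inner - 1L] & counts[inner] > counts[inner + 1L]
  peaks <- c(if (counts[1] > counts[2]) 1L, inner[isMax],
             if (counts[n] > counts[n - 1L]) n)
  if (length(peaks) < 2L)
    stop("no nadir found: histogram is unimodal")
  top2 <- peaks[order(-counts[peaks], peaks)][1:2]
  p1bin <- min(top2); p2bin <- max(top2)
  between <- (p1bin + 1L):(p2bin - 1L)
  nadir <- between[which.min(counts[between])]
  new("ThresholdResult",
      threshold = hist@edges[nadir + 1L],
      firstPeakBin = as.integer(p1bin), secondPeakBin = as.integer(p2bin),
      nadirBin = as.integer(nadir), p2 = hist@edges[p2bin + 1L])
}

#' Per-scan association by chain connectivity with isolated-point rescue
#'
#' Dyads closer than \code{threshold} are directly associated; connected
#' components of the resulting graph become cliques of co-membership, so
#' individuals linked through intermediaries count as associated (chain
#' rule). An individual with no direct neighbour is rescued in a single
#' pass: if its nearest neighbour lies within \code{p2} it joins that
#' neighbour's (pre-rescue) component, otherwise it is dropped from the
#' scan.
#'
#' @param scanRows data.frame with \code{individual_id}, \code{x_m},
#'   \code{y_m} for one scan.
#' @param threshold association threshold in metres.
#' @param p2 rescue limit in metres (second histogram peak); must exceed
#'   \code{threshold}.
#' @return List with \code{edges} (symmetric 0/1 co-membership matrix over
#'   the retained individuals) and \code{present} (named logical over all
#'   input individuals; FALSE for dropped isolates).
#' @export
scanAssociation <- function(scanRows, threshold, p2) {
  if (threshold >= p2) stop("need threshold < p2")
  ids <- scanRows$individual_id
  n <- length(ids)
  present <- stats::setNames(rep(TRUE, n), ids)
  if (n == 0L)
    return(list(edges = matrix(0, 0, 0), present = present))
  if (n == 1L)
    return(list(edges = matrix(0, 1, 1, dimnames = list(ids, ids)),
                present = present))
  d <- as.matrix(dist(scanRows[, c("x_m", "y_m")]))
  dimnames(d) <- list(ids, ids)
  adj <- d < threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  isolated <- which(tabulate(comp)[comp] == 1L)
  compAfter <- comp
  for (i in isolated) {
    di <- d[i, ]; di[i] <- Inf
    j <- which.min(di)
    if (di[j] < p2) compAfter[i] <- comp[j] else present[i] <- FALSE
  }
  keep <- which(present)
  edges <- outer(compAfter[keep], compAfter[keep], "==") * 1
  diag(edges) <- 0
  dimnames(edges) <- list(ids[keep], ids[keep])
  list(edges = edges, present = present)
}

#' Simple-ratio-index association matrix over scans
#'
#' For each dyad, SRI = (number of scans in which both were present and
#' associated) / (number of scans in which at least one was present).
#' Dyads never observed together score 0.
#'
#' @param scanAssociations list of \code{\link{scanAssociation}} results.
#' @param ids character vector fixing individual order; defaults to the
#'   union of individuals over scans.
#' @param unitOf optional named character of unit labels.
#' @return An unnormalized herd-level \linkS4class{AssociationNetwork}.
#' @export
sriMatrix <- function(scanAssociations, ids = NULL, unitOf = NULL) {
  if (!length(scanAssociations)) stop("need at least one scan")
  if (is.null(ids))
    ids <- sort(unique(unlist(lapply(scanAssociations,
                                     function(s) names(s$present)))))
  n <- length(ids)
  together <- either <- matrix(0, n, n, dimnames = list(ids, ids))
  for (s in scanAssociations) {
    pres <- stats::setNames(rep(FALSE, n), ids)
    pres[names(s$present)[s$present]] <- TRUE
    eitherScan <- outer(pres, pres, "|")
    either <- either + eitherScan
    if (nrow(s$edges)) {
      e <- s$edges
      idx <- match(rownames(e), ids)
      together[idx, idx] <- together[idx, idx] + e
    }
  }
  w <- ifelse(either > 0, together / pmax(either, 1), 0)
  diag(w) <- 0
  neverSeen <- rowSums(either) - diag(either) == 0
  if (any(neverSeen))
    warning("individual(s) never present in any scan: ",
            paste(ids[neverSeen], collapse = ", "))
  if (is.null(unitOf)) unitOf <- stats::setNames(rep("unit01", n), ids)
  else unitOf <- unitOf[ids]
  new("AssociationNetwork", weights = w,
      unitOf = stats::setNames(as.character(unitOf), ids),
      normalized = FALSE, level = "herd")
}

#' Row-normalize an association network
#'
#' Scales each row so its off-diagonal sum equals N, i.e. the average
#' weight becomes 1. Row i is read as the directed influence of every other
#' individual k on i; with equal weights the social drive then matches the
#' anonymous drive C * n_s up to a factor N/(N-1).
#'
#' @param net an \linkS4class{AssociationNetwork}.
#' @return The normalized network.
#' @export
normalizeRows <- function(net) {
  stopifnot(is(net, "AssociationNetwork"))
  w <- net@weights
  rs <- rowSums(w)
  if (any(rs <= 0))
    stop("cannot normalize: zero row sum for individual(s) ",
         paste(rownames(w)[rs <= 0], collapse = ", "))
  w <- w * (nrow(w) / rs)
  new("AssociationNetwork", weights = w, unitOf = net@unitOf,
      normalized = TRUE, level = net@level)
}

#' Restrict a herd network to its intra-unit part
#'
#' Zeroes every inter-unit weight and leaves intra-unit weights untouched
#' (no re-normalization), so the unit-level hypotheses see exactly the same
#' intra-unit relationships as the herd-level ones.
#'
#' @param net a normalized herd-level \linkS4class{AssociationNetwork}.
#' @param unitOf optional named character unit labels (defaults to the
#'   network's own).
#' @return A unit-level \linkS4class{AssociationNetwork}.
#' @export
unitSubnetwork <- function(net, unitOf = NULL) {
  stopifnot(is(net, "AssociationNetwork"))
  ids <- rownames(net@weights)
  unitOf <- unitOf %||% net@unitOf
  if (!all(ids %in% names(unitOf)) || anyNA(unitOf[ids]))
    stop("missing unit label for some individuals")
  unitOf <- stats::setNames(as.character(unitOf[ids]), ids)
  w <- net@weights
  w[outer(unitOf, unitOf, "!=")] <- 0
  new("AssociationNetwork", weights = w, unitOf = unitOf,
      normalized = net@normalized, level = "unit")
}

#' Summary statistics of an association network
#'
#' @param net an \linkS4class{AssociationNetwork} with unit labels.
#' @return List with \code{density} (fraction of nonzero off-diagonal
#'   dyads), \code{withinMean}, \code{withinSD}, \code{acrossMean},
#'   \code{acrossSD} (over unordered dyads) and \code{ratio}
#'   (withinMean / acrossMean; NA when no across-unit dyad exists or the
#'   across mean is zero).
#' @export
networkSummary <- function(net) {
  stopifnot(is(net, "AssociationNetwork"))
  w <- net@weights
  sameUnit <- outer(net@unitOf, net@unitOf, "==")
  ut <- upper.tri(w)
  vals <- w[ut]
  within <- w[ut & sameUnit]
  across <- w[ut & !sameUnit]
  ratio <- if (!length(across) || mean(across) == 0) NA_real_
           else mean(within) / mean(across)
  list(
    density = mean(vals > 0),
    withinMean = mean(within), withinSD = stats::sd(within),
    acrossMean = if (length(across)) mean(across) else NA_real_,
    acrossSD = if (length(across)) stats::sd(across) else NA_real_,
    ratio = ratio
  )
}

#' Build the herd association network from a scan table
#'
#' The full network pipeline: pool pairwise distances over scans, choose a
#' bin width (plug-in rule unless given), build the histogram, locate the
#' nadir threshold between the two modes, score per-scan association by
#' chain connectivity with isolated-point rescue, form the simple-ratio
#' network and row-normalize it.
#'
#' @param scans scan table (see \code{\link{readScanTable}}).
#' @param unitOf named character of unit labels per individual.
#' @param binWidth optional histogram bin width override (metres).
#' @param threshold,p2 optional overrides of the data-driven threshold and
#'   rescue limit (metres).
#' @return List with \code{network} (normalized herd-level
#'   \linkS4class{AssociationNetwork}), \code{threshold}
#'   (\linkS4class{ThresholdResult} or NULL when both overrides are given),
#'   \code{histogram} (\linkS4class{DistanceHistogram}) and
#'   \code{summary} (\code{\link{networkSummary}} of the network).
#' @export
buildNetwork <- function(scans, unitOf, binWidth = NULL, threshold = NULL,
                         p2 = NULL) {
  scans <- validateScanTable(scans, requireState = FALSE)
  byScan <- split(scans, scans$scan_id)
  allDist <- unlist(lapply(byScan, function(s) pairwiseDistances(s)$distance),
                    use.names = FALSE)
  hist <- buildDistanceHistogram(allDist, binWidth = binWidth)
  thr <- NULL
  if (is.null(threshold) || is.null(p2)) {
    thr <- findThreshold(hist)
    threshold <- threshold %||% thr@threshold
    p2 <- p2 %||% thr@p2
  }
  assoc <- lapply(byScan, scanAssociation, threshold = threshold, p2 = p2)
  ids <- sort(unique(scans$individual_id))
  net <- sriMatrix(assoc, ids = ids, unitOf = unitOf)
  net <- normalizeRows(net)
  list(network = net, threshold = thr, histogram = hist,
       summary = networkSummary(net))
}
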