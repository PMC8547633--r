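test_that("pairwise distances are plain Euclidean over unordered pairs", {
  d <- pairwiseDistances(data.frame(individual_id = c("a", "b"),
                                    x_m = c(0, 3), y_m = c(0, 4)))
  expect_equal(d$distance, 5)
  k <- 7
  pts <- data.frame(individual_id = letters[1:k],
                    x_m = rnorm(k), y_m = rnorm(k))
  expect_equal(nrow(pairwiseDistances(pts)), k * (k - 1) / 2)
  dup <- pairwiseDistances(data.frame(individual_id = c("a", "b"),
                                      x_m = c(1, 1), y_m = c(2, 2)))
  expect_equal(dup$distance, 0)
  expect_equal(nrow(pairwiseDistances(pts[1, ])), 0L)
})

test_that("plug-in bin width is scale-equivariant and guarded", {
  set.seed(42)
  # bimodal sample shaped like a multilevel herd's distances
  d <- c(sqrt(rnorm(400)^2 + rnorm(400)^2) * sqrt(2),
         sqrt(rnorm(600, 0, 35)^2 + rnorm(600, 0, 35)^2))
  w <- chooseBinWidth(d)
  expect_gt(w, 0.1); expect_lt(w, 10)  # same order as the study's 0.92 m
  expect_equal(chooseBinWidth(d * 10), w * 10, tolerance = 1e-8)
  expect_error(chooseBinWidth(rep(1, 50)), "explicit binWidth")
  expect_error(chooseBinWidth(d[1:5]), "at least 10")
})

test_that("histogram geometry matches the printed bin spans at width 0.92", {
  set.seed(1)
  h <- buildDistanceHistogram(runif(500, 0, 60), binWidth = 0.92)
  expect_equal(h@edges[12], 0.92 * 11)        # lower edge of 12th bin
  expect_equal(round(h@edges[12], 1), 10.1)
  expect_equal(round(h@edges[13], 1), 11.0)   # upper edge: the threshold
  expect_equal(h@edges[56], 50.6)             # upper edge of 55th bin
  expect_equal(sum(h@counts), 500L)

  single <- buildDistanceHistogram(0.5, binWidth = 1)
  expect_equal(single@counts, 1L)
  expect_equal(length(single@counts), 1L)
  expect_error(buildDistanceHistogram(numeric(0)), "no distances")
})

test_that("nadir threshold detection matches the study-like histogram", {
  # counts shaped like the field histogram: tall peak in bin 2, unique
  # minimum in bin 12, second peak in bin 55, decaying tail to bin 80
  counts <- numeric(80)
  counts[1:12] <- c(800, 2000, 900, 500, 300, 200, 140, 100, 70, 50, 40, 30)
  counts[13:54] <- round(seq(35, 280, length.out = 42))
  counts[55] <- 300
  counts[56:80] <- round(seq(280, 40, length.out = 25))
  counts <- as.integer(counts)
  h <- new("DistanceHistogram", binWidth = 0.92, counts = counts,
           edges = seq(0, by = 0.92, length.out = 81))
  thr <- findThreshold(h)
  expect_equal(thr@firstPeakBin, 2L)
  expect_equal(thr@secondPeakBin, 55L)
  expect_equal(thr@nadirBin, 12L)
  expect_equal(thr@threshold, 0.92 * 12)       # 11.04, prints as 11.0
  expect_equal(thr@p2, 0.92 * 55)

  tiny <- new("DistanceHistogram", binWidth = 1, counts = c(5L, 1L, 7L),
              edges = 0:3)
  expect_equal(findThreshold(tiny)@nadirBin, 2L)

  tied <- new("DistanceHistogram", binWidth = 1,
              counts = c(9L, 2L, 5L, 2L, 8L), edges = 0:5)
  expect_equal(findThreshold(tied)@nadirBin, 2L)  # tie broken low

  uni <- new("DistanceHistogram", binWidth = 1, counts = c(1L, 5L, 2L),
             edges = 0:3)
  expect_error(findThreshold(uni), "no nadir")
})

test_that("scan association applies the chain rule and the rescue rule", {
  # A-B 5 m, B-C 8 m, A-C 13 m: all chained into one clique
  chain <- data.frame(individual_id = c("A", "B", "C"),
                      x_m = c(0, 5, 13), y_m = 0)
  sa <- scanAssociation(chain, threshold = 11, p2 = 50.6)
  expect_true(all(sa$edges[upper.tri(sa$edges)] == 1))
  expect_true(all(sa$present))

  # lone individual 30 m out is rescued into its nearest's component;
  # 60 m out it is dropped
  resc <- data.frame(individual_id = c("A", "B", "L"),
                     x_m = c(0, 5, 35), y_m = 0)
  sa2 <- scanAssociation(resc, threshold = 11, p2 = 50.6)
  expect_equal(sa2$edges["L", "A"], 1)
  expect_equal(sa2$edges["L", "B"], 1)
  drop <- data.frame(individual_id = c("A", "B", "L"),
                     x_m = c(0, 5, 65), y_m = 0)
  sa3 <- scanAssociation(drop, threshold = 11, p2 = 50.6)
  expect_false(sa3$present[["L"]])
  expect_false("L" %in% rownames(sa3$edges))
  expect_error(scanAssociation(chain, threshold = 11, p2 = 10), "threshold < p2")
})

test_that("scan association components are cliques (transitive closure)", {
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(3:9, 1)
    pts <- data.frame(individual_id = sprintf("i%d", 1:n),
                      x_m = runif(n, 0, 40), y_m = runif(n, 0, 40))
    e <- scanAssociation(pts, threshold = 8, p2 = 30)$edges
    if (!nrow(e)) next
    # e + I must be idempotent on {0,1} under boolean matrix product
    reach <- ((e + diag(nrow(e))) %*% (e + diag(nrow(e)))) > 0
    expect_equal(unname(reach * 1 - diag(nrow(e))), unname(e))
  }
})

test_that("simple ratio index matches hand counts and brute-force recount", {
  mkAssoc <- function(ids, edges, present) {
    n <- length(ids)
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    for (e in edges) { m[e[1], e[2]] <- 1; m[e[2], e[1]] <- 1 }
    keep <- ids[present]
    list(edges = m[keep, keep, drop = FALSE],
         present = stats::setNames(present, ids))
  }
  ids <- c("A", "B")
  assocs <- c(
    replicate(3, mkAssoc(ids, list(c("A", "B")), c(TRUE, TRUE)),
              simplify = FALSE),
    list(mkAssoc(ids, list(), c(TRUE, TRUE)),
         mkAssoc(ids, list(), c(TRUE, FALSE)))
  )
  net <- sriMatrix(assocs, ids = ids)
  expect_equal(assocWeights(net)["A", "B"], 3 / 5)  # x/(x + yAB + yA)

  # always together -> 1; never co-present -> 0
  together <- replicate(4, mkAssoc(ids, list(c("A", "B")), c(TRUE, TRUE)),
                        simplify = FALSE)
  expect_equal(assocWeights(sriMatrix(together, ids = ids))["A", "B"], 1)
  apart <- list(mkAssoc(ids, list(), c(TRUE, FALSE)),
                mkAssoc(ids, list(), c(FALSE, TRUE)))
  expect_equal(assocWeights(sriMatrix(apart, ids = ids))["A", "B"], 0)

  # property: equality with a per-dyad recount on random scan sets
  set.seed(31)
  ids <- c("p", "q", "r", "s")
  for (rep in 1:10) {
    assocs <- replicate(6, {
      pres <- runif(4) < 0.8
      pts <- data.frame(individual_id = ids,
                        x_m = runif(4, 0, 25), y_m = runif(4, 0, 25))
      scanAssociation(pts[pres, , drop = FALSE], threshold = 10, p2 = 20)
    }, simplify = FALSE)
    # make presence cover all ids
    assocs <- lapply(assocs, function(a) {
      p <- stats::setNames(rep(FALSE, 4), ids)
      p[names(a$present)] <- a$present
      list(edges = a$edges, present = p)
    })
    net <- assocWeights(sriMatrix(assocs, ids = ids))
    for (i in 1:3) for (j in (i + 1):4)
      expect_equal(net[ids[i], ids[j]], bruteSRI(assocs, ids[i], ids[j]))
  }
})

test_that("row normalization scales off-diagonal sums to N", {
  ids <- letters[1:4]
  w <- rbind(c(0, 1, 1, 2), c(1, 0, 0, 1), c(1, 1, 0, 2), c(0, 1, 1, 0))
  dimnames(w) <- list(ids, ids)
  net <- new("AssociationNetwork", weights = w,
             unitOf = stats::setNames(rep("u1", 4), ids),
             normalized = FALSE, level = "herd")
  norm <- normalizeRows(net)
  expect_true(isNormalized(norm))
  expect_equal(unname(assocWeights(norm)[1, ]), c(0, 1, 1, 2))  # fixed point
  expect_equal(unname(assocWeights(norm)[4, ]), c(0, 2, 2, 0))  # scaled x2
  expect_equal(unname(rowSums(assocWeights(norm))), rep(4, 4), tolerance = 1e-9)

  w0 <- w; w0[2, ] <- 0; dimnames(w0) <- list(ids, ids)
  net0 <- new("AssociationNetwork", weights = w0,
              unitOf = stats::setNames(rep("u1", 4), ids),
              normalized = FALSE, level = "herd")
  expect_error(normalizeRows(net0), "b")
})

test_that("unit subnetwork zeroes cross-unit weights only", {
  ids <- letters[1:4]
  unitOf <- stats::setNames(c("u1", "u1", "u2", "u2"), ids)
  w <- matrix(1, 4, 4, dimnames = list(ids, ids)); diag(w) <- 0
  net <- normalizeRows(new("AssociationNetwork", weights = w, unitOf = unitOf,
                           normalized = FALSE, level = "herd"))
  sub <- unitSubnetwork(net)
  expect_identical(networkLevel(sub), "unit")
  ww <- assocWeights(sub)
  expect_true(all(ww[outer(unitOf, unitOf, "!=")] == 0))
  expect_equal(ww["a", "b"], assocWeights(net)["a", "b"])  # intra untouched
  expect_true(all(rowSums(ww) <= 4 + 1e-9))

  oneUnit <- normalizeRows(new("AssociationNetwork", weights = w,
                               unitOf = stats::setNames(rep("u", 4), ids),
                               normalized = FALSE, level = "herd"))
  expect_equal(assocWeights(unitSubnetwork(oneUnit)), assocWeights(oneUnit))
})

test_that("network summary matches hand computation on a toy network", {
  ids <- letters[1:4]
  unitOf <- stats::setNames(c("u1", "u1", "u2", "u2"), ids)
  w <- rbind(c(0, 3, 1, 0), c(3, 0, 0, 0), c(1, 0, 0, 5), c(0, 0, 5, 0))
  dimnames(w) <- list(ids, ids)
  net <- new("AssociationNetwork", weights = w, unitOf = unitOf,
             normalized = FALSE, level = "herd")
  s <- networkSummary(net)
  expect_equal(s$density, 3 / 6)
  expect_equal(s$withinMean, mean(c(3, 5)))
  expect_equal(s$acrossMean, mean(c(1, 0, 0, 0)))
  expect_equal(s$ratio, 4 / 0.25)

  full <- new("AssociationNetwork",
              weights = matrix(1, 4, 4, dimnames = list(ids, ids)) - diag(4),
              unitOf = unitOf, normalized = FALSE, level = "herd")
  expect_equal(networkSummary(full)$density, 1)
})

test_that("the full network pipeline separates levels on synthetic data", {
  cfg <- societyConfig(nDays = 2, seed = 6)
  soc <- generateSociety(cfg)
  pos <- generateScanPositions(soc, cfg)
  fit <- buildNetwork(pos, unitOf = unitLabels(soc))
  net <- fit$network
  expect_true(isNormalized(net))
  n <- nrow(assocWeights(net))
  # normalized rows: global mean off-diagonal weight is N/(N-1)
  expect_equal(mean(assocWeights(net)[row(assocWeights(net)) !=
                                      col(assocWeights(net))]),
               n / (n - 1), tolerance = 1e-9)
  # within-unit weights dominate across-unit weights by 1-2 orders
  expect_gt(fit$summary$ratio, 10)
  expect_lt(fit$summary$ratio, 1000)
  # the data-driven threshold separates intra- from inter-unit distances
  thr <- fit$threshold@threshold
  intra <- inter <- numeric(0)
  for (s in split(pos, pos$scan_id)) {
    d <- as.matrix(dist(s[, c("x_m", "y_m")]))
    su <- outer(unitLabels(soc)[s$individual_id],
                unitLabels(soc)[s$individual_id], "==")
    intra <- c(intra, d[upper.tri(d) & su])
    inter <- c(inter, d[upper.tri(d) & !su])
  }
  expect_gt(mean(intra < thr), 0.95)
  expect_lt(mean(inter < thr), 0.05)
})
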