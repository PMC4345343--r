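test_that("gromos DRMS clustering separates constructed groups", {
  # two tight groups of frames, far apart between groups
  spec <- tinySpec(M = 40L, seed = 51L,
                   basins = data.frame(rotation = c(0, 3), slide = c(0, -3),
                                       weight = c(0.6, 0.4)),
                   modeSd = c(rotation = 0.03, slide = 0.03), noiseSd = 0.005)
  syn <- syntheticEnsemble(spec)
  pm <- pairwiseMatrix(syn$ensemble, "drms")
  cr <- drmsCluster(pm, cutoff = 0.2)
  expect_equal(length(clusterProbs(cr)), 2L)
  # recovered partition matches the generating basins
  expect_equal(length(unique(paste(clusterLabels(cr), syn$truth@basin))), 2L)
  expect_equal(sum(clusterProbs(cr)), 1, tolerance = 1e-12)

  # all frames within the cutoff: a single cluster holding everything
  one <- drmsCluster(pm, cutoff = 1e3)
  expect_equal(clusterProbs(one), 1)
  expect_error(drmsCluster(pm, cutoff = -1), "validation error")
})

test_that("rho and delta match hand evaluation on collinear points", {
  pts <- cbind(c(0, 1, 2), 0)
  dd <- densityDelta(pts, dc = 1.5, kernel = "cutoff")
  expect_equal(dd@rho, c(1, 2, 1))
  expect_equal(dd@delta[2], 2)                  # global peak: max distance
  expect_equal(dd@delta[c(1, 3)], c(1, 1))
  expect_true(is.na(dd@nearestHigher[2]))
  expect_error(densityDelta(matrix(1, 4, 2)), "degenerate-density")
})

test_that("rho and delta match the brute-force definitions on random points", {
  set.seed(52)
  P <- matrix(rnorm(1000), 500, 2)
  d <- as.matrix(dist(P))
  for (kern in c("cutoff", "gaussian")) {
    dc <- 0.4
    dd <- densityDelta(P, dc = dc, kernel = kern)
    rho <- vapply(1:500, function(i) {
      if (kern == "cutoff") sum(d[i, -i] < dc) else sum(exp(-(d[i, -i] / dc)^2))
    }, numeric(1))
    delta <- vapply(1:500, function(i) {
      higher <- which(rho > rho[i] | (rho == rho[i] & seq_len(500) < i))
      if (!length(higher)) max(d) else min(d[i, higher])
    }, numeric(1))
    expect_equal(dd@rho, rho, tolerance = 1e-12)
    expect_equal(dd@delta, delta, tolerance = 1e-12)
  }
})

test_that("three well-separated blobs are recovered almost perfectly", {
  skip_if_not_installed("mclust")
  set.seed(53)
  centers <- rbind(c(0, 0), c(3, 0), c(0, 3))
  pts <- do.call(rbind, lapply(1:3, function(b)
    sweep(matrix(rnorm(600, sd = 0.3), 300, 2), 2, centers[b, ], "+")))
  truthLab <- rep(1:3, each = 300)
  cr <- densityPeakCluster(pts, k = 3L)
  expect_equal(length(clusterProbs(cr)), 3L)
  ari <- mclust::adjustedRandIndex(clusterLabels(cr), truthLab)
  expect_gt(ari, 0.95)

  single <- densityPeakCluster(pts[1:300, ], k = 1L)
  expect_equal(clusterProbs(single), 1)
  expect_error(densityPeakCluster(pts, k = 5000L), "parameter error")
})

test_that("explicit rho/delta thresholds select the same centers", {
  set.seed(54)
  pts <- rbind(matrix(rnorm(400, sd = 0.25), 200, 2),
               sweep(matrix(rnorm(400, sd = 0.25), 200, 2), 2, c(3, 3), "+"))
  auto <- densityPeakCluster(pts, k = 2L)
  dd <- densityDelta(pts)
  gam <- dd@rho * dd@delta
  cut <- sort(gam, decreasing = TRUE)[2]
  manual <- densityPeakCluster(pts, rhoMin = min(dd@rho[gam >= cut]),
                               deltaMin = min(dd@delta[gam >= cut]))
  expect_equal(sort(auto@centers$point), sort(manual@centers$point))
})

test_that("the two-basin fixture recovers weights and centers", {
  fx <- twoBasinFixture(M = 1500L, seed = 2015L)
  proj <- projectEnsemble(fx$ensemble, truthBasis(fx$truth), K = 2)
  pts <- as.matrix(proj[, c("pe1", "pe2")])
  cr <- densityPeakCluster(pts, k = 2L)
  p <- clusterProbs(cr)
  trueW <- as.numeric(table(fx$truth@basin)) / nFrames(fx$ensemble)
  expect_equal(sort(p), sort(trueW), tolerance = 0.03)
  # centers land near the planted basin centers
  cen <- as.matrix(cr@centers[, c("center1", "center2")])
  planted <- as.matrix(fx$truth@spec$basins[, c("rotation", "slide")])
  for (b in 1:2) {
    dists <- sqrt(rowSums(sweep(planted, 2, cen[b, ])^2))
    expect_lt(min(dists), 0.2)
  }
  # grouping clusters by negative-slide centers recovers the minor weight
  neg <- which(cr@centers$center2 < 0)
  expect_equal(unname(clusterProbabilities(cr, list(neg = neg))),
               min(trueW), tolerance = 0.03)
  expect_error(clusterProbabilities(cr, list(bad = 99L)), "unknown cluster")
})

test_that("cluster probabilities follow label counts and conserve mass", {
  cr <- new("ClusterResult", labels = c(1L, 1L, 1L, 2L),
            centers = data.frame(cluster = 1:2, point = c(1L, 4L)),
            probabilities = c(0.75, 0.25), parameters = list())
  expect_equal(clusterProbabilities(cr), c(0.75, 0.25))
  expect_equal(unname(clusterProbabilities(cr, list(all = 1:2))), 1)
})
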