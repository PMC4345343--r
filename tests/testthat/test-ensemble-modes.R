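test_that("iterative mean recovers the shape shared by rigidly posed frames", {
  set.seed(21)
  shape <- randomSites(10)
  frames <- t(vapply(1:6, function(i) rigidly(shape), numeric(30)))
  e <- makeEnsemble(data.frame(chain = "A", resno = 1:10), frames)
  im <- iterativeMean(e)
  expect_lt(calcRMSD(im$mean, shape), 1e-6)
  expect_lte(im$fitted@provenance$iterations, 3L)
  # returned mean is exactly the average of the returned fitted frames
  expect_lt(max(abs(colMeans(frameMatrix(im$fitted)) - im$mean)), 1e-12)
})

test_that("the mean of two frames is the midpoint of the fitted frames", {
  set.seed(22)
  a <- randomSites(8)
  b <- a + rnorm(24, sd = 0.05)
  e <- makeEnsemble(data.frame(chain = "A", resno = 1:8),
                    rbind(rigidly(a), rigidly(b)))
  im <- iterativeMean(e)
  mid <- colMeans(frameMatrix(im$fitted))
  expect_equal(as.numeric(im$mean), as.numeric(mid), tolerance = 1e-12)
})

test_that("the planted-ensemble mean approaches the template", {
  syn <- syntheticEnsemble(tinySpec(M = 2000L, seed = 23L,
                                    modeSd = c(rotation = 0, slide = 0),
                                    noiseSd = 0.01))
  im <- iterativeMean(syn$ensemble)
  expect_lt(calcRMSD(im$mean, siteCoords(syn$template)), 0.002)
})

test_that("covariance handles identical and rank-1 ensembles exactly", {
  lab <- data.frame(chain = "A", resno = 1:5)
  x <- randomSites(5, seed = 24)
  e <- makeEnsemble(lab, rbind(x, x, x))
  expect_equal(max(abs(coordCovariance(e, x))), 0)

  v <- rnorm(15); v <- v / sqrt(sum(v^2))
  a <- 0.3
  e2 <- makeEnsemble(lab, rbind(x + a * v, x - a * v))
  C <- coordCovariance(e2, x)
  expect_equal(C, a^2 * tcrossprod(v), tolerance = 1e-12)
  basis <- pcaModes(C, x, lab)
  expect_equal(modeValues(basis)[1], a^2, tolerance = 1e-12)
  expect_equal(modeOverlap(modeVectors(basis)[, 1], v), 1, tolerance = 1e-9)
})

test_that("PCA conserves the trace and fixes eigenvector signs", {
  syn <- syntheticEnsemble(tinySpec(M = 80L, seed = 25L))
  pca <- ensemblePCA(syn$ensemble)
  C <- coordCovariance(pca$fitted, pca$mean)
  expect_equal(sum(modeValues(pca$basis)), sum(diag(C)),
               tolerance = 1e-8)
  V <- modeVectors(pca$basis)
  for (k in c(1L, 2L, 5L))
    expect_gt(V[which.max(abs(V[, k])), k], 0)
  g <- crossprod(V[, 1:10])
  expect_lt(max(abs(g - diag(10))), 1e-8)
  expect_error(pcaModes(matrix(c(1, 2, 0, 1), 2), c(0, 0), lab = NULL),
               "symmetric")
})

test_that("projection and extrapolation round-trip exactly", {
  syn <- syntheticEnsemble(tinySpec(M = 40L, seed = 26L))
  pca <- ensemblePCA(syn$ensemble)
  basis <- pca$basis
  # the mean projects to zero
  expect_equal(unname(projectSiteSet(makeSiteSet(siteLabels(basis),
                                                 centerCoords(basis)),
                                     basis, K = 2)),
               c(0, 0), tolerance = 1e-9)
  # mean + 0.5 v2 projects to (0, 0.5)
  fr <- extrapolateMode(basis, 2L, 0.5)
  expect_equal(unname(projectSiteSet(fr, basis, K = 2)), c(0, 0.5),
               tolerance = 1e-9)
  # linearity of extrapolation
  ab <- siteCoords(extrapolateMode(basis, 1L, 0.7))
  expect_equal(ab, siteCoords(extrapolateMode(basis, 1L, 0.3)) +
                 0.4 * modeVectors(basis)[, 1], tolerance = 1e-12)
  # fitted-ensemble projections have zero mean per mode by construction
  pe <- projectEnsemble(pca$fitted, basis, K = 2, fit = FALSE)
  expect_lt(max(abs(colMeans(pe[, -1L]))), 1e-9)
  expect_error(projectEnsemble(syn$ensemble, basis, K = 9999L), "index error")
})

test_that("mode bases round-trip through the TSV bundle format", {
  syn <- syntheticEnsemble(tinySpec(M = 30L, seed = 28L))
  pca <- ensemblePCA(syn$ensemble)
  b <- pca$basis
  trimmed <- new("ModeBasis", labels = b@labels, center = b@center,
                 values = b@values[1:4], vectors = b@vectors[, 1:4],
                 kind = b@kind)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeModeBasisTSV(trimmed, f)
  back <- readModeBasisTSV(f)
  expect_equal(back@kind, "pca")
  expect_equal(siteLabels(back), siteLabels(trimmed))
  expect_equal(modeValues(back), modeValues(trimmed), tolerance = 1e-9)
  expect_lt(max(abs(modeVectors(back) - modeVectors(trimmed))), 1e-9)
  expect_lt(max(abs(centerCoords(back) - centerCoords(trimmed))), 1e-9)
})

test_that("PCA recovers the planted two-mode structure", {
  spec <- tinySpec(M = 2000L, seed = 27L)
  syn <- syntheticEnsemble(spec)
  pca <- ensemblePCA(syn$ensemble)
  aligned <- alignBasisTo(pca$basis, siteCoords(syn$template))
  cross <- crossprod(modeVectors(aligned)[, 1:2], syn$truth@modes)
  overlap <- sqrt(mean(svd(cross)$d^2))
  expect_gt(overlap, 0.97)
  # eigenvalue spectrum collapses after mode 2
  vals <- modeValues(pca$basis)
  expect_lt(vals[3] / vals[2], 0.1)
  # projections onto the planted basis reproduce the planted correlation
  pe <- projectEnsemble(syn$ensemble, truthBasis(syn$truth), K = 2)
  expect_equal(cor(pe$pe1, pe$pe2), spec$modeCorrelation, tolerance = 0.07)
})
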