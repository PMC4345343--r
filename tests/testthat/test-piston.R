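test_that("degenerate and mismatched piston inputs are rejected", {
  tmpl <- makeTemplate(tinySpec())
  expect_error(buildPistonVector(tmpl, tmpl), "degenerate-PV")
  other <- makeSiteSet(data.frame(chain = "A", resno = 1:3), rnorm(9))
  expect_error(buildPistonVector(tmpl, other), "comparability")
})

test_that("a pure alpha4 shift yields the masked unit field", {
  spec <- tinySpec()
  tmpl <- makeTemplate(spec)
  a4 <- list(A = spec$helixRanges[4L, , drop = FALSE],
             B = spec$helixRanges[4L, , drop = FALSE])
  lab <- siteLabels(tmpl)
  mask <- lab$resno >= 146 & lab$resno <= 175
  delta <- 0.2
  xyz <- matrix(siteCoords(tmpl), ncol = 3, byrow = TRUE)
  xyz[mask, 3] <- xyz[mask, 3] - delta
  holo <- makeSiteSet(lab, xyz)
  pv <- buildPistonVector(tmpl, holo, a4)
  expect_s4_class(pv, "PistonVector")
  expect_equal(sum(pvVector(pv)^2), 1, tolerance = 1e-12)
  v <- matrix(pvVector(pv), ncol = 3, byrow = TRUE)
  expect_equal(max(abs(v[!mask, ])), 0)                 # support on mask only
  expect_true(all(v[mask, 3] < 0))                      # all pointing -z
  expect_equal(sd(v[mask, 3]), 0, tolerance = 1e-12)    # equal components
  expect_equal(pv@rawNorm, delta * sqrt(sum(mask)), tolerance = 1e-9)
})

test_that("a mixed displacement reproduces mask.delta/|mask.delta| exactly", {
  set.seed(41)
  spec <- tinySpec()
  tmpl <- makeTemplate(spec)
  lab <- siteLabels(tmpl)
  disp <- matrix(rnorm(3 * nSites(tmpl), sd = 0.05), ncol = 3)
  holo <- makeSiteSet(lab, matrix(siteCoords(tmpl), ncol = 3, byrow = TRUE) + disp)
  a4 <- list(A = spec$helixRanges[4L, , drop = FALSE],
             B = spec$helixRanges[4L, , drop = FALSE])
  # no superposition: PV must equal the independently computed masked field
  pv <- buildPistonVector(tmpl, holo, a4, fitSites = "none", orient = "raw")
  mask <- lab$resno >= 146 & lab$resno <= 175
  md <- disp; md[!mask, ] <- 0
  expected <- as.vector(t(md)) / sqrt(sum(md^2))
  expect_equal(pvVector(pv), expected, tolerance = 1e-12)
})

test_that("the spectrum is (1, 0, ...) on a basis led by the PV itself", {
  spec <- tinySpec()
  tmpl <- makeTemplate(spec)
  truth <- plantedModes(tmpl, spec)
  holo <- makeSiteSet(siteLabels(tmpl),
                      siteCoords(tmpl) + 0.3 * truth@fields[, "slide"])
  pv <- buildPistonVector(tmpl, holo, alpha4Ranges())
  # complete the PV to an orthonormal basis
  n3 <- length(pvVector(pv))
  Q <- qr.Q(qr(cbind(pvVector(pv), matrix(rnorm(n3 * 5), n3))))
  Q[, 1] <- Q[, 1] * sign(sum(Q[, 1] * pvVector(pv)))
  basis <- new("ModeBasis", labels = siteLabels(tmpl),
               center = siteCoords(tmpl), values = rev(seq_len(6)) * 1.0,
               vectors = Q, kind = "pca")
  sp <- pvSpectrum(pv, basis)
  expect_equal(abs(sp$projection[1]), 1, tolerance = 1e-9)
  expect_lt(max(abs(sp$projection[-1])), 1e-9)
})

test_that("Parseval holds on the complete PCA basis and mode 2 dominates", {
  spec <- tinySpec(M = 1500L, seed = 43L)
  syn <- syntheticEnsemble(spec)
  pca <- ensemblePCA(syn$ensemble)
  holo <- makeSiteSet(siteLabels(syn$template),
                      siteCoords(syn$template) + 0.3 * syn$truth@fields[, "slide"])
  pv <- buildPistonVector(syn$template, holo,
                          list(A = spec$helixRanges[4L, , drop = FALSE],
                               B = spec$helixRanges[4L, , drop = FALSE]))
  # exact consistency with the planted slide field
  expect_equal(modeOverlap(pvVector(pv), syn$truth@fields[, "slide"]), 1,
               tolerance = 1e-9)
  sp <- pvSpectrum(pv, pca$basis)
  expect_equal(sum(sp$projection^2), 1, tolerance = 1e-8)
  # the slide-dominated mode 2 carries the largest projection; its
  # magnitude is capped by the rigid-filtered share of the PV
  expect_equal(which.max(abs(sp$projection)), 2L)
  cap <- modeOverlap(syn$truth@fields[, "slide"], syn$truth@modes[, 2])
  expect_gt(abs(sp$projection[2]), 0.75)
  expect_lte(abs(sp$projection[2]), cap + 0.02)
})

test_that("chain-swapping apo and holo yields the chain-swapped PV", {
  set.seed(44)
  spec <- tinySpec()
  tmpl <- makeTemplate(spec)
  lab <- siteLabels(tmpl)
  disp <- matrix(rnorm(3 * nSites(tmpl), sd = 0.05), ncol = 3)
  holo <- makeSiteSet(lab, matrix(siteCoords(tmpl), ncol = 3, byrow = TRUE) + disp)
  a4 <- list(A = spec$helixRanges[4L, , drop = FALSE],
             B = spec$helixRanges[4L, , drop = FALSE])
  pv <- buildPistonVector(tmpl, holo, a4, fitSites = "none", orient = "raw")
  pvSw <- buildPistonVector(swapChains(tmpl), swapChains(holo), a4,
                            fitSites = "none", orient = "raw")
  # swapping the PV's site order must reproduce the swapped-build PV
  perm <- receptorModes:::.swapPermutation(lab, NULL)
  idx <- as.vector(t(cbind(3 * perm - 2, 3 * perm - 1, 3 * perm)))
  expect_equal(pvVector(pvSw), pvVector(pv)[idx], tolerance = 1e-10)
})
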