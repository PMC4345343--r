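test_that("the diatomic spring network matches its closed form", {
  p <- anmParameters()
  # beyond the cutoff: no springs at all
  H0 <- anmHessian(c(0, 0, 0, 2, 0, 0), p)
  expect_equal(max(abs(H0)), 0)
  # within the cutoff: stretch mode along the bond
  H <- anmHessian(c(0, 0, 0, 1, 0, 0), p)
  expect_equal(H[1:3, 4:6], diag(c(-100, 0, 0)), tolerance = 1e-12)
  md <- anmModes(H, data.frame(chain = "A", resno = 1:2), c(0, 0, 0, 1, 0, 0))
  expect_equal(md@meta$nZero, 5L)             # collinear: 5 rigid dof
  expect_equal(modeValues(md), 200, tolerance = 1e-9)   # 2 * gamma
})

test_that("the analytic Hessian equals the numerical Hessian of the energy", {
  p <- anmParameters()
  h <- 1e-4
  set.seed(31)
  for (rep in 1:2) {
    x0 <- randomSites(20)
    H <- anmHessian(x0, p)
    n3 <- length(x0)
    fd <- matrix(0, n3, n3)
    for (a in seq_len(n3)) for (b in a:n3) {
      ea <- eb <- rep(0, n3); ea[a] <- h; eb[b] <- h
      v <- (anmEnergy(x0 + ea + eb, x0, p) - anmEnergy(x0 + ea - eb, x0, p) -
            anmEnergy(x0 - ea + eb, x0, p) + anmEnergy(x0 - ea - eb, x0, p)) /
           (4 * h^2)
      fd[a, b] <- fd[b, a] <- v
    }
    expect_lt(max(abs(fd - H)), 1e-4)
  }
})

test_that("the Hessian is translation-invariant and positive semidefinite", {
  set.seed(32)
  x0 <- randomSites(15)
  H <- anmHessian(x0, anmParameters())
  n <- 15L
  for (i in seq_len(n)) {
    rows <- (3 * i - 2):(3 * i)
    blockSum <- matrix(0, 3, 3)
    for (j in seq_len(n))
      blockSum <- blockSum + H[rows, (3 * j - 2):(3 * j)]
    expect_lt(max(abs(blockSum)), 1e-10)
  }
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * max(ev))
})

test_that("gamma scales eigenvalues but not eigenvectors", {
  set.seed(33)
  x0 <- randomSites(12)
  m1 <- anmModes(anmHessian(x0, anmParameters(gamma = 100)),
                 data.frame(chain = "A", resno = 1:12), x0)
  m2 <- anmModes(anmHessian(x0, anmParameters(gamma = 200)),
                 data.frame(chain = "A", resno = 1:12), x0)
  expect_equal(modeValues(m2), 2 * modeValues(m1), tolerance = 1e-9)
  for (k in 1:5)
    expect_equal(modeOverlap(modeVectors(m1)[, k], modeVectors(m2)[, k]), 1,
                 tolerance = 1e-10)
})

test_that("zero-mode counting flags disconnected networks", {
  set.seed(34)
  x0 <- randomSites(10)
  md <- anmModes(anmHessian(x0, anmParameters()),
                 data.frame(chain = "A", resno = 1:10), x0)
  expect_equal(md@meta$nZero, 6L)
  # two fragments farther apart than the cutoff: 12 zero modes
  far <- c(randomSites(5), randomSites(5) + rep(c(50, 0, 0), 5))
  expect_error(anmModes(anmHessian(far, anmParameters()),
                        data.frame(chain = "A", resno = 1:10), far),
               "disconnected-network")
  expect_error(anmHessian(c(0, 0, 0, 0, 0, 0), anmParameters()),
               "coincident")
})

test_that("overlaps follow the normalized dot product and Parseval", {
  expect_equal(modeOverlap(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(modeOverlap(c(1, 0, 0), c(0, 1, 0)), 0)
  expect_equal(modeOverlap(c(0.6, 0.8, 0, 0), c(1, 0, 0, 0)), 0.6,
               tolerance = 1e-12)
  expect_error(modeOverlap(c(0, 0), c(1, 1)), "undefined-overlap")

  set.seed(35)
  x0 <- randomSites(10)
  lab <- data.frame(chain = "A", resno = 1:10)
  md <- anmModes(anmHessian(x0, anmParameters()), lab, x0)
  self <- overlapMatrix(md, md)
  expect_equal(self@values, diag(ncol(modeVectors(md))), tolerance = 1e-9)
  # rows against a complete basis satisfy Parseval
  C <- crossprod(matrix(rnorm(900), 30))
  full <- pcaModes(C, x0, lab)
  om <- overlapMatrix(md, full)
  expect_equal(unname(rowSums(om@values^2)), rep(1, nrow(om@values)),
               tolerance = 1e-8)
})

test_that("the tuned weakly-connected bundle has a slide-like first mode", {
  spec <- shortBundleSpec()
  tmpl <- makeTemplate(spec)
  truth <- plantedModes(tmpl, spec)
  anm <- anmSiteSet(tmpl)
  expect_equal(anm@meta$nZero, 6L)
  expect_gt(modeOverlap(modeVectors(anm)[, 1], truth@modes[, 2]), 0.7)
})

test_that("ANM modes agree with an independent implementation", {
  skip_if_not_installed("bio3d")
  spec <- shortBundleSpec()
  tmpl <- makeTemplate(spec)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeEnsemblePDB(tmpl, f)
  pdb <- bio3d::read.pdb(f)
  # bio3d warns about multi-chain input; only the eigenvectors are compared
  ref <- suppressWarnings(
    bio3d::nma(pdb, ff = "anm", cutoff = 15, mass = FALSE, temp = NULL))
  mine <- anmSiteSet(tmpl, anmParameters(rc = 1.5))
  for (k in 1:3)
    expect_gt(modeOverlap(modeVectors(mine)[, k],
                          ref$modes[, 6 + k]), 0.999)
})
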