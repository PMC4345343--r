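# Synthetic dimer templates and ensembles with planted, correlated
# collective modes. The generator emulates the statistical structure of a
# C-alpha trajectory of a two-chain four-helix-bundle dimer: a template,
# two planted orthonormal modes (anti-symmetric inter-monomer rotation and
# alpha4 axial slide), correlated Gaussian mode amplitudes with optional
# multi-basin mixtures, isotropic site noise, and per-frame random rigid
# poses. No physics is emulated, only statistics.

#' Synthetic-ensemble specification
#'
#' Defaults define the package's reference study conditions: Tar-like helix
#' ranges on two chains (228 sites), ideal helices (rise 0.15 nm/residue,
#' helix radius 0.23 nm, 100 degrees/residue), planted rotation/slide modes
#' with amplitude standard deviations 0.2 and 0.1 nm (variances 0.04 and
#' 0.01 nm^2), amplitude correlation 0.6, site noise sigma = 0.01 nm,
#' M = 5000 frames, a single basin at the origin, and per-frame random
#' rigid poses switched on.
#'
#' @param helixRanges 4 x 2 matrix of per-monomer helix residue ranges
#' @param alpha4Helix index of the alpha4 helix within \code{helixRanges}
#' @param rise helical rise per residue (nm)
#' @param helixRadius C-alpha helix radius (nm)
#' @param phiStep helical twist per residue (degrees)
#' @param bundleRadius distance of the core helix axes from the bundle axis
#'   (nm)
#' @param alpha4Radius distance of the alpha4 helix axis from the bundle
#'   axis (nm); placing it outboard gives it fewer network contacts than
#'   the core
#' @param modeSd amplitude standard deviations (nm) of the planted modes,
#'   named rotation/slide
#' @param modeCorrelation correlation between the two mode amplitudes
#' @param noiseSd isotropic per-coordinate Gaussian site noise (nm)
#' @param basins data.frame(rotation, slide, weight): mode-space basin
#'   centers (nm) and mixture weights summing to 1
#' @param M number of frames
#' @param seed RNG seed for \code{\link{sampleEnsemble}}
#' @param rigidJitter apply a random rigid transform to every frame?
#' @param rigidTransSd standard deviation of the random translation (nm)
#' @return a validated spec list
#' @export
syntheticSpec <- function(helixRanges = tarHelixRanges(chains = "A")[["A"]],
                          alpha4Helix = 4L,
                          rise = 0.15, helixRadius = 0.23, phiStep = 100,
                          bundleRadius = 0.8, alpha4Radius = 1.6,
                          modeSd = c(rotation = 0.2, slide = 0.1),
                          modeCorrelation = 0.6,
                          noiseSd = 0.01,
                          basins = data.frame(rotation = 0, slide = 0,
                                              weight = 1),
                          M = 5000L, seed = 1L,
                          rigidJitter = TRUE, rigidTransSd = 0.5) {
  stopifnot(is.matrix(helixRanges), ncol(helixRanges) == 2L)
  if (any(modeSd < 0) || noiseSd < 0 || M < 1L)
    stop("validation error: modeSd and noiseSd must be >= 0 and M >= 1")
  if (abs(modeCorrelation) >= 1)
    stop("validation error: |modeCorrelation| must be < 1")
  if (abs(sum(basins$weight) - 1) > 1e-9 || any(basins$weight < 0))
    stop("validation error: basin weights must be nonnegative and sum to 1")
  list(helixRanges = helixRanges, alpha4Helix = as.integer(alpha4Helix),
       rise = rise, helixRadius = helixRadius, phiStep = phiStep,
       bundleRadius = bundleRadius, alpha4Radius = alpha4Radius,
       modeSd = modeSd, modeCorrelation = modeCorrelation,
       noiseSd = noiseSd, basins = basins, M = as.integer(M),
       seed = seed, rigidJitter = rigidJitter, rigidTransSd = rigidTransSd)
}

# Amplitude covariance implied by a spec (2 x 2, nm^2).
.modeCovariance <- function(spec) {
  s <- spec$modeSd
  corr <- matrix(c(1, spec$modeCorrelation, spec$modeCorrelation, 1), 2L)
  diag(s) %*% corr %*% diag(s)
}

#' Idealised C2-symmetric four-helix-bundle dimer template
#'
#' Two chains (A, B) of four straight ideal-helix C-alpha traces arranged
#' as an antiparallel bundle around the z axis; chain B is the exact C2
#' image (180-degree rotation about z) of chain A. Residue numbering
#' follows the spec's helix ranges so that selection logic is exercised
#' end-to-end. The alpha4 helix sits at \code{alpha4Radius}, outboard of the
#' core helices.
#'
#' @param spec a \code{\link{syntheticSpec}}
#' @return a \linkS4class{SiteSet} (chain A sites then chain B sites)
#' @export
makeTemplate <- function(spec = syntheticSpec()) {
  hr <- spec$helixRanges
  nh <- nrow(hr)
  if (spec$alpha4Helix < 1L || spec$alpha4Helix > nh)
    stop("parameter error: alpha4Helix index out of range")
  # helix axis placements for chain A: core helices spread over a half
  # plane, alpha4 outboard; antiparallel directions alternate
  angles <- seq(150, 30, length.out = nh) * pi / 180
  radii <- rep(spec$bundleRadius, nh)
  radii[spec$alpha4Helix] <- spec$alpha4Radius
  dirs <- rep(c(1, -1), length.out = nh)
  coordsA <- list(); labsA <- list()
  for (h in seq_len(nh)) {
    res <- hr[h, 1L]:hr[h, 2L]
    n <- length(res)
    axis <- c(radii[h] * cos(angles[h]), radii[h] * sin(angles[h]))
    t <- seq_len(n) - (n + 1) / 2
    z <- dirs[h] * t * spec$rise
    phi <- dirs[h] * (seq_len(n) - 1L) * spec$phiStep * pi / 180
    coordsA[[h]] <- cbind(axis[1] + spec$helixRadius * cos(phi),
                          axis[2] + spec$helixRadius * sin(phi),
                          z)
    labsA[[h]] <- data.frame(chain = "A", resno = res)
  }
  xyzA <- do.call(rbind, coordsA)
  labA <- do.call(rbind, labsA)
  oA <- order(labA$resno)
  xyzA <- xyzA[oA, , drop = FALSE]
  labA <- labA[oA, , drop = FALSE]
  xyzB <- cbind(-xyzA[, 1L], -xyzA[, 2L], xyzA[, 3L])   # exact C2 about z
  labB <- data.frame(chain = "B", resno = labA$resno)
  makeSiteSet(rbind(labA, labB), rbind(xyzA, xyzB),
              selection = list(ranges = list(A = hr, B = hr)))
}

# alpha4 ranges of a spec, for both chains.
.specAlpha4 <- function(spec) {
  r <- spec$helixRanges[spec$alpha4Helix, , drop = TRUE]
  list(A = matrix(as.integer(r), ncol = 2L),
       B = matrix(as.integer(r), ncol = 2L))
}

#' Planted collective-mode vectors for a template
#'
#' Builds the two raw geometric fields — the anti-symmetric inter-monomer
#' rotation (chain A displaced by an infinitesimal rotation +theta about
#' the bundle axis, chain B by -theta) and the alpha4 axial slide (both
#' chains' alpha4 sites displaced along -z) — then projects out the
#' template's six rigid-body fields and Gram-Schmidt-orthonormalises in
#' listed order. The rigid-body filtering puts the planted truth in the
#' model class of superposition-based PCA, whose modes are orthogonal to
#' rigid motions by construction; the raw unit fields are retained in the
#' \code{fields} slot for geometric comparisons such as the piston vector.
#'
#' @param template a \linkS4class{SiteSet} from \code{\link{makeTemplate}}
#' @param spec the generating \code{\link{syntheticSpec}}
#' @return a \linkS4class{GroundTruth} (without amplitudes)
#' @export
plantedModes <- function(template, spec = syntheticSpec()) {
  stopifnot(is(template, "SiteSet"))
  lab <- siteLabels(template)
  xyz <- .asXYZ(siteCoords(template))
  n <- nrow(xyz)
  # raw anti-symmetric rotation field: z x r per site, sign per chain
  sgn <- ifelse(lab$chain == lab$chain[1L], 1, -1)
  rot <- cbind(-xyz[, 2L], xyz[, 1L], 0) * sgn
  rot <- .flattenXYZ(rot)
  rot <- rot / sqrt(sum(rot^2))
  # raw alpha4 slide field: unit -z on alpha4 sites of both chains
  mask <- .rangeMask(lab, .specAlpha4(spec))
  slide <- matrix(0, n, 3L)
  slide[mask, 3L] <- -1
  slide <- .flattenXYZ(slide)
  slide <- slide / sqrt(sum(slide^2))
  fields <- cbind(rotation = rot, slide = slide)
  # rigid-body filter + Gram-Schmidt in listed order
  Q <- .rigidBasis(siteCoords(template))
  modes <- fields
  for (k in seq_len(ncol(modes))) {
    v <- .projectOut(modes[, k], Q)
    if (k > 1L)
      for (j in seq_len(k - 1L)) v <- v - sum(v * modes[, j]) * modes[, j]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-8)
      stop("degeneracy error: planted field ", k,
           " is linearly dependent on rigid-body motions or earlier fields")
    modes[, k] <- v / nv
  }
  new("GroundTruth", template = template, modes = modes, fields = fields,
      spec = spec)
}

#' Sample a synthetic ensemble with planted modes
#'
#' Per frame: draw a basin by its weight, draw correlated Gaussian mode
#' amplitudes about the basin center, displace the template along the
#' planted modes, add isotropic Gaussian site noise, and (optionally)
#' apply a random rigid pose. Fully reproducible from \code{spec$seed}.
#'
#' @param truth a \linkS4class{GroundTruth} from \code{\link{plantedModes}}
#' @param spec the \code{\link{syntheticSpec}} (defaults to the truth's)
#' @return list with \code{ensemble} (\linkS4class{Ensemble}) and
#'   \code{truth} (the input \linkS4class{GroundTruth} with per-frame
#'   amplitudes and basin labels filled in)
#' @export
sampleEnsemble <- function(truth, spec = NULL) {
  stopifnot(is(truth, "GroundTruth"))
  if (is.null(spec)) spec <- truth@spec
  tmpl <- siteCoords(truth@template)
  V <- truth@modes
  K <- ncol(V)
  M <- spec$M
  set.seed(spec$seed)
  nb <- nrow(spec$basins)
  basin <- if (nb == 1L) rep(1L, M)
           else sample.int(nb, M, replace = TRUE, prob = spec$basins$weight)
  # square root via eigendecomposition (tolerates singular covariances,
  # e.g. a zero-variance mode)
  S <- .modeCovariance(spec)
  es <- eigen(S, symmetric = TRUE)
  L <- es$vectors %*% diag(sqrt(pmax(es$values, 0)), K) %*% t(es$vectors)
  z <- matrix(rnorm(M * K), M, K)
  amp <- z %*% L
  amp[, 1L] <- amp[, 1L] + spec$basins$rotation[basin]
  amp[, 2L] <- amp[, 2L] + spec$basins$slide[basin]
  frames <- matrix(rep(tmpl, each = M), M, length(tmpl))
  frames <- frames + amp %*% t(V)
  if (spec$noiseSd > 0)
    frames <- frames + matrix(rnorm(M * length(tmpl), sd = spec$noiseSd),
                              M, length(tmpl))
  if (isTRUE(spec$rigidJitter)) {
    for (m in seq_len(M)) {
      R <- .randomRotation()
      tr <- rnorm(3L, sd = spec$rigidTransSd)
      frames[m, ] <- .flattenXYZ(sweep(.asXYZ(frames[m, ]) %*% R, 2L, tr, "+"))
    }
  }
  ens <- makeEnsemble(siteLabels(truth@template), frames,
                      provenance = list(source = "synthetic",
                                        seed = spec$seed, M = M))
  truth@amplitudes <- amp
  truth@basin <- as.integer(basin)
  truth@spec <- spec
  list(ensemble = ens, truth = truth)
}

#' Template, planted modes and sampled ensemble in one call
#' @param spec a \code{\link{syntheticSpec}}
#' @return list with \code{ensemble}, \code{truth} and \code{template}
#' @export
syntheticEnsemble <- function(spec = syntheticSpec()) {
  template <- makeTemplate(spec)
  truth <- plantedModes(template, spec)
  out <- sampleEnsemble(truth, spec)
  list(ensemble = out$ensemble, truth = out$truth, template = template)
}

#' Two-basin landscape fixture
#'
#' A fixed-seed ensemble whose mode-space amplitude distribution is a
#' two-component mixture with centers (0.15, 0.75) and (1.53, -1.83) nm and
#' weights 0.7/0.3 — the shape of a one-attractant-bound conformational
#' landscape with a symmetric basin and a rotated/piston-down basin.
#'
#' @param M number of frames
#' @param seed RNG seed
#' @param weights basin weights (length 2, summing to 1)
#' @return list with \code{ensemble}, \code{truth} and \code{template}
#' @export
twoBasinFixture <- function(M = 3000L, seed = 2015L, weights = c(0.7, 0.3)) {
  spec <- syntheticSpec(
    basins = data.frame(rotation = c(0.15, 1.53), slide = c(0.75, -1.83),
                        weight = weights),
    M = M, seed = seed)
  syntheticEnsemble(spec)
}

#' ModeBasis view of planted ground-truth modes
#'
#' Wraps the planted orthonormal mode vectors as a \linkS4class{ModeBasis}
#' centered on the template, so frames can be projected onto the ground
#' truth with \code{\link{projectEnsemble}}.
#'
#' @param truth a \linkS4class{GroundTruth}
#' @return a \linkS4class{ModeBasis} of kind "pca" whose eigenvalues are the
#'   planted amplitude variances
#' @export
truthBasis <- function(truth) {
  stopifnot(is(truth, "GroundTruth"))
  vals <- as.numeric(diag(.modeCovariance(truth@spec)))
  o <- order(-vals)
  new("ModeBasis", labels = siteLabels(truth@template),
      center = siteCoords(truth@template),
      values = vals[o], vectors = truth@modes[, o, drop = FALSE],
      kind = "pca", meta = list(groundTruth = TRUE))
}
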