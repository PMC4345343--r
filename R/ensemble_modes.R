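# Ensemble PCA: iterative mean structure, 3N x 3N coordinate covariance,
# eigenmodes, projections and mode extrapolation.

# Kabsch-fit every frame onto a reference; returns the fitted frame matrix.
.fitFramesTo <- function(frames, ref) {
  out <- frames
  refXYZ <- .asXYZ(ref)
  cr <- colMeans(refXYZ)
  Bc <- sweep(refXYZ, 2L, cr)
  for (m in seq_len(nrow(frames))) {
    A <- .asXYZ(frames[m, ])
    cm <- colMeans(A)
    Ac <- sweep(A, 2L, cm)
    s <- svd(crossprod(Ac, Bc))
    d <- sign(det(s$v %*% t(s$u))); if (d == 0) d <- 1
    R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
    out[m, ] <- .flattenXYZ(sweep(Ac %*% R, 2L, cr, "+"))
  }
  out
}

#' Iterative mean structure of an ensemble
#'
#' Alternates (i) Kabsch-fitting all frames to the current mean and (ii)
#' recomputing the mean, until the raw RMSD between successive means drops
#' below \code{tol}. The returned mean is exactly the average of the
#' returned fitted frames, so fitted displacements sum to zero.
#'
#' @param e an \linkS4class{Ensemble} with at least 2 frames
#' @param tol convergence tolerance on the mean displacement RMSD (nm)
#' @param maxIter maximum number of fit/average iterations
#' @return list with \code{mean} (flat 3N vector, nm) and \code{fitted}
#'   (the superposed \linkS4class{Ensemble})
#' @export
iterativeMean <- function(e, tol = 1e-6, maxIter = 100L) {
  stopifnot(is(e, "Ensemble"))
  if (nFrames(e) < 2L) stop("insufficient-data error: need at least 2 frames")
  mean0 <- e@frames[1L, ]
  fitted <- e@frames
  change <- Inf
  for (it in seq_len(maxIter)) {
    fitted <- .fitFramesTo(e@frames, mean0)
    mean1 <- colMeans(fitted)
    change <- sqrt(sum((mean1 - mean0)^2) / (length(mean0) / 3L))
    mean0 <- mean1
    if (change < tol) {
      # one final fit so the returned mean is the exact average of the
      # returned frames
      fitted <- .fitFramesTo(e@frames, mean0)
      mean0 <- colMeans(fitted)
      fe <- makeEnsemble(e@labels, fitted,
                         c(e@provenance, list(fitted = TRUE, iterations = it)))
      return(list(mean = mean0, fitted = fe))
    }
  }
  stop("convergence error: iterative mean did not converge in ", maxIter,
       " iterations (last change ", signif(change, 3), " nm)")
}

#' Coordinate covariance of a superposed ensemble
#'
#' \eqn{C = (1/M) \sum_m (x_m - \bar x)(x_m - \bar x)^T} with the population
#' divisor 1/M. Frames are assumed already superposed onto \code{mean}.
#'
#' @param fitted a superposed \linkS4class{Ensemble}
#' @param mean flat 3N mean coordinates (nm)
#' @return 3N x 3N symmetric positive semidefinite matrix (nm^2)
#' @export
coordCovariance <- function(fitted, mean) {
  stopifnot(is(fitted, "Ensemble"))
  M <- nFrames(fitted)
  if (M < 2L) stop("insufficient-data error: need at least 2 frames")
  X <- sweep(fitted@frames, 2L, mean)
  crossprod(X) / M
}

#' PCA mode basis from a covariance matrix
#'
#' Full eigendecomposition with eigenvalues sorted descending. The sign of
#' each eigenvector is fixed so that its largest-magnitude component is
#' positive.
#'
#' @param C symmetric covariance matrix (nm^2)
#' @param mean flat 3N mean coordinates the covariance was taken about (nm)
#' @param labels site label data.frame
#' @return a \linkS4class{ModeBasis} of kind "pca"
#' @export
pcaModes <- function(C, mean, labels) {
  if (max(abs(C - t(C))) > 1e-10)
    stop("validation error: covariance matrix must be symmetric")
  dec <- eigen(C, symmetric = TRUE)   # eigen() returns descending order
  V <- dec$vectors
  for (k in seq_len(ncol(V))) {
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) V[, k] <- -V[, k]
  }
  new("ModeBasis", labels = labels, center = as.numeric(mean),
      values = pmax(dec$values, 0), vectors = V, kind = "pca",
      meta = list(trace = sum(diag(C))))
}

#' Ensemble PCA in one call
#'
#' Convenience wrapper: iterative mean, covariance, eigenmodes.
#'
#' @param e an \linkS4class{Ensemble}
#' @param tol,maxIter passed to \code{\link{iterativeMean}}
#' @return list with \code{basis} (\linkS4class{ModeBasis}), \code{fitted}
#'   (superposed \linkS4class{Ensemble}) and \code{mean}
#' @export
ensemblePCA <- function(e, tol = 1e-6, maxIter = 100L) {
  im <- iterativeMean(e, tol = tol, maxIter = maxIter)
  C <- coordCovariance(im$fitted, im$mean)
  basis <- pcaModes(C, im$mean, e@labels)
  list(basis = basis, fitted = im$fitted, mean = im$mean)
}

#' Project ensemble frames onto mode eigenvectors
#'
#' \eqn{pe_k = (x - \bar x) \cdot v_k} per frame, in nm. With
#' \code{fit = TRUE} each frame is first Kabsch-fitted to the basis mean;
#' use \code{fit = FALSE} for ensembles already superposed (e.g. the fitted
#' ensemble returned by \code{\link{iterativeMean}}), in which case
#' projections have exactly zero mean over frames by construction.
#'
#' @param e an \linkS4class{Ensemble} (labels must match the basis)
#' @param basis a \linkS4class{ModeBasis}
#' @param K number of leading modes to project onto
#' @param fit superpose frames onto the basis mean first?
#' @return data.frame(frame, pe1, ..., peK)
#' @export
projectEnsemble <- function(e, basis, K = 2L, fit = TRUE) {
  stopifnot(is(e, "Ensemble"), is(basis, "ModeBasis"))
  .stopIfLabelMismatch(e@labels, basis@labels, "ensemble and basis")
  K <- as.integer(K)
  if (K < 1L || K > ncol(basis@vectors))
    stop("index error: K must be between 1 and the basis mode count")
  frames <- if (fit) .fitFramesTo(e@frames, basis@center) else e@frames
  X <- sweep(frames, 2L, basis@center)
  pe <- X %*% basis@vectors[, seq_len(K), drop = FALSE]
  out <- data.frame(frame = seq_len(nrow(pe)))
  for (k in seq_len(K)) out[[paste0("pe", k)]] <- pe[, k]
  out
}

#' Project a single SiteSet onto mode eigenvectors
#' @param s a \linkS4class{SiteSet}
#' @param basis a \linkS4class{ModeBasis}
#' @param K number of leading modes
#' @param fit superpose onto the basis mean first?
#' @return numeric vector pe_1..pe_K (nm)
#' @export
projectSiteSet <- function(s, basis, K = 2L, fit = TRUE) {
  e <- makeEnsemble(siteLabels(s), matrix(siteCoords(s), nrow = 1L))
  unlist(projectEnsemble(e, basis, K = K, fit = fit)[1L, -1L])
}

#' Extrapolate coordinates along one mode
#'
#' Moves the sites from the basis mean along eigenvector k:
#' \code{mean + amplitude * v_k}.
#'
#' @param basis a \linkS4class{ModeBasis}
#' @param k mode index
#' @param amplitude displacement amplitude (nm)
#' @return a \linkS4class{SiteSet}
#' @export
extrapolateMode <- function(basis, k, amplitude) {
  stopifnot(is(basis, "ModeBasis"))
  k <- as.integer(k)
  if (k < 1L || k > ncol(basis@vectors))
    stop("index error: mode index out of range")
  makeSiteSet(basis@labels, basis@center + amplitude * basis@vectors[, k])
}

#' Rigidly align a mode basis onto reference coordinates
#'
#' Superposes the basis mean onto \code{reference} and rotates the
#' eigenvectors accordingly, so that mode vectors can be compared with
#' fields defined in the reference frame (e.g. planted ground-truth modes).
#'
#' @param basis a \linkS4class{ModeBasis}
#' @param reference SiteSet or flat 3N coordinates (nm)
#' @return the rotated \linkS4class{ModeBasis}
#' @export
alignBasisTo <- function(basis, reference) {
  stopifnot(is(basis, "ModeBasis"))
  rv <- .coordsOf(reference)
  kb <- kabschSuperpose(basis@center, rv)
  R <- kb$transform@rotation
  rotVec <- function(v) .flattenXYZ(.asXYZ(v) %*% R)
  V <- apply(basis@vectors, 2L, rotVec)
  new("ModeBasis", labels = basis@labels,
      center = applyTransform(basis@center, kb$transform),
      values = basis@values, vectors = V, kind = basis@kind,
      meta = c(basis@meta, list(alignedRMSD = kb$rmsd)))
}
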