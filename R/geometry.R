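# Rigid-body superposition (Kabsch) and the two pairwise structural metrics
# (RMSD, DRMS). DRMS is superposition-free; RMSD is reported after an
# optimal least-squares fit unless fit = FALSE.

.coordsOf <- function(x) {
  if (is(x, "SiteSet")) return(siteCoords(x))
  as.numeric(x)
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares proper rotation and translation minimising the RMSD of the
#' mobile coordinates onto the reference. The returned transform is applied
#' to row-vector coordinates as \code{y = x \%*\% rotation + translation};
#' reflections are never returned.
#'
#' @param mobile SiteSet or flat 3N coordinates (nm)
#' @param reference SiteSet or flat 3N coordinates (nm)
#' @return list with elements \code{transform} (\linkS4class{RigidTransform}),
#'   \code{rmsd} (nm) and \code{unique} (FALSE when the covariance is
#'   rank-deficient, e.g. collinear sites, and the minimiser is not unique)
#' @export
kabschSuperpose <- function(mobile, reference) {
  mv <- .coordsOf(mobile); rv <- .coordsOf(reference)
  if (length(mv) != length(rv))
    stop("dimension error: coordinate lengths differ")
  A <- .asXYZ(mv); B <- .asXYZ(rv)
  n <- nrow(A)
  if (n < 3L) stop("dimension error: at least 3 sites are required")
  cm <- colMeans(A); cr <- colMeans(B)
  Ac <- sweep(A, 2L, cm); Bc <- sweep(B, 2L, cr)
  H <- crossprod(Ac, Bc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  uniq <- TRUE
  if (s$d[2L] < 1e-12 * max(s$d[1L], 1e-300)) {
    warning("degenerate-geometry: sites are (nearly) collinear; ",
            "superposition is a valid but non-unique minimiser")
    uniq <- FALSE
  }
  rmsd <- sqrt(sum((Ac %*% R - Bc)^2) / n)   # explicit residual: no cancellation
  tr <- new("RigidTransform", rotation = R,
            translation = as.numeric(cr - cm %*% R))
  list(transform = tr, rmsd = rmsd, unique = uniq)
}

#' Apply a rigid transform to coordinates
#' @param x SiteSet, flat 3N vector, or N x 3 matrix (nm)
#' @param transform a \linkS4class{RigidTransform}
#' @return object of the same shape as \code{x}
#' @export
applyTransform <- function(x, transform) {
  stopifnot(is(transform, "RigidTransform"))
  tf <- function(m) sweep(m %*% transform@rotation, 2L,
                          transform@translation, "+")
  if (is(x, "SiteSet"))
    return(makeSiteSet(siteLabels(x), tf(.asXYZ(siteCoords(x))), x@selection))
  if (is.matrix(x) && ncol(x) == 3L) return(tf(x))
  .flattenXYZ(tf(.asXYZ(as.numeric(x))))
}

#' Root mean square deviation between two site sets
#'
#' With \code{fit = TRUE} (default) the RMSD after optimal Kabsch
#' superposition; with \code{fit = FALSE} the raw coordinate RMSD
#' \eqn{\sqrt{(1/N)\sum_i \|a_i - b_i\|^2}}.
#'
#' @param a,b SiteSets (labels must match) or flat 3N vectors
#' @param fit superpose before measuring?
#' @return RMSD in nm
#' @export
calcRMSD <- function(a, b, fit = TRUE) {
  if (is(a, "SiteSet") && is(b, "SiteSet"))
    .stopIfLabelMismatch(siteLabels(a), siteLabels(b))
  av <- .coordsOf(a); bv <- .coordsOf(b)
  if (length(av) != length(bv)) stop("dimension error: coordinate lengths differ")
  if (fit) return(kabschSuperpose(av, bv)$rmsd)
  sqrt(sum((av - bv)^2) / (length(av) / 3L))
}

# All-pairs intramolecular distances of a flat coordinate vector.
.pairDistances <- function(v) as.vector(dist(.asXYZ(v)))

#' Distance root mean square between two conformations
#'
#' \eqn{DRMS = \sqrt{(1/P) \sum_{i<j} (d_{ij}^a - d_{ij}^b)^2}} over all
#' P = N(N-1)/2 site pairs; invariant under rigid transforms of either input
#' (no superposition is performed).
#'
#' @param a,b SiteSets (labels must match) or flat 3N vectors
#' @return DRMS in nm
#' @export
calcDRMS <- function(a, b) {
  if (is(a, "SiteSet") && is(b, "SiteSet"))
    .stopIfLabelMismatch(siteLabels(a), siteLabels(b))
  av <- .coordsOf(a); bv <- .coordsOf(b)
  if (length(av) != length(bv)) stop("dimension error: coordinate lengths differ")
  if (length(av) < 6L) stop("dimension error: DRMS needs at least 2 sites")
  da <- .pairDistances(av); db <- .pairDistances(bv)
  sqrt(mean((da - db)^2))
}

#' Pairwise metric matrix over an ensemble
#'
#' Computes all M(M-1)/2 frame pairs. The RMSD variant fits every pair
#' independently (pairwise Kabsch, not a common reference); the DRMS variant
#' uses the superposition-free distance-matrix metric.
#'
#' @param e an \linkS4class{Ensemble} with at least 2 frames
#' @param metric "rmsd" or "drms"
#' @return a \linkS4class{PairwiseMatrix}
#' @export
pairwiseMatrix <- function(e, metric = c("rmsd", "drms")) {
  stopifnot(is(e, "Ensemble"))
  metric <- match.arg(metric)
  M <- nFrames(e)
  if (M < 2L) stop("input error: pairwise matrix needs at least 2 frames")
  vals <- matrix(0, M, M)
  if (metric == "drms") {
    D <- t(apply(e@frames, 1L, .pairDistances))    # M x P
    P <- ncol(D)
    vals <- as.matrix(dist(D)) / sqrt(P)
    dimnames(vals) <- NULL
  } else {
    n <- nSites(e)
    centered <- vector("list", M)
    for (m in seq_len(M)) {
      xyz <- .asXYZ(e@frames[m, ])
      centered[[m]] <- sweep(xyz, 2L, colMeans(xyz))
    }
    for (i in seq_len(M - 1L)) for (j in (i + 1L):M) {
      s <- svd(crossprod(centered[[i]], centered[[j]]))
      d <- sign(det(s$v %*% t(s$u))); if (d == 0) d <- 1
      R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
      vals[i, j] <- vals[j, i] <-
        sqrt(sum((centered[[i]] %*% R - centered[[j]])^2) / n)
    }
  }
  new("PairwiseMatrix", values = vals, metric = metric)
}

#' Histogram of the upper-triangle values of a pairwise matrix
#' @param m a \linkS4class{PairwiseMatrix}
#' @param breaks passed to \code{hist}
#' @return data.frame(center, count), suitable for TSV export
#' @export
pairwiseHistogram <- function(m, breaks = 50L) {
  stopifnot(is(m, "PairwiseMatrix"))
  v <- m@values[upper.tri(m@values)]
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  data.frame(center = h$mids, count = h$counts)
}
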