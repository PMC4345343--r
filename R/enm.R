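# Anisotropic network model: Hessian construction, normal modes with
# rigid-body zero-mode removal, and overlap analysis between mode sets.

#' ANM parameters
#'
#' Defaults follow common coarse-grained practice for C-alpha networks:
#' cutoff \code{rc} = 1.5 nm and uniform spring constant \code{gamma} =
#' 100 kcal mol^-1 nm^-2. The spring constant scales eigenvalues only; mode
#' directions are independent of it.
#'
#' @param rc interaction cutoff (nm), > 0
#' @param gamma uniform spring constant (kcal mol^-1 nm^-2), > 0
#' @return list of validated parameters
#' @export
anmParameters <- function(rc = 1.5, gamma = 100) {
  if (!is.numeric(rc) || rc <= 0) stop("parameter error: rc must be > 0")
  if (!is.numeric(gamma) || gamma <= 0) stop("parameter error: gamma must be > 0")
  list(rc = rc, gamma = gamma)
}

# Contact list (i < j pairs within the cutoff) for a coordinate set.
.anmContacts <- function(xyz, rc) {
  d <- as.matrix(dist(xyz))
  which(upper.tri(d) & d <= rc, arr.ind = TRUE)
}

#' ANM Hessian of a coordinate set
#'
#' Standard anisotropic-network Hessian: for each pair (i, j) within the
#' cutoff, the off-diagonal 3x3 block is
#' \eqn{H_{ij} = -\gamma\, r_{ij} r_{ij}^T / |r_{ij}|^2} with \eqn{r_{ij}}
#' the equilibrium separation; diagonal blocks are
#' \eqn{H_{ii} = -\sum_{j \ne i} H_{ij}}. The result is symmetric positive
#' semidefinite with zero block-row sums (translation invariance).
#'
#' @param x SiteSet or flat 3N coordinates (nm)
#' @param params list from \code{\link{anmParameters}}
#' @return 3N x 3N Hessian matrix
#' @export
anmHessian <- function(x, params = anmParameters()) {
  v <- .coordsOf(x)
  xyz <- .asXYZ(v)
  n <- nrow(xyz)
  if (n < 2L) stop("geometry error: at least 2 sites are required")
  dm <- as.matrix(dist(xyz))
  if (any(dm[upper.tri(dm)] < 1e-6))
    stop("geometry error: coincident sites (distance < 1e-6 nm)")
  H <- matrix(0, 3L * n, 3L * n)
  pairs <- which(upper.tri(dm) & dm <= params$rc, arr.ind = TRUE)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1L]; j <- pairs[p, 2L]
    r <- xyz[j, ] - xyz[i, ]
    blk <- -params$gamma * tcrossprod(r) / sum(r^2)
    ii <- (3L * i - 2L):(3L * i); jj <- (3L * j - 2L):(3L * j)
    H[ii, jj] <- blk
    H[jj, ii] <- blk
    H[ii, ii] <- H[ii, ii] - blk
    H[jj, jj] <- H[jj, jj] - blk
  }
  H
}

#' ANM spring-network energy
#'
#' \eqn{E = (\gamma/2) \sum_{(i,j) \in contacts} (|r_{ij}| - |r_{ij}^0|)^2}
#' over the fixed contact set defined by the equilibrium structure
#' \code{x0}. The analytic \code{\link{anmHessian}} equals the second
#' derivative of this energy at \code{x0}.
#'
#' @param x coordinates to evaluate (flat 3N vector or SiteSet)
#' @param x0 equilibrium coordinates defining the contact set
#' @param params list from \code{\link{anmParameters}}
#' @return energy (kcal mol^-1)
#' @export
anmEnergy <- function(x, x0, params = anmParameters()) {
  xyz <- .asXYZ(.coordsOf(x)); xyz0 <- .asXYZ(.coordsOf(x0))
  contacts <- .anmContacts(xyz0, params$rc)
  i <- contacts[, 1L]; j <- contacts[, 2L]
  d <- sqrt(rowSums((xyz[j, , drop = FALSE] - xyz[i, , drop = FALSE])^2))
  d0 <- sqrt(rowSums((xyz0[j, , drop = FALSE] - xyz0[i, , drop = FALSE])^2))
  0.5 * params$gamma * sum((d - d0)^2)
}

#' ANM normal modes from a Hessian
#'
#' Symmetric eigendecomposition with rigid-body zero modes (eigenvalues
#' below \code{zeroTol} times the largest) removed; remaining modes are
#' sorted ascending by eigenvalue. A connected non-collinear network has
#' exactly 6 zero modes (5 for a collinear one); more indicates floating
#' fragments and raises a disconnected-network error.
#'
#' @param H Hessian matrix from \code{\link{anmHessian}}
#' @param labels site label data.frame
#' @param coords flat 3N equilibrium coordinates stored as the basis center
#' @param zeroTol relative zero-mode threshold
#' @return a \linkS4class{ModeBasis} of kind "anm"; \code{meta$nZero} holds
#'   the number of removed rigid-body modes
#' @export
anmModes <- function(H, labels, coords, zeroTol = 1e-8) {
  if (max(abs(H - t(H))) > 1e-9)
    stop("validation error: Hessian must be symmetric")
  dec <- eigen(H, symmetric = TRUE)
  vals <- rev(dec$values)                 # ascending
  vecs <- dec$vectors[, rev(seq_len(ncol(dec$vectors))), drop = FALSE]
  lmax <- max(abs(vals))
  if (lmax == 0)
    stop("disconnected-network error: all eigenvalues vanish (no springs)")
  zero <- vals < zeroTol * lmax
  nZero <- sum(zero)
  n <- length(vals) / 3L
  # expected rigid-body count: 6 generically, 5 if all sites are collinear
  xyz <- .asXYZ(coords)
  rel <- sweep(xyz, 2L, colMeans(xyz))
  collinear <- n >= 2L && (svd(rel)$d[2L] < 1e-10 * max(svd(rel)$d[1L], 1e-300))
  expected <- if (collinear) 5L else 6L
  if (nZero > expected)
    stop("disconnected-network error: ", nZero, " zero modes detected ",
         "(expected ", expected, "); the spring network has floating fragments")
  keep <- which(!zero)
  V <- vecs[, keep, drop = FALSE]
  for (k in seq_len(ncol(V))) {
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) V[, k] <- -V[, k]
  }
  new("ModeBasis", labels = labels, center = as.numeric(coords),
      values = vals[keep], vectors = V, kind = "anm",
      meta = list(nZero = nZero))
}

#' ANM normal modes of a SiteSet in one call
#' @param s a \linkS4class{SiteSet}
#' @param params list from \code{\link{anmParameters}}
#' @param zeroTol relative zero-mode threshold
#' @return a \linkS4class{ModeBasis} of kind "anm"
#' @export
anmSiteSet <- function(s, params = anmParameters(), zeroTol = 1e-8) {
  stopifnot(is(s, "SiteSet"))
  anmModes(anmHessian(s, params), siteLabels(s), siteCoords(s),
           zeroTol = zeroTol)
}

#' Overlap between two displacement vectors
#'
#' Absolute normalised dot product \eqn{|\hat a \cdot \hat b|} in [0, 1];
#' 1 means parallel motions.
#'
#' @param a,b numeric vectors of equal length, both nonzero
#' @return scalar in [0, 1]
#' @export
modeOverlap <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("dimension error: vector lengths differ")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("undefined-overlap error: zero vector")
  abs(sum(a * b)) / (na * nb)
}

#' Overlap matrix between two mode bases (or a basis and a vector)
#'
#' Entry (i, j) is \code{modeOverlap} between mode i of A and mode j of B.
#' When B is a complete orthonormal basis each row's sum of squares is 1
#' (Parseval).
#'
#' @param A a \linkS4class{ModeBasis}
#' @param B a \linkS4class{ModeBasis}, \linkS4class{PistonVector} or numeric
#'   3N vector
#' @param kA,kB number of leading modes of A / B to compare (default all)
#' @return an \linkS4class{OverlapMatrix}
#' @export
overlapMatrix <- function(A, B, kA = NULL, kB = NULL) {
  stopifnot(is(A, "ModeBasis"))
  VA <- A@vectors
  if (is(B, "ModeBasis")) {
    .stopIfLabelMismatch(A@labels, B@labels, "mode bases")
    VB <- B@vectors
  } else if (is(B, "PistonVector")) {
    .stopIfLabelMismatch(A@labels, B@labels, "basis and piston vector")
    VB <- matrix(B@vector, ncol = 1L)
  } else {
    VB <- matrix(as.numeric(B), ncol = 1L)
    if (nrow(VB) != nrow(VA)) stop("dimension error: vector length mismatch")
  }
  if (!is.null(kA)) VA <- VA[, seq_len(kA), drop = FALSE]
  if (!is.null(kB)) VB <- VB[, seq_len(kB), drop = FALSE]
  nb <- sqrt(colSums(VB^2))
  if (any(nb == 0)) stop("undefined-overlap error: zero vector")
  vals <- abs(crossprod(VA, sweep(VB, 2L, nb, "/")))
  new("OverlapMatrix", values = vals)
}
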