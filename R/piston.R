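# Piston vector: normalised apo->holo C-alpha displacement restricted to
# the alpha4-helix sites, and its signed projection spectrum across a mode
# basis.

# Logical mask (per site) for sites inside the given per-chain ranges.
.rangeMask <- function(labels, ranges) {
  pairs <- .rangesToPairs(ranges)
  mask <- rep(FALSE, nrow(labels))
  for (i in seq_len(nrow(pairs)))
    mask <- mask | (labels$chain == pairs$chain[i] &
                    labels$resno >= pairs$start[i] &
                    labels$resno <= pairs$end[i])
  mask
}

#' Build the piston vector from an apo/holo structure pair
#'
#' Superposes the holo structure onto the apo structure, measures the
#' per-site displacement, zeroes all components outside the alpha4 ranges
#' and normalises. By default the superposition uses only the non-alpha4
#' "static core" sites whenever the mask covers less than half the sites,
#' so that the piston motion itself does not contaminate the reference
#' frame; \code{fitSites} overrides this.
#'
#' @param apo,holo \linkS4class{SiteSet}s with identical labels
#' @param alpha4 per-chain alpha4 residue ranges (default both chains,
#'   146-175)
#' @param fitSites "auto" (core fit when mask < 50\% of sites), "core",
#'   "all", or "none" (no superposition)
#' @param orient "downward" flips the vector so the mean z-component of the
#'   masked displacement is negative (the classical piston-down convention);
#'   "raw" keeps the apo->holo direction
#' @return a \linkS4class{PistonVector}
#' @export
buildPistonVector <- function(apo, holo, alpha4 = alpha4Ranges(),
                              fitSites = c("auto", "core", "all", "none"),
                              orient = c("downward", "raw")) {
  stopifnot(is(apo, "SiteSet"), is(holo, "SiteSet"))
  fitSites <- match.arg(fitSites)
  orient <- match.arg(orient)
  .stopIfLabelMismatch(siteLabels(apo), siteLabels(holo), "apo and holo")
  labels <- siteLabels(apo)
  mask <- .rangeMask(labels, alpha4)
  if (!any(mask)) stop("selection error: alpha4 ranges select no sites")
  if (fitSites == "auto")
    fitSites <- if (mean(mask) < 0.5) "core" else "all"
  holoFit <- siteCoords(holo)
  if (fitSites != "none") {
    sub <- if (fitSites == "core") !mask else rep(TRUE, length(mask))
    if (sum(sub) < 3L) stop("selection error: too few sites to fit on")
    idx <- as.vector(t(cbind(3L * which(sub) - 2L, 3L * which(sub) - 1L,
                             3L * which(sub))))
    kb <- kabschSuperpose(siteCoords(holo)[idx], siteCoords(apo)[idx])
    holoFit <- applyTransform(siteCoords(holo), kb$transform)
  }
  disp <- .asXYZ(holoFit - siteCoords(apo))
  disp[!mask, ] <- 0
  rawNorm <- sqrt(sum(disp^2))
  if (rawNorm < 1e-12)
    stop("degenerate-PV error: masked apo->holo displacement is zero")
  v <- .flattenXYZ(disp) / rawNorm
  flipped <- FALSE
  if (orient == "downward") {
    meanZ <- mean(disp[mask, 3L]) / rawNorm
    if (meanZ > 0) { v <- -v; flipped <- TRUE }
  }
  new("PistonVector", labels = labels, vector = v, mask = mask,
      rawNorm = rawNorm,
      provenance = list(fitSites = fitSites, orient = orient,
                        flipped = flipped, apoCoords = siteCoords(apo)))
}

#' Signed projection spectrum of a piston vector across a mode basis
#'
#' Signed dot products \eqn{PV \cdot v_k} for k = 1..K. Squared projections
#' sum to at most 1, with equality on a complete basis (Parseval).
#'
#' The piston vector is defined in the apo structure's frame while the
#' basis eigenvectors live in the frame of the basis mean; with
#' \code{align = TRUE} (default) the apo coordinates recorded in the PV's
#' provenance are Kabsch-fitted onto the basis mean and the piston vector
#' is rotated accordingly before the dot products are taken, so the two
#' mode descriptions are compared in a common frame.
#'
#' @param pv a \linkS4class{PistonVector}
#' @param basis a \linkS4class{ModeBasis} with matching labels
#' @param K number of leading modes (default all)
#' @param align rotate the PV into the basis frame first?
#' @return data.frame(mode, eigenvalue, projection)
#' @export
pvSpectrum <- function(pv, basis, K = NULL, align = TRUE) {
  stopifnot(is(pv, "PistonVector"), is(basis, "ModeBasis"))
  .stopIfLabelMismatch(pv@labels, basis@labels, "piston vector and basis")
  if (is.null(K)) K <- ncol(basis@vectors)
  K <- as.integer(K)
  if (K < 1L || K > ncol(basis@vectors))
    stop("index error: K out of range")
  vec <- pv@vector
  if (align && !is.null(pv@provenance$apoCoords)) {
    kb <- kabschSuperpose(pv@provenance$apoCoords, basis@center)
    vec <- .flattenXYZ(.asXYZ(vec) %*% kb$transform@rotation)
  }
  proj <- as.numeric(crossprod(basis@vectors[, seq_len(K), drop = FALSE],
                               vec))
  data.frame(mode = seq_len(K), eigenvalue = basis@values[seq_len(K)],
             projection = proj)
}
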