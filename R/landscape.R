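# Conformational-landscape clustering: gromos-style leader clustering on a
# DRMS pairwise matrix, and density-peak clustering (local density rho,
# separation delta) of 2D mode projections.

#' Gromos-style leader clustering on a pairwise DRMS matrix
#'
#' Repeatedly takes the frame with the most neighbours within the cutoff as
#' a cluster center, assigns it and its unassigned neighbours to a cluster,
#' removes them, and repeats. Deterministic, with lowest-index tie-breaking;
#' every frame receives a label.
#'
#' @param m a \linkS4class{PairwiseMatrix} (metric "drms")
#' @param cutoff neighbour cutoff (nm), > 0; default 0.2
#' @return a \linkS4class{ClusterResult}; clusters are numbered in order of
#'   extraction (1 = most populated leader)
#' @export
drmsCluster <- function(m, cutoff = 0.2) {
  stopifnot(is(m, "PairwiseMatrix"))
  if (!is.numeric(cutoff) || cutoff <= 0)
    stop("validation error: cutoff must be > 0")
  M <- nrow(m@values)
  if (M < 1L) stop("input error: empty pairwise matrix")
  adj <- m@values < cutoff
  labels <- rep(NA_integer_, M)
  centers <- integer()
  cl <- 0L
  remaining <- rep(TRUE, M)
  while (any(remaining)) {
    counts <- colSums(adj[remaining, , drop = FALSE]) # neighbours incl self
    counts[!remaining] <- -1L
    center <- which.max(counts)                        # lowest index on ties
    members <- which(remaining & adj[center, ])
    cl <- cl + 1L
    labels[members] <- cl
    centers <- c(centers, center)
    remaining[members] <- FALSE
  }
  sizes <- tabulate(labels, nbins = cl)
  new("ClusterResult", labels = labels,
      centers = data.frame(cluster = seq_len(cl), frame = centers,
                           size = sizes),
      probabilities = sizes / M,
      parameters = list(method = "drms-leader", cutoff = cutoff))
}

#' Rule-of-thumb kernel scale for density-peak clustering
#'
#' The distance at which the average neighbour count is a given fraction of
#' the points (default 2\%): the \code{frac} quantile of the pairwise
#' distance distribution.
#'
#' @param points M x d numeric matrix
#' @param frac target average neighbour fraction
#' @return dc (same units as the points)
#' @export
dcRuleOfThumb <- function(points, frac = 0.02) {
  d <- as.vector(dist(points))
  as.numeric(quantile(d, frac, names = FALSE))
}

#' Local density and separation for density-peak clustering
#'
#' For each point: local density rho (cutoff kernel: neighbour count within
#' \code{dc}; gaussian kernel: \eqn{\sum_{j \ne i} \exp(-(d_{ij}/dc)^2)})
#' and delta, the distance to the nearest point of higher density (ties
#' broken by lower index). The global density maximum receives delta equal
#' to the maximum pairwise distance.
#'
#' @param points M x d numeric matrix (typically M x 2 mode projections, nm)
#' @param dc kernel scale; default from \code{\link{dcRuleOfThumb}}
#' @param kernel "gaussian" (default) or "cutoff"
#' @return a \linkS4class{DensityDelta}
#' @export
densityDelta <- function(points, dc = NULL, kernel = c("gaussian", "cutoff")) {
  points <- as.matrix(points)
  kernel <- match.arg(kernel)
  M <- nrow(points)
  if (M < 2L) stop("input error: need at least 2 points")
  d <- as.matrix(dist(points))
  if (max(d) == 0) stop("degenerate-density error: all points identical")
  if (is.null(dc)) dc <- dcRuleOfThumb(points)
  if (!is.numeric(dc) || dc <= 0) stop("parameter error: dc must be > 0")
  rho <- if (kernel == "cutoff") unname(rowSums(d < dc)) - 1
         else unname(rowSums(exp(-(d / dc)^2))) - 1
  # process in decreasing density, lower index first on exact ties
  ord <- order(-rho, seq_len(M))
  delta <- numeric(M)
  nearest <- rep(NA_integer_, M)
  delta[ord[1L]] <- max(d)
  for (r in 2:M) {
    i <- ord[r]
    higher <- ord[seq_len(r - 1L)]
    j <- higher[which.min(d[i, higher])]
    delta[i] <- d[i, j]
    nearest[i] <- j
  }
  new("DensityDelta", rho = rho, delta = delta, nearestHigher = nearest)
}

#' Density-peak clustering of a 2D projection landscape
#'
#' Computes (rho, delta), selects cluster centers either as the top-k points
#' by gamma = rho * delta or by explicit (rhoMin, deltaMin) thresholds, and
#' assigns every other point the label of its nearest higher-density
#' neighbour, processed in decreasing density order. Cluster probabilities
#' are cluster sizes divided by M.
#'
#' @param points M x 2 numeric matrix (nm)
#' @param dc kernel scale; default from \code{\link{dcRuleOfThumb}}
#' @param kernel "gaussian" or "cutoff"
#' @param k number of centers (top-k by gamma); ignored if thresholds given
#' @param rhoMin,deltaMin explicit center-selection thresholds (both must be
#'   given to use threshold selection)
#' @return a \linkS4class{ClusterResult}; \code{centers} holds the center
#'   point index and coordinates, and the rho/delta decision-graph values
#'   are stored in \code{parameters}
#' @export
densityPeakCluster <- function(points, dc = NULL,
                               kernel = c("gaussian", "cutoff"),
                               k = NULL, rhoMin = NULL, deltaMin = NULL) {
  points <- as.matrix(points)
  kernel <- match.arg(kernel)
  M <- nrow(points)
  if (is.null(dc)) dc <- dcRuleOfThumb(points)
  dd <- densityDelta(points, dc = dc, kernel = kernel)
  if (!is.null(rhoMin) && !is.null(deltaMin)) {
    centerIdx <- which(dd@rho >= rhoMin & dd@delta >= deltaMin)
    if (length(centerIdx) == 0L)
      stop("parameter error: no points satisfy the center thresholds")
  } else {
    if (is.null(k)) k <- 1L
    k <- as.integer(k)
    if (k < 1L || k > M)
      stop("parameter error: k must be between 1 and the number of points")
    gamma <- dd@rho * dd@delta
    centerIdx <- order(-gamma, seq_len(M))[seq_len(k)]
  }
  labels <- rep(NA_integer_, M)
  labels[centerIdx] <- seq_along(centerIdx)
  ord <- order(-dd@rho, seq_len(M))
  for (i in ord) {
    if (!is.na(labels[i])) next
    labels[i] <- labels[dd@nearestHigher[i]]
  }
  if (anyNA(labels))
    stop("internal error: density-peak assignment left unlabeled points")
  sizes <- tabulate(labels, nbins = length(centerIdx))
  centers <- data.frame(cluster = seq_along(centerIdx), point = centerIdx)
  for (cc in seq_len(ncol(points)))
    centers[[paste0("center", cc)]] <- points[centerIdx, cc]
  new("ClusterResult", labels = labels, centers = centers,
      probabilities = sizes / M,
      parameters = list(method = "density-peak", dc = dc, kernel = kernel,
                        rho = dd@rho, delta = dd@delta))
}

#' Per-cluster and grouped occupancy probabilities
#'
#' Fraction of frames in each cluster and, optionally, summed probabilities
#' over requested groups of cluster ids (e.g. all clusters whose center has
#' negative pe2).
#'
#' @param cr a \linkS4class{ClusterResult}
#' @param grouping optional named list of cluster-id vectors
#' @return if \code{grouping} is NULL, the per-cluster probabilities;
#'   otherwise a named numeric vector of group totals
#' @export
clusterProbabilities <- function(cr, grouping = NULL) {
  stopifnot(is(cr, "ClusterResult"))
  p <- cr@probabilities
  if (is.null(grouping)) return(p)
  vapply(grouping, function(ids) {
    ids <- as.integer(ids)
    if (any(ids < 1L | ids > length(p)))
      stop("parameter error: unknown cluster id in grouping")
    sum(p[ids])
  }, numeric(1))
}
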