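# Accessor generics. Slot access outside the package should go through these.

#' Number of sites
#' @param x a SiteSet, Ensemble, ModeBasis or PistonVector
#' @return integer
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' Number of frames
#' @param x an Ensemble or ClusterResult
#' @return integer
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Site labels
#' @param x an object carrying site labels
#' @return data.frame with columns chain, resno
#' @export
setGeneric("siteLabels", function(x) standardGeneric("siteLabels"))

#' Flat coordinates (nm, site-major)
#' @param x a SiteSet
#' @return numeric 3N vector
#' @export
setGeneric("siteCoords", function(x) standardGeneric("siteCoords"))

#' Frame matrix of an ensemble
#' @param x an Ensemble
#' @return numeric M x 3N matrix (nm)
#' @export
setGeneric("frameMatrix", function(x) standardGeneric("frameMatrix"))

#' Eigenvalues of a mode basis
#' @param x a ModeBasis
#' @return numeric vector
#' @export
setGeneric("modeValues", function(x) standardGeneric("modeValues"))

#' Eigenvector matrix of a mode basis
#' @param x a ModeBasis
#' @return 3N x K matrix, orthonormal columns
#' @export
setGeneric("modeVectors", function(x) standardGeneric("modeVectors"))

#' Mean / reference coordinates of a mode basis
#' @param x a ModeBasis
#' @return numeric 3N vector (nm)
#' @export
setGeneric("centerCoords", function(x) standardGeneric("centerCoords"))

#' Per-frame cluster labels
#' @param x a ClusterResult
#' @return integer vector (-1 = halo)
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' Swap the symmetric chains of a homodimer
#'
#' Relabels sites through a chain bijection and reorders coordinates so the
#' output site list is identical to the input's; for a homodimer this maps
#' each frame onto its chain-exchanged image.
#'
#' @param x a SiteSet or Ensemble
#' @param chainMap named character vector, e.g. c(A = "B", B = "A")
#' @return object of the same class
#' @export
setGeneric("swapChains", function(x, chainMap = NULL) standardGeneric("swapChains"))

setMethod("nSites", "SiteSet", function(x) nrow(x@labels))
setMethod("nSites", "Ensemble", function(x) nrow(x@labels))
setMethod("nSites", "ModeBasis", function(x) nrow(x@labels))
setMethod("nSites", "PistonVector", function(x) nrow(x@labels))

setMethod("nFrames", "Ensemble", function(x) nrow(x@frames))
setMethod("nFrames", "ClusterResult", function(x) length(x@labels))

setMethod("siteLabels", "SiteSet", function(x) x@labels)
setMethod("siteLabels", "Ensemble", function(x) x@labels)
setMethod("siteLabels", "ModeBasis", function(x) x@labels)
setMethod("siteLabels", "PistonVector", function(x) x@labels)

setMethod("siteCoords", "SiteSet", function(x) x@coords)
setMethod("frameMatrix", "Ensemble", function(x) x@frames)
setMethod("modeValues", "ModeBasis", function(x) x@values)
setMethod("modeVectors", "ModeBasis", function(x) x@vectors)
setMethod("centerCoords", "ModeBasis", function(x) x@center)
setMethod("clusterLabels", "ClusterResult", function(x) x@labels)

#' Cluster occupancy probabilities
#' @param x a ClusterResult
#' @return numeric vector summing to 1
#' @export
clusterProbs <- function(x) {
  stopifnot(is(x, "ClusterResult"))
  x@probabilities
}

#' Piston vector as a numeric 3N vector
#' @param x a PistonVector
#' @return unit numeric vector
#' @export
pvVector <- function(x) {
  stopifnot(is(x, "PistonVector"))
  x@vector
}
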