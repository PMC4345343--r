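#' @import methods
NULL

# Central S4 containers. Coordinates are always nm and site-major flattened
# (x1, y1, z1, x2, ...). Site labels are a data.frame with columns `chain`
# (character) and `resno` (integer), strictly ordered by (chain, resno).

#' Structure: atom records of one PDB model
#'
#' Carrier for a parsed structure: one row per atom with chain id, residue
#' number, residue name, atom name and coordinates in nm.
#'
#' @slot atoms data.frame with columns chain, resno, resid, elety, x, y, z
#'   (coordinates in nm).
#' @slot model integer model id (1 for single-model files).
#' @exportClass Structure
setClass("Structure",
  representation(atoms = "data.frame", model = "integer"))

setValidity("Structure", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) > 0) {
    if (anyDuplicated(paste(a$chain, a$resno, a$elety)))
      return("(chain, resno, atom name) must be unique within a model")
    if (!all(is.finite(c(a$x, a$y, a$z))))
      return("all coordinates must be finite")
  }
  TRUE
})

#' SiteSet: ordered, labeled C-alpha sites of a dimer
#'
#' The universal coordinate carrier: N labeled sites with a flat 3N
#' coordinate vector in nm, plus the selection specification that produced it.
#'
#' @slot labels data.frame(chain, resno), strictly ordered by (chain, resno).
#' @slot coords numeric 3N vector, nm, site-major.
#' @slot selection list recording the helix ranges used and any skipped
#'   residues.
#' @exportClass SiteSet
setClass("SiteSet",
  representation(labels = "data.frame", coords = "numeric", selection = "list"),
  prototype(selection = list()))

.checkLabels <- function(labels) {
  if (!all(c("chain", "resno") %in% names(labels)))
    return("labels must have columns chain, resno")
  if (nrow(labels) > 0) {
    o <- order(labels$chain, labels$resno)
    if (!identical(o, seq_len(nrow(labels))))
      return("labels must be strictly ordered by (chain, resno)")
    if (anyDuplicated(.labelKey(labels)))
      return("duplicate (chain, resno) labels")
  }
  TRUE
}

setValidity("SiteSet", function(object) {
  chk <- .checkLabels(object@labels)
  if (!isTRUE(chk)) return(chk)
  if (length(object@coords) != 3L * nrow(object@labels))
    return("coords length must equal 3 * number of labels")
  if (length(object@coords) && !all(is.finite(object@coords)))
    return("all coordinates must be finite")
  TRUE
})

#' Ensemble: frames sharing one site ordering
#'
#' M frames (rows) of flattened 3N coordinate vectors over a shared label
#' list; the in-memory form of an MD trajectory or synthetic sample.
#'
#' @slot labels shared site labels (as in \linkS4class{SiteSet}).
#' @slot frames numeric M x 3N matrix, nm.
#' @slot provenance list (source file, stride, fitting state, ...).
#' @exportClass Ensemble
setClass("Ensemble",
  representation(labels = "data.frame", frames = "matrix",
                 provenance = "list"),
  prototype(provenance = list()))

setValidity("Ensemble", function(object) {
  chk <- .checkLabels(object@labels)
  if (!isTRUE(chk)) return(chk)
  if (ncol(object@frames) != 3L * nrow(object@labels))
    return("frame width must equal 3 * number of labels")
  if (nrow(object@frames) < 1L) return("an ensemble needs at least one frame")
  if (!all(is.finite(object@frames))) return("all coordinates must be finite")
  TRUE
})

#' RigidTransform: proper rotation plus translation
#'
#' Applied to row-vector coordinates as \code{y = x \%*\% rotation + translation}.
#'
#' @slot rotation 3x3 proper orthogonal matrix.
#' @slot translation length-3 numeric, nm.
#' @exportClass RigidTransform
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9) return("rotation must be orthogonal")
  if (abs(det(R) - 1) > 1e-9) return("rotation must be proper (det +1)")
  if (length(object@translation) != 3L) return("translation must be length 3")
  TRUE
})

#' PairwiseMatrix: symmetric frame-by-frame metric matrix
#'
#' @slot values M x M symmetric numeric matrix, nm.
#' @slot metric "rmsd" or "drms".
#' @exportClass PairwiseMatrix
setClass("PairwiseMatrix",
  representation(values = "matrix", metric = "character"))

setValidity("PairwiseMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("matrix must be square")
  if (max(abs(diag(v))) > 1e-12) return("diagonal must be zero")
  if (max(abs(v - t(v))) > 1e-12) return("matrix must be symmetric")
  if (min(v) < -1e-12) return("values must be nonnegative")
  if (!object@metric %in% c("rmsd", "drms")) return("metric must be rmsd or drms")
  TRUE
})

#' ModeBasis: mean coordinates plus eigenvalues and orthonormal eigenvectors
#'
#' Result of ensemble PCA (kind "pca", eigenvalues in nm^2, descending) or
#' anisotropic-network-model normal mode analysis (kind "anm", spring-energy
#' curvature units, ascending after zero-mode removal).
#'
#' @slot labels shared site labels.
#' @slot center numeric 3N mean/reference coordinates, nm.
#' @slot values numeric eigenvalues.
#' @slot vectors 3N x K matrix of orthonormal eigenvectors (columns).
#' @slot kind "pca" or "anm".
#' @slot meta list (e.g. number of removed zero modes, sign conventions).
#' @exportClass ModeBasis
setClass("ModeBasis",
  representation(labels = "data.frame", center = "numeric", values = "numeric",
                 vectors = "matrix", kind = "character", meta = "list"),
  prototype(meta = list()))

setValidity("ModeBasis", function(object) {
  chk <- .checkLabels(object@labels)
  if (!isTRUE(chk)) return(chk)
  n3 <- 3L * nrow(object@labels)
  if (length(object@center) != n3) return("center length must be 3N")
  if (nrow(object@vectors) != n3) return("eigenvectors must be 3N long")
  if (ncol(object@vectors) != length(object@values))
    return("one eigenvalue per eigenvector")
  if (!object@kind %in% c("pca", "anm")) return("kind must be pca or anm")
  k <- ncol(object@vectors)
  if (k > 0) {
    g <- crossprod(object@vectors)
    if (max(abs(g - diag(k))) > 1e-8)
      return("eigenvectors must be pairwise orthonormal")
    srt <- if (object@kind == "pca") !is.unsorted(rev(object@values))
           else !is.unsorted(object@values)
    if (!srt) return("eigenvalues must be sorted (pca: descending, anm: ascending)")
  }
  TRUE
})

#' PistonVector: unit 3N displacement supported on alpha4-helix sites
#'
#' @slot labels site labels.
#' @slot vector unit 3N numeric, zero outside the mask.
#' @slot mask logical per site (TRUE = alpha4 site).
#' @slot rawNorm displacement norm before normalization, nm.
#' @slot provenance list (fit policy, orientation, sources).
#' @exportClass PistonVector
setClass("PistonVector",
  representation(labels = "data.frame", vector = "numeric", mask = "logical",
                 rawNorm = "numeric", provenance = "list"),
  prototype(provenance = list()))

setValidity("PistonVector", function(object) {
  chk <- .checkLabels(object@labels)
  if (!isTRUE(chk)) return(chk)
  n <- nrow(object@labels)
  if (length(object@vector) != 3L * n) return("vector must be 3N long")
  if (length(object@mask) != n) return("one mask entry per site")
  if (abs(sqrt(sum(object@vector^2)) - 1) > 1e-10) return("vector must be unit norm")
  off <- .asXYZ(object@vector)[!object@mask, , drop = FALSE]
  if (length(off) && max(abs(off)) > 1e-12)
    return("vector must vanish at unmasked sites")
  TRUE
})

#' OverlapMatrix: absolute mode-mode dot products in [0, 1]
#'
#' @slot values matrix of |dot products|; rows = modes of basis A, columns =
#'   modes of basis B (or a single displacement vector).
#' @exportClass OverlapMatrix
setClass("OverlapMatrix", representation(values = "matrix"))

setValidity("OverlapMatrix", function(object) {
  v <- object@values
  if (length(v) && (min(v) < -1e-12 || max(v) > 1 + 1e-9))
    return("overlaps must lie in [0, 1]")
  TRUE
})

#' ClusterResult: per-frame labels with occupancy probabilities
#'
#' @slot labels integer per frame/point; -1 marks an optional halo point.
#' @slot centers data.frame describing cluster centers (index and, for
#'   landscape clustering, the center coordinates).
#' @slot probabilities per-cluster fraction of assigned frames.
#' @slot parameters list of the clustering parameters used.
#' @exportClass ClusterResult
setClass("ClusterResult",
  representation(labels = "integer", centers = "data.frame",
                 probabilities = "numeric", parameters = "list"),
  prototype(parameters = list()))

setValidity("ClusterResult", function(object) {
  p <- object@probabilities
  if (any(p < 0)) return("probabilities must be nonnegative")
  if (length(p) && abs(sum(p) - 1) > 1e-9)
    return("probabilities must sum to 1 over assigned frames")
  lab <- object@labels[object@labels != -1L]
  if (length(lab) && !all(lab %in% seq_along(p)))
    return("every non-halo frame must carry a valid cluster label")
  TRUE
})

#' DensityDelta: local density and separation for density-peak clustering
#'
#' @slot rho per-point local density.
#' @slot delta per-point distance to the nearest point of higher density.
#' @slot nearestHigher index of that point (NA for the global density maximum).
#' @exportClass DensityDelta
setClass("DensityDelta",
  representation(rho = "numeric", delta = "numeric", nearestHigher = "integer"))

setValidity("DensityDelta", function(object) {
  if (length(object@rho) != length(object@delta) ||
      length(object@rho) != length(object@nearestHigher))
    return("rho, delta and nearestHigher must have equal length")
  TRUE
})

#' GroundTruth: planted structure of a synthetic ensemble
#'
#' @slot template the template \linkS4class{SiteSet}.
#' @slot modes 3N x K orthonormal planted mode vectors (rigid-body filtered);
#'   the basis actually used for sampling.
#' @slot fields 3N x K raw geometric fields (rotation / slide) before
#'   rigid-body filtering, each unit norm.
#' @slot amplitudes M x K per-frame mode amplitudes (nm), if sampled.
#' @slot basin integer per-frame basin label, if sampled.
#' @slot spec the generating specification.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(template = "SiteSet", modes = "matrix", fields = "matrix",
                 amplitudes = "matrix", basin = "integer", spec = "list"),
  prototype(amplitudes = matrix(numeric(), 0, 0), basin = integer(),
            spec = list()))

setValidity("GroundTruth", function(object) {
  k <- ncol(object@modes)
  if (k > 0) {
    g <- crossprod(object@modes)
    if (max(abs(g - diag(k))) > 1e-8)
      return("planted mode vectors must be orthonormal")
  }
  TRUE
})

setMethod("show", "SiteSet", function(object) {
  cat("SiteSet:", nrow(object@labels), "sites on chains",
      paste(unique(object@labels$chain), collapse = ", "), "\n")
})

setMethod("show", "Ensemble", function(object) {
  cat("Ensemble:", nrow(object@frames), "frames x",
      nrow(object@labels), "sites\n")
})

setMethod("show", "ModeBasis", function(object) {
  k <- length(object@values)
  cat("ModeBasis (", object@kind, "): ", k, " modes over ",
      nrow(object@labels), " sites\n", sep = "")
  if (k) cat("  leading eigenvalues:",
             paste(signif(head(object@values, 5L), 4), collapse = ", "), "\n")
})

setMethod("show", "PistonVector", function(object) {
  cat("PistonVector:", sum(object@mask), "of", length(object@mask),
      "sites masked; raw displacement norm", signif(object@rawNorm, 4), "nm\n")
})

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult:", length(object@probabilities), "clusters over",
      length(object@labels), "frames\n")
  cat("  probabilities:", paste(signif(object@probabilities, 3), collapse = ", "), "\n")
})
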