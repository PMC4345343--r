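# Structure and ensemble I/O. PDB files are in Angstrom by convention; all
# in-memory coordinates are nm, so conversion happens here and only here.

.ANG_PER_NM <- 10

#' Default Tar periplasmic helix ranges
#'
#' The four-helix-bundle helix boundaries of the Tar periplasmic monomer
#' (alpha1-alpha4: 44-75, 89-113, 118-144, 146-175), replicated over the
#' requested chains. Ranges are inclusive, 1-based PDB residue numbering.
#'
#' @param chains chain ids to apply the ranges to
#' @return named list mapping chain id to a 4 x 2 matrix of ranges
#' @export
tarHelixRanges <- function(chains = c("A", "B")) {
  m <- matrix(c(44L, 75L, 89L, 113L, 118L, 144L, 146L, 175L),
              ncol = 2L, byrow = TRUE,
              dimnames = list(paste0("alpha", 1:4), c("start", "end")))
  stats::setNames(rep(list(m), length(chains)), chains)
}

#' Default Tar alpha4-helix ranges
#' @param chains chain ids
#' @return named list mapping chain id to a 1 x 2 range matrix
#' @export
alpha4Ranges <- function(chains = c("A", "B")) {
  m <- matrix(c(146L, 175L), ncol = 2L,
              dimnames = list("alpha4", c("start", "end")))
  stats::setNames(rep(list(m), length(chains)), chains)
}

#' Construct a SiteSet from labels and coordinates
#' @param labels data.frame(chain, resno)
#' @param coords numeric 3N vector (nm) or N x 3 matrix
#' @param selection optional selection spec list
#' @return a \linkS4class{SiteSet}
#' @export
makeSiteSet <- function(labels, coords, selection = list()) {
  if (is.matrix(coords)) coords <- .flattenXYZ(coords)
  labels <- data.frame(chain = as.character(labels$chain),
                       resno = as.integer(labels$resno),
                       stringsAsFactors = FALSE)
  new("SiteSet", labels = labels, coords = as.numeric(coords),
      selection = selection)
}

#' Construct an Ensemble from a frame matrix
#' @param labels data.frame(chain, resno) shared by all frames
#' @param frames numeric M x 3N matrix (nm)
#' @param provenance optional provenance list
#' @return an \linkS4class{Ensemble}
#' @export
makeEnsemble <- function(labels, frames, provenance = list()) {
  labels <- data.frame(chain = as.character(labels$chain),
                       resno = as.integer(labels$resno),
                       stringsAsFactors = FALSE)
  new("Ensemble", labels = labels, frames = as.matrix(frames),
      provenance = provenance)
}

#' Ensemble from a list of SiteSets
#' @param sitesets list of \linkS4class{SiteSet} objects with identical labels
#' @param provenance optional provenance list
#' @return an \linkS4class{Ensemble}
#' @export
asEnsemble <- function(sitesets, provenance = list()) {
  stopifnot(length(sitesets) >= 1L)
  lab <- siteLabels(sitesets[[1L]])
  for (s in sitesets) .stopIfLabelMismatch(lab, siteLabels(s), "ensemble members")
  makeEnsemble(lab, do.call(rbind, lapply(sitesets, siteCoords)), provenance)
}

#' Extract one frame of an ensemble as a SiteSet
#' @param e an \linkS4class{Ensemble}
#' @param i frame index
#' @return a \linkS4class{SiteSet}
#' @export
getFrame <- function(e, i) {
  stopifnot(is(e, "Ensemble"), i >= 1L, i <= nFrames(e))
  makeSiteSet(e@labels, e@frames[i, ])
}

# Count ATOM/HETATM records per MODEL block; used to give a clear
# inconsistent-ensemble error before delegating parsing to bio3d.
.modelAtomCounts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  isAtom <- rec == "ATOM  "
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L) return(sum(isAtom))
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  mapply(function(s, e) sum(isAtom[s:e]), starts, ends[seq_along(starts)])
}

#' Read structures from a PDB file
#'
#' Parses ATOM records (altloc ' ' or 'A' only) and converts coordinates
#' from Angstrom to nm.
#'
#' @param path PDB file path
#' @param model "first" (default) or "all"; with "all" a list of
#'   \linkS4class{Structure} objects is returned, one per MODEL block
#' @return a \linkS4class{Structure} or a list of them
#' @export
readStructures <- function(path, model = c("first", "all")) {
  model <- match.arg(model)
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  counts <- .modelAtomCounts(path)
  if (length(counts) > 1L && length(unique(counts)) > 1L)
    stop("inconsistent-ensemble error: models differ in ATOM count (model ",
         which(counts != counts[1L])[1L], " has ", counts[counts != counts[1L]][1L],
         " vs ", counts[1L], ")")
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = (model == "all"), verbose = FALSE),
    error = function(e) stop("format error: cannot parse PDB file ", path,
                             ": ", conditionMessage(e)))
  atoms <- pdb$atom
  keep <- atoms$type == "ATOM" & (is.na(atoms$alt) | atoms$alt %in% c("", " ", "A"))
  if (!any(keep)) stop("empty-structure error: no ATOM records in ", path)
  atab <- function(xyz) {
    a <- atoms[keep, , drop = FALSE]
    data.frame(chain = ifelse(is.na(a$chain), "A", a$chain),
               resno = as.integer(a$resno), resid = a$resid, elety = a$elety,
               x = xyz[keep, 1L] / .ANG_PER_NM,
               y = xyz[keep, 2L] / .ANG_PER_NM,
               z = xyz[keep, 3L] / .ANG_PER_NM,
               stringsAsFactors = FALSE)
  }
  xyzAll <- matrix(pdb$xyz, ncol = 3L, byrow = TRUE)
  if (model == "first") {
    if (is.matrix(pdb$xyz) && nrow(pdb$xyz) > 1L)
      xyzAll <- matrix(pdb$xyz[1L, ], ncol = 3L, byrow = TRUE)
    return(new("Structure", atoms = atab(xyzAll), model = 1L))
  }
  xyzMat <- if (is.matrix(pdb$xyz)) pdb$xyz else matrix(pdb$xyz, nrow = 1L)
  lapply(seq_len(nrow(xyzMat)), function(m) {
    new("Structure", atoms = atab(matrix(xyzMat[m, ], ncol = 3L, byrow = TRUE)),
        model = as.integer(m))
  })
}

#' Select C-alpha sites over helix residue ranges
#'
#' Keeps atoms named CA whose residue number falls in one of the per-chain
#' inclusive ranges; the result is ordered by (chain, resno). Residues
#' missing inside a range are skipped with a warning and recorded in the
#' selection spec.
#'
#' @param s a \linkS4class{Structure}
#' @param ranges named list: chain id -> matrix/list of c(start, end) ranges
#' @return a \linkS4class{SiteSet}
#' @export
selectCalpha <- function(s, ranges = tarHelixRanges()) {
  stopifnot(is(s, "Structure"))
  pairs <- .rangesToPairs(ranges)
  missingChains <- setdiff(unique(pairs$chain), unique(s@atoms$chain))
  if (length(missingChains))
    stop("selection error: chain(s) ", paste(missingChains, collapse = ", "),
         " named in ranges are absent from the structure")
  ca <- s@atoms[s@atoms$elety == "CA", , drop = FALSE]
  rows <- list(); skipped <- list()
  for (i in seq_len(nrow(pairs))) {
    ch <- pairs$chain[i]
    want <- pairs$start[i]:pairs$end[i]
    have <- ca[ca$chain == ch & ca$resno %in% want, , drop = FALSE]
    if (nrow(have) == 0L)
      stop("selection error: range ", pairs$start[i], "-", pairs$end[i],
           " on chain ", ch, " overlaps no residues in the structure")
    gap <- setdiff(want, have$resno)
    if (length(gap)) {
      warning("skipping ", length(gap), " missing residue(s) in range ",
              pairs$start[i], "-", pairs$end[i], " on chain ", ch, ": ",
              paste(gap, collapse = ", "))
      skipped[[length(skipped) + 1L]] <- data.frame(chain = ch, resno = gap)
    }
    rows[[length(rows) + 1L]] <- have
  }
  sel <- do.call(rbind, rows)
  sel <- sel[order(sel$chain, sel$resno), , drop = FALSE]
  makeSiteSet(sel[, c("chain", "resno")],
              cbind(sel$x, sel$y, sel$z),
              selection = list(ranges = ranges,
                               skipped = if (length(skipped))
                                 do.call(rbind, skipped) else NULL))
}

# Permutation sending each site to the one whose mapped label equals its own.
.swapPermutation <- function(labels, chainMap) {
  chains <- unique(labels$chain)
  if (is.null(chainMap)) {
    if (length(chains) != 2L)
      stop("swap error: a chain map is required unless there are exactly two chains")
    chainMap <- stats::setNames(rev(chains), chains)
  }
  if (!setequal(names(chainMap), chains) || !setequal(chainMap, chains) ||
      anyDuplicated(chainMap))
    stop("swap error: chain map must be a bijection over the chains present")
  mappedKey <- paste(unname(chainMap[labels$chain]), labels$resno, sep = ":")
  perm <- match(.labelKey(labels), mappedKey)
  if (anyNA(perm))
    stop("swap error: relabeled site list does not match the original ",
         "(heterodimer residue sets?)")
  perm
}

setMethod("swapChains", "SiteSet", function(x, chainMap = NULL) {
  perm <- .swapPermutation(x@labels, chainMap)
  xyz <- .asXYZ(x@coords)
  makeSiteSet(x@labels, xyz[perm, , drop = FALSE], x@selection)
})

setMethod("swapChains", "Ensemble", function(x, chainMap = NULL) {
  perm <- .swapPermutation(x@labels, chainMap)
  idx <- as.vector(t(cbind(3L * perm - 2L, 3L * perm - 1L, 3L * perm)))
  makeEnsemble(x@labels, x@frames[, idx, drop = FALSE],
               c(x@provenance, list(swapped = TRUE)))
})

#' Read an ensemble from a multi-model PDB file
#' @param path PDB file path
#' @param ranges per-chain residue ranges passed to \code{\link{selectCalpha}}
#' @return an \linkS4class{Ensemble}
#' @export
readEnsemblePDB <- function(path, ranges = tarHelixRanges()) {
  structs <- readStructures(path, model = "all")
  if (!is.list(structs)) structs <- list(structs)
  sets <- lapply(structs, selectCalpha, ranges = ranges)
  lab <- siteLabels(sets[[1L]])
  for (m in seq_along(sets))
    if (!.sameLabels(lab, siteLabels(sets[[m]])))
      stop("inconsistent-ensemble error: model ", m,
           " selects a different site set than model 1")
  asEnsemble(sets, provenance = list(source = path, format = "pdb"))
}

#' Write an ensemble (or single SiteSet) as a multi-model PDB file
#'
#' Sites are written as CA atoms of residue GLY placeholders; coordinates are
#' converted from nm to Angstrom at 3-decimal PDB precision.
#'
#' @param x an \linkS4class{Ensemble} or \linkS4class{SiteSet}
#' @param path output file
#' @return invisibly, the path
#' @export
writeEnsemblePDB <- function(x, path) {
  if (is(x, "SiteSet")) x <- makeEnsemble(siteLabels(x), matrix(siteCoords(x), nrow = 1L))
  stopifnot(is(x, "Ensemble"))
  lab <- x@labels
  bio3d::write.pdb(file = path,
                   xyz = x@frames * .ANG_PER_NM,
                   resno = lab$resno, chain = lab$chain,
                   resid = rep("GLY", nrow(lab)),
                   elety = rep("CA", nrow(lab)))
  invisible(path)
}

#' Read an ensemble from a TSV coordinate table
#'
#' One frame per row; columns x, y, z per site; a header row of
#' \code{chain:resno} site labels (each label repeated for its x/y/z
#' columns with suffixes .x/.y/.z). Comment lines start with '#'.
#'
#' @param path TSV file path
#' @return an \linkS4class{Ensemble}
#' @export
readEnsembleTSV <- function(path) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE)
  cn <- colnames(tab)
  keys <- unique(sub("\\.[xyz]$", "", cn))
  if (length(cn) %% 3L != 0L || length(keys) * 3L != length(cn))
    stop("format error: coordinate table must have x/y/z columns per site")
  parts <- strsplit(keys, ":", fixed = TRUE)
  labels <- data.frame(chain = vapply(parts, `[`, "", 1L),
                       resno = as.integer(vapply(parts, `[`, "", 2L)))
  makeEnsemble(labels, as.matrix(tab), provenance = list(source = path,
                                                         format = "tsv"))
}

#' Write an ensemble as a TSV coordinate table
#' @param e an \linkS4class{Ensemble}
#' @param path output file
#' @param header optional provenance comment lines
#' @return invisibly, the path
#' @export
writeEnsembleTSV <- function(e, path, header = character()) {
  stopifnot(is(e, "Ensemble"))
  keys <- .labelKey(e@labels)
  cn <- as.vector(t(outer(keys, c(".x", ".y", ".z"), paste0)))
  df <- as.data.frame(e@frames)
  colnames(df) <- cn
  .writeTSV(df, path, header)
  invisible(path)
}
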