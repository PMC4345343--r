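# Binding-pocket geometry: pairwise C-alpha distances among the three key
# pocket residues for both (front and back) pockets, measured along frames
# or mode extrapolations, and a front/back anti-symmetry score.

#' Binding-pocket residue specification
#'
#' The two pockets of a homodimer are chain-swapped images of each other:
#' residues 1 and 2 sit on the "own" chain and residue 3 on the other chain.
#' The front pocket is the one whose residues 1 and 2 are on the first chain
#' in label order. Defaults are the Tar pocket residues Q152, R64 and R69'.
#'
#' @param res1,res2 residue numbers on the own chain (default 152, 64)
#' @param res3 residue number on the other chain (default 69)
#' @param chains the two chain ids, first = front pocket's own chain
#' @return a validated pocket spec list
#' @export
pocketSpec <- function(res1 = 152L, res2 = 64L, res3 = 69L,
                       chains = c("A", "B")) {
  if (length(chains) != 2L || chains[1] == chains[2])
    stop("parameter error: exactly two distinct chains are required")
  list(res1 = as.integer(res1), res2 = as.integer(res2),
       res3 = as.integer(res3), chains = as.character(chains))
}

.siteIndex <- function(labels, chain, resno) {
  i <- which(labels$chain == chain & labels$resno == resno)
  if (length(i) != 1L)
    stop("selection error: site ", chain, ":", resno, " not present")
  i
}

#' Pocket distances of a single conformation
#'
#' Euclidean C-alpha distances d12, d13', d23' for the front and back
#' pockets.
#'
#' @param s a \linkS4class{SiteSet}
#' @param spec a \code{\link{pocketSpec}}
#' @return one-row data.frame with columns d12_front, d13_front, d23_front,
#'   d12_back, d13_back, d23_back (nm)
#' @export
pocketDistances <- function(s, spec = pocketSpec()) {
  stopifnot(is(s, "SiteSet"))
  lab <- siteLabels(s)
  xyz <- .asXYZ(siteCoords(s))
  ch <- spec$chains
  one <- function(own, other) {
    p1 <- xyz[.siteIndex(lab, own, spec$res1), ]
    p2 <- xyz[.siteIndex(lab, own, spec$res2), ]
    p3 <- xyz[.siteIndex(lab, other, spec$res3), ]
    c(d12 = sqrt(sum((p1 - p2)^2)),
      d13 = sqrt(sum((p1 - p3)^2)),
      d23 = sqrt(sum((p2 - p3)^2)))
  }
  f <- one(ch[1], ch[2]); b <- one(ch[2], ch[1])
  data.frame(d12_front = f["d12"], d13_front = f["d13"], d23_front = f["d23"],
             d12_back = b["d12"], d13_back = b["d13"], d23_back = b["d23"],
             row.names = NULL)
}

#' Pocket distances along a mode extrapolation
#'
#' Evaluates \code{\link{pocketDistances}} on
#' \code{\link{extrapolateMode}(basis, k, a)} for every amplitude a of the
#' grid.
#'
#' @param basis a \linkS4class{ModeBasis}
#' @param k mode index
#' @param amplitudes numeric amplitude grid (nm); default -2..2 in 0.1 steps
#' @param spec a \code{\link{pocketSpec}}
#' @return data.frame(amplitude, d12_front, ..., d23_back)
#' @export
distancesAlongMode <- function(basis, k, amplitudes = seq(-2, 2, by = 0.1),
                               spec = pocketSpec()) {
  if (length(amplitudes) == 0L) stop("parameter error: empty amplitude grid")
  rows <- lapply(amplitudes, function(a)
    pocketDistances(extrapolateMode(basis, k, a), spec))
  cbind(data.frame(amplitude = amplitudes), do.call(rbind, rows))
}

#' Front/back anti-symmetry score of a pocket-distance series
#'
#' For each distance pair, the Pearson correlation between the front and
#' back deviations from their amplitude-zero values. Strongly negative
#' scores are the anti-symmetric (negative-cooperativity) signature: when a
#' distance opens in the front pocket it closes in the back pocket.
#'
#' @param series data.frame from \code{\link{distancesAlongMode}}; the
#'   amplitude grid must contain 0
#' @return named numeric vector (d12, d13, d23) of correlations in [-1, 1]
#' @export
antisymmetryScore <- function(series) {
  need <- c("amplitude", "d12_front", "d13_front", "d23_front",
            "d12_back", "d13_back", "d23_back")
  if (!all(need %in% names(series)))
    stop("validation error: series lacks required columns")
  if (nrow(series) < 3L)
    stop("validation error: need at least 3 amplitude points")
  i0 <- which(abs(series$amplitude) < 1e-12)
  if (length(i0) != 1L)
    stop("validation error: amplitude grid must contain 0 exactly once")
  score <- function(pair) {
    f <- series[[paste0(pair, "_front")]] - series[[paste0(pair, "_front")]][i0]
    b <- series[[paste0(pair, "_back")]] - series[[paste0(pair, "_back")]][i0]
    if (sd(f) == 0 || sd(b) == 0)
      stop("undefined-score error: zero-variance distance series for ", pair)
    cor(f, b)
  }
  c(d12 = score("d12"), d13 = score("d13"), d23 = score("d23"))
}
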