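# Internal helpers shared across modules. All coordinates are in nm;
# flattened coordinate vectors are site-major: (x1, y1, z1, x2, y2, z2, ...).

#' @importFrom stats dist quantile rnorm cor sd
#' @importFrom utils write.table read.table head
NULL

# N x 3 matrix view of a flat 3N vector (no copy semantics guaranteed).
.asXYZ <- function(v) {
  stopifnot(length(v) %% 3L == 0L)
  matrix(v, ncol = 3L, byrow = TRUE)
}

# Flat 3N vector from an N x 3 matrix.
.flattenXYZ <- function(m) as.vector(t(m))

# Canonical string key for (chain, resno) label rows.
.labelKey <- function(labels) paste(labels$chain, labels$resno, sep = ":")

.sameLabels <- function(a, b) {
  nrow(a) == nrow(b) && all(.labelKey(a) == .labelKey(b))
}

.stopIfLabelMismatch <- function(a, b, what = "inputs") {
  if (!.sameLabels(a, b))
    stop("comparability error: ", what, " do not share an identical site label list")
  invisible(TRUE)
}

# Expand per-chain inclusive residue ranges into an ordered label data.frame.
# `ranges` is a named list (chain id -> matrix/list of c(start, end) pairs).
.rangesToPairs <- function(ranges) {
  out <- list()
  for (ch in names(ranges)) {
    rr <- ranges[[ch]]
    if (is.numeric(rr) && length(rr) == 2L) rr <- list(rr)
    if (is.matrix(rr)) rr <- split(rr, seq_len(nrow(rr)))
    for (r in rr) {
      r <- as.integer(r)
      if (length(r) != 2L || r[1] > r[2])
        stop("parameter error: malformed residue range for chain ", ch)
      out[[length(out) + 1L]] <- data.frame(chain = ch, start = r[1], end = r[2],
                                            stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Orthonormal basis (3N x k) spanning the rigid-body fields (3 translations,
# 3 infinitesimal rotations about the centroid) of a template coordinate set.
.rigidBasis <- function(coords) {
  xyz <- .asXYZ(coords)
  n <- nrow(xyz)
  cen <- colMeans(xyz)
  rel <- sweep(xyz, 2L, cen)
  fields <- matrix(0, nrow = 3L * n, ncol = 6L)
  for (ax in 1:3) {                                # translations
    m <- matrix(0, n, 3L); m[, ax] <- 1
    fields[, ax] <- .flattenXYZ(m)
  }
  axes <- diag(3)
  for (ax in 1:3) {                                # linearised rotations
    m <- t(apply(rel, 1L, function(r) .cross3(axes[ax, ], r)))
    fields[, 3L + ax] <- .flattenXYZ(m)
  }
  dec <- qr(fields)
  qr.Q(dec)[, seq_len(dec$rank), drop = FALSE]
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Project v onto the orthogonal complement of the column span of Q (orthonormal).
.projectOut <- function(v, Q) v - Q %*% (crossprod(Q, v))

# Haar-uniform random rotation matrix from a normalised quaternion.
.randomRotation <- function() {
  q <- rnorm(4L)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3L, byrow = TRUE)
}

# Deterministic fixed-format TSV writer used for all pipeline artifacts.
.writeTSV <- function(df, path, header = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}
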