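# TSV persistence for mode bases and piston vectors: one bundle file with
# the site labels, mean coordinates and eigenvectors as columns, plus a
# small metadata sidecar written as comment lines.

#' Write a ModeBasis as a TSV bundle
#'
#' Layout: comment header (kind, eigenvalues), then one row per coordinate
#' (site label, axis, mean, v1..vK).
#'
#' @param basis a \linkS4class{ModeBasis}
#' @param path output file
#' @return invisibly, the path
#' @export
writeModeBasisTSV <- function(basis, path) {
  stopifnot(is(basis, "ModeBasis"))
  keys <- rep(.labelKey(basis@labels), each = 3L)
  axis <- rep(c("x", "y", "z"), nrow(basis@labels))
  df <- data.frame(site = keys, axis = axis, mean = basis@center)
  for (k in seq_along(basis@values))
    df[[paste0("v", k)]] <- basis@vectors[, k]
  .writeTSV(df, path, header = c(
    paste0("kind ", basis@kind),
    paste0("eigenvalues ", paste(sprintf("%.12g", basis@values),
                                 collapse = " "))))
  invisible(path)
}

#' Read a ModeBasis from a TSV bundle
#' @param path file written by \code{\link{writeModeBasisTSV}}
#' @return a \linkS4class{ModeBasis}
#' @export
readModeBasisTSV <- function(path) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  hdr <- grep("^# ", readLines(path, n = 10L), value = TRUE)
  kind <- sub("^# kind ", "", grep("^# kind ", hdr, value = TRUE))
  vals <- as.numeric(strsplit(sub("^# eigenvalues ", "",
                                  grep("^# eigenvalues ", hdr, value = TRUE)),
                              " ")[[1L]])
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE)
  keys <- tab$site[seq(1L, nrow(tab), by = 3L)]
  parts <- strsplit(keys, ":", fixed = TRUE)
  labels <- data.frame(chain = vapply(parts, `[`, "", 1L),
                       resno = as.integer(vapply(parts, `[`, "", 2L)))
  vcols <- grep("^v[0-9]+$", names(tab), value = TRUE)
  new("ModeBasis", labels = labels, center = tab$mean, values = vals,
      vectors = as.matrix(tab[, vcols, drop = FALSE]), kind = kind,
      meta = list(source = path))
}

#' Write a PistonVector as a TSV bundle
#'
#' One row per coordinate (site label, axis, component, per-site mask).
#'
#' @param pv a \linkS4class{PistonVector}
#' @param path output file
#' @return invisibly, the path
#' @export
writePistonVectorTSV <- function(pv, path) {
  stopifnot(is(pv, "PistonVector"))
  keys <- rep(.labelKey(pv@labels), each = 3L)
  df <- data.frame(site = keys, axis = rep(c("x", "y", "z"), nrow(pv@labels)),
                   component = pv@vector,
                   mask = rep(as.integer(pv@mask), each = 3L))
  .writeTSV(df, path, header = c(
    paste0("rawNorm ", sprintf("%.12g", pv@rawNorm)),
    paste0("fitSites ", pv@provenance$fitSites %||% "unknown")))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
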