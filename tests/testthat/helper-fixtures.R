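# Shared fixtures: all built in code, no stored data files.

# Small-M synthetic spec under the package's reference conditions.
tinySpec <- function(M = 50L, seed = 42L, ...) {
  syntheticSpec(M = as.integer(M), seed = seed, ...)
}

# Short-helix bundle whose alpha4 helices are weakly connected: the tuned
# contact topology for which the softest ANM mode is the alpha4 slide.
shortBundleSpec <- function(...) {
  hr <- matrix(c(44L, 53L, 89L, 98L, 118L, 127L, 146L, 155L),
               ncol = 2L, byrow = TRUE)
  syntheticSpec(helixRanges = hr, bundleRadius = 0.7, alpha4Radius = 1.6, ...)
}

# Haar-uniform random rotation (independent of the package's internal one).
randomRotationFix <- function() {
  repeat {
    m <- matrix(rnorm(9L), 3L)
    q <- qr(m)
    R <- qr.Q(q) %*% diag(sign(diag(qr.R(q))))
    if (det(R) > 0) return(R)
  }
}

rigidly <- function(coords, R = randomRotationFix(), t = rnorm(3)) {
  m <- matrix(coords, ncol = 3L, byrow = TRUE)
  as.vector(t(sweep(m %*% R, 2L, t, "+")))
}

# Minimal hand-rolled PDB text writer for I/O edge cases (missing residues,
# HETATM-only files, inconsistent models); coordinates given in Angstrom.
writeMiniPDB <- function(path, models, type = "ATOM") {
  lines <- character()
  multi <- length(models) > 1L
  for (m in seq_along(models)) {
    df <- models[[m]]
    if (multi) lines <- c(lines, sprintf("MODEL     %4d", m))
    for (i in seq_len(nrow(df)))
      lines <- c(lines, sprintf(
        "%-6s%5d  %-3s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        type, i, df$elety[i], df$resid[i], df$chain[i], df$resno[i],
        df$x[i], df$y[i], df$z[i]))
    if (multi) lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

miniAtoms <- function(resno = 1:4, chain = "A", elety = "CA") {
  n <- length(resno)
  data.frame(chain = rep(chain, length.out = n), resno = resno,
             resid = "ALA", elety = rep(elety, length.out = n),
             x = resno * 1.5, y = rep(2, n), z = rep(3, n))
}

# Flat coordinates (nm) of a small non-degenerate point set with a
# physical minimum separation (C-alpha traces never pack closer).
randomSites <- function(n, box = 2, seed = NULL, minSep = 0.35) {
  if (!is.null(seed)) set.seed(seed)
  pts <- matrix(numeric(0), 0, 3)
  while (nrow(pts) < n) {
    cand <- runif(3, 0, box)
    if (nrow(pts) == 0 ||
        min(sqrt(rowSums(sweep(pts, 2, cand)^2))) >= minSep)
      pts <- rbind(pts, cand)
  }
  as.vector(t(pts))
}
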