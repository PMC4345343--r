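# End-to-end pipeline: synthetic generation (or ensemble input), C-alpha
# selection, iterative mean + PCA, ANM of the mean, piston vector and its
# spectrum, 2D landscape projection, density-peak and DRMS clustering, and
# pocket anti-symmetry — each stage written as a TSV artifact with a
# provenance header. Runs are deterministic for a fixed config and seed.

#' Pipeline configuration
#'
#' All defaults equal the package's reference parameters: Tar helix ranges,
#' ANM cutoff 1.5 nm and gamma 100 kcal mol^-1 nm^-2, DRMS cutoff 0.2 nm,
#' two PCA landscape modes, density-peak clustering with the 2\%-neighbour
#' kernel scale. Without an input ensemble, the run operates on the default
#' synthetic spec ("reference conditions on synthetic data").
#'
#' @param input optional path to a multi-model PDB or ensemble TSV; when
#'   NULL the synthetic generator provides the ensemble
#' @param ranges per-chain helix selection ranges (PDB input only)
#' @param synthetic a \code{\link{syntheticSpec}} for generated input
#' @param seed seed overriding the synthetic spec's
#' @param anm \code{\link{anmParameters}}
#' @param K number of landscape modes
#' @param drmsCutoff gromos clustering cutoff (nm)
#' @param drmsMaxFrames frame subsample cap for the pairwise metrics stage
#' @param dcFrac neighbour fraction for the density-peak kernel scale
#' @param landscapeKernel "gaussian" or "cutoff"
#' @param landscapeCenters number of density-peak centers (top-k by gamma)
#' @param pvAmplitude alpha4 slide amplitude (nm) used to build the
#'   synthetic holo structure for the piston vector stage
#' @param pocket a \code{\link{pocketSpec}}
#' @param pocketAmplitudes amplitude grid for the pocket stage (nm)
#' @return a validated config list
#' @export
pipelineConfig <- function(input = NULL, ranges = tarHelixRanges(),
                           synthetic = syntheticSpec(M = 1000L),
                           seed = NULL,
                           anm = anmParameters(), K = 2L,
                           drmsCutoff = 0.2, drmsMaxFrames = 150L,
                           dcFrac = 0.02,
                           landscapeKernel = "gaussian",
                           landscapeCenters = NULL,
                           pvAmplitude = 0.3,
                           pocket = pocketSpec(),
                           pocketAmplitudes = seq(-2, 2, by = 0.1)) {
  if (!is.null(seed)) synthetic$seed <- seed
  if (drmsCutoff <= 0)
    stop("validation error: drmsCutoff must be > 0")
  if (K < 1L) stop("validation error: K must be >= 1")
  if (dcFrac <= 0 || dcFrac >= 1)
    stop("validation error: dcFrac must be in (0, 1)")
  list(input = input, ranges = ranges, synthetic = synthetic,
       anm = anm, K = as.integer(K), drmsCutoff = drmsCutoff,
       drmsMaxFrames = as.integer(drmsMaxFrames), dcFrac = dcFrac,
       landscapeKernel = landscapeKernel,
       landscapeCenters = landscapeCenters,
       pvAmplitude = pvAmplitude, pocket = pocket,
       pocketAmplitudes = pocketAmplitudes)
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of \code{\link{pipelineConfig}};
#' nested keys (synthetic, anm, pocket) mirror their constructors. Missing
#' keys keep their defaults.
#'
#' @param path YAML file
#' @return a config list
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  direct <- intersect(names(y), c("input", "seed", "K", "drmsCutoff",
                                  "drmsMaxFrames", "dcFrac",
                                  "landscapeKernel", "landscapeCenters",
                                  "pvAmplitude"))
  args[direct] <- y[direct]
  if (!is.null(y$synthetic)) {
    sa <- y$synthetic
    if (!is.null(sa$basins)) sa$basins <- as.data.frame(sa$basins)
    if (!is.null(sa$modeSd)) sa$modeSd <- unlist(sa$modeSd)
    args$synthetic <- do.call(syntheticSpec, sa)
  }
  if (!is.null(y$anm)) args$anm <- do.call(anmParameters, y$anm)
  if (!is.null(y$pocket)) args$pocket <- do.call(pocketSpec, y$pocket)
  do.call(pipelineConfig, args)
}

.configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(config, file = f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Chains: ensemble input (synthetic or file) -> selection -> iterative
#' mean + PCA -> ANM of the mean -> piston vector + spectrum -> landscape
#' projection -> density-peak clustering -> DRMS metrics + gromos
#' clustering -> pocket distances along mode 1 -> summary. Every artifact
#' is a TSV with a provenance header (config hash, package version); reruns
#' with an identical config produce byte-identical artifacts.
#'
#' @param config a \code{\link{pipelineConfig}}
#' @param outDir output directory (created if missing)
#' @param verbose log stage progress to stderr?
#' @return invisibly, a list of the main in-memory results
#' @export
runPipeline <- function(config = pipelineConfig(), outDir, verbose = TRUE) {
  stopifnot(!missing(outDir))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  hash <- .configHash(config)
  ver <- as.character(utils::packageVersion("receptorModes"))
  hdr <- c(paste0("receptorModes ", ver), paste0("config-md5 ", hash))
  log <- function(...) if (verbose) message("[pipeline] ", ...)
  art <- function(name) file.path(outDir, name)

  truth <- NULL
  if (is.null(config$input)) {
    log("generating synthetic ensemble (M = ", config$synthetic$M, ")")
    syn <- syntheticEnsemble(config$synthetic)
    ens <- syn$ensemble
    truth <- syn$truth
    template <- syn$template
    hdr <- c(hdr, paste0("input synthetic seed=", config$synthetic$seed))
  } else {
    log("reading ensemble from ", config$input)
    ens <- if (grepl("\\.(tsv|txt)$", config$input))
      readEnsembleTSV(config$input)
    else readEnsemblePDB(config$input, ranges = config$ranges)
    template <- getFrame(ens, 1L)
    hdr <- c(hdr, paste0("input ", config$input, " md5=",
                         unname(tools::md5sum(config$input))))
  }

  log("iterative mean + PCA over ", nFrames(ens), " frames")
  pca <- ensemblePCA(ens)
  basis <- pca$basis
  nShow <- min(20L, length(basis@values))
  .writeTSV(data.frame(mode = seq_len(nShow),
                       eigenvalue = basis@values[seq_len(nShow)],
                       fraction = basis@values[seq_len(nShow)] /
                         sum(basis@values)),
            art("pca_eigenvalues.tsv"), hdr)

  topK <- min(10L, length(basis@values))
  writeModeBasisTSV(new("ModeBasis", labels = basis@labels,
                        center = basis@center,
                        values = basis@values[seq_len(topK)],
                        vectors = basis@vectors[, seq_len(topK), drop = FALSE],
                        kind = basis@kind),
                    art("pca_basis.tsv"))

  log("ANM normal modes of the mean structure")
  meanSet <- makeSiteSet(siteLabels(ens), pca$mean)
  anmBasis <- anmSiteSet(meanSet, config$anm)
  .writeTSV(data.frame(mode = seq_len(nShow),
                       eigenvalue = anmBasis@values[seq_len(nShow)]),
            art("anm_eigenvalues.tsv"), hdr)
  ov <- overlapMatrix(anmBasis, basis, kA = 5L, kB = 5L)
  ovDf <- as.data.frame(ov@values)
  colnames(ovDf) <- paste0("pca", seq_len(ncol(ovDf)))
  .writeTSV(cbind(data.frame(anm = seq_len(nrow(ovDf))), ovDf),
            art("anm_pca_overlaps.tsv"), hdr)

  log("piston vector and projection spectrum")
  a4 <- if (is.null(truth)) alpha4Ranges() else .specAlpha4(config$synthetic)
  if (is.null(truth)) {
    # canonical piston probe: slide the alpha4 sites of the mean down in z
    apoSet <- meanSet
    mask <- .rangeMask(siteLabels(ens), a4)
    disp <- matrix(0, nSites(ens), 3L)
    disp[mask, 3L] <- -config$pvAmplitude / sqrt(sum(mask))
    holoSet <- makeSiteSet(siteLabels(ens), pca$mean + .flattenXYZ(disp))
  } else {
    apoSet <- template
    holoXYZ <- siteCoords(template) + config$pvAmplitude * truth@fields[, "slide"]
    holoSet <- makeSiteSet(siteLabels(template), holoXYZ)
  }
  pv <- buildPistonVector(apoSet, holoSet, a4)
  writePistonVectorTSV(pv, art("piston_vector.tsv"))
  spec10 <- pvSpectrum(pv, basis, K = min(10L, length(basis@values)))
  .writeTSV(spec10, art("pv_spectrum.tsv"), hdr)

  log("landscape projection and density-peak clustering")
  proj <- projectEnsemble(pca$fitted, basis, K = config$K, fit = FALSE)
  .writeTSV(proj, art("projections.tsv"), hdr)
  pts <- as.matrix(proj[, -1L, drop = FALSE])
  dc <- dcRuleOfThumb(pts, config$dcFrac)
  kCenters <- config$landscapeCenters
  if (is.null(kCenters)) kCenters <- max(1L, nrow(config$synthetic$basins))
  dpc <- densityPeakCluster(pts, dc = dc, kernel = config$landscapeKernel,
                            k = kCenters)
  .writeTSV(data.frame(frame = proj$frame, label = clusterLabels(dpc)),
            art("landscape_labels.tsv"), hdr)
  centers <- dpc@centers
  centers$probability <- clusterProbs(dpc)
  .writeTSV(centers, art("landscape_clusters.tsv"), hdr)

  log("pairwise metrics and DRMS clustering")
  M <- nFrames(ens)
  stride <- max(1L, ceiling(M / config$drmsMaxFrames))
  sub <- seq(1L, M, by = stride)
  subEns <- makeEnsemble(siteLabels(ens), pca$fitted@frames[sub, , drop = FALSE])
  drmsMat <- pairwiseMatrix(subEns, "drms")
  rmsdMat <- pairwiseMatrix(subEns, "rmsd")
  .writeTSV(pairwiseHistogram(drmsMat), art("drms_histogram.tsv"), hdr)
  .writeTSV(pairwiseHistogram(rmsdMat), art("rmsd_histogram.tsv"), hdr)
  gromos <- drmsCluster(drmsMat, config$drmsCutoff)
  .writeTSV(data.frame(cluster = seq_along(clusterProbs(gromos)),
                       probability = clusterProbs(gromos)),
            art("drms_clusters.tsv"), hdr)

  log("pocket distances along mode 1")
  pock <- distancesAlongMode(basis, 1L, config$pocketAmplitudes,
                             config$pocket)
  .writeTSV(pock, art("pocket_distances.tsv"), hdr)
  anti <- antisymmetryScore(pock)
  .writeTSV(data.frame(pair = names(anti), score = as.numeric(anti)),
            art("pocket_antisymmetry.tsv"), hdr)

  log("summary")
  summary <- data.frame(
    quantity = c("frames", "sites", "pca_lambda1", "pca_lambda2",
                 "pv_mode_max_abs_projection", "landscape_clusters",
                 "drms_clusters", "biggest_drms_cluster_fraction",
                 "min_antisymmetry_score"),
    value = c(M, nSites(ens), basis@values[1L], basis@values[2L],
              max(abs(spec10$projection)), length(clusterProbs(dpc)),
              length(clusterProbs(gromos)), max(clusterProbs(gromos)),
              min(anti)))
  .writeTSV(summary, art("summary.tsv"), hdr)
  invisible(list(ensemble = ens, pca = pca, anm = anmBasis, pv = pv,
                 spectrum = spec10, projections = proj, landscape = dpc,
                 gromos = gromos, pockets = pock, antisymmetry = anti,
                 truth = truth))
}
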