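## End-to-end wiring: configuration, the depth-to-surface chain, the
## train/evaluate experiment, and a manifest-producing e2e run.

#' Default pipeline configuration
#'
#' Every numeric default equals the corresponding module-level default; the
#' object round-trips losslessly through JSON ([writeConfig()] /
#' [readConfig()]).
#'
#' @param ... overrides of the defaults.
#' @return a named list.
#' @export
bcs3dConfig <- function(...) {
  cfg <- list(
    grid_n = 150L, margin = 0.1, idw_k = 8L, idw_radius = 25,
    impute_min_valid = 0.6,
    variance_threshold = 0.95, k_max = 20L,
    span = 0.75, degree = 2L,
    bcs_thresh = 0.5, bw_frac = 0.20,
    noise_sd = 3, dropout = 0.05,
    bcs_range = c(2.0, 3.5),
    prominence_thresh = 3,
    seed = 42L, verbose = FALSE)
  ovr <- list(...)
  bad <- setdiff(names(ovr), names(cfg))
  if (length(bad))
    bcsStop("invalidArgument", paste("unknown config fields:", paste(bad, collapse = ", ")))
  cfg[names(ovr)] <- ovr
  cfg
}

#' Write / read a pipeline configuration as JSON
#'
#' @param cfg a [bcs3dConfig()] list.
#' @param path JSON file path.
#' @return `readConfig` returns the configuration list.
#' @export
writeConfig <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  def <- bcs3dConfig()
  for (f in intersect(names(cfg), names(def)))  # restore each field's mode
    storage.mode(cfg[[f]]) <- storage.mode(def[[f]])
  do.call(bcs3dConfig, cfg)
}

#' From one depth frame to a complete normalized surface
#'
#' Back-projects the depth map, detects the four landmarks (unless truth is
#' supplied), builds the canonical frame, resamples the ROI and imputes
#' missing cells — the per-frame path of the scoring pipeline.
#'
#' @param depth a [DepthMap-class].
#' @param landmarks optional [LandmarkSet-class] in the camera frame; when
#'   `NULL` they are detected automatically.
#' @param config a [bcs3dConfig()] list.
#' @return a complete [NormalizedSurface-class], with the used landmarks
#'   attached as attribute `landmarks`.
#' @export
processDepth <- function(depth, landmarks = NULL, config = bcs3dConfig()) {
  cloud <- depthToPointCloud(depth)
  if (is.null(landmarks))
    landmarks <- detectLandmarks(
      cloud, landmarkConfig(prominenceThresh = config$prominence_thresh))
  fr <- roiFrame(landmarks)
  surf <- extractROI(cloud, fr, gridN = config$grid_n, margin = config$margin,
                     k = config$idw_k, radius = config$idw_radius)
  surf <- imputeSurface(surf, minValid = config$impute_min_valid)
  attr(surf, "landmarks") <- landmarks
  surf
}

#' Train-and-evaluate experiment on synthetic heifers
#'
#' Simulates `nTrain + nTest` synthetic heifers ([simulateAnimals()]), runs
#' every corrupted depth frame through the full landmark-detection and
#' normalization chain, trains the shape model on the first `nTrain` animals
#' and evaluates the held-out rest.
#'
#' @param nTrain,nTest cohort split.
#' @param seed integer run seed.
#' @param config a [bcs3dConfig()] list.
#' @return list with `rmsep`, `pred`, `truth` (held-out true BCS), `model`
#'   and the per-animal `train_scores`.
#' @export
rmsepExperiment <- function(nTrain = 200L, nTest = 100L, seed = 42L,
                            config = bcs3dConfig()) {
  n <- nTrain + nTest
  sim <- simulateAnimals(n, bcsRange = config$bcs_range,
                         noiseSd = config$noise_sd,
                         dropoutFrac = config$dropout, seed = seed)
  surfs <- vector("list", n)
  for (i in seq_len(n)) surfs[[i]] <- processDepth(sim$depths[[i]], config = config)
  bcs <- sim$truth$bcs_true
  trIdx <- seq_len(nTrain)
  model <- fitShapeModel(surfs[trIdx], bcs[trIdx],
                         varianceThreshold = config$variance_threshold,
                         kMax = config$k_max, seed = seed)
  pred <- vapply(surfs[-trIdx], predictBCS, numeric(1), model = model)
  list(rmsep = evaluateRMSEP(pred, bcs[-trIdx]),
       pred = pred, truth = bcs[-trIdx], model = model,
       train_scores = bcs[trIdx])
}

#' Run the end-to-end pipeline and write a manifest
#'
#' Simulates a small cohort, writes depth frames (16-bit PNG + sidecar),
#' detected landmarks (JSON), the trained model and a prediction CSV under
#' `out`, then writes `manifest.json` listing every artifact with its MD5
#' content hash. Identical seeds produce identical manifests.
#'
#' @param out output directory (created if needed).
#' @param nTrain,nTest cohort split (kept small; this is a wiring check, not
#'   the evaluation experiment).
#' @param seed integer run seed.
#' @param config a [bcs3dConfig()] list.
#' @return the manifest list, invisibly; `manifest.json` on disk.
#' @export
runPipeline <- function(out, nTrain = 24L, nTest = 6L, seed = 42L,
                        config = bcs3dConfig()) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  res <- rmsepExperiment(nTrain, nTest, seed = seed, config = config)
  sim <- simulateAnimals(nTrain + nTest, bcsRange = config$bcs_range,
                         noiseSd = config$noise_sd,
                         dropoutFrac = config$dropout, seed = seed)
  nshow <- min(3L, length(sim$depths))
  for (i in seq_len(nshow))
    writeDepthPNG(sim$depths[[i]], file.path(out, sprintf("depth_%03d.png", i)))
  saveModel(res$model, file.path(out, "model.bcs3d"))
  predDf <- data.frame(animal_id = sprintf("animal%03d", nTrain + seq_along(res$pred)),
                       bcs_true = round(res$truth, 4),
                       bcs3d = round(res$pred, 2))
  utils::write.csv(predDf, file.path(out, "predictions.csv"), row.names = FALSE)
  files <- sort(setdiff(list.files(out), "manifest.json"))
  manifest <- list(seed = seed,
                   rmsep = round(res$rmsep, 4),
                   artifacts = lapply(files, function(f)
                     list(file = f,
                          md5 = unname(tools::md5sum(file.path(out, f))))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
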