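# Reproducible pipeline tying the stages together: YAML configuration,
# 16-bit TIFF fields in, CSV/JSON tables out, checksummed manifests and
# stage-wise plain-text logging so every density denominator is auditable.

#' Pipeline configuration
#'
#' Captures every free parameter of the pipeline as explicit configuration
#' (replacing interactive threshold adjustment), serialized verbatim into
#' every output for provenance.
#'
#' @param pixelSizeUm micrometres per pixel (default 0.415; a 424 um field
#'   side is then 1022 px and a ~50 um^2 soma ~290 px).
#' @param fieldSideUm square field side, micrometres (default 424.26, field
#'   area 0.18 mm^2).
#' @param somaQuantile,backgroundQuantile intensity quantile fractions.
#' @param minSizePx minimum soma size, pixels.
#' @param pruneLenUm skeleton spur-pruning length, micrometres.
#' @param somaMarginUm soma dilation margin for tracing, micrometres.
#' @param alpha significance level.
#' @param seed integer RNG seed.
#' @param region region label attached to outputs (e.g. \code{"DG"}).
#' @param cellType generator preset, \code{"astrocyte"} or
#'   \code{"microglia"}.
#' @param nAnimals,fieldsPerAnimal simulated study size.
#' @param factors named list of mutant/WT regime factors (see
#'   [makeGroupDataset()]).
#' @param noiseSd,psfSigmaUm acquisition noise model for simulated fields.
#' @param borderCells border-cell policy, see [measureField()].
#' @param denoiseSigmaPx Gaussian pre-smoothing SD in pixels applied before
#'   thresholding (0 = none), see [measureField()].
#' @param cellsPerField override of the regime's expected cells per field
#'   (\code{NULL} keeps the preset).
#' @param poissonCounts Poisson-vary the per-field counts (default TRUE);
#'   \code{FALSE} plants a fixed count, useful for threshold calibration.
#' @return named list of class \code{"gliamorphConfig"}.
#' @export
pipelineConfig <- function(pixelSizeUm = 0.415, fieldSideUm = 424.26,
                           somaQuantile = 0.995, backgroundQuantile = 0.90,
                           minSizePx = 150, pruneLenUm = 2, somaMarginUm = 0.5,
                           alpha = 0.05, seed = 1, region = "DG",
                           cellType = "astrocyte", nAnimals = 5,
                           fieldsPerAnimal = 1,
                           factors = list(totalLength = 0.58),
                           noiseSd = 200, psfSigmaUm = 0.3,
                           borderCells = "countOnly", denoiseSigmaPx = 0,
                           cellsPerField = NULL, poissonCounts = TRUE) {
  cfg <- list(pixelSizeUm = pixelSizeUm, fieldSideUm = fieldSideUm,
              somaQuantile = somaQuantile,
              backgroundQuantile = backgroundQuantile, minSizePx = minSizePx,
              pruneLenUm = pruneLenUm, somaMarginUm = somaMarginUm,
              alpha = alpha, seed = seed, region = region, cellType = cellType,
              nAnimals = nAnimals, fieldsPerAnimal = fieldsPerAnimal,
              factors = factors, noiseSd = noiseSd, psfSigmaUm = psfSigmaUm,
              borderCells = borderCells, denoiseSigmaPx = denoiseSigmaPx,
              cellsPerField = cellsPerField, poissonCounts = poissonCounts)
  class(cfg) <- "gliamorphConfig"
  cfg
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @return [pipelineConfig()] list (read) or the path (write, invisibly).
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipelineConfig()
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  cfg[names(raw)] <- raw
  class(cfg) <- "gliamorphConfig"
  cfg
}

#' @rdname readPipelineConfig
#' @param config a [pipelineConfig()] list.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Stable hash of a configuration (md5 of its canonical YAML).
configHash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

writeFieldTiff <- function(image, path) {
  m <- fieldPixels(image)
  scaled <- pmin(m / 65535, 1)   # first arg keeps the matrix dim
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

readFieldTiff <- function(path, pixelSizeUm, channel = "IBA1-like") {
  if (is.null(pixelSizeUm) || !is.finite(pixelSizeUm))
    stop("pixel-size calibration missing: refusing to measure in pixel units")
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  FieldImage(m * 65535, pixelSizeUm, channel)
}

writeManifest <- function(dir, files) {
  paths <- file.path(dir, files)
  md5 <- tools::md5sum(paths)
  mf <- data.frame(file = files, md5 = unname(md5))
  write.csv(mf, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(mf)
}

#' Simulate a study and write fields, truth tables and manifest
#'
#' Generates the two-genotype synthetic study described by the
#' configuration, writing one 16-bit single-channel TIFF per field, the
#' per-cell ground truth as CSV and JSON, the generation config as YAML, a
#' plain-text log, and a checksum manifest. Deterministic for a fixed
#' config seed.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created if needed; must be writable).
#' @return invisibly, the manifest data.frame.
#' @export
runSimulate <- function(config = pipelineConfig(), outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outDir, 2) != 0) stop("output directory is not writable")
  regime <- morphRegime(config$cellType, noiseSd = config$noiseSd,
                        psfSigmaUm = config$psfSigmaUm)
  if (!is.null(config$cellsPerField))
    regime$cellsPerField <- config$cellsPerField
  ds <- makeGroupDataset(regime, factors = config$factors,
                         nAnimals = config$nAnimals,
                         fieldsPerAnimal = config$fieldsPerAnimal,
                         fieldSideUm = config$fieldSideUm,
                         pixelSizeUm = config$pixelSizeUm,
                         seed = config$seed, render = TRUE,
                         poissonCounts = isTRUE(config$poissonCounts))
  hash <- configHash(config)
  files <- character()
  for (key in names(ds$images)) {
    f <- paste0(key, ".tif")
    writeFieldTiff(ds$images[[key]], file.path(outDir, f))
    files <- c(files, f)
  }
  writeCsvExact(ds$truth, file.path(outDir, "truth_cells.csv"),
                comment = paste("gliamorph config", hash))
  writeCsvExact(ds$fields, file.path(outDir, "truth_fields.csv"),
                comment = paste("gliamorph config", hash))
  jsonlite::write_json(list(config_hash = hash, fields = ds$fields,
                            cells = ds$truth),
                       file.path(outDir, "truth.json"), digits = NA,
                       dataframe = "rows")
  writePipelineConfig(config, file.path(outDir, "config.yaml"))
  log <- c(sprintf("gliamorph simulate | config %s", hash),
           sprintf("fields written: %d", length(files)),
           sprintf("cells planted: %d", nrow(ds$truth)))
  writeLines(log, file.path(outDir, "simulate.log"))
  files <- c(files, "truth_cells.csv", "truth_fields.csv", "truth.json",
             "config.yaml", "simulate.log")
  invisible(writeManifest(outDir, files))
}

#' Measure fields and write per-cell and per-field tables
#'
#' Runs [measureField()] on every TIFF, writing a per-cell CSV mirroring the
#' morphology-table layout, a per-field summary CSV, a QC overlay TIFF per
#' field (foreground, soma and skeleton at increasing intensity), and a log
#' recording the counts retained at each stage.
#'
#' @param images character vector of TIFF paths, or a directory containing
#'   \code{*.tif}.
#' @param config a [pipelineConfig()]; supplies the pixel-size calibration
#'   (an error if missing - measurements are never silently reported in
#'   pixel units).
#' @param outDir output directory.
#' @return invisibly, a list with \code{cells} and \code{fields}
#'   data.frames.
#' @export
runMeasure <- function(images, config = pipelineConfig(), outDir) {
  if (length(images) == 1L && dir.exists(images))
    images <- list.files(images, pattern = "\\.tiff?$", full.names = TRUE)
  if (!length(images)) stop("no TIFF images to measure")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hash <- configHash(config)
  log <- c(sprintf("gliamorph measure | config %s", hash))
  allCells <- list(); allFields <- list()
  for (path in images) {
    key <- sub("\\.tiff?$", "", basename(path))
    img <- readFieldTiff(path, config$pixelSizeUm)
    mf <- measureField(img, somaQuantile = config$somaQuantile,
                       backgroundQuantile = config$backgroundQuantile,
                       minSizePx = config$minSizePx,
                       pruneLenUm = config$pruneLenUm,
                       somaMarginUm = config$somaMarginUm,
                       borderCells = config$borderCells,
                       denoiseSigmaPx = config$denoiseSigmaPx)
    meta <- strsplit(key, "_")[[1]]
    ann <- if (length(meta) >= 3)
      data.frame(genotype = meta[1], animal = paste0(meta[1], sub("^a", "", meta[2])),
                 field = sub("^f", "", meta[3])) else
      data.frame(genotype = NA, animal = key, field = 1L)
    annRep <- ann[rep(1L, nrow(mf$cells)), , drop = FALSE]
    allCells[[key]] <- cbind(annRep,
                             region = rep(config$region, nrow(mf$cells)),
                             mf$cells, row.names = NULL)
    allFields[[key]] <- cbind(ann, region = config$region, mf$summary,
                              row.names = NULL)
    log <- c(log, sprintf(
      "%s: detected %d soma(ta), %d on border, %d measured, density %.2f cells/mm2",
      key, mf$summary$nDetected, mf$summary$nBorder, mf$summary$nMorphology,
      mf$summary$density))
    overlay <- (foregroundMask(img, mf$thresholds) * 1 +
                  (somaLabels(mf$somata) > 0) * 1) / 3
    for (sk in mf$skeletons)
      if (nrow(sk@coords)) overlay[sk@coords] <- 1
    tiff::writeTIFF(overlay, file.path(outDir, paste0(key, "_overlay.tif")),
                    bits.per.sample = 8L)
  }
  cells <- do.call(rbind, c(allCells, list(make.row.names = FALSE)))
  fields <- do.call(rbind, c(allFields, list(make.row.names = FALSE)))
  writeCsvExact(cells, file.path(outDir, "cells.csv"),
                comment = paste("gliamorph config", hash))
  writeCsvExact(fields, file.path(outDir, "fields.csv"),
                comment = paste("gliamorph config", hash))
  writeLines(log, file.path(outDir, "measure.log"))
  invisible(list(cells = cells, fields = fields))
}

#' Compare genotypes from a per-cell table and write the report
#'
#' Aggregates the per-cell table to per-animal means (the sampling unit),
#' adds field densities when a fields table is given, and produces the
#' morphology-table-style report: per-parameter mean +/- SEM by genotype,
#' the test used (normality-gated), p, and significance markers (* p < 0.05,
#' ** p < 0.01).
#'
#' @param percellCsv path to a cells CSV from [runMeasure()] (or a
#'   ground-truth cells CSV from [runSimulate()]).
#' @param config a [pipelineConfig()].
#' @param outDir output directory.
#' @param fieldsCsv optional path to the per-field summary CSV; adds the
#'   density row.
#' @return invisibly, the comparison data.frame.
#' @export
runCompare <- function(percellCsv, config = pipelineConfig(), outDir,
                       fieldsCsv = NULL) {
  cells <- readCsvExact(percellCsv)
  long <- animalMeans(cells)
  if (!is.null(fieldsCsv)) {
    fl <- readCsvExact(fieldsCsv)
    dens <- stats::aggregate(fl$density,
                             by = list(genotype = fl$genotype,
                                       animal = fl$animal), FUN = mean)
    long <- rbind(long, data.frame(genotype = dens$genotype,
                                   animal = dens$animal,
                                   parameter = "density", value = dens$x))
  }
  cmp <- compareGroups(long, alpha = config$alpha)
  cmp$region <- config$region
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeCsvExact(cmp, file.path(outDir, "comparison.csv"),
                comment = paste("gliamorph config", configHash(config),
                                "|", attr(cmp, "footnote")))
  invisible(cmp)
}

#' Normalize a densitometry CSV and write the report
#'
#' @param csv path to a densitometry CSV (columns \code{blot}, \code{lane},
#'   \code{genotype}, \code{target}, \code{targetIntensity},
#'   \code{actinIntensity}, optional \code{region}).
#' @param config a [pipelineConfig()].
#' @param outDir output directory.
#' @return invisibly, the [densitometryPercent()] result.
#' @export
runDensitometry <- function(csv, config = pipelineConfig(), outDir) {
  tab <- readCsvExact(csv)
  res <- densitometryPercent(tab, alpha = config$alpha)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hash <- configHash(config)
  writeCsvExact(res$table, file.path(outDir, "densitometry_normalized.csv"),
                comment = paste("gliamorph config", hash))
  writeCsvExact(res$comparison, file.path(outDir, "densitometry_comparison.csv"),
                comment = paste("gliamorph config", hash))
  invisible(res)
}
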