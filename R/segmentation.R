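# Quantile-based soma detection: empirical intensity quantiles of the whole
# field set a bright threshold that isolates somata and a lower one that
# separates all labelled signal (somata plus processes) from background.

#' Compute soma and background intensity thresholds
#'
#' Thresholds are the empirical quantiles (linear-interpolation convention,
#' \code{stats::quantile} type 7) of all pixel intensities of the field.
#' They are monotone in the requested fractions. On a constant image both
#' thresholds coincide; the result is flagged degenerate and soma detection
#' downstream returns no objects.
#'
#' @param image a [FieldImage-class].
#' @param somaQuantile fraction in (0, 1) above which pixels count as soma
#'   signal (default 0.995).
#' @param backgroundQuantile fraction in (0, 1) above which pixels count as
#'   labelled foreground (default 0.90); must be below \code{somaQuantile}.
#' @return a [QuantileThresholds-class].
#' @examples
#' img <- FieldImage(matrix(1:100, 10, 10), 0.5)
#' computeThresholds(img, 0.9, 0.5)
#' @export
computeThresholds <- function(image, somaQuantile = 0.995,
                              backgroundQuantile = 0.90) {
  stopifnot(is(image, "FieldImage"))
  if (somaQuantile <= 0 || somaQuantile >= 1 ||
      backgroundQuantile <= 0 || backgroundQuantile >= 1)
    stop("quantile fractions must lie strictly between 0 and 1")
  if (backgroundQuantile >= somaQuantile)
    stop("backgroundQuantile must be below somaQuantile")
  qs <- quantile(image@pixels, c(backgroundQuantile, somaQuantile),
                 names = FALSE, type = 7)
  new("QuantileThresholds", somaQuantile = somaQuantile,
      backgroundQuantile = backgroundQuantile,
      tSoma = qs[2], tBg = qs[1], degenerate = qs[1] == qs[2])
}

#' Detect somata by thresholding and size-filtered component labelling
#'
#' Pixels at or above the soma threshold are grouped into 8-connected
#' components; components smaller than \code{minSizePx} are discarded.
#' Surviving components are labelled in raster-scan order of their first
#' pixel, so labels are deterministic. Components touching the image border
#' are flagged (border cells are typically kept for density but excluded
#' from morphology). The conventional minimum object size for a soma at this
#' magnification is 100-200 px; other values are allowed with a warning.
#'
#' @param image a [FieldImage-class].
#' @param thresholds a [QuantileThresholds-class] computed on the same image.
#' @param minSizePx minimum component area in pixels (default 150).
#' @return a [SomaDetections-class]; empty (zero rows) for an empty or
#'   degenerate-threshold image.
#' @seealso [somaShape()], [foregroundMask()]
#' @export
detectSomata <- function(image, thresholds, minSizePx = 150) {
  stopifnot(is(image, "FieldImage"), is(thresholds, "QuantileThresholds"))
  if (minSizePx < 100 || minSizePx > 200)
    warning(sprintf("minSizePx = %d is outside the conventional 100-200 px range",
                    as.integer(minSizePx)))
  ps <- image@pixelSize
  empty <- list(table = data.frame(label = integer(0), areaPx = integer(0),
                                   areaUm2 = numeric(0), x = numeric(0),
                                   y = numeric(0), eccentricity = numeric(0),
                                   onBorder = logical(0),
                                   degenerateShape = logical(0)),
                labels = matrix(0L, nrow(image@pixels), ncol(image@pixels)))
  if (thresholds@degenerate)
    return(new("SomaDetections", table = empty$table, labels = empty$labels,
               pixelSize = ps))
  mask <- image@pixels >= thresholds@tSoma
  lab <- labelComponents(mask, connectivity = 8L)
  nlab <- max(lab)
  if (nlab == 0L)
    return(new("SomaDetections", table = empty$table, labels = empty$labels,
               pixelSize = ps))
  nr <- nrow(lab); nc <- ncol(lab)
  w <- which(lab > 0L)
  r <- ((w - 1L) %% nr) + 1L
  c <- ((w - 1L) %/% nr) + 1L
  lv <- lab[w]
  keepLab <- which(tabulate(lv, nlab) >= minSizePx)
  if (!length(keepLab))
    return(new("SomaDetections", table = empty$table, labels = empty$labels,
               pixelSize = ps))
  out <- matrix(0L, nr, nc)
  rows <- vector("list", length(keepLab))
  for (i in seq_along(keepLab)) {
    k <- keepLab[i]
    sel <- lv == k
    rr <- r[sel]; cc <- c[sel]
    out[w[sel]] <- i
    ecc <- momentEccentricity(cbind(rr, cc))
    rows[[i]] <- data.frame(
      label = i, areaPx = length(rr), areaUm2 = length(rr) * ps^2,
      x = (mean(cc) - 0.5) * ps, y = (mean(rr) - 0.5) * ps,
      eccentricity = ecc$eccentricity,
      onBorder = any(rr == 1L | rr == nr | cc == 1L | cc == nc),
      degenerateShape = ecc$degenerate)
  }
  new("SomaDetections", table = do.call(rbind, rows), labels = out,
      pixelSize = ps)
}

#' Area and moment-ellipse eccentricity of a soma pixel region
#'
#' Eccentricity comes from the second-central-moment (covariance) ellipse of
#' the pixel coordinates: with eigenvalues \eqn{\lambda_1 \ge \lambda_2},
#' eccentricity is \eqn{\sqrt{1 - \lambda_2/\lambda_1}} - 0 for a perfect
#' disc, approaching 1 for a line-like region. A region with fewer than two
#' pixels has no defined ellipse; its eccentricity is reported as 0 and
#' flagged.
#'
#' @param pixels integer matrix (n x 2) of (row, col) pixel coordinates.
#' @param pixelSizeUm micrometres per pixel.
#' @return list with \code{areaUm2}, \code{eccentricity}, \code{degenerate}.
#' @examples
#' disc <- which(outer((-20:20)^2, (-20:20)^2, "+") <= 15^2, arr.ind = TRUE)
#' somaShape(disc, 0.5)$eccentricity   # ~0
#' @export
somaShape <- function(pixels, pixelSizeUm) {
  stopifnot(is.matrix(pixels), ncol(pixels) == 2L, nrow(pixels) >= 1L)
  ecc <- momentEccentricity(pixels)
  list(areaUm2 = nrow(pixels) * pixelSizeUm^2,
       eccentricity = ecc$eccentricity, degenerate = ecc$degenerate)
}

#' Foreground (soma plus process) mask of a field
#'
#' All pixels at or above the background threshold; by construction a
#' superset of the soma mask. Raising the background quantile never grows
#' the mask.
#'
#' @param image a [FieldImage-class].
#' @param thresholds a [QuantileThresholds-class] computed on the same image.
#' @return logical matrix.
#' @export
foregroundMask <- function(image, thresholds) {
  stopifnot(is(image, "FieldImage"), is(thresholds, "QuantileThresholds"))
  image@pixels >= thresholds@tBg
}

#' Sweep the soma quantile and report detection counts
#'
#' Convenience sweep replacing interactive threshold adjustment: for each
#' candidate soma quantile, the number of detections passing the size filter
#' is reported, so a plateau (stable count) can be picked as the operating
#' point.
#'
#' @param image a [FieldImage-class].
#' @param quantiles candidate soma quantile fractions.
#' @param backgroundQuantile background fraction used alongside each.
#' @param minSizePx minimum soma size in pixels.
#' @return data.frame with columns \code{somaQuantile}, \code{tSoma},
#'   \code{nDetected}.
#' @export
sweepSomaQuantiles <- function(image, quantiles = seq(0.990, 0.999, by = 0.001),
                               backgroundQuantile = 0.90, minSizePx = 150) {
  rows <- lapply(quantiles, function(q) {
    th <- computeThresholds(image, q, backgroundQuantile)
    n <- suppressWarnings(nSomata(detectSomata(image, th, minSizePx)))
    data.frame(somaQuantile = q, tSoma = th@tSoma, nDetected = n)
  })
  do.call(rbind, rows)
}
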