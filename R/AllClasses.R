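#' @include gliamorph-package.R
NULL

# ---- FieldImage --------------------------------------------------------------

#' FieldImage: a calibrated single-channel fluorescence field
#'
#' Container for one 2-D intensity grid standing for a single confocal field
#' of one channel (e.g. an IBA-1 or GFAP stain imaged at 20x), together with
#' the pixel-size calibration needed to express measurements in micrometres.
#'
#' @slot pixels numeric matrix of non-negative intensities; rows index y,
#'   columns index x. The centre of pixel \code{[r, c]} sits at
#'   \code{((c - 0.5) * pixelSize, (r - 0.5) * pixelSize)} micrometres.
#' @slot pixelSize micrometres per pixel side (> 0).
#' @slot channel free-text channel label, e.g. \code{"IBA1-like"}.
#'
#' @seealso [FieldImage()] for construction, [pixelSize()], [fieldPixels()]
#' @export
setClass("FieldImage",
  representation(pixels = "matrix", pixelSize = "numeric", channel = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0)
      msg <- c(msg, "pixelSize must be a single positive number")
    if (!is.numeric(object@pixels))
      msg <- c(msg, "pixels must be a numeric matrix")
    else if (any(!is.finite(object@pixels)) || any(object@pixels < 0))
      msg <- c(msg, "all intensities must be finite and >= 0")
    if (length(msg)) msg else TRUE
  })

#' Construct a FieldImage
#'
#' @param pixels numeric matrix of non-negative intensities (rows = y).
#' @param pixelSize micrometres per pixel side.
#' @param channel channel label.
#' @return A [FieldImage-class] object.
#' @examples
#' img <- FieldImage(matrix(0, 64, 64), pixelSize = 0.415)
#' pixelSize(img)
#' @export
FieldImage <- function(pixels, pixelSize, channel = "IBA1-like") {
  new("FieldImage", pixels = pixels, pixelSize = as.numeric(pixelSize),
      channel = as.character(channel))
}

# ---- QuantileThresholds ------------------------------------------------------

#' QuantileThresholds: soma and background intensity cut-offs
#'
#' Empirical intensity quantiles of a whole field used to separate bright
#' somata from dimmer processes and background. When the two thresholds
#' coincide (e.g. a constant image) the object is flagged degenerate and the
#' soma mask downstream is empty.
#'
#' @slot somaQuantile,backgroundQuantile requested quantile fractions in (0, 1).
#' @slot tSoma,tBg resulting intensity thresholds (tBg <= tSoma).
#' @slot degenerate TRUE when tSoma == tBg.
#' @seealso [computeThresholds()]
#' @export
setClass("QuantileThresholds",
  representation(somaQuantile = "numeric", backgroundQuantile = "numeric",
                 tSoma = "numeric", tBg = "numeric", degenerate = "logical"),
  validity = function(object) {
    msg <- character()
    q <- c(object@somaQuantile, object@backgroundQuantile)
    if (any(q <= 0) || any(q >= 1))
      msg <- c(msg, "quantile fractions must lie strictly between 0 and 1")
    if (object@backgroundQuantile >= object@somaQuantile)
      msg <- c(msg, "backgroundQuantile must be below somaQuantile")
    if (object@tBg > object@tSoma)
      msg <- c(msg, "tBg must not exceed tSoma")
    if (length(msg)) msg else TRUE
  })

# ---- SomaDetections ----------------------------------------------------------

#' SomaDetections: labelled somata of one field
#'
#' Result of minimum-size-filtered connected-component labelling of the soma
#' mask. Holds a per-soma table and the integer label image used downstream
#' to root process tracing.
#'
#' @slot table data.frame with one row per retained soma: \code{label},
#'   \code{areaPx}, \code{areaUm2}, \code{x}, \code{y} (centroid, um),
#'   \code{eccentricity}, \code{onBorder}, \code{degenerateShape}.
#' @slot labels integer matrix; 0 = not soma, k = soma \code{k}. Labels are
#'   assigned in raster-scan order of each component's first pixel.
#' @slot pixelSize micrometres per pixel.
#' @seealso [detectSomata()], [somaTable()], [somaLabels()]
#' @export
setClass("SomaDetections",
  representation(table = "data.frame", labels = "matrix", pixelSize = "numeric"))

# ---- ProcessSkeleton ---------------------------------------------------------

#' ProcessSkeleton: traced processes of one cell
#'
#' Rooted pixel graph of the skeletonized processes assigned to one soma.
#' Vertices are skeleton pixels outside the soma region; edges connect
#' 8-neighbours and carry geodesic step lengths in micrometres (orthogonal
#' steps \code{pixelSize}, diagonal steps \code{sqrt(2) * pixelSize};
#' diagonal shortcuts redundant with an orthogonal two-step are dropped).
#' Anchor vertices are those meeting the soma region; terminal spurs shorter
#' than the pruning length have been removed.
#'
#' @slot cellLabel integer soma label the skeleton belongs to.
#' @slot coords integer matrix (n x 2) of skeleton pixel (row, col).
#' @slot graph an \pkg{igraph} graph on the rows of \code{coords} with edge
#'   attribute \code{w_um}.
#' @slot anchor logical per vertex: meets the soma region boundary.
#' @slot root numeric (x, y) soma centroid in micrometres.
#' @slot pixelSize micrometres per pixel.
#' @slot pruneLenUm spur-pruning length applied, micrometres.
#' @slot ambiguous TRUE when the cell shared a foreground component with
#'   another soma and was split at the geodesic midline.
#' @seealso [traceProcesses()], [countPrimaryBranches()],
#'   [countBranchPoints()], [totalBranchLength()], [cellRadius()]
#' @export
setClass("ProcessSkeleton",
  representation(cellLabel = "integer", coords = "matrix", graph = "ANY",
                 anchor = "logical", root = "numeric", pixelSize = "numeric",
                 pruneLenUm = "numeric", ambiguous = "logical"))

# ---- CellSpec ----------------------------------------------------------------

#' CellSpec: generative description of one branched glial cell
#'
#' Analytic specification from which a synthetic cell is rasterized and its
#' ground-truth morphology derived in closed form. The soma is an ellipse
#' (semi-axes \code{a >= b}); processes are recursive bifurcating polyline
#' trees of straight segments growing outward from the soma boundary.
#'
#' @slot somaCenter numeric (x, y) in micrometres.
#' @slot somaAxes numeric (a, b) semi-axes in micrometres, \code{a >= b > 0}.
#' @slot somaAngle orientation of the major axis, radians.
#' @slot branches list of primary-branch trees; each tree is a nested list
#'   with fields \code{len} (um), \code{angle} (absolute direction, radians)
#'   and \code{children} (list of 0 or more sub-trees).
#' @slot processWidth stroke width of rasterized processes, micrometres.
#' @slot intensitySoma,intensityProcess,intensityBackground intensities in
#'   arbitrary units, strictly decreasing in that order.
#' @slot noiseSd additive Gaussian noise SD (>= 0), arbitrary units.
#' @slot psfSigma isotropic Gaussian point-spread SD, micrometres (>= 0).
#' @seealso [cellSpec()], [cellGroundTruth()], [renderCell()]
#' @export
setClass("CellSpec",
  representation(somaCenter = "numeric", somaAxes = "numeric",
                 somaAngle = "numeric", branches = "list",
                 processWidth = "numeric",
                 intensitySoma = "numeric", intensityProcess = "numeric",
                 intensityBackground = "numeric",
                 noiseSd = "numeric", psfSigma = "numeric"),
  validity = function(object) {
    msg <- character()
    ax <- object@somaAxes
    if (length(ax) != 2L || any(!is.finite(ax)) || ax[2] <= 0 || ax[1] < ax[2])
      msg <- c(msg, "somaAxes must satisfy a >= b > 0")
    if (object@processWidth <= 0)
      msg <- c(msg, "processWidth must be > 0")
    if (!(object@intensitySoma > object@intensityProcess &&
          object@intensityProcess > object@intensityBackground &&
          object@intensityBackground >= 0))
      msg <- c(msg, "need intensitySoma > intensityProcess > intensityBackground >= 0")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (object@psfSigma < 0) msg <- c(msg, "psfSigma must be >= 0")
    bad <- function(b) {
      if (!is.list(b) || is.null(b$len) || is.null(b$angle)) return(TRUE)
      if (!is.finite(b$len) || b$len <= 0) return(TRUE)
      kids <- b$children
      if (is.null(kids)) kids <- list()
      any(vapply(kids, bad, logical(1)))
    }
    if (length(object@branches) &&
        any(vapply(object@branches, bad, logical(1))))
      msg <- c(msg, "every branch segment needs a positive length and an angle")
    if (length(msg)) msg else TRUE
  })

# ---- show methods ------------------------------------------------------------

setMethod("show", "FieldImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("FieldImage: %d x %d px (%.1f x %.1f um), channel '%s'\n",
              d[1], d[2], d[1] * object@pixelSize, d[2] * object@pixelSize,
              object@channel))
  cat(sprintf("  pixelSize %.4g um/px, intensity range [%.4g, %.4g]\n",
              object@pixelSize, min(object@pixels), max(object@pixels)))
})

setMethod("show", "QuantileThresholds", function(object) {
  cat(sprintf("QuantileThresholds: T_soma = %.4g (q = %.4g), T_bg = %.4g (q = %.4g)%s\n",
              object@tSoma, object@somaQuantile, object@tBg,
              object@backgroundQuantile,
              if (object@degenerate) " [degenerate]" else ""))
})

setMethod("show", "SomaDetections", function(object) {
  cat(sprintf("SomaDetections: %d soma(ta) in a %d x %d px field\n",
              nrow(object@table), nrow(object@labels), ncol(object@labels)))
  if (nrow(object@table)) print(head(object@table, 6L))
})

setMethod("show", "ProcessSkeleton", function(object) {
  cat(sprintf(
    "ProcessSkeleton: cell %d, %d skeleton px, %d anchor px%s\n",
    object@cellLabel, nrow(object@coords), sum(object@anchor),
    if (object@ambiguous) " [split from shared component]" else ""))
})

setMethod("show", "CellSpec", function(object) {
  cat(sprintf(
    "CellSpec: soma (%.3g x %.3g um semi-axes) at (%.3g, %.3g), %d primary branch(es)\n",
    object@somaAxes[1], object@somaAxes[2], object@somaCenter[1],
    object@somaCenter[2], length(object@branches)))
})

# ---- accessors ---------------------------------------------------------------

#' @rdname FieldImage-class
#' @param object,x a \code{FieldImage}
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname FieldImage-class
#' @export
setMethod("pixelSize", "FieldImage", function(object) object@pixelSize)

#' @rdname SomaDetections-class
#' @export
setMethod("pixelSize", "SomaDetections", function(object) object@pixelSize)

#' @rdname ProcessSkeleton-class
#' @export
setMethod("pixelSize", "ProcessSkeleton", function(object) object@pixelSize)

#' @rdname FieldImage-class
#' @export
setGeneric("fieldPixels", function(object) standardGeneric("fieldPixels"))

#' @rdname FieldImage-class
#' @export
setMethod("fieldPixels", "FieldImage", function(object) object@pixels)

#' @rdname FieldImage-class
#' @export
setGeneric("channelLabel", function(object) standardGeneric("channelLabel"))

#' @rdname FieldImage-class
#' @export
setMethod("channelLabel", "FieldImage", function(object) object@channel)

#' @rdname FieldImage-class
#' @export
setMethod("dim", "FieldImage", function(x) dim(x@pixels))

#' Per-soma table of a SomaDetections object
#' @param object a [SomaDetections-class]
#' @return data.frame with one row per retained soma.
#' @export
setGeneric("somaTable", function(object) standardGeneric("somaTable"))

#' @rdname somaTable
#' @export
setMethod("somaTable", "SomaDetections", function(object) object@table)

#' Integer label image of a SomaDetections object
#' @param object a [SomaDetections-class]
#' @return integer matrix, 0 outside somata.
#' @export
setGeneric("somaLabels", function(object) standardGeneric("somaLabels"))

#' @rdname somaLabels
#' @export
setMethod("somaLabels", "SomaDetections", function(object) object@labels)

#' Number of detected somata
#' @param object a [SomaDetections-class]
#' @export
setGeneric("nSomata", function(object) standardGeneric("nSomata"))

#' @rdname nSomata
#' @export
setMethod("nSomata", "SomaDetections", function(object) nrow(object@table))

#' Skeleton graph of a ProcessSkeleton
#' @param object a [ProcessSkeleton-class]
#' @return the underlying \pkg{igraph} graph (edge attribute \code{w_um}).
#' @export
setGeneric("skeletonGraph", function(object) standardGeneric("skeletonGraph"))

#' @rdname skeletonGraph
#' @export
setMethod("skeletonGraph", "ProcessSkeleton", function(object) object@graph)
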