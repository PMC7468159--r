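# Synthetic fluorescence fields of branched glial cells with closed-form
# ground truth. Cells are ellipse somata plus recursive bifurcating polyline
# trees; every morphological parameter reported by the measurement pipeline
# can be derived exactly from the generating specification, so recovery can
# be tested without any reference images.

#' Build one branch-tree segment
#'
#' A branch tree is a nested list of straight segments. Each node carries the
#' segment length (micrometres), its absolute direction (radians, measured in
#' the image plane), and a list of child sub-trees starting where the segment
#' ends. A node with two or more children is a bifurcation vertex and counts
#' as one branch point in the ground truth.
#'
#' @param len segment length in micrometres (> 0).
#' @param angle absolute direction in radians.
#' @param children list of child segments (default none).
#' @return a list usable inside the \code{branches} slot of a [cellSpec()].
#' @examples
#' y <- branchSegment(20, 0, list(branchSegment(10, 0.5), branchSegment(10, -0.5)))
#' @export
branchSegment <- function(len, angle, children = list()) {
  stopifnot(is.numeric(len), len > 0, is.numeric(angle))
  list(len = len, angle = angle, children = children)
}

#' Construct a CellSpec
#'
#' @param somaCenter numeric (x, y) in micrometres.
#' @param somaAxes numeric (a, b) soma semi-axes in micrometres, a >= b > 0.
#' @param somaAngle major-axis orientation, radians.
#' @param branches list of primary-branch trees built with [branchSegment()].
#'   Primary branches emanate from the soma boundary along their root angle.
#' @param processWidth process stroke width, micrometres.
#' @param intensitySoma,intensityProcess,intensityBackground intensities in
#'   arbitrary units, strictly decreasing in that order.
#' @param noiseSd additive Gaussian noise SD (clipped at zero after adding).
#' @param psfSigma isotropic Gaussian point-spread SD, micrometres.
#' @return a [CellSpec-class] object.
#' @examples
#' sp <- cellSpec(c(30, 30), c(4, 4), branches = list(branchSegment(15, 0)))
#' cellGroundTruth(sp)
#' @export
cellSpec <- function(somaCenter, somaAxes, somaAngle = 0, branches = list(),
                     processWidth = 1.2, intensitySoma = 4000,
                     intensityProcess = 1500, intensityBackground = 400,
                     noiseSd = 0, psfSigma = 0) {
  new("CellSpec", somaCenter = as.numeric(somaCenter),
      somaAxes = as.numeric(somaAxes), somaAngle = as.numeric(somaAngle),
      branches = branches, processWidth = as.numeric(processWidth),
      intensitySoma = as.numeric(intensitySoma),
      intensityProcess = as.numeric(intensityProcess),
      intensityBackground = as.numeric(intensityBackground),
      noiseSd = as.numeric(noiseSd), psfSigma = as.numeric(psfSigma))
}

# Radius of a rotated ellipse along direction phi from its centre.
ellipseRadius <- function(axes, theta, phi) {
  psi <- phi - theta
  axes[1] * axes[2] /
    sqrt((axes[2] * cos(psi))^2 + (axes[1] * sin(psi))^2)
}

# Flatten a CellSpec's branch trees into a segment table with absolute
# endpoint coordinates (um) and bifurcation bookkeeping.
collectSegments <- function(spec) {
  segs <- list()
  walk <- function(node, start, primary) {
    end <- start + node$len * c(cos(node$angle), sin(node$angle))
    kids <- node$children
    if (is.null(kids)) kids <- list()
    segs[[length(segs) + 1L]] <<- list(
      x0 = start[1], y0 = start[2], x1 = end[1], y1 = end[2],
      len = node$len, primary = primary,
      bifurcates = length(kids) >= 2L)
    for (k in kids) walk(k, end, primary)
  }
  for (i in seq_along(spec@branches)) {
    b <- spec@branches[[i]]
    r0 <- ellipseRadius(spec@somaAxes, spec@somaAngle, b$angle)
    start <- spec@somaCenter + r0 * c(cos(b$angle), sin(b$angle))
    walk(b, start, i)
  }
  if (!length(segs)) return(NULL)
  do.call(rbind, lapply(segs, as.data.frame))
}

#' Closed-form ground truth of a CellSpec
#'
#' Derives the morphological parameters analytically from the generating
#' specification, never from any raster: soma area \eqn{\pi a b}, soma
#' eccentricity \eqn{\sqrt{1 - (b/a)^2}}, total branch length as the sum of
#' segment lengths, branch points as the number of bifurcation vertices,
#' primary branches as the number of root segments, and cell radius as the
#' largest distance from the soma centre to any branch vertex (at least the
#' semi-major axis). Cell area is approximated as soma area plus total
#' branch length times process width; unlike the other parameters it is not
#' an exact value for the rasterized union and is flagged as approximate in
#' the column name used by downstream reports.
#'
#' @param spec a [CellSpec-class].
#' @return one-row data.frame with columns \code{nPrimary},
#'   \code{nBranchPoints}, \code{totalLengthUm}, \code{cellRadiusUm},
#'   \code{cellAreaUm2}, \code{somaAreaUm2}, \code{somaEccentricity}.
#' @examples
#' sp <- cellSpec(c(30, 30), c(4, 2))
#' cellGroundTruth(sp)$somaEccentricity  # sqrt(1 - (2/4)^2)
#' @export
cellGroundTruth <- function(spec) {
  stopifnot(is(spec, "CellSpec"))
  a <- spec@somaAxes[1]; b <- spec@somaAxes[2]
  segs <- collectSegments(spec)
  if (is.null(segs)) {
    totalLen <- 0; nBif <- 0L; radius <- a
  } else {
    totalLen <- sum(segs$len)
    nBif <- sum(segs$bifurcates)
    vert <- rbind(as.matrix(segs[, c("x0", "y0")]),
                  as.matrix(segs[, c("x1", "y1")]))
    radius <- max(a, sqrt(rowSums(sweep(vert, 2, spec@somaCenter)^2)))
  }
  data.frame(
    nPrimary = length(spec@branches),
    nBranchPoints = as.integer(nBif),
    totalLengthUm = totalLen,
    cellRadiusUm = radius,
    cellAreaUm2 = pi * a * b + totalLen * spec@processWidth,
    somaAreaUm2 = pi * a * b,
    somaEccentricity = sqrt(1 - (b / a)^2))
}

# Rasterize a CellSpec onto a canvas of dims (nr, nc) at the given pixel
# size. Returns linear pixel indices of the soma ellipse and of the process
# strokes (pixel-centre-in-shape convention).
rasterizeCell <- function(spec, pixelSizeUm, dims) {
  nr <- dims[1]; nc <- dims[2]
  ps <- pixelSizeUm
  a <- spec@somaAxes[1]; b <- spec@somaAxes[2]
  th <- spec@somaAngle
  cx <- spec@somaCenter[1]; cy <- spec@somaCenter[2]

  inBox <- function(xmin, xmax, ymin, ymax) {
    cmin <- max(1L, floor(xmin / ps + 0.5)); cmax <- min(nc, ceiling(xmax / ps + 0.5))
    rmin <- max(1L, floor(ymin / ps + 0.5)); rmax <- min(nr, ceiling(ymax / ps + 0.5))
    if (cmin > cmax || rmin > rmax) return(NULL)
    list(r = rmin:rmax, c = cmin:cmax)
  }

  # soma ellipse
  box <- inBox(cx - a, cx + a, cy - a, cy + a)
  somaIdx <- integer()
  if (!is.null(box)) {
    g <- expand.grid(r = box$r, c = box$c)
    px <- (g$c - 0.5) * ps - cx
    py <- (g$r - 0.5) * ps - cy
    u <- px * cos(th) + py * sin(th)
    v <- -px * sin(th) + py * cos(th)
    sel <- (u / a)^2 + (v / b)^2 <= 1
    somaIdx <- (g$c[sel] - 1L) * nr + g$r[sel]
  }

  # process strokes
  segs <- collectSegments(spec)
  procIdx <- integer()
  if (!is.null(segs)) {
    hw <- spec@processWidth / 2
    for (i in seq_len(nrow(segs))) {
      s <- segs[i, ]
      box <- inBox(min(s$x0, s$x1) - hw, max(s$x0, s$x1) + hw,
                   min(s$y0, s$y1) - hw, max(s$y0, s$y1) + hw)
      if (is.null(box)) next
      g <- expand.grid(r = box$r, c = box$c)
      px <- (g$c - 0.5) * ps
      py <- (g$r - 0.5) * ps
      dx <- s$x1 - s$x0; dy <- s$y1 - s$y0
      L2 <- dx * dx + dy * dy
      t <- pmin(1, pmax(0, ((px - s$x0) * dx + (py - s$y0) * dy) / L2))
      d2 <- (px - (s$x0 + t * dx))^2 + (py - (s$y0 + t * dy))^2
      sel <- d2 <= hw * hw
      procIdx <- c(procIdx, (g$c[sel] - 1L) * nr + g$r[sel])
    }
    procIdx <- unique(procIdx)
  }
  list(soma = somaIdx, process = procIdx)
}

# Footprint radius used for bounds and collision checks: farthest cell
# extent from the soma centre including stroke width.
cellReach <- function(spec, truth = cellGroundTruth(spec)) {
  truth$cellRadiusUm + spec@processWidth
}

composeField <- function(specs, nr, nc, pixelSizeUm, seed, channel) {
  bg <- specs[[1]]@intensityBackground
  noiseSd <- specs[[1]]@noiseSd
  psf <- specs[[1]]@psfSigma
  m <- matrix(bg, nr, nc)
  for (spec in specs) {
    ras <- rasterizeCell(spec, pixelSizeUm, c(nr, nc))
    m[ras$process] <- spec@intensityProcess
    m[ras$soma] <- spec@intensitySoma
  }
  if (psf > 0)
    m <- EBImage::imageData(EBImage::gblur(m, sigma = psf / pixelSizeUm))
  if (noiseSd > 0) {
    addNoise <- function() {
      m + matrix(rnorm(nr * nc, 0, noiseSd), nr, nc)
    }
    m <- if (is.null(seed)) addNoise() else withr::with_seed(seed, addNoise())
  }
  m[m < 0] <- 0
  FieldImage(m, pixelSizeUm, channel)
}

#' Render one synthetic cell to an image patch
#'
#' Rasterizes the ellipse soma and anti-aliased process strokes of a single
#' [CellSpec-class] on a square patch, applies the Gaussian point spread and
#' additive Gaussian noise (clipped at zero), and returns the patch together
#' with the analytic ground truth. The truth is computed from the spec, never
#' from the raster, so it is unaffected by noise or blur.
#'
#' @param spec a [CellSpec-class]; \code{somaCenter} is interpreted in patch
#'   coordinates (micrometres from the patch origin).
#' @param pixelSizeUm micrometres per pixel.
#' @param patchSideUm side of the square patch in micrometres; by default the
#'   smallest side that contains the cell. A cell extending beyond the patch
#'   bounds is rejected with an error, never clipped silently.
#' @param seed optional integer seed controlling the noise draw only.
#' @param channel channel label for the patch.
#' @return list with elements \code{image} ([FieldImage-class]) and
#'   \code{truth} (one-row data.frame, see [cellGroundTruth()]).
#' @examples
#' sp <- cellSpec(c(25, 25), c(4, 4), branches = list(branchSegment(12, 1)))
#' out <- renderCell(sp, pixelSizeUm = 0.5)
#' out$truth$nPrimary
#' @export
renderCell <- function(spec, pixelSizeUm, patchSideUm = NULL, seed = NULL,
                       channel = "IBA1-like") {
  stopifnot(is(spec, "CellSpec"))
  truth <- cellGroundTruth(spec)
  reach <- cellReach(spec, truth)
  if (is.null(patchSideUm))
    patchSideUm <- max(spec@somaCenter) + reach + 2 * pixelSizeUm
  lo <- spec@somaCenter - reach
  hi <- spec@somaCenter + reach
  if (any(lo < 0) || any(hi > patchSideUm))
    stop(sprintf(
      "cell extends beyond patch bounds: needs [%.1f, %.1f] x [%.1f, %.1f] um within a %.1f um patch",
      lo[1], hi[1], lo[2], hi[2], patchSideUm))
  n <- as.integer(round(patchSideUm / pixelSizeUm))
  img <- composeField(list(spec), n, n, pixelSizeUm, seed, channel)
  list(image = img, truth = truth)
}

#' Render a synthetic field of several cells with ground truth
#'
#' Composes all cells on one square field, applies the shared point spread
#' and noise model, and returns the image plus per-cell and per-field ground
#' truth. All specs must agree on background intensity, noise SD and PSF
#' (they describe one acquisition). Unless \code{allowOverlap} is set, cells
#' whose footprints (cell radius plus stroke width) intersect are rejected
#' with an error naming the colliding pair, and cells must lie fully inside
#' the field.
#'
#' @param specs list of [CellSpec-class] objects.
#' @param fieldSideUm field side, micrometres (default 424.26, i.e. a field
#'   area of 0.18 mm^2).
#' @param pixelSizeUm micrometres per pixel (default 0.415, giving a 1022 px
#'   field side).
#' @param seed optional integer seed for the noise draw; with a fixed seed
#'   the raster is bit-identical across calls.
#' @param allowOverlap permit intersecting cell footprints.
#' @param channel channel label.
#' @return list with \code{image} ([FieldImage-class]), \code{cells}
#'   (per-cell truth with soma centres), and \code{field} (one-row
#'   data.frame: \code{nCells}, \code{fieldAreaMm2}, \code{density} in
#'   cells/mm^2).
#' @examples
#' sp <- list(cellSpec(c(40, 40), c(4, 4)), cellSpec(c(120, 120), c(4, 3)))
#' fld <- renderField(sp, fieldSideUm = 160, pixelSizeUm = 0.5)
#' fld$field$density
#' @export
renderField <- function(specs, fieldSideUm = 424.26, pixelSizeUm = 0.415,
                        seed = NULL, allowOverlap = FALSE,
                        channel = "IBA1-like") {
  stopifnot(length(specs) == 0 || all(vapply(specs, is, logical(1), "CellSpec")))
  n <- as.integer(round(fieldSideUm / pixelSizeUm))
  areaMm2 <- (fieldSideUm / 1000)^2
  if (!length(specs)) {
    img <- FieldImage(matrix(0, n, n), pixelSizeUm, channel)
    return(list(image = img,
                cells = cbind(cell = integer(0), x = numeric(0), y = numeric(0)),
                field = data.frame(nCells = 0L, fieldAreaMm2 = areaMm2,
                                   density = 0)))
  }
  if (length(specs) > 1L) {
    shared <- vapply(specs, function(s)
      c(s@intensityBackground, s@noiseSd, s@psfSigma), numeric(3))
    if (any(apply(shared, 1, function(v) diff(range(v)) > 0)))
      stop("all cells of one field must share background intensity, noise SD and PSF")
  }
  truths <- do.call(rbind, lapply(specs, cellGroundTruth))
  centers <- t(vapply(specs, function(s) s@somaCenter, numeric(2)))
  reach <- mapply(cellReach, specs, split(truths, seq_len(nrow(truths))))
  out <- centers[, 1] - reach < 0 | centers[, 2] - reach < 0 |
         centers[, 1] + reach > fieldSideUm | centers[, 2] + reach > fieldSideUm
  if (any(out))
    stop(sprintf("cell %d extends beyond the field bounds", which(out)[1]))
  if (!allowOverlap && length(specs) > 1L) {
    dd <- as.matrix(stats::dist(centers))
    lim <- outer(reach, reach, "+")
    diag(dd) <- Inf
    hit <- which(dd < lim, arr.ind = TRUE)
    if (nrow(hit))
      stop(sprintf("cells %d and %d overlap (centres %.1f um apart, footprints need %.1f um)",
                   min(hit[1, ]), max(hit[1, ]),
                   dd[hit[1, 1], hit[1, 2]], lim[hit[1, 1], hit[1, 2]]))
  }
  img <- composeField(specs, n, n, pixelSizeUm, seed, channel)
  cells <- cbind(data.frame(cell = seq_along(specs),
                            x = centers[, 1], y = centers[, 2]), truths)
  list(image = img, cells = cells,
       field = data.frame(nCells = length(specs), fieldAreaMm2 = areaMm2,
                          density = length(specs) / areaMm2))
}

#' Morphological regime for the random cell generator
#'
#' Bundles the target morphology of a cell population: the regimes observed
#' for hippocampal microglia (soma ~48-57 um^2, 4 primary branches, ~5 branch
#' points, total branch length ~150-170 um, ~4-7 cells per 0.18 mm^2 field)
#' and astrocytes (5-6 primaries, ~6 branch points, ~170-200 um, ~10-17
#' cells per field) are provided as presets. Individual cells drawn from a
#' regime jitter around these targets; the recorded ground truth always
#' reflects the realized cell, not the target.
#'
#' @param type preset, \code{"microglia"} or \code{"astrocyte"}.
#' @param ... overrides for any regime field: \code{nPrimary},
#'   \code{nBranchPoints}, \code{totalLengthUm}, \code{somaAreaUm2},
#'   \code{eccentricity}, \code{processWidthUm}, \code{cellsPerField},
#'   \code{cellCV} (lognormal CV of per-cell sizes), \code{jitterCounts}
#'   (vary integer counts by +/-1), \code{intensityBackground},
#'   \code{intensityProcess}, \code{intensitySoma}, \code{noiseSd},
#'   \code{psfSigmaUm}.
#' @return named list of regime parameters.
#' @examples
#' morphRegime("astrocyte", totalLengthUm = 97)
#' @export
morphRegime <- function(type = c("astrocyte", "microglia"), ...) {
  type <- match.arg(type)
  base <- list(
    nPrimary = 5L, nBranchPoints = 5L, totalLengthUm = 167,
    somaAreaUm2 = 50, eccentricity = 0.83, processWidthUm = 1.2,
    cellsPerField = 12, cellCV = 0.10, jitterCounts = TRUE,
    intensityBackground = 400, intensityProcess = 1500,
    intensitySoma = 4000, noiseSd = 0, psfSigmaUm = 0)
  if (type == "microglia") {
    base$nPrimary <- 4L; base$nBranchPoints <- 5L
    base$totalLengthUm <- 153; base$somaAreaUm2 <- 48.3
    base$eccentricity <- 0.79; base$cellsPerField <- 4
  }
  over <- list(...)
  stopifnot(all(names(over) %in% names(base)))
  base[names(over)] <- over
  base
}

# Scale a regime by named multiplicative factors (used to derive the mutant
# group from the wild-type regime).
scaleRegime <- function(regime, factors = list()) {
  map <- c(totalLength = "totalLengthUm", somaArea = "somaAreaUm2",
           eccentricity = "eccentricity", nPrimary = "nPrimary",
           nBranchPoints = "nBranchPoints", density = "cellsPerField")
  stopifnot(all(names(factors) %in% names(map)))
  for (nm in names(factors)) {
    fld <- map[[nm]]
    regime[[fld]] <- regime[[fld]] * factors[[nm]]
    if (fld %in% c("nPrimary", "nBranchPoints"))
      regime[[fld]] <- max(0L, as.integer(round(regime[[fld]])))
  }
  regime$eccentricity <- min(0.95, regime$eccentricity)
  regime
}

#' Draw a random CellSpec from a regime
#'
#' Samples one cell around the regime targets: soma area and segment lengths
#' jitter lognormally with CV \code{cellCV}; integer counts optionally move
#' by one; primary branches take near-evenly spaced directions with bounded
#' jitter and children diverge from their parent by 0.30-0.50 rad, which
#' keeps sibling sub-trees angularly separated so that rasterized branches
#' of one cell never cross each other (a requirement for exact branch-point
#' recovery). Segment lengths are floored at 5 um so junctions stay resolvable
#' at typical pixel sizes. Uses the current R random number state.
#'
#' @param center numeric (x, y) soma centre, micrometres.
#' @param regime a [morphRegime()] list.
#' @param maxRadiusUm optional hard cap on the cell radius; segment lengths
#'   are shrunk proportionally if the drawn cell would exceed it.
#' @return a [CellSpec-class].
#' @export
randomCellSpec <- function(center, regime = morphRegime(), maxRadiusUm = Inf) {
  area <- regime$somaAreaUm2 * rlnorm(1, 0, regime$cellCV)
  ecc <- min(0.95, max(0.3, regime$eccentricity + rnorm(1, 0, 0.015)))
  ratio <- sqrt(1 - ecc^2)                    # b / a
  a <- sqrt(area / (pi * ratio))
  b <- area / (pi * a)
  nP <- regime$nPrimary
  nJ <- regime$nBranchPoints
  if (isTRUE(regime$jitterCounts)) {
    nP <- max(3L, nP + sample(c(-1L, 0L, 1L), 1, prob = c(0.25, 0.5, 0.25)))
    nJ <- max(0L, nJ + sample(c(-1L, 0L, 1L), 1, prob = c(0.25, 0.5, 0.25)))
  }
  nP <- as.integer(nP)
  nJ <- min(as.integer(nJ), 3L * nP)
  nSeg <- nP + 2L * nJ
  baseLen <- regime$totalLengthUm / nSeg
  segLen <- function() max(5, baseLen * rlnorm(1, 0, regime$cellCV))

  # distribute bifurcations breadth-first: primaries first, then children
  level1 <- min(nJ, nP)
  bifPrim <- sample(nP, level1)
  level2 <- nJ - level1
  slots <- if (level1) cbind(rep(bifPrim, each = 2L), rep(1:2, level1)) else
    matrix(integer(0), 0, 2)
  bifChild <- if (level2 > 0 && nrow(slots))
    slots[sample(nrow(slots), min(level2, nrow(slots))), , drop = FALSE] else
    matrix(integer(0), 0, 2)

  spacing <- 2 * pi / nP
  baseAng <- runif(1, 0, 2 * pi) + spacing * (seq_len(nP) - 1L) +
    runif(nP, -0.15, 0.15) * spacing
  branches <- vector("list", nP)
  for (i in seq_len(nP)) {
    kids <- list()
    if (i %in% bifPrim) {
      s1 <- runif(1, 0.35, 0.50)
      for (side in 1:2) {
        ang2 <- baseAng[i] + c(-1, 1)[side] * s1
        gkids <- list()
        if (nrow(bifChild) && any(bifChild[, 1] == i & bifChild[, 2] == side)) {
          s2 <- runif(1, 0.25, 0.35)
          gkids <- list(branchSegment(segLen(), ang2 - s2),
                        branchSegment(segLen(), ang2 + s2))
        }
        kids[[side]] <- branchSegment(segLen(), ang2, gkids)
      }
    }
    branches[[i]] <- branchSegment(segLen(), baseAng[i], kids)
  }
  spec <- cellSpec(center, c(a, b), somaAngle = runif(1, 0, pi),
                   branches = branches,
                   processWidth = regime$processWidthUm,
                   intensitySoma = regime$intensitySoma,
                   intensityProcess = regime$intensityProcess,
                   intensityBackground = regime$intensityBackground,
                   noiseSd = regime$noiseSd, psfSigma = regime$psfSigmaUm)
  if (is.finite(maxRadiusUm)) {
    for (k in 1:3) {
      tr <- cellGroundTruth(spec)
      if (tr$cellRadiusUm + spec@processWidth <= maxRadiusUm) break
      f <- (maxRadiusUm - a - spec@processWidth) / (tr$cellRadiusUm - a)
      shrink <- function(nd) {
        nd$len <- max(5, nd$len * f * 0.95)
        nd$children <- lapply(nd$children, shrink)
        nd
      }
      spec@branches <- lapply(spec@branches, shrink)
    }
  }
  spec
}

#' Place random cells on a jittered grid inside a field
#'
#' Draws \code{n} cells from a regime and positions them on a jittered
#' square grid sized so that cell footprints (radius plus stroke width)
#' cannot intersect; cell radii are capped at 38 percent of the grid
#' spacing. Uses the current R random number state.
#'
#' @param n number of cells.
#' @param regime a [morphRegime()] list.
#' @param fieldSideUm field side, micrometres.
#' @return list of [CellSpec-class] ready for [renderField()].
#' @export
placeCells <- function(n, regime, fieldSideUm) {
  k <- max(2L, ceiling(sqrt(n)))
  s <- fieldSideUm / k
  maxR <- 0.38 * s
  sites <- expand.grid(i = seq_len(k), j = seq_len(k))
  pick <- sample(nrow(sites), n)
  lapply(pick, function(ix) {
    ctr <- c((sites$i[ix] - 0.5) * s, (sites$j[ix] - 0.5) * s) +
      runif(2, -0.05, 0.05) * s
    randomCellSpec(ctr, regime, maxRadiusUm = maxR)
  })
}

#' Simulate a two-genotype morphometry study with ground truth
#'
#' Generates per-animal synthetic fields for a wild-type and a mutant group.
#' The mutant regime is the wild-type regime scaled by the given factors
#' (e.g. a total-branch-length factor of 0.58 emulates the astrocyte process
#' retraction regime; a density factor of 1.71 the increased microglial
#' density regime). The animal is the sampling unit: each animal carries a
#' lognormal random effect of CV \code{animalCV} on cell sizes, and fields
#' within an animal share it. Cell counts per field are Poisson around the
#' regime density. Ground truth is returned for every cell; images are
#' rendered only when requested, since most statistical checks need only the
#' truth tables.
#'
#' @param wtRegime wild-type [morphRegime()].
#' @param factors named list of mutant/WT multiplicative factors (see
#'   [morphRegime()] fields; names \code{totalLength}, \code{somaArea},
#'   \code{eccentricity}, \code{nPrimary}, \code{nBranchPoints},
#'   \code{density}).
#' @param nAnimals animals per group (>= 2).
#' @param fieldsPerAnimal fields imaged per animal (>= 1).
#' @param fieldSideUm,pixelSizeUm field geometry.
#' @param animalCV between-animal lognormal CV on size parameters.
#' @param seed integer seed; the whole dataset is deterministic given it.
#' @param render also rasterize the fields (list of [FieldImage-class]).
#' @param mutRegime explicit mutant regime overriding the scaled one.
#' @param poissonCounts draw per-field cell counts as Poisson around the
#'   regime density (default); \code{FALSE} plants exactly
#'   \code{round(cellsPerField)} cells per field.
#' @return list with \code{truth} (per-cell data.frame with genotype, animal,
#'   field and all ground-truth columns), \code{fields} (per-field table with
#'   \code{nCells} and \code{density}), and \code{images} (named list, only
#'   when \code{render = TRUE}).
#' @examples
#' ds <- makeGroupDataset(morphRegime("microglia"), nAnimals = 2, seed = 1)
#' table(ds$truth$genotype)
#' @export
makeGroupDataset <- function(wtRegime = morphRegime(),
                             factors = list(),
                             nAnimals = 5, fieldsPerAnimal = 1,
                             fieldSideUm = 424.26, pixelSizeUm = 0.415,
                             animalCV = 0.12, seed = 1, render = FALSE,
                             mutRegime = NULL, poissonCounts = TRUE) {
  if (nAnimals < 2) stop("need at least 2 animals per group")
  if (fieldsPerAnimal < 1) stop("need at least 1 field per animal")
  if (is.null(mutRegime)) mutRegime <- scaleRegime(wtRegime, factors)
  regimes <- list(WT = wtRegime, NL3 = mutRegime)
  withr::with_seed(seed, {
    truth <- list(); fieldInfo <- list(); images <- list()
    for (g in names(regimes)) {
      reg <- regimes[[g]]
      for (an in seq_len(nAnimals)) {
        eff <- rlnorm(1, 0, animalCV)
        regA <- reg
        regA$totalLengthUm <- reg$totalLengthUm * eff
        regA$somaAreaUm2 <- reg$somaAreaUm2 * eff
        for (fd in seq_len(fieldsPerAnimal)) {
          nSitesMax <- max(2L, ceiling(sqrt(reg$cellsPerField)))^2
          nCells <- if (poissonCounts) rpois(1, reg$cellsPerField) else
            round(reg$cellsPerField)
          nCells <- min(nSitesMax, max(1L, nCells))
          specs <- placeCells(nCells, regA, fieldSideUm)
          fl <- renderField(specs, fieldSideUm, pixelSizeUm,
                            seed = NULL, allowOverlap = FALSE)
          key <- sprintf("%s_a%02d_f%02d", g, an, fd)
          truth[[key]] <- cbind(genotype = g, animal = sprintf("%s%02d", g, an),
                                field = fd, fl$cells)
          fieldInfo[[key]] <- cbind(genotype = g,
                                    animal = sprintf("%s%02d", g, an),
                                    field = fd, fl$field)
          if (render) images[[key]] <- fl$image
        }
      }
    }
    list(truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
         fields = do.call(rbind, c(fieldInfo, list(make.row.names = FALSE))),
         images = if (render) images else NULL)
  })
}

#' Per-animal means of a per-cell table
#'
#' Aggregates cell-level values to one mean per animal and parameter, the
#' sampling unit used by the group comparisons.
#'
#' @param cells data.frame with columns \code{genotype}, \code{animal} and
#'   numeric parameter columns.
#' @param params parameter column names (default: all numeric except ids).
#' @return long data.frame with columns \code{genotype}, \code{animal},
#'   \code{parameter}, \code{value}.
#' @export
animalMeans <- function(cells, params = NULL) {
  drop <- c("cell", "field", "x", "y", "label")
  if (is.null(params))
    params <- setdiff(names(cells)[vapply(cells, is.numeric, logical(1))], drop)
  out <- lapply(params, function(p) {
    ag <- stats::aggregate(cells[[p]],
                           by = list(genotype = cells$genotype,
                                     animal = cells$animal), FUN = mean)
    data.frame(genotype = ag$genotype, animal = ag$animal,
               parameter = p, value = ag$x)
  })
  do.call(rbind, out)
}
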