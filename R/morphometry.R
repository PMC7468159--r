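# Outward process tracing and per-cell morphometry. The foreground mask is
# topologically skeletonized; skeleton pixels are attributed to the soma they
# reach through the mask (geodesic connectivity), rooted where they meet the
# soma region, spur-pruned, and quantified.

#' Trace processes outward from detected somata
#'
#' Skeletonizes the foreground mask (Guo-Hall thinning), assigns every
#' foreground pixel to the soma it connects to through the mask using
#' geodesic propagation, and builds one rooted skeleton graph per soma from
#' the skeleton pixels outside the (slightly dilated) soma region. Terminal
#' spurs shorter than \code{pruneLenUm} - including whole process stubs, a
#' guard against noise specks touching the soma - are removed. A skeleton
#' component connecting two somata is split at the geodesic midline between
#' them and both cells are flagged ambiguous.
#'
#' @param mask logical foreground matrix from [foregroundMask()].
#' @param somata a [SomaDetections-class] for the same field; somata must lie
#'   inside the mask.
#' @param pruneLenUm terminal spurs shorter than this are removed (default
#'   2 um, suppressing skeletonization artifacts).
#' @param somaMarginUm the soma region is dilated by this margin before the
#'   "outside the soma" boundary is drawn (default 0.5 um); this keeps the
#'   radial spokes that thinning drives across the soma boundary from being
#'   mistaken for junctions.
#' @return list of [ProcessSkeleton-class], one per soma, in label order,
#'   with the pixel-to-cell assignment matrix attached as attribute
#'   \code{"assignment"}.
#' @export
traceProcesses <- function(mask, somata, pruneLenUm = 2, somaMarginUm = 0.5) {
  stopifnot(is.matrix(mask), is(somata, "SomaDetections"))
  ps <- somata@pixelSize
  labs <- somata@labels
  tab <- somata@table
  nr <- nrow(mask); nc <- ncol(mask)
  if (any(dim(labs) != dim(mask)))
    stop("mask and soma labels have different dimensions")
  if (nrow(tab) == 0L) {
    out <- list()
    attr(out, "assignment") <- matrix(0L, nr, nc)
    return(out)
  }
  if (any(!mask[labs > 0L]))
    stop("somata must lie inside the foreground mask")

  # regularize the mask before thinning: a one-pixel-radius closing smooths
  # ragged noise boundaries, then enclosed background holes (single-pixel
  # noise dropouts) are filled so the skeleton neither sprouts spurious
  # side-branches nor loops around holes, both of which would inflate the
  # junction count
  mask <- EBImage::imageData(
    EBImage::closing(mask * 1L, EBImage::makeBrush(3L, "disc"))) > 0
  mask <- EBImage::imageData(EBImage::fillHull(mask * 1L)) > 0
  sk <- thinMask(mask)
  assign <- EBImage::imageData(EBImage::propagate(matrix(0, nr, nc),
                                                  seeds = labs, mask = mask))
  storage.mode(assign) <- "integer"

  # soma zone: soma regions dilated by the margin, attributed to their soma
  marginPx <- somaMarginUm / ps
  zone <- dilateByDisc(labs > 0L, marginPx)
  zoneLab <- EBImage::imageData(EBImage::propagate(matrix(0, nr, nc),
                                                   seeds = labs, mask = zone))
  storage.mode(zoneLab) <- "integer"

  # ambiguity: somata sharing one foreground component
  comp <- labelComponents(mask, 8L)
  somaComp <- vapply(seq_len(nrow(tab)), function(L) {
    comp[which(labs == L)[1]]
  }, integer(1))
  shared <- somaComp %in% somaComp[duplicated(somaComp)]

  outMask <- sk & !zone
  skels <- vector("list", nrow(tab))
  for (L in seq_len(nrow(tab))) {
    cellMask <- outMask & assign == L
    se <- skeletonEdges(cellMask)
    coords <- se$coords
    g <- igraph::make_empty_graph(n = nrow(coords), directed = FALSE)
    if (!is.null(se$edges)) {
      g <- igraph::add_edges(g, t(se$edges[, 1:2, drop = FALSE]))
      igraph::E(g)$w_um <- se$edges[, 3] * ps
    } else if (nrow(coords)) {
      # no edges at all; w_um attribute still needs to exist
      igraph::E(g)$w_um <- numeric(0)
    }
    anchor <- logical(nrow(coords))
    if (nrow(coords)) {
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        rr <- coords[, 1] + dr; cc <- coords[, 2] + dc
        ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        hit <- ok
        hit[ok] <- zone[cbind(rr[ok], cc[ok])] &
          zoneLab[cbind(rr[ok], cc[ok])] == L
        anchor <- anchor | hit
      }
    }
    pr <- pruneSkeletonGraph(g, anchor, pruneLenUm)
    skels[[L]] <- new("ProcessSkeleton", cellLabel = L,
                      coords = coords[pr$keep, , drop = FALSE],
                      graph = pr$graph, anchor = anchor[pr$keep],
                      root = c(tab$x[L], tab$y[L]), pixelSize = ps,
                      pruneLenUm = pruneLenUm, ambiguous = shared[L])
  }
  attr(skels, "assignment") <- assign
  skels
}

# Iteratively remove endpoint-terminated paths shorter than pruneUm, then
# drop residual components whose total length falls below pruneUm.
# Returns the pruned graph and the logical keep-vector over input vertices.
pruneSkeletonGraph <- function(g, anchor, pruneUm) {
  n <- igraph::vcount(g)
  keep <- rep(TRUE, n)
  if (n == 0L) return(list(graph = g, keep = keep))
  igraph::V(g)$origId <- seq_len(n)
  igraph::V(g)$anchor <- anchor
  repeat {
    deg <- igraph::degree(g)
    eps <- which(deg <= 1L & !igraph::V(g)$anchor)
    if (!length(eps)) break
    drop <- rep(FALSE, igraph::vcount(g))
    for (v in eps) {
      if (drop[v]) next
      if (deg[v] == 0L) { drop[v] <- TRUE; next }
      path <- v; acc <- 0; prev <- -1L; cur <- v
      repeat {
        nbrs <- as.integer(igraph::neighbors(g, cur))
        nbrs <- nbrs[nbrs != prev]
        if (!length(nbrs)) break                       # path component
        nxt <- nbrs[1]
        eid <- igraph::get_edge_ids(g, c(cur, nxt))
        acc <- acc + igraph::E(g)$w_um[eid]
        if (acc >= pruneUm) { path <- NULL; break }    # long enough, keep
        if (igraph::degree(g, nxt) >= 3L || igraph::V(g)$anchor[nxt]) break
        path <- c(path, nxt)
        prev <- cur; cur <- nxt
      }
      if (!is.null(path) && acc < pruneUm) drop[path] <- TRUE
    }
    if (!any(drop)) break
    keep[igraph::V(g)$origId[drop]] <- FALSE
    g <- igraph::delete_vertices(g, which(drop))
  }
  # drop whole components shorter than the pruning length (noise stubs)
  if (igraph::vcount(g)) {
    cmp <- igraph::components(g)
    el <- igraph::as_edgelist(g, names = FALSE)
    compLen <- rep(0, cmp$no)
    if (nrow(el)) {
      lenByComp <- tapply(igraph::E(g)$w_um, cmp$membership[el[, 1]], sum)
      compLen[as.integer(names(lenByComp))] <- lenByComp
    }
    bad <- which(compLen < pruneUm)
    if (length(bad)) {
      drop <- cmp$membership %in% bad
      keep[igraph::V(g)$origId[drop]] <- FALSE
      g <- igraph::delete_vertices(g, which(drop))
    }
  }
  list(graph = g, keep = keep)
}

#' Number of primary branches of a traced cell
#'
#' Primary branches are the distinct skeleton strands crossing the soma
#' boundary: clusters of mutually adjacent anchor pixels each count once.
#'
#' @param skel a [ProcessSkeleton-class].
#' @return integer count (0 for a process-free soma).
#' @export
countPrimaryBranches <- function(skel) {
  stopifnot(is(skel, "ProcessSkeleton"))
  a <- which(skel@anchor)
  if (!length(a)) return(0L)
  sg <- igraph::induced_subgraph(skel@graph, a)
  as.integer(igraph::components(sg)$no)
}

#' Number of branch points of a traced cell
#'
#' Branch points are skeleton vertices of degree >= 3 outside the soma.
#' Junction pixels within a short geodesic distance of each other along the
#' skeleton are merged into a single branch point: thinning renders one
#' anatomical bifurcation as up to two junction pixels a couple of pixels
#' apart when the branches diverge at a shallow angle. The merge radius must
#' stay well below the shortest real inter-junction segment (micrometres),
#' so distinct bifurcations are never fused.
#'
#' @param skel a [ProcessSkeleton-class] (already spur-pruned).
#' @param mergeUm junction merge radius, micrometres (default 1.5).
#' @return integer count.
#' @export
countBranchPoints <- function(skel, mergeUm = 1.5) {
  stopifnot(is(skel, "ProcessSkeleton"))
  if (igraph::vcount(skel@graph) == 0L) return(0L)
  j <- which(igraph::degree(skel@graph) >= 3L)
  if (length(j) <= 1L) return(length(j))
  d <- igraph::distances(skel@graph, v = j, to = j,
                         weights = igraph::E(skel@graph)$w_um)
  adj <- d <= mergeUm
  gj <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                            diag = FALSE)
  as.integer(igraph::components(gj)$no)
}

#' Total branch length of a traced cell
#'
#' Sum of skeleton step lengths outside the soma: orthogonal steps count one
#' pixel size, diagonal steps \code{sqrt(2)} pixel sizes.
#'
#' @param skel a [ProcessSkeleton-class].
#' @return length in micrometres.
#' @export
totalBranchLength <- function(skel) {
  stopifnot(is(skel, "ProcessSkeleton"))
  if (igraph::ecount(skel@graph) == 0L) return(0)
  sum(igraph::E(skel@graph)$w_um)
}

#' Cell radius of a traced cell
#'
#' Maximum Euclidean distance from the soma centroid to any skeleton pixel.
#' For a process-free cell the radius of the soma region itself should be
#' used instead; this function then returns \code{NA} so the caller can fall
#' back (as [measureField()] does, flagging the cell).
#'
#' @param skel a [ProcessSkeleton-class].
#' @param somaCentroid numeric (x, y) um; defaults to the skeleton root.
#' @return radius in micrometres, or \code{NA} for a process-free cell.
#' @export
cellRadius <- function(skel, somaCentroid = NULL) {
  stopifnot(is(skel, "ProcessSkeleton"))
  if (is.null(somaCentroid)) somaCentroid <- skel@root
  if (nrow(skel@coords) == 0L) return(NA_real_)
  ps <- skel@pixelSize
  x <- (skel@coords[, 2] - 0.5) * ps
  y <- (skel@coords[, 1] - 0.5) * ps
  sqrt(max((x - somaCentroid[1])^2 + (y - somaCentroid[2])^2))
}

#' Cell density of a field
#'
#' @param nCells number of cells counted in the field.
#' @param fieldAreaMm2 field area in mm^2 (> 0).
#' @return cells per mm^2.
#' @examples
#' fieldDensity(4, 0.18)   # 22.2, the scale of hippocampal microglia
#' @export
fieldDensity <- function(nCells, fieldAreaMm2) {
  if (!is.finite(fieldAreaMm2) || fieldAreaMm2 <= 0)
    stop("fieldAreaMm2 must be > 0")
  nCells / fieldAreaMm2
}

#' Measure all cells of one field
#'
#' Runs the full single-field pipeline: quantile thresholds, soma detection,
#' foreground mask, process tracing, and extraction of the eight
#' morphological parameters per cell. Border-touching cells are kept in the
#' density count but excluded from morphology by default (switchable).
#'
#' @param image a [FieldImage-class].
#' @param somaQuantile,backgroundQuantile quantile fractions, see
#'   [computeThresholds()].
#' @param minSizePx minimum soma size, see [detectSomata()].
#' @param pruneLenUm,somaMarginUm tracing parameters, see [traceProcesses()].
#' @param borderCells how to treat somata touching the field border:
#'   \code{"countOnly"} (default: counted for density, excluded from the
#'   morphology table), \code{"include"}, or \code{"exclude"} (dropped from
#'   both).
#' @param cellRadiusFrom \code{"skeleton"} (default; maximal centroid-to-
#'   skeleton distance) or \code{"mask"} (maximal centroid-to-assigned-
#'   foreground distance, a hull-like alternative).
#' @param denoiseSigmaPx SD (pixels) of an isotropic Gaussian smoothing
#'   applied before thresholding; 0 (default) thresholds the raw
#'   intensities. On noisy acquisitions a ~1 px smooth suppresses both the
#'   background specks and the in-process dropouts that otherwise fragment
#'   the traced mask; leave at 0 for clean or already-filtered data.
#' @return list with \code{cells} (per-cell data.frame: soma area and
#'   eccentricity, primary branches, branch points, total branch length,
#'   cell radius, cell area, flags), \code{summary} (one-row field summary
#'   with counts at each stage and density), \code{somata}, \code{thresholds},
#'   \code{skeletons}, and the pixel \code{assignment} matrix.
#' @export
measureField <- function(image, somaQuantile = 0.995, backgroundQuantile = 0.90,
                         minSizePx = 150, pruneLenUm = 2, somaMarginUm = 0.5,
                         borderCells = c("countOnly", "include", "exclude"),
                         cellRadiusFrom = c("skeleton", "mask"),
                         denoiseSigmaPx = 0) {
  stopifnot(is(image, "FieldImage"))
  borderCells <- match.arg(borderCells)
  cellRadiusFrom <- match.arg(cellRadiusFrom)
  ps <- image@pixelSize
  if (denoiseSigmaPx > 0)
    image <- FieldImage(
      EBImage::imageData(EBImage::gblur(image@pixels, sigma = denoiseSigmaPx)),
      ps, image@channel)
  th <- computeThresholds(image, somaQuantile, backgroundQuantile)
  som <- detectSomata(image, th, minSizePx)
  tab <- somaTable(som)
  emptyCells <- data.frame(label = integer(0), x = numeric(0), y = numeric(0),
                           somaAreaUm2 = numeric(0), somaEccentricity = numeric(0),
                           nPrimary = integer(0), nBranchPoints = integer(0),
                           totalLengthUm = numeric(0), cellRadiusUm = numeric(0),
                           cellAreaUm2 = numeric(0), onBorder = logical(0),
                           processFree = logical(0), ambiguous = logical(0))
  areaMm2 <- prod(dim(image@pixels)) * (ps / 1000)^2
  if (nrow(tab) == 0L) {
    return(list(cells = emptyCells,
                summary = data.frame(nDetected = 0L, nBorder = 0L,
                                     nMorphology = 0L, fieldAreaMm2 = areaMm2,
                                     density = 0),
                somata = som, thresholds = th, skeletons = list(),
                assignment = matrix(0L, nrow(image@pixels), ncol(image@pixels))))
  }
  mask <- foregroundMask(image, th)
  skels <- traceProcesses(mask, som, pruneLenUm = pruneLenUm,
                          somaMarginUm = somaMarginUm)
  assign <- attr(skels, "assignment")
  assignCounts <- tabulate(assign[assign > 0L], nbins = nrow(tab))
  labsMat <- somaLabels(som)

  rows <- lapply(seq_len(nrow(tab)), function(L) {
    sk <- skels[[L]]
    processFree <- nrow(sk@coords) == 0L
    rad <- if (cellRadiusFrom == "mask") {
      w <- which(assign == L)
      rr <- ((w - 1L) %% nrow(assign)) + 1L
      cc <- ((w - 1L) %/% nrow(assign)) + 1L
      sqrt(max(((cc - 0.5) * ps - tab$x[L])^2 + ((rr - 0.5) * ps - tab$y[L])^2))
    } else if (!processFree) {
      cellRadius(sk)
    } else NA_real_
    if (is.na(rad)) {   # process-free fallback: radius of the soma region
      w <- which(labsMat == L)
      rr <- ((w - 1L) %% nrow(labsMat)) + 1L
      cc <- ((w - 1L) %/% nrow(labsMat)) + 1L
      rad <- sqrt(max(((cc - 0.5) * ps - tab$x[L])^2 +
                      ((rr - 0.5) * ps - tab$y[L])^2))
    }
    data.frame(label = L, x = tab$x[L], y = tab$y[L],
               somaAreaUm2 = tab$areaUm2[L],
               somaEccentricity = tab$eccentricity[L],
               nPrimary = countPrimaryBranches(sk),
               nBranchPoints = countBranchPoints(sk),
               totalLengthUm = totalBranchLength(sk),
               cellRadiusUm = rad,
               cellAreaUm2 = assignCounts[L] * ps^2,
               onBorder = tab$onBorder[L],
               processFree = processFree, ambiguous = sk@ambiguous)
  })
  cells <- do.call(rbind, rows)
  nBorder <- sum(cells$onBorder)
  keepMorph <- if (borderCells == "include") rep(TRUE, nrow(cells)) else
    !cells$onBorder
  nForDensity <- if (borderCells == "exclude") sum(!cells$onBorder) else
    nrow(cells)
  list(cells = cells[keepMorph, , drop = FALSE],
       summary = data.frame(nDetected = nrow(cells), nBorder = nBorder,
                            nMorphology = sum(keepMorph),
                            fieldAreaMm2 = areaMm2,
                            density = fieldDensity(nForDensity, areaMm2)),
       somata = som, thresholds = th, skeletons = skels, assignment = assign)
}
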