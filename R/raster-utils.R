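# Low-level binary-raster operations shared by segmentation and morphometry.
# All matrices are indexed [row, col]; linear index = (col - 1) * nrow + row.

# 8- or 4-connected component labelling with labels assigned in raster-scan
# order (column-major, as R stores matrices) of each component's first pixel,
# so labelling is deterministic and reproducible across runs.
labelComponents <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  nr <- nrow(mask)
  nc <- ncol(mask)
  w <- which(mask)
  out <- matrix(0L, nr, nc)
  if (!length(w)) return(out)
  id <- integer(nr * nc)
  id[w] <- seq_along(w)
  r <- ((w - 1L) %% nr) + 1L
  c <- ((w - 1L) %/% nr) + 1L
  shifts <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8L) shifts <- c(shifts, list(c(1L, 1L), c(-1L, 1L)))
  edges <- NULL
  for (s in shifts) {
    dr <- s[1]; dc <- s[2]
    ok <- r + dr >= 1L & r + dr <= nr & c + dc >= 1L & c + dc <= nc
    nb <- w + dr + dc * nr
    sel <- ok
    sel[ok] <- mask[nb[ok]]
    if (any(sel)) edges <- rbind(edges, cbind(id[w[sel]], id[nb[sel]]))
  }
  if (is.null(edges)) {
    comp <- seq_along(w)
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    if (igraph::vcount(g) < length(w))
      g <- igraph::add_vertices(g, length(w) - igraph::vcount(g))
    comp <- igraph::components(g)$membership
  }
  # relabel so that component k is the k-th encountered in raster-scan order
  first <- !duplicated(comp)
  relab <- integer(max(comp))
  relab[comp[first]] <- seq_len(sum(first))
  out[w] <- relab[comp]
  out
}

# Guo-Hall thinning (two-subiteration). Preserves 8-connectivity and yields
# unit-width skeletons without the 2-px staircase residue of Zhang-Suen,
# which matters for branch-point counting downstream.
thinMask <- function(mask) {
  stopifnot(is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  nrp <- nr + 2L
  p <- matrix(0L, nrp, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mask * 1L
  oN <- -1L; oS <- 1L; oE <- nrp; oW <- -nrp
  # p2..p9 clockwise from north: N, NE, E, SE, S, SW, W, NW
  offs <- c(oN, oN + oE, oE, oS + oE, oS, oS + oW, oW, oN + oW)
  fg <- which(p == 1L)
  nb <- matrix(0L, length(fg), 8L)
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      if (!length(fg)) break
      if (nrow(nb) != length(fg)) nb <- matrix(0L, length(fg), 8L)
      for (k in 1:8) nb[, k] <- p[fg + offs[k]]
      p2 <- nb[, 1]; p3 <- nb[, 2]; p4 <- nb[, 3]; p5 <- nb[, 4]
      p6 <- nb[, 5]; p7 <- nb[, 6]; p8 <- nb[, 7]; p9 <- nb[, 8]
      C <- ((1L - p2) & (p3 | p4)) + ((1L - p4) & (p5 | p6)) +
           ((1L - p6) & (p7 | p8)) + ((1L - p8) & (p9 | p2))
      N1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
      N2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
      N <- pmin(N1, N2)
      m <- if (sub == 1L) ((p6 | p7 | (1L - p9)) & p8) else
                          ((p2 | p3 | (1L - p5)) & p4)
      cond <- C == 1L & N >= 2L & N <= 3L & m == 0L
      if (any(cond)) {
        p[fg[cond]] <- 0L
        fg <- fg[!cond]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- matrix(FALSE, nr, nc)
  if (length(fg)) {
    rr <- ((fg - 1L) %% nrp) + 1L
    cc <- ((fg - 1L) %/% nrp) + 1L
    out[cbind(rr - 1L, cc - 1L)] <- TRUE
  }
  out
}

# Adjacency edges of a skeleton (or any sparse binary) image, each listed
# once, with step weights in pixels (1 orthogonal, sqrt(2) diagonal).
# A diagonal edge is dropped as redundant when one of the two pixels
# completing its unit square is itself foreground, so staircase chains are
# measured along their orthogonal steps and never double-connected.
skeletonEdges <- function(sk) {
  nr <- nrow(sk); nc <- ncol(sk)
  w <- which(sk)
  id <- integer(nr * nc)
  id[w] <- seq_along(w)
  r <- ((w - 1L) %% nr) + 1L
  c <- ((w - 1L) %/% nr) + 1L
  add <- function(dr, dc, wt) {
    ok <- r + dr >= 1L & r + dr <= nr & c + dc >= 1L & c + dc <= nc
    nb <- w + dr + dc * nr
    sel <- ok
    sel[ok] <- sk[nb[ok]]
    if (wt > 1) {
      n1 <- w + dc * nr   # (r, c + dc)
      n2 <- w + dr        # (r + dr, c)
      red <- sel
      red[sel] <- sk[n1[sel]] | sk[n2[sel]]
      sel <- sel & !red
    }
    if (any(sel)) cbind(id[w[sel]], id[nb[sel]], wt) else NULL
  }
  edges <- rbind(add(0L, 1L, 1), add(1L, 0L, 1),
                 add(1L, 1L, sqrt(2)), add(-1L, 1L, sqrt(2)))
  list(coords = cbind(r = r, c = c), edges = edges)
}

# Binary dilation by a disc of the given pixel radius (EBImage brush).
dilateByDisc <- function(mask, radiusPx) {
  if (radiusPx <= 0) return(mask)
  size <- 2L * as.integer(ceiling(radiusPx)) + 1L
  brush <- EBImage::makeBrush(size, shape = "disc")
  EBImage::imageData(EBImage::dilate(mask * 1, brush)) > 0
}

# Second-central-moment eccentricity of a pixel region given (row, col)
# coordinates: sqrt(1 - lambda2/lambda1) with lambda1 >= lambda2 the
# eigenvalues of the coordinate covariance; 0 (flagged) for degenerate
# regions with no spatial extent.
momentEccentricity <- function(coords) {
  if (nrow(coords) < 2L)
    return(list(eccentricity = 0, degenerate = TRUE))
  cv <- stats::cov(coords)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] <= 0)
    return(list(eccentricity = 0, degenerate = TRUE))
  list(eccentricity = sqrt(max(0, 1 - ev[2] / ev[1])), degenerate = FALSE)
}

# CSV writers/readers used across the pipeline: full double precision and a
# leading comment line carrying provenance (config hash), skipped on read.
writeCsvExact <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  num <- vapply(df, is.double, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  write.csv(out, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

readCsvExact <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
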