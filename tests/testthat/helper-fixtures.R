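# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no binary fixtures.

# Quantile fractions that place the thresholds between the planted
# intensity levels of a synthetic field: the soma threshold at the
# soma/process midpoint, the background threshold at least 3.5 noise SDs
# above the background level (background noise pixels crossing a lower
# threshold would attach speck chains to the processes and inflate the
# junction count). Zero-noise images take exactly the planted values, so
# any fraction inside the right block works.
plantedQuantiles <- function(image, regime) {
  px <- fieldPixels(image)
  noiseSd <- if (is.null(regime$noiseSd)) 0 else regime$noiseSd
  somaMid <- (regime$intensitySoma + regime$intensityProcess) / 2
  bgMid <- regime$intensityBackground +
    max((regime$intensityProcess - regime$intensityBackground) / 2,
        3.5 * noiseSd)
  soma <- 1 - mean(px >= somaMid)
  # a process-free field has no pixels between the two midpoints; nudge the
  # background fraction just below the soma fraction (well under one order
  # statistic) so both thresholds interpolate inside the soma block
  list(soma = soma, bg = min(1 - mean(px >= bgMid), soma - 0.001 / length(px)))
}

# Match measured cells to planted truth rows by nearest soma centre.
matchCells <- function(measured, truth) {
  ord <- vapply(seq_len(nrow(measured)), function(i)
    which.min((truth$x - measured$x[i])^2 + (truth$y - measured$y[i])^2),
    integer(1))
  truth[ord, ]
}

# A simple star cell: n straight rays of given length from a circular soma.
starSpec <- function(center = c(75, 75), somaR = 4, nRays = 4, rayLen = 40,
                     angles = NULL, ...) {
  if (is.null(angles)) angles <- 2 * pi * (seq_len(nRays) - 1) / nRays + 0.2
  cellSpec(center, c(somaR, somaR),
           branches = lapply(angles, function(a) branchSegment(rayLen, a)),
           ...)
}

# Independent Mann-Whitney oracle: U by direct pair counting (not ranks),
# tail probabilities by explicit enumeration over index subsets.
mwEnumOracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pairU <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  U <- pairU(x, y)
  pooled <- c(x, y)
  ix <- utils::combn(nx + ny, nx)
  Uall <- apply(ix, 2, function(i) pairU(pooled[i], pooled[-i]))
  eps <- 1e-9
  list(U = U,
       p = min(1, 2 * min(mean(Uall <= U + eps), mean(Uall >= U - eps))))
}

# Build a ProcessSkeleton directly from a logical skeleton matrix (for
# testing the length/junction arithmetic in isolation from tracing).
skeletonFromMask <- function(sk, pixelSize = 0.5, root = c(0, 0),
                             anchor = NULL) {
  se <- gliamorph:::skeletonEdges(sk)
  g <- igraph::make_empty_graph(n = nrow(se$coords), directed = FALSE)
  if (!is.null(se$edges)) {
    g <- igraph::add_edges(g, t(se$edges[, 1:2, drop = FALSE]))
    igraph::E(g)$w_um <- se$edges[, 3] * pixelSize
  }
  if (is.null(anchor)) anchor <- logical(nrow(se$coords))
  new("ProcessSkeleton", cellLabel = 1L, coords = se$coords, graph = g,
      anchor = anchor, root = root, pixelSize = pixelSize, pruneLenUm = 0,
      ambiguous = FALSE)
}
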