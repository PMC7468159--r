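# Process tracing and the eight morphological parameters, validated against
# planted geometry and hand-built skeletons.

measurePlanted <- function(fl, reg, minSizePx = 150, ...) {
  q <- plantedQuantiles(fl$image, reg)
  mf <- measureField(fl$image, somaQuantile = q$soma, backgroundQuantile = q$bg,
                     minSizePx = minSizePx, ...)
  mf
}

test_that("a star of straight rays has that many primaries and no junctions", {
  reg <- morphRegime("astrocyte")
  star <- starSpec(c(75, 75), somaR = 4, nRays = 4, rayLen = 40)
  fl <- renderField(list(star), 150, 0.5)
  mf <- measurePlanted(fl, reg)
  expect_identical(mf$cells$nPrimary, 4L)
  expect_identical(mf$cells$nBranchPoints, 0L)
  expect_equal(mf$cells$totalLengthUm, 160, tolerance = 0.1)
  expect_false(mf$cells$processFree)
})

test_that("a Y-shaped process has exactly one junction", {
  reg <- morphRegime("astrocyte")
  y <- cellSpec(c(60, 60), c(4, 4), branches = list(
    branchSegment(20, 0.8, list(branchSegment(12, 1.25),
                                branchSegment(12, 0.35)))))
  fl <- renderField(list(y), 120, 0.5)
  mf <- measurePlanted(fl, reg)
  expect_identical(mf$cells$nPrimary, 1L)
  expect_identical(mf$cells$nBranchPoints, 1L)
})

test_that("a depth-2 binary tree has three junctions per primary", {
  reg <- morphRegime("astrocyte")
  mkTree <- function(angle) {
    lvl2 <- function(a) list(branchSegment(9, a - 0.3), branchSegment(9, a + 0.3))
    branchSegment(12, angle, list(
      branchSegment(10, angle - 0.45, lvl2(angle - 0.45)),
      branchSegment(10, angle + 0.45, lvl2(angle + 0.45))))
  }
  sp <- cellSpec(c(75, 75), c(4, 4), branches = list(mkTree(0.3), mkTree(pi)))
  expect_identical(cellGroundTruth(sp)$nBranchPoints, 6L)
  fl <- renderField(list(sp), 150, 0.5)
  mf <- measurePlanted(fl, reg)
  expect_identical(mf$cells$nPrimary, 2L)
  expect_identical(mf$cells$nBranchPoints, 6L)
})

test_that("skeleton length arithmetic weights diagonal steps by sqrt(2)", {
  # straight horizontal run of 101 px at 0.5 um/px: 100 steps = 50 um
  m <- matrix(FALSE, 20, 120)
  m[10, 10:110] <- TRUE
  sk <- skeletonFromMask(m, pixelSize = 0.5)
  expect_equal(totalBranchLength(sk), 50)

  # 10-step diagonal
  d <- matrix(FALSE, 30, 30)
  for (k in 0:10) d[5 + k, 5 + k] <- TRUE
  expect_equal(totalBranchLength(skeletonFromMask(d, 0.5)), 10 * sqrt(2) * 0.5)

  # staircase: orthogonal steps only, diagonal shortcut edges are redundant
  s <- matrix(FALSE, 10, 10)
  s[cbind(c(2, 2, 3, 3, 4, 4), c(2, 3, 3, 4, 4, 5))] <- TRUE
  expect_equal(totalBranchLength(skeletonFromMask(s, 1)), 5)
})

test_that("cell radius measures maximal reach from the soma centroid", {
  # hand-built: pixels at known distances
  m <- matrix(FALSE, 40, 40)
  m[20, 20:35] <- TRUE
  sk <- skeletonFromMask(m, pixelSize = 1, root = c(19.5, 19.5))
  expect_equal(cellRadius(sk), 15)

  # planted 30-um single ray: radius = soma boundary + 30 within 5%
  reg <- morphRegime("astrocyte")
  sp <- cellSpec(c(60, 60), c(4, 4), branches = list(branchSegment(30, 1.1)))
  fl <- renderField(list(sp), 120, 0.5)
  mf <- measurePlanted(fl, reg)
  expect_equal(mf$cells$cellRadiusUm, 34, tolerance = 0.05)
  expect_equal(mf$cells$cellRadiusUm,
               cellGroundTruth(sp)$cellRadiusUm, tolerance = 0.05)
})

test_that("process-free cells fall back to the soma radius and are flagged", {
  reg <- morphRegime("astrocyte")
  sp <- cellSpec(c(40, 40), c(5, 4))
  fl <- renderField(list(sp), 80, 0.5)
  mf <- measurePlanted(fl, reg)
  expect_true(mf$cells$processFree)
  expect_identical(mf$cells$nPrimary, 0L)
  expect_equal(mf$cells$cellRadiusUm, 5, tolerance = 0.15)
  expect_equal(mf$cells$cellAreaUm2, mf$cells$somaAreaUm2, tolerance = 0.05)
})

test_that("cell area covers soma plus processes of the assigned cell", {
  reg <- morphRegime("astrocyte")
  star <- starSpec(c(75, 75), somaR = 4, nRays = 4, rayLen = 30,
                   processWidth = 1.5)
  fl <- renderField(list(star), 150, 0.5)
  mf <- measurePlanted(fl, reg)
  expect_gte(mf$cells$cellAreaUm2, mf$cells$somaAreaUm2)
  # planted support area (exact on a zero-noise field)
  support <- sum(fieldPixels(fl$image) > star@intensityBackground) * 0.25
  expect_equal(mf$cells$cellAreaUm2, support)
})

test_that("field density is the exact quotient and errors on zero area", {
  expect_equal(fieldDensity(4, 0.18), 22.2, tolerance = 0.01)
  expect_identical(fieldDensity(0, 0.18), 0)
  expect_equal(fieldDensity(8, 0.18), 2 * fieldDensity(4, 0.18))
  expect_error(fieldDensity(1, 0), "must be > 0")
})

test_that("spur pruning is monotone in the pruning length", {
  set.seed(31)
  reg <- morphRegime("astrocyte", noiseSd = 150, psfSigmaUm = 0.3)
  specs <- gliamorph:::placeCells(3, reg, 180)
  fl <- renderField(specs, 180, 0.5, seed = 4)
  q <- plantedQuantiles(fl$image, reg)
  th <- computeThresholds(fl$image, q$soma, q$bg)
  det <- detectSomata(fl$image, th, 150)
  mask <- foregroundMask(fl$image, th)
  prev <- NULL
  for (pl in c(0.5, 2, 5, 10)) {
    sks <- traceProcesses(mask, det, pruneLenUm = pl)
    bp <- sum(vapply(sks, countBranchPoints, integer(1)))
    len <- sum(vapply(sks, totalBranchLength, numeric(1)))
    if (!is.null(prev)) {
      expect_lte(bp, prev[1])
      expect_lte(len, prev[2] + 1e-9)
    }
    prev <- c(bp, len)
  }
})

test_that("skeleton measurements are rotation-tolerant", {
  reg <- morphRegime("astrocyte")
  set.seed(5)
  spec <- randomCellSpec(c(75, 75), reg)
  measure <- function(m) {
    img <- FieldImage(m, 0.5)
    mid <- (reg$intensitySoma + reg$intensityProcess) / 2
    bgm <- (reg$intensityProcess + reg$intensityBackground) / 2
    mf <- measureField(img, 1 - mean(m >= mid), 1 - mean(m >= bgm), 150)
    mf$cells
  }
  base <- measure(fieldPixels(renderField(list(spec), 150, 0.5)$image))
  rot90 <- function(m) t(m)[, nrow(m):1]
  m <- fieldPixels(renderField(list(spec), 150, 0.5)$image)
  for (k in 1:3) {
    m <- rot90(m)
    r <- measure(m)
    expect_identical(r$nPrimary, base$nPrimary)
    expect_identical(r$nBranchPoints, base$nBranchPoints)
    expect_equal(r$totalLengthUm, base$totalLengthUm, tolerance = 0.01)
  }
  # arbitrary rotation applied analytically to the spec
  for (ang in c(0.4, 1.9)) {
    rotNode <- function(nd) {
      nd$angle <- nd$angle + ang
      nd$children <- lapply(nd$children, rotNode)
      nd
    }
    sp2 <- spec
    sp2@branches <- lapply(spec@branches, rotNode)
    sp2@somaAngle <- spec@somaAngle + ang
    r <- measure(fieldPixels(renderField(list(sp2), 150, 0.5)$image))
    expect_equal(r$totalLengthUm, base$totalLengthUm, tolerance = 0.05)
  }
})

test_that("somata sharing a foreground component are split and flagged", {
  reg <- morphRegime("astrocyte")
  # two somata joined by one straight process
  a <- cellSpec(c(40, 60), c(4, 4),
                branches = list(branchSegment(32, 0)))  # reaches x = 76
  b <- cellSpec(c(80, 60), c(4, 4))
  fl <- renderField(list(a, b), 120, 0.5, allowOverlap = TRUE)
  mf <- measurePlanted(fl, reg)
  expect_identical(nrow(mf$cells), 2L)
  expect_true(all(mf$cells$ambiguous))
  # the connecting strand is split: both cells get some share
  expect_gt(mf$cells$totalLengthUm[1], 0)
})

test_that("an empty field measures to an empty table without error", {
  img <- FieldImage(matrix(0, 120, 120), 0.5)
  mf <- measureField(img)
  expect_identical(nrow(mf$cells), 0L)
  expect_identical(mf$summary$nDetected, 0L)
  expect_identical(mf$summary$density, 0)
})
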