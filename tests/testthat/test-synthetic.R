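# Ground truth of the generator is analytic; these tests pin the closed
# forms and the rendering contracts (determinism, bounds, collisions).

test_that("ground-truth closed forms match geometry exactly", {
  # circular soma of radius 4 um
  circ <- cellSpec(c(30, 30), c(4, 4))
  tr <- cellGroundTruth(circ)
  expect_equal(tr$somaAreaUm2, pi * 16)
  expect_equal(tr$somaEccentricity, 0)
  expect_equal(tr$cellRadiusUm, 4)

  # a = 2b ellipse: eccentricity sqrt(1 - 1/4) = sqrt(3)/2
  ell <- cellSpec(c(30, 30), c(4, 2), somaAngle = 0.7)
  expect_equal(cellGroundTruth(ell)$somaEccentricity, sqrt(3) / 2)
  expect_equal(cellGroundTruth(ell)$somaAreaUm2, pi * 8)

  # four straight 40-um primaries, no bifurcations
  star <- starSpec(c(75, 75), somaR = 4, nRays = 4, rayLen = 40)
  tr <- cellGroundTruth(star)
  expect_identical(tr$nPrimary, 4L)
  expect_identical(tr$nBranchPoints, 0L)
  expect_equal(tr$totalLengthUm, 160)
  expect_equal(tr$cellRadiusUm, 44)   # soma radius + ray length

  # one bifurcating primary: one branch point, summed segment lengths
  y <- cellSpec(c(40, 40), c(4, 4), branches = list(
    branchSegment(20, 0, list(branchSegment(10, 0.5), branchSegment(10, -0.5)))))
  tr <- cellGroundTruth(y)
  expect_identical(tr$nBranchPoints, 1L)
  expect_equal(tr$totalLengthUm, 40)
})

test_that("ground truth is noise-invariant; raster is seed-deterministic", {
  base <- starSpec(c(50, 50), rayLen = 20)
  noisy <- starSpec(c(50, 50), rayLen = 20, noiseSd = 300, psfSigma = 0.4)
  expect_equal(cellGroundTruth(noisy), cellGroundTruth(base))

  f1 <- renderField(list(noisy), 100, 0.5, seed = 5)
  f2 <- renderField(list(noisy), 100, 0.5, seed = 5)
  f3 <- renderField(list(noisy), 100, 0.5, seed = 6)
  expect_identical(fieldPixels(f1$image), fieldPixels(f2$image))
  expect_false(identical(fieldPixels(f1$image), fieldPixels(f3$image)))
  expect_equal(f1$cells$totalLengthUm, f3$cells$totalLengthUm)
})

test_that("out-of-bounds cells and colliding cells are rejected by name", {
  sp <- starSpec(c(10, 50), rayLen = 20)    # reach 34 > 10 from left edge
  expect_error(renderField(list(sp), 100, 0.5), "beyond the field")
  expect_error(renderCell(starSpec(c(10, 10), rayLen = 20), 0.5,
                          patchSideUm = 100), "beyond patch bounds")

  a <- starSpec(c(40, 50), rayLen = 20)
  b <- starSpec(c(70, 50), rayLen = 20)     # 30 um apart, footprints ~25 each
  expect_error(renderField(list(a, b), 120, 0.5), "cells 1 and 2 overlap")
  expect_silent(renderField(list(a, b), 120, 0.5, allowOverlap = TRUE))
})

test_that("field density is the planted count over the field area", {
  specs <- lapply(list(c(80, 80), c(80, 344), c(344, 80), c(344, 344)),
                  function(ctr) starSpec(ctr, rayLen = 15))
  fl <- renderField(specs, 424.26, 0.83)   # coarser grid keeps this quick
  expect_equal(fl$field$fieldAreaMm2, 0.18, tolerance = 1e-4)
  expect_equal(fl$field$density, 4 / 0.18, tolerance = 0.01)
  empty <- renderField(list(), 424.26, 0.83)
  expect_identical(empty$field$density, 0)
})

test_that("rendered intensities follow the spec (zero-noise case exact)", {
  sp <- starSpec(c(50, 50), rayLen = 20)
  fl <- renderField(list(sp), 100, 0.5)
  px <- fieldPixels(fl$image)
  expect_setequal(unique(as.vector(px)),
                  c(sp@intensityBackground, sp@intensityProcess,
                    sp@intensitySoma))
  # soma pixel count approximates the analytic area
  somaPx <- sum(px == sp@intensitySoma)
  expect_equal(somaPx * 0.25, pi * 16, tolerance = 0.05)
})

test_that("group datasets scale the mutant regime by the requested factors", {
  reg <- morphRegime("astrocyte")
  expect_identical(gliamorph:::scaleRegime(reg, list()), reg)

  # branch-length factor ~0.58 (the DG astrocyte retraction regime)
  ds <- makeGroupDataset(reg, factors = list(totalLength = 96.8 / 167),
                         nAnimals = 6, seed = 3)
  mWT <- mean(ds$truth$totalLengthUm[ds$truth$genotype == "WT"])
  mNL <- mean(ds$truth$totalLengthUm[ds$truth$genotype == "NL3"])
  # between-animal CV 0.12 with 6 animals per group gives the ratio a
  # sampling SD of ~0.04; allow three of those
  expect_lt(abs(mNL / mWT - 96.8 / 167), 0.12)

  # density factor ~1.71 (the DG microglia regime) scales planted counts
  regM <- morphRegime("microglia")
  scaled <- gliamorph:::scaleRegime(regM, list(density = 38.7 / 22.6))
  expect_equal(scaled$cellsPerField, 4 * 38.7 / 22.6)
  dsM <- makeGroupDataset(regM, factors = list(density = 38.7 / 22.6),
                          nAnimals = 5, fieldsPerAnimal = 2, seed = 9)
  nWT <- mean(dsM$fields$nCells[dsM$fields$genotype == "WT"])
  nNL <- mean(dsM$fields$nCells[dsM$fields$genotype == "NL3"])
  # Poisson counts over 10 fields per group: ratio SD ~0.3 around 1.71
  expect_gt(nNL / nWT, 1.0)
  expect_lt(nNL / nWT, 2.6)

  expect_error(makeGroupDataset(reg, nAnimals = 1), "at least 2 animals")
})

test_that("random cells drawn from a regime satisfy the spec invariants", {
  set.seed(21)
  reg <- morphRegime("astrocyte")
  for (i in 1:10) {
    sp <- randomCellSpec(c(100, 100), reg)
    expect_true(validObject(sp))
    tr <- cellGroundTruth(sp)
    expect_gte(tr$nPrimary, 3)
    expect_gte(tr$cellRadiusUm, sp@somaAxes[1])
    expect_gte(tr$cellAreaUm2, tr$somaAreaUm2)
    # realized totals stay in the glial regime ballpark
    expect_gt(tr$totalLengthUm, 60)
    expect_lt(tr$totalLengthUm, 350)
  }
})
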