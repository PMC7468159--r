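# Quantile thresholds, component labelling with the minimum-size filter,
# and moment-ellipse soma shape.

test_that("thresholds are the empirical type-7 quantiles", {
  img <- FieldImage(matrix(1:100, 10, 10), 0.5)
  th <- computeThresholds(img, somaQuantile = 0.90, backgroundQuantile = 0.50)
  # independent oracle: linear interpolation on the sorted values
  v <- sort(1:100)
  interp <- function(q) {
    h <- 1 + q * 99
    v[floor(h)] + (h - floor(h)) * (v[floor(h) + 1] - v[floor(h)])
  }
  expect_equal(th@tSoma, interp(0.90))
  expect_equal(th@tBg, interp(0.50))
  expect_false(th@degenerate)

  # monotone in the requested fraction
  set.seed(4)
  img2 <- FieldImage(matrix(rlnorm(400), 20, 20), 0.5)
  qs <- seq(0.5, 0.99, by = 0.07)
  ts <- vapply(qs, function(q)
    computeThresholds(img2, q, q / 2)@tSoma, numeric(1))
  expect_true(all(diff(ts) >= 0))

  expect_error(computeThresholds(img, 1.0, 0.5), "strictly between")
  expect_error(computeThresholds(img, 0.5, 0.9), "below somaQuantile")
})

test_that("a constant image yields degenerate thresholds and no somata", {
  img <- FieldImage(matrix(7, 50, 50), 0.5)
  th <- computeThresholds(img)
  expect_true(th@degenerate)
  expect_identical(th@tSoma, th@tBg)
  det <- detectSomata(img, th)
  expect_identical(nSomata(det), 0L)
})

test_that("minimum-size filter keeps components of >= minSizePx pixels", {
  m <- matrix(0, 100, 100)
  m[10:18, 10:20] <- 10          # 9 x 11 = 99 px
  img <- FieldImage(m, 0.5)
  th <- computeThresholds(img, 0.995, 0.9)
  expect_identical(nSomata(detectSomata(img, th, minSizePx = 100)), 0L)

  m[40:49, 40:54] <- 10          # 150 px
  m[70:78, 70:79] <- 10          # 90 px
  img <- FieldImage(m, 0.5)      # 339 of 10^4 px now carry signal
  th <- computeThresholds(img, 0.97, 0.9)
  det <- detectSomata(img, th, minSizePx = 100)
  expect_identical(nSomata(det), 1L)
  expect_equal(somaTable(det)$areaPx, 150)
  expect_equal(somaTable(det)$areaUm2, 150 * 0.25)
  expect_warning(detectSomata(img, th, minSizePx = 50), "100-200")
})

test_that("detected centroid of a planted circular soma is within one pixel", {
  sp <- cellSpec(c(30.2, 24.7), c(4, 4))
  fl <- renderField(list(sp), 60, 0.5)
  q <- plantedQuantiles(fl$image, list(intensitySoma = sp@intensitySoma,
                                       intensityProcess = sp@intensityProcess,
                                       intensityBackground = sp@intensityBackground))
  th <- computeThresholds(fl$image, q$soma, q$bg)
  det <- detectSomata(fl$image, th, minSizePx = 150)
  expect_identical(nSomata(det), 1L)
  expect_lt(abs(somaTable(det)$x - 30.2), 0.5)
  expect_lt(abs(somaTable(det)$y - 24.7), 0.5)
  expect_false(somaTable(det)$onBorder)
})

test_that("moment-ellipse eccentricity recovers planted soma shapes", {
  # rasterized disc: eccentricity ~ 0
  disc <- which(outer((-30:30)^2, (-30:30)^2, "+") <= 25^2, arr.ind = TRUE)
  expect_lt(somaShape(disc, 0.5)$eccentricity, 0.05)

  # a = 2b ellipse: eccentricity sqrt(3)/2 within raster tolerance
  sp <- cellSpec(c(30, 30), c(6, 3), somaAngle = 0.6)
  fl <- renderField(list(sp), 60, 0.25)
  px <- fieldPixels(fl$image)
  reg <- which(px == sp@intensitySoma, arr.ind = TRUE)
  expect_equal(somaShape(reg, 0.25)$eccentricity, sqrt(3) / 2,
               tolerance = 0.025)

  # elongated-microglia regime (planted 0.87) recovered within 0.03
  ar <- 56.7; ecc <- 0.87; ratio <- sqrt(1 - ecc^2)
  a <- sqrt(ar / (pi * ratio)); b <- ar / (pi * a)
  sp2 <- cellSpec(c(30, 30), c(a, b), somaAngle = 1.1)
  fl2 <- renderField(list(sp2), 60, 0.415)
  reg2 <- which(fieldPixels(fl2$image) == sp2@intensitySoma, arr.ind = TRUE)
  expect_lt(abs(somaShape(reg2, 0.415)$eccentricity - 0.87), 0.03)

  # degenerate one-pixel region: eccentricity defined 0, flagged
  one <- somaShape(matrix(c(3L, 5L), 1, 2), 0.5)
  expect_identical(one$eccentricity, 0)
  expect_true(one$degenerate)
})

test_that("foreground mask equals the planted support on zero-noise fields", {
  set.seed(8)
  reg <- morphRegime("astrocyte")
  specs <- gliamorph:::placeCells(3, reg, 180)
  fl <- renderField(specs, 180, 0.5)
  q <- plantedQuantiles(fl$image, reg)
  th <- computeThresholds(fl$image, q$soma, q$bg)
  mask <- foregroundMask(fl$image, th)
  support <- fieldPixels(fl$image) > reg$intensityBackground
  expect_identical(mask, support)
  # superset of the soma mask
  expect_true(all(mask[fieldPixels(fl$image) >= th@tSoma]))
})

test_that("detections shrink monotonically in size filter and soma quantile", {
  set.seed(13)
  reg <- morphRegime("astrocyte", noiseSd = 150, psfSigmaUm = 0.3)
  specs <- gliamorph:::placeCells(4, reg, 200)
  fl <- renderField(specs, 200, 0.5, seed = 2)
  q <- plantedQuantiles(fl$image, reg)
  th <- computeThresholds(fl$image, q$soma, q$bg)

  sizes <- c(50, 100, 150, 250, 400)
  nBySize <- vapply(sizes, function(s)
    suppressWarnings(nSomata(detectSomata(fl$image, th, s))), integer(1))
  expect_true(all(diff(nBySize) <= 0))

  # count monotonicity holds once the threshold separates somata from the
  # process band (below that, merged components can split as it rises)
  sweep <- sweepSomaQuantiles(fl$image, seq(q$soma - 0.003, 0.9995,
                                            length.out = 8),
                              backgroundQuantile = 0.9, minSizePx = 100)
  expect_true(all(diff(sweep$nDetected) <= 0))
  full <- sweepSomaQuantiles(fl$image, seq(0.95, 0.999, by = 0.007),
                             backgroundQuantile = 0.9, minSizePx = 100)
  expect_true(all(diff(full$tSoma) >= 0))

  # raising the background quantile never grows the mask
  m1 <- foregroundMask(fl$image, computeThresholds(fl$image, 0.999, 0.90))
  m2 <- foregroundMask(fl$image, computeThresholds(fl$image, 0.999, 0.95))
  expect_true(all(m1[m2]))

  # area conservation
  det <- detectSomata(fl$image, th, 100)
  expect_lte(sum(somaTable(det)$areaUm2), 200 * 200)
})
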