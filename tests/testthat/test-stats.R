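# Statistical layer: each test statistic is checked against an independent
# oracle (closed form, base-R reference implementation, enumeration, or
# permutation), and the dispatch logic against simulated group shapes.

test_that("pooled Student t matches the closed form and base R", {
  ht <- studentTTwoSample(c(1, 2, 3), c(2, 3, 4))
  expect_equal(unname(ht$statistic), -sqrt(1.5), tolerance = 1e-12)
  expect_identical(unname(ht$parameter), 4)
  expect_equal(ht$p.value, 0.2879, tolerance = 5e-4)

  set.seed(2)
  for (i in 1:20) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1))
    ref <- stats::t.test(x, y, var.equal = TRUE)
    ht <- studentTTwoSample(x, y)
    expect_equal(unname(ht$statistic), unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ht$p.value, ref$p.value, tolerance = 1e-12)
    # label swap flips t, keeps p
    expect_equal(studentTTwoSample(y, x)$p.value, ht$p.value, tolerance = 1e-12)
  }

  expect_identical(studentTTwoSample(c(2, 2, 2), c(2, 2))$p.value, 1)
  expect_error(studentTTwoSample(c(1, 1), c(2, 2)), "undefined")
  expect_error(studentTTwoSample(1, c(1, 2)), "at least 2")
})

test_that("pooled t agrees with a permutation test on small samples", {
  set.seed(7)
  x <- rnorm(8); y <- rnorm(8, 0.8)
  pT <- studentTTwoSample(x, y)$p.value
  pooled <- c(x, y)
  obs <- abs(mean(x) - mean(y))
  perm <- replicate(4000, {
    ix <- sample(16, 8)
    abs(mean(pooled[ix]) - mean(pooled[-ix]))
  })
  pPerm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(pT - pPerm), 0.05)
})

test_that("exact Mann-Whitney equals independent enumeration (n <= 6)", {
  ht <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_identical(unname(ht$statistic), 0)
  expect_equal(ht$p.value, 0.1)
  expect_match(ht$method, "exact")

  set.seed(12)
  for (nx in 2:6) for (ny in 2:6) {
    for (rep in 1:2) {
      x <- sample(1:8, nx, replace = TRUE)   # ties likely
      y <- sample(1:8, ny, replace = TRUE)
      or <- mwEnumOracle(x, y)
      ht <- mannWhitneyU(x, y)
      expect_equal(unname(ht$statistic), or$U)
      expect_equal(ht$p.value, or$p)
    }
  }
  # untied case also agrees with base R's exact test
  x <- c(1.2, 3.4, 2.2, 5.1); y <- c(4.4, 6.2, 7.0, 2.9)
  expect_equal(mannWhitneyU(x, y)$p.value,
               stats::wilcox.test(x, y, exact = TRUE)$p.value)
})

test_that("tied data and approximation branches behave as documented", {
  ht <- mannWhitneyU(c(3, 3, 3), c(3, 3))
  expect_identical(ht$p.value, 1)
  expect_match(ht$method, "tied")

  expect_identical(mannWhitneyU(c(1, 2, 3), c(3, 2, 1))$p.value, 1)

  # exact and normal-approximation p agree within 0.02 for 6 vs 6, no ties
  set.seed(3)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(6, runif(1, -1.5, 1.5))
    pe <- mannWhitneyU(x, y, exactMax = 12)$p.value
    pa <- mannWhitneyU(x, y, exactMax = 0)$p.value
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("Lilliefors test matches the reference implementation", {
  library(nortest)
  set.seed(9)
  for (n in c(5, 10, 30, 80, 150)) {
    x <- rnorm(n) + rexp(n) * (n %% 2)
    mine <- lillieforsKS(x)
    ref <- nortest::lillie.test(x)
    expect_equal(unname(mine$statistic), unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-9)
  }
  # quantile-perfect normal sample: comfortably normal
  expect_gt(lillieforsKS(qnorm(ppoints(20)))$p.value, 0.5)
  # strongly bimodal sample: rejected
  bim <- c(rnorm(25, -4, 0.3), rnorm(25, 4, 0.3))
  expect_lt(lillieforsKS(bim)$p.value, 0.01)
  # zero variance: non-normal verdict, flagged
  z <- lillieforsKS(rep(2, 6))
  expect_identical(z$p.value, 0)
  expect_match(z$note, "zero-variance")
  expect_error(lillieforsKS(c(1, 2, 3)), "at least 4")
})

test_that("summary t-test equals the sample t on its own summaries", {
  set.seed(15)
  for (i in 1:10) {
    n <- sample(4:9, 1)
    x <- rnorm(n); y <- rnorm(n, 0.5)   # equal group sizes: exact identity
    ht <- studentTTwoSample(x, y)
    hs <- summaryTTest(mean(x), sd(x) / sqrt(n), n, mean(y), sd(y) / sqrt(n), n)
    expect_equal(unname(hs$statistic), unname(ht$statistic), tolerance = 1e-12)
    expect_equal(hs$p.value, ht$p.value, tolerance = 1e-12)
  }
  expect_identical(summaryTTest(5, 1, 5, 5, 1, 5)$p.value, 1)
})

test_that("normality gating dispatches to the right test", {
  set.seed(19)
  gauss <- compareParameter(rnorm(12, 10), rnorm(12, 10.5), "x")
  expect_identical(gauss$testUsed, "student_t")

  skewed <- compareParameter(rexp(15)^3, rnorm(15, 2), "x")
  expect_identical(skewed$testUsed, "mann_whitney")

  expect_warning(compareParameter(c(1, 2, 3), c(2, 3, 4)), "n < 4")
})

test_that("p-values live in [0,1] and are invariant to group-label swap", {
  set.seed(23)
  for (i in 1:25) {
    x <- rnorm(sample(4:8, 1)); y <- rexp(sample(4:8, 1))
    for (f in list(studentTTwoSample, mannWhitneyU)) {
      p1 <- f(x, y)$p.value; p2 <- f(y, x)$p.value
      expect_gte(p1, 0); expect_lte(p1, 1)
      expect_equal(p1, p2, tolerance = 1e-12)
    }
    pl <- lillieforsKS(x)$p.value
    expect_gte(pl, 0); expect_lte(pl, 1)
  }
})

test_that("compareGroups reports mean/SEM per genotype with star markers", {
  set.seed(27)
  d <- rbind(
    data.frame(genotype = "WT", animal = paste0("w", 1:5), parameter = "len",
               value = rnorm(5, 167, 30)),
    data.frame(genotype = "NL3", animal = paste0("m", 1:5), parameter = "len",
               value = rnorm(5, 90, 25)))
  cmp <- compareGroups(d)
  expect_identical(nrow(cmp), 1L)
  expect_equal(cmp$wtMean, mean(d$value[d$genotype == "WT"]))
  expect_identical(cmp$stars, gliamorph:::significanceStars(cmp$p))
  expect_match(attr(cmp, "footnote"), "No multiple-testing correction")

  dbad <- d[d$genotype == "WT" | d$parameter != "len", ]
  expect_error(compareGroups(dbad), "exactly two genotypes")
  d2 <- rbind(d, data.frame(genotype = "NL3", animal = "m9",
                            parameter = "area", value = 1))
  expect_error(compareGroups(d2), "only one genotype")
})
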