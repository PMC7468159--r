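# Two-group statistical layer: Lilliefors-corrected Kolmogorov-Smirnov
# normality gating, pooled-variance Student t, exact/approximate
# Mann-Whitney U, and summary-statistics cross-checks. All tests are
# two-tailed. No multiple-testing correction is applied across parameters,
# matching the convention of per-parameter glial morphometry tables; reports
# carry a footnote stating the implied family-wise error.

#' Lilliefors-corrected Kolmogorov-Smirnov normality test
#'
#' Kolmogorov-Smirnov distance of the sample against a normal distribution
#' with mean and SD estimated from the same sample, with the p-value from
#' the Dallal-Wilkinson approximation (the correction appropriate when the
#' reference parameters are estimated). The Dallal-Wilkinson formula is
#' accurate for p <= 0.1; above that the Stephens modified-statistic
#' approximation is used instead, and values are clipped to \[0, 1\].
#'
#' @param x numeric vector, n >= 4.
#' @return an object of class \code{"htest"} with the D statistic and
#'   p-value; a zero-variance sample gets \code{p.value = 0} (certainly not
#'   normal) and a \code{note} element flagging the degeneracy.
#' @examples
#' lillieforsKS(qnorm(ppoints(20)))$p.value   # large: consistent with normal
#' @export
lillieforsKS <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4) stop("Lilliefors test needs at least 4 observations")
  s <- sd(x)
  res <- list(method = "Lilliefors (Dallal-Wilkinson) normality test",
              data.name = deparse(substitute(x)), note = NULL)
  if (s == 0) {
    res$statistic <- c(D = 1)
    res$p.value <- 0
    res$note <- "zero-variance sample: non-normal by convention"
    class(res) <- "htest"
    return(res)
  }
  z <- sort((x - mean(x)) / s)
  p <- pnorm(z)
  i <- seq_len(n)
  D <- max(i / n - p, p - (i - 1) / n)
  # Dallal & Wilkinson (1986) approximation
  if (n > 100) { Kd <- D * (n / 100)^0.49; nd <- 100 } else { Kd <- D; nd <- n }
  pv <- exp(-7.01256 * Kd^2 * (nd + 2.78019) +
            2.99587 * Kd * sqrt(nd + 2.78019) - 0.122119 +
            0.974598 / sqrt(nd) + 1.67997 / nd)
  if (pv > 0.1) {
    # Stephens (1974) modified statistic, valid in the upper tail
    KK <- (sqrt(n) - 0.01 + 0.85 / sqrt(n)) * D
    pv <- if (KK <= 0.302) 1 else
      if (KK <= 0.5) 2.76773 - 19.828315 * KK + 80.709644 * KK^2 -
        138.55152 * KK^3 + 81.218052 * KK^4 else
      if (KK <= 0.9) -4.901232 + 40.662806 * KK - 97.490286 * KK^2 +
        94.029866 * KK^3 - 32.355711 * KK^4 else
      if (KK <= 1.31) 6.198765 - 19.558097 * KK + 23.186922 * KK^2 -
        12.234627 * KK^3 + 2.423045 * KK^4 else 0
  }
  res$statistic <- c(D = D)
  res$p.value <- min(1, max(0, pv))
  class(res) <- "htest"
  res
}

#' Two-sample pooled-variance Student t-test (two-tailed)
#'
#' The classic unpaired Student t with pooled variance and
#' \code{df = n_x + n_y - 2}. (The Welch variant is available via
#' \code{pooled = FALSE} but is never the default, matching the usual
#' "Student's t-test" convention of morphometry reports.)
#'
#' @param x,y numeric vectors with at least 2 values each.
#' @param pooled use the pooled-variance form (default TRUE).
#' @return \code{"htest"} with \code{statistic} (t), \code{parameter} (df)
#'   and two-tailed \code{p.value}. If both samples are constant and equal,
#'   \code{t = 0, p = 1}; constant samples with different means are an error
#'   (the statistic is undefined).
#' @examples
#' studentTTwoSample(c(1, 2, 3), c(2, 3, 4))   # t = -1.2247, p = 0.2879
#' @export
studentTTwoSample <- function(x, y, pooled = TRUE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("each sample needs at least 2 values")
  vx <- var(x); vy <- var(y)
  if (pooled) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    df <- nx + ny - 2
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  dm <- mean(x) - mean(y)
  if (se == 0) {
    if (dm == 0) {
      res <- list(statistic = c(t = 0), parameter = c(df = df), p.value = 1,
                  method = "Two-sample Student t-test (pooled variance)",
                  data.name = "x and y")
      class(res) <- "htest"
      return(res)
    }
    stop("zero pooled variance with unequal means: t statistic undefined")
  }
  t <- dm / se
  res <- list(statistic = c(t = t), parameter = c(df = df),
              p.value = 2 * pt(-abs(t), df),
              method = if (pooled) "Two-sample Student t-test (pooled variance)"
                       else "Welch two-sample t-test",
              data.name = "x and y")
  class(res) <- "htest"
  res
}

# U statistic of x against y from midranks (handles ties).
uStatistic <- function(x, y) {
  nx <- length(x)
  r <- rank(c(x, y))
  sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
}

#' Two-tailed Mann-Whitney U test
#'
#' For small samples (\code{n_x + n_y <= exactMax}, default 12) the p-value
#' is exact, by full enumeration of all \eqn{C(n_x+n_y, n_x)} assignments of
#' the pooled observed values to the two groups (ties handled naturally);
#' the two-tailed p doubles the smaller tail and is capped at 1. Larger
#' samples use the normal approximation with midrank tie correction and
#' continuity correction. The method actually used is recorded.
#'
#' @param x,y numeric vectors, at least 1 value each.
#' @param exactMax maximum pooled size for exact enumeration.
#' @return \code{"htest"} with \code{statistic} (U of the first sample),
#'   two-tailed \code{p.value}, and \code{method} naming the branch used.
#'   Completely tied data give \code{p = 1} with a \code{note}.
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))$p.value   # exact 2/20 = 0.1
#' @export
mannWhitneyU <- function(x, y, exactMax = 12) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 1 || ny < 1) stop("each sample needs at least 1 value")
  U <- uStatistic(x, y)
  pooled <- c(x, y)
  res <- list(statistic = c(U = U), data.name = "x and y", note = NULL)
  if (length(unique(pooled)) == 1L) {
    res$p.value <- 1
    res$method <- "Mann-Whitney U test (degenerate: all values tied)"
    res$note <- "all observations are tied"
    class(res) <- "htest"
    return(res)
  }
  if (nx + ny <= exactMax) {
    splits <- combn(nx + ny, nx)
    Uall <- apply(splits, 2, function(ix)
      uStatistic(pooled[ix], pooled[-ix]))
    eps <- 1e-9
    pl <- mean(Uall <= U + eps)
    pg <- mean(Uall >= U - eps)
    res$p.value <- min(1, 2 * min(pl, pg))
    res$method <- "Mann-Whitney U test (exact enumeration)"
  } else {
    N <- nx + ny
    ties <- table(pooled)
    tieAdj <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- nx * ny / 12 * ((N + 1) - tieAdj)
    mu <- nx * ny / 2
    cc <- if (U == mu) 0 else 0.5
    z <- (U - mu - sign(U - mu) * cc) / sqrt(sigma2)
    res$p.value <- min(1, 2 * pnorm(-abs(z)))
    res$method <- "Mann-Whitney U test (normal approximation, tie-corrected)"
  }
  class(res) <- "htest"
  res
}

#' t-test from printed summary statistics (mean, SEM, n)
#'
#' Cross-checks published mean +/- SEM rows:
#' \eqn{t = (m_1 - m_2) / \sqrt{SEM_1^2 + SEM_2^2}} with
#' \eqn{df = n_1 + n_2 - 2}. For equal group sizes this is algebraically
#' identical to the pooled two-sample t computed from the raw data; for
#' unequal sizes it is the usual summary approximation. Because published
#' SEMs are rounded, recomputed p-values can differ from printed ones in the
#' second decimal; treat results as cross-checks, not equalities.
#'
#' @param mean1,sem1,n1 first group summary (sem1 > 0, n1 >= 2).
#' @param mean2,sem2,n2 second group summary.
#' @return \code{"htest"} with t, df and two-tailed p.
#' @examples
#' # astrocyte total branch length, 167 +/- 15 vs 96.8 +/- 13 (n = 5, 5)
#' summaryTTest(167, 15, 5, 96.8, 13, 5)$p.value   # ~0.008
#' @export
summaryTTest <- function(mean1, sem1, n1, mean2, sem2, n2) {
  stopifnot(sem1 > 0, sem2 > 0, n1 >= 2, n2 >= 2)
  t <- (mean1 - mean2) / sqrt(sem1^2 + sem2^2)
  df <- n1 + n2 - 2
  res <- list(statistic = c(t = t), parameter = c(df = df),
              p.value = 2 * pt(-abs(t), df),
              method = "Two-sample t-test from summary statistics",
              data.name = "summaries")
  class(res) <- "htest"
  res
}

#' Normality-gated two-group comparison of one parameter
#'
#' Applies the Lilliefors normality test to each group at level 0.05; when
#' both pass, the groups are compared with the pooled two-tailed Student
#' t-test, otherwise with the two-tailed Mann-Whitney U test. Groups too
#' small for the normality test (n < 4) fall back to the t-test with a
#' warning.
#'
#' @param wt,mut numeric vectors of per-animal values (the animal is the
#'   sampling unit).
#' @param parameter parameter name carried into the result.
#' @param alpha significance level (default 0.05).
#' @return one-row data.frame: \code{parameter}, \code{testUsed}
#'   (\code{"student_t"} or \code{"mann_whitney"}), \code{statistic},
#'   \code{p}, \code{normalWT}, \code{normalMut}, \code{significant}.
#' @export
compareParameter <- function(wt, mut, parameter = "parameter", alpha = 0.05) {
  wt <- wt[is.finite(wt)]; mut <- mut[is.finite(mut)]
  testable <- length(wt) >= 4 && length(mut) >= 4
  if (!testable) {
    warning("groups of n < 4 cannot be tested for normality; using Student t")
    normWT <- normMut <- NA
  } else {
    normWT <- lillieforsKS(wt)$p.value > 0.05
    normMut <- lillieforsKS(mut)$p.value > 0.05
  }
  useT <- !testable || (normWT && normMut)
  ht <- if (useT) studentTTwoSample(wt, mut) else mannWhitneyU(wt, mut)
  data.frame(parameter = parameter,
             testUsed = if (useT) "student_t" else "mann_whitney",
             statistic = unname(ht$statistic), p = ht$p.value,
             normalWT = if (testable) normWT else NA,
             normalMut = if (testable) normMut else NA,
             significant = ht$p.value < alpha)
}

#' Compare all parameters of a long per-animal table
#'
#' @param data long data.frame with columns \code{genotype} (two levels, the
#'   reference genotype first alphabetically unless given), \code{animal},
#'   \code{parameter}, \code{value}; optionally \code{region}, compared
#'   separately.
#' @param alpha significance level.
#' @param reference genotype treated as wild type (default \code{"WT"}).
#' @return data.frame with one row per (region x) parameter: group means and
#'   SEMs, test used, statistic, p and a significance marker (\code{*} for
#'   p < 0.05, \code{**} for p < 0.01, \code{NS} otherwise).
#' @export
compareGroups <- function(data, alpha = 0.05, reference = "WT") {
  stopifnot(all(c("genotype", "animal", "parameter", "value") %in% names(data)))
  if (!"region" %in% names(data)) data$region <- "all"
  gts <- unique(data$genotype)
  if (length(gts) != 2L) stop("need exactly two genotypes")
  if (!reference %in% gts)
    stop(sprintf("reference genotype '%s' not present", reference))
  other <- setdiff(gts, reference)
  sem <- function(v) sd(v) / sqrt(length(v))
  out <- list()
  for (rg in unique(data$region)) {
    drg <- data[data$region == rg, ]
    for (pm in unique(drg$parameter)) {
      d <- drg[drg$parameter == pm, ]
      wt <- d$value[d$genotype == reference]
      mu <- d$value[d$genotype == other]
      if (!length(wt) || !length(mu))
        stop(sprintf("parameter '%s' present in only one genotype", pm))
      cr <- compareParameter(wt, mu, parameter = pm, alpha = alpha)
      out[[length(out) + 1L]] <- data.frame(
        region = rg, parameter = pm,
        wtMean = mean(wt), wtSEM = sem(wt), nWT = length(wt),
        mutMean = mean(mu), mutSEM = sem(mu), nMut = length(mu),
        testUsed = cr$testUsed, statistic = cr$statistic, p = cr$p,
        stars = significanceStars(cr$p))
    }
  }
  res <- do.call(rbind, out)
  attr(res, "footnote") <- sprintf(
    paste0("No multiple-testing correction applied across %d comparisons; ",
           "family-wise type-I error at alpha = %.2f is up to %.2f."),
    nrow(res), alpha, 1 - (1 - alpha)^nrow(res))
  res
}

# The significance-marker convention of the source tables.
significanceStars <- function(p) {
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "NS"))
}
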