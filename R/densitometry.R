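# Western-blot densitometry: band intensities relative to a loading control
# (beta-actin), expressed per blot as a percentage of the wild-type mean.

#' Normalize densitometry band intensities and compare genotypes
#'
#' For every lane the target-band intensity is divided by the actin
#' (loading-control) intensity of the same lane; within each blot group
#' (unique combination of \code{blot}, \code{target} and, when present,
#' \code{region}) every ratio is then expressed as a percentage of the mean
#' wild-type ratio of that group, so the wild-type group mean is 100 exactly
#' by construction. Genotypes are compared per target (and region) with the
#' two-tailed pooled Student t-test on the percentages.
#'
#' @param table data.frame with columns \code{blot}, \code{lane},
#'   \code{genotype}, \code{target}, \code{targetIntensity},
#'   \code{actinIntensity}; optional \code{region}. All actin intensities
#'   must be positive, and every blot group needs at least one lane of the
#'   reference genotype.
#' @param alpha significance level for the comparison table.
#' @param reference reference genotype (default \code{"WT"}).
#' @return list with \code{table} (input plus \code{ratio} and
#'   \code{percentOfWT}) and \code{comparison} (per target/region group
#'   means +/- SEM, t, p, significance marker; \code{NA} test columns when a
#'   group has a single genotype only).
#' @examples
#' tb <- data.frame(blot = 1, lane = 1:4, genotype = c("WT", "WT", "NL3", "NL3"),
#'                  target = "SNAP-25", targetIntensity = c(10, 12, 7, 8),
#'                  actinIntensity = c(10, 11, 10, 11))
#' densitometryPercent(tb)$comparison
#' @export
densitometryPercent <- function(table, alpha = 0.05, reference = "WT") {
  need <- c("blot", "lane", "genotype", "target", "targetIntensity",
            "actinIntensity")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("densitometry table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"region" %in% names(table)) table$region <- "all"
  bad <- which(!is.finite(table$actinIntensity) | table$actinIntensity <= 0)
  if (length(bad))
    stop(sprintf("missing or non-positive actin intensity in lane %s of blot %s",
                 table$lane[bad[1]], table$blot[bad[1]]))
  grp <- interaction(table$blot, table$target, table$region, drop = TRUE)
  table$ratio <- table$targetIntensity / table$actinIntensity
  table$percentOfWT <- NA_real_
  for (g in levels(grp)) {
    ix <- which(grp == g)
    wt <- ix[table$genotype[ix] == reference]
    if (!length(wt))
      stop(sprintf("blot group '%s' has no %s lane to normalize against",
                   g, reference))
    table$percentOfWT[ix] <- 100 * table$ratio[ix] / mean(table$ratio[wt])
  }
  cmp <- list()
  for (tg in unique(table$target)) for (rg in unique(table$region)) {
    d <- table[table$target == tg & table$region == rg, ]
    if (!nrow(d)) next
    wt <- d$percentOfWT[d$genotype == reference]
    mu <- d$percentOfWT[d$genotype != reference]
    row <- data.frame(target = tg, region = rg,
                      wtMeanPct = mean(wt), nWT = length(wt),
                      mutMeanPct = if (length(mu)) mean(mu) else NA_real_,
                      mutSEMPct = if (length(mu) > 1)
                        sd(mu) / sqrt(length(mu)) else NA_real_,
                      nMut = length(mu),
                      t = NA_real_, p = NA_real_, stars = NA_character_)
    if (length(mu) >= 2 && length(wt) >= 2) {
      ht <- studentTTwoSample(wt, mu)
      row$t <- unname(ht$statistic)
      row$p <- ht$p.value
      row$stars <- significanceStars(ht$p.value)
    }
    cmp[[length(cmp) + 1L]] <- row
  }
  list(table = table, comparison = do.call(rbind, cmp))
}

#' Simulate a densitometry table with a known mutant effect
#'
#' Generates lane intensities for one synthetic blot per target: actin lanes
#' lognormal around a common level, target/actin ratios lognormal around 1
#' for the reference genotype and around \code{effect} for the mutant (e.g.
#' 0.67 emulates a one-third reduction of a presynaptic protein in cortex).
#' Uses the current R random number state.
#'
#' @param nPerGroup lanes (animals) per genotype (default 6).
#' @param effect mutant/WT ratio of expected ratios.
#' @param cv lognormal coefficient of variation of lane ratios.
#' @param target,region labels for the simulated blot.
#' @return data.frame in the format accepted by [densitometryPercent()].
#' @export
simulateDensitometry <- function(nPerGroup = 6, effect = 0.67, cv = 0.15,
                                 target = "SNAP-25", region = "cortex") {
  n <- 2 * nPerGroup
  actin <- rlnorm(n, log(1000), 0.1)
  ratio <- c(rlnorm(nPerGroup, 0, cv), rlnorm(nPerGroup, log(effect), cv))
  data.frame(blot = 1L, lane = seq_len(n),
             genotype = rep(c("WT", "NL3"), each = nPerGroup),
             target = target, region = region,
             targetIntensity = ratio * actin, actinIntensity = actin)
}
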