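#' Lilliefors normality gate
#'
#' Kolmogorov-Smirnov test with estimated mean/SD (Lilliefors) at alpha =
#' 0.05, used to route continuous group comparisons: when both groups pass,
#' a t-test is used, otherwise the Wilcoxon rank-sum test.
#'
#' @param x numeric sample, n >= 5.
#' @param alpha significance level of the gate (default 0.05).
#' @return `"normal"` or `"non-normal"`. A constant sample is flagged
#'   non-normal with a warning.
#' @export
normalityGate <- function(x, alpha = 0.05) {
  stopIfNot(length(x) >= 5L, "normality gate needs n >= 5")
  if (sd(x) == 0) {
    warning("constant sample: treated as non-normal")
    return("non-normal")
  }
  p <- nortest::lillie.test(x)$p.value
  if (p >= alpha) "normal" else "non-normal"
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact p by hypergeometric enumeration: with margins fixed, the p-value is
#' the sum of probabilities of all tables no more probable than the observed
#' one. A zero margin gives p = 1.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return two-sided p-value.
#' @examples
#' fisherExact2x2(matrix(c(46, 36, 36, 57), 2, byrow = TRUE))  # ~0.024
#' @export
fisherExact2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopIfNot(all(dim(tab) == 2L) && all(tab >= 0) && all(tab == round(tab)),
            "tab must be a 2x2 matrix of nonnegative integers")
  m <- sum(tab[1L, ])          # row-1 margin
  n <- sum(tab[2L, ])          # row-2 margin
  k <- sum(tab[, 1L])          # column-1 margin
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  support <- max(0L, k - n):min(k, m)
  d <- dhyper(support, m, n, k)
  dObs <- dhyper(tab[1L, 1L], m, n, k)
  # relative tolerance guards against ties lost to floating point
  min(1, sum(d[d <= dObs * (1 + 1e-7)]))
}

#' Gender-adjusted logistic group test for one network metric
#'
#' Fits group ~ metric + gender by maximum likelihood and reports the Wald
#' p-value of the metric coefficient. Significance is flagged both
#' unadjusted (p < 0.05) and at the Bonferroni level used for nodal
#' comparisons (p < 0.05 / nComparisons, default 116 regions).
#'
#' @param metric numeric per-subject metric values.
#' @param group two-level group labels (case level = last factor level, or
#'   `"MCI"` if present).
#' @param gender labels coded to 0/1 internally.
#' @param metricName,sparsityValue identifiers echoed into the result.
#' @param nComparisons Bonferroni denominator (default 116).
#' @return one-row data.frame: metric, sparsity, coefficient, p_value,
#'   significant_unadjusted, significant_bonferroni. Perfect separation is
#'   flagged with `p_value = NA`.
#' @export
logisticGroupTest <- function(metric, group, gender, metricName = "metric",
                              sparsityValue = NA_real_, nComparisons = 116L) {
  stopIfNot(length(unique(group)) == 2L, "both groups must be present")
  stopIfNot(!anyNA(metric) && !anyNA(group) && !anyNA(gender),
            "missing values not allowed")
  lev <- if ("MCI" %in% group) c(setdiff(unique(group), "MCI"), "MCI")
         else sort(unique(group))
  y <- as.integer(factor(group, levels = lev)) - 1L
  z <- as.integer(factor(gender)) - 1L
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ metric + z, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  sm <- summary(fit)$coefficients
  if (!("metric" %in% rownames(sm))) {
    # rank-deficient fit (constant metric): no estimable coefficient
    beta <- NA_real_
    p <- NA_real_
  } else {
    beta <- unname(sm["metric", "Estimate"])
    p <- if (separated) NA_real_ else unname(sm["metric", "Pr(>|z|)"])
  }
  data.frame(metric = metricName, sparsity = sparsityValue,
             coefficient = beta, p_value = p,
             significant_unadjusted = isTRUE(p < 0.05),
             significant_bonferroni = isTRUE(p < 0.05 / nComparisons),
             separation = separated, stringsAsFactors = FALSE)
}

#' Partial correlation controlling a covariate
#'
#' Pearson correlation of the residuals of `x` and `y` after regressing each
#' on the covariate (gender coded 0/1); p from the t distribution with n - 3
#' degrees of freedom.
#'
#' @param x,y numeric vectors (n >= 4).
#' @param z covariate labels (two-level) or numeric vector.
#' @param metricName,scoreName,sparsityValue identifiers echoed in the
#'   result.
#' @return one-row data.frame: metric, score, sparsity, r_partial, p_value.
#' @export
partialCorrelation <- function(x, y, z, metricName = "x", scoreName = "y",
                               sparsityValue = NA_real_) {
  n <- length(x)
  stopIfNot(n >= 4L && length(y) == n && length(z) == n,
            "need n >= 4 and equal-length inputs")
  zn <- if (is.numeric(z)) z else as.integer(factor(z)) - 1L
  rx <- resid(lm(x ~ zn))
  ry <- resid(lm(y ~ zn))
  stopIfNot(sd(rx) > 1e-10 * (1 + abs(mean(x))) &&
              sd(ry) > 1e-10 * (1 + abs(mean(y))),
            "zero residual variance")
  r <- cor(rx, ry)
  r <- max(-1, min(1, r))
  tStat <- r * sqrt((n - 3) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tStat), df = n - 3)
  data.frame(metric = metricName, score = scoreName, sparsity = sparsityValue,
             r_partial = r, p_value = p, stringsAsFactors = FALSE)
}

#' Demographic and clinical comparison table
#'
#' Gender is compared with Fisher's exact test; each continuous score is
#' routed through the normality gate ([normalityGate()]) to a t-test (both
#' groups normal) or a Wilcoxon rank-sum test.
#'
#' @param metadata cohort metadata with columns group, gender and the four
#'   cognitive scores.
#' @param scoreNames continuous variables to compare.
#' @return data.frame: variable, test, statistic, p_value, and per-group
#'   mean (SD) or counts.
#' @export
demographicsTable <- function(metadata,
                              scoreNames = c("ADAS13", "CDRSB", "MMSE",
                                             "FAQ")) {
  groups <- sort(unique(metadata$group))
  stopIfNot(length(groups) == 2L, "metadata must contain two groups")
  g1 <- metadata$group == groups[1L]
  tab <- table(factor(metadata$gender, levels = c("M", "F")),
               factor(metadata$group, levels = groups))
  rows <- list(data.frame(
    variable = "gender", test = "fisher",
    statistic = NA_real_, p_value = fisherExact2x2(t(tab)),
    summary1 = paste(tab[, 1L], collapse = "/"),
    summary2 = paste(tab[, 2L], collapse = "/"),
    stringsAsFactors = FALSE))
  for (nm in scoreNames) {
    x1 <- metadata[[nm]][g1]
    x2 <- metadata[[nm]][!g1]
    normal <- normalityGate(x1) == "normal" && normalityGate(x2) == "normal"
    ht <- if (normal) t.test(x1, x2)
          else suppressWarnings(wilcox.test(x1, x2))
    rows[[length(rows) + 1L]] <- data.frame(
      variable = nm, test = if (normal) "t" else "wilcoxon",
      statistic = unname(ht$statistic), p_value = ht$p.value,
      summary1 = sprintf("%.2f ± %.2f", mean(x1), sd(x1)),
      summary2 = sprintf("%.2f ± %.2f", mean(x2), sd(x2)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  names(out)[names(out) == "summary1"] <- groups[1L]
  names(out)[names(out) == "summary2"] <- groups[2L]
  out
}
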