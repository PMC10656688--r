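# Diagnostic performance and reader-agreement statistics: confusion-matrix
# metrics, tie-aware ordinal AUC with DeLong variance and paired test,
# Cohen's kappa with conventional interpretation bins, McNemar's test, and
# percent-agreement tables.

#' Round to integer percent, half away from zero
#'
#' Reporting convention used throughout the agreement tables.
#'
#' @param x proportion in `[0,1]`.
#' @return integer percent.
#' @export
percent_int <- function(x) {
  sign(x) * floor(abs(x) * 100 + 0.5)
}

#' Confusion-matrix performance metrics
#'
#' @param tp,fp,fn,tn nonnegative lesion counts.
#' @return list with `sensitivity`, `specificity`, `ppv`, `npv`, `fp_rate`,
#'   `fn_rate`, `accuracy` (proportions) and `percent`, the same metrics
#'   rounded to integer percent (half away from zero).
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  safe_div <- function(num, den, what) {
    if (den == 0) stop("undefined metric ", what, ": zero denominator")
    num / den
  }
  m <- list(
    sensitivity = safe_div(tp, tp + fn, "sensitivity"),
    specificity = safe_div(tn, tn + fp, "specificity"),
    ppv = safe_div(tp, tp + fp, "ppv"),
    npv = safe_div(tn, tn + fn, "npv"),
    fp_rate = safe_div(fp, tn + fp, "fp_rate"),
    fn_rate = safe_div(fn, tp + fn, "fn_rate"),
    accuracy = safe_div(tp + tn, tp + fp + fn + tn, "accuracy"))
  m$percent <- vapply(m, percent_int, numeric(1))
  m
}

# DeLong structural components: for each positive the mean indicator
# (with half credit for ties) against all negatives, and vice versa.
delong_components <- function(ratings, truth) {
  stopifnot(length(ratings) == length(truth))
  pos <- ratings[truth == 1]
  neg <- ratings[truth == 0]
  if (length(pos) == 0 || length(neg) == 0)
    stop("AUC requires both classes present")
  psi <- outer(pos, neg, function(x, y) (x > y) + 0.5 * (x == y))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi),
       m = length(pos), n = length(neg))
}

#' Ordinal AUC and DeLong inference
#'
#' `auc_ordinal()` is the tie-aware Mann-Whitney statistic: the probability
#' that a random positive outranks a random negative, with half credit for
#' ties. `delong_ci()` adds the DeLong structural-components variance and a
#' normal 95% CI truncated to `[0,1]`. `delong_paired_test()` compares two
#' correlated AUCs measured on the same lesions via the covariance of their
#' structural components (two-sided normal p).
#'
#' @param ratings,ratingsA,ratingsB numeric or ordinal ratings (higher =
#'   more suspicious).
#' @param truth 0/1 (or logical) ground truth, 1 = positive/malignant.
#' @return `auc_ordinal`: scalar AUC. `delong_ci`: named numeric
#'   `c(auc, lo, hi, se)`. `delong_paired_test`: named numeric
#'   `c(auc_a, auc_b, z, p)`.
#' @export
auc_ordinal <- function(ratings, truth) {
  delong_components(ratings, as.integer(truth))$auc
}

#' @rdname auc_ordinal
#' @export
delong_ci <- function(ratings, truth, level = 0.95) {
  comp <- delong_components(ratings, as.integer(truth))
  s10 <- if (comp$m > 1) stats::var(comp$v10) else 0
  s01 <- if (comp$n > 1) stats::var(comp$v01) else 0
  se <- sqrt(s10 / comp$m + s01 / comp$n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(auc = comp$auc,
    lo = max(0, comp$auc - z * se),
    hi = min(1, comp$auc + z * se),
    se = se)
}

#' @rdname auc_ordinal
#' @export
delong_paired_test <- function(ratingsA, ratingsB, truth) {
  truth <- as.integer(truth)
  a <- delong_components(ratingsA, truth)
  b <- delong_components(ratingsB, truth)
  d <- a$auc - b$auc
  if (a$m > 1 && a$n > 1) {
    s10 <- stats::var(a$v10) + stats::var(b$v10) - 2 * stats::cov(a$v10, b$v10)
    s01 <- stats::var(a$v01) + stats::var(b$v01) - 2 * stats::cov(a$v01, b$v01)
    v <- s10 / a$m + s01 / a$n
  } else v <- 0
  if (v <= 0) {
    z <- if (abs(d) < 1e-12) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(v)
  }
  p <- if (is.infinite(z)) 0 else 2 * stats::pnorm(-abs(z))
  c(auc_a = a$auc, auc_b = b$auc, z = z, p = min(1, p))
}

KAPPA_BINS <- data.frame(
  lo = c(-Inf, 0.4, 0.6, 0.8, 0.9),
  hi = c(0.4, 0.6, 0.8, 0.9, Inf),
  label = c("below weak", "weak", "moderate", "strong", "perfect"),
  stringsAsFactors = FALSE)

#' Cohen's kappa with interpretation bin
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with `p_o` the diagonal fraction and
#' `p_e = sum(row_i * col_i) / N^2`. Interpretation: 0.4-0.59 weak,
#' 0.6-0.79 moderate, 0.8-0.9 strong, above 0.9 perfect, below 0.4
#' "below weak".
#'
#' @param table square contingency matrix of two raters over the same label
#'   set (identical row/column order).
#' @return list with `kappa`, `p_o`, `p_e`, `interpretation`.
#' @export
cohen_kappa <- function(table) {
  table <- as.matrix(table)
  stopifnot(nrow(table) == ncol(table), all(table >= 0))
  n <- sum(table)
  if (n == 0) stop("cohen_kappa: empty table")
  p_o <- sum(diag(table)) / n
  p_e <- sum(rowSums(table) * colSums(table)) / n^2
  if (abs(1 - p_e) < 1e-12) stop("cohen_kappa: degenerate marginals (p_e = 1)")
  k <- (p_o - p_e) / (1 - p_e)
  kr <- round(k, 10) # guard the published bin edges against FP noise
  bin <- if (kr > 0.9) "perfect"
  else if (kr >= 0.8) "strong"
  else if (kr >= 0.6) "moderate"
  else if (kr >= 0.4) "weak"
  else "below weak"
  list(kappa = k, p_o = p_o, p_e = p_e, interpretation = bin)
}

#' McNemar's test on discordant counts
#'
#' Exact two-sided binomial test when `b + c < 25`, otherwise the
#' continuity-corrected chi-square `(|b - c| - 1)^2 / (b + c)` on 1 df.
#' `b = c = 0` returns `p = 1` with a degenerate-input note.
#'
#' @param b,c nonnegative discordant counts.
#' @return list with `statistic` (chi-square, or `NA` for the exact
#'   branch), `p`, `method`.
#' @export
mcnemar_test <- function(b, c) {
  stopifnot(b >= 0, c >= 0)
  n <- b + c
  if (n == 0) {
    message("mcnemar_test: no discordant pairs; p = 1 by convention")
    return(list(statistic = NA_real_, p = 1, method = "degenerate"))
  }
  if (n < 25) {
    p <- min(1, 2 * stats::pbinom(min(b, c), n, 0.5))
    return(list(statistic = NA_real_, p = p, method = "exact binomial"))
  }
  stat <- (abs(b - c) - 1)^2 / n
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       method = "corrected chi-square")
}

#' Percent agreement between two raters
#'
#' Overall agreement as integer percent (half away from zero), and the
#' conditional rate within the stratum of lesions the stratifying rater
#' assigned to one category.
#'
#' @param labelsA,labelsB equal-length label vectors.
#' @param category stratum label (matched against `labelsA`, the
#'   stratifying rater).
#' @return `percent_agreement`: list with `percent`, `matches`, `n`.
#'   `conditional_agreement`: the same, within the stratum.
#' @export
percent_agreement <- function(labelsA, labelsB) {
  stopifnot(length(labelsA) == length(labelsB), length(labelsA) > 0)
  matches <- sum(labelsA == labelsB)
  list(percent = percent_int(matches / length(labelsA)),
       matches = matches, n = length(labelsA))
}

#' @rdname percent_agreement
#' @export
conditional_agreement <- function(labelsA, labelsB, category) {
  stopifnot(length(labelsA) == length(labelsB))
  idx <- labelsA == category
  if (!any(idx)) stop("conditional_agreement: empty stratum for category ", category)
  percent_agreement(labelsA[idx], labelsB[idx])
}
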