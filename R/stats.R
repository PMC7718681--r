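#' Group comparison with a normality gate
#'
#' Shapiro-Wilk on each group at alpha = 0.05 decides the test: if both
#' groups are compatible with normality, a two-sample Student t-test is
#' used, otherwise the Wilcoxon rank-sum test. The effect size is always
#' Cohen's d with pooled standard deviation (sign follows `a - b`),
#' regardless of which test ran.
#'
#' @param a,b numeric vectors, each of length >= 3.
#' @param alphaNormal significance level of the normality gate.
#' @return List with `p_value`, `test_used` ("t" or "wilcoxon"),
#'   `effect_size` (Cohen's d).
#' @export
groupCompare <- function(a, b, alphaNormal = 0.05) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3 || length(b) < 3) stop("each group needs n >= 3")
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) stop("zero pooled variance: effect size undefined")
  d <- (mean(a) - mean(b)) / sqrt(sp2)
  normal <- function(x) {
    if (stats::sd(x) == 0) return(FALSE)
    stats::shapiro.test(x)$p.value >= alphaNormal
  }
  if (normal(a) && normal(b)) {
    p <- stats::t.test(a, b, var.equal = TRUE)$p.value
    used <- "t"
  } else {
    p <- stats::wilcox.test(a, b, exact = FALSE)$p.value
    used <- "wilcoxon"
  }
  list(p_value = p, test_used = used, effect_size = d)
}

#' Spearman rank correlation
#'
#' Rank correlation (average ranks for ties) between an objective feature
#' and a clinical scale, used as the validity measure.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return List with `rho` and `p_value`.
#' @export
spearmanValidity <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4) stop("need n >= 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: rank correlation undefined")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

.t2PowerFixed <- function(d, n1, n2, alpha, twoSided) {
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  if (twoSided) {
    tc <- stats::qt(1 - alpha / 2, df)
    (1 - stats::pt(tc, df, ncp)) + stats::pt(-tc, df, ncp)
  } else {
    tc <- stats::qt(1 - alpha, df)
    1 - stats::pt(tc, df, ncp)
  }
}

#' Minimum detectable effect size of a two-sample t-test
#'
#' The smallest Cohen's d at which a two-sample t-test with group sizes
#' `n1`, `n2` (df = n1 + n2 - 2, noncentrality `d * sqrt(n1 n2/(n1+n2))`)
#' attains the target power at significance level `alpha`. Solved by
#' bisection to 1e-6.
#'
#' @param n1,n2 group sizes (>= 2).
#' @param power target power (default 0.80).
#' @param alpha significance level (default 0.05).
#' @param twoSided two-sided test (default TRUE).
#' @return Cohen's d.
#' @examples
#' minDetectableEffect(14, 41)  # ~0.88
#' @export
minDetectableEffect <- function(n1, n2, power = 0.80, alpha = 0.05,
                                twoSided = TRUE) {
  stopifnot(n1 >= 2, n2 >= 2, power > 0, power < 1)
  lo <- 0; hi <- 1
  while (.t2PowerFixed(hi, n1, n2, alpha, twoSided) < power) hi <- hi * 2
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (.t2PowerFixed(mid, n1, n2, alpha, twoSided) < power) lo <- mid
    else hi <- mid
  }
  (lo + hi) / 2
}

#' Per-feature group statistics table
#'
#' For every catalog feature with enough data: group means and SDs,
#' Cohen's d, the gated group-comparison p-value, and Spearman correlations
#' against total and upper-limb SARA scores.
#'
#' @param ft an [AtaxiaFeatureTable-class].
#' @return data.frame with one row per feature.
#' @export
groupStatsTable <- function(ft) {
  X <- featureMatrix(ft)
  sd_ <- subjectData(ft)
  ata <- sd_$group == "ataxic"
  rows <- lapply(colnames(X), function(f) {
    va <- X[ata, f]; vb <- X[!ata, f]
    gc <- tryCatch(groupCompare(va, vb), error = function(e) NULL)
    spT <- tryCatch(spearmanValidity(X[, f], sd_$sara_total),
                    error = function(e) NULL)
    spU <- tryCatch(spearmanValidity(X[, f], sd_$sara_ul_sum),
                    error = function(e) NULL)
    data.frame(
      feature = f,
      mean_ataxic = mean(va, na.rm = TRUE), sd_ataxic = stats::sd(va, na.rm = TRUE),
      mean_control = mean(vb, na.rm = TRUE), sd_control = stats::sd(vb, na.rm = TRUE),
      effect_size = if (is.null(gc)) NA_real_ else gc$effect_size,
      p_value = if (is.null(gc)) NA_real_ else gc$p_value,
      test_used = if (is.null(gc)) NA_character_ else gc$test_used,
      rho_sara_total = if (is.null(spT)) NA_real_ else spT$rho,
      rho_sara_ul = if (is.null(spU)) NA_real_ else spU$rho,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
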