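## Group-level inference: covariate residualization, one-way ANOVA with
## pooled post hoc t-tests, the gender chi-square, the study's exact
## Bonferroni families, FDR, and partial correlation with covariates.

#' Residualize a metric on age and gender
#'
#' OLS residuals of the metric on an intercept, age, and gender coded
#' 0/1, pooled across all subjects. A constant covariate column is
#' dropped with a warning.
#'
#' @param values numeric metric vector.
#' @param age numeric covariate.
#' @param gender two-level factor/character (coded 0/1 internally).
#' @return residual vector.
#' @export
residualize <- function(values, age, gender) {
  stop_if_not(!anyNA(values) && !anyNA(age) && !anyNA(gender),
              "missing values in metric or covariates")
  g01 <- as.numeric(factor(gender)) - 1
  X <- cbind(intercept = 1, age = age, gender = g01)
  keep <- c(TRUE, apply(X[, -1L, drop = FALSE], 2L, function(col)
    stats::sd(col) > 0))
  if (!all(keep)) {
    warning(sprintf("dropping constant covariate(s): %s",
                    paste(colnames(X)[!keep], collapse = ", ")))
    X <- X[, keep, drop = FALSE]
  }
  unname(qr.resid(qr(X), values))
}

#' One-way ANOVA
#'
#' Classical between/within mean-square F ratio with its p-value from the
#' F distribution (equal variances assumed). Zero within-group variance
#' with distinct means yields F = Inf, p = 0.
#'
#' @param values numeric response.
#' @param groups group labels (2 or more levels, each with 2+ members).
#' @return list with `f`, `p`, `df1`, `df2`.
#' @export
oneway_anova <- function(values, groups) {
  groups <- as.factor(groups)
  stop_if_not(nlevels(groups) >= 2L, "need at least 2 groups")
  stop_if_not(all(table(groups) >= 2L), "every group needs 2+ members")
  fit <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  list(f = unname(fit$statistic), p = fit$p.value,
       df1 = unname(fit$parameter[1L]), df2 = unname(fit$parameter[2L]))
}

#' Pairwise two-sample t-tests between groups
#' @param values numeric response.
#' @param groups group labels.
#' @param pooled pooled-variance (default) or Welch.
#' @return data frame: group_1, group_2, t, p.
#' @export
pairwise_t <- function(values, groups, pooled = TRUE) {
  groups <- as.factor(groups)
  levs <- levels(groups)
  out <- list()
  for (i in seq_len(length(levs) - 1L)) {
    for (j in (i + 1L):length(levs)) {
      tt <- stats::t.test(values[groups == levs[i]],
                          values[groups == levs[j]], var.equal = pooled)
      out[[length(out) + 1L]] <- data.frame(
        group_1 = levs[i], group_2 = levs[j],
        t = unname(tt$statistic), p = tt$p.value)
    }
  }
  do.call(rbind, out)
}

#' Gender chi-square test
#'
#' Pearson chi-square without continuity correction on a groups x gender
#' contingency table.
#'
#' @param counts matrix of nonnegative integer counts with positive
#'   margins (e.g. 3 groups x M/F).
#' @return list with `chi2`, `p`, `df`.
#' @export
gender_chisq <- function(counts) {
  counts <- as.matrix(counts)
  stop_if_not(all(counts >= 0) && all(counts == round(counts)),
              "counts must be nonnegative integers")
  stop_if_not(all(rowSums(counts) > 0) && all(colSums(counts) > 0),
              "zero margin in contingency table")
  ct <- stats::chisq.test(counts, correct = FALSE)
  list(chi2 = unname(ct$statistic), p = ct$p.value,
       df = unname(ct$parameter))
}

#' Multiple-comparison correction with fixed families
#'
#' Bonferroni compares each p-value to 0.05 / `family_size` using the
#' a-priori family denominator (e.g. 7 for the seven global metrics; 40,
#' 8 and 64 for the three correlation families). FDR is Benjamini-
#' Hochberg at q = 0.05.
#'
#' @param p numeric p-values in [0, 1].
#' @param method `"bonferroni"` or `"fdr"`.
#' @param family_size Bonferroni denominator (required for bonferroni;
#'   warned about if smaller than `length(p)`).
#' @param alpha base level (default 0.05).
#' @return list with `significant` (logical), `threshold` (bonferroni)
#'   or `p_adjusted` (fdr), plus the recorded `family_size`/`method`.
#' @export
correct_p <- function(p, method = c("bonferroni", "fdr"), family_size = NULL,
                      alpha = 0.05) {
  method <- match.arg(method)
  stop_if_not(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  if (method == "bonferroni") {
    stop_if_not(!is.null(family_size) && family_size > 0,
                "bonferroni requires a positive family_size")
    if (family_size < length(p)) {
      warning(sprintf("family_size %d is smaller than the %d tests supplied",
                      family_size, length(p)))
    }
    thr <- alpha / family_size
    list(method = "bonferroni", family_size = family_size, threshold = thr,
         significant = p < thr)
  } else {
    padj <- stats::p.adjust(p, method = "BH")
    list(method = "fdr", p_adjusted = padj, significant = padj <= alpha)
  }
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the OLS residuals of `x` and `y` on the
#' covariates (plus intercept); the p-value comes from the t distribution
#' with n - 2 - q degrees of freedom, q the number of non-constant
#' covariates.
#'
#' @param x,y numeric vectors.
#' @param covariates matrix/data frame of covariates (constant columns
#'   are dropped, reducing to plain Pearson correlation if none remain).
#' @param family_size optional Bonferroni family annotation.
#' @return list with `r`, `p`, `df`, `family_size`.
#' @export
partial_corr <- function(x, y, covariates, family_size = NULL) {
  Zdf <- as.data.frame(covariates)
  Z <- vapply(Zdf, function(col) {
    if (is.numeric(col)) as.numeric(col) else as.numeric(factor(col))
  }, numeric(nrow(Zdf)))
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1L)
  keep <- apply(Z, 2L, function(col) stats::sd(col) > 0)
  Z <- Z[, keep, drop = FALSE]
  q <- ncol(Z)
  n <- length(x)
  stop_if_not(n > q + 2L, "need n > number of covariates + 2")
  X <- cbind(1, Z)
  rx <- qr.resid(qr(X), x)
  ry <- qr.resid(qr(X), y)
  stop_if_not(stats::sd(rx) > 0 && stats::sd(ry) > 0,
              "degenerate residual variance")
  r <- stats::cor(rx, ry)
  df <- n - 2L - q
  tval <- r * sqrt(df) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(-abs(tval), df), df = df,
       family_size = family_size)
}

#' Omnibus group comparison of metric AUCs with correction and post hocs
#'
#' The metric-level inference pipeline: residualize each metric on
#' age/gender, one-way ANOVA across groups, multiple-comparison
#' correction over the metric family, and pooled post hoc t-tests for
#' metrics that survive.
#'
#' @param metrics data frame or matrix, one column per metric (e.g. the
#'   seven global AUCs), one row per subject.
#' @param groups group label per subject.
#' @param age,gender covariates to residualize on (skipped if NULL).
#' @param method,family_size see [correct_p()]; family defaults to the
#'   number of metrics.
#' @return data frame with metric, f, p, threshold/adjusted p,
#'   significant, and post hoc t/p per group pair (wide columns).
#' @export
group_metric_tests <- function(metrics, groups, age = NULL, gender = NULL,
                               method = "bonferroni", family_size = NULL) {
  metrics <- as.data.frame(metrics)
  family_size <- family_size %||% ncol(metrics)
  res <- lapply(names(metrics), function(mn) {
    v <- metrics[[mn]]
    if (!is.null(age) && !is.null(gender)) v <- residualize(v, age, gender)
    an <- oneway_anova(v, groups)
    ph <- pairwise_t(v, groups)
    list(metric = mn, f = an$f, p = an$p, posthoc = ph)
  })
  p <- vapply(res, `[[`, 0, "p")
  corr <- correct_p(p, method = method, family_size = family_size)
  out <- data.frame(metric = vapply(res, `[[`, "", "metric"),
                    f = vapply(res, `[[`, 0, "f"), p = p,
                    significant = corr$significant)
  if (corr$method == "bonferroni") out$threshold <- corr$threshold
  else out$p_fdr <- corr$p_adjusted
  ph <- res[[1L]]$posthoc
  for (k in seq_len(nrow(ph))) {
    pair <- sprintf("%s_vs_%s", ph$group_1[k], ph$group_2[k])
    out[[paste0("t_", pair)]] <-
      vapply(res, function(r) r$posthoc$t[k], 0)
    out[[paste0("p_", pair)]] <-
      vapply(res, function(r) r$posthoc$p[k], 0)
  }
  out
}
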