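# Cohort-level statistics: age-at-scan residualization, correlation with
# gestational age at birth, normality-gated group comparison with FDR
# control, and repeated stratified cross-validated logistic
# classification.

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the sample-size-corrected skewness z-score (D'Agostino 1970)
#' and kurtosis z-score (Anscombe-Glynn 1983) into
#' `K2 = z1^2 + z2^2 ~ chi^2(2)` under normality.
#'
#' @param x Numeric vector, n >= 8.
#' @return List with `statistic` (K2) and `p.value`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson test requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  g1 <- mean((x - m)^3) / m2^1.5
  g2 <- mean((x - m)^4) / m2^2

  # skewness z (D'Agostino)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * asinh(y / alpha)

  # kurtosis z (Anscombe-Glynn)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - eb2) / sqrt(vb2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  z2 <- ((1 - 2 / (9 * a)) -
         ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(statistic = k2, p.value = pchisq(k2, df = 2, lower.tail = FALSE))
}

#' Remove the linear age-at-scan effect from each metric
#'
#' Ordinary least squares of each metric on GA at scan over the whole
#' sample; the residuals (observed minus fitted) feed all downstream
#' analyses.
#'
#' @param cohort A `cohort_table` with the six metric columns filled.
#' @param metrics Metric column names (default the six PS metrics).
#' @return A `residualized_metrics`: list with `residuals` (n x metric
#'   matrix), `coef` (2 x metric: intercept, slope), `metrics`,
#'   `subject_id`.
#' @export
residualize <- function(cohort, metrics = PS_METRICS) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (nrow(cohort) < 3) stop("residualization requires >= 3 subjects")
  if (sd(cohort$ga_scan) == 0) stop("GA at scan is constant")
  miss <- setdiff(metrics, names(cohort))
  if (length(miss))
    stop("cohort lacks metric column(s): ", paste(miss, collapse = ", "))
  res <- matrix(NA_real_, nrow(cohort), length(metrics),
                dimnames = list(NULL, metrics))
  cf <- matrix(NA_real_, 2, length(metrics),
               dimnames = list(c("intercept", "slope"), metrics))
  for (m in metrics) {
    fit <- lm(cohort[[m]] ~ cohort$ga_scan)
    res[, m] <- stats::residuals(fit)
    cf[, m] <- coef(fit)
  }
  structure(list(residuals = res, coef = cf, metrics = metrics,
                 subject_id = cohort$subject_id),
            class = "residualized_metrics")
}

#' @export
print.residualized_metrics <- function(x, ...) {
  cat(sprintf("Residualized metrics: %d subjects x %d metrics (slopes: %s)\n",
              nrow(x$residuals), length(x$metrics),
              paste(sprintf("%s %.3g", x$metrics, x$coef["slope", ]),
                    collapse = ", ")))
  invisible(x)
}

#' Pearson correlation of residualized metrics with GA at birth
#'
#' @param resid A `residualized_metrics` from [residualize()].
#' @param cohort The matching `cohort_table`.
#' @return Data frame with columns `metric`, `r`, `p`.
#' @export
correlate_with_ga <- function(resid, cohort) {
  stopifnot(inherits(resid, "residualized_metrics"),
            inherits(cohort, "cohort_table"))
  if (nrow(cohort) < 3) stop("correlation requires n >= 3")
  out <- lapply(resid$metrics, function(m) {
    v <- resid$residuals[, m]
    if (sd(v) == 0) stop("zero-variance metric: ", m)
    ct <- cor.test(v, cohort$ga_birth, method = "pearson")
    data.frame(metric = m, r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Group comparison with a normality gate and FDR control
#'
#' Per metric, a D'Agostino-Pearson omnibus test on the pooled residuals
#' gates the choice between a two-sample equal-variance t-test (normal)
#' and the Mann-Whitney U test (non-normal); raw p-values are adjusted
#' across metrics by the Benjamini-Hochberg step-up procedure. With
#' fewer than 8 subjects in either group the normality test is
#' unreliable and the Mann-Whitney branch is used with a warning.
#'
#' @param resid A `residualized_metrics`.
#' @param cohort The matching `cohort_table` (groups `term`/`preterm`).
#' @param alpha_norm Normality-gate level (default 0.05).
#' @param var_equal Use the equal-variance t statistic (default TRUE).
#' @return Data frame with columns `metric`, `normality_p`, `test`,
#'   `statistic` (t, or U for the Mann-Whitney branch, oriented
#'   preterm vs term), `p`, `p_fdr`.
#' @export
group_compare <- function(resid, cohort, alpha_norm = 0.05,
                          var_equal = TRUE) {
  stopifnot(inherits(resid, "residualized_metrics"),
            inherits(cohort, "cohort_table"))
  pre <- cohort$group == "preterm"
  ter <- cohort$group == "term"
  if (!any(pre) || !any(ter)) stop("both groups must be non-empty")
  small <- min(sum(pre), sum(ter)) < 8
  if (small)
    warning("a group has fewer than 8 subjects; normality test unreliable, using Mann-Whitney throughout")
  rows <- lapply(resid$metrics, function(m) {
    v <- resid$residuals[, m]
    norm_p <- if (small) NA_real_ else dagostino_pearson(v)$p.value
    use_t <- !small && norm_p >= alpha_norm
    if (use_t) {
      tt <- t.test(v[pre], v[ter], var.equal = var_equal)
      data.frame(metric = m, normality_p = norm_p, test = "t",
                 statistic = unname(tt$statistic), p = tt$p.value,
                 stringsAsFactors = FALSE)
    } else {
      wt <- suppressWarnings(wilcox.test(v[pre], v[ter], exact = FALSE))
      data.frame(metric = m, normality_p = norm_p, test = "mann-whitney",
                 statistic = unname(wt$statistic), p = wt$p.value,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- p.adjust(out$p, method = "BH")
  out
}

stratified_folds <- function(y, n_folds) {
  # per-class cyclic assignment of a random permutation: every fold's
  # class count deviates from proportionality by at most one subject
  fold <- integer(length(y))
  for (cl in unique(y)) {
    i <- which(y == cl)
    fold[i[sample.int(length(i))]] <- rep_len(seq_len(n_folds), length(i))
  }
  fold
}

fit_logistic <- function(X, y) {
  suppressWarnings(glm.fit(cbind(1, X), y, family = binomial()))$coefficients
}

#' Repeated stratified cross-validated logistic classification
#'
#' Discriminates preterm from term subjects with an unregularized
#' logistic regression on residualized metrics. Each of `n_repeats`
#' repetitions draws a fresh stratified `n_folds`-fold partition (class
#' proportions preserved to within one subject per fold); features are
#' standardized inside each training fold, the held-out fold is
#' predicted, and accuracy is aggregated over all folds x repetitions.
#'
#' @param resid A `residualized_metrics`.
#' @param cohort The matching `cohort_table`.
#' @param feature_sets Named list of metric subsets; default the six
#'   univariate models plus `dti` (MD/FA/AD/RD widths), `noddi`
#'   (NDI/ODI widths) and `all`.
#' @param n_repeats,n_folds Cross-validation design (defaults 30 and 10).
#' @param seed Master RNG seed; each repetition's partition derives from
#'   it deterministically.
#' @return Data frame with `feature_set`, `accuracy_mean`, `accuracy_sd`
#'   (mean and sd over the `n_repeats * n_folds` fold-level accuracies).
#' @export
cv_classify <- function(resid, cohort, feature_sets = NULL,
                        n_repeats = 30, n_folds = 10, seed = 1L) {
  stopifnot(inherits(resid, "residualized_metrics"),
            inherits(cohort, "cohort_table"))
  if (is.null(feature_sets)) {
    feature_sets <- c(setNames(as.list(PS_METRICS), PS_METRICS),
                      list(dti = c("psmd", "psfa", "psad", "psrd"),
                           noddi = c("psndi", "psodi"),
                           all = PS_METRICS))
  }
  y <- as.integer(cohort$group == "preterm")
  if (n_folds > min(table(y)))
    stop("n_folds exceeds the smaller group size; stratification impossible")
  acc <- lapply(feature_sets, function(fs)
    matrix(NA_real_, n_repeats, n_folds))
  with_local_seed(seed, {
    for (r in seq_len(n_repeats)) {
      fold <- stratified_folds(y, n_folds)
      if (any(tapply(y, fold, function(v) length(unique(v))) < 2))
        stop("internal error: a fold contains a single class")
      for (k in seq_len(n_folds)) {
        tr <- fold != k
        for (fi in seq_along(feature_sets)) {
          X <- resid$residuals[, feature_sets[[fi]], drop = FALSE]
          mu <- colMeans(X[tr, , drop = FALSE])
          sdv <- apply(X[tr, , drop = FALSE], 2, sd)
          sdv[sdv == 0] <- 1
          Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
          cf <- fit_logistic(Xs[tr, , drop = FALSE], y[tr])
          eta <- drop(cbind(1, Xs[!tr, , drop = FALSE]) %*% cf)
          acc[[fi]][r, k] <- mean((eta > 0) == (y[!tr] == 1L))
        }
      }
    }
  })
  data.frame(feature_set = names(feature_sets),
             accuracy_mean = vapply(acc, mean, 0),
             accuracy_sd = vapply(acc, sd, 0),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Full cohort statistical report
#'
#' Runs [residualize()], [correlate_with_ga()], [group_compare()] and
#' [cv_classify()] and assembles the per-metric report: correlation with
#' GA at birth, normality-gated group test with FDR-adjusted p, and
#' cross-validated classification accuracy.
#'
#' @param cohort A `cohort_table` with metric columns.
#' @param alpha_norm,var_equal Passed to [group_compare()].
#' @param n_repeats,n_folds,seed Passed to [cv_classify()].
#' @param feature_sets Passed to [cv_classify()] (default adds the
#'   multivariate dti/noddi/all models).
#' @return A `stat_report`: list with `table` (per-metric data frame),
#'   `multivariate` (accuracy rows for multi-metric models),
#'   `residualized`, and the settings used.
#' @export
stat_report <- function(cohort, alpha_norm = 0.05, var_equal = TRUE,
                        n_repeats = 30, n_folds = 10, seed = 1L,
                        feature_sets = NULL) {
  resid <- residualize(cohort)
  corr <- correlate_with_ga(resid, cohort)
  names(corr)[names(corr) == "p"] <- "r_p"
  grp <- group_compare(resid, cohort, alpha_norm, var_equal)
  cv <- cv_classify(resid, cohort, feature_sets, n_repeats, n_folds, seed)
  tab <- merge(merge(corr, grp, by = "metric"),
               cv[cv$feature_set %in% PS_METRICS,
                  c("feature_set", "accuracy_mean", "accuracy_sd")],
               by.x = "metric", by.y = "feature_set", all.x = TRUE)
  tab <- tab[match(PS_METRICS[PS_METRICS %in% tab$metric], tab$metric), ]
  rownames(tab) <- NULL
  structure(list(table = tab,
                 multivariate = cv[!cv$feature_set %in% PS_METRICS, ],
                 residualized = resid,
                 settings = list(alpha_norm = alpha_norm,
                                 var_equal = var_equal,
                                 n_repeats = n_repeats, n_folds = n_folds,
                                 seed = seed)),
            class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  cat("Cohort statistics (metrics residualized on GA at scan)\n")
  cat(sprintf("%-7s %22s %26s %18s\n", "Metric", "Corr. with GA birth",
              "Group comparison", "Classification"))
  for (i in seq_len(nrow(x$table))) {
    r <- x$table[i, ]
    stat_lab <- if (r$test == "t") "t" else "u"
    cat(sprintf("%-7s r = %5.2f, p = %-9.3g %s = %8.6g, p = %-9.3g %.2f +/- %.2f\n",
                toupper(r$metric), r$r, r$r_p, stat_lab, r$statistic,
                r$p_fdr, r$accuracy_mean, r$accuracy_sd))
  }
  if (nrow(x$multivariate)) {
    cat("Multivariate models:\n")
    for (i in seq_len(nrow(x$multivariate))) {
      r <- x$multivariate[i, ]
      cat(sprintf("  %-6s accuracy %.2f +/- %.2f\n", r$feature_set,
                  r$accuracy_mean, r$accuracy_sd))
    }
  }
  invisible(x)
}
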