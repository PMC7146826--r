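test_that("the omnibus normality statistic matches an external reference", {
  # frozen reference values from an independent implementation of the
  # D'Agostino-Pearson K^2 test on fixed samples
  x1 <- c(-1.423825, 1.263728, -0.870662, -0.259173, -0.075343, -0.740885,
          -1.367793, 0.648893, 0.361058, -1.952863, 2.34741, 0.968497,
          -0.759387, 0.902198, -0.466953, -0.06069, 0.788844, -1.256668,
          0.575858, 1.398979, 1.322298, -0.299699, 0.902919, -1.621583,
          -0.158189, 0.449484, -1.343601, -0.081688, 1.72474, 2.618159,
          0.777361, 0.828633, -0.958988, -1.209388, -1.412292, 0.541547,
          0.751939, -0.65876, -1.228675, 0.257558)
  r1 <- dagostino_pearson(x1)
  expect_equal(r1$statistic, 1.1510510919, tolerance = 1e-9)
  expect_equal(r1$p.value, 0.5624092192, tolerance = 1e-9)

  x2 <- c(0.43398, 2.399746, 1.087537, 3.260049, 0.579917, 0.502018,
          0.508296, 0.402321, 0.009372, 0.786646, 0.117334, 0.065405,
          1.038062, 0.054279, 0.912369, 1.039891, 0.458251, 1.19488,
          4.125331, 2.134233, 0.386032, 0.086451, 1.348715, 0.754572,
          1.200541, 0.150635, 1.354366, 0.555525, 0.159277, 0.169183,
          1.174806, 0.291176, 1.43149, 0.587044, 0.308978, 4.469679,
          0.100007, 0.180713, 0.828289, 0.973081, 1.044074, 0.265799,
          0.381225, 0.789906, 0.175851, 0.283987, 0.388868, 0.210685,
          0.95525, 0.605975, 0.022568, 0.356131, 1.50837, 2.865679,
          0.424387, 0.595436, 0.223505, 3.742125, 0.309818, 0.132646)
  r2 <- dagostino_pearson(x2)
  expect_equal(r2$statistic, 36.9912953144, tolerance = 1e-9)
  expect_equal(r2$p.value, 9.2777e-09, tolerance = 1e-4)

  expect_error(dagostino_pearson(rnorm(5)), "n >= 8")
})

test_that("residualization removes the age-at-scan effect exactly", {
  co <- simulate_cohort(cohort_spec(seed = 2))
  # metric that is an exact linear function of GA at scan
  co$psmd <- 2 * co$ga_scan + 1
  rz <- residualize(co)
  expect_lt(max(abs(rz$residuals[, "psmd"])), 1e-10)
  expect_equal(unname(rz$coef[, "psmd"]), c(1, 2), tolerance = 1e-10)

  # metric independent of GA at scan (constant, no noise):
  # residual = metric - mean = 0
  co$psfa <- rep(0.32, nrow(co))
  rz <- residualize(co)
  expect_equal(rz$residuals[, "psfa"], co$psfa - mean(co$psfa),
               tolerance = 1e-10)

  # residuals centred and orthogonal to GA at scan
  rz <- residualize(simulate_cohort(cohort_spec(seed = 3)))
  for (m in colnames(rz$residuals)) {
    expect_lt(abs(sum(rz$residuals[, m])), 1e-8)
    expect_lt(abs(cor(rz$residuals[, m],
                      simulate_cohort(cohort_spec(seed = 3))$ga_scan)),
              1e-10)
  }

  # known generator slope recovered within 3 standard errors
  co4 <- simulate_cohort(cohort_spec(age_slope = c(psmd = 0.01, psfa = 0,
                                                   psad = 0, psrd = 0,
                                                   psndi = 0, psodi = 0),
                                     seed = 4))
  grp <- as.integer(co4$group == "preterm")
  fit <- summary(lm(co4$psmd ~ co4$ga_scan + grp))
  expect_lt(abs(fit$coefficients[2, 1] - 0.01),
            3 * fit$coefficients[2, 2])

  co_flat <- simulate_cohort(cohort_spec(seed = 5))
  co_flat$ga_scan <- rep(40, nrow(co_flat))
  expect_error(residualize(co_flat), "constant")
})

test_that("correlations with GA at birth behave in the exact limits", {
  co <- simulate_cohort(cohort_spec(seed = 6))
  rz <- residualize(co)
  # residuals engineered to equal GA at birth -> r = 1
  rz$residuals[, "psmd"] <- co$ga_birth
  rz$residuals[, "psfa"] <- -co$ga_birth + rnorm(nrow(co), 0, 1e-8)
  out <- correlate_with_ga(rz, co)
  expect_equal(out$r[out$metric == "psmd"], 1, tolerance = 1e-12)
  expect_equal(out$r[out$metric == "psfa"], -1, tolerance = 1e-6)
  expect_lt(out$p[out$metric == "psmd"], 1e-100)

  rz$residuals[, "psad"] <- 0
  expect_error(correlate_with_ga(rz, co), "zero-variance")
})

test_that("sample correlations concentrate inside the Fisher interval", {
  # population correlation about -0.5 at n = 135: nearly all seeds must
  # land within the +/- 0.15 Fisher-z band
  hits <- 0
  for (s in 1:40) {
    set.seed(s)
    n <- 135
    ga <- runif(n, 24, 42)
    # population correlation exactly -0.5 by construction
    y <- -0.5 * scale(ga)[, 1] + rnorm(n, 0, sqrt(1 - 0.25))
    r <- cor(y, ga)
    if (r > -0.65 && r < -0.35) hits <- hits + 1
  }
  expect_gte(hits, 38)
})

test_that("BH adjustment matches the explicit step-up definition", {
  p <- c(0.01, 0.02, 0.03, 0.04, 0.05, 0.9)
  expect_equal(p.adjust(p, "BH"), bh_oracle(p))
  set.seed(13)
  for (i in 1:100) {
    pv <- sample(seq(0.01, 1, by = 0.01), 6, replace = TRUE)
    adj <- p.adjust(pv, "BH")
    expect_equal(adj, bh_oracle(pv))
    expect_true(all(adj >= pv))
    o <- order(pv)
    expect_true(all(diff(adj[o]) >= -1e-15))
  }
})

test_that("group comparison gates on normality and controls the null", {
  co <- simulate_cohort(cohort_spec(seed = 21))
  rz <- residualize(co)
  out <- group_compare(rz, co)
  expect_equal(out$metric, c("psmd", "psfa", "psad", "psrd", "psndi",
                             "psodi"))
  expect_true(all(out$p_fdr >= out$p))
  expect_true(all(out$test %in% c("t", "mann-whitney")))
  # the gate is consistent with the normality p-value
  expect_equal(out$test == "t", out$normality_p >= 0.05)

  # mirrored data: t statistic 0, p = 1
  n <- 30
  df <- data.frame(subject_id = sprintf("m%02d", 1:(2 * n)),
                   group = rep(c("term", "preterm"), each = n),
                   ga_birth = rep(c(39, 29), each = n),
                   ga_scan = rep(runif(n, 39, 43), 2),
                   stringsAsFactors = FALSE)
  set.seed(1)
  base <- rnorm(n, 0.5, 0.05)
  for (m in c("psmd", "psfa", "psad", "psrd", "psndi", "psodi"))
    df[[m]] <- rep(base, 2)
  co_m <- as_cohort_table(df)
  rz_m <- residualize(co_m)
  out_m <- group_compare(rz_m, co_m)
  tm <- out_m[out_m$test == "t", ]
  if (nrow(tm)) {
    expect_lt(max(abs(tm$statistic)), 1e-8)
    expect_equal(tm$p, rep(1, nrow(tm)), tolerance = 1e-8)
  }

  # tiny group: Mann-Whitney fallback with a warning
  co_small <- as_cohort_table(df[c(1:4, 31:60), ])
  expect_warning(out_s <- group_compare(residualize(co_small), co_small),
                 "fewer than 8")
  expect_true(all(out_s$test == "mann-whitney"))
})

test_that("type-I error stays controlled on null cohorts", {
  # no group effect: same locations and scales for both groups
  null_loc <- list(term = pswm:::TABLE2_DEFAULTS$loc$term,
                   preterm = pswm:::TABLE2_DEFAULTS$loc$term)
  null_scale <- list(term = pswm:::TABLE2_DEFAULTS$scale$term,
                     preterm = pswm:::TABLE2_DEFAULTS$scale$term)
  frac <- sapply(1:200, function(s) {
    co <- simulate_cohort(cohort_spec(loc = null_loc, scale = null_scale,
                                      seed = 1000 + s))
    out <- group_compare(residualize(co), co)
    mean(out$p_fdr < 0.05)
  })
  expect_lte(mean(frac), 0.05)
})

test_that("stratified folds preserve class proportions within one subject", {
  set.seed(17)
  for (i in 1:50) {
    n1 <- sample(20:80, 1); n0 <- sample(20:80, 1)
    k <- sample(2:10, 1)
    y <- sample(rep(c(0, 1), c(n0, n1)))
    fold <- pswm:::stratified_folds(y, k)
    for (f in seq_len(k)) {
      got <- sum(y[fold == f])
      expected <- n1 * sum(fold == f) / (n0 + n1)
      expect_lte(abs(got - expected), 1)
    }
  }
})

test_that("cross-validated classification hits the separable and null limits", {
  co <- separable_cohort()
  rz <- residualize(co)
  cv <- cv_classify(rz, co, feature_sets = list(psmd = "psmd"),
                    n_repeats = 5, n_folds = 5, seed = 2)
  expect_equal(cv$accuracy_mean, 1)
  expect_equal(cv$accuracy_sd, 0)

  # permuted labels: chance level
  set.seed(3)
  co_perm <- co
  co_perm$group <- sample(co$group)
  class(co_perm) <- class(co)
  rz_p <- residualize(co_perm)
  cv_p <- cv_classify(rz_p, co_perm, feature_sets = list(psmd = "psmd"),
                      n_repeats = 30, n_folds = 10, seed = 2)
  expect_gte(cv_p$accuracy_mean, 0.30)
  expect_lte(cv_p$accuracy_mean, 0.70)

  expect_error(cv_classify(rz, co, n_folds = 25, seed = 1),
               "exceeds the smaller group")
})

test_that("a single informative feature is not beaten by adding noise ones", {
  # sample large enough that both models approach the Bayes rate of the
  # generating distribution
  co <- separable_cohort(n_per = 80, margin = 2, seed = 9)
  rz <- residualize(co)
  cv <- cv_classify(rz, co,
                    feature_sets = list(uni = "psmd",
                                        all = c("psmd", "psfa", "psad",
                                                "psrd", "psndi", "psodi")),
                    n_repeats = 20, n_folds = 10, seed = 4)
  expect_lt(abs(cv$accuracy_mean[cv$feature_set == "all"] -
                  cv$accuracy_mean[cv$feature_set == "uni"]), 0.05)
})

test_that("the full report is deterministic given the seed", {
  co <- simulate_cohort(cohort_spec(seed = 33))
  r1 <- stat_report(co, n_repeats = 3, seed = 7)
  r2 <- stat_report(co, n_repeats = 3, seed = 7)
  expect_identical(r1$table, r2$table)
  expect_identical(r1$multivariate, r2$multivariate)
  expect_true(all(r1$table$accuracy_mean >= 0 &
                    r1$table$accuracy_mean <= 1))
})
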