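test_that("gradient schemes have the requested layout and are seeded", {
  gt <- make_gradient_scheme(8, list(c(750, 64)), seed = 3)
  expect_length(gt, 72)
  expect_equal(sum(gt$bvals == 0), 8)
  expect_equal(sum(gt$bvals == 750), 64)

  # minimal 6-direction design is full rank
  g6 <- make_gradient_scheme(1, list(c(1000, 6)), seed = 4)
  gdw <- g6$bvecs[, g6$bvals > 0]
  M <- rbind(gdw[1, ]^2, gdw[2, ]^2, gdw[3, ]^2,
             gdw[1, ] * gdw[2, ], gdw[1, ] * gdw[3, ], gdw[2, ] * gdw[3, ])
  expect_equal(qr(M)$rank, 6L)

  expect_error(make_gradient_scheme(0, list(c(750, 6))), "b=0")
  expect_error(make_gradient_scheme(1, list(c(750, 0))), "fewer than 1")

  # determinism and near-uniformity (no two directions closer than a
  # plausible packing bound for 64 antipodal pairs)
  gt2 <- make_gradient_scheme(8, list(c(750, 64)), seed = 3)
  expect_identical(gt, gt2)
  v <- gt$bvecs[, gt$bvals > 0]
  cosang <- abs(crossprod(v))
  diag(cosang) <- 0
  expect_lt(max(cosang), cos(10 * pi / 180))
})

test_that("noiseless forward signals follow the tensor model exactly", {
  # single voxel, g along the principal axis: S = exp(-b * 1.7e-3)
  g1 <- gradient_table(c(0, 1000), cbind(c(0, 0, 0), c(1, 0, 0)))
  spec <- phantom_spec(c(1, 1, 1),
                       list(phantom_tract("x", c(1, 1), radius = 1,
                                          profile = "flat")),
                       s0 = 1, noise_model = "none")
  sim <- simulate_dwi(spec, g1)
  expect_equal(sim$dwi$data[1, 1, 1, 2], exp(-1.7), tolerance = 1e-12)

  # isotropic CSF-like background: identical signal in every direction
  gt <- fix_small_scheme()
  spec_bg <- phantom_spec(c(2, 2, 2),
                          list(phantom_tract("x", c(-5, -5), radius = 1)),
                          background = 3.0, noise_model = "none")
  sim_bg <- simulate_dwi(spec_bg, gt)
  s750 <- sim_bg$dwi$data[1, 1, 1, gt$bvals == 750]
  expect_lt(max(s750) - min(s750), 1e-12)
  expect_equal(s750, rep(spec_bg$s0 * exp(-750e-3 * 3.0), length(s750)),
               tolerance = 1e-12)
})

test_that("ground-truth maps satisfy the eigenvalue identities", {
  spec <- tube_spec()
  gtm <- simulate_dwi(spec, fix_small_scheme())$ground_truth
  md <- gtm$MD$data; ad <- gtm$AD$data; rd <- gtm$RD$data; fa <- gtm$FA$data
  # MD = (AD + 2 RD) / 3 for the axially symmetric construction
  expect_equal(md, (ad + 2 * rd) / 3, tolerance = 1e-12)
  expect_true(all(ad >= rd))
  # isotropic voxels have FA exactly 0
  iso <- abs(ad - rd) < 1e-14
  expect_true(any(iso))
  expect_equal(max(fa[iso]), 0)
  expect_true(all(fa >= 0 & fa <= 1))
})

test_that("rician noise matches the analytic small-signal statistics", {
  # Monte-Carlo oracle for the Rician mean at snr = 30
  s0 <- 100; snr <- 30; sdn <- s0 / snr
  set.seed(99)
  mc <- mean(sqrt((s0 + rnorm(2e5, 0, sdn))^2 + rnorm(2e5, 0, sdn)^2))

  spec <- tube_spec(snr = snr, noise_model = "rician", seed = 11)
  gt <- fix_small_scheme()
  sim <- simulate_dwi(spec, gt)
  tract <- sim$ground_truth$FA$data > 0.5
  b0 <- sim$dwi$data[, , , which(gt$bvals == 0)[1]]
  vals <- b0[tract]
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - mc), 3 * se)
})

test_that("identical seeds give bit-identical phantoms", {
  gt <- fix_small_scheme()
  s1 <- simulate_dwi(tube_spec(snr = 20, seed = 5), gt)
  s2 <- simulate_dwi(tube_spec(snr = 20, seed = 5), gt)
  expect_identical(s1$dwi$data, s2$dwi$data)
  s3 <- simulate_dwi(tube_spec(snr = 20, seed = 6), gt)
  expect_false(identical(s1$dwi$data, s3$dwi$data))
})

test_that("custom mask construction follows erosion and exclusion rules", {
  spec <- tube_spec()
  # no rim: mask equals the (FA > 0.15) tract support
  tm <- make_template_and_mask(spec, rim = 0)
  expect_equal(tm$custom_mask$data, (tm$template_fa$data > 0.15) * 1)

  # rim 1: explicit 6-neighbourhood morphological erosion oracle
  tm1 <- make_template_and_mask(spec, rim = 1)
  m <- tm$custom_mask$data == 1
  d <- dim(m)
  ero <- array(FALSE, d)
  for (i in 2:(d[1] - 1)) for (j in 2:(d[2] - 1)) for (k in 2:(d[3] - 1))
    ero[i, j, k] <- m[i, j, k] && m[i - 1, j, k] && m[i + 1, j, k] &&
      m[i, j - 1, k] && m[i, j + 1, k] && m[i, j, k - 1] && m[i, j, k + 1]
  expect_equal(tm1$custom_mask$data == 1, ero)

  # excluded tract contributes nothing
  spec2 <- phantom_spec(c(20, 20, 8),
                        list(phantom_tract("x", c(6, 4), radius = 3,
                                           sigma = 1.4),
                             phantom_tract("x", c(14, 4), radius = 3,
                                           sigma = 1.4, excluded = TRUE)))
  tm2 <- make_template_and_mask(spec2, rim = 0)
  expect_equal(sum(tm2$custom_mask$data[, 10:20, ]), 0)
  expect_gt(sum(tm2$custom_mask$data[, 1:9, ]), 0)
})

test_that("synthetic cohorts track the published group medians", {
  # seed-averaged sample medians near the published term/preterm values
  meds <- t(sapply(1:30, function(s) {
    co <- simulate_cohort(cohort_spec(seed = s))
    c(term = median(co$psmd[co$group == "term"]),
      preterm = median(co$psmd[co$group == "preterm"]))
  }))
  expect_gt(mean(meds[, "term"]), 0.45)
  expect_lt(mean(meds[, "term"]), 0.55)
  expect_gt(mean(meds[, "preterm"]), 0.55)
  expect_lt(mean(meds[, "preterm"]), 0.65)
})

test_that("cohort generator is exact in the zero-noise limits", {
  zero_scale <- lapply(pswm:::TABLE2_DEFAULTS$scale, function(x) x * 0)
  # zero noise, zero slope: every term subject sits on the term location
  co <- simulate_cohort(cohort_spec(scale = zero_scale,
                                    age_slope = c(psmd = 0, psfa = 0,
                                                  psad = 0, psrd = 0,
                                                  psndi = 0, psodi = 0),
                                    seed = 3))
  expect_equal(unique(co$psmd[co$group == "term"]), 0.50)
  expect_equal(unique(co$psrd[co$group == "preterm"]), 0.72)

  # zero noise, known slope: closed-form least squares recovers it
  co2 <- simulate_cohort(cohort_spec(scale = zero_scale,
                                     age_slope = c(psmd = 0.01, psfa = 0,
                                                   psad = 0, psrd = 0,
                                                   psndi = 0, psodi = 0),
                                     seed = 4))
  x <- co2$ga_scan; y <- co2$psmd
  grp <- as.integer(co2$group == "preterm")
  # per-group OLS slope (groups differ only by intercept)
  fit <- lm(y ~ x + grp)
  expect_equal(unname(coef(fit)["x"]), 0.01, tolerance = 1e-10)

  # determinism
  expect_identical(simulate_cohort(cohort_spec(seed = 8)),
                   simulate_cohort(cohort_spec(seed = 8)))
})
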