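# Synthetic multi-shell DWI phantoms and synthetic two-group cohorts.
#
# Phantoms live on a shared voxel grid (no registration): axis-aligned
# tube "tracts" with known tensor eigenvalues and NODDI parameters inside
# an isotropic CSF-like background. Every stochastic generator is seeded
# and restores the caller's RNG state.

with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Describe one synthetic tract
#'
#' An axis-aligned tube with given centerline, radius and ground-truth
#' microstructure. With `profile = "gaussian"` the tensor is blended
#' radially toward the isotropic background with weight
#' `exp(-r^2 / (2 sigma^2))`, producing a smooth FA ridge that peaks on
#' the centerline; `profile = "flat"` keeps the tract tensor uniform.
#'
#' @param axis Tube axis: `"x"`, `"y"` or `"z"`.
#' @param center Length-2 centerline position (voxel units) in the two
#'   remaining axes, in x-before-y-before-z order.
#' @param radius Tube radius in voxels (>= 1).
#' @param evals Ground-truth tensor eigenvalues (1e-3 mm^2/s), descending;
#'   the first is aligned with the tube axis.
#' @param ndi,odi Ground-truth NODDI neurite density and orientation
#'   dispersion inside the tract, both in [0, 1].
#' @param profile Radial profile of the tensor blend.
#' @param sigma Gaussian profile width in voxels (default `radius / 2`).
#' @param excluded Flag the tract as a cerebellum/brainstem analogue that
#'   the custom mask must remove.
#' @return A `phantom_tract` list.
#' @export
phantom_tract <- function(axis = "x", center, radius,
                          evals = c(1.7, 0.3, 0.3), ndi = 0.6, odi = 0.2,
                          profile = c("gaussian", "flat"),
                          sigma = radius / 2, excluded = FALSE) {
  profile <- match.arg(profile)
  axis <- match.arg(axis, c("x", "y", "z"))
  stopifnot(length(center) == 2L, radius >= 1, length(evals) == 3L)
  evals <- as.numeric(evals)
  if (is.unsorted(rev(evals)) || any(evals < 0))
    stop("tensor eigenvalues must satisfy l1 >= l2 >= l3 >= 0")
  if (ndi < 0 || ndi > 1 || odi < 0 || odi > 1)
    stop("NDI and ODI must lie in [0, 1]")
  structure(list(axis = axis, center = as.numeric(center),
                 radius = radius, evals = evals, ndi = ndi, odi = odi,
                 profile = profile, sigma = sigma, excluded = excluded),
            class = "phantom_tract")
}

#' Specify a synthetic DWI phantom
#'
#' @param grid_shape Length-3 integer grid dimensions.
#' @param tracts List of [phantom_tract()]s.
#' @param background Isotropic background diffusivity (1e-3 mm^2/s);
#'   default 3.0 (CSF-like). Background voxels carry NDI = 0, ODI = 1 and
#'   a pure free-water NODDI composition.
#' @param s0 Baseline (b = 0) signal amplitude.
#' @param snr S0-relative signal-to-noise ratio (`Inf` = noiseless).
#' @param noise_model `"rician"` (magnitude MRI, default), `"gaussian"`,
#'   or `"none"`.
#' @param signal_model Forward model for the simulated signal:
#'   `"tensor"` (mono-exponential, exactly recoverable by [fit_tensor()])
#'   or `"noddi"` (three-compartment signal from the tract's NDI/ODI).
#' @param voxdim Voxel dimensions in mm (default 2 mm isotropic).
#' @param seed Integer RNG seed for the noise draw.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape, tracts, background = 3.0, s0 = 100,
                         snr = Inf, noise_model = c("rician", "gaussian", "none"),
                         signal_model = c("tensor", "noddi"),
                         voxdim = c(2, 2, 2), seed = 1L) {
  noise_model <- match.arg(noise_model)
  signal_model <- match.arg(signal_model)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1))
  if (!length(tracts) || !all(vapply(tracts, inherits, TRUE, "phantom_tract")))
    stop("tracts must be a non-empty list of phantom_tract objects")
  if (!is.finite(background) || background < 0)
    stop("background diffusivity must be non-negative")
  if (!(snr > 0)) stop("snr must be positive")
  structure(list(grid_shape = as.integer(grid_shape), tracts = tracts,
                 background = background, s0 = s0, snr = snr,
                 noise_model = noise_model, signal_model = signal_model,
                 voxdim = as.numeric(voxdim), seed = as.integer(seed)),
            class = "phantom_spec")
}

AXIS_PERP <- list(x = c(2L, 3L), y = c(1L, 3L), z = c(1L, 2L))

# Per-voxel ground truth for a phantom: blended tensor eigenvalues in the
# world frame (axis-aligned), NODDI parameters, and tract attribution.
phantom_ground_truth <- function(spec) {
  gs <- spec$grid_shape
  nvox <- prod(gs)
  co <- arrayInd(seq_len(nvox), gs)     # voxel centres at integer coords
  bg <- spec$background
  lam <- matrix(bg, nvox, 3)            # world-axis diagonal diffusivities
  ndi <- numeric(nvox); odi <- rep(1, nvox); viso <- rep(1, nvox)
  tract_id <- integer(nvox)
  weight <- numeric(nvox)
  mu <- matrix(0, nvox, 3)

  for (ti in seq_along(spec$tracts)) {
    tr <- spec$tracts[[ti]]
    perp <- AXIS_PERP[[tr$axis]]
    ax <- setdiff(1:3, perp)
    r2 <- (co[, perp[1]] - tr$center[1])^2 + (co[, perp[2]] - tr$center[2])^2
    inside <- r2 <= tr$radius^2
    w <- ifelse(inside,
                if (tr$profile == "gaussian")
                  exp(-r2 / (2 * tr$sigma^2)) else 1, 0)
    take <- w > weight
    if (!any(take)) next
    weight[take] <- w[take]
    tract_id[take] <- ti
    # blend tensor toward the isotropic background in the tract eigenframe
    lw <- cbind(w[take] * tr$evals[1] + (1 - w[take]) * bg,
                w[take] * tr$evals[2] + (1 - w[take]) * bg,
                w[take] * tr$evals[3] + (1 - w[take]) * bg)
    lam[take, ax] <- lw[, 1]
    lam[take, perp[1]] <- lw[, 2]
    lam[take, perp[2]] <- lw[, 3]
    ndi[take] <- tr$ndi
    odi[take] <- tr$odi
    viso[take] <- 0
    mu[take, ] <- 0
    mu[take, ax] <- 1
  }
  list(lam = lam, ndi = ndi, odi = odi, viso = viso, mu = mu,
       tract_id = tract_id, weight = weight, coords = co)
}

ground_truth_maps <- function(spec) {
  gt <- phantom_ground_truth(spec)
  gs <- spec$grid_shape
  ev <- t(apply(gt$lam, 1, sort, decreasing = TRUE))
  mk <- function(kind, v) scalar_map(kind, array(v, gs), spec$voxdim)
  list(MD = mk("MD", rowMeans(ev)),
       FA = mk("FA", fa_from_evals(ev)),
       AD = mk("AD", ev[, 1]),
       RD = mk("RD", (ev[, 2] + ev[, 3]) / 2),
       NDI = mk("NDI", gt$ndi),
       ODI = mk("ODI", gt$odi))
}

#' Simulate a multi-shell DWI acquisition from a phantom
#'
#' Noiseless signals follow either the mono-exponential tensor model
#' `S = S0 exp(-b g' D g)` with the phantom's blended ground-truth tensor,
#' or the three-compartment NODDI forward model of [noddi_signal()] using
#' the tract's NDI/ODI (background voxels are pure free water). Rician
#' noise replaces S by `sqrt((S + e1)^2 + e2^2)` with
#' `e ~ Normal(0, S0/snr)`.
#'
#' @param spec A [phantom_spec()].
#' @param gradients A [gradient_table()].
#' @return List with elements `dwi` (a [dwi_volume()]) and `ground_truth`
#'   (named list of six [scalar_map()]s: MD, FA, AD, RD, NDI, ODI).
#' @export
simulate_dwi <- function(spec, gradients) {
  stopifnot(inherits(spec, "phantom_spec"),
            inherits(gradients, "gradient_table"))
  gt <- phantom_ground_truth(spec)
  gs <- spec$grid_shape
  nvox <- prod(gs)
  beff <- gradients$bvals * 1e-3
  g <- gradients$bvecs

  if (spec$signal_model == "tensor") {
    # diagonal (world-axis) tensors: g'Dg = sum_i lam_i g_i^2
    Bg <- rbind(beff * g[1, ]^2, beff * g[2, ]^2, beff * g[3, ]^2)
    S <- spec$s0 * exp(-(gt$lam %*% Bg))
  } else {
    S <- matrix(0, nvox, length(gradients))
    key <- paste(gt$tract_id, gt$viso)
    for (k in unique(key)) {
      sel <- key == k
      i <- which(sel)[1]
      if (gt$viso[i] >= 1) {
        s <- noddi_signal(noddi_params(v_ic = 0, kappa = 0, v_iso = 1,
                                       mu = c(1, 0, 0),
                                       d_iso = spec$background),
                          gradients, s0 = spec$s0)
      } else {
        s <- noddi_signal(noddi_params(v_ic = gt$ndi[i],
                                       kappa = kappa_from_odi(gt$odi[i]),
                                       v_iso = 0, mu = gt$mu[i, ]),
                          gradients, s0 = spec$s0)
      }
      S[sel, ] <- matrix(s, sum(sel), length(s), byrow = TRUE)
    }
  }

  if (spec$noise_model != "none" && is.finite(spec$snr)) {
    sdn <- spec$s0 / spec$snr
    S <- with_local_seed(spec$seed, {
      if (spec$noise_model == "rician") {
        e1 <- matrix(rnorm(length(S), 0, sdn), nrow(S))
        e2 <- matrix(rnorm(length(S), 0, sdn), nrow(S))
        sqrt((S + e1)^2 + e2^2)
      } else {
        pmax(S + matrix(rnorm(length(S), 0, sdn), nrow(S)), 0)
      }
    })
  }
  dwi <- dwi_volume(array(S, c(gs, length(gradients))), spec$voxdim,
                    gradients)
  list(dwi = dwi, ground_truth = ground_truth_maps(spec))
}

erode6 <- function(mask, times = 1L) {
  for (i in seq_len(times)) {
    p <- array(FALSE, dim(mask) + 2L)
    p[2:(dim(mask)[1] + 1), 2:(dim(mask)[2] + 1), 2:(dim(mask)[3] + 1)] <- mask
    d <- dim(mask)
    i1 <- 2:(d[1] + 1); i2 <- 2:(d[2] + 1); i3 <- 2:(d[3] + 1)
    mask <- p[i1, i2, i3] &
      p[i1 - 1, i2, i3] & p[i1 + 1, i2, i3] &
      p[i1, i2 - 1, i3] & p[i1, i2 + 1, i3] &
      p[i1, i2, i3 - 1] & p[i1, i2, i3 + 1]
  }
  mask
}

#' Build the phantom's FA template and custom analysis mask
#'
#' The template FA is the phantom's noiseless ground-truth FA. The custom
#' mask keeps, for each tract not flagged `excluded`, the voxels whose
#' ground-truth FA exceeds `fa_threshold`, eroded by `rim` voxels
#' (6-connectivity) as a proxy for trimming CSF/GM-contaminated tract
#' borders.
#'
#' @param spec A [phantom_spec()].
#' @param rim Number of erosion passes (default 0).
#' @param fa_threshold Support threshold (default 0.15).
#' @return List with `template_fa` and `custom_mask` (both [scalar_map()];
#'   the mask is binary with kind `"mask"`).
#' @export
make_template_and_mask <- function(spec, rim = 0L, fa_threshold = 0.15) {
  stopifnot(inherits(spec, "phantom_spec"))
  gt <- phantom_ground_truth(spec)
  maps <- ground_truth_maps(spec)
  fa <- maps$FA$data
  gs <- spec$grid_shape
  mask <- array(FALSE, gs)
  for (ti in seq_along(spec$tracts)) {
    if (spec$tracts[[ti]]$excluded) next
    m <- array(gt$tract_id == ti, gs) & fa > fa_threshold
    if (rim > 0) m <- erode6(m, rim)
    mask <- mask | m
  }
  list(template_fa = maps$FA,
       custom_mask = scalar_map("mask", array(as.numeric(mask), gs),
                                spec$voxdim))
}

#' Generate a near-uniform multi-shell gradient scheme
#'
#' Directions are spread on the sphere by electrostatic repulsion with
#' antipodal symmetry from a seeded random start, run for a fixed number
#' of iterations, so the scheme is deterministic given the seed.
#'
#' @param n_b0 Number of b = 0 baseline volumes (must be >= 1).
#' @param shells List of `c(bval, n_dirs)` pairs, e.g.
#'   `list(c(750, 64), c(2500, 64))`.
#' @param seed RNG seed.
#' @param n_iter Repulsion iterations.
#' @return A [gradient_table()] with b0 volumes first.
#' @export
make_gradient_scheme <- function(n_b0, shells, seed = 1L, n_iter = 120L) {
  if (n_b0 < 1) stop("at least one b=0 baseline volume is required")
  if (!length(shells)) stop("at least one shell is required")
  bvals <- rep(0, n_b0)
  vecs <- matrix(0, 3, n_b0)
  with_local_seed(seed, {
    for (sh in shells) {
      b <- sh[1]; n <- as.integer(sh[2])
      if (n < 1) stop("shell with fewer than 1 direction")
      p <- matrix(rnorm(3 * n), 3, n)
      p <- sweep(p, 2, sqrt(colSums(p^2)), "/")
      if (n > 1) {
        step <- 0.1
        for (it in seq_len(n_iter)) {
          f <- matrix(0, 3, n)
          for (i in seq_len(n)) {
            dplus <- p - p[, i]
            dminus <- -p - p[, i]
            np <- pmax(sqrt(colSums(dplus^2)), 1e-9)
            nm <- pmax(sqrt(colSums(dminus^2)), 1e-9)
            np[i] <- Inf                       # skip self
            f[, i] <- -rowSums(sweep(dplus, 2, np^3, "/")) -
                       rowSums(sweep(dminus, 2, nm^3, "/"))
          }
          # project force onto the tangent plane and take a damped step
          f <- f - sweep(p, 2, colSums(f * p), "*")
          p <- p + step * f / max(sqrt(colSums(f^2)), 1e-9)
          p <- sweep(p, 2, sqrt(colSums(p^2)), "/")
          step <- step * 0.97
        }
      }
      bvals <- c(bvals, rep(b, n))
      vecs <- cbind(vecs, p)
    }
  })
  gradient_table(bvals, vecs)
}

#' The two-acquisition neonatal multi-shell scheme
#'
#' 16 baselines plus shells of 3 directions at b = 200, 6 at b = 500,
#' 64 at b = 750 and 64 at b = 2500 s/mm^2 (153 volumes in total),
#' mirroring a two-acquisition neonatal protocol.
#'
#' @param seed RNG seed for the direction sets.
#' @return A [gradient_table()].
#' @export
neonatal_scheme <- function(seed = 1L) {
  make_gradient_scheme(16, list(c(200, 3), c(500, 6), c(750, 64),
                                c(2500, 64)), seed = seed)
}

TABLE2_DEFAULTS <- list(
  loc = list(
    term    = c(psmd = 0.50, psfa = 0.32, psad = 0.70, psrd = 0.62,
                psndi = 0.22, psodi = 0.26),
    preterm = c(psmd = 0.60, psfa = 0.32, psad = 0.75, psrd = 0.72,
                psndi = 0.24, psodi = 0.27)),
  # sd approximated as IQR / 1.349 from the printed quartiles
  scale = list(
    term    = c(psmd = 0.06, psfa = 0.02, psad = 0.04, psrd = 0.09,
                psndi = 0.02, psodi = 0.02) / 1.349,
    preterm = c(psmd = 0.09, psfa = 0.02, psad = 0.06, psrd = 0.09,
                psndi = 0.02, psodi = 0.01) / 1.349))

#' Specify a synthetic two-group cohort
#'
#' Group location and scale defaults reproduce the published summary
#' quartiles of the six peak-width metrics in term and preterm neonates
#' (normal approximation, sd = IQR / 1.349). Gestational ages are drawn
#' uniformly within group-specific ranges.
#'
#' @param n_term,n_preterm Group sizes (defaults 59 and 76).
#' @param loc,scale Named lists with elements `term` and `preterm`, each a
#'   named numeric vector over the six metrics.
#' @param ga_birth_range Named list of length-2 ranges (weeks) per group.
#' @param ga_scan_range Length-2 scan-age range (weeks).
#' @param age_slope Named per-metric linear dependence on GA at scan
#'   (units per week); default -0.005 for all metrics except `psfa` (0).
#' @param seed RNG seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_term = 59L, n_preterm = 76L,
                        loc = TABLE2_DEFAULTS$loc,
                        scale = TABLE2_DEFAULTS$scale,
                        ga_birth_range = list(term = c(36.42, 42),
                                              preterm = c(23.42, 32)),
                        ga_scan_range = c(38, 44.56),
                        age_slope = c(psmd = -0.005, psfa = 0,
                                      psad = -0.005, psrd = -0.005,
                                      psndi = -0.005, psodi = -0.005),
                        seed = 1L) {
  if (n_term < 1 || n_preterm < 1) stop("group sizes must be positive")
  for (grp in c("term", "preterm")) {
    if (any(scale[[grp]] < 0)) stop("scales must be non-negative")
    rng <- ga_birth_range[[grp]]
    if (rng[1] < GA_RANGE[1] || rng[2] > GA_RANGE[2])
      stop("ga_birth range outside plausible weeks")
  }
  if (ga_scan_range[1] < GA_RANGE[1] || ga_scan_range[2] > GA_RANGE[2])
    stop("ga_scan range outside plausible weeks")
  structure(list(n_term = as.integer(n_term),
                 n_preterm = as.integer(n_preterm),
                 loc = loc, scale = scale,
                 ga_birth_range = ga_birth_range,
                 ga_scan_range = ga_scan_range,
                 age_slope = age_slope, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a two-group cohort of peak-width metrics
#'
#' Each subject's metric is drawn as
#' `location(group) + age_slope * (ga_scan - mean(ga_scan)) + noise`,
#' with Gaussian noise of the group's scale. GA at scan is drawn uniformly
#' in `ga_scan_range`, truncated below at the subject's GA at birth.
#'
#' @param spec A [cohort_spec()].
#' @return A `cohort_table` data frame with metric columns filled.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_local_seed(spec$seed, {
    groups <- rep(c("term", "preterm"), c(spec$n_term, spec$n_preterm))
    n <- length(groups)
    ga_birth <- numeric(n); ga_scan <- numeric(n)
    for (grp in c("term", "preterm")) {
      sel <- groups == grp
      rng <- spec$ga_birth_range[[grp]]
      ga_birth[sel] <- runif(sum(sel), rng[1], rng[2])
      lo <- pmax(spec$ga_scan_range[1], ga_birth[sel])
      ga_scan[sel] <- lo + runif(sum(sel)) * (spec$ga_scan_range[2] - lo)
    }
    df <- data.frame(subject_id = sprintf("sub-%03d", seq_len(n)),
                     group = groups, ga_birth = ga_birth,
                     ga_scan = ga_scan, stringsAsFactors = FALSE)
    dev <- ga_scan - mean(ga_scan)
    for (m in PS_METRICS) {
      v <- numeric(n)
      for (grp in c("term", "preterm")) {
        sel <- groups == grp
        v[sel] <- spec$loc[[grp]][[m]] +
          spec$age_slope[[m]] * dev[sel] +
          rnorm(sum(sel), 0, spec$scale[[grp]][[m]])
      }
      df[[m]] <- v
    }
    as_cohort_table(df)
  })
}
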