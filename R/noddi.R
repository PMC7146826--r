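# NODDI: three-compartment (intracellular Watson-dispersed sticks,
# extracellular tortuosity-constrained zeppelin, isotropic free water)
# signal model and per-voxel fit.
#
# S/S0 = (1 - v_iso) [ v_ic A_ic + (1 - v_ic) A_ec ] + v_iso exp(-b d_iso)
#   A_ic = int W(n; mu, kappa) exp(-b d_par (g'n)^2) dn
#   A_ec = exp(-b g' D_ec g),  D_ec the Watson-averaged zeppelin with
#          d_perp = d_par (1 - v_ic) (tortuosity constraint)
#
# The Watson integral is evaluated by fixed-order spherical quadrature
# (Gauss-Legendre in cos(theta) x uniform azimuth). Because the integrand
# depends on the node only through its angles to mu and g, the quadrature
# is exactly invariant under joint rotation of mu and the gradients.

KAPPA_MAX <- 64

#' Orientation dispersion index from a Watson concentration
#'
#' `ODI = (2/pi) atan(1/kappa)`, extended by continuity to `ODI(0) = 1`.
#'
#' @param kappa Watson concentration parameter(s), >= 0.
#' @return ODI value(s) in [0, 1].
#' @export
odi_from_kappa <- function(kappa) {
  if (any(!is.finite(kappa) & !is.infinite(kappa)) || any(kappa < 0))
    stop("kappa must be non-negative")
  ifelse(kappa == 0, 1, (2 / pi) * atan(1 / kappa))
}

#' Watson concentration from an orientation dispersion index
#'
#' Inverse of [odi_from_kappa()]; `kappa` is capped at the fitting bound.
#'
#' @param odi ODI value(s) in (0, 1].
#' @return Watson concentration(s).
#' @export
kappa_from_odi <- function(odi) {
  if (any(odi <= 0) || any(odi > 1)) stop("ODI must lie in (0, 1]")
  pmin(1 / tan(pi / 2 * odi), KAPPA_MAX)
}

#' Single-voxel NODDI parameters
#'
#' @param v_ic Intracellular (neurite) volume fraction in [0, 1]; this is
#'   the NDI scalar.
#' @param kappa Watson concentration, in [0, 64].
#' @param v_iso Isotropic free-water fraction in [0, 1].
#' @param mu Dominant orientation (unit 3-vector; normalized on input).
#' @param d_par Intrinsic parallel diffusivity (1e-3 mm^2/s), default 1.7.
#' @param d_iso Free-water diffusivity (1e-3 mm^2/s), default 3.0.
#' @return A `noddi_params` list.
#' @export
noddi_params <- function(v_ic, kappa, v_iso = 0, mu = c(1, 0, 0),
                         d_par = 1.7, d_iso = 3.0) {
  if (v_ic < 0 || v_ic > 1 || v_iso < 0 || v_iso > 1)
    stop("volume fractions must lie in [0, 1]")
  if (kappa < 0 || kappa > KAPPA_MAX)
    stop("kappa must lie in [0, ", KAPPA_MAX, "]")
  nm <- sqrt(sum(mu^2))
  if (nm == 0) stop("mu must be a non-zero vector")
  structure(list(v_ic = v_ic, kappa = kappa, v_iso = v_iso, mu = mu / nm,
                 d_par = d_par, d_iso = d_iso),
            class = "noddi_params")
}

# Golub-Welsch Gauss-Legendre nodes/weights on [-1, 1]
gauss_legendre <- function(n) {
  if (n == 1) return(list(x = 0, w = 2))
  k <- seq_len(n - 1)
  beta <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- beta
  J[cbind(k + 1, k)] <- beta
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = 2 * e$vectors[1, ord]^2)
}

# Quadrature workspace for repeated signal evaluations at fixed gradients,
# orientation and d_par. E[i, k] = exp(-b_i d_par u_ik^2) over all
# diffusion-weighted volumes i and sphere nodes k.
noddi_workspace <- function(gradients, mu, d_par = 1.7,
                            quad = c(48, 48)) {
  mu <- mu / sqrt(sum(mu^2))
  dw <- which(!is_b0(gradients))
  beff <- gradients$bvals[dw] * 1e-3
  g <- gradients$bvecs[, dw, drop = FALSE]
  cpsi <- pmin(abs(drop(crossprod(g, mu))), 1)
  spsi <- sqrt(1 - cpsi^2)

  gl <- gauss_legendre(quad[1])
  nphi <- quad[2]
  phi <- 2 * pi * (seq_len(nphi) - 0.5) / nphi
  z <- rep(gl$x, each = nphi)
  wq <- rep(gl$w, each = nphi) * (2 * pi / nphi)
  cphi <- rep(cos(phi), quad[1])
  sz <- sqrt(pmax(1 - z^2, 0))
  # u[i, k] = g_i . n_k in the mu-aligned frame (azimuth relative to g_i)
  U <- outer(cpsi, z) + outer(spsi, sz * cphi)
  E <- exp(-(beff * d_par) * U^2)
  list(E = E, z2 = z^2, wq = wq, cpsi2 = cpsi^2, beff = beff,
       dw = dw, d_par = d_par, n_vol = length(gradients))
}

# Normalized signal over diffusion-weighted volumes for one parameter set.
noddi_signal_dw <- function(ws, v_ic, kappa, v_iso, d_iso = 3.0) {
  wk <- ws$wq * exp(kappa * ws$z2)
  wk <- wk / sum(wk)
  a_ic <- drop(ws$E %*% wk)
  tau1 <- sum(wk * ws$z2)
  d_perp <- ws$d_par * (1 - v_ic)
  proj <- tau1 * ws$cpsi2 + (1 - tau1) * (1 - ws$cpsi2) / 2
  a_ec <- exp(-ws$beff * (d_perp + (ws$d_par - d_perp) * proj))
  (1 - v_iso) * (v_ic * a_ic + (1 - v_ic) * a_ec) +
    v_iso * exp(-ws$beff * d_iso)
}

#' Evaluate the NODDI forward signal for one voxel
#'
#' @param params A [noddi_params()].
#' @param gradients A [gradient_table()].
#' @param s0 Baseline signal amplitude.
#' @param quad Quadrature order `c(n_polar, n_azimuth)` for the Watson
#'   sphere integral.
#' @return Numeric signal vector, one value per volume (equal to `s0` at
#'   b = 0).
#' @export
noddi_signal <- function(params, gradients, s0 = 1, quad = c(48, 48)) {
  stopifnot(inherits(params, "noddi_params"),
            inherits(gradients, "gradient_table"))
  ws <- noddi_workspace(gradients, params$mu, params$d_par, quad)
  s <- rep(s0, length(gradients))
  s[ws$dw] <- s0 * noddi_signal_dw(ws, params$v_ic, params$kappa,
                                   params$v_iso, params$d_iso)
  s
}

ODI_MIN <- 2 / pi * atan(1 / KAPPA_MAX)

#' Fit the NODDI model voxelwise
#'
#' Requires at least two non-zero shells. The dominant orientation is
#' fixed from the principal eigenvector of a diffusion tensor fit on the
#' low-b shell; `(v_ic, ODI, v_iso)` are then estimated by a coarse grid
#' search followed by bounded local refinement (L-BFGS-B) of the sum of
#' squared normalized-signal residuals. The fit is deterministic.
#'
#' @param dwi A [dwi_volume()].
#' @param mask Optional [scalar_map()] restricting the fit.
#' @param d_par,d_iso Fixed model diffusivities (1e-3 mm^2/s).
#' @param quad Quadrature order `c(n_polar, n_azimuth)`.
#' @param optim_control Extra `control` entries for the L-BFGS-B
#'   refinement (e.g. a looser `factr` for bulk fits).
#' @return A `noddi_fit`: list with per-voxel `v_ic`, `kappa`, `v_iso`,
#'   `mu` (n x 3), `valid`, `idx`, `dim`, `voxdim`.
#' @export
fit_noddi <- function(dwi, mask = NULL, d_par = 1.7, d_iso = 3.0,
                      quad = c(48, 48), optim_control = list()) {
  stopifnot(inherits(dwi, "dwi_volume"))
  gtab <- dwi$gradients
  shells <- unique(round(gtab$bvals[!is_b0(gtab)]))
  if (length(shells) < 2L)
    stop("NODDI requires multi-shell data (>= 2 non-zero shells), got ",
         length(shells), " shell(s)")

  # orientation prior from the tensor on the weakest shell(s)
  low_b <- if (sum(gtab$bvals > B0_MAX & gtab$bvals <= 1200) >= 6)
    1200 else max(gtab$bvals)
  tf <- fit_tensor(dwi, mask, max_bval = low_b)

  dims <- dim(dwi$data)[1:3]
  sig <- matrix(dwi$data, nrow = prod(dims))[tf$idx, , drop = FALSE]
  b0 <- is_b0(gtab)
  s0 <- rowMeans(sig[, b0, drop = FALSE])
  dwv <- which(!b0)

  n <- length(tf$idx)
  v_ic <- rep(NA_real_, n); kap <- rep(NA_real_, n)
  v_iso <- rep(NA_real_, n)
  mu <- matrix(NA_real_, n, 3)
  valid <- rep(FALSE, n)

  grid_vic <- seq(0.05, 0.95, by = 0.1)
  grid_odi <- c(ODI_MIN, 0.02, 0.05, 0.1, 0.2, 0.4, 0.7, 1)
  grid_viso <- c(0, 0.15, 0.4, 0.7, 1)

  for (j in seq_len(n)) {
    if (!tf$valid[j] || !is.finite(s0[j]) || s0[j] <= 0) next
    mu_j <- tf$evecs[, 1, j]
    ws <- noddi_workspace(gtab, mu_j, d_par, quad)
    y <- sig[j, dwv] / s0[j]

    best <- NULL; best_sse <- Inf
    for (odi in grid_odi) {
      k <- kappa_from_odi(odi)
      wk <- ws$wq * exp(k * ws$z2); wk <- wk / sum(wk)
      a_ic <- drop(ws$E %*% wk)
      tau1 <- sum(wk * ws$z2)
      for (vic in grid_vic) {
        d_perp <- d_par * (1 - vic)
        proj <- tau1 * ws$cpsi2 + (1 - tau1) * (1 - ws$cpsi2) / 2
        a_ec <- exp(-ws$beff * (d_perp + (d_par - d_perp) * proj))
        tiss <- vic * a_ic + (1 - vic) * a_ec
        iso <- exp(-ws$beff * d_iso)
        for (viso in grid_viso) {
          sse <- sum((y - ((1 - viso) * tiss + viso * iso))^2)
          if (sse < best_sse) { best_sse <- sse; best <- c(vic, odi, viso) }
        }
      }
    }
    iso <- exp(-ws$beff * d_iso)
    obj <- function(p) {
      k <- min(1 / tan(pi / 2 * p[2]), KAPPA_MAX)
      wk <- ws$wq * exp(k * ws$z2)
      wk <- wk / sum(wk)
      a_ic <- drop(ws$E %*% wk)
      tau1 <- sum(wk * ws$z2)
      d_perp <- d_par * (1 - p[1])
      a_ec <- exp(-ws$beff * (d_perp + (d_par - d_perp) *
                  (tau1 * ws$cpsi2 + (1 - tau1) * (1 - ws$cpsi2) / 2)))
      sum((y - ((1 - p[3]) * (p[1] * a_ic + (1 - p[1]) * a_ec) +
                  p[3] * iso))^2)
    }
    fit <- optim(best, obj, method = "L-BFGS-B",
                 lower = c(1e-4, ODI_MIN, 0), upper = c(1, 1, 1),
                 control = utils::modifyList(list(maxit = 200),
                                             optim_control))
    v_ic[j] <- fit$par[1]
    kap[j] <- kappa_from_odi(fit$par[2])
    v_iso[j] <- fit$par[3]
    mu[j, ] <- mu_j
    valid[j] <- TRUE
  }
  structure(list(v_ic = v_ic, kappa = kap, v_iso = v_iso, mu = mu,
                 valid = valid, idx = tf$idx, dim = dims,
                 voxdim = dwi$voxdim, d_par = d_par, d_iso = d_iso),
            class = "noddi_fit")
}

#' @export
print.noddi_fit <- function(x, ...) {
  cat(sprintf("NODDI fit: %d voxels (%d valid); d_par=%.3g, d_iso=%.3g (1e-3 mm^2/s)\n",
              length(x$idx), sum(x$valid), x$d_par, x$d_iso))
  invisible(x)
}

#' Derive NDI and ODI scalar maps from a NODDI fit
#'
#' NDI is the intracellular fraction `v_ic`; ODI is
#' `(2/pi) atan(1/kappa)`. Unfit voxels are NaN.
#'
#' @param fit A `noddi_fit` from [fit_noddi()].
#' @return Named list of two [scalar_map()]s: `NDI`, `ODI`.
#' @export
noddi_scalars <- function(fit) {
  stopifnot(inherits(fit, "noddi_fit"))
  n <- prod(fit$dim)
  ndi <- rep(NaN, n); odi <- rep(NaN, n)
  ndi[fit$idx[fit$valid]] <- pmin(pmax(fit$v_ic[fit$valid], 0), 1)
  odi[fit$idx[fit$valid]] <- odi_from_kappa(fit$kappa[fit$valid])
  list(NDI = scalar_map("NDI", array(ndi, fit$dim), fit$voxdim),
       ODI = scalar_map("ODI", array(odi, fit$dim), fit$voxdim))
}
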