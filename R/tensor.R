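# Diffusion tensor fitting and scalar map derivation.
#
# Model: ln S = ln S0 - b g' D g, with D in units of 1e-3 mm^2/s (so the
# effective b in the design matrix is bval * 1e-3). Estimator is two-pass
# weighted least squares: an OLS pass on the log signal, then a WLS pass
# with weights equal to the squared predicted signal — the standard
# heteroscedasticity correction for log-transformed Rician-corrupted data.

tensor_design <- function(gtab) {
  b <- gtab$bvals * 1e-3
  g <- gtab$bvecs
  cbind(1,
        -b * g[1, ]^2, -b * g[2, ]^2, -b * g[3, ]^2,
        -2 * b * g[1, ] * g[2, ],
        -2 * b * g[1, ] * g[3, ],
        -2 * b * g[2, ] * g[3, ])
}

tensor_from_coef <- function(cf) {
  matrix(c(cf[2], cf[5], cf[6],
           cf[5], cf[3], cf[7],
           cf[6], cf[7], cf[4]), 3, 3)
}

#' Fit the diffusion tensor voxelwise
#'
#' Weighted least squares on the log signal, restricted to volumes with
#' b-value at most `max_bval` (the low shell plus baselines; Gaussian
#' tensor assumptions degrade at strong diffusion weighting). Voxels with
#' non-positive signal in some volumes are fit on the positive subset when
#' at least 7 usable volumes remain, otherwise flagged invalid. Negative
#' eigenvalues are clamped to zero after decomposition.
#'
#' @param dwi A [dwi_volume()].
#' @param mask Optional [scalar_map()] (non-zero = fit this voxel).
#' @param max_bval Largest b-value (s/mm^2) entering the fit; default 1000.
#' @return A `tensor_field`: list with `coef` (n_voxel x 6 matrix of unique
#'   tensor elements Dxx, Dyy, Dzz, Dxy, Dxz, Dyz in 1e-3 mm^2/s), `s0`,
#'   `valid`, `evals` (n x 3, descending, clamped at 0), `evecs`
#'   (3 x 3 x n), `idx` (voxel indices fit), `dim`, `voxdim`.
#' @export
fit_tensor <- function(dwi, mask = NULL, max_bval = 1000) {
  stopifnot(inherits(dwi, "dwi_volume"))
  gtab <- dwi$gradients
  use <- gtab$bvals <= max_bval
  dw <- use & !is_b0(gtab)
  if (!any(use & is_b0(gtab))) stop("no b=0 volume at or below max_bval")
  gdw <- gtab$bvecs[, dw, drop = FALSE]
  if (qr(crossprod(rbind(gdw[1, ]^2, gdw[2, ]^2, gdw[3, ]^2,
                         gdw[1, ] * gdw[2, ], gdw[1, ] * gdw[3, ],
                         gdw[2, ] * gdw[3, ])))$rank < 6L)
    stop("fewer than 6 non-collinear diffusion directions at b <= max_bval")
  X <- tensor_design(gtab)[use, , drop = FALSE]
  if (kappa(X, exact = TRUE) > 1e8)
    stop("degenerate gradient design (condition number > 1e8)")

  dims <- dim(dwi$data)[1:3]
  nvox <- prod(dims)
  sig <- matrix(dwi$data, nrow = nvox)[, use, drop = FALSE]
  idx <- seq_len(nvox)
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "scalar_map"))
    if (!all(dim(mask$data) == dims)) stop("mask grid mismatch")
    m <- is.finite(mask$data) & mask$data != 0
    idx <- which(as.vector(m))
    sig <- sig[idx, , drop = FALSE]
  }
  n <- length(idx)
  cf <- matrix(NA_real_, n, 7)
  valid <- rep(FALSE, n)
  allpos <- rowSums(sig <= 0) == 0L
  XtX <- crossprod(X)
  XtXi_Xt <- solve(XtX, t(X))

  # vectorized OLS for fully positive voxels, then per-voxel WLS
  if (any(allpos)) {
    Y <- log(t(sig[allpos, , drop = FALSE]))
    beta0 <- XtXi_Xt %*% Y                      # 7 x n_ok
    W <- exp(2 * (X %*% beta0))                 # squared predicted signal
    ok <- which(allpos)
    for (j in seq_along(ok)) {
      w <- W[, j]
      Xw <- X * w
      cf[ok[j], ] <- tryCatch(
        drop(solve(crossprod(Xw, X), crossprod(Xw, Y[, j]))),
        error = function(e) beta0[, j])
      valid[ok[j]] <- TRUE
    }
  }
  part <- which(!allpos)
  for (j in part) {
    keep <- sig[j, ] > 0
    if (sum(keep) < 7L) next
    Xj <- X[keep, , drop = FALSE]
    if (qr(Xj)$rank < 7L) next
    y <- log(sig[j, keep])
    b0 <- drop(solve(crossprod(Xj), crossprod(Xj, y)))
    w <- exp(2 * drop(Xj %*% b0))
    Xw <- Xj * w
    cf[j, ] <- tryCatch(drop(solve(crossprod(Xw, Xj), crossprod(Xw, y))),
                        error = function(e) b0)
    valid[j] <- TRUE
  }

  evals <- matrix(NA_real_, n, 3)
  evecs <- array(NA_real_, c(3, 3, n))
  for (j in which(valid)) {
    e <- eigen(tensor_from_coef(cf[j, ]), symmetric = TRUE)
    evals[j, ] <- pmax(e$values, 0)
    evecs[, , j] <- e$vectors
  }
  structure(list(coef = cf[, 2:7, drop = FALSE], s0 = exp(cf[, 1]),
                 valid = valid, evals = evals, evecs = evecs,
                 idx = idx, dim = dims, voxdim = dwi$voxdim),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("Tensor field: %d voxels fit (%d valid) on a %s grid\n",
              length(x$idx), sum(x$valid),
              paste(x$dim, collapse = " x ")))
  invisible(x)
}

fa_from_evals <- function(ev) {
  # ev: n x 3 matrix of clamped eigenvalues
  md <- rowMeans(ev)
  num <- (ev[, 1] - md)^2 + (ev[, 2] - md)^2 + (ev[, 3] - md)^2
  den <- ev[, 1]^2 + ev[, 2]^2 + ev[, 3]^2
  fa <- sqrt(1.5) * sqrt(num) / sqrt(den)
  fa[den == 0] <- 0
  pmin(pmax(fa, 0), 1)
}

#' Derive scalar maps from a fitted tensor field
#'
#' MD = (l1+l2+l3)/3, AD = l1, RD = (l2+l3)/2,
#' FA = sqrt(3/2) * sqrt(sum((l_i - MD)^2)) / sqrt(sum(l_i^2)), with FA
#' defined as 0 when all eigenvalues vanish. Invalid voxels are NaN.
#'
#' @param field A `tensor_field` from [fit_tensor()].
#' @return Named list of four [scalar_map()]s: `MD`, `FA`, `AD`, `RD`
#'   (diffusivities in 1e-3 mm^2/s).
#' @export
tensor_scalars <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  n <- prod(field$dim)
  out <- list()
  vals <- list(MD = rowMeans(field$evals),
               FA = fa_from_evals(field$evals),
               AD = field$evals[, 1],
               RD = (field$evals[, 2] + field$evals[, 3]) / 2)
  for (k in names(vals)) {
    v <- rep(NaN, n)
    v[field$idx[field$valid]] <- vals[[k]][field$valid]
    out[[k]] <- scalar_map(k, array(v, field$dim), field$voxdim)
  }
  out
}
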