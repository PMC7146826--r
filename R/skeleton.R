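# White-matter skeletonization and FA-driven projection.
#
# A voxel lies on the skeleton when it is a local maximum of the template
# FA along the direction perpendicular to the local tract sheet, and its
# FA clears the threshold. The perpendicular direction is estimated from
# the FA-weighted centre of gravity of the 3x3x3 neighbourhood when that
# offset is informative (> 0.1 voxel), otherwise as the discrete direction
# of strongest negative second derivative among the 13 axis/diagonal
# lines, with ties broken in a fixed axis-first order.

# the 13 unique lines through a voxel: axes, face diagonals, body diagonals
D13 <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
             c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
             c(0, 1, 1), c(0, 1, -1),
             c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(-1, 1, 1))

pad_array <- function(a, fill = 0) {
  d <- dim(a)
  p <- array(fill, d + 2L)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- a
  p
}

#' Build the white-matter skeleton from a template FA map
#'
#' @param template_fa A [scalar_map()] of kind FA (values in [0, 1]; NaN
#'   treated as 0).
#' @param fa_threshold Minimum template FA for a skeleton voxel
#'   (default 0.15).
#' @return A `wm_skeleton`: list with `mask` (3-D logical), `idx`
#'   (n x 3 voxel indices), `dirs` (n x 3 integer perpendicular search
#'   directions from the 13-line set), `fa_threshold`, `dim`, `voxdim`.
#'   An empty skeleton (with a warning) results when no voxel clears the
#'   threshold.
#' @export
build_skeleton <- function(template_fa, fa_threshold = 0.15) {
  stopifnot(inherits(template_fa, "scalar_map"))
  fa <- template_fa$data
  fa[!is.finite(fa)] <- 0
  d <- dim(fa)
  cand <- which(fa >= fa_threshold)
  empty <- function() {
    warning("empty skeleton: no voxel reaches the FA threshold")
    structure(list(mask = array(FALSE, d),
                   idx = matrix(0L, 0, 3), dirs = matrix(0L, 0, 3),
                   fa_threshold = fa_threshold, dim = d,
                   voxdim = template_fa$voxdim),
              class = "wm_skeleton")
  }
  if (!length(cand)) return(empty())

  P <- pad_array(fa)
  pd <- dim(P)
  ci <- arrayInd(cand, d)                    # 1-based in original grid
  pidx <- (ci[, 1] + 1) + (ci[, 2]) * pd[1] + (ci[, 3]) * pd[1] * pd[2]

  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ostride <- offs[, 1] + offs[, 2] * pd[1] + offs[, 3] * pd[1] * pd[2]
  NB <- matrix(P[rep(pidx, times = 27) +
                 rep(ostride, each = length(pidx))],
               nrow = length(pidx))          # n_cand x 27 neighbourhood FA

  # FA-weighted centre-of-gravity offset
  wsum <- rowSums(NB)
  cog <- cbind(NB %*% offs[, 1], NB %*% offs[, 2], NB %*% offs[, 3]) / wsum
  cog_norm <- sqrt(rowSums(cog^2))

  # second derivative (negated) along each of the 13 lines
  d13n <- sqrt(rowSums(D13^2))
  iplus <- match(apply(D13, 1, paste, collapse = ","),
                 apply(offs, 1, paste, collapse = ","))
  iminus <- match(apply(-D13, 1, paste, collapse = ","),
                  apply(offs, 1, paste, collapse = ","))
  center <- which(offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] == 0)
  # normalized by squared step length so diagonal lines are comparable
  curv <- sweep(2 * NB[, center] - NB[, iplus, drop = FALSE] -
                  NB[, iminus, drop = FALSE], 2, d13n^2, "/")

  # per-voxel perpendicular direction: CofG when informative, else the
  # line of maximal curvature (ties -> first in the fixed order)
  align <- abs(cog %*% t(sweep(D13, 1, d13n, "/"))) / pmax(cog_norm, 1e-12)
  u_cog <- max.col(align, ties.method = "first")
  u_curv <- max.col(curv, ties.method = "first")
  u <- ifelse(cog_norm > 0.1, u_cog, u_curv)

  fap <- NB[cbind(seq_along(u), iplus[u])]
  fam <- NB[cbind(seq_along(u), iminus[u])]
  fa0 <- NB[, center]
  keep <- fa0 >= fap & fa0 >= fam & (fa0 > fap | fa0 > fam)
  if (!any(keep)) return(empty())

  mask <- array(FALSE, d)
  mask[cand[keep]] <- TRUE
  structure(list(mask = mask,
                 idx = ci[keep, , drop = FALSE],
                 dirs = D13[u[keep], , drop = FALSE],
                 fa_threshold = fa_threshold, dim = d,
                 voxdim = template_fa$voxdim),
            class = "wm_skeleton")
}

#' @export
print.wm_skeleton <- function(x, ...) {
  cat(sprintf("WM skeleton: %d voxels (FA threshold %.2f) on a %s grid\n",
              nrow(x$idx), x$fa_threshold, paste(x$dim, collapse = " x ")))
  invisible(x)
}

#' Project subject maps onto the skeleton, driven by the subject FA
#'
#' For each skeleton voxel the subject FA is searched along the stored
#' perpendicular direction (both ways, up to `search_radius` steps); the
#' voxel with maximal subject FA is located, the skeletonized FA takes
#' that maximum, and every other metric takes its value at that same
#' located voxel. Ties prefer the smallest step (on-skeleton first, then
#' alternating +1, -1, +2, ...).
#'
#' @param subject_fa Subject FA [scalar_map()] on the template grid.
#' @param other_maps List of further [scalar_map()]s for the same subject.
#' @param skel A `wm_skeleton` from [build_skeleton()].
#' @param search_radius Maximum search distance in steps (default 4).
#' @param subject_id Optional provenance string.
#' @return List of `skeletonized_map` objects (subject FA first), each
#'   with `values`, `idx` (skeleton voxels), `located` (sampled voxels),
#'   `kind`, `subject_id`, `mask_applied = FALSE`.
#' @export
project_onto_skeleton <- function(subject_fa, other_maps = list(), skel,
                                  search_radius = 4, subject_id = NULL) {
  stopifnot(inherits(subject_fa, "scalar_map"), inherits(skel, "wm_skeleton"))
  maps <- c(list(subject_fa), other_maps)
  for (m in maps) {
    stopifnot(inherits(m, "scalar_map"))
    if (!all(dim(m$data) == skel$dim))
      stop(sprintf("map grid mismatch: %s is %s, skeleton grid is %s",
                   m$kind, paste(dim(m$data), collapse = "x"),
                   paste(skel$dim, collapse = "x")))
  }
  n <- nrow(skel$idx)
  if (n == 0L) stop("cannot project onto an empty skeleton")
  steps <- c(0, as.vector(rbind(seq_len(search_radius),
                                -seq_len(search_radius))))
  d <- skel$dim
  fa <- subject_fa$data

  # candidate FA per (skeleton voxel, step); out-of-bounds/NaN -> -Inf
  val <- matrix(-Inf, n, length(steps))
  pos <- array(NA_integer_, c(n, length(steps)))
  for (si in seq_along(steps)) {
    s <- steps[si]
    p1 <- skel$idx[, 1] + s * skel$dirs[, 1]
    p2 <- skel$idx[, 2] + s * skel$dirs[, 2]
    p3 <- skel$idx[, 3] + s * skel$dirs[, 3]
    ok <- p1 >= 1 & p1 <= d[1] & p2 >= 1 & p2 <= d[2] & p3 >= 1 & p3 <= d[3]
    lin <- p1 + (p2 - 1) * d[1] + (p3 - 1) * d[1] * d[2]
    v <- rep(-Inf, n)
    v[ok] <- fa[lin[ok]]
    v[!is.finite(v)] <- -Inf
    val[, si] <- v
    pos[ok, si] <- lin[ok]
  }
  best <- max.col(val, ties.method = "first")
  loc <- pos[cbind(seq_len(n), best)]
  fa_val <- val[cbind(seq_len(n), best)]
  fa_val[!is.finite(fa_val)] <- NaN
  loc_idx <- arrayInd(loc, d)

  out <- vector("list", length(maps))
  for (mi in seq_along(maps)) {
    v <- if (mi == 1L) fa_val else maps[[mi]]$data[loc]
    out[[mi]] <- structure(list(kind = maps[[mi]]$kind, values = v,
                                idx = skel$idx, located = loc_idx,
                                subject_id = subject_id,
                                mask_applied = FALSE, dim = d),
                           class = "skeletonized_map")
  }
  names(out) <- vapply(maps, function(m) m$kind, "")
  out
}

#' @export
print.skeletonized_map <- function(x, ...) {
  cat(sprintf("Skeletonized %s map%s: %d voxels%s\n", x$kind,
              if (!is.null(x$subject_id))
                paste0(" (", x$subject_id, ")") else "",
              length(x$values),
              if (x$mask_applied) ", custom mask applied" else ""))
  invisible(x)
}

#' Restrict a skeletonized map to the custom mask
#'
#' Voxels outside the mask are dropped from the value set (set
#' restriction, not zeroing: injected zeros would corrupt the histogram
#' percentiles the peak width is built on).
#'
#' @param skel_map A `skeletonized_map`.
#' @param custom_mask Binary [scalar_map()] on the template grid.
#' @return The masked `skeletonized_map` with `mask_applied = TRUE`.
#' @export
apply_custom_mask <- function(skel_map, custom_mask) {
  stopifnot(inherits(skel_map, "skeletonized_map"),
            inherits(custom_mask, "scalar_map"))
  md <- custom_mask$data
  if (!all(dim(md) == skel_map$dim)) stop("mask grid mismatch")
  fin <- md[is.finite(md)]
  if (!all(fin %in% c(0, 1))) stop("custom mask must be binary (0/1)")
  d <- skel_map$dim
  lin <- skel_map$idx[, 1] + (skel_map$idx[, 2] - 1) * d[1] +
    (skel_map$idx[, 3] - 1) * d[1] * d[2]
  keep <- is.finite(md[lin]) & md[lin] == 1
  if (!any(keep)) warning("custom mask removes every skeleton voxel")
  structure(list(kind = skel_map$kind,
                 values = skel_map$values[keep],
                 idx = skel_map$idx[keep, , drop = FALSE],
                 located = skel_map$located[keep, , drop = FALSE],
                 subject_id = skel_map$subject_id,
                 mask_applied = TRUE, dim = d),
            class = "skeletonized_map")
}
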