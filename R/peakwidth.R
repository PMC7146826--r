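# Histogram peak width: the distance between the 5th and 95th percentiles
# of a skeletonized metric's value set. Percentiles use linear
# interpolation with (n-1)-spacing (position q*(n-1) between order
# statistics), i.e. stats::quantile type 7 — no histogram binning is ever
# performed, so no bandwidth parameter enters.

MIN_PW_VALUES <- 20L

#' Peak width of a value set
#'
#' @param values Numeric vector of masked skeletonized metric values; all
#'   must be finite and at least 20 are required for stable percentiles.
#' @return List with `p5`, `p95` and `width = p95 - p5` (same units as
#'   the input).
#' @export
peak_width <- function(values) {
  values <- as.numeric(values)
  if (any(!is.finite(values)))
    stop("non-finite values in the skeletonized set; mask before peak width")
  if (length(values) < MIN_PW_VALUES)
    stop(sprintf("peak width needs >= %d values, got %d",
                 MIN_PW_VALUES, length(values)))
  q <- quantile(values, c(0.05, 0.95), type = 7, names = FALSE)
  list(p5 = q[1], p95 = q[2], width = q[2] - q[1])
}

#' All six peak-width metrics for one subject
#'
#' @param skel_maps Named list of six masked `skeletonized_map`s with
#'   kinds MD, FA, AD, RD, NDI, ODI sampled on identical voxel supports
#'   (the FA-driven projection guarantees this).
#' @param subject_id Subject identifier (taken from the maps if absent).
#' @return A `ps_result`: list with `subject_id`, the six widths
#'   (`psmd`, `psfa`, `psad`, `psrd`, `psndi`, `psodi`), per-metric `p5`
#'   and `p95`, and the shared voxel count `n_voxels`.
#' @export
compute_ps_all <- function(skel_maps, subject_id = NULL) {
  kinds <- vapply(skel_maps, function(m) m$kind, "")
  names(skel_maps) <- kinds
  miss <- setdiff(SCALAR_KINDS, kinds)
  if (length(miss))
    stop("missing skeletonized map(s): ", paste(miss, collapse = ", "))
  ref <- skel_maps[[SCALAR_KINDS[1]]]
  if (is.null(subject_id)) subject_id <- ref$subject_id
  for (k in SCALAR_KINDS) {
    m <- skel_maps[[k]]
    if (!isTRUE(m$mask_applied))
      stop("skeletonized ", k, " map has not been masked")
    if (nrow(m$idx) != nrow(ref$idx) || !all(m$idx == ref$idx))
      stop("differing voxel supports across metrics (", k,
           " vs ", ref$kind, ")")
  }
  widths <- lapply(skel_maps[SCALAR_KINDS],
                   function(m) peak_width(m$values))
  res <- list(subject_id = subject_id, n_voxels = nrow(ref$idx))
  for (i in seq_along(SCALAR_KINDS)) {
    m <- PS_METRICS[i]
    res[[m]] <- widths[[i]]$width
    res[[paste0(m, "_p5")]] <- widths[[i]]$p5
    res[[paste0(m, "_p95")]] <- widths[[i]]$p95
  }
  structure(res, class = "ps_result")
}

#' @export
print.ps_result <- function(x, ...) {
  cat(sprintf("Peak-width metrics for %s (%d skeleton voxels):\n",
              x$subject_id, x$n_voxels))
  for (m in PS_METRICS)
    cat(sprintf("  %-6s %8.4f  (p5 %8.4f, p95 %8.4f)\n",
                toupper(m), x[[m]], x[[paste0(m, "_p5")]],
                x[[paste0(m, "_p95")]]))
  invisible(x)
}

#' Collect per-subject peak-width results into a data frame
#'
#' @param results List of `ps_result` objects.
#' @return Data frame with one row per subject: `subject_id`, `n_voxels`,
#'   and per metric the width plus `_p5`/`_p95` columns.
#' @export
ps_results_table <- function(results) {
  do.call(rbind, lapply(results, function(r)
    as.data.frame(unclass(r), stringsAsFactors = FALSE)))
}
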