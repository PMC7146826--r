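#' @importFrom stats coef cor.test glm.fit lm median optim p.adjust pchisq
#'   quantile rnorm runif sd t.test wilcox.test setNames binomial
#' @importFrom utils read.csv write.csv
NULL

# b-values at or below this (s/mm^2) are treated as unweighted baselines;
# scanners commonly report small nonzero values for b0 volumes.
B0_MAX <- 50

#' Construct a diffusion gradient table
#'
#' A gradient table pairs one b-value (s/mm^2) with one gradient direction
#' per acquired volume. Directions for diffusion-weighted volumes must be
#' unit vectors; directions for b=0 baselines are arbitrary.
#'
#' @param bvals Numeric vector of b-values, one per volume (s/mm^2).
#' @param bvecs 3 x n numeric matrix of gradient directions (columns are
#'   volumes), or an n x 3 matrix which is transposed automatically.
#' @return An object of class `gradient_table`: a list with elements
#'   `bvals` (numeric) and `bvecs` (3 x n matrix).
#' @export
gradient_table <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L && ncol(bvecs) == 3L) bvecs <- t(bvecs)
  if (nrow(bvecs) != 3L)
    stop("gradient directions must form a 3 x n (or n x 3) matrix")
  if (length(bvals) != ncol(bvecs))
    stop(sprintf("gradient table mismatch: %d b-values but %d directions",
                 length(bvals), ncol(bvecs)))
  if (any(!is.finite(bvals)) || any(bvals < 0))
    stop("all b-values must be finite and non-negative")
  if (!any(bvals <= B0_MAX))
    stop("gradient table contains no b=0 baseline volume")
  dw <- bvals > B0_MAX
  if (any(dw)) {
    nrm <- sqrt(colSums(bvecs[, dw, drop = FALSE]^2))
    bad <- abs(nrm - 1) > 1e-3
    if (any(bad)) {
      if (all(abs(nrm[bad] - 1) <= 0.05)) {
        warning(sprintf(
          "renormalizing %d gradient direction(s) within 5%% of unit length",
          sum(bad)))
        idx <- which(dw)[bad]
        bvecs[, idx] <- sweep(bvecs[, idx, drop = FALSE], 2, nrm[bad], "/")
      } else {
        stop("non-unit gradient direction at b > 0 (off by more than 5%)")
      }
    }
  }
  structure(list(bvals = bvals, bvecs = unname(bvecs)),
            class = "gradient_table")
}

#' @export
print.gradient_table <- function(x, ...) {
  shells <- table(round(x$bvals[x$bvals > B0_MAX]))
  cat(sprintf("Gradient table: %d volumes (%d b0)\n",
              length(x$bvals), sum(x$bvals <= B0_MAX)))
  for (b in names(shells))
    cat(sprintf("  shell b=%s s/mm^2: %d directions\n", b, shells[[b]]))
  invisible(x)
}

#' @export
length.gradient_table <- function(x) length(x$bvals)

is_b0 <- function(gtab) gtab$bvals <= B0_MAX

#' Construct a 4-D diffusion-weighted volume
#'
#' @param data 4-D array (x, y, z, volume) of non-negative signal values.
#' @param voxdim Numeric length-3 voxel dimensions in mm.
#' @param gradients A [gradient_table()] whose length equals `dim(data)[4]`.
#' @return An object of class `dwi_volume`.
#' @export
dwi_volume <- function(data, voxdim, gradients) {
  stopifnot(inherits(gradients, "gradient_table"))
  data <- as.array(data)
  if (length(dim(data)) != 4L)
    stop("DWI data must be a 4-D array (x, y, z, volume)")
  if (dim(data)[4] != length(gradients$bvals))
    stop(sprintf(
      "volume count mismatch: image has %d volumes, gradient table has %d",
      dim(data)[4], length(gradients$bvals)))
  voxdim <- as.numeric(voxdim)
  if (length(voxdim) != 3L || any(!is.finite(voxdim)) || any(voxdim <= 0))
    stop("voxel dimensions must be three positive numbers (mm)")
  if (any(data < 0, na.rm = TRUE))
    stop("signal values must be non-negative")
  structure(list(data = data, voxdim = voxdim, gradients = gradients),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("DWI volume: %d x %d x %d voxels, %d volumes, voxels %s mm\n",
              d[1], d[2], d[3], d[4],
              paste(format(x$voxdim), collapse = " x ")))
  print(x$gradients)
  invisible(x)
}

#' Read a multi-shell DWI acquisition from NIfTI + bval/bvec files
#'
#' The b-value file is a whitespace-separated row of numbers; the b-vector
#' file uses the FSL 3-row layout (rows x/y/z, columns volumes). A 3-column
#' layout is auto-detected from the matrix shape and transposed. Directions
#' at b > 0 that are within 5% of unit length are renormalized with a
#' warning; larger deviations are an error.
#'
#' @param image_path Path to a 4-D NIfTI file.
#' @param bval_path,bvec_path Paths to the gradient text files.
#' @return A [dwi_volume()].
#' @export
read_dwi <- function(image_path, bval_path, bvec_path) {
  img <- RNifti::readNifti(image_path)
  data <- as.array(img)
  if (length(dim(data)) != 4L)
    stop(sprintf("'%s' is not a 4-D image", image_path))
  bvals <- scan(bval_path, quiet = TRUE)
  bvec_rows <- lapply(readLines(bvec_path), function(l) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
    v[!is.na(v)]
  })
  bvec_rows <- bvec_rows[lengths(bvec_rows) > 0]
  ncols <- unique(lengths(bvec_rows))
  if (length(ncols) != 1L)
    stop("ragged bvec file: rows have differing lengths")
  bvecs <- do.call(rbind, bvec_rows)
  if (nrow(bvecs) != 3L && ncol(bvecs) == 3L) bvecs <- t(bvecs)
  nvol <- dim(data)[4]
  if (nrow(bvecs) != 3L || length(bvals) != nvol || ncol(bvecs) != nvol)
    stop(sprintf(
      "inconsistent acquisition: image has %d volumes, bval file %d entries, bvec file %d columns",
      nvol, length(bvals), if (nrow(bvecs) == 3L) ncol(bvecs) else nrow(bvecs)))
  vd <- RNifti::pixdim(img)[1:3]
  dwi_volume(data, vd, gradient_table(bvals, bvecs))
}

SCALAR_KINDS <- c("MD", "FA", "AD", "RD", "NDI", "ODI")

#' Construct a 3-D scalar map
#'
#' Diffusivity maps (MD/AD/RD) are in units of 1e-3 mm^2/s; FA, NDI and
#' ODI are dimensionless in [0, 1]. NaN marks voxels outside the brain.
#'
#' @param kind One of `"MD"`, `"FA"`, `"AD"`, `"RD"`, `"NDI"`, `"ODI"`,
#'   or `"mask"` for binary masks / templates that carry no metric units.
#' @param data 3-D numeric array.
#' @param voxdim Length-3 voxel dimensions in mm.
#' @return An object of class `scalar_map`.
#' @export
scalar_map <- function(kind, data, voxdim) {
  kind <- toupper(as.character(kind)[1])
  if (!kind %in% c(SCALAR_KINDS, "MASK"))
    stop("unknown scalar map kind: ", kind)
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("scalar map data must be 3-D")
  voxdim <- as.numeric(voxdim)
  if (length(voxdim) != 3L || any(voxdim <= 0))
    stop("voxel dimensions must be three positive numbers (mm)")
  fin <- data[is.finite(data)]
  if (kind %in% c("FA", "NDI", "ODI") &&
      length(fin) && (min(fin) < -1e-6 || max(fin) > 1 + 1e-6))
    stop(kind, " values must lie in [0, 1] where defined")
  if (kind %in% c("MD", "AD", "RD") && length(fin) && min(fin) < -1e-9)
    stop(kind, " values must be non-negative")
  structure(list(kind = kind, data = data, voxdim = voxdim),
            class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  d <- dim(x$data)
  rng <- range(x$data[is.finite(x$data)])
  cat(sprintf("%s map: %d x %d x %d voxels, range [%.4g, %.4g]\n",
              x$kind, d[1], d[2], d[3], rng[1], rng[2]))
  invisible(x)
}

#' Write a scalar map to NIfTI
#'
#' Data are stored as 32-bit float; NaN (outside-mask) voxels are
#' preserved. A round trip through [read_scalar_map()] reproduces values
#' to float32 precision and the voxel dimensions exactly.
#'
#' @param map A [scalar_map()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_scalar_map <- function(map, path) {
  stopifnot(inherits(map, "scalar_map"))
  data <- map$data
  attr(data, "pixdim") <- map$voxdim
  RNifti::writeNifti(data, path, datatype = "float")
  invisible(path)
}

#' Read a scalar map from NIfTI
#'
#' @param path Path to a 3-D NIfTI file.
#' @param kind Metric kind; see [scalar_map()].
#' @return A [scalar_map()].
#' @export
read_scalar_map <- function(path, kind) {
  img <- RNifti::readNifti(path)
  data <- as.array(img)
  if (length(dim(data)) == 4L && dim(data)[4] == 1L)
    data <- array(data, dim(data)[1:3])
  scalar_map(kind, data, RNifti::pixdim(img)[1:3])
}

#' Write a gradient table as FSL-style bval/bvec text files
#'
#' @param gtab A [gradient_table()].
#' @param bval_path,bvec_path Output paths.
#' @export
write_gradients <- function(gtab, bval_path, bvec_path) {
  stopifnot(inherits(gtab, "gradient_table"))
  writeLines(paste(format(gtab$bvals, trim = TRUE), collapse = " "),
             bval_path)
  writeLines(apply(gtab$bvecs, 1, function(r)
    paste(format(r, digits = 10, trim = TRUE), collapse = " ")), bvec_path)
  invisible(NULL)
}

PS_METRICS <- c("psmd", "psfa", "psad", "psrd", "psndi", "psodi")
GA_RANGE <- c(22, 46)

#' Read and validate a cohort table
#'
#' The CSV must have columns `subject_id`, `group` (term/preterm),
#' `ga_birth` and `ga_scan` (gestational age in weeks); metric columns
#' (`psmd`, `psfa`, `psad`, `psrd`, `psndi`, `psodi`) are optional and may
#' be filled in later by the pipeline.
#'
#' @param csv_path Path to the cohort CSV file.
#' @return A `cohort_table`: a data frame with normalized group labels.
#' @export
read_cohort <- function(csv_path) {
  df <- read.csv(csv_path, stringsAsFactors = FALSE)
  as_cohort_table(df)
}

#' Validate a data frame as a cohort table
#'
#' @param df Data frame with at least `subject_id`, `group`, `ga_birth`,
#'   `ga_scan`.
#' @return The validated data frame with class `cohort_table`.
#' @export
as_cohort_table <- function(df) {
  req <- c("subject_id", "group", "ga_birth", "ga_scan")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("cohort table missing required column(s): ",
         paste(miss, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  df$group <- tolower(trimws(as.character(df$group)))
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject id(s): ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]),
               collapse = ", "))
  if (any(!nzchar(df$group)) || any(is.na(df$group)))
    stop("empty group label")
  for (col in c("ga_birth", "ga_scan")) {
    v <- df[[col]]
    bad <- which(!is.finite(v) | v < GA_RANGE[1] | v > GA_RANGE[2])
    if (length(bad))
      stop(sprintf("%s out of plausible range [%g, %g] weeks in row(s) %s",
                   col, GA_RANGE[1], GA_RANGE[2],
                   paste(bad, collapse = ", ")))
  }
  bad <- which(df$ga_birth > df$ga_scan)
  if (length(bad))
    stop("ga_birth exceeds ga_scan in row(s) ", paste(bad, collapse = ", "))
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("Cohort: %d subjects (%s)\n", nrow(x),
              paste(sprintf("%s n=%d", names(table(x$group)),
                            as.integer(table(x$group))), collapse = ", ")))
  NextMethod()
}
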