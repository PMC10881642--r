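#' Separable 3-D Gaussian smoothing
#'
#' Smooths a 3-D scalar image with an isotropic Gaussian kernel specified by
#' its full width at half maximum (FWHM) in millimetres, converted per axis
#' to voxel units via `sigma = fwhm / (2 * sqrt(2 * log(2)))`. Convolution
#' is separable with reflect padding at the boundaries, so interior image
#' mass is conserved and constant images are reproduced exactly.
#'
#' @param image 3-D numeric array.
#' @param fwhm_mm Positive scalar FWHM in mm.
#' @param voxel_size_mm Numeric length-3 voxel dimensions in mm.
#' @return Smoothed array of the same dimension.
#' @export
gaussian_smooth <- function(image, fwhm_mm, voxel_size_mm = c(1, 1, 1)) {
  if (length(dim(image)) != 3L) stop("image must be a 3-D array")
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm <= 0) {
    stop("fwhm_mm must be a positive scalar")
  }
  if (any(voxel_size_mm <= 0)) stop("voxel sizes must be positive")
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  out <- image
  for (axis in 1:3) {
    k <- gaussian_kernel_1d(sigma_vox[axis])
    out <- convolve_axis_reflect(out, k, axis)
  }
  out
}

gaussian_kernel_1d <- function(sigma) {
  half <- max(1L, ceiling(4 * sigma))
  x <- (-half):half
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# reflect-padded 1-D convolution applied along one axis of a 3-D array
convolve_axis_reflect <- function(a, k, axis) {
  d <- dim(a)
  n <- d[axis]
  half <- (length(k) - 1L) / 2L
  # reflect index: 1,2,...,n with mirror at both ends (no edge repetition
  # beyond single reflection; clamp for kernels wider than the axis)
  idx <- seq_len(n + 2L * half) - half
  idx <- ifelse(idx < 1L, 2L - idx, idx)
  idx <- ifelse(idx > n, 2L * n - idx, idx)
  idx <- pmin(pmax(idx, 1L), n)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  m <- matrix(ap, nrow = dp[1])
  padded <- m[idx, , drop = FALSE]
  res <- matrix(0, nrow = dp[1], ncol = ncol(m))
  for (j in seq_along(k)) {
    res <- res + k[j] * padded[seq_len(dp[1]) + (j - 1L), , drop = FALSE]
  }
  out <- array(res, dim = dp)
  aperm(out, order(perm))
}

#' Extract regional means from a labelled image
#'
#' Computes the mean image value within each atlas VOI of a label map, in
#' canonical atlas order, together with per-region voxel counts for volume
#' weighting.
#'
#' @param image 3-D numeric array (for example a smoothed FDG-PET volume in
#'   atlas space).
#' @param labels 3-D integer array of the same dimension, holding atlas
#'   labels.
#' @param atlas A `dlb_atlas`.
#' @return A tibble with columns `label`, `name`, `mean`, `n_voxels`,
#'   one row per region in atlas order.
#' @export
extract_voi_means <- function(image, labels, atlas = hammers_atlas()) {
  if (!identical(dim(image), dim(labels))) {
    stop("image and label map must share dimensions")
  }
  lab <- as.integer(labels)
  img <- as.numeric(image)
  want <- atlas$regions$label
  present <- unique(lab)
  absent <- setdiff(want, present)
  if (length(absent)) {
    stop("atlas label(s) absent from label map: ",
         paste(atlas$regions$name[match(absent, want)], collapse = ", "))
  }
  f <- factor(lab, levels = want)
  keep <- !is.na(f)
  sums <- tapply(img[keep], f[keep], sum)
  counts <- tapply(rep(1L, sum(keep)), f[keep], sum)
  tibble::tibble(
    label = want,
    name = atlas$regions$name,
    mean = as.numeric(sums / counts),
    n_voxels = as.integer(counts)
  )
}

#' Read a NIfTI volume as an array
#'
#' Convenience wrapper for image-space ingestion; requires the RNifti
#' package. The canonical pipeline input is the regional table, and images
#' are assumed to be in atlas space already (no registration is performed).
#'
#' @param path Path to a NIfTI-1 file.
#' @return A numeric array.
#' @export
read_image_volume <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("reading NIfTI volumes requires the RNifti package")
  }
  as.array(RNifti::readNifti(path))
}
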