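#' Nucleus image container
#'
#' A 2D intensity grid with physical pixel size, a nucleus mask and an
#' exclusion mask (nucleoli / extranuclear regions). Excluded pixels are
#' zeroed before box-based heterogeneity analysis.
#'
#' @param intensity non-negative numeric matrix.
#' @param pixel_size um per pixel.
#' @param nucleus_mask logical matrix, same shape (default: all `TRUE`).
#' @param exclusion_mask logical matrix, same shape (default: all `FALSE`).
#' @return an object of class `nucleus_image`.
#' @export
nucleus_image <- function(intensity, pixel_size,
                          nucleus_mask = NULL, exclusion_mask = NULL) {
  intensity <- as.matrix(intensity)
  if (any(intensity < 0)) stop("image intensities must be non-negative")
  stopifnot(pixel_size > 0)
  if (is.null(nucleus_mask))
    nucleus_mask <- matrix(TRUE, nrow(intensity), ncol(intensity))
  if (is.null(exclusion_mask))
    exclusion_mask <- matrix(FALSE, nrow(intensity), ncol(intensity))
  if (!identical(dim(nucleus_mask), dim(intensity)) ||
      !identical(dim(exclusion_mask), dim(intensity)))
    stop("masks must share the image grid shape")
  structure(list(intensity = intensity, pixel_size = pixel_size,
                 nucleus_mask = nucleus_mask, exclusion_mask = exclusion_mask),
            class = "nucleus_image")
}

#' @export
print.nucleus_image <- function(x, ...) {
  cat(sprintf("nucleus_image: %d x %d px (%.3f um/px), %d nucleus px, %d excluded\n",
              nrow(x$intensity), ncol(x$intensity), x$pixel_size,
              sum(x$nucleus_mask), sum(x$exclusion_mask)))
  invisible(x)
}

#' Fluorescence trace container
#'
#' Time series of bleached-ROI and reference-ROI (unbleached) intensities,
#' with the number of pre-bleach frames marking the bleach event.
#'
#' @param times acquisition times in seconds, strictly increasing.
#' @param bleached bleached-ROI intensities (> 0).
#' @param reference reference-ROI intensities (> 0).
#' @param pre_bleach_count number of frames acquired before the bleach (>= 1).
#' @return an object of class `fluor_trace`.
#' @export
fluor_trace <- function(times, bleached, reference, pre_bleach_count) {
  stopifnot(length(times) == length(bleached),
            length(times) == length(reference))
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  if (pre_bleach_count < 1) stop("pre_bleach_count must be >= 1")
  if (pre_bleach_count >= length(times)) stop("no post-bleach frames")
  if (any(bleached <= 0) || any(reference <= 0))
    stop("intensities must be positive")
  structure(list(times = as.numeric(times), bleached = as.numeric(bleached),
                 reference = as.numeric(reference),
                 pre_bleach_count = as.integer(pre_bleach_count)),
            class = "fluor_trace")
}

#' @export
print.fluor_trace <- function(x, ...) {
  cat(sprintf("fluor_trace: %d frames (%d pre-bleach), t in [%.3g, %.3g] s\n",
              length(x$times), x$pre_bleach_count, min(x$times), max(x$times)))
  invisible(x)
}

#' Voxel cloud container
#'
#' Integer 3D voxel coordinates with intensities, for radius-of-gyration
#' analysis of segmented chromosome territories. Voxel size may be
#' anisotropic (z typically differs from xy).
#'
#' @param coords integer matrix with columns x, y, z (no duplicate rows).
#' @param intensity non-negative intensities, one per voxel.
#' @param voxel_size length-3 vector, um per voxel along x, y, z (scalar
#'   recycled).
#' @param label optional component label.
#' @return an object of class `voxel_cloud`.
#' @export
voxel_cloud <- function(coords, intensity, voxel_size, label = NA_integer_) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, nrow(coords) == length(intensity))
  if (nrow(coords) == 0) stop("voxel cloud must contain at least one voxel")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  if (all(intensity == 0)) stop("at least one voxel intensity must be positive")
  if (anyDuplicated(coords)) stop("duplicate voxel coordinates")
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  stopifnot(all(voxel_size > 0))
  structure(list(coords = coords, intensity = as.numeric(intensity),
                 voxel_size = voxel_size, label = label),
            class = "voxel_cloud")
}

#' @export
print.voxel_cloud <- function(x, ...) {
  cat(sprintf("voxel_cloud: %d voxels, voxel size %s um, label %s\n",
              nrow(x$coords), paste(signif(x$voxel_size, 3), collapse = "x"),
              x$label))
  invisible(x)
}
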