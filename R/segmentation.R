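#' Threshold Doppler intensities inside the region of interest
#'
#' Selects voxels whose power-Doppler magnitude reaches the intensity
#' threshold (default 100 of 255) and that lie inside the vascular region
#' mask; the selection is the utero-placental vascular volume (uPVV). The
#' volume in cm^3 is exactly `selected-voxel count * sx*sy*sz / 1000`. No
#' connected-component filtering is applied by default: artefact removal in
#' the reference workflow is manual, so the optional `min_component_voxels`
#' filter is intended for phantom experiments only.
#'
#' @param vol a [doppler_volume()].
#' @param roi a [region_mask()] with the same shape.
#' @param tau intensity threshold in \[0, 255\]; default 100.
#' @param inclusive logical; `TRUE` (default) selects `intensity >= tau`,
#'   `FALSE` selects `intensity > tau`.
#' @param min_component_voxels drop 26-connected selection components smaller
#'   than this many voxels; 0 (default) disables the filter.
#' @return An object of class `vessel_volume`: `selection` (logical array),
#'   `spacing`, `threshold`, `inclusive`, and `upvv_cm3`.
#' @examples
#' vol <- doppler_volume(array(c(99L, 100L, 255L, 0L), c(4, 1, 1)), 0.5)
#' roi <- region_mask(array(1, c(4, 1, 1)), 0.5)
#' vv <- apply_threshold(vol, roi)
#' sum(vv$selection)  # 2: intensities 100 and 255
#' @export
apply_threshold <- function(vol, roi, tau = 100L, inclusive = TRUE,
                            min_component_voxels = 0L) {
  stopifnot(inherits(vol, "doppler_volume"), inherits(roi, "region_mask"))
  stop_shape_mismatch(roi$mask, vol$intensities, what = "ROI mask")
  if (length(tau) != 1L || is.na(tau) || tau < 0 || tau > 255)
    stop("`tau` must be a single value in [0, 255]", call. = FALSE)
  sel <- if (inclusive) vol$intensities >= tau else vol$intensities > tau
  sel <- sel & roi$mask
  if (min_component_voxels > 0L && any(sel)) {
    lab <- .label_components_cpp(sel, dim(sel))
    keep <- which(tabulate(lab[lab > 0L]) >= min_component_voxels)
    sel <- array(lab %in% keep, dim(sel))
  }
  structure(list(selection = sel,
                 spacing = vol$spacing,
                 threshold = as.integer(tau),
                 inclusive = inclusive,
                 upvv_cm3 = sum(sel) * voxel_volume_cm3(vol$spacing)),
            class = "vessel_volume")
}

#' @export
print.vessel_volume <- function(x, ...) {
  cat("<vessel_volume> tau=", x$threshold, if (x$inclusive) " (inclusive)" else " (exclusive)",
      ", ", sum(x$selection), " voxels, uPVV = ",
      format(x$upvv_cm3), " cm^3\n", sep = "")
  invisible(x)
}

#' Physical volume of a binary mask in cm^3
#'
#' Used to obtain the placental volume (PV) from a placenta mask that already
#' excludes the gestational sac. PV may instead be supplied as a scalar per
#' subject downstream; see [run_pipeline()].
#'
#' @param mask a [region_mask()].
#' @return Volume in cm^3 (voxel count times voxel volume).
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "region_mask"))
  n <- sum(mask$mask)
  if (n == 0L) warning("mask is empty; volume is 0 cm^3", call. = FALSE)
  n * voxel_volume_cm3(mask$spacing)
}
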