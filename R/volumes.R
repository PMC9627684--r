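#' Construct a Doppler intensity volume
#'
#' A `doppler_volume` holds an 8-bit power-Doppler magnitude grid together
#' with its physical voxel spacing. Intensities must already be in
#' \[0, 255\]; values outside that range are an error, never clamped
#' silently.
#'
#' @param intensities 3D numeric/integer array, values in \[0, 255\].
#' @param spacing numeric length 3, voxel spacing `c(sx, sy, sz)` in mm
#'   (or a single number for isotropic voxels).
#' @return An object of class `doppler_volume`: a list with elements
#'   `intensities` (integer array) and `spacing` (named numeric, mm).
#' @examples
#' vol <- doppler_volume(array(0L, c(4, 4, 4)), spacing = 0.5)
#' dim(vol$intensities)
#' @export
doppler_volume <- function(intensities, spacing) {
  if (length(dim(intensities)) != 3L)
    stop("`intensities` must be a 3D array, got ", length(dim(intensities)), " dims", call. = FALSE)
  if (any(dim(intensities) < 1L)) stop("volume must have >= 1 voxel per axis", call. = FALSE)
  if (anyNA(intensities)) stop("intensities contain missing values", call. = FALSE)
  rng <- range(intensities)
  if (rng[1] < 0 || rng[2] > 255)
    stop("intensity outside [0, 255]: range observed [", rng[1], ", ", rng[2], "]", call. = FALSE)
  if (any(intensities != round(intensities)))
    stop("intensities must be integer-valued 8-bit data", call. = FALSE)
  spacing <- check_spacing(spacing)
  storage.mode(intensities) <- "integer"
  structure(list(intensities = intensities, spacing = spacing), class = "doppler_volume")
}

#' Construct a binary region mask
#'
#' Region masks represent either the manually segmented vascular region of
#' interest (decidua + placenta, embryo and myometrium removed) or a placenta
#' mask used for placental-volume (PV) computation. Any nonzero value is
#' stored as `TRUE`.
#'
#' @param mask 3D array; nonzero entries are selected.
#' @param spacing voxel spacing in mm (see [doppler_volume()]).
#' @param role `"vascular-ROI"` or `"placenta"`.
#' @return An object of class `region_mask` with elements `mask` (logical
#'   array), `spacing` and `role`.
#' @export
region_mask <- function(mask, spacing, role = c("vascular-ROI", "placenta")) {
  role <- match.arg(role)
  if (length(dim(mask)) != 3L) stop("`mask` must be a 3D array", call. = FALSE)
  if (anyNA(mask)) stop("mask contains missing values", call. = FALSE)
  m <- mask != 0
  if (!any(m)) warning("region mask is empty", call. = FALSE)
  spacing <- check_spacing(spacing)
  structure(list(mask = m, spacing = spacing, role = role), class = "region_mask")
}

check_spacing <- function(spacing) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || anyNA(spacing) || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive finite values (mm)", call. = FALSE)
  names(spacing) <- c("sx", "sy", "sz")
  spacing
}

stop_shape_mismatch <- function(a, b, what = "mask") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("shape mismatch: %s is %s but volume is %s", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")), call. = FALSE)
  invisible(TRUE)
}

voxel_volume_cm3 <- function(spacing) prod(spacing) / 1000

#' @export
print.doppler_volume <- function(x, ...) {
  cat("<doppler_volume> ", paste(dim(x$intensities), collapse = " x "),
      " voxels, spacing (", paste(format(x$spacing), collapse = ", "), ") mm\n", sep = "")
  cat("  intensity range: [", min(x$intensities), ", ", max(x$intensities), "]\n", sep = "")
  invisible(x)
}

#' @export
print.region_mask <- function(x, ...) {
  cat("<region_mask> role=", x$role, ", ", sum(x$mask), " / ", length(x$mask),
      " voxels selected\n", sep = "")
  invisible(x)
}

# 0-based voxel coordinates of TRUE entries, as a tibble with physical positions
voxel_table <- function(mask, spacing) {
  w <- which(mask)
  d <- dim(mask)
  i0 <- w - 1L
  x <- i0 %% d[1]
  y <- (i0 %/% d[1]) %% d[2]
  z <- i0 %/% (d[1] * d[2])
  tibble(x = x, y = y, z = z,
         px = x * spacing[[1]], py = y * spacing[[2]], pz = z * spacing[[3]])
}
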