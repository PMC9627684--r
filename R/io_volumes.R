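#' Read a 3D Doppler volume from disk
#'
#' Supported containers: NIfTI-1 (`.nii`, `.nii.gz`), multi-page TIFF
#' (`.tif`, `.tiff`) and MetaImage (`.mha`, `.mhd` + raw). Spacing is taken
#' from the header where the format carries it (NIfTI pixdim, MetaImage
#' ElementSpacing); TIFF stores no 3D spacing, so `spacing` must be supplied.
#' An explicit `spacing` always overrides the header.
#'
#' Native GE Kretz `.vol` files are not parsed; export/convert them to one of
#' the supported containers first.
#'
#' @param path file path.
#' @param format one of `"nifti"`, `"tiff"`, `"metaimage"`; inferred from the
#'   file extension when `NULL`.
#' @param spacing optional voxel spacing override, mm (length 1 or 3).
#' @return A [doppler_volume()].
#' @export
read_volume <- function(path, format = NULL, spacing = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- format %||% guess_format(path)
  raw <- switch(format,
    nifti     = read_nifti_grid(path),
    tiff      = read_tiff_grid(path),
    metaimage = read_metaimage_grid(path),
    stop("unsupported format: ", format, call. = FALSE)
  )
  sp <- spacing %||% raw$spacing
  if (is.null(sp))
    stop("missing spacing: ", basename(path),
         " carries no voxel spacing metadata and no `spacing` override was given",
         call. = FALSE)
  doppler_volume(raw$data, spacing = sp)
}

#' Write a 3D volume to disk
#'
#' Inverse of [read_volume()]; NIfTI and MetaImage keep the spacing in the
#' header, TIFF does not (re-supply it on read).
#'
#' @param vol a [doppler_volume()] or [region_mask()] (masks are written as
#'   0/1 intensities).
#' @param path output path; the extension selects the format unless `format`
#'   is given.
#' @inheritParams read_volume
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = NULL) {
  if (inherits(vol, "region_mask"))
    vol <- doppler_volume(array(as.integer(vol$mask), dim(vol$mask)), vol$spacing)
  stopifnot(inherits(vol, "doppler_volume"))
  format <- format %||% guess_format(path)
  switch(format,
    nifti     = write_nifti_grid(vol, path),
    tiff      = write_tiff_grid(vol, path),
    metaimage = write_metaimage_grid(vol, path),
    stop("unsupported format: ", format, call. = FALSE)
  )
  invisible(path)
}

#' Read a binary mask co-registered with a volume
#'
#' Any nonzero stored value is treated as selected. The mask must have
#' exactly the shape of its paired volume; an empty mask is allowed but
#' raises a warning.
#'
#' @param path file path (same formats as [read_volume()]).
#' @param paired the [doppler_volume()] the mask belongs to.
#' @param role `"vascular-ROI"` (the manual vascular-region segmentation) or
#'   `"placenta"`.
#' @inheritParams read_volume
#' @return A [region_mask()] sharing the paired volume's spacing.
#' @export
read_mask <- function(path, paired, role = c("vascular-ROI", "placenta"),
                      format = NULL) {
  stopifnot(inherits(paired, "doppler_volume"))
  role <- match.arg(role)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- format %||% guess_format(path)
  raw <- switch(format,
    nifti     = read_nifti_grid(path),
    tiff      = read_tiff_grid(path),
    metaimage = read_metaimage_grid(path),
    stop("unsupported format: ", format, call. = FALSE)
  )
  stop_shape_mismatch(raw$data, paired$intensities, what = basename(path))
  region_mask(raw$data, spacing = paired$spacing, role = role)
}

guess_format <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) return("nifti")
  if (grepl("\\.tiff?$", lower)) return("tiff")
  if (grepl("\\.(mha|mhd)$", lower)) return("metaimage")
  stop("cannot infer format from extension of ", basename(path),
       " (use `format`)", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- NIfTI (via RNifti) ----

read_nifti_grid <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1L, drop = TRUE]
  if (length(dim(arr)) != 3L) stop("non-3D NIfTI data in ", basename(path), call. = FALSE)
  arr <- array(as.vector(arr), dim(arr))  # drop NIfTI header attributes
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0)) sp <- NULL
  list(data = arr, spacing = sp)
}

write_nifti_grid <- function(vol, path) {
  img <- RNifti::asNifti(vol$intensities)
  RNifti::pixdim(img) <- unname(vol$spacing)
  RNifti::writeNifti(img, path)
}

## ---- multi-page TIFF (via tiff) ----
## page k = z slice; within a page rows = y, cols = x (standard raster order).

read_tiff_grid <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d2 <- dim(pages[[1]])
  if (length(d2) > 2L) stop("non-grayscale TIFF in ", basename(path), call. = FALSE)
  arr <- array(0L, c(d2[2], d2[1], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- t(pages[[k]])
  list(data = arr, spacing = NULL)
}

write_tiff_grid <- function(vol, path) {
  pages <- lapply(seq_len(dim(vol$intensities)[3]),
                  function(k) t(vol$intensities[, , k]) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
}

## ---- MetaImage (.mha local / .mhd + raw): text header + raw block ----

meta_types <- c(MET_UCHAR = "integer", MET_CHAR = "integer",
                MET_USHORT = "integer", MET_SHORT = "integer",
                MET_UINT = "integer", MET_INT = "integer",
                MET_FLOAT = "double", MET_DOUBLE = "double")
meta_sizes <- c(MET_UCHAR = 1L, MET_CHAR = 1L, MET_USHORT = 2L, MET_SHORT = 2L,
                MET_UINT = 4L, MET_INT = 4L, MET_FLOAT = 4L, MET_DOUBLE = 8L)

read_metaimage_grid <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list(); data_offset <- 0L
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("truncated MetaImage header in ", basename(path), call. = FALSE)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed MetaImage header line: ", line, call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr[["NDims"]], "3")) stop("non-3D MetaImage data", call. = FALSE)
  if (identical(tolower(hdr[["CompressedData"]] %||% "false"), "true"))
    stop("compressed MetaImage data is not supported", call. = FALSE)
  dims <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  sp <- hdr[["ElementSpacing"]]
  sp <- if (is.null(sp)) NULL else as.numeric(strsplit(sp, "\\s+")[[1]])
  etype <- hdr[["ElementType"]] %||% "MET_UCHAR"
  if (!etype %in% names(meta_types)) stop("unsupported ElementType: ", etype, call. = FALSE)
  msb <- identical(tolower(hdr[["BinaryDataByteOrderMSB"]] %||%
                           hdr[["ElementByteOrderMSB"]] %||% "false"), "true")
  n <- prod(dims)
  if (identical(hdr[["ElementDataFile"]], "LOCAL")) {
    vals <- readBin(con, meta_types[[etype]], n = n, size = meta_sizes[[etype]],
                    signed = !etype %in% c("MET_UCHAR", "MET_USHORT"),
                    endian = if (msb) "big" else "little")
  } else {
    rawpath <- file.path(dirname(path), hdr[["ElementDataFile"]])
    if (!file.exists(rawpath)) stop("raw data file not found: ", rawpath, call. = FALSE)
    rcon <- file(rawpath, "rb"); on.exit(close(rcon), add = TRUE)
    vals <- readBin(rcon, meta_types[[etype]], n = n, size = meta_sizes[[etype]],
                    signed = !etype %in% c("MET_UCHAR", "MET_USHORT"),
                    endian = if (msb) "big" else "little")
  }
  if (length(vals) != n) stop("MetaImage data block shorter than DimSize implies", call. = FALSE)
  list(data = array(vals, dims), spacing = sp)
}

write_metaimage_grid <- function(vol, path) {
  d <- dim(vol$intensities)
  local <- grepl("\\.mha$", tolower(path))
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", paste(d, collapse = " ")),
           paste("ElementSpacing =", paste(format(unname(vol$spacing), scientific = FALSE),
                                           collapse = " ")),
           "ElementType = MET_UCHAR")
  if (local) {
    con <- file(path, "wb"); on.exit(close(con))
    writeLines(c(hdr, "ElementDataFile = LOCAL"), con)
    writeBin(as.raw(vol$intensities), con)
  } else {
    rawname <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
    writeLines(c(hdr, paste("ElementDataFile =", rawname)), path)
    con <- file(file.path(dirname(path), rawname), "wb"); on.exit(close(con))
    writeBin(as.raw(vol$intensities), con)
  }
}

## ---- tabular results ----

#' Canonical per-volume result columns
#'
#' The seven morphologic characteristics, in their fixed reporting order:
#' four voxel-class counts followed by the three length/thickness metrics.
#' @return Character vector of column names.
#' @export
upvs_characteristics <- function() {
  c("n_end", "n_vessel", "n_bif", "n_cross",
    "total_length_mm", "avg_vessel_length_mm", "avg_thickness_mm")
}

results_column_order <- function() {
  ch <- upvs_characteristics()
  c("id", "ga_weeks", "pv_cm3", "upvv_cm3", ch,
    paste0(ch, "_per_pv"), paste0(ch, "_per_upvv"))
}

#' Write per-volume characteristic tables
#'
#' One row per analysed volume, in a fixed documented column order
#' (identifiers, gestational age, PV, uPVV, the seven characteristics, then
#' the 14 density ratios); any extra columns follow. `format = "json"`
#' writes the identical content as a JSON array of records.
#'
#' @param records data frame with at least one row.
#' @param path output path.
#' @param format `"csv"` (default) or `"json"`; inferred from the extension
#'   when `NULL`.
#' @return `path`, invisibly.
#' @seealso [read_results()]
#' @export
write_results <- function(records, path, format = NULL) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) stop("empty records: nothing to write", call. = FALSE)
  format <- format %||% (if (grepl("\\.json$", tolower(path))) "json" else "csv")
  known <- intersect(results_column_order(), names(records))
  records <- records[, c(known, setdiff(names(records), known)), drop = FALSE]
  if (format == "csv") {
    write.csv(records, path, row.names = FALSE)
  } else if (format == "json") {
    jsonlite::write_json(records, path, digits = NA, na = "null")
  } else stop("unsupported results format: ", format, call. = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results()]
#' @inheritParams write_results
#' @return A tibble.
#' @export
read_results <- function(path, format = NULL) {
  format <- format %||% (if (grepl("\\.json$", tolower(path))) "json" else "csv")
  out <- if (format == "json") jsonlite::fromJSON(path) else read.csv(path)
  as_tibble(out)
}
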