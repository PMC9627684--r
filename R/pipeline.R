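#' Pipeline configuration
#'
#' Collects every tunable of the volume-to-characteristics pipeline. The
#' defaults reproduce the reference workflow: inclusive intensity threshold
#' of 100, no component-size filtering, EDT radii, voxel-count length
#' formula.
#'
#' @param threshold intensity threshold in \[0, 255\].
#' @param threshold_inclusive select `>= threshold` (default) or `>`.
#' @param min_component_voxels drop smaller 26-connected components
#'   (0 = off; intended for phantom experiments).
#' @param radius_mode `"edt"` or `"peel_iterations"` (see [skeletonize()]).
#' @param length_mode `"voxel_count"` or `"edge_sum"` (see [characterize()]).
#' @param seed integer seed recorded in provenance (the pipeline itself is
#'   deterministic; the seed feeds phantom/cohort generation).
#' @return A `run_config` list.
#' @export
run_config <- function(threshold = 100L, threshold_inclusive = TRUE,
                       min_component_voxels = 0L,
                       radius_mode = c("edt", "peel_iterations"),
                       length_mode = c("voxel_count", "edge_sum"),
                       seed = 1L) {
  structure(list(threshold = as.integer(threshold),
                 threshold_inclusive = isTRUE(threshold_inclusive),
                 min_component_voxels = as.integer(min_component_voxels),
                 radius_mode = match.arg(radius_mode),
                 length_mode = match.arg(length_mode),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full single-volume pipeline
#'
#' Volume + ROI mask in, one tidy results row out: thresholding, uPVV,
#' skeletonization, classification, the seven characteristics and all 14
#' density ratios, plus a provenance record (configuration, input
#' checksums, stage-wise voxel counts) sufficient to reproduce the row.
#'
#' @param volume a [doppler_volume()] or a path readable by [read_volume()].
#' @param roi a [region_mask()] or a path readable by [read_mask()].
#' @param pv placental volume: a scalar in cm^3, a placenta [region_mask()],
#'   or a path to one; `NA` leaves the PV ratios undefined.
#' @param config a [run_config()].
#' @param id identifier written into the results row.
#' @param ga_weeks optional gestational age at scan, weeks.
#' @param spacing spacing override forwarded to [read_volume()] for
#'   formats without spacing metadata.
#' @return An object of class `upvs_result`: `row` (one-row tibble in the
#'   [write_results()] column order), `morphology` (the full
#'   [characterize()] object) and `provenance` (named list).
#' @examples
#' ph <- rasterize_phantom(phantom_y(radius = 3))
#' res <- run_pipeline(ph$volume, ph$roi, pv = 10)
#' res$row[, c("n_end", "n_bif", "upvv_cm3")]
#' @export
run_pipeline <- function(volume, roi, pv = NA_real_, config = run_config(),
                         id = "volume", ga_weeks = NA_real_, spacing = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- "io"
  result <- tryCatch({
    if (is.character(volume)) volume <- read_volume(volume, spacing = spacing)
    if (is.character(roi)) roi <- read_mask(roi, paired = volume)
    if (!inherits(roi, "region_mask"))
      stop("ROI mask is missing or not a region_mask", call. = FALSE)
    prov_inputs <- list(
      volume_checksum = grid_checksum(volume$intensities),
      roi_checksum = grid_checksum(roi$mask),
      dim = dim(volume$intensities), spacing = unname(volume$spacing))

    stage <- "segmentation"
    vv <- apply_threshold(volume, roi, tau = config$threshold,
                          inclusive = config$threshold_inclusive,
                          min_component_voxels = config$min_component_voxels)
    pv_cm3 <- if (inherits(pv, "region_mask")) mask_volume(pv)
              else if (is.character(pv)) mask_volume(read_mask(pv, paired = volume,
                                                               role = "placenta"))
              else as.numeric(pv)

    stage <- "morphology"
    m <- characterize(vv, radius_mode = config$radius_mode,
                      length_mode = config$length_mode)
    ratios <- withCallingHandlers(
      density_ratios(m, pv_cm3 = if (is.na(pv_cm3)) 0 else pv_cm3),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.na(pv_cm3)) ratios[paste0(upvs_characteristics(), "_per_pv")] <- NA_real_

    row <- dplyr::bind_cols(
      tibble(id = id, ga_weeks = ga_weeks,
             pv_cm3 = pv_cm3, upvv_cm3 = vv$upvv_cm3),
      m$characteristics, ratios)
    provenance <- list(
      config = unclass(config),
      inputs = prov_inputs,
      stages = list(
        n_roi_voxels = sum(roi$mask),
        n_selected_voxels = sum(vv$selection),
        n_skeleton_voxels = sum(m$counts),
        class_counts = as.list(m$counts),
        n_segments = nrow(m$segments),
        mean_neighbor_distance_mm = m$dbar))
    structure(list(row = row, morphology = m, provenance = provenance),
              class = "upvs_result")
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  result
}

#' @export
print.upvs_result <- function(x, ...) {
  cat("<upvs_result> id =", x$row$id, "\n")
  print(as.data.frame(x$row[, c("upvv_cm3", upvs_characteristics())]))
  invisible(x)
}

#' @rdname run_pipeline
#' @param x an `upvs_result`.
#' @param ... unused.
#' @export
tidy.upvs_result <- function(x, ...) x$row

#' Run the pipeline over a manifest of volumes
#'
#' Batch mode for study-scale processing: the manifest has one row per scan
#' with columns `volume` and `roi` (paths), and optionally `id`,
#' `ga_weeks`, `pv` (path to a placenta mask) or `pv_cm3` (scalar).
#'
#' @param manifest data frame or path to a manifest CSV.
#' @param config a [run_config()].
#' @return Tibble of result rows ready for [write_results()].
#' @export
run_batch <- function(manifest, config = run_config()) {
  if (is.character(manifest)) manifest <- read.csv(manifest)
  stopifnot(all(c("volume", "roi") %in% names(manifest)))
  purrr::map_dfr(seq_len(nrow(manifest)), function(i) {
    r <- manifest[i, ]
    pv <- if ("pv_cm3" %in% names(r) && !is.na(r$pv_cm3)) r$pv_cm3
          else if ("pv" %in% names(r) && !is.na(r$pv)) r$pv
          else NA_real_
    id <- if ("id" %in% names(r)) as.character(r$id) else paste0("row", i)
    ga <- if ("ga_weeks" %in% names(r)) r$ga_weeks else NA_real_
    run_pipeline(r$volume, r$roi, pv = pv, config = config,
                 id = id, ga_weeks = ga)$row
  })
}

grid_checksum <- function(a) {
  # order-stable checksum of grid content + shape, no external digest needed
  v <- as.numeric(a)
  n <- length(v)
  s <- sum(v * (seq_len(n) %% 97 + 1))
  sprintf("%dx%dx%d-%.0f-%.6f", dim(a)[1], dim(a)[2], dim(a)[3], sum(v), s %% 1e9)
}
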