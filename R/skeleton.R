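#' Skeletonize a vascular volume
#'
#' Reduces the thresholded vascular volume to a one-voxel-wide centerline
#' network (the uPVS) by repeatedly peeling simple voxels off the boundary,
#' outermost first. The thinning is homotopic for 26-connected foreground /
#' 6-connected background: a voxel is deleted only when deletion provably
#' preserves local topology (Bertrand-Malandain characterization), and curve
#' endpoints (a single 26-neighbour) are retained, so the skeleton has
#' exactly as many 26-connected components as the input selection. Deletion
#' candidates are ordered by the Euclidean distance transform with
#' deterministic tie-breaks; the result is reproducible to the bit.
#'
#' Each skeleton voxel carries a local radius estimate. The default
#' (`radius_mode = "edt"`) samples the anisotropic Euclidean distance
#' transform of the selection — the distance in mm to the nearest background
#' voxel, with the grid border counting as background. The alternative
#' `"peel_iterations"` records the chessboard (26-neighbourhood) peel count
#' in voxel units, the literal number of layers removed before the voxel
#' became central; [average_thickness()] converts it to mm via the mean
#' neighbour distance.
#'
#' Voxel discretization of a thick tube produces spurious terminal branches
#' — short bumps at junctions, or strands running parallel to a true
#' centerline inside the same vessel. These carry no centerline information:
#' a terminal branch is redundant exactly when every one of its voxels lies
#' inside the maximal inscribed ball of some other skeleton voxel, i.e. when
#' deleting it leaves the reconstructable vascular volume unchanged. By
#' default such reconstruction-redundant terminal branches are pruned and
#' the prune/re-thin cycle repeated to a fixpoint; genuine branches reach
#' beyond the calibre of neighbouring vessels and are untouched. Set
#' `prune_spurs = FALSE` for the raw thinning output.
#'
#' @param vv a `vessel_volume` from [apply_threshold()], or any
#'   [region_mask()]/logical array wrapped in one.
#' @param radius_mode `"edt"` (default) or `"peel_iterations"`.
#' @param prune_spurs prune reconstruction-redundant terminal branches
#'   (default `TRUE`).
#' @return An object of class `upvs_skeleton`: `skeleton` (logical array),
#'   `radius` (numeric array, values at skeleton voxels; mm for `"edt"`,
#'   peel counts for `"peel_iterations"`), `spacing`, `radius_mode`.
#' @examples
#' sel <- array(FALSE, c(20, 7, 7))
#' sel[3:18, 2:6, 2:6] <- TRUE          # a thick bar
#' vv <- structure(list(selection = sel, spacing = c(sx = 1, sy = 1, sz = 1),
#'                      threshold = 100L, inclusive = TRUE,
#'                      upvv_cm3 = sum(sel) / 1000), class = "vessel_volume")
#' sk <- skeletonize(vv)
#' sum(sk$skeleton) < sum(sel)
#' @export
skeletonize <- function(vv, radius_mode = c("edt", "peel_iterations"),
                        prune_spurs = TRUE) {
  stopifnot(inherits(vv, "vessel_volume"))
  radius_mode <- match.arg(radius_mode)
  sel <- vv$selection
  d <- dim(sel)
  sp <- unname(vv$spacing)
  if (!any(sel)) {
    return(structure(list(skeleton = array(FALSE, d),
                          radius = array(NA_real_, d),
                          spacing = vv$spacing, radius_mode = radius_mode),
                     class = "upvs_skeleton"))
  }
  # pad one background layer so the grid border behaves as background for the
  # distance transforms, then crop back
  dp <- d + 2L
  pad <- function(a) { p <- array(FALSE, dp); p[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- a; p }
  core <- function(a) array(a[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L), drop = FALSE], d)
  padded <- pad(sel)
  edt_p <- .edt_cpp(padded, dp, sp)
  skel <- core(.thin_cpp(padded, dp, sp))
  if (prune_spurs) {
    edt_mm <- core(edt_p)
    repeat {
      pruned <- prune_spur_branches(skel, edt_mm, vv$spacing)
      if (identical(pruned, skel)) break
      # re-thin so pruning cannot leave removable corner voxels behind
      skel <- core(.thin_cpp(pad(pruned), dp, sp))
    }
  }
  rad_p <- if (radius_mode == "edt") edt_p else {
    array(as.numeric(.chessboard_dt_cpp(padded, dp)), dp)
  }
  radius <- core(rad_p)
  radius[!skel] <- NA_real_
  structure(list(skeleton = skel, radius = radius,
                 spacing = vv$spacing, radius_mode = radius_mode),
            class = "upvs_skeleton")
}

#' @export
print.upvs_skeleton <- function(x, ...) {
  cat("<upvs_skeleton> ", sum(x$skeleton), " voxels, radius mode '",
      x$radius_mode, "'\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.upvs_skeleton <- function(x, ...) {
  tb <- voxel_table(x$skeleton, x$spacing)
  tb$radius <- x$radius[which(x$skeleton)]
  tb
}

# Remove terminal branches (endpoint up to the first junction) that are
# reconstruction-redundant: every branch voxel lies within the maximal
# inscribed ball (EDT radius, plus half-voxel slack) of some skeleton voxel
# outside the branch. Pure-path components (endpoint to endpoint) are never
# pruned.
prune_spur_branches <- function(skel, edt_mm, spacing) {
  d <- dim(skel)
  nb <- .neighbor_count_cpp(skel, d)
  ends <- which(!is.na(nb) & nb == 1L)
  if (!length(ends)) return(skel)
  sp <- unname(spacing)
  neighbors_of <- function(i) {
    i0 <- i - 1L
    x <- i0 %% d[1]; y <- (i0 %/% d[1]) %% d[2]; z <- i0 %/% (d[1] * d[2])
    out <- integer(0)
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0L && dy == 0L && dz == 0L) next
      xx <- x + dx; yy <- y + dy; zz <- z + dz
      if (xx < 0L || yy < 0L || zz < 0L || xx >= d[1] || yy >= d[2] || zz >= d[3]) next
      j <- xx + d[1] * (yy + d[2] * zz) + 1L
      if (skel[j]) out <- c(out, j)
    }
    out
  }
  coords_mm <- function(idx) {
    i0 <- idx - 1L
    cbind((i0 %% d[1]) * sp[1],
          ((i0 %/% d[1]) %% d[2]) * sp[2],
          (i0 %/% (d[1] * d[2])) * sp[3])
  }
  slack <- 0.5 * mean(sp)
  out <- skel
  for (e in ends) {
    if (!out[e]) next
    # walk from the endpoint to the first junction (>= 3 neighbours)
    path <- e
    prev <- 0L; cur <- e
    repeat {
      nxts <- setdiff(neighbors_of(cur), c(prev, path))
      if (length(nxts) == 0L) { path <- NULL; break }        # isolated path end
      nxt <- nxts[1]
      if (nb[nxt] >= 3L) break                                # junction reached
      if (nb[nxt] == 1L) { path <- NULL; break }              # endpoint-to-endpoint
      path <- c(path, nxt)
      prev <- cur; cur <- nxt
      if (length(path) > sum(skel)) { path <- NULL; break }
    }
    if (is.null(path)) next
    # redundant iff every branch voxel is inside the maximal ball of a
    # skeleton voxel outside the branch (evaluated against the current state)
    others <- setdiff(which(out), path)
    if (!length(others)) next
    pc <- coords_mm(path); oc <- coords_mm(others)
    reach <- edt_mm[others] + slack
    covered <- vapply(seq_len(nrow(pc)), function(i) {
      dist2 <- (oc[, 1] - pc[i, 1])^2 + (oc[, 2] - pc[i, 2])^2 + (oc[, 3] - pc[i, 3])^2
      any(dist2 <= reach^2)
    }, TRUE)
    if (all(covered)) out[path] <- FALSE
  }
  out
}

# half-space of the 26-neighbourhood: each unordered pair counted once
half_offsets <- function() {
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off[off$dz > 0 | (off$dz == 0 & (off$dy > 0 | (off$dy == 0 & off$dx > 0))), ]
}

# number of skeleton voxel pairs at a given offset
shifted_pair_count <- function(a, dx, dy, dz) {
  d <- dim(a)
  xr <- max(1, 1 + dx):min(d[1], d[1] + dx)
  yr <- max(1, 1 + dy):min(d[2], d[2] + dy)
  zr <- max(1, 1 + dz):min(d[3], d[3] + dz)
  if (length(xr) == 0 || length(yr) == 0 || length(zr) == 0) return(0L)
  sum(a[xr, yr, zr, drop = FALSE] & a[xr - dx, yr - dy, zr - dz, drop = FALSE])
}

#' Mean physical distance between neighbouring skeleton voxels
#'
#' The average Euclidean distance in mm between the centers of all unordered
#' 26-adjacent skeleton voxel pairs. This per-scan quantity converts voxel
#' counts into physical lengths in [total_network_length()],
#' [average_vessel_length()] and (in peel mode) [average_thickness()]. A
#' skeleton with no adjacent pair has no defined value; the mean face-step
#' `(sx + sy + sz) / 3` is returned with a warning.
#'
#' @param sk an `upvs_skeleton`.
#' @return Mean neighbour distance in mm.
#' @examples
#' # a straight 5-voxel chain along x at 1 mm spacing has only face pairs
#' a <- array(FALSE, c(7, 3, 3)); a[2:6, 2, 2] <- TRUE
#' sk <- structure(list(skeleton = a, radius = array(1, dim(a)),
#'                      spacing = c(sx = 1, sy = 1, sz = 1), radius_mode = "edt"),
#'                 class = "upvs_skeleton")
#' mean_neighbor_distance(sk)  # 1
#' @export
mean_neighbor_distance <- function(sk) {
  stopifnot(inherits(sk, "upvs_skeleton"))
  off <- half_offsets()
  sp <- sk$spacing
  dist <- sqrt((off$dx * sp[[1]])^2 + (off$dy * sp[[2]])^2 + (off$dz * sp[[3]])^2)
  counts <- mapply(shifted_pair_count, off$dx, off$dy, off$dz,
                   MoreArgs = list(a = sk$skeleton))
  total <- sum(counts)
  if (total == 0) {
    warning("skeleton has no adjacent voxel pair; returning mean face-neighbour spacing",
            call. = FALSE)
    return(mean(sp))
  }
  sum(counts * dist) / total
}

# 26-connected component count of a logical array
component_count <- function(a) {
  if (!any(a)) return(0L)
  max(.label_components_cpp(a, dim(a)))
}
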