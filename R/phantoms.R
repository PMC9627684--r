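#' Specify a synthetic vascular phantom
#'
#' A phantom is a spatial graph — nodes at physical positions, edges with a
#' tube radius — rasterized as a union of capsules (cylinders with
#' hemispherical caps) into a Doppler-like 8-bit volume. Ground truth
#' (endpoint/bifurcation/crossing counts, exact centerline length) comes
#' from the graph alone, never from the rasterized volume, so every pipeline
#' stage can be validated against known topology.
#'
#' @param nodes numeric matrix (n x 3) of node positions in mm (x, y, z).
#' @param edges data frame with columns `from`, `to` (node row indices) and
#'   `radius` (tube radius in voxel units, >= 1).
#' @param shape grid dimensions `c(nx, ny, nz)`.
#' @param spacing voxel spacing in mm (length 1 or 3).
#' @param vessel_intensity intensity written inside vessels (default 200).
#' @param background_intensity intensity elsewhere (default 0).
#' @param artifacts list with any of `n_stripes`, `n_blobs`, `n_isolated`
#'   (all default 0) controlling [add_artifacts()].
#' @param seed integer seed driving all phantom randomness.
#' @return An object of class `phantom_spec`.
#' @seealso [phantom_tube()], [phantom_y()], [phantom_tree()] for ready-made
#'   families; [rasterize_phantom()].
#' @export
phantom_spec <- function(nodes, edges, shape, spacing = 1,
                         vessel_intensity = 200L, background_intensity = 0L,
                         artifacts = list(), seed = 1L) {
  nodes <- as.matrix(nodes)
  stopifnot(ncol(nodes) == 3L, nrow(nodes) >= 2L)
  edges <- as.data.frame(edges)
  stopifnot(all(c("from", "to", "radius") %in% names(edges)))
  if (any(edges$radius < 1)) stop("edge radii must be >= 1 voxel", call. = FALSE)
  spacing <- check_spacing(spacing)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  # nodes must sit inside the grid with a margin of at least the largest radius
  margin_mm <- max(edges$radius) * max(spacing)
  lo <- c(0, 0, 0) + margin_mm
  hi <- (shape - 1L) * spacing - margin_mm
  if (any(t(nodes) < lo) || any(t(nodes) > hi))
    stop("phantom nodes violate the grid margin (>= max radius from every face)",
         call. = FALSE)
  artifacts <- modifyList(list(n_stripes = 0L, n_blobs = 0L, n_isolated = 0L),
                          artifacts)
  structure(list(nodes = nodes, edges = edges, shape = shape, spacing = spacing,
                 vessel_intensity = as.integer(vessel_intensity),
                 background_intensity = as.integer(background_intensity),
                 artifacts = artifacts, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Graph-level ground truth of a phantom
#'
#' Node degrees give the expected morphology counts — endpoints are
#' degree-1 nodes, bifurcations degree-3, crossings degree-4 — and the exact
#' centerline length is the summed Euclidean edge length.
#'
#' @param spec a [phantom_spec()].
#' @return One-row tibble: `n_end`, `n_bif`, `n_cross`,
#'   `centerline_length_mm`, `n_components`.
#' @export
phantom_truth <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  deg <- tabulate(c(spec$edges$from, spec$edges$to), nbins = nrow(spec$nodes))
  seg_len <- sqrt(rowSums((spec$nodes[spec$edges$from, , drop = FALSE] -
                           spec$nodes[spec$edges$to, , drop = FALSE])^2))
  # connected components of the node graph
  parent <- seq_len(nrow(spec$nodes))
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(spec$edges))) {
    a <- find(spec$edges$from[r]); b <- find(spec$edges$to[r])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(nrow(spec$nodes)), find, numeric(1))
  tibble(n_end = sum(deg == 1L), n_bif = sum(deg == 3L), n_cross = sum(deg == 4L),
         centerline_length_mm = sum(seg_len),
         n_components = length(unique(roots[deg > 0L])))
}

#' Rasterize a phantom into a Doppler volume with ground truth
#'
#' Vessel voxels are all voxels whose center lies within an edge's radius of
#' that edge's segment (capsule union). Branch nodes (graph degree >= 3)
#' additionally receive a spherical bulge two voxels larger than the widest
#' incident vessel — mimicking the dilated confluence of real junctions and
#' giving the distance transform a unique maximum at the node, so the
#' junction thins to a single voxel. The region mask covers the full grid.
#'
#' @param spec a [phantom_spec()].
#' @param apply_artifacts add the spec's artefacts via [add_artifacts()]
#'   (default `FALSE`: a clean phantom).
#' @param junction_bulge extra radius (voxels) of the sphere painted at
#'   branch nodes; 0 disables the bulge.
#' @return List with `volume` ([doppler_volume()]), `roi` ([region_mask()]),
#'   and `truth` ([phantom_truth()] row).
#' @examples
#' ph <- rasterize_phantom(phantom_y(radius = 3))
#' ph$truth
#' @export
rasterize_phantom <- function(spec, apply_artifacts = FALSE, junction_bulge = 2) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  sp <- spec$spacing
  inside <- array(FALSE, d)
  ax <- (seq_len(d[1]) - 1) * sp[[1]]
  ay <- (seq_len(d[2]) - 1) * sp[[2]]
  az <- (seq_len(d[3]) - 1) * sp[[3]]
  paint_capsule <- function(p, q, rad_mm) {
    lo <- pmin(p, q) - rad_mm; hi <- pmax(p, q) + rad_mm
    xi <- which(ax >= lo[1] & ax <= hi[1])
    yi <- which(ay >= lo[2] & ay <= hi[2])
    zi <- which(az >= lo[3] & az <= hi[3])
    if (!length(xi) || !length(yi) || !length(zi)) return(invisible())
    g <- expand.grid(x = ax[xi], y = ay[yi], z = az[zi])
    v <- q - p
    vv <- sum(v * v)
    w <- cbind(g$x - p[1], g$y - p[2], g$z - p[3])
    t <- if (vv == 0) rep(0, nrow(w)) else pmin(1, pmax(0, as.vector(w %*% v) / vv))
    d2 <- (w[, 1] - t * v[1])^2 + (w[, 2] - t * v[2])^2 + (w[, 3] - t * v[3])^2
    hit <- array(d2 <= rad_mm^2, c(length(xi), length(yi), length(zi)))
    inside[xi, yi, zi] <<- inside[xi, yi, zi] | hit
  }
  for (r in seq_len(nrow(spec$edges))) {
    paint_capsule(spec$nodes[spec$edges$from[r], ], spec$nodes[spec$edges$to[r], ],
                  spec$edges$radius[r] * mean(sp))
  }
  if (junction_bulge > 0) {
    deg <- tabulate(c(spec$edges$from, spec$edges$to), nbins = nrow(spec$nodes))
    for (nd in which(deg >= 3L)) {
      r_mm <- (max(spec$edges$radius[spec$edges$from == nd | spec$edges$to == nd]) +
               junction_bulge) * mean(sp)
      paint_capsule(spec$nodes[nd, ], spec$nodes[nd, ], r_mm)
    }
  }
  intens <- array(spec$background_intensity, d)
  intens[inside] <- spec$vessel_intensity
  vol <- doppler_volume(intens, sp)
  if (apply_artifacts) vol <- add_artifacts(vol, spec)
  roi <- suppressWarnings(region_mask(array(1L, d), sp, role = "vascular-ROI"))
  list(volume = vol, roi = roi, truth = phantom_truth(spec))
}

#' Add stripe, blob and isolated-voxel artefacts to a volume
#'
#' Emulates the stripe-like power-Doppler artefacts, hollow/solid signal
#' accumulations (which skeletonize into cluster voxels) and isolated noise
#' voxels seen in clinical scans, so exclusion logic can be exercised.
#' Deterministic for a fixed `spec$seed`.
#'
#' @param vol a [doppler_volume()].
#' @param spec the [phantom_spec()] carrying `artifacts` and `seed`.
#' @return The volume with artefacts burned in at the vessel intensity.
#' @export
add_artifacts <- function(vol, spec) {
  stopifnot(inherits(vol, "doppler_volume"), inherits(spec, "phantom_spec"))
  a <- spec$artifacts
  if (a$n_stripes == 0L && a$n_blobs == 0L && a$n_isolated == 0L) return(vol)
  d <- dim(vol$intensities)
  out <- vol$intensities
  hit <- withr::with_seed(spec$seed, {
    h <- array(FALSE, d)
    for (s in seq_len(a$n_stripes)) {
      axis <- sample(3L, 1L)
      pos <- sample(d[axis], 1L)
      # one-voxel-thick supra-threshold plane
      if (axis == 1L) h[pos, , ] <- TRUE
      else if (axis == 2L) h[, pos, ] <- TRUE
      else h[, , pos] <- TRUE
    }
    for (b in seq_len(a$n_blobs)) {
      c0 <- vapply(d, function(n) sample(seq(3L, max(3L, n - 2L)), 1L), 1L)
      rr <- 2L
      xr <- max(1L, c0[1] - rr):min(d[1], c0[1] + rr)
      yr <- max(1L, c0[2] - rr):min(d[2], c0[2] + rr)
      zr <- max(1L, c0[3] - rr):min(d[3], c0[3] + rr)
      g <- expand.grid(x = xr, y = yr, z = zr)
      keep <- (g$x - c0[1])^2 + (g$y - c0[2])^2 + (g$z - c0[3])^2 <= rr^2
      h[cbind(g$x, g$y, g$z)[keep, , drop = FALSE]] <- TRUE
    }
    if (a$n_isolated > 0L) {
      # isolated voxels, kept clear of existing signal and of each other
      free <- which(out < spec$vessel_intensity)
      placed <- 0L; guard <- 0L
      while (placed < a$n_isolated && guard < 1000L) {
        guard <- guard + 1L
        cand <- sample(free, 1L)
        i0 <- cand - 1L
        x <- i0 %% d[1] + 1L; y <- (i0 %/% d[1]) %% d[2] + 1L; z <- i0 %/% (d[1] * d[2]) + 1L
        xr <- max(1L, x - 2L):min(d[1], x + 2L)
        yr <- max(1L, y - 2L):min(d[2], y + 2L)
        zr <- max(1L, z - 2L):min(d[3], z + 2L)
        if (any(h[xr, yr, zr]) || any(out[xr, yr, zr] >= spec$vessel_intensity)) next
        h[x, y, z] <- TRUE
        placed <- placed + 1L
      }
    }
    h
  })
  out[hit] <- spec$vessel_intensity
  doppler_volume(out, vol$spacing)
}

## ---- ready-made phantom families ----

#' Straight-tube phantom
#'
#' An axis-aligned solid tube: ground truth is 2 endpoints, 0 bifurcations.
#'
#' @param radius tube radius in voxels.
#' @param length centerline length in voxels.
#' @param spacing voxel spacing in mm.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @return A [phantom_spec()].
#' @export
phantom_tube <- function(radius = 3, length = 40, spacing = 1, axis = "x") {
  sp <- check_spacing(spacing)
  margin <- ceiling(radius) + 2
  along <- length + 2 * margin
  across <- 2 * margin + 1
  shape <- switch(axis, x = c(along, across, across),
                  y = c(across, along, across), z = c(across, across, along))
  mid <- (shape - 1) / 2 * sp
  a <- b <- mid
  k <- match(axis, c("x", "y", "z"))
  a[k] <- margin * sp[[k]]; b[k] <- (margin + length) * sp[[k]]
  phantom_spec(rbind(a, b), data.frame(from = 1, to = 2, radius = radius),
               shape = shape, spacing = sp)
}

#' Y-shaped (single bifurcation) phantom
#'
#' One stem splitting into two diverging arms: ground truth is 3 endpoints,
#' 1 bifurcation.
#'
#' @param radius tube radius in voxels.
#' @param stem,arm stem and arm lengths in voxels.
#' @param spacing voxel spacing in mm.
#' @return A [phantom_spec()].
#' @export
phantom_y <- function(radius = 3, stem = 16, arm = 16, spacing = 1) {
  sp <- check_spacing(spacing)
  margin <- ceiling(radius) + 2
  reach <- ceiling(arm * 0.8)
  nx <- stem + ceiling(arm * 0.7) + 2 * margin
  ny <- 2 * (reach + margin) + 1
  nz <- 2 * margin + 1
  y0 <- (ny - 1) / 2; z0 <- (nz - 1) / 2
  nodes <- rbind(c(margin, y0, z0),
                 c(margin + stem, y0, z0),
                 c(margin + stem + arm * 0.7, y0 + arm * 0.7, z0),
                 c(margin + stem + arm * 0.7, y0 - arm * 0.7, z0)) * rep(sp, each = 4)
  edges <- data.frame(from = c(1, 2, 2), to = c(2, 3, 4), radius = radius)
  phantom_spec(nodes, edges, shape = c(nx, ny, nz), spacing = sp)
}

#' Random vascular-tree phantom
#'
#' Grows a binary tree of capsules by splitting active tips at successive
#' bifurcations. Arms run along randomly drawn 26-neighbourhood lattice
#' directions, and at every bifurcation the stem and the two daughter
#' directions are constrained to pairwise non-adjacent lattice offsets, so
#' each branch node is realized by a single junction voxel rather than a
#' cluster of near-tangent centerlines; non-adjacent arms additionally keep
#' a clearance of two tube radii. With `n_bif` bifurcations the ground
#' truth has `n_bif + 2` endpoints (the root plus `n_bif + 1` leaves) and
#' `n_bif` bifurcation nodes. This lattice-aligned family with radius >= 3
#' and arms >= 10 voxels and no artefacts is the documented clean family
#' recovered exactly by [characterize()].
#'
#' @param n_bif number of bifurcations (0 gives a straight tube).
#' @param radius tube radius in voxels.
#' @param arm_length mean arm length in voxel steps (each arm is drawn
#'   within +/- 20%).
#' @param spacing voxel spacing in mm.
#' @param seed integer seed.
#' @return A [phantom_spec()].
#' @export
phantom_tree <- function(n_bif = 5, radius = 3, arm_length = 14, spacing = 1,
                         seed = 1L) {
  sp <- check_spacing(spacing)
  clearance_vox <- 2 * radius + 4
  all_offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  all_offsets <- all_offsets[rowSums(abs(all_offsets)) > 0, ]
  nonadjacent <- function(o1, o2) max(abs(o1 - o2)) >= 2
  res <- withr::with_seed(seed, {
    # positions in lattice (voxel) coordinates; converted to mm at the end
    nodes <- matrix(c(0, 0, 0), ncol = 3)
    edges <- data.frame(from = integer(), to = integer(), radius = numeric())
    tips <- list(list(node = 1L, off = c(1L, 0L, 0L)))
    seg_dist <- function(p1, q1, p2, q2) {
      u <- q1 - p1; v <- q2 - p2; w <- p1 - p2
      a <- sum(u * u); b <- sum(u * v); c <- sum(v * v)
      dd <- sum(u * w); e <- sum(v * w)
      den <- a * c - b * b
      s <- if (den < 1e-12) 0 else max(0, min(1, (b * e - c * dd) / den))
      t <- if (c < 1e-12) 0 else max(0, min(1, (b * s + e) / c))
      s <- if (a < 1e-12) 0 else max(0, min(1, (b * t - dd) / a))
      sqrt(sum((p1 + s * u - p2 - t * v)^2))
    }
    clear_of_others <- function(p, q, exclude_nodes, skip_tip = 0L) {
      for (r in seq_len(nrow(edges))) {
        if (edges$from[r] %in% exclude_nodes || edges$to[r] %in% exclude_nodes) next
        if (seg_dist(p, q, nodes[edges$from[r], ], nodes[edges$to[r], ]) < clearance_vox)
          return(FALSE)
      }
      # other active tips reserve their full future arm as an obstacle
      for (t in seq_along(tips)) {
        if (t == skip_tip || tips[[t]]$node %in% exclude_nodes) next
        tp <- nodes[tips[[t]]$node, ]
        if (seg_dist(p, q, tp, tp + tips[[t]]$off * arm_length * 1.2) < clearance_vox)
          return(FALSE)
      }
      TRUE
    }
    grow <- function(node, off, steps) {
      newpos <- nodes[node, ] + off * steps
      nodes <<- rbind(nodes, newpos)
      id <- nrow(nodes)
      edges <<- rbind(edges, data.frame(from = node, to = id, radius = radius))
      id
    }
    done_bif <- 0L
    while (done_bif < n_bif) {
      placed <- FALSE
      for (try in 1:200) {
        k <- sample(length(tips), 1L)
        tip <- tips[[k]]
        steps <- round(arm_length * runif(1, 0.8, 1.2))
        bpos <- nodes[tip$node, ] + tip$off * steps
        # daughters: forward lattice offsets that diverge clearly from the
        # stem direction (else the junction smears along the through-line),
        # pairwise non-adjacent to each other and to the incoming stem side
        onorm <- sqrt(rowSums(all_offsets^2))
        cosang <- as.vector(all_offsets %*% tip$off) / (onorm * sqrt(sum(tip$off^2)))
        fwd <- which(cosang > 0 & cosang <= 0.75)
        if (length(fwd) < 2L) next
        cand <- all_offsets[sample(fwd), , drop = FALSE]
        pair <- NULL
        for (i in seq_len(nrow(cand) - 1)) {
          for (j in (i + 1):nrow(cand)) {
            if (nonadjacent(cand[i, ], cand[j, ]) &&
                nonadjacent(cand[i, ], -tip$off) &&
                nonadjacent(cand[j, ], -tip$off) &&
                # no two arms at the junction may lie in a common axis-aligned
                # plane, where the distance transform forms an ambiguous flat
                # ridge
                !any(cand[i, ] == 0 & cand[j, ] == 0) &&
                !any(cand[i, ] == 0 & tip$off == 0) &&
                !any(cand[j, ] == 0 & tip$off == 0)) {
              pair <- rbind(cand[i, ], cand[j, ]); break
            }
          }
          if (!is.null(pair)) break
        }
        if (is.null(pair)) next
        probe <- arm_length
        if (clear_of_others(nodes[tip$node, ], bpos, tip$node, skip_tip = k) &&
            clear_of_others(bpos, bpos + pair[1, ] * probe, tip$node, skip_tip = k) &&
            clear_of_others(bpos, bpos + pair[2, ] * probe, tip$node, skip_tip = k) &&
            seg_dist(bpos + pair[1, ] * probe / 2, bpos + pair[1, ] * probe,
                     bpos + pair[2, ] * probe / 2, bpos + pair[2, ] * probe) >= clearance_vox) {
          branch_node <- grow(tip$node, tip$off, steps)
          tips[[k]] <- list(node = branch_node, off = pair[1, ])
          tips[[length(tips) + 1L]] <- list(node = branch_node, off = pair[2, ])
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("phantom_tree: could not place a clear bifurcation; try another seed",
                        call. = FALSE)
      done_bif <- done_bif + 1L
    }
    for (t in seq_along(tips)) {
      tip <- tips[[t]]
      steps <- round(arm_length * runif(1, 0.8, 1.2))
      floor_steps <- round(arm_length * 0.8)
      while (steps > floor_steps &&
             !clear_of_others(nodes[tip$node, ], nodes[tip$node, ] + tip$off * steps,
                              tip$node, skip_tip = t)) {
        steps <- steps - 1L
      }
      grow(tip$node, tip$off, steps)
    }
    list(nodes = nodes, edges = edges)
  })
  # translate into a margin-respecting box and convert to mm
  margin_vox <- radius + 3
  lo <- apply(res$nodes, 2, min); hi <- apply(res$nodes, 2, max)
  nodes_vox <- sweep(res$nodes, 2, margin_vox - lo, `+`)
  shape <- as.integer(hi - lo + 2 * margin_vox + 1)
  nodes <- nodes_vox * rep(sp, each = nrow(nodes_vox))
  phantom_spec(nodes, res$edges, shape = shape, spacing = sp, seed = seed)
}

#' Two disjoint parallel tubes
#'
#' Ground truth: 4 endpoints, 2 connected components; used to check that
#' skeletonization preserves the component count of disconnected networks.
#'
#' @inheritParams phantom_tube
#' @param gap center-to-center separation of the tubes in voxels.
#' @return A [phantom_spec()].
#' @export
phantom_two_tubes <- function(radius = 3, length = 30, gap = 14, spacing = 1) {
  sp <- check_spacing(spacing)
  margin <- ceiling(radius) + 2
  nx <- length + 2 * margin
  ny <- gap + 2 * margin + 1
  nz <- 2 * margin + 1
  z0 <- (nz - 1) / 2
  nodes <- rbind(c(margin, margin, z0),
                 c(margin + length, margin, z0),
                 c(margin, margin + gap, z0),
                 c(margin + length, margin + gap, z0)) * rep(sp, each = 4)
  edges <- data.frame(from = c(1, 3), to = c(2, 4), radius = radius)
  phantom_spec(nodes, edges, shape = c(nx, ny, nz), spacing = sp)
}
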