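#' Classify skeleton voxels by 26-neighbour count
#'
#' Each skeleton voxel is labelled by how many of its 26 neighbours are also
#' skeleton voxels: isolated (0), endpoint (1), vessel point (2), bifurcation
#' point (3), crossing point (4), or cluster (>= 5). Isolated voxels and
#' clusters are treated as Doppler noise or scanning artefacts and are
#' excluded from all downstream characteristics; the remaining four classes
#' are the count-type morphologic characteristics.
#'
#' @param sk an `upvs_skeleton` from [skeletonize()].
#' @return An object of class `upvs_classification`: `labels` (factor-coded
#'   integer array: values 0-5 in the order above, `NA` off-skeleton),
#'   `counts` (named integer vector: `n_isolated`, `n_end`, `n_vessel`,
#'   `n_bif`, `n_cross`, `n_cluster`), `spacing`.
#' @examples
#' a <- array(FALSE, c(5, 3, 3)); a[2:4, 2, 2] <- TRUE   # 3-voxel chain
#' sk <- structure(list(skeleton = a, radius = array(1, dim(a)),
#'                      spacing = c(sx = 1, sy = 1, sz = 1), radius_mode = "edt"),
#'                 class = "upvs_skeleton")
#' classify_voxels(sk)$counts
#' @export
classify_voxels <- function(sk) {
  stopifnot(inherits(sk, "upvs_skeleton"))
  nb <- .neighbor_count_cpp(sk$skeleton, dim(sk$skeleton))
  lab <- nb
  lab[!is.na(nb) & nb >= 5L] <- 5L
  counts <- c(n_isolated = sum(lab == 0L, na.rm = TRUE),
              n_end      = sum(lab == 1L, na.rm = TRUE),
              n_vessel   = sum(lab == 2L, na.rm = TRUE),
              n_bif      = sum(lab == 3L, na.rm = TRUE),
              n_cross    = sum(lab == 4L, na.rm = TRUE),
              n_cluster  = sum(lab == 5L, na.rm = TRUE))
  structure(list(labels = lab, counts = counts, spacing = sk$spacing),
            class = "upvs_classification")
}

voxel_class_names <- function() {
  c("isolated", "endpoint", "vessel", "bifurcation", "crossing", "cluster")
}

#' @export
print.upvs_classification <- function(x, ...) {
  cat("<upvs_classification>\n")
  print(x$counts)
  invisible(x)
}

#' @export
as_tibble.upvs_classification <- function(x, ...) {
  w <- which(!is.na(x$labels))
  tb <- voxel_table(array(!is.na(x$labels), dim(x$labels)), x$spacing)
  tb$class <- factor(voxel_class_names()[x$labels[w] + 1L],
                     levels = voxel_class_names())
  tb$n_neighbors <- x$labels[w]
  tb
}

# 2-column matrix of linear-index pairs of 26-adjacent TRUE voxels
adjacency_pairs <- function(a) {
  d <- dim(a)
  off <- half_offsets()
  out <- vector("list", nrow(off))
  for (r in seq_len(nrow(off))) {
    dx <- off$dx[r]; dy <- off$dy[r]; dz <- off$dz[r]
    xr <- max(1, 1 + dx):min(d[1], d[1] + dx)
    yr <- max(1, 1 + dy):min(d[2], d[2] + dy)
    zr <- max(1, 1 + dz):min(d[3], d[3] + dz)
    sub <- a[xr, yr, zr, drop = FALSE] & a[xr - dx, yr - dy, zr - dz, drop = FALSE]
    if (!any(sub)) next
    w <- which(sub)
    i0 <- w - 1L
    lx <- i0 %% length(xr); rest <- i0 %/% length(xr)
    ly <- rest %% length(yr); lz <- rest %/% length(yr)
    x1 <- xr[1] + lx; y1 <- yr[1] + ly; z1 <- zr[1] + lz
    p <- x1 + d[1] * (y1 - 1L + d[2] * (z1 - 1L))
    q <- (x1 - dx) + d[1] * (y1 - dy - 1L + d[2] * (z1 - dz - 1L))
    out[[r]] <- cbind(p, q)
  }
  do.call(rbind, c(out, list(matrix(integer(0), ncol = 2))))
}

#' Extract vessel segments from a classified skeleton
#'
#' A segment is a maximal run of vessel points between two boundary nodes
#' (endpoints, bifurcation or crossing points). Excluded voxels (isolated,
#' cluster) are removed from the traversal graph first, so a vessel run that
#' abuts a cluster terminates there with an undefined boundary class. Two
#' directly adjacent boundary nodes form a segment with zero interior vessel
#' points; a closed loop of pure vessel points forms one segment flagged
#' `cyclic` whose interior count is the component size.
#'
#' @param sk an `upvs_skeleton`.
#' @param cls its [classify_voxels()] result.
#' @return A tibble with one row per segment: `segment_id`, `n_interior`
#'   (vessel points strictly between the boundary nodes), `cyclic`, and the
#'   boundary node classes `end1_class`, `end2_class` (`NA` where the run was
#'   truncated by an excluded voxel or the volume edge).
#' @export
extract_segments <- function(sk, cls) {
  stopifnot(inherits(sk, "upvs_skeleton"), inherits(cls, "upvs_classification"))
  lab <- cls$labels
  d <- dim(lab)
  vessel <- !is.na(lab) & lab == 2L
  node <- !is.na(lab) & (lab == 1L | lab == 3L | lab == 4L)
  empty <- tibble(segment_id = integer(), n_interior = integer(),
                  cyclic = logical(), end1_class = character(),
                  end2_class = character())
  if (!any(vessel) && !any(node)) return(empty)

  cls_name <- function(idx) voxel_class_names()[lab[idx] + 1L]
  segs <- list()

  ## vessel-vessel components (paths or cycles, since vessel degree <= 2)
  if (any(vessel)) {
    vw <- which(vessel)
    vid <- integer(length(lab)); vid[vw] <- seq_along(vw)
    vp <- adjacency_pairs(vessel)
    deg <- tabulate(c(vid[vp[, 1]], vid[vp[, 2]]), nbins = length(vw))
    adj1 <- adj2 <- integer(length(vw))   # up to two vessel neighbours each
    for (r in seq_len(nrow(vp))) {
      a <- vid[vp[r, 1]]; b <- vid[vp[r, 2]]
      if (adj1[a] == 0L) adj1[a] <- b else adj2[a] <- b
      if (adj1[b] == 0L) adj1[b] <- a else adj2[b] <- a
    }
    # node voxels adjacent to each vessel voxel (for boundary classes)
    both <- vessel | node
    bp <- adjacency_pairs(both)
    nb_nodes <- vector("list", length(vw))
    for (r in seq_len(nrow(bp))) {
      p <- bp[r, 1]; q <- bp[r, 2]
      if (vessel[p] && node[q]) nb_nodes[[vid[p]]] <- c(nb_nodes[[vid[p]]], q)
      if (vessel[q] && node[p]) nb_nodes[[vid[q]]] <- c(nb_nodes[[vid[q]]], p)
    }
    visited <- logical(length(vw))
    for (s in seq_along(vw)) {
      if (visited[s] || deg[s] > 1L) next
      # walk a path starting at a vessel voxel of vessel-degree 0 or 1
      path <- s; visited[s] <- TRUE
      prev <- 0L; cur <- s
      repeat {
        nxt <- if (adj1[cur] != 0L && adj1[cur] != prev && !visited[adj1[cur]]) adj1[cur]
               else if (adj2[cur] != 0L && adj2[cur] != prev && !visited[adj2[cur]]) adj2[cur]
               else 0L
        if (nxt == 0L) break
        visited[nxt] <- TRUE; path <- c(path, nxt); prev <- cur; cur <- nxt
      }
      b1 <- nb_nodes[[path[1]]]; b2 <- nb_nodes[[path[length(path)]]]
      segs[[length(segs) + 1L]] <- list(
        n_interior = length(path), cyclic = FALSE,
        end1 = if (length(b1)) cls_name(b1[1]) else NA_character_,
        end2 = if (length(b2)) cls_name(b2[length(b2)]) else NA_character_)
    }
    # remaining unvisited vessel voxels lie on pure-vessel cycles
    for (s in seq_along(vw)) {
      if (visited[s]) next
      cyc <- s; visited[s] <- TRUE
      prev <- 0L; cur <- s
      repeat {
        nxt <- if (adj1[cur] != 0L && adj1[cur] != prev && !visited[adj1[cur]]) adj1[cur]
               else if (adj2[cur] != 0L && adj2[cur] != prev && !visited[adj2[cur]]) adj2[cur]
               else 0L
        if (nxt == 0L) break
        visited[nxt] <- TRUE; cyc <- c(cyc, nxt); prev <- cur; cur <- nxt
      }
      segs[[length(segs) + 1L]] <- list(n_interior = length(cyc), cyclic = TRUE,
                                        end1 = NA_character_, end2 = NA_character_)
    }
  }

  ## direct node-node adjacencies: zero-interior segments
  if (any(node)) {
    np <- adjacency_pairs(node)
    for (r in seq_len(nrow(np))) {
      segs[[length(segs) + 1L]] <- list(n_interior = 0L, cyclic = FALSE,
                                        end1 = cls_name(np[r, 1]),
                                        end2 = cls_name(np[r, 2]))
    }
  }

  if (!length(segs)) return(empty)
  tibble(segment_id = seq_along(segs),
         n_interior = vapply(segs, function(s) as.integer(s$n_interior), 1L),
         cyclic = vapply(segs, function(s) s$cyclic, TRUE),
         end1_class = vapply(segs, function(s) s$end1, ""),
         end2_class = vapply(segs, function(s) s$end2, ""))
}

#' Total network length
#'
#' The included-voxel count (endpoints + vessel + bifurcation + crossing
#' points) multiplied by the mean neighbour distance. This voxel-count form
#' slightly overestimates a chain's geometric length (by one step per open
#' chain); see [characterize()]'s `length_mode = "edge_sum"` for the per-edge
#' alternative.
#'
#' @param cls an `upvs_classification`.
#' @param dbar mean neighbour distance in mm, from [mean_neighbor_distance()]
#'   of the same skeleton.
#' @return Length in mm (0 when no voxel is included).
#' @export
total_network_length <- function(cls, dbar) {
  stopifnot(inherits(cls, "upvs_classification"))
  n <- sum(cls$counts[c("n_end", "n_vessel", "n_bif", "n_cross")])
  as.numeric(n) * dbar
}

#' Average vessel length
#'
#' Mean number of interior vessel points per segment multiplied by the mean
#' neighbour distance. Zero-interior segments (two directly adjacent nodes)
#' are included in the mean. With no segments the quantity is undefined and
#' `NaN` is returned with a warning.
#'
#' @param segments tibble from [extract_segments()].
#' @inheritParams total_network_length
#' @return Length in mm, or `NaN` when undefined.
#' @export
average_vessel_length <- function(segments, dbar) {
  if (nrow(segments) == 0L) {
    warning("no segments: average vessel length is undefined", call. = FALSE)
    return(NaN)
  }
  mean(segments$n_interior) * dbar
}

#' Average vascular thickness
#'
#' Mean local radius over the included (non-excluded) skeleton voxels. In
#' `"edt"` radius mode the per-voxel radii are already physical mm; in
#' `"peel_iterations"` mode the mean peel count is multiplied by the mean
#' neighbour distance, mirroring the layers-peeled-off description.
#'
#' @param sk an `upvs_skeleton`.
#' @param cls its classification.
#' @return Thickness in mm; `NaN` with a warning when every voxel is
#'   excluded.
#' @export
average_thickness <- function(sk, cls) {
  stopifnot(inherits(sk, "upvs_skeleton"), inherits(cls, "upvs_classification"))
  included <- !is.na(cls$labels) & cls$labels >= 1L & cls$labels <= 4L
  if (!any(included)) {
    warning("no included skeleton voxels: average thickness is undefined", call. = FALSE)
    return(NaN)
  }
  m <- mean(sk$radius[included])
  if (sk$radius_mode == "peel_iterations") m * mean_neighbor_distance(sk) else m
}

# edge-sum alternative: sum of true centre-to-centre distances over all
# 26-adjacent included-voxel pairs
total_length_edge_sum <- function(sk, cls) {
  included <- !is.na(cls$labels) & cls$labels >= 1L & cls$labels <= 4L
  off <- half_offsets()
  sp <- sk$spacing
  dist <- sqrt((off$dx * sp[[1]])^2 + (off$dy * sp[[2]])^2 + (off$dz * sp[[3]])^2)
  counts <- mapply(shifted_pair_count, off$dx, off$dy, off$dz,
                   MoreArgs = list(a = included))
  sum(counts * dist)
}

#' Compute the seven uPVS morphologic characteristics
#'
#' Orchestrates the full morphometric stage: skeletonization, 26-neighbour
#' classification, segment extraction and the three length/thickness
#' metrics. The seven characteristics are the endpoint, vessel-point,
#' bifurcation-point and crossing-point counts, the total network length,
#' the average vessel length and the average vascular thickness. The result
#' is deterministic for a fixed input and configuration.
#'
#' @param vv a `vessel_volume` from [apply_threshold()].
#' @param radius_mode passed to [skeletonize()].
#' @param length_mode `"voxel_count"` (default: included voxels times mean
#'   neighbour distance) or `"edge_sum"` (sum of true inter-voxel distances).
#' @return An object of class `upvs_morphology`: `characteristics` (one-row
#'   tibble, columns [upvs_characteristics()]), `counts` (all six class
#'   counts), `dbar` (mean neighbour distance, mm), `upvv_cm3`, and the
#'   intermediate `skeleton`, `classification`, `segments`.
#' @examples
#' ph <- rasterize_phantom(phantom_tube(radius = 3, length = 30))
#' vv <- apply_threshold(ph$volume, ph$roi)
#' m <- characterize(vv)
#' tidy(m)
#' @export
characterize <- function(vv, radius_mode = c("edt", "peel_iterations"),
                         length_mode = c("voxel_count", "edge_sum")) {
  radius_mode <- match.arg(radius_mode)
  length_mode <- match.arg(length_mode)
  sk <- skeletonize(vv, radius_mode = radius_mode)
  cls <- classify_voxels(sk)
  segments <- extract_segments(sk, cls)
  n_included <- sum(cls$counts[c("n_end", "n_vessel", "n_bif", "n_cross")])
  if (n_included == 0L) {
    dbar <- NA_real_
    total_len <- 0
    avg_len <- NaN
    avg_thick <- NaN
  } else {
    dbar <- suppressWarnings(mean_neighbor_distance(sk))
    total_len <- if (length_mode == "edge_sum") total_length_edge_sum(sk, cls)
                 else total_network_length(cls, dbar)
    avg_len <- suppressWarnings(average_vessel_length(segments, dbar))
    avg_thick <- suppressWarnings(average_thickness(sk, cls))
  }
  ch <- tibble(n_end = unname(cls$counts["n_end"]),
               n_vessel = unname(cls$counts["n_vessel"]),
               n_bif = unname(cls$counts["n_bif"]),
               n_cross = unname(cls$counts["n_cross"]),
               total_length_mm = total_len,
               avg_vessel_length_mm = avg_len,
               avg_thickness_mm = avg_thick)
  structure(list(characteristics = ch, counts = cls$counts, dbar = dbar,
                 upvv_cm3 = vv$upvv_cm3, spacing = vv$spacing,
                 radius_mode = radius_mode, length_mode = length_mode,
                 skeleton = sk, classification = cls, segments = segments),
            class = "upvs_morphology")
}

#' @export
print.upvs_morphology <- function(x, ...) {
  cat("<upvs_morphology> uPVV =", format(x$upvv_cm3), "cm^3, dbar =",
      format(x$dbar), "mm\n")
  print(as.data.frame(x$characteristics))
  cat("excluded: ", x$counts["n_isolated"], " isolated, ",
      x$counts["n_cluster"], " cluster voxels\n", sep = "")
  invisible(x)
}

#' @rdname characterize
#' @param x an `upvs_morphology` object.
#' @param ... unused.
#' @export
tidy.upvs_morphology <- function(x, ...) x$characteristics

#' @rdname characterize
#' @export
glance.upvs_morphology <- function(x, ...) {
  tibble(upvv_cm3 = x$upvv_cm3,
         mean_neighbor_distance_mm = x$dbar,
         n_skeleton_voxels = sum(x$counts),
         n_excluded = unname(x$counts["n_isolated"] + x$counts["n_cluster"]),
         n_segments = nrow(x$segments))
}

#' Vascular-branching density ratios
#'
#' Each of the seven characteristics divided by the placental volume (PV)
#' and by the vascular volume (uPVV), giving 14 densities (counts per cm^3,
#' lengths in mm per cm^3). A zero denominator makes the corresponding
#' ratios undefined: they are returned as `NA` with a warning, never as 0.
#'
#' @param mc an `upvs_morphology` or a one-row data frame with the
#'   [upvs_characteristics()] columns.
#' @param pv_cm3 placental volume in cm^3 (from [mask_volume()] or supplied
#'   as a scalar).
#' @param upvv_cm3 vascular volume in cm^3; defaults to the one carried by
#'   `mc` when it is an `upvs_morphology`.
#' @return One-row tibble with columns `<characteristic>_per_pv` and
#'   `<characteristic>_per_upvv`.
#' @export
density_ratios <- function(mc, pv_cm3, upvv_cm3 = NULL) {
  if (inherits(mc, "upvs_morphology")) {
    upvv_cm3 <- upvv_cm3 %||% mc$upvv_cm3
    mc <- mc$characteristics
  }
  if (is.null(upvv_cm3)) stop("`upvv_cm3` is required", call. = FALSE)
  if (is.na(pv_cm3) || is.na(upvv_cm3) || pv_cm3 < 0 || upvv_cm3 < 0)
    stop("denominators must be non-negative", call. = FALSE)
  ch <- upvs_characteristics()
  vals <- as.numeric(mc[1, ch])
  per <- function(den, tag) {
    if (den == 0) {
      warning("zero ", tag, ": the corresponding density ratios are undefined",
              call. = FALSE)
      rep(NA_real_, length(vals))
    } else vals / den
  }
  out <- c(per(pv_cm3, "PV"), per(upvv_cm3, "uPVV"))
  names(out) <- c(paste0(ch, "_per_pv"), paste0(ch, "_per_upvv"))
  as_tibble(as.list(out))
}
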