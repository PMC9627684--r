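# Build a vessel_volume through the real segmentation path from a logical array
vv_from_mask <- function(a, spacing = 1) {
  intens <- array(0L, dim(a))
  intens[a] <- 200L
  vol <- doppler_volume(intens, spacing)
  roi <- suppressWarnings(region_mask(array(1L, dim(a)), spacing))
  apply_threshold(vol, roi)
}

# Wrap a logical array directly as a skeleton object (unit radius)
sk_from_mask <- function(a, spacing = 1) {
  sp <- if (length(spacing) == 1) rep(spacing, 3) else spacing
  names(sp) <- c("sx", "sy", "sz")
  r <- array(NA_real_, dim(a)); r[a] <- 1
  structure(list(skeleton = a, radius = r, spacing = sp, radius_mode = "edt"),
            class = "upvs_skeleton")
}

# Independent 26-neighbour count: plain R loop over explicit offsets
brute_neighbor_counts <- function(a) {
  d <- dim(a)
  w <- which(a)
  out <- integer(length(w))
  for (k in seq_along(w)) {
    i0 <- w[k] - 1L
    x <- i0 %% d[1] + 1L
    y <- (i0 %/% d[1]) %% d[2] + 1L
    z <- i0 %/% (d[1] * d[2]) + 1L
    n <- 0L
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      xx <- x + dx; yy <- y + dy; zz <- z + dz
      if (xx >= 1 && yy >= 1 && zz >= 1 && xx <= d[1] && yy <= d[2] && zz <= d[3] &&
          a[xx, yy, zz]) n <- n + 1L
    }
    out[k] <- n
  }
  out
}

# Exact Mann-Whitney two-sided p by full enumeration of group assignments
brute_mwu_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - nx * (nx + 1) / 2
  }
  u_obs <- u_of(seq_len(nx))
  combos <- utils::combn(n, nx)
  us <- apply(combos, 2, function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - nx * (nx + 1) / 2
  })
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# random sparse logical array (fixed density), used by classification oracles
random_voxel_set <- function(dim3, density = 0.15) {
  array(stats::runif(prod(dim3)) < density, dim3)
}
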