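test_that("voxel classes follow the 26-neighbour count", {
  # middle voxel of a 3-chain is a vessel point, ends are endpoints
  a <- array(FALSE, c(5, 3, 3)); a[2:4, 2, 2] <- TRUE
  cls <- classify_voxels(sk_from_mask(a))
  expect_equal(unname(cls$counts[c("n_end", "n_vessel")]), c(2L, 1L))

  # centre of a "Y" of three chain arms is a bifurcation point
  y <- array(FALSE, c(7, 7, 3))
  y[4, 4, 2] <- TRUE                      # centre
  y[3, 4, 2] <- y[2, 4, 2] <- TRUE        # arm 1
  y[5, 5, 2] <- y[6, 6, 2] <- TRUE        # arm 2
  y[5, 3, 2] <- y[6, 2, 2] <- TRUE        # arm 3
  cls <- classify_voxels(sk_from_mask(y))
  expect_equal(unname(cls$counts["n_bif"]), 1L)
  expect_equal(unname(cls$counts["n_end"]), 3L)
  expect_equal(cls$labels[4, 4, 2], 3L)

  # isolated voxel and a dense cluster land in the excluded classes
  c3 <- array(FALSE, c(8, 8, 8)); c3[2:4, 2:4, 2:4] <- TRUE; c3[7, 7, 7] <- TRUE
  cls <- classify_voxels(sk_from_mask(c3))
  expect_equal(unname(cls$counts["n_isolated"]), 1L)
  expect_gt(cls$counts["n_cluster"], 0)
})

test_that("classification matches a brute-force neighbour count on random sets", {
  set.seed(23)
  for (i in 1:25) {
    a <- random_voxel_set(c(sample(6:20, 1), sample(6:20, 1), sample(6:20, 1)),
                          density = runif(1, 0.05, 0.35))
    cls <- classify_voxels(sk_from_mask(a))
    nb_ref <- brute_neighbor_counts(a)
    lab_ref <- pmin(nb_ref, 5L)
    expect_identical(cls$labels[which(a)], lab_ref, label = paste("case", i))
    # conservation: class counts account for every skeleton voxel
    expect_equal(sum(cls$counts), sum(a))
  }
})

test_that("segments are maximal vessel runs between boundary nodes", {
  # open 5-chain: 2 endpoints + 3 vessel points, one segment
  a <- array(FALSE, c(7, 3, 3)); a[2:6, 2, 2] <- TRUE
  sk <- sk_from_mask(a)
  segs <- extract_segments(sk, classify_voxels(sk))
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$n_interior, 3L)
  expect_setequal(c(segs$end1_class, segs$end2_class), "endpoint")

  # Y with arms of 2 vessel points each: 3 segments of 2 interior
  y <- array(FALSE, c(9, 9, 3))
  y[5, 5, 2] <- TRUE
  y[4, 5, 2] <- y[3, 5, 2] <- y[2, 5, 2] <- TRUE
  y[6, 6, 2] <- y[7, 7, 2] <- y[8, 8, 2] <- TRUE
  y[6, 4, 2] <- y[7, 3, 2] <- y[8, 2, 2] <- TRUE
  sk <- sk_from_mask(y)
  segs <- extract_segments(sk, classify_voxels(sk))
  expect_equal(nrow(segs), 3L)
  expect_equal(sort(segs$n_interior), c(2L, 2L, 2L))
  expect_true(all(segs$end2_class == "bifurcation" | segs$end1_class == "bifurcation"))

  # two directly adjacent endpoints: a zero-interior segment
  p <- array(FALSE, c(4, 3, 3)); p[2:3, 2, 2] <- TRUE
  sk <- sk_from_mask(p)
  segs <- extract_segments(sk, classify_voxels(sk))
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$n_interior, 0L)

  # pure vessel cycle: one cyclic segment containing the whole component
  ring <- array(FALSE, c(6, 6, 3))
  ring[2, 2, 2] <- ring[3, 2, 2] <- ring[4, 3, 2] <- ring[4, 4, 2] <-
    ring[3, 5, 2] <- ring[2, 5, 2] <- ring[1, 4, 2] <- ring[1, 3, 2] <- TRUE
  sk <- sk_from_mask(ring)
  cls <- classify_voxels(sk)
  expect_equal(unname(cls$counts["n_vessel"]), 8L)
  segs <- extract_segments(sk, cls)
  expect_equal(nrow(segs), 1L)
  expect_true(segs$cyclic)
  expect_equal(segs$n_interior, 8L)

  # empty skeleton: no segments
  e <- sk_from_mask(array(FALSE, c(3, 3, 3)))
  expect_equal(nrow(extract_segments(e, classify_voxels(e))), 0L)
})

test_that("length formulas follow voxel counts times mean neighbour distance", {
  a <- array(FALSE, c(7, 3, 3)); a[2:6, 2, 2] <- TRUE      # straight 5-chain
  sk <- sk_from_mask(a)
  cls <- classify_voxels(sk)
  dbar <- mean_neighbor_distance(sk)
  expect_equal(total_network_length(cls, dbar), 5)

  b <- array(FALSE, c(5, 5, 5)); for (i in 1:3) b[i + 1, i + 1, i + 1] <- TRUE
  skb <- sk_from_mask(b)
  expect_equal(total_network_length(classify_voxels(skb), mean_neighbor_distance(skb)),
               3 * sqrt(3))

  # averages over segments, zero-interior included
  segs <- tibble::tibble(n_interior = c(3L))
  expect_equal(average_vessel_length(segs, 1), 3)
  segs <- tibble::tibble(n_interior = c(2L, 2L, 2L))
  expect_equal(average_vessel_length(segs, 1), 2)
  segs <- tibble::tibble(n_interior = c(4L, 0L))
  expect_equal(average_vessel_length(segs, 2), 4)
  expect_warning(v <- average_vessel_length(segs[0, ], 1))
  expect_true(is.nan(v))

  # excluded voxels never contribute to total length
  iso <- array(FALSE, c(9, 3, 3)); iso[2:5, 2, 2] <- TRUE; iso[8, 2, 2] <- TRUE
  ski <- sk_from_mask(iso)
  clsi <- classify_voxels(ski)
  expect_equal(total_network_length(clsi, 1), 4)  # the isolated voxel is excluded
})

test_that("average thickness averages radius over included voxels", {
  ph <- rasterize_phantom(phantom_tube(radius = 3, length = 30))
  vv <- apply_threshold(ph$volume, ph$roi)
  sk <- skeletonize(vv)
  cls <- classify_voxels(sk)
  th <- average_thickness(sk, cls)
  expect_gte(th, 2); expect_lte(th, 4)

  # one-voxel-wide line: radius is one voxel unit everywhere
  a <- array(FALSE, c(8, 5, 5)); a[2:7, 3, 3] <- TRUE
  skl <- skeletonize(vv_from_mask(a))
  expect_equal(average_thickness(skl, classify_voxels(skl)), 1)

  # all voxels excluded: undefined
  lone <- sk_from_mask(array(FALSE, c(3, 3, 3)))
  expect_warning(t0 <- average_thickness(lone, classify_voxels(lone)))
  expect_true(is.nan(t0))
})

test_that("characterize recovers phantom ground truth end to end", {
  ph <- rasterize_phantom(phantom_tube(radius = 3, length = 40))
  m <- characterize(apply_threshold(ph$volume, ph$roi))
  expect_equal(m$characteristics$n_end, 2L)
  expect_equal(m$characteristics$n_bif, 0L)
  expect_equal(m$characteristics$n_cross, 0L)

  phy <- rasterize_phantom(phantom_y(radius = 3))
  my <- characterize(apply_threshold(phy$volume, phy$roi))
  expect_equal(my$characteristics$n_end, 3L)
  expect_equal(my$characteristics$n_bif, 1L)

  # empty selection: zero counts, zero length, undefined averages
  m0 <- suppressWarnings(characterize(vv_from_mask(array(FALSE, c(4, 4, 4)))))
  expect_true(all(unlist(m0$characteristics[c("n_end", "n_vessel", "n_bif", "n_cross")]) == 0))
  expect_equal(m0$characteristics$total_length_mm, 0)
  expect_true(is.nan(m0$characteristics$avg_vessel_length_mm))
})

test_that("lengths scale linearly with voxel spacing, counts are invariant", {
  spec1 <- phantom_tree(n_bif = 2, seed = 3, spacing = 1)
  spec2 <- phantom_tree(n_bif = 2, seed = 3, spacing = 2)
  m1 <- characterize(apply_threshold(rasterize_phantom(spec1)$volume,
                                     rasterize_phantom(spec1)$roi))
  m2 <- characterize(apply_threshold(rasterize_phantom(spec2)$volume,
                                     rasterize_phantom(spec2)$roi))
  for (cnt in c("n_end", "n_vessel", "n_bif", "n_cross"))
    expect_equal(m2$characteristics[[cnt]], m1$characteristics[[cnt]], label = cnt)
  for (len in c("total_length_mm", "avg_vessel_length_mm", "avg_thickness_mm"))
    expect_equal(m2$characteristics[[len]], 2 * m1$characteristics[[len]],
                 tolerance = 1e-9, label = len)
})

test_that("total network length approximates true centerline length on tubes", {
  for (len in c(25, 40)) {
    ph <- rasterize_phantom(phantom_tube(radius = 3, length = len))
    m <- characterize(apply_threshold(ph$volume, ph$roi))
    ratio <- m$characteristics$total_length_mm / ph$truth$centerline_length_mm
    expect_gte(ratio, 0.9); expect_lte(ratio, 1.3)
  }
})

test_that("vessel points are the modal class on random trees", {
  for (s in 1:4) {
    ph <- rasterize_phantom(phantom_tree(n_bif = 3, seed = s))
    m <- characterize(apply_threshold(ph$volume, ph$roi))
    cnt <- m$counts[c("n_end", "n_vessel", "n_bif", "n_cross")]
    expect_equal(names(which.max(cnt)), "n_vessel", label = paste("seed", s))
  }
})

test_that("density ratios divide each characteristic by each volume", {
  mc <- tibble::tibble(n_end = 100, n_vessel = 0, n_bif = 0, n_cross = 0,
                       total_length_mm = 50, avg_vessel_length_mm = 2,
                       avg_thickness_mm = 1)
  r <- density_ratios(mc, pv_cm3 = 10, upvv_cm3 = 0.5)
  expect_equal(r$n_end_per_upvv, 200)
  expect_equal(r$n_end_per_pv, 10)
  expect_equal(ncol(r), 14L)

  # ratio times denominator reproduces the numerator
  set.seed(5)
  for (i in 1:20) {
    vals <- stats::runif(7, 0, 500)
    mc <- tibble::as_tibble(as.list(setNames(vals, upvs_characteristics())))
    pv <- stats::runif(1, 0.1, 100); up <- stats::runif(1, 0.1, 10)
    r <- density_ratios(mc, pv, up)
    expect_equal(as.numeric(r[1, 1:7]) * pv, vals, tolerance = 1e-9)
    expect_equal(as.numeric(r[1, 8:14]) * up, vals, tolerance = 1e-9)
  }

  # zero denominators flag undefined, never silently zero
  expect_warning(rz <- density_ratios(mc, pv_cm3 = 0, upvv_cm3 = 1), "PV")
  expect_true(all(is.na(rz[1, 1:7])))
  expect_false(anyNA(rz[1, 8:14]))
  expect_error(density_ratios(mc, pv_cm3 = -1, upvv_cm3 = 1), "non-negative")
})
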