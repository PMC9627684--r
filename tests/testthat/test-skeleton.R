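test_that("degenerate inputs: empty selection and single voxel", {
  sk0 <- skeletonize(vv_from_mask(array(FALSE, c(4, 4, 4))))
  expect_equal(sum(sk0$skeleton), 0L)

  a <- array(FALSE, c(5, 5, 5)); a[3, 3, 3] <- TRUE
  sk1 <- skeletonize(vv_from_mask(a, spacing = 1))
  expect_equal(sum(sk1$skeleton), 1L)
  expect_true(sk1$skeleton[3, 3, 3])
  # nothing to peel: radius is the distance to the adjacent background voxel
  expect_equal(sk1$radius[3, 3, 3], 1)
})

test_that("a thick axis-aligned tube thins to its exact centerline", {
  ph <- rasterize_phantom(phantom_tube(radius = 3, length = 40, spacing = 1))
  vv <- apply_threshold(ph$volume, ph$roi)
  sk <- skeletonize(vv)
  tb <- tibble::as_tibble(sk)
  # single chain within 1 voxel of the true axis
  expect_lte(diff(range(tb$y)), 1)
  expect_lte(diff(range(tb$z)), 1)
  expect_equal(upvs:::component_count(sk$skeleton), 1L)
  # radius recovered within +/- 1 voxel away from the tube ends
  mid <- tb$radius[tb$x > min(tb$x) + 3 & tb$x < max(tb$x) - 3]
  expect_true(all(abs(mid - 3) <= 1))
})

test_that("tube phantoms of radius 2, 3, 5 recover their radius", {
  for (r in c(2, 3, 5)) {
    ph <- rasterize_phantom(phantom_tube(radius = r, length = 30))
    sk <- skeletonize(apply_threshold(ph$volume, ph$roi))
    tb <- tibble::as_tibble(sk)
    mid <- tb[tb$px > min(tb$px) + r & tb$px < max(tb$px) - r, ]
    expect_gte(mean(mid$radius), r - 1)
    expect_lte(mean(mid$radius), r + 1)
  }
})

test_that("skeletonization preserves 26-connected component count", {
  # two disjoint tubes stay two components
  ph <- rasterize_phantom(phantom_two_tubes(radius = 3, length = 30, gap = 14))
  vv <- apply_threshold(ph$volume, ph$roi)
  sk <- skeletonize(vv)
  expect_equal(upvs:::component_count(vv$selection), 2L)
  expect_equal(upvs:::component_count(sk$skeleton), 2L)

  # random blobs: component count preserved on every case
  set.seed(11)
  for (i in 1:10) {
    a <- random_voxel_set(c(14, 14, 14), density = 0.25)
    vv <- vv_from_mask(a)
    sk <- skeletonize(vv)
    expect_equal(upvs:::component_count(sk$skeleton),
                 upvs:::component_count(vv$selection),
                 label = paste("replicate", i))
    expect_true(all(sk$skeleton[!vv$selection] == FALSE))  # skeleton subset of input
  }
})

test_that("skeletonizing a skeleton is the identity", {
  for (gen in list(phantom_tube(radius = 3, length = 25),
                   phantom_y(radius = 3),
                   phantom_tree(n_bif = 2, seed = 5))) {
    ph <- rasterize_phantom(gen)
    sk <- skeletonize(apply_threshold(ph$volume, ph$roi))
    sk2 <- skeletonize(vv_from_mask(sk$skeleton))
    expect_identical(sk2$skeleton, sk$skeleton)
  }
})

test_that("mean neighbour distance follows the step geometry", {
  # straight axis-aligned chain: all pairs are face neighbours
  a <- array(FALSE, c(8, 3, 3)); a[2:7, 2, 2] <- TRUE
  expect_equal(mean_neighbor_distance(sk_from_mask(a)), 1)

  # body-diagonal chain: all pairs are corner neighbours
  b <- array(FALSE, c(6, 6, 6)); for (i in 1:5) b[i, i, i] <- TRUE
  expect_equal(mean_neighbor_distance(sk_from_mask(b)), sqrt(3))

  # mixed chain: 2 face steps then 2 body-diagonal steps
  m <- array(FALSE, c(8, 8, 8))
  m[2, 2, 2] <- m[3, 2, 2] <- m[4, 2, 2] <- m[5, 3, 3] <- m[6, 4, 4] <- TRUE
  expect_equal(mean_neighbor_distance(sk_from_mask(m)), (2 * 1 + 2 * sqrt(3)) / 4)

  # anisotropic spacing enters the physical distance
  expect_equal(mean_neighbor_distance(sk_from_mask(a, spacing = c(2, 1, 1))), 2)

  # no adjacent pair: warn and fall back to the mean face step
  lone <- array(FALSE, c(5, 5, 5)); lone[2, 2, 2] <- TRUE
  expect_warning(d <- mean_neighbor_distance(sk_from_mask(lone, spacing = c(1, 2, 3))))
  expect_equal(d, 2)
})

test_that("peel-iteration radius mode scales thickness like the EDT mode", {
  ph <- rasterize_phantom(phantom_tube(radius = 3, length = 30))
  vv <- apply_threshold(ph$volume, ph$roi)
  m_edt <- characterize(vv, radius_mode = "edt")
  m_peel <- characterize(vv, radius_mode = "peel_iterations")
  expect_gt(m_peel$characteristics$avg_thickness_mm, 0)
  # both modes agree on the order of magnitude of a radius-3 tube
  expect_equal(m_peel$characteristics$avg_thickness_mm,
               m_edt$characteristics$avg_thickness_mm, tolerance = 0.5)
})
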