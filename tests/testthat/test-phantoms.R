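test_that("ground truth comes from the graph alone", {
  spec <- phantom_spec(rbind(c(5, 5, 5), c(25, 5, 5)),
                       data.frame(from = 1, to = 2, radius = 2),
                       shape = c(31, 11, 11))
  expect_equal(phantom_truth(spec)$n_end, 2L)
  expect_equal(phantom_truth(spec)$n_bif, 0L)
  expect_equal(phantom_truth(spec)$centerline_length_mm, 20)

  y <- phantom_y(radius = 3)
  ty <- phantom_truth(y)
  expect_equal(ty$n_end, 3L)
  expect_equal(ty$n_bif, 1L)
  expect_equal(ty$n_components, 1L)

  tw <- phantom_truth(phantom_two_tubes())
  expect_equal(tw$n_end, 4L)
  expect_equal(tw$n_components, 2L)

  tr <- phantom_truth(phantom_tree(n_bif = 5, seed = 2))
  expect_equal(tr$n_end, 7L)   # root + n_bif + 1 leaves
  expect_equal(tr$n_bif, 5L)
})

test_that("capsule rasterization matches the analytic tube volume", {
  ph <- rasterize_phantom(phantom_tube(radius = 3, length = 40, spacing = 1))
  vox <- sum(ph$volume$intensities >= 100)
  analytic <- pi * 3^2 * 40 + 4 / 3 * pi * 3^3   # cylinder + spherical caps
  expect_equal(vox, analytic, tolerance = 0.1)
})

test_that("phantom nodes must respect the grid margin", {
  expect_error(
    phantom_spec(rbind(c(1, 5, 5), c(25, 5, 5)),
                 data.frame(from = 1, to = 2, radius = 3),
                 shape = c(31, 11, 11)),
    "margin")
  expect_error(
    phantom_spec(rbind(c(5, 5, 5), c(25, 5, 5)),
                 data.frame(from = 1, to = 2, radius = 0.5),
                 shape = c(31, 11, 11)),
    "radii")
})

test_that("artefacts are seeded, additive, and visible downstream", {
  spec0 <- phantom_tube(radius = 3, length = 25)
  ph <- rasterize_phantom(spec0)

  # no artefacts requested: identical volume
  expect_identical(add_artifacts(ph$volume, spec0)$intensities, ph$volume$intensities)

  spec <- phantom_spec(spec0$nodes, spec0$edges, spec0$shape, spec0$spacing,
                       artifacts = list(n_isolated = 5, n_blobs = 1), seed = 9)
  v1 <- add_artifacts(ph$volume, spec)
  v2 <- add_artifacts(ph$volume, spec)
  expect_identical(v1$intensities, v2$intensities)   # deterministic per seed
  expect_gt(sum(v1$intensities >= 100), sum(ph$volume$intensities >= 100))

  # isolated voxels and blobs surface as excluded classes after the pipeline
  roi <- ph$roi
  m <- characterize(apply_threshold(v1, roi))
  expect_gte(m$counts["n_isolated"] + m$counts["n_cluster"], 5)

  # stripes cut through and are supra-threshold
  spec_s <- phantom_spec(spec0$nodes, spec0$edges, spec0$shape, spec0$spacing,
                         artifacts = list(n_stripes = 2), seed = 4)
  vs <- add_artifacts(ph$volume, spec_s)
  expect_gt(sum(vs$intensities >= 100), sum(ph$volume$intensities >= 100))
})

test_that("clean-family trees are recovered exactly end to end", {
  for (s in 1:3) for (B in c(0, 1, 2, 5)) {
    ph <- rasterize_phantom(phantom_tree(n_bif = B, seed = s))
    m <- characterize(apply_threshold(ph$volume, ph$roi))
    lab <- sprintf("B=%d seed=%d", B, s)
    expect_equal(m$characteristics$n_end, ph$truth$n_end, label = lab)
    expect_equal(m$characteristics$n_bif, ph$truth$n_bif, label = lab)
    expect_equal(m$characteristics$n_cross, 0L, label = lab)
    expect_equal(unname(m$counts["n_isolated"] + m$counts["n_cluster"]), 0L, label = lab)
  }
})

test_that("synthetic cohorts are reproducible and carry the full schema", {
  c1 <- synth_cohort(n_subjects = 25, seed = 42)
  c2 <- synth_cohort(n_subjects = 25, seed = 42)
  expect_identical(c1, c2)
  expect_false(identical(c1, synth_cohort(n_subjects = 25, seed = 43)))

  expect_true(all(upvs_characteristics() %in% names(c1)))
  expect_true(all(c("id", "ga_weeks", "scheduled_week", "complication",
                    "pv_cm3", "upvv_cm3") %in% names(c1)))
  expect_true(all(c1$ga_weeks > 5 & c1$ga_weeks < 14))
  expect_true(all(as.matrix(c1[, upvs_characteristics()]) > 0))
  expect_equal(nrow(c1), 75L)  # three visits per subject by default

  expect_error(synth_cohort(prevalence = 0), "prevalence")
  expect_error(synth_cohort(prevalence = 1.2), "prevalence")

  # multiplicative complication effect lowers the complication stratum
  ce <- synth_cohort(n_subjects = 150, effect = 0.5, seed = 7)
  med <- tapply(ce$n_vessel, ce$complication, median)
  expect_lt(med[["1"]], med[["0"]])
})

test_that("gaussian-noise cohorts follow the additive mixed model", {
  g <- cohort_growth_defaults()[1, ]
  g$b0 <- 10; g$b1 <- 2; g$b2 <- 0.5; g$sd_subject <- 2; g$sd_noise <- 1
  coh <- synth_cohort(n_subjects = 150, growth = g, noise = "gaussian", seed = 2)
  fit <- lmm_trajectories(coh, "n_end")
  est <- fit$fixed$estimate
  # generator is centred at 9 weeks: convert truth to the raw-GA scale
  truth <- c(10 - 9 * 2 + 81 * 0.5, 2 - 18 * 0.5, 0.5)
  expect_equal(est, truth, tolerance = 0.15)
  expect_equal(fit$ranef_sd, 2, tolerance = 0.3)
})
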