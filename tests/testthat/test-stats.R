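test_that("Spearman correlation is invariant under monotone transforms", {
  d <- data.frame(a = 1:10, b = (1:10)^3, c = -(1:10), e = exp(1:10))
  s <- spearman_matrix(d, c("a", "b", "c", "e"))
  expect_equal(s$rho["a", "b"], 1)
  expect_equal(s$rho["a", "e"], 1)
  expect_equal(s$rho["a", "c"], -1)
  expect_true(isSymmetric(s$rho))
  expect_equal(unname(diag(s$rho)), rep(1, 4))

  set.seed(31)
  x <- rnorm(40); y <- x + rnorm(40)
  d2 <- data.frame(x = x, y = y, ylog = exp(y))
  s2 <- spearman_matrix(d2, c("x", "y", "ylog"))
  expect_equal(s2$rho["x", "y"], s2$rho["x", "ylog"], tolerance = 1e-12)

  # constant column: flagged undefined, not fabricated
  expect_warning(s3 <- spearman_matrix(data.frame(x = 1:5, k = rep(2, 5)),
                                       c("x", "k")), "constant")
  expect_true(is.na(s3$rho["x", "k"]))
})

test_that("Mann-Whitney p-values match exhaustive enumeration", {
  res <- mwu_compare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$u, 0)
  expect_equal(res$p.value, 0.1)
  expect_true(res$exact)

  set.seed(17)
  for (i in 1:15) {
    n0 <- sample(2:6, 1); n1 <- sample(2:6, 1)
    x <- sample(1:50, n0); y <- sample(51:100, n1) - sample(0:49, n1)
    while (anyDuplicated(c(x, y))) y <- y + stats::runif(n1, 0, 0.9)
    expect_equal(mwu_compare(x, y)$p.value, brute_mwu_p(x, y),
                 tolerance = 1e-12, label = paste("case", i))
  }

  # identical groups: no evidence of a difference
  expect_gte(mwu_compare(1:6, 1:6)$p.value, 0.99)
  expect_error(mwu_compare(numeric(0), 1:3), "non-empty")

  # large samples switch to the corrected normal approximation
  set.seed(3)
  big <- mwu_compare(rnorm(30), rnorm(30, 0.2))
  expect_false(big$exact)
  expect_true(big$p.value > 0 && big$p.value <= 1)
})

test_that("PCA standardizes, orders components, and normalizes variance", {
  set.seed(13)
  n <- 120
  base <- rnorm(n)
  d <- data.frame(a = base + rnorm(n, sd = 0.01),
                  b = 1000 * base + rnorm(n, sd = 10),  # same signal, huge scale
                  c = rnorm(n), e = rnorm(n), f = rnorm(n), g = rnorm(n), h = rnorm(n))
  p <- pca_characteristics(d, names(d))
  expect_equal(sum(p$explained_variance), 1, tolerance = 1e-9)
  expect_true(all(diff(p$explained_variance) <= 1e-9))
  # the correlated pair loads PC1 together despite the scale difference
  expect_gt(abs(p$loadings["a", "PC1"]), 0.6)
  expect_gt(abs(p$loadings["b", "PC1"]), 0.6)
  # components are orthonormal
  gram <- t(p$loadings) %*% p$loadings
  expect_equal(gram, diag(ncol(p$loadings)), tolerance = 1e-9,
               ignore_attr = TRUE)
  # sign convention: dominant loading positive
  for (j in seq_len(ncol(p$loadings)))
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)

  expect_error(pca_characteristics(d[1, ], names(d)), ">= 2")
  dz <- d; dz$a <- 1
  expect_warning(pz <- pca_characteristics(dz, names(dz)), "zero-variance")
  expect_equal(length(pz$variables), 6L)

  # isotropic noise spreads variance roughly evenly across 7 components
  set.seed(99)
  iso <- as.data.frame(matrix(rnorm(7 * 4000), ncol = 7))
  pi7 <- pca_characteristics(iso, names(iso))
  expect_true(all(abs(pi7$explained_variance - 1 / 7) < 0.03))
})

test_that("per-week comparisons reproduce hand-computed medians", {
  d <- tibble::tibble(
    id = sprintf("S%d", 1:6),
    ga_weeks = c(9.1, 8.8, 9.0, 9.2, 8.9, 9.0),
    complication = c(0, 0, 0, 1, 1, 1),
    n_end = c(10, 20, 30, 5, 15, 25))
  out <- compare_groups_at_ga(d, 9, variables = "n_end")
  expect_equal(out$median_0, 20)
  expect_equal(out$median_1, 15)
  expect_equal(out$n_0, 3L); expect_equal(out$n_1, 3L)
  expect_equal(out$p.value, mwu_compare(c(10, 20, 30), c(5, 15, 25))$p.value)

  # visits further than 1 week from the scheduled week are excluded
  d2 <- rbind(d, tibble::tibble(id = "S7", ga_weeks = 10.4, complication = 0, n_end = 99))
  out2 <- compare_groups_at_ga(d2, 9, variables = "n_end")
  expect_equal(out2$n_0, 3L)

  expect_error(compare_groups_at_ga(d[d$complication == 0, ], 9,
                                    variables = "n_end"), "stratum")

  # BH adjustment helper appends a column without altering raw p-values
  coh <- synth_cohort(n_subjects = 40, seed = 5)
  tab <- compare_groups_at_ga(coh, 9, variables = upvs_characteristics())
  adj <- adjust_comparison(tab)
  expect_true(all(adj$p.adjusted >= adj$p.value - 1e-12))
})

test_that("mixed-model trajectories fit by ML and expose the interaction LRT", {
  g <- cohort_growth_defaults()[1, ]
  g$b0 <- 10; g$b1 <- 2; g$b2 <- 0.5; g$sd_subject <- 2; g$sd_noise <- 1
  coh <- synth_cohort(n_subjects = 80, growth = g, noise = "gaussian", seed = 8)

  fit <- lmm_trajectories(coh, "n_end", interaction = "complication")
  expect_s3_class(fit$lrt, "tbl_df")
  expect_equal(fit$lrt$df, 3)          # main effect + two GA interactions
  expect_true(fit$lrt$p.value > 0 && fit$lrt$p.value <= 1)
  expect_true(is.numeric(fit$ranef_sd))
  expect_true(fit$converged)
  expect_equal(nrow(tidy(fit)), 6L)

  # ML (not REML): the base fit's deviance matches an explicit ML refit
  d <- as.data.frame(coh); d$.y <- d$n_end; d$.ga <- d$ga_weeks
  ref <- lme4::lmer(.y ~ .ga + I(.ga^2) + (1 | id), data = d, REML = FALSE)
  base <- lmm_trajectories(coh, "n_end")
  expect_equal(as.numeric(logLik(base$fit)), as.numeric(logLik(ref)), tolerance = 1e-6)

  # no subject-level variation: variance estimate collapses to the boundary
  g0 <- g; g0$sd_subject <- 0
  coh0 <- synth_cohort(n_subjects = 60, growth = g0, noise = "gaussian", seed = 12)
  fit0 <- suppressWarnings(suppressMessages(lmm_trajectories(coh0, "n_end")))
  expect_lt(fit0$ranef_sd, 0.15)
})
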