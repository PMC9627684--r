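#' Spearman rank-correlation matrix with p-values
#'
#' Pairwise Spearman correlations between the selected variables, with
#' midrank tie handling; the workhorse for assessing cohesion between the
#' uPVS characteristics and the volumetric measures. Entries involving a
#' constant variable are undefined and returned as `NA` with a warning.
#'
#' @param data data frame of observations.
#' @param variables character vector of column names; defaults to
#'   [upvs_characteristics()] plus `pv_cm3`/`upvv_cm3` where present.
#' @return An object of class `upvs_spearman`: `rho` and `p` (symmetric
#'   matrices, unit diagonal), `n` complete pairs per entry.
#' @export
spearman_matrix <- function(data, variables = NULL) {
  variables <- variables %||% intersect(
    c(upvs_characteristics(), "pv_cm3", "upvv_cm3"), names(data))
  stopifnot(length(variables) >= 2L, all(variables %in% names(data)))
  k <- length(variables)
  rho <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  diag(rho) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    x <- data[[variables[i]]]; y <- data[[variables[j]]]
    ok <- stats::complete.cases(x, y)
    nmat[i, j] <- nmat[j, i] <- sum(ok)
    if (sum(ok) < 3L) next
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      warning("constant variable in pair (", variables[i], ", ", variables[j],
              "): correlation undefined", call. = FALSE)
      next
    }
    ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman"))
    rho[i, j] <- rho[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  diag(nmat) <- vapply(variables, function(v) sum(!is.na(data[[v]])), 1)
  structure(list(rho = rho, p = p, n = nmat), class = "upvs_spearman")
}

#' @export
print.upvs_spearman <- function(x, digits = 2, ...) {
  cat("<upvs_spearman> rank correlations:\n")
  print(round(x$rho, digits))
  invisible(x)
}

#' @rdname spearman_matrix
#' @param x an `upvs_spearman` object.
#' @param ... unused.
#' @export
tidy.upvs_spearman <- function(x, ...) {
  vars <- rownames(x$rho)
  idx <- which(upper.tri(x$rho), arr.ind = TRUE)
  tibble(var1 = vars[idx[, 1]], var2 = vars[idx[, 2]],
         rho = x$rho[idx], p.value = x$p[idx], n = x$n[idx])
}

#' Principal component analysis of the uPVS characteristics
#'
#' Correlation-matrix PCA: variables are standardized to mean 0, unit
#' variance before eigendecomposition, because the characteristics span
#' orders of magnitude (counts in the hundreds vs lengths in mm). All
#' components are returned with explained-variance fractions summing to 1;
#' the two with the largest eigenvalues are reported as PC1/PC2. Signs
#' follow the convention that each component's largest-magnitude loading is
#' positive. Zero-variance columns are dropped with a warning.
#'
#' @param data data frame (typically one gestational-age stratum).
#' @param variables columns to enter; default [upvs_characteristics()].
#' @return An object of class `upvs_pca`: `loadings` (variables x
#'   components), `scores`, `sdev`, `explained_variance` (fractions),
#'   `variables`.
#' @export
pca_characteristics <- function(data, variables = upvs_characteristics()) {
  stopifnot(all(variables %in% names(data)))
  mat <- as.matrix(as.data.frame(data)[, variables, drop = FALSE])
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  if (nrow(mat) < 2L) stop("need >= 2 complete rows for PCA", call. = FALSE)
  vars_sd <- apply(mat, 2, sd)
  if (any(vars_sd == 0)) {
    warning("dropping zero-variance column(s): ",
            paste(colnames(mat)[vars_sd == 0], collapse = ", "), call. = FALSE)
    mat <- mat[, vars_sd > 0, drop = FALSE]
  }
  fit <- prcomp(mat, center = TRUE, scale. = TRUE)
  # sign convention: largest-|loading| entry of each component is positive
  for (j in seq_len(ncol(fit$rotation))) {
    m <- which.max(abs(fit$rotation[, j]))
    if (fit$rotation[m, j] < 0) {
      fit$rotation[, j] <- -fit$rotation[, j]
      fit$x[, j] <- -fit$x[, j]
    }
  }
  ev <- fit$sdev^2
  structure(list(loadings = fit$rotation, scores = fit$x, sdev = fit$sdev,
                 explained_variance = ev / sum(ev),
                 variables = colnames(mat)),
            class = "upvs_pca")
}

#' @export
print.upvs_pca <- function(x, ...) {
  cat("<upvs_pca> explained variance:",
      paste0(round(100 * x$explained_variance, 1), "%", collapse = ", "), "\n")
  invisible(x)
}

#' @rdname pca_characteristics
#' @param x an `upvs_pca` object.
#' @param ... unused.
#' @export
tidy.upvs_pca <- function(x, ...) {
  lt <- as.data.frame(x$loadings)
  lt$variable <- rownames(x$loadings)
  tidyr::pivot_longer(as_tibble(lt), -"variable",
                      names_to = "component", values_to = "loading")
}

#' @rdname pca_characteristics
#' @export
glance.upvs_pca <- function(x, ...) {
  tibble(n_components = length(x$explained_variance),
         pc1_variance = x$explained_variance[1],
         pc2_variance = x$explained_variance[2],
         pc1_pc2_variance = sum(x$explained_variance[1:2]))
}

#' Mann-Whitney U comparison of two groups
#'
#' Two-sided rank-sum comparison. For combined sample size <= 20 without
#' ties the exact null distribution is used; otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param values_group0,values_group1 numeric vectors (both non-empty).
#' @return One-row tibble: `u` (U statistic of group 0), `p.value`,
#'   `n0`, `n1`, `exact`.
#' @examples
#' mwu_compare(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mwu_compare <- function(values_group0, values_group1) {
  x <- values_group0[!is.na(values_group0)]
  y <- values_group1[!is.na(values_group1)]
  if (!length(x) || !length(y)) stop("both groups must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= 20L) && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE, alternative = "two.sided"))
  tibble(u = unname(wt$statistic), p.value = wt$p.value,
         n0 = length(x), n1 = length(y), exact = exact)
}

#' Linear mixed-model trajectories of a characteristic over gestational age
#'
#' Fits `value ~ GA + GA^2 + (1 | subject)` by maximum likelihood (not
#' REML, so that nested models are comparable by likelihood-ratio test).
#' With `interaction` set to a covariate column (e.g. `"complication"`),
#' the covariate's main effect and its interactions with GA and GA^2 are
#' added and the three-term block is tested by an LRT against the base
#' model.
#'
#' @param cohort data frame with `id`, `ga_weeks` and the outcome column.
#' @param characteristic name of the outcome column.
#' @param interaction optional covariate column name.
#' @param log_scale model `log(value)` instead of `value` (default
#'   `FALSE`); natural for the positive, right-skewed characteristics.
#' @return An object of class `upvs_lmm`: the `lme4` fits (`fit`, and
#'   `fit_base` when an interaction is tested), `fixed` (tidy fixed
#'   effects with Wald 95% CIs), `ranef_sd`, `lrt` (tibble or `NULL`),
#'   `converged`.
#' @export
lmm_trajectories <- function(cohort, characteristic, interaction = NULL,
                             log_scale = FALSE) {
  stopifnot(all(c("id", "ga_weeks", characteristic) %in% names(cohort)))
  d <- as.data.frame(cohort)
  d$.y <- if (log_scale) log(d[[characteristic]]) else d[[characteristic]]
  d$.ga <- d$ga_weeks
  base_f <- .y ~ .ga + I(.ga^2) + (1 | id)
  fit_base <- lme4::lmer(base_f, data = d, REML = FALSE)
  if (is.null(interaction)) {
    fit <- fit_base
    lrt <- NULL
  } else {
    stopifnot(interaction %in% names(cohort))
    d$.g <- d[[interaction]]
    fit <- lme4::lmer(.y ~ .ga + I(.ga^2) + .g + .ga:.g + I(.ga^2):.g + (1 | id),
                      data = d, REML = FALSE)
    lr <- anova(fit_base, fit)
    lrt <- tibble(statistic = lr$Chisq[2], df = lr$Df[2],
                  p.value = lr$`Pr(>Chisq)`[2])
  }
  msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(msgs)
  if (!converged)
    warning("mixed model did not converge cleanly: ",
            paste(unlist(msgs), collapse = "; "), call. = FALSE)
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  fixed <- tibble(term = names(est), estimate = unname(est), std.error = se,
                  conf.low = unname(est) - 1.96 * se,
                  conf.high = unname(est) + 1.96 * se)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(fit = fit, fit_base = if (is.null(interaction)) NULL else fit_base,
                 fixed = fixed,
                 ranef_sd = vc$sdcor[vc$grp == "id"],
                 resid_sd = vc$sdcor[vc$grp == "Residual"],
                 lrt = lrt, converged = converged,
                 characteristic = characteristic, log_scale = log_scale),
            class = "upvs_lmm")
}

#' @export
print.upvs_lmm <- function(x, ...) {
  cat("<upvs_lmm> ", x$characteristic,
      if (x$log_scale) " (log scale)", ", ML fit\n", sep = "")
  print(as.data.frame(x$fixed))
  cat("random-intercept SD:", format(x$ranef_sd),
      " residual SD:", format(x$resid_sd), "\n")
  if (!is.null(x$lrt))
    cat("interaction LRT: chisq =", format(x$lrt$statistic),
        "df =", x$lrt$df, "p =", format(x$lrt$p.value), "\n")
  invisible(x)
}

#' @rdname lmm_trajectories
#' @param x an `upvs_lmm` object.
#' @param ... unused.
#' @export
tidy.upvs_lmm <- function(x, ...) x$fixed

#' @rdname lmm_trajectories
#' @export
glance.upvs_lmm <- function(x, ...) {
  tibble(logLik = as.numeric(logLik(x$fit)), AIC = stats::AIC(x$fit),
         ranef_sd = x$ranef_sd, resid_sd = x$resid_sd,
         converged = x$converged,
         lrt_p = if (is.null(x$lrt)) NA_real_ else x$lrt$p.value)
}

#' Per-week group comparison of characteristics and density ratios
#'
#' Assigns each visit to the nearest scheduled week (within +/- 1 week;
#' other visits are excluded), then reports medians and IQRs per stratum
#' and the Mann-Whitney p-value per variable at one gestational-age week —
#' the stratified-comparison table of a complication analysis.
#'
#' @param cohort data frame with `ga_weeks`, the grouping column and the
#'   variables.
#' @param ga_week scheduled week to compare at (one of `weeks`).
#' @param variables columns to compare; defaults to the seven
#'   characteristics plus all density-ratio columns present.
#' @param group grouping column (default `"complication"`), binary.
#' @param weeks the scheduled visit weeks (default `c(7, 9, 11)`).
#' @return Tibble with one row per variable: group sizes, `median_0`,
#'   `iqr_lo_0`, `iqr_hi_0`, the same for group 1, and `p.value`.
#' @export
compare_groups_at_ga <- function(cohort, ga_week, variables = NULL,
                                 group = "complication", weeks = c(7, 9, 11)) {
  stopifnot(ga_week %in% weeks, group %in% names(cohort))
  variables <- variables %||% intersect(
    c(upvs_characteristics(),
      paste0(upvs_characteristics(), "_per_pv"),
      paste0(upvs_characteristics(), "_per_upvv")),
    names(cohort))
  nearest <- weeks[apply(abs(outer(cohort$ga_weeks, weeks, "-")), 1, which.min)]
  keep <- nearest == ga_week & abs(cohort$ga_weeks - ga_week) <= 1
  d <- cohort[keep, , drop = FALSE]
  g <- d[[group]]
  if (length(unique(g)) < 2L)
    stop("a stratum is empty at week ", ga_week, call. = FALSE)
  purrr::map_dfr(variables, function(v) {
    x0 <- d[[v]][g == 0]; x1 <- d[[v]][g == 1]
    q0 <- quantile(x0, c(0.25, 0.5, 0.75), na.rm = TRUE)
    q1 <- quantile(x1, c(0.25, 0.5, 0.75), na.rm = TRUE)
    mw <- mwu_compare(x0, x1)
    tibble(variable = v, ga_week = ga_week,
           n_0 = sum(g == 0), n_1 = sum(g == 1),
           median_0 = q0[[2]], iqr_lo_0 = q0[[1]], iqr_hi_0 = q0[[3]],
           median_1 = q1[[2]], iqr_lo_1 = q1[[1]], iqr_hi_1 = q1[[3]],
           p.value = mw$p.value)
  })
}

#' Benjamini-Hochberg adjustment helper for comparison tables
#'
#' The primary analysis applies no multiplicity correction (each p-value is
#' read at the 0.05 level); this helper adds an adjusted column for users
#' who want FDR control across a comparison table.
#'
#' @param comparison a tibble with a `p.value` column, e.g. from
#'   [compare_groups_at_ga()].
#' @return The tibble with an extra `p.adjusted` column.
#' @export
adjust_comparison <- function(comparison) {
  stopifnot("p.value" %in% names(comparison))
  comparison$p.adjusted <- stats::p.adjust(comparison$p.value, method = "BH")
  comparison
}
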