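#' Default first-trimester growth model for the cohort simulator
#'
#' Log-scale quadratic trajectories (intercept at 9 weeks GA, per-week slope
#' and curvature) for the seven characteristics plus PV and uPVV, with
#' subject-level random-intercept and residual standard deviations on the
#' log scale. Magnitudes are chosen to emulate a first-trimester
#' utero-placental cohort: counts in the hundreds that roughly double
#' between 7 and 9 weeks, volumes growing faster than the skeleton so the
#' density ratios fall with gestational age.
#'
#' @return A data frame with one row per variable: `variable`, `b0`, `b1`,
#'   `b2` (log-scale quadratic in centred GA), `sd_subject`, `sd_noise`.
#' @export
cohort_growth_defaults <- function() {
  data.frame(
    variable   = c(upvs_characteristics(), "pv_cm3", "upvv_cm3"),
    b0         = c(log(250), log(900), log(140), log(50),
                   log(900), log(2), log(1.5), log(30), log(1.5)),
    b1         = c(0.22, 0.24, 0.24, 0.26, 0.24, 0.0, 0.05, 0.45, 0.40),
    b2         = c(-0.015, -0.015, -0.015, -0.015, -0.015, 0, 0, -0.02, -0.02),
    sd_subject = c(0.35, 0.35, 0.35, 0.40, 0.35, 0.30, 0.20, 0.30, 0.45),
    sd_noise   = c(0.25, 0.25, 0.25, 0.30, 0.25, 0.35, 0.25, 0.20, 0.30)
  )
}

#' Simulate a longitudinal cohort of uPVS characteristics
#'
#' Generates per subject-visit rows of the seven characteristics, PV and
#' uPVV, emulating a first-trimester study design with visits scheduled at
#' 7, 9 and 11 weeks GA. Each variable follows a quadratic-in-GA mean
#' trajectory with a subject-level random intercept; with the default
#' `noise = "lognormal"` the model lives on the log scale, giving positive,
#' right-skewed values, and the complication stratum (prevalence 0.25 by
#' default) is scaled by a multiplicative `effect` (< 1 = less advanced
#' vascular development). `noise = "gaussian"` instead applies the model
#' additively on the response scale — the exact generating process assumed
#' by [lmm_trajectories()], used for parameter-recovery simulation.
#'
#' @param n_subjects number of pregnancies.
#' @param ga_weeks scheduled visit weeks (default `c(7, 9, 11)`).
#' @param growth data frame as [cohort_growth_defaults()] (any subset of its
#'   rows; see that format for a custom model).
#' @param effect multiplicative complication effect on the characteristics
#'   (default 1 = no group difference). Applied to the seven characteristics
#'   only, not to PV/uPVV.
#' @param prevalence complication prevalence in (0, 1); default 0.25.
#' @param visit_prob per-week attendance probabilities (default 1: every
#'   subject attends every visit).
#' @param ga_jitter_sd SD in weeks of the actual visit GA around the
#'   scheduled week (default 0.3).
#' @param cor_subject correlation of subject intercepts across variables
#'   (default 0.7): one latent "vascular development" factor per pregnancy
#'   drives all characteristics, reproducing the strong mutual rank
#'   correlations seen between skeleton characteristics in real cohorts.
#' @param noise `"lognormal"` (default) or `"gaussian"`.
#' @param seed integer seed; the output is deterministic per seed.
#' @return A tibble with columns `id`, `ga_weeks`, `scheduled_week`,
#'   `complication`, `nulliparous`, `ivf_icsi`, `fetal_sex_male`, the seven
#'   characteristics, `pv_cm3`, `upvv_cm3`, and the 14 density-ratio
#'   columns.
#' @examples
#' coh <- synth_cohort(n_subjects = 20, seed = 7)
#' dplyr::count(coh, scheduled_week)
#' @export
synth_cohort <- function(n_subjects = 214, ga_weeks = c(7, 9, 11),
                         growth = cohort_growth_defaults(),
                         effect = 1, prevalence = 0.25,
                         visit_prob = 1, ga_jitter_sd = 0.3, cor_subject = 0.7,
                         noise = c("lognormal", "gaussian"), seed = 1L) {
  noise <- match.arg(noise)
  if (prevalence <= 0 || prevalence >= 1)
    stop("`prevalence` must be inside (0, 1)", call. = FALSE)
  if (length(visit_prob) == 1L) visit_prob <- rep(visit_prob, length(ga_weeks))
  stopifnot(length(visit_prob) == length(ga_weeks), all(is.finite(effect)), effect > 0)
  chars <- upvs_characteristics()
  withr::with_seed(seed, {
    subj <- tibble(
      id = sprintf("S%04d", seq_len(n_subjects)),
      complication = rbinom(n_subjects, 1L, prevalence),
      nulliparous = rbinom(n_subjects, 1L, 0.57),
      ivf_icsi = rbinom(n_subjects, 1L, 0.41),
      fetal_sex_male = rbinom(n_subjects, 1L, 0.50)
    )
    # subject intercepts: one shared latent factor plus a variable-specific
    # part, each scaled to the variable's subject-level SD
    stopifnot(cor_subject >= 0, cor_subject <= 1)
    u_common <- rnorm(n_subjects)
    u <- sapply(growth$sd_subject, function(s) {
      s * (sqrt(cor_subject) * u_common + sqrt(1 - cor_subject) * rnorm(n_subjects))
    })
    colnames(u) <- growth$variable
    rows <- list()
    for (v in seq_along(ga_weeks)) {
      attend <- runif(n_subjects) <= visit_prob[v]
      if (!any(attend)) next
      idx <- which(attend)
      ga <- ga_weeks[v] + rnorm(length(idx), 0, ga_jitter_sd)
      ga <- pmin(pmax(ga, 5.5), 13.5)
      gac <- ga - 9
      vals <- matrix(NA_real_, length(idx), nrow(growth),
                     dimnames = list(NULL, growth$variable))
      for (g in seq_len(nrow(growth))) {
        mu <- growth$b0[g] + growth$b1[g] * gac + growth$b2[g] * gac^2 +
          u[idx, g]
        eps <- rnorm(length(idx), 0, growth$sd_noise[g])
        y <- if (noise == "lognormal") exp(mu + eps) else mu + eps
        if (growth$variable[g] %in% chars && effect != 1) {
          comp <- subj$complication[idx] == 1L
          y[comp] <- y[comp] * effect
        }
        vals[, g] <- y
      }
      sw <- ga_weeks[v]
      rows[[v]] <- dplyr::bind_cols(
        subj[idx, ], tibble(ga_weeks = ga, scheduled_week = rep(sw, length(idx))),
        as_tibble(vals))
    }
    out <- dplyr::arrange(dplyr::bind_rows(rows), .data$id, .data$ga_weeks)
    # density ratios where the volume columns exist
    if (all(c("pv_cm3", "upvv_cm3") %in% names(out)) &&
        all(chars %in% names(out))) {
      for (ch in chars) {
        out[[paste0(ch, "_per_pv")]] <- out[[ch]] / out$pv_cm3
        out[[paste0(ch, "_per_upvv")]] <- out[[ch]] / out$upvv_cm3
      }
    }
    out
  })
}
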