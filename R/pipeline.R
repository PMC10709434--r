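#' Per-subject analysis statistics for a simulated cohort, streaming
#'
#' Simulates one subject at a time (design, planted code, BOLD, gaze,
#' behaviour), computes the requested per-subject statistics and discards
#' the raw data, so cohorts of any size fit in memory. The statistics are
#' the per-subject summaries that the corresponding `run_*` cohort
#' functions aggregate: adaptation modulator beta, cross-context decoding
#' accuracy minus chance, rotation score, grid-RSA Fisher z per symmetry,
#' goal-modulation contrast, gaze correlations and behavioural rates.
#'
#' @param n_subjects cohort size.
#' @param params a [sim_params()] list.
#' @param seed master seed; subject `i` uses `seed * 1000 + i`.
#' @param analyses subset of `c("adaptation", "decoding", "rotation",
#'   "grid", "goalmod", "gaze", "behavior")`.
#' @param variant adaptation variant (see [run_adaptation_analysis()]).
#' @param rotation_control passed to [rotation_score()].
#' @param n_folds grid symmetries to score.
#' @return a tibble with one row per subject and one column per computed
#'   statistic (`adaptation_beta`, `decoding_acc`, `rotation_score`,
#'   `grid_z<k>`, `goalmod_contrast`, `r_ego_x`, `r_ego_y`, `r_choice_x`,
#'   `r_choice_y`, `hit_rate_target`).
#' @export
cohort_statistics <- function(n_subjects = 40, params = sim_params(),
                              seed = 1,
                              analyses = c("adaptation", "decoding",
                                           "rotation", "grid"),
                              variant = "main", rotation_control = "none",
                              n_folds = 6) {
  rows <- lapply(seq_len(n_subjects), function(i) {
    s <- simulate_subject(i, seed = seed * 1000L + i, params = params,
                          with_gaze = "gaze" %in% analyses)
    out <- list(subject = i)
    if ("adaptation" %in% analyses) {
      out$adaptation_beta <- mean(subject_adaptation(s, variant)$beta)
    }
    if ("decoding" %in% analyses) {
      out$decoding_acc <- cross_context_decode(
        subject_ego_patterns(s))$accuracy_minus_chance
    }
    if ("rotation" %in% analyses) {
      out$rotation_score <- rotation_score(
        rotation_similarity_matrix(subject_quadrant_patterns(s)),
        control = rotation_control)
    }
    if ("grid" %in% analyses) {
      p <- subject_direction_patterns(s)
      for (k in n_folds) {
        out[[paste0("grid_z", k)]] <- suppressWarnings(
          grid_rsa_score(p$blue, p$green, build_symmetry_model(k)))
      }
    }
    if ("goalmod" %in% analyses) {
      cl <- subject_goal_modulation(s)
      b <- stats::setNames(cl$beta, cl$class)
      out$goalmod_contrast <- b[["close"]] - b[["far"]]
    }
    if ("gaze" %in% analyses) {
      out <- c(out, as.list(gaze_subject_summary(s$gaze, s$session)))
    }
    if ("behavior" %in% analyses) {
      bm <- behavior_metrics(s$session)
      out$hit_rate_target <-
        mean(bm$hits[bm$question == "target"])
    }
    tibble::as_tibble(out)
  })
  dplyr::bind_rows(rows)
}

#' Replicate-cohort detection rates for a planted effect
#'
#' Runs `n_cohorts` independent synthetic cohorts and, for each, applies a
#' one-sided group test to the chosen per-subject statistic. Returns the
#' fraction of cohorts in which the effect is detected (p < alpha with the
#' expected sign), the per-cohort p-values and group means.
#'
#' @param statistic column name produced by [cohort_statistics()].
#' @param n_cohorts number of replicate cohorts.
#' @param n_subjects subjects per cohort.
#' @param params a [sim_params()] list (the planted truth).
#' @param seed base seed; cohort `c` uses `seed + c`.
#' @param alpha significance level.
#' @param ... further arguments to [cohort_statistics()] (e.g. `analyses`,
#'   `variant`, `n_folds`).
#' @return tibble with one row per cohort (`cohort`, `mean`, `p`,
#'   `detected`); the detection rate is in attribute `rate`.
#' @export
replicate_detection <- function(statistic, n_cohorts = 20, n_subjects = 40,
                                params = sim_params(), seed = 1,
                                alpha = 0.05, ...) {
  rows <- lapply(seq_len(n_cohorts), function(cc) {
    st <- cohort_statistics(n_subjects, params, seed = seed + cc, ...)
    vals <- st[[statistic]]
    gt <- group_test(vals, sided = "greater", label = statistic)
    tibble::tibble(cohort = cc, mean = gt$mean, p = gt$p,
                   detected = gt$p < alpha)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "rate") <- mean(out$detected)
  out
}

#' Run every analysis on a materialised cohort
#'
#' Convenience wrapper returning the full result set for an `hx_cohort`:
#' adaptation (chosen variant), cross-context decoding, rotation, grid RSA,
#' goal modulation, gaze correlations and behavioural metrics.
#'
#' @param cohort an `hx_cohort` from [simulate_cohort()].
#' @param variant adaptation variant.
#' @return named list of result objects and tibbles.
#' @export
analyze_cohort <- function(cohort, variant = "main") {
  gaze <- dplyr::bind_rows(lapply(cohort$subjects, function(s) {
    gaze_subject_summary(s$gaze, s$session)
  }))
  behavior <- dplyr::bind_rows(lapply(seq_along(cohort$subjects),
                                      function(i) {
    dplyr::mutate(behavior_metrics(cohort$subjects[[i]]$session),
                  subject = i, .before = 1)
  }))
  list(
    adaptation = run_adaptation_analysis(cohort, variant),
    decoding = run_decoding_analysis(cohort),
    rotation = run_rotation_analysis(cohort),
    grid_rsa = run_grid_rsa(cohort),
    goal_modulation = goal_modulation_analysis(cohort),
    gaze = gaze,
    behavior = behavior
  )
}
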