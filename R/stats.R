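#' Fisher r-to-z transform
#'
#' `atanh(r)`, variance-stabilising for correlation coefficients.
#' Correlations at or beyond +/-1 are clipped to `1 - 1e-6` in magnitude
#' (with a warning) so the transform stays finite.
#'
#' @param r correlation value(s).
#' @return transformed value(s).
#' @examples
#' fisher_z(0.5) # 0.5493
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    warning("|r| >= 1 clipped to 1 - 1e-6 before Fisher z")
    r <- pmin(pmax(r, -1 + 1e-6), 1 - 1e-6)
  }
  atanh(r)
}

#' One-sample group-level test with a normality gate
#'
#' A one-sample t-test against 0 unless the Shapiro-Wilk test rejects
#' normality at 0.05 (and `gate_normality` is `TRUE`), in which case a
#' Wilcoxon signed-rank test is used.
#'
#' @param values per-subject statistics.
#' @param sided `"two"`, `"greater"` or `"less"`.
#' @param gate_normality use the Shapiro-Wilk gate?
#' @param label optional name for the tested quantity.
#' @return a one-row tibble of class `hx_group_test`: `label`, `n`, `mean`,
#'   `statistic`, `p`, `method`, `sided`, `shapiro_p`.
#' @export
group_test <- function(values, sided = c("two", "greater", "less"),
                       gate_normality = TRUE, label = "effect") {
  sided <- match.arg(sided)
  values <- values[!is.na(values)]
  alt <- c(two = "two.sided", greater = "greater", less = "less")[[sided]]
  if (stats::sd(values) == 0) {
    # degenerate sample: every subject identical
    m <- mean(values)
    p <- if (m == 0) 1 else if (sided == "two") 0 else
      if ((sided == "greater") == (m > 0)) 0 else 1
    out <- tibble::tibble(label = label, n = length(values), mean = m,
                          statistic = sign(m) * Inf, p = p, method = "t",
                          sided = sided, shapiro_p = NA_real_)
    class(out) <- c("hx_group_test", class(out))
    return(out)
  }
  sw <- if (length(values) >= 3 && length(values) <= 5000) {
    stats::shapiro.test(values)$p.value
  } else {
    NA_real_
  }
  if (gate_normality && !is.na(sw) && sw < 0.05) {
    ht <- stats::wilcox.test(values, mu = 0, alternative = alt, exact = FALSE)
    method <- "wilcoxon"
  } else {
    ht <- stats::t.test(values, mu = 0, alternative = alt)
    method <- "t"
  }
  out <- tibble::tibble(
    label = label, n = length(values), mean = mean(values),
    statistic = unname(ht$statistic), p = ht$p.value, method = method,
    sided = sided, shapiro_p = sw
  )
  class(out) <- c("hx_group_test", class(out))
  out
}

# gaze estimate at the volume nearest each time
gaze_at <- function(gaze, times) {
  idx <- pmin(pmax(round(times / (gaze$time[2] - gaze$time[1])) + 1L, 1L),
              nrow(gaze))
  list(x = gaze$x[idx], y = gaze$y[idx])
}

# gaze estimate at the last volume at or before each time
gaze_floor_at <- function(gaze, times) {
  idx <- pmin(pmax(floor(times / (gaze$time[2] - gaze$time[1])) + 1L, 1L),
              nrow(gaze))
  list(x = gaze$x[idx], y = gaze$y[idx])
}

#' Correlate gaze displacement with the egocentric goal angle
#'
#' For each trial the gaze displacement is the estimate at the volume
#' nearest the imagination onset minus the estimate at the volume nearest
#' the morphing onset; the trial-wise displacements are correlated
#' (Pearson) with the signed egocentric condition, separately for the
#' horizontal and vertical axes.
#'
#' @param gaze an `hx_gaze` trace (per-volume estimates) for one run.
#' @param trials the matching run tibble.
#' @return a one-row tibble: `r_horizontal`, `r_vertical`, `n_trials`.
#' @export
gaze_egocentric_correlation <- function(gaze, trials) {
  g_morph <- gaze_at(gaze, trials$morph_onset)
  g_imag <- gaze_at(gaze, trials$imagine_onset)
  dx <- g_imag$x - g_morph$x
  dy <- g_imag$y - g_morph$y
  tibble::tibble(
    r_horizontal = stats::cor(dx, trials$ego_offset),
    r_vertical = stats::cor(dy, trials$ego_offset),
    n_trials = nrow(trials)
  )
}

#' Correlate question-period gaze change with the chosen option's side
#'
#' Validation of the gaze estimates: the horizontal gaze change after the
#' question onset should correlate with the screen side of the option the
#' subject chose. The change is measured as the estimate at the volume
#' nearest the midpoint of the question period (always inside it) minus
#' the estimate at the last volume at or before the question onset (the
#' pre-question baseline).
#'
#' @param gaze an `hx_gaze` trace for one run.
#' @param trials the matching run tibble with a `choice_side` column
#'   (+1 right, -1 left).
#' @return a one-row tibble: `r_horizontal`, `r_vertical`, `n_trials`.
#' @export
gaze_choice_validation <- function(gaze, trials) {
  stopifnot("choice_side" %in% names(trials))
  g_q <- gaze_floor_at(gaze, trials$question_onset)
  g_end <- gaze_at(gaze, trials$question_onset + trials$question_dur / 2)
  tibble::tibble(
    r_horizontal = stats::cor(g_end$x - g_q$x, trials$choice_side),
    r_vertical = stats::cor(g_end$y - g_q$y, trials$choice_side),
    n_trials = nrow(trials)
  )
}

#' Per-subject gaze analyses over a whole session
#'
#' Pools trials across runs of a subject: displacement vs egocentric angle
#' and (when responses are present) question-period change vs chosen side.
#'
#' @param gaze list of per-run `hx_gaze` traces.
#' @param session the subject's session tibble.
#' @return one-row tibble: `r_ego_x`, `r_ego_y`, `r_choice_x`, `r_choice_y`.
#' @export
gaze_subject_summary <- function(gaze, session) {
  runs <- split(session, session$run)
  dx <- c(); dy <- c(); ego <- c()
  qx <- c(); qy <- c(); side <- c()
  for (i in seq_along(runs)) {
    tr <- runs[[i]]
    g_m <- gaze_at(gaze[[i]], tr$morph_onset)
    g_i <- gaze_at(gaze[[i]], tr$imagine_onset)
    dx <- c(dx, g_i$x - g_m$x); dy <- c(dy, g_i$y - g_m$y)
    ego <- c(ego, tr$ego_offset)
    if ("choice_side" %in% names(tr)) {
      g_q <- gaze_floor_at(gaze[[i]], tr$question_onset)
      g_e <- gaze_at(gaze[[i]], tr$question_onset + tr$question_dur / 2)
      qx <- c(qx, g_e$x - g_q$x); qy <- c(qy, g_e$y - g_q$y)
      side <- c(side, tr$choice_side)
    }
  }
  tibble::tibble(
    r_ego_x = stats::cor(dx, ego), r_ego_y = stats::cor(dy, ego),
    r_choice_x = if (length(side)) stats::cor(qx, side) else NA_real_,
    r_choice_y = if (length(side)) stats::cor(qy, side) else NA_real_
  )
}

#' Hit and false-alarm rates per context and question type
#'
#' Hits: probability (in %) of answering "yes" when yes was correct; false
#' alarms: probability of "yes" when no was correct.
#'
#' @param events trial tibble with `context`, `question`, `expected_answer`
#'   and `response` columns (one or more subjects/runs).
#' @return tibble with one row per context x question: `hits`,
#'   `false_alarms` (percent), `n_yes_correct`, `n_no_correct`.
#' @export
behavior_metrics <- function(events) {
  stopifnot("response" %in% names(events))
  events |>
    dplyr::group_by(.data$context, .data$question) |>
    dplyr::summarise(
      hits = 100 * mean(.data$response[.data$expected_answer == "yes"] == "yes"),
      false_alarms = 100 *
        mean(.data$response[.data$expected_answer == "no"] == "yes"),
      n_yes_correct = sum(.data$expected_answer == "yes"),
      n_no_correct = sum(.data$expected_answer == "no"),
      .groups = "drop"
    )
}
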