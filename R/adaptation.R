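#' Log-recency lags for repeated conditions
#'
#' For each trial, the natural log of the time elapsed since the last trial
#' of the same key (e.g. the same egocentric condition) within the same
#' run. First presentations of a key have no lag and are flagged for
#' exclusion; lags never cross run boundaries.
#'
#' @param trials trial tibble with `onset` and `run` columns, onsets
#'   strictly increasing within run.
#' @param key per-trial grouping values (same length as `nrow(trials)`),
#'   e.g. `trials$ego_offset` or `sign(trials$ego_offset)`.
#' @return `trials` with columns `log_lag` (natural log seconds, `NA` on
#'   first presentations) and `first_presentation`.
#' @examples
#' tr <- tibble::tibble(run = 1, onset = c(60, 100), ego_offset = c(45, 45))
#' adaptation_lags(tr, tr$ego_offset)$log_lag # NA, log(40)
#' @export
adaptation_lags <- function(trials, key) {
  stopifnot(length(key) == nrow(trials))
  lags <- unlist(lapply(split(seq_len(nrow(trials)), trials$run), function(i) {
    o <- trials$onset[i]
    if (is.unsorted(o, strictly = TRUE)) {
      stop("onsets must be strictly increasing within run")
    }
    lag_log_dt(o, key[i])
  }), use.names = FALSE)
  dplyr::mutate(trials, log_lag = lags, first_presentation = is.na(lags))
}

adaptation_variants <- c("main", "off_target_only", "per_context",
                         "left_right", "distance_controlled",
                         "startpoint_controlled", "headdirection_controlled")

# Build the adaptation design for one run and return the ROI-mean recency
# modulator beta.
adaptation_run_beta <- function(run, bold, variant) {
  ev <- run
  ev$condition <- "imagine"
  if (variant == "off_target_only") {
    ev$condition[ev$ego_offset == 0] <- "imagine_catch"
    key <- ev$ego_offset
    # lags computed on the filtered (off-target) trial list
    keep <- ev$condition == "imagine"
    lag <- rep(NA_real_, nrow(ev))
    lag[keep] <- lag_log_dt(ev$onset[keep], key[keep])
  } else if (variant == "left_right") {
    ev$condition[ev$ego_offset == 0] <- "imagine_catch"
    keep <- ev$condition == "imagine"
    lag <- rep(NA_real_, nrow(ev))
    lag[keep] <- lag_log_dt(ev$onset[keep], sign(ev$ego_offset[keep]))
  } else {
    lag <- lag_log_dt(ev$onset, ev$ego_offset)
  }
  ev$condition[ev$condition == "imagine" & is.na(lag)] <- "imagine_first"

  mods <- list(recency = ifelse(ev$condition == "imagine", lag, NA_real_))
  if (variant == "distance_controlled") {
    mods$distance <- ifelse(ev$condition == "imagine", ev$goal_distance,
                            NA_real_)
  } else if (variant == "startpoint_controlled") {
    sp <- lag_log_dt(ev$onset, ev$quadrant)
    mods$startpoint <- ifelse(ev$condition == "imagine", sp, NA_real_)
  } else if (variant == "headdirection_controlled") {
    hd <- lag_log_dt(ev$onset, ev$allo_bin)
    mods$headdirection <- ifelse(ev$condition == "imagine", hd, NA_real_)
  }

  fit <- run_glm_fit(run, bold, ev$condition, mods)
  mean(fit$betas["recency", ])
}

subject_adaptation <- function(subject, variant) {
  runs <- split(subject$session, subject$session$run)
  betas <- vapply(seq_along(runs), function(i) {
    adaptation_run_beta(runs[[i]], subject$bold[[i]], variant)
  }, numeric(1))
  ctx <- vapply(runs, function(r) r$context[1], character(1))
  if (variant == "per_context") {
    tibble::tibble(context = c("blue", "green"),
                   beta = c(mean(betas[ctx == "blue"]),
                            mean(betas[ctx == "green"])))
  } else {
    tibble::tibble(context = "both", beta = mean(betas))
  }
}

#' Egocentric adaptation analysis across a cohort
#'
#' Fits, per subject and run, a GLM with one regressor over the imagination
#' periods and a parametric modulator carrying the log time since the same
#' egocentric condition was last presented (first presentations get their
#' own unmodulated regressor; a response-time regressor and cosine drifts
#' are always included). The per-subject region-mean modulator beta
#' (positive = release from adaptation) is tested against zero at the group
#' level with a one-sided test.
#'
#' Variants: `"main"`; `"off_target_only"` (on-target trials modelled
#' separately, lags recomputed on the off-target list);
#' `"per_context"` (per-colour betas); `"left_right"` (conditions collapsed
#' to the sign of the egocentric angle); `"distance_controlled"` /
#' `"startpoint_controlled"` / `"headdirection_controlled"` (goal distance,
#' start-quadrant log-recency, or direction-bin log-recency added as a
#' jointly entered modulator).
#'
#' @param cohort an `hx_cohort` from [simulate_cohort()].
#' @param variant one of the variant names above.
#' @return object of class `hx_adaptation`: list with `subjects` (tibble of
#'   per-subject betas), `group` (an `hx_group_test` per context) and
#'   `variant`.
#' @export
run_adaptation_analysis <- function(cohort, variant = "main") {
  variant <- match.arg(variant, adaptation_variants)
  subjects <- purrr::imap(cohort$subjects, function(s, i) {
    dplyr::mutate(subject_adaptation(s, variant), subject = i, .before = 1)
  }) |> dplyr::bind_rows()
  group <- subjects |>
    dplyr::group_by(.data$context) |>
    dplyr::group_map(~ group_test(.x$beta, sided = "greater",
                                  label = paste0("adaptation_", .y$context))) |>
    dplyr::bind_rows()
  structure(list(subjects = subjects, group = group, variant = variant),
            class = "hx_adaptation")
}

#' Correlation between adaptation effect and behavioural performance
#'
#' Two-sided Pearson correlation across subjects between the adaptation
#' modulator beta and the percentage of hits.
#'
#' @param betas per-subject adaptation betas.
#' @param hit_rates per-subject hit percentages (same order).
#' @return one-row tibble: `r`, `p`, `n`.
#' @export
brain_behavior_correlation <- function(betas, hit_rates) {
  ct <- stats::cor.test(betas, hit_rates, alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(betas))
}
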