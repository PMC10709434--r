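#' Angular distance in 60-degree rotational space
#'
#' Distance between two directions after collapsing the circle to one
#' 60-degree period: `min(d mod 60, 60 - d mod 60)` with
#' `d = |theta1 - theta2|`. Two trajectories 60 degrees apart are perfectly
#' aligned (distance 0); the maximal misalignment is 30 degrees.
#'
#' @param theta1,theta2 directions in degrees (recycled).
#' @return distance(s) in `[0, 30]`.
#' @examples
#' delta60(30, 90) # 0: 60 degrees apart, perfectly aligned
#' delta60(0, 90)  # 30: maximally misaligned
#' @export
delta60 <- function(theta1, theta2) {
  d <- abs(theta1 - theta2) %% 60
  pmin(d, 60 - d)
}

allo_bins <- seq(0, 330, by = 30)

#' Model similarity structure for an n-fold rotational symmetry
#'
#' Builds the 12 x 12 aligned/misaligned indicator matrix over the
#' 30-degree direction-bin centres: a pair of directions is aligned iff
#' their angular difference is an exact multiple of the period
#' `360 / n_fold` (within 1e-6). The diagonal is removed (set `NA`). For
#' the 6-fold (hexadirectional) model this classifies every off-diagonal
#' pair: 30 aligned and 36 misaligned unordered pairs. On 30-degree bins
#' the 5-fold (72 degrees) and 7-fold (51.4 degrees) control periods have
#' no exact off-diagonal multiples, so their aligned sets are empty and
#' the model is flagged degenerate.
#'
#' @param n_fold rotational symmetry, one of 3, 4, 5, 6, 7, 8.
#' @return object of class `hx_symmetry`: list with `n_fold`, `period`
#'   (degrees), `aligned` (12 x 12 0/1 matrix, `NA` diagonal) and
#'   `degenerate`.
#' @export
build_symmetry_model <- function(n_fold) {
  stopifnot(n_fold %in% 3:8)
  period <- 360 / n_fold
  d <- abs(outer(allo_bins, allo_bins, `-`))
  d <- pmin(d, 360 - d)
  rem <- d %% period
  aligned <- (pmin(rem, period - rem) < 1e-6) * 1
  diag(aligned) <- NA
  dimnames(aligned) <- list(allo_bins, allo_bins)
  structure(
    list(n_fold = n_fold, period = period, aligned = aligned,
         degenerate = sum(aligned, na.rm = TRUE) == 0),
    class = "hx_symmetry"
  )
}

#' Grid representational similarity score
#'
#' Correlates the activity patterns of the 12 allocentric direction bins
#' in one context with those in the other (Pearson, 12 x 12), symmetrises
#' the matrix by averaging the lower and upper triangles, removes the
#' diagonal, and correlates the lower triangle with the lower triangle of
#' the aligned/misaligned model; the result is Fisher-z transformed. A
#' degenerate model (empty aligned set) yields `NA`.
#'
#' @param patterns_blue,patterns_green 12 x voxel matrices of direction
#'   betas with row names `0, 30, ..., 330`.
#' @param model an `hx_symmetry` from [build_symmetry_model()].
#' @return scalar Fisher-z score (`NA` for degenerate models).
#' @export
grid_rsa_score <- function(patterns_blue, patterns_green, model) {
  stopifnot(inherits(model, "hx_symmetry"))
  bins <- as.character(allo_bins)
  stopifnot(all(bins %in% rownames(patterns_blue)),
            all(bins %in% rownames(patterns_green)))
  if (model$degenerate) {
    warning("degenerate symmetry model (no aligned pairs on 30-degree bins)")
    return(NA_real_)
  }
  C <- stats::cor(t(patterns_blue[bins, , drop = FALSE]),
                  t(patterns_green[bins, , drop = FALSE]))
  S <- (C + t(C)) / 2
  lt <- lower.tri(S)
  fisher_z(stats::cor(S[lt], model$aligned[lt]))
}

# direction-bin patterns per context for one subject, averaged across the
# runs in which each bin occurs; errors if a bin never occurs in a context
subject_direction_patterns <- function(subject) {
  runs <- split(subject$session, subject$session$run)
  acc <- list(blue = list(sum = 0, n = numeric(12)),
              green = list(sum = 0, n = numeric(12)))
  for (i in seq_along(runs)) {
    run <- runs[[i]]
    ctx <- run$context[1]
    present <- as.character(sort(unique(run$allo_bin)))
    fit <- run_glm_fit(run, subject$bold[[i]], as.character(run$allo_bin))
    m <- matrix(0, 12, subject$bold[[i]]$n_voxels,
                dimnames = list(allo_bins, NULL))
    m[present, ] <- fit$betas[present, , drop = FALSE]
    hit <- as.character(allo_bins) %in% present
    acc[[ctx]]$sum <- acc[[ctx]]$sum + m
    acc[[ctx]]$n <- acc[[ctx]]$n + hit
  }
  lapply(acc, function(a) {
    if (any(a$n == 0)) {
      stop("direction bin(s) never sampled in a context: ",
           paste(allo_bins[a$n == 0], collapse = ", "))
    }
    a$sum / a$n
  })
}

#' Cohort-level grid RSA across control symmetries
#'
#' Estimates 12-direction patterns per subject and context, scores the
#' cross-context similarity structure against each n-fold model and tests
#' the 6-fold group mean against zero (one-sided).
#'
#' @param cohort an `hx_cohort`.
#' @param n_folds symmetries to evaluate.
#' @return object of class `hx_grid_rsa`: `subjects` tibble (`subject`,
#'   `n_fold`, `z`), `group` tests (one row per symmetry) and `n_folds`.
#' @export
run_grid_rsa <- function(cohort, n_folds = 3:8) {
  models <- lapply(n_folds, build_symmetry_model)
  subjects <- purrr::imap(cohort$subjects, function(s, i) {
    p <- subject_direction_patterns(s)
    tibble::tibble(
      subject = i, n_fold = n_folds,
      z = vapply(models, function(m) {
        suppressWarnings(grid_rsa_score(p$blue, p$green, m))
      }, numeric(1))
    )
  }) |> dplyr::bind_rows()
  group <- subjects |>
    dplyr::filter(!is.na(.data$z)) |>
    dplyr::group_by(.data$n_fold) |>
    dplyr::group_map(~ group_test(.x$z, sided = "greater",
                                  label = paste0("grid_", .y$n_fold, "fold"))) |>
    dplyr::bind_rows()
  structure(list(subjects = subjects, group = group, n_folds = n_folds),
            class = "hx_grid_rsa")
}

# per-run goal-modulation betas: ROI-mean grid modulator beta per quadrant
goalmod_run_betas <- function(run, bold, modulator_sign = 1) {
  d60 <- c(NA, delta60(run$allo_bin[-1], run$allo_bin[-nrow(run)]))
  ev_labels <- run$quadrant
  mods <- list()
  flagged <- character()
  for (q in quadrant_levels) {
    v <- ifelse(ev_labels == q, modulator_sign * d60, NA_real_)
    use <- !is.na(v)
    if (sum(use) < 2L || stats::sd(v[use]) == 0) {
      flagged <- c(flagged, q)
    } else {
      mods[[paste0("grid_", q)]] <- v
    }
  }
  fit <- run_glm_fit(run, bold, ev_labels, mods)
  betas <- stats::setNames(rep(NA_real_, 4), quadrant_levels)
  for (q in setdiff(quadrant_levels, flagged)) {
    betas[q] <- mean(fit$betas[paste0("grid_", q), ])
  }
  list(betas = betas, flagged = flagged)
}

subject_goal_modulation <- function(subject, modulator_sign = 1) {
  runs <- split(subject$session, subject$session$run)
  rows <- lapply(seq_along(runs), function(i) {
    run <- runs[[i]]
    rb <- goalmod_run_betas(run, subject$bold[[i]], modulator_sign)
    tibble::tibble(context = run$context[1], quadrant = quadrant_levels,
                   beta = unname(rb$betas),
                   flagged = quadrant_levels %in% rb$flagged)
  }) |> dplyr::bind_rows()
  rows |>
    dplyr::mutate(class = goal_distance_class(.data$quadrant, .data$context)) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(beta = mean(.data$beta, na.rm = TRUE), .groups = "drop")
}

#' Goal-proximity modulation of the grid-like signal
#'
#' Per run, trials are modelled with one regressor per quadrant, each
#' carrying a parametric modulator equal to the angular distance (in
#' 60-degree rotational space) between the trial's direction and the
#' immediately preceding trial's direction -- a release-from-suppression
#' regressor; the first trial of a run is excluded from modulation.
#' Per-subject region-mean modulator betas are mapped to goal-distance
#' classes (close = goal quadrant, far = opposite quadrant, medium =
#' Q1/Q4 averaged, classes swap between contexts) and averaged across
#' contexts. The group contrast is close minus far (one-sided), with the
#' linear trend over (far, medium, close) reported alongside.
#'
#' @param cohort an `hx_cohort`.
#' @param modulator_sign `+1` models release from suppression (larger
#'   rotational distance, larger signal); `-1` flips the convention.
#' @return object of class `hx_goalmod`: `subjects` tibble (`close`,
#'   `medium`, `far`, `contrast`, `trend`), `group` test on the contrast.
#' @export
goal_modulation_analysis <- function(cohort, modulator_sign = 1) {
  subjects <- purrr::imap(cohort$subjects, function(s, i) {
    cl <- subject_goal_modulation(s, modulator_sign)
    b <- stats::setNames(cl$beta, cl$class)
    tibble::tibble(
      subject = i, close = b[["close"]], medium = b[["medium"]],
      far = b[["far"]], contrast = b[["close"]] - b[["far"]],
      trend = (b[["close"]] - b[["far"]]) / 2
    )
  }) |> dplyr::bind_rows()
  group <- group_test(subjects$contrast, sided = "greater",
                      label = "goal_modulation")
  structure(list(subjects = subjects, group = group),
            class = "hx_goalmod")
}
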