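#' Cross-context quadrant similarity matrix under 180-degree rotation
#'
#' Correlates (Pearson) the quadrant activity patterns of the blue context
#' (rows, Q1..Q4) with those of the green context in reversed order
#' (columns, Q4..Q1), as if one space were rotated by 180 degrees. The
#' diagonal then holds the rotation-matched pairs (Q1 blue with Q4 green,
#' Q2 with Q3, Q3 with Q2, Q4 with Q1).
#'
#' @param patterns an `hx_patterns` tibble with quadrant conditions
#'   (`"Q1".."Q4"`) for both contexts; run-level patterns are averaged
#'   within context.
#' @return 4x4 matrix of class `hx_rotation_matrix`, rows `Q1b..Q4b`,
#'   columns `Q4g..Q1g`.
#' @export
rotation_similarity_matrix <- function(patterns) {
  pb <- patterns_matrix(patterns, "blue", quadrant_levels)
  pg <- patterns_matrix(patterns, "green", quadrant_levels)
  rev_order <- rev(quadrant_levels)
  M <- stats::cor(t(pb), t(pg[rev_order, , drop = FALSE]))
  dimnames(M) <- list(paste0(quadrant_levels, "b"), paste0(rev_order, "g"))
  class(M) <- c("hx_rotation_matrix", class(M))
  M
}

#' Rotation-alignment score from a quadrant similarity matrix
#'
#' Mean Fisher-z transformed on-diagonal correlation minus mean off-
#' diagonal correlation. Controls: `"exclude_goal_quadrants"` removes the
#' blue-goal row (Q2 blue) and the green-goal column (Q3 green) before
#' scoring, so no correlation involving a goal quadrant's own-context
#' pattern contributes; `"q1q4_only"` scores only the 2x2 submatrix of the
#' two quadrants equidistant from both goals (Q1/Q4 rows by Q4/Q1
#' columns). Correlations at |r| = 1 are clipped before the transform.
#'
#' @param matrix an `hx_rotation_matrix`.
#' @param control `"none"`, `"exclude_goal_quadrants"` or `"q1q4_only"`.
#' @return scalar score (positive = rotation-aligned representation).
#' @export
rotation_score <- function(matrix,
                           control = c("none", "exclude_goal_quadrants",
                                       "q1q4_only")) {
  control <- match.arg(control)
  keep_r <- rep(TRUE, 4)
  keep_c <- rep(TRUE, 4)
  if (control == "exclude_goal_quadrants") {
    keep_r[2] <- FALSE        # Q2 blue row
    keep_c[2] <- FALSE        # Q3 green column (order Q4,Q3,Q2,Q1)
  } else if (control == "q1q4_only") {
    keep_r <- c(TRUE, FALSE, FALSE, TRUE)
    keep_c <- c(TRUE, FALSE, FALSE, TRUE)
  }
  z <- fisher_z(unclass(matrix))
  on <- diag(4) == 1
  keep <- outer(keep_r, keep_c, `&`)
  mean(z[on & keep]) - mean(z[!on & keep])
}

# quadrant GLM patterns for one subject, run-level
subject_quadrant_patterns <- function(subject) {
  runs <- split(subject$session, subject$session$run)
  fits <- lapply(seq_along(runs), function(i) {
    run_glm_fit(runs[[i]], subject$bold[[i]], runs[[i]]$quadrant)
  })
  extract_condition_patterns(
    fits, quadrant_levels,
    context = vapply(runs, function(r) r$context[1], character(1)),
    run = as.integer(names(runs))
  )
}

#' Cohort-level rotation analysis
#'
#' Estimates quadrant patterns per subject (4 regressors per run, averaged
#' across the 4 runs of each context), forms the reversed-order cross-
#' context similarity matrix and tests the group mean on- minus off-
#' diagonal score against zero (one-sided).
#'
#' @param cohort an `hx_cohort`.
#' @param control passed to [rotation_score()].
#' @return object of class `hx_rotation`: `subjects` tibble (scores),
#'   `matrices` (list of per-subject similarity matrices), `group` test,
#'   `control`.
#' @export
run_rotation_analysis <- function(cohort, control = "none") {
  matrices <- lapply(cohort$subjects, function(s) {
    rotation_similarity_matrix(subject_quadrant_patterns(s))
  })
  subjects <- tibble::tibble(
    subject = seq_along(matrices),
    score = vapply(matrices, rotation_score, numeric(1), control = control)
  )
  group <- group_test(subjects$score, sided = "greater",
                      label = paste0("rotation_", control))
  structure(list(subjects = subjects, matrices = matrices, group = group,
                 control = control),
            class = "hx_rotation")
}
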