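result_tidy <- function(x) tibble::as_tibble(x$subjects)

result_glance <- function(x) tibble::as_tibble(x$group)

#' Broom-style accessors for analysis results
#'
#' `tidy()` returns the per-subject statistics; `glance()` the one-row (or
#' one-row-per-context/symmetry) group-level summary.
#'
#' @param x an analysis result (`hx_adaptation`, `hx_decoding`,
#'   `hx_rotation`, `hx_grid_rsa`, `hx_goalmod`).
#' @param ... unused.
#' @return a tibble.
#' @name hexsearch-tidiers
NULL

#' @rdname hexsearch-tidiers
#' @export
tidy.hx_adaptation <- function(x, ...) result_tidy(x)
#' @rdname hexsearch-tidiers
#' @export
glance.hx_adaptation <- function(x, ...) result_glance(x)
#' @rdname hexsearch-tidiers
#' @export
tidy.hx_decoding <- function(x, ...) result_tidy(x)
#' @rdname hexsearch-tidiers
#' @export
glance.hx_decoding <- function(x, ...) result_glance(x)
#' @rdname hexsearch-tidiers
#' @export
tidy.hx_rotation <- function(x, ...) result_tidy(x)
#' @rdname hexsearch-tidiers
#' @export
glance.hx_rotation <- function(x, ...) result_glance(x)
#' @rdname hexsearch-tidiers
#' @export
tidy.hx_grid_rsa <- function(x, ...) result_tidy(x)
#' @rdname hexsearch-tidiers
#' @export
glance.hx_grid_rsa <- function(x, ...) result_glance(x)
#' @rdname hexsearch-tidiers
#' @export
tidy.hx_goalmod <- function(x, ...) result_tidy(x)
#' @rdname hexsearch-tidiers
#' @export
glance.hx_goalmod <- function(x, ...) result_glance(x)

#' @export
print.hx_group_test <- function(x, ...) {
  NextMethod()
  invisible(x)
}

subject_dotplot <- function(values, ylab) {
  df <- tibble::tibble(subject = seq_along(values), value = values)
  ggplot2::ggplot(df, ggplot2::aes(x = "", y = .data$value)) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3,
                          colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_minimal()
}

#' Plots of analysis results
#'
#' Per-subject distributions with group means for scalar results, a
#' heatmap for the rotation similarity matrix, per-symmetry scores for the
#' grid RSA, and class profiles for the goal modulation.
#'
#' @param object an analysis result object.
#' @param ... unused.
#' @return a ggplot.
#' @name hexsearch-autoplot
NULL

#' @rdname hexsearch-autoplot
#' @export
autoplot.hx_adaptation <- function(object, ...) {
  subject_dotplot(object$subjects$beta, "recency modulator beta (a.u.)")
}

#' @rdname hexsearch-autoplot
#' @export
autoplot.hx_decoding <- function(object, ...) {
  subject_dotplot(object$subjects$accuracy_minus_chance,
                  "decoding accuracy - chance (%)")
}

#' @rdname hexsearch-autoplot
#' @export
autoplot.hx_rotation <- function(object, ...) {
  subject_dotplot(object$subjects$score, "rotation score (Fisher z)")
}

#' @rdname hexsearch-autoplot
#' @export
autoplot.hx_grid_rsa <- function(object, ...) {
  ggplot2::ggplot(object$subjects,
                  ggplot2::aes(x = factor(.data$n_fold), y = .data$z)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.4) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "rotational symmetry (n-fold)",
                  y = "model correlation (Fisher z)") +
    ggplot2::theme_minimal()
}

#' @rdname hexsearch-autoplot
#' @export
autoplot.hx_goalmod <- function(object, ...) {
  long <- tidyr::pivot_longer(object$subjects, c("far", "medium", "close"),
                              names_to = "class", values_to = "beta")
  long$class <- factor(long$class, levels = c("far", "medium", "close"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$beta)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.4) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "firebrick") +
    ggplot2::labs(x = "quadrant distance from goal",
                  y = "grid modulator beta (a.u.)") +
    ggplot2::theme_minimal()
}

#' @rdname hexsearch-autoplot
#' @export
autoplot.hx_rotation_matrix <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame(as.table(unclass(object))),
                          .name_repair = ~ c("blue", "green", "r"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$green, y = .data$blue,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = "green quadrants (reversed order)",
                  y = "blue quadrants") +
    ggplot2::theme_minimal()
}
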