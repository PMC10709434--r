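#' Nearest-neighbour classification of activity patterns
#'
#' Each test pattern receives the label of the closest training pattern
#' under correlation distance (`1 - Pearson r`; configurable to Euclidean).
#' Exact ties are broken towards the first training exemplar.
#'
#' @param train numeric matrix, training exemplars in rows.
#' @param labels training labels (length `nrow(train)`).
#' @param test numeric matrix of test patterns (same voxel columns).
#' @param metric `"correlation"` or `"euclidean"`.
#' @return list with `predicted` labels and `accuracy` (percent correct,
#'   `NA` when no `true` labels given via `rownames(test)`).
#' @export
nn_classify <- function(train, labels, test,
                        metric = c("correlation", "euclidean")) {
  metric <- match.arg(metric)
  stopifnot(nrow(train) == length(labels), ncol(train) == ncol(test))
  if (metric == "correlation") {
    if (any(apply(train, 1, stats::sd) == 0) ||
        any(apply(test, 1, stats::sd) == 0)) {
      stop("zero-variance pattern: correlation distance undefined")
    }
    D <- 1 - stats::cor(t(test), t(train))
  } else {
    D <- outer(seq_len(nrow(test)), seq_len(nrow(train)),
               Vectorize(function(i, j) sqrt(sum((test[i, ] - train[j, ])^2))))
  }
  predicted <- labels[apply(D, 1, which.min)]
  truth <- rownames(test)
  acc <- if (!is.null(truth)) 100 * mean(predicted == truth) else NA_real_
  list(predicted = predicted, accuracy = acc)
}

# run-level condition x voxel matrices for one context
run_pattern_list <- function(patterns, ctx, conditions) {
  sel <- patterns$context == ctx
  lapply(unique(patterns$run[sel]), function(r) {
    i <- which(sel & patterns$run == r)
    m <- do.call(rbind,
                 patterns$pattern[i][match(conditions,
                                           patterns$condition[i])])
    rownames(m) <- conditions
    m
  })
}

#' Cross-context (and within-context) decoding of egocentric conditions
#'
#' Trains the nearest-neighbour classifier on the run-level condition
#' patterns of one context and tests it on each run of the other context
#' (both directions, averaged), or cross-validates across runs within each
#' context. Chance (100/7 = 14.29%, or 100/6 when the on-target condition
#' is excluded) is subtracted from the accuracy.
#'
#' @param patterns an `hx_patterns` tibble with run-level egocentric
#'   condition patterns (conditions named by signed angle).
#' @param scheme `"cross_context"` or `"within_context"`.
#' @param exclude_on_target drop the 0-degree condition and use chance 1/6?
#' @param metric passed to [nn_classify()].
#' @return one-row tibble: `scheme`, `n_conditions`, `chance`, `accuracy`,
#'   `accuracy_minus_chance` (all accuracies in percent).
#' @export
cross_context_decode <- function(patterns,
                                 scheme = c("cross_context", "within_context"),
                                 exclude_on_target = FALSE,
                                 metric = "correlation") {
  scheme <- match.arg(scheme)
  conditions <- as.character(if (exclude_on_target)
    setdiff(ego_levels, 0) else ego_levels)
  k <- length(conditions)
  accs <- c()
  if (scheme == "cross_context") {
    for (pair in list(c("blue", "green"), c("green", "blue"))) {
      train_runs <- run_pattern_list(patterns, pair[1], conditions)
      test_runs <- run_pattern_list(patterns, pair[2], conditions)
      train <- do.call(rbind, train_runs)
      labels <- rep(conditions, length(train_runs))
      for (te in test_runs) {
        accs <- c(accs, nn_classify(train, labels, te, metric)$accuracy)
      }
    }
  } else {
    for (ctx in c("blue", "green")) {
      runs <- run_pattern_list(patterns, ctx, conditions)
      for (i in seq_along(runs)) {
        train <- do.call(rbind, runs[-i])
        labels <- rep(conditions, length(runs) - 1L)
        accs <- c(accs, nn_classify(train, labels, runs[[i]], metric)$accuracy)
      }
    }
  }
  acc <- mean(accs)
  tibble::tibble(scheme = scheme, n_conditions = k, chance = 100 / k,
                 accuracy = acc, accuracy_minus_chance = acc - 100 / k)
}

# 7-condition egocentric GLM patterns for one subject, run-level
subject_ego_patterns <- function(subject) {
  runs <- split(subject$session, subject$session$run)
  fits <- lapply(seq_along(runs), function(i) {
    run_glm_fit(runs[[i]], subject$bold[[i]],
                as.character(runs[[i]]$ego_offset))
  })
  extract_condition_patterns(
    fits, as.character(ego_levels),
    context = vapply(runs, function(r) r$context[1], character(1)),
    run = as.integer(names(runs))
  )
}

# imagination events labelled by condition + response sticks
condition_events <- function(run, labels) {
  events <- tibble::tibble(
    onset = c(run$imagine_onset,
              run$question_onset + if ("rt" %in% names(run)) run$rt else 0),
    duration = c(run$imagine_dur, rep(0, nrow(run))),
    condition = c(labels, rep("response", nrow(run)))
  )
  events[order(events$onset), ]
}

#' Cohort-level egocentric decoding analysis
#'
#' Estimates run-level patterns of the 7 egocentric conditions per subject
#' (separate GLM regressors per condition), decodes across contexts and
#' tests the group mean accuracy-minus-chance against zero (one-sided).
#'
#' @param cohort an `hx_cohort`.
#' @inheritParams cross_context_decode
#' @return object of class `hx_decoding`: `subjects` tibble, `group` test,
#'   `scheme`, `chance`.
#' @export
run_decoding_analysis <- function(cohort, scheme = "cross_context",
                                  exclude_on_target = FALSE) {
  subjects <- purrr::imap(cohort$subjects, function(s, i) {
    res <- cross_context_decode(subject_ego_patterns(s), scheme,
                                exclude_on_target)
    dplyr::mutate(res, subject = i, .before = 1)
  }) |> dplyr::bind_rows()
  group <- group_test(subjects$accuracy_minus_chance, sided = "greater",
                      label = paste0("decoding_", scheme))
  structure(list(subjects = subjects, group = group, scheme = scheme,
                 chance = subjects$chance[1]),
            class = "hx_decoding")
}

#' Generic searchlight over a 3D voxel lattice
#'
#' Computes a statistic in a sphere (default radius 3 voxels) centred on
#' every voxel of the lattice and stores it at the centre. Works for any
#' per-sphere statistic: decoding, rotation or grid scores alike. Spheres
#' truncated at the lattice edge keep fewer voxels; those with fewer than
#' 10 voxels are still computed but flagged.
#'
#' @param data numeric matrix: one row per lattice voxel (column-major
#'   order over `dims`), columns are features (e.g. condition betas).
#' @param dims integer c(nx, ny, nz) of the lattice.
#' @param statistic_fn function of the sphere's rows of `data` (a matrix)
#'   returning a scalar.
#' @param radius sphere radius in voxels.
#' @return list with `map` (3D array of statistics), `n_voxels` (sphere
#'   sizes) and `small_sphere` (logical array, sphere < 10 voxels).
#' @export
searchlight_map <- function(data, dims, statistic_fn, radius = 3) {
  stopifnot(nrow(data) == prod(dims))
  off <- expand.grid(dx = -radius:radius, dy = -radius:radius,
                     dz = -radius:radius)
  off <- off[off$dx^2 + off$dy^2 + off$dz^2 <= radius^2, ]
  map <- array(NA_real_, dims)
  nvox <- array(0L, dims)
  for (z in seq_len(dims[3])) for (y in seq_len(dims[2]))
    for (x in seq_len(dims[1])) {
      cx <- x + off$dx; cy <- y + off$dy; cz <- z + off$dz
      ok <- cx >= 1 & cx <= dims[1] & cy >= 1 & cy <= dims[2] &
        cz >= 1 & cz <= dims[3]
      idx <- cx[ok] + (cy[ok] - 1L) * dims[1] +
        (cz[ok] - 1L) * dims[1] * dims[2]
      map[x, y, z] <- statistic_fn(data[idx, , drop = FALSE])
      nvox[x, y, z] <- length(idx)
    }
  list(map = map, n_voxels = nvox, small_sphere = nvox < 10L)
}

#' Multidimensional scaling of condition patterns
#'
#' Classical MDS of the condition-by-condition correlation-distance matrix
#' (`1 - Pearson r`). To fix the arbitrary reflection, the sign of each
#' axis is chosen so that the coordinate with the largest magnitude on
#' that axis is positive.
#'
#' @param patterns an `hx_patterns` tibble (averaged across runs if
#'   needed) or a condition x voxel matrix with row names.
#' @param k embedding dimension.
#' @return tibble: `condition`, `dim1`, `dim2`, ...
#' @export
mds_embed <- function(patterns, k = 2) {
  m <- if (is.matrix(patterns)) patterns else {
    ps <- patterns |>
      dplyr::group_by(.data$condition) |>
      dplyr::summarise(pattern = list(Reduce(`+`, .data$pattern) / dplyr::n()),
                       .groups = "drop")
    stats::setNames(do.call(rbind, ps$pattern), NULL) |>
      `rownames<-`(ps$condition)
  }
  D <- 1 - suppressWarnings(stats::cor(t(m)))
  # zero-variance patterns: distance 0 to identical rows, max otherwise
  if (anyNA(D)) {
    na <- which(is.na(D), arr.ind = TRUE)
    D[na] <- ifelse(
      sapply(seq_len(nrow(na)), function(i) {
        isTRUE(all.equal(m[na[i, 1], ], m[na[i, 2], ]))
      }), 0, 2)
  }
  D[D < 0] <- 0
  xy <- stats::cmdscale(stats::as.dist(D), k = k)
  if (ncol(xy) < k) {  # fewer positive eigenvalues than requested axes
    xy <- cbind(xy, matrix(0, nrow(xy), k - ncol(xy)))
  }
  for (j in seq_len(ncol(xy))) {
    if (xy[which.max(abs(xy[, j])), j] < 0) xy[, j] <- -xy[, j]
  }
  colnames(xy) <- paste0("dim", seq_len(k))
  out <- tibble::as_tibble(xy)
  dplyr::mutate(out, condition = rownames(m), .before = 1)
}
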