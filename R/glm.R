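#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities (peak delay 6 s, undershoot delay 16 s,
#' unit dispersions, peak-to-undershoot ratio 6), truncated at 32 s and
#' normalised to unit peak. The kernel value at `t = 0` is 0 and the peak
#' sits near 5 s.
#'
#' @param t_grid time points in seconds at which to sample the kernel.
#' @param peak_delay,undershoot_delay,ratio shape parameters.
#' @return numeric vector of kernel values, unit peak.
#' @export
canonical_hrf <- function(t_grid, peak_delay = 6, undershoot_delay = 16,
                          ratio = 6) {
  h <- stats::dgamma(t_grid, shape = peak_delay, rate = 1) -
    stats::dgamma(t_grid, shape = undershoot_delay, rate = 1) / ratio
  h[t_grid > 32] <- 0
  h / max(h)
}

# HRF convolution of event boxcars, evaluated at volume sample times.
#
# Events are snapped to an oversampled grid (dt = tr / oversample); the
# discrete convolution of a boxcar with the kernel equals a difference of
# the kernel's cumulative sum, so each column is computed exactly (to
# machine precision) without an FFT and only at the volume samples.
# Zero-duration events become single-sample sticks. With `combine = TRUE`
# the events are summed into a single column (heights weighting them);
# otherwise one column per event is returned.
conv_event_columns <- function(onsets, durations, heights, n_volumes, tr,
                               oversample = 10, hrf_fun = canonical_hrf,
                               combine = TRUE) {
  dt <- tr / oversample
  n_os <- n_volumes * oversample
  K <- cumsum(hrf_fun(seq(0, 32, by = dt)))
  len <- length(K)
  # lookup table L(m) for m in 0..n_os: 0 below, plateau above
  L <- c(0, K, rep(K[len], max(0L, n_os - len)))
  i0 <- pmin(floor(onsets / dt) + 1L, n_os)
  i1 <- pmin(pmax(ceiling((onsets + durations) / dt), i0), n_os)
  vol_os <- (seq_len(n_volumes) - 1L) * oversample + 1L
  m_hi <- outer(vol_os + 1L, i0, `-`)
  m_hi[m_hi < 0L] <- 0L
  m_hi[m_hi > n_os] <- n_os
  m_lo <- outer(vol_os, i1, `-`)
  m_lo[m_lo < 0L] <- 0L
  m_lo[m_lo > n_os] <- n_os
  cols <- matrix(L[m_hi + 1L] - L[m_lo + 1L], n_volumes) * dt
  if (combine) drop(cols %*% heights)
  else cols * rep(heights, each = n_volumes)
}

#' Build a first-level design matrix
#'
#' Condition boxcars (one column per level of the `condition` column of
#' `events`) are built on an oversampled grid (`oversample` times the TR),
#' convolved with the HRF and sampled at volume acquisition times.
#' Parametric modulators are the same boxcars with per-event heights equal
#' to the modulator values after mean-centering within the run; events with
#' `NA` modulator values are left out of the modulator column (the caller
#' decides whether such events get their own condition). Nuisance columns
#' are appended untouched, followed by a discrete-cosine drift basis
#' (cutoff `drift_cutoff` seconds) and an intercept.
#'
#' @param events tibble with columns `onset`, `duration` (seconds) and the
#'   condition column; rows must be sorted by onset.
#' @param tr repetition time in seconds.
#' @param n_volumes number of volumes in the run.
#' @param condition name of the events column holding condition labels.
#' @param modulators named list of numeric vectors (one value per events
#'   row, `NA` = event excluded from that modulator), each paired with the
#'   events of one or more conditions.
#' @param nuisance optional numeric matrix of nuisance regressors
#'   (`n_volumes` rows).
#' @param drift_cutoff high-pass cutoff in seconds for the cosine drift
#'   basis; `NULL` drops the drift columns.
#' @param oversample oversampling factor for the convolution grid.
#' @param hrf_fun function of a time grid returning the kernel.
#' @return an object of class `hx_design`: a list with the matrix `X`
#'   (`n_volumes` x columns), column `roles` (`"task"`, `"modulator"`,
#'   `"nuisance"`, `"drift"`, `"intercept"`) and the build settings.
#' @export
build_design_matrix <- function(events, tr, n_volumes,
                                condition = "condition",
                                modulators = NULL, nuisance = NULL,
                                drift_cutoff = 128, oversample = 10,
                                hrf_fun = canonical_hrf) {
  stopifnot(all(c("onset", "duration", condition) %in% names(events)))
  if (is.unsorted(events$onset)) stop("events must be sorted by onset")
  if (any(events$onset + events$duration > n_volumes * tr)) {
    stop("events extend beyond the end of the scan")
  }
  labels <- events[[condition]]
  conds <- unique(labels)

  cols <- list()
  roles <- character()
  for (cn in conds) {
    sel <- labels == cn
    cols[[cn]] <- conv_event_columns(
      events$onset[sel], events$duration[sel], rep(1, sum(sel)),
      n_volumes, tr, oversample, hrf_fun
    )
    roles <- c(roles, "task")
  }
  for (mn in names(modulators)) {
    vals <- modulators[[mn]]
    stopifnot(length(vals) == nrow(events))
    use <- !is.na(vals)
    if (sum(use) < 2L) stop("modulator '", mn, "' covers fewer than 2 events")
    cols[[mn]] <- conv_event_columns(
      events$onset[use], events$duration[use],
      vals[use] - mean(vals[use]), n_volumes, tr, oversample, hrf_fun
    )
    roles <- c(roles, "modulator")
  }

  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)

  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    stopifnot(nrow(nuisance) == n_volumes)
    if (is.null(colnames(nuisance))) {
      colnames(nuisance) <- paste0("nuis_", seq_len(ncol(nuisance)))
    }
    X <- cbind(X, nuisance)
    roles <- c(roles, rep("nuisance", ncol(nuisance)))
  }
  if (!is.null(drift_cutoff)) {
    D <- drift_basis(n_volumes, tr, drift_cutoff)
    if (!is.null(D)) {
      X <- cbind(X, D)
      roles <- c(roles, rep("drift", ncol(D)))
    }
  }
  X <- cbind(X, intercept = 1)
  roles <- c(roles, "intercept")

  # all-zero modulator columns (e.g. a constant modulator centred away) are
  # permitted in the built matrix; the rank check covers the live columns
  live <- colSums(X^2) > 0
  if (qr(X[, live, drop = FALSE])$rank < sum(live)) {
    stop("design matrix is rank deficient")
  }
  structure(
    list(X = X, roles = roles, tr = tr, n_volumes = n_volumes,
         oversample = oversample, names = colnames(X)),
    class = "hx_design"
  )
}

#' Fit a voxel-wise ordinary-least-squares GLM
#'
#' @param bold an `hx_bold` run (voxel x time matrix, see
#'   [simulate_bold_run()]) or a plain time x voxel numeric matrix.
#' @param design an `hx_design` from [build_design_matrix()].
#' @param variance compute residual variances? (needed for [contrast_t()];
#'   skippable when only the coefficients are used).
#' @return an object of class `hx_glm_fit`: per-voxel coefficient matrix
#'   `betas` (regressors x voxels), residual variances `sigma2` (unbiased,
#'   residual sum of squares over `dof`), degrees of freedom
#'   `dof = n_volumes - rank(X)`, and `xtx_inv` for contrast variances.
#' @export
fit_glm <- function(bold, design, variance = TRUE) {
  D <- if (inherits(bold, "hx_bold")) bold$data else t(as.matrix(bold))
  X <- design$X
  stopifnot(ncol(D) == nrow(X))
  XtX <- crossprod(X)
  R <- tryCatch(chol(XtX),
                error = function(e) stop("design matrix is rank deficient"))
  if (min(diag(R)) < 1e-8 * max(diag(R))) {
    stop("design matrix is rank deficient")
  }
  xtx_inv <- chol2inv(R)
  XtY <- t(D %*% X)                      # regressors x voxels
  betas <- xtx_inv %*% XtY
  rownames(betas) <- colnames(X)
  dof <- ncol(D) - ncol(X)
  sigma2 <- if (variance) {
    pmax(rowSums(D^2) - 2 * colSums(betas * XtY) +
           colSums(betas * (XtX %*% betas)), 0) / dof
  }
  structure(
    list(betas = betas, sigma2 = sigma2, dof = dof,
         xtx_inv = xtx_inv, design = design),
    class = "hx_glm_fit"
  )
}

#' Per-voxel t statistic for a contrast of GLM coefficients
#'
#' `t = w'b / sqrt(sigma2 * w' (X'X)^-1 w)` per voxel.
#'
#' @param fit an `hx_glm_fit`.
#' @param weights contrast vector, either full length or named by regressor
#'   (unnamed regressors get weight 0).
#' @return numeric vector of t values (one per voxel), with the degrees of
#'   freedom in attribute `dof`.
#' @export
contrast_t <- function(fit, weights) {
  p <- nrow(fit$betas)
  if (!is.null(names(weights))) {
    w <- stats::setNames(numeric(p), fit$design$names)
    stopifnot(all(names(weights) %in% fit$design$names))
    w[names(weights)] <- weights
  } else {
    stopifnot(length(weights) == p)
    w <- weights
  }
  if (all(w == 0)) stop("contrast weights are all zero")
  num <- drop(crossprod(w, fit$betas))
  se <- sqrt(fit$sigma2 * drop(crossprod(w, fit$xtx_inv %*% w)))
  structure(num / se, dof = fit$dof)
}

#' Extract condition-wise activity patterns from per-run GLM fits
#'
#' Collects the task-regressor coefficient vectors (one beta map per
#' condition) from a set of run-level fits into a long "pattern set": one
#' row per (context, run, condition) with the voxel pattern in a list
#' column. Every requested condition must be present in every run.
#'
#' @param fits a list of `hx_glm_fit` objects.
#' @param conditions character vector of condition (regressor) names to
#'   extract.
#' @param context,run vectors (length of `fits`) labelling each fit.
#' @param average_runs average patterns across runs within context?
#' @return a tibble of class `hx_patterns` with columns `context`, `run`
#'   (dropped when averaging), `condition`, `pattern` (list of numeric
#'   voxel vectors).
#' @export
extract_condition_patterns <- function(fits, conditions, context, run,
                                       average_runs = FALSE) {
  stopifnot(length(fits) == length(context), length(fits) == length(run))
  rows <- purrr::map2(seq_along(fits), fits, function(i, f) {
    missing <- setdiff(conditions, rownames(f$betas))
    if (length(missing)) {
      stop("condition(s) missing from run ", run[i], " (", context[i], "): ",
           paste(missing, collapse = ", "))
    }
    tibble::tibble(
      context = context[i], run = run[i], condition = conditions,
      pattern = lapply(conditions, function(cn) unname(f$betas[cn, ]))
    )
  })
  out <- dplyr::bind_rows(rows)
  if (average_runs) {
    out <- out |>
      dplyr::group_by(.data$context, .data$condition) |>
      dplyr::summarise(
        pattern = list(Reduce(`+`, .data$pattern) / dplyr::n()),
        .groups = "drop"
      )
  }
  class(out) <- c("hx_patterns", class(out))
  out
}

drift_basis <- function(n_volumes, tr, cutoff = 128) {
  K <- floor(2 * n_volumes * tr / cutoff)
  if (K < 1) return(NULL)
  tgrid <- seq_len(n_volumes) - 0.5
  D <- sapply(seq_len(K), function(k) cos(pi * tgrid * k / n_volumes))
  colnames(D) <- paste0("drift_", seq_len(K))
  D
}

#' Fit a condition GLM for one run
#'
#' Convenience wrapper used by every analysis: the imagination period of
#' each trial is assigned to a condition regressor by `labels`, parametric
#' modulators are trial-aligned vectors (`NA` = trial excluded from that
#' modulator), and a response-time stick regressor, cosine drifts and an
#' intercept are appended. When the BOLD run carries its cached per-trial
#' design columns (as simulated runs do), the design is assembled from them
#' by linearity; otherwise it is built with [build_design_matrix()]. Both
#' paths produce identical regressors up to column order.
#'
#' @param run one run's trial tibble.
#' @param bold the matching `hx_bold`.
#' @param labels per-trial condition labels.
#' @param modulators named list of per-trial numeric vectors.
#' @return an `hx_glm_fit`.
#' @export
run_glm_fit <- function(run, bold, labels, modulators = NULL) {
  n_t <- nrow(run)
  stopifnot(length(labels) == n_t)
  if (!is.null(bold$trial_design)) {
    Tm <- bold$trial_design
    conds <- unique(labels)
    cols <- Tm %*% vapply(conds, function(cn) as.numeric(labels == cn),
                          numeric(n_t))
    colnames(cols) <- conds
    roles <- rep("task", length(conds))
    for (mn in names(modulators)) {
      v <- modulators[[mn]]
      use <- !is.na(v)
      if (sum(use) < 2L) stop("modulator '", mn, "' covers fewer than 2 trials")
      h <- numeric(n_t)
      h[use] <- v[use] - mean(v[use])
      cols <- cbind(cols, Tm %*% h)
      colnames(cols)[ncol(cols)] <- mn
      roles <- c(roles, "modulator")
    }
    if (!is.null(bold$response_design)) {
      cols <- cbind(cols, response = bold$response_design)
      roles <- c(roles, "task")
    }
    D <- drift_basis(bold$n_volumes, bold$tr)
    if (!is.null(D)) {
      cols <- cbind(cols, D)
      roles <- c(roles, rep("drift", ncol(D)))
    }
    cols <- cbind(cols, intercept = 1)
    roles <- c(roles, "intercept")
    design <- structure(
      list(X = cols, roles = roles, tr = bold$tr,
           n_volumes = bold$n_volumes, names = colnames(cols)),
      class = "hx_design"
    )
  } else {
    events <- condition_events(run, labels)
    ord <- order(c(run$imagine_onset,
                   run$question_onset + if ("rt" %in% names(run)) run$rt
                   else 0))
    mods <- lapply(modulators, function(m) c(m, rep(NA_real_, n_t))[ord])
    design <- build_design_matrix(events, tr = bold$tr,
                                  n_volumes = bold$n_volumes,
                                  modulators = mods)
  }
  fit_glm(bold, design, variance = FALSE)
}

# patterns as a condition x voxel matrix for one context (run-averaged)
patterns_matrix <- function(patterns, ctx, conditions = NULL) {
  sel <- patterns$context == ctx
  if (is.null(conditions)) conditions <- unique(patterns$condition[sel])
  m <- do.call(rbind, lapply(conditions, function(cn) {
    i <- which(sel & patterns$condition == cn)
    if (!length(i)) stop("condition ", cn, " missing for context ", ctx)
    Reduce(`+`, patterns$pattern[i]) / length(i)
  }))
  rownames(m) <- as.character(conditions)
  m
}
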