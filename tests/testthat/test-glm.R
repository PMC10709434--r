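test_that("the canonical HRF is zero at onset, peaks near 5 s, spans 32 s", {
  tg <- seq(0, 32, by = 0.01)
  h <- canonical_hrf(tg)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)
  # dense-grid maximisation of the analytic expression
  expect_equal(tg[which.max(h)], 5.0, tolerance = 0.05)
  expect_equal(length(h), length(tg))
  expect_lt(min(h), 0)  # undershoot present
})

test_that("design matrices centre modulators and reject bad inputs", {
  ev <- tibble::tibble(onset = c(10, 40, 70), duration = 4,
                       condition = "imagine")
  X <- build_design_matrix(ev, tr = 1.5, n_volumes = 80,
                           modulators = list(m = c(3, 3, 3)))
  expect_equal(unname(X$X[, "m"]), rep(0, 80))  # constant value centres away
  # adding a constant to modulator values leaves the column unchanged
  X2 <- build_design_matrix(ev, tr = 1.5, n_volumes = 80,
                            modulators = list(m = c(1, 2, 6) + 100))
  X3 <- build_design_matrix(ev, tr = 1.5, n_volumes = 80,
                            modulators = list(m = c(1, 2, 6)))
  expect_equal(X2$X[, "m"], X3$X[, "m"])
  expect_error(build_design_matrix(ev, tr = 1.5, n_volumes = 10),
               "beyond the end")
  ev2 <- ev; ev2$onset <- rev(ev2$onset)
  expect_error(build_design_matrix(ev2, tr = 1.5, n_volumes = 80), "sorted")
})

test_that("convolution is linear: a two-trial column is the sum of its trials", {
  ev12 <- tibble::tibble(onset = c(12, 33), duration = 4, condition = "a")
  ev1 <- ev12[1, ]; ev2 <- ev12[2, ]
  n <- 40
  col12 <- build_design_matrix(ev12, 1.5, n, drift_cutoff = NULL)$X[, "a"]
  col1 <- build_design_matrix(ev1, 1.5, n, drift_cutoff = NULL)$X[, "a"]
  col2 <- build_design_matrix(ev2, 1.5, n, drift_cutoff = NULL)$X[, "a"]
  expect_equal(col12, col1 + col2)
})

test_that("OLS recovers exact coefficients and matches univariate projections", {
  set.seed(42)
  X <- cbind(a = rnorm(60), b = rnorm(60), intercept = 1)
  design <- structure(list(X = X, names = colnames(X),
                           roles = c("task", "task", "intercept")),
                      class = "hx_design")
  beta_true <- matrix(c(2, -1, 0.5, 3, 0, 1), 3)
  Y <- X %*% beta_true
  fit <- fit_glm(Y, design)
  expect_equal(unname(fit$betas), unname(beta_true), tolerance = 1e-10)
  expect_equal(fit$dof, 57)
  # orthogonal columns: betas equal univariate projections
  Q <- qr.Q(qr(matrix(rnorm(60 * 3), 60)))
  dQ <- structure(list(X = Q, names = c("q1", "q2", "q3"),
                       roles = rep("task", 3)), class = "hx_design")
  y <- rnorm(60)
  fitq <- fit_glm(matrix(y), dQ)
  expect_equal(unname(fitq$betas[, 1]), drop(crossprod(Q, y)),
               tolerance = 1e-10)
  # rank deficiency is an error
  Xbad <- cbind(X, a2 = X[, "a"])
  dbad <- structure(list(X = Xbad, names = colnames(Xbad),
                         roles = rep("task", 4)), class = "hx_design")
  expect_error(fit_glm(Y, dbad), "rank deficient")
})

test_that("contrast t values match an independent lm() oracle", {
  set.seed(8)
  n <- 50
  X <- cbind(a = rnorm(n), b = rnorm(n), intercept = 1)
  design <- structure(list(X = X, names = colnames(X),
                           roles = c("task", "task", "intercept")),
                      class = "hx_design")
  Y <- matrix(rnorm(n * 3), n)
  fit <- fit_glm(Y, design)
  t_pkg <- contrast_t(fit, c(a = 1))
  t_lm <- sapply(1:3, function(v) {
    summary(lm(Y[, v] ~ 0 + X))$coefficients["Xa", "t value"]
  })
  expect_equal(as.numeric(t_pkg), t_lm, tolerance = 1e-10)
  # sign flip of the weights flips t
  expect_equal(as.numeric(contrast_t(fit, c(a = -1))), -as.numeric(t_pkg))
  expect_error(contrast_t(fit, c(a = 0)), "all zero")
})

test_that("t statistics of pure-noise fits reject at the nominal rate", {
  set.seed(99)
  ev <- tibble::tibble(onset = seq(5, 120, by = 12), duration = 4,
                       condition = "imagine")
  X <- build_design_matrix(ev, tr = 1.5, n_volumes = 100)
  nrej <- 0; nsim <- 400
  crit <- qt(0.975, 100 - ncol(X$X))
  for (i in 1:4) {
    Y <- matrix(rnorm(100 * (nsim / 4)), 100)
    tv <- contrast_t(fit_glm(Y, X), c(imagine = 1))
    nrej <- nrej + sum(abs(tv) > crit)
  }
  expect_gt(nrej / nsim, 0.02)
  expect_lt(nrej / nsim, 0.10)
})

test_that("condition patterns are collected per run and checked for completeness", {
  s <- mini_subject(seed = 2)
  ps <- subject_ego_patterns(s)
  expect_s3_class(ps, "hx_patterns")
  expect_equal(nrow(ps), 8 * 7)
  avg <- extract_condition_patterns(
    lapply(1:2, function(i) run_glm_fit(
      split(s$session, s$session$run)[[i]], s$bold[[i]],
      split(s$session, s$session$run)[[i]]$quadrant)),
    quadrant_levels, context = c("blue", "blue"), run = 1:2,
    average_runs = TRUE
  )
  expect_equal(nrow(avg), 4)
  expect_error(
    extract_condition_patterns(
      list(run_glm_fit(split(s$session, s$session$run)[[1]], s$bold[[1]],
                       split(s$session, s$session$run)[[1]]$quadrant)),
      c(quadrant_levels, "Q9"), context = "blue", run = 1
    ), "missing"
  )
})

test_that("the cached fast design path equals the reference builder", {
  s <- mini_subject(seed = 3)
  run <- split(s$session, s$session$run)[[1]]
  bold <- s$bold[[1]]
  lag <- adaptation_lags(run, run$ego_offset)$log_lag
  labels <- ifelse(is.na(lag), "imagine_first", "imagine")
  mods <- list(recency = ifelse(is.na(lag), NA, lag),
               dist = run$goal_distance)
  fit_fast <- run_glm_fit(run, bold, labels, mods)
  bold_plain <- bold
  bold_plain$trial_design <- NULL
  fit_ref <- run_glm_fit(run, bold_plain, labels, mods)
  for (nm in c("imagine", "imagine_first", "recency", "dist", "response")) {
    expect_equal(fit_fast$betas[nm, ], fit_ref$betas[nm, ],
                 tolerance = 1e-8, info = nm)
  }
})
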