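test_that("delta60 collapses directions into the 60-degree rotational space", {
  expect_equal(delta60(30, 90), 0)    # 60 apart: perfectly aligned
  expect_equal(delta60(0, 90), 30)    # maximally misaligned
  for (th in seq(0, 330, by = 30)) expect_equal(delta60(th, th), 0)
  # symmetry, bounds, invariance under +60 on either argument
  set.seed(4)
  a <- runif(50, 0, 360); b <- runif(50, 0, 360)
  expect_equal(delta60(a, b), delta60(b, a))
  expect_true(all(delta60(a, b) >= 0 & delta60(a, b) <= 30))
  expect_equal(delta60(a + 60, b), delta60(a, b))
  expect_equal(delta60(a, b + 120), delta60(a, b))
})

test_that("symmetry models classify bin pairs exactly", {
  m6 <- build_symmetry_model(6)
  expect_equal(m6$period, 60)
  expect_false(m6$degenerate)
  # 30 degrees is aligned with 90, 150, 210, 270, 330
  aligned_30 <- as.numeric(colnames(m6$aligned)[which(m6$aligned["30", ] == 1)])
  expect_equal(aligned_30, c(90, 150, 210, 270, 330))
  # brute-force pair counts over all 66 unordered pairs
  bins <- seq(0, 330, by = 30)
  cnt_aligned <- 0; cnt_mis <- 0
  for (i in 1:11) for (j in (i + 1):12) {
    d <- abs(bins[i] - bins[j]); d <- min(d, 360 - d)
    if (d %% 60 == 0) cnt_aligned <- cnt_aligned + 1 else cnt_mis <- cnt_mis + 1
  }
  expect_equal(cnt_aligned, 30)
  expect_equal(cnt_mis, 36)
  expect_equal(sum(m6$aligned[lower.tri(m6$aligned)]), cnt_aligned)
  expect_equal(sum(m6$aligned[lower.tri(m6$aligned)] == 0), cnt_mis)
  # 4-fold: 0 aligns with 90, 180, 270
  m4 <- build_symmetry_model(4)
  expect_equal(as.numeric(colnames(m4$aligned)[which(m4$aligned["0", ] == 1)]),
               c(90, 180, 270))
  # periods of the control symmetries
  expect_equal(sapply(c(3, 4, 5, 6, 7, 8),
                      function(k) build_symmetry_model(k)$period),
               c(120, 90, 72, 60, 360 / 7, 45))
  # 5- and 7-fold have no exact multiples on 30-degree bins
  expect_true(build_symmetry_model(5)$degenerate)
  expect_true(build_symmetry_model(7)$degenerate)
  expect_false(build_symmetry_model(3)$degenerate)
  expect_false(build_symmetry_model(8)$degenerate)
})

make_direction_patterns <- function(fold, phase = 17, V = 60, noise = 0.05,
                                    seed = 1) {
  withr::local_seed(seed)
  w <- rnorm(V)
  bins <- seq(0, 330, by = 30)
  mk <- function() {
    m <- outer(cos(fold * (bins - phase) * pi / 180), w) +
      matrix(rnorm(12 * V, 0, noise), 12)
    rownames(m) <- bins
    m
  }
  list(blue = mk(), green = mk())
}

test_that("grid RSA scores peak at the planted symmetry", {
  p6 <- make_direction_patterns(6)
  scores <- sapply(c(3, 4, 6, 8), function(k) {
    grid_rsa_score(p6$blue, p6$green, build_symmetry_model(k))
  })
  expect_gt(scores[3], 0)
  expect_equal(which.max(scores), 3)
  # degenerate control models return NA with a warning
  expect_warning(s5 <- grid_rsa_score(p6$blue, p6$green,
                                      build_symmetry_model(5)), "degenerate")
  expect_true(is.na(s5))
  # 4-fold planting leaves the 6-fold score near zero
  z6_under4 <- sapply(1:10, function(i) {
    p4 <- make_direction_patterns(4, seed = i, noise = 0.3)
    grid_rsa_score(p4$blue, p4$green, build_symmetry_model(6))
  })
  expect_lt(abs(mean(z6_under4)), 0.15)
})

test_that("the score is invariant to context order and 180-degree relabelling", {
  p <- make_direction_patterns(6, seed = 3, noise = 0.2)
  m6 <- build_symmetry_model(6)
  expect_equal(grid_rsa_score(p$blue, p$green, m6),
               grid_rsa_score(p$green, p$blue, m6))
  # rotating one context's direction labels by 180 (a multiple of 60)
  # leaves a 6-fold code untouched: exact on noiseless patterns
  p0 <- make_direction_patterns(6, seed = 3, noise = 0)
  rot <- p0$green[as.character((as.numeric(rownames(p0$green)) + 180) %% 360), ]
  rownames(rot) <- rownames(p0$green)
  # rank-one noiseless patterns correlate at exactly +/-1, so the final
  # transform clips identically on both sides
  expect_equal(suppressWarnings(grid_rsa_score(p0$blue, rot, m6)),
               suppressWarnings(grid_rsa_score(p0$blue, p0$green, m6)))
})

test_that("a graded model-like similarity structure gives exactly atanh(r)", {
  m6 <- build_symmetry_model(6)
  A <- m6$aligned; A[is.na(A)] <- 1
  S <- 0.4 + 0.3 * A
  S[2, 1] <- S[1, 2] <- 0.55   # break the exact affine match
  lt <- lower.tri(S)
  r_direct <- cor(S[lt], m6$aligned[lt])
  expect_lt(r_direct, 1)
  expect_equal(fisher_z(r_direct), atanh(r_direct))
})

test_that("goal-distance classes map quadrants as the contexts dictate", {
  expect_equal(goal_distance_class(c("Q1", "Q2", "Q3", "Q4"), rep("blue", 4)),
               c("medium", "close", "far", "medium"))
  expect_equal(goal_distance_class(c("Q1", "Q2", "Q3", "Q4"), rep("green", 4)),
               c("medium", "far", "close", "medium"))
})

test_that("goal modulation recovers ordered planted gains", {
  quiet <- noise_model(white_sd = 0, drift_amp = 0, subject_sd = 0)
  s <- mini_subject(seed = 71, ego_amplitude = 0, adapt_k = 0,
                    quad_amplitude = 0, quad_specific = 0,
                    grid_mode = "repetition_suppression",
                    grid_gains = c(close = 0.09, medium = 0.06, far = 0.03),
                    noise = quiet)
  cl <- hexsearch:::subject_goal_modulation(s)
  b <- setNames(cl$beta, cl$class)
  expect_gt(b[["close"]], b[["medium"]])
  expect_gt(b[["medium"]], b[["far"]])
  expect_gt(b[["close"]] - b[["far"]], 0)
  # equal gains: contrast vanishes (noiseless)
  s_eq <- mini_subject(seed = 71, ego_amplitude = 0, adapt_k = 0,
                       quad_amplitude = 0, quad_specific = 0,
                       grid_mode = "repetition_suppression",
                       grid_gains = c(close = 0.06, medium = 0.06,
                                      far = 0.06),
                       noise = quiet)
  cl_eq <- hexsearch:::subject_goal_modulation(s_eq)
  b_eq <- setNames(cl_eq$beta, cl_eq$class)
  expect_lt(abs(b_eq[["close"]] - b_eq[["far"]]),
            (b[["close"]] - b[["far"]]) / 50)
})

test_that("with no planted structure the 6-fold score is centred on zero", {
  m6 <- build_symmetry_model(6)
  zs <- sapply(1:120, function(i) {
    p <- make_direction_patterns(6, seed = 6000 + i, noise = 1)
    p$blue <- p$blue * 0 + matrix(rnorm(12 * 60), 12,
                                  dimnames = dimnames(p$blue))
    p$green <- p$green * 0 + matrix(rnorm(12 * 60), 12,
                                    dimnames = dimnames(p$green))
    grid_rsa_score(p$blue, p$green, m6)
  })
  expect_lt(abs(mean(zs)), 3 * sd(zs) / sqrt(length(zs)) + 0.02)
  expect_gt(mean(zs > 0), 0.35)
  expect_lt(mean(zs > 0), 0.65)
})
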