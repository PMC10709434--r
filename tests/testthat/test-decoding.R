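test_that("nearest-neighbour classification on clean patterns is perfect", {
  set.seed(5)
  train <- matrix(rnorm(7 * 30), 7)
  labels <- as.character(ego_levels)
  test <- train
  rownames(test) <- labels
  expect_equal(nn_classify(train, labels, test)$accuracy, 100)
  # orthogonal planted patterns, noiseless held-out exemplars
  train2 <- diag(7) %x% matrix(1, 1, 5)
  test2 <- 3 * train2 + 1  # scaled and shifted: correlation is invariant
  rownames(test2) <- labels
  expect_equal(nn_classify(train2, labels, test2)$accuracy, 100)
  expect_error(nn_classify(rbind(train, 0), c(labels, "x"), test),
               "zero-variance")
})

test_that("permuted labels decode at chance", {
  set.seed(6)
  train <- matrix(rnorm(28 * 40), 28)
  labels <- rep(as.character(ego_levels), 4)
  test <- matrix(rnorm(7 * 40), 7)
  rownames(test) <- as.character(ego_levels)
  accs <- sapply(1:200, function(i) {
    nn_classify(train, sample(labels), test)$accuracy
  })
  # binomial CI around 1/7 over 200 x 7 predictions
  expect_equal(mean(accs) / 100, 1 / 7, tolerance = 0.2)
})

test_that("cross-context decoding recovers shared codes and not specific ones", {
  s <- mini_subject(seed = 41)
  res <- cross_context_decode(subject_ego_patterns(s))
  expect_equal(res$chance, 100 / 7, tolerance = 1e-12)
  expect_gt(res$accuracy_minus_chance, 20)
  res6 <- cross_context_decode(subject_ego_patterns(s),
                               exclude_on_target = TRUE)
  expect_equal(res6$chance, 100 / 6)
  expect_equal(res6$n_conditions, 6)
  # context-specific planting: cross-context at chance, within-context above
  cross <- c(); within <- c()
  for (i in 1:6) {
    sd <- mini_subject(seed = 50 + i, ego_shared = FALSE)
    ps <- subject_ego_patterns(sd)
    cross <- c(cross, cross_context_decode(ps)$accuracy_minus_chance)
    within <- c(within,
                cross_context_decode(ps, "within_context")$accuracy_minus_chance)
  }
  expect_lt(abs(mean(cross)), 10)
  expect_gt(mean(within), 25)
  expect_gt(mean(within), mean(cross) + 15)
})

test_that("decoding is invariant to global scaling and mean shifts", {
  s <- mini_subject(seed = 43)
  ps <- subject_ego_patterns(s)
  ps_t <- ps
  ps_t$pattern <- lapply(ps_t$pattern, function(p) 2.5 * p + 7)
  expect_equal(cross_context_decode(ps)$accuracy,
               cross_context_decode(ps_t)$accuracy)
})

test_that("searchlight spheres have the right size and localise effects", {
  dims <- c(9, 9, 9)
  # brute-force sphere size at an interior voxel, radius 3
  n_expected <- sum(outer(outer((-3:3)^2, (-3:3)^2, `+`), (-3:3)^2, `+`) <= 9)
  sl <- searchlight_map(matrix(1, prod(dims), 1), dims,
                        statistic_fn = function(m) nrow(m), radius = 3)
  expect_equal(sl$map[5, 5, 5], n_expected)
  expect_equal(sl$map[5, 5, 5], 123)
  expect_false(sl$small_sphere[5, 5, 5])
  expect_true(sl$n_voxels[1, 1, 1] < n_expected)
  # constant statistic gives a constant map
  slc <- searchlight_map(matrix(rnorm(prod(dims)), prod(dims)), dims,
                         statistic_fn = function(m) 1)
  expect_true(all(slc$map == 1))
  # an effect planted in a 3^3 block localises within a radius of its centre
  data <- matrix(0, prod(dims), 1)
  arr <- array(0, dims); arr[4:6, 4:6, 4:6] <- 1
  data[, 1] <- as.vector(arr)
  slm <- searchlight_map(data, dims, statistic_fn = function(m) mean(m[, 1]))
  peak <- which(slm$map == max(slm$map), arr.ind = TRUE)
  expect_true(all(abs(peak - 5) <= 3))
})

test_that("MDS embeds condition structure faithfully", {
  # identical patterns collapse to a single point
  m <- matrix(rep(rnorm(20), 4), nrow = 4, byrow = TRUE)
  rownames(m) <- c("a", "b", "c", "d")
  xy <- suppressWarnings(mds_embed(m))
  expect_lt(max(dist(as.matrix(xy[, c("dim1", "dim2")]))), 1e-8)
  # a planted 1D gradient is recovered in order
  set.seed(9)
  base <- matrix(rnorm(7 * 80), 7)
  grad <- outer(seq(-3, 3), rnorm(80))
  patt <- 0.2 * base + grad
  rownames(patt) <- as.character(ego_levels)
  xy2 <- mds_embed(patt)
  ord <- order(xy2$dim1)
  expect_true(identical(ord, 1:7) || identical(ord, 7:1))
  # left/right clusters share a component within but not across clusters
  u <- rnorm(50); v <- rnorm(50)
  lr <- rbind(t(sapply(1:3, function(i) u + 0.4 * rnorm(50))),
              t(sapply(1:3, function(i) v + 0.4 * rnorm(50))))
  rownames(lr) <- c("l1", "l2", "l3", "r1", "r2", "r3")
  xy3 <- mds_embed(lr)
  co <- as.matrix(xy3[, c("dim1", "dim2")])
  between <- mean(as.matrix(dist(co))[1:3, 4:6])
  within <- mean(dist(co[1:3, ]))
  expect_gt(between, within)
})
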