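test_that("planted amplitudes reduce to baseline when all gains are zero", {
  run <- toy_run()
  code <- planted_code(n_voxels = 10, seed = 1, ego_amplitude = 0,
                       adapt_k = 0, quad_amplitude = 0, quad_specific = 0,
                       grid_gains = c(close = 0, medium = 0, far = 0),
                       baseline = 2)
  amp <- plant_trial_amplitudes(run, code)
  expect_equal(unname(amp), matrix(2, nrow(run), 10))
})

test_that("the repetition-suppression grid term is zero after an identical direction", {
  run <- toy_run(ego = rep(45, 4), allo = c(10, 10, 100, 160))
  code <- planted_code(n_voxels = 5, seed = 2, ego_amplitude = 0,
                       adapt_k = 0, quad_amplitude = 0, quad_specific = 0,
                       grid_gains = c(close = 1, medium = 1, far = 1),
                       grid_mode = "repetition_suppression")
  amp <- plant_trial_amplitudes(run, code)
  expect_equal(amp[2, ], rep(0, 5))          # same bin as previous: delta60 = 0
  expect_equal(amp[1, ], rep(0, 5))          # first trial: no previous
  d3 <- delta60(run$allo_bin[3], run$allo_bin[2]) / 30
  expect_equal(amp[3, ], d3 * abs(code$grid_w))
})

test_that("the rsa-tuning grid term has the closed cosine form", {
  run <- toy_run(ego = rep(45, 3), allo = c(10, 100, 40))
  code <- planted_code(n_voxels = 4, seed = 3, ego_amplitude = 0,
                       adapt_k = 0, quad_amplitude = 0, quad_specific = 0,
                       grid_gains = c(close = 2, medium = 2, far = 2),
                       grid_phase = 10, grid_mode = "rsa_tuning")
  amp <- plant_trial_amplitudes(run, code)
  for (t in 1:3) {
    expect_equal(amp[t, ],
                 2 * cos(6 * (run$allo_bin[t] - 10) * pi / 180) * code$grid_w)
  }
})

test_that("noiseless simulation reproduces the forward model exactly", {
  run <- toy_run()
  quiet <- noise_model(white_sd = 0, drift_amp = 0)
  amp0 <- matrix(0, nrow(run), 3)
  b0 <- simulate_bold_run(run, amp0, quiet, seed = 1)
  expect_equal(b0$data, matrix(0, 3, b0$n_volumes))
  # one active trial: time course equals the design column, scaled
  amp1 <- amp0; amp1[2, 1] <- 1.5
  b1 <- simulate_bold_run(run, amp1, quiet, seed = 1)
  col <- trial_design_columns(run, 1.5, b1$n_volumes)[, 2]
  expect_equal(b1$data[1, ], 1.5 * col)
  expect_equal(b1$data[2, ], rep(0, b1$n_volumes))
  # and matches the design-matrix builder's column for the same event
  ev <- tibble::tibble(onset = run$imagine_onset[2], duration = 4,
                       condition = "trial2")
  Xref <- build_design_matrix(ev, 1.5, b1$n_volumes, drift_cutoff = NULL)
  expect_equal(unname(b1$data[1, ]), 1.5 * unname(Xref$X[, "trial2"]))
})

test_that("simulation is reproducible under a fixed seed", {
  run <- toy_run()
  amp <- matrix(rnorm(nrow(run) * 4), nrow(run), 4)
  b1 <- simulate_bold_run(run, amp, seed = 7)
  b2 <- simulate_bold_run(run, amp, seed = 7)
  expect_identical(b1$data, b2$data)
  b3 <- simulate_bold_run(run, amp, seed = 8)
  expect_false(identical(b3$data, b2$data))
})

test_that("gaze traces carry the planted egocentric displacement", {
  run <- generate_run("blue", seed = 4)
  # noiseless: displacement is exactly slope x ego wherever the two
  # lookup volumes differ
  g <- simulate_gaze_run(run, slope = 1, noise_sd = 0, seed = 1)
  d <- suppressWarnings(gaze_egocentric_correlation(g, run))
  expect_gt(d$r_horizontal, 0.7)
  gm <- hexsearch:::gaze_at(g, run$morph_onset)
  gi <- hexsearch:::gaze_at(g, run$imagine_onset)
  dx <- gi$x - gm$x
  measurable <- dx != 0
  expect_gt(sum(measurable), 10)
  # displacement is a (possibly partial, via the morph-period ramp)
  # fraction of slope x ego, never exceeding it and matching its sign
  expect_true(all(abs(dx) <= abs(run$ego_offset) + 1e-9))
  expect_equal(sign(dx[measurable]), sign(run$ego_offset[measurable]))
  # slope 0: no systematic correlation across seeds
  rs <- sapply(1:30, function(s) {
    g0 <- simulate_gaze_run(run, slope = 0, noise_sd = 2, seed = s)
    gaze_egocentric_correlation(g0, run)$r_horizontal
  })
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("question-period gaze follows the chosen side", {
  run <- simulate_behavior(generate_run("green", seed = 5), seed = 5)
  g <- simulate_gaze_run(run, slope = 0, noise_sd = 0, question_gain = 1,
                         seed = 2)
  v <- suppressWarnings(gaze_choice_validation(g, run))
  # exact except for trials whose pre-question volume falls on the grid
  # boundary of the question onset
  expect_gt(v$r_horizontal, 0.95)
})

test_that("behavioural rates are honoured", {
  run <- generate_run("blue", seed = 6)
  perfect <- list(target = list(blue = c(hit = 1, fa = 0),
                                green = c(hit = 1, fa = 0)),
                  filler = list(blue = c(hit = 1, fa = 0),
                                green = c(hit = 1, fa = 0)))
  b <- simulate_behavior(run, perfect, seed = 1)
  expect_equal(b$response, ifelse(b$expected_answer == "yes", "yes", "no"))
  m <- behavior_metrics(b)
  expect_equal(m$hits, c(100, 100))
  expect_equal(m$false_alarms, c(0, 0))
  # empirical rates converge to the configured probabilities
  many <- dplyr::bind_rows(lapply(1:40, function(i) {
    simulate_behavior(generate_run("blue", seed = i), seed = 100 + i)
  }))
  mm <- behavior_metrics(many)
  tgt <- mm[mm$question == "target", ]
  expect_equal(tgt$hits, 73.3, tolerance = 0.1)       # relative tolerance
  expect_equal(tgt$false_alarms, 2.11, tolerance = 0.35)
  # always-yes responder: 100% hits and 100% false alarms
  always <- run
  always$response <- "yes"
  ma <- behavior_metrics(always)
  expect_equal(ma$hits, c(100, 100))
  expect_equal(ma$false_alarms, c(100, 100))
})

test_that("cohorts have the documented structure and ground-truth manifest", {
  p <- mini_params()
  p$noise$subject_sd <- 0
  cohort <- simulate_cohort(n_subjects = 2, params = p, seed = 3)
  expect_length(cohort$subjects, 2)
  expect_length(cohort$subjects[[1]]$bold, 8)
  # zero between-subject variance: identical planted effect sizes
  expect_equal(cohort$subjects[[1]]$code$ego_amplitude,
               cohort$subjects[[2]]$code$ego_amplitude)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  expect_true(file.exists(file.path(dir, "sub-01", "run-03_events.tsv")))
  expect_true(file.exists(file.path(dir, "sub-02", "behavior.tsv")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$n_runs, 8)
  expect_equal(man$n_subjects, 2)
  expect_length(man$code, 2)
})

test_that("downstream effect sizes grow with the planted gain", {
  zs <- sapply(c(0, 0.05, 0.2), function(g) {
    mean(sapply(1:3, function(i) {
      s <- mini_subject(seed = 400 + i, ego_amplitude = 0, adapt_k = 0,
                        quad_amplitude = 0, quad_specific = 0,
                        grid_gains = c(close = g, medium = g, far = g))
      p <- subject_direction_patterns(s)
      grid_rsa_score(p$blue, p$green, build_symmetry_model(6))
    }))
  })
  expect_true(all(diff(zs) > 0))
  expect_lt(abs(zs[1]), 0.3)
})
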