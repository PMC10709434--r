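#' Noise model for synthetic BOLD
#'
#' @param white_sd innovation standard deviation of the voxel noise.
#' @param ar1 AR(1) coefficient of the temporal noise, in `[0, 1)`.
#' @param subject_sd between-subject log-normal spread of planted effect
#'   sizes (sd of the log multiplier).
#' @param drift_amp amplitude of the slow cosine drift set added per voxel.
#' @return a list of class `hx_noise`.
#' @export
noise_model <- function(white_sd = 1, ar1 = 0.3, subject_sd = 0.3,
                        drift_amp = 0.5) {
  stopifnot(ar1 >= 0, ar1 < 1, white_sd >= 0)
  structure(list(white_sd = white_sd, ar1 = ar1, subject_sd = subject_sd,
                 drift_amp = drift_amp), class = "hx_noise")
}

#' Planted representational code for a simulated subject
#'
#' Defines the ground-truth neural codes carried by the synthetic BOLD:
#'
#' * an egocentric code: each voxel has a preferred egocentric goal angle
#'   (von-Mises-shaped tuning with concentration `ego_kappa` over the 7
#'   discrete conditions) whose response is scaled by a release-from-
#'   adaptation factor `1 + adapt_k * log(dt)` where `dt` is the time since
#'   the same egocentric condition was last presented (factor 1 on first
#'   presentations);
#' * a quadrant code: one multivoxel pattern per quadrant. Under
#'   `quad_mode = "rotation"` the green-context pattern of quadrant Q equals
#'   the blue-context pattern of its 180-degree rotation image (Q1<->Q4,
#'   Q2<->Q3); under `"identity"` the same quadrant shares the pattern
#'   across contexts. A context-specific component of amplitude
#'   `quad_specific` is always added;
#' * a grid-like direction code with `grid_fold`-fold rotational symmetry
#'   and phase `grid_phase` shared across contexts. Under
#'   `grid_mode = "rsa_tuning"` each trial adds
#'   `gain * w_v * cos(grid_fold * (direction - phase))` with a fixed random
#'   voxel weight map `w`; under `"repetition_suppression"` it adds
#'   `gain * |w_v| * delta60(direction, previous direction) / 30`, i.e. a
#'   release from suppression growing with misalignment in 60-degree
#'   rotational space. The gain depends on the trial quadrant's distance
#'   from the context's goal (`close`, `medium`, `far`).
#'
#' With `ego_shared = FALSE` the voxel preferences are drawn independently
#' per context (a context-specific egocentric code that cannot transfer
#' across contexts).
#'
#' @param n_voxels number of voxels in the simulated region.
#' @param seed integer seed making the code reproducible.
#' @param ego_amplitude,ego_kappa,adapt_k egocentric code parameters.
#' @param quad_amplitude,quad_specific quadrant pattern amplitudes
#'   (shared-under-rotation and context-specific parts).
#' @param quad_mode `"rotation"` or `"identity"` cross-context
#'   correspondence of quadrant patterns.
#' @param ego_shared logical; share egocentric tuning across contexts?
#' @param grid_gains named vector `c(close=, medium=, far=)`, gains >= 0 of
#'   the grid code by goal-distance class.
#' @param grid_phase grid orientation in degrees, `[0, 60)`; `NULL` draws
#'   one uniformly.
#' @param grid_fold rotational symmetry of the planted direction code.
#' @param grid_mode `"rsa_tuning"` or `"repetition_suppression"`.
#' @param baseline constant amplitude added to every trial.
#' @return a list of class `hx_code` with the realised per-voxel fields.
#' @export
planted_code <- function(n_voxels = 200, seed = 1,
                         ego_amplitude = 0.1, ego_kappa = 2, adapt_k = 0.25,
                         quad_amplitude = 0.06, quad_specific = 0.05,
                         quad_mode = c("rotation", "identity"),
                         ego_shared = TRUE,
                         grid_gains = c(close = 0.05, medium = 0.05,
                                        far = 0.05),
                         grid_phase = NULL, grid_fold = 6,
                         grid_mode = c("rsa_tuning", "repetition_suppression"),
                         baseline = 0) {
  quad_mode <- match.arg(quad_mode)
  grid_mode <- match.arg(grid_mode)
  stopifnot(all(grid_gains >= 0), ego_kappa > 0,
            all(c("close", "medium", "far") %in% names(grid_gains)))
  withr::local_seed(seed)
  pref <- sample(ego_levels, n_voxels, replace = TRUE)
  pref_green <- if (ego_shared) pref else sample(ego_levels, n_voxels, TRUE)
  quad_blue <- matrix(stats::rnorm(4 * n_voxels, 0, quad_amplitude), 4,
                      dimnames = list(quadrant_levels, NULL))
  quad_shared_green <- if (quad_mode == "rotation") {
    quad_blue[rotate_quadrant(quadrant_levels), , drop = FALSE]
  } else {
    quad_blue
  }
  rownames(quad_shared_green) <- quadrant_levels
  spec <- function() matrix(stats::rnorm(4 * n_voxels, 0, quad_specific), 4,
                            dimnames = list(quadrant_levels, NULL))
  if (is.null(grid_phase)) grid_phase <- stats::runif(1, 0, 60)
  stopifnot(grid_phase >= 0, grid_phase < 60)
  structure(list(
    n_voxels = n_voxels,
    ego_amplitude = ego_amplitude, ego_kappa = ego_kappa, adapt_k = adapt_k,
    ego_pref = list(blue = pref, green = pref_green),
    quad_patterns = list(blue = quad_blue + spec(),
                         green = quad_shared_green + spec()),
    quad_mode = quad_mode, ego_shared = ego_shared,
    grid_gains = grid_gains[c("close", "medium", "far")],
    grid_phase = grid_phase, grid_fold = grid_fold, grid_mode = grid_mode,
    grid_w = stats::rnorm(n_voxels),
    baseline = baseline
  ), class = "hx_code")
}

#' Goal-distance class of each quadrant within a context
#'
#' The goal quadrant is `close` (Q2 blue, Q3 green), the diagonally opposite
#' quadrant is `far` (Q3 blue, Q2 green) and Q1/Q4 are `medium` in both
#' contexts (equidistant from both goals).
#'
#' @param quadrant character vector of `"Q1".."Q4"`.
#' @param context matching vector of `"blue"`/`"green"`.
#' @return character vector of `"close"`, `"medium"`, `"far"`.
#' @export
goal_distance_class <- function(quadrant, context) {
  goal_q <- ifelse(context == "blue", "Q2", "Q3")
  far_q <- ifelse(context == "blue", "Q3", "Q2")
  dplyr::case_when(
    quadrant == goal_q ~ "close",
    quadrant == far_q ~ "far",
    TRUE ~ "medium"
  )
}

# log time since last trial with the same key, within run; NA on first
# presentation. Used both to plant adaptation and by the analysis module.
lag_log_dt <- function(onset, key) {
  out <- rep(NA_real_, length(onset))
  last <- list()
  for (i in seq_along(onset)) {
    k <- as.character(key[i])
    if (!is.null(last[[k]])) out[i] <- log(onset[i] - last[[k]])
    last[[k]] <- onset[i]
  }
  out
}

#' Plant per-trial neural amplitudes for one run
#'
#' Combines the egocentric (with log-recency adaptation), quadrant and grid
#' components of a [planted_code()] into a trials x voxels amplitude matrix
#' for one run. With all gains zero the result is the constant baseline.
#'
#' @param run one run's trial tibble (from [generate_run()]).
#' @param code an `hx_code`.
#' @return numeric matrix, trials x voxels.
#' @export
plant_trial_amplitudes <- function(run, code) {
  ctx <- run$context[1]
  n_t <- nrow(run)
  V <- code$n_voxels
  amp <- matrix(code$baseline, n_t, V)

  if (code$ego_amplitude != 0) {
    pref <- code$ego_pref[[ctx]]
    d <- outer(run$ego_offset, pref, function(a, b) wrap_180(a - b))
    tuning <- exp(code$ego_kappa * (cos(d * pi / 180) - 1))
    ldt <- lag_log_dt(run$onset, run$ego_offset)
    release <- ifelse(is.na(ldt), 1, 1 + code$adapt_k * ldt)
    amp <- amp + code$ego_amplitude * release * tuning
  }

  amp <- amp + code$quad_patterns[[ctx]][run$quadrant, , drop = FALSE]

  gains <- code$grid_gains[goal_distance_class(run$quadrant, ctx)]
  if (any(gains > 0)) {
    if (code$grid_mode == "rsa_tuning") {
      mod <- cos(code$grid_fold * (run$allo_bin - code$grid_phase) * pi / 180)
      amp <- amp + (gains * mod) %o% code$grid_w
    } else {
      d60 <- c(0, delta60(run$allo_bin[-1], run$allo_bin[-nrow(run)])) / 30
      amp <- amp + (gains * d60) %o% abs(code$grid_w)
    }
  }
  amp
}

# HRF-convolved per-trial design columns over the imagination periods --
# the forward model shared by the simulator and the GLM engine.
trial_design_columns <- function(run, tr, n_volumes, oversample = 10,
                                 hrf_fun = canonical_hrf) {
  conv_event_columns(run$imagine_onset, run$imagine_dur,
                     rep(1, nrow(run)), n_volumes, tr, oversample, hrf_fun,
                     combine = FALSE)
}

n_volumes_for <- function(run, tr) {
  as.integer(ceiling((max(run$question_onset + run$question_dur) + 6) / tr))
}

#' Simulate one BOLD run
#'
#' Each trial contributes a boxcar over its imagination period scaled by
#' its per-voxel amplitude, convolved with the canonical HRF and sampled at
#' the TR; AR(1) noise (innovation sd `noise$white_sd`, coefficient
#' `noise$ar1`) plus a slow cosine drift are added.
#'
#' @param run one run's trial tibble.
#' @param amplitudes trials x voxels matrix from [plant_trial_amplitudes()].
#' @param noise an [noise_model()]; use `white_sd = 0, drift_amp = 0` for a
#'   noiseless forward simulation.
#' @param seed integer seed.
#' @param tr repetition time in seconds.
#' @param n_volumes number of volumes; default covers the last question
#'   period plus 6 s.
#' @return an object of class `hx_bold`: list with `data` (voxels x time),
#'   `tr`, `n_volumes` and `n_voxels`.
#' @export
simulate_bold_run <- function(run, amplitudes, noise = noise_model(),
                              seed = 1, tr = 1.5,
                              n_volumes = n_volumes_for(run, tr)) {
  stopifnot(nrow(amplitudes) == nrow(run))
  withr::local_seed(seed)
  X <- trial_design_columns(run, tr, n_volumes)
  Y <- X %*% amplitudes
  V <- ncol(amplitudes)
  resp <- NULL
  if ("rt" %in% names(run)) {
    resp <- conv_event_columns(run$question_onset + run$rt,
                               rep(0, nrow(run)), rep(1, nrow(run)),
                               n_volumes, tr)
  }
  if (noise$white_sd > 0) {
    E <- matrix(stats::rnorm(n_volumes * V, 0, noise$white_sd), n_volumes, V)
    if (noise$ar1 > 0) {
      E <- apply_ar1(E, noise$ar1)
    }
    Y <- Y + E
  }
  if (noise$drift_amp > 0) {
    tgrid <- seq_len(n_volumes) - 0.5
    D <- sapply(1:3, function(k) cos(pi * tgrid * k / n_volumes))
    Y <- Y + D %*% matrix(stats::rnorm(3 * V, 0, noise$drift_amp), 3, V)
  }
  structure(list(data = t(Y), tr = tr, n_volumes = n_volumes, n_voxels = V,
                 trial_design = X, response_design = resp),
            class = "hx_bold")
}

apply_ar1 <- function(E, rho) {
  for (t in 2:nrow(E)) E[t, ] <- E[t, ] + rho * E[t - 1L, ]
  E
}

#' Simulate a per-volume gaze trace for one run
#'
#' Emulates the output of an eyeball-decoding model: horizontal and
#' vertical gaze estimates at each volume. The horizontal displacement
#' between the start of the morphing period and the start of the
#' imagination period equals `slope * ego_offset` plus noise (the planted
#' egocentric gaze signature); vertical gaze carries no signal. During the
#' question period the horizontal gaze drifts by `question_gain` towards
#' the side of the chosen answer when responses are present.
#'
#' @param run one run's trial tibble, optionally with `choice_side` from
#'   [simulate_behavior()].
#' @param slope screen units per degree of egocentric goal angle.
#' @param noise_sd per-phase gaze noise sd (screen units).
#' @param question_gain horizontal drift towards the chosen option.
#' @param seed integer seed.
#' @param tr repetition time.
#' @param n_volumes number of volumes (match the BOLD run).
#' @return a tibble of class `hx_gaze`: `volume`, `time`, `x`, `y`.
#' @export
simulate_gaze_run <- function(run, slope = 0.003, noise_sd = 5,
                              question_gain = 0.2, seed = 1, tr = 1.5,
                              n_volumes = n_volumes_for(run, tr)) {
  withr::local_seed(seed)
  n_t <- nrow(run)
  lev_pre <- stats::rnorm(n_t, 0, noise_sd)
  lev_im_x <- lev_pre + slope * run$ego_offset + stats::rnorm(n_t, 0, noise_sd)
  lev_pre_y <- stats::rnorm(n_t, 0, noise_sd)
  lev_im_y <- lev_pre_y + stats::rnorm(n_t, 0, noise_sd)
  side <- if ("choice_side" %in% names(run)) run$choice_side else
    sample(c(-1, 1), n_t, TRUE)
  lev_q_x <- lev_im_x + question_gain * side + stats::rnorm(n_t, 0, noise_sd)
  lev_q_y <- lev_im_y + stats::rnorm(n_t, 0, noise_sd)

  t_vol <- (seq_len(n_volumes) - 1L) * tr
  x <- numeric(n_volumes)
  y <- numeric(n_volumes)
  trial_of <- findInterval(t_vol, run$onset)
  for (v in seq_len(n_volumes)) {
    i <- trial_of[v]
    if (i == 0L) next
    tt <- t_vol[v]
    if (tt >= run$question_onset[i] + run$question_dur[i]) next  # ITI
    if (tt < run$morph_onset[i]) {
      x[v] <- lev_pre[i]; y[v] <- lev_pre_y[i]
    } else if (tt < run$imagine_onset[i]) {
      w <- (tt - run$morph_onset[i]) / run$morph_dur[i]
      x[v] <- (1 - w) * lev_pre[i] + w * lev_im_x[i]
      y[v] <- (1 - w) * lev_pre_y[i] + w * lev_im_y[i]
    } else if (tt < run$question_onset[i]) {
      x[v] <- lev_im_x[i]; y[v] <- lev_im_y[i]
    } else {
      x[v] <- lev_q_x[i]; y[v] <- lev_q_y[i]
    }
  }
  out <- tibble::tibble(volume = seq_len(n_volumes), time = t_vol,
                        x = x, y = y)
  class(out) <- c("hx_gaze", class(out))
  out
}

#' Default hit / false-alarm rates of the simulated responder
#'
#' Per context and question type: probability of answering "yes" when the
#' correct answer is yes (hit) or no (false alarm).
#'
#' @return nested list `rates[[question]][[context]] = c(hit=, fa=)`.
#' @export
behavior_rates <- function() {
  list(
    target = list(blue = c(hit = 0.733, fa = 0.0211),
                  green = c(hit = 0.774, fa = 0.0347)),
    filler = list(blue = c(hit = 0.59, fa = 0.159),
                  green = c(hit = 0.608, fa = 0.14))
  )
}

#' Simulate behavioural responses for one run
#'
#' Bernoulli "yes"/"no" responses with per-question-type, per-context hit
#' and false-alarm rates; log-normal reaction times capped at the question
#' duration; and the screen side of the chosen option (the side of the
#' "yes" option is balanced at random across trials).
#'
#' @param run one run's trial tibble.
#' @param rates a [behavior_rates()] list.
#' @param seed integer seed.
#' @param rt_meanlog,rt_sdlog log-normal RT parameters (seconds).
#' @return `run` with columns `response`, `rt`, `yes_side`, `choice_side`.
#' @export
simulate_behavior <- function(run, rates = behavior_rates(), seed = 1,
                              rt_meanlog = log(0.9), rt_sdlog = 0.3) {
  withr::local_seed(seed)
  flat <- unlist(rates)  # names like "target.blue.hit"
  key <- paste(run$question, run$context,
               ifelse(run$expected_answer == "yes", "hit", "fa"), sep = ".")
  p_yes <- unname(flat[key])
  response <- ifelse(stats::runif(nrow(run)) < p_yes, "yes", "no")
  rt <- pmin(stats::rlnorm(nrow(run), rt_meanlog, rt_sdlog),
             run$question_dur - 0.05)
  yes_side <- sample(c(-1L, 1L), nrow(run), TRUE)
  dplyr::mutate(run, response = response, rt = rt, yes_side = yes_side,
                choice_side = ifelse(response == "yes", yes_side, -yes_side))
}

#' Simulation parameter bundle
#'
#' Collects every knob of the synthetic cohort: design configuration, BOLD
#' noise, planted-code arguments, gaze and behaviour settings.
#'
#' @param n_voxels voxels per simulated region.
#' @param design a [design_config()].
#' @param noise a [noise_model()].
#' @param code named list of overrides passed to [planted_code()].
#' @param gaze named list: `slope`, `noise_sd`, `question_gain`.
#' @param rates a [behavior_rates()] list.
#' @return a named list.
#' @export
sim_params <- function(n_voxels = 200, design = design_config(),
                       noise = noise_model(), code = list(),
                       gaze = list(slope = 0.003, noise_sd = 5,
                                   question_gain = 0.2),
                       rates = behavior_rates()) {
  list(n_voxels = n_voxels, design = design, noise = noise, code = code,
       gaze = gaze, rates = rates)
}

#' Simulate one subject (design, code, BOLD, gaze, behaviour)
#'
#' Draws the subject's session, realises a [planted_code()] whose effect
#' sizes (`ego_amplitude`, `adapt_k`, `quad_amplitude`, `grid_gains`) are
#' scaled by a shared log-normal subject factor `exp(N(0, subject_sd))`,
#' and simulates all 8 BOLD runs, gaze traces and responses.
#'
#' @param subject_id subject label.
#' @param seed integer seed (everything about the subject derives from it).
#' @param params a [sim_params()] list.
#' @param with_gaze simulate gaze traces? (skippable for BOLD-only use).
#' @return list with `session` (trial tibble incl. responses), `bold` and
#'   `gaze` (lists over runs), `code` (the realised ground truth) and
#'   `subject_factor`.
#' @export
simulate_subject <- function(subject_id = 1L, seed = 1L,
                             params = sim_params(), with_gaze = TRUE) {
  session <- generate_session(subject_id, seed = seed,
                              config = params$design)
  withr::local_seed(seed + 500000L)
  sf <- exp(stats::rnorm(1, 0, params$noise$subject_sd))
  code_args <- utils::modifyList(
    list(n_voxels = params$n_voxels, seed = seed + 600000L), params$code
  )
  code <- do.call(planted_code, code_args)
  code$ego_amplitude <- code$ego_amplitude * sf
  code$quad_patterns <- lapply(code$quad_patterns, function(m) m * sf)
  code$grid_gains <- code$grid_gains * sf

  runs <- split(session, session$run)
  bold <- vector("list", length(runs))
  gaze <- vector("list", length(runs))
  out_runs <- vector("list", length(runs))
  for (i in seq_along(runs)) {
    run <- runs[[i]]
    run <- simulate_behavior(run, params$rates, seed = seed + 1000L + i)
    amp <- plant_trial_amplitudes(run, code)
    bold[[i]] <- simulate_bold_run(run, amp, params$noise,
                                   seed = seed + 2000L + i)
    if (with_gaze) {
      gaze[[i]] <- simulate_gaze_run(
        run, slope = params$gaze$slope, noise_sd = params$gaze$noise_sd,
        question_gain = params$gaze$question_gain, seed = seed + 3000L + i,
        n_volumes = bold[[i]]$n_volumes
      )
    }
    out_runs[[i]] <- run
  }
  list(session = dplyr::bind_rows(out_runs), bold = bold, gaze = gaze,
       code = code, subject_factor = sf)
}

#' Simulate a full cohort
#'
#' @param n_subjects number of subjects (the study tested 40).
#' @param params a [sim_params()] list.
#' @param seed integer master seed; subject `i` uses `seed * 1000 + i`.
#' @param out_dir optional directory; when given the cohort is written to
#'   disk via [write_cohort()].
#' @return list of class `hx_cohort`: `subjects` (list from
#'   [simulate_subject()]), `params`, `seed`.
#' @export
simulate_cohort <- function(n_subjects = 40, params = sim_params(),
                            seed = 1, out_dir = NULL) {
  subjects <- lapply(seq_len(n_subjects), function(i) {
    simulate_subject(i, seed = seed * 1000L + i, params = params)
  })
  cohort <- structure(list(subjects = subjects, params = params, seed = seed),
                      class = "hx_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' Write a cohort to disk in a BIDS-like layout
#'
#' Creates `sub-XX/` directories with per-run `run-YY_events.tsv` and
#' `run-YY_gaze.tsv`, a per-subject `behavior.tsv`, and a cohort-level
#' `manifest.json` holding the planted ground-truth parameters (the test
#' oracle). BOLD matrices are written as `run-YY_bold.tsv` only when
#' `write_bold = TRUE` (they are large).
#'
#' @param cohort an `hx_cohort`.
#' @param dir output directory.
#' @param write_bold write voxel x time BOLD matrices as TSV?
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, write_bold = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort$subjects)) {
    sub <- cohort$subjects[[i]]
    sdir <- file.path(dir, sprintf("sub-%02d", i))
    dir.create(sdir, showWarnings = FALSE)
    for (r in sort(unique(sub$session$run))) {
      run <- dplyr::filter(sub$session, .data$run == r)
      write_events_tsv(run, file.path(sdir, sprintf("run-%02d_events.tsv", r)))
      readr::write_tsv(sub$gaze[[r]],
                       file.path(sdir, sprintf("run-%02d_gaze.tsv", r)))
      if (write_bold) {
        readr::write_tsv(
          tibble::as_tibble(as.data.frame(sub$bold[[r]]$data)),
          file.path(sdir, sprintf("run-%02d_bold.tsv", r)),
          col_names = FALSE
        )
      }
    }
    readr::write_tsv(
      dplyr::select(sub$session, "subject", "run", "trial", "context",
                    "question", "expected_answer", "response", "rt"),
      file.path(sdir, "behavior.tsv")
    )
  }
  manifest <- list(
    n_subjects = length(cohort$subjects),
    n_runs = length(cohort$subjects[[1]]$bold),
    seed = cohort$seed,
    params = cohort$params[c("n_voxels", "gaze")],
    code = lapply(cohort$subjects, function(s) {
      s$code[c("ego_amplitude", "ego_kappa", "adapt_k", "quad_mode",
               "ego_shared", "grid_gains", "grid_phase", "grid_fold",
               "grid_mode", "baseline")]
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
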