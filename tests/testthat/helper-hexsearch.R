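# small-scale simulation settings used across unit tests; the acceptance
# suite uses the package defaults (200 voxels, full cohorts)
mini_params <- function(...) {
  sim_params(n_voxels = 60, code = list(...))
}

mini_subject <- function(seed = 1, ..., noise = noise_model(),
                         with_gaze = FALSE) {
  p <- mini_params(...)
  p$noise <- noise
  simulate_subject(1L, seed = seed, params = p, with_gaze = with_gaze)
}

# a minimal hand-built run: n trials with fixed spacing, all fields the
# analyses touch; geometry is synthetic but self-consistent
toy_run <- function(ego = c(0, 45, 45, -90, 0, 45), spacing = 12,
                    context = "blue", quadrant = NULL, allo = NULL) {
  n <- length(ego)
  onset <- seq(2, by = spacing, length.out = n)
  goal <- drop(goal_position(context))
  tibble::tibble(
    context = context, run = 1L, trial = seq_len(n),
    onset = onset, morph_onset = onset + 0.5, imagine_onset = onset + 1.5,
    question_onset = onset + 5.5, static_dur = 0.5, morph_dur = 1,
    imagine_dur = 4, question_dur = 2.5, iti = 3,
    start_x = 0.25, start_y = 0.25, heading = if (is.null(allo)) 10 else allo,
    ego_offset = ego,
    allo_bin = bin_allocentric(if (is.null(allo)) rep(10, n) else allo),
    quadrant = if (is.null(quadrant)) rep("Q1", n) else quadrant,
    goal_x = goal[1], goal_y = goal[2],
    goal_distance = sqrt((0.25 - goal[1])^2 + (0.25 - goal[2])^2),
    question = "target", filler_offset = NA_real_,
    expected_answer = ifelse(ego == 0, "yes", "no")
  )
}
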