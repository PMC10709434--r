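#' Default design and simulation configuration
#'
#' Central list of geometry, timing and generator settings shared by the
#' trial generator and the simulators. Values can be overridden by name;
#' everything is in space units (unit square) and seconds.
#'
#' @param ... named overrides of the defaults.
#' @return a named list of settings.
#' @details
#' * `quadrant_margin` (0.05): start points are sampled uniformly within
#'   their quadrant shrunk by this margin on every side, so no start or
#'   morph endpoint can touch a midline.
#' * `morph_length` (0.15): displacement of the visible morphing segment.
#' * `min_goal_distance` (0.12): minimum start-to-goal distance so the
#'   bearing is well defined; on-target trials additionally require
#'   `morph_length + 0.05` so the visible morph never reaches the goal.
#' * `static_dur` (0.5), `morph_dur` (1), `imagine_dur` (4),
#'   `question_dur` (2.5): trial phase durations.
#' * `iti_range` (2--6): uniform inter-trial jitter.
#' * `max_r_ego_dist` (0.03): session-level bound on the absolute Pearson
#'   correlation between the signed egocentric condition and start-to-goal
#'   distance.
#' * `max_session_attempts` (10000), `max_trial_attempts` (500): rejection
#'   sampling caps.
#' @export
design_config <- function(...) {
  cfg <- list(
    quadrant_margin = 0.05,
    morph_length = 0.15,
    min_goal_distance = 0.12,
    static_dur = 0.5,
    morph_dur = 1,
    imagine_dur = 4,
    question_dur = 2.5,
    iti_range = c(2, 6),
    n_trials = 48L,
    n_runs = 8L,
    max_r_ego_dist = 0.03,
    max_session_attempts = 10000L,
    max_trial_attempts = 500L,
    tr = 1.5
  )
  dots <- list(...)
  stopifnot(all(names(dots) %in% names(cfg)))
  cfg[names(dots)] <- dots
  cfg
}

ego_levels <- c(-135, -90, -45, 0, 45, 90, 135)
quadrant_levels <- c("Q1", "Q2", "Q3", "Q4")

quadrant_box <- function(quadrant, margin) {
  lo <- c(Q1 = 0, Q2 = 0.5, Q3 = 0, Q4 = 0.5)[quadrant] + margin
  hi <- lo + 0.5 - 2 * margin
  lo_y <- c(Q1 = 0, Q2 = 0, Q3 = 0.5, Q4 = 0.5)[quadrant] + margin
  hi_y <- lo_y + 0.5 - 2 * margin
  cbind(xlo = unname(lo), xhi = unname(hi),
        ylo = unname(lo_y), yhi = unname(hi_y))
}

# Sample start points for all (quadrant, ego_offset) trials of a run at
# once: the morph segment must stay strictly inside its quadrant and the
# start keeps a minimum distance from the goal (larger for on-target
# trials, so the visible morph never reaches the goal). Rejection sampling
# proceeds in rounds of `chunk` candidates per unplaced trial.
sample_starts <- function(quadrant, ego, goal, cfg, chunk = 16L) {
  n <- length(quadrant)
  box <- quadrant_box(quadrant, cfg$quadrant_margin)
  qlo_x <- box[, "xlo"] - cfg$quadrant_margin + 0.01
  qhi_x <- box[, "xhi"] + cfg$quadrant_margin - 0.01
  qlo_y <- box[, "ylo"] - cfg$quadrant_margin + 0.01
  qhi_y <- box[, "yhi"] + cfg$quadrant_margin - 0.01
  min_d <- ifelse(ego == 0,
                  pmax(cfg$min_goal_distance, cfg$morph_length + 0.05),
                  cfg$min_goal_distance)
  out_x <- out_y <- out_h <- rep(NA_real_, n)
  active <- seq_len(n)
  spent <- 0L
  while (length(active)) {
    idx <- rep(active, each = chunk)
    xs <- runif(length(idx), box[idx, "xlo"], box[idx, "xhi"])
    ys <- runif(length(idx), box[idx, "ylo"], box[idx, "yhi"])
    d2 <- (xs - goal[1])^2 + (ys - goal[2])^2
    bearing <- wrap_360(atan2(goal[2] - ys, goal[1] - xs) * 180 / pi)
    heading <- wrap_360(bearing - ego[idx])
    ex <- xs + cfg$morph_length * cos(heading * pi / 180)
    ey <- ys + cfg$morph_length * sin(heading * pi / 180)
    ok <- d2 >= min_d[idx]^2 &
      ex > qlo_x[idx] & ex < qhi_x[idx] &
      ey > qlo_y[idx] & ey < qhi_y[idx] &
      abs((heading - 15) %% 30) > 1e-9   # not exactly on a bin edge
    hit <- which(ok)
    first <- hit[!duplicated(idx[hit])]
    placed <- idx[first]
    out_x[placed] <- xs[first]
    out_y[placed] <- ys[first]
    out_h[placed] <- heading[first]
    active <- setdiff(active, placed)
    spent <- spent + chunk
    if (spent >= cfg$max_trial_attempts && length(active)) {
      stop(sprintf(
        "could not place %d trial(s) (e.g. quadrant %s, offset %g) after %d samples",
        length(active), quadrant[active[1]], ego[active[1]], spent
      ))
    }
  }
  list(x = out_x, y = out_y, heading = out_h)
}

#' Generate one run of the recall task
#'
#' Produces a 48-trial run satisfying every design constraint: 12 on-target
#' trials (egocentric condition 0) and 6 per each of the six off-target
#' conditions (-135, -90, -45, +45, +90, +135 degrees); 12 trials per
#' quadrant; 24 target questions (6 expected "yes", 18 expected "no") and 24
#' filler questions whose probe lies on the imagined trajectory on 8 trials
#' and off it by -60 / +60 degrees on 8 + 8; no morphing segment crosses a
#' quadrant boundary. Start points are sampled uniformly within their
#' quadrant (with margin) and the heading is set to the start-to-goal
#' bearing minus the egocentric condition.
#'
#' @param context `"blue"` or `"green"`.
#' @param run_index integer run label.
#' @param seed optional integer; when given, the run is reproducible.
#' @param config a [design_config()] list.
#' @return a tibble with one row per trial: timing columns (`onset`,
#'   `morph_onset`, `imagine_onset`, `question_onset`, durations, `iti`),
#'   geometry (`start_x`, `start_y`, `heading`, `ego_offset`, `allo_bin`,
#'   `quadrant`, `goal_x`, `goal_y`, `goal_distance`) and question structure
#'   (`question`, `filler_offset`, `expected_answer`).
#' @export
generate_run <- function(context, run_index = 1L, seed = NULL,
                         config = design_config()) {
  stopifnot(context %in% c("blue", "green"))
  if (!is.null(seed)) withr::local_seed(seed)
  cfg <- config
  goal <- drop(goal_position(context))

  ego <- c(rep(0, 12), rep(setdiff(ego_levels, 0), each = 6))
  quadrant <- sample(rep(quadrant_levels, 12L))
  ego <- sample(ego)

  # question assignment: 6 of the 12 on-target trials get the target
  # question (expected yes); 18 of the 36 off-target trials get the target
  # question (expected no); the remaining 24 trials get filler questions.
  question <- rep("filler", cfg$n_trials)
  on_idx <- which(ego == 0)
  off_idx <- which(ego != 0)
  question[sample(on_idx, 6L)] <- "target"
  question[sample(off_idx, 18L)] <- "target"
  filler_offset <- rep(NA_real_, cfg$n_trials)
  filler_offset[question == "filler"] <- sample(rep(c(0, -60, 60), each = 8L))
  expected <- ifelse(
    question == "target",
    ifelse(ego == 0, "yes", "no"),
    ifelse(filler_offset == 0, "yes", "no")
  )

  placed <- sample_starts(quadrant, ego, goal, cfg)
  start <- cbind(placed$x, placed$y)
  heading <- placed$heading

  iti <- runif(cfg$n_trials, cfg$iti_range[1], cfg$iti_range[2])
  trial_len <- cfg$static_dur + cfg$morph_dur + cfg$imagine_dur +
    cfg$question_dur
  onset <- cumsum(c(cfg$iti_range[1], head(trial_len + iti, -1L)))

  tibble::new_tibble(list(
    context = rep(context, cfg$n_trials),
    run = rep(as.integer(run_index), cfg$n_trials),
    trial = seq_len(cfg$n_trials),
    onset = onset,
    morph_onset = onset + cfg$static_dur,
    imagine_onset = onset + cfg$static_dur + cfg$morph_dur,
    question_onset = onset + cfg$static_dur + cfg$morph_dur + cfg$imagine_dur,
    static_dur = rep(cfg$static_dur, cfg$n_trials),
    morph_dur = rep(cfg$morph_dur, cfg$n_trials),
    imagine_dur = rep(cfg$imagine_dur, cfg$n_trials),
    question_dur = rep(cfg$question_dur, cfg$n_trials),
    iti = iti,
    start_x = start[, 1],
    start_y = start[, 2],
    heading = heading,
    ego_offset = ego,
    allo_bin = bin_allocentric(heading),
    quadrant = quadrant,
    goal_x = rep(goal[1], cfg$n_trials),
    goal_y = rep(goal[2], cfg$n_trials),
    goal_distance = sqrt((start[, 1] - goal[1])^2 + (start[, 2] - goal[2])^2),
    question = question,
    filler_offset = filler_offset,
    expected_answer = expected
  ), nrow = cfg$n_trials)
}

#' Generate a subject's full session
#'
#' Eight runs of the recall task, four per colour context in a random
#' intermixed order. Whole sessions are rejection-sampled until the absolute
#' Pearson correlation, pooled over all 384 trials, between the signed
#' egocentric condition and the start-to-goal distance is at most
#' `config$max_r_ego_dist` (0.03 by default), so goal distance cannot
#' confound egocentric-angle analyses.
#'
#' @param subject_id integer or character subject label.
#' @param seed integer seed; the session is a deterministic function of it.
#' @param config a [design_config()] list.
#' @return a tibble of 384 trials (8 runs x 48) with a `subject` column,
#'   carrying the achieved correlation in attribute `r_ego_dist`.
#' @export
generate_session <- function(subject_id = 1L, seed = 1L,
                             config = design_config()) {
  cfg <- config
  withr::local_seed(seed)
  for (attempt in seq_len(cfg$max_session_attempts)) {
    contexts <- sample(rep(c("blue", "green"), cfg$n_runs / 2L))
    runs <- purrr::map2(contexts, seq_len(cfg$n_runs),
                        function(ctx, i) generate_run(ctx, i, config = cfg))
    session <- dplyr::bind_rows(runs)
    r <- stats::cor(session$ego_offset, session$goal_distance)
    if (abs(r) <= cfg$max_r_ego_dist) {
      session <- dplyr::mutate(session, subject = subject_id,
                               .before = "context")
      attr(session, "r_ego_dist") <- r
      attr(session, "seed") <- seed
      return(session)
    }
  }
  stop("session-level rejection sampling cap exceeded")
}

#' Design diagnostics for a generated session
#'
#' Recomputes every design count and constraint from the trial table:
#' per-run egocentric-condition, quadrant and question counts, the pooled
#' egocentric-angle/goal-distance correlation, and geometric flags (morph
#' segment inside its quadrant; on-target iff the extended trajectory passes
#' within tolerance of the goal).
#'
#' @param session a session tibble from [generate_session()] (or one run).
#' @param config the [design_config()] the session was built with.
#' @return a list with elements `counts` (tibble of per-run condition /
#'   quadrant / question counts), `pooled_r` (Pearson r between signed
#'   egocentric condition and goal distance), `n_trials`,
#'   `boundary_crossings` (must be 0) and `constraints_ok`.
#' @export
design_diagnostics <- function(session, config = design_config()) {
  cfg <- config
  counts <- session |>
    dplyr::group_by(.data$run, .data$context) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_on_target = sum(.data$ego_offset == 0),
      n_per_offset_ok = all(table(.data$ego_offset[.data$ego_offset != 0]) == 6L),
      n_per_quadrant_ok = all(table(.data$quadrant) == 12L),
      n_target_q = sum(.data$question == "target"),
      n_expected_yes = sum(.data$question == "target" &
                             .data$expected_answer == "yes"),
      n_filler_q = sum(.data$question == "filler"),
      .groups = "drop"
    )

  ex <- session$start_x + cfg$morph_length * cos(session$heading * pi / 180)
  ey <- session$start_y + cfg$morph_length * sin(session$heading * pi / 180)
  crossed <- assign_quadrant(cbind(ex, ey)) != session$quadrant
  # on-target check: perpendicular distance of the goal from the morph ray
  goal <- cbind(session$goal_x, session$goal_y)
  start <- cbind(session$start_x, session$start_y)
  rel_bearing <- wrap_180(bearing_to(start, goal) - session$heading)
  on_target_geom <- abs(rel_bearing) < 1e-6
  mismatch <- xor(on_target_geom, session$ego_offset == 0)

  pooled_r <- stats::cor(session$ego_offset, session$goal_distance)
  ok <- all(counts$n == cfg$n_trials) &&
    all(counts$n_on_target == 12L) &&
    all(counts$n_per_offset_ok) &&
    all(counts$n_per_quadrant_ok) &&
    all(counts$n_target_q == 24L) &&
    all(counts$n_expected_yes == 6L) &&
    all(counts$n_filler_q == 24L) &&
    sum(crossed) == 0L && sum(mismatch) == 0L &&
    abs(pooled_r) <= cfg$max_r_ego_dist

  list(
    counts = counts,
    pooled_r = pooled_r,
    n_trials = nrow(session),
    boundary_crossings = sum(crossed),
    on_target_mismatches = sum(mismatch),
    constraints_ok = ok
  )
}

#' Write / read run events as BIDS-style TSV
#'
#' One file per run with columns `onset`, `duration` (imagination period),
#' `trial_type`, `context`, `ego_offset`, `allo_bin`, `quadrant`,
#' `question`, `filler_offset`, `expected_answer`, and -- when behavioural
#' responses are present -- `response` and `rt`.
#'
#' @param run a run tibble (one run's rows of a session).
#' @param path output file path.
#' @return `write_events_tsv()`: `path`, invisibly. `read_events_tsv()`:
#'   a tibble.
#' @export
write_events_tsv <- function(run, path) {
  out <- tibble::tibble(
    onset = run$imagine_onset,
    duration = run$imagine_dur,
    trial_type = "imagine",
    context = run$context,
    ego_offset = run$ego_offset,
    allo_bin = run$allo_bin,
    quadrant = run$quadrant,
    question = run$question,
    filler_offset = run$filler_offset,
    expected_answer = run$expected_answer,
    response = if ("response" %in% names(run)) run$response else NA_character_,
    rt = if ("rt" %in% names(run)) run$rt else NA_real_
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
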