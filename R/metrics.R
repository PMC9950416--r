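# Crossing-level and group-level behavioral measures: crossing times,
# slips per crossing, posture at the first manipulated step, speed
# profiles, the speedup index, and jump statistics.

#' Crossing duration in seconds
#'
#' @param crossing one row of a crossing table (`start_frame`, `end_frame`).
#' @param frame_rate frames per second.
#' @return duration, s.
#' @export
crossing_time <- function(crossing, frame_rate) {
  dt <- (crossing$end_frame - crossing$start_frame) / frame_rate
  if (any(dt <= 0)) stop("zero-length crossing")
  dt
}

#' Per-group, per-session crossing-time summary
#'
#' @param records trial table with `group`, `session`, `crossing_time`.
#' @param criterion performance cutoff, s; a session "meets criterion" when
#'   its mean crossing time is strictly below it (one second per obstacle,
#'   eight seconds per crossing, by default).
#' @return data frame with `group`, `session`, `n`, `mean`, `sd`,
#'   `meets_criterion`.
#' @export
session_summary <- function(records, criterion = 8) {
  agg <- do.call(rbind, lapply(
    split(records, interaction(records$group, records$session, drop = TRUE)),
    function(d) data.frame(group = d$group[1], session = d$session[1],
                           n = nrow(d), mean = mean(d$crossing_time),
                           sd = stats::sd(d$crossing_time))))
  agg$meets_criterion <- agg$mean < criterion
  rownames(agg) <- NULL
  agg[order(agg$group, agg$session), ]
}

#' Split a transition session around its condition change
#'
#' Returns the 20 trials immediately preceding the change and the trials
#' from the change onward. With fewer than 20 pre-change trials all
#' available ones are returned with a warning.
#'
#' @param records session trial table, in trial order, with a `trial`
#'   column (1-based).
#' @param change_trial 1-based ordinal of the first post-change trial.
#' @param n_pre number of pre-change trials to keep.
#' @return list with `pre` and `post` record subsets.
#' @export
split_transition_session <- function(records, change_trial, n_pre = 20L) {
  pre_idx <- records$trial < change_trial
  post <- records[records$trial >= change_trial, , drop = FALSE]
  pre <- records[pre_idx, , drop = FALSE]
  if (nrow(pre) < n_pre)
    warning(sprintf("only %d pre-change trials available (wanted %d)",
                    nrow(pre), n_pre))
  else
    pre <- pre[(nrow(pre) - n_pre + 1L):nrow(pre), , drop = FALSE]
  list(pre = pre, post = post)
}

#' Confirmed slips per crossing
#'
#' @param slips slip-event table (rows are confirmed slips; an optional
#'   `confirmed` column filters automatically).
#' @param n_crossings number of crossings in the same record set.
#' @param limb optional limb filter ("fore"/"hind").
#' @return slips-per-crossing rate.
#' @export
slips_per_crossing <- function(slips, n_crossings, limb = NULL) {
  if (n_crossings <= 0) stop("need at least one crossing")
  if (!is.null(slips$confirmed)) slips <- slips[slips$confirmed, , drop = FALSE]
  if (!is.null(limb)) slips <- slips[!is.na(slips$limb) & slips$limb == limb, ,
                                     drop = FALSE]
  nrow(slips) / n_crossings
}

#' Nose posture at a step event
#'
#' The nose position at the frame of a paw contact, expressed relative to a
#' reference point: progression is the signed distance along the travel
#' direction (cm, + = forward of the reference) and height the distance
#' above it (cm, + = up).
#'
#' @param poses pose table (px).
#' @param event_frame 0-based frame of the step event.
#' @param reference `c(x_cm, y_cm)` reference point: typically the near
#'   edge of the first manipulated step and a height baseline.
#' @param geometry a [course_geometry()].
#' @param direction travel direction of the crossing ("LR"/"RL").
#' @return data frame with `progression`, `height` (cm), or `NULL` when the
#'   pose at that frame is invalid.
#' @export
posture_at_step <- function(poses, event_frame, reference, geometry,
                            direction = "LR") {
  row <- poses[poses$frame == event_frame, , drop = FALSE]
  if (!nrow(row) || !row$valid[1]) return(NULL)
  x_cm <- px_to_cm_x(geometry, row$nose_x[1])
  y_cm <- px_to_cm_y(geometry, row$nose_y[1])
  sgn <- if (direction == "LR") 1 else -1
  data.frame(progression = (x_cm - reference[1]) * sgn,
             height = y_cm - reference[2])
}

#' Posture statistics by condition
#'
#' Groups posture samples by the current trial state or by the state of the
#' two previous trials (mixed histories excluded) and compares the two
#' conditions with an unpaired Student's t-test on each measure.
#'
#' @param samples data frame with `progression`, `height`, `state`,
#'   and `prev1`, `prev2` (states of the two preceding trials, NA when
#'   unavailable).
#' @param conditioning "current_state" or "prev_two_states".
#' @return list with `stats` (per-condition mean/sd/n for both measures)
#'   and `tests` (a [t_test()] result per measure, `NULL` when a condition
#'   has fewer than 2 samples).
#' @export
condition_posture_stats <- function(samples,
                                    conditioning = c("current_state",
                                                     "prev_two_states")) {
  conditioning <- match.arg(conditioning)
  if (conditioning == "current_state") {
    samples$condition <- samples$state
  } else {
    keep <- !is.na(samples$prev1) & !is.na(samples$prev2) &
      samples$prev1 == samples$prev2
    samples <- samples[keep, , drop = FALSE]
    samples$condition <- samples$prev1
  }
  stats_tab <- do.call(rbind, lapply(split(samples, samples$condition),
    function(d) data.frame(
      condition = d$condition[1], n = nrow(d),
      progression_mean = mean(d$progression),
      progression_sd = stats::sd(d$progression),
      height_mean = mean(d$height), height_sd = stats::sd(d$height))))
  rownames(stats_tab) <- NULL
  tests <- list(progression = NULL, height = NULL)
  conds <- unique(samples$condition)
  if (length(conds) == 2L) {
    a <- samples[samples$condition == conds[1], ]
    b <- samples[samples$condition == conds[2], ]
    if (nrow(a) >= 2L && nrow(b) >= 2L) {
      tests$progression <- t_test_samples(a$progression, b$progression)
      tests$height <- t_test_samples(a$height, b$height)
    }
  }
  list(stats = stats_tab, tests = tests)
}

#' Speed profile of a crossing over fixed spatial segments
#'
#' Divides the course into equal-length segments (by default one per
#' step-plus-gap interval), measures the nose speed on each traversed
#' segment, and subtracts the mean speed over the approach segments (those
#' strictly before the first manipulated step in travel direction) as a
#' per-trial baseline.
#'
#' @param poses pose table of one crossing.
#' @param geometry a [course_geometry()].
#' @param direction travel direction.
#' @param n_segments number of equal segments covering the course.
#' @param approach optional explicit indices of approach segments,
#'   overriding the geometric rule.
#' @return list of class `speed_profile`: `speed`, `baselined` (cm/s per
#'   segment, NA when not traversed), `baseline` (cm/s), `segments`
#'   (boundaries, cm).
#' @export
speed_profile <- function(poses, geometry, direction = "LR",
                          n_segments = NULL, approach = NULL) {
  if (is.null(n_segments)) n_segments <- geometry$n_steps
  bounds <- seq(0, geometry$course_length, length.out = n_segments + 1L)
  p <- poses[poses$valid, ]
  x <- px_to_cm_x(geometry, p$nose_x)
  t <- p$time_s
  if (direction == "RL") x <- geometry$course_length - x   # travel coords
  # time at which the nose crosses each boundary, by linear interpolation
  ord <- order(x)
  tb <- suppressWarnings(stats::approx(x[ord], t[ord], xout = bounds,
                                       ties = "ordered")$y)
  seg_dt <- diff(tb)
  seg_len <- diff(bounds)
  speed <- seg_len / seg_dt
  speed[!is.finite(speed)] <- NA_real_

  if (is.null(approach)) {
    se <- step_edges(geometry)
    x_first <- se$x0[geometry$center_steps[1]]
    if (direction == "RL")
      x_first <- geometry$course_length - se$x1[geometry$center_steps[2]]
    approach <- which(bounds[-1L] <= x_first + 1e-9)
  }
  if (!any(is.finite(speed[approach])))
    stop("no valid approach segments for baseline")
  baseline <- mean(speed[approach], na.rm = TRUE)
  structure(list(speed = speed, baselined = speed - baseline,
                 baseline = baseline, segments = bounds,
                 approach_segments = approach),
            class = "speed_profile")
}

#' Speedup index between stable and unstable trials
#'
#' For each spatial segment, the mean baselined speed over stable trials
#' minus the mean over unstable trials, summed over segments (segments
#' missing from either condition are excluded pairwise). Positive values
#' indicate the animal moves slower on unstable trials.
#'
#' @param stable_profiles,unstable_profiles lists of [speed_profile()]s.
#' @return scalar index, cm/s.
#' @export
speedup_index <- function(stable_profiles, unstable_profiles) {
  if (!length(stable_profiles) || !length(unstable_profiles))
    stop("need at least one profile per state")
  seg_mean <- function(profiles) {
    m <- do.call(rbind, lapply(profiles, function(p) p$baselined))
    colMeans(m, na.rm = TRUE)
  }
  s <- seg_mean(stable_profiles)
  u <- seg_mean(unstable_profiles)
  ok <- is.finite(s) & is.finite(u)
  sum(s[ok] - u[ok])
}

#' Probability of skipping the center steps, and jumper classification
#'
#' A crossing "skips" when it has no paw contact (fore or hind) on either
#' center step. An animal is a jumper when its skip probability exceeds the
#' threshold; jumpers are excluded from randomized-protocol posture
#' analyses since their experience does not depend on the step state.
#'
#' @param step_events step-event table with `crossing` and `step`.
#' @param crossings crossing table.
#' @param geometry a [course_geometry()].
#' @return list of class `jump_stats`: `probability`, `n_crossings`,
#'   `n_skipped`.
#' @export
jump_probability <- function(step_events, crossings, geometry) {
  n <- nrow(crossings)
  if (n == 0L) stop("need at least one crossing")
  on_center <- step_events$step %in% geometry$center_steps
  contacted <- unique(step_events$crossing[on_center])
  skipped <- sum(!(crossings$crossing %in% contacted))
  structure(list(probability = skipped / n, n_crossings = n,
                 n_skipped = skipped), class = "jump_stats")
}

#' @rdname jump_probability
#' @param stats a `jump_stats` (or bare probability) per animal.
#' @param threshold skip-probability cutoff above which an animal is a
#'   jumper.
#' @return `classify_jumpers()`: logical vector.
#' @export
classify_jumpers <- function(stats, threshold = 0.5) {
  p <- vapply(stats, function(s)
    if (inherits(s, "jump_stats")) s$probability else as.numeric(s), 0)
  flags <- p > threshold
  if (all(flags))
    warning("all animals classified as jumpers; randomized-protocol posture analysis set is empty")
  flags
}
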