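# Ground-truth crossing generator: kinematics, paw contacts, slips.

#' Crossing style parameters
#'
#' Bundles the behavioral parameters of the crossing generator. Posture
#' offsets are the nose position, relative to the near edge of the first
#' manipulated step (progression) and to the animal's baseline nose height
#' (height), at the moment the forepaw contacts that step. Defaults emulate
#' the group behavior observed in the assay: on stable trials animals carry
#' the nose forward and high (0.77 +/- 0.93 cm progression, 0.61 +/- 1.02 cm
#' height), on unstable trials low and held back (-0.25 +/- 0.73 cm,
#' -0.25 +/- 0.69 cm), and they slow down ~20% after the manipulated step
#' when it is unstable.
#'
#' @param p_jump probability of the jump strategy (skipping both center
#'   steps) on a given crossing.
#' @param posture_mean named list of `c(progression, height)` mean offsets
#'   (cm) per trial state.
#' @param posture_sd named list of matching standard deviations (cm).
#' @param posture_shift additive `c(progression, height)` shift (cm), e.g.
#'   a trial-history effect.
#' @param nose_lead nose lead over the near step edge at forepaw contact on
#'   non-manipulated steps, cm.
#' @param hind_lead nose lead at hindpaw contact, cm; hindpaw contacts occur
#'   when the head is well past the next step and are what the
#'   head-position constraint must reject.
#' @param base_height baseline nose height above the step surface, cm.
#' @param approach_speed nose speed on the approach, cm/s.
#' @param speed_factor named per-state multiplier applied to speed after the
#'   first manipulated step.
#' @param slip_prob per-gap probability of a paw slip.
#' @param slip_limb_probs probabilities `c(fore, hind)` for the slipping limb.
#' @param start_margin distance outside either course end where the nose
#'   path starts/ends, cm.
#' @param bump_width spatial width (cm) of the smooth nose-height excursion
#'   centered on the manipulated-step contact.
#' @return a list of class `crossing_style`.
#' @export
crossing_style <- function(p_jump = 0,
                           posture_mean = list(stable = c(0.77, 0.61),
                                               unstable = c(-0.25, -0.25)),
                           posture_sd = list(stable = c(0.93, 1.02),
                                             unstable = c(0.73, 0.69)),
                           posture_shift = c(0, 0),
                           nose_lead = 1.0, hind_lead = 8.0,
                           base_height = 6.0, approach_speed = 8.0,
                           speed_factor = c(stable = 1.0, unstable = 0.8),
                           slip_prob = 0,
                           slip_limb_probs = c(fore = 0.3, hind = 0.7),
                           start_margin = 4.0, bump_width = 3.0) {
  if (p_jump < 0 || p_jump > 1) stop("p_jump must be in [0, 1]")
  if (slip_prob < 0 || slip_prob > 1) stop("slip_prob must be in [0, 1]")
  s <- list(p_jump = p_jump, posture_mean = posture_mean,
            posture_sd = posture_sd, posture_shift = posture_shift,
            nose_lead = nose_lead, hind_lead = hind_lead,
            base_height = base_height, approach_speed = approach_speed,
            speed_factor = speed_factor, slip_prob = slip_prob,
            slip_limb_probs = slip_limb_probs, start_margin = start_margin,
            bump_width = bump_width)
  class(s) <- "crossing_style"
  s
}

#' Generate one ground-truth crossing
#'
#' Produces a kinematically consistent crossing: a nose path sampled at the
#' camera frame rate, time-stamped paw contacts on each step (forelimb, then
#' a later hindlimb contact once the head has moved on), optional slips into
#' gaps, and the posture offset realized at the first manipulated step. The
#' jump strategy omits all contacts on the two center steps.
#'
#' @param geometry a [course_geometry()].
#' @param style a [crossing_style()].
#' @param trial_state "stable" or "unstable" state of the center steps.
#' @param seed integer seed; the crossing is a deterministic function of it.
#' @param direction "LR" or "RL" travel direction.
#' @return a list of class `crossing_gt` with elements `direction`,
#'   `strategy`, `trial_state`, `nose_path` (frame, t, x, y in cm),
#'   `contacts` (t, frame, step, limb, side), `slips` (t, frame, gap, limb),
#'   `posture_offset` and `params`.
#' @export
generate_crossing <- function(geometry, style = crossing_style(),
                              trial_state = "stable", seed = 1L,
                              direction = c("LR", "RL")) {
  direction <- match.arg(direction)
  trial_state <- match.arg(trial_state, c("stable", "unstable"))
  with_seed(seed, {
    strategy <- if (stats::runif(1) < style$p_jump) "jump" else "walk"
    mu <- style$posture_mean[[trial_state]] + style$posture_shift
    sd <- style$posture_sd[[trial_state]]
    offset <- stats::rnorm(2, mu, sd)

    se <- step_edges(geometry)
    first_center <- geometry$center_steps[1]
    x_change <- se$x0[first_center]
    x0 <- -style$start_margin
    x1 <- geometry$course_length + style$start_margin
    v0 <- style$approach_speed
    v1 <- v0 * unname(style$speed_factor[trial_state])
    t_change <- (x_change - x0) / v0
    t_end <- t_change + (x1 - x_change) / v1
    x_of_t <- function(t) ifelse(t <= t_change, x0 + v0 * t,
                                 x_change + v1 * (t - t_change))
    t_of_x <- function(x) ifelse(x <= x_change, (x - x0) / v0,
                                 t_change + (x - x_change) / v1)

    dt <- 1 / geometry$frame_rate
    tt <- seq(0, t_end, by = dt)
    x_star <- x_change + offset[1]   # nose x at the measured contact
    xx <- x_of_t(tt)
    yy <- style$base_height +
      offset[2] * exp(-0.5 * ((xx - x_star) / style$bump_width)^2)

    # paw contacts: forelimb when the nose reaches its lead over the near
    # edge; hindlimb later, once the head is hind_lead past the edge
    skip <- if (strategy == "jump") geometry$center_steps else integer(0)
    steps <- setdiff(seq_len(geometry$n_steps), skip)
    lead <- ifelse(steps == first_center, offset[1], style$nose_lead)
    side0 <- if (stats::runif(1) < 0.5) 0L else 1L
    sides <- c("left", "right")
    contacts <- rbind(
      data.frame(t = t_of_x(se$x0[steps] + lead), step = steps, limb = "fore",
                 side = sides[1L + (side0 + steps) %% 2L]),
      data.frame(t = t_of_x(se$x0[steps] + style$hind_lead), step = steps,
                 limb = "hind", side = sides[1L + (side0 + steps + 1L) %% 2L])
    )
    contacts <- contacts[contacts$t > 0 & contacts$t < t_end, , drop = FALSE]
    contacts <- contacts[order(contacts$t), , drop = FALSE]
    contacts$frame <- pmin(length(tt) - 1L, round(contacts$t / dt))

    ge <- gap_edges(geometry)
    slipped <- which(stats::runif(nrow(ge)) < style$slip_prob)
    slips <- data.frame(t = numeric(0), gap = integer(0), limb = character(0))
    if (length(slipped)) {
      slips <- data.frame(
        t = t_of_x((ge$x0[slipped] + ge$x1[slipped]) / 2),
        gap = slipped,
        limb = sample(names(style$slip_limb_probs), length(slipped),
                      replace = TRUE, prob = style$slip_limb_probs))
      slips <- slips[order(slips$t), , drop = FALSE]
    }
    slips$frame <- if (nrow(slips)) pmin(length(tt) - 1L, round(slips$t / dt)) else integer(0)

    if (direction == "RL") {
      xx <- geometry$course_length - xx
      contacts$step <- geometry$n_steps + 1L - contacts$step
      if (nrow(slips)) slips$gap <- (geometry$n_steps - 1L) + 1L - slips$gap
    }
    nose_path <- data.frame(frame = seq_along(tt) - 1L, t = tt, x = xx, y = yy)

    gt <- list(direction = direction, strategy = strategy,
               trial_state = trial_state, nose_path = nose_path,
               contacts = contacts[, c("t", "frame", "step", "limb", "side")],
               slips = slips, posture_offset = offset,
               params = list(style = style, seed = seed,
                             first_center = first_center,
                             x_change = x_change, base_height = style$base_height))
    class(gt) <- "crossing_gt"
    gt
  })
}

#' Ideal pose samples from ground truth
#'
#' Converts a generated nose path into the per-frame pose table the tracker
#' would produce on perfect data (nose rounded to whole pixels, all frames
#' valid). Used to exercise event detection and behavioral statistics
#' independently of the video pipeline.
#'
#' @param gt a `crossing_gt`.
#' @param geometry a [course_geometry()].
#' @return data frame with `frame`, `time_s`, `nose_x`, `nose_y` (px),
#'   `valid`.
#' @export
poses_from_gt <- function(gt, geometry) {
  data.frame(frame = gt$nose_path$frame,
             time_s = gt$nose_path$t,
             nose_x = round(cm_to_px_x(geometry, gt$nose_path$x)),
             nose_y = round(cm_to_px_y(geometry, gt$nose_path$y)),
             valid = TRUE)
}
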