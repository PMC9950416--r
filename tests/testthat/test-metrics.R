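# Behavioral measures: crossing times, transition splits, slip rates,
# posture, speed profiles and the speedup index, jump statistics.

test_that("crossing time and the performance criterion", {
  expect_equal(crossing_time(data.frame(start_frame = 0, end_frame = 960),
                             frame_rate = 120), 8)
  expect_error(crossing_time(data.frame(start_frame = 5, end_frame = 5), 120),
               "zero-length")
  rec <- data.frame(group = "control", session = 0,
                    crossing_time = c(7.9, 7.9, 7.9))
  expect_true(session_summary(rec)$meets_criterion)
  rec$crossing_time <- c(8.1, 8.1, 8.1)
  expect_false(session_summary(rec)$meets_criterion)
})

test_that("transition sessions split into last-20 pre and post", {
  rec <- data.frame(trial = 1:60, y = rnorm(60))
  sp <- split_transition_session(rec, change_trial = 21)
  expect_equal(sp$pre$trial, 1:20)
  expect_equal(sp$post$trial, 21:60)
  sp2 <- split_transition_session(rec, change_trial = 25)
  expect_equal(sp2$pre$trial, 5:24)
  expect_warning(sp3 <- split_transition_session(rec, change_trial = 10),
                 "pre-change")
  expect_equal(sp3$pre$trial, 1:9)
})

test_that("slips per crossing with limb filters", {
  slips <- data.frame(limb = c(rep("hind", 4), rep("fore", 2)),
                      confirmed = TRUE)
  expect_equal(slips_per_crossing(slips, 20), 0.3)
  expect_equal(slips_per_crossing(slips, 20, limb = "fore"), 0.1)
  all_hind <- data.frame(limb = rep("hind", 3), confirmed = TRUE)
  expect_equal(slips_per_crossing(all_hind, 10, limb = "fore"), 0)
  expect_error(slips_per_crossing(slips, 0), "at least one")
})

test_that("posture is measured relative to the reference with direction sign", {
  geom <- test_geometry()
  ref <- c(20, 6)
  poses <- data.frame(frame = 0L, nose_x = cm_to_px_x(geom, 20),
                      nose_y = cm_to_px_y(geom, 6), valid = TRUE)
  p <- posture_at_step(poses, 0, ref, geom, "LR")
  expect_equal(p$progression, 0)
  expect_equal(p$height, 0)

  poses2 <- data.frame(frame = 0L, nose_x = cm_to_px_x(geom, 22.5),
                       nose_y = cm_to_px_y(geom, 7.2), valid = TRUE)
  lr <- posture_at_step(poses2, 0, ref, geom, "LR")
  rl <- posture_at_step(poses2, 0, ref, geom, "RL")
  expect_equal(lr$progression, 2.5)
  expect_equal(rl$progression, -2.5)   # direction flip negates progression
  expect_equal(lr$height, rl$height)   # ... and preserves height
  expect_equal(lr$height, 1.2)

  poses2$valid <- FALSE
  expect_null(posture_at_step(poses2, 0, ref, geom))
})

test_that("generator posture offsets are recovered through the event pipeline", {
  geom <- test_geometry()
  style <- test_style()
  ref_x <- step_edges(geom)$x0[geom$center_steps[1]]
  measure <- function(state, seeds) {
    vapply(seeds, function(s) {
      gt <- generate_crossing(geom, style, state, seed = s)
      tr <- synthesize_roi_traces(gt, geom, seed = s)
      poses <- poses_from_gt(gt, geom)
      f <- detect_step(tr$values[, sprintf("step_%d_surface",
                                           geom$center_steps[1])])
      p <- posture_at_step(poses, f, c(ref_x, style$base_height), geom,
                           gt$direction)
      c(p$progression, p$height)
    }, numeric(2))
  }
  st <- measure("stable", 1:120)
  un <- measure("unstable", 121:240)
  # configured means: stable (0.77, 0.61), unstable (-0.25, -0.25);
  # tolerance 3 SE plus the 1-frame detection / 1-px quantization grain
  grain <- 0.15
  expect_within(mean(st[1, ]), 0.77, 3 * 0.93 / sqrt(120) + grain)
  expect_within(mean(st[2, ]), 0.61, 3 * 1.02 / sqrt(120) + grain)
  expect_within(mean(un[1, ]), -0.25, 3 * 0.73 / sqrt(120) + grain)
  expect_within(mean(un[2, ]), -0.25, 3 * 0.69 / sqrt(120) + grain)
})

test_that("history conditioning keeps only pure two-back histories", {
  samples <- data.frame(
    progression = c(1, 2, 3, 4, 5), height = 0,
    state = "stable",
    prev1 = c("stable", "stable", "unstable", "stable", NA),
    prev2 = c("stable", "unstable", "unstable", "stable", "stable"))
  out <- condition_posture_stats(samples, "prev_two_states")
  expect_equal(sum(out$stats$n), 3)   # mixed and NA histories dropped
  expect_equal(sort(out$stats$condition), c("stable", "unstable"))
})

test_that("a configured history effect is detected with the right sign", {
  geom <- test_geometry()
  gen <- function(shift, seeds, label) {
    do.call(rbind, lapply(seeds, function(s) {
      gt <- generate_crossing(geom, test_style(posture_shift = c(shift, 0)),
                              "stable", seed = s)
      data.frame(progression = gt$posture_offset[1],
                 height = gt$posture_offset[2],
                 state = "stable", prev1 = label, prev2 = label)
    }))
  }
  samples <- rbind(gen(0, 1:80, "stable"), gen(-0.2, 81:160, "unstable"))
  out <- condition_posture_stats(samples, "prev_two_states")
  m <- out$stats
  diff <- m$progression_mean[m$condition == "stable"] -
    m$progression_mean[m$condition == "unstable"]
  expect_gt(diff, 0)   # history effect sign recovered
  expect_true(!is.null(out$tests$progression))
})

test_that("speed profiles baseline against the approach segments", {
  geom <- test_geometry()
  # constant-velocity crossing: all baselined values zero
  gt <- generate_crossing(geom, test_style(speed_factor = c(stable = 1,
                                                            unstable = 1)),
                          "stable", seed = 3)
  sp <- speed_profile(poses_from_gt(gt, geom), geom)
  expect_true(all(abs(sp$baselined) < 0.35))   # px quantization only

  # decelerating after the manipulated step: negative post-step values
  gtu <- generate_crossing(geom, test_style(), "unstable", seed = 3)
  spu <- speed_profile(poses_from_gt(gtu, geom), geom, "LR")
  post <- setdiff(seq_along(spu$baselined), spu$approach_segments)
  expect_true(all(spu$baselined[post[-1]] < 0))
})

test_that("speedup index arithmetic, identity and antisymmetry", {
  prof <- function(v) structure(list(baselined = v), class = "speed_profile")
  stable <- list(prof(c(0, 0, 2, 2)))
  unstable <- list(prof(c(0, 0, -1, -1)))
  expect_equal(speedup_index(stable, unstable), 6)
  expect_equal(speedup_index(stable, stable), 0)
  expect_equal(speedup_index(unstable, stable),
               -speedup_index(stable, unstable))
  # arithmetic example: speeds (10,10,10,20), 3 approach segments
  geom <- test_geometry()
  poses <- local({
    bounds <- seq(0, geom$course_length, length.out = 5)
    seg_t <- c(bounds[1:4] / 10, NA)
    seg_t[5] <- seg_t[4] + diff(bounds)[4] / 20
    tt <- seq(0, seg_t[5], by = 1 / geom$frame_rate)
    x <- stats::approx(seg_t, bounds, xout = tt)$y
    data.frame(frame = seq_along(tt) - 1, time_s = tt,
               nose_x = cm_to_px_x(geom, x), nose_y = 70, valid = TRUE)
  })
  sp <- speed_profile(poses, geom, n_segments = 4, approach = 1:3)
  expect_equal(sp$speed, c(10, 10, 10, 20), tolerance = 0.05)
  expect_equal(sp$baselined, c(0, 0, 0, 10), tolerance = 0.15)
})

test_that("jump probability and jumper classification", {
  geom <- test_geometry()
  crossings <- data.frame(crossing = 1:10)
  events <- data.frame(crossing = rep(1:10, each = 2),
                       step = rep(geom$center_steps, 10))
  expect_equal(jump_probability(events, crossings, geom)$probability, 0)

  # generator with jump strategy: recovered within the binomial 95% CI
  style <- test_style(p_jump = 0.8)
  skipped <- vapply(1:60, function(s) {
    gt <- generate_crossing(geom, style, "unstable", seed = s)
    !any(gt$contacts$step %in% geom$center_steps)
  }, logical(1))
  ci <- stats::binom.test(sum(skipped), 60)$conf.int
  expect_true(ci[1] <= 0.8 && 0.8 <= ci[2])

  stats_list <- list(structure(list(probability = 0.9), class = "jump_stats"),
                     structure(list(probability = 0.2), class = "jump_stats"))
  expect_equal(classify_jumpers(stats_list), c(TRUE, FALSE))
  expect_warning(classify_jumpers(list(0.9, 0.8)), "jumpers")
})
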