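# Shared fixtures: a scaled-down camera geometry (4 px/cm, 256x136 px,
# 50 Hz) keeps rendered-video tests fast while preserving all course
# proportions.

test_geometry <- function(frame_rate = 50)
  course_geometry(px_per_cm = 4, frame_size = c(256L, 136L),
                  frame_rate = frame_rate)

# a brisk crossing style so fixtures stay short
test_style <- function(...) crossing_style(approach_speed = 12, ...)

# rendered crossing fixture shared by tracking tests (built once per run)
.render_cache <- new.env(parent = emptyenv())
rendered_fixture <- function() {
  if (is.null(.render_cache$fix)) {
    geom <- test_geometry()
    gt <- generate_crossing(geom, test_style(), "stable", seed = 11)
    vid <- render_frames(gt, geom)
    .render_cache$fix <- list(geom = geom, gt = gt, frames = vid$frames,
                              background = vid$background)
  }
  .render_cache$fix
}

expect_within <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("%.6g within %.3g of %.6g", object, tol,
                              expected))
}
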