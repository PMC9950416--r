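# Frame renderer: high-contrast animal blob over a static background.
# The appearance model is deliberately minimal (ellipse body + triangular
# nose protrusion + paw disks at contacts); the tracker relies only on
# segmentation geometry, not on photorealism.

render_defaults <- function() {
  list(bg_base = 20, step_intensity = 45, body_intensity = 200,
       paw_intensity = c(left = 130, right = 235),
       body_semi_major = 5.5, body_semi_minor = 2.5, body_height = 4.5,
       nose_len = 2.5, nose_halfwidth = 0.8,
       paw_radius = 1.2, paw_height = 0.3, slip_depth = 0.5,
       contact_dur = 0.12, noise_sd = 0)
}

#' Static background frame for a course geometry
#'
#' @param geometry a [course_geometry()].
#' @param opts rendering options, see `render_frames()`.
#' @return an integer-valued intensity matrix (rows = y, cols = x).
#' @export
render_background <- function(geometry, opts = list()) {
  o <- utils::modifyList(render_defaults(), opts)
  w <- geometry$frame_size[1]; h <- geometry$frame_size[2]
  bg <- matrix(o$bg_base, nrow = h, ncol = w)
  se <- step_edges(geometry)
  y0 <- round(cm_to_px_y(geometry, 0))
  y1 <- min(h - 1L, round(cm_to_px_y(geometry, -2.5)))
  for (i in seq_len(nrow(se))) {
    xs <- round(cm_to_px_x(geometry, se$x0[i])):(round(cm_to_px_x(geometry, se$x1[i])) - 1L)
    bg[(y0:y1) + 1L, xs + 1L] <- o$step_intensity
  }
  bg
}

# draw a filled ellipse onto `img` (0-based center coordinates, px)
draw_ellipse_px <- function(img, cx, cy, a, b, val) {
  h <- nrow(img); w <- ncol(img)
  xs <- max(0L, floor(cx - a)):min(w - 1L, ceiling(cx + a))
  ys <- max(0L, floor(cy - b)):min(h - 1L, ceiling(cy + b))
  if (!length(xs) || !length(ys)) return(img)
  m <- outer(((ys - cy) / b)^2, ((xs - cx) / a)^2, "+") <= 1
  sub <- img[ys + 1L, xs + 1L, drop = FALSE]
  sub[m] <- val
  img[ys + 1L, xs + 1L] <- sub
  img
}

# triangle from a base centered at (xb, yb) to an apex at (xa, ya); the base
# half-height tapers linearly to the apex
draw_taper_px <- function(img, xb, yb, xa, ya, halfwidth, val) {
  h <- nrow(img); w <- ncol(img)
  xs <- max(0L, floor(min(xb, xa))):min(w - 1L, ceiling(max(xb, xa)))
  if (!length(xs) || xa == xb) return(img)
  s <- pmin(1, pmax(0, (xs - xb) / (xa - xb)))
  yc <- yb + s * (ya - yb)
  hw <- (1 - s) * halfwidth + 0.5
  for (i in seq_along(xs)) {
    ys <- max(0L, ceiling(yc[i] - hw[i])):min(h - 1L, floor(yc[i] + hw[i]))
    if (length(ys)) img[ys + 1L, xs[i] + 1L] <- val
  }
  img
}

#' Render a crossing as a stream of video frames
#'
#' Composites the animal (ellipse body, triangular nose protrusion whose
#' apex is the ground-truth nose point, paw disks during contacts and slips)
#' over the static background, one frame per nose-path sample. The blob is
#' brighter than the background by a configurable margin so that
#' segmentation depends only on the threshold choice.
#'
#' @param gt a `crossing_gt` from [generate_crossing()].
#' @param geometry a [course_geometry()].
#' @param opts named list overriding rendering defaults (intensities, body
#'   dimensions in cm, `contact_dur` s, `noise_sd`).
#' @param seed seed for the optional pixel noise.
#' @return list with `frames` (list of intensity matrices) and `background`.
#' @export
render_frames <- function(gt, geometry, opts = list(), seed = 1L) {
  o <- utils::modifyList(render_defaults(), opts)
  bg <- render_background(geometry, opts)
  w <- geometry$frame_size[1]; h <- geometry$frame_size[2]
  np <- gt$nose_path
  n <- nrow(np)
  dirsign <- if (identical(gt$direction, "RL")) -1 else 1
  se <- step_edges(geometry)
  ge <- gap_edges(geometry)
  ppc <- geometry$px_per_cm

  nx <- cm_to_px_x(geometry, np$x); ny <- cm_to_px_y(geometry, np$y)
  bad <- which(nx < 0 | nx > w - 1 | ny < 0 | ny > h - 1)
  if (length(bad))
    stop(sprintf("nose path exits frame bounds at frame %d", np$frame[bad[1]]))

  a <- o$body_semi_major * ppc; b <- o$body_semi_minor * ppc
  cy <- cm_to_px_y(geometry, o$body_height)
  nose_len <- o$nose_len * ppc
  paw_r <- o$paw_radius * ppc

  dur_frames <- max(1L, round(o$contact_dur * geometry$frame_rate))
  active <- function(events, frame) {
    if (!nrow(events)) return(events[0, , drop = FALSE])
    events[events$frame <= frame & frame < events$frame + dur_frames, ,
           drop = FALSE]
  }
  frames <- with_seed(seed, lapply(seq_len(n), function(i) {
    f <- bg
    fr <- np$frame[i]
    cx <- nx[i] - dirsign * (nose_len + a)
    f <- draw_ellipse_px(f, cx, cy, a, b, o$body_intensity)
    f <- draw_taper_px(f, cx + dirsign * a, cy, nx[i], ny[i],
                       o$nose_halfwidth * ppc, o$body_intensity)
    ct <- active(gt$contacts, fr)
    for (j in seq_len(nrow(ct))) {
      px <- cm_to_px_x(geometry, se$x0[ct$step[j]] + geometry$step_width / 2)
      py <- cm_to_px_y(geometry, o$paw_height)
      f <- draw_ellipse_px(f, px, py, paw_r, paw_r,
                           o$paw_intensity[[ct$side[j]]])
    }
    sl <- active(gt$slips, fr)
    for (j in seq_len(nrow(sl))) {
      px <- cm_to_px_x(geometry, (ge$x0[sl$gap[j]] + ge$x1[sl$gap[j]]) / 2)
      py <- cm_to_px_y(geometry, -o$slip_depth)
      f <- draw_ellipse_px(f, px, py, paw_r, paw_r, o$paw_intensity[["left"]])
    }
    if (o$noise_sd > 0)
      f <- f + matrix(stats::rnorm(length(f), 0, o$noise_sd), nrow = h)
    f
  }))
  list(frames = frames, background = bg)
}
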