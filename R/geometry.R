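#' Obstacle-course geometry
#'
#' Describes the physical course and the camera calibration used to convert
#' between world coordinates (cm) and image coordinates (px). The default
#' course is 48 cm long with eight 2 cm steps spaced by 4 cm gaps; the two
#' interior "center" steps are the ones whose rotational stability is
#' manipulated. The default camera is 1280x680 px at 120 Hz.
#'
#' World coordinates place x = 0 at the left end of the course structure and
#' measure height y upward from the step surface plane (y = 0). Image
#' coordinates are 0-based with origin at the top-left corner, x rightward
#' and y downward; conversions negate y so that reported heights are upward.
#'
#' @param n_steps number of steps.
#' @param step_width step surface width, cm.
#' @param gap_width gap between consecutive steps, cm.
#' @param course_length total course length, cm; the step/gap ladder is
#'   centered inside it.
#' @param center_steps indices of the two adjacent interior manipulated steps.
#' @param px_per_cm camera calibration factor.
#' @param frame_size frame `c(width, height)` in px.
#' @param frame_rate acquisition rate, Hz.
#' @param surface_frac vertical position of the step-surface plane as a
#'   fraction of frame height (from the top).
#' @return an object of class `course_geometry`.
#' @export
course_geometry <- function(n_steps = 8L, step_width = 2, gap_width = 4,
                            course_length = 48, center_steps = NULL,
                            px_per_cm = 20, frame_size = c(1280L, 680L),
                            frame_rate = 120, surface_frac = 0.75) {
  n_steps <- as.integer(n_steps)
  if (n_steps < 2L) stop("n_steps must be >= 2")
  if (step_width <= 0 || gap_width <= 0 || course_length <= 0)
    stop("all lengths must be positive")
  if (px_per_cm <= 0) stop("px_per_cm must be positive")
  ladder <- n_steps * step_width + (n_steps - 1L) * gap_width
  if (ladder > course_length)
    stop("steps and gaps do not fit in course_length")
  if (is.null(center_steps)) {
    k <- n_steps %/% 2L
    center_steps <- c(k, k + 1L)
  }
  center_steps <- sort(as.integer(center_steps))
  if (length(center_steps) != 2L || diff(center_steps) != 1L ||
      center_steps[1] < 2L || center_steps[2] > n_steps - 1L)
    stop("center_steps must be two adjacent interior step indices")
  g <- list(
    n_steps = n_steps, step_width = step_width, gap_width = gap_width,
    course_length = course_length, center_steps = center_steps,
    px_per_cm = px_per_cm,
    frame_size = as.integer(frame_size), frame_rate = frame_rate,
    surface_frac = surface_frac,
    # left margin between course x=0 and the first step's near edge
    ladder_offset = (course_length - ladder) / 2
  )
  class(g) <- "course_geometry"
  g
}

#' @export
print.course_geometry <- function(x, ...) {
  cat(sprintf(
    "<course_geometry> %d steps of %.3g cm, gaps %.3g cm, course %.3g cm\n",
    x$n_steps, x$step_width, x$gap_width, x$course_length))
  cat(sprintf("  center steps: %d-%d; %.3g px/cm; %dx%d px @ %.4g Hz\n",
              x$center_steps[1], x$center_steps[2], x$px_per_cm,
              x$frame_size[1], x$frame_size[2], x$frame_rate))
  invisible(x)
}

#' Step and gap edges in course coordinates
#'
#' @param geometry a [course_geometry()].
#' @return `step_edges()`: data frame with `step`, `x0`, `x1` (cm);
#'   `gap_edges()`: data frame with `gap`, `x0`, `x1` where gap `k` lies
#'   between steps `k` and `k + 1`.
#' @export
step_edges <- function(geometry) {
  k <- seq_len(geometry$n_steps)
  pitch <- geometry$step_width + geometry$gap_width
  x0 <- geometry$ladder_offset + (k - 1) * pitch
  data.frame(step = k, x0 = x0, x1 = x0 + geometry$step_width)
}

#' @rdname step_edges
#' @export
gap_edges <- function(geometry) {
  se <- step_edges(geometry)
  n <- nrow(se)
  data.frame(gap = seq_len(n - 1L), x0 = se$x1[-n], x1 = se$x0[-1L])
}

# world (cm) <-> image (px) conversions. World x is centered in the frame.
world_margin <- function(geometry) {
  (geometry$frame_size[1] / geometry$px_per_cm - geometry$course_length) / 2
}

#' Convert between course (cm) and image (px) coordinates
#'
#' Image x and y are 0-based pixel coordinates; world heights are measured
#' upward from the step-surface plane.
#' @param geometry a [course_geometry()].
#' @param x,y world coordinates (cm) or image coordinates (px).
#' @return numeric vector of converted coordinates.
#' @export
cm_to_px_x <- function(geometry, x) (x + world_margin(geometry)) * geometry$px_per_cm

#' @rdname cm_to_px_x
#' @export
px_to_cm_x <- function(geometry, x) x / geometry$px_per_cm - world_margin(geometry)

surface_row <- function(geometry) geometry$surface_frac * geometry$frame_size[2]

#' @rdname cm_to_px_x
#' @export
cm_to_px_y <- function(geometry, y) surface_row(geometry) - y * geometry$px_per_cm

#' @rdname cm_to_px_x
#' @export
px_to_cm_y <- function(geometry, y) (surface_row(geometry) - y) / geometry$px_per_cm

#' Regions of interest around step surfaces and gaps
#'
#' Builds one axis-aligned rectangular ROI over the surface of each step (a
#' band just above the surface plane, where a planted paw appears) and one in
#' each gap (a band straddling the surface plane, where a slipping paw
#' appears). Coordinates are inclusive integer pixel bounds.
#'
#' @param geometry a [course_geometry()].
#' @param surface_band height of the step-surface band above the surface, cm.
#' @param gap_depth depth of the gap band below the surface, cm.
#' @param gap_rise rise of the gap band above the surface, cm.
#' @return data frame with `label`, `role` ("surface"/"gap"), `index`,
#'   `x0`, `x1`, `y0`, `y1` (px, inclusive).
#' @export
course_rois <- function(geometry, surface_band = 1.5, gap_depth = 1.5,
                        gap_rise = 0.5) {
  se <- step_edges(geometry)
  ge <- gap_edges(geometry)
  rect <- function(x0, x1, ytop, ybot) {
    c(round(cm_to_px_x(geometry, x0)), round(cm_to_px_x(geometry, x1)) - 1L,
      round(cm_to_px_y(geometry, ytop)), round(cm_to_px_y(geometry, ybot)) - 1L)
  }
  rows <- vector("list", nrow(se) + nrow(ge))
  for (i in seq_len(nrow(se))) {
    r <- rect(se$x0[i], se$x1[i], surface_band, 0)
    rows[[i]] <- data.frame(label = sprintf("step_%d_surface", i),
                            role = "surface", index = i,
                            x0 = r[1], x1 = r[2], y0 = r[3], y1 = r[4])
  }
  for (i in seq_len(nrow(ge))) {
    r <- rect(ge$x0[i], ge$x1[i], gap_rise, -gap_depth)
    rows[[nrow(se) + i]] <- data.frame(label = sprintf("gap_%d", i),
                                       role = "gap", index = i,
                                       x0 = r[1], x1 = r[2], y0 = r[3], y1 = r[4])
  }
  rois <- do.call(rbind, rows)
  w <- geometry$frame_size[1]; h <- geometry$frame_size[2]
  if (any(rois$x0 < 0 | rois$x1 >= w | rois$y0 < 0 | rois$y1 >= h))
    stop("ROI outside frame bounds; check px_per_cm / frame_size")
  rois
}
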