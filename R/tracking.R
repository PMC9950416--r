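# Video tracking: background subtraction, 8-connected component labeling,
# moment-based ellipse fit, nose-tip extraction, ROI activation traces.

#' Temporal-median background model
#'
#' Pixel-wise temporal median of the provided (typically subsampled) frames.
#' With the animal present in fewer than half the sampled frames at any
#' pixel, the median recovers the empty arena exactly.
#'
#' @param frames list of intensity matrices of identical dimensions.
#' @return list of class `background_model` with `image` and `method`.
#' @export
estimate_background <- function(frames) {
  if (!length(frames)) stop("need at least one frame")
  dims <- dim(frames[[1]])
  arr <- array(unlist(frames, use.names = FALSE),
               dim = c(dims[1], dims[2], length(frames)))
  img <- apply(arr, c(1, 2), stats::median)
  structure(list(image = img, method = "temporal_median"),
            class = "background_model")
}

#' Label connected components (8-connectivity)
#'
#' Run-based two-pass labeling with union-find merging. Exported because
#' segmentation behavior (8- vs 4-connectivity) is part of the tracking
#' contract.
#'
#' @param mask logical matrix.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  prev_runs <- NULL   # matrix: start col, end col, label (runs of row above)
  for (r in seq_len(h)) {
    row <- mask[r, ]
    if (!any(row)) { prev_runs <- NULL; next }
    d <- diff(c(FALSE, row, FALSE))
    starts <- which(d == 1); ends <- which(d == -1) - 1L
    runs <- matrix(0L, nrow = length(starts), ncol = 3)
    for (k in seq_along(starts)) {
      lab <- 0L
      if (!is.null(prev_runs)) {
        # 8-connectivity: runs touching within one column diagonal overlap
        touch <- which(prev_runs[, 1] <= ends[k] + 1L &
                       prev_runs[, 2] >= starts[k] - 1L)
        for (t in touch) {
          tl <- find(prev_runs[t, 3])
          if (lab == 0L) lab <- tl
          else if (tl != lab) parent[tl] <- lab   # union: keep lab as root
        }
      }
      if (lab == 0L) {
        parent[length(parent) + 1L] <- length(parent) + 1L
        lab <- length(parent)
      }
      labels[r, starts[k]:ends[k]] <- lab
      runs[k, ] <- c(starts[k], ends[k], lab)
    }
    prev_runs <- runs
  }
  if (!length(parent)) return(labels)
  # resolve equivalences to consecutive component ids
  roots <- vapply(seq_along(parent), find, 1L)
  ids <- match(roots, unique(roots))
  nz <- labels != 0L
  labels[nz] <- ids[labels[nz]]
  labels
}

#' Segment the animal as the largest connected component
#'
#' Thresholds the absolute difference between a frame and the background,
#' labels 8-connected components, and returns the largest one if it meets
#' the minimum area.
#'
#' @param frame intensity matrix.
#' @param background a `background_model` (or plain matrix).
#' @param threshold intensity difference threshold (> 0).
#' @param min_area smallest acceptable component area, px.
#' @return list with `mask` (logical matrix), `area`, or `NULL` when no
#'   component qualifies.
#' @export
segment_animal <- function(frame, background, threshold, min_area = 20L) {
  if (threshold <= 0) stop("threshold must be positive")
  bg <- if (inherits(background, "background_model")) background$image else background
  if (!all(dim(frame) == dim(bg))) stop("frame/background dimensions differ")
  mask <- abs(frame - bg) > threshold
  if (!any(mask)) return(NULL)
  labels <- label_components(mask)
  tab <- tabulate(labels[labels > 0L])
  best <- which.max(tab)
  if (tab[best] < min_area) return(NULL)
  list(mask = labels == best, area = tab[best])
}

#' Ellipse fit from image moments
#'
#' Centroid, principal axes and orientation from the second-order central
#' moments of a binary component. For a filled ideal ellipse the principal
#' standard deviations are half the semi-axes, so semi-axes are reported as
#' `2 * sqrt(eigenvalue)`.
#'
#' @param mask logical matrix (the component).
#' @return list with `cx`, `cy` (0-based px), `major`, `minor` (semi-axes,
#'   px), `orientation` (radians in `[0, pi)`, measured from the +x axis
#'   toward +y, i.e. image-downward), `degenerate` flag.
#' @export
fit_ellipse <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  if (n < 5L) stop("component area must be at least 5 px")
  y <- idx[, 1] - 1; x <- idx[, 2] - 1
  cx <- mean(x); cy <- mean(y)
  # add the 1/12 variance of a unit pixel so single-row masks stay finite
  cxx <- mean((x - cx)^2) + 1 / 12
  cyy <- mean((y - cy)^2) + 1 / 12
  cxy <- mean((x - cx) * (y - cy))
  e <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2), symmetric = TRUE)
  major <- 2 * sqrt(max(e$values[1], 0))
  minor <- 2 * sqrt(max(e$values[2], 0))
  v <- e$vectors[, 1]
  orientation <- atan2(v[2], v[1]) %% pi
  list(cx = cx, cy = cy, major = major, minor = minor,
       orientation = orientation, degenerate = minor < 1e-6)
}

#' Extract the nose tip from a segmented animal
#'
#' The nose is the mask pixel with the largest signed projection onto the
#' ellipse's major axis, with the axis direction disambiguated by the
#' expected travel heading. Projection ties are broken by distance to the
#' axis line.
#'
#' @param mask logical matrix.
#' @param ellipse a [fit_ellipse()] result.
#' @param heading expected travel direction: +1 (image +x), -1, or a length-2
#'   direction vector.
#' @return list with `x`, `y` (0-based px).
#' @export
extract_nose <- function(mask, ellipse, heading = 1) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty mask")
  y <- idx[, 1] - 1; x <- idx[, 2] - 1
  u <- c(cos(ellipse$orientation), sin(ellipse$orientation))
  hv <- if (length(heading) == 2L) heading else c(heading, 0)
  if (sum(u * hv) < 0) u <- -u
  proj <- (x - ellipse$cx) * u[1] + (y - ellipse$cy) * u[2]
  perp <- abs(-(x - ellipse$cx) * u[2] + (y - ellipse$cy) * u[1])
  best <- which(proj == max(proj))
  if (length(best) > 1L) best <- best[which.min(perp[best])]
  list(x = x[best], y = y[best])
}

#' Background-subtracted ROI activation traces
#'
#' Per frame and per ROI, the sum of the thresholded absolute difference
#' from the background over the ROI's pixels.
#'
#' @param frames list of intensity matrices.
#' @param background a `background_model` or matrix.
#' @param rois ROI table from [course_rois()] (inclusive 0-based px bounds).
#' @param threshold intensity difference threshold.
#' @return object of class `roi_traces` (frames x ROIs matrix in `values`).
#' @export
compute_activations <- function(frames, background, rois, threshold) {
  if (threshold <= 0) stop("threshold must be positive")
  bg <- if (inherits(background, "background_model")) background$image else background
  roi_rows <- lapply(seq_len(nrow(rois)), function(i)
    (rois$y0[i]:rois$y1[i]) + 1L)
  roi_cols <- lapply(seq_len(nrow(rois)), function(i)
    (rois$x0[i]:rois$x1[i]) + 1L)
  values <- matrix(0, nrow = length(frames), ncol = nrow(rois),
                   dimnames = list(NULL, rois$label))
  for (f in seq_along(frames)) {
    d <- abs(frames[[f]] - bg)
    d[d <= threshold] <- 0
    for (i in seq_len(nrow(rois)))
      values[f, i] <- sum(d[roi_rows[[i]], roi_cols[[i]]])
  }
  structure(list(values = values, rois = rois, frame_rate = NA_real_),
            class = "roi_traces")
}

#' Track a frame stream
#'
#' Runs segmentation, ellipse fitting and nose extraction on every frame and
#' computes ROI activation traces. Frames with no acceptable component yield
#' invalid pose samples. The heading used to disambiguate the nose end of
#' the major axis is the sign of the recent centroid displacement, falling
#' back to `fallback_heading` until movement is observed.
#'
#' @param frames list of intensity matrices.
#' @param background a `background_model` or matrix.
#' @param rois ROI table from [course_rois()]; `NULL` skips traces.
#' @param threshold segmentation threshold.
#' @param min_area minimum component area, px.
#' @param fallback_heading heading before movement is observed (+1/-1).
#' @param frame_rate frames per second for the `time_s` column.
#' @return list with `poses` (data frame: `frame`, `time_s`, `nose_x`,
#'   `nose_y`, `cx`, `cy`, `major`, `minor`, `orientation`, `valid`) and
#'   `activations` (a `roi_traces` or `NULL`).
#' @export
track <- function(frames, background, rois = NULL, threshold,
                  min_area = 20L, fallback_heading = 1, frame_rate = NA_real_) {
  n <- length(frames)
  poses <- data.frame(frame = seq_len(n) - 1L,
                      time_s = (seq_len(n) - 1L) / frame_rate,
                      nose_x = NA_real_, nose_y = NA_real_,
                      cx = NA_real_, cy = NA_real_,
                      major = NA_real_, minor = NA_real_,
                      orientation = NA_real_, valid = FALSE)
  last_cx <- NA_real_
  heading <- fallback_heading
  for (f in seq_len(n)) {
    comp <- segment_animal(frames[[f]], background, threshold, min_area)
    if (is.null(comp)) { last_cx <- NA_real_; next }
    ell <- fit_ellipse(comp$mask)
    if (!is.na(last_cx) && abs(ell$cx - last_cx) > 1e-9)
      heading <- sign(ell$cx - last_cx)
    nose <- extract_nose(comp$mask, ell, heading)
    poses[f, c("nose_x", "nose_y", "cx", "cy", "major", "minor",
               "orientation")] <-
      c(nose$x, nose$y, ell$cx, ell$cy, ell$major, ell$minor, ell$orientation)
    poses$valid[f] <- TRUE
    last_cx <- ell$cx
  }
  activations <- if (!is.null(rois))
    compute_activations(frames, background, rois, threshold) else NULL
  if (!is.null(activations)) activations$frame_rate <- frame_rate
  list(poses = poses, activations = activations)
}
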