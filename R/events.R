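# Event detection: crossings from pose runs, paw-step events from ROI
# activation derivatives with a head-position plausibility constraint, slip
# candidate screening, label joining, and K-means paw-side classification.

#' Extract crossings from a pose sequence
#'
#' Maximal runs of valid poses (tolerating short gaps) whose first and last
#' nose x positions fall on opposite sides of the course midline become
#' crossings; other runs are discarded.
#'
#' @param poses pose table (`frame`, `nose_x`, `valid`, optional `time_s`).
#' @param geometry a [course_geometry()].
#' @param max_gap_s longest tolerated run of invalid poses inside a
#'   crossing, seconds.
#' @return data frame with `crossing`, `start_frame`, `end_frame`,
#'   `direction` ("LR"/"RL").
#' @export
extract_crossings <- function(poses, geometry, max_gap_s = 0.25) {
  gap_frames <- max(0L, round(max_gap_s * geometry$frame_rate))
  valid_idx <- which(poses$valid)
  out <- data.frame(crossing = integer(0), start_frame = integer(0),
                    end_frame = integer(0), direction = character(0))
  if (!length(valid_idx)) return(out)
  brk <- which(diff(valid_idx) > gap_frames + 1L)
  run_start <- valid_idx[c(1L, brk + 1L)]
  run_end <- valid_idx[c(brk, length(valid_idx))]
  midline <- cm_to_px_x(geometry, geometry$course_length / 2)
  rows <- list()
  for (i in seq_along(run_start)) {
    seg <- poses[run_start[i]:run_end[i], ]
    seg <- seg[seg$valid, ]
    x0 <- seg$nose_x[1]; x1 <- seg$nose_x[nrow(seg)]
    if ((x0 - midline) * (x1 - midline) >= 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      start_frame = seg$frame[1], end_frame = seg$frame[nrow(seg)],
      direction = if (x1 > x0) "LR" else "RL")
  }
  if (!length(rows)) return(out)
  res <- do.call(rbind, rows)
  cbind(crossing = seq_len(nrow(res)), res)
}

# derivative-peak candidates: local maxima of the first difference that
# exceed the threshold; plateaus yield their earliest frame
derivative_peaks <- function(trace, threshold) {
  d <- diff(trace)
  n <- length(d)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  peaks <- i[d[i] > threshold & d[i] > d[i - 1L] & d[i] >= d[i + 1L]]
  # d[k] is the rise into frame k (0-based frame index = k)
  as.integer(peaks)
}

#' Default derivative threshold for a trace
#'
#' Five times the median absolute first difference (a robust noise scale);
#' when the trace's baseline is noiseless this falls back to 5% of the
#' largest rise.
#'
#' @param trace numeric activation trace.
#' @return threshold value (> 0), or `NA` for a flat trace.
#' @export
default_step_threshold <- function(trace) {
  d <- abs(diff(trace))
  med <- stats::median(d)
  thr <- 5 * med
  if (thr <= 0) thr <- 0.05 * max(d)
  if (!is.finite(thr) || thr <= 0) NA_real_ else thr
}

#' Detect the paw-step moment on one activation trace
#'
#' The step moment is the first supra-threshold peak of the trace's first
#' derivative within the crossing window.
#'
#' @param trace numeric activation trace (full recording, one ROI).
#' @param crossing one row of [extract_crossings()] output (or `NULL` for
#'   the whole trace).
#' @param threshold derivative threshold; default from
#'   [default_step_threshold()].
#' @return 0-based candidate frame, or `NA` when no peak qualifies.
#' @export
detect_step <- function(trace, crossing = NULL, threshold = NULL) {
  frames <- detect_step_candidates(trace, crossing, threshold)
  if (length(frames)) frames[1] else NA_integer_
}

#' @rdname detect_step
#' @param min_gap candidate peaks closer than this many frames to the
#'   previous kept candidate merge into it (an activation pulse's rise can
#'   split into neighboring derivative maxima under noise); the default
#'   covers an activation pulse's rise and plateau at typical frame rates.
#' @return `detect_step_candidates()`: all qualifying 0-based frames in
#'   order.
#' @export
detect_step_candidates <- function(trace, crossing = NULL, threshold = NULL,
                                   min_gap = 10L) {
  if (is.null(threshold)) threshold <- default_step_threshold(trace)
  if (is.na(threshold)) return(integer(0))
  if (threshold <= 0) stop("threshold must be positive")
  lo <- 1L; hi <- length(trace)
  if (!is.null(crossing)) {
    lo <- max(1L, crossing$start_frame + 1L)
    hi <- min(hi, crossing$end_frame + 1L)
  }
  if (hi - lo < 3L) return(integer(0))
  peaks <- derivative_peaks(trace[lo:hi], threshold)
  if (length(peaks) > 1L) {
    keep <- peaks[1]
    for (p in peaks[-1]) if (p - keep[length(keep)] >= min_gap)
      keep <- c(keep, p)
    peaks <- keep
  }
  peaks + (lo - 1L)   # back to 0-based frames of the full trace
}

#' Validate a step candidate with the head-position constraint
#'
#' A genuine forelimb contact happens while the head has not yet passed the
#' next step: the nose (or, optionally, the body centroid) at the candidate
#' frame must lie before the near edge of the next step in the direction of
#' travel. Hindlimb and tail activations occur when the head is further
#' ahead and are rejected.
#'
#' @param candidate_frame 0-based frame of the candidate.
#' @param step_index index of the contacted step.
#' @param poses pose table.
#' @param geometry a [course_geometry()].
#' @param direction crossing direction ("LR"/"RL").
#' @param use "nose" (default) or "centroid" as the head position.
#' @return list with `accepted`, `reason` ("none", "head_ahead",
#'   "no_pose"), `frame`, `step`.
#' @export
validate_step <- function(candidate_frame, step_index, poses, geometry,
                          direction = "LR", use = c("nose", "centroid")) {
  use <- match.arg(use)
  row <- poses[poses$frame == candidate_frame, , drop = FALSE]
  if (!nrow(row) || !row$valid[1])
    return(list(accepted = FALSE, reason = "no_pose",
                frame = candidate_frame, step = step_index))
  head_x <- if (use == "nose") row$nose_x[1] else row$cx[1]
  head_cm <- px_to_cm_x(geometry, head_x)
  se <- step_edges(geometry)
  if (direction == "LR") {
    bound <- if (step_index < geometry$n_steps) se$x0[step_index + 1L]
             else geometry$course_length
    ok <- head_cm < bound
  } else {
    bound <- if (step_index > 1L) se$x1[step_index - 1L] else 0
    ok <- head_cm > bound
  }
  list(accepted = ok, reason = if (ok) "none" else "head_ahead",
       frame = candidate_frame, step = step_index)
}

#' Detect slip candidates on gap ROI traces
#'
#' Every supra-threshold derivative peak on a gap ROI becomes a candidate;
#' the head-position constraint is deliberately relaxed so that no genuine
#' slip can be missed (at the cost of false positives, which are resolved by
#' annotation, see [apply_slip_labels()]).
#'
#' @param traces a `roi_traces` object (gap ROIs are selected by role).
#' @param threshold derivative threshold; default per-trace via
#'   [default_step_threshold()].
#' @param crossings optional crossing table to restrict the search and tag
#'   candidates.
#' @return data frame with `candidate_id`, `frame`, `gap`, `crossing`.
#' @export
detect_slip_candidates <- function(traces, threshold = NULL, crossings = NULL) {
  gaps <- which(traces$rois$role == "gap")
  rows <- list()
  windows <- if (is.null(crossings)) data.frame(crossing = NA_integer_)
             else crossings
  for (g in gaps) {
    tr <- traces$values[, g]
    for (w in seq_len(nrow(windows))) {
      cr <- if (is.null(crossings)) NULL else windows[w, ]
      frames <- detect_step_candidates(tr, cr, threshold)
      for (f in frames)
        rows[[length(rows) + 1L]] <- data.frame(
          frame = f, gap = traces$rois$index[g],
          crossing = windows$crossing[w])
    }
  }
  if (!length(rows))
    return(data.frame(candidate_id = integer(0), frame = integer(0),
                      gap = integer(0), crossing = integer(0)))
  res <- do.call(rbind, rows)
  res <- res[order(res$frame, res$gap), , drop = FALSE]
  cbind(candidate_id = seq_len(nrow(res)), res, row.names = NULL)
}

#' Join manual slip verdicts onto candidates
#'
#' @param candidates output of [detect_slip_candidates()].
#' @param labels data frame `candidate_id`, `verdict` ("genuine", "tail",
#'   "head", "exploration"), optional `limb`. Candidates without a label
#'   remain unconfirmed.
#' @return data frame of slip events: candidates plus `confirmed`,
#'   `reject_reason`, `limb`.
#' @export
apply_slip_labels <- function(candidates, labels) {
  unknown <- setdiff(labels$candidate_id, candidates$candidate_id)
  if (length(unknown))
    stop("labels reference unknown candidate ids: ",
         paste(unknown, collapse = ", "))
  m <- match(candidates$candidate_id, labels$candidate_id)
  verdict <- ifelse(is.na(m), "unlabeled", labels$verdict[m])
  out <- candidates
  out$confirmed <- verdict == "genuine"
  out$reject_reason <- ifelse(out$confirmed | verdict == "unlabeled",
                              "none", verdict)
  out$limb <- if (!is.null(labels$limb)) {
    ifelse(is.na(m), NA_character_, labels$limb[m])
  } else NA_character_
  out
}

#' Classify the stepping paw side from frame brightness histograms
#'
#' Encodes each step-aligned frame as its brightness histogram and
#' partitions the encodings with seeded, restarted K-means (k = 2). The
#' cluster-to-side mapping comes from `reference`: either a named mapping
#' (`c("1" = "left", "2" = "right")`) or a partial vector of known side
#' labels (NA where unknown), from which the majority mapping is inferred;
#' the same mechanism supports manual correction.
#'
#' @param frames list of intensity matrices (one per step event).
#' @param k number of clusters.
#' @param bins histogram bin count.
#' @param range intensity range spanned by the histogram.
#' @param seed seed for K-means initialization.
#' @param nstart K-means restarts.
#' @param reference mapping or partial labels (see above); `NULL` leaves
#'   cluster ids unmapped.
#' @return list with `cluster` (per frame), `side` (per frame, or cluster
#'   id as character when unmapped), `degenerate` flag (fewer than `k`
#'   distinct encodings).
#' @export
classify_paw_side <- function(frames, k = 2L, bins = 32L, range = c(0, 255),
                              seed = 1L, nstart = 10L, reference = NULL) {
  if (length(frames) < k) stop("need at least k frames")
  breaks <- seq(range[1], range[2], length.out = bins + 1L)
  enc <- t(vapply(frames, function(f) {
    h <- graphics::hist(pmin(pmax(as.numeric(f), range[1]), range[2]),
                        breaks = breaks, plot = FALSE)
    h$counts / length(f)
  }, numeric(bins)))
  if (nrow(unique(enc)) < k)
    return(list(cluster = rep(1L, length(frames)), side = NULL,
                degenerate = TRUE))
  km <- with_seed(seed, stats::kmeans(enc, centers = k, nstart = nstart))
  cluster <- km$cluster
  side <- as.character(cluster)
  if (!is.null(reference)) {
    if (!is.null(names(reference))) {
      side <- unname(reference[as.character(cluster)])
    } else {
      map <- character(k)
      for (cl in seq_len(k)) {
        known <- reference[cluster == cl]
        known <- known[!is.na(known)]
        map[cl] <- if (length(known)) names(which.max(table(known)))
                   else NA_character_
      }
      side <- map[cluster]
    }
  }
  list(cluster = cluster, side = side, degenerate = FALSE)
}
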