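# Direct ROI activation-trace synthesis: a lightweight alternative to
# rendering + measuring video, sharing the same ground-truth contract.

#' Synthesize ROI activation traces from ground truth
#'
#' Each paw contact appears on the corresponding step-surface ROI, and each
#' slip on its gap ROI, as a rectangular activation pulse smoothed by a
#' short moving average (so the trace's first derivative has a single clear
#' rising-edge peak per event). Baseline is zero plus bounded
#' (uniform) sensor noise, clipped at zero as activation energies are
#' non-negative; bounded noise keeps the derivative-peak detector's robust
#' default threshold strictly above the largest possible noise step.
#'
#' @param gt a `crossing_gt` from [generate_crossing()].
#' @param geometry a [course_geometry()].
#' @param amplitude pulse amplitude, activation units.
#' @param pulse_dur pulse duration, s.
#' @param smooth moving-average width, frames (odd).
#' @param noise_amp baseline noise amplitude (uniform on `[-noise_amp,
#'   noise_amp]`).
#' @param seed seed for the noise.
#' @return object of class `roi_traces`: list with `values` (frames x ROIs
#'   matrix, ROI labels as column names), `rois` and `frame_rate`.
#' @export
synthesize_roi_traces <- function(gt, geometry, amplitude = 100,
                                  pulse_dur = 0.12, smooth = 3L,
                                  noise_amp = 1, seed = 1L) {
  rois <- course_rois(geometry)
  n <- nrow(gt$nose_path)
  values <- matrix(0, nrow = n, ncol = nrow(rois),
                   dimnames = list(NULL, rois$label))
  dur <- max(1L, round(pulse_dur * geometry$frame_rate))

  add_pulse <- function(values, col, frame) {
    f0 <- frame + 1L                      # frames are 0-based
    f1 <- min(n, f0 + dur - 1L)
    values[f0:f1, col] <- values[f0:f1, col] + amplitude
    values
  }
  roi_col <- function(role, index) {
    j <- which(rois$role == role & rois$index == index)
    if (!length(j)) stop(sprintf("no %s ROI with index %d", role, index))
    j
  }
  for (i in seq_len(nrow(gt$contacts)))
    values <- add_pulse(values, roi_col("surface", gt$contacts$step[i]),
                        gt$contacts$frame[i])
  for (i in seq_len(nrow(gt$slips)))
    values <- add_pulse(values, roi_col("gap", gt$slips$gap[i]),
                        gt$slips$frame[i])

  if (smooth > 1L) {
    k <- rep(1 / smooth, smooth)
    values <- apply(values, 2, function(v)
      as.numeric(stats::filter(v, k, sides = 2, circular = FALSE)))
    values[is.na(values)] <- 0
  }
  if (noise_amp > 0)
    values <- with_seed(seed,
      values + matrix(stats::runif(length(values), -noise_amp, noise_amp),
                      nrow = n))
  values <- pmax(values, 0)
  structure(list(values = values, rois = rois,
                 frame_rate = geometry$frame_rate),
            class = "roi_traces")
}
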