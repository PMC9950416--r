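# Frame-synchronized evoked-potential analysis: strobe/counter mapping,
# epoch extraction, zero-phase low-pass filtering, baselining, bad-channel
# exclusion, condition averaging and peak measurement.

#' Map video frames to recording samples via the camera strobe
#'
#' Detects falling edges in the strobe trace (threshold at half the signal
#' range, one-sample debounce) and pairs each edge's sample index with the
#' hardware frame counter captured for that exposure. Dropped frames leave
#' holes in the map rather than being interpolated; counter wraparound is
#' resolved by monotone unwrapping.
#'
#' @param strobe numeric strobe trace.
#' @param frame_counters integer hardware counter per detected edge
#'   (possibly wrapped).
#' @param counter_mod wrap modulus of the hardware counter.
#' @return list of class `frame_sample_map`: `frame` (unwrapped, 0-based),
#'   `sample` (1-based sample index of the edge).
#' @export
build_frame_sample_map <- function(strobe, frame_counters,
                                   counter_mod = 2^16) {
  thr <- (max(strobe) + min(strobe)) / 2
  below <- strobe < thr
  edges <- which(!below[-length(below)] & below[-1L]) + 1L
  # one-sample debounce: drop edges that follow another within one sample
  if (length(edges) > 1L) edges <- edges[c(TRUE, diff(edges) > 1L)]
  if (length(frame_counters) > length(edges))
    stop(sprintf("more counters (%d) than strobe edges (%d)",
                 length(frame_counters), length(edges)))
  counters <- as.numeric(frame_counters)
  wraps <- cumsum(c(0, diff(counters) < 0))
  frames <- counters + wraps * counter_mod
  frames <- frames - frames[1]
  if (any(diff(frames) <= 0)) stop("frame counters not strictly increasing")
  structure(list(frame = as.integer(frames),
                 sample = edges[seq_along(frames)]),
            class = "frame_sample_map")
}

#' Look up the sample index of a frame
#'
#' @param map a `frame_sample_map`.
#' @param frame 0-based frame indices.
#' @return 1-based sample indices (`NA` for unmapped/dropped frames).
#' @export
frame_to_sample <- function(map, frame) {
  map$sample[match(frame, map$frame)]
}

#' Extract event-aligned epochs
#'
#' Cuts the recording into windows around each event's sample (250 ms
#' before to 500 ms after contact by default, 750 ms total). Events whose
#' window would leave the recording, or whose frame is missing from the
#' map, are skipped and reported in the `skipped` attribute.
#'
#' @param recording an `ecog_recording` (or any list with `samples` and
#'   `sample_rate`).
#' @param events data frame with `frame` plus metadata columns (`side`,
#'   `state`, ...).
#' @param map a [build_frame_sample_map()] result.
#' @param pre_ms,post_ms window extent around the event, ms.
#' @return list of class `epoch_set`: `data` (epochs x channels x time
#'   array), `times_ms` (relative to the event), `meta` (admitted events),
#'   `sample_rate`; skipped events in `attr(, "skipped")`.
#' @export
extract_epochs <- function(recording, events, map, pre_ms = 250,
                           post_ms = 500) {
  fs <- recording$sample_rate
  pre <- round(pre_ms / 1000 * fs)
  post <- round(post_ms / 1000 * fs)
  n <- ncol(recording$samples)
  s0 <- frame_to_sample(map, events$frame)
  ok <- !is.na(s0) & s0 - pre >= 1 & s0 + post - 1 <= n
  if (!any(ok)) stop("no admissible events (all windows leave the recording)")
  idx <- which(ok)
  n_ch <- nrow(recording$samples)
  len <- pre + post
  data <- array(NA_real_, dim = c(length(idx), n_ch, len))
  for (e in seq_along(idx)) {
    s <- s0[idx[e]]
    data[e, , ] <- recording$samples[, (s - pre):(s + post - 1L)]
  }
  out <- structure(list(data = data,
                        times_ms = (seq_len(len) - pre - 1) / fs * 1000,
                        meta = events[idx, , drop = FALSE],
                        sample_rate = fs),
                   class = "epoch_set")
  attr(out, "skipped") <- events[!ok, , drop = FALSE]
  out
}

# zero-phase (forward-backward) IIR filtering with odd-symmetric reflective
# padding to suppress edge transients inside short epochs
filtfilt_reflect <- function(b, a, x, pad = NULL) {
  if (is.null(pad)) pad <- 300L   # long enough for low corner frequencies
  pad <- min(pad, length(x) - 1L)
  head_pad <- 2 * x[1] - x[(pad + 1L):2L]
  tail_pad <- 2 * x[length(x)] - x[(length(x) - 1L):(length(x) - pad)]
  xx <- c(head_pad, x, tail_pad)
  y <- signal::filter(b, a, xx)
  y <- rev(as.numeric(signal::filter(b, a, rev(as.numeric(y)))))
  y[(pad + 1L):(pad + length(x))]
}

#' Zero-phase Butterworth low-pass filter an epoch set
#'
#' Two-pass (forward-backward) 4th-order Butterworth low-pass at 50 Hz by
#' default, applied per channel per epoch: the effective magnitude response
#' is the squared single-pass response and the phase lag is zero, so peak
#' latencies are preserved.
#'
#' @param epochs an `epoch_set` (or a numeric vector with `sample_rate`
#'   given).
#' @param cutoff low-pass corner frequency, Hz.
#' @param order filter order (per pass).
#' @param sample_rate required when `epochs` is a bare numeric vector.
#' @return the filtered object, same shape.
#' @export
filter_epoch <- function(epochs, cutoff = 50, order = 4,
                         sample_rate = NULL) {
  fs <- if (inherits(epochs, "epoch_set")) epochs$sample_rate else sample_rate
  if (is.null(fs)) stop("sample_rate required")
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  if (!inherits(epochs, "epoch_set"))
    return(filtfilt_reflect(bf$b, bf$a, epochs))
  d <- epochs$data
  for (e in seq_len(dim(d)[1]))
    for (ch in seq_len(dim(d)[2]))
      d[e, ch, ] <- filtfilt_reflect(bf$b, bf$a, d[e, ch, ])
  epochs$data <- d
  epochs
}

#' Baseline-correct an epoch set
#'
#' Subtracts, per channel and epoch, the mean over the first `baseline_ms`
#' of the pre-event span. Idempotent.
#'
#' @param epochs an `epoch_set`.
#' @param baseline_ms baseline window length, ms (must fit in the pre-event
#'   span).
#' @return the baselined `epoch_set`.
#' @export
baseline_epoch <- function(epochs, baseline_ms = 250) {
  pre_span <- -epochs$times_ms[1]
  if (baseline_ms > pre_span + 1e-9)
    stop("baseline window exceeds the epoch's pre-event span")
  nb <- round(baseline_ms / 1000 * epochs$sample_rate)
  d <- epochs$data
  base <- apply(d[, , seq_len(nb), drop = FALSE], c(1, 2), mean)
  epochs$data <- d - array(base, dim = dim(d))
  epochs
}

#' Exclude channels with damaged contacts
#'
#' A channel is excluded when its broadband variance exceeds
#' `variance_factor` times the median channel variance (wide-amplitude
#' random oscillation), or when its impedance exceeds `impedance_limit`.
#'
#' @param recording an `ecog_recording`.
#' @param variance_factor multiple of the median variance.
#' @param impedance_limit optional impedance ceiling; requires an
#'   `impedance` column in `recording$channel_info`.
#' @return data frame with `channel`, `keep`, `reason`.
#' @export
exclude_bad_channels <- function(recording, variance_factor = 10,
                                 impedance_limit = NULL) {
  v <- apply(recording$samples, 1, stats::var)
  if (length(v) < 2L) stop("need at least 2 channels")
  bad_var <- v > variance_factor * stats::median(v)
  bad_imp <- rep(FALSE, length(v))
  if (!is.null(impedance_limit)) {
    imp <- recording$channel_info$impedance
    if (is.null(imp)) stop("no impedance metadata in recording")
    bad_imp <- !is.na(imp) & imp > impedance_limit
  }
  keep <- !(bad_var | bad_imp)
  if (!any(keep)) stop("all channels excluded")
  data.frame(channel = seq_along(v), keep = keep,
             reason = ifelse(bad_var, "variance",
                             ifelse(bad_imp, "impedance", "none")))
}

#' Condition-average evoked potentials
#'
#' Pointwise mean over epochs within each combination of the grouping
#' metadata columns, with the trial count and a 95% pointwise normal
#' confidence band of the mean.
#'
#' @param epochs an `epoch_set`.
#' @param grouping metadata column names to group by.
#' @param channels channel subset to keep (default all).
#' @return list of `erp` objects (one per non-empty condition), each with
#'   `condition`, `mean` (channels x time), `band` (half-width), `n`,
#'   `times_ms`.
#' @export
average_evoked <- function(epochs, grouping = c("side", "state"),
                           channels = NULL) {
  if (is.null(channels)) channels <- seq_len(dim(epochs$data)[2])
  key <- interaction(epochs$meta[grouping], drop = TRUE, sep = "/")
  out <- list()
  for (cond in levels(key)) {
    sel <- which(key == cond)
    d <- epochs$data[sel, channels, , drop = FALSE]
    m <- apply(d, c(2, 3), mean)
    s <- if (length(sel) > 1L) apply(d, c(2, 3), stats::sd) else m * 0
    out[[cond]] <- structure(
      list(condition = cond, mean = m,
           band = 1.96 * s / sqrt(length(sel)),
           n = length(sel), times_ms = epochs$times_ms,
           channels = channels),
      class = "erp")
  }
  if (!length(out)) warning("no epochs in any requested condition")
  out
}

#' Measure an evoked-potential peak
#'
#' Extremum of the requested polarity within a post-event search window of
#' the channel-pooled (or single-channel) ERP trace.
#'
#' @param erp an `erp` object, or a numeric trace with `times_ms` given.
#' @param polarity "negative" or "positive".
#' @param window_ms `c(from, to)` search window relative to the event, ms.
#' @param pool_channels average over channels first (default) or a channel
#'   index.
#' @param times_ms time axis when `erp` is a bare trace.
#' @return list with `amplitude` (uV), `latency_ms`, and `polarity_flag`
#'   (`TRUE` when the found extremum actually has the requested sign).
#' @export
measure_peak <- function(erp, polarity = c("negative", "positive"),
                         window_ms = c(0, 500), pool_channels = TRUE,
                         times_ms = NULL) {
  polarity <- match.arg(polarity)
  if (inherits(erp, "erp")) {
    times_ms <- erp$times_ms
    trace <- if (isTRUE(pool_channels)) colMeans(erp$mean)
             else erp$mean[pool_channels, ]
  } else trace <- as.numeric(erp)
  sel <- which(times_ms >= window_ms[1] & times_ms <= window_ms[2])
  if (!length(sel)) stop("empty search window")
  v <- trace[sel]
  i <- if (polarity == "negative") which.min(v) else which.max(v)
  amp <- v[i]
  list(amplitude = amp, latency_ms = times_ms[sel[i]],
       polarity_flag = if (polarity == "negative") amp < 0 else amp > 0)
}
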