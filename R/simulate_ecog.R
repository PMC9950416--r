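# Synthetic multichannel ECoG with camera-strobe synchronization.

#' ECoG simulation parameters
#'
#' Default evoked-potential templates follow the responses characterized in
#' the assay: stepping on a stable obstacle with the contralateral paw
#' evokes a -100 uV negativity peaking 10 ms after contact; an unexpected
#' collapse of an unstable obstacle evokes a much larger -300 uV negativity
#' peaking at 70 ms, followed by a slower positive rebound. Ipsilateral-paw
#' events evoke nothing (configurable gain). Templates are injected on the
#' anterior-grid channels only.
#'
#' @param n_channels total channel count.
#' @param n_anterior number of anterior-grid channels (channels `1:n_anterior`).
#' @param sample_rate acquisition rate, Hz.
#' @param strobe_rate camera frame rate, Hz.
#' @param frame_counter_start first hardware frame counter value.
#' @param counter_mod modulus at which the hardware counter wraps.
#' @param templates per-condition template parameters: `amp` (uV), `latency`
#'   (ms), `width` (Gaussian sigma, ms), `rebound_amp` (uV), `rebound_decay`
#'   (ms).
#' @param noise `c(white, pink)` noise scales, uV.
#' @param ipsi_gain template gain for ipsilateral-paw events.
#' @return list of class `ecog_sim_spec`.
#' @export
ecog_sim_spec <- function(n_channels = 16L, n_anterior = 8L,
                          sample_rate = 1000, strobe_rate = 120,
                          frame_counter_start = 0L, counter_mod = 2^16,
                          templates = list(
                            stable = list(amp = -100, latency = 10, width = 6,
                                          rebound_amp = 0, rebound_decay = 150),
                            unstable = list(amp = -300, latency = 70, width = 15,
                                            rebound_amp = 300, rebound_decay = 150)),
                          noise = c(white = 50, pink = 20),
                          ipsi_gain = 0) {
  if (sample_rate <= 100) stop("sample_rate must exceed 100 Hz (2 x 50 Hz)")
  if (strobe_rate > sample_rate) stop("strobe_rate must not exceed sample_rate")
  stopifnot(all(vapply(templates, function(tp) all(is.finite(unlist(tp))), TRUE)))
  structure(list(n_channels = as.integer(n_channels),
                 n_anterior = as.integer(n_anterior),
                 sample_rate = sample_rate, strobe_rate = strobe_rate,
                 frame_counter_start = as.integer(frame_counter_start),
                 counter_mod = counter_mod, templates = templates,
                 noise = noise, ipsi_gain = ipsi_gain),
            class = "ecog_sim_spec")
}

# evoked-potential template sampled at millisecond offsets `t_ms` from onset
ep_template <- function(t_ms, tp) {
  v <- tp$amp * exp(-0.5 * ((t_ms - tp$latency) / tp$width)^2)
  if (tp$rebound_amp != 0) {
    u <- (t_ms - tp$latency) / tp$rebound_decay
    v <- v + ifelse(u > 0, tp$rebound_amp * u * exp(1 - u), 0)
  }
  v
}

# 1/f ("pink") noise via spectral shaping of white noise
pink_noise <- function(n, scale) {
  if (scale <= 0) return(numeric(n))
  m <- stats::nextn(n, 2)
  f <- c(1, seq_len(m / 2), seq(m / 2 - 1, 1))  # avoid f = 0 blowup
  x <- stats::fft(stats::rnorm(m) / sqrt(f), inverse = FALSE)
  scale * Re(x)[seq_len(n)] / sqrt(m) * sqrt(2)
}

#' Synthesize a strobe-synchronized ECoG recording
#'
#' Builds a multichannel voltage matrix with per-condition evoked-potential
#' templates injected at the sample of each contralateral-paw step event, a
#' camera strobe square wave whose falling edges mark frame exposures, the
#' matching hardware frame counters (with wraparound), and optional
#' load-cell traces pulsing at contact times.
#'
#' @param events data frame with `frame` (0-based video frame of the step),
#'   `side` ("contra"/"ipsi") and `state` ("stable"/"unstable"); an optional
#'   `step` column adds load-cell pulses.
#' @param spec an [ecog_sim_spec()].
#' @param seed integer seed.
#' @param duration_s recording length; default covers the last event + 1 s.
#' @return list of class `ecog_recording`: `samples` (channels x samples,
#'   uV), `sample_rate`, `strobe`, `frame_counters`, `channel_info`,
#'   `n_frames`, and `truth` (injected event samples).
#' @export
synthesize_ecog <- function(events, spec = ecog_sim_spec(), seed = 1L,
                            duration_s = NULL) {
  fs <- spec$sample_rate
  if (is.null(duration_s))
    duration_s <- (max(events$frame) + 1) / spec$strobe_rate + 1
  n <- ceiling(duration_s * fs)
  n_frames <- floor(duration_s * spec$strobe_rate)
  if (any(events$frame < 0 | events$frame >= n_frames))
    stop("event frame beyond recording duration")

  # strobe: high, with a low half-period starting at each frame's edge sample
  edge_samples <- round((seq_len(n_frames) - 0.5) * fs / spec$strobe_rate) + 1L
  half <- max(1L, floor(fs / spec$strobe_rate / 2))
  strobe <- rep(1, n)
  low_idx <- as.vector(outer(0:(half - 1L), edge_samples, "+"))
  strobe[low_idx[low_idx <= n]] <- 0
  frame_counters <- (spec$frame_counter_start + seq_len(n_frames) - 1L) %%
    spec$counter_mod

  with_seed(seed, {
    samples <- matrix(stats::rnorm(spec$n_channels * n, 0, spec$noise["white"]),
                      nrow = spec$n_channels)
    if (spec$noise["pink"] > 0)
      for (ch in seq_len(spec$n_channels))
        samples[ch, ] <- samples[ch, ] + pink_noise(n, spec$noise["pink"])

    event_samples <- integer(nrow(events))
    ant <- seq_len(spec$n_anterior)
    for (i in seq_len(nrow(events))) {
      s0 <- edge_samples[events$frame[i] + 1L]
      event_samples[i] <- s0
      gain <- if (identical(events$side[i], "contra")) 1 else spec$ipsi_gain
      if (gain == 0) next
      tp <- spec$templates[[events$state[i]]]
      len <- min(n - s0 + 1L, ceiling((tp$latency + 6 * tp$width +
                                         6 * tp$rebound_decay) * fs / 1000))
      t_ms <- (seq_len(len) - 1) / fs * 1000
      idx <- s0:(s0 + len - 1L)
      samples[ant, idx] <- samples[ant, idx] +
        rep(gain * ep_template(t_ms, tp), each = length(ant))
    }

    load <- NULL
    if (!is.null(events$step)) {
      n_steps <- max(events$step)
      load <- matrix(0, nrow = n_steps, ncol = n)
      plen <- round(0.1 * fs)             # 100 ms half-sine contact pulse
      pulse <- sin(pi * seq_len(plen) / plen)
      for (i in seq_len(nrow(events))) {
        s0 <- event_samples[i]
        idx <- s0:min(n, s0 + plen - 1L)
        load[events$step[i], idx] <- load[events$step[i], idx] +
          pulse[seq_along(idx)]
      }
    }

    structure(list(samples = samples, sample_rate = fs, strobe = strobe,
                   frame_counters = frame_counters,
                   channel_info = data.frame(
                     channel = seq_len(spec$n_channels),
                     grid = rep(c("anterior", "posterior"),
                                c(spec$n_anterior,
                                  spec$n_channels - spec$n_anterior))),
                   n_frames = n_frames, load = load,
                   truth = list(event_samples = event_samples,
                                edge_samples = edge_samples,
                                templates = spec$templates)),
              class = "ecog_recording")
  })
}
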