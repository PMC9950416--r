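# ECoG pipeline: strobe/counter synchronization, epoching, zero-phase
# filtering, baselining, bad channels, averaging, peak measurement.

noise_free_recording <- function(events, seed = 1) {
  synthesize_ecog(events, ecog_sim_spec(noise = c(white = 0, pink = 0)),
                  seed = seed)
}

test_that("frame-sample map pairs falling edges with hardware counters", {
  ev <- data.frame(frame = 60, side = "contra", state = "stable")
  rec <- synthesize_ecog(ev, ecog_sim_spec(), seed = 1, duration_s = 1)
  map <- build_frame_sample_map(rec$strobe, rec$frame_counters)
  expect_equal(length(map$frame), 120)   # 120 Hz strobe over 1 s
  expect_true(all(diff(map$sample) %in% 8:9))   # 1 kHz / 120 Hz spacing
  # map round trip is the identity on mapped frames
  expect_equal(map$frame[match(map$sample, map$sample)], map$frame)
})

test_that("dropped frames leave holes and counter wrap is unwrapped", {
  strobe <- rep(1, 200)
  edges <- c(20, 60, 100, 140)
  for (e in edges) strobe[e:(e + 3)] <- 0
  map <- build_frame_sample_map(strobe, c(0, 1, 3, 4))
  expect_equal(map$frame, c(0, 1, 3, 4))   # frame 2 dropped
  expect_true(is.na(frame_to_sample(map, 2)))
  expect_equal(frame_to_sample(map, 3), 100)

  wrapped <- build_frame_sample_map(strobe, c(65534, 65535, 0, 1))
  expect_equal(wrapped$frame, 0:3)
  expect_error(build_frame_sample_map(strobe, 0:10), "more counters")
})

test_that("event samples are recovered within one sample on fixtures", {
  ev <- data.frame(frame = c(100, 220, 340), side = "contra",
                   state = "unstable")
  rec <- noise_free_recording(ev)
  map <- build_frame_sample_map(rec$strobe, rec$frame_counters)
  expect_lte(max(abs(frame_to_sample(map, ev$frame) -
                       rec$truth$event_samples)), 1)
})

test_that("epochs are 750 ms, zero-aligned, and edge events are skipped", {
  # events spaced 100 frames (833 ms) so each 750 ms window holds one event
  ev <- data.frame(frame = c(1, seq(100, 1000, by = 100)), side = "contra",
                   state = "stable")
  rec <- noise_free_recording(ev)
  map <- build_frame_sample_map(rec$strobe, rec$frame_counters)
  ep <- extract_epochs(rec, ev, map)
  expect_equal(nrow(attr(ep, "skipped")), 1)   # event at recording start
  expect_equal(dim(ep$data)[1], 10)
  expect_equal(dim(ep$data)[3], 750)           # 750 ms at 1 kHz
  expect_equal(ep$times_ms[1], -250)
  expect_equal(ep$times_ms[which(ep$times_ms == 0)], 0)
  # template onset coincides with epoch time zero: the stable template's
  # minimum sits at its 10 ms latency on every epoch
  tmin <- apply(ep$data[, 1, ], 1, function(v) ep$times_ms[which.min(v)])
  expect_true(all(abs(tmin - 10) <= 1))
})

test_that("zero-phase Butterworth matches its analytic magnitude response", {
  fs <- 1000
  tt <- seq(0, 2, by = 1 / fs)
  for (f0 in c(10, 200)) {
    x <- sin(2 * pi * f0 * tt)
    y <- filter_epoch(x, cutoff = 50, order = 4, sample_rate = fs)
    mid <- 500:1500
    gain <- max(abs(y[mid]))
    analytic <- 1 / (1 + (f0 / 50)^8)   # squared single-pass response
    if (f0 == 10) expect_within(gain, analytic, 0.01)
    else expect_lte(gain, 0.01)         # > 99% attenuation in the stopband
  }
  # DC passes with unit gain
  expect_equal(filter_epoch(rep(3, 1000), sample_rate = fs),
               rep(3, 1000), tolerance = 1e-6)
  # symmetric pulse keeps its peak latency (no phase lag)
  pulse <- exp(-0.5 * ((seq_len(1000) - 500) / 20)^2)
  yp <- filter_epoch(pulse, sample_rate = fs)
  expect_equal(which.max(yp), 500)
  expect_error(filter_epoch(pulse, cutoff = 600, sample_rate = fs),
               "Nyquist")
})

test_that("filtering and baselining commute with sums and reverse with time", {
  ev <- data.frame(frame = c(100, 200), side = "contra", state = "unstable")
  rec <- synthesize_ecog(ev, ecog_sim_spec(noise = c(white = 30, pink = 10)),
                         seed = 5)
  map <- build_frame_sample_map(rec$strobe, rec$frame_counters)
  ep <- extract_epochs(rec, ev, map)
  a <- ep$data[1, 1, ]; b <- ep$data[2, 1, ]
  proc <- function(x) {
    y <- filter_epoch(x, sample_rate = 1000)
    y - mean(y[1:250])
  }
  expect_equal(proc(a + b), proc(a) + proc(b), tolerance = 1e-9)
  # zero-phase: processing the time-reversed epoch reverses the output
  expect_equal(proc(rev(a)), rev(filter_epoch(a, sample_rate = 1000)) -
                 mean(rev(filter_epoch(a, sample_rate = 1000))[1:250]),
               tolerance = 1e-9)
})

test_that("baselining zeroes each channel and is idempotent", {
  ev <- data.frame(frame = 100, side = "ipsi", state = "stable")
  rec <- noise_free_recording(ev)
  map <- build_frame_sample_map(rec$strobe, rec$frame_counters)
  ep <- extract_epochs(rec, ev, map)
  ep$data <- ep$data + array(rep(1:16 * 10, each = 1),
                             dim = dim(ep$data))   # per-channel offsets
  b1 <- baseline_epoch(ep)
  base_means <- apply(b1$data[, , 1:250, drop = FALSE], c(1, 2), mean)
  expect_true(max(abs(base_means)) < 1e-9)
  b2 <- baseline_epoch(b1)
  expect_equal(b2$data, b1$data)
  expect_error(baseline_epoch(ep, baseline_ms = 400), "pre-event")
})

test_that("bad channels are excluded by variance, good ones kept", {
  ev <- data.frame(frame = 100, side = "contra", state = "stable")
  rec <- synthesize_ecog(ev, ecog_sim_spec(noise = c(white = 30, pink = 0)),
                         seed = 2)
  mask <- exclude_bad_channels(rec)
  expect_true(all(mask$keep))   # homogeneous noise: none excluded

  corrupt <- c(3, 7, 12)
  rec$samples[corrupt, ] <- rec$samples[corrupt, ] * 30
  mask2 <- exclude_bad_channels(rec)
  expect_equal(which(!mask2$keep), corrupt)
  expect_true(all(mask2$reason[corrupt] == "variance"))
})

test_that("condition averages separate contra/ipsi and shrink with n", {
  # inter-trial spacing of 2 s keeps the slow positive rebound of one
  # trial out of the next trial's epoch
  frames <- seq(100, 100 + 39 * 240, by = 240)
  ev <- data.frame(frame = frames,
                   side = rep(c("contra", "ipsi"), 20),
                   state = "unstable")
  rec <- synthesize_ecog(ev, ecog_sim_spec(noise = c(white = 50, pink = 20)),
                         seed = 8)
  map <- build_frame_sample_map(rec$strobe, rec$frame_counters)
  ep <- baseline_epoch(filter_epoch(extract_epochs(rec, ev, map)))
  erps <- average_evoked(ep, grouping = "side", channels = 1:8)
  contra <- measure_peak(erps[["contra"]], "negative", c(20, 150))
  ipsi <- measure_peak(erps[["ipsi"]], "negative", c(20, 150))
  expect_within(contra$amplitude, -300, 45)   # within 15%
  expect_within(contra$latency_ms, 70, 5)
  expect_lte(abs(ipsi$amplitude), 0.25 * abs(contra$amplitude))
})

test_that("identical epochs average to themselves; noise shrinks as 1/sqrt(n)", {
  ev <- data.frame(frame = c(150, 150), side = "contra", state = "stable")
  rec <- noise_free_recording(ev)
  map <- build_frame_sample_map(rec$strobe, rec$frame_counters)
  ep <- extract_epochs(rec, ev, map)
  erp <- average_evoked(ep, grouping = "side")[[1]]
  expect_equal(erp$mean[1, ], ep$data[1, 1, ])

  set.seed(9)
  sup <- vapply(c(5, 80), function(n) {
    m <- colMeans(matrix(rnorm(n * 200), n))
    max(abs(m))
  }, 0)
  expect_lt(sup[2], sup[1])
})

test_that("peak measurement returns the template extremum and flags polarity", {
  spec <- ecog_sim_spec()
  t_ms <- seq(0, 500, by = 1)
  tpl <- rungwalk:::ep_template(t_ms, spec$templates$unstable)
  pk <- measure_peak(tpl, "negative", c(0, 500), times_ms = t_ms)
  expect_equal(pk$amplitude, -300)
  expect_equal(pk$latency_ms, 70)
  expect_true(pk$polarity_flag)
  neg_only <- -abs(sin(seq(0, pi, length.out = 100)))
  pos <- measure_peak(neg_only, "positive", c(0, 99),
                      times_ms = seq(0, 99))
  expect_false(pos$polarity_flag)
})

test_that("noise-free stable and unstable ERPs differ by the template difference", {
  ev_s <- data.frame(frame = 100, side = "contra", state = "stable")
  ev_u <- data.frame(frame = 100, side = "contra", state = "unstable")
  spec <- ecog_sim_spec(noise = c(white = 0, pink = 0))
  pipeline <- function(ev) {
    rec <- synthesize_ecog(ev, spec, seed = 1)
    map <- build_frame_sample_map(rec$strobe, rec$frame_counters)
    average_evoked(extract_epochs(rec, ev, map), grouping = "state")[[1]]
  }
  d <- pipeline(ev_u)$mean[1, ] - pipeline(ev_s)$mean[1, ]
  t_ms <- pipeline(ev_u)$times_ms
  truth <- rungwalk:::ep_template(pmax(t_ms, 0), spec$templates$unstable) -
    rungwalk:::ep_template(pmax(t_ms, 0), spec$templates$stable)
  truth[t_ms < 0] <- 0
  expect_equal(as.numeric(d), truth, tolerance = 1e-9)
})
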