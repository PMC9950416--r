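#!/usr/bin/env Rscript
# Stage 6: frame-synchronized evoked-potential analysis on synthetic
# stable/unstable sessions (40 contralateral + 40 ipsilateral steps each).

suppressMessages(library(rungwalk))
dir.create("results", showWarnings = FALSE)

run_session <- function(state, seed) {
  frames <- seq(100, 100 + 79 * 240, by = 240)   # 2 s inter-trial spacing
  ev <- data.frame(frame = frames,
                   side = rep(c("contra", "ipsi"), 40), state = state)
  rec <- synthesize_ecog(ev, ecog_sim_spec(noise = c(white = 50, pink = 20)),
                         seed = seed)
  map <- build_frame_sample_map(rec$strobe, rec$frame_counters)
  keep <- exclude_bad_channels(rec)
  ep <- baseline_epoch(filter_epoch(extract_epochs(rec, ev, map)))
  ant <- intersect(which(keep$keep), 1:8)
  erps <- average_evoked(ep, grouping = "side", channels = ant)
  lapply(erps, function(e) measure_peak(e, "negative", c(0, 150)))
}

rows <- list()
for (state in c("stable", "unstable")) {
  pk <- run_session(state, seed = if (state == "stable") 31 else 32)
  for (side in names(pk))
    rows[[length(rows) + 1L]] <- data.frame(
      state = state, side = side,
      amplitude_uV = pk[[side]]$amplitude,
      latency_ms = pk[[side]]$latency_ms)
}
peaks <- do.call(rbind, rows)
write.csv(peaks, "results/erp_peaks.csv", row.names = FALSE)
cat("ERP peak measurements (templates: stable -100 uV @ 10 ms,",
    "unstable -300 uV @ 70 ms, ipsilateral none):\n")
print(peaks, row.names = FALSE)
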