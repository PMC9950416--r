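#!/usr/bin/env Rscript
# Stage 1: generate the month-long training schedule and verify its
# structure (transition days switch after exactly 20 trials; the final
# four days randomize the center-step state per trial).

suppressMessages(library(rungwalk))
dir.create("results", showWarnings = FALSE)

protocol <- generate_protocol(n_trials = 60, seed = 1)
write.csv(protocol, "results/protocol.csv", row.names = FALSE)
write_protocol_json(protocol, "results/protocol.json")

per_day <- aggregate(state ~ day + condition, protocol,
                     function(s) mean(s == "unstable"))
names(per_day)[3] <- "frac_unstable"
write.csv(per_day, "results/protocol_summary.csv", row.names = FALSE)

day5 <- protocol$state[protocol$day == 5]
cat(sprintf("Day 5 switches to unstable after trial %d (expected 20).\n",
            which(day5 == "unstable")[1] - 1))
cat(sprintf("Randomized days: %s; overall unstable fraction %.2f.\n",
            paste(unique(protocol$day[protocol$condition == "randomized"]),
                  collapse = ", "),
            mean(protocol$state[protocol$condition == "randomized"] ==
                   "unstable")))
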