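# Synthetic ethogram cohorts with configured response-outcome counts.

#' Simulate a cohort of response ethograms
#'
#' Builds one synthetic ethogram per animal such that a configured number
#' of animals per group produce each response pattern. Halting-dominant
#' animals open with a long halting bout; the others open with a short
#' compensation bout followed by investigation. `n_third` (per group, and
#' at least `n_halt`) controls how many animals exceed the one-third
#' halting-fraction criterion: the non-halting-dominant among them receive
#' an additional mid-window halting bout.
#'
#' @param n named vector: animals per group, e.g. `c(control = 11,
#'   lesion = 11)`.
#' @param n_halt named vector: animals per group whose first and dominant
#'   response is halting.
#' @param n_third named vector: animals per group whose halting fraction
#'   exceeds one third of the first `window` seconds.
#' @param window analysis window, s.
#' @param seed seed for bout-duration jitter.
#' @return list of [ethogram()] objects.
#' @export
simulate_ethograms <- function(n = c(control = 11, lesion = 11),
                               n_halt = c(control = 1, lesion = 8),
                               n_third = c(control = 2, lesion = 9),
                               window = 5, seed = 1L) {
  stopifnot(all(n_halt <= n), all(n_halt <= n_third), all(n_third <= n))
  with_seed(seed, {
    out <- list()
    for (g in names(n)) {
      for (i in seq_len(n[[g]])) {
        jit <- stats::runif(1, 0, 0.2)   # rigid time shift keeps durations
        if (i <= n_halt[[g]]) {
          # halting-first and halting-dominant (and > 1/3 of the window)
          iv <- data.frame(
            category = c("halting", "investigation"),
            onset_s = jit + c(0.1, 3.6), offset_s = jit + c(3.6, 4.7))
        } else if (i <= n_third[[g]]) {
          # prompt reaction; halting exceeds a third of the annotated
          # window but is not the dominant category
          iv <- data.frame(
            category = c("compensation", "halting", "investigation"),
            onset_s = jit + c(0.1, 1.7, 3.2),
            offset_s = jit + c(1.7, 3.2, 4.2))
        } else {
          iv <- data.frame(
            category = c("compensation", "investigation"),
            onset_s = jit + c(0.1, 1.2), offset_s = jit + c(1.2, 4.5))
        }
        out[[length(out) + 1L]] <-
          ethogram(iv, animal = sprintf("%s_%02d", g, i), group = g)
      }
    }
    out
  })
}
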