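# Trial protocol scheduler for the stable/unstable obstacle assay.

#' Generate the day-by-day trial protocol
#'
#' Reproduces the training schedule of the assay: a habituation day, four
#' days with all steps stable, a transition day with exactly 20 stable trials
#' before the center steps become unstable, five unstable days, a transition
#' day with exactly 20 unstable trials before reverting to stable, one more
#' stable day, and four days in which the center-step state is randomized
#' independently on every trial.
#'
#' @param n_trials trials per session. Transition sessions consist of 20
#'   trials of the pre-change state followed by `n_trials - 20` post-change
#'   trials, so `n_trials` must exceed 20.
#' @param p_unstable per-trial probability of the unstable state on
#'   randomized days.
#' @param seed integer seed; the randomized-day state sequences are
#'   a deterministic function of it.
#' @return data frame with one row per trial: `day` (0-16), `condition`,
#'   `trial` (1-based within session), `state` ("stable"/"unstable").
#' @export
generate_protocol <- function(n_trials = 40L, p_unstable = 0.5, seed = 1L) {
  n_trials <- as.integer(n_trials)
  if (n_trials <= 0L) stop("n_trials must be positive")
  if (n_trials <= 20L) stop("n_trials must exceed the 20 pre-change trials")
  if (p_unstable < 0 || p_unstable > 1) stop("p_unstable must be in [0, 1]")

  session <- function(day, condition, states) {
    data.frame(day = day, condition = condition,
               trial = seq_along(states), state = states)
  }
  all_stable <- rep("stable", n_trials)
  all_unstable <- rep("unstable", n_trials)
  to_unstable <- c(rep("stable", 20L), rep("unstable", n_trials - 20L))
  to_stable <- c(rep("unstable", 20L), rep("stable", n_trials - 20L))

  out <- list(session(0L, "habituation", all_stable))
  for (d in 1:4) out <- c(out, list(session(d, "stable", all_stable)))
  out <- c(out, list(session(5L, "transition_to_unstable", to_unstable)))
  for (d in 6:10) out <- c(out, list(session(d, "unstable", all_unstable)))
  out <- c(out, list(session(11L, "transition_to_stable", to_stable)))
  out <- c(out, list(session(12L, "stable", all_stable)))
  rnd <- with_seed(seed, lapply(13:16, function(d)
    ifelse(stats::runif(n_trials) < p_unstable, "unstable", "stable")))
  for (i in seq_along(rnd))
    out <- c(out, list(session(12L + i, "randomized", rnd[[i]])))
  do.call(rbind, out)
}

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
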