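# Ethogram representation and the response-outcome statistics: first /
# dominant / fraction-based outcomes, 2x2 contingency tables, chi-square
# with Yates continuity correction, and Student's unpaired t-tests
# (including the summary-statistics form used for published group tables).

RESPONSE_CATEGORIES <- c("compensation", "investigation", "halting")

#' Construct an ethogram
#'
#' An ordered, non-overlapping sequence of response intervals aligned to
#' the first contact with the manipulated step (time zero).
#'
#' @param intervals data frame with `category`, `onset_s`, `offset_s`.
#' @param animal,group identifiers.
#' @param crossed_at time the animal crossed the course (s), or `NA`.
#' @return list of class `ethogram`.
#' @export
ethogram <- function(intervals, animal = NA_character_,
                     group = NA_character_, crossed_at = NA_real_) {
  if (!all(intervals$category %in% RESPONSE_CATEGORIES))
    stop("unknown category; expected one of: ",
         paste(RESPONSE_CATEGORIES, collapse = ", "))
  if (any(intervals$onset_s < 0) || any(intervals$offset_s <= intervals$onset_s))
    stop("intervals need 0 <= onset < offset")
  intervals <- intervals[order(intervals$onset_s), , drop = FALSE]
  if (nrow(intervals) > 1L &&
      any(intervals$onset_s[-1L] < intervals$offset_s[-nrow(intervals)] - 1e-9))
    stop("overlapping intervals; truncate the earlier interval at the ",
         "later one's onset to repair")
  if (!is.na(crossed_at) && any(intervals$offset_s > crossed_at + 1e-9))
    stop("intervals must precede crossed_at")
  structure(list(animal = animal, group = group, intervals = intervals,
                 crossed_at = crossed_at), class = "ethogram")
}

#' Read ethogram annotations from CSV
#'
#' Expects columns `animal`, `group`, `category`, `onset_s`, `offset_s`
#' (optional `crossed_at`); one ethogram per animal.
#'
#' @param path CSV file path.
#' @return list of [ethogram()] objects, named by animal.
#' @export
read_ethograms <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(d, d$animal), function(a)
    ethogram(a[, c("category", "onset_s", "offset_s")],
             animal = a$animal[1], group = a$group[1],
             crossed_at = if (!is.null(a$crossed_at)) a$crossed_at[1]
                          else NA_real_))
}

#' First, dominant and fractional response outcomes
#'
#' `first_response()` is the category of the earliest interval.
#' `dominant_response()` is the category with the greatest total duration
#' inside `[0, window]` (intervals clipped at the window edge; ties go to
#' the category with the earliest onset). `halting_fraction()` is halting
#' duration divided by total annotated duration within the window, and
#' `exceeds_one_third()` tests it strictly against 1/3.
#'
#' @param eth an [ethogram()].
#' @param window analysis window after first contact, s.
#' @return category string / fraction / logical flag.
#' @export
first_response <- function(eth) {
  iv <- eth$intervals
  if (!nrow(iv)) stop("empty ethogram")
  iv$category[which.min(iv$onset_s)]
}

#' @rdname first_response
#' @export
dominant_response <- function(eth, window = 5) {
  if (window <= 0) stop("window must be positive")
  iv <- eth$intervals
  dur <- pmax(0, pmin(iv$offset_s, window) - iv$onset_s)
  if (all(dur == 0)) stop("no interval intersects the window")
  tot <- tapply(dur, factor(iv$category, RESPONSE_CATEGORIES), sum,
                default = 0)
  top <- names(tot)[tot == max(tot)]
  if (length(top) == 1L) return(top)
  first_onset <- tapply(iv$onset_s, factor(iv$category, RESPONSE_CATEGORIES),
                        min, default = Inf)
  top[which.min(first_onset[top])]
}

#' @rdname first_response
#' @export
halting_fraction <- function(eth, window = 5) {
  if (window <= 0) stop("window must be positive")
  iv <- eth$intervals
  dur <- pmax(0, pmin(iv$offset_s, window) - iv$onset_s)
  total <- sum(dur)
  if (total == 0) stop("no annotated duration inside the window")
  sum(dur[iv$category == "halting"]) / total
}

#' @rdname first_response
#' @param fraction a halting fraction.
#' @export
exceeds_one_third <- function(fraction) fraction > 1 / 3

#' Cross-tabulate a binary outcome by group
#'
#' @param groups group label per animal (exactly two distinct values).
#' @param outcomes logical outcome per animal.
#' @return 2x2 integer matrix (rows = groups, columns = `yes`/`no`).
#' @export
contingency <- function(groups, outcomes) {
  if (length(unique(groups)) != 2L) stop("exactly two groups required")
  if (!is.logical(outcomes)) stop("outcomes must be logical")
  tab <- table(factor(groups), factor(outcomes, c(TRUE, FALSE)))
  m <- matrix(as.integer(tab), 2, 2, dimnames = list(rownames(tab),
                                                     c("yes", "no")))
  m
}

#' Chi-square test for a 2x2 table with Yates continuity correction
#'
#' Statistic `N * (max(|ad - bc| - N/2, 0))^2 / (r1 r2 c1 c2)` with one
#' degree of freedom; the correction is floored at zero so identical rows
#' give a statistic of exactly 0.
#'
#' @param table 2x2 non-negative count matrix.
#' @return list of class `test_result`: `statistic`, `df`, `p`.
#' @export
chi_square_yates <- function(table) {
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(table < 0)) stop("counts must be non-negative")
  n <- sum(table)
  r <- rowSums(table); co <- colSums(table)
  if (any(r == 0) || any(co == 0)) stop("zero row/column margin")
  ad_bc <- abs(table[1, 1] * table[2, 2] - table[1, 2] * table[2, 1])
  stat <- n * max(ad_bc - n / 2, 0)^2 / prod(r, co)
  structure(list(statistic = stat, df = 1L,
                 p = stats::pchisq(stat, df = 1, lower.tail = FALSE)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> statistic = %.4g, df = %s, p = %.4g\n",
              x$statistic, format(x$df), x$p))
  invisible(x)
}

#' Student's unpaired t-test from summary statistics
#'
#' Pooled-variance two-sided t-test computed from group means, standard
#' deviations and sizes — the form needed to test published group tables.
#' [t_test_samples()] is the raw-sample overload; it reduces exactly to the
#' summary form evaluated on the samples' own mean/sd/n.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries.
#' @return list of class `test_result`: `statistic` (|t|), `df`, `p`.
#' @export
t_test <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be non-negative")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (se == 0) {
    if (mean1 == mean2)
      return(structure(list(statistic = 0, df = df, p = 1),
                       class = "test_result"))
    warning("zero pooled variance with non-zero mean difference")
    return(structure(list(statistic = Inf, df = df, p = 0),
                     class = "test_result"))
  }
  t <- abs(mean1 - mean2) / se
  structure(list(statistic = t, df = df,
                 p = 2 * stats::pt(-t, df)), class = "test_result")
}

#' @rdname t_test
#' @param x,y raw samples.
#' @export
t_test_samples <- function(x, y) {
  t_test(mean(x), stats::sd(x), length(x), mean(y), stats::sd(y), length(y))
}
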