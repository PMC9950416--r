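# Ethogram outcomes and the group statistics: response categories,
# contingency tables, chi-square with Yates correction, pooled t-tests.

eth <- function(categories, onsets, offsets, ...)
  ethogram(data.frame(category = categories, onset_s = onsets,
                      offset_s = offsets), ...)

test_that("ethograms enforce ordering, categories and non-overlap", {
  expect_error(eth("halting", 2, 1), "onset")
  expect_error(eth("grooming", 0, 1), "category")
  expect_error(eth(c("halting", "investigation"), c(0, 1), c(2, 3)),
               "overlap")
  e <- eth(c("investigation", "halting"), c(3, 0.5), c(4, 3))
  expect_equal(e$intervals$category, c("halting", "investigation"))
})

test_that("first response is the earliest interval's category", {
  e <- eth(c("halting", "investigation"), c(0.1, 2.0), c(2.0, 3.0))
  expect_equal(first_response(e), "halting")
  expect_equal(first_response(eth("compensation", 0, 1)), "compensation")
  expect_error(first_response(eth(character(0), numeric(0), numeric(0))),
               "empty")
})

test_that("dominant response clips at the window and breaks ties by onset", {
  e <- eth(c("halting", "investigation"), c(0, 3), c(3, 4))
  expect_equal(dominant_response(e, window = 5), "halting")
  # interval spanning the window edge: only the inside portion counts
  e2 <- eth(c("compensation", "halting"), c(0, 2), c(2, 10))
  expect_equal(dominant_response(e2, window = 3), "compensation")
  # tie 2 s vs 2 s, halting first
  e3 <- eth(c("halting", "investigation"), c(0, 2), c(2, 4))
  expect_equal(dominant_response(e3, window = 5), "halting")
})

test_that("halting fraction uses annotated time and a strict 1/3 rule", {
  e <- eth(c("halting", "compensation"), c(0, 2), c(2, 6))
  expect_equal(halting_fraction(e, window = 6), 1 / 3)
  expect_false(exceeds_one_third(halting_fraction(e, window = 6)))
  e2 <- eth(c("halting", "compensation"), c(0, 2.5), c(2.5, 6))
  expect_true(exceeds_one_third(halting_fraction(e2, window = 6)))
  e3 <- eth("compensation", 0, 4)
  expect_equal(halting_fraction(e3, 5), 0)
})

test_that("contingency tables cross-tabulate and ignore animal order", {
  groups <- c(rep("control", 11), rep("lesion", 11))
  outcomes <- c(rep(TRUE, 1), rep(FALSE, 10), rep(TRUE, 8), rep(FALSE, 3))
  tab <- contingency(groups, outcomes)
  expect_equal(unname(tab), matrix(c(1, 8, 10, 3), 2))
  perm <- sample(22)
  expect_equal(contingency(groups[perm], outcomes[perm]), tab)
  expect_equal(unname(contingency(groups, rep(FALSE, 22))[, "yes"]), c(0, 0))
  expect_error(contingency(c("a", "b", "c"), c(TRUE, TRUE, FALSE)), "two")
})

test_that("Yates chi-square reproduces published worked examples", {
  r1 <- chi_square_yates(matrix(c(1, 8, 10, 3), 2))
  expect_equal(round(r1$p, 3), 0.009)
  r2 <- chi_square_yates(matrix(c(2, 9, 9, 2), 2))
  expect_equal(r2$statistic, 95832 / 14641)
  expect_equal(round(r2$p, 3), 0.011)
  # identical rows: continuity floor gives exactly zero
  r3 <- chi_square_yates(matrix(c(5, 5, 6, 6), 2))
  expect_equal(r3$statistic, 0)
  expect_equal(r3$p, 1)
  expect_error(chi_square_yates(matrix(c(0, 0, 5, 6), 2)), "margin")
})

test_that("Yates statistic matches the base-R oracle and its invariances", {
  set.seed(7)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 6) + 1, 2)
    ours <- chi_square_yates(tab)
    oracle <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    expect_equal(ours$statistic, unname(oracle$statistic), tolerance = 1e-12)
    expect_equal(ours$p, oracle$p.value, tolerance = 1e-12)
    # never exceeds the uncorrected statistic
    un <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_lte(ours$statistic, unname(un$statistic) + 1e-12)
    # invariant to simultaneous row and column swaps
    swapped <- chi_square_yates(tab[2:1, 2:1])
    expect_equal(swapped$statistic, ours$statistic)
  }
})

test_that("the Yates correction keeps null type-I error conservative", {
  set.seed(123)
  n <- 11
  reject <- logical(2000)
  for (i in seq_len(2000)) {
    a <- rbinom(1, n, 0.4); b <- rbinom(1, n, 0.4)
    tab <- matrix(c(a, b, n - a, n - b), 2)
    reject[i] <- !any(rowSums(tab) == 0) && !any(colSums(tab) == 0) &&
      chi_square_yates(tab)$p < 0.05
  }
  expect_lte(mean(reject), 0.05 + 2 * sqrt(0.05 * 0.95 / 2000))
})

test_that("pooled t-test reproduces published group rows and base R", {
  expect_equal(t_test(5, 1, 10, 5, 1, 10)$p, 1)
  r0 <- t_test(15.86, 3.89, 11, 15.16, 3.13, 11)
  expect_within(r0$p, 0.645, 0.005)
  r1 <- t_test(13.70, 4.02, 11, 11.42, 2.65, 11)
  expect_within(r1$p, 0.133, 0.005)

  set.seed(11)
  x <- rnorm(11, 15.86, 3.89); y <- rnorm(11, 15.16, 3.13)
  ours <- t_test_samples(x, y)
  oracle <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(ours$p, oracle$p.value, tolerance = 1e-12)
  expect_equal(ours$statistic, abs(unname(oracle$statistic)),
               tolerance = 1e-12)
  # raw overload reduces exactly to the summary form
  summ <- t_test(mean(x), sd(x), 11, mean(y), sd(y), 11)
  expect_equal(ours$statistic, summ$statistic)

  expect_warning(res <- t_test(1, 0, 5, 2, 0, 5), "zero pooled")
  expect_equal(res$p, 0)
  expect_equal(t_test(3, 0, 5, 3, 0, 5)$p, 1)
  expect_error(t_test(1, 1, 1, 2, 1, 5), "n >= 2")
})

test_that("simulated cohorts reproduce configured outcome contingencies", {
  cohort <- simulate_ethograms(seed = 4)
  groups <- vapply(cohort, function(e) e$group, "")
  halt_first <- vapply(cohort, function(e)
    first_response(e) == "halting", TRUE)
  halt_dom <- vapply(cohort, function(e)
    dominant_response(e, 5) == "halting", TRUE)
  third <- vapply(cohort, function(e)
    exceeds_one_third(halting_fraction(e, 5)), TRUE)
  expect_equal(unname(contingency(groups, halt_first)),
               matrix(c(1, 8, 10, 3), 2))
  expect_equal(unname(contingency(groups, halt_dom)),
               matrix(c(1, 8, 10, 3), 2))
  expect_equal(unname(contingency(groups, third)),
               matrix(c(2, 9, 9, 2), 2))
})

test_that("ethogram CSV round trip preserves outcomes", {
  cohort <- simulate_ethograms(n = c(control = 3, lesion = 3),
                               n_halt = c(control = 1, lesion = 2),
                               n_third = c(control = 1, lesion = 3), seed = 2)
  rows <- do.call(rbind, lapply(cohort, function(e)
    cbind(animal = e$animal, group = e$group, e$intervals[,
      c("category", "onset_s", "offset_s")])))
  path <- tempfile(fileext = ".csv")
  utils::write.csv(rows, path, row.names = FALSE)
  back <- read_ethograms(path)
  expect_equal(length(back), 6)
  orig_first <- sort(unname(vapply(cohort, first_response, "")))
  expect_equal(sort(unname(vapply(back, first_response, ""))), orig_first)
})
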