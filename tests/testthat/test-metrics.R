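# Confusion metrics, rare-event planning, and coefficient-of-variation
# analysis.

test_that("confusion tallies match a brute-force count", {
  y <- c("CTCC", "NC", "NC", "CTCC", "NC", "CTCC", "NC", "NC", "CTCC", "NC")
  p <- c("CTCC", "NC", "CTCC", "NC", "NC", "CTCC", "NC", "CTCC", "CTCC", "NC")
  cm <- confusion(y, p)
  # exhaustive manual tally
  tally <- table(truth = y, pred = p)
  expect_identical(cm$tp, unname(tally["CTCC", "CTCC"]))
  expect_identical(cm$fp, unname(tally["NC", "CTCC"]))
  expect_identical(cm$tn, unname(tally["NC", "NC"]))
  expect_identical(cm$fn, unname(tally["CTCC", "NC"]))
  # perfect predictions
  perfect <- confusion(y, y)
  expect_identical(perfect$fp + perfect$fn, 0L)
  # all-negative predictions
  allneg <- confusion(y, rep("NC", 10))
  expect_identical(allneg$tp, 0L)
  expect_identical(allneg$fn, sum(y == "CTCC"))
  expect_error(confusion(y, p[1:3]), "length")
})

test_that("core metrics match their formulas and handle undefined cases", {
  set.seed(60)
  for (i in 1:20) {
    c <- structure(list(tp = sample(0:50, 1), fp = sample(0:50, 1),
                        tn = sample(0:50, 1), fn = sample(0:50, 1)),
                   class = "confusion_counts")
    if (c$tp + c$fp + c$tn + c$fn == 0) next
    m <- core_metrics(c)
    if (c$tp + c$fp > 0) expect_equal(m$purity, c$tp / (c$tp + c$fp))
    if (c$tp + c$fn > 0) expect_equal(m$sensitivity, c$tp / (c$tp + c$fn))
    if (c$tn + c$fp > 0) expect_equal(m$specificity, c$tn / (c$tn + c$fp))
    expect_equal(m$accuracy,
                 (c$tp + c$tn) / (c$tp + c$fp + c$tn + c$fn))
    if (!is.na(m$f1) && !is.na(m$purity) && !is.na(m$sensitivity) &&
        m$f1 > 0) {
      # harmonic mean lies between min and arithmetic mean
      expect_lte(m$f1, (m$purity + m$sensitivity) / 2 + 1e-12)
      expect_gte(m$f1, min(m$purity, m$sensitivity) - 1e-12)
    }
  }
  ideal <- core_metrics(confusion(c(1, 0), c(1, 0)))
  expect_equal(unlist(ideal[c("purity", "sensitivity", "specificity",
                              "accuracy", "f1")]),
               c(purity = 1, sensitivity = 1, specificity = 1,
                 accuracy = 1, f1 = 1))
  # undefined denominators are NA, not zero
  none_pos <- core_metrics(confusion(c(0, 0), c(0, 0)))
  expect_true(is.na(none_pos$purity))
  expect_true(is.na(none_pos$sensitivity))
})

test_that("false alarm rate is false positives per minute", {
  expect_equal(false_alarm_rate(137, 175), 0.7828571, tolerance = 1e-6)
  expect_equal(false_alarm_rate(0, 33), 0)
  expect_equal(false_alarm_rate(13, 20), 13 / 20)
  expect_error(false_alarm_rate(5, 0), "positive")
})

test_that("net sensitivity and specificity combine the two stages", {
  expect_equal(net_sensitivity(0.851, 0.415), 0.353165, tolerance = 1e-6)
  expect_equal(net_sensitivity(1, 0.7), 0.7)
  expect_equal(net_sensitivity(0.5, 0.5), 0.25)
  expect_error(net_sensitivity(1.2, 0.5), "\\[0, 1\\]")
  expect_equal(net_specificity(100, 100, 0), 1)
  expect_equal(net_specificity(120, 60, 180), 0.5)
  set.seed(61)
  for (i in 1:10) {
    td <- sample(0:500, 1); tc <- sample(0:500, 1); fp <- sample(0:50, 1)
    if (td + tc + fp == 0) next
    expect_equal(net_specificity(td, tc, fp), (td + tc) / (td + tc + fp))
  }
})

test_that("pearson correlation matches the covariance formula", {
  expect_equal(pearson_correlation(1:5, 1:5), 1)
  expect_equal(pearson_correlation(5:1, 1:5), -1)
  x <- c(3, 7, 1, 9, 4); y <- c(10, 30, 8, 41, 15)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_correlation(x, y), oracle, tolerance = 1e-12)
  expect_true(is.na(pearson_correlation(c(1, 1, 1), 1:3)))
  expect_error(pearson_correlation(1:2, 1:2), ">= 3")
})

test_that("Poisson planning reproduces the clinical arithmetic", {
  plan <- poisson_min_events(0.353)
  expect_equal(plan$n, 1 / 0.353, tolerance = 1e-12)
  expect_equal(plan$n, 2.83, tolerance = 0.005)
  expect_identical(plan$n_ceiling, 3)
  expect_identical(poisson_min_events(1)$n_ceiling, 1)
  expect_identical(poisson_min_events(0.25, x = 2)$n, 8)
  # n * p = x exactly before rounding
  for (p in c(0.1, 0.353, 0.9)) {
    expect_equal(poisson_min_events(p, x = 1.7)$n * p, 1.7,
                 tolerance = 1e-12)
  }
  expect_error(poisson_min_events(0), "0, 1")
  expect_error(poisson_min_events(0.5, x = -1), "positive")
})

test_that("blood volume and processing time follow the planning chain", {
  n <- poisson_min_events(0.353)$n
  plan <- blood_volume_and_time(n, c(0.4, 0.5), 3)
  expect_equal(plan$volume_ml, c(n / 0.5, n / 0.4), tolerance = 1e-12)
  expect_equal(plan$volume_ml, c(5.7, 7.1), tolerance = 0.02)
  # 7 mL at 3 uL/min is ~38.9 h
  expect_equal(blood_volume_and_time(7 * 0.5, c(0.5, 0.5), 3)$time_hours[1],
               38.9, tolerance = 0.01)
  # unit identity
  ez <- blood_volume_and_time(10, c(1, 1), 1000)
  expect_equal(ez$volume_ml, c(10, 10))
  expect_equal(ez$time_hours, c(10 / 60, 10 / 60))
  expect_error(blood_volume_and_time(3, c(0, 1), 3), "positive")
})

test_that("theoretical %CV is the Poisson counting law", {
  expect_equal(theoretical_cv(100), 10)
  expect_equal(theoretical_cv(5), 44.72136, tolerance = 1e-5)
  # Monte-Carlo cross-check
  set.seed(62)
  draws <- stats::rpois(2e5, 5)
  expect_equal(100 * stats::sd(draws) / mean(draws), theoretical_cv(5),
               tolerance = 0.02)
  # strictly decreasing over the spike ladder
  ladder <- theoretical_cv(c(5, 10, 30, 50))
  expect_true(all(diff(ladder) < 0))
  expect_error(theoretical_cv(0), "positive")
})

test_that("combined variance adds sources with signed covariance", {
  expect_equal(combined_variance(4, 0, 0), 4)
  expect_equal(combined_variance(4, 9, 3), 19)
  expect_equal(combined_variance(4, 9, -3), 7)
  expect_warning(out <- combined_variance(1, 1, -2), "floored")
  expect_equal(out, 0)
  # two independent Poisson streams: empirical variance of the sum
  set.seed(63)
  a <- stats::rpois(5e4, 4); b <- stats::rpois(5e4, 9)
  expect_equal(stats::var(a + b), combined_variance(4, 9, 0),
               tolerance = 0.05)
  expect_error(combined_variance(-1, 0), ">= 0")
})

test_that("fixed-count subsampling takes nested stream prefixes", {
  ev <- data.frame(label = c("NC", "NC", "CTCC", "NC", "NC", "NC", "CTCC",
                             "NC", "CTCC"),
                   t = 1:9)
  subs <- spiking_subsample(ev, c(1, 2, 3))
  expect_identical(nrow(subs[["1"]]), 3L)
  expect_identical(nrow(subs[["2"]]), 7L) # through the 2nd cluster
  expect_identical(nrow(subs[["3"]]), 9L)
  # nesting
  expect_true(all(subs[["1"]]$t %in% subs[["2"]]$t))
  expect_true(all(subs[["2"]]$t %in% subs[["3"]]$t))
  # zero target: empty subset
  expect_identical(nrow(spiking_subsample(ev, 0)[["0"]]), 0L)
  # unattainable targets dropped with a warning
  expect_warning(short <- spiking_subsample(ev, c(2, 50)), "unattainable")
  expect_identical(names(short), "2")
})

test_that("cv_study separates counting and volume variability", {
  # zero-variance replicates: observed %CV is exactly 0
  fixed <- list("10" = rep(10, 5))
  rep0 <- cv_study(fixed)
  expect_equal(rep0$observed_cv, 0)
  expect_equal(rep0$theoretical_cv, theoretical_cv(10))
  # ideal detector on Poisson replicates: observed consistent with theory
  set.seed(64)
  counts <- list("5" = stats::rpois(80, 5), "30" = stats::rpois(80, 30))
  rep1 <- cv_study(counts)
  for (i in 1:2) {
    mu <- rep1$target[i]
    nrep <- 80
    stat <- (nrep - 1) * rep1$count_variance[i] / mu
    expect_gt(stat, stats::qchisq(0.005, nrep - 1))
    expect_lt(stat, stats::qchisq(0.995, nrep - 1))
  }
  # volume term enters through the summed variance
  vol <- list("10" = c(100, 120, 90, 110, 95))
  rep2 <- cv_study(list("10" = rep(10, 5)), volume_counts = vol)
  expect_gt(rep2$volume_variance, 0)
  expect_equal(rep2$combined_variance,
               10 + rep2$volume_variance, tolerance = 1e-12)
  expect_error(cv_study(list("5" = c(1, 2))), ">= 3")
})
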