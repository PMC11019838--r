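# ROI detection chain: clot handling, filtering, normalization, anomaly
# scoring, peak extraction, equalization, FWHM, width gate.

test_that("cumulative scatter is the element-wise channel sum", {
  m <- matrix(stats::rnorm(300), 100, 3,
              dimnames = list(NULL, c("scatter405", "scatter488",
                                      "scatter633")))
  seg <- trace_segment(m, 1000)
  expect_equal(cumulative_scatter(seg), m[, 1] + m[, 2] + m[, 3])
  z <- trace_segment(m * 0, 1000)
  expect_true(all(cumulative_scatter(z) == 0))
})

test_that("independent channel variances add to ~1.132 V^2 in the sum", {
  set.seed(42)
  n <- 2e5
  m <- cbind(scatter405 = stats::rnorm(n, 0, sqrt(0.169)),
             scatter488 = stats::rnorm(n, 0, sqrt(0.452)),
             scatter633 = stats::rnorm(n, 0, sqrt(0.511)))
  cum <- cumulative_scatter(trace_segment(m, 60000))
  expect_equal(stats::var(cum), 1.132, tolerance = 0.02)
})

test_that("clot detection uses a strict 1.75 V threshold", {
  params <- detection_params()
  expect_false(detect_clot(rep(3.2, 100), params))
  # exactly at the threshold: not a clot (strict inequality)
  x <- drop(scale(stats::rnorm(1000))) * 1.75
  expect_equal(stats::sd(x), 1.75)
  expect_false(detect_clot(x, params))
  expect_true(detect_clot(x * 1.01, params))
  # injected random-walk drift with sd 2.5 V
  set.seed(9)
  rw <- cumsum(stats::rnorm(5000))
  rw <- drop(scale(rw)) * 2.5
  expect_true(detect_clot(rw, params))
})

test_that("clot correction removes drift, preserves the mean, caps at 3 passes", {
  params <- detection_params()
  # clean segment: untouched, zero iterations
  seg <- noise_segment(duration = 1)
  out <- correct_clot(seg, params)
  expect_identical(out$segment$data, seg$data)
  expect_identical(out$report$iterations, 0L)
  expect_false(out$report$detected)
  # linear ramp + noise with cumulative sd ~3 V: corrected below 1.75 V
  n <- 60000
  set.seed(10)
  ramp <- seq(0, 10, length.out = n) / 3
  m <- cbind(scatter405 = ramp + stats::rnorm(n, 0, 0.4),
             scatter488 = ramp + stats::rnorm(n, 0, 0.65),
             scatter633 = ramp + stats::rnorm(n, 0, 0.7))
  seg2 <- trace_segment(m, 60000)
  pre_means <- colMeans(m)
  expect_gt(stats::sd(cumulative_scatter(seg2)), 1.75)
  out2 <- correct_clot(seg2, params)
  expect_true(out2$report$detected)
  expect_lt(out2$report$final_std, 1.75)
  expect_lte(out2$report$final_std, out2$report$initial_std)
  expect_equal(colMeans(out2$segment$data), pre_means, tolerance = 1e-6)
  # fast oscillation a moving average cannot remove: exactly 3 iterations
  t <- seq_len(n) / 60000
  osc <- 3 * sin(2 * pi * 3000 * t)
  m3 <- cbind(scatter405 = osc, scatter488 = osc, scatter633 = osc)
  out3 <- correct_clot(trace_segment(m3, 60000), params)
  expect_identical(out3$report$iterations, 3L)
  expect_gt(out3$report$final_std, 1.75)
})

test_that("band-pass filter matches the analytic Butterworth response", {
  params <- detection_params()
  fs <- 60000
  zero <- trace_segment(matrix(0, 1000, 3,
                               dimnames = list(NULL, scatter_channels <-
                                 c("scatter405", "scatter488", "scatter633"))),
                        fs)
  expect_true(all(bandpass_filter(zero, params)$data == 0))
  # DC rejection
  dc <- trace_segment(matrix(5, 30000, 3,
                             dimnames = list(NULL, scatter_channels)), fs)
  expect_lt(abs(mean(bandpass_filter(dc, params)$data[, 1])), 0.05)
  # tone attenuation vs analog Butterworth magnitude at prewarped
  # frequencies, squared for the forward-backward application
  t <- seq_len(60000) / fs
  tone <- function(f) sin(2 * pi * f * t)
  m <- cbind(scatter405 = tone(1000), scatter488 = tone(25000),
             scatter633 = tone(1000))
  filt <- bandpass_filter(trace_segment(m, fs), params)
  rms_mid <- function(x) {
    n <- length(x)
    sqrt(mean(x[(n %/% 4):(3 * n %/% 4)]^2))
  }
  gain <- function(f) {
    warp <- function(f) 2 * fs * tan(pi * f / fs)
    wl <- warp(50); wh <- warp(10000); w <- warp(f)
    om <- (w^2 - wl * wh) / ((wh - wl) * w)
    (1 / sqrt(1 + om^4))^2
  }
  emp_ratio <- rms_mid(filt$data[, "scatter488"]) /
    rms_mid(filt$data[, "scatter405"])
  expect_equal(emp_ratio, gain(25000) / gain(1000), tolerance = 0.05)
  # band beyond Nyquist is rejected up front
  low_fs <- trace_segment(matrix(0, 100, 3,
                                 dimnames = list(NULL, scatter_channels)),
                          15000)
  expect_error(bandpass_filter(low_fs, params), "Nyquist")
})

test_that("normalization maps each scatter channel onto [0, 1]", {
  m <- cbind(scatter405 = seq(-1, 3, length.out = 100),
             scatter488 = stats::runif(100),
             scatter633 = stats::rnorm(100))
  seg <- trace_segment(m, 1000)
  nrm <- normalize_segment(seg)
  expect_equal(range(nrm$data[, "scatter405"]), c(0, 1))
  expect_equal(nrm$data[, "scatter405"], (m[, 1] + 1) / 4)
  # idempotence and scale invariance
  expect_equal(normalize_segment(nrm)$data, nrm$data)
  doubled <- trace_segment(m * 2, 1000)
  expect_equal(normalize_segment(doubled)$data, nrm$data)
  # constant channel collapses to 0 with a warning
  m2 <- m; m2[, "scatter488"] <- 7
  expect_warning(out <- normalize_segment(trace_segment(m2, 1000)),
                 "constant")
  expect_true(all(out$data[, "scatter488"] == 0))
})

test_that("T^2 with all components equals the squared Mahalanobis distance", {
  set.seed(33)
  n <- 500
  base <- matrix(stats::rnorm(3 * n), n, 3) %*%
    matrix(c(1, 0.4, 0.1, 0, 1, 0.3, 0, 0, 1), 3, 3)
  colnames(base) <- c("scatter405", "scatter488", "scatter633")
  seg <- trace_segment(base, 1000)
  t2 <- hotelling_t2_trace(seg, detection_params(n_principal_components = 3))
  oracle <- stats::mahalanobis(base, colMeans(base), stats::cov(base))
  expect_equal(t2, unname(oracle), tolerance = 1e-8)
  # an observation at the centroid scores zero
  sym <- rbind(base, sweep(-base, 2, 2 * colMeans(base), "+")) # symmetrized
  sym <- rbind(sym, colMeans(sym))
  colnames(sym) <- colnames(base)
  t2s <- hotelling_t2_trace(trace_segment(sym, 1000),
                            detection_params(n_principal_components = 3))
  expect_lt(t2s[nrow(sym)], 1e-12)
  # retained-component count truncates the sum
  t2p <- hotelling_t2_trace(seg, detection_params(n_principal_components = 2))
  expect_true(all(t2p <= t2 + 1e-10))
})

test_that("find_rois extracts supra-threshold runs with a single peak each", {
  params <- detection_params()
  expect_identical(nrow(find_rois(rep(0, 1000), params)), 0L)
  # triangular excursion 0 -> 50 -> 0 with analytic crossing points
  t2 <- c(rep(0, 99), seq(0, 50, length.out = 26),
          seq(50, 0, length.out = 26)[-1], rep(0, 100))
  rois <- find_rois(t2, params)
  expect_identical(nrow(rois), 1L)
  expect_identical(rois$peak_index, 125L)      # apex of the triangle
  expect_equal(rois$peak_t2, 50)
  # strict crossings: ramp value 2k at sample 100+k, so >10 from sample 106
  expect_identical(rois$start_index, 106L)
  expect_identical(rois$end_index, 144L)
  # two local maxima in one run keep the taller one only
  t2b <- c(rep(0, 10), 20, 15, 30, rep(0, 10))
  rois_b <- find_rois(t2b, params)
  expect_identical(nrow(rois_b), 1L)
  expect_identical(rois_b$peak_index, 13L)
  expect_error(find_rois(c(-1, 5), params), "non-negative")
})

test_that("height equalization matches the pointwise linear-interpolant oracle", {
  # single symmetric pulse of height 0.8 scales to unit peak
  w <- 0.8 * exp(-((1:41) - 21)^2 / 50)
  eq <- equalize_heights(w)
  expect_equal(max(eq), 1)
  expect_equal(eq, w / 0.8)
  # arbitrary two-peak fixture: interior samples divided by the line
  # joining the peak heights
  w2 <- c(0.1, 0.5, 1.0, 0.6, 0.35, 0.4, 0.3, 0.1)
  peaks <- peakcascade:::local_maxima(w2)
  expect_identical(peaks, c(3L, 6L))
  eq2 <- equalize_heights(w2)
  line <- approx(c(3, 6), c(1.0, 0.4), xout = 3:6)$y
  expect_equal(eq2[3:6], w2[3:6] / line)
  expect_equal(eq2[1:3], w2[1:3] / 1.0)
  expect_equal(eq2[6:8], w2[6:8] / 0.4)
  expect_equal(eq2[peaks], c(1, 1))
  # idempotence
  expect_equal(equalize_heights(eq2), eq2, tolerance = 1e-12)
  expect_warning(equalize_heights(rep(0, 5)), "all-zero")
})

test_that("FWHM measurement matches closed forms", {
  # symmetric triangle, base 40, apex 1 -> FWHM 20
  tri <- pmax(0, 1 - abs(-20:20) / 20)
  expect_identical(measure_fwhm(tri, 21L), 20L)
  # Gaussian sigma = 5 -> 2.355 * 5 = 11.8 samples
  g <- exp(-((-30:30)^2) / (2 * 25))
  expect_equal(measure_fwhm(g, 31L, round = FALSE), 2 * sqrt(2 * log(2)) * 5,
               tolerance = 0.01)
  expect_identical(measure_fwhm(g, 31L), 12L)
  # rendered two-cell cluster pulse exceeds the gate
  pk <- render_peak("ctcc", 26, c(a = 1))
  w <- pk[, 1] / max(pk[, 1])
  expect_gte(measure_fwhm(w, which.max(w)), 17L)
  # no crossing inside the region: flagged, region length returned
  flat <- rep(1, 9)
  f <- measure_fwhm(flat, 5L)
  expect_identical(as.integer(f), 9L)
  expect_true(attr(f, "flagged"))
})

test_that("the width gate is an inclusive-at-17 pure filter", {
  ev <- data.frame(fwhm_samples = c(12, 16, 17, 30), id = 1:4)
  kept <- width_gate(ev, detection_params())
  expect_identical(kept$id, 3:4)
  expect_identical(width_gate(kept, detection_params()), kept) # idempotent
  expect_identical(nrow(width_gate(ev[0, ], detection_params())), 0L)
})

test_that("full chain finds injected clusters and nothing in pure noise", {
  params <- detection_params()
  cfg <- short_cfg(duration = 30, ctcc_rate = 8, single_cell_rate = 30,
                   clot_rate = 0)
  day <- simulate_day(cfg, 1, seed = 11)
  det <- detect_rois(day$segments[[1]], params)
  tr <- day$truth[day$truth$kind == "ctcc", ]
  hits <- vapply(seq_len(nrow(tr)), function(i) {
    any(det$events$start_index <= tr$end_index[i] &
        det$events$end_index >= tr$start_index[i])
  }, logical(1))
  expect_true(all(hits))
  # single cells (below the gate) never survive
  sc <- day$truth[day$truth$kind == "single_cell", ]
  sc_hits <- vapply(seq_len(nrow(sc)), function(i) {
    any(det$events$start_index <= sc$end_index[i] &
        det$events$end_index >= sc$start_index[i])
  }, logical(1))
  expect_false(any(sc_hits))
  # event-free noise yields zero gated ROIs
  det0 <- detect_rois(noise_segment(duration = 10, seed = 77), params)
  expect_identical(nrow(det0$events), 0L)
})

test_that("gfp ground-truth regions co-locate with simulated clusters", {
  params <- detection_params()
  cfg <- short_cfg(duration = 20, ctcc_rate = 9, single_cell_rate = 0,
                   clot_rate = 0)
  day <- simulate_day(cfg, 1, seed = 15)
  seg <- day$segments[[1]]
  gfp <- detect_gfp_rois(seg, params)
  tr <- day$truth[day$truth$kind == "ctcc", ]
  expect_identical(nrow(gfp), nrow(tr))
  for (i in seq_len(nrow(tr))) {
    expect_true(any(gfp$start_index <= tr$end_index[i] &
                    gfp$end_index >= tr$start_index[i]))
  }
  expect_true(all(is.na(gfp$t2_score)))
  # a segment with no fluorescence events yields none
  gfp0 <- detect_gfp_rois(noise_segment(duration = 5, seed = 3), params)
  expect_identical(nrow(gfp0), 0L)
})
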