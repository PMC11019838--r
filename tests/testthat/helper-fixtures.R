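# Shared fixtures. Everything is generated in code; short segments and a
# reduced sample rate keep unit tests fast while the acceptance tests run
# full-scale 90 s segments.

# A config with full 60 kHz sampling but a short segment.
short_cfg <- function(duration = 10, ...) {
  sim_config(segment_duration = duration, ...)
}

# A lightweight config for rate/determinism checks where waveform detail is
# irrelevant.
coarse_cfg <- function(duration = 60, ...) {
  sim_config(sample_rate = 6000, segment_duration = duration, ...)
}

# A noise-only segment (no events, no clots).
noise_segment <- function(duration = 10, seed = 7, sample_rate = 60000) {
  cfg <- sim_config(sample_rate = sample_rate, segment_duration = duration,
                    ctcc_rate = 0, single_cell_rate = 0, clot_rate = 0)
  simulate_day(cfg, 1, seed = seed)$segments[[1]]
}

# 297-point synthetic feature examples: "wide" cluster-like pulses with a
# 405-dominant amplitude signature vs "narrow" confounder-like pulses with a
# 633-dominant signature, linearly separable at this SNR.
make_feature_examples <- function(n_pos, n_neg, seed = 1, noise_sd = 0.3) {
  with_seed <- peakcascade:::with_seed
  with_seed(seed, {
    one <- function(wide) {
      len <- if (wide) stats::runif(1, 24, 40) else stats::runif(1, 18, 24)
      amp <- if (wide) c(a = 5, b = 4.5, c = 4) else c(a = 1.5, b = 3, c = 5)
      x <- stats::rnorm(297, 0, noise_sd)
      pk <- render_peak("x", len, amp * exp(stats::rnorm(1, 0, 0.15)))
      ctr <- attr(pk, "center")
      for (ch in 1:3) {
        mid <- (ch - 1) * 99 + 50
        lo <- max(1, ctr - 49); hi <- min(nrow(pk), ctr + 49)
        rows <- (mid - (ctr - lo)):(mid + (hi - ctr))
        x[rows] <- x[rows] + pk[lo:hi, ch]
      }
      x
    }
    x <- rbind(t(vapply(seq_len(n_pos), function(i) one(TRUE), numeric(297))),
               t(vapply(seq_len(n_neg), function(i) one(FALSE), numeric(297))))
    y <- c(rep(1L, n_pos), rep(0L, n_neg))
    idx <- sample(length(y))
    list(x = x[idx, , drop = FALSE], y = y[idx])
  })
}

# A tiny trained-network stand-in that predicts everything positive.
always_positive_cascade <- function() {
  spec <- network_spec(channel_widths = c(2L, 2L, 2L, 2L, 2L, 2L))
  net <- peakcascade:::cnn_init(spec, seed = 1)
  net$fc$W[] <- 0
  net$fc$b <- 20
  structure(list(stages = list(net),
                 histories = list(), stage_sizes = data.frame(),
                 config = train_config(), spec = spec),
            class = "peak_cascade")
}
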