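fs <- 12207

test_that("band-pass preserves passband tones and rejects stopband tones", {
  n <- 2e5
  tone <- function(f) sin(2 * pi * f * (0:(n - 1)) / fs)
  mid <- 4e4:1.6e5
  # 100 Hz through the LFP band: preserved within 1%
  y <- bandpass(waveform(tone(100), fs), 3, 300)
  expect_equal(max(abs(y$samples[mid])), 1, tolerance = 0.01)
  # 100 Hz through the MUA band: attenuated at least 40 dB
  y2 <- bandpass(waveform(tone(100), fs), 300, 6000)
  expect_lt(20 * log10(max(abs(y2$samples[mid]))), -40)
  # 1 kHz through the MUA band: preserved
  y3 <- bandpass(waveform(tone(1000), fs), 300, 6000)
  expect_equal(max(abs(y3$samples[mid])), 1, tolerance = 0.01)
  # DC offset removed by any band with low >= 3 Hz
  y4 <- bandpass(waveform(rep(2.5, 4096), fs), 3, 300)
  expect_lt(max(abs(y4$samples)), 1e-10)
  # band edges above Nyquist are an error
  expect_error(bandpass(waveform(tone(100), fs), 300, 7000), "Nyquist")
})

test_that("filtering is idempotent in the passband", {
  n <- 2e5
  x <- waveform(sin(2 * pi * 100 * (0:(n - 1)) / fs), fs)
  once <- bandpass(x, 3, 300)
  twice <- bandpass(once, 3, 300)
  a1 <- max(abs(once$samples[4e4:1.6e5]))
  a2 <- max(abs(twice$samples[4e4:1.6e5]))
  expect_lt(abs(a2 - a1) / a1, 0.02)
})

test_that("zero-phase filtering does not delay a transient", {
  n <- 8192
  x <- numeric(n); x[4096] <- 1
  y <- bandpass(waveform(x, fs), 300, 6000)
  expect_equal(which.max(abs(y$samples)), 4096)
})

test_that("spike detection implements the -3 SD crossing rule", {
  # constant signal: no spikes, zero-variance guard
  expect_length(detect_spikes(waveform(rep(1, 1000), fs))$times, 0)
  # spikes in near-silence: every injected event found, nothing else
  tpl <- spike_template(fs)
  n <- fs * 2
  x <- numeric(n)
  at <- c(0.2, 0.5, 0.9, 1.4, 1.8)
  for (t0 in at) {
    i <- round(t0 * fs); x[i:(i + length(tpl$samples) - 1)] <-
      x[i:(i + length(tpl$samples) - 1)] + 8 * tpl$samples
  }
  set.seed(71)
  x <- x + rnorm(n, 0, 0.05)
  st <- detect_spikes(waveform(x, fs))
  # every injected event is recovered; with no refractory lockout the
  # damped second lobe of the biphasic shape may legitimately re-cross,
  # so extra detections must all sit inside an injected event's footprint
  found <- vapply(at, function(t0) any(abs(st$times - t0) < 2e-3),
                  logical(1))
  expect_true(all(found))
  near_event <- vapply(st$times, function(tt) any(tt - at > -1e-3 &
                                                  tt - at < 2.5e-3),
                       logical(1))
  expect_true(all(near_event))
  # with realistic noise, spikes 5x the noise SD are all recovered
  set.seed(72)
  noise <- bandpass(waveform(rnorm(n), fs), 300, 6000)$samples
  xs <- noise
  for (t0 in at) {
    i <- round(t0 * fs)
    xs[i:(i + length(tpl$samples) - 1)] <-
      xs[i:(i + length(tpl$samples) - 1)] + 5 * sd(noise) * tpl$samples
  }
  st2 <- detect_spikes(waveform(xs, fs))
  found <- vapply(at, function(t0) any(abs(st2$times - t0) < 2e-3),
                  logical(1))
  expect_true(all(found))
})

test_that("a trough crossing the threshold boundary flips detection", {
  # a single-sample deflection against a long noise carrier barely moves
  # mean and SD, so the threshold is effectively fixed while the trough is
  # scaled across it — a few percent of amplitude decides the detection,
  # mirroring how small crosstalk-induced amplitude shifts gain or lose
  # spikes
  set.seed(121)
  n <- 1e5
  carrier <- rnorm(n, 0, 1)
  thr <- mean(carrier) - 3 * sd(carrier)
  i0 <- 5e4
  deep <- carrier; deep[i0] <- 1.02 * thr       # trough just beyond
  shallow <- carrier; shallow[i0] <- 0.98 * thr # trough just short
  t_deep <- detect_spikes(waveform(deep, fs))$times
  t_shallow <- detect_spikes(waveform(shallow, fs))$times
  hit <- function(tt) any(abs(tt - i0 / fs) < 5e-4)
  expect_true(hit(t_deep))
  expect_false(hit(t_shallow))
  expect_equal(length(t_deep), length(t_shallow) + 1L)
})

test_that("PSTH accumulates counts per bin across triggers", {
  # all-empty train: zeros
  z <- psth(spike_train(numeric(0)), triggers = c(1, 2, 3), bin = 1e-3,
            window = 10e-3)
  expect_true(all(z$count == 0))
  expect_equal(nrow(z), 10)
  # single spike 2.5 ms after a trigger lands in the third 1-ms bin
  s <- psth(spike_train(1.0025), triggers = 1, bin = 1e-3, window = 10e-3)
  expect_equal(s$count[3], 1)
  expect_equal(sum(s$count), 1)
  # Poisson rate lambda: mean counts/bin ~ lambda * bin * n_triggers
  set.seed(81)
  lambda <- 20; T <- 250
  tr <- poisson_train(lambda, T)
  trig <- seq(1, 240, by = 4)
  h <- psth(tr, trig, bin = 1e-3, window = 50e-3)
  expected <- lambda * 1e-3 * length(trig)
  se <- sqrt(sum(h$count)) / nrow(h)
  expect_lt(abs(mean(h$count) - expected), 3 * se + 1e-9)
  expect_error(psth(tr, numeric(0)), "trigger")
})

test_that("cross-correlogram gives conditional probability per lag bin", {
  set.seed(91)
  # independent Poisson trains: flat at lambda_target * bin
  ref <- poisson_train(20, 30)
  tgt <- poisson_train(30, 30)
  cc <- crosscorrelogram(ref, tgt, bin = 1e-3, lag_window = 50e-3)
  p_expect <- 30 * 1e-3
  se_mean <- sqrt(p_expect / (length(ref$times) * nrow(cc)))
  expect_lt(abs(mean(cc$probability) - p_expect), 4 * se_mean)
  # copy shifted to the centre of the [3, 4) ms bin: unit peak there
  sh <- spike_train(ref$times + 3.5e-3)
  cc2 <- crosscorrelogram(ref, sh, bin = 1e-3, lag_window = 10e-3)
  pk <- cc2$probability[which.min(abs(cc2$lag - 3e-3))]
  expect_gte(pk, 1)           # every ref spike has its shifted partner
  # autocorrelogram of a single spike: self-pair excluded, all zero
  cc3 <- crosscorrelogram(spike_train(1), spike_train(1), bin = 1e-3,
                          lag_window = 10e-3)
  expect_true(all(cc3$probability == 0))
  expect_error(crosscorrelogram(spike_train(numeric(0)), tgt), "non-empty")
})

test_that("correlation matrix is symmetric with unit diagonal and flags dead channels", {
  set.seed(101)
  n <- fs * 2
  a <- rnorm(n)
  rec <- multichannel_recording(rbind(a, a, -a, rnorm(n)), fs)
  m <- correlation_matrix(rec, "lfp")
  expect_equal(diag(m), rep(1, 4), ignore_attr = TRUE)
  expect_equal(m, t(m), ignore_attr = TRUE)
  expect_equal(m[1, 2], 1, tolerance = 1e-10)   # duplicated channel
  expect_equal(m[1, 3], -1, tolerance = 1e-10)  # sign-flipped copy
  expect_lt(abs(m[1, 4]), 0.1)                  # independent noise
  # zero-variance channel flagged
  rec2 <- multichannel_recording(rbind(a, rep(0, n)), fs)
  m2 <- correlation_matrix(rec2, "lfp")
  expect_true(2 %in% attr(m2, "flagged_channels"))
  expect_true(is.na(m2[1, 2]))
})

test_that("Welch coherence is 1 against itself and its filtered copy, near 0 for noise", {
  set.seed(111)
  n <- fs * 60
  a <- rnorm(n); b <- rnorm(n)
  af <- bandpass(waveform(a, fs), 3, 300)$samples
  rec <- multichannel_recording(rbind(a, af, b), fs)
  cp <- coherence_profile(rec, ref_channel = 1)
  expect_equal(dim(cp$coherence)[1], 3)
  expect_true(all(cp$frequencies >= 3 & cp$frequencies <= 4000))
  expect_true(all(cp$coherence >= 0 & cp$coherence <= 1 + 1e-12))
  expect_true(all(cp$coherence[1, ] == 1))          # self
  # linear filtering preserves coherence where the band passes (finite
  # Welch segments leak a little against the long LFP impulse response,
  # so "equal to 1" is approximate at segment resolution)
  inband <- cp$frequencies > 20 & cp$frequencies < 250
  expect_gt(min(cp$coherence[2, inband]), 0.95)
  expect_gt(median(cp$coherence[2, inband]), 0.99)
  # independent white noise: mean coherence well below 0.05
  expect_lt(mean(cp$coherence[3, ]), 0.05)
  # record too short for 4 segments
  tiny <- multichannel_recording(rbind(rnorm(900), rnorm(900)), fs)
  expect_error(coherence_profile(tiny), "short")
})
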