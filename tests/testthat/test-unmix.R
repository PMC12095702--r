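model_ref <- four_line_model(ref_params)

test_that("sinc probe satisfies its spectral invariants", {
  pr <- make_sinc_probe(4000, 0.1, 12207)
  n <- length(pr$samples)
  expect_true(n %% 2 == 1)
  expect_equal(which.max(pr$samples), (n + 1) / 2)   # peak at record centre
  expect_equal(pr$samples, rev(pr$samples))          # even symmetry
  expect_equal(max(pr$samples), 1)                   # unit peak
  X <- Mod(fft(pr$samples))
  f <- (seq_len(n) - 1) * pr$fs / n
  half <- f <= pr$fs / 2
  inb <- f[half] > 0.05 * 4000 & f[half] < 0.95 * 4000
  flat <- 20 * log10(X[half][inb] / median(X[half][inb]))
  expect_lt(max(abs(flat)), 1)                       # flat within +/- 1 dB
  eout <- sum(X[f > 4000 & f < pr$fs - 4000]^2) / sum(X^2)
  expect_lt(eout, 0.01)                              # < 1% energy out of band
  # Parseval
  expect_equal(sum(pr$samples^2), sum(X^2) / n, tolerance = 1e-10)
  expect_error(make_sinc_probe(7000, 0.1, 12207), "Nyquist")
  expect_error(make_sinc_probe(4000, 0.001, 12207), "64 samples")
})

test_that("probe and model routes to the transfer set agree in-band", {
  pr <- make_sinc_probe(4000, 0.1, 12207)
  ps <- probe_transfer_set(model_ref, pr)
  ok <- ps$valid
  expect_gt(sum(ok), 100)
  ms <- model_transfer_set(model_ref, ps$frequencies[ok])
  for (h in c("H_N", "H_M", "H_F")) {
    rel <- Mod(ps[[h]][ok] - ms[[h]]) / Mod(ms[[h]])
    expect_lt(max(rel), 0.01)
  }
  # out-of-band bins are invalid and NA, never extrapolated
  expect_true(all(is.na(ps$H_N[!ok])))
  expect_true(all(ps$frequencies[ok] <= 4000))
})

test_that("transfer set obeys the adjacency ordering and matches the dense oracle", {
  f <- c(3, 30, 300, 1000, 2500, 4000, 6000)
  hs <- model_transfer_set(model_ref, f)
  expect_true(all(Mod(hs$H_N) >= Mod(hs$H_M)))
  expect_true(all(Mod(hs$H_M) >= Mod(hs$H_F)))
  expect_true(all(Mod(hs$H_N) <= 1))
  V <- oracle_four_line(ref_params, f)
  expect_equal(hs$H_N, V[, 2] / V[, 1], tolerance = 1e-10)
  expect_equal(hs$H_M, V[, 3] / V[, 1], tolerance = 1e-10)
  expect_equal(hs$H_F, V[, 4] / V[, 1], tolerance = 1e-10)
  # |H_N| grows strictly over 1-4 kHz
  g <- model_transfer_set(model_ref, seq(1000, 4000, by = 250))
  expect_true(all(diff(Mod(g$H_N)) > 0))
  # no coupling: all three vanish
  p0 <- chain_parameters(R_Imp = Inf, C_Imp = 0, R_Int = Inf, C_Int = 0)
  h0 <- model_transfer_set(four_line_model(p0), f)
  expect_identical(Mod(h0$H_N), rep(0, length(f)))
  expect_identical(Mod(h0$H_F), rep(0, length(f)))
})

test_that("forward mixing is the identity without coupling and per-bin exact", {
  fs <- 12207; n <- 4096
  set.seed(21)
  x <- matrix(rnorm(4 * n), 4)
  cs <- column_signals(x, fs)
  p0 <- chain_parameters(R_Imp = Inf, C_Imp = 0, R_Int = Inf, C_Int = 0)
  y0 <- forward_mix(cs, four_line_model(p0))
  expect_equal(y0$samples, cs$samples, tolerance = 1e-12)
  # single integer-period tone on A only: B picks up |H_N| times it
  k <- 256; ftone <- k * fs / n
  tone <- sin(2 * pi * k * (0:(n - 1)) / n)
  cs1 <- column_signals(rbind(tone, 0, 0, 0), fs)
  y1 <- forward_mix(cs1, model_ref)
  hs <- model_transfer_set(model_ref, ftone)
  amp <- function(v) sqrt(2 * mean(v^2))   # exact for a pure tone
  expect_equal(amp(y1$samples[2, ]), Mod(hs$H_N), tolerance = 1e-9)
  expect_equal(amp(y1$samples[3, ]), Mod(hs$H_M), tolerance = 1e-9)
  expect_equal(amp(y1$samples[4, ]), Mod(hs$H_F), tolerance = 1e-9)
})

test_that("back-correction inverts forward mixing to numerical precision", {
  fs <- 12207; n <- 2048
  set.seed(31)
  f_half <- (0:(n %/% 2)) * fs / n
  for (trial in 1:20) {
    p <- if (trial <= 10) ref_params else random_chain_parameters()
    # keep the draw inside the conditioning envelope the correction
    # guarantees (diagonal dominance for coupling magnitudes below 0.5):
    # scale the coupling blocks down if a draw couples too hard
    repeat {
      hmax <- max(Mod(model_transfer_set(four_line_model(p), f_half)$H_N))
      if (hmax <= 0.25) break
      # H is nonlinear in the coupling admittance, so shrink iteratively
      for (el in c("C_Imp", "C_Int")) p <- scale_element(p, el, 0.2)
      for (el in c("R_Imp", "R_Int")) p <- scale_element(p, el, 5)
    }
    x <- matrix(rnorm(4 * n), 4)
    cs <- column_signals(x, fs)
    m <- four_line_model(p)
    rec <- backcorrect(forward_mix(cs, m), m)
    err <- sqrt(sum((rec$samples - x)^2) / sum(x^2))
    expect_lt(err, 1e-9)
    expect_true(rec$corrected)
    expect_length(attr(rec, "diagnostics")$bins_passed_through, 0)
  }
})

test_that("back-correction is linear and the trivial cases pass through", {
  fs <- 12207; n <- 1024
  set.seed(41)
  x <- matrix(rnorm(4 * n), 4); y <- matrix(rnorm(4 * n), 4)
  a <- 0.7; b <- -2.2
  m <- model_ref
  bc <- function(z) backcorrect(column_signals(z, fs), m)$samples
  expect_equal(bc(a * x + b * y), a * bc(x) + b * bc(y), tolerance = 1e-9)
  # no coupling: output equals input
  p0 <- chain_parameters(R_Imp = Inf, C_Imp = 0, R_Int = Inf, C_Int = 0)
  expect_equal(backcorrect(column_signals(x, fs),
                           four_line_model(p0))$samples, x,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("corrected signals are real with bounded energy change", {
  fs <- 12207; n <- 8192
  set.seed(51)
  x <- matrix(rnorm(4 * n), 4)
  obs <- forward_mix(column_signals(x, fs), model_ref)
  rec <- backcorrect(obs, model_ref)
  expect_true(is.numeric(rec$samples))         # imaginary part discarded
  # energy sanity bound: RMS change limited by 3 * h_max * max other RMS
  hs <- model_transfer_set(model_ref, (1:(n / 2)) * fs / n)
  h_max <- max(Mod(hs$H_N))
  rms <- function(v) sqrt(mean(v^2))
  for (i in 1:4) {
    delta <- rms(rec$samples[i, ] - obs$samples[i, ])
    expect_lt(delta, 3 * h_max * max(apply(obs$samples[-i, ], 1, rms)))
  }
})

test_that("ill-conditioned bins are passed through and reported", {
  fs <- 1000; n <- 256
  # an artificial transfer set with |H| = 1 at every bin: the mixing matrix
  # is singular there, so every bin must be passed through untouched
  f_half <- (0:(n %/% 2)) * fs / n
  hs <- neuroxtalk:::new_column_transfer_set(
    f_half,
    H_N = rep(1 + 0i, length(f_half)),
    H_M = rep(1 + 0i, length(f_half)),
    H_F = rep(1 + 0i, length(f_half)))
  set.seed(61)
  x <- matrix(rnorm(4 * n), 4)
  out <- backcorrect(column_signals(x, fs), hs)
  d <- attr(out, "diagnostics")
  expect_equal(length(d$bins_passed_through), n)
  expect_equal(out$samples, x, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("mixing rejects grids that do not match the signals", {
  fs <- 12207; n <- 1024
  x <- column_signals(matrix(rnorm(4 * n), 4), fs)
  wrong <- model_transfer_set(model_ref, (0:100) * fs / 512)
  expect_error(forward_mix(x, wrong), "grid")
  part <- probe_transfer_set(model_ref, make_sinc_probe(4000, 0.1, 12207))
  expect_error(backcorrect(x, part), "grid|valid")
})
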