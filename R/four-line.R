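#' Four-line transmission model
#'
#' Extension of the two-line network to the four adjacently routed channels
#' that form one column of the electrode grid. The four lines are
#' electrically identical; each neighboring pair is bridged by the parallel
#' combination of the implant-level and interconnect-level coupling paths.
#' The top line (A) is driven by the source; the passive lines are named by
#' routing distance from it: NEAR (B), MID (C) and FAR (D). Coupling to MID
#' and FAR is not modeled by dedicated bridges — it emerges from the chain
#' of adjacent bridges in the nodal solution.
#'
#' @param params a [chain_parameters()] object
#' @return An object of class `four_line_model`.
#' @export
four_line_model <- function(params) {
  stopifnot(inherits(params, "chain_parameters"))
  structure(list(params = params, n_lines = 4L), class = "four_line_model")
}

# Vectorized tridiagonal nodal solve of the four-line network, driven
# through line `drive` (1 or 4 by symmetry). Returns the four node voltages
# per unit source V_E as a list V[[1..4]] of complex vectors over f >= 0.
solve_four_line_nodes <- function(model, f, drive = 1L) {
  y <- line_admittances(model$params, f)
  Yt <- y$Ys + y$Ysh
  Yc <- y$Yc
  d <- list(Yt + Yc, Yt + 2 * Yc, Yt + 2 * Yc, Yt + Yc)  # node self-admittances
  r <- list(0, 0, 0, 0)
  r[[drive]] <- y$Ys
  # Thomas algorithm, off-diagonal entries all -Yc
  cp <- vector("list", 3); rp <- vector("list", 4)
  dp <- d
  rp[[1]] <- r[[1]]
  for (i in 2:4) {
    m <- (-Yc) / dp[[i - 1]]
    dp[[i]] <- d[[i]] - m * (-Yc)
    rp[[i]] <- r[[i]] - m * rp[[i - 1]]
  }
  V <- vector("list", 4)
  V[[4]] <- rp[[4]] / dp[[4]]
  for (i in 3:1) V[[i]] <- (rp[[i]] + Yc * V[[i + 1]]) / dp[[i]]
  V
}

new_column_transfer_set <- function(frequencies, H_N, H_M, H_F,
                                    valid = rep(TRUE, length(frequencies))) {
  structure(list(frequencies = frequencies, H_N = H_N, H_M = H_M, H_F = H_F,
                 valid = valid),
            class = "column_transfer_set")
}

#' @export
print.column_transfer_set <- function(x, ...) {
  ok <- x$valid
  cat("Column transfer set: ", length(x$frequencies), " bins (",
      sum(ok), " valid), ",
      signif(min(x$frequencies), 3), "-", signif(max(x$frequencies), 3),
      " Hz\n", sep = "")
  if (any(ok))
    cat(sprintf("  max |H_N| %.3g, |H_M| %.3g, |H_F| %.3g\n",
                max(Mod(x$H_N[ok])), max(Mod(x$H_M[ok])),
                max(Mod(x$H_F[ok]))))
  invisible(x)
}

#' Evaluate the column transfer set directly from the circuit
#'
#' Solves the four-line network at each grid frequency and returns the three
#' coupling transfer functions `H_N = V_NEAR/V_ACT`, `H_M = V_MID/V_ACT`,
#' `H_F = V_FAR/V_ACT` analytically per bin. This is the route used to
#' supply `H` on a recording's full FFT grid (the probe route is limited to
#' the probe bandwidth). At every frequency `|H_N| >= |H_M| >= |H_F|`, since
#' each additional adjacent bridge attenuates multiplicatively.
#'
#' @param model a [four_line_model()]
#' @param frequencies evaluation grid, Hz (`>= 0`; the DC bin is the
#'   resistive limit of the circuit)
#' @return A `column_transfer_set`.
#' @export
model_transfer_set <- function(model, frequencies) {
  stopifnot(inherits(model, "four_line_model"))
  if (any(!is.finite(frequencies)) || any(frequencies < 0))
    stop("frequencies must be finite and >= 0", call. = FALSE)
  V <- solve_four_line_nodes(model, frequencies)
  new_column_transfer_set(frequencies,
                          H_N = V[[2]] / V[[1]],
                          H_M = V[[3]] / V[[1]],
                          H_F = V[[4]] / V[[1]])
}

#' Band-limited sinc probe
#'
#' Time-symmetric sinc waveform with unit peak at the record center. Its
#' Fourier transform is flat (within a fraction of a dB) across the probe
#' bandwidth, which makes the FFT ratios that define the column transfer
#' functions well conditioned at every in-band bin.
#'
#' @param bandwidth one-sided bandwidth, Hz (must be below Nyquist)
#' @param duration record duration, s (`duration * fs >= 64` samples)
#' @param fs sampling rate, Hz
#' @return A [waveform()] with subclass `sinc_probe` and field `bandwidth`.
#' @examples
#' p <- make_sinc_probe(4000, 0.1, 12207)
#' @export
make_sinc_probe <- function(bandwidth, duration, fs) {
  if (bandwidth >= fs / 2)
    stop("probe bandwidth must be below the Nyquist frequency", call. = FALSE)
  if (bandwidth <= 0 || duration <= 0)
    stop("bandwidth and duration must be positive", call. = FALSE)
  n <- 2 * floor(duration * fs / 2) + 1     # odd length: peak exactly centered
  if (n < 64)
    stop("probe too short: need at least 64 samples", call. = FALSE)
  t <- (seq_len(n) - (n + 1) / 2) / fs
  x <- ifelse(t == 0, 1, sin(2 * pi * bandwidth * t) / (2 * pi * bandwidth * t))
  w <- waveform(x, fs, units = "normalized")
  w$bandwidth <- bandwidth
  class(w) <- c("sinc_probe", class(w))
  w
}

#' Estimate the column transfer set with a sinc probe
#'
#' Reproduces the simulation-side estimation procedure: the probe is
#' injected as source `V_IN` into the active line of the four-line network,
#' the four output signals `V_ACT`, `V_NEAR`, `V_MID`, `V_FAR` are simulated
#' in the frequency domain, and each transfer function is the ratio of the
#' FFT of the respective passive output to the FFT of the active output.
#' The estimate is only valid inside the probe bandwidth; out-of-band bins
#' (and any bin where `|FFT(V_ACT)|` falls below a numerical floor) are
#' marked invalid and returned as `NA`, never extrapolated.
#'
#' @param model a [four_line_model()]
#' @param probe a [make_sinc_probe()] waveform
#' @param floor_frac bins with `|FFT(V_ACT)|` below this fraction of the
#'   in-band maximum are marked invalid (default 0.1)
#' @return A `column_transfer_set` on the probe's positive FFT grid with a
#'   `valid` mask.
#' @export
probe_transfer_set <- function(model, probe, floor_frac = 0.1) {
  stopifnot(inherits(model, "four_line_model"), inherits(probe, "sinc_probe"))
  n <- length(probe$samples)
  fs <- probe$fs
  X <- stats::fft(probe$samples)
  # simulate the four outputs through the circuit on the full FFT grid
  outs <- lapply(1:4, function(i) {
    g <- full_fft_gain(function(f) solve_four_line_nodes(model, f)[[i]],
                       n, fs)
    Re(stats::fft(X * g, inverse = TRUE)) / n
  })
  k <- seq_len(n %/% 2)                     # positive-frequency bins
  f_pos <- k * fs / n
  F_act <- stats::fft(outs[[1]])[k + 1]
  inband <- f_pos <= probe$bandwidth
  floor_val <- floor_frac * max(Mod(F_act)[inband])
  valid <- inband & Mod(F_act) >= floor_val
  ratio <- function(v) {
    h <- stats::fft(v)[k + 1] / F_act
    h[!valid] <- NA_complex_
    h
  }
  new_column_transfer_set(f_pos,
                          H_N = ratio(outs[[2]]),
                          H_M = ratio(outs[[3]]),
                          H_F = ratio(outs[[4]]),
                          valid = valid)
}
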