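#' Amplitude-threshold spike detection
#'
#' Detects putative extracellular spikes on a MUA-band filtered trace as
#' negative-going crossings of `mean(x) - 3*SD(x)` (threshold multiple
#' configurable). No refractory lockout is applied; the spike time is the
#' sample at which the signal crosses the threshold. A zero-variance input
#' yields an empty train.
#'
#' @param x a [waveform()] (expected MUA-band filtered)
#' @param k threshold in standard deviations below the mean (default 3)
#' @return An object of class `spike_train`: strictly increasing `times`
#'   in seconds, plus the `threshold` used (same units as `x`).
#' @export
detect_spikes <- function(x, k = 3) {
  stopifnot(inherits(x, "waveform"))
  s <- x$samples
  sdv <- stats::sd(s)
  thr <- mean(s) - k * sdv
  if (sdv == 0) return(spike_train(numeric(0), thr))
  below <- s < thr
  cross <- which(!below[-length(below)] & below[-1]) + 1L
  spike_train(cross / x$fs, thr)
}

#' @rdname detect_spikes
#' @param times strictly increasing spike times, s
#' @param threshold detection threshold that produced the train
#' @export
spike_train <- function(times, threshold = NA_real_) {
  if (length(times) > 1 && is.unsorted(times, strictly = TRUE))
    stop("spike times must be strictly increasing", call. = FALSE)
  structure(list(times = as.numeric(times), threshold = threshold),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat("Spike train: ", length(x$times), " events",
      if (!is.na(x$threshold)) sprintf(", threshold %.3g", x$threshold),
      "\n", sep = "")
  invisible(x)
}

#' Peri-stimulus time histogram
#'
#' Counts spikes in fixed bins relative to each trigger, accumulated over
#' triggers: counts per bin at `t0 + t` with `t0` the trigger (stimulation
#' onset) and bins of width `bin` covering `[0, window)`.
#'
#' @param train a [spike_train()]
#' @param triggers trigger times, s (non-empty)
#' @param bin bin width, s (default 1 ms)
#' @param window histogram span after the trigger, s; must be a multiple of
#'   `bin`
#' @return A data frame with `t` (bin left edge, s, relative to trigger) and
#'   `count`.
#' @export
psth <- function(train, triggers, bin = 1e-3, window = 50e-3) {
  stopifnot(inherits(train, "spike_train"))
  if (length(triggers) == 0)
    stop("psth needs at least one trigger", call. = FALSE)
  nb <- window / bin
  if (abs(nb - round(nb)) > 1e-9)
    stop("window must be a whole number of bins", call. = FALSE)
  nb <- as.integer(round(nb))
  edges <- seq(0, window, by = bin)
  counts <- integer(nb)
  for (t0 in triggers) {
    rel <- train$times - t0
    rel <- rel[rel >= 0 & rel < window]
    if (length(rel))
      counts <- counts + tabulate(pmin(floor(rel / bin) + 1L, nb), nb)
  }
  data.frame(t = edges[-length(edges)], count = counts)
}

#' Spike cross-correlogram as conditional probability
#'
#' For each reference spike, target spikes are binned by lag within
#' `[-lag_window, lag_window)` and the counts normalized by the number of
#' reference spikes, giving the conditional probability of a target spike
#' at `t0 + t` per bin. When reference and target are the same train, each
#' spike's zero-lag pairing with itself is excluded so the autocorrelogram
#' does not saturate at probability 1.
#'
#' @param ref reference [spike_train()] (non-empty)
#' @param target target [spike_train()]
#' @param bin bin width, s (default 1 ms)
#' @param lag_window one-sided lag span, s
#' @return A data frame with `lag` (bin left edge, s) and `probability`.
#' @export
crosscorrelogram <- function(ref, target, bin = 1e-3, lag_window = 50e-3) {
  stopifnot(inherits(ref, "spike_train"), inherits(target, "spike_train"))
  if (length(ref$times) == 0)
    stop("cross-correlogram needs a non-empty reference train", call. = FALSE)
  self <- identical(ref$times, target$times)
  nb <- as.integer(round(2 * lag_window / bin))
  edges <- seq(-lag_window, lag_window, by = bin)
  counts <- numeric(nb)
  tt <- target$times
  for (i in seq_along(ref$times)) {
    lags <- tt - ref$times[i]
    keep <- lags >= -lag_window & lags < lag_window
    if (self) keep[i] <- FALSE           # a spike is not its own target
    lags <- lags[keep]
    if (length(lags))
      counts <- counts + tabulate(pmin(floor((lags + lag_window) / bin) + 1L,
                                       nb), nb)
  }
  data.frame(lag = edges[-length(edges)],
             probability = counts / length(ref$times))
}

#' Band-limited Pearson correlation matrix
#'
#' Channel-by-channel Pearson correlation computed on band-filtered signals
#' (LFP 3-300 Hz or MUA 300-6000 Hz by default). Zero-variance channels
#' yield `NA` entries and are reported in the `flagged_channels` attribute.
#'
#' @param rec a [multichannel_recording()] with at least 2 channels
#' @param band `"lfp"`, `"mua"`, or a numeric length-2 vector of band edges
#'   in Hz
#' @return Symmetric channels x channels correlation matrix with unit
#'   diagonal.
#' @export
correlation_matrix <- function(rec, band = "lfp") {
  stopifnot(inherits(rec, "multichannel_recording"))
  if (nrow(rec$samples) < 2)
    stop("correlation matrix needs at least 2 channels", call. = FALSE)
  edges <- band_edges(band)
  filt <- bandpass(rec, edges[1], edges[2])
  sds <- apply(filt$samples, 1, stats::sd)
  flagged <- which(sds == 0)
  m <- suppressWarnings(stats::cor(t(filt$samples)))
  diag(m) <- 1
  attr(m, "flagged_channels") <- flagged
  m
}

band_edges <- function(band) {
  if (is.character(band))
    switch(match.arg(band, c("lfp", "mua")), lfp = lfp_band(),
           mua = mua_band())
  else {
    stopifnot(is.numeric(band), length(band) == 2)
    band
  }
}

#' Welch magnitude-squared coherence against a reference channel
#'
#' Coherence of every channel with a reference channel as a function of
#' frequency, estimated by Welch's method: Hamming-windowed segments of
#' `2 * n_freq` samples with the given overlap, averaged cross- and
#' auto-spectra, `Coh = |Pxy|^2 / (Pxx * Pyy)`. With `n_freq = 256`
#' (segment length 512) this matches the common vendor dialect reporting
#' 256 positive-frequency values. Estimates are reported on the requested
#' band only (default 3 Hz to 4 kHz).
#'
#' @param rec a [multichannel_recording()]
#' @param ref_channel reference channel index (default 1)
#' @param n_freq number of positive-frequency values (default 256; the
#'   Welch segment length is `2 * n_freq`)
#' @param overlap fractional segment overlap (default 0.5)
#' @param fmin,fmax reported frequency range, Hz (defaults 3 and 4000)
#' @return An object of class `coherence_profile`: `frequencies` (Hz) and
#'   `coherence`, a channels x frequencies matrix in `[0, 1]` with the
#'   reference row identically 1.
#' @export
coherence_profile <- function(rec, ref_channel = 1, n_freq = 256,
                              overlap = 0.5, fmin = 3, fmax = 4000) {
  stopifnot(inherits(rec, "multichannel_recording"))
  L <- 2L * as.integer(n_freq)
  hop <- max(1L, as.integer(round(L * (1 - overlap))))
  n <- ncol(rec$samples)
  starts <- seq(1L, n - L + 1L, by = hop)
  if (length(starts) < 4)
    stop("record too short for Welch coherence: need >= 4 segments of ",
         L, " samples", call. = FALSE)
  win <- 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))  # Hamming
  seg_fft <- function(x) {
    segs <- vapply(starts, function(s) x[s:(s + L - 1)] * win,
                   numeric(L))
    stats::mvfft(segs)[2:(n_freq + 1), , drop = FALSE]  # positive bins
  }
  Fr <- seg_fft(rec$samples[ref_channel, ])
  Prr <- rowMeans(Mod(Fr)^2)
  nch <- nrow(rec$samples)
  coh <- matrix(NA_real_, nch, n_freq)
  for (i in seq_len(nch)) {
    if (i == ref_channel) { coh[i, ] <- 1; next }
    Fi <- seg_fft(rec$samples[i, ])
    Pii <- rowMeans(Mod(Fi)^2)
    Pri <- rowMeans(Fr * Conj(Fi))
    coh[i, ] <- Mod(Pri)^2 / (Prr * Pii)
  }
  f <- (1:n_freq) * rec$fs / L
  keep <- f >= fmin & f <= fmax
  structure(list(frequencies = f[keep],
                 coherence = coh[, keep, drop = FALSE],
                 ref_channel = ref_channel),
            class = "coherence_profile")
}

#' @export
print.coherence_profile <- function(x, ...) {
  cat("Coherence profile vs channel ", x$ref_channel, ": ",
      nrow(x$coherence), " channels x ", length(x$frequencies),
      " frequencies (", signif(min(x$frequencies), 3), "-",
      signif(max(x$frequencies), 3), " Hz)\n", sep = "")
  invisible(x)
}
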