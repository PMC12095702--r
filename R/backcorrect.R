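#' Four-channel column signals
#'
#' The signals of the four adjacently routed channels forming one column of
#' the electrode grid, ordered A (top, the line closest to the source in the
#' probe setup), B, C, D. All channels share length and sampling rate.
#'
#' @param samples a 4 x n numeric matrix (rows A, B, C, D) or a list of four
#'   equal-length vectors
#' @param fs sampling rate, Hz
#' @param corrected logical: whether these signals have been back-corrected
#' @return An object of class `column_signals`.
#' @export
column_signals <- function(samples, fs, corrected = FALSE) {
  if (is.list(samples)) samples <- do.call(rbind, samples)
  if (!is.matrix(samples) || nrow(samples) != 4L)
    stop("column signals must be a 4 x n matrix (channels A-D)",
         call. = FALSE)
  if (any(!is.finite(samples)))
    stop("column signals must be finite", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("sampling rate must be a positive scalar", call. = FALSE)
  rownames(samples) <- c("A", "B", "C", "D")
  structure(list(samples = samples, fs = fs, corrected = corrected),
            class = "column_signals")
}

#' @export
print.column_signals <- function(x, ...) {
  cat("Column signals (A-D): ", ncol(x$samples), " samples @ ", x$fs,
      " Hz", if (x$corrected) ", back-corrected", "\n", sep = "")
  invisible(x)
}

# Resolve the three coupling transfer functions on the full Hermitian FFT
# grid of a length-n record. `h` may be a four_line_model (evaluated
# analytically per bin, DC included) or a column_transfer_set whose grid
# must equal the non-negative FFT frequencies exactly (no interpolation).
column_hset_fft <- function(h, n, fs) {
  if (inherits(h, "four_line_model")) {
    hs <- model_transfer_set(h, (0:(n %/% 2)) * fs / n)
  } else if (inherits(h, "column_transfer_set")) {
    f_half <- (0:(n %/% 2)) * fs / n
    if (length(h$frequencies) != length(f_half) ||
        max(abs(h$frequencies - f_half)) > 1e-6 * fs)
      stop("transfer-set grid does not match the signals' FFT grid; ",
           "evaluate with model_transfer_set() on this grid", call. = FALSE)
    if (!all(h$valid))
      stop("transfer set contains invalid bins; supply a fully valid set ",
           "(model route) for mixing/back-correction", call. = FALSE)
    hs <- h
  } else {
    stop("h must be a four_line_model or column_transfer_set", call. = FALSE)
  }
  mirror <- function(g_half) {
    full_fft_gain(function(f) {
      # f is exactly the half grid by construction
      g_half
    }, n, fs)
  }
  list(H_N = mirror(hs$H_N), H_M = mirror(hs$H_M), H_F = mirror(hs$H_F))
}

# per-bin 4x4 mixing matrix rows (symmetric):
#   A: (1,  H_N, H_M, H_F)
#   B: (H_N, 1,  H_N, H_M)
#   C: (H_M, H_N, 1,  H_N)
#   D: (H_F, H_M, H_N, 1)
mixing_rows <- function(hn, hm, hf) {
  one <- rep(1 + 0i, length(hn))
  list(list(one, hn, hm, hf),
       list(hn, one, hn, hm),
       list(hm, hn, one, hn),
       list(hf, hm, hn, one))
}

#' Apply the forward crosstalk mixing to true column signals
#'
#' Each observed channel is its true signal plus the true signal of each of
#' the other three channels multiplied by the appropriate coupling transfer
#' function, applied per FFT bin with the symmetric 4 x 4 mixing matrix
#' (rows A:(1, H_N, H_M, H_F), B:(H_N, 1, H_N, H_M), C:(H_M, H_N, 1, H_N),
#' D:(H_F, H_M, H_N, 1)). The mixing is circular on the record's own FFT
#' grid; the inverse FFT uses Hermitian symmetry so outputs are real.
#'
#' @param truth a [column_signals()] object (the crosstalk-free signals)
#' @param h a [four_line_model()] (evaluated on the record's FFT grid) or a
#'   fully valid `column_transfer_set` on exactly that grid
#' @return A `column_signals` object of observed (crosstalk-corrupted)
#'   signals.
#' @export
forward_mix <- function(truth, h) {
  stopifnot(inherits(truth, "column_signals"))
  n <- ncol(truth$samples)
  H <- column_hset_fft(h, n, truth$fs)
  X <- lapply(1:4, function(i) stats::fft(truth$samples[i, ]))
  M <- mixing_rows(H$H_N, H$H_M, H$H_F)
  out <- matrix(0, 4, n)
  for (i in 1:4) {
    Yi <- M[[i]][[1]] * X[[1]] + M[[i]][[2]] * X[[2]] +
          M[[i]][[3]] * X[[3]] + M[[i]][[4]] * X[[4]]
    out[i, ] <- Re(stats::fft(Yi, inverse = TRUE)) / n
  }
  column_signals(out, truth$fs, corrected = FALSE)
}

# Unrolled Gaussian elimination of the per-bin 4x4 complex systems,
# vectorized across bins. No pivoting: the mixing matrix is diagonally
# dominant whenever back-correction is attempted (bins that are not are
# passed through by the caller).
solve_mixing_bins <- function(M, Y) {
  A <- lapply(M, function(row) lapply(row, identity))
  B <- Y
  for (k in 1:3) {
    for (i in (k + 1):4) {
      m <- A[[i]][[k]] / A[[k]][[k]]
      for (j in k:4) A[[i]][[j]] <- A[[i]][[j]] - m * A[[k]][[j]]
      B[[i]] <- B[[i]] - m * B[[k]]
    }
  }
  X <- vector("list", 4)
  X[[4]] <- B[[4]] / A[[4]][[4]]
  for (i in 3:1) {
    acc <- B[[i]]
    for (j in (i + 1):4) acc <- acc - A[[i]][[j]] * X[[j]]
    X[[i]] <- acc / A[[i]][[i]]
  }
  X
}

#' Back-correct crosstalk-corrupted column signals
#'
#' Solves the per-frequency 4 x 4 linear mixing system in reverse: at every
#' FFT bin the observed spectra are multiplied by the inverse of the mixing
#' matrix, recovering the true (crosstalk-free) signals. Bins whose mixing
#' matrix is too ill-conditioned — judged by the diagonal-dominance bound
#' `(1 + s)/(1 - s)` with `s` the largest off-diagonal row sum — are passed
#' through unchanged and reported in the diagnostics, never silently
#' corrected. With coupling magnitudes below 0.5 the matrix is diagonally
#' dominant and no bin triggers the guard.
#'
#' @param observed a [column_signals()] object
#' @param h a [four_line_model()] or matching `column_transfer_set` (see
#'   [forward_mix()])
#' @param cond_threshold per-bin condition-bound threshold (default `1e6`)
#' @return A `column_signals` object with `corrected = TRUE` and attribute
#'   `diagnostics`: a list with `n_bins`, `bins_passed_through` (indices of
#'   uncorrected bins, 1-based over the full FFT grid) and `max_cond_bound`.
#' @export
backcorrect <- function(observed, h, cond_threshold = 1e6) {
  stopifnot(inherits(observed, "column_signals"))
  n <- ncol(observed$samples)
  H <- column_hset_fft(h, n, observed$fs)
  hn <- Mod(H$H_N); hm <- Mod(H$H_M); hf <- Mod(H$H_F)
  s <- pmax(hn + hm + hf, 2 * hn + hm)     # largest off-diagonal row sum
  cond_bound <- ifelse(s < 1, (1 + s) / (1 - s), Inf)
  bad <- !(cond_bound < cond_threshold)

  Y <- lapply(1:4, function(i) stats::fft(observed$samples[i, ]))
  M <- mixing_rows(H$H_N, H$H_M, H$H_F)
  if (any(bad)) {
    # neutralize bad bins to the identity so elimination stays benign,
    # then restore the observed spectra there
    for (i in 1:4) for (j in 1:4)
      M[[i]][[j]][bad] <- if (i == j) 1 + 0i else 0 + 0i
  }
  X <- solve_mixing_bins(M, Y)
  out <- matrix(0, 4, n)
  for (i in 1:4) {
    if (any(bad)) X[[i]][bad] <- Y[[i]][bad]
    xi <- stats::fft(X[[i]], inverse = TRUE) / n
    out[i, ] <- Re(xi)
  }
  res <- column_signals(out, observed$fs, corrected = TRUE)
  attr(res, "diagnostics") <- list(
    n_bins = n,
    bins_passed_through = which(bad),
    max_cond_bound = max(cond_bound[!bad], 1))
  res
}
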