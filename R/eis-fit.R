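#' Impedance spectrum container
#'
#' A frequency-indexed complex impedance curve from electrochemical
#' impedance spectroscopy, optionally labeled with the chain block it
#' characterizes. Frequencies must be strictly increasing; capacitive
#' spectra have negative imaginary part.
#'
#' @param frequencies Hz, strictly increasing
#' @param impedance complex ohm, one per frequency
#' @param label free-text description (e.g. `"Z2 implanted electrode"`)
#' @return An object of class `impedance_spectrum`.
#' @export
impedance_spectrum <- function(frequencies, impedance, label = "") {
  if (length(frequencies) != length(impedance))
    stop("frequencies and impedance must have equal length", call. = FALSE)
  if (is.unsorted(frequencies, strictly = TRUE))
    stop("frequencies must be strictly increasing", call. = FALSE)
  if (any(!is.finite(frequencies)) || any(frequencies <= 0))
    stop("frequencies must be finite and > 0", call. = FALSE)
  impedance <- as.complex(impedance)
  if (any(!is.finite(Re(impedance))) || any(!is.finite(Im(impedance))))
    stop("impedance values must be finite", call. = FALSE)
  structure(list(frequencies = as.numeric(frequencies),
                 impedance = impedance, label = label),
            class = "impedance_spectrum")
}

#' @export
print.impedance_spectrum <- function(x, ...) {
  cat("Impedance spectrum", if (nzchar(x$label)) paste0(" [", x$label, "]"),
      ": ", length(x$frequencies), " points, ",
      signif(min(x$frequencies), 3), "-", signif(max(x$frequencies), 3),
      " Hz\n", sep = "")
  invisible(x)
}

#' Simulate an impedance spectrum from a forward model
#'
#' Generates a synthetic EIS curve from one of the block forward models,
#' optionally corrupted by multiplicative complex Gaussian noise
#' (`Z * (1 + eps)`, `eps` circular complex normal with RMS magnitude
#' `noise_level`). Used to exercise the fitting routines without measured
#' spectra.
#'
#' @param model `"randles"` (params `R_E`, `R_F`, `C_H`), `"parallel_rc"`
#'   (params `R`, `C`) or `"resistor"` (param `R`)
#' @param params named list of model parameters
#' @param frequencies evaluation grid, Hz
#' @param noise_level relative noise RMS (0 = exact forward model)
#' @param seed optional integer seed; identical seeds give identical spectra
#' @return An `impedance_spectrum`.
#' @export
simulate_spectrum <- function(model = c("randles", "parallel_rc", "resistor"),
                              params, frequencies, noise_level = 0,
                              seed = NULL) {
  model <- match.arg(model)
  check_frequencies(frequencies)
  if (noise_level < 0) stop("noise_level must be >= 0", call. = FALSE)
  Z <- switch(model,
    randles = randles_impedance(params$R_E, params$R_F, params$C_H,
                                frequencies),
    parallel_rc = element_impedance(params$R, params$C, frequencies),
    resistor = {
      if (params$R <= 0) stop("R must be positive", call. = FALSE)
      rep(complex(real = params$R), length(frequencies))
    })
  if (noise_level > 0) {
    n <- length(frequencies)
    eps <- with_seed(seed, complex(real = stats::rnorm(n, 0, 1 / sqrt(2)),
                                   imaginary = stats::rnorm(n, 0, 1 / sqrt(2))))
    Z <- Z * (1 + noise_level * eps)
  }
  impedance_spectrum(frequencies, Z, label = model)
}

# normalized complex residual: |Z_model - Z| / |Z| per point, stacked re/im
eis_residual <- function(Zm, Z) {
  w <- Mod(Z)
  c(Re(Zm - Z) / w, Im(Zm - Z) / w)
}

eis_residual_norm <- function(Zm, Z) {
  sqrt(mean(Mod(Zm - Z)^2 / Mod(Z)^2))
}

# optimizer search box (log-transformed internally)
.r_bounds <- c(1, 1e13)       # ohm
.c_bounds <- c(1e-14, 1e-3)   # farad

near_bound <- function(x, bounds, tol = 0.05) {
  lx <- log(x)
  (lx - log(bounds[1])) < tol || (log(bounds[2]) - lx) < tol
}

#' Fit a Randles model to an impedance spectrum
#'
#' Complex nonlinear least squares of [randles_impedance()] to the measured
#' spectrum with modulus weighting (residuals divided by `|Z|` per point),
#' appropriate for spectra spanning several decades of impedance.
#' Parameters are optimized on a log scale by Levenberg-Marquardt. Initial
#' guesses are data-derived: `R_E` from the high-frequency `|Z|` plateau,
#' `R_F` from the low-frequency plateau minus `R_E`, `C_H` from the
#' frequency at which `-Im(Z)` peaks (`w = 1/(R_F C_H)`).
#'
#' Convergence failure is an error. A fit that converges but leaves a large
#' normalized residual, or parks a parameter at a search bound (e.g. when
#' the spectrum has no faradaic arc), is returned with `flagged = TRUE`.
#'
#' @param spectrum an [impedance_spectrum()] with at least 6 points spanning
#'   two decades or more
#' @param residual_threshold normalized residual above which the fit is
#'   flagged (default 0.1)
#' @return A list with elements `R_E`, `R_F`, `C_H` (SI units), `residual`
#'   (normalized complex residual norm), `flagged` and `message`.
#' @export
fit_randles <- function(spectrum, residual_threshold = 0.1) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  f <- spectrum$frequencies; Z <- spectrum$impedance
  if (length(f) < 6)
    stop("Randles fit needs at least 6 frequency points", call. = FALSE)
  if (log10(max(f) / min(f)) < 2)
    stop("Randles fit needs a spectrum spanning >= 2 decades", call. = FALSE)

  n <- length(f)
  hi <- f >= max(f) / 10^0.5
  R_E0 <- max(stats::median(Mod(Z)[hi]), .r_bounds[1] * 2)
  R_F0 <- max(Mod(Z[1]) - R_E0, R_E0)           # low-f plateau minus R_E
  f_pk <- f[which.max(-Im(Z))]                  # -Im peak at w = 1/(R_F C_H)
  C_H0 <- min(max(1 / (2 * pi * f_pk * R_F0), .c_bounds[1] * 2),
              .c_bounds[2] / 2)

  fit <- minpack.lm::nls.lm(
    par = log(c(R_E0, R_F0, C_H0)),
    lower = log(c(.r_bounds[1], .r_bounds[1], .c_bounds[1])),
    upper = log(c(.r_bounds[2], .r_bounds[2], .c_bounds[2])),
    fn = function(lp) {
      p <- exp(lp)
      eis_residual(randles_impedance(p[1], p[2], p[3], f), Z)
    },
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (fit$info == 0 || fit$info == 5)
    stop("Randles fit did not converge (", fit$message, ")", call. = FALSE)

  p <- exp(fit$par)
  Zm <- randles_impedance(p[1], p[2], p[3], f)
  res <- eis_residual_norm(Zm, Z)
  at_bound <- near_bound(p[1], .r_bounds) || near_bound(p[2], .r_bounds) ||
    near_bound(p[3], .c_bounds)
  flagged <- at_bound || res > residual_threshold
  msg <- if (at_bound) "parameter at search bound (non-Randles shape?)"
         else if (res > residual_threshold) "high residual (non-Randles shape?)"
         else ""
  list(R_E = p[1], R_F = p[2], C_H = p[3], residual = res,
       flagged = flagged, message = msg)
}

#' Fit a parallel RC model to an impedance spectrum
#'
#' Modulus-weighted complex least squares of [element_impedance()]; used to
#' extract the shunt (`R_Sh`, `C_Sh`) and coupling (`R_Imp`/`C_Imp`,
#' `R_Int`/`C_Int`) blocks from insulation spectra. Initial guesses: `R`
#' from the low-frequency plateau, `C` from the -3 dB corner where
#' `|Z| = R/sqrt(2)`.
#'
#' @inheritParams fit_randles
#' @return A list with elements `R`, `C`, `residual`, `flagged`, `message`.
#' @export
fit_parallel_rc <- function(spectrum, residual_threshold = 0.1) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  f <- spectrum$frequencies; Z <- spectrum$impedance
  if (length(f) < 4)
    stop("parallel-RC fit needs at least 4 frequency points", call. = FALSE)

  R0 <- min(max(Mod(Z[1]), .r_bounds[1] * 2), .r_bounds[2] / 2)
  i_c <- which.min(abs(Mod(Z) - R0 / sqrt(2)))
  C0 <- min(max(1 / (2 * pi * f[i_c] * R0), .c_bounds[1] * 2),
            .c_bounds[2] / 2)

  fit <- minpack.lm::nls.lm(
    par = log(c(R0, C0)),
    lower = log(c(.r_bounds[1], .c_bounds[1])),
    upper = log(c(.r_bounds[2], .c_bounds[2])),
    fn = function(lp) {
      p <- exp(lp)
      eis_residual(element_impedance(p[1], p[2], f), Z)
    },
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (fit$info == 0 || fit$info == 5)
    stop("parallel-RC fit did not converge (", fit$message, ")",
         call. = FALSE)

  p <- exp(fit$par)
  res <- eis_residual_norm(element_impedance(p[1], p[2], f), Z)
  at_bound <- near_bound(p[1], .r_bounds) || near_bound(p[2], .c_bounds)
  flagged <- at_bound || res > residual_threshold
  msg <- if (at_bound) "parameter at search bound (degenerate spectrum?)"
         else if (res > residual_threshold) "high residual"
         else ""
  list(R = p[1], C = p[2], residual = res, flagged = flagged, message = msg)
}

#' Access resistance from the high-frequency plateau
#'
#' Extracts the series (access/spread) resistance as the median of the real
#' part of the impedance over the top half-decade of frequencies, where the
#' interface capacitance has shorted out the faradaic branch. A slope test
#' on `Re(Z)` vs `log10(f)` over that range flags spectra that have not
#' reached a plateau.
#'
#' @param spectrum an [impedance_spectrum()] extending to at least 10 kHz
#' @param slope_tol maximum tolerated |slope| of `Re(Z)` per decade,
#'   relative to the plateau value (default 0.05)
#' @return The access resistance in ohm, with attribute `flagged` set to
#'   `TRUE` when the plateau test fails.
#' @export
access_resistance <- function(spectrum, slope_tol = 0.05) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  f <- spectrum$frequencies
  if (max(f) < 1e4)
    stop("access-resistance extraction needs a spectrum reaching 10 kHz",
         call. = FALSE)
  top <- f >= max(f) / 10^0.5
  re <- Re(spectrum$impedance[top])
  val <- stats::median(re)
  flagged <- FALSE
  if (sum(top) >= 3) {
    sl <- stats::coef(stats::lm(re ~ log10(f[top])))[2]
    flagged <- abs(sl) > slope_tol * abs(val)
  }
  structure(val, flagged = flagged)
}

# ---- CSV I/O ---------------------------------------------------------------

#' Read and write impedance spectra as CSV
#'
#' Dialect: header `frequency_hz,z_real_ohm,z_imag_ohm`, one row per
#' frequency, plain ohm and Hz (no unit prefixes). Capacitive spectra have
#' negative `z_imag_ohm`. Rows are sorted by frequency on read.
#'
#' @param path CSV file path
#' @param label label attached to the spectrum on read
#' @return `read_eis_csv()` returns an [impedance_spectrum()];
#'   `write_eis_csv()` returns `path` invisibly.
#' @export
read_eis_csv <- function(path, label = "") {
  d <- utils::read.csv(path)
  need <- c("frequency_hz", "z_real_ohm", "z_imag_ohm")
  if (!all(need %in% names(d)))
    stop("EIS CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  d <- d[order(d$frequency_hz), ]
  impedance_spectrum(d$frequency_hz,
                     complex(real = d$z_real_ohm, imaginary = d$z_imag_ohm),
                     label = label)
}

#' @rdname read_eis_csv
#' @param spectrum an [impedance_spectrum()]
#' @export
write_eis_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  utils::write.csv(
    data.frame(frequency_hz = spectrum$frequencies,
               z_real_ohm = Re(spectrum$impedance),
               z_imag_ohm = Im(spectrum$impedance)),
    path, row.names = FALSE)
  invisible(path)
}
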