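#' Multichannel recording container
#'
#' A channels-by-samples matrix with sampling rate, amplitude units and an
#' optional [electrode_layout()] describing cortical positions and routing.
#'
#' @param samples numeric matrix, channels x samples, microvolt by default
#' @param fs sampling rate, Hz (the modeled acquisition system digitizes at
#'   12207 samples/s)
#' @param channel_ids optional channel labels (default `1:n_channels`)
#' @param units amplitude units string (default `"uV"`)
#' @param layout optional `electrode_layout`
#' @return An object of class `multichannel_recording`.
#' @export
multichannel_recording <- function(samples, fs, channel_ids = NULL,
                                   units = "uV", layout = NULL) {
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("samples must be a numeric channels x samples matrix", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("sampling rate must be a positive scalar", call. = FALSE)
  if (is.null(channel_ids)) channel_ids <- seq_len(nrow(samples))
  if (length(channel_ids) != nrow(samples))
    stop("channel_ids length must match the number of channels",
         call. = FALSE)
  if (!is.null(layout)) {
    validate_layout(layout)
    if (!setequal(layout$channel, seq_len(nrow(samples))))
      stop("layout channels must be 1..n_channels", call. = FALSE)
  }
  structure(list(samples = samples, fs = fs,
                 channel_ids = channel_ids, units = units, layout = layout),
            class = "multichannel_recording")
}

#' @export
print.multichannel_recording <- function(x, ...) {
  cat("Multichannel recording: ", nrow(x$samples), " channels x ",
      ncol(x$samples), " samples @ ", x$fs, " Hz (",
      signif(ncol(x$samples) / x$fs, 4), " s), ", x$units, "\n", sep = "")
  if (!is.null(x$layout))
    cat("  layout: ", nrow(x$layout), " electrodes, ",
        length(unique(x$layout$routing_group)), " routing groups\n", sep = "")
  invisible(x)
}

#' Write and read the flat binary recording container
#'
#' Samples are stored channel-major (all samples of channel 1, then channel
#' 2, ...) as little-endian float32 in `<path>`, with a JSON sidecar at
#' `<path>.json` holding `sampling_rate_hz`, `n_channels`, `n_samples`,
#' `channel_ids`, `units` and the embedded layout. Float32 storage is
#' lossless for amplifier-scaled microvolt data at the resolutions of
#' interest; the sidecar must agree with the binary length or reading fails
#' with an integrity error.
#'
#' @param rec a [multichannel_recording()]
#' @param path binary file path (sidecar path is derived by appending
#'   `.json`)
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns a `multichannel_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "multichannel_recording"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(rec$samples)), con, size = 4, endian = "little")
  meta <- list(sampling_rate_hz = rec$fs,
               n_channels = nrow(rec$samples),
               n_samples = ncol(rec$samples),
               channel_ids = rec$channel_ids,
               units = rec$units,
               layout = if (!is.null(rec$layout))
                 as.data.frame(unclass(rec$layout)))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(sidecar))
    stop("recording binary or sidecar not found for ", path, call. = FALSE)
  meta <- jsonlite::fromJSON(sidecar)
  n_total <- meta$n_channels * meta$n_samples
  sz <- file.info(path)$size
  if (sz != 4 * n_total)
    stop("integrity error: binary holds ", sz %/% 4,
         " float32 values, sidecar declares ", n_total, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, what = "numeric", n = n_total, size = 4,
               endian = "little")
  samples <- matrix(x, nrow = meta$n_channels, byrow = TRUE)
  layout <- NULL
  if (!is.null(meta$layout) && length(meta$layout) > 0) {
    layout <- as.data.frame(meta$layout)
    class(layout) <- c("electrode_layout", "data.frame")
  }
  multichannel_recording(samples, meta$sampling_rate_hz,
                         channel_ids = meta$channel_ids,
                         units = meta$units, layout = layout)
}
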