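#' Frequency-filter settings
#'
#' Mirrors the tool's "Set Filters" panel: an optional power-line notch and
#' an optional band-pass, both applied zero-phase (forward-backward), and an
#' `apply` switch that defaults to off so the raw signal passes through
#' bit-identically unless filtering is requested.
#'
#' @param notch_hz Notch centre frequency in Hz (default 60); `NULL` disables
#'   the notch.
#' @param notch_q Notch quality factor (default 30).
#' @param bandpass_low_hz,bandpass_high_hz Band-pass edges in Hz (defaults
#'   0.3 and 45); `NULL` for either disables the band-pass.
#' @param apply Master switch (default `FALSE`).
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(notch_hz = 60, notch_q = 30, bandpass_low_hz = 0.3,
                          bandpass_high_hz = 45, apply = FALSE) {
  if (!is.null(bandpass_low_hz) && !is.null(bandpass_high_hz) &&
      (bandpass_low_hz <= 0 || bandpass_high_hz <= bandpass_low_hz))
    stop("band-pass requires 0 < low < high", call. = FALSE)
  structure(list(notch_hz = notch_hz, notch_q = notch_q,
                 bandpass_low_hz = bandpass_low_hz,
                 bandpass_high_hz = bandpass_high_hz, apply = apply),
            class = "filter_config")
}

#' Apply notch and band-pass filters to an EEG record
#'
#' With `config$apply = FALSE` the record is returned unchanged. Otherwise
#' each channel is filtered zero-phase: first the notch (a biquad of the
#' given quality factor), then the band-pass, realized as an order-8
#' Butterworth low-pass cascaded with an order-2 Butterworth high-pass (the
#' high-pass order is kept low because the 0.3 Hz edge sits at a tiny
#' fraction of Nyquist, where high-order recursions lose precision).
#'
#' @param record An [eeg_record()].
#' @param config A [filter_config()].
#' @return The filtered `eeg_record`.
#' @export
apply_frequency_filters <- function(record, config = filter_config()) {
  stopifnot(inherits(record, "eeg_record"), inherits(config, "filter_config"))
  if (!isTRUE(config$apply)) return(record)
  fs <- record$fs
  nyq <- fs / 2
  edges <- c(config$notch_hz, config$bandpass_low_hz, config$bandpass_high_hz)
  if (length(edges) && any(edges >= nyq))
    stop("filter edge at or above the Nyquist frequency (", nyq, " Hz)",
         call. = FALSE)
  x <- record$samples
  if (!is.null(config$notch_hz)) {
    w0 <- 2 * pi * config$notch_hz / fs
    alpha <- sin(w0) / (2 * config$notch_q)
    b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
    a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
    for (ch in seq_len(ncol(x))) x[, ch] <- signal::filtfilt(b, a, x[, ch])
  }
  if (!is.null(config$bandpass_low_hz) && !is.null(config$bandpass_high_hz)) {
    lp <- signal::butter(8, config$bandpass_high_hz / nyq, type = "low")
    hp <- signal::butter(2, config$bandpass_low_hz / nyq, type = "high")
    for (ch in seq_len(ncol(x))) {
      x[, ch] <- signal::filtfilt(lp, x[, ch])
      x[, ch] <- signal::filtfilt(hp, x[, ch])
    }
  }
  record$samples <- x
  record
}

#' Epoch-quality filter settings
#'
#' The three epoch filters: maximum absolute amplitude, flat (near-constant)
#' signal, and unwanted annotations (e.g. bathroom breaks).
#'
#' @param max_amplitude_uv Reject an epoch when any channel exceeds this
#'   absolute amplitude in microvolts (default 500).
#' @param flat_std_uv Reject an epoch when any channel's standard deviation
#'   falls below this floor in microvolts (default 0.1).
#' @param excluded_annotations Stage/annotation labels whose epochs are
#'   rejected (default none).
#' @return Object of class `epoch_quality_config`.
#' @export
epoch_quality_config <- function(max_amplitude_uv = 500, flat_std_uv = 0.1,
                                 excluded_annotations = character()) {
  if (max_amplitude_uv <= 0 || flat_std_uv <= 0)
    stop("epoch-quality thresholds must be positive", call. = FALSE)
  structure(list(max_amplitude_uv = max_amplitude_uv, flat_std_uv = flat_std_uv,
                 excluded_annotations = as.character(excluded_annotations)),
            class = "epoch_quality_config")
}

#' Flag artifact epochs
#'
#' Marks an epoch when any channel exceeds the amplitude ceiling, any
#' channel is flat (standard deviation below the floor), or its annotation
#' is in the excluded list. Use [drop_epochs()] to remove flagged epochs
#' from both the stage sequence and the signal before detection and spectral
#' analysis.
#'
#' @param epoched An [epoch_and_align()] result.
#' @param config An [epoch_quality_config()].
#' @return List with `mask` (logical, `TRUE` = flagged) and `reasons`
#'   (data frame `epoch` — original 0-based index — and `reason`).
#' @export
flag_bad_epochs <- function(epoched, config = epoch_quality_config()) {
  stopifnot(inherits(epoched, "epoched_recording"),
            inherits(config, "epoch_quality_config"))
  n_ep <- length(epoched$stages)
  amp <- apply(abs(epoched$epochs), 3L, max)
  sd_min <- apply(epoched$epochs, 3L, function(block) min(apply(block, 2L, stats::sd)))
  reasons <- character(n_ep)
  reasons[amp > config$max_amplitude_uv] <- "amplitude"
  flat <- sd_min < config$flat_std_uv & !nzchar(reasons)
  reasons[flat] <- "flat"
  ann <- epoched$stages %in% config$excluded_annotations & !nzchar(reasons)
  reasons[ann] <- paste0("annotation:", epoched$stages[ann])
  mask <- nzchar(reasons)
  list(mask = mask,
       reasons = data.frame(epoch = epoched$epoch_index[mask],
                            reason = reasons[mask]))
}
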