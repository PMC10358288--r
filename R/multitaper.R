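#' Multitaper spectrogram configuration
#'
#' The per-epoch spectral estimate is evaluated on a fixed inclusive grid of
#' `(freq_max_hz - freq_min_hz) / freq_step_hz + 1` frequencies — 901 points
#' for the default 0–45 Hz in 0.05 Hz steps, covering the delta through gamma
#' bands. Windows coincide with scoring epochs (no overlap) so each
#' spectrogram column maps to exactly one hypnogram epoch.
#'
#' @param freq_min_hz,freq_max_hz,freq_step_hz Frequency grid (defaults 0,
#'   45, 0.05 Hz; both endpoints included).
#' @param time_bandwidth Taper time-bandwidth product (default 4; about
#'   0.27 Hz half-bandwidth over a 30-s window).
#' @param n_tapers Number of Slepian tapers (default 7 = 2*4 - 1; must not
#'   exceed `2 * time_bandwidth - 1`).
#' @param db_ref Power reference for the dB display scale (1 microvolt^2/Hz).
#' @param db_floor Display floor in dB (default -60); zero power maps exactly
#'   to the floor.
#' @return Object of class `spectral_config`.
#' @export
spectral_config <- function(freq_min_hz = 0, freq_max_hz = 45,
                            freq_step_hz = 0.05, time_bandwidth = 4,
                            n_tapers = 7, db_ref = 1, db_floor = -60) {
  if (freq_min_hz < 0 || freq_max_hz <= freq_min_hz || freq_step_hz <= 0)
    stop("need 0 <= freq_min_hz < freq_max_hz and freq_step_hz > 0", call. = FALSE)
  nb <- (freq_max_hz - freq_min_hz) / freq_step_hz
  if (abs(nb - round(nb)) > 1e-9)
    stop("freq_step_hz must divide the frequency span exactly", call. = FALSE)
  if (n_tapers > 2 * time_bandwidth - 1 + 1e-9)
    stop("n_tapers must not exceed 2 * time_bandwidth - 1", call. = FALSE)
  structure(list(freq_min_hz = freq_min_hz, freq_max_hz = freq_max_hz,
                 freq_step_hz = freq_step_hz,
                 n_freq_bins = as.integer(round(nb)) + 1L,
                 time_bandwidth = time_bandwidth, n_tapers = as.integer(n_tapers),
                 db_ref = db_ref, db_floor = db_floor),
            class = "spectral_config")
}

#' Per-epoch multitaper power spectra aligned to the hypnogram
#'
#' For every retained epoch and channel, averages the periodograms of the
#' `n_tapers` Slepian-tapered copies of the (demeaned) epoch signal,
#' evaluated at the exact grid frequencies: the transform length is chosen so
#' the native bin spacing divides the grid step, and grid values are read off
#' directly (no interpolation). Power is one-sided spectral density in
#' microvolt^2/Hz.
#'
#' @param epoched An [epoch_and_align()] result.
#' @param config A [spectral_config()].
#' @return Object of class `spectrogram`:
#'   \describe{
#'     \item{power}{array, epochs x frequency bins x channels, linear scale}
#'     \item{freqs_hz}{the frequency grid (length `n_freq_bins`)}
#'     \item{epoch_index_map}{0-based hypnogram epoch of each spectrogram
#'       column (identity after joint filtering)}
#'     \item{channel_names, stages, config}{carried metadata}
#'   }
#' @export
multitaper_spectrogram <- function(epoched, config = spectral_config()) {
  stopifnot(inherits(epoched, "epoched_recording"),
            inherits(config, "spectral_config"))
  fs <- epoched$fs
  if (fs < 2 * config$freq_max_hz)
    stop("sampling rate ", fs, " Hz cannot resolve ", config$freq_max_hz,
         " Hz; lower freq_max_hz to at most fs/2", call. = FALSE)
  n <- dim(epoched$epochs)[1]
  if (n < 2 * config$n_tapers)
    stop("epoch too short for ", config$n_tapers, " tapers", call. = FALSE)

  # transform length: smallest multiple of fs/freq_step_hz that covers the
  # epoch, so every grid frequency falls on a native FFT bin
  base <- fs / config$freq_step_hz
  if (abs(base - round(base)) > 1e-6)
    stop("freq_step_hz must divide the sampling rate (fs/step must be an integer)",
         call. = FALSE)
  base <- as.integer(round(base))
  nfft <- base * as.integer(ceiling(n / base))
  freqs <- config$freq_min_hz + config$freq_step_hz * (seq_len(config$n_freq_bins) - 1L)
  bin <- round(freqs / (fs / nfft)) + 1L  # 1-based FFT bin per grid frequency
  stopifnot(max(bin) <= nfft %/% 2L + 1L)

  tapers <- dpss_tapers(n, nw = config$time_bandwidth, k = config$n_tapers)
  n_ep <- dim(epoched$epochs)[3]
  n_ch <- dim(epoched$epochs)[2]
  power <- array(0, dim = c(n_ep, config$n_freq_bins, n_ch))
  # one-sided density scaling: x2 except at DC and Nyquist
  scale <- rep(2 / fs, config$n_freq_bins)
  scale[freqs == 0] <- 1 / fs
  scale[abs(freqs - fs / 2) < 1e-9] <- 1 / fs

  pad <- matrix(0, nfft, 1)
  for (ch in seq_len(n_ch)) {
    x <- epoched$epochs[, ch, , drop = FALSE]
    dim(x) <- c(n, n_ep)
    x <- sweep(x, 2L, colMeans(x))  # demean per epoch
    chunk <- 64L
    for (c0 in seq(1L, n_ep, by = chunk)) {
      cols <- c0:min(c0 + chunk - 1L, n_ep)
      xp <- matrix(0, nfft, length(cols))
      acc <- matrix(0, config$n_freq_bins, length(cols))
      for (tp in seq_len(config$n_tapers)) {
        xp[seq_len(n), ] <- x[, cols, drop = FALSE] * tapers[, tp]
        X <- stats::mvfft(xp)[bin, , drop = FALSE]
        acc <- acc + Re(X)^2 + Im(X)^2
      }
      power[cols, , ch] <- t(acc / config$n_tapers * scale)
    }
  }
  structure(list(power = power, freqs_hz = freqs,
                 epoch_index_map = epoched$epoch_index,
                 channel_names = epoched$channel_names,
                 stages = epoched$stages,
                 fs = fs, config = config),
            class = "spectrogram")
}

#' Collapse a spectrogram across channels for display
#'
#' Converts power to dB (re `db_ref`, floored at `db_floor`; zero power maps
#' exactly to the floor) and aggregates across channels.
#'
#' @param spec A [multitaper_spectrogram()] result.
#' @param method `"mean"` (default), `"median"`, or `"channel"` for a single
#'   channel.
#' @param channel Channel name, required when `method = "channel"`.
#' @return Matrix, epochs x frequency bins, in dB.
#' @export
aggregate_display <- function(spec, method = c("mean", "median", "channel"),
                              channel = NULL) {
  stopifnot(inherits(spec, "spectrogram"))
  method <- match.arg(method)
  floor_lin <- spec$config$db_ref * 10^(spec$config$db_floor / 10)
  db <- 10 * log10(pmax(spec$power, floor_lin) / spec$config$db_ref)
  if (method == "channel") {
    if (is.null(channel) || !(channel %in% spec$channel_names))
      stop("method = 'channel' needs a channel present in the spectrogram",
           call. = FALSE)
    return(db[, , match(channel, spec$channel_names)])
  }
  if (dim(db)[3] == 1L) return(db[, , 1L])
  apply(db, c(1, 2), if (method == "mean") mean else stats::median)
}

#' @export
print.spectrogram <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("<spectrogram> %d epoch(s) x %d frequencies (%g-%g Hz) x %d channel(s)\n",
              d[1], d[2], min(x$freqs_hz), max(x$freqs_hz), d[3]))
  invisible(x)
}
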