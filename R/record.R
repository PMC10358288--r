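#' Construct a multichannel EEG record
#'
#' Holds per-channel voltage series (microvolts) sampled at one common rate.
#' Channels recorded at different rates must be resampled to a common rate
#' before construction; [load_recording()] does this automatically.
#'
#' @param samples Numeric matrix, samples x channels, in microvolts.
#' @param fs Sampling rate in Hz (shared by all channels).
#' @param channel_names Character vector, one name per column.
#' @param origin_time Optional `POSIXct` start time.
#' @return Object of class `eeg_record`.
#' @export
eeg_record <- function(samples, fs, channel_names = colnames(samples),
                       origin_time = NULL) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("samples must be numeric", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive sampling rate in Hz", call. = FALSE)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(ncol(samples)))
  if (length(channel_names) != ncol(samples))
    stop("channel_names length must match the number of signal columns", call. = FALSE)
  colnames(samples) <- channel_names
  structure(list(samples = samples, fs = as.numeric(fs),
                 channel_names = as.character(channel_names),
                 origin_time = origin_time),
            class = "eeg_record")
}

#' Duration of an EEG record in seconds
#' @param record An `eeg_record`.
#' @return Seconds of signal per channel.
#' @export
record_duration_s <- function(record) {
  stopifnot(inherits(record, "eeg_record"))
  nrow(record$samples) / record$fs
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %d channel(s) @ %g Hz, %.1f s\n",
              ncol(x$samples), x$fs, record_duration_s(x)))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' Segment a record into epochs aligned with a hypnogram
#'
#' Divides the signal into consecutive epochs of the hypnogram's epoch length
#' and pairs each with its stage annotation. Epochs present in only one
#' stream, unannotated (`NA`) epochs, and any trailing partial signal epoch
#' are dropped from *both* streams, so period detection and spectral analysis
#' always see the same epochs.
#'
#' @param record An [eeg_record()].
#' @param hyp A [hypnogram()] sharing the record's origin.
#' @return Object of class `epoched_recording` with fields:
#'   \describe{
#'     \item{epochs}{numeric array, samples x channels x retained epochs}
#'     \item{stages}{stage per retained epoch}
#'     \item{epoch_index}{original 0-based hypnogram index of each retained epoch}
#'     \item{dropped}{data frame (`epoch`, `reason`) of removed epochs}
#'     \item{fs, epoch_len_s, channel_names}{carried metadata}
#'   }
#' @export
epoch_and_align <- function(record, hyp) {
  stopifnot(inherits(record, "eeg_record"), inherits(hyp, "hypnogram"))
  spe <- hyp$epoch_len_s * record$fs
  if (abs(spe - round(spe)) > 1e-6)
    stop("epoch_len_s x fs must be an integer number of samples (got ",
         spe, ")", call. = FALSE)
  spe <- as.integer(round(spe))
  n_total <- nrow(record$samples)
  if (n_total < spe)
    stop("signal shorter than one epoch (", n_total, " < ", spe, " samples)",
         call. = FALSE)
  n_sig <- n_total %/% spe
  discard_s <- (n_total - n_sig * spe) / record$fs
  n_hyp <- n_epochs(hyp)
  n <- min(n_sig, n_hyp)

  idx0 <- seq_len(n) - 1L
  annotated <- !is.na(hyp$stages[seq_len(n)])
  dropped <- hyp$dropped
  if (any(!annotated))
    dropped <- rbind(dropped, data.frame(epoch = idx0[!annotated],
                                         reason = "unannotated"))
  if (n_hyp > n)
    dropped <- rbind(dropped, data.frame(epoch = seq.int(n, n_hyp - 1L),
                                         reason = "no signal"))
  log <- character()
  if (discard_s > 0)
    log <- c(log, sprintf("trailing partial signal epoch discarded (%.3f s)", discard_s))
  if (n_sig > n)
    log <- c(log, sprintf("%d signal epoch(s) beyond the hypnogram discarded", n_sig - n))

  keep <- which(annotated)
  if (!length(keep)) stop("no annotated epochs overlap the signal", call. = FALSE)
  arr <- array(record$samples[seq_len(n * spe), , drop = FALSE],
               dim = c(spe, n, ncol(record$samples)))
  arr <- aperm(arr[, keep, , drop = FALSE], c(1, 3, 2))
  structure(list(epochs = arr,
                 stages = hyp$stages[keep],
                 epoch_index = keep - 1L,
                 dropped = dropped,
                 fs = record$fs,
                 epoch_len_s = hyp$epoch_len_s,
                 channel_names = record$channel_names,
                 origin_time = hyp$origin_time %||% record$origin_time,
                 log = log),
            class = "epoched_recording")
}

#' Hypnogram of the retained epochs of an epoched recording
#'
#' @param epoched An `epoched_recording`.
#' @return A compacted [hypnogram()] over the retained epochs (re-indexed
#'   consecutively; see `epoched$epoch_index` for the original indices).
#' @export
epoched_hypnogram <- function(epoched) {
  stopifnot(inherits(epoched, "epoched_recording"))
  hypnogram(epoched$stages, epoched$epoch_len_s, epoched$origin_time,
            dropped = epoched$dropped)
}

#' Remove epochs from an epoched recording
#'
#' Drops the given epochs from both the stage sequence and the signal blocks,
#' recording a reason per epoch (used by the epoch-quality filters).
#'
#' @param epoched An `epoched_recording`.
#' @param drop Integer positions (1-based into the retained epochs) to remove.
#' @param reason Character reason(s), recycled over `drop`.
#' @return The filtered `epoched_recording`.
#' @export
drop_epochs <- function(epoched, drop, reason = "filtered") {
  stopifnot(inherits(epoched, "epoched_recording"))
  if (!length(drop)) return(epoched)
  drop <- sort(unique(as.integer(drop)))
  if (any(drop < 1L | drop > length(epoched$stages)))
    stop("drop indices out of range", call. = FALSE)
  reason <- rep_len(reason, length(drop))
  epoched$dropped <- rbind(epoched$dropped,
                           data.frame(epoch = epoched$epoch_index[drop],
                                      reason = reason))
  keep <- setdiff(seq_along(epoched$stages), drop)
  if (!length(keep)) stop("all epochs removed by filtering", call. = FALSE)
  epoched$epochs <- epoched$epochs[, , keep, drop = FALSE]
  epoched$stages <- epoched$stages[keep]
  epoched$epoch_index <- epoched$epoch_index[keep]
  epoched
}

#' @export
print.epoched_recording <- function(x, ...) {
  cat(sprintf("<epoched_recording> %d epoch(s) x %gs, %d channel(s) @ %g Hz\n",
              length(x$stages), x$epoch_len_s, length(x$channel_names), x$fs))
  if (nrow(x$dropped)) cat("  dropped:", nrow(x$dropped), "epoch(s)\n")
  invisible(x)
}
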