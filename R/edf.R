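# EDF / EDF+ input and output.
#
# EDF stores an ASCII header (256 bytes + 256 per signal) followed by data
# records of 16-bit little-endian integers, one block per signal per record.
# EDF+ adds an "EDF Annotations" signal whose byte stream carries TALs
# (time-stamped annotation lists): "+onset[\x15duration]\x14text\x14...\x00".
# This implementation covers the standard EDF/EDF+C layout; vendor dialects
# that deviate from it need a user-supplied text annotation file instead.

ANNOT_LABEL <- "EDF Annotations"

pad_ascii <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

fmt_num8 <- function(x) {
  # numeric header field, max 8 ASCII chars
  s <- formatC(x, format = "fg", width = 1, digits = 7)
  if (grepl(".", s, fixed = TRUE)) s <- sub("\\.?0+$", "", s)
  if (nchar(s) > 8) s <- substr(formatC(x, format = "g", digits = 3), 1, 8)
  s
}

#' Write an EDF or EDF+ file
#'
#' Writes the record's channels as 16-bit EDF signals (default physical range
#' of ±1000 microvolts) using 1-second data records. When a hypnogram is
#' supplied, an EDF+ annotations signal is added carrying one stage event per
#' scored epoch, which [load_recording()] reads back.
#'
#' @param record An [eeg_record()]; sampling rate must be an integer Hz and
#'   the duration a whole number of seconds.
#' @param path Output file path.
#' @param hypnogram Optional [hypnogram()] aligned with the record.
#' @param physical_range Symmetric physical range in microvolts (default
#'   1000); samples outside it are clipped.
#' @return `path`, invisibly.
#' @export
write_edf <- function(record, path, hypnogram = NULL, physical_range = 1000) {
  stopifnot(inherits(record, "eeg_record"))
  if (!is.null(hypnogram)) {
    stopifnot(inherits(hypnogram, "hypnogram"))
    if (!length(hypnogram$stages)) stop("empty hypnogram", call. = FALSE)
  }
  fs <- record$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF export requires an integer sampling rate in Hz", call. = FALSE)
  fs <- as.integer(round(fs))
  n_samp <- nrow(record$samples)
  if (n_samp %% fs != 0L)
    stop("EDF export requires a whole number of seconds of signal", call. = FALSE)
  n_rec <- n_samp %/% fs
  nch <- ncol(record$samples)
  has_annot <- !is.null(hypnogram)
  ns <- nch + as.integer(has_annot)
  annot_spr <- 60L  # 120 bytes of TAL space per record

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)

  start <- record$origin_time %||% (if (has_annot) hypnogram$origin_time else NULL)
  sd <- if (inherits(start, "POSIXct")) format(start, "%d.%m.%y") else "01.01.00"
  st <- if (inherits(start, "POSIXct")) format(start, "%H.%M.%S") else "00.00.00"

  header <- paste0(
    pad_ascii("0", 8),
    pad_ascii("X X X X", 80),
    pad_ascii("Startdate X X X X", 80),
    pad_ascii(sd, 8), pad_ascii(st, 8),
    pad_ascii(256L * (1L + ns), 8),
    pad_ascii(if (has_annot) "EDF+C" else "", 44),
    pad_ascii(n_rec, 8),
    pad_ascii("1", 8),
    pad_ascii(ns, 4))
  writeChar(header, con, eos = NULL)

  labels <- c(record$channel_names, if (has_annot) ANNOT_LABEL)
  pmin_ <- c(rep(-physical_range, nch), if (has_annot) -1)
  pmax_ <- c(rep(physical_range, nch), if (has_annot) 1)
  dmin_ <- rep(-32768L, ns); dmax_ <- rep(32767L, ns)
  spr <- c(rep(fs, nch), if (has_annot) annot_spr)
  field <- function(vals, width) writeChar(paste(vapply(vals, pad_ascii, "", width),
                                                 collapse = ""), con, eos = NULL)
  field(labels, 16)
  field(rep("", ns), 80)
  field(c(rep("uV", nch), if (has_annot) ""), 8)
  field(vapply(pmin_, fmt_num8, ""), 8)
  field(vapply(pmax_, fmt_num8, ""), 8)
  field(dmin_, 8)
  field(dmax_, 8)
  field(rep("", ns), 80)
  field(spr, 8)
  field(rep("", ns), 32)

  # digital conversion (shared gain across EEG channels)
  gain <- (dmax_[1] - dmin_[1]) / (2 * physical_range)
  x <- pmin(pmax(record$samples, -physical_range), physical_range)
  dig <- matrix(as.integer(round((x + physical_range) * gain) + dmin_[1]),
                nrow = n_samp)

  annot_block <- function(t0) {
    tals <- c(charToRaw(paste0("+", t0, "\x14\x14")), as.raw(0L))
    if (has_annot && t0 %% hypnogram$epoch_len_s == 0) {
      ep <- t0 %/% hypnogram$epoch_len_s + 1L
      if (ep <= length(hypnogram$stages) && !is.na(hypnogram$stages[ep]))
        tals <- c(tals,
                  charToRaw(paste0("+", t0, "\x15", fmt_num8(hypnogram$epoch_len_s),
                                   "\x14", hypnogram$stages[ep], "\x14")),
                  as.raw(0L))
    }
    if (length(tals) > 2L * annot_spr)
      stop("annotation too long for the annotation signal block", call. = FALSE)
    c(tals, raw(2L * annot_spr - length(tals)))
  }

  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(dig[rows, , drop = FALSE]), con, size = 2L,
             endian = "little")
    if (has_annot) writeBin(annot_block(r - 1L), con)
  }
  invisible(path)
}

# Low-level EDF reader: header, per-signal physical samples, annotation events.
read_edf <- function(path) {
  if (!file.exists(path)) stop("cannot read EDF file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  rd <- function(n) {
    s <- readChar(con, n, useBytes = TRUE)
    if (length(s) == 0 || nchar(s, type = "bytes") < n)
      stop("truncated EDF header in ", path, call. = FALSE)
    trimws(s)
  }
  version <- rd(8); patient <- rd(80); recording <- rd(80)
  startdate <- rd(8); starttime <- rd(8)
  header_bytes <- as.integer(rd(8)); reserved <- rd(44)
  n_rec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8)); ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop("invalid EDF header (signal count) in ", path, call. = FALSE)
  fieldv <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fieldv(16); transducer <- fieldv(80); dims <- fieldv(8)
  pmin_ <- as.numeric(fieldv(8)); pmax_ <- as.numeric(fieldv(8))
  dmin_ <- as.numeric(fieldv(8)); dmax_ <- as.numeric(fieldv(8))
  prefilter <- fieldv(80); spr <- as.integer(fieldv(8)); fieldv(32)
  if (anyNA(spr) || any(spr < 1L)) stop("invalid samples-per-record in ", path, call. = FALSE)

  rec_bytes <- sum(spr) * 2L
  data <- readBin(con, "raw", n = as.numeric(n_rec) * rec_bytes)
  if (length(data) < n_rec * rec_bytes) {
    n_rec <- length(data) %/% rec_bytes  # tolerate a truncated final record
    data <- data[seq_len(n_rec * rec_bytes)]
  }
  offs <- c(0L, cumsum(spr * 2L))  # within-record byte offsets per signal

  is_annot <- labels == ANNOT_LABEL
  signals <- vector("list", ns)
  events <- list()
  rec_starts <- (seq_len(n_rec) - 1L) * rec_bytes
  for (s in seq_len(ns)) {
    sel <- as.vector(outer(seq.int(offs[s] + 1L, offs[s + 1L]), rec_starts, `+`))
    raw_s <- data[sel]
    if (is_annot[s]) {
      events[[length(events) + 1L]] <- parse_tals(raw_s)
    } else {
      dig <- readBin(raw_s, "integer", n = length(raw_s) %/% 2L, size = 2L,
                     signed = TRUE, endian = "little")
      scale <- (pmax_[s] - pmin_[s]) / (dmax_[s] - dmin_[s])
      phys <- (dig - dmin_[s]) * scale + pmin_[s]
      if (grepl("^mV$", dims[s], ignore.case = TRUE)) phys <- phys * 1000
      signals[[s]] <- phys
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(onset = numeric(), duration = numeric(), text = character())
  list(labels = labels[!is_annot],
       fs = spr[!is_annot] / rec_dur,
       signals = signals[!is_annot],
       events = events,
       n_records = n_rec, record_duration = rec_dur,
       startdate = startdate, starttime = starttime, reserved = reserved)
}

# Parse the TAL byte stream of an annotations signal. Each TAL is a run of
# non-NUL bytes terminated by a NUL: onset[\x15duration]\x14text\x14[text\x14...]
parse_tals <- function(raw_bytes) {
  zero <- raw_bytes == as.raw(0L)
  r <- rle(as.logical(zero))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in which(!r$values)) {
    fields <- strsplit(rawToChar(raw_bytes[starts[k]:ends[k]]),
                       "\x14", fixed = TRUE)[[1]]
    if (!length(fields)) next
    head_ <- strsplit(fields[1], "\x15", fixed = TRUE)[[1]]
    onset <- suppressWarnings(as.numeric(head_[1]))
    if (is.na(onset)) next
    duration <- if (length(head_) > 1L) suppressWarnings(as.numeric(head_[2])) else NA_real_
    for (tx in fields[-1][nzchar(fields[-1])])
      out[[length(out) + 1L]] <- data.frame(onset = onset, duration = duration,
                                            text = tx)
  }
  if (!length(out)) data.frame(onset = numeric(), duration = numeric(),
                               text = character())
  else do.call(rbind, out)
}

#' Default EEG channel selection
#'
#' The frontal, central, occipital and mastoid derivations most
#' polysomnography montages record.
#'
#' @return Character vector of channel names.
#' @export
default_channels <- function() c("F3", "F4", "C3", "C4", "O1", "O2", "M1", "M2")

#' Load an EDF/EDF+ polysomnography recording
#'
#' Reads the selected EEG channels and, when the file carries embedded
#' stage-annotation events, builds the hypnogram by mapping each event's text
#' through the label map and snapping its onset to the epoch grid (tolerance
#' 0.5 s; larger offsets are an alignment error). Missing requested channels
#' are reported and the run continues with the intersection; channels sampled
#' at different rates are linearly resampled to the highest rate among the
#' selection (logged).
#'
#' @param path EDF/EDF+ file.
#' @param channels Channels to retain (default [default_channels()]); `NULL`
#'   keeps every signal channel.
#' @param label_map [stage_label_map()] for the embedded annotation texts.
#' @param epoch_len_s Epoch length in seconds (default 30).
#' @return List with `record` ([eeg_record()]), `hypnogram` ([hypnogram()] or
#'   `NULL` when the file has no stage annotations, in which case only the
#'   spectrogram can be produced), and `log` (character).
#' @export
load_recording <- function(path, channels = default_channels(),
                           label_map = default_stage_map(), epoch_len_s = 30) {
  edf <- read_edf(path)
  log <- character()
  if (is.null(channels)) channels <- edf$labels
  present <- intersect(channels, edf$labels)
  missing_ <- setdiff(channels, edf$labels)
  if (length(missing_))
    log <- c(log, paste0("requested channel(s) not in file: ",
                         paste(missing_, collapse = ", ")))
  if (!length(present))
    stop("none of the requested channels are present (file has: ",
         paste(edf$labels, collapse = ", "), ")", call. = FALSE)
  sel <- match(present, edf$labels)
  fs_sel <- edf$fs[sel]
  fs <- max(fs_sel)
  sigs <- edf$signals[sel]
  if (any(fs_sel != fs)) {
    slow <- present[fs_sel != fs]
    log <- c(log, paste0("resampled to ", fs, " Hz: ", paste(slow, collapse = ", ")))
    n_out <- as.integer(round(edf$n_records * edf$record_duration * fs))
    sigs <- lapply(seq_along(sigs), function(i) {
      if (fs_sel[i] == fs) return(sigs[[i]])
      t_in <- (seq_along(sigs[[i]]) - 1) / fs_sel[i]
      stats::approx(t_in, sigs[[i]], xout = (seq_len(n_out) - 1) / fs,
                    rule = 2)$y
    })
  }
  record <- eeg_record(do.call(cbind, sigs), fs = fs, channel_names = present)

  ev <- edf$events
  ev <- ev[!is.na(ev$duration) & ev$duration > 0, , drop = FALSE]
  hyp <- NULL
  if (nrow(ev)) {
    mapped <- map_stage_labels(ev$text, label_map)
    if (length(mapped$unmapped))
      stop("unmapped annotation label(s) in EDF: ",
           paste(sprintf("'%s'", mapped$unmapped), collapse = ", "),
           "; extend the stage_label_map (or map them to exclude_marker())",
           call. = FALSE)
    grid <- ev$onset / epoch_len_s
    snapped <- round(grid)
    off <- abs(ev$onset - snapped * epoch_len_s)
    if (any(off > 0.5))
      stop(sprintf(paste0("annotation onset %.3f s is %.3f s from the nearest ",
                          "epoch boundary (epoch length %g s, tolerance 0.5 s)"),
                   ev$onset[which.max(off)], max(off), epoch_len_s), call. = FALSE)
    ep <- as.integer(snapped)
    span <- pmax(1L, as.integer(round(ev$duration / epoch_len_s)))
    n_hyp <- max(as.integer(floor(record_duration_s(record) / epoch_len_s)),
                 max(ep + span))
    stages <- rep(NA_character_, n_hyp)
    dropped <- data.frame(epoch = integer(), reason = character())
    for (i in seq_len(nrow(ev))) {
      idx <- ep[i] + seq_len(span[i]) - 1L
      if (mapped$excluded[i]) {
        dropped <- rbind(dropped, data.frame(epoch = idx,
                                             reason = paste0("excluded_annotation:",
                                                             ev$text[i])))
      } else {
        stages[idx + 1L] <- mapped$stage[i]
      }
    }
    if (any(!is.na(stages)))
      hyp <- hypnogram(stages, epoch_len_s, dropped = dropped)
    else
      log <- c(log, "annotation events present but none scored a stage")
  } else {
    log <- c(log, "no stage annotations in EDF; spectrogram-only mode")
  }
  list(record = record, hypnogram = hyp, log = log)
}
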