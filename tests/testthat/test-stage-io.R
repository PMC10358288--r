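test_that("text annotations parse to a hypnogram, in any line order and dialect", {
  h <- read_stage_annotations(text = c("0 W", "1 N1", "2 N2"))
  expect_s3_class(h, "hypnogram")
  expect_identical(h$stages, c("W", "N1", "N2"))
  expect_identical(h$epoch_len_s, 30)

  # vendor labels through an explicit map
  m <- stage_label_map("Wake" = "W", "Stage1" = "N1", base = NULL)
  h2 <- read_stage_annotations(text = c("0 Wake", "1 Stage1"), label_map = m)
  expect_identical(h2$stages, c("W", "N1"))

  # line order must not matter; comma dialect and comments accepted
  h3 <- read_stage_annotations(text = c("# scored by tech A", "2,N2", "0,W", "1,N1"))
  expect_identical(h3$stages, h$stages)

  # 1-based files are re-based with a note
  h4 <- read_stage_annotations(text = c("1 W", "2 N1"))
  expect_identical(h4$stages, c("W", "N1"))
  expect_match(attr(h4, "log"), "re-based")
})

test_that("annotation parse errors are specific: duplicates, gaps, unmapped labels", {
  expect_error(read_stage_annotations(text = c("0 W", "0 N1")), "duplicate epoch number 0")
  expect_error(read_stage_annotations(text = c("0 W", "2 N1")), "not consecutive")
  expect_error(read_stage_annotations(text = c("0 W", "1 Foo", "2 Bar")),
               "'Foo', 'Bar'")
  expect_error(read_stage_annotations(text = "0"), "two columns")
  expect_error(read_stage_annotations(text = c("# only a comment")), "no data lines")
})

test_that("excluded labels drop epochs like unannotated ones", {
  m <- stage_label_map(exclude = "Movement")
  h <- read_stage_annotations(text = c("0 W", "1 Movement", "2 N2"), label_map = m)
  expect_true(is.na(h$stages[2]))
  expect_identical(h$dropped$epoch, 1L)
  expect_match(h$dropped$reason, "Movement")
  compact <- drop_unscored(h)
  expect_identical(compact$hypnogram$stages, c("W", "N2"))
  expect_identical(compact$epoch_index, c(0L, 2L))
})

test_that("synthetic EDF round-trips through the loader", {
  hyp <- hypnogram(c("N2", "N2"))
  rec <- generate_eeg(hyp, fs = 200, n_channels = 2, seed = 11)
  f <- withr::local_tempfile(fileext = ".edf")
  write_recording(rec, hyp, f)
  lr <- load_recording(f, channels = NULL)
  expect_identical(lr$hypnogram$stages, hyp$stages)
  expect_identical(lr$record$channel_names, rec$channel_names)
  expect_equal(lr$record$fs, 200)
  # samples survive within the 16-bit quantization of the +-1000 uV range
  expect_lt(max(abs(lr$record$samples - rec$samples)), 2000 / 65535)
})

test_that("an EDF without stage annotations loads in spectrogram-only mode", {
  rec <- tone_record(10, fs = 100, n_epochs = 3)
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, f)  # no hypnogram
  lr <- load_recording(f, channels = NULL)
  expect_null(lr$hypnogram)
  expect_match(paste(lr$log, collapse = " "), "spectrogram-only")
  # 90 s at 30-s epochs -> 3 signal epochs
  expect_equal(floor(record_duration_s(lr$record) / 30), 3)
})

test_that("missing requested channels are reported, run continues with the intersection", {
  hyp <- hypnogram(c("N2", "N2"))
  rec <- generate_eeg(hyp, fs = 100, n_channels = 2, seed = 3)  # F3, F4
  f <- withr::local_tempfile(fileext = ".edf")
  write_recording(rec, hyp, f)
  lr <- load_recording(f, channels = c("F3", "Cz"))
  expect_identical(lr$record$channel_names, "F3")
  expect_match(paste(lr$log, collapse = " "), "Cz")
  expect_error(load_recording(f, channels = c("X1", "X2")), "none of the requested")
})

test_that("epoch alignment drops partial and one-sided epochs from both streams", {
  # 95 s of signal at 30-s epochs -> 3 epochs, 5 s discarded
  rec <- eeg_record(matrix(stats::rnorm(95 * 100), ncol = 1), 100, "C3")
  hyp <- hypnogram(c("N2", "N2", "N2"))
  ep <- epoch_and_align(rec, hyp)
  expect_equal(length(ep$stages), 3)
  expect_match(paste(ep$log, collapse = " "), "5.000 s")

  # hypnogram of 4, signal of 2 -> 2 aligned + 2 dropped "no signal"
  rec2 <- eeg_record(matrix(stats::rnorm(60 * 100), ncol = 1), 100, "C3")
  hyp4 <- hypnogram(rep("N2", 4))
  ep2 <- epoch_and_align(rec2, hyp4)
  expect_equal(length(ep2$stages), 2)
  expect_equal(sum(ep2$dropped$reason == "no signal"), 2)

  # conservation: epochs_in = retained + dropped, retained strictly increasing
  hyp_na <- hypnogram(c("N2", NA, "N2", NA, "N2"))
  rec5 <- eeg_record(matrix(stats::rnorm(5 * 30 * 100), ncol = 1), 100, "C3")
  ep3 <- epoch_and_align(rec5, hyp_na)
  expect_equal(length(ep3$stages) + nrow(ep3$dropped), 5)
  expect_true(all(diff(ep3$epoch_index) > 0))
  expect_identical(ep3$epoch_index, c(0L, 2L, 4L))

  # less than one epoch of signal is an error
  expect_error(epoch_and_align(eeg_record(matrix(0, 10, 1), 100, "C3"), hyp),
               "shorter than one epoch")
})

test_that("channels at different sampling rates are resampled to the highest", {
  # minimal 2-signal EDF with unequal samples-per-record, written here byte by
  # byte (independently of write_edf, so this also cross-checks the reader)
  n_rec <- 60L; fs_fast <- 200L; fs_slow <- 100L
  t_fast <- (0:(n_rec * fs_fast - 1)) / fs_fast
  t_slow <- (0:(n_rec * fs_slow - 1)) / fs_slow
  x_fast <- 100 * sin(2 * pi * 3 * t_fast)
  x_slow <- 100 * sin(2 * pi * 3 * t_slow)
  f <- withr::local_tempfile(fileext = ".edf")
  con <- file(f, "wb")
  pad <- function(x, w) formatC(substr(as.character(x), 1, w), width = w, flag = "-")
  writeChar(paste0(pad("0", 8), pad("", 80), pad("", 80), pad("01.01.00", 8),
                   pad("00.00.00", 8), pad(256 * 3, 8), pad("", 44),
                   pad(n_rec, 8), pad("1", 8), pad("2", 4)), con, eos = NULL)
  fld <- function(vals, w)
    writeChar(paste(vapply(vals, pad, "", w), collapse = ""), con, eos = NULL)
  fld(c("C3", "C4"), 16); fld(c("", ""), 80); fld(c("uV", "uV"), 8)
  fld(c("-1000", "-1000"), 8); fld(c("1000", "1000"), 8)
  fld(c("-32768", "-32768"), 8); fld(c("32767", "32767"), 8)
  fld(c("", ""), 80); fld(c(fs_fast, fs_slow), 8); fld(c("", ""), 32)
  dig <- function(x) as.integer(round((x + 1000) * 65535 / 2000) - 32768L)
  for (r in seq_len(n_rec)) {
    writeBin(dig(x_fast[((r - 1) * fs_fast + 1):(r * fs_fast)]), con,
             size = 2L, endian = "little")
    writeBin(dig(x_slow[((r - 1) * fs_slow + 1):(r * fs_slow)]), con,
             size = 2L, endian = "little")
  }
  close(con)

  lr <- load_recording(f, channels = NULL)
  expect_equal(lr$record$fs, 200)
  expect_equal(nrow(lr$record$samples), n_rec * fs_fast)
  expect_match(paste(lr$log, collapse = " "), "resampled.*C4")
  expect_lt(max(abs(lr$record$samples[, "C3"] - x_fast)), 0.05)
  # linear interpolation of a 3 Hz tone sampled at 100 Hz stays within ~0.5%
  # (the final sample is clamped extrapolation beyond the slow grid: skip it)
  body <- seq_len(n_rec * fs_fast - 2L)
  expect_lt(max(abs(lr$record$samples[body, "C4"] - x_fast[body])), 0.5)
})
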