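make_night_edf <- function(path, seed = 21) {
  tpl <- period_template(
    template_block("WAKE_GAP", rep("W", 10)),
    template_block("NREMP", c(rep("N2", 25), rep("N3", 15))),
    template_block("REMP", rep("R", 12)),
    template_block("NREMP", rep("N2", 35)))
  g <- generate_hypnogram(tpl)
  rec <- generate_eeg(g$hypnogram, fs = 100, n_channels = 2, seed = seed)
  write_recording(rec, g$hypnogram, path)
  g
}

test_that("a full EDF run writes all four artifacts", {
  edf <- withr::local_tempfile(fileext = ".edf")
  g <- make_night_edf(edf)
  out <- withr::local_tempdir()
  res <- run_pipeline(run_config(input = edf, outdir = out,
                                 channels = c("F3", "F4")))
  expect_equal(res$status, 0L)
  expect_true(file.exists(file.path(out, "figure.jpeg")))
  expect_true(file.exists(file.path(out, "stage_listing.tsv")))
  expect_true(file.exists(file.path(out, "period_listing.tsv")))
  expect_true(file.exists(file.path(out, "spectrogram", "power.npy")))

  # one stage-listing row per retained epoch
  stages <- utils::read.delim(file.path(out, "stage_listing.tsv"))
  expect_equal(nrow(stages), n_epochs(g$hypnogram))
  # period listing matches the detection and the template truth
  periods <- utils::read.delim(file.path(out, "period_listing.tsv"))
  expect_equal(periods$start_epoch, g$truth$start_epoch)
  expect_equal(periods$kind, g$truth$kind)
  # durations (wake-excluded) agree with per-epoch label counts here because
  # the template periods contain no internal wake
  for (i in seq_len(nrow(periods)))
    expect_equal(periods$duration_min[i],
                 sum(stages$period == periods$label[i]) * 30 / 60)
  # exported matrix round-trips and matches the in-memory spectrogram
  pw <- read_npy(file.path(out, "spectrogram", "power.npy"))
  expect_equal(dim(pw), dim(res$spectrogram$power))
  expect_equal(pw, res$spectrogram$power)
})

test_that("repeated runs produce byte-identical listings and matrix export", {
  edf <- withr::local_tempfile(fileext = ".edf")
  make_night_edf(edf)
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  run_pipeline(run_config(input = edf, outdir = out1, channels = c("F3", "F4")))
  run_pipeline(run_config(input = edf, outdir = out2, channels = c("F3", "F4")))
  for (f in c("stage_listing.tsv", "period_listing.tsv",
              file.path("spectrogram", "power.npy"))) {
    expect_identical(readBin(file.path(out1, f), "raw", file.size(file.path(out1, f))),
                     readBin(file.path(out2, f), "raw", file.size(file.path(out2, f))),
                     info = f)
  }
})

test_that("annotation-only input yields listings and hypnogram figure, no matrix", {
  tpl <- period_template(
    template_block("NREMP", rep("N2", 40)),
    template_block("REMP", rep("R", 12)))
  g <- generate_hypnogram(tpl)
  ann <- withr::local_tempfile(fileext = ".txt")
  writeLines(sprintf("%d\t%s", seq_len(n_epochs(g$hypnogram)) - 1,
                     g$hypnogram$stages), ann)
  out <- withr::local_tempdir()
  res <- run_pipeline(run_config(annotations = ann, outdir = out))
  expect_null(res$spectrogram)
  expect_true(file.exists(file.path(out, "figure.jpeg")))
  expect_true(file.exists(file.path(out, "period_listing.tsv")))
  expect_false(dir.exists(file.path(out, "spectrogram")))
  expect_equal(res$detection$periods$kind, c("NREMP", "REMP"))
})

test_that("an EDF without annotations yields a spectrogram-only run", {
  rec <- tone_record(10, fs = 100, n_epochs = 4, n_channels = 1,
                     channel_names = "C3")
  edf <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, edf)
  out <- withr::local_tempdir()
  res <- run_pipeline(run_config(input = edf, outdir = out, channels = "C3"))
  expect_null(res$detection)
  expect_true(file.exists(file.path(out, "figure.jpeg")))
  expect_true(file.exists(file.path(out, "spectrogram", "power.npy")))
  expect_false(file.exists(file.path(out, "period_listing.tsv")))
})

test_that("epoch filters remove flagged epochs from listings and spectrogram alike", {
  tpl <- period_template(
    template_block("NREMP", rep("N2", 40)),
    template_block("REMP", rep("R", 12)))
  g <- generate_hypnogram(tpl)
  rec <- generate_eeg(g$hypnogram, fs = 200, n_channels = 2, seed = 31)
  # in-band 800 uV artifact throughout epoch 0 (survives the band-pass)
  t0 <- (0:5999) / 200
  rec$samples[1:6000, 1] <- 800 * sin(2 * pi * 10 * t0)
  edf <- withr::local_tempfile(fileext = ".edf")
  write_recording(rec, g$hypnogram, edf)
  out <- withr::local_tempdir()
  res <- run_pipeline(run_config(input = edf, outdir = out,
                                 channels = c("F3", "F4"),
                                 filters = filter_config(apply = TRUE)))
  stages <- utils::read.delim(file.path(out, "stage_listing.tsv"))
  expect_equal(nrow(stages), 51)
  expect_false(0 %in% stages$epoch)
  expect_equal(dim(res$spectrogram$power)[1], 51)
  expect_match(paste(readLines(file.path(out, "run_log.txt")), collapse = "\n"),
               "amplitude")
})

test_that("render_figure guards its contracts", {
  expect_error(render_figure(NULL, NULL, tempfile()), "nothing to render")
  ep <- noise_epoched(rep("N2", 2), fs = 200, n_channels = 1)
  sp <- multitaper_spectrogram(ep)
  det <- detect_periods(hypnogram(rep("N2", 40)))
  disp <- aggregate_display(sp)
  expect_error(render_figure(det, disp, tempfile(fileext = ".png"),
                             format = "png"),
               "freqs_hz")
  expect_error(render_figure(det, disp[1, , drop = FALSE],
                             tempfile(fileext = ".png"), format = "png",
                             freqs_hz = sp$freqs_hz,
                             epoch_index_map = sp$epoch_index_map),
               "does not match")
  f <- withr::local_tempfile(fileext = ".svg")
  render_figure(det, sp, f, format = "svg")
  expect_gt(file.size(f), 1000)
})

test_that("npy files are valid for NumPy and round-trip through R", {
  arr <- array(stats::rnorm(24), dim = c(2, 3, 4))
  f <- withr::local_tempfile(fileext = ".npy")
  write_npy(arr, f)
  expect_equal(read_npy(f), arr)
  v <- c(1.5, -2.5, 3.25)
  f2 <- withr::local_tempfile(fileext = ".npy")
  write_npy(v, f2)
  expect_equal(read_npy(f2), v)
  # cross-check with NumPy itself
  py <- Sys.which("python")
  expect_true(nzchar(py))
  out <- system2(py, c("-c", shQuote(sprintf(
    "import numpy; a = numpy.load('%s'); print(a.shape, float(a.sum()))", f))),
    stdout = TRUE)
  expect_match(out, "\\(2, 3, 4\\)")
  py_sum <- as.numeric(sub(".*\\) ", "", out))
  expect_equal(py_sum, sum(arr), tolerance = 1e-12)
})

test_that("YAML run configuration reproduces the same pipeline settings", {
  cfgf <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "annotations: ann.txt",
    "epoch_len_s: 30",
    "channels: [C3, C4]",
    "detection:",
    "  wake_break_min: 6",
    "filters:",
    "  apply: true",
    "  notch_hz: 50",
    "stage_map:",
    "  'Sleep stage 1': N1",
    "  'Movement': exclude"), cfgf)
  cfg <- read_run_config(cfgf)
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$channels, c("C3", "C4"))
  expect_equal(cfg$detection$wake_break_min, 6)
  expect_true(cfg$filters$apply)
  expect_equal(cfg$filters$notch_hz, 50)
  expect_equal(unclass(cfg$label_map)[["Sleep stage 1"]], "N1")
  expect_equal(unclass(cfg$label_map)[["Movement"]], exclude_marker())
})
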