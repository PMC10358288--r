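# Shared fixture builders. Everything is generated in code at test time.

# Shorthand for building stage vectors: stg(W = 10, N2 = 40, R = 12, ...)
# (names repeat: use the list form runs() below when a stage recurs).
runs <- function(...) {
  spec <- list(...)
  unlist(lapply(spec, function(x) rep(x[[1]], x[[2]])), use.names = FALSE)
}
r_ <- function(stage, n) list(stage, n)

# Single-tone record: amp * sin(2 pi f t), one or more identical channels.
tone_record <- function(freq_hz, fs = 200, n_epochs = 2, epoch_len_s = 30,
                        amp = 1, n_channels = 1,
                        channel_names = paste0("C", seq_len(n_channels))) {
  t <- (seq_len(n_epochs * epoch_len_s * fs) - 1) / fs
  x <- amp * sin(2 * pi * freq_hz * t)
  eeg_record(matrix(rep(x, n_channels), ncol = n_channels), fs,
             channel_names = channel_names)
}

# Epoched recording straight from a stage vector (noise-only EEG).
noise_epoched <- function(stages, fs = 200, n_channels = 2, epoch_len_s = 30,
                          seed = 42, sd = 10) {
  hyp <- hypnogram(stages, epoch_len_s)
  withr::with_seed(seed, {
    x <- matrix(stats::rnorm(length(stages) * epoch_len_s * fs * n_channels,
                             sd = sd), ncol = n_channels)
  })
  epoch_and_align(eeg_record(x, fs, paste0("C", seq_len(n_channels))), hyp)
}

# Random valid period template (caller controls the seed). Blocks respect
# every rule threshold so detection must recover the template exactly.
random_template <- function(epoch_len_s = 30) {
  short_run <- function(stage_pool, max_len = 9)
    rep(sample(stage_pool, 1), sample(max_len, 1))
  nremp_block <- function(allow_r) {
    st <- rep("N2", sample(10:20, 1))  # opening run >= transition threshold
    n_mid <- sample(0:4, 1)
    for (i in seq_len(n_mid)) {
      pool <- c("N1", "N2", "N3")
      extra <- if (allow_r && stats::runif(1) < 0.4) short_run("R")
        else if (stats::runif(1) < 0.4) short_run("W")
        else character(0)
      st <- c(st, extra, rep(sample(pool, 1), sample(3:15, 1)))
    }
    st <- c(st, rep("N2", sample(10:20, 1)))  # closing run, own family
    # enforce the wake-excluded duration window [15, 120] min
    sleep_ep <- sum(st != "W")
    if (sleep_ep < 30) st <- c(st, rep("N2", 30 - sleep_ep))
    if (sleep_ep > 240) st <- st[st != "W"][1:240]
    template_block("NREMP", st)
  }
  remp_block <- function() {
    st <- rep("R", sample(10:20, 1))
    n_mid <- sample(0:2, 1)
    for (i in seq_len(n_mid)) {
      extra <- if (stats::runif(1) < 0.5) short_run(c("N1", "N2")) else short_run("W")
      st <- c(st, extra, rep("R", sample(3:10, 1)))
    }
    template_block("REMP", c(st, rep("R", 10)))
  }
  gap_block <- function() template_block("WAKE_GAP", rep("W", sample(10:20, 1)))

  blocks <- list()
  if (stats::runif(1) < 0.3) blocks <- c(blocks, list(gap_block()))
  n_periods <- sample(2:5, 1)
  seen_remp <- FALSE
  last_kind <- "WAKE_GAP"
  for (i in seq_len(n_periods)) {
    want_remp <- i > 1 && stats::runif(1) < 0.45
    if (want_remp) {
      if (last_kind == "REMP") blocks <- c(blocks, list(gap_block()))
      blocks <- c(blocks, list(remp_block()))
      seen_remp <- TRUE
      last_kind <- "REMP"
    } else {
      if (last_kind == "NREMP") blocks <- c(blocks, list(gap_block()))
      blocks <- c(blocks, list(nremp_block(allow_r = seen_remp)))
      last_kind <- "NREMP"
    }
  }
  if (stats::runif(1) < 0.3) blocks <- c(blocks, list(gap_block()))
  period_template(blocks, epoch_len_s = epoch_len_s)
}
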