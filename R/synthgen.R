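# Synthetic fixtures: template hypnograms with known ground-truth periods and
# band-structured EEG, so the whole pipeline is testable without clinical
# recordings.

#' Build one block of a period template
#'
#' @param kind `"NREMP"`, `"REMP"` or `"WAKE_GAP"`.
#' @param stages Character vector of stages for the block, in epoch order
#'   (build runs with `rep()`).
#' @return A template block (list).
#' @export
#' @examples
#' template_block("NREMP", rep("N2", 40))
template_block <- function(kind = c("NREMP", "REMP", "WAKE_GAP"), stages) {
  kind <- match.arg(kind)
  list(kind = kind, stages = as.character(stages))
}

#' Assemble and validate a period template
#'
#' A template is an ordered list of blocks whose concatenation is the
#' hypnogram and whose NREMP/REMP blocks are, by construction, the periods
#' the detection engine must recover. Validation rejects any block the rule
#' engine would re-segment: period blocks must start and end with their own
#' sleep family, internal wake runs must stay below the wake-break
#' threshold, internal opposite-family runs below the transition threshold,
#' NREMP durations must lie within the configured bounds (wake-excluded),
#' non-first REMPs must meet the REMP minimum, NREMP blocks before the first
#' REMP must contain no R epochs (a single R epoch would end them), blocks
#' adjacent with no wake gap must open with a transition-length run, and
#' same-kind neighbours must be separated by a wake gap.
#'
#' @param ... [template_block()]s (or a single list of them).
#' @param epoch_len_s Epoch length in seconds (default 30).
#' @param config [detection_config()] the template must respect.
#' @return Object of class `period_template`.
#' @export
period_template <- function(..., epoch_len_s = 30,
                            config = detection_config(epoch_len_s = epoch_len_s)) {
  blocks <- list(...)
  if (length(blocks) == 1L && is.null(blocks[[1]]$kind)) blocks <- blocks[[1]]
  if (!length(blocks)) stop("template needs at least one block", call. = FALSE)
  L <- epoch_len_s
  wake_ep <- epochs_at_least(config$wake_break_min, L)
  trans_ep <- epochs_at_least(config$transition_run_min, L)
  fail <- function(i, why)
    stop(sprintf("template block %d (%s): %s", i, blocks[[i]]$kind, why),
         call. = FALSE)

  seen_remp <- FALSE
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    st <- b$stages
    if (!length(st)) fail(i, "empty block")
    bad <- setdiff(st, sleep_stages())
    if (length(bad)) fail(i, paste("unknown stage", bad[1]))
    runs <- stage_runs(stage_family(st))
    if (b$kind == "WAKE_GAP") {
      if (any(st != "W")) fail(i, "wake gap must be all W")
      if (length(st) < wake_ep)
        fail(i, sprintf("wake gap of %d epochs is below the %d-epoch break threshold",
                        length(st), wake_ep))
      next
    }
    own <- if (b$kind == "NREMP") "N" else "R"
    other <- if (b$kind == "NREMP") "R" else "N"
    if (runs$value[1] != own || runs$value[nrow(runs)] != own)
      fail(i, "period block must start and end with its own sleep family")
    w_runs <- runs$len[runs$value == "W"]
    if (length(w_runs) && max(w_runs) >= wake_ep)
      fail(i, "internal wake run reaches the wake-break threshold")
    o_runs <- runs$len[runs$value == other]
    if (length(o_runs) && max(o_runs) >= trans_ep)
      fail(i, "internal opposite-family run reaches the transition threshold")
    sleep_ep <- sum(st != "W")
    if (b$kind == "NREMP") {
      min_n <- epochs_at_least(config$min_nremp_min, L)
      max_n <- as.integer(floor(config$max_nremp_min * 60 / L))
      if (sleep_ep < min_n)
        fail(i, sprintf("NREMP of %.1f min is below the %g min minimum",
                        sleep_ep * L / 60, config$min_nremp_min))
      if (sleep_ep > max_n)
        fail(i, sprintf("NREMP of %.1f min exceeds the %g min maximum",
                        sleep_ep * L / 60, config$max_nremp_min))
      if (!seen_remp && any(st == "R"))
        fail(i, "NREMP before the first REMP must contain no R epochs")
    } else {
      if (seen_remp && sleep_ep < epochs_at_least(config$min_remp_min, L))
        fail(i, sprintf("non-first REMP of %.1f min is below the %g min minimum",
                        sleep_ep * L / 60, config$min_remp_min))
      seen_remp <- TRUE
    }
    if (i > 1L && blocks[[i - 1L]]$kind != "WAKE_GAP") {
      prev <- blocks[[i - 1L]]
      if (prev$kind == b$kind)
        fail(i, "same-kind neighbours need a WAKE_GAP between them")
      # transition recognized only from a long enough opening run (except a
      # first REMP directly after an NREMP, which opens at its first R epoch)
      first_remp_here <- b$kind == "REMP" &&
        !any(vapply(blocks[seq_len(i - 1L)], function(x) x$kind == "REMP", TRUE))
      if (!first_remp_here && runs$len[1] < trans_ep)
        fail(i, sprintf("opening run of %d epochs cannot trigger the %d-epoch transition",
                        runs$len[1], trans_ep))
    }
  }
  kinds <- vapply(blocks, `[[`, "", "kind")
  first_period <- which(kinds != "WAKE_GAP")[1]
  if (is.na(first_period))
    stop("template must contain at least one period block", call. = FALSE)
  if (kinds[first_period] == "REMP")
    stop("template cannot open with a REMP: leading R epochs are ignored by the scan",
         call. = FALSE)
  structure(list(blocks = blocks, epoch_len_s = L, config = config),
            class = "period_template")
}

#' Realize a template as a hypnogram plus its ground truth
#'
#' @param template A [period_template()].
#' @return List with `hypnogram` and `truth` (the period table — `kind`,
#'   `start_epoch`, `end_epoch` — that [detect_periods()] must recover;
#'   wake gaps are inter-period wake, not periods).
#' @export
generate_hypnogram <- function(template) {
  stopifnot(inherits(template, "period_template"))
  stages <- character()
  truth <- new_periods()
  at <- 0L
  for (b in template$blocks) {
    n <- length(b$stages)
    if (b$kind != "WAKE_GAP")
      truth[nrow(truth) + 1L, ] <- list(b$kind, at, at + n)
    stages <- c(stages, b$stages)
    at <- at + n
  }
  list(hypnogram = hypnogram(stages, template$epoch_len_s),
       truth = truth)
}

#' Stage-dependent spectral profile for synthetic EEG
#'
#' Each stage is a set of sinusoidal components (band centre, amplitude)
#' added to white Gaussian noise. The defaults follow the classic band
#' associations: alpha-dominated wake, theta in N1/REM, theta plus a spindle
#' component in N2, high-amplitude delta in N3.
#'
#' @param profiles Named list (one entry per stage) of data frames with
#'   columns `freq_hz` and `amp_uv`. Missing stages get noise only.
#' @param noise_sigma_uv White-noise standard deviation (default 5).
#' @return Object of class `stage_band_profile`.
#' @export
stage_band_profile <- function(profiles = NULL, noise_sigma_uv = 5) {
  if (is.null(profiles))
    profiles <- list(
      W = data.frame(freq_hz = c(10, 20), amp_uv = c(10, 5)),
      N1 = data.frame(freq_hz = 5, amp_uv = 15),
      N2 = data.frame(freq_hz = c(5, 13), amp_uv = c(15, 10)),
      N3 = data.frame(freq_hz = 2, amp_uv = 30),
      R = data.frame(freq_hz = c(6, 20), amp_uv = c(10, 5)))
  stopifnot(is.list(profiles))
  for (p in profiles)
    if (!all(c("freq_hz", "amp_uv") %in% names(p)) || any(p$amp_uv < 0))
      stop("each profile needs freq_hz and non-negative amp_uv columns", call. = FALSE)
  if (noise_sigma_uv < 0) stop("noise_sigma_uv must be non-negative", call. = FALSE)
  structure(list(profiles = profiles, noise_sigma_uv = noise_sigma_uv),
            class = "stage_band_profile")
}

#' Generate band-structured synthetic EEG for a hypnogram
#'
#' Each epoch's signal is the sum of its stage's sinusoids (phase continuous
#' across epochs) plus white Gaussian noise; unscored (`NA`) epochs get noise
#' only. Channels differ only in their independent noise. Deterministic for
#' a fixed seed.
#'
#' @param hyp A [hypnogram()].
#' @param profile A [stage_band_profile()].
#' @param fs Sampling rate in Hz (default 200; must exceed twice the highest
#'   band centre).
#' @param n_channels Number of channels (default 2).
#' @param channel_names Optional names (default the first `n_channels` of
#'   [default_channels()]).
#' @param seed Integer seed.
#' @return An [eeg_record()].
#' @export
generate_eeg <- function(hyp, profile = stage_band_profile(), fs = 200,
                         n_channels = 2, channel_names = NULL, seed = 1) {
  stopifnot(inherits(hyp, "hypnogram"), inherits(profile, "stage_band_profile"))
  fmax <- max(vapply(profile$profiles, function(p) max(p$freq_hz, 0), 0))
  if (fs < 2 * fmax)
    stop("fs = ", fs, " Hz aliases the ", fmax, " Hz band component; need fs >= ",
         2 * fmax, call. = FALSE)
  spe <- hyp$epoch_len_s * fs
  if (abs(spe - round(spe)) > 1e-9)
    stop("epoch_len_s x fs must be an integer number of samples", call. = FALSE)
  spe <- as.integer(round(spe))
  n_ep <- n_epochs(hyp)
  if (is.null(channel_names))
    channel_names <- c(default_channels(), paste0("ch", seq_len(max(0, n_channels - 8))))[
      seq_len(n_channels)]

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)

  n_samp <- n_ep * spe
  t <- (seq_len(n_samp) - 1) / fs
  base <- numeric(n_samp)
  for (ep in seq_len(n_ep)) {
    stg <- hyp$stages[ep]
    if (is.na(stg) || is.null(profile$profiles[[stg]])) next
    p <- profile$profiles[[stg]]
    idx <- ((ep - 1L) * spe + 1L):(ep * spe)
    for (j in seq_len(nrow(p)))
      base[idx] <- base[idx] + p$amp_uv[j] * sin(2 * pi * p$freq_hz[j] * t[idx])
  }
  samples <- base + matrix(stats::rnorm(n_samp * n_channels, sd = profile$noise_sigma_uv),
                           n_samp, n_channels)
  eeg_record(samples, fs = fs, channel_names = channel_names)
}

#' Write a synthetic recording as an EDF+ file
#'
#' Thin wrapper over [write_edf()] that requires an aligned hypnogram, so the
#' file round-trips through [load_recording()] with stages reproduced
#' exactly and samples within the 16-bit quantization of the physical range.
#'
#' @param record An [eeg_record()].
#' @param hyp The aligned [hypnogram()].
#' @param path Output path.
#' @param physical_range Physical range in microvolts (default 1000).
#' @return `path`, invisibly.
#' @export
write_recording <- function(record, hyp, path, physical_range = 1000) {
  stopifnot(inherits(record, "eeg_record"), inherits(hyp, "hypnogram"))
  n_sig <- floor(record_duration_s(record) / hyp$epoch_len_s)
  if (n_sig < 1) stop("record shorter than one epoch", call. = FALSE)
  write_edf(record, path, hypnogram = hyp, physical_range = physical_range)
}
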