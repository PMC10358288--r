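#' Configure a full pipeline run
#'
#' Bundles every setting of a run: input files, output directory, channel
#' selection, label map, and the detection, filter, epoch-quality and
#' spectral configurations. At least one of `input` (EDF) or `annotations`
#' (text) must be given; period detection requires stage annotations (from
#' either source), while an EDF without annotations still yields the
#' spectrogram.
#'
#' @param input Optional EDF/EDF+ file with EEG signals (and usually
#'   embedded stage annotations).
#' @param annotations Optional two-column text annotation file; when both
#'   inputs are given, the text annotations take precedence over embedded
#'   ones.
#' @param outdir Output directory (created if needed).
#' @param channels EEG channels to analyse (default [default_channels()]).
#' @param label_map A [stage_label_map()].
#' @param detection A [detection_config()].
#' @param filters A [filter_config()]; set `apply = TRUE` (or
#'   `apply_filters = TRUE` here) to enable.
#' @param quality An [epoch_quality_config()]; applied only when filters are.
#' @param spectral A [spectral_config()].
#' @param cut_selection Passed to [detect_periods()] (`--cut` on the CLI).
#' @param apply_filters Convenience override of `filters$apply`.
#' @param format Figure format: `"jpeg"` (default), `"png"` or `"svg"`.
#' @param epoch_len_s Epoch length in seconds (default 30).
#' @return Object of class `run_config`.
#' @export
run_config <- function(input = NULL, annotations = NULL, outdir = ".",
                       channels = default_channels(),
                       label_map = default_stage_map(),
                       detection = NULL, filters = filter_config(),
                       quality = epoch_quality_config(),
                       spectral = spectral_config(), cut_selection = NULL,
                       apply_filters = NULL, format = "jpeg",
                       epoch_len_s = 30) {
  if (is.null(input) && is.null(annotations))
    stop("need an EDF input and/or a text annotation file", call. = FALSE)
  if (!is.null(apply_filters)) filters$apply <- isTRUE(apply_filters)
  detection <- detection %||% detection_config(epoch_len_s = epoch_len_s)
  structure(list(input = input, annotations = annotations, outdir = outdir,
                 channels = channels, label_map = label_map,
                 detection = detection, filters = filters, quality = quality,
                 spectral = spectral, cut_selection = cut_selection,
                 format = format, epoch_len_s = epoch_len_s),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Recognised keys (all optional): `input`, `annotations`, `outdir`,
#' `channels` (list), `epoch_len_s`, `format`, `stage_map` (mapping of
#' vendor label to stage or `exclude`), `detection`, `filters`, `quality`,
#' `spectral` (each a mapping of the corresponding configuration function's
#' arguments), `cut_selection` (list of candidate indices).
#'
#' @param path YAML file.
#' @param ... Overrides passed on to [run_config()].
#' @return A [run_config()].
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  map <- default_stage_map()
  if (!is.null(y$stage_map)) {
    m <- unlist(y$stage_map)
    excl <- names(m)[m %in% c("exclude", exclude_marker())]
    m <- m[!(m %in% c("exclude", exclude_marker()))]
    map <- do.call(stage_label_map, c(as.list(m), list(exclude = excl)))
  }
  args <- list(
    input = y$input, annotations = y$annotations,
    outdir = y$outdir %||% ".",
    channels = unlist(y$channels) %||% default_channels(),
    label_map = map,
    epoch_len_s = y$epoch_len_s %||% 30,
    format = y$format %||% "jpeg",
    cut_selection = unlist(y$cut_selection))
  args$detection <- do.call(detection_config,
                            c(y$detection, list(epoch_len_s = args$epoch_len_s)))
  if (!is.null(y$filters)) args$filters <- do.call(filter_config, y$filters)
  if (!is.null(y$quality)) args$quality <- do.call(epoch_quality_config, y$quality)
  if (!is.null(y$spectral)) args$spectral <- do.call(spectral_config, y$spectral)
  do.call(run_config, utils::modifyList(args, list(...)))
}

#' Run the full detection + spectrogram pipeline
#'
#' Loads the input(s), optionally applies the frequency and epoch-quality
#' filters, runs period detection (when stage annotations exist), computes
#' the multitaper spectrogram (when EEG exists), and writes every applicable
#' artifact into `config$outdir`:
#' \itemize{
#'   \item `figure.<format>` — hypnogram + spectrogram visualization
#'   \item `stage_listing.tsv` — one row per retained epoch
#'   \item `period_listing.tsv` — one row per detected period
#'   \item `spectrogram/` — power matrix export ([write_spectrogram_matrix()])
#'   \item `run_log.txt` — dropped epochs and rule firings
#' }
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `status` (0 on success), `paths` (written
#'   artifacts), `detection`, `spectrogram`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log <- character()
  record <- NULL; hyp <- NULL

  if (!is.null(config$input)) {
    loaded <- load_recording(config$input, channels = config$channels,
                             label_map = config$label_map,
                             epoch_len_s = config$epoch_len_s)
    record <- loaded$record
    hyp <- loaded$hypnogram
    log <- c(log, loaded$log)
  }
  if (!is.null(config$annotations)) {
    hyp <- read_stage_annotations(config$annotations,
                                  label_map = config$label_map,
                                  epoch_len_s = config$epoch_len_s)
    log <- c(log, attr(hyp, "log") %||% character())
  }
  if (is.null(hyp))
    log <- c(log, "no stage annotations: spectrogram only, no period detection")

  det <- NULL; spec <- NULL; epoch_index <- NULL
  if (!is.null(record)) {
    if (isTRUE(config$filters$apply))
      record <- apply_frequency_filters(record, config$filters)
    ep_hyp <- hyp %||% hypnogram(rep("W", max(1L, floor(record_duration_s(record) /
                                                          config$epoch_len_s))),
                                 config$epoch_len_s)
    epoched <- epoch_and_align(record, ep_hyp)
    log <- c(log, epoched$log)
    if (isTRUE(config$filters$apply)) {
      flags <- flag_bad_epochs(epoched, config$quality)
      if (any(flags$mask)) {
        log <- c(log, sprintf("epoch%d: dropped (%s)", flags$reasons$epoch,
                              flags$reasons$reason))
        epoched <- drop_epochs(epoched, which(flags$mask), flags$reasons$reason)
      }
    }
    if (nrow(epoched$dropped))
      log <- c(log, sprintf("epoch%d: dropped (%s)",
                            epoched$dropped$epoch, epoched$dropped$reason))
    spec <- multitaper_spectrogram(epoched, config$spectral)
    if (!is.null(hyp)) {
      det <- detect_periods(epoched_hypnogram(epoched), config$detection,
                            cut_selection = config$cut_selection)
      epoch_index <- epoched$epoch_index
    }
  } else {
    compact <- drop_unscored(hyp)
    if (nrow(compact$hypnogram$dropped))
      log <- c(log, sprintf("epoch%d: dropped (%s)",
                            compact$hypnogram$dropped$epoch,
                            compact$hypnogram$dropped$reason))
    det <- detect_periods(compact$hypnogram, config$detection,
                          cut_selection = config$cut_selection)
    epoch_index <- compact$epoch_index
  }

  paths <- list()
  fig <- file.path(config$outdir, paste0("figure.", config$format))
  if (!is.null(det) && !is.null(spec)) {
    # detection ran on the jointly filtered (compacted) hypnogram, so the
    # shared x axis is the retained-epoch axis: plot spectrogram columns at
    # their compacted positions
    render_figure(det, aggregate_display(spec), fig, format = config$format,
                  freqs_hz = spec$freqs_hz,
                  epoch_index_map = seq_along(spec$epoch_index_map) - 1L)
  } else {
    render_figure(det, spec, fig, format = config$format)
  }
  paths$figure <- fig
  if (!is.null(det)) {
    paths$stage_listing <- write_stage_listing(
      det, file.path(config$outdir, "stage_listing.tsv"), epoch_index)
    paths$period_listing <- write_period_listing(
      det, file.path(config$outdir, "period_listing.tsv"))
    log <- c(log, det$log)
  }
  if (!is.null(spec))
    paths$spectrogram <- write_spectrogram_matrix(
      spec, file.path(config$outdir, "spectrogram"))
  log_path <- file.path(config$outdir, "run_log.txt")
  writeLines(log, log_path)
  paths$log <- log_path
  invisible(list(status = 0L, paths = paths, detection = det, spectrogram = spec))
}
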