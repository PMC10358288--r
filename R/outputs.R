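# Text listings: one row per retained epoch, and one row per detected period.
# Tab-separated with a single header line; byte-identical across repeated
# runs on the same inputs.

#' Write the epoch-based stage listing
#'
#' One row per retained epoch: 0-based epoch number, stage, and the period
#' label (NC1..., RC1...) or wake classification from the detection result.
#'
#' @param det A [detect_periods()] result.
#' @param path Output file.
#' @param epoch_index Optional original 0-based epoch indices (when detection
#'   ran on a compacted hypnogram); defaults to 0..n-1.
#' @return `path`, invisibly.
#' @export
write_stage_listing <- function(det, path, epoch_index = NULL) {
  stopifnot(inherits(det, "period_detection"))
  n <- n_epochs(det$hypnogram)
  idx <- epoch_index %||% (seq_len(n) - 1L)
  df <- data.frame(epoch = idx, stage = det$hypnogram$stages,
                   period = det$per_epoch_label)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the sleep-period listing
#'
#' One row per period: per-kind ordinal, NC/RC label, kind, 0-based half-open
#' epoch interval, wake-excluded duration in minutes, and clock times when
#' the hypnogram has an origin time.
#'
#' @param det A [detect_periods()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_period_listing <- function(det, path) {
  stopifnot(inherits(det, "period_detection"))
  p <- det$periods
  df <- data.frame(ordinal = p$ordinal, label = p$label, kind = p$kind,
                   start_epoch = p$start_epoch, end_epoch = p$end_epoch,
                   duration_min = sprintf("%.2f", p$duration_min))
  if (!is.null(det$hypnogram$origin_time)) {
    t0 <- det$hypnogram$origin_time
    L <- det$hypnogram$epoch_len_s
    df$start_time <- format(t0 + p$start_epoch * L, "%H:%M:%S")
    df$end_time <- format(t0 + p$end_epoch * L, "%H:%M:%S")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the rule-firing log
#'
#' @param det A [detect_periods()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_rule_log <- function(det, path) {
  stopifnot(inherits(det, "period_detection"))
  writeLines(det$log, path)
  invisible(path)
}
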