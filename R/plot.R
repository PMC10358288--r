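# Visualization: hypnogram with shaded NREM/REM periods, stacked above a
# time-matched spectrogram heatmap sharing the epoch axis.

stage_y <- c(N3 = 1, N2 = 2, N1 = 3, R = 4, W = 5)  # W on top

plot_hypnogram_panel <- function(det, xlim) {
  hyp <- det$hypnogram
  n <- n_epochs(hyp)
  y <- stage_y[hyp$stages]
  graphics::plot(NA, xlim = xlim, ylim = c(0.5, 5.5), xlab = "",
                 ylab = "Stage", yaxt = "n", xaxt = "n", bty = "o")
  graphics::axis(2, at = stage_y, labels = names(stage_y), las = 1)
  p <- det$periods
  if (nrow(p)) {
    cols <- ifelse(p$kind == "NREMP", grDevices::adjustcolor("steelblue", 0.25),
                   grDevices::adjustcolor("indianred", 0.35))
    graphics::rect(p$start_epoch, 0.5, p$end_epoch, 5.5, col = cols, border = NA)
    graphics::text((p$start_epoch + p$end_epoch) / 2, 5.25, p$label, cex = 0.8)
  }
  # step trace: each epoch holds its stage over [i, i+1)
  graphics::lines(c(seq_len(n) - 1, n), c(y, y[n]), type = "s",
                  lwd = 1.2, col = "grey20")
}

plot_spectrogram_panel <- function(display, epoch_x, freqs, epoch_len_s, xlim) {
  pal <- grDevices::hcl.colors(128, "viridis")
  graphics::image(x = epoch_x, y = freqs, z = display, col = pal,
                  xlab = sprintf("Epoch (%g s)", epoch_len_s),
                  ylab = "Frequency (Hz)", xlim = xlim, useRaster = TRUE)
}

#' Render the hypnogram + spectrogram figure
#'
#' Stacked panels on a shared epoch axis: the hypnogram trace (stage order
#' W > R > N1 > N2 > N3 top to bottom) with NREM/REM periods shaded and
#' labelled NC1..., RC1..., and the spectrogram heatmap below. Either panel
#' alone is drawn when only one input is available.
#'
#' @param det A [detect_periods()] result, or `NULL` (spectrogram-only).
#' @param display Optional epochs x frequencies dB matrix from
#'   [aggregate_display()], or a `spectrogram` (aggregated with the default
#'   mean), or `NULL` (hypnogram-only).
#' @param path Output image file.
#' @param format `"jpeg"` (default), `"png"` or `"svg"`.
#' @param freqs_hz,epoch_index_map Axes for `display` when it is a plain
#'   matrix; taken from the `spectrogram` object otherwise.
#' @param width,height Device size in pixels (svg: interpreted at 96 dpi).
#' @return `path`, invisibly.
#' @export
render_figure <- function(det = NULL, display = NULL, path,
                          format = c("jpeg", "png", "svg"),
                          freqs_hz = NULL, epoch_index_map = NULL,
                          width = 1200, height = 700) {
  format <- match.arg(format)
  if (is.null(det) && is.null(display))
    stop("nothing to render: no detection result and no spectrogram", call. = FALSE)
  if (inherits(display, "spectrogram")) {
    freqs_hz <- display$freqs_hz
    epoch_index_map <- display$epoch_index_map
    display <- aggregate_display(display)
  }
  if (!is.null(display)) {
    if (is.null(freqs_hz) || is.null(epoch_index_map))
      stop("display matrix needs freqs_hz and epoch_index_map", call. = FALSE)
    if (nrow(display) != length(epoch_index_map))
      stop("display epoch axis (", nrow(display), ") does not match the epoch map (",
           length(epoch_index_map), ")", call. = FALSE)
    if (!is.null(det) && max(epoch_index_map) >= n_epochs(det$hypnogram))
      stop("spectrogram epochs extend beyond the hypnogram; axes mismatch",
           call. = FALSE)
  }
  switch(format,
         jpeg = grDevices::jpeg(path, width = width, height = height, quality = 92),
         png = grDevices::png(path, width = width, height = height),
         svg = grDevices::svg(path, width = width / 96, height = height / 96))
  on.exit(grDevices::dev.off(), add = TRUE)
  n_panel <- (!is.null(det)) + (!is.null(display))
  graphics::par(mfrow = c(n_panel, 1), mar = c(4, 5, 1.5, 1), oma = c(0, 0, 1, 0))
  xlim <- if (!is.null(det)) c(0, n_epochs(det$hypnogram)) else
    c(min(epoch_index_map), max(epoch_index_map) + 1)
  if (!is.null(det)) plot_hypnogram_panel(det, xlim)
  if (!is.null(display)) {
    L <- if (!is.null(det)) det$hypnogram$epoch_len_s else NA
    plot_spectrogram_panel(display, epoch_index_map + 0.5, freqs_hz,
                           if (is.na(L)) 30 else L, xlim)
  }
  invisible(path)
}
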