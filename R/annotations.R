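#' Read a plain-text sleep-stage annotation file
#'
#' Parses the two-column annotation format exported by most scoring software:
#' epoch number and stage label, whitespace- or comma-delimited (the delimiter
#' is auto-detected from the first data line). Lines starting with `#` and
#' blank lines are skipped. Lines may appear in any order; the result is
#' sorted by epoch number.
#'
#' Epoch numbers must be consecutive: gaps are an error, never silently
#' filled. Files numbered from 1 (common in vendor exports) are re-based to 0
#' and the shift is recorded in the returned hypnogram's log attribute.
#' Labels mapped to [exclude_marker()] become unscored (`NA`) epochs recorded
#' as dropped; any label absent from the map aborts with a list of every
#' unmapped label.
#'
#' @param file Path to the annotation file. Ignored when `text` is given.
#' @param label_map A [stage_label_map()] translating the file's labels.
#' @param epoch_len_s Epoch length in seconds (default 30).
#' @param text Optional character vector of lines (or a single string with
#'   embedded newlines) parsed instead of `file`; convenient for testing.
#' @return A [hypnogram()]. Excluded epochs are `NA` with the reason recorded
#'   in the hypnogram's `dropped` table.
#' @export
#' @examples
#' h <- read_stage_annotations(text = c("0 W", "1 N1", "2 N2"))
#' h$stages
read_stage_annotations <- function(file, label_map = default_stage_map(),
                                   epoch_len_s = 30, text = NULL) {
  lines <- if (!is.null(text)) {
    unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  } else {
    if (!file.exists(file)) stop("annotation file not found: ", file, call. = FALSE)
    readLines(file, warn = FALSE)
  }
  src_line_no <- seq_along(lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]; src_line_no <- src_line_no[keep]
  if (!length(lines)) stop("annotation input has no data lines", call. = FALSE)

  delim <- if (grepl(",", lines[[1]], fixed = TRUE)) "," else "[[:space:]]+"
  parts <- strsplit(trimws(lines), delim)
  nf <- lengths(parts)
  if (any(nf < 2L))
    stop("annotation line ", src_line_no[which(nf < 2L)[1L]],
         " does not have two columns (epoch number, stage)", call. = FALSE)
  epoch <- suppressWarnings(as.integer(trimws(vapply(parts, `[[`, "", 1L))))
  label <- trimws(vapply(parts, `[[`, "", 2L))
  if (anyNA(epoch))
    stop("non-numeric epoch number at line ", src_line_no[which(is.na(epoch))[1L]],
         call. = FALSE)

  dup <- duplicated(epoch)
  if (any(dup))
    stop("duplicate epoch number ", epoch[which(dup)[1L]], " at line ",
         src_line_no[which(dup)[1L]], call. = FALSE)

  ord <- order(epoch)
  epoch <- epoch[ord]; label <- label[ord]
  log <- character()
  if (epoch[1L] == 1L) {
    epoch <- epoch - 1L
    log <- "epoch numbering starts at 1; re-based to 0"
  }
  expected <- seq.int(epoch[1L], length.out = length(epoch))
  if (epoch[1L] != 0L || !identical(epoch, as.integer(expected))) {
    gap <- setdiff(seq.int(0L, max(epoch)), epoch)
    stop("epoch numbers are not consecutive from 0 (missing: ",
         paste(utils::head(gap, 10L), collapse = ", "),
         if (length(gap) > 10L) ", ..." else "",
         "); gaps are not filled silently", call. = FALSE)
  }

  mapped <- map_stage_labels(label, label_map)
  if (length(mapped$unmapped))
    stop("unmapped stage label(s): ",
         paste(sprintf("'%s'", mapped$unmapped), collapse = ", "),
         "; extend the stage_label_map (or map them to exclude_marker())",
         call. = FALSE)
  excl <- which(mapped$excluded)
  dropped <- data.frame(epoch = epoch[excl],
                        reason = if (length(excl))
                          paste0("excluded_annotation:", label[excl]) else character())
  hyp <- hypnogram(mapped$stage, epoch_len_s = epoch_len_s, dropped = dropped)
  attr(hyp, "log") <- log
  hyp
}
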