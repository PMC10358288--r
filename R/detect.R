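#' Detect NREM and REM sleep periods in a hypnogram
#'
#' Full rule pipeline: [scan_periods()] segments the night, then
#' [merge_short_periods()] enforces the duration minima, then every NREMP
#' whose wake-excluded duration exceeds `max_nremp_min` is split at a cut
#' point from [find_cut_candidates()] until no over-long splittable NREMP
#' remains. An over-long NREMP with no viable cut point is kept and logged.
#' The result is deterministic for a fixed cut selection.
#'
#' @param hyp A fully scored [hypnogram()] (apply [drop_unscored()] first if
#'   it carries `NA` epochs).
#' @param config A [detection_config()].
#' @param cut_selection How to choose among multiple cut candidates: `NULL`
#'   (take the first, i.e. earliest, candidate), an integer vector of 1-based
#'   candidate indices consumed one per split (the non-interactive equivalent
#'   of choosing an epoch in a prompt), or a function
#'   `function(candidates, period)` returning one index.
#' @return Object of class `period_detection`:
#'   \describe{
#'     \item{periods}{`sleep_periods` table: `kind`, `start_epoch`,
#'       `end_epoch` (0-based half-open), per-kind `ordinal`, `label`
#'       (NC1..., RC1...), wake-excluded `duration_min`}
#'     \item{per_epoch_label}{for every hypnogram epoch, its period label or
#'       one of `leading_wake`, `trailing_wake`, `inter_period_wake`,
#'       `unassigned`}
#'     \item{log}{ordered rule-firing log}
#'   }
#' @export
#' @examples
#' h <- hypnogram(c(rep("W", 4), rep("N2", 40), rep("R", 12), rep("N2", 40)))
#' det <- detect_periods(h)
#' det$periods
detect_periods <- function(hyp, config = detection_config(epoch_len_s = hyp$epoch_len_s),
                           cut_selection = NULL) {
  stopifnot(inherits(hyp, "hypnogram"), inherits(config, "detection_config"))
  raw <- scan_periods(hyp, config)
  log <- attr(raw, "log") %||% character()
  merged <- merge_short_periods(raw, hyp, config)
  log <- c(log, attr(merged, "log") %||% character())
  p <- finalize_periods(merged, hyp)

  pick <- make_cut_picker(cut_selection)
  unsplittable <- character()
  repeat {
    if (!nrow(p)) break
    key <- paste(p$start_epoch, p$end_epoch)
    over <- which(p$kind == "NREMP" & p$duration_min > config$max_nremp_min &
                    !(key %in% unsplittable))
    if (!length(over)) break
    i <- over[1L]
    cand <- find_cut_candidates(p[i, ], hyp, config)
    for (x in seq_len(nrow(attr(cand, "excluded") %||% data.frame())))
      log <- c(log, sprintf("epoch%d: %s cut suppressed (fragment below %g min)",
                            attr(cand, "excluded")$cut_epoch[x],
                            attr(cand, "excluded")$kind[x], config$min_nremp_min))
    if (!nrow(cand)) {
      log <- c(log, sprintf("epoch%d: NREMP of %.1f min exceeds %g min but has no viable cut point",
                            p$start_epoch[i], p$duration_min[i], config$max_nremp_min))
      warning("over-long NREMP at epoch ", p$start_epoch[i],
              " has no viable cut point; kept whole", call. = FALSE)
      unsplittable <- c(unsplittable, key[i])
      next
    }
    j <- pick(cand, p[i, ])
    if (!is.numeric(j) || length(j) != 1L || j < 1L || j > nrow(cand))
      stop("cut selection must pick one candidate index in 1..", nrow(cand),
           call. = FALSE)
    log <- c(log, sprintf("epoch%d: %s cut applied to NREMP [%d, %d)",
                          cand$cut_epoch[j], cand$kind[j],
                          p$start_epoch[i], p$end_epoch[i]))
    p <- apply_cut(p, p[i, ], cand[j, ], hyp, config)
  }

  structure(list(periods = p,
                 per_epoch_label = label_epochs(hyp, p),
                 log = log,
                 hypnogram = hyp,
                 config = config),
            class = "period_detection")
}

make_cut_picker <- function(cut_selection) {
  if (is.null(cut_selection)) return(function(cand, period) 1L)
  if (is.function(cut_selection)) return(cut_selection)
  if (is.numeric(cut_selection)) {
    queue <- as.integer(cut_selection)
    k <- 0L
    return(function(cand, period) {
      k <<- k + 1L
      if (k > length(queue)) 1L else queue[k]
    })
  }
  stop("cut_selection must be NULL, an integer vector, or a function", call. = FALSE)
}

# One label per hypnogram epoch: its period label, or where the epoch falls
# relative to the final periods.
label_epochs <- function(hyp, periods) {
  n <- n_epochs(hyp)
  lab <- rep("unassigned", n)
  is_w <- hyp$stages == "W"
  if (!nrow(periods)) {
    lab[is_w] <- "leading_wake"
    return(lab)
  }
  first_start <- min(periods$start_epoch)
  last_end <- max(periods$end_epoch)
  idx0 <- seq_len(n) - 1L
  lab[is_w & idx0 < first_start] <- "leading_wake"
  lab[is_w & idx0 >= last_end] <- "trailing_wake"
  lab[is_w & idx0 >= first_start & idx0 < last_end] <- "inter_period_wake"
  for (i in seq_len(nrow(periods))) {
    span <- (periods$start_epoch[i] + 1L):periods$end_epoch[i]
    lab[span] <- periods$label[i]
  }
  lab
}

#' @export
print.period_detection <- function(x, ...) {
  cat(sprintf("<period_detection> %d period(s) over %d epochs\n",
              nrow(x$periods), n_epochs(x$hypnogram)))
  if (nrow(x$periods)) print.data.frame(x$periods, row.names = FALSE)
  if (length(x$log)) cat(sprintf("  %d rule firing(s); see $log\n", length(x$log)))
  invisible(x)
}
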