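#' Detection thresholds for sleep-period segmentation
#'
#' Every duration rule the engine applies, in minutes. Rules are converted to
#' epoch counts against the hypnogram's epoch length: a run of `k` epochs
#' satisfies an "at least m minutes" rule iff `k * epoch_len_s >= m * 60`,
#' and an "exceeding m minutes" rule iff `k * epoch_len_s > m * 60`.
#'
#' @param min_nremp_min Minimum NREM-period duration, wake-excluded (default
#'   15). Shorter NREMPs are merged into an adjacent period.
#' @param max_nremp_min Maximum NREM-period duration (default 120). Longer
#'   NREMPs are split at an arousal or lightening-of-sleep point.
#' @param min_remp_min Minimum REM-period duration (default 5). Does not
#'   apply to the first REMP of the night.
#' @param wake_break_min Consecutive wake tolerated inside a period (default
#'   5). A wake run at least this long ends the current period; the wake
#'   epochs are removed and a new period begins at the next sleep epoch.
#' @param transition_run_min Run length of the opposite sleep family that
#'   ends a period once the first REMP has occurred (default 5).
#' @param arousal_cut_min Wake run that, when immediately followed by N3,
#'   marks an arousal cut point in an over-long NREMP; the rule is strict
#'   ("exceeding", default 1).
#' @param lightening_cut_min N1 run that, when immediately followed by N3,
#'   marks a lightening-of-sleep cut point (strict, default 3).
#' @param epoch_len_s Epoch length in seconds (default 30).
#' @return Object of class `detection_config`.
#' @export
#' @examples
#' cfg <- detection_config()
#' wake_tolerance_epochs(cfg)  # 10 epochs at 30 s
detection_config <- function(min_nremp_min = 15, max_nremp_min = 120,
                             min_remp_min = 5, wake_break_min = 5,
                             transition_run_min = 5, arousal_cut_min = 1,
                             lightening_cut_min = 3, epoch_len_s = 30) {
  cfg <- list(min_nremp_min = min_nremp_min, max_nremp_min = max_nremp_min,
              min_remp_min = min_remp_min, wake_break_min = wake_break_min,
              transition_run_min = transition_run_min,
              arousal_cut_min = arousal_cut_min,
              lightening_cut_min = lightening_cut_min,
              epoch_len_s = epoch_len_s)
  bad <- names(cfg)[!vapply(cfg, function(v)
    is.numeric(v) && length(v) == 1L && v > 0, TRUE)]
  if (length(bad))
    stop("detection_config durations must be single positive numbers: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (max_nremp_min <= min_nremp_min)
    stop("max_nremp_min must exceed min_nremp_min", call. = FALSE)
  structure(cfg, class = "detection_config")
}

#' Wake tolerance of a detection configuration, in epochs
#'
#' The smallest number of consecutive W epochs that ends the current sleep
#' period (10 epochs for the default 5 minutes at 30-s epochs). Wake runs
#' shorter than this stay inside the period but never count toward its
#' duration.
#'
#' @param config A [detection_config()].
#' @return Integer epoch count.
#' @export
wake_tolerance_epochs <- function(config = detection_config()) {
  stopifnot(inherits(config, "detection_config"))
  epochs_at_least(config$wake_break_min, config$epoch_len_s)
}

stage_family <- function(stages) {
  ifelse(stages == "W", "W", ifelse(stages == "R", "R", "N"))
}

stage_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  data.frame(value = r$values, start = ends - r$lengths, len = r$lengths,
             end = ends)  # 0-based half-open [start, end)
}

new_periods <- function(kind = character(), start = integer(), end = integer()) {
  data.frame(kind = kind, start_epoch = as.integer(start),
             end_epoch = as.integer(end))
}

#' Scan a hypnogram into raw NREM and REM periods
#'
#' The forward pass of the rule engine. Scanning starts at the first N1/N2
#' epoch (a leading N3 run with no prior N1/N2 also opens an NREMP, logged as
#' atypical); leading wake and REM epochs are ignored. Every NREMP that
#' precedes the first REMP ends at the first R epoch encountered; once a REMP
#' has occurred, periods end only at an opposite-family run of at least
#' `transition_run_min` minutes. A wake run of at least `wake_break_min`
#' minutes closes the current period at its last sleep epoch; the next
#' non-wake epoch opens a new period whose type follows that epoch's stage.
#' Trailing wake is ignored. The raw periods still need
#' [merge_short_periods()] to enforce the duration minima.
#'
#' @param hyp A fully scored [hypnogram()] (no `NA` stages).
#' @param config A [detection_config()].
#' @return `data.frame` (`kind`, `start_epoch`, `end_epoch`; 0-based,
#'   half-open) with the scan log in `attr(, "log")`. An all-wake hypnogram
#'   yields zero rows.
#' @export
scan_periods <- function(hyp, config = detection_config(epoch_len_s = hyp$epoch_len_s)) {
  stopifnot(inherits(hyp, "hypnogram"), inherits(config, "detection_config"))
  if (anyNA(hyp$stages))
    stop("hypnogram has unscored epochs; apply drop_unscored() first", call. = FALSE)
  L <- hyp$epoch_len_s
  wake_ep <- epochs_at_least(config$wake_break_min, L)
  trans_ep <- epochs_at_least(config$transition_run_min, L)
  runs <- stage_runs(stage_family(hyp$stages))
  log <- character()
  out <- new_periods()

  cur_kind <- NULL; cur_start <- NA_integer_; last_sleep_end <- NA_integer_
  seen_remp <- FALSE; started <- FALSE
  close_cur <- function() {
    out[nrow(out) + 1L, ] <<- list(cur_kind, cur_start, last_sleep_end)
    cur_kind <<- NULL
  }
  open_cur <- function(kind, at) {
    cur_kind <<- kind; cur_start <<- at
    if (kind == "REMP") seen_remp <<- TRUE
  }

  for (i in seq_len(nrow(runs))) {
    fam <- runs$value[i]; rs <- runs$start[i]; rl <- runs$len[i]; re <- runs$end[i]
    if (!started) {
      if (fam != "N") next  # leading W/R epochs are ignored
      started <- TRUE
      if (hyp$stages[rs + 1L] == "N3")
        log <- c(log, sprintf("epoch%d: sleep onset at N3 with no prior N1/N2 (atypical)", rs))
      open_cur("NREMP", rs); last_sleep_end <- re
      next
    }
    if (is.null(cur_kind)) {  # between periods after a wake break
      if (fam == "W") next
      open_cur(if (fam == "R") "REMP" else "NREMP", rs)
      log <- c(log, sprintf("epoch%d: new %s after wake break", rs, cur_kind))
      last_sleep_end <- re
      next
    }
    if (fam == "W") {
      if (rl >= wake_ep) {
        log <- c(log, sprintf("epoch%d: wake run of %d epochs (>= %g min) ended %s",
                              rs, rl, config$wake_break_min, cur_kind))
        close_cur()
      }
      # short wake runs stay inside the period (excluded from duration)
    } else if (fam == "N") {
      if (cur_kind == "NREMP") {
        last_sleep_end <- re
      } else if (rl >= trans_ep) {
        log <- c(log, sprintf("epoch%d: NREM run of %d epochs (>= %g min) ended REMP",
                              rs, rl, config$transition_run_min))
        close_cur(); open_cur("NREMP", rs); last_sleep_end <- re
      } else {
        last_sleep_end <- re  # short NREM run inside the REMP
      }
    } else {  # fam == "R"
      if (cur_kind == "REMP") {
        last_sleep_end <- re
      } else if (!seen_remp) {
        log <- c(log, sprintf("epoch%d: first R epoch ended NREMP preceding the first REMP", rs))
        close_cur(); open_cur("REMP", rs); last_sleep_end <- re
      } else if (rl >= trans_ep) {
        log <- c(log, sprintf("epoch%d: REM run of %d epochs (>= %g min) ended NREMP",
                              rs, rl, config$transition_run_min))
        close_cur(); open_cur("REMP", rs); last_sleep_end <- re
      } else {
        last_sleep_end <- re  # short REM run inside the NREMP
      }
    }
  }
  if (!is.null(cur_kind)) close_cur()
  attr(out, "log") <- log
  out
}

# Wake-excluded epoch count of an interval.
sleep_epochs_in <- function(hyp, start, end) {
  if (start >= end) return(0L)
  sum(hyp$stages[(start + 1L):end] != "W")
}

#' Wake-excluded duration of a period interval
#'
#' @param period One-row period data frame (or list) with `start_epoch` and
#'   `end_epoch` (0-based, half-open).
#' @param hyp The [hypnogram()] the interval indexes.
#' @return Duration in minutes, counting only non-W epochs.
#' @export
period_duration <- function(period, hyp) {
  stopifnot(inherits(hyp, "hypnogram"))
  s <- period$start_epoch; e <- period$end_epoch
  if (length(s) != 1L || length(e) != 1L)
    stop("period_duration expects a single period", call. = FALSE)
  if (s < 0 || e > n_epochs(hyp) || s > e)
    stop("period interval [", s, ", ", e, ") outside the hypnogram", call. = FALSE)
  sleep_epochs_in(hyp, s, e) * hyp$epoch_len_s / 60
}

#' Merge under-length periods and coalesce neighbours
#'
#' Enforces the duration minima on the raw scan: any NREMP shorter than
#' `min_nremp_min` (wake-excluded) and any REMP other than the first shorter
#' than `min_remp_min` is absorbed into the immediately preceding period when
#' one is temporally adjacent (no intervening wake break), otherwise into the
#' following adjacent period, otherwise — isolated by wake breaks on both
#' sides — dropped and logged. After every absorption, adjacent periods of
#' the same kind are coalesced. Iterated to a fixpoint.
#'
#' @param raw Raw periods from [scan_periods()].
#' @param hyp The scored [hypnogram()].
#' @param config A [detection_config()].
#' @return Period data frame like [scan_periods()]'s, satisfying the minima;
#'   log in `attr(, "log")`.
#' @export
merge_short_periods <- function(raw, hyp,
                                config = detection_config(epoch_len_s = hyp$epoch_len_s)) {
  stopifnot(inherits(hyp, "hypnogram"), inherits(config, "detection_config"))
  L <- hyp$epoch_len_s
  min_n <- epochs_at_least(config$min_nremp_min, L)
  min_r <- epochs_at_least(config$min_remp_min, L)
  wake_ep <- epochs_at_least(config$wake_break_min, L)
  p <- raw[order(raw$start_epoch), , drop = FALSE]
  log <- character()

  adjacent <- function(a_end, b_start) (b_start - a_end) < wake_ep
  coalesce <- function(p) {
    i <- 2L
    while (i <= nrow(p)) {
      if (p$kind[i] == p$kind[i - 1L] &&
          adjacent(p$end_epoch[i - 1L], p$start_epoch[i])) {
        log <<- c(log, sprintf("epoch%d: coalesced adjacent %ss",
                               p$start_epoch[i], p$kind[i]))
        p$end_epoch[i - 1L] <- p$end_epoch[i]
        p <- p[-i, , drop = FALSE]
      } else i <- i + 1L
    }
    p
  }

  for (iter in seq_len(max(nrow(p), 1L))) {
    if (!nrow(p)) break
    dur <- vapply(seq_len(nrow(p)), function(i)
      sleep_epochs_in(hyp, p$start_epoch[i], p$end_epoch[i]), 0L)
    remps <- which(p$kind == "REMP")
    first_remp <- if (length(remps)) remps[which.min(p$start_epoch[remps])] else NA_integer_
    short <- (p$kind == "NREMP" & dur < min_n) |
      (p$kind == "REMP" & dur < min_r & seq_len(nrow(p)) != first_remp)
    v <- which(short)
    if (!length(v)) break
    v <- v[1L]
    prev_adj <- v > 1L && adjacent(p$end_epoch[v - 1L], p$start_epoch[v])
    next_adj <- v < nrow(p) && adjacent(p$end_epoch[v], p$start_epoch[v + 1L])
    if (prev_adj) {
      log <- c(log, sprintf("epoch%d: short %s (%.1f min) absorbed into preceding %s",
                            p$start_epoch[v], p$kind[v], dur[v] * L / 60, p$kind[v - 1L]))
      p$end_epoch[v - 1L] <- p$end_epoch[v]
      p <- p[-v, , drop = FALSE]
    } else if (next_adj) {
      log <- c(log, sprintf("epoch%d: short %s (%.1f min) absorbed into following %s",
                            p$start_epoch[v], p$kind[v], dur[v] * L / 60, p$kind[v + 1L]))
      p$start_epoch[v + 1L] <- p$start_epoch[v]
      p <- p[-v, , drop = FALSE]
    } else {
      log <- c(log, sprintf("epoch%d: short isolated %s (%.1f min) dropped",
                            p$start_epoch[v], p$kind[v], dur[v] * L / 60))
      p <- p[-v, , drop = FALSE]
    }
    p <- coalesce(p)
  }
  rownames(p) <- NULL
  attr(p, "log") <- log
  p
}

# Attach per-kind ordinals, NC/RC labels and wake-excluded durations.
finalize_periods <- function(p, hyp) {
  p <- p[order(p$start_epoch), , drop = FALSE]
  rownames(p) <- NULL
  if (!nrow(p)) {
    p$ordinal <- integer(); p$label <- character(); p$duration_min <- numeric()
    class(p) <- c("sleep_periods", "data.frame")
    return(p)
  }
  ord <- integer(nrow(p))
  for (k in unique(p$kind)) ord[p$kind == k] <- seq_len(sum(p$kind == k))
  p$ordinal <- ord
  p$label <- paste0(ifelse(p$kind == "NREMP", "NC", "RC"), ord)
  p$duration_min <- vapply(seq_len(nrow(p)), function(i)
    period_duration(p[i, ], hyp), 0)
  class(p) <- c("sleep_periods", "data.frame")
  p
}

#' @export
print.sleep_periods <- function(x, ...) {
  cat(sprintf("<sleep_periods> %d period(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(x, row.names = FALSE)
  invisible(x)
}
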