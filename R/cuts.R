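#' Find candidate split points inside an over-long NREM period
#'
#' An NREMP whose wake-excluded duration exceeds `max_nremp_min` can be split
#' at two kinds of points, listed in epoch order:
#' \describe{
#'   \item{arousal}{the first epoch of an N3 run immediately preceded by a
#'     wake run exceeding `arousal_cut_min` (cut lands on the N3 epoch; the
#'     wake run is trimmed when the cut is applied);}
#'   \item{lightening}{the first epoch of an N1 run exceeding
#'     `lightening_cut_min` that is immediately followed by N3 (cut lands on
#'     the start of the N1 run).}
#' }
#' Candidates that would leave either fragment below `min_nremp_min`
#' (wake-excluded) are suppressed and reported in `attr(, "excluded")`.
#'
#' @param period One-row NREMP from the period table.
#' @param hyp The scored [hypnogram()].
#' @param config A [detection_config()].
#' @return `data.frame` (`cut_epoch`, `kind`, `run_start`, `run_len`) of
#'   class `cut_candidates`; zero rows when the period is not over-long or no
#'   trigger exists. The parent interval is kept in
#'   `attr(, "parent")`.
#' @export
find_cut_candidates <- function(period, hyp,
                                config = detection_config(epoch_len_s = hyp$epoch_len_s)) {
  stopifnot(inherits(hyp, "hypnogram"), inherits(config, "detection_config"))
  if (period$kind != "NREMP")
    stop("cut candidates are defined for NREMPs only (REM periods are never split)",
         call. = FALSE)
  s <- period$start_epoch; e <- period$end_epoch
  empty <- structure(
    data.frame(cut_epoch = integer(), kind = character(),
               run_start = integer(), run_len = integer()),
    parent = c(start_epoch = s, end_epoch = e), excluded = NULL,
    class = c("cut_candidates", "data.frame"))
  if (period_duration(period, hyp) <= config$max_nremp_min) return(empty)

  L <- hyp$epoch_len_s
  arousal_ep <- epochs_exceeding(config$arousal_cut_min, L)
  light_ep <- epochs_exceeding(config$lightening_cut_min, L)
  min_n <- epochs_at_least(config$min_nremp_min, L)
  runs <- stage_runs(hyp$stages[(s + 1L):e])
  runs$start <- runs$start + s; runs$end <- runs$end + s

  cand <- empty
  for (j in seq_len(nrow(runs))) {
    if (runs$value[j] == "N3" && j > 1L && runs$value[j - 1L] == "W" &&
        runs$len[j - 1L] >= arousal_ep)
      cand[nrow(cand) + 1L, ] <- list(runs$start[j], "arousal",
                                      runs$start[j - 1L], runs$len[j - 1L])
    if (runs$value[j] == "N1" && runs$len[j] >= light_ep &&
        j < nrow(runs) && runs$value[j + 1L] == "N3")
      cand[nrow(cand) + 1L, ] <- list(runs$start[j], "lightening",
                                      runs$start[j], runs$len[j])
  }
  cand <- cand[order(cand$cut_epoch), , drop = FALSE]
  rownames(cand) <- NULL
  ok <- vapply(cand$cut_epoch, function(cut)
    sleep_epochs_in(hyp, s, cut) >= min_n && sleep_epochs_in(hyp, cut, e) >= min_n,
    TRUE)
  excl <- cand[!ok, , drop = FALSE]
  cand <- cand[ok, , drop = FALSE]
  rownames(cand) <- NULL
  attr(cand, "parent") <- c(start_epoch = s, end_epoch = e)
  attr(cand, "excluded") <- if (nrow(excl)) excl else NULL
  class(cand) <- c("cut_candidates", "data.frame")
  cand
}

#' Apply a chosen cut to an over-long NREM period
#'
#' Replaces the parent NREMP with the two fragments `[start, cut_epoch)` and
#' `[cut_epoch, end)`. Trailing wake is trimmed from the first fragment and
#' leading wake from the second (those epochs become inter-period wake);
#' both fragments are NREMPs and ordinals are reassigned.
#'
#' @param periods Current period table.
#' @param parent The row of `periods` being split (matched by interval).
#' @param candidate One row of [find_cut_candidates()] output for `parent`;
#'   a candidate that was not generated for this parent is a contract error.
#' @param hyp The scored [hypnogram()].
#' @param config A [detection_config()].
#' @return The updated period table ([finalize_periods()] applied).
#' @export
apply_cut <- function(periods, parent, candidate, hyp,
                      config = detection_config(epoch_len_s = hyp$epoch_len_s)) {
  stopifnot(inherits(hyp, "hypnogram"))
  row <- which(periods$start_epoch == parent$start_epoch &
                 periods$end_epoch == parent$end_epoch &
                 periods$kind == "NREMP")
  if (length(row) != 1L)
    stop("parent period not found in the period table", call. = FALSE)
  legal <- find_cut_candidates(periods[row, ], hyp, config)
  hit <- which(legal$cut_epoch == candidate$cut_epoch & legal$kind == candidate$kind)
  if (length(hit) != 1L)
    stop("candidate (epoch ", candidate$cut_epoch,
         ", ", candidate$kind, ") was not generated for this period", call. = FALSE)

  s <- parent$start_epoch; e <- parent$end_epoch; cut <- candidate$cut_epoch
  st <- hyp$stages
  end1 <- cut
  while (end1 > s && st[end1] == "W") end1 <- end1 - 1L  # st[end1] is epoch end1-1
  start2 <- cut
  while (start2 < e && st[start2 + 1L] == "W") start2 <- start2 + 1L
  frag <- new_periods(c("NREMP", "NREMP"), c(s, start2), c(end1, e))
  out <- rbind(periods[seq_len(row - 1L), c("kind", "start_epoch", "end_epoch")],
               frag,
               periods[seq_len(nrow(periods))[-seq_len(row)],
                       c("kind", "start_epoch", "end_epoch")])
  finalize_periods(out, hyp)
}
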