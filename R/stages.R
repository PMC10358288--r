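#' Canonical sleep-stage labels
#'
#' The five AASM sleep stages used throughout the package: wake (`W`), the
#' three NREM stages (`N1`, `N2`, `N3`) and REM (`R`). Every hypnogram epoch
#' carries exactly one of these values (or `NA` for an unscored epoch that
#' will be dropped before detection).
#'
#' @return Character vector of the five stage labels.
#' @export
#' @examples
#' sleep_stages()
sleep_stages <- function() c("W", "N1", "N2", "N3", "R")

#' Marker used in a stage label map to exclude an annotation
#'
#' Vendor annotation streams often carry labels that are not sleep stages
#' ("Movement", "Lights on", bathroom breaks). Mapping such a label to
#' `exclude_marker()` drops the affected epochs from both the stage sequence
#' and the signal, exactly like an unannotated epoch.
#'
#' @return The exclusion marker string.
#' @export
exclude_marker <- function() ".exclude"

#' Build a stage label map
#'
#' Maps vendor annotation labels to the five canonical stages (or to the
#' exclusion marker). The map must be total over the labels present in an
#' input: any unmapped label aborts the load with a listing of every
#' offending label, so mapping problems surface once, not epoch by epoch.
#'
#' @param ... Named arguments `vendor_label = canonical_stage`, e.g.
#'   `"Sleep stage W" = "W"`. Values must be in [sleep_stages()] or
#'   [exclude_marker()].
#' @param exclude Character vector of labels to map to the exclusion marker.
#' @param base A map to extend (default [default_stage_map()]). Use `NULL`
#'   to start from an empty map.
#' @return Named character vector of class `stage_label_map`.
#' @export
#' @examples
#' m <- stage_label_map("Wake" = "W", "Stage1" = "N1", exclude = "Movement")
#' m[["Wake"]]
stage_label_map <- function(..., exclude = character(), base = default_stage_map()) {
  extra <- c(...)
  if (length(extra) && (is.null(names(extra)) || any(!nzchar(names(extra)))))
    stop("stage_label_map() entries must be named: vendor label = stage", call. = FALSE)
  bad <- setdiff(unname(extra), c(sleep_stages(), exclude_marker()))
  if (length(bad))
    stop("stage_label_map() values must be canonical stages or exclude_marker(); got: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  map <- if (is.null(base)) character() else unclass(base)
  map[names(extra)] <- unname(extra)
  if (length(exclude)) map[exclude] <- exclude_marker()
  structure(map, class = "stage_label_map")
}

#' Default stage label map
#'
#' Identity over the five canonical stages plus the synonyms most scoring
#' software emits (EDF+ "Sleep stage X" events, "Wake", "REM", numeric stage
#' names).
#'
#' @return A `stage_label_map`.
#' @export
default_stage_map <- function() {
  structure(c(
    W = "W", N1 = "N1", N2 = "N2", N3 = "N3", R = "R",
    "Sleep stage W" = "W", "Sleep stage N1" = "N1", "Sleep stage N2" = "N2",
    "Sleep stage N3" = "N3", "Sleep stage R" = "R",
    Wake = "W", REM = "R", "Stage 1" = "N1", "Stage 2" = "N2", "Stage 3" = "N3"
  ), class = "stage_label_map")
}

# Map raw labels through a stage_label_map.
# Returns list(stage = chr (NA where excluded), excluded = lgl, unmapped = chr).
map_stage_labels <- function(labels, map) {
  stopifnot(inherits(map, "stage_label_map"))
  idx <- match(labels, names(map))
  unmapped <- unique(labels[is.na(idx)])
  stage <- unname(unclass(map)[idx])
  excluded <- !is.na(stage) & stage == exclude_marker()
  stage[excluded] <- NA_character_
  list(stage = stage, excluded = excluded, unmapped = unmapped)
}

#' Construct a hypnogram
#'
#' An ordered sequence of fixed-length scoring epochs, each annotated with one
#' sleep stage. Epoch indices are 0-based everywhere in this package and all
#' period intervals are half-open `[start, end)`.
#'
#' @param stages Character vector of stages, in epoch order (element `i + 1`
#'   is epoch `i`). `NA` marks an unscored epoch; such epochs must be dropped
#'   (see [drop_unscored()]) before period detection.
#' @param epoch_len_s Epoch length in seconds (default 30).
#' @param origin_time Optional `POSIXct` wall-clock time of epoch 0.
#' @param dropped Optional data frame (`epoch`, `reason`) of epochs already
#'   removed upstream, carried along for reporting.
#' @return Object of class `hypnogram`.
#' @export
#' @examples
#' h <- hypnogram(c("W", "N1", "N2", "N2", "R"))
#' n_epochs(h)
hypnogram <- function(stages, epoch_len_s = 30, origin_time = NULL, dropped = NULL) {
  stages <- as.character(stages)
  if (!length(stages)) stop("hypnogram requires at least one epoch", call. = FALSE)
  if (!is.numeric(epoch_len_s) || length(epoch_len_s) != 1L || epoch_len_s <= 0)
    stop("epoch_len_s must be a single positive number of seconds", call. = FALSE)
  bad <- setdiff(stages[!is.na(stages)], sleep_stages())
  if (length(bad))
    stop("unknown sleep stage(s): ", paste(unique(bad), collapse = ", "),
         "; map vendor labels through a stage_label_map first", call. = FALSE)
  structure(list(stages = stages, epoch_len_s = as.numeric(epoch_len_s),
                 origin_time = origin_time,
                 dropped = dropped %||% data.frame(epoch = integer(), reason = character())),
            class = "hypnogram")
}

#' Number of epochs in a hypnogram
#' @param x A `hypnogram`.
#' @return Integer epoch count.
#' @export
n_epochs <- function(x) {
  stopifnot(inherits(x, "hypnogram"))
  length(x$stages)
}

#' Drop unscored epochs from a hypnogram
#'
#' Removes `NA` (unannotated or excluded) epochs and compacts the sequence,
#' returning the mapping back to the original 0-based epoch indices. Period
#' detection requires a fully scored sequence, so pipelines call this first.
#'
#' @param hyp A `hypnogram`.
#' @return List with `hypnogram` (compacted) and `epoch_index` (integer
#'   vector: original 0-based index of each retained epoch).
#' @export
drop_unscored <- function(hyp) {
  stopifnot(inherits(hyp, "hypnogram"))
  keep <- !is.na(hyp$stages)
  if (!any(keep)) stop("hypnogram has no scored epochs", call. = FALSE)
  na_idx <- which(!keep) - 1L
  dropped <- rbind(hyp$dropped,
                   data.frame(epoch = na_idx,
                              reason = rep("unannotated", length(na_idx))))
  out <- hypnogram(hyp$stages[keep], hyp$epoch_len_s, hyp$origin_time, dropped = dropped)
  list(hypnogram = out, epoch_index = which(keep) - 1L)
}

#' @export
print.hypnogram <- function(x, ...) {
  n <- n_epochs(x)
  cat(sprintf("<hypnogram> %d epochs x %gs (%.1f min)\n", n, x$epoch_len_s,
              n * x$epoch_len_s / 60))
  tab <- table(factor(x$stages, levels = sleep_stages()), useNA = "ifany")
  cat("  stages:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  if (nrow(x$dropped)) cat("  dropped upstream:", nrow(x$dropped), "epoch(s)\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Convert a "at least m minutes" rule to an epoch count: a run of k epochs
# satisfies the rule iff k * epoch_len_s >= m * 60.
epochs_at_least <- function(minutes, epoch_len_s) {
  as.integer(ceiling(minutes * 60 / epoch_len_s - 1e-9))
}

# Convert an "exceeding m minutes" rule: k * epoch_len_s > m * 60.
epochs_exceeding <- function(minutes, epoch_len_s) {
  as.integer(floor(minutes * 60 / epoch_len_s + 1e-9)) + 1L
}
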