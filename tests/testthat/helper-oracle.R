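# Independent reference implementation of the period rules, used only to
# cross-check the engine. Deliberately structured differently from the
# package: global searches over the stage string (trim, locate wake breaks,
# split into segments, place boundaries inside each segment), not an
# incremental run-by-run automaton. Indices here are 1-based; converted to
# the package's 0-based half-open intervals at the end.

oracle_scan <- function(stages, epoch_len_s = 30, wake_break_min = 5,
                        transition_run_min = 5) {
  n <- length(stages)
  fam <- ifelse(stages == "W", "W", ifelse(stages == "R", "R", "N"))
  k_at_least <- function(m) ceiling(m * 60 / epoch_len_s)
  wake_k <- k_at_least(wake_break_min)
  trans_k <- k_at_least(transition_run_min)
  empty <- data.frame(kind = character(), start_epoch = integer(),
                      end_epoch = integer())

  first_n <- which(fam == "N")[1]
  if (is.na(first_n)) return(empty)
  last_sleep <- max(which(fam != "W"))

  # wake breaks inside the trimmed range -> segment boundaries
  in_break <- rep(FALSE, n)
  i <- first_n
  while (i <= last_sleep) {
    if (fam[i] == "W") {
      j <- i
      while (j <= last_sleep && fam[j] == "W") j <- j + 1
      if (j - i >= wake_k) in_break[i:(j - 1)] <- TRUE
      i <- j
    } else i <- i + 1
  }
  active <- rep(FALSE, n)
  active[first_n:last_sleep] <- !in_break[first_n:last_sleep]
  rr <- rle(active)
  seg_end <- cumsum(rr$lengths)
  seg_start <- seg_end - rr$lengths + 1
  segments <- cbind(seg_start[rr$values], seg_end[rr$values])

  r0 <- which(fam == "R")
  r0 <- r0[r0 >= first_n & r0 <= last_sleep][1]  # first R epoch of the night

  # length of the maximal same-family run covering position j, within [a, b]
  run_len <- function(j, b) {
    f <- fam[j]; e <- j
    while (e < b && fam[e + 1] == f) e <- e + 1
    e - j + 1
  }

  out <- empty
  for (s in seq_len(nrow(segments))) {
    a <- segments[s, 1]; b <- segments[s, 2]
    pos <- a
    while (pos <= b) {
      if (fam[pos] == "W") { pos <- pos + 1; next }
      kind <- if (fam[pos] == "R") "REMP" else "NREMP"
      nxt <- NA_integer_
      if (kind == "NREMP" && (is.na(r0) || pos < r0)) {
        # any R epoch ends an NREMP that precedes the first REMP
        cand <- which(fam == "R")
        cand <- cand[cand > pos & cand <= b]
        if (length(cand)) nxt <- cand[1]
      } else {
        opp <- if (kind == "NREMP") "R" else "N"
        j <- pos + 1
        while (j <= b) {
          if (fam[j] == opp && fam[j - 1] != opp && run_len(j, b) >= trans_k) {
            nxt <- j
            break
          }
          j <- j + 1
        }
      }
      endpos <- if (is.na(nxt)) b else nxt - 1
      while (fam[endpos] == "W") endpos <- endpos - 1
      out[nrow(out) + 1, ] <- list(kind, pos - 1L, endpos)  # 0-based half-open
      pos <- if (is.na(nxt)) b + 1 else nxt
    }
  }
  out
}

oracle_merge <- function(periods, stages, epoch_len_s = 30, min_nremp_min = 15,
                         min_remp_min = 5, wake_break_min = 5) {
  k_at_least <- function(m) ceiling(m * 60 / epoch_len_s)
  wake_k <- k_at_least(wake_break_min)
  min_n <- k_at_least(min_nremp_min)
  min_r <- k_at_least(min_remp_min)
  p <- periods[order(periods$start_epoch), , drop = FALSE]
  rownames(p) <- NULL
  sleep_len <- function(i)
    sum(stages[(p$start_epoch[i] + 1):p$end_epoch[i]] != "W")
  adj <- function(i, j) (p$start_epoch[j] - p$end_epoch[i]) < wake_k

  repeat {
    changed <- FALSE
    if (!nrow(p)) break
    remps <- which(p$kind == "REMP")
    first_remp <- if (length(remps)) remps[which.min(p$start_epoch[remps])] else 0L
    for (i in seq_len(nrow(p))) {
      d <- sleep_len(i)
      bad <- (p$kind[i] == "NREMP" && d < min_n) ||
        (p$kind[i] == "REMP" && i != first_remp && d < min_r)
      if (!bad) next
      if (i > 1 && adj(i - 1, i)) {
        p$end_epoch[i - 1] <- p$end_epoch[i]
      } else if (i < nrow(p) && adj(i, i + 1)) {
        p$start_epoch[i + 1] <- p$start_epoch[i]
      }
      p <- p[-i, , drop = FALSE]
      rownames(p) <- NULL
      changed <- TRUE
      break
    }
    # coalesce same-kind adjacent neighbours, repeatedly
    repeat {
      hit <- 0L
      for (i in seq_len(max(nrow(p) - 1L, 0L)))
        if (p$kind[i] == p$kind[i + 1] && adj(i, i + 1)) { hit <- i; break }
      if (!hit) break
      p$end_epoch[hit] <- p$end_epoch[hit + 1]
      p <- p[-(hit + 1L), , drop = FALSE]
      rownames(p) <- NULL
      changed <- TRUE
    }
    if (!changed) break
  }
  p
}

oracle_periods <- function(stages, epoch_len_s = 30) {
  raw <- oracle_scan(stages, epoch_len_s)
  oracle_merge(raw, stages, epoch_len_s)
}

# Run-structured random stage sequences (fixed seed set by callers): runs of
# random stage and length, biased to straddle the 3/7/10-epoch thresholds.
random_stage_seq <- function(n_max = 200) {
  stages <- character(0)
  repeat {
    st <- sample(c("W", "N1", "N2", "N3", "R"), 1,
                 prob = c(0.25, 0.15, 0.25, 0.15, 0.2))
    len <- sample(c(1:12, 15, 20, 30), 1)
    stages <- c(stages, rep(st, len))
    if (length(stages) >= n_max || stats::runif(1) < 0.06) break
  }
  utils::head(stages, n_max)
}

# Structural invariants every final period set must satisfy.
check_period_invariants <- function(periods, stages, epoch_len_s = 30,
                                    wake_break_min = 5) {
  wake_k <- ceiling(wake_break_min * 60 / epoch_len_s)
  if (!nrow(periods)) return(invisible(TRUE))
  expect_true(all(periods$start_epoch < periods$end_epoch))
  if (nrow(periods) > 1) {
    expect_true(all(diff(periods$start_epoch) > 0))
    expect_true(all(utils::head(periods$end_epoch, -1) <=
                      utils::tail(periods$start_epoch, -1)))
  }
  for (i in seq_len(nrow(periods))) {
    s <- periods$start_epoch[i]; e <- periods$end_epoch[i]
    expect_false(stages[s + 1] == "W")
    expect_false(stages[e] == "W")
    runs <- rle(stages[(s + 1):e] == "W")
    if (any(runs$values))
      expect_lt(max(runs$lengths[runs$values]), wake_k)
  }
  invisible(TRUE)
}
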