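test_that("the scan splits a night into raw periods at R onsets and wake breaks", {
  # leading wake ignored; first R ends the first NREMP; trailing wake ignored
  h <- hypnogram(runs(r_("W", 10), r_("N2", 40), r_("R", 12), r_("N2", 40),
                      r_("W", 5)))
  raw <- scan_periods(h)
  expect_equal(raw$kind, c("NREMP", "REMP", "NREMP"))
  expect_equal(raw$start_epoch, c(10L, 50L, 62L))
  expect_equal(raw$end_epoch, c(50L, 62L, 102L))

  # a 12-epoch (6 min) wake run breaks the period; the wake is excluded
  h2 <- hypnogram(runs(r_("N2", 30), r_("W", 12), r_("N2", 34)))
  raw2 <- scan_periods(h2)
  expect_equal(raw2$start_epoch, c(0L, 42L))
  expect_equal(raw2$end_epoch, c(30L, 76L))
  expect_equal(raw2$kind, c("NREMP", "NREMP"))

  # no sleep, no periods
  expect_equal(nrow(scan_periods(hypnogram(rep("W", 100)))), 0)

  # a 9-epoch wake run (4.5 min) stays inside the period
  h3 <- hypnogram(runs(r_("N2", 30), r_("W", 9), r_("N2", 34)))
  expect_equal(nrow(scan_periods(h3)), 1)

  # unscored epochs must be dropped first
  expect_error(scan_periods(hypnogram(c("N2", NA, "N2"))), "drop_unscored")
})

test_that("short periods are absorbed into adjacent periods and neighbours coalesce", {
  st <- runs(r_("N2", 40), r_("R", 12), r_("N2", 18), r_("R", 12), r_("N2", 40))
  h <- hypnogram(st)
  raw <- scan_periods(h)
  expect_equal(nrow(raw), 5)
  merged <- merge_short_periods(raw, h)
  expect_equal(merged$kind, c("NREMP", "REMP", "NREMP"))
  expect_equal(merged$start_epoch, c(0L, 40L, 82L))
  expect_equal(merged$end_epoch, c(40L, 82L, 122L))
  expect_match(paste(attr(merged, "log"), collapse = " "), "absorbed")

  # the first REMP is exempt from the 5-min minimum
  h2 <- hypnogram(runs(r_("N2", 40), r_("R", 2), r_("N2", 40)))
  m2 <- merge_short_periods(scan_periods(h2), h2)
  expect_true(any(m2$kind == "REMP"))
  expect_equal(m2$end_epoch[m2$kind == "REMP"] - m2$start_epoch[m2$kind == "REMP"], 2L)

  # compliant input is a fixpoint
  h3 <- hypnogram(runs(r_("N2", 40), r_("R", 12), r_("N2", 40)))
  raw3 <- scan_periods(h3)
  m3 <- merge_short_periods(raw3, h3)
  expect_equal(m3$start_epoch, raw3$start_epoch)
  expect_equal(m3$end_epoch, raw3$end_epoch)

  # a short period isolated by wake breaks on both sides is dropped
  h4 <- hypnogram(runs(r_("N2", 40), r_("W", 10), r_("N2", 10), r_("W", 10),
                       r_("N2", 40)))
  m4 <- merge_short_periods(scan_periods(h4), h4)
  expect_equal(nrow(m4), 2)
  expect_match(paste(attr(m4, "log"), collapse = " "), "dropped")
})

test_that("period duration excludes internal wake", {
  h <- hypnogram(runs(r_("N2", 20), r_("W", 4), r_("N2", 20)))
  expect_equal(period_duration(list(start_epoch = 0, end_epoch = 44), h), 20)
  h2 <- hypnogram(rep("W", 10))
  expect_equal(period_duration(list(start_epoch = 0, end_epoch = 10), h2), 0)
  h3 <- hypnogram(rep("R", 10))
  expect_equal(period_duration(list(start_epoch = 0, end_epoch = 10), h3), 5)
  expect_error(period_duration(list(start_epoch = 0, end_epoch = 11), h3),
               "outside the hypnogram")
})

test_that("detection assigns every epoch exactly one label", {
  st <- runs(r_("W", 6), r_("R", 3), r_("N2", 40), r_("R", 12), r_("W", 11),
             r_("N2", 40), r_("W", 4))
  h <- hypnogram(st)
  det <- detect_periods(h)
  expect_length(det$per_epoch_label, n_epochs(h))
  expect_true(all(nzchar(det$per_epoch_label)))
  expect_equal(det$per_epoch_label[1:6], rep("leading_wake", 6))
  expect_equal(det$per_epoch_label[7:9], rep("unassigned", 3))  # leading REM
  expect_equal(unique(det$per_epoch_label[62:72]), "inter_period_wake")
  expect_equal(det$per_epoch_label[113:116], rep("trailing_wake", 4))
  # epochs inside a period carry its label
  for (i in seq_len(nrow(det$periods))) {
    span <- (det$periods$start_epoch[i] + 1):det$periods$end_epoch[i]
    expect_equal(unique(det$per_epoch_label[span]), det$periods$label[i])
  }
})

test_that("detection is idempotent after removing non-period epochs", {
  # holds when consecutive periods alternate in kind: removing the wake
  # between two same-kind periods necessarily fuses them, so alternating
  # template nights are the meaningful domain for this property
  withr::local_seed(500)
  tested <- 0
  while (tested < 15) {
    tpl <- random_template()
    g <- generate_hypnogram(tpl)
    if (any(diff(match(g$truth$kind, c("NREMP", "REMP"))) == 0)) next
    tested <- tested + 1
    st <- g$hypnogram$stages
    det <- detect_periods(g$hypnogram)
    keep <- !(det$per_epoch_label %in%
                c("leading_wake", "trailing_wake", "inter_period_wake", "unassigned"))
    det2 <- detect_periods(hypnogram(st[keep]))
    expect_equal(det2$periods$kind, det$periods$kind)
    expect_equal(det2$periods$end_epoch - det2$periods$start_epoch,
                 det$periods$end_epoch - det$periods$start_epoch)
  }
})

test_that("raising the wake-break threshold never increases the raw period count", {
  withr::local_seed(900)
  for (rep_i in 1:40) {
    st <- random_stage_seq(sample(40:200, 1))
    h <- hypnogram(st)
    counts <- vapply(c(3, 5, 7, 10), function(wb)
      nrow(scan_periods(h, detection_config(wake_break_min = wb))), 0L)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("final periods satisfy the structural invariants on random input", {
  withr::local_seed(701)
  cfg <- detection_config()
  min_n <- 15; min_r <- 5
  for (rep_i in 1:200) {
    st <- random_stage_seq(sample(30:200, 1))
    h <- hypnogram(st)
    det <- detect_periods(h)
    p <- det$periods
    check_period_invariants(p, st)
    if (!nrow(p)) next
    # duration bounds (over-long NREMPs may persist only when logged un-splittable)
    overlong_ok <- any(grepl("no viable cut point", det$log))
    for (i in seq_len(nrow(p))) {
      if (p$kind[i] == "NREMP") {
        expect_gte(p$duration_min[i], min_n)
        if (!overlong_ok) expect_lte(p$duration_min[i], 120)
      } else if (p$ordinal[i] > 1) {
        expect_gte(p$duration_min[i], min_r)
      }
    }
    # NREMPs preceding the first REMP contain no R epochs
    remps <- which(p$kind == "REMP")
    if (length(remps)) {
      r0 <- min(p$start_epoch[remps])
      for (i in which(p$kind == "NREMP" & p$end_epoch <= r0))
        expect_false(any(st[(p$start_epoch[i] + 1):p$end_epoch[i]] == "R"))
    }
  }
})

test_that("the wake tolerance converts to 10 epochs at the defaults", {
  expect_identical(wake_tolerance_epochs(detection_config()), 10L)
  # 20-s epochs: 5 min = 15 epochs
  expect_identical(wake_tolerance_epochs(detection_config(epoch_len_s = 20)), 15L)
})
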