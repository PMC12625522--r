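day_df <- function(...) {
  # build a day-window tibble from one or more 1440-label days
  days <- list(...)
  purrr::imap_dfr(days, function(lab, i) {
    tibble::tibble(participant_id = "p1", label = lab, day = i)
  })
}

test_that("time_use counts minutes per activity and averages over days", {
  one <- day_df(rep("sitting", 1440))
  tu <- time_use(one)
  expect_equal(c(tu$minutes_walking, tu$minutes_standing, tu$minutes_sitting,
                 tu$minutes_lying), c(0, 0, 1440, 0))

  two <- day_df(rep("sitting", 1440), rep("lying", 1440))
  tu2 <- time_use(two)
  expect_equal(c(tu2$minutes_sitting, tu2$minutes_lying), c(720, 720))

  # counting oracle on a random day
  lab <- random_labels(1440)
  tu3 <- time_use(day_df(lab))
  for (a in analysis_labels()) {
    expect_equal(tu3[[paste0("minutes_", a)]], sum(lab == a))
  }
  expect_error(time_use(day_df(character(0))), "no day windows")
})

test_that("percent_sedentary matches the printed-daily-means arithmetic", {
  expect_equal(round(percent_sedentary(c(17.6, 66, 594, 762)), 1), 94.2)
  expect_equal(round(percent_sedentary(c(17.6, 66, 594, 762))), 94)
  expect_equal(percent_sedentary(c(0, 0, 720, 720)), 100)
  expect_equal(percent_sedentary(c(1440, 0, 0, 0)), 0)
})

test_that("detect_bouts is a maximal run-length encoding", {
  b <- detect_bouts(c("walking", "walking", "sitting", "sitting", "sitting", "walking"))
  expect_equal(b$activity, c("walking", "sitting", "walking"))
  expect_equal(b$duration_minutes, c(2, 3, 1))
  expect_equal(b$start_epoch, c(1L, 3L, 6L))

  single <- detect_bouts("lying")
  expect_equal(nrow(single), 1)
  expect_equal(single$duration_minutes, 1)

  expect_error(detect_bouts(c("sitting", "gap", "sitting")), "non-analysis")

  # brute-force oracle on random sequences
  set.seed(401)
  for (rep in 1:3) {
    lab <- random_labels(2000)
    got <- detect_bouts(lab)
    want <- oracle_bouts(lab)
    expect_equal(got$activity, want$activity)
    expect_equal(got$start_epoch, want$start_epoch)
    expect_equal(got$duration_minutes, want$duration)
  }
})

test_that("bout binning is half-open and conserves bout counts", {
  b <- tibble::tibble(activity = "walking", start_epoch = 1L, duration_minutes = 2)
  h <- bin_bouts(b, 1)
  expect_equal(h$daily_mean_count[h$activity == "walking" & h$bin == "2-3 min"], 1)

  b60 <- tibble::tibble(activity = "sitting", start_epoch = 1L, duration_minutes = 60)
  h60 <- bin_bouts(b60, 1)
  expect_equal(h60$daily_mean_count[h60$activity == "sitting" & h60$bin == ">60 min"], 1)

  # conservation: bin totals x n_valid_days = number of bouts
  set.seed(402)
  bouts <- detect_bouts(random_labels(5000))
  for (nd in c(1, 3)) {
    h <- bin_bouts(bouts, nd)
    expect_equal(sum(h$daily_mean_count) * nd, nrow(bouts))
  }

  expect_error(bin_bouts(tibble::tibble(activity = "gap", start_epoch = 1L,
                                        duration_minutes = 5), 1), "bin scheme")

  # sub-minute bouts (epochs < 60 s) are excluded with a message
  subm <- tibble::tibble(activity = "walking", start_epoch = 1L,
                         duration_minutes = 0.5)
  expect_message(h0 <- bin_bouts(subm, 1), "sub-minute")
  expect_equal(sum(h0$daily_mean_count), 0)
})

test_that("count_transitions counts exactly the four sedentary-to-active pairs", {
  tr <- count_transitions(c("lying", "sitting", "standing", "walking",
                            "sitting", "walking"))
  expect_equal(attr(tr, "total"), 2L)  # sitting->standing and sitting->walking
  expect_equal(tr$n[tr$from == "sitting" & tr$to == "standing"], 1L)
  expect_equal(tr$n[tr$from == "lying" & tr$to == "sitting"], integer(0))  # not a counted pair

  expect_equal(attr(count_transitions(rep("sitting", 1440)), "total"), 0L)

  set.seed(403)
  for (rep in 1:5) {
    lab <- random_labels(3000)
    expect_equal(attr(count_transitions(lab), "total"), oracle_transitions(lab))
  }
})

test_that("transition counting is monotone and bounded", {
  set.seed(404)
  lab <- c(random_labels(500), "sitting")
  base <- attr(count_transitions(lab), "total")
  expect_equal(attr(count_transitions(c(lab, "walking")), "total"), base + 1L)
  # bounded by the number of adjacent label changes
  expect_lte(base, sum(lab[-1] != lab[-length(lab)]))
})

test_that("splitting a sequence inside a bout only affects the split bout", {
  set.seed(405)
  lab <- random_labels(800)
  whole <- detect_bouts(lab)
  cut <- 357
  while (lab[cut] != lab[cut + 1]) cut <- cut + 1  # ensure a within-bout cut
  left <- detect_bouts(lab[1:cut])
  right <- detect_bouts(lab[(cut + 1):length(lab)])
  naive <- c(left$duration_minutes, right$duration_minutes)
  # merging the boundary pair reconstructs the whole-sequence bout list
  k <- nrow(left)
  merged <- c(naive[seq_len(k - 1)], naive[k] + naive[k + 1],
              naive[-seq_len(k + 1)])
  expect_equal(merged, whole$duration_minutes)
})

test_that("summarize_cohort equals the per-participant operations it composes", {
  set.seed(406)
  ep <- dplyr::bind_rows(
    make_epochs(random_labels(2880), id = "a"),
    make_epochs(random_labels(3000), id = "b")
  )
  seg <- find_valid_segments(ep, quiet = TRUE)
  s <- summarize_cohort(seg)
  expect_equal(nrow(s), 2)

  for (id in c("a", "b")) {
    lab_seg <- seg$label[seg$participant_id == id]
    nd <- length(lab_seg) %/% 1440
    lab_days <- lab_seg[seq_len(nd * 1440)]
    row <- s[s$participant_id == id, ]
    # time use
    for (a in analysis_labels()) {
      expect_equal(row[[paste0("minutes_", a)]], sum(lab_days == a) / nd)
    }
    # bouts (whole segment, including remainder)
    h <- bin_bouts(detect_bouts(lab_seg), nd)
    for (i in seq_len(nrow(h))) {
      col <- sprintf("bouts_%s_%s", h$activity[i], actipat:::bin_code(h$bin[i]))
      expect_equal(row[[col]], h$daily_mean_count[i], info = col)
    }
    # transitions (full day windows)
    expect_equal(row$transitions_daily,
                 attr(count_transitions(lab_days), "total") / nd)
  }
})

test_that("degenerate all-sitting segment gives the expected composite summary", {
  seg <- find_valid_segments(make_epochs(rep("sitting", 1440)), quiet = TRUE)
  s <- summarize_participant(seg)
  expect_equal(s$minutes_sitting, 1440)
  expect_equal(s$pct_sedentary, 100)
  expect_equal(s$bouts_sitting_gt60, 1)
  expect_equal(sum(dplyr::select(s, dplyr::starts_with("bouts_")) != 0), 1)
  expect_equal(s$transitions_daily, 0)
})

test_that("identical participants produce identical summaries", {
  lab <- random_labels(1500)
  ep <- dplyr::bind_rows(make_epochs(lab, id = "x"), make_epochs(lab, id = "y"))
  s <- summarize_cohort(find_valid_segments(ep, quiet = TRUE))
  a <- dplyr::select(dplyr::filter(s, participant_id == "x"), -participant_id)
  b <- dplyr::select(dplyr::filter(s, participant_id == "y"), -participant_id)
  expect_equal(a, b)
})

test_that("minutes and bout durations conserve total labelled time", {
  set.seed(407)
  seg <- find_valid_segments(make_epochs(random_labels(2880)), quiet = TRUE)
  s <- summarize_cohort(seg)
  expect_equal(s$minutes_walking + s$minutes_standing + s$minutes_sitting +
                 s$minutes_lying, 1440)
  bouts <- detect_bouts(seg$label)
  expect_equal(sum(bouts$duration_minutes), nrow(seg))
})
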