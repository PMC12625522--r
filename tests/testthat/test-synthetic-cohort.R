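test_that("a chain funnelled into sitting with a huge dwell is essentially all sitting", {
  P <- matrix(c(
    0, 0, 1, 0,
    0, 0, 1, 0,
    0, 0, 0, 1,
    0, 0, 1, 0
  ), nrow = 4, byrow = TRUE)
  p <- state_params(P, dwell_meanlog = c(-2, -2, 10, -2),
                    dwell_sdlog = rep(0.1, 4))
  ep <- simulate_activity_sequence(p, 24, seed = 801)
  expect_gt(mean(ep$label == "sitting"), 0.99)
})

test_that("invalid transition matrices are rejected", {
  P <- default_transition_matrix()
  P[1, 2] <- P[1, 2] + 0.1
  expect_error(state_params(P, rep(1, 4), rep(0.5, 4)))
  P2 <- diag(4)
  expect_error(state_params(P2, rep(1, 4), rep(0.5, 4)))
})

test_that("simulated dwell times match the configured discretised mean", {
  # walking dwell calibrated to a 3-minute discretised mean
  m <- actipat:::solve_dwell_meanlog(3, 0.6)
  P <- default_transition_matrix()
  p <- state_params(P, dwell_meanlog = c(as.numeric(m), log(3), log(10), log(20)),
                    dwell_sdlog = c(0.6, 0.6, 0.8, 0.8))
  ep <- simulate_activity_sequence(p, 24 * 14, seed = 802)
  dw <- attr(ep, "dwells")
  wd <- dw$dwell_epochs[dw$state == "walking"]
  expect_gt(length(wd), 300)
  se <- sd(wd) / sqrt(length(wd))
  expect_lt(abs(mean(wd) - 3), 3 * se + 0.05)
})

test_that("sequence simulation is seed-deterministic", {
  cfg <- default_cohort_config()
  p <- cfg$params[[1]]
  a <- simulate_activity_sequence(p, 24, seed = 803)
  b <- simulate_activity_sequence(p, 24, seed = 803)
  expect_identical(a$label, b$label)
  c_ <- simulate_activity_sequence(p, 24, seed = 804)
  expect_false(identical(a$label, c_$label))
})

test_that("empirical time fractions follow the stationary-dwell identity", {
  # expected fraction in state s = pi_s E[dwell_s] / sum_k pi_k E[dwell_k]
  P <- default_transition_matrix()
  meanlog <- c(log(2), log(4), log(15), log(30))
  sdlog <- c(0.5, 0.5, 0.7, 0.8)
  p <- state_params(P, meanlog, sdlog)
  pi_ <- stationary_distribution(P)
  d <- vapply(seq_len(4), function(i) actipat:::disc_dwell_mean(meanlog[i], sdlog[i]),
              numeric(1))
  expected <- pi_ * d / sum(pi_ * d)
  ep <- simulate_activity_sequence(p, 24 * 40, seed = 805)
  emp <- as.numeric(table(factor(ep$label, levels = analysis_labels()))) / nrow(ep)
  expect_lt(max(abs(emp - expected)), 0.03)
})

test_that("calibration hits daily-minute and transition targets", {
  minutes <- c(walking = 20, standing = 80, sitting = 600, lying = 740)
  p <- calibrate_state_params(minutes, 25)
  cal <- attr(p, "calibration")
  expect_lt(max(abs(cal$achieved_minutes - minutes)), 0.5)
  expect_lt(abs(cal$achieved_transitions - 25), 0.2)
  expect_false(any(cal$clamped))

  # with heterogeneity the mixture-averaged targets are still met
  ph <- calibrate_state_params(minutes, 25, tempo_sdlog = 0.55, active_sdlog = 0.45)
  calh <- attr(ph, "calibration")
  expect_lt(max(abs(calh$achieved_minutes[!calh$clamped] -
                      minutes[!calh$clamped])), 1)
  expect_lt(abs(calh$achieved_transitions - 25), 0.3)
})

test_that("a sparse-walking target clamps at the one-epoch floor and reports it", {
  minutes <- c(walking = 5, standing = 27, sitting = 527, lying = 881)
  p <- calibrate_state_params(minutes, 10, tempo_sdlog = 0.55, active_sdlog = 0.45)
  cal <- attr(p, "calibration")
  expect_true(cal$clamped[["walking"]])
  expect_gte(cal$achieved_minutes[["walking"]], minutes[["walking"]])
})

test_that("simulate_cohort emits the configured group sizes and valid wear", {
  cfg <- default_cohort_config(wear_days = 1, seed = 806)
  coh <- simulate_cohort(cfg)
  expect_equal(nrow(coh$clinical), 163)
  expect_equal(as.integer(table(coh$clinical$group)[names(cfg$groups)]),
               c(25L, 73L, 47L, 18L))
  expect_equal(dplyr::n_distinct(coh$epochs$participant_id), 163)
  # every participant passes the 24-h validity gate by construction
  seg <- find_valid_segments(coh$epochs, quiet = TRUE)
  expect_equal(nrow(attr(seg, "exclusions")), 0)
  expect_equal(nrow(seg), nrow(coh$epochs))
  # truth ledger mirrors the calibration
  expect_equal(coh$truth$groups$mild_dementia$n, 73)
  expect_equal(coh$truth$groups$mild_dementia$target_transitions, 27)
})

test_that("cohort generation is reproducible and files round-trip", {
  cfg <- default_cohort_config(n_total = 20, wear_days = 1, seed = 807)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$epochs, c2$epochs)
  expect_identical(c1$clinical, c2$clinical)

  dir <- tempfile()
  paths <- write_cohort(c1, dir)
  dir2 <- tempfile()
  write_cohort(c2, dir2)
  expect_identical(readLines(paths[["epochs"]]),
                   readLines(file.path(dir2, "epochs.csv")))

  ep <- read_epoch_csv(paths[["epochs"]])
  expect_equal(nrow(ep), nrow(c1$epochs))
  cl <- read_clinical_csv(paths[["clinical"]])
  scored <- score_clinical(cl)
  expect_equal(as.character(scored$severity), as.character(cl$group))
  expect_true(all(scored$sppb_total >= 0 & scored$sppb_total <= 12))
})

test_that("pipeline metrics on a simulated participant match the simulator's bookkeeping", {
  cfg <- default_cohort_config()
  p <- cfg$params[["mild_dementia"]]
  ep <- simulate_activity_sequence(p, 24, seed = 808, participant_id = "p1")
  dw <- attr(ep, "dwells")
  s <- summarize_participant(ep)
  for (a in analysis_labels()) {
    expect_equal(s[[paste0("minutes_", a)]],
                 sum(dw$dwell_epochs[dw$state == a]), info = a)
  }
  # every dwell is one bout (no self-transitions in the embedded chain)
  bouts <- detect_bouts(ep$label)
  expect_equal(nrow(bouts), nrow(dw))
  expect_equal(bouts$duration_minutes, dw$dwell_epochs)
  # counted transitions = sedentary->active steps of the dwell sequence
  steps <- sum(dw$state[-nrow(dw)] %in% sedentary_labels() &
                 dw$state[-1] %in% active_labels())
  expect_equal(s$transitions_daily, steps)
})

test_that("null-truth clinical outcomes are independent of activity", {
  set.seed(809)
  summ <- make_summaries(1000)
  clin <- simulate_clinical_outcomes(summ, sppb_coef = 0)
  scored <- score_clinical(clin)
  j <- dplyr::inner_join(summ, scored, by = "participant_id")
  expect_lt(abs(cor(j$minutes_walking, j$sppb_total)), 0.1)
  expect_lt(abs(cor(j$transitions_daily, j$nps_agitation)), 0.1)
  expect_true(all(j$sppb_total >= 0 & j$sppb_total <= 12))
  tr <- attr(clin, "truth")
  expect_equal(tr$lambda, 0)
})

test_that("null cohort config equalises activity across severity groups", {
  cfg <- null_cohort_config(n = 40, seed = 810)
  expect_equal(sum(vapply(cfg$groups, function(g) g$n, numeric(1))), 40)
  tgts <- vapply(cfg$groups, function(g) g$minutes[["walking"]], numeric(1))
  expect_true(all(tgts == tgts[1]))
  expect_equal(cfg$association_truth, "null")
})
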