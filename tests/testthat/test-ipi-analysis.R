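test_that("IPI planning labels follow the window-size rule", {
  expect_equal(label_ipi(3, 2), "preplanned")
  expect_equal(label_ipi(2, 1), "preplanned")
  expect_equal(label_ipi(2, 2), "online")
  expect_equal(label_ipi(1, 7), "SR")
  expect_equal(label_ipi(14, 13), "online")
  expect_equal(label_ipi(4, 3), "preplanned")
  expect_equal(label_ipi(4, 4), "online")
  expect_error(label_ipi(3, 14), "transition")
  expect_error(label_ipi(0, 1), "'w'")
  # preplanned count = min(w-1, 3) for w >= 2, 0 for w = 1
  for (w in c(1:8, 14)) {
    lab <- label_ipi(rep(w, 13), 1:13)
    expect_length(lab, 13)
    expect_equal(sum(lab == "preplanned"), if (w == 1) 0 else min(w - 1, 3))
    if (w == 1) expect_true(all(lab == "SR"))
  }
})

test_that("the IPI table has 13 transitions per correct trial only", {
  p <- small_params(n_participants = 2, n_days = 1)
  ex <- simulate_experiment(p)
  ts <- summarize_trials(ex$presses)
  ipis <- ipi_table(ex$presses)
  cnt <- aggregate(transition ~ participant + day + block + trial, ipis,
                   length)
  expect_true(all(cnt$transition == 13))
  expect_equal(nrow(cnt), sum(!ts$is_error))
  expect_true(all(ipis$duration > 0))
  # robustness flag drops the final transition
  ipis12 <- ipi_table(ex$presses, exclude_last_transition = TRUE)
  expect_equal(max(ipis12$transition), 12)
})

test_that("profiles equal loop-based two-stage recomputation exactly", {
  p <- small_params(n_participants = 3, n_days = 1)
  ipis <- ipi_table(simulate_experiment(p)$presses)
  prof <- ipi_profile(ipis)
  ipis$wg <- as.character(w_group(ipis$w))
  oracle <- two_stage_mean(ipis, "duration", "participant",
                           c("wg", "transition"))
  got <- prof$mean_ipi
  names(got) <- paste(prof$w_group, prof$transition, sep = "|")
  expect_equal(got[names(oracle)], oracle[names(oracle)],
               ignore_attr = TRUE, tolerance = 1e-12)

  # single trial: profile equals that trial's IPIs
  one <- ipis[ipis$participant == 1 & ipis$day == 1 & ipis$block == 1 &
                ipis$trial == ipis$trial[1], ]
  prof1 <- ipi_profile(one)
  expect_equal(prof1$mean_ipi[order(prof1$transition)],
               one$duration[order(one$transition)])
})

test_that("middle IPIs shorten with window size and tests match formulas", {
  p <- small_params(n_participants = 6, n_days = 1, blocks_per_day = 6,
                    trials_per_block = 18, b_true = 1, wstar_sd = 0.3,
                    seed = 19)
  ipis <- ipi_table(simulate_experiment(p)$presses)
  res <- middle_ipi_contrasts(ipis)
  gm <- tapply(res$means$mean_ipi, res$means$w, mean)
  expect_gt(gm["1"], gm["2"])
  expect_gt(gm["2"], gm["3"])
  expect_gt(gm["3"], gm["4"])

  # t statistic equals the hand-rolled difference-score formula
  m <- reshape(res$means, idvar = "participant", timevar = "w",
               direction = "wide")
  d <- m$mean_ipi.1 - m$mean_ipi.2
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(res$tests$t[res$tests$w1 == 1], t_hand, tolerance = 1e-12)

  # identical data in both conditions -> t = 0
  ident <- data.frame(participant = rep(1:5, 2), w = rep(1:2, each = 5),
                      transition = 6, duration = rep(runif(5, 400, 500), 2),
                      category = "online")
  res0 <- middle_ipi_contrasts(ident, pairs = cbind(1, 2))
  expect_equal(unname(res0$tests$t), 0)
  expect_equal(unname(res0$tests$p), 1)
})

test_that("normalised improvement follows its arithmetic identity", {
  d <- data.frame(participant = 1, day = c(1, 5), w = 2, mt = c(600, 400))
  expect_equal(normalized_improvement(d, "mt", "w")$improvement_pct, 40)
  d5 <- data.frame(participant = 1, day = c(1, 5), w = 2, mt = c(500, 500))
  expect_equal(normalized_improvement(d5, "mt", "w")$improvement_pct, 0)
  # invariant to rescaling a participant's durations
  p <- small_params(n_participants = 3, n_days = 2, seed = 31)
  ts <- summarize_trials(simulate_experiment(p)$presses)
  imp1 <- normalized_improvement(ts, "mt", "w", day_first = 1, day_last = 2)
  ts2 <- ts
  ts2$mt <- ts2$mt * ifelse(ts2$participant == 2, 3.7, 1)
  imp2 <- normalized_improvement(ts2, "mt", "w", day_first = 1, day_last = 2)
  expect_equal(imp1$improvement_pct, imp2$improvement_pct, tolerance = 1e-12)
  expect_error(normalized_improvement(ts, "mt", "w", day_first = 1,
                                      day_last = 9), "present")
})

test_that("practice gains grow with window size up to the plateau", {
  # noise-free cohort with day learning and horizon expansion
  p <- noiseless_params(n_participants = 1, n_days = 5, blocks_per_day = 2,
                        horizon_growth = 0.0369)
  ts <- summarize_trials(simulate_experiment(p)$presses)
  imp <- normalized_improvement(ts, "mt", "w", day_first = 1, day_last = 5)
  v <- imp$improvement_pct[order(imp$w)]
  expect_gt(v[2], v[1])     # w = 2 gains more than w = 1
  expect_gt(v[3], v[2])     # w = 3 more than w = 2
  expect_gt(v[9], v[1])     # full view beats the serial condition
  expect_lt(abs(v[6] - v[5]), abs(v[3] - v[2]))  # plateau for large w
})
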