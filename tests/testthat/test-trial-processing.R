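make_trace <- function(times, force, key = 1) {
  data.frame(time_ms = times, key = key, force_n = force)
}

test_that("press detection finds threshold crossings", {
  t <- seq(0, 400, by = 5)
  f <- ifelse(t >= 100 & t < 250, 2, 0)
  ev <- detect_presses(make_trace(t, f))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$press_time, 100)
  expect_equal(ev$release_time, 250)

  none <- detect_presses(make_trace(t, rep(0.5, length(t))))
  expect_equal(nrow(none), 0)

  # trace ends mid-press: release is missing
  f2 <- ifelse(t >= 300, 2, 0)
  ev2 <- detect_presses(make_trace(t, f2))
  expect_equal(ev2$press_time, 300)
  expect_true(is.na(ev2$release_time))
})

test_that("sub-debounce dips are merged, longer gaps are separate presses", {
  t <- seq(0, 500, by = 5)
  f <- ifelse(t >= 100 & t < 300, 2, 0)
  f[t >= 195 & t < 205] <- 0.4                 # 10 ms dip < 20 ms debounce
  ev <- detect_presses(make_trace(t, f))
  expect_equal(nrow(ev), 1)

  f2 <- ifelse((t >= 100 & t < 180) | (t >= 240 & t < 300), 2, 0)
  ev2 <- detect_presses(make_trace(t, f2))     # 60 ms gap
  expect_equal(nrow(ev2), 2)
  expect_equal(ev2$press_time, c(100, 240))
})

test_that("RT, MT and IPIs follow their definitions and telescope", {
  trial <- data.frame(
    press_time_ms = seq(1000, by = 500, length.out = 14),
    release_time_ms = seq(1120, by = 500, length.out = 14),
    stim_onset_ms = 250)
  expect_equal(compute_rt(trial), 750)
  expect_equal(compute_mt(trial), (1120 + 13 * 500) - 1000)
  ipis <- compute_ipis(trial)
  expect_equal(ipis, rep(500, 13))
  # telescoping identities
  expect_equal(sum(ipis), trial$press_time_ms[14] - trial$press_time_ms[1])
  expect_equal(compute_mt(trial),
               sum(ipis) + trial$release_time_ms[14] - trial$press_time_ms[14])
  # RT ignores everything after the first press
  trial2 <- trial
  trial2$press_time_ms[2:14] <- trial2$press_time_ms[2:14] + 999
  expect_equal(compute_rt(trial2), 750)

  short <- trial[1:10, ]
  expect_true(is.na(compute_mt(short)))
  expect_error(compute_ipis(short), "error trial")
  expect_true(is.na(compute_rt(trial[0, ])))
  trial$release_time_ms[14] <- NA
  expect_true(is.na(compute_mt(trial)))
})

test_that("detection on rendered noiseless trials reproduces the schedule", {
  p <- noiseless_params(blocks_per_day = 1, trials_per_block = 3)
  ex <- simulate_experiment(p, force_traces = TRUE)
  dt <- 1000 / p$sample_rate_hz
  for (tid in 1:3) {
    ev <- detect_presses(ex$force[ex$force$trial == tid, ])
    sched <- ex$presses[ex$presses$trial == tid, ]
    sched <- sched[order(sched$press_time_ms), ]
    expect_equal(nrow(ev), 14)
    expect_true(all(abs(ev$press_time - sched$press_time_ms) <= dt))
    expect_true(all(abs(ev$release_time - sched$release_time_ms) <= dt))
    expect_equal(ev$key, sched$produced)
  }
})

test_that("adaptive threshold updates only when both criteria hold", {
  st <- new_threshold_state(4000, best_median_mt = 3200)
  expect_equal(update_threshold(st, 3000, 0.10)$current_threshold, 3800)
  expect_equal(update_threshold(st, 3000, 0.10)$best_median_mt, 3000)
  expect_equal(update_threshold(st, 3000, 0.20)$current_threshold, 4000)
  expect_equal(update_threshold(st, 3200, 0.10)$current_threshold, 4000)
  # threshold sequence is non-increasing under arbitrary block histories
  set.seed(1)
  st <- new_threshold_state(8000)
  prev <- st$current_threshold
  for (i in 1:50) {
    st <- update_threshold(st, runif(1, 2000, 9000), runif(1, 0, 0.4))
    expect_lte(st$current_threshold, prev)
    prev <- st$current_threshold
  }
})

test_that("points are 0 for errors, 3 at the inclusive 5% margin, else 1", {
  expect_equal(award_points(3000, TRUE, 4000), 0L)
  expect_equal(award_points(0.95 * 4000, FALSE, 4000), 3L)
  expect_equal(award_points(4000, FALSE, 4000), 1L)
  set.seed(2)
  pts <- award_points(runif(100, 2000, 9000), runif(100) < 0.2, 5000)
  expect_true(all(pts %in% c(0L, 1L, 3L)))
})

test_that("error trials are flagged and excluded from aggregates", {
  p <- small_params(n_participants = 2, n_days = 1)
  ex <- simulate_experiment(p)
  ts <- summarize_trials(ex$presses)
  wrong <- aggregate((produced != target) ~ participant + day + block + trial,
                     ex$presses, any)
  m <- merge(ts, wrong, by = c("participant", "day", "block", "trial"))
  expect_equal(m$is_error, m[["(produced != target)"]])

  # corrupt one correct trial's MT: aggregates must not move if it is an error
  ts2 <- ts
  i <- which(!ts2$is_error)[1]
  ts2$is_error[i] <- TRUE
  ts2$mt[i] <- 1e9
  before <- mt_by_window(ts)
  after <- mt_by_window(ts2)
  expect_false(isTRUE(all.equal(before, after)))   # cell lost one trial
  expect_true(all(after$mt < 1e6))                 # but the outlier is gone
})
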