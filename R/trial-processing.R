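#' Detect keypress events from a force trace
#'
#' A press is the first sample at or above `threshold` after the key was
#' below it; the release is the first sample back below `threshold`. One
#' event is emitted per contiguous supra-threshold excursion per key; events
#' from all keys are merged and sorted by press time. Sub-threshold dips
#' shorter than `debounce_ms` between two excursions of the same key are
#' treated as part of one press (transducer-noise guard). A trace ending
#' mid-press yields an event with `release_time = NA`.
#'
#' @param trace long data frame with columns `time_ms`, `key`, `force_n`
#'   (times strictly increasing within key, forces >= 0).
#' @param threshold detection threshold in newtons.
#' @param debounce_ms minimum time a key must stay below threshold before a
#'   new press on the same key is registered.
#' @return data frame `key`, `press_time`, `release_time`, sorted by
#'   `press_time`; zero rows if the threshold is never crossed.
#' @examples
#' tr <- simulate_force_trace(
#'   data.frame(key = 3, press_time = 100, release_time = 250))
#' detect_presses(tr)
#' @export
detect_presses <- function(trace, threshold = 1.0, debounce_ms = 20) {
  stopifnot(all(c("time_ms", "key", "force_n") %in% names(trace)))
  if (nrow(trace) == 0L) stop("'trace' is empty", call. = FALSE)
  out <- lapply(split(trace, trace$key), function(tr) {
    tr <- tr[order(tr$time_ms), ]
    above <- tr$force_n >= threshold
    if (!any(above)) return(NULL)
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    # merge below-threshold gaps shorter than the debounce window
    keep <- rep(TRUE, length(r$values))
    for (j in seq_along(r$values)) {
      if (!r$values[j] && j > 1L && j < length(r$values)) {
        gap <- tr$time_ms[ends[j]] - tr$time_ms[starts[j]] +
          (tr$time_ms[starts[j] + 1L] - tr$time_ms[starts[j]])
        if (gap < debounce_ms) keep[j] <- FALSE
      }
    }
    above2 <- inverse.rle(list(
      lengths = r$lengths, values = r$values | !keep))
    r2 <- rle(above2)
    e2 <- cumsum(r2$lengths)
    s2 <- e2 - r2$lengths + 1L
    on <- which(r2$values)
    data.frame(
      key = tr$key[1],
      press_time = tr$time_ms[s2[on]],
      release_time = ifelse(e2[on] < nrow(tr), tr$time_ms[e2[on] + 1L], NA)
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(data.frame(key = numeric(), press_time = numeric(),
                      release_time = numeric()))
  }
  out <- out[order(out$press_time), ]
  rownames(out) <- NULL
  out
}

#' Per-trial timing measures
#'
#' `compute_rt()` is the time from stimulus onset to the first press (first
#' crossing of the force threshold). `compute_mt()` is the time between the
#' first press and the release of the last press in the sequence.
#' `compute_ipis()` returns the `seq_length - 1` interpress intervals, the
#' times between consecutive press-threshold crossings.
#'
#' @param trial data frame of one trial's presses, with columns
#'   `press_time_ms`, `release_time_ms` and `stim_onset_ms`, ordered by press
#'   time.
#' @param seq_length required number of presses for MT/IPIs.
#' @return `compute_rt()` and `compute_mt()` a single value in ms (`NA` when
#'   events are missing); `compute_ipis()` a numeric vector of length
#'   `seq_length - 1`.
#' @examples
#' tr <- data.frame(press_time_ms = seq(500, 7000, by = 500),
#'                  release_time_ms = seq(620, 7120, by = 500),
#'                  stim_onset_ms = 0)
#' compute_rt(tr)
#' compute_mt(tr)
#' compute_ipis(tr)
#' @export
compute_rt <- function(trial) {
  if (nrow(trial) == 0L) return(NA_real_)
  min(trial$press_time_ms) - trial$stim_onset_ms[1]
}

#' @rdname compute_rt
#' @export
compute_mt <- function(trial, seq_length = 14) {
  if (nrow(trial) < seq_length) return(NA_real_)
  trial <- trial[order(trial$press_time_ms), ]
  last_rel <- trial$release_time_ms[seq_length]
  if (is.na(last_rel)) return(NA_real_)
  last_rel - trial$press_time_ms[1]
}

#' @rdname compute_rt
#' @export
compute_ipis <- function(trial, seq_length = 14) {
  if (nrow(trial) < seq_length) {
    stop("trial has fewer than 'seq_length' presses (error trial)",
         call. = FALSE)
  }
  pt <- sort(trial$press_time_ms)[seq_len(seq_length)]
  diff(pt)
}

#' Summarise a press-level table into one row per trial
#'
#' Computes RT, MT and the error flag for every trial of a press-level table
#' (schema of [simulate_experiment()]`$presses`). A trial is an error if any
#' produced digit differs from its target or the press count differs from
#' `seq_length`; presses beyond the `seq_length`-th are ignored for timing.
#'
#' @param presses press-level data frame.
#' @param seq_length presses per correct sequence.
#' @return data frame with one row per trial: `participant, day, block,
#'   trial, w, rt, mt, n_press, is_error`.
#' @export
summarize_trials <- function(presses, seq_length = 14) {
  o <- order(presses$participant, presses$day, presses$block,
             presses$trial, presses$press_time_ms)
  x <- presses[o, ]
  f <- paste(x$participant, x$day, x$block, x$trial, sep = "\r")
  new <- f != c("", f[-length(f)])
  g <- cumsum(new)
  first_i <- which(new)
  last_i <- c(first_i[-1] - 1L, nrow(x))
  n_press <- tabulate(g)
  wrong <- rowsum((x$produced != x$target) + 0, g)[, 1] > 0
  # timing uses the first seq_length presses only
  nth_i <- pmin(first_i + seq_length - 1L, last_i)
  mt <- ifelse(n_press >= seq_length,
               x$release_time_ms[nth_i] - x$press_time_ms[first_i], NA_real_)
  data.frame(
    participant = x$participant[first_i], day = x$day[first_i],
    block = x$block[first_i], trial = x$trial[first_i], w = x$w[first_i],
    rt = x$press_time_ms[first_i] - x$stim_onset_ms[first_i],
    mt = mt, n_press = n_press,
    is_error = wrong | n_press != seq_length
  )
}

#' Adaptive movement-time threshold for the point reward
#'
#' The MT threshold decreases by 5% from one block to the next only when both
#' criteria hold: the current block's median MT is strictly faster than the
#' best median recorded so far, and the block's error rate is at most 15%.
#' Otherwise threshold and best median are unchanged.
#'
#' @param state list with `current_threshold` (ms) and `best_median_mt` (ms);
#'   create with `new_threshold_state()`.
#' @param block_median_mt median MT of the completed block (ms).
#' @param block_error_rate fraction of error trials in the completed block.
#' @param max_error_rate error criterion (default 0.15).
#' @return updated state list.
#' @examples
#' st <- new_threshold_state(4000, best_median_mt = 3200)
#' update_threshold(st, 3000, 0.10)$current_threshold # 3800
#' update_threshold(st, 3000, 0.20)$current_threshold # unchanged
#' @export
update_threshold <- function(state, block_median_mt, block_error_rate,
                             max_error_rate = 0.15) {
  stopifnot(state$current_threshold > 0)
  if (!is.na(block_median_mt) &&
      block_median_mt < state$best_median_mt &&
      block_error_rate <= max_error_rate) {
    state$current_threshold <- 0.95 * state$current_threshold
    state$best_median_mt <- block_median_mt
  }
  state
}

#' @rdname update_threshold
#' @param initial_threshold starting MT threshold (ms).
#' @param best_median_mt best block-median MT recorded so far (ms).
#' @export
new_threshold_state <- function(initial_threshold, best_median_mt = Inf) {
  list(current_threshold = initial_threshold,
       best_median_mt = best_median_mt)
}

#' Points awarded for a trial
#'
#' Error trials earn 0 points, correct trials 1 point, and correct trials
#' whose MT is 5% or more faster than the current threshold
#' (`mt <= 0.95 * threshold`, inclusive) earn 3 points.
#'
#' @param mt trial movement time(s), ms.
#' @param is_error logical error flag(s).
#' @param threshold current MT threshold(s), ms.
#' @return integer vector of points in \{0, 1, 3\}.
#' @export
award_points <- function(mt, is_error, threshold) {
  ifelse(is_error, 0L, ifelse(!is.na(mt) & mt <= 0.95 * threshold, 3L, 1L))
}

#' Block-level summaries with the running reward threshold
#'
#' Walks each participant's blocks in (day, block) order, records the
#' threshold in effect during each block, the block's median MT and error
#' rate, and applies [update_threshold()] after each block.
#'
#' @param trial_summary output of [summarize_trials()].
#' @param initial_threshold starting MT threshold (ms).
#' @param include_errors should error trials enter the block median MT?
#'   Default `FALSE`.
#' @return data frame `participant, day, block, threshold, median_mt,
#'   error_rate, n_trials`.
#' @export
block_summary <- function(trial_summary, initial_threshold = 10000,
                          include_errors = FALSE) {
  out <- list()
  for (p in sort(unique(trial_summary$participant))) {
    tp <- trial_summary[trial_summary$participant == p, ]
    st <- new_threshold_state(initial_threshold)
    for (d in sort(unique(tp$day))) {
      td <- tp[tp$day == d, ]
      for (b in sort(unique(td$block))) {
        tb <- td[td$block == b, ]
        mts <- if (include_errors) tb$mt else tb$mt[!tb$is_error]
        med <- stats::median(mts, na.rm = TRUE)
        er <- mean(tb$is_error)
        out[[length(out) + 1L]] <- data.frame(
          participant = p, day = d, block = b,
          threshold = st$current_threshold, median_mt = med,
          error_rate = er, n_trials = nrow(tb))
        st <- update_threshold(st, med, er)
      }
    }
  }
  do.call(rbind, out)
}
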