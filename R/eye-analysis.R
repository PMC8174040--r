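#' Gaze digit at the time of a keypress
#'
#' Maps tracker-unit gaze samples to digit units at a press:
#' `D_t = 1 + (x_t - x0) / px`, where `x_t` is the median horizontal gaze
#' position inside a 25 ms window centred on the press, `x0` the gaze
#' position of the first digit at trial start, and `px` the tracker units per
#' digit spacing (a block constant). Missing samples (blinks) are dropped
#' before taking the median; an empty window gives `NA`.
#'
#' @param samples data frame with columns `time_ms`, `gaze_x` for one trial.
#' @param press_time press onset time (ms).
#' @param calib list or one-row data frame with `x0` and `px` (`px > 0`).
#' @param window_ms width of the time window around the press.
#' @return fractional digit position `D_t`, or `NA`.
#' @examples
#' s <- data.frame(time_ms = 90:110, gaze_x = 170)
#' eye_digit_at_press(s, 100, list(x0 = 100, px = 35)) # 3
#' @export
eye_digit_at_press <- function(samples, press_time, calib, window_ms = 25) {
  stopifnot(calib$px > 0)
  half <- window_ms / 2
  x <- samples$gaze_x[samples$time_ms >= press_time - half &
                        samples$time_ms <= press_time + half]
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  1 + (stats::median(x) - calib$x0) / calib$px
}

#' Eye position relative to the current press
#'
#' Subtracts the press position (1-14) from the gaze digit `D_t`: 0 means
#' the eye is exactly on the digit being pressed, +1 a full digit ahead,
#' negative values lagging behind.
#'
#' @param d_t gaze digit(s) from [eye_digit_at_press()].
#' @param press_position press position(s) in the sequence, 1-14.
#' @param seq_length sequence length (positions validated against it).
#' @return digits ahead (fractional).
#' @export
relative_eye_position <- function(d_t, press_position, seq_length = 14) {
  if (any(press_position < 1 | press_position > seq_length)) {
    stop(sprintf("'press_position' must lie in 1..%d", seq_length),
         call. = FALSE)
  }
  d_t - press_position
}

#' Press-level eye positions for a whole experiment
#'
#' Computes `D_t` and the press-relative eye position for every press of
#' every correct trial that has gaze samples. Trials or participants without
#' eye data are silently excluded (as a participant with missing eye
#' recordings would be).
#'
#' @param presses press-level data frame.
#' @param eye gaze samples with `participant, day, block, trial, time_ms,
#'   gaze_x`.
#' @param calibration per-block calibration with `participant, day, block,
#'   x0, px`.
#' @param seq_length presses per sequence.
#' @param window_ms analysis window around each press.
#' @return data frame `participant, day, block, trial, w, position, d_t,
#'   rel_pos`.
#' @export
eye_press_table <- function(presses, eye, calibration, seq_length = 14,
                            window_ms = 25) {
  ts <- summarize_trials(presses, seq_length)
  ok <- ts[!ts$is_error, c("participant", "day", "block", "trial", "w")]
  key <- function(d) paste(d$participant, d$day, d$block, d$trial, sep = "\r")
  eye_split <- split(eye[c("time_ms", "gaze_x")], key(eye))
  cal_key <- paste(calibration$participant, calibration$day,
                   calibration$block, sep = "\r")
  rows <- vector("list", nrow(ok))
  for (i in seq_len(nrow(ok))) {
    k <- paste(ok$participant[i], ok$day[i], ok$block[i], ok$trial[i],
               sep = "\r")
    smp <- eye_split[[k]]
    if (is.null(smp)) next
    cal <- calibration[match(paste(ok$participant[i], ok$day[i], ok$block[i],
                                   sep = "\r"), cal_key), ]
    tr <- presses[presses$participant == ok$participant[i] &
                    presses$day == ok$day[i] & presses$block == ok$block[i] &
                    presses$trial == ok$trial[i], ]
    tr <- tr[order(tr$position), ]
    d_t <- vapply(tr$press_time_ms, function(pt)
      eye_digit_at_press(smp, pt, cal, window_ms), numeric(1))
    rows[[i]] <- data.frame(
      participant = ok$participant[i], day = ok$day[i], block = ok$block[i],
      trial = ok$trial[i], w = ok$w[i], position = tr$position, d_t = d_t,
      rel_pos = relative_eye_position(d_t, tr$position, seq_length))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Press-relative eye position profiles
#'
#' Aggregates a press-level eye table to mean relative eye position per
#' (day, window group, press position), participant means first, plus the
#' day x window-group cell means over a press subset (presses 3-10 by
#' default, the mid-sequence presses most sensitive to fixation strategy)
#' used for the repeated-measures ANOVA.
#'
#' @param eye_presses output of [eye_press_table()].
#' @param press_subset press positions entering the ANOVA cells.
#' @param days days to include in the cell table (default: first and last).
#' @return list with `profile` (`day, w_group, position, mean_rel,
#'   n_participants`) and `cells` (`participant, day, w_group, mean_rel`).
#' @export
eye_profile <- function(eye_presses, press_subset = 3:10, days = NULL) {
  x <- eye_presses[!is.na(eye_presses$rel_pos), ]
  x$w_group <- w_group(x$w)
  per_part <- stats::aggregate(
    list(rel = x$rel_pos),
    by = x[c("participant", "day", "w_group", "position")], FUN = mean)
  profile <- stats::aggregate(
    list(mean_rel = per_part$rel),
    by = per_part[c("day", "w_group", "position")], FUN = mean)
  n <- stats::aggregate(list(n_participants = per_part$participant),
                        by = per_part[c("day", "w_group", "position")],
                        FUN = function(z) length(unique(z)))
  profile <- merge(profile, n, by = c("day", "w_group", "position"),
                   sort = FALSE)
  if (is.null(days)) days <- range(x$day)
  sub <- per_part[per_part$position %in% press_subset &
                    per_part$day %in% days, ]
  cells <- stats::aggregate(list(mean_rel = sub$rel),
                            by = sub[c("participant", "day", "w_group")],
                            FUN = mean)
  ord <- order(profile$day, profile$w_group, profile$position)
  list(profile = profile[ord, ], cells = cells)
}
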