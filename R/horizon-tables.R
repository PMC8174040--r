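#' Mean movement time per viewing window
#'
#' Aggregates correct trials to participant-level mean MT per window size
#' (optionally per day), the 9-point curves the horizon model is fit to.
#' Error trials are always excluded.
#'
#' @param trial_summary output of [summarize_trials()].
#' @param by_day keep days separate (`TRUE`) or pool across days.
#' @param value which measure to average, `"mt"` or `"rt"`.
#' @return data frame `participant[, day], w, mean_value`.
#' @export
mt_by_window <- function(trial_summary, by_day = FALSE, value = "mt") {
  ok <- trial_summary[!trial_summary$is_error & !is.na(trial_summary[[value]]), ]
  keys <- if (by_day) c("participant", "day", "w") else c("participant", "w")
  out <- stats::aggregate(ok[[value]], by = ok[keys], FUN = mean)
  names(out)[ncol(out)] <- value
  out[do.call(order, out[keys]), , drop = FALSE]
}

#' Per-participant (per-day) horizon fits
#'
#' Fits the exponential MT model to every participant's (or participant x
#' day's) mean-MT-per-window curve and derives the effective horizon. All
#' non-error trials of a participant(-day) are pooled before averaging per w.
#'
#' @param trial_summary output of [summarize_trials()].
#' @param by_day fit per participant x day rather than per participant.
#' @param criterion horizon criterion, see [effective_horizon()].
#' @return data frame `participant[, day], a, b, c, sse, converged, valid,
#'   n_points, w_star`. Invalid fits carry `NA` horizons and should be
#'   excluded downstream.
#' @export
horizon_table <- function(trial_summary, by_day = TRUE, criterion = 0.01) {
  means <- mt_by_window(trial_summary, by_day = by_day)
  keys <- if (by_day) c("participant", "day") else "participant"
  cells <- unique(means[keys])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- rep(TRUE, nrow(means))
    for (k in keys) sel <- sel & means[[k]] == cells[[k]][i]
    f <- fit_exponential(means$w[sel], means$mt[sel])
    data.frame(cells[i, , drop = FALSE],
               a = f$a, b = f$b, c = f$c, sse = f$sse,
               converged = f$converged, valid = f$valid,
               n_points = f$n_points,
               w_star = if (f$valid) wstar_from_b(f$b, criterion) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Split-half horizon and movement time for one day
#'
#' For each participant, estimates the effective planning horizon from
#' odd-numbered blocks and the mean MT for large windows (`w > w_min`) from
#' even-numbered blocks, removing the statistical dependency that would arise
#' from using the same trials for both. Participants with fewer than two odd
#' or two even blocks get `NA`.
#'
#' @param trial_summary output of [summarize_trials()].
#' @param day which day to analyse.
#' @param w_min MT is averaged over windows strictly larger than this
#'   (default 5).
#' @param criterion horizon criterion.
#' @return data frame `participant, w_star_odd, mt_even`.
#' @export
split_half_horizon_mt <- function(trial_summary, day, w_min = 5,
                                  criterion = 0.01) {
  td <- trial_summary[trial_summary$day == day & !trial_summary$is_error &
                        !is.na(trial_summary$mt), ]
  rows <- lapply(sort(unique(trial_summary$participant)), function(p) {
    tp <- td[td$participant == p, ]
    odd <- tp[tp$block %% 2 == 1, ]
    even <- tp[tp$block %% 2 == 0, ]
    if (length(unique(odd$block)) < 2 || length(unique(even$block)) < 2) {
      return(data.frame(participant = p, w_star_odd = NA_real_,
                        mt_even = NA_real_))
    }
    m <- stats::aggregate(mt ~ w, odd, mean)
    f <- fit_exponential(m$w, m$mt)
    ws <- if (f$valid) wstar_from_b(f$b, criterion) else NA_real_
    data.frame(participant = p, w_star_odd = ws,
               mt_even = mean(even$mt[even$w > w_min]))
  })
  do.call(rbind, rows)
}

#' Day-level correlation between planning horizon and movement time
#'
#' Pearson correlation, across participants, of the odd-block horizon with
#' the even-block mean MT for large windows, for each requested day.
#'
#' @inheritParams split_half_horizon_mt
#' @param days days to analyse (default all).
#' @return data frame `day, r, p, n`. `r` is `NA` when fewer than 3
#'   participants have complete values or when either measure has zero
#'   variance.
#' @export
split_half_correlation <- function(trial_summary, days = NULL, w_min = 5) {
  if (is.null(days)) days <- sort(unique(trial_summary$day))
  rows <- lapply(days, function(d) {
    sh <- split_half_horizon_mt(trial_summary, d, w_min = w_min)
    ok <- stats::complete.cases(sh)
    r <- pearson_r(sh$w_star_odd[ok], sh$mt_even[ok])
    data.frame(day = d, r = r["r"], p = r["p"], n = sum(ok))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Contrast each window's MT against the average over larger windows
#'
#' For every window size `w` below the maximum, computes a two-sided paired
#' t test, across participants, of mean MT at `w` against the average of the
#' participant's mean MTs over all larger windows. Locates where the benefit
#' of additional preview saturates.
#'
#' @param trial_summary output of [summarize_trials()].
#' @return data frame `w, mean_diff, t, df, p`.
#' @export
mt_window_contrasts <- function(trial_summary) {
  means <- mt_by_window(trial_summary)
  ws <- sort(unique(means$w))
  parts <- sort(unique(means$participant))
  M <- matrix(NA_real_, length(parts), length(ws),
              dimnames = list(parts, ws))
  M[cbind(match(means$participant, parts), match(means$w, ws))] <- means$mt
  rows <- lapply(seq_len(length(ws) - 1L), function(i) {
    x <- M[, i]
    y <- rowMeans(M[, (i + 1):length(ws), drop = FALSE])
    tt <- paired_t(x, y)
    data.frame(w = ws[i], mean_diff = mean(x - y, na.rm = TRUE),
               t = tt["t"], df = tt["df"], p = tt["p"])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
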