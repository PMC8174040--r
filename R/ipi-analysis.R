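#' Planning-process label for an interpress interval
#'
#' Each transition is attributed to one planning process purely from the
#' viewing-window size `w` and the transition index: with `w = 1` nothing
#' beyond the current press is visible so intervals reflect serial
#' stimulus-response cycling (`"SR"`); the first `min(w - 1, 3)` transitions
#' can be prepared before the sequence starts (`"preplanned"`: transition 1
#' for w = 2, transitions 1-2 for w = 3, transitions 1-3 for w >= 4); all
#' remaining transitions must be planned online (`"online"`).
#'
#' @param w viewing-window size(s), >= 1.
#' @param transition transition index(es), 1 to `max_transition`.
#' @param max_transition largest valid transition (13 for 14-press sequences).
#' @return character vector in `c("SR", "preplanned", "online")`.
#' @examples
#' label_ipi(3, 2)   # "preplanned"
#' label_ipi(1, 7)   # "SR"
#' label_ipi(14, 13) # "online"
#' @export
label_ipi <- function(w, transition, max_transition = 13) {
  if (any(transition < 1 | transition > max_transition)) {
    stop(sprintf("'transition' must lie in 1..%d", max_transition),
         call. = FALSE)
  }
  if (any(w < 1)) stop("'w' must be >= 1", call. = FALSE)
  ifelse(w == 1, "SR",
         ifelse(transition <= pmin(w - 1, 3), "preplanned", "online"))
}

#' Group viewing windows as 1, 2, 3, 4+
#'
#' @param w viewing-window sizes.
#' @return factor with levels `"1", "2", "3", "4+"`.
#' @export
w_group <- function(w) {
  factor(ifelse(w >= 4, "4+", as.character(w)), levels = c("1", "2", "3", "4+"))
}

#' Long-format interpress-interval table
#'
#' Expands correct trials of a press-level table into one row per transition,
#' with duration, the 4+ window grouping and the planning-process category
#' from [label_ipi()]. Error trials are excluded.
#'
#' @param presses press-level data frame (schema of
#'   [simulate_experiment()]`$presses`).
#' @param seq_length presses per sequence.
#' @param exclude_last_transition drop the final transition (a robustness
#'   check: the last interval is executed atypically fast and would otherwise
#'   enter the "online" category).
#' @return data frame `participant, day, block, trial, w, w_group,
#'   transition, duration, category`.
#' @export
ipi_table <- function(presses, seq_length = 14,
                      exclude_last_transition = FALSE) {
  o <- order(presses$participant, presses$day, presses$block,
             presses$trial, presses$press_time_ms)
  x <- presses[o, ]
  f <- paste(x$participant, x$day, x$block, x$trial, sep = "\r")
  new <- f != c("", f[-length(f)])
  g <- cumsum(new)
  n_press <- tabulate(g)
  wrong <- rowsum((x$produced != x$target) + 0, g)[, 1] > 0
  bad <- wrong | n_press != seq_length
  keep <- !bad[g]                      # drop error trials entirely
  x <- x[keep, ]
  g <- g[keep]
  last_of_trial <- c(g[-1] != g[-length(g)], TRUE)
  dur <- c(x$press_time_ms[-1] - x$press_time_ms[-nrow(x)], NA_real_)
  tra <- stats::ave(g, g, FUN = seq_along)
  sel <- !last_of_trial
  out <- data.frame(
    participant = x$participant[sel], day = x$day[sel],
    block = x$block[sel], trial = x$trial[sel], w = x$w[sel],
    w_group = w_group(x$w[sel]), transition = tra[sel],
    duration = dur[sel]
  )
  out$category <- label_ipi(out$w, out$transition,
                            max_transition = seq_length - 1L)
  if (exclude_last_transition) {
    out <- out[out$transition < seq_length - 1L, ]
  }
  rownames(out) <- NULL
  out
}

#' IPI placement profile
#'
#' Mean IPI duration per window group and transition index: participant-level
#' means are computed first, then averaged across participants, so every
#' participant contributes equally regardless of trial counts.
#'
#' @param ipis output of [ipi_table()].
#' @param by_day keep days separate.
#' @return data frame `[day, ]w_group, transition, mean_ipi, n_participants`.
#' @export
ipi_profile <- function(ipis, by_day = FALSE) {
  keys <- c(if (by_day) "day", "w_group", "transition")
  per_part <- stats::aggregate(
    ipis["duration"], by = ipis[c("participant", keys)], FUN = mean)
  out <- stats::aggregate(
    list(mean_ipi = per_part$duration), by = per_part[keys], FUN = mean)
  n <- stats::aggregate(list(n_participants = per_part$participant),
                        by = per_part[keys], FUN = function(z) length(unique(z)))
  out <- merge(out, n, by = keys, sort = FALSE)
  out[do.call(order, out[keys]), , drop = FALSE]
}

#' Middle-IPI means and adjacent-window contrasts
#'
#' Restricts the analysis to the middle transitions (5-12 by default), which
#' index the speed of online planning, computes each participant's mean per
#' window size, and runs two-sided paired t tests between adjacent window
#' sizes (1 vs 2, 2 vs 3, 3 vs 4).
#'
#' @param ipis output of [ipi_table()].
#' @param transitions middle transitions to keep.
#' @param pairs 2-column matrix of window pairs to contrast.
#' @return list with `means` (`participant, w, mean_ipi`) and `tests`
#'   (`w1, w2, mean_diff, t, df, p`).
#' @export
middle_ipi_contrasts <- function(ipis, transitions = 5:12,
                                 pairs = cbind(1:3, 2:4)) {
  mid <- ipis[ipis$transition %in% transitions, ]
  means <- stats::aggregate(list(mean_ipi = mid$duration),
                            by = mid[c("participant", "w")], FUN = mean)
  if (length(unique(means$participant)) < 2) {
    stop("need >= 2 participants for contrasts", call. = FALSE)
  }
  tests <- lapply(seq_len(nrow(pairs)), function(i) {
    m1 <- means[means$w == pairs[i, 1], c("participant", "mean_ipi")]
    m2 <- means[means$w == pairs[i, 2], c("participant", "mean_ipi")]
    m <- merge(m1, m2, by = "participant")
    tt <- paired_t(m$mean_ipi.x, m$mean_ipi.y)
    data.frame(w1 = pairs[i, 1], w2 = pairs[i, 2],
               mean_diff = mean(m$mean_ipi.x - m$mean_ipi.y),
               t = tt["t"], df = tt["df"], p = tt["p"])
  })
  tests <- do.call(rbind, tests)
  rownames(tests) <- NULL
  list(means = means, tests = tests)
}

#' Normalised practice improvement between two days
#'
#' For each participant and cell (e.g. window size, or planning category x
#' window size), computes the percent change between the first and last day:
#' `(mean_first - mean_last) / mean(c(mean_first, mean_last)) * 100`, i.e.
#' the difference normalised by the across-day average of that cell. The
#' measure is invariant to rescaling all of a participant's durations by a
#' constant.
#'
#' @param data long data frame with `participant`, `day`, the cell columns
#'   and the value column (e.g. [summarize_trials()] output with
#'   `value = "mt"`, `cells = "w"`, or [ipi_table()] output with
#'   `value = "duration"`, `cells = c("category", "w")`).
#' @param value name of the value column.
#' @param cells character vector of cell-defining columns.
#' @param day_first,day_last the two days compared.
#' @param exclude_errors drop rows flagged `is_error` when present.
#' @return data frame `participant, <cells>, mean_first, mean_last,
#'   improvement_pct`; `NA` where a day is missing for a cell.
#' @examples
#' d <- data.frame(participant = 1, day = c(1, 5), w = 2,
#'                 mt = c(600, 400))
#' normalized_improvement(d, "mt", "w")$improvement_pct # 40
#' @export
normalized_improvement <- function(data, value, cells,
                                   day_first = 1, day_last = 5,
                                   exclude_errors = TRUE) {
  if (exclude_errors && "is_error" %in% names(data)) {
    data <- data[!data$is_error, ]
  }
  data <- data[!is.na(data[[value]]), ]
  if (!any(data$day == day_first) || !any(data$day == day_last)) {
    stop("both 'day_first' and 'day_last' must be present", call. = FALSE)
  }
  agg <- function(d) {
    out <- stats::aggregate(d[value], by = d[c("participant", cells)],
                            FUN = mean)
    names(out)[ncol(out)] <- "m"
    out
  }
  m1 <- agg(data[data$day == day_first, ])
  m5 <- agg(data[data$day == day_last, ])
  if (nrow(m1) == 0L || nrow(m5) == 0L) {
    stop("both 'day_first' and 'day_last' must be present", call. = FALSE)
  }
  out <- merge(m1, m5, by = c("participant", cells), all = TRUE,
               suffixes = c("_first", "_last"))
  names(out)[names(out) == "m_first"] <- "mean_first"
  names(out)[names(out) == "m_last"] <- "mean_last"
  out$improvement_pct <- (out$mean_first - out$mean_last) /
    ((out$mean_first + out$mean_last) / 2) * 100
  out[do.call(order, out[c("participant", cells)]), , drop = FALSE]
}
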