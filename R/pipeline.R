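#' Run the full viewing-window analysis pipeline
#'
#' Executes the complete analysis chain — trial summarisation, block-level
#' reward bookkeeping, horizon-model fits, practice-improvement scores, IPI
#' placement and planning-category analyses, split-half horizon-MT
#' correlations, the repeated-measures ANOVA / t-test battery, and (when eye
#' data are present) the gaze analysis — and optionally writes every result
#' as a tidy CSV. All exclusions (error trials, invalid fits, participants
#' without eye data) are counted in the `exclusions` element.
#'
#' @param experiment a `"horizon_experiment"` (from [simulate_experiment()]
#'   or [read_experiment()]). If `NULL`, one is simulated from `params`.
#' @param params a [horizon_sim_params()] object used when `experiment` is
#'   `NULL`.
#' @param out_dir directory for the output CSVs; `NULL` skips writing.
#' @param seed overrides `params$seed` before simulating.
#' @param initial_threshold starting reward threshold (ms).
#' @param strict error (rather than warn) if any horizon fit is invalid.
#' @return (invisibly) a list of class `"horizon_pipeline"` with elements
#'   `trial_summary, block_summary, mt_curve, rt_curve, fits, improvement,
#'   ipi_profile, ipi_contrasts, ipi_improvement, correlation, anova, ttests,
#'   eye, recovery, exclusions`.
#' @examples
#' p <- horizon_sim_params(n_participants = 4, n_days = 2,
#'                         blocks_per_day = 2, trials_per_block = 9)
#' res <- run_pipeline(params = p)
#' res$fits[1:3, ]
#' @export
run_pipeline <- function(experiment = NULL, params = horizon_sim_params(),
                         out_dir = NULL, seed = NULL,
                         initial_threshold = 10000, strict = FALSE) {
  if (is.null(experiment)) {
    if (!is.null(seed)) params$seed <- as.integer(seed)
    experiment <- simulate_experiment(params)
  }
  params <- experiment$params
  seq_len_ <- params$seq_length
  days <- sort(unique(experiment$presses$day))
  d_first <- min(days)
  d_last <- max(days)

  ts <- summarize_trials(experiment$presses, seq_len_)
  bs <- block_summary(ts, initial_threshold = initial_threshold)
  ts$points <- award_points(
    ts$mt, ts$is_error,
    bs$threshold[match(paste(ts$participant, ts$day, ts$block),
                       paste(bs$participant, bs$day, bs$block))])

  mt_curve <- mt_by_window(ts, by_day = FALSE, value = "mt")
  rt_curve <- mt_by_window(ts, by_day = FALSE, value = "rt")
  fits <- horizon_table(ts, by_day = TRUE)
  n_invalid <- sum(!fits$valid)
  if (n_invalid > 0) {
    msg <- sprintf("%d invalid horizon fit(s) excluded", n_invalid)
    if (strict) stop(msg, call. = FALSE) else warning(msg)
  }

  ipis <- ipi_table(experiment$presses, seq_len_)
  res <- list(
    trial_summary = ts,
    block_summary = bs,
    mt_curve = mt_curve,
    rt_curve = rt_curve,
    fits = fits,
    ipi_profile = ipi_profile(ipis),
    ipi_contrasts = middle_ipi_contrasts(ipis)$tests,
    correlation = split_half_correlation(ts)
  )

  if (d_last > d_first) {
    res$improvement <- normalized_improvement(
      ts, "mt", "w", day_first = d_first, day_last = d_last)
    res$ipi_improvement <- normalized_improvement(
      ipis, "duration", c("category", "w"),
      day_first = d_first, day_last = d_last, exclude_errors = FALSE)
  }

  # ANOVA / t-test battery
  anovas <- list()
  mt_pd <- mt_by_window(ts, by_day = TRUE)
  a1 <- rm_anova(mt_pd, "mt", "w")
  a1$analysis <- "mt_by_w"
  anovas[[1]] <- a1
  if (d_last > d_first) {
    two <- mt_pd[mt_pd$day %in% c(d_first, d_last), ]
    a2 <- rm_anova(two, "mt", c("day", "w"))
    a2$analysis <- "mt_day_by_w"
    anovas[[2]] <- a2
  }
  rt_pd <- mt_by_window(ts, by_day = TRUE, value = "rt")
  a3 <- rm_anova(rt_pd, "rt", "w")
  a3$analysis <- "rt_by_w"
  anovas[[length(anovas) + 1]] <- a3
  res$anova <- do.call(rbind, anovas)
  res$ttests <- mt_window_contrasts(ts)

  if (!is.null(experiment$eye)) {
    ept <- eye_press_table(experiment$presses, experiment$eye,
                           experiment$calibration, seq_len_)
    res$eye <- eye_profile(ept, days = c(d_first, d_last))
    eye_an <- rm_anova(res$eye$cells, "mean_rel",
                       if (d_last > d_first) c("day", "w_group") else
                         "w_group")
    eye_an$analysis <- "eye_lead"
    res$anova <- rbind(res$anova, eye_an)
  }

  if (!is.null(experiment$truth)) {
    rec <- merge(experiment$truth[c("participant", "day", "b", "w_star")],
                 fits[c("participant", "day", "w_star", "valid")],
                 by = c("participant", "day"),
                 suffixes = c("_true", "_est"))
    rec$error <- rec$w_star_est - rec$w_star_true
    res$recovery <- rec[order(rec$participant, rec$day), ]
  }

  res$exclusions <- data.frame(
    what = c("error_trials", "invalid_fits", "participants_without_eye"),
    n = c(sum(ts$is_error), n_invalid,
          if (is.null(experiment$eye)) NA_integer_ else
            length(setdiff(unique(ts$participant),
                           unique(experiment$eye$participant))))
  )
  res$params <- params
  class(res) <- "horizon_pipeline"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tabs <- c("trial_summary", "block_summary", "mt_curve", "rt_curve",
              "fits", "improvement", "ipi_profile", "ipi_contrasts",
              "ipi_improvement", "correlation", "anova", "ttests",
              "recovery", "exclusions")
    for (nm in tabs) {
      if (!is.null(res[[nm]])) {
        utils::write.csv(res[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                         row.names = FALSE)
      }
    }
    if (!is.null(res$eye)) {
      utils::write.csv(res$eye$profile, file.path(out_dir, "eye_profile.csv"),
                       row.names = FALSE)
      utils::write.csv(res$eye$cells, file.path(out_dir, "eye_cells.csv"),
                       row.names = FALSE)
    }
  }
  invisible(res)
}

#' @export
print.horizon_pipeline <- function(x, ...) {
  cat("Viewing-window DSP analysis results\n")
  cat(sprintf("  trials: %d (%d errors excluded)\n",
              nrow(x$trial_summary), sum(x$trial_summary$is_error)))
  ok <- x$fits$valid
  cat(sprintf("  horizon fits: %d valid / %d; mean w* = %.2f items\n",
              sum(ok), nrow(x$fits), mean(x$fits$w_star[ok])))
  invisible(x)
}
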