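#' Generative parameters for a simulated viewing-window DSP experiment
#'
#' Bundles every constant of the "soft horizon" generative model used by
#' [simulate_experiment()]. Defaults emulate the canonical study design:
#' 14-press sequences over the digits 1-5, viewing windows
#' w in \{1,...,8,14\} randomised within block, 8 sequence blocks of 27 trials
#' per day, 5 days, 14 participants, roughly 10-15% error trials, movement
#' time (MT) decreasing in w with exponential saturation, preplanned and final
#' interpress intervals (IPIs) faster than middle ones, and gaze leading the
#' current press by an amount that grows with w.
#'
#' The MT model is `MT(w) = a * exp(-b * (w - 1)) + c` (ms), so `a_true` is the
#' span between the w = 1 condition and the asymptote `c_true`, and `b_true`
#' (1/window-item) sets the true effective planning horizon
#' `w* = -log(0.01)/b + 1`.
#'
#' @param n_participants,n_days,blocks_per_day,trials_per_block design counts.
#' @param window_set integer viewing-window sizes presented within each block.
#' @param seq_length presses per sequence.
#' @param n_digits number of distinct digits/fingers.
#' @param a_true exponential span (ms).
#' @param b_true day-1 decay rate of the MT saturation curve (1/window-item).
#'   The default corresponds to a day-1 horizon of 3.2 items.
#' @param c_true MT asymptote (ms).
#' @param sr_time serial response time (ms) implied for w = 1; `NULL` derives
#'   it from `a_true`, `c_true` and `press_dur` (informational).
#' @param horizon_growth per-day additive increase of `1/b` (horizon
#'   expansion with practice); 0 freezes the horizon across days.
#' @param wstar_sd between-participant SD of the true horizon (items).
#' @param skill_cv coefficient of variation of a participant-level
#'   multiplicative skill factor applied to `a_true` and `c_true`.
#' @param horizon_speed_rho correlation (0-1) coupling slow participants to
#'   short horizons; generates the negative horizon-vs-MT association.
#' @param day_gain_w1 per-day multiplicative learning factor on MT at w = 1
#'   (`a + c`), the improvement attributable to single-response processes.
#' @param day_gain_c per-day multiplicative learning factor on the asymptote
#'   `c` (online-planning speed); setting it below `day_gain_w1` makes
#'   practice gains grow with window size before plateauing, as observed.
#' @param rt_base,rt_per_item,preplan_cap reaction-time model: RT =
#'   `rt_base + rt_per_item * min(w, preplan_cap)` (ms), capturing the RT
#'   plateau for windows larger than about 3.
#' @param first_last_discount ms speed-up applied to preplanned and final IPIs.
#' @param press_dur press-to-release duration (ms).
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   noise on RT and IPIs.
#' @param press_error_rate per-press probability of producing a wrong digit.
#' @param eye_lead_gain digits of gaze lead per item of available information.
#' @param lead_cap cap (items) on the information count driving the gaze lead.
#' @param eye_noise_sd SD of per-sample gaze noise (digit units).
#' @param sample_rate_hz sampling rate for simulated force and eye traces.
#' @param x0,px simulated eye-tracker calibration: tracker units of the first
#'   digit and units per digit spacing.
#' @param seed master seed; per-participant child streams are derived from it
#'   so adding participants never changes earlier participants' data.
#'
#' @return An object of class `"horizon_sim_params"` (a validated list).
#' @seealso [simulate_experiment()], [sample_sequence()]
#' @examples
#' p <- horizon_sim_params(n_participants = 2, n_days = 1)
#' p$window_set
#' @export
horizon_sim_params <- function(n_participants = 14,
                               n_days = 5,
                               blocks_per_day = 8,
                               trials_per_block = 27,
                               window_set = c(1:8, 14),
                               seq_length = 14,
                               n_digits = 5,
                               a_true = 2800,
                               b_true = log(100) / 2.2,
                               c_true = 3200,
                               sr_time = NULL,
                               horizon_growth = 0.0369,
                               wstar_sd = 1.0,
                               skill_cv = 0.10,
                               horizon_speed_rho = 0.6,
                               day_gain_w1 = (5414 / 6000)^(1 / 4),
                               day_gain_c = (2090 / 3200)^(1 / 4),
                               rt_base = 550,
                               rt_per_item = 70,
                               preplan_cap = 3,
                               first_last_discount = 80,
                               press_dur = 120,
                               noise_cv = 0.12,
                               press_error_rate = 0.0095,
                               eye_lead_gain = 0.4,
                               lead_cap = 3,
                               eye_noise_sd = 0.3,
                               sample_rate_hz = 200,
                               x0 = 100,
                               px = 35,
                               seed = 1L) {
  p <- list(
    n_participants = as.integer(n_participants), n_days = as.integer(n_days),
    blocks_per_day = as.integer(blocks_per_day),
    trials_per_block = as.integer(trials_per_block),
    window_set = as.integer(window_set), seq_length = as.integer(seq_length),
    n_digits = as.integer(n_digits),
    a_true = a_true, b_true = b_true, c_true = c_true,
    horizon_growth = horizon_growth, wstar_sd = wstar_sd,
    skill_cv = skill_cv, horizon_speed_rho = horizon_speed_rho,
    day_gain_w1 = day_gain_w1, day_gain_c = day_gain_c,
    rt_base = rt_base, rt_per_item = rt_per_item,
    preplan_cap = preplan_cap,
    first_last_discount = first_last_discount, press_dur = press_dur,
    noise_cv = noise_cv, press_error_rate = press_error_rate,
    eye_lead_gain = eye_lead_gain, lead_cap = lead_cap,
    eye_noise_sd = eye_noise_sd, sample_rate_hz = sample_rate_hz,
    x0 = x0, px = px, seed = as.integer(seed)
  )
  p$sr_time <- if (is.null(sr_time)) {
    (a_true + c_true - press_dur) / (p$seq_length - 1)
  } else {
    sr_time
  }

  counts <- c("n_participants", "n_days", "blocks_per_day",
              "trials_per_block", "seq_length")
  for (nm in counts) {
    if (length(p[[nm]]) != 1L || is.na(p[[nm]]) || p[[nm]] < 1L) {
      stop(sprintf("'%s' must be a count >= 1", nm), call. = FALSE)
    }
  }
  if (p$n_digits < 2L) stop("'n_digits' must be >= 2", call. = FALSE)
  if (!(p$b_true > 0)) stop("'b_true' must be > 0", call. = FALSE)
  for (nm in c("a_true", "c_true", "sr_time")) {
    if (!(p[[nm]] > 0)) stop(sprintf("'%s' must be > 0", nm), call. = FALSE)
  }
  if (p$press_error_rate < 0 || p$press_error_rate >= 1) {
    stop("'press_error_rate' must lie in [0, 1)", call. = FALSE)
  }
  if (any(p$window_set < 1L) || any(p$window_set > p$seq_length)) {
    stop("'window_set' values must lie within [1, seq_length]", call. = FALSE)
  }
  if (p$noise_cv < 0) stop("'noise_cv' must be >= 0", call. = FALSE)
  if (p$press_dur <= 0) stop("'press_dur' must be > 0", call. = FALSE)
  if (p$c_true - p$press_dur <= (p$seq_length - 1) * p$first_last_discount) {
    stop("'first_last_discount' too large: scheduled IPIs must stay positive",
         call. = FALSE)
  }
  class(p) <- "horizon_sim_params"
  p
}

#' @export
print.horizon_sim_params <- function(x, ...) {
  cat("Viewing-window DSP simulation parameters\n")
  cat(sprintf("  design : %d participants x %d days x %d blocks x %d trials\n",
              x$n_participants, x$n_days, x$blocks_per_day, x$trials_per_block))
  cat(sprintf("  windows: {%s}, sequence length %d over digits 1..%d\n",
              paste(x$window_set, collapse = ","), x$seq_length, x$n_digits))
  cat(sprintf("  MT law : %.0f * exp(-%.3f (w-1)) + %.0f ms  (day-1 w* = %.2f)\n",
              x$a_true, x$b_true, x$c_true, wstar_from_b(x$b_true)))
  cat(sprintf("  noise  : CV %.2f, per-press error %.4f\n",
              x$noise_cv, x$press_error_rate))
  invisible(x)
}

#' Convert between decay rate and effective planning horizon
#'
#' The effective horizon at the 99% criterion is
#' `w* = -log(0.01)/b + 1`; these helpers invert that mapping.
#'
#' @param b decay rate (1/window-item), `b > 0`.
#' @param w_star effective horizon (items), `w_star > 1`.
#' @param criterion fraction above the asymptote defining the horizon.
#' @return the corresponding `w_star` or `b`.
#' @examples
#' wstar_from_b(log(100) / 2.5) # 3.5
#' b_from_wstar(3.5)
#' @export
wstar_from_b <- function(b, criterion = 0.01) -log(criterion) / b + 1

#' @rdname wstar_from_b
#' @export
b_from_wstar <- function(w_star, criterion = 0.01) -log(criterion) / (w_star - 1)
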