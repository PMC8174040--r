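#' Sample a random target sequence
#'
#' Target sequences are built the way the task builds them: independent random
#' permutations of `1:n_digits` are concatenated and truncated to
#' `seq_length`, so every digit appears at least
#' `floor(seq_length / n_digits)` times and runs of the same digit can only
#' occur across permutation boundaries. Uses the current RNG state; call
#' `set.seed()` for reproducibility.
#'
#' @param n_digits number of distinct digits (>= 2).
#' @param seq_length number of presses in the sequence (> 0).
#' @return integer vector of length `seq_length` with values in `1:n_digits`.
#' @examples
#' set.seed(1)
#' sample_sequence(5, 14)
#' @export
sample_sequence <- function(n_digits = 5, seq_length = 14) {
  if (length(seq_length) != 1L || is.na(seq_length) || seq_length <= 0) {
    stop("'seq_length' must be a positive integer", call. = FALSE)
  }
  if (n_digits < 2) stop("'n_digits' must be >= 2", call. = FALSE)
  n_perm <- ceiling(seq_length / n_digits)
  digits <- unlist(lapply(seq_len(n_perm), function(i) sample.int(n_digits)))
  digits[seq_len(seq_length)]
}

# Deterministic per-participant child seed from the master seed, so adding
# participants never perturbs earlier participants' streams.
participant_seed <- function(seed, participant) {
  as.integer((as.numeric(seed) * 7919 + participant * 104729) %% 2147483629)
}

# Lognormal multiplicative noise with mean 1 and coefficient of variation cv.
lnorm_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Scheduled (noise-free) IPIs for a set of trials.
#
# Transition i (1..L-1) sees k_i = min(w - 1, L - i) upcoming items; its raw
# duration is c_ipi + a_ipi * exp(-b * k_i), with preplanned transitions
# (i <= min(w - 1, 3)) and the final transition discounted by
# `first_last_discount`. Each trial's 13 raw IPIs are then rescaled by a
# common factor so the scheduled movement time (sum of IPIs + press duration)
# equals the exponential law a * exp(-b (w - 1)) + c exactly.
schedule_ipis <- function(w, a, b, c, params) {
  L <- params$seq_length
  nt <- length(w)
  i <- seq_len(L - 1L)
  K <- outer(w - 1L, L - i, pmin)                      # nt x (L-1)
  raw <- (c - params$press_dur) / (L - 1) + (a / (L - 1)) * exp(-b * K)
  disc <- outer(pmin(w - 1L, 3L), i, `>=`)             # preplanned prefix
  disc[, L - 1L] <- w > 1L                             # final transition
  raw <- raw - params$first_last_discount * disc
  target <- a * exp(-b * (w - 1)) + c - params$press_dur
  raw * (target / rowSums(raw))
}

scheduled_rt <- function(w, params) {
  params$rt_base + params$rt_per_item * pmin(w, params$preplan_cap)
}

# Per-participant latent draws: skill factor on (a, c) and a true horizon,
# negatively coupled so slower participants have shorter horizons.
draw_participant <- function(params) {
  z1 <- stats::rnorm(1)
  z2 <- stats::rnorm(1)
  rho <- params$horizon_speed_rho
  skill <- exp(params$skill_cv * z1)
  u <- -rho * z1 + sqrt(1 - rho^2) * z2
  w_star1 <- wstar_from_b(params$b_true) + params$wstar_sd * u
  w_star1 <- max(w_star1, 1.3)
  list(skill = skill, inv_b1 = 1 / b_from_wstar(w_star1))
}

#' Simulate a complete viewing-window DSP experiment
#'
#' Generates the full factorial of participants x days x blocks x trials, with
#' viewing-window size randomised within every block, press-level timing from
#' the soft-horizon generative model described in
#' [horizon_sim_params()], per-press digit errors, and (optionally) force
#' traces and eye samples for every trial. The returned truth table records
#' the generating MT-curve parameters and true effective horizon for every
#' participant x day, which makes parameter-recovery studies possible.
#'
#' @param params a [horizon_sim_params()] object.
#' @param force_traces,eye_samples logical; also render per-trial force
#'   traces / gaze samples (intended for small designs — the rendered traces
#'   are large).
#' @return An object of class `"horizon_experiment"`: a list with
#'   \describe{
#'     \item{presses}{press-level data frame (one row per press):
#'       `participant, day, block, trial, w, position, target, produced,
#'       press_time_ms, release_time_ms, stim_onset_ms`. Times are in ms
#'       relative to stimulus onset.}
#'     \item{truth}{per participant x day generating values
#'       (`a, b, c, w_star, skill`).}
#'     \item{force}{long force-trace data frame or `NULL`.}
#'     \item{eye}{gaze-sample data frame or `NULL`.}
#'     \item{calibration}{per-block eye calibration (`x0`, `px`).}
#'     \item{params}{the input parameters.}
#'   }
#' @examples
#' p <- horizon_sim_params(n_participants = 2, n_days = 1, blocks_per_day = 2)
#' ex <- simulate_experiment(p)
#' nrow(ex$presses) / p$seq_length # number of trials
#' @export
simulate_experiment <- function(params, force_traces = FALSE,
                                eye_samples = FALSE) {
  stopifnot(inherits(params, "horizon_sim_params"))
  L <- params$seq_length
  n_tr <- params$trials_per_block
  press_rows <- vector("list", params$n_participants)
  truth_rows <- vector("list", params$n_participants)
  force_rows <- if (force_traces) list() else NULL
  eye_rows <- if (eye_samples) list() else NULL

  for (p_id in seq_len(params$n_participants)) {
    set.seed(participant_seed(params$seed, p_id))
    latent <- draw_participant(params)
    day_list <- vector("list", params$n_days)
    truth_p <- vector("list", params$n_days)

    for (day in seq_len(params$n_days)) {
      # learning: MT(1) = a + c shrinks by day_gain_w1 per day, the asymptote
      # c by day_gain_c; the span a absorbs the difference
      mt1 <- (params$a_true + params$c_true) * latent$skill *
        params$day_gain_w1^(day - 1)
      c_pd <- params$c_true * latent$skill * params$day_gain_c^(day - 1)
      a_pd <- mt1 - c_pd
      if (a_pd <= 0) {
        stop("day gains make the exponential span non-positive; ",
             "use a larger 'day_gain_c' or fewer days", call. = FALSE)
      }
      b_pd <- 1 / (latent$inv_b1 + params$horizon_growth * (day - 1))
      truth_p[[day]] <- data.frame(
        participant = p_id, day = day, a = a_pd, b = b_pd, c = c_pd,
        w_star = wstar_from_b(b_pd), skill = latent$skill
      )
      blk_list <- vector("list", params$blocks_per_day)

      for (blk in seq_len(params$blocks_per_day)) {
        w <- sample(rep_len(params$window_set, n_tr))
        targets <- t(vapply(seq_len(n_tr), function(t)
          sample_sequence(params$n_digits, L), integer(L)))
        ipi <- schedule_ipis(w, a_pd, b_pd, c_pd, params) *
          matrix(lnorm_noise(n_tr * (L - 1L), params$noise_cv), n_tr)
        rt <- scheduled_rt(w, params) * lnorm_noise(n_tr, params$noise_cv)
        press_t <- t(apply(cbind(rt, ipi), 1L, cumsum))
        produced <- targets
        if (params$press_error_rate > 0) {
          err <- matrix(stats::runif(n_tr * L) < params$press_error_rate, n_tr)
          if (any(err)) {
            shift <- sample.int(params$n_digits - 1L, sum(err), replace = TRUE)
            produced[err] <- 1L +
              (targets[err] - 1L + shift) %% params$n_digits
          }
        }
        blk_list[[blk]] <- data.frame(
          participant = p_id, day = day, block = blk,
          trial = rep(seq_len(n_tr), each = L),
          w = rep(w, each = L), position = rep(seq_len(L), times = n_tr),
          target = as.integer(t(targets)),
          produced = as.integer(t(produced)),
          press_time_ms = as.numeric(t(press_t)),
          release_time_ms = as.numeric(t(press_t)) + params$press_dur,
          stim_onset_ms = 0
        )
        if (force_traces || eye_samples) {
          for (t_id in seq_len(n_tr)) {
            ev <- data.frame(key = produced[t_id, ],
                             press_time = press_t[t_id, ],
                             release_time = press_t[t_id, ] + params$press_dur)
            id <- data.frame(participant = p_id, day = day, block = blk,
                             trial = t_id)
            if (force_traces) {
              tr <- simulate_force_trace(ev, sample_rate_hz =
                                           params$sample_rate_hz,
                                         n_keys = params$n_digits)
              force_rows[[length(force_rows) + 1L]] <-
                cbind(id[rep(1L, nrow(tr)), ], tr, row.names = NULL)
            }
            if (eye_samples) {
              es <- simulate_eye_samples(ev$press_time, w[t_id], params)
              eye_rows[[length(eye_rows) + 1L]] <-
                cbind(id[rep(1L, nrow(es)), ], es, row.names = NULL)
            }
          }
        }
      }
      day_list[[day]] <- do.call(rbind, blk_list)
    }
    press_rows[[p_id]] <- do.call(rbind, day_list)
    truth_rows[[p_id]] <- do.call(rbind, truth_p)
  }

  grid <- expand.grid(block = seq_len(params$blocks_per_day),
                      day = seq_len(params$n_days),
                      participant = seq_len(params$n_participants))
  out <- list(
    presses = do.call(rbind, press_rows),
    truth = do.call(rbind, truth_rows),
    force = if (force_traces) do.call(rbind, force_rows) else NULL,
    eye = if (eye_samples) do.call(rbind, eye_rows) else NULL,
    calibration = data.frame(grid[c("participant", "day", "block")],
                             x0 = params$x0, px = params$px),
    params = params
  )
  rownames(out$presses) <- NULL
  rownames(out$truth) <- NULL
  class(out) <- "horizon_experiment"
  out
}

#' @export
print.horizon_experiment <- function(x, ...) {
  nt <- nrow(x$presses) / x$params$seq_length
  cat(sprintf(
    "Simulated viewing-window DSP experiment: %d trials (%d participants x %d days)\n",
    nt, x$params$n_participants, x$params$n_days))
  cat(sprintf("  force traces: %s, eye samples: %s\n",
              if (is.null(x$force)) "no" else "yes",
              if (is.null(x$eye)) "no" else "yes"))
  invisible(x)
}

#' Render a force trace for one trial
#'
#' Each press becomes a smooth half-cosine force pulse on its key that crosses
#' the 1 N detection threshold exactly at the scheduled press time and falls
#' below it at the scheduled release time. Pulse shape is cosmetic; only the
#' threshold-crossing times carry information.
#'
#' @param events data frame with columns `key`, `press_time`, `release_time`
#'   (ms).
#' @param sample_rate_hz sampling rate of the rendered trace.
#' @param n_keys number of keys on the keyboard.
#' @param threshold force (N) the pulse must cross at press/release times.
#' @param flank_ms rise time from zero force to the threshold crossing.
#' @return long data frame `time_ms`, `key`, `force_n` covering the trial.
#' @examples
#' ev <- data.frame(key = c(1, 2), press_time = c(100, 500),
#'                  release_time = c(220, 620))
#' tr <- simulate_force_trace(ev)
#' detect_presses(tr)
#' @export
simulate_force_trace <- function(events, sample_rate_hz = 200, n_keys = 5,
                                 threshold = 1, flank_ms = 30) {
  dt <- 1000 / sample_rate_hz
  t_end <- max(events$release_time, na.rm = TRUE) + 100
  times <- seq(0, t_end, by = dt)
  force <- matrix(0, nrow = length(times), ncol = n_keys)
  for (j in seq_len(nrow(events))) {
    s <- events$press_time[j] - flank_ms
    e <- events$release_time[j] + flank_ms
    span <- e - s
    amp <- 2 * threshold / (1 - cos(2 * pi * flank_ms / span))
    idx <- which(times >= s & times <= e)
    pulse <- amp * (1 - cos(2 * pi * (times[idx] - s) / span)) / 2
    k <- events$key[j]
    force[idx, k] <- pmax(force[idx, k], pulse)
  }
  data.frame(time_ms = rep(times, times = n_keys),
             key = rep(seq_len(n_keys), each = length(times)),
             force_n = as.numeric(force))
}

#' Render scripted gaze samples for one trial
#'
#' Gaze is a saccade-and-fixate step function: around press `i` the eye
#' fixates digit `min(i + lead, seq_length)` where
#' `lead = min(w - 1, lead_cap) * eye_lead_gain`, with saccades placed halfway
#' between consecutive presses so the 25 ms analysis window around each press
#' sees a stable fixation. Gaussian per-sample noise (`eye_noise_sd`, digit
#' units) is added before converting to tracker units via `x0` and `px`.
#'
#' @param press_times press onset times (ms) of one trial.
#' @param w viewing-window size of the trial.
#' @param params a [horizon_sim_params()] object.
#' @return data frame `time_ms`, `gaze_x` (tracker units).
#' @export
simulate_eye_samples <- function(press_times, w, params) {
  L <- params$seq_length
  lead <- min(w - 1, params$lead_cap) * params$eye_lead_gain
  level <- pmin(seq_along(press_times) + lead, L)
  bounds <- c(press_times[1] / 2,
              (press_times[-1] + press_times[-length(press_times)]) / 2)
  dt <- 1000 / params$sample_rate_hz
  times <- seq(0, max(press_times) + params$press_dur + 50, by = dt)
  digit <- c(1, level)[findInterval(times, bounds) + 1L]
  digit <- digit + stats::rnorm(length(times), sd = params$eye_noise_sd)
  data.frame(time_ms = times,
             gaze_x = params$x0 + (digit - 1) * params$px)
}
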