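# Independent oracles used across test files.

# Brute-force SSE minimiser for MT = a*exp(-b(w-1)) + c: profiles b over a
# fine grid and solves the conditionally linear (a, c) exactly per b.
grid_fit <- function(w, mt, b_grid = exp(seq(log(0.01), log(20),
                                             length.out = 400))) {
  best <- list(sse = Inf)
  for (b in b_grid) {
    X <- cbind(exp(-b * (w - 1)), 1)
    fit <- stats::lm.fit(X, mt)
    sse <- sum(fit$residuals^2)
    if (sse < best$sse) {
      best <- list(a = fit$coefficients[1], b = b, c = fit$coefficients[2],
                   sse = sse)
    }
  }
  best
}

# Small, quick simulated cohort.
small_params <- function(...) {
  defaults <- list(n_participants = 4, n_days = 2, blocks_per_day = 4,
                   trials_per_block = 9, seed = 42)
  do.call(horizon_sim_params, utils::modifyList(defaults, list(...)))
}

# Noise-free deterministic cohort (one participant unless overridden).
noiseless_params <- function(...) {
  defaults <- list(n_participants = 1, n_days = 1, blocks_per_day = 2,
                   trials_per_block = 27, noise_cv = 0, press_error_rate = 0,
                   wstar_sd = 0, skill_cv = 0, horizon_growth = 0, seed = 9)
  do.call(horizon_sim_params, utils::modifyList(defaults, list(...)))
}

# Plain-loop participant-then-group two-stage mean.
two_stage_mean <- function(df, value, participant, cells) {
  key <- do.call(paste, c(df[cells], sep = "|"))
  out <- numeric(0)
  for (k in unique(key)) {
    sub <- df[key == k, ]
    pm <- c()
    for (p in unique(sub[[participant]])) {
      pm <- c(pm, mean(sub[[value]][sub[[participant]] == p]))
    }
    out[k] <- mean(pm)
  }
  out
}
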