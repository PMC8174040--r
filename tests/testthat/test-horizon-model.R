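test_that("noiseless curves are recovered to numerical precision", {
  w <- c(1:8, 14)
  mt <- 2000 * exp(-1.0 * (w - 1)) + 3000
  f <- fit_exponential(w, mt)
  expect_true(f$valid)
  expect_equal(f$a, 2000, tolerance = 1e-6)
  expect_equal(f$b, 1.0, tolerance = 1e-6)
  expect_equal(f$c, 3000, tolerance = 1e-6)
  expect_lt(f$sse, 1e-10)
})

test_that("degenerate inputs are flagged invalid or rejected", {
  w <- c(1:8, 14)
  flat <- fit_exponential(w, rep(3000, 9))
  expect_false(flat$valid)
  expect_error(fit_exponential(1:3, c(3, 2, 1)), "4 distinct")
  expect_error(fit_exponential(w, rep(-1, 9)), "positive")
  expect_warning(expect_true(is.na(effective_horizon(flat))), "invalid")
})

test_that("LM fit never loses to the grid-search oracle", {
  set.seed(33)
  for (i in 1:10) {
    a <- runif(1, 500, 4000); b <- runif(1, 0.3, 3); cc <- runif(1, 2000, 5000)
    w <- c(1:8, 14)
    mt <- a * exp(-b * (w - 1)) + cc + rnorm(9, 0, 150)
    f <- fit_exponential(w, mt)
    g <- grid_fit(w, mt)
    expect_lte(f$sse, g$sse + 1e-6)
  }
})

test_that("effective horizon follows the closed form and its root", {
  expect_equal(effective_horizon(4.60517), 2.0, tolerance = 1e-6)
  w <- c(1:8, 14)
  f <- horizon_fit(w, 2500 * exp(-0.9 * (w - 1)) + 3100)
  cf <- coef(f)
  # MT'(w*) sits exactly criterion*a above the asymptote
  expect_equal(unname(predict(f, f$w_star) - cf["c"]), unname(0.01 * cf["a"]),
               tolerance = 1e-8)
  # numeric root of MT'(w) = c + 0.01 a agrees with the closed form
  root <- uniroot(function(x) predict(f, x) - cf["c"] - 0.01 * cf["a"],
                  c(1, 50), tol = 1e-10)$root
  expect_equal(root, f$w_star, tolerance = 1e-6)
})

test_that("criterion changes rescale w*-1 and never reorder participants", {
  bs <- c(0.6, 1.1, 1.9, 3.2)
  w1 <- wstar_from_b(bs, 0.01)
  w2 <- wstar_from_b(bs, 0.05)
  expect_equal((w2 - 1) / (w1 - 1),
               rep(log(0.05) / log(0.01), 4), tolerance = 1e-12)
  expect_identical(order(w1), order(w2))
  # w* strictly decreasing in b
  expect_true(all(diff(wstar_from_b(seq(0.2, 5, by = 0.1))) < 0))
})

test_that("the decay rate is invariant to affine rescaling of MT", {
  w <- c(1:8, 14)
  set.seed(4)
  mt <- 2200 * exp(-1.3 * (w - 1)) + 2900 + rnorm(9, 0, 80)
  f1 <- fit_exponential(w, mt)
  f2 <- fit_exponential(w, 1.7 * mt + 400)
  expect_equal(f2$b, f1$b, tolerance = 1e-5)
  expect_equal(f2$a, 1.7 * f1$a, tolerance = 1e-4)
  expect_equal(f2$c, 1.7 * f1$c + 400, tolerance = 1e-4)
})

test_that("horizon_fit methods behave like a standard model object", {
  w <- c(1:8, 14)
  set.seed(5)
  d <- data.frame(w = w, mt = 2000 * exp(-1.1 * (w - 1)) + 3000 +
                    rnorm(9, 0, 50))
  f <- horizon_fit(mt ~ w, d)
  g <- horizon_fit(d$w, d$mt)
  expect_s3_class(f, "horizon_fit")
  expect_equal(coef(f), coef(g))
  expect_named(coef(f), c("a", "b", "c"))
  expect_equal(unname(predict(f, 1)), sum(coef(f)[c("a", "c")]),
               tolerance = 1e-9)
  expect_equal(fitted(f) + residuals(f), d$mt)
  expect_output(print(f), "Effective horizon")
  expect_output(print(summary(f)), "Residual SE")
  sims <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(9L, 3L))
  pdf(NULL); plot(f); dev.off()
})

test_that("replicated window sizes are averaged before fitting", {
  w <- c(1, 1, 2, 3, 4, 5)
  mt <- c(5000, 5200, 4000, 3500, 3300, 3250)
  f <- fit_exponential(w, mt)
  f2 <- fit_exponential(c(1, 2, 3, 4, 5), c(5100, 4000, 3500, 3300, 3250))
  expect_equal(f$b, f2$b, tolerance = 1e-8)
})

test_that("split-half analysis yields negative horizon-MT correlations", {
  p <- small_params(n_participants = 8, n_days = 1, blocks_per_day = 6,
                    trials_per_block = 18, wstar_sd = 1.2,
                    horizon_speed_rho = 0.9, seed = 15)
  ts <- summarize_trials(simulate_experiment(p)$presses)
  sh <- split_half_horizon_mt(ts, day = 1)
  expect_equal(nrow(sh), 8)
  expect_true(all(is.finite(sh$w_star_odd)))
  tab <- split_half_correlation(ts)
  expect_lt(tab$r[1], 0)

  # too few blocks on either half -> missing values
  one_block <- ts[ts$block == 1, ]
  sh2 <- split_half_horizon_mt(one_block, day = 1)
  expect_true(all(is.na(sh2$w_star_odd)))
})

test_that("shuffling one split-half vector attenuates the correlation", {
  set.seed(8)
  x <- rnorm(200)
  y <- -x + rnorm(200, 0, 0.3)
  r0 <- pearson_r(x, y)["r"]
  rs <- replicate(50, pearson_r(x, sample(y))["r"])
  expect_lt(abs(mean(rs)), abs(r0) / 4)
})

test_that("per-participant-day horizon table recovers heterogeneous truth", {
  p <- small_params(n_participants = 6, n_days = 2, blocks_per_day = 6,
                    trials_per_block = 18, noise_cv = 0.10, seed = 23)
  ex <- simulate_experiment(p)
  ts <- summarize_trials(ex$presses)
  fits <- horizon_table(ts, by_day = TRUE)
  expect_equal(nrow(fits), 12)
  rec <- merge(ex$truth, fits, by = c("participant", "day"))
  ok <- rec$valid
  expect_gt(mean(ok), 0.8)
  expect_gt(cor(rec$w_star.x[ok], rec$w_star.y[ok]), 0.6)
})
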