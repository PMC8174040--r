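test_that("two-level within-subject ANOVA equals the paired t squared", {
  set.seed(61)
  for (i in 1:5) {
    d <- data.frame(participant = rep(1:8, 2),
                    cond = rep(c("a", "b"), each = 8),
                    y = rnorm(16, rep(c(10, 12), each = 8)))
    an <- rm_anova(d, "y", "cond")
    tt <- paired_t(d$y[d$cond == "a"], d$y[d$cond == "b"])
    expect_equal(an$F, unname(tt["t"]^2), tolerance = 1e-9)
    expect_equal(an$p, unname(tt["p"]), tolerance = 1e-9)
    expect_equal(an$df_num, 1)
    expect_equal(an$df_den, 7)
  }
})

test_that("zero effect SS reports F = 0 and constants do not move F", {
  d <- expand.grid(participant = 1:5, cond = 1:3)
  d$y <- 100 + 7 * d$participant          # identical across levels
  an <- rm_anova(d, "y", "cond")
  expect_equal(an$F, 0)
  expect_equal(an$p, 1)

  set.seed(62)
  d$y <- d$y + rnorm(nrow(d))
  a1 <- rm_anova(d, "y", "cond")
  d2 <- d; d2$y <- d2$y + 1234
  a2 <- rm_anova(d2, "y", "cond")
  expect_equal(a1$F, a2$F, tolerance = 1e-9)
  expect_true(all(a1$p >= 0 & a1$p <= 1))
})

test_that("two-way decomposition matches hand-computed sums of squares", {
  set.seed(63)
  n <- 6; ka <- 3; kb <- 2
  d <- expand.grid(participant = 1:n, A = 1:ka, B = 1:kb)
  d$y <- rnorm(nrow(d), mean = 2 * d$A + 3 * d$B + d$A * d$B)
  an <- rm_anova(d, "y", c("A", "B"))

  # classical within-subject decomposition by explicit loops
  gm <- mean(d$y)
  mA <- tapply(d$y, d$A, mean); mB <- tapply(d$y, d$B, mean)
  mS <- tapply(d$y, d$participant, mean)
  mSA <- tapply(d$y, list(d$participant, d$A), mean)
  mSB <- tapply(d$y, list(d$participant, d$B), mean)
  mAB <- tapply(d$y, list(d$A, d$B), mean)
  ssA <- n * kb * sum((mA - gm)^2)
  ssSA <- kb * sum((mSA - matrix(mS, n, ka) -
                      matrix(mA, n, ka, byrow = TRUE) + gm)^2)
  FA <- (ssA / (ka - 1)) / (ssSA / ((ka - 1) * (n - 1)))
  expect_equal(an$F[an$effect == "A"], FA, tolerance = 1e-9)

  ssB <- n * ka * sum((mB - gm)^2)
  ssSB <- ka * sum((mSB - matrix(mS, n, kb) -
                      matrix(mB, n, kb, byrow = TRUE) + gm)^2)
  FB <- (ssB / (kb - 1)) / (ssSB / ((kb - 1) * (n - 1)))
  expect_equal(an$F[an$effect == "B"], FB, tolerance = 1e-9)

  expect_equal(an$df_den[an$effect == "A"], (ka - 1) * (n - 1))
  expect_equal(an$df_den[an$effect == "A:B"], (ka - 1) * (kb - 1) * (n - 1))
})

test_that("subjects with missing cells are listwise dropped with a warning", {
  d <- expand.grid(participant = 1:5, cond = 1:3)
  set.seed(64)
  d$y <- rnorm(nrow(d))
  d <- d[!(d$participant == 5 & d$cond == 3), ]
  expect_warning(an <- rm_anova(d, "y", "cond"), "missing cells")
  expect_equal(an$df_den, 2 * 3)   # 4 subjects remain
  expect_error(rm_anova(d[d$participant == 1, ], "y", "cond"), "subjects")
  expect_error(rm_anova(d[d$cond == 1, ], "y", "cond"), "levels")
})

test_that("Greenhouse-Geisser epsilon is sane and shrinks significance", {
  set.seed(65)
  d <- expand.grid(participant = 1:10, cond = 1:4)
  d$y <- rnorm(nrow(d)) + d$cond * (1 + d$participant / 10)
  a0 <- rm_anova(d, "y", "cond")
  a1 <- rm_anova(d, "y", "cond", gg = TRUE)
  k <- 4
  expect_gte(a1$epsilon, 1 / (k - 1) - 1e-12)
  expect_lte(a1$epsilon, 1 + 1e-12)
  expect_gte(a1$p, a0$p - 1e-12)
  expect_equal(a1$F, a0$F)        # F itself is uncorrected
})

test_that("t tests and correlations match their textbook formulas", {
  x <- c(3.1, 4.5, 2.2, 5.0, 3.3)
  y <- c(2.0, 4.1, 2.5, 4.0, 2.9)
  tt <- paired_t(x, y)
  d <- x - y
  expect_equal(unname(tt["t"]), mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-12)
  expect_equal(unname(tt["df"]), 4)
  expect_equal(unname(tt["p"]),
               2 * pt(-abs(mean(d) / (sd(d) / sqrt(5))), 4), tolerance = 1e-12)

  expect_equal(unname(paired_t(x, x)["t"]), 0)
  expect_equal(unname(paired_t(x, x)["p"]), 1)
  expect_warning(paired_t(x, x + 1), "zero variance")

  ot <- one_sample_t(x, mu = 3)
  expect_equal(unname(ot["t"]), mean(x - 3) / (sd(x) / sqrt(5)),
               tolerance = 1e-12)

  r <- pearson_r(1:5, 2 * (1:5) + 3)
  expect_equal(unname(r["r"]), 1)
  expect_warning(r0 <- pearson_r(1:5, rep(2, 5)), "zero variance")
  expect_true(is.na(r0["r"]))
  expect_equal(unname(pearson_r(1:2, 2:1)["n"]), 2)  # too few -> NA
  expect_true(is.na(pearson_r(1:2, 2:1)["r"]))
})

test_that("within-subject SEM removes between-subject offsets", {
  M <- matrix(c(10, 20, 30,
                12, 22, 32,
                15, 25, 35), nrow = 3, byrow = TRUE)
  colnames(M) <- c("c1", "c2", "c3")
  ws <- within_subject_sem(M)
  expect_equal(ws$sem, rep(0, 3))
  expect_equal(ws$mean, unname(colMeans(M)))

  set.seed(66)
  M2 <- M + matrix(rnorm(9), 3)
  ws2 <- within_subject_sem(M2)
  centered <- M2 - rowMeans(M2) + mean(M2)
  expect_equal(ws2$sem, unname(apply(centered, 2, sd)) / sqrt(3),
               tolerance = 1e-12)

  # single condition: SEM of centered data (zero by construction)
  ws1 <- within_subject_sem(M2[, 1, drop = FALSE])
  expect_equal(ws1$sem, 0)

  # long-format input agrees with the matrix input
  d <- data.frame(participant = rep(1:3, 3),
                  condition = rep(colnames(M2), each = 3),
                  value = as.vector(M2))
  wsl <- within_subject_sem(d)
  expect_equal(wsl$sem[order(wsl$condition)], ws2$sem, tolerance = 1e-12)
})
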