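# Frozen full-precision oracle values for the ICC(2,k) estimate and its
# McGraw-Wong confidence interval, computed with an independent scipy-based
# implementation and cross-checked against pingouin's ICC(A,k) row.
icc_fixtures <- list(
  m6x3 = list(
    m = matrix(c(180.8385, 180.572, 180.7517,
                 176.8882, 177.9277, 177.8667,
                 181.9157, 182.5525, 182.1566,
                 181.8358, 182.5727, 181.7761,
                 175.6495, 175.0925, 175.0115,
                 176.336, 177.4781, 176.6518), nrow = 6, byrow = TRUE),
    ms = c(26.058337735556, 0.331973303889, 0.159098037222),
    icc = 0.992796814537, ci = c(0.970679773563, 0.998904075500)
  ),
  m8x2 = list(
    m = matrix(c(180.8872, 181.5365, 181.6037, 182.6602,
                 183.0076, 183.4445, 182.3186, 183.8562,
                 183.1971, 183.897, 182.5289, 183.7777,
                 186.3416, 187.1926, 181.6229, 182.099),
               nrow = 8, byrow = TRUE),
    ms = c(5.628437786339, 3.024207950625, 0.074621133482),
    icc = 0.926078135399, ci = c(-0.088973861031, 0.989236472133)
  ),
  m5x3_offset = list(
    m = matrix(c(7.3, 8.7, 8.15, 10, 12, 11, 5.8, 8.2, 6.9,
                 9.1, 10.9, 10.05, 8, 10, 9), nrow = 5, byrow = TRUE),
    ms = c(7.55275, 4.608666666667, 0.03575),
    icc = 0.887764742934, ci = c(0.173235988073, 0.988175765523)
  )
)

test_that("two-way mean squares match hand-derived and brute-force values", {
  m <- matrix(c(1, 1, 2, 2, 3, 3), nrow = 3, byrow = TRUE)
  ms <- anova_mean_squares(m)
  expect_equal(ms$ms_rows, 2)
  expect_equal(ms$ms_cols, 0)
  expect_equal(ms$ms_error, 0)

  const <- anova_mean_squares(matrix(5, 3, 2))
  expect_equal(unlist(const), c(ms_rows = 0, ms_cols = 0, ms_error = 0))

  # constant rater offset: residual zero, column effect positive
  off <- anova_mean_squares(matrix(c(7, 9, 10, 12, 6, 8), nrow = 3, byrow = TRUE))
  expect_equal(off$ms_error, 0)
  expect_gt(off$ms_cols, 0)

  set.seed(11)
  for (i in 1:200) {
    n <- sample(3:10, 1)
    k <- sample(2:5, 1)
    m <- random_ratings(n, k)
    got <- anova_mean_squares(m)
    want <- ms_oracle(m)
    expect_equal(got, want, tolerance = 1e-10)
    # decomposition is exhaustive: SSR + SSC + SSE = total SS
    expect_equal(got$ms_rows * (n - 1) + got$ms_cols * (k - 1) +
                   got$ms_error * (n - 1) * (k - 1),
                 sum((m - mean(m))^2), tolerance = 1e-10)
  }
})

test_that("mean squares agree with the aov decomposition", {
  set.seed(5)
  for (i in 1:10) {
    m <- random_ratings(sample(4:8, 1), sample(2:4, 1))
    long <- data.frame(y = as.vector(m),
                       subj = factor(rep(seq_len(nrow(m)), ncol(m))),
                       meas = factor(rep(seq_len(ncol(m)), each = nrow(m))))
    tab <- summary(stats::aov(y ~ subj + meas, data = long))[[1]]
    ms <- anova_mean_squares(m)
    expect_equal(ms$ms_rows, tab["subj", "Mean Sq"], tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(ms$ms_cols, tab["meas", "Mean Sq"], tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(ms$ms_error, tab["Residuals", "Mean Sq"], tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("ICC(2,k) point estimate and CI reproduce the frozen external oracle", {
  for (fx in icc_fixtures) {
    res <- icc2k(fx$m)
    expect_equal(res$ms_rows, fx$ms[1], tolerance = 1e-9)
    expect_equal(res$ms_cols, fx$ms[2], tolerance = 1e-9)
    expect_equal(res$ms_error, fx$ms[3], tolerance = 1e-9)
    expect_equal(res$estimate, fx$icc, tolerance = 1e-9)
    expect_equal(res$ci_low, fx$ci[1], tolerance = 1e-8)
    expect_equal(res$ci_high, fx$ci[2], tolerance = 1e-8)
    expect_true(res$ci_low <= res$estimate && res$estimate <= res$ci_high)
  }
})

test_that("ICC(2,k) handles perfect agreement, offsets, and degenerate input", {
  perfect <- icc2k(matrix(c(1, 1, 2, 2, 3, 3), nrow = 3, byrow = TRUE))
  expect_equal(perfect$estimate, 1)
  expect_equal(perfect$interpretation, "excellent")

  shifted <- matrix(c(7, 9, 10, 12, 6, 8), nrow = 3, byrow = TRUE)
  res <- icc2k(shifted)
  expect_lt(res$estimate, 1)  # absolute agreement penalizes the offset
  expect_equal(res$estimate, icc_ak_oracle(shifted), tolerance = 1e-12)

  expect_error(icc2k(matrix(5, 4, 2)), "constant")
  expect_error(ratings_matrix(matrix(1:4, 2, 2)), "3 subjects")
  expect_error(ratings_matrix(matrix(1:3, 3, 1)), "2 measurements")
  expect_error(ratings_matrix(matrix(c(1, NA, 3, 4, 5, 6), 3, 2)), "complete")
})

test_that("ICC(2,k) matches the brute-force oracle on many random matrices", {
  set.seed(202)
  for (i in 1:400) {
    m <- random_ratings(sample(3:12, 1), sample(2:5, 1),
                        subject_sd = runif(1, 0.5, 4),
                        col_sd = runif(1, 0, 1.5),
                        noise_sd = runif(1, 0.1, 2))
    expect_equal(icc2k(m)$estimate, icc_ak_oracle(m), tolerance = 1e-10)
  }
})

test_that("ICC(2,k) is invariant under positive affine transforms", {
  set.seed(303)
  for (i in 1:30) {
    m <- random_ratings(8, 3)
    a <- runif(1, -50, 50)
    b <- runif(1, 0.1, 10)
    r0 <- icc2k(m)
    r1 <- icc2k(a + b * m)
    expect_equal(r1$estimate, r0$estimate, tolerance = 1e-9)
    expect_equal(r1$ci_low, r0$ci_low, tolerance = 1e-7)
    expect_equal(r1$ci_high, r0$ci_high, tolerance = 1e-7)
  }
})

test_that("expected ICC(2,k) falls with added noise and matches theory", {
  # mean-rating ICC at k=2 with subject SD 2.5 and noise SD 2.5:
  # population value sigma_s^2 / (sigma_s^2 + sigma_e^2 / 2) = 2/3
  set.seed(404)
  reps <- 200
  ests <- replicate(reps, {
    m <- 180 + outer(rnorm(50, 0, 2.5), c(0, 0), "+") +
      matrix(rnorm(100, 0, 2.5), 50, 2)
    icc2k(m)$estimate
  })
  theory <- 2.5^2 / (2.5^2 + 2.5^2 / 2)
  expect_equal(mean(ests), theory, tolerance = 0.03)

  # monotone decline of the mean estimate as noise grows
  noise_levels <- c(0.5, 1, 2, 4)
  means <- vapply(noise_levels, function(s) {
    mean(replicate(100, {
      m <- 180 + outer(rnorm(15, 0, 2.5), c(0, 0), "+") +
        matrix(rnorm(30, 0, s), 15, 2)
      icc2k(m)$estimate
    }))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("Koo-Li interpretation bands use the quoted boundary rule", {
  expect_equal(interpret_icc(0.991), "excellent")
  expect_equal(interpret_icc(0.3), "poor")
  expect_equal(interpret_icc(0.5), "moderate")
  expect_equal(interpret_icc(0.75), "moderate")
  expect_equal(interpret_icc(0.9), "good")
  expect_equal(interpret_icc(0.91), "excellent")
  expect_error(interpret_icc(1.5))
})

test_that("Bland-Altman reproduces hand calculations and exact limit identities", {
  x <- c(181.2, 179.5, 183.3, 177.8)
  same <- bland_altman(x, x)
  expect_equal(same$bias, 0)
  expect_equal(c(same$loa_low, same$loa_high), c(0, 0))

  two <- bland_altman(c(1, 3), c(0, 0))
  expect_equal(two$bias, 2)
  expect_equal(two$sd_diff, sqrt(2))
  expect_equal(two$loa_low, 2 - 1.96 * sqrt(2))
  expect_equal(two$loa_high, 2 + 1.96 * sqrt(2))

  set.seed(21)
  for (i in 1:100) {
    n <- sample(2:40, 1)
    a <- rnorm(n, 180, 5)
    b <- rnorm(n, 180, 5)
    mult <- runif(1, 1, 3)
    res <- bland_altman(a, b, multiplier = mult)
    d <- a - b
    expect_equal(res$bias, sum(d) / n, tolerance = 1e-12)
    expect_equal(res$sd_diff, sqrt(sum((d - mean(d))^2) / (n - 1)),
                 tolerance = 1e-12)
    expect_equal(res$loa_high - res$loa_low, 2 * mult * res$sd_diff,
                 tolerance = 1e-12)
    expect_true(res$loa_low <= res$bias && res$bias <= res$loa_high)
  }
  expect_error(bland_altman(1:3, 1:4), "equal length")
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("Pearson correlation matches cor.test and hits the exact cases", {
  x <- c(1, 2, 4, 8, 9)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  set.seed(31)
  for (i in 1:100) {
    n <- sample(3:50, 1)
    a <- rnorm(n)
    b <- a * runif(1, -2, 2) + rnorm(n)
    ref <- stats::cor.test(a, b)
    got <- pearson_r(a, b)
    expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
  }
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("OLS matches the normal-equations oracle and lm", {
  # exact recovery of the noise-free calibration line
  pka <- c(173.1, 178.0, 180.0, 182.6, 186.4, 192.4)
  hka <- -10.54 + 1.0364 * pka
  fit <- ols_fit(pka, hka)
  expect_equal(fit$slope, 1.0364, tolerance = 1e-10)
  expect_equal(fit$intercept, -10.54, tolerance = 1e-7)
  expect_equal(fit$see, 0, tolerance = 1e-10)

  flat <- ols_fit(c(1, 2, 3, 4), c(5, 5, 5, 5))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r2, 0)

  set.seed(41)
  for (i in 1:100) {
    n <- sample(3:30, 1)
    a <- rnorm(n)
    b <- 2 + a * rnorm(1) + rnorm(n)
    got <- ols_fit(a, b)
    want <- ols_oracle(a, b)
    expect_equal(got$intercept, want$intercept, tolerance = 1e-10)
    expect_equal(got$slope, want$slope, tolerance = 1e-10)
    expect_equal(got$see, want$see, tolerance = 1e-10)
    ref <- stats::lm(b ~ a)
    expect_equal(got$slope, unname(stats::coef(ref)[2]), tolerance = 1e-10)
    expect_equal(got$see, summary(ref)$sigma, tolerance = 1e-10)
  }
  expect_error(ols_fit(rep(2, 5), rnorm(5)), "constant predictor")
})

test_that("regression R-squared equals the squared correlation", {
  set.seed(51)
  for (i in 1:50) {
    n <- sample(3:30, 1)
    a <- rnorm(n)
    b <- a + rnorm(n)
    fit <- ols_fit(a, b)
    r <- pearson_r(a, b)$r
    expect_equal(fit$r2, r^2, tolerance = 1e-12)
    expect_equal(fit$r, r, tolerance = 1e-12)
  }
})
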