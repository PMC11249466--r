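test_that("stratum descriptives agree with a sort-based oracle", {
  d <- data.frame(complexity_score = rep(0, 4), x = c(7, 7, 7, 7))
  r <- describe_strata(d, "x")
  expect_equal(r$mean, 7); expect_equal(r$median, 7)
  expect_equal(r$min, 7); expect_equal(r$max, 7); expect_equal(r$sd, 0)

  d2 <- data.frame(complexity_score = rep(1, 4), x = c(2, 4, 6, 10))
  expect_equal(describe_strata(d2, "x")$median, 5)  # mean-of-middle-two

  set.seed(51)
  d3 <- data.frame(complexity_score = sample(0:3, 200, replace = TRUE),
                   x = rnorm(200))
  r3 <- describe_strata(d3, "x")
  for (i in seq_len(nrow(r3))) {
    v <- sort(d3$x[d3$complexity_score == r3$stratum[i]])
    n <- length(v)
    med <- if (n %% 2) v[(n + 1) / 2] else mean(v[n / 2 + 0:1])
    expect_equal(r3$median[i], med)
    expect_equal(r3$min[i], v[1]); expect_equal(r3$max[i], v[n])
    expect_equal(r3$mean[i], sum(v) / n)
  }

  # an empty requested stratum is reported missing, not zero
  r4 <- describe_strata(d3, "x", strata = 0:5)
  expect_true(all(is.na(r4[r4$stratum == 5, c("mean", "median")])))
  expect_equal(r4$n[r4$stratum == 5], 0L)
})

test_that("trend test separates separated groups and degenerates gracefully", {
  d <- data.frame(complexity_score = rep(0:2, each = 30),
                  x = c(rnorm(30, 0, 0.1), rnorm(30, 10, 0.1),
                        rnorm(30, 20, 0.1)))
  tt <- trend_test(d, "x")
  expect_lt(tt$kw_p, 1e-12)
  expect_false(is.null(tt$pairwise))
  expect_equal(nrow(tt$pairwise), 3L)
  expect_true(all(tt$pairwise$p < 1e-6))

  # all-equal data: H = 0, p = 1, no pairwise follow-up under gating
  d0 <- data.frame(complexity_score = rep(0:1, each = 5), x = rep(3, 10))
  t0 <- trend_test(d0, "x")
  expect_equal(t0$kw_statistic, 0)
  expect_equal(t0$kw_p, 1)
  expect_null(t0$pairwise)
  expect_error(trend_test(data.frame(complexity_score = 1, x = 1), "x"),
               "at least two strata")
})

test_that("two-group Kruskal-Wallis agrees with the u-test asymptotically", {
  set.seed(52)
  d <- data.frame(complexity_score = rep(0:1, each = 100),
                  x = c(rnorm(100), rnorm(100, 0.3)))
  tt <- trend_test(d, "x", pairwise = "always")
  expect_equal(round(tt$pairwise$p[1], 3), round(tt$kw_p, 3))
})

test_that("type-I error of the omnibus test is near nominal under the null", {
  set.seed(53)
  reps <- 400
  rej <- 0
  for (r in seq_len(reps)) {
    d <- data.frame(complexity_score = rep(0:5, each = 30), x = rnorm(180))
    rej <- rej + (trend_test(d, "x", pairwise = "never")$kw_p < 0.05)
  }
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(rej / reps - 0.05), 3 * se)
})

test_that("rate_table rounds half away from zero to integer percents", {
  expect_identical(rate_table(c(0, 1, 1, 0, 2, 1), c(18, 44, 45, 31, 34, 18)),
                   c(0L, 2L, 2L, 0L, 6L, 6L))
  expect_identical(rate_table(c(1, 1, 3, 0, 1, 2), c(18, 44, 45, 31, 34, 18)),
                   c(6L, 2L, 7L, 0L, 3L, 11L))
  expect_identical(rate_table(0, 7), 0L)
  expect_identical(rate_table(1, 8), 13L)    # 12.5 rounds up, not to even
  expect_error(rate_table(5, 4), "domain error")
  expect_error(rate_table(c(1, 2), 10), "equal length")
})

test_that("pain trajectories are per-stratum medians of the pain columns", {
  coh <- generate_cohort(seed = 54)
  pt <- pain_trajectory(coh)
  expect_equal(nrow(pt), 6L)
  for (cn in names(pt)[-1]) {
    d <- describe_strata(coh, cn)
    expect_equal(pt[[cn]], d$median)
  }
  zero <- coh
  for (cn in names(pt)[-1]) zero[[cn]] <- 0L
  expect_true(all(as.matrix(pain_trajectory(zero)[, -1]) == 0))
})
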