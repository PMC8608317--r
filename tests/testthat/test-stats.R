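test_that("logistic fit matches a brute-force likelihood search on tiny data", {
  set.seed(101)
  for (k in 1:3) {
    x <- runif(20)
    p <- stats::plogis(3 * x - 1)
    y <- stats::rbinom(20, 1, p)
    if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
    f <- fit_hvs_logistic(data.frame(hvs = x, correct = y))
    if (f$separation) next
    g <- grid_search_logistic(x, y, a_range = f$slope + c(-4, 4),
                              b_range = f$intercept + c(-4, 4))
    expect_equal(unname(f$slope), unname(g["a"]), tolerance = 5e-4)
    expect_equal(unname(f$intercept), unname(g["b"]), tolerance = 5e-4)
  }
})

test_that("fit object carries deviances with D_r <= D_0", {
  set.seed(102)
  for (k in 1:10) {
    x <- runif(80)
    y <- stats::rbinom(80, 1, stats::plogis(2 * x - 0.5))
    if (length(unique(y)) < 2) next
    f <- fit_hvs_logistic(data.frame(hvs = x, correct = y))
    expect_lte(f$residual_deviance, f$null_deviance + 1e-9)
    expect_gte(f$reduced_deviance_ratio, -1e-9)
  }
})

test_that("degenerate fitting inputs error clearly", {
  expect_error(fit_hvs_logistic(data.frame(hvs = c(0.2, 0.4),
                                           correct = c(1, 1))),
               "one outcome class")
  expect_error(fit_hvs_logistic(data.frame(hvs = c(0.5, 0.5, 0.5),
                                           correct = c(0, 1, 0))),
               "constant")
  expect_error(fit_hvs_logistic(data.frame(hvs = c(1.2, 0.5),
                                           correct = c(0, 1))),
               "\\[0, 1\\]")
  expect_error(fit_hvs_logistic(data.frame(a = 1)), "must contain")
})

test_that("perfect separation is flagged rather than silently reported", {
  x <- c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9)
  y <- c(0, 0, 0, 1, 1, 1)
  f <- fit_hvs_logistic(data.frame(hvs = x, correct = y))
  expect_true(f$separation)
  expect_false(f$converged)
})

test_that("S3 methods for the fit behave like standard modelling objects", {
  set.seed(103)
  x <- runif(200); y <- stats::rbinom(200, 1, stats::plogis(3 * x - 1))
  f <- fit_hvs_logistic(data.frame(hvs = x, correct = y))
  expect_output(print(f), "slope")
  expect_named(coef(f), c("slope", "intercept"))
  ci <- confint(f)
  expect_lt(ci[1], f$slope); expect_gt(ci[2], f$slope)
  p <- predict(f, newdata = c(0, 0.5, 1))
  expect_true(all(p > 0 & p < 1))
  expect_true(all(diff(p) > 0))
  s <- summary(f)
  expect_true(is.list(s))
})

test_that("predicted_probability implements the logistic response", {
  f <- list(slope = 2, intercept = -1)
  class(f) <- "hvs_logit"
  expect_equal(predicted_probability(f, 0.5), 0.5)
  expect_equal(predicted_probability(list(slope = 0, intercept = 0.3) |>
                                       structure(class = "hvs_logit"),
                                     c(0, 1)),
               rep(stats::plogis(0.3), 2))
  xs <- seq(0, 1, 0.1)
  expect_true(all(diff(predicted_probability(f, xs)) > 0))
})

test_that("LR test statistic is the deviance difference with 1 df", {
  set.seed(104)
  x <- runif(300); y <- stats::rbinom(300, 1, stats::plogis(4 * x - 2))
  f <- fit_hvs_logistic(data.frame(hvs = x, correct = y))
  lr <- lr_test_vs_null(f)
  expect_equal(lr$statistic, f$null_deviance - f$residual_deviance)
  expect_equal(lr$df, 1)
  expect_equal(lr$p_value,
               stats::pchisq(lr$statistic, 1, lower.tail = FALSE))
})

test_that("LR test type-I error is near the nominal level", {
  set.seed(105)
  n_rep <- 2000
  rejections <- 0L
  for (r in seq_len(n_rep)) {
    x <- runif(100)
    y <- stats::rbinom(100, 1, 0.6)  # null: no dependence on x
    if (length(unique(y)) < 2) next
    f <- fit_hvs_logistic(data.frame(hvs = x, correct = y))
    if (lr_test_vs_null(f)$p_value < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / n_rep
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("slope recovery is accurate in large simulated experiments", {
  set.seed(106)
  for (A in c(1.5, 3.0, 5.5)) {
    for (B in c(-2, 0)) {
      err <- replicate(7, {
        x <- runif(1750)
        sim <- simulate_observer(x, A, B, seed = sample.int(1e6, 1))
        f <- fit_hvs_logistic(data.frame(hvs = x, correct = sim$correct))
        abs(f$slope - A) / A
      })
      expect_lt(stats::median(err), 0.15)
    }
  }
})

test_that("reduced deviance ratio grows with effect size on average", {
  set.seed(107)
  mean_ratio <- vapply(c(0.5, 2, 6), function(A) {
    mean(replicate(12, {
      x <- runif(250)
      sim <- simulate_observer(x, A, B = -A / 2, seed = sample.int(1e6, 1))
      fit_hvs_logistic(data.frame(hvs = x,
                                  correct = sim$correct))$reduced_deviance_ratio
    }))
  }, numeric(1))
  expect_true(all(diff(mean_ratio) > 0))
})

test_that("simulate_observer is reproducible and respects the guess floor", {
  x <- seq(0, 1, length.out = 50)
  s1 <- simulate_observer(x, 3, -1, guess_floor = 0.2, seed = 42)
  s2 <- simulate_observer(x, 3, -1, guess_floor = 0.2, seed = 42)
  expect_identical(s1$correct, s2$correct)
  expect_true(all(s1$p >= 0.2))
  expect_error(simulate_observer(x, 3, -1), "seed")
  expect_error(simulate_observer(x, 3, -1, guess_floor = 1, seed = 1),
               "guess_floor")
  # the simulator does not disturb the global RNG stream
  set.seed(9); before <- runif(1)
  set.seed(9); invisible(simulate_observer(x, 3, -1, seed = 5)); after <- runif(1)
  expect_identical(before, after)
})

test_that("chow test detects a real slope difference and respects the null", {
  set.seed(108)
  mk <- function(A, B, n, seed) {
    x <- runif(n)
    sim <- simulate_observer(x, A, B, seed = seed)
    data.frame(hvs = x, correct = sim$correct)
  }
  # the two printed group slopes: strongly different
  ch <- chow_test(mk(3.02, -1, 1750, 1), mk(1.54, -1, 1750, 2))
  expect_equal(ch$df[1], 2)
  expect_lt(ch$p_value, 0.01)
  # same generating process: typically not significant; check statistic sane
  ch0 <- chow_test(mk(3, -1, 800, 3), mk(3, -1, 800, 4))
  expect_gte(ch0$statistic, 0)
  expect_gt(ch0$p_value, 0.001)
})

test_that("chow test power at the printed slope pair is high", {
  set.seed(109)
  hits <- replicate(10, {
    x1 <- runif(1750); x2 <- runif(1750)
    s1 <- simulate_observer(x1, 3.02, -1, seed = sample.int(1e6, 1))
    s2 <- simulate_observer(x2, 1.54, -1, seed = sample.int(1e6, 1))
    chow_test(data.frame(hvs = x1, correct = s1$correct),
              data.frame(hvs = x2, correct = s2$correct))$p_value < 0.05
  })
  expect_gte(mean(hits), 0.8)
})

test_that("bin_trials covers [0,1] with half-open bins and a closed last bin", {
  d <- data.frame(hvs = c(0, 0.05, 0.1, 0.95, 1, 1), correct = c(0, 1, 1, 1, 0, 1))
  b <- bin_trials(d)
  expect_equal(sum(b$n), nrow(d))
  expect_equal(b$n[b$bin_lo == 0], 2)       # 0 and 0.05
  expect_equal(b$n[abs(b$bin_lo - 0.9) < 1e-9], 3)  # 0.95 and both 1s
  acc <- b$n_correct[b$n > 0] / b$n[b$n > 0]
  expect_true(all(acc >= 0 & acc <= 1))
  expect_equal(acc[1], 0.5)
  expect_error(bin_trials(d, bin_width = 0.3), "evenly")
})

test_that("meta-regression returns slope, intercept and R squared", {
  x <- c(1, 2, 3, 4)
  y <- 2 - 0.5 * x
  f <- slope_vs_vision_regression(y, x)
  expect_equal(f$slope, -0.5, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  set.seed(110)
  y2 <- y + rnorm(4, 0, 0.1)
  f2 <- slope_vs_vision_regression(y2, x)
  expect_lt(f2$r_squared, 1)
  expect_error(slope_vs_vision_regression(1:3, 1:2), "paired")
})

test_that("random-intercept pooled fit runs when lme4 is present", {
  skip_if_not_installed("lme4")
  set.seed(111)
  subj <- rep(1:5, each = 80)
  b_subj <- rnorm(5, -1, 0.4)
  x <- runif(400)
  y <- stats::rbinom(400, 1, stats::plogis(3 * x + b_subj[subj]))
  f <- fit_hvs_logistic(data.frame(hvs = x, correct = y, subject = subj),
                        random_intercept = TRUE)
  expect_true(f$random_intercept)
  expect_gt(f$slope, 0)
})

test_that("bundled low-vision reference table is complete and consistent", {
  lv <- low_vision_subjects()
  expect_equal(nrow(lv), 10)
  expect_true(all(c("acuity_logmar", "cs_pelli_robson", "slope",
                    "null_deviance", "residual_deviance") %in% names(lv)))
  expect_true(all(lv$residual_deviance <= lv$null_deviance))
  expect_true(all(lv$slope > 0))
  expect_true(all(lv$slope_ci_lo < lv$slope & lv$slope < lv$slope_ci_hi))
})
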