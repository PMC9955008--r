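test_that("product-limit fit matches the distinct-time oracle on small samples", {
  set.seed(42)
  for (n in 1:8) {
    for (rep in 1:25) {
      time <- sample(1:6, n, replace = TRUE)   # many ties by construction
      status <- stats::rbinom(n, 1, 0.6)
      z <- surv_sample(time, status)
      for (complete in c(FALSE, TRUE)) {
        fit <- km_fit(z, complete = complete)
        for (t in c(0, sort(unique(time)), max(time) + 1)) {
          expect_equal(surv_after(fit, t),
                       oracle_km_surv(time, status, t, complete),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("fit agrees with survival::survfit on the NCOG arms", {
  skip_if_not_installed("survival")
  for (arm in c("arm_a", "arm_b")) {
    z <- ncog(arm)$sample
    fit <- km_fit(z, complete = FALSE)
    sf <- summary(survival::survfit(survival::Surv(z$time, z$status) ~ 1))
    expect_equal(surv_after(fit, sf$time), sf$surv, tolerance = 1e-12)
    pos <- sf$surv > 0   # survfit reports NaN where S = 0
    expect_equal(greenwood_sd(fit, sf$time[pos]), sf$std.err[pos],
                 tolerance = 1e-9)
  }
})

test_that("survival step function is monotone, left-continuous, S(0) = 1", {
  set.seed(7)
  for (rep in 1:20) {
    fit <- random_completed_fit()
    expect_equal(surv_at(fit, 0), 1)
    expect_true(all(diff(fit$surv) <= 1e-12))
    expect_true(all(fit$q >= -1e-15))
    expect_true(all(fit$hazard >= 0 & fit$hazard <= 1))
    # left continuity: value at an event time is the pre-jump value
    td <- fit$time[fit$q > 0][1]
    expect_equal(surv_at(fit, td), surv_after(fit, td - 1e-9))
    # conservation for completed fits
    expect_equal(sum(fit$q), 1, tolerance = 1e-12)
  }
})

test_that("completion relocates the residual mass to the largest time", {
  # single death record: all mass at its time
  f1 <- km_fit(surv_sample(10, 1))
  expect_equal(f1$q, 1)
  expect_equal(surv_at(f1, 10), 1)
  expect_equal(surv_after(f1, 10), 0)

  # (1,1),(2,0),(3,1),(4,0): drops 1/4 at 1, 3/8 at 3, residual 3/8 at 4
  f2 <- km_fit(surv_sample(c(1, 2, 3, 4), c(1, 0, 1, 0)))
  expect_equal(f2$q, c(0.25, 0, 0.375, 0.375))
  expect_true(f2$completed)
  expect_equal(f2$q_fin, 0.375)

  # Arm B: survival after the last death is 22.99%, relocated to 2297
  b <- ncog("arm_b")$sample
  fb <- km_fit(b, complete = FALSE)
  expect_equal(round(100 * surv_after(fb, 1776), 2), 22.99)
  fbc <- km_fit(b, complete = TRUE)
  expect_equal(fbc$q_fin, surv_after(fb, 1776), tolerance = 1e-12)
  expect_equal(fbc$q[fbc$time == 2297], fbc$q_fin)
  expect_error(km_fit(surv_sample(numeric(0), numeric(0))), "empty")
})

test_that("life expectancy is the strictly truncated mean", {
  # equal masses 1/3 at 1, 2, 3; theta = 1.5 renormalises to 1/2 at 2 and 3
  f <- km_fit(surv_sample(c(1, 2, 3), c(1, 1, 1)))
  expect_equal(life_expectancy(f, 1.5), 1.0)
  # strict truncation: theta exactly at an atom excludes that atom
  expect_equal(life_expectancy(f, 2), 1.0)

  f2 <- km_fit(surv_sample(c(1, 2, 3, 4), c(1, 0, 1, 0)))
  expect_equal(life_expectancy(f2, 0), 0.25 * 1 + 0.375 * 3 + 0.375 * 4)
  expect_equal(life_expectancy(f2, 0), oracle_trunc_mean(f2$time, f2$q, 0))

  expect_error(life_expectancy(f, 3), "no death mass")
  expect_error(life_expectancy(km_fit(surv_sample(c(1, 2), c(1, 0)),
                                      complete = FALSE), 0),
               "not completed")
})

test_that("truncated-mean and integral forms of life expectancy agree", {
  set.seed(11)
  for (rep in 1:100) {
    fit <- random_completed_fit()
    theta <- stats::runif(1, 0, max(fit$time[fit$q > 0]) - 0.01)
    if (theta %in% fit$time) theta <- theta + 1e-4
    expect_equal(life_expectancy(fit, theta),
                 oracle_integral_expectancy(fit, theta),
                 tolerance = 1e-9)
  }
})

test_that("Greenwood standard deviation matches direct formula evaluation", {
  f <- km_fit(surv_sample(c(1, 2, 3), c(1, 1, 1)))
  expect_equal(greenwood_sd(f, 1), (2 / 3) * sqrt((1 / 3) / ((2 / 3) * 3)))
  expect_equal(greenwood_sd(f, 0.5), 0)   # empty sum before first event
  # final record has h = 1: zero-summand convention, sd finite
  expect_true(is.finite(greenwood_sd(f, 3)))
  # all prior hazards equal to 1 give sd 0
  f1 <- km_fit(surv_sample(1, 1))
  expect_equal(greenwood_sd(f1, 2), 0)
})

test_that("log-scale confidence interval has closed-form values and clamps", {
  expect_equal(km_confint(0.5, 0, 0.95), cbind(lower = 0.5, upper = 0.5))
  ci <- km_confint(0.5, 0.1, 0.95)
  z <- qnorm(0.975)
  expect_equal(unname(ci[, "lower"]), exp(log(0.5) - z * 0.2), tolerance = 1e-12)
  expect_equal(unname(ci[, "upper"]), exp(log(0.5) + z * 0.2), tolerance = 1e-12)
  expect_equal(round(ci, 3), cbind(lower = 0.338, upper = 0.74))
  expect_equal(km_confint(1, 0), cbind(lower = 1, upper = 1))
  expect_equal(km_confint(0, 0.2), cbind(lower = 0, upper = 0))
  expect_true(km_confint(0.9, 1)[, "upper"] <= 1)  # clamped
})
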