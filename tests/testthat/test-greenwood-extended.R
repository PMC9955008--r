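arm_a <- ncog("arm_a")

test_that("merging standard and imputed records keeps order and flags", {
  fit <- codmi(arm_a$sample, arm_a$covid_times,
               codmi_control(tolerance = 0.1, init = "at_theta"))
  y <- merge_imputed(arm_a$sample, fit)
  expect_equal(nrow(y), 56)
  expect_equal(sum(y$delta_prime), 5)
  expect_equal(attr(y, "n"), 51)
  expect_equal(attr(y, "m"), 5)
  expect_true(all(diff(y$time) >= 0))

  # empty imputation set: y is z with delta_prime all FALSE
  y0 <- merge_imputed(arm_a$sample, codmi(arm_a$sample, numeric(0)))
  expect_equal(y0$time, arm_a$sample$time)
  expect_equal(sum(y0$delta_prime), 0)

  # a death tying at an imputed time keeps the deaths-first order
  z <- surv_sample(c(1, 3), c(1, 0))
  adj <- adjust_for_censoring(3, 4, 0.9, 2)   # tau* = 3 ties the censoring
  y2 <- merge_imputed(z, adj)
  expect_equal(y2$d_prime, c(1, 1, 0))
  expect_equal(y2$delta_prime, c(FALSE, TRUE, FALSE))
})

test_that("fractional deaths conserve mass: per-j sums 1, total sums m", {
  # 3 deaths plus one imputation at 2.5 from theta = 1.5: direct masses
  # 1/4 each at {1,2,2.5,3}; truncation at 1.5 keeps {2,2.5,3} renormalised
  z <- surv_sample(c(1, 2, 3), c(1, 1, 1))
  adj <- adjust_for_censoring(2.5, 99, 1, 1.5)
  y <- merge_imputed(z, adj)
  tab <- fractional_deaths(y, 1.5, 1)
  expect_equal(tab$q_direct, rep(0.25, 4))
  expect_equal(tab$q_direct_trunc[1, ], c(0, 1, 1, 1) / 3)
  expect_equal(tab$Q, c(0, 1, 1, 1) / 3)
  expect_equal(sum(tab$Q), 1)
  expect_equal(rowSums(tab$q_star), 1)

  # m = 1 with theta before all deaths: Q_i = q_i
  tab0 <- fractional_deaths(y, 0.5, 1)
  expect_equal(tab0$Q, tab0$q_direct)

  # m = 0: Q = 0, nu = 1
  y0 <- merge_imputed(z, codmi(z, numeric(0)))
  t0 <- fractional_deaths(y0, numeric(0), numeric(0))
  expect_equal(t0$Q, rep(0, 3))
  expect_equal(t0$nu, rep(1, 3))

  # empty truncation support names the offending index
  expect_error(fractional_deaths(y, 3.5, 1), "theta_1")

  # on the Arm A worked example the total equals m = 5
  fitA <- codmi(arm_a$sample, arm_a$covid_times,
                codmi_control(tolerance = 0.1, init = "at_theta"))
  yA <- merge_imputed(arm_a$sample, fitA)
  tabA <- fractional_deaths(yA, arm_a$covid_times, rep(1, 5))
  expect_equal(sum(tabA$Q), 5, tolerance = 1e-9)
  expect_equal(unname(rowSums(tabA$q_direct_trunc)), rep(1, 5),
               tolerance = 1e-12)
  expect_true(all(tabA$Q2 >= 0 & tabA$Q2 <= tabA$Q + 1e-12))
})

test_that("with no imputations the extended formula reduces to Greenwood", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    time <- sample(1:15, n, replace = TRUE)
    status <- stats::rbinom(n, 1, 0.6)
    if (all(status == 0)) status[1] <- 1
    z <- surv_sample(time, status)
    y <- merge_imputed(z, codmi(z, numeric(0)))
    tab <- fractional_deaths(y, numeric(0), numeric(0))
    fit <- km_fit(z, complete = TRUE)
    tt <- c(0, sort(unique(time)), max(time) + 1)
    expect_equal(extended_sd(y, tab, tt), greenwood_sd(fit, tt),
                 tolerance = 1e-12)
    # both at-risk readings coincide when m = 0
    expect_equal(extended_sd(y, tab, tt, at_risk_lag = FALSE),
                 greenwood_sd(fit, tt), tolerance = 1e-12)
  }
})

test_that("extended sd matches an independent term-by-term transcription", {
  z <- surv_sample(c(1, 2, 3), c(1, 1, 1))
  adj <- adjust_for_censoring(2.5, 99, 1, 1.5)
  y <- merge_imputed(z, adj)
  tab <- fractional_deaths(y, 1.5, 1)
  for (t in c(0.5, 1, 2, 2.5, 3)) {
    expect_equal(extended_sd(y, tab, t),
                 oracle_extended_sd(y$time, y$d_prime,
                                    as.numeric(y$delta_prime),
                                    1.5, 1, t),
                 tolerance = 1e-12)
  }

  # mixed direct/reverse deltas on the Arm A worked example
  fitA <- codmi(arm_a$sample, arm_a$covid_times,
                codmi_control(tolerance = 0.1, init = "at_theta"))
  tau_r <- reverse_km_lifetimes(fitA, arm_a$covid_times)
  adjA <- adjust_for_censoring(fitA$tau_hat, tau_r,
                               c(0.623, 0.781, 0.699, 0.402, 0.193),
                               arm_a$covid_times)
  yA <- merge_imputed(arm_a$sample, adjA)
  tabA <- fractional_deaths(yA, arm_a$covid_times, adjA$delta)
  for (t in c(100, 500, 1000, 1400)) {
    expect_equal(suppressWarnings(extended_sd(yA, tabA, t)),
                 suppressWarnings(
                   oracle_extended_sd(yA$time, yA$d_prime,
                                      as.numeric(yA$delta_prime),
                                      arm_a$covid_times, adjA$delta, t)),
                 tolerance = 1e-12)
  }
})

test_that("extended interval contains the estimate within [0, 1]", {
  fitA <- codmi(arm_a$sample, arm_a$covid_times,
                codmi_control(tolerance = 0.1, init = "at_theta"))
  tab <- suppressWarnings(
    ci_table(arm_a$sample, fitA, arm_a$covid_times, level = 0.95))
  pos <- tab$surv > 0
  expect_true(all(tab$lower[pos] <= tab$surv[pos] + 1e-12))
  expect_true(all(tab$upper[pos] >= tab$surv[pos] - 1e-12))
  expect_true(all(tab$lower >= 0 & tab$upper <= 1))
})
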