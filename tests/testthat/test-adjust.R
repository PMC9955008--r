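arm_a <- ncog("arm_a")
arm_b <- ncog("arm_b")

test_that("reverse-KM lifetimes reproduce the worked example and toy oracle", {
  fit <- codmi(arm_a$sample, arm_a$covid_times,
               codmi_control(tolerance = 0.1, init = "at_theta"))
  tau_r <- reverse_km_lifetimes(fit, arm_a$covid_times)
  expect_equal(round(tau_r, 1), c(1207.5, 1296.2, 1347.8, 1347.8, 1398.1))

  # toy: {(1,0),(2,1),(3,0)} reversed = {(1,1),(2,0),(3,1)};
  # reverse mass 1/3 at 1, completed 2/3 at 3; beyond 1.5 only the atom at 3
  toy <- surv_sample(c(1, 2, 3), c(0, 1, 0))
  expect_equal(reverse_km_lifetimes(toy, 1.5), 3)

  # all-censored sample: reversal flips everything to deaths, and the
  # reverse expectancy equals the plain expectancy of the flipped sample
  cen <- surv_sample(c(1, 2, 3), c(0, 0, 0))
  flip <- km_fit(reverse_sample(cen))
  expect_equal(reverse_km_lifetimes(cen, 0.5),
               0.5 + life_expectancy(flip, 0.5))

  # double reverse returns the original lifetimes exactly
  w <- fit$imputed_sample
  expect_equal(reverse_km_lifetimes(reverse_sample(reverse_sample(w)),
                                    arm_a$covid_times),
               reverse_km_lifetimes(w, arm_a$covid_times))
  expect_equal(reverse_km_lifetimes(w, numeric(0)), numeric(0))
})

test_that("grid hazards: empirical rates, family recovery, degenerate cells", {
  # constant-hazard data with exponential family recovers events/person-time
  z <- surv_sample(c(1, 2, 3, 4, 5, 6, 7, 8), rep(1, 8))
  g <- grid_hazard(z, n_cells = 4, family = "exponential")
  expect_equal(g$fitted, rep(sum(g$events) / sum(g$exposure), 4),
               tolerance = 1e-9)
  expect_true(all(g$fitted >= 0))
  expect_equal(sum(g$events), 8)

  # weibull self-consistency: data drawn from a Weibull lifetime
  # distribution yields a fitted Weibull hazard with the generating shape
  set.seed(99)
  shape <- 1.6
  tw <- stats::rweibull(4000, shape = shape, scale = 100)
  gw <- grid_hazard(surv_sample(tw, rep(1, 4000)), n_cells = 10,
                    family = "weibull")
  slope <- unname(log(gw$hazard_fun(80) / gw$hazard_fun(20)) / log(80 / 20))
  expect_equal(slope, shape - 1, tolerance = 0.1)
  # and the wls route agrees on the shape to coarser tolerance
  gw2 <- grid_hazard(surv_sample(tw, rep(1, 4000)), n_cells = 10,
                     family = "weibull", fit = "wls")
  slope2 <- unname(log(gw2$hazard_fun(80) / gw2$hazard_fun(20)) / log(80 / 20))
  expect_equal(slope2, shape - 1, tolerance = 0.25)

  # cells without events still get a finite fitted value from the curve
  z2 <- surv_sample(c(1, 2, 10), c(1, 1, 1))
  g2 <- grid_hazard(z2, n_cells = 5, family = "weibull")
  expect_true(any(g2$events == 0))
  expect_true(all(is.finite(g2$fitted) & g2$fitted >= 0))

  expect_warning(grid_hazard(surv_sample(c(1, 2), c(0, 0)), 2), "no events")
  expect_error(grid_hazard(z, n_cells = 5, family = "lognormal"))
})

test_that("alpha curve boundary behaviour and symmetry", {
  # no censorings: reverse fit has no events, alpha = 1 everywhere it is
  # defined by the direct hazard
  z <- surv_sample(1:10, rep(1, 10))
  suppressWarnings(ac <- alpha_curve(z, n_cells = 3))
  expect_true(all(ac$alpha >= 0 & ac$alpha <= 1))
  expect_true(all(ac$alpha[ac$direct$fitted > 0] > 0.99))

  # sample identical to its reverse as a multiset: alpha = 0.5 in every cell
  z2 <- surv_sample(c(1, 1, 2, 2, 3, 3), c(1, 0, 1, 0, 1, 0))
  ac2 <- alpha_curve(z2, n_cells = 3)
  expect_equal(ac2$alpha, rep(0.5, 3), tolerance = 1e-9)

  # swapping direct and reverse maps alpha to 1 - alpha cell-wise
  z3 <- arm_a$sample
  a_direct <- alpha_curve(z3, n_cells = 6)
  a_swapped <- alpha_curve(reverse_sample(z3), n_cells = 6)
  expect_equal(a_swapped$alpha, 1 - a_direct$alpha, tolerance = 1e-9)
})

test_that("alpha classification matches the worked examples on both arms", {
  aa <- alpha_curve(arm_a$sample)$at(arm_a$covid_times)
  expect_equal(aa >= 0.5, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  ab <- alpha_curve(arm_b$sample)$at(arm_b$covid_times)
  expect_equal(ab >= 0.5, c(TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("selection rule mixes direct and reverse estimates by alpha", {
  tau_d <- c(894.32, 1118.85, 1253.58, 1286.24, 1354.00)
  tau_r <- c(1207.49, 1296.23, 1347.78, 1347.78, 1398.13)
  alpha <- c(0.623, 0.781, 0.699, 0.402, 0.193)
  theta <- arm_a$covid_times
  adj <- adjust_for_censoring(tau_d, tau_r, alpha, theta)
  expect_equal(adj$tau_star,
               c(894.32, 1118.85, 1253.58, 1347.78, 1398.13))
  expect_equal(adj$delta, c(1, 1, 1, 0, 0))
  expect_equal(adj$source, c("direct", "direct", "direct",
                             "reverse", "reverse"))

  # all alpha >= 0.5 is the identity on (tau, delta = 1); boundary is direct
  adj2 <- adjust_for_censoring(tau_d, tau_r, c(0.9, 0.8, 0.7, 0.6, 0.5), theta)
  expect_equal(adj2$tau_star, tau_d)
  expect_equal(adj2$delta, rep(1, 5))

  # overrides take precedence and are labelled
  adj3 <- adjust_for_censoring(tau_d, tau_r, alpha, theta,
                               overrides = c("4" = 1, "5" = 1))
  expect_equal(adj3$tau_star, tau_d)
  expect_equal(adj3$source[4:5], c("override", "override"))
  expect_error(
    adjust_for_censoring(tau_d, tau_r, alpha, theta, overrides = c("9" = 1)),
    "out of range")
})
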