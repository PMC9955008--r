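# Independent oracles used across the suite. These deliberately use the
# distinct-time formulation of the product-limit estimator (aggregated
# deaths per unique time, risk set = everyone with time >= t), a different
# route from the package's per-record accounting.

# post-jump survival S(t+) by the distinct-time product-limit formula
oracle_km_surv <- function(time, status, t, complete = FALSE) {
  completed <- complete && any(time == max(time) & status == 0)
  ut <- sort(unique(time))
  S <- 1
  for (tt in ut[ut <= t]) {
    R <- sum(time >= tt)
    d <- sum(time == tt & status == 1)
    S <- S * (1 - d / R)
  }
  # completion flips the record that sorts last (after every other record
  # at t_max), which forces S(t_max) = 0 regardless of earlier ties
  if (completed && t >= max(time)) S <- 0
  S
}

# brute-force truncated mean over an atomic death-mass distribution
oracle_trunc_mean <- function(time, q, theta) {
  keep <- time > theta
  sum((time[keep] - theta) * q[keep]) / sum(q[keep])
}

# random completed km_fit with at least one death
random_completed_fit <- function() {
  n <- sample(3:12, 1)
  time <- sample(1:20, n, replace = TRUE) + round(stats::runif(n), 2)
  status <- stats::rbinom(n, 1, 0.7)
  if (all(status == 0)) status[sample(n, 1)] <- 1
  km_fit(surv_sample(time, status), complete = TRUE)
}

# life expectancy by numerical integration of the survival step function:
# e_theta = int_theta^tmax P(T > t) dt / P(T > theta)
oracle_integral_expectancy <- function(fit, theta) {
  knots <- sort(unique(c(theta, fit$time[fit$time > theta])))
  widths <- diff(knots)
  heights <- surv_after(fit, knots[-length(knots)])
  sum(widths * heights) / surv_after(fit, theta)
}

# term-by-term transcription of the extended variance formula, explicit
# loops over records and Covid events, independent of the package's
# vectorised implementation
oracle_extended_sd <- function(time, d_prime, delta_prime, theta, delta,
                               t_eval) {
  nm <- length(time)
  m <- length(theta)
  q_dir <- local({
    f <- km_fit(surv_sample(time, d_prime), complete = TRUE)
    q <- numeric(nm)
    # map masses back by position: times/status already in canonical order
    stopifnot(all(f$time == time))
    f$q
  })
  q_rev <- local({
    o <- order(time, -(1 - d_prime))
    f <- km_fit(surv_sample(time, 1 - d_prime), complete = TRUE)
    q <- numeric(nm)
    q[o] <- f$q
    q
  })
  Q <- Q2 <- numeric(nm)
  for (j in seq_len(m)) {
    qd <- ifelse(time > theta[j], q_dir, 0)
    qr <- ifelse(time > theta[j], q_rev, 0)
    qd <- qd / sum(qd)
    qr <- qr / sum(qr)
    qs <- delta[j] * qd + (1 - delta[j]) * qr
    Q <- Q + qs
    Q2 <- Q2 + qs^2
  }
  nu <- (1 - delta_prime) + Q
  Rbar <- numeric(nm)
  Rbar[1] <- nm
  for (i in 2:nm) Rbar[i] <- Rbar[i - 1] - 1 + (nu[i - 1] - 1) * d_prime[i - 1]
  hbar <- d_prime * nu / Rbar
  total <- 0
  for (i in seq_len(nm)) {
    if (time[i] > t_eval || hbar[i] >= 1) next
    extra <- max(0, ((Rbar[i] - 1) / Rbar[i]) * Q[i] - Q2[i])
    total <- total + hbar[i] / ((1 - hbar[i]) * Rbar[i]) +
      extra / ((1 - hbar[i])^2 * Rbar[i]^2)
  }
  f <- km_fit(surv_sample(time, d_prime), complete = TRUE)
  surv_after(f, t_eval) * sqrt(total)
}

# shared cache for the expensive N = 2000 simulation runs used by the
# acceptance-level checks (computed once per test session)
.sim_cache <- new.env(parent = emptyenv())
cached_simulation <- function(arm, endpoint, n = 2000, seed = 1) {
  key <- paste(arm, endpoint, n, seed, sep = "_")
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_scenarios(
      ncog(arm)$sample, n,
      scenario_config(truth_endpoint = endpoint), seed = seed)
  }
  .sim_cache[[key]]
}
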