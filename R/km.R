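# Product-limit estimation with per-record at-risk accounting.
#
# The at-risk count decrements by one per record rather than per distinct
# time. With the deaths-before-censorings tie convention this decomposition
# reproduces the classical KM survival curve exactly (the per-record hazard
# factors at a tied death time telescope to the aggregated factor), while
# giving every record its own hazard and death-mass slot -- which is what
# the fractional-death variance machinery needs.

# fast internal core used in the EM and simulation loops: takes raw vectors,
# returns sorted times/statuses and the death-mass distribution.
.km_core <- function(time, status, complete = TRUE) {
  o <- order(time, -status)
  t <- time[o]
  d <- status[o]
  n <- length(t)
  completed <- FALSE
  if (complete && d[n] == 0) {
    d[n] <- 1
    completed <- TRUE
  }
  h <- d / (n:1)
  S <- cumprod(1 - h)
  q <- c(1, S[-n]) - S
  list(time = t, status = d, at_risk = n:1, hazard = h, surv = S, q = q,
       completed = completed, order = o)
}

#' Kaplan-Meier fit with optional distribution completion
#'
#' Fits the product-limit estimator
#' \deqn{\hat S(t) = \prod_{i:\,t_{(i)} \le t} \left(1 - \frac{d_{(i)}}{R(t_{(i)})}\right)}
#' to a right-censored sample, with the at-risk count `R` decrementing by
#' one per record (see the note below) and deaths preceding censorings at
#' tied times.
#'
#' When `complete = TRUE` and the largest observation is censored, the
#' survival distribution is *completed*: the residual survival mass
#' \eqn{Q_{fin} = \hat S(t_{max}^{(D)})} remaining after the last observed
#' death is relocated to the last observed time point \eqn{t_{max}},
#' implemented as treating the status of that single largest record as 1.
#' The input sample is never mutated; the flip is recorded in the fit.
#' Completion makes the fitted death-mass distribution proper
#' (\eqn{\sum_i q_{(i)} = 1}), which is required before life expectancies
#' can be computed. The completed distribution is naturally read as the
#' distribution of the lifetime *within the study*,
#' \eqn{\min\{T_0, t_{max}\}}.
#'
#' @param sample a [surv_sample] with at least one record.
#' @param complete force \eqn{\hat S(t_{max}) = 0} when the largest
#'   observation is censored (default `TRUE`).
#' @return An object of class `km_fit` with per-record components `time`,
#'   `status` (after any completion flip), `at_risk`, `hazard`, `surv`
#'   (\eqn{\hat S(t_{(i)}^+)}, the post-jump value) and `q` (death mass, 0
#'   at censorings), plus `t_max`, `t_max_d` (last uncensored time in the
#'   original data), `completed`, `q_fin` (relocated mass, 0 if not
#'   completed) and `n`.
#' @examples
#' fit <- km_fit(surv_sample(c(1, 2, 3, 4), c(1, 0, 1, 0)))
#' fit$q          # 0.25 0 0.375 0.375 -- residual mass moved to t = 4
#' surv_at(fit, 3)  # pre-jump value 0.75
#' @export
km_fit <- function(sample, complete = TRUE) {
  stopifnot(inherits(sample, "surv_sample"))
  if (nrow(sample) == 0) stop("cannot fit an empty sample", call. = FALSE)
  core <- .km_core(sample$time, sample$status, complete)
  d_orig <- sample$status   # sample rows are already in canonical order
  t_max_d <- if (any(d_orig == 1)) max(sample$time[d_orig == 1]) else NA_real_
  n <- nrow(sample)
  fit <- list(
    time = core$time, status = core$status, at_risk = core$at_risk,
    hazard = core$hazard, surv = core$surv, q = core$q,
    t_max = core$time[n], t_max_d = t_max_d,
    completed = core$completed,
    q_fin = if (core$completed) core$q[n] else 0,
    is_imputed = sample$is_imputed, n = n
  )
  class(fit) <- "km_fit"
  fit
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("Kaplan-Meier fit: %d records, %d death-mass atoms%s\n",
              x$n, sum(x$q > 0),
              if (x$completed)
                sprintf(" (completed: mass %.4f relocated to t=%g)",
                        x$q_fin, x$t_max)
              else ""))
  cat(sprintf("  S(t_max_d=%g) post-jump = %.4f\n", x$t_max_d,
              surv_after(x, x$t_max_d)))
  invisible(x)
}

#' Evaluate the fitted survival step function
#'
#' `surv_at` returns the left-continuous value \eqn{\hat S(t) = P(T \ge t)}:
#' at exactly an event time it returns the pre-jump value. `surv_after`
#' returns the right-continuous (post-jump) value \eqn{\hat S(t^+)}, the
#' product over all records with \eqn{t_{(i)} \le t} as in the product-limit
#' formula.
#'
#' @param fit a [km_fit].
#' @param t numeric vector of evaluation times.
#' @return Numeric vector of survival probabilities.
#' @export
surv_at <- function(fit, t) {
  stopifnot(inherits(fit, "km_fit"))
  idx <- findInterval(t, fit$time, left.open = TRUE)  # records with time < t
  c(1, fit$surv)[idx + 1L]
}

#' @rdname surv_at
#' @export
surv_after <- function(fit, t) {
  stopifnot(inherits(fit, "km_fit"))
  idx <- findInterval(t, fit$time)                    # records with time <= t
  c(1, fit$surv)[idx + 1L]
}

# truncated conditional expectations for a completed death-mass
# distribution, vectorised over theta via tail cumulative sums.
# Returns e_theta = sum_{t_i > theta} (t_i - theta) q_i / sum_{t_i > theta} q_i.
.life_expectancy <- function(time, q, theta) {
  Wq <- rev(cumsum(rev(q)))          # tail mass including record i
  Wtq <- rev(cumsum(rev(time * q)))
  idx <- findInterval(theta, time)   # records with time <= theta (strict truncation)
  den <- c(Wq, 0)[idx + 1L]
  num <- c(Wtq, 0)[idx + 1L] - theta * den
  bad <- den <= .Machine$double.eps * 8
  if (any(bad)) {
    stop(sprintf(
      "no death mass strictly beyond theta = %s: life expectancy undefined",
      paste(theta[bad], collapse = ", ")), call. = FALSE)
  }
  num / den
}

#' Truncated life expectancy from a completed fit
#'
#' The expected future lifetime beyond `theta`,
#' \deqn{\hat e_\theta = \frac{\sum_{t_{(i)} > \theta} (t_{(i)} - \theta)\, q_{(i)}}
#'                            {\sum_{t_{(i)} > \theta} q_{(i)}},}
#' the mean of the renormalised death-mass distribution truncated strictly
#' beyond `theta`. The truncation is strict: mass sitting exactly at
#' `theta` is excluded. Equivalently (for a completed step function)
#' \eqn{\hat e_\theta = \int_\theta^{t_{max}} \hat S(t)\,dt / \hat S(\theta^+)}.
#'
#' @param fit a *completed* [km_fit] (total death mass 1).
#' @param theta numeric vector of non-negative truncation times, each below
#'   the largest death time.
#' @return Numeric vector of life expectancies (days), one per `theta`.
#'   Errors if some `theta` has no death mass strictly beyond it -- the
#'   result would be undefined, never silently 0.
#' @examples
#' fit <- km_fit(surv_sample(c(1, 2, 3, 4), c(1, 0, 1, 0)))
#' life_expectancy(fit, 0)   # 2.875, the mean of the completed distribution
#' @export
life_expectancy <- function(fit, theta) {
  stopifnot(inherits(fit, "km_fit"))
  if (anyNA(theta) || any(theta < 0)) {
    stop("theta must be non-negative", call. = FALSE)
  }
  if (abs(sum(fit$q) - 1) > 1e-8) {
    stop("fit is not completed: total death mass < 1; refit with complete = TRUE",
         call. = FALSE)
  }
  .life_expectancy(fit$time, fit$q, theta)
}

#' Greenwood standard deviation of the survival estimate
#'
#' The classical Greenwood formula
#' \deqn{\mathrm{s.d.}\,\hat S(t) = \hat S(t) \Big[\sum_{i:\,t_{(i)} \le t}
#'   \frac{h_{(i)}}{(1 - h_{(i)})\, R(t_{(i)})}\Big]^{1/2}}
#' evaluated on the per-record decomposition (which agrees exactly with the
#' distinct-time version). Summands with \eqn{h_{(i)} = 1} are set to 0.
#'
#' @param fit a [km_fit].
#' @param t numeric vector of evaluation times.
#' @return Numeric vector of standard deviations of \eqn{\hat S(t^+)}.
#' @export
greenwood_sd <- function(fit, t) {
  stopifnot(inherits(fit, "km_fit"))
  h <- fit$hazard
  term <- ifelse(h == 1, 0, h / ((1 - h) * fit$at_risk))
  csum <- cumsum(term)
  idx <- findInterval(t, fit$time)
  surv_after(fit, t) * sqrt(c(0, csum)[idx + 1L])
}

#' Log-scale confidence interval for a survival probability
#'
#' Bounds computed on the log scale,
#' \eqn{\exp(\log \hat S(t) \pm z\,\mathrm{s.d.}/\hat S(t))}, with `z` the
#' standard normal quantile for `level`, clamped to `[0, 1]`. `S = 0`
#' yields the degenerate interval (0, 0).
#'
#' @param s survival estimate(s) in (0, 1].
#' @param sd standard deviation(s) of the estimate.
#' @param level two-sided confidence level (default 0.95, i.e. z = 1.96).
#' @return A two-column matrix with columns `lower`, `upper`.
#' @export
km_confint <- function(s, sd, level = 0.95) {
  stopifnot(all(s >= 0 & s <= 1), all(sd >= 0), level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  lower <- upper <- numeric(length(s))
  pos <- s > 0
  lower[pos] <- pmin(1, pmax(0, exp(log(s[pos]) - z * sd[pos] / s[pos])))
  upper[pos] <- pmin(1, pmax(0, exp(log(s[pos]) + z * sd[pos] / s[pos])))
  cbind(lower = lower, upper = upper)
}

#' Export the fitted step function
#'
#' Writes (or returns) the survival step function as a two-column table of
#' post-jump values at each record time, consumable by any plotting tool.
#'
#' @param fit a [km_fit].
#' @param path optional CSV path; if `NULL` the data frame is returned.
#' @return A data frame with columns `time`, `surv` (invisibly if written).
#' @export
surv_steps <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "km_fit"))
  df <- data.frame(time = c(0, fit$time), surv = c(1, fit$surv))
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    return(invisible(df))
  }
  df
}
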