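# Adjustment for censoring: relaxing the assumption that every Covid death
# would have ended in a death of disease.
#
# The CoDMI iteration imputes every virtual lifetime with status 1. If the
# virtual endpoint would instead have been a censoring, the appropriate
# conditional expectation comes from the distribution of censoring times --
# estimated by the reverse Kaplan-Meier curve (all status indicators
# flipped). The choice between the direct and reverse imputation for each
# Covid death is driven by alpha(theta_j), the estimated probability that
# an event at that time is a death of disease rather than a censoring,
# computed from hazard-rate curves for deaths and censorings fitted on a
# common time grid.

#' Reverse-KM virtual lifetimes
#'
#' Flips every status of the imputed sample \eqn{\hat w} (observed and
#' imputed times fixed), fits the completed Kaplan-Meier estimator to the
#' reversed sample, and returns the alternative lifetimes
#' \eqn{\hat\tau_j^{(R)} = \theta_j + \hat e^{(R)}_{\theta_j}} computed on
#' the reverse death-mass (i.e. censoring-time) distribution.
#'
#' @param imputed a [surv_sample] as produced by [codmi()]
#'   (`$imputed_sample`), or a `codmi_fit`.
#' @param covid_times the Covid-death times \eqn{\theta_j}.
#' @return Numeric vector \eqn{\hat\tau_j^{(R)}}.
#' @examples
#' arm_a <- ncog("arm_a")
#' fit <- codmi(arm_a$sample, arm_a$covid_times,
#'              codmi_control(tolerance = 0.1, init = "at_theta"))
#' round(reverse_km_lifetimes(fit, arm_a$covid_times), 2)
#' # 1207.49 1296.23 1347.78 1347.78 1398.13
#' @export
reverse_km_lifetimes <- function(imputed, covid_times) {
  if (inherits(imputed, "codmi_fit")) imputed <- imputed$imputed_sample
  stopifnot(inherits(imputed, "surv_sample"))
  covid_times <- as.numeric(covid_times)
  if (length(covid_times) == 0) return(numeric(0))
  rev_fit <- km_fit(reverse_sample(imputed), complete = TRUE)
  covid_times + life_expectancy(rev_fit, covid_times)
}

#' Per-cell hazard rates on a time grid
#'
#' Partitions \eqn{[0, t_{max}]} into `n_cells` equal-width cells, computes
#' the empirical hazard in each cell as events divided by person-time at
#' risk, and fits a parametric hazard curve through the cells. The default
#' fit is a piecewise-exponential Poisson regression (cell event counts
#' with log person-time offset and the family's log-hazard shape as linear
#' predictor), which handles zero-event cells gracefully;
#' `fit = "wls"` selects exposure-weighted least squares on the empirical
#' cell hazards instead. Cells with no exposure are excluded from the fit
#' but still receive a fitted value from the parametric curve.
#'
#' Families (hazard shapes): `weibull` \eqn{h(t) = a b t^{b-1}} (log-linear
#' in \eqn{\log t}), `gompertz` \eqn{h(t) = a e^{b t}} (log-linear in `t`),
#' `exponential` \eqn{h(t) = a} (constant; the fit recovers total events /
#' total person-time exactly).
#'
#' @param sample a [surv_sample]; events are its status-1 records.
#' @param n_cells number of grid cells G (>= 2).
#' @param family hazard family: `"weibull"`, `"gompertz"` or
#'   `"exponential"`.
#' @param fit `"poisson"` (default) or `"wls"`.
#' @return A list of class `hazard_grid`: `edges` (G+1 cell boundaries),
#'   `mid` (cell midpoints), `events`, `exposure`, `empirical` (per-cell
#'   events/person-time, `NA` where no exposure), `fitted` (parametric
#'   hazard at cell midpoints, all >= 0), `family`, `hazard_fun` (the
#'   fitted curve as a function of time).
#' @export
grid_hazard <- function(sample, n_cells = 6,
                        family = c("weibull", "gompertz", "exponential"),
                        fit = c("poisson", "wls")) {
  stopifnot(inherits(sample, "surv_sample"), n_cells >= 2)
  family <- match.arg(family)
  fit <- match.arg(fit)
  t_max <- max(sample$time)
  if (t_max <= 0) stop("sample must span positive time", call. = FALSE)
  edges <- seq(0, t_max, length.out = n_cells + 1)
  mid <- (edges[-1] + edges[-(n_cells + 1)]) / 2
  events <- exposure <- numeric(n_cells)
  for (l in seq_len(n_cells)) {
    lo <- edges[l]; hi <- edges[l + 1]
    exposure[l] <- sum(pmax(0, pmin(sample$time, hi) - lo))
    hi_inc <- if (l == n_cells) hi + 1e-9 else hi  # last cell closed at t_max
    events[l] <- sum(sample$status == 1 & sample$time > lo & sample$time <= hi_inc)
  }
  empirical <- ifelse(exposure > 0, events / exposure, NA_real_)
  if (sum(events) == 0) {
    warning("no events in the sample; fitted hazards are all zero")
    hfun <- function(t) rep(0, length(t))
    fitted <- rep(0, n_cells)
  } else {
    xfun <- switch(family,
      weibull = function(t) log(t),
      gompertz = function(t) t,
      exponential = function(t) rep(0, length(t))
    )
    ok <- exposure > 0
    x <- xfun(mid)
    if (fit == "poisson") {
      if (family == "exponential") {
        gfit <- stats::glm(events[ok] ~ 1 + offset(log(exposure[ok])),
                           family = stats::poisson())
      } else {
        gfit <- stats::glm(events[ok] ~ x[ok] + offset(log(exposure[ok])),
                           family = stats::poisson())
      }
      p <- stats::coef(gfit)
      if (length(p) == 1) p <- c(p, 0)
    } else {
      pos <- ok & empirical > 0
      if (family == "exponential") {
        p <- c(log(sum(events) / sum(exposure)), 0)
      } else {
        p0 <- stats::coef(stats::lm(log(empirical[pos]) ~ x[pos],
                                    weights = exposure[pos]))
        obj <- function(p) {
          sum(exposure[ok] * (exp(p[1] + p[2] * x[ok]) - empirical[ok])^2)
        }
        p <- stats::optim(p0, obj)$par
      }
    }
    hfun <- function(t) exp(p[1] + p[2] * xfun(t))
    fitted <- hfun(mid)
  }
  structure(list(edges = edges, mid = mid, events = events,
                 exposure = exposure, empirical = empirical, fitted = fitted,
                 family = family, hazard_fun = hfun),
            class = "hazard_grid")
}

#' Non-censoring probability curve alpha(t)
#'
#' Estimates, per grid cell, the probability that an event observed at time
#' `t` is a death of disease rather than a censoring:
#' \eqn{\hat\alpha(t) = \hat h_{l(t)} / (\hat h_{l(t)} + \hat h^{(R)}_{l(t)})},
#' where \eqn{\hat h} is the hazard curve fitted to the standard
#' observations and \eqn{\hat h^{(R)}} the one fitted to the same
#' observations with statuses reversed, both on the same grid, and `l(t)`
#' is the cell containing `t`. The curve is piecewise constant per cell
#' (both hazards evaluated at the cell midpoint). Cells where both hazards
#' vanish get \eqn{\hat\alpha = 0.5} (reported via a message).
#'
#' alpha is fitted on the standard (non-imputed) observations only.
#'
#' @param sample the standard observations `z` as a [surv_sample].
#' @inheritParams grid_hazard
#' @return A list of class `alpha_curve`: `edges`, `alpha` (per cell, in
#'   `[0, 1]`), the two `hazard_grid` objects (`direct`, `reverse`), and
#'   `at(t)` -- a function evaluating the curve at arbitrary times.
#' @examples
#' ac <- alpha_curve(ncog("arm_a")$sample)
#' ac$at(c(250, 1250))   # first >= 0.5, last < 0.5
#' @export
alpha_curve <- function(sample, n_cells = 6,
                        family = c("weibull", "gompertz", "exponential"),
                        fit = c("poisson", "wls")) {
  family <- match.arg(family)
  fit <- match.arg(fit)
  direct <- grid_hazard(sample, n_cells, family, fit)
  reverse <- grid_hazard(reverse_sample(sample), n_cells, family, fit)
  hd <- direct$fitted
  hr <- reverse$fitted
  alpha <- rep(0.5, n_cells)
  pos <- (hd + hr) > 0
  alpha[pos] <- hd[pos] / (hd[pos] + hr[pos])
  if (any(!pos)) {
    message(sprintf(
      "alpha_curve: both hazards are zero in %d cell(s); alpha set to 0.5 there",
      sum(!pos)))
  }
  edges <- direct$edges
  at <- function(t) {
    cell <- pmin(pmax(findInterval(t, edges, rightmost.closed = TRUE), 1L),
                 n_cells)
    alpha[cell]
  }
  structure(list(edges = edges, alpha = alpha, direct = direct,
                 reverse = reverse, at = at),
            class = "alpha_curve")
}

#' @export
print.alpha_curve <- function(x, ...) {
  cat(sprintf("alpha(t) curve: %d cells over [0, %g], family %s\n",
              length(x$alpha), max(x$edges), x$direct$family))
  print(data.frame(from = x$edges[-length(x$edges)], to = x$edges[-1],
                   alpha = round(x$alpha, 4)))
  invisible(x)
}

#' Select direct or reverse imputations per Covid death
#'
#' Applies the selection rule
#' \eqn{\hat\tau^*_j = \hat\tau_j} (status \eqn{\delta_j = 1}) if
#' \eqn{\alpha(\theta_j) \ge 0.5}, else \eqn{\hat\tau^{(R)}_j}
#' (\eqn{\delta_j = 0}); the boundary 0.5 selects the direct estimate.
#' Expert overrides take precedence: `overrides` is a named list/vector
#' mapping the Covid-death index `j` to a forced `delta` (0 or 1), and
#' records so decided carry `source = "override"`.
#'
#' @param tau_direct CoDMI virtual lifetimes \eqn{\hat\tau_j}.
#' @param tau_reverse reverse-KM lifetimes \eqn{\hat\tau^{(R)}_j}
#'   ([reverse_km_lifetimes()]).
#' @param alpha_at_theta \eqn{\alpha(\theta_j)} values, same length.
#' @param covid_times the \eqn{\theta_j} (used for validation and carried
#'   through).
#' @param overrides optional named numeric vector of forced deltas, names
#'   are indices `j`.
#' @return A list of class `codmi_adjustment`: `tau_star`, `delta`,
#'   `alpha_at_theta`, `source` (`"direct"`, `"reverse"` or `"override"`),
#'   `theta`.
#' @export
adjust_for_censoring <- function(tau_direct, tau_reverse, alpha_at_theta,
                                 covid_times, overrides = NULL) {
  m <- length(tau_direct)
  stopifnot(length(tau_reverse) == m, length(alpha_at_theta) == m,
            length(covid_times) == m)
  use_direct <- alpha_at_theta >= 0.5
  tau_star <- ifelse(use_direct, tau_direct, tau_reverse)
  delta <- as.numeric(use_direct)
  source <- ifelse(use_direct, "direct", "reverse")
  if (!is.null(overrides) && length(overrides)) {
    j <- as.integer(names(overrides))
    if (anyNA(j) || any(j < 1) || any(j > m)) {
      stop("override index out of range", call. = FALSE)
    }
    forced <- as.numeric(overrides)
    if (!all(forced %in% c(0, 1))) {
      stop("override delta must be 0 or 1", call. = FALSE)
    }
    delta[j] <- forced
    tau_star[j] <- ifelse(forced == 1, tau_direct[j], tau_reverse[j])
    source[j] <- "override"
  }
  if (any(tau_star <= covid_times)) {
    stop("adjusted lifetime not beyond its Covid-death time", call. = FALSE)
  }
  structure(list(tau_star = tau_star, delta = delta,
                 alpha_at_theta = alpha_at_theta, source = source,
                 theta = covid_times),
            class = "codmi_adjustment")
}

#' @export
print.codmi_adjustment <- function(x, ...) {
  print(data.frame(theta = x$theta, alpha = round(x$alpha_at_theta, 4),
                   tau_star = round(x$tau_star, 2), delta = x$delta,
                   source = x$source))
  invisible(x)
}
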