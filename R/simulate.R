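# Monte-Carlo evaluation of the mean-imputation estimator.
#
# Each scenario resamples a seed data set into pseudo standard observations,
# plants Covid-death times by uniform thinning of resampled death times,
# constructs "true" virtual lifetimes consistently with the estimator's own
# probabilistic structure (iterated KM refits, then conditional sampling
# from the truncated distribution), and measures the prediction error of
# the CoDMI life-expectancy estimate against that truth, alongside the two
# naive estimators (Covid deaths counted as disease deaths, or as
# censorings).

#' Scenario configuration for the simulation study
#'
#' Defaults reproduce the reference study conditions: 100 standard
#' observations per scenario, 10 Covid deaths, CoDMI tolerance 1 day with
#' at most 100 iterations and the theta-plus-expectancy initialisation,
#' and 10 truth-construction iterations.
#'
#' @param n_sim standard records per scenario.
#' @param m_sim Covid deaths per scenario.
#' @param n_iter truth-construction iterations before the final conditional
#'   sampling.
#' @param tolerance,max_iter,init CoDMI settings (see [codmi_control()]).
#' @param truth_endpoint `"death"`: true virtual lifetimes end in a death
#'   of disease (delta = 1) and are drawn from the truncated direct
#'   distribution. `"censored"`: all true endpoints are censorings
#'   (delta = 0), truth is drawn from the truncated *reverse* distribution,
#'   and the CoDMI estimate is reported both without and with the
#'   adjustment for censoring (all alpha(theta_j) forced to 0: the EM is
#'   re-run with every expectation read from the reverse distribution,
#'   see the `delta` argument of [codmi()]).
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_sim = 100, m_sim = 10, n_iter = 10,
                            tolerance = 1, max_iter = 100,
                            init = "theta_plus_expectancy",
                            truth_endpoint = c("death", "censored")) {
  stopifnot(n_sim >= 1, m_sim >= 0, n_iter >= 1, tolerance > 0, max_iter >= 1)
  structure(list(n_sim = as.integer(n_sim), m_sim = as.integer(m_sim),
                 n_iter = as.integer(n_iter), tolerance = tolerance,
                 max_iter = as.integer(max_iter), init = init,
                 truth_endpoint = match.arg(truth_endpoint)),
            class = "scenario_config")
}

#' Stratified bootstrap of standard observations
#'
#' Draws `n_sim` records with replacement from the seed data, keeping the
#' death/censoring proportion: `round(n_sim * deaths/n)` records come from
#' the seed deaths, the remainder from the seed censorings. A seed with no
#' censorings (or no deaths) degenerates gracefully to resampling from the
#' one stratum present.
#'
#' @param seed_data a [surv_sample].
#' @param n_sim number of records to draw (>= 1).
#' @return A [surv_sample] of `n_sim` records. Uses the current RNG state.
#' @export
simulate_standard_data <- function(seed_data, n_sim) {
  stopifnot(inherits(seed_data, "surv_sample"))
  if (n_sim < 1) stop("n_sim must be >= 1", call. = FALSE)
  td <- seed_data$time[seed_data$status == 1]
  tc <- seed_data$time[seed_data$status == 0]
  k_d <- round(n_sim * length(td) / nrow(seed_data))
  if (length(td) == 0) k_d <- 0
  if (length(tc) == 0) k_d <- n_sim
  k_c <- n_sim - k_d
  surv_sample(
    c(td[sample.int(length(td), k_d, replace = TRUE)],
      tc[sample.int(length(tc), k_c, replace = TRUE)]),
    c(rep(1, k_d), rep(0, k_c))
  )
}

#' Simulate Covid-death time points by uniform thinning
#'
#' Draws `m_sim` temporary virtual lifetimes \eqn{\tilde\tau^{(0)}_j} with
#' replacement from the seed death times not exceeding
#' `t_max_d` (the largest uncensored time of the resampled data), and
#' thins each uniformly: \eqn{\tilde\theta_j = \tilde u_j \tilde\tau^{(0)}_j}
#' with \eqn{\tilde u_j \sim U(0,1)}, so \eqn{0 < \tilde\theta_j <
#' \tilde\tau^{(0)}_j \le \tilde t_{max}^{(D)}}.
#'
#' @param seed_data the real seed [surv_sample] (source of death times).
#' @param t_max_d upper bound for eligible death times.
#' @param m_sim number of Covid deaths.
#' @return A list with `tau0` and `theta`, each of length `m_sim`.
#' @export
simulate_doc_times <- function(seed_data, t_max_d, m_sim) {
  stopifnot(inherits(seed_data, "surv_sample"))
  if (m_sim == 0) return(list(tau0 = numeric(0), theta = numeric(0)))
  eligible <- seed_data$time[seed_data$status == 1 & seed_data$time <= t_max_d]
  if (length(eligible) == 0) {
    stop("no eligible death time at or below t_max_d", call. = FALSE)
  }
  tau0 <- eligible[sample.int(length(eligible), m_sim, replace = TRUE)]
  theta <- stats::runif(m_sim) * tau0
  list(tau0 = tau0, theta = theta)
}

# death-mass distribution of z + imputed deaths, direct or reverse
.truth_mass <- function(z_time, z_status, tau, endpoint) {
  t <- c(z_time, tau)
  d <- c(z_status, rep(1, length(tau)))
  if (endpoint == "censored") d <- 1 - d
  .km_core(t, d, complete = TRUE)
}

#' Construct true virtual lifetimes for one scenario
#'
#' Iterates `n_iter` times: fit the completed KM estimator (direct, or
#' reverse for the censored-endpoint regime) to
#' \eqn{\tilde z \cup \{(\tilde\tau_j, 1)\}} and replace each
#' \eqn{\tilde\tau_j} by the conditional expectation beyond
#' \eqn{\tilde\theta_j}. After the iterations, the definitive
#' \eqn{\tilde\tau_j} are drawn by conditional sampling from the
#' normalised truncated distribution of the final fit. If some
#' \eqn{\tilde\theta_j} ends up with empty truncation support (extreme
#' pseudo-data), its uniform \eqn{\tilde u_j} is redrawn (up to
#' `max_redraws` times in total) before the scenario is abandoned.
#'
#' @param z_tilde resampled standard observations ([surv_sample]).
#' @param theta,tau0 output of [simulate_doc_times()].
#' @param n_iter number of self-consistency iterations.
#' @param endpoint `"death"` or `"censored"`.
#' @param max_redraws total redraw budget for degenerate support.
#' @return A list with `tau` (sampled true lifetimes), `theta` (possibly
#'   redrawn), `e_true = tau - theta`.
#' @export
generate_truth <- function(z_tilde, theta, tau0, n_iter,
                           endpoint = c("death", "censored"),
                           max_redraws = 100) {
  endpoint <- match.arg(endpoint)
  m <- length(theta)
  if (m == 0) return(list(tau = numeric(0), theta = theta, e_true = numeric(0)))
  zt <- z_tilde$time; zs <- z_tilde$status
  redraws <- 0L
  # support check + redraw helper: mass strictly beyond each theta_j
  ensure_support <- function(core, theta) {
    repeat {
      Wq <- rev(cumsum(rev(core$q)))
      idx <- findInterval(theta, core$time)
      den <- c(Wq, 0)[idx + 1L]
      bad <- which(den <= .Machine$double.eps * 8)
      if (length(bad) == 0) return(theta)
      if (redraws + length(bad) > max_redraws) {
        stop("degenerate scenario: truncation support empty after redraws",
             call. = FALSE)
      }
      redraws <<- redraws + length(bad)
      theta[bad] <- stats::runif(length(bad)) * tau0[bad]
    }
  }
  tau <- tau0
  for (k in seq_len(n_iter)) {
    core <- .truth_mass(zt, zs, tau, endpoint)
    theta <- ensure_support(core, theta)
    tau <- theta + .life_expectancy(core$time, core$q, theta)
  }
  core <- .truth_mass(zt, zs, tau, endpoint)
  theta <- ensure_support(core, theta)
  tau_final <- numeric(m)
  for (j in seq_len(m)) {
    keep <- core$time > theta[j] & core$q > 0
    idx <- which(keep)
    tau_final[j] <- if (length(idx) == 1) core$time[idx]
                    else core$time[sample(idx, 1, prob = core$q[idx])]
  }
  if (redraws > 0) {
    attr(theta, "redraws") <- redraws
  }
  list(tau = tau_final, theta = as.numeric(theta), e_true = tau_final - as.numeric(theta))
}

# naive life expectancies: Covid deaths counted as deaths (delta = 1) or
# censorings (delta = 0); NA where the truncated mean is undefined
.naive_expectancy <- function(z_time, z_status, theta, delta) {
  t <- c(z_time, theta)
  d <- c(z_status, rep(delta, length(theta)))
  core <- .km_core(t, d, complete = TRUE)
  out <- rep(NA_real_, length(theta))
  ok <- tryCatch({
    out <- .life_expectancy(core$time, core$q, theta)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    for (j in seq_along(theta)) {
      out[j] <- tryCatch(.life_expectancy(core$time, core$q, theta[j]),
                         error = function(e) NA_real_)
    }
  }
  out
}

#' Run one simulated scenario
#'
#' Executes the full scenario pipeline: stratified bootstrap, Covid-time
#' thinning, truth construction, CoDMI estimation, and the two naive
#' estimators. A scenario where CoDMI fails to converge (or any stage
#' degenerates) is returned with `converged = FALSE` and carries no CoDMI
#' estimates; it never aborts a batch.
#'
#' @param config a [scenario_config()].
#' @param seed_data the real seed [surv_sample].
#' @return A list of class `scenario_result` with `theta`, `e_true`,
#'   `e_codmi`, `e_codmi_adj` (censored regime only, else `NA`),
#'   `e_naive_dod`, `e_naive_cen`, `converged`.
#' @export
run_scenario <- function(config, seed_data) {
  stopifnot(inherits(config, "scenario_config"))
  m <- config$m_sim
  empty <- structure(list(
    theta = numeric(0), e_true = numeric(0), e_codmi = numeric(0),
    e_codmi_adj = numeric(0), e_naive_dod = numeric(0),
    e_naive_cen = numeric(0), converged = TRUE
  ), class = "scenario_result")
  tryCatch({
    z <- simulate_standard_data(seed_data, config$n_sim)
    if (m == 0) return(empty)
    t_max_d <- max(z$time[z$status == 1], -Inf)
    if (!is.finite(t_max_d)) stop("resampled data contain no death")
    doc <- simulate_doc_times(seed_data, t_max_d, m)
    truth <- generate_truth(z, doc$theta, doc$tau0, config$n_iter,
                            config$truth_endpoint)
    theta <- truth$theta
    ctrl <- codmi_control(tolerance = config$tolerance,
                          max_iter = config$max_iter, init = config$init)
    fit <- codmi(z, theta, ctrl)
    converged <- fit$status %in% c("converged", "cycle_accepted")
    e_codmi <- if (converged) fit$e_hat else rep(NA_real_, m)
    e_adj <- rep(NA_real_, m)
    if (config$truth_endpoint == "censored") {
      # adjustment for censoring with all alpha(theta_j) forced to 0:
      # every expectation is read from the reverse (censoring-time)
      # distribution inside the EM loop (delta = 0 for every imputation)
      fit_adj <- codmi(z, theta, ctrl, delta = rep(0, m))
      adj_ok <- fit_adj$status %in% c("converged", "cycle_accepted")
      converged <- converged && adj_ok
      if (adj_ok) e_adj <- fit_adj$e_hat
      if (!converged) e_codmi <- rep(NA_real_, m)
    }
    structure(list(
      theta = theta, e_true = truth$e_true, e_codmi = e_codmi,
      e_codmi_adj = e_adj,
      e_naive_dod = .naive_expectancy(z$time, z$status, theta, 1),
      e_naive_cen = .naive_expectancy(z$time, z$status, theta, 0),
      converged = converged
    ), class = "scenario_result")
  }, error = function(e) {
    structure(list(
      theta = rep(NA_real_, m), e_true = rep(NA_real_, m),
      e_codmi = rep(NA_real_, m), e_codmi_adj = rep(NA_real_, m),
      e_naive_dod = rep(NA_real_, m), e_naive_cen = rep(NA_real_, m),
      converged = FALSE
    ), class = "scenario_result")
  })
}

#' Run a batch of simulated scenarios
#'
#' Runs `n_scenarios` scenarios with a deterministic per-scenario RNG
#' substream derived from `seed`, so batches are reproducible and could be
#' split across workers without changing results.
#'
#' @param seed_data the real seed [surv_sample] (or a `codmi_dataset`).
#' @param n_scenarios number of scenarios N.
#' @param config a [scenario_config()].
#' @param seed integer RNG seed for the batch.
#' @return A list of class `codmi_simulation` with `results` (list of
#'   [run_scenario()] outputs), `config` and `summary`
#'   (see [summarize_scenarios()]).
#' @export
simulate_scenarios <- function(seed_data, n_scenarios,
                               config = scenario_config(), seed = 1) {
  if (inherits(seed_data, "codmi_dataset")) seed_data <- seed_data$sample
  stopifnot(inherits(seed_data, "surv_sample"), n_scenarios >= 1)
  results <- vector("list", n_scenarios)
  for (k in seq_len(n_scenarios)) {
    set.seed((as.integer(seed) + 7919L * k) %% 2147483647L)
    results[[k]] <- run_scenario(config, seed_data)
  }
  out <- list(results = results, config = config,
              summary = summarize_scenarios(results))
  class(out) <- "codmi_simulation"
  out
}

# column-binds a field across scenario results into an N x m matrix
.field_matrix <- function(results, field, m) {
  do.call(rbind, lapply(results, function(r) {
    v <- r[[field]]
    if (length(v) != m) rep(NA_real_, m) else v
  }))
}

#' Summarise a batch of scenario results
#'
#' Per Covid-death slot `j` and overall, over the convergent scenarios
#' only: means of \eqn{\tilde\theta_j}, \eqn{\tilde e_j}, \eqn{\hat e_j};
#' the mean prediction error \eqn{\bar\Delta_j = \bar{\tilde e}_j -
#' \bar{\hat e}_j}; its standard error (sample sd of the per-scenario
#' errors divided by \eqn{\sqrt{N_c}}); the relative error
#' \eqn{\bar\Delta_j / \bar{\tilde e}_j}; and min/max of the per-scenario
#' errors. The overall block aggregates over `j` (the overall s.e.m. uses
#' the per-scenario mean error across slots) and reports the same overall
#' statistics for the two naive estimators, and -- when present -- for the
#' censoring-adjusted CoDMI estimate.
#'
#' @param results list of [run_scenario()] outputs (at least one
#'   convergent).
#' @return A list of class `simulation_summary`: `per_j` (data frame),
#'   `overall` (data frame, one row per estimator), `n_convergent`, `n`.
#' @export
summarize_scenarios <- function(results) {
  conv <- vapply(results, function(r) isTRUE(r$converged), logical(1))
  n_c <- sum(conv)
  if (n_c == 0) stop("no convergent scenario to summarise", call. = FALSE)
  m <- max(vapply(results, function(r) length(r$theta), integer(1)))
  if (m == 0) {
    return(structure(list(per_j = data.frame(), overall = data.frame(),
                          n_convergent = n_c, n = length(results)),
                     class = "simulation_summary"))
  }
  res <- results[conv]
  th <- .field_matrix(res, "theta", m)
  et <- .field_matrix(res, "e_true", m)
  blocks <- list(codmi = "e_codmi", naive_dod = "e_naive_dod",
                 naive_cen = "e_naive_cen", codmi_adj = "e_codmi_adj")
  deltas <- lapply(blocks, function(f) et - .field_matrix(res, f, m))
  d <- deltas$codmi
  per_j <- data.frame(
    j = seq_len(m),
    theta_mean = colMeans(th),
    e_true_mean = colMeans(et),
    e_codmi_mean = colMeans(et - d),
    error_mean = colMeans(d),
    error_rel = colMeans(d) / colMeans(et),
    sem = apply(d, 2, stats::sd) / sqrt(n_c),
    min = apply(d, 2, min),
    max = apply(d, 2, max)
  )
  overall_row <- function(dd) {
    scen_mean <- rowMeans(dd)
    keep <- !is.na(scen_mean)
    data.frame(
      error_mean = mean(dd, na.rm = TRUE),
      error_rel = mean(dd, na.rm = TRUE) / mean(et[keep, ]),
      sem = stats::sd(scen_mean[keep]) / sqrt(sum(keep))
    )
  }
  has_adj <- any(!is.na(deltas$codmi_adj))
  use <- c("codmi", "naive_dod", "naive_cen", if (has_adj) "codmi_adj")
  overall <- do.call(rbind, lapply(deltas[use], overall_row))
  overall <- cbind(estimator = use, theta_mean = mean(th),
                   e_true_mean = mean(et), overall)
  rownames(overall) <- NULL
  structure(list(per_j = per_j, overall = overall,
                 n_convergent = n_c, n = length(results)),
            class = "simulation_summary")
}

#' @export
print.simulation_summary <- function(x, ...) {
  cat(sprintf("Simulation summary: %d/%d convergent scenarios\n",
              x$n_convergent, x$n))
  if (nrow(x$overall)) {
    ov <- x$overall
    ov$error_rel <- sprintf("%.2f%%", 100 * ov$error_rel)
    print(ov, digits = 4)
  }
  invisible(x)
}

#' @export
print.codmi_simulation <- function(x, ...) {
  print(x$summary)
  invisible(x)
}
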