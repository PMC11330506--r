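#' Baseline epidemic model parameters
#'
#' Parameter container for the comparison models: SI, SIR, SIS (each with an
#' infection rate `beta` and, where applicable, a recovery/return rate
#' `gamma`) and SEDIS (a four-compartment
#' Susceptible-Exposed-Doubtful-Infected model with its own seven rates).
#' The SI/SIR/SIS infection term is constant-hazard (linear, proportional
#' to S alone) by default; a mass-action toggle (`beta * S * I / N`) is
#' available for contrast but is not the form under which the comparison
#' table is computed.
#'
#' @param model one of `"SI"`, `"SIR"`, `"SIS"`, `"SEDIS"`.
#' @param beta infection rate (ignored for SEDIS).
#' @param gamma recovery/return rate (ignored for SI and SEDIS).
#' @param sedis_rates named list/vector with `alpha, beta1, beta2, gamma,
#'   mu1, mu2, mu3` (SEDIS only).
#' @param mass_action logical; use mass-action infection for SI/SIR/SIS.
#' @return object of class `baseline_params`.
#' @export
baseline_params <- function(model = c("SI", "SIR", "SIS", "SEDIS"),
                            beta = 0, gamma = 0, sedis_rates = NULL,
                            mass_action = FALSE) {
  model <- match.arg(model)
  if (model == "SEDIS") {
    need <- c("alpha", "beta1", "beta2", "gamma", "mu1", "mu2", "mu3")
    if (is.null(sedis_rates) || !all(need %in% names(sedis_rates)))
      stop("SEDIS requires sedis_rates with: ", paste(need, collapse = ", "))
    sedis_rates <- as.list(sedis_rates)[need]
    if (any(unlist(sedis_rates) < 0)) stop("SEDIS rates must be >= 0")
  }
  if (beta < 0 || gamma < 0) stop("rates must be >= 0")
  structure(list(model = model, beta = beta, gamma = gamma,
                 sedis_rates = sedis_rates, mass_action = mass_action),
            class = "baseline_params")
}

baseline_dim <- function(model) {
  switch(model, SI = 2L, SIS = 2L, SIR = 3L, SEDIS = 4L)
}

baseline_state_names <- function(model) {
  switch(model, SI = c("S", "I"), SIS = c("S", "I"),
         SIR = c("S", "I", "R"), SEDIS = c("S", "E", "D", "I"))
}

#' Baseline model right-hand side
#'
#' Derivatives for the comparison models. Constant-hazard (default):
#' SI `dS = -beta S`; SIR adds `dR = gamma I`; SIS returns recoveries to S.
#' SEDIS: `dS = mu1 E + mu2 D + mu3 I - alpha S`,
#' `dE = alpha S - (beta1 + beta2 + mu1) E`,
#' `dD = beta1 E - (gamma + mu2) D`, `dI = gamma D + beta2 E - mu3 I`.
#' Component sums are zero for every model (mass conservation).
#'
#' @param state numeric state vector, dimension matching the model
#'   (SI/SIS: 2, SIR: 3, SEDIS: 4).
#' @param params a [baseline_params].
#' @return named numeric derivative vector.
#' @export
baseline_rhs <- function(state, params) {
  model <- params$model
  if (length(state) != baseline_dim(model))
    stop(model, " state must have dimension ", baseline_dim(model))
  x <- unname(unlist(state))
  b <- params$beta; g <- params$gamma
  inf <- if (isTRUE(params$mass_action)) b * x[1L] * x[2L] / sum(x)
         else b * x[1L]
  d <- switch(model,
    SI  = c(-inf, inf),
    SIS = c(-inf + g * x[2L], inf - g * x[2L]),
    SIR = c(-inf, inf - g * x[2L], g * x[2L]),
    SEDIS = with(params$sedis_rates, {
      S <- x[1L]; E <- x[2L]; D <- x[3L]; I <- x[4L]
      c(mu1 * E + mu2 * D + mu3 * I - alpha * S,
        alpha * S - (beta1 + beta2 + mu1) * E,
        beta1 * E - (gamma + mu2) * D,
        gamma * D + beta2 * E - mu3 * I)
    }))
  stats::setNames(d, baseline_state_names(model))
}

#' Run a baseline model
#'
#' Adaptive integration sampled at integer days, with a summary of the
#' susceptible and infected counts at days 0, 10 and 100 (where within the
#' horizon) and the peak infected count, rounded to the nearest integer.
#'
#' @param params a [baseline_params].
#' @param init non-negative numeric initial state (dimension per model).
#' @param t_end horizon in days.
#' @return list with `trajectory` (data.frame `time` + compartments) and
#'   `summary` (list: `model`, `S_day`/`I_day` named vectors at reported
#'   days, `peak_infection`, `peak_day`).
#' @examples
#' run_baseline(baseline_params("SIR", beta = 0.1, gamma = 0.035),
#'              init = c(S = 299990, I = 10, R = 0), t_end = 100)$summary
#' @export
run_baseline <- function(params, init, t_end) {
  x0 <- unname(unlist(init))
  if (any(x0 < 0)) stop("init must be non-negative")
  if (length(x0) != baseline_dim(params$model))
    stop("init dimension must be ", baseline_dim(params$model),
         " for ", params$model)
  times <- 0:as.integer(t_end)
  out <- deSolve::ode(y = x0, times = times,
                      func = function(t, y, p) list(baseline_rhs(y, p)),
                      parms = params, method = "lsoda",
                      rtol = 1e-10, atol = 1e-8)
  traj <- data.frame(out)
  names(traj) <- c("time", baseline_state_names(params$model))
  report_days <- intersect(c(0, 10, 100), times)
  icol <- traj$I
  pk <- which.max(icol)
  summary <- list(
    model = params$model,
    S_day = stats::setNames(round(traj$S[traj$time %in% report_days]),
                            report_days),
    I_day = stats::setNames(round(icol[traj$time %in% report_days]),
                            report_days),
    peak_infection = round(max(icol)),
    peak_day = traj$time[pk])
  list(trajectory = traj, summary = summary)
}

#' Comparison table across baseline runs
#'
#' Assembles the day-0/10/100 susceptible and infected counts and peak
#' infection for a set of model runs into one table (the layout of the
#' published cross-model comparison).
#'
#' @param runs list of results from [run_baseline] (or of their `summary`
#'   elements). Runs must share the same population and horizon.
#' @return data.frame with columns `model, day, S, I, peak_infection`.
#' @export
comparison_table <- function(runs) {
  summaries <- lapply(runs, function(r)
    if (!is.null(r$summary)) r$summary else r)
  pops <- vapply(runs, function(r) {
    tr <- r$trajectory
    if (is.null(tr)) NA_real_ else sum(tr[1L, -1L])
  }, numeric(1))
  if (length(unique(round(stats::na.omit(pops)))) > 1L)
    stop("runs must share the same total population")
  do.call(rbind, lapply(summaries, function(s) {
    days <- as.integer(names(s$S_day))
    data.frame(model = s$model, day = days,
               S = unname(s$S_day), I = unname(s$I_day),
               peak_infection = s$peak_infection)
  }))
}
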