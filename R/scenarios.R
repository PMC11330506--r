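#' Distrust-extension parameters
#'
#' Extends the SEDPNR rates with a distrustful compartment V fed from S at
#' rate `nu` and decaying at rate `tau`; `tau` doubles as the fraction by
#' which distrust attenuates the exposure-driven infection terms (the
#' `(1 - tau) * v * e` products), so it must lie in \[0, 1\].
#'
#' @param base a [sedpnr_params].
#' @param nu rate S -> V (>= 0).
#' @param tau distrust growth rate / attenuation fraction in \[0, 1\].
#' @return object of class `distrust_params`.
#' @export
distrust_params <- function(base, nu = 0, tau = 0) {
  stopifnot(inherits(base, "sedpnr_params"))
  if (nu < 0) stop("nu must be >= 0")
  if (tau < 0 || tau > 1) stop("tau must be in [0, 1]")
  structure(list(base = base, nu = nu, tau = tau),
            class = "distrust_params")
}

distrust_state_names <- c("s", "e", "v", "d", "p", "n", "r")

#' Distrust-model right-hand side
#'
#' Seven-compartment system with a distrustful class V:
#' `ds/dt = mu1 e + mu2 d - alpha s`,
#' `de/dt = alpha s - (beta1+beta2+gamma+mu1) e`,
#' `dv/dt = nu s - tau v`,
#' `dd/dt = gamma e - (beta3+beta4+mu2) d`,
#' `dp/dt = beta1 (1-tau) v e + beta3 d - lambda1 p`,
#' `dn/dt = beta2 (1-tau) v e + beta4 d - lambda2 n`,
#' `dr/dt = lambda1 p + lambda2 n`.
#' Note this system does not conserve total mass: the `nu s` inflow to V
#' has no matching outflow from S, and the nonlinear `(1-tau) v e`
#' products inject mass into P and N. Per-step totals are therefore
#' reported by [run_distrust] rather than asserted constant.
#'
#' @param state named numeric vector `s,e,v,d,p,n,r`.
#' @param params a [distrust_params].
#' @return named derivative vector.
#' @export
distrust_rhs <- function(state, params) {
  x <- unlist(state)
  if (length(x) != 7L) stop("distrust state must have 7 components")
  if (is.null(names(x)) || !all(distrust_state_names %in% names(x)))
    names(x) <- distrust_state_names
  b <- unclass(params$base)
  with(c(as.list(x[distrust_state_names]), b,
         list(nu = params$nu, tau = params$tau)), c(
    s = mu1 * e + mu2 * d - alpha * s,
    e = alpha * s - (beta1 + beta2 + gamma + mu1) * e,
    v = nu * s - tau * v,
    d = gamma * e - (beta3 + beta4 + mu2) * d,
    p = beta1 * (1 - tau) * v * e + beta3 * d - lambda1 * p,
    n = beta2 * (1 - tau) * v * e + beta4 * d - lambda2 * n,
    r = lambda1 * p + lambda2 * n
  ))
}

#' Integrate the distrust model
#'
#' @param params a [distrust_params].
#' @param init named non-negative vector `s,e,v,d,p,n,r`.
#' @param t_end horizon.
#' @return data.frame `time,s,e,v,d,p,n,r,total` (total reported per step;
#'   the system is not mass-conserving as written).
#' @export
run_distrust <- function(params, init, t_end) {
  x0 <- unlist(init)
  names(x0) <- distrust_state_names
  if (any(x0 < 0)) stop("init must be non-negative")
  out <- deSolve::ode(y = x0, times = 0:as.integer(t_end),
                      func = function(t, y, p) list(distrust_rhs(y, p)),
                      parms = params, method = "lsoda",
                      rtol = 1e-8, atol = 1e-8)
  traj <- data.frame(out)
  names(traj) <- c("time", distrust_state_names)
  traj$total <- rowSums(traj[, distrust_state_names])
  traj
}

#' Time-windowed intervention specification
#'
#' @param t_start day the intervention begins.
#' @param duration length in days (> 0).
#' @param reduction fraction in \[0, 1\] by which target rates are reduced.
#' @param targets rate names to reduce; defaults to the transmission rates
#'   `beta1..beta4` and `alpha`.
#' @return object of class `intervention_window`.
#' @export
intervention_window <- function(t_start, duration, reduction,
                                targets = c("beta1", "beta2", "beta3",
                                            "beta4", "alpha")) {
  if (reduction < 0 || reduction > 1) stop("reduction must be in [0, 1]")
  if (duration <= 0) stop("duration must be > 0")
  valid <- c("alpha", "beta1", "beta2", "beta3", "beta4", "gamma",
             "lambda1", "lambda2", "mu1", "mu2")
  if (!all(targets %in% valid))
    stop("unknown target rate(s): ",
         paste(setdiff(targets, valid), collapse = ", "))
  structure(list(t_start = t_start, duration = duration,
                 reduction = reduction, targets = targets),
            class = "intervention_window")
}

#' Run an intervention scenario
#'
#' Integrates the SEDPNR model twice with identical parameters and initial
#' conditions: once unmodified and once with the window's target rates
#' multiplied by `(1 - reduction)` for `t` in
#' `[t_start, t_start + duration)`. Integration is piecewise so the rate
#' switch is exact at the window boundaries.
#'
#' @param params a [sedpnr_params].
#' @param init a [sedpnr_state].
#' @param t_end horizon; the window must lie within `[0, t_end]`.
#' @param window an [intervention_window].
#' @param scheme an [integration_scheme].
#' @return list with `baseline` and `intervened` trajectories,
#'   `peak_reduction` (fraction, `1 - intervened_peak / baseline_peak`) and
#'   the `window`.
#' @export
run_intervention <- function(params, init, t_end, window,
                             scheme = integration_scheme("adaptive")) {
  stopifnot(inherits(window, "intervention_window"))
  w0 <- window$t_start
  w1 <- window$t_start + window$duration
  if (w0 < 0 || w1 > t_end) stop("window must lie within [0, t_end]")

  baseline <- sedpnr_integrate(params, init, t_end, scheme)

  if (window$reduction == 0) {
    # no-op intervention: trajectories are identical by construction
    return(list(baseline = baseline, intervened = baseline,
                peak_reduction = 0, window = window))
  }

  reduced <- unclass(params)
  for (nm in window$targets)
    reduced[[nm]] <- reduced[[nm]] * (1 - window$reduction)
  # internal reconstruction: any outflow advisory already fired when the
  # caller built `params`, so don't repeat it here
  reduced <- suppressWarnings(do.call(sedpnr_params, reduced))

  segments <- list(
    list(par = params, from = 0, to = w0),
    list(par = reduced, from = w0, to = w1),
    list(par = params, from = w1, to = t_end))
  pieces <- list()
  y <- as_state_vector(init)
  for (seg in segments) {
    len <- seg$to - seg$from
    if (len <= 0) next
    tr <- sedpnr_integrate(seg$par, do.call(sedpnr_state, as.list(y)),
                           len, scheme)
    tr$time <- tr$time + seg$from
    y <- as_state_vector(tr[nrow(tr), state_names])
    pieces <- c(pieces, list(if (seg$from > 0) tr[-1L, ] else tr))
  }
  intervened <- do.call(rbind, pieces)
  attr(intervened, "scheme") <- scheme
  attr(intervened, "params") <- params
  class(intervened) <- c("sedpnr_trajectory", "data.frame")

  pk_b <- peak_infection(baseline)$value
  pk_i <- peak_infection(intervened)$value
  list(baseline = baseline, intervened = intervened,
       peak_reduction = if (pk_b > 0) 1 - pk_i / pk_b else 0,
       window = window)
}

#' Country-level infection/recovery constants from development indices
#'
#' Maps a nation's Human Development Index `h` (0-1) and internet
#' penetration `i` (percent, 0-100) to a recovery constant `phi` and an
#' infection constant `omega`, rounded to 3 decimals. The default
#' `"table"` convention is `phi = h/100`, `omega = (i/100)/10`, which
#' reproduces all published country constants; the `"literal"` convention
#' applies the published formula text verbatim with the symbols the other
#' way around (`phi = i/10`, `omega = h/100`) and is retained for fidelity.
#'
#' @param h HDI in \[0, 1\].
#' @param i internet penetration in percent, \[0, 100\].
#' @param convention `"table"` (default) or `"literal"`.
#' @return list with `phi` and `omega`.
#' @examples
#' country_rates(0.921, 96)  # phi 0.009, omega 0.096
#' @export
country_rates <- function(h, i, convention = c("table", "literal")) {
  convention <- match.arg(convention)
  if (h < 0 || h > 1) stop("h (HDI) must be in [0, 1]")
  if (i < 0 || i > 100) stop("i (internet penetration %) must be in [0, 100]")
  if (convention == "table") {
    list(phi = round(h / 100, 3), omega = round((i / 100) / 10, 3))
  } else {
    list(phi = round(i / 10, 3), omega = round(h / 100, 3))
  }
}

#' Country stiffness run
#'
#' Constant-hazard SIR run parameterized by a country's indices:
#' `beta = omega`, `gamma = phi`, with 99.9% of the population initially
#' susceptible, 0.1% infected, nobody recovered. Summarizes how fast the
#' susceptible pool is depleted and how long spreaders stay active.
#'
#' @param name country name (metadata only).
#' @param h,i development indices as in [country_rates].
#' @param population community size (default 100,000).
#' @param days horizon (default 500).
#' @param convention passed to [country_rates].
#' @return list with `trajectory` (SIR data.frame), `rates` (phi/omega),
#'   and `summary`: `t_s_below_1pct` (first day S < 1% of its initial
#'   value, NA if never) and `t_i_below_10pct_peak` (first day at or after
#'   the peak with I < 10% of peak, NA if never).
#' @export
stiffness_run <- function(name, h, i, population = 1e5, days = 500,
                          convention = "table") {
  if (population <= 0) stop("population must be > 0")
  cr <- country_rates(h, i, convention)
  init <- c(S = 0.999 * population, I = 0.001 * population, R = 0)
  run <- run_baseline(baseline_params("SIR", beta = cr$omega,
                                      gamma = cr$phi), init, days)
  tr <- run$trajectory
  s_thr <- which(tr$S < 0.01 * init[["S"]])
  pk <- which.max(tr$I)
  i_thr <- which(tr$I < 0.1 * tr$I[pk] & tr$time >= tr$time[pk])
  list(name = name, rates = cr, trajectory = tr,
       summary = list(
         t_s_below_1pct = if (length(s_thr)) tr$time[s_thr[1L]] else NA,
         t_i_below_10pct_peak = if (length(i_thr)) tr$time[i_thr[1L]]
                                else NA,
         peak_infection = round(max(tr$I)),
         peak_day = tr$time[pk]))
}
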