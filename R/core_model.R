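#' SEDPNR right-hand side
#'
#' Evaluates the time derivatives of the six compartments:
#' \deqn{ds/dt = \mu_1 e + \mu_2 d - \alpha s}
#' \deqn{de/dt = \alpha s - (\beta_1+\beta_2+\gamma+\mu_1) e}
#' \deqn{dd/dt = \gamma e - (\beta_3+\beta_4+\mu_2) d}
#' \deqn{dp/dt = \beta_1 e + \beta_3 d - \lambda_1 p}
#' \deqn{dn/dt = \beta_2 e + \beta_4 d - \lambda_2 n}
#' \deqn{dr/dt = \lambda_1 p + \lambda_2 n}
#' The six derivatives sum to zero identically, so total population is
#' conserved along any exact trajectory.
#'
#' @param state a [sedpnr_state] (or named numeric vector with components
#'   `s,e,d,p,n,r`).
#' @param params a [sedpnr_params].
#' @return Named numeric vector of the six derivatives.
#' @examples
#' p <- sedpnr_params(alpha = 0.1)
#' sedpnr_rhs(sedpnr_state(s = 1), p)
#' @export
sedpnr_rhs <- function(state, params) {
  x <- as_state_vector(state)
  if (!all(is.finite(x))) stop("non-finite state passed to sedpnr_rhs")
  with(c(as.list(x), unclass(params)), c(
    s = mu1 * e + mu2 * d - alpha * s,
    e = alpha * s - (beta1 + beta2 + gamma + mu1) * e,
    d = gamma * e - (beta3 + beta4 + mu2) * d,
    p = beta1 * e + beta3 * d - lambda1 * p,
    n = beta2 * e + beta4 * d - lambda2 * n,
    r = lambda1 * p + lambda2 * n
  ))
}

# deSolve-compatible wrapper
.rhs_desolve <- function(t, y, parms) list(sedpnr_rhs(y, parms))

#' Integration scheme specification
#'
#' @param kind `"adaptive"` (lsoda with dense output sampled at integer
#'   steps, the default) or `"euler"` (fixed-step forward Euler).
#' @param step_size Euler step size in time units; must divide 1 evenly so
#'   integer steps fall on grid points. Ignored for the adaptive scheme.
#' @return An object of class `sedpnr_scheme`.
#' @export
integration_scheme <- function(kind = c("adaptive", "euler"), step_size = 1) {
  kind <- match.arg(kind)
  if (!is.numeric(step_size) || step_size <= 0)
    stop("step_size must be > 0")
  structure(list(kind = kind, step_size = step_size),
            class = "sedpnr_scheme")
}

#' Integrate the SEDPNR system
#'
#' Produces a trajectory sampled at integer steps `0..t_end`, with step 0
#' equal to the initial state. Negative values larger than `-1e-12`
#' (floating-point underflow) are clipped to zero; the Euler scheme aborts
#' with an informative error if a compartment goes genuinely negative
#' (outflow rates too large for the step size).
#'
#' @param params a [sedpnr_params].
#' @param init a [sedpnr_state] initial condition.
#' @param t_end positive integer horizon (days/steps).
#' @param scheme an [integration_scheme]; default adaptive.
#' @return A `sedpnr_trajectory`: a data.frame with columns
#'   `time, s, e, d, p, n, r` plus attributes `scheme` and `params`.
#' @examples
#' p <- fixtures("sensitivity_a01")
#' traj <- sedpnr_integrate(p$params, p$init, t_end = 100)
#' peak_infection(traj)
#' @export
sedpnr_integrate <- function(params, init, t_end,
                             scheme = integration_scheme("adaptive")) {
  stopifnot(inherits(params, "sedpnr_params"))
  if (!is.numeric(t_end) || t_end <= 0) stop("t_end must be > 0")
  t_end <- as.integer(round(t_end))
  y0 <- as_state_vector(init)
  if (any(y0 < 0)) stop("initial state must be non-negative")
  times <- as.numeric(0:t_end)

  if (scheme$kind == "adaptive") {
    out <- deSolve::ode(y = y0, times = times, func = .rhs_desolve,
                        parms = params, method = "lsoda",
                        rtol = 1e-8, atol = 1e-8)
    states <- unname(as.matrix(out[, state_names]))
  } else {
    h <- scheme$step_size
    n_sub <- round(1 / h)
    if (abs(n_sub * h - 1) > 1e-9)
      stop("euler step_size must evenly divide 1")
    states <- matrix(0, nrow = t_end + 1L, ncol = 6L)
    y <- y0
    states[1L, ] <- y
    for (k in seq_len(t_end)) {
      for (sub in seq_len(n_sub)) {
        y <- y + h * sedpnr_rhs(y, params)
        neg <- y < -1e-12
        if (any(neg))
          stop("euler integration drove compartment '",
               state_names[which(neg)[1L]], "' negative (",
               signif(y[which(neg)[1L]], 4), ") at step ", k,
               "; reduce step_size or the outflow rates")
        y[y < 0] <- 0
      }
      states[k + 1L, ] <- y
    }
  }

  # clip floating-point underflow
  n_clip <- sum(states < 0)
  if (n_clip > 0) {
    if (any(states < -1e-12))
      stop("integration produced negative compartment values below -1e-12")
    if (isTRUE(getOption("sedpnr.verbose")))
      message("clipped ", n_clip, " negative underflow value(s) to 0")
    states[states < 0] <- 0
  }

  traj <- data.frame(time = times, states)
  names(traj) <- c("time", state_names)
  attr(traj, "scheme") <- scheme
  attr(traj, "params") <- params
  class(traj) <- c("sedpnr_trajectory", "data.frame")
  traj
}

#' @export
print.sedpnr_trajectory <- function(x, ...) {
  sc <- attr(x, "scheme")
  pk <- peak_infection(x)
  cat("SEDPNR trajectory: ", nrow(x) - 1L, " steps, scheme = ",
      sc$kind, "\n", sep = "")
  cat("  total population: ", format(sum(x[1L, state_names])),
      "   peak P+N: ", format(round(pk$value)), " at step ", pk$step,
      "\n", sep = "")
  invisible(x)
}

#' Peak total infection of a trajectory
#'
#' The total infection at a step is the sum of the positively and negatively
#' infected compartments, P + N. Ties are broken by the earliest step.
#'
#' @param traj a `sedpnr_trajectory` (or data.frame with `p` and `n`
#'   columns and a `time` column).
#' @return list with `value` (individuals) and `step` (integer time of the
#'   earliest maximum).
#' @export
peak_infection <- function(traj) {
  if (nrow(traj) < 1L) stop("trajectory is empty")
  tot <- traj$p + traj$n
  i <- which.max(tot)  # which.max returns the first maximum
  list(value = tot[i], step = traj$time[i])
}

#' Check exponential lower bounds and monotonicity along a trajectory
#'
#' Each transient compartment of the SEDPNR system decays no faster than its
#' total outflow rate, giving the lower bounds
#' `s(t) >= s(0) exp(-alpha t)`,
#' `e(t) >= e(0) exp(-(beta1+beta2+gamma+mu1) t)`,
#' `d(t) >= d(0) exp(-(beta3+beta4+mu2) t)`,
#' `p(t) >= p(0) exp(-lambda1 t)`, `n(t) >= n(0) exp(-lambda2 t)`, and the
#' restrained compartment is nondecreasing. These bounds imply positivity of
#' the solution for non-negative initial conditions.
#'
#' @param traj a `sedpnr_trajectory` produced by [sedpnr_integrate] (needs
#'   the `params` attribute).
#' @param tol additive slack for floating-point comparisons.
#' @return data.frame with one row per bound: `bound`, `pass`,
#'   `worst_margin` (minimum of observed minus bound; negative = violation)
#'   and `worst_step`.
#' @export
check_decay_bounds <- function(traj, tol = 1e-8) {
  params <- attr(traj, "params")
  if (is.null(params)) stop("trajectory carries no params attribute")
  rates <- outflow_rates(params)
  t <- traj$time
  res <- lapply(names(rates), function(nm) {
    lb <- traj[[nm]][1L] * exp(-rates[[nm]] * t)
    margin <- traj[[nm]] - lb
    i <- which.min(margin)
    data.frame(bound = paste0(nm, "_exp_lower"),
               pass = margin[i] >= -tol,
               worst_margin = margin[i], worst_step = t[i])
  })
  dr <- diff(traj$r)
  i <- if (length(dr)) which.min(dr) else 1L
  res <- c(res, list(data.frame(
    bound = "r_nondecreasing",
    pass = !length(dr) || min(dr) >= -tol,
    worst_margin = if (length(dr)) min(dr) else 0,
    worst_step = t[i + 1L])))
  do.call(rbind, res)
}
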