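#' SEDPNR transition-rate parameter set
#'
#' Bundles the ten transition rates of the SEDPNR model: `alpha` (S to E),
#' `beta1`/`beta2` (E to P / E to N), `gamma` (E to D), `beta3`/`beta4`
#' (D to P / D to N), `lambda1`/`lambda2` (P to R / N to R) and
#' `mu1`/`mu2` (E to S / D to S). All rates are per unit time step and must
#' be finite and non-negative.
#'
#' For forward-Euler integration with step 1 (and for the stochastic network
#' simulation, where rates are read as per-step probabilities) each
#' compartment's total outflow must not exceed 1 per step. Violations of that
#' bound produce a warning, not an error, because adaptive integration
#' remains well defined.
#'
#' @param alpha rate S -> E.
#' @param beta1,beta2 rates E -> P and E -> N.
#' @param gamma rate E -> D.
#' @param beta3,beta4 rates D -> P and D -> N.
#' @param lambda1,lambda2 rates P -> R and N -> R.
#' @param mu1,mu2 rates E -> S and D -> S.
#' @return An object of class `sedpnr_params` (a named list of the ten rates).
#' @examples
#' sedpnr_params(alpha = 0.1, beta1 = 0.05, beta2 = 0.05, beta3 = 0.05,
#'               beta4 = 0.05, gamma = 0.025, lambda1 = 0.035,
#'               lambda2 = 0.035, mu1 = 0.01, mu2 = 0.1)
#' @export
sedpnr_params <- function(alpha = 0, beta1 = 0, beta2 = 0, beta3 = 0,
                          beta4 = 0, gamma = 0, lambda1 = 0, lambda2 = 0,
                          mu1 = 0, mu2 = 0) {
  p <- list(alpha = alpha, beta1 = beta1, beta2 = beta2, beta3 = beta3,
            beta4 = beta4, gamma = gamma, lambda1 = lambda1,
            lambda2 = lambda2, mu1 = mu1, mu2 = mu2)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
    if (v < 0)
      stop("parameter '", nm, "' must be non-negative, got ", v)
  }
  ofl <- outflow_rates(p)
  bad <- names(ofl)[ofl > 1 + 1e-12]
  if (length(bad))
    warning("total outflow rate exceeds 1 per step for compartment(s) ",
            paste(bad, collapse = ", "),
            "; forward-Euler with step 1 and the network simulation ",
            "require outflow <= 1")
  structure(p, class = "sedpnr_params")
}

# Total per-step outflow rate of each transient compartment.
outflow_rates <- function(p) {
  c(s = p$alpha,
    e = p$beta1 + p$beta2 + p$gamma + p$mu1,
    d = p$beta3 + p$beta4 + p$mu2,
    p = p$lambda1,
    n = p$lambda2)
}

#' @export
print.sedpnr_params <- function(x, ...) {
  cat("SEDPNR parameters:\n")
  cat(sprintf("  %-8s %g\n", names(x), unlist(x)), sep = "")
  invisible(x)
}

#' SEDPNR compartment state
#'
#' Population counts (or densities) of the six compartments: Susceptible,
#' Exposed, Doubtful, Positively infected, Negatively infected, Restrained.
#'
#' @param s,e,d,p,n,r non-negative counts per compartment.
#' @return A named numeric vector of class `sedpnr_state` with components
#'   `s, e, d, p, n, r`.
#' @examples
#' sedpnr_state(s = 299990, p = 5, n = 5)
#' @export
sedpnr_state <- function(s = 0, e = 0, d = 0, p = 0, n = 0, r = 0) {
  x <- c(s = s, e = e, d = d, p = p, n = n, r = r)
  if (!all(is.finite(x))) stop("state components must be finite")
  if (any(x < 0)) {
    bad <- names(x)[x < 0][1L]
    stop("state component '", bad, "' must be non-negative, got ", x[[bad]])
  }
  structure(x, class = "sedpnr_state")
}

state_names <- c("s", "e", "d", "p", "n", "r")

as_state_vector <- function(state) {
  if (inherits(state, "sedpnr_state")) return(unclass(state))
  x <- unlist(state)
  if (length(x) != 6L) stop("state must have six components (s,e,d,p,n,r)")
  if (is.null(names(x)) || !all(state_names %in% names(x)))
    names(x) <- state_names
  x[state_names]
}
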