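#' Jacobian of the SEDPNR system
#'
#' The system is linear, so the Jacobian is constant in the state. Two
#' variants are exposed: `"corrected"` (the exact derivative matrix of the
#' right-hand side; this is what every computation in the package uses) and
#' `"as_printed"` (a variant that differs in one entry, carrying `+lambda2`
#' instead of `-lambda2` on the negatively-infected diagonal; kept for
#' fidelity checks against the published matrix).
#'
#' @param params a [sedpnr_params].
#' @param variant `"corrected"` (default) or `"as_printed"`.
#' @return 6x6 numeric matrix with rows/columns ordered `s,e,d,p,n,r`.
#' @export
sedpnr_jacobian <- function(params, variant = c("corrected", "as_printed")) {
  variant <- match.arg(variant)
  with(unclass(params), {
    J <- matrix(0, 6, 6, dimnames = list(state_names, state_names))
    J["s", ] <- c(-alpha, mu1, mu2, 0, 0, 0)
    J["e", ] <- c(alpha, -(beta1 + beta2 + gamma + mu1), 0, 0, 0, 0)
    J["d", ] <- c(0, gamma, -(beta3 + beta4 + mu2), 0, 0, 0)
    J["p", ] <- c(0, beta1, beta3, -lambda1, 0, 0)
    J["n", ] <- c(0, beta2, beta4, 0,
                  if (variant == "corrected") -lambda2 else lambda2, 0)
    J["r", ] <- c(0, 0, 0, lambda1, lambda2, 0)
    J
  })
}

#' Basic reproduction number
#'
#' R0 for the SEDPNR model is `max(beta1/lambda1, beta2/lambda2)`: the
#' larger of the ratios of the transmission rates into the two spreader
#' compartments to their respective restraint rates. The value is
#' cross-checked against the spectral radius of the next-generation matrix
#' built from the transmission matrix F and the removal matrix V. F and V
#' are also returned in their published 5x5 layout (transmission entries
#' `beta1`, `beta2` in the last two columns of the first row; removal rates
#' `lambda1`, `lambda2` leading the diagonal); because that layout misaligns
#' the transmission and removal slots, the spectral radius is computed on
#' the infectious (p, n) block, where the next-generation matrix is
#' `diag(beta1/lambda1, beta2/lambda2)`.
#'
#' @param params a [sedpnr_params] with `lambda1 > 0` and `lambda2 > 0`.
#' @return list with `r0`, `F` and `V` (5x5 matrices in the published
#'   layout), `ngm` (2x2 next-generation matrix on the (p, n) block),
#'   `spectral_radius`, and `agreement` (TRUE when formula and spectral
#'   radius agree to 1e-12 relative).
#' @examples
#' basic_reproduction_number(fixtures("sensitivity_a01")$params)$r0
#' @export
basic_reproduction_number <- function(params) {
  with(unclass(params), {
    if (lambda1 <= 0 || lambda2 <= 0)
      stop("basic_reproduction_number requires lambda1 > 0 and lambda2 > 0")
    r0 <- max(beta1 / lambda1, beta2 / lambda2)
    Fm <- matrix(0, 5, 5)
    Fm[1, 4] <- beta1
    Fm[1, 5] <- beta2
    Vm <- diag(c(lambda1, lambda2, 0, 0, 0))
    ngm <- diag(c(beta1 / lambda1, beta2 / lambda2), 2, 2)
    rho <- max(abs(eigen(ngm, only.values = TRUE)$values))
    list(r0 = r0, F = Fm, V = Vm, ngm = ngm, spectral_radius = rho,
         agreement = isTRUE(abs(r0 - rho) <= 1e-12 * max(1, r0)))
  })
}

#' Eigenvalue stability conditions for the rumor-free state
#'
#' Linearizing the (s, e, d) subsystem around the exposed-free steady state
#' gives the 3x3 matrix
#' `[-alpha, mu1, mu2; alpha, -(beta1+beta2+gamma+mu1), 0;
#'   0, gamma, -(beta3+beta4+mu2)]`.
#' Three closed-form eigenvalue expressions (`delta1..delta3`) and the
#' associated die-out inequalities are evaluated as published; the numeric
#' eigenvalues of the explicit matrix and their maximum real part are
#' reported alongside as the practical stability verdict. Note the published
#' `delta1` radicand exceeds `alpha^2` whenever `mu1 > 0`, which makes the
#' first published die-out inequality unsatisfiable for positive `mu1`; the
#' two verdicts are therefore reported side by side and not forced to agree.
#'
#' @param params a [sedpnr_params].
#' @return list with `delta1`, `delta2`, `delta3`, `dies_out_printed`
#'   (all three published inequalities hold), `matrix_3x3`,
#'   `numeric_eigenvalues` (possibly complex), `max_real_part` and
#'   `dies_out_numeric` (`max_real_part < 0`).
#' @export
eigenvalue_conditions <- function(params) {
  with(unclass(params), {
    oe <- beta1 + beta2 + gamma + mu1
    od <- beta3 + beta4 + mu2
    rad1 <- sqrt(alpha^2 + 4 * mu1 * oe)
    rad2 <- sqrt(od^2 + 4 * gamma * oe)
    delta1 <- (-alpha + rad1) / 2
    delta2 <- (-od + rad2) / 2
    delta3 <- (-od - rad2) / 2
    dies_out_printed <- (alpha - rad1 > 0) && (od - rad2 > 0) &&
      (od + rad2 > 0)
    A <- matrix(c(-alpha, mu1, mu2,
                  alpha, -oe, 0,
                  0, gamma, -od), 3, 3, byrow = TRUE)
    ev <- eigen(A, only.values = TRUE)$values
    list(delta1 = delta1, delta2 = delta2, delta3 = delta3,
         dies_out_printed = dies_out_printed,
         matrix_3x3 = A, numeric_eigenvalues = ev,
         max_real_part = max(Re(ev)),
         dies_out_numeric = max(Re(ev)) < 0)
  })
}

#' Equilibrium analysis
#'
#' Reports two views of the model's equilibria. The numeric fixed point is
#' obtained from the null space of the (corrected) system matrix,
#' normalized to the given total population with non-negative components;
#' for all-positive rates the only such fixed point is the all-Restrained
#' state `(0,0,0,0,0,total)`. The closed-form expressions published for an
#' endemic equilibrium are also evaluated verbatim (the `p`/`n` expressions
#' are self-referential and are resolved through the homogeneous 2x2 linear
#' relation they define, when nonsingular) and their residuals under the
#' right-hand side are reported rather than asserted to vanish.
#'
#' @param params a [sedpnr_params].
#' @param total total population used to scale the numeric fixed point.
#' @return list with `closed_form` (named values, `NA` where a denominator
#'   vanishes or the p/n relation is singular, with a `flags` attribute
#'   naming them), `numeric_fixed_point` (a [sedpnr_state]),
#'   `rhs_residual_at_closed_form` and `rhs_residual_at_numeric` (max
#'   absolute derivative components).
#' @export
sedpnr_equilibrium <- function(params, total) {
  stopifnot(is.numeric(total), total > 0)
  pl <- unclass(params)
  oe <- pl$beta1 + pl$beta2 + pl$gamma + pl$mu1
  od <- pl$beta3 + pl$beta4 + pl$mu2

  flags <- character(0)
  safe_div <- function(num, den, name) {
    if (abs(den) < .Machine$double.eps) {
      flags <<- c(flags, name)
      return(NA_real_)
    }
    num / den
  }
  cf <- c(
    s = safe_div(pl$mu1 * od * (pl$lambda1 + pl$lambda2),
                 pl$mu1 * pl$beta3 + pl$mu2 * pl$lambda1, "s"),
    e = safe_div(pl$alpha * od * (pl$lambda1 + pl$lambda2),
                 pl$alpha * pl$beta3 + oe * pl$lambda1, "e"),
    d = safe_div(pl$gamma * (pl$lambda1 + pl$lambda2) * oe,
                 pl$gamma * pl$beta1 + od * pl$lambda2, "d")
  )
  # published p/n expressions: p = A (lambda2 p + lambda1 n),
  #                            n = B (lambda1 p + lambda2 n)
  A_den <- pl$beta1 * pl$lambda2
  B_den <- pl$beta2 * pl$lambda1
  if (abs(A_den) < .Machine$double.eps || abs(B_den) < .Machine$double.eps) {
    flags <- c(flags, "p", "n")
    cf <- c(cf, p = NA_real_, n = NA_real_)
  } else {
    A <- (pl$mu1 * pl$beta3 + pl$mu2 * pl$lambda1) / A_den
    B <- (oe * pl$lambda2) / B_den
    M <- matrix(c(1 - A * pl$lambda2, -A * pl$lambda1,
                  -B * pl$lambda1, 1 - B * pl$lambda2), 2, 2, byrow = TRUE)
    if (abs(det(M)) < 1e-12) {
      flags <- c(flags, "p", "n")
      cf <- c(cf, p = NA_real_, n = NA_real_)
    } else {
      pn <- solve(M, c(0, 0))
      cf <- c(cf, p = pn[1], n = pn[2])
    }
  }
  attr(cf, "flags") <- unique(flags)

  # numeric fixed point: null space of the linear system matrix, scaled to
  # the total and required non-negative
  J <- sedpnr_jacobian(params, "corrected")
  sv <- svd(J)
  null_idx <- which(sv$d < 1e-10 * max(sv$d, 1))
  fp <- NULL
  for (i in null_idx) {
    v <- sv$v[, i]
    if (all(v >= -1e-10) || all(v <= 1e-10)) {
      v <- abs(v) * sign(sum(v))^0  # orient non-negative
      v <- pmax(v, 0)
      if (sum(v) > 0) {
        fp <- v / sum(v) * total
        break
      }
    }
  }
  if (is.null(fp)) {
    # fall back: combine null vectors and project to the simplex direction r
    fp <- c(0, 0, 0, 0, 0, total)
  }
  names(fp) <- state_names
  numeric_fp <- do.call(sedpnr_state, as.list(fp))

  res_num <- max(abs(sedpnr_rhs(numeric_fp, params)))
  cf_state <- cf
  cf_state[is.na(cf_state)] <- 0
  cf6 <- c(cf_state[c("s", "e", "d", "p", "n")], r = 0)
  res_cf <- max(abs(sedpnr_rhs(cf6, params)))

  list(closed_form = cf,
       numeric_fixed_point = numeric_fp,
       rhs_residual_at_closed_form = res_cf,
       rhs_residual_at_numeric = res_num)
}

#' Clustering comparison rules for belief-specific spread
#'
#' Verdicts on whether network clustering facilitates or hinders spread
#' among positively and negatively believing individuals, from strict
#' comparisons of the belief-specific transmission rates: positive spread is
#' facilitated when `beta1 > beta4` and `beta1 > beta2`, hindered when
#' `beta1 < beta4` and `beta1 < beta2`; negative spread likewise compares
#' `beta2` against `beta3` and `beta1`. When neither pair of strict
#' inequalities holds the verdict is `"indeterminate"`.
#'
#' @param params a [sedpnr_params].
#' @return list with `positive` and `negative`, each one of
#'   `"facilitates"`, `"hinders"`, `"indeterminate"`.
#' @export
clustering_comparison <- function(params) {
  verdict <- function(x, a, b) {
    if (x > a && x > b) "facilitates"
    else if (x < a && x < b) "hinders"
    else "indeterminate"
  }
  with(unclass(params), list(
    positive = verdict(beta1, beta4, beta2),
    negative = verdict(beta2, beta3, beta1)
  ))
}

#' Lyapunov diagnostic along a trajectory
#'
#' Evaluates the quadratic functional `V = s^2+e^2+d^2+p^2+n^2+r^2` at each
#' sampled step, its time derivative by central differences, and whether V
#' is constant to a relative tolerance. The diagnostic records the empirical
#' behavior of V; for generic states the algebraic derivative of V along
#' the flow does not vanish, so constancy is reported, never assumed.
#'
#' @param traj a `sedpnr_trajectory`.
#' @param tol relative tolerance on `max |delta V| / V(0)` for the
#'   constancy verdict (ignored when `V(0) = 0`, where constancy means all
#'   values remain 0).
#' @return list with `v_values`, `dv_dt_values` (central differences,
#'   one-sided at the ends) and `is_constant`.
#' @export
lyapunov_diagnostic <- function(traj, tol = 1e-6) {
  if (nrow(traj) < 1L) stop("trajectory is empty")
  S <- as.matrix(traj[, state_names])
  v <- rowSums(S^2)
  t <- traj$time
  m <- length(v)
  dv <- numeric(m)
  if (m >= 2L) {
    dv[1L] <- (v[2L] - v[1L]) / (t[2L] - t[1L])
    dv[m] <- (v[m] - v[m - 1L]) / (t[m] - t[m - 1L])
    if (m >= 3L) {
      i <- 2:(m - 1L)
      dv[i] <- (v[i + 1L] - v[i - 1L]) / (t[i + 1L] - t[i - 1L])
    }
  }
  if (v[1L] > 0) {
    is_const <- max(abs(diff(v)), 0) / v[1L] < tol
  } else {
    is_const <- all(v == 0)
  }
  list(v_values = v, dv_dt_values = dv, is_constant = is_const)
}

#' Full stability report
#'
#' Convenience wrapper assembling the Jacobians (both variants), the
#' next-generation R0, the closed-form eigenvalue conditions and the
#' numeric eigenvalues into one report.
#'
#' @param params a [sedpnr_params].
#' @return list of class `sedpnr_stability_report`.
#' @export
stability_report <- function(params) {
  r0 <- basic_reproduction_number(params)
  ec <- eigenvalue_conditions(params)
  structure(list(
    jacobian_printed = sedpnr_jacobian(params, "as_printed"),
    jacobian_corrected = sedpnr_jacobian(params, "corrected"),
    next_gen_F = r0$F, next_gen_V = r0$V,
    r0 = r0$r0, r0_spectral_radius = r0$spectral_radius,
    r0_agreement = r0$agreement,
    delta1 = ec$delta1, delta2 = ec$delta2, delta3 = ec$delta3,
    numeric_eigenvalues_3x3 = ec$numeric_eigenvalues,
    max_real_part = ec$max_real_part,
    dies_out_printed = ec$dies_out_printed,
    dies_out_numeric = ec$dies_out_numeric
  ), class = "sedpnr_stability_report")
}

#' @export
print.sedpnr_stability_report <- function(x, ...) {
  cat("SEDPNR stability report\n")
  cat("  R0 =", format(x$r0),
      if (x$r0_agreement) "(next-generation check: agrees)"
      else "(next-generation check: DISAGREES)", "\n")
  cat("  delta1/2/3 =", format(c(x$delta1, x$delta2, x$delta3)), "\n")
  cat("  max Re(eigenvalue, 3x3) =", format(x$max_real_part), "\n")
  cat("  dies out (printed conditions):", x$dies_out_printed,
      " | (numeric):", x$dies_out_numeric, "\n")
  invisible(x)
}
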