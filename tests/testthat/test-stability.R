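test_that("jacobian variants match the published matrix and the exact one", {
  z <- sedpnr_params()
  expect_equal(sedpnr_jacobian(z, "corrected"),
               matrix(0, 6, 6, dimnames = list(c("s","e","d","p","n","r"),
                                               c("s","e","d","p","n","r"))))
  expect_equal(unname(sedpnr_jacobian(z, "as_printed")), matrix(0, 6, 6))

  p <- sedpnr_params(alpha = 0.1, mu1 = 0.01, mu2 = 0.1)
  expect_equal(unname(sedpnr_jacobian(p, "as_printed")[1, ]),
               c(-0.1, 0.01, 0.1, 0, 0, 0))

  # the two variants differ only in the sign of the n-diagonal
  p2 <- sedpnr_params(lambda2 = 0.3)
  d <- sedpnr_jacobian(p2, "as_printed") - sedpnr_jacobian(p2, "corrected")
  expect_equal(d["n", "n"], 0.6)
  d["n", "n"] <- 0
  expect_equal(max(abs(d)), 0)
})

test_that("corrected jacobian matches a finite-difference oracle", {
  set.seed(7)
  for (k in 1:100) {
    par <- random_params()
    expect_equal(unname(sedpnr_jacobian(par, "corrected")),
                 fd_jacobian(par), tolerance = 1e-6)
  }
})

test_that("R0 formula agrees with the next-generation spectral radius", {
  expect_equal(basic_reproduction_number(
    sedpnr_params(lambda1 = 0.1, lambda2 = 0.1))$r0, 0)
  # threshold case: beta = lambda gives R0 = 1
  expect_equal(basic_reproduction_number(
    sedpnr_params(beta1 = 0.3, lambda1 = 0.3,
                  beta2 = 0.07, lambda2 = 0.07))$r0, 1)
  r <- basic_reproduction_number(
    sedpnr_params(beta1 = 0.05, lambda1 = 0.035,
                  beta2 = 0.04, lambda2 = 0.035))
  expect_equal(r$r0, 0.05 / 0.035, tolerance = 1e-12)
  expect_error(basic_reproduction_number(sedpnr_params(lambda1 = 0)),
               "lambda")

  set.seed(8)
  for (k in 1:100) {
    rr <- basic_reproduction_number(random_params())
    expect_equal(rr$r0, rr$spectral_radius, tolerance = 1e-12)
    expect_true(rr$agreement)
    expect_gte(rr$r0, 0)
  }
})

test_that("eigenvalue conditions evaluate closed forms and numerics", {
  z <- eigenvalue_conditions(sedpnr_params())
  expect_equal(c(z$delta1, z$delta2, z$delta3), c(0, 0, 0))
  expect_equal(Re(z$numeric_eigenvalues), rep(0, 3))

  # mu1 = gamma = 0 collapses the first radicand to alpha^2
  z2 <- eigenvalue_conditions(sedpnr_params(alpha = 0.4, beta1 = 0.1))
  expect_equal(z2$delta1, 0)

  f <- fixtures("sensitivity_a01")
  ec <- eigenvalue_conditions(f$params)
  expect_true(all(Re(ec$numeric_eigenvalues) < 0))
  expect_true(ec$dies_out_numeric)
  # the published first inequality is unsatisfiable for mu1 > 0
  expect_false(ec$dies_out_printed)

  set.seed(9)
  for (k in 1:100) {
    e <- eigenvalue_conditions(random_params())
    expect_gte(e$delta2, e$delta3)
  }
})

test_that("equilibrium: numeric fixed point is all-Restrained for positive rates", {
  f <- fixtures("sensitivity_a01")
  eq <- sedpnr_equilibrium(f$params, total = 3e5)
  fp <- as.numeric(eq$numeric_fixed_point)
  expect_equal(fp, c(0, 0, 0, 0, 0, 3e5))
  expect_lte(eq$rhs_residual_at_numeric, 1e-8 * 3e5)

  # closed-form s evaluates the published fraction verbatim
  pl <- unclass(f$params)
  s_expect <- pl$mu1 * (pl$beta3 + pl$beta4 + pl$mu2) *
    (pl$lambda1 + pl$lambda2) /
    (pl$mu1 * pl$beta3 + pl$mu2 * pl$lambda1)
  expect_equal(unname(eq$closed_form[["s"]]), s_expect)

  # the published expressions are not a root of the system: residual > 0
  expect_gt(eq$rhs_residual_at_closed_form, 0)

  # zero denominators are flagged, values withheld
  eq0 <- sedpnr_equilibrium(sedpnr_params(lambda1 = 0.1, lambda2 = 0.1),
                            total = 100)
  expect_true("s" %in% attr(eq0$closed_form, "flags"))
  expect_true(is.na(eq0$closed_form[["s"]]))
})

test_that("equilibrium agrees with the long-run trajectory limit", {
  f <- fixtures("sensitivity_a01")
  n_total <- sum(as.numeric(f$init))
  eq <- sedpnr_equilibrium(f$params, n_total)
  traj <- sedpnr_integrate(f$params, f$init, 5000)
  last <- as.numeric(traj[nrow(traj), c("s","e","d","p","n","r")])
  expect_equal(last, as.numeric(eq$numeric_fixed_point),
               tolerance = 1e-3)
})

test_that("clustering comparison applies the strict-inequality rules", {
  mk <- function(b1, b2, b3, b4)
    sedpnr_params(beta1 = b1, beta2 = b2, beta3 = b3, beta4 = b4)
  expect_equal(clustering_comparison(mk(0.9, 0.1, 0.5, 0.1))$positive,
               "facilitates")
  expect_equal(clustering_comparison(mk(0.1, 0.9, 0.1, 0.5))$negative,
               "facilitates")
  expect_equal(clustering_comparison(mk(0.1, 0.5, 0.3, 0.4))$positive,
               "hinders")
  eqv <- clustering_comparison(mk(0.2, 0.2, 0.2, 0.2))
  expect_equal(eqv$positive, "indeterminate")
  expect_equal(eqv$negative, "indeterminate")
})

test_that("lyapunov diagnostic reports V and constancy honestly", {
  f <- fixtures("sensitivity_a01")
  const <- sedpnr_integrate(f$params, sedpnr_state(r = 100), 10)
  ly <- lyapunov_diagnostic(const)
  expect_true(ly$is_constant)
  expect_equal(ly$v_values, rep(1e4, 11), tolerance = 1e-8)

  zero <- sedpnr_integrate(f$params, sedpnr_state(), 5)
  expect_equal(lyapunov_diagnostic(zero)$v_values, rep(0, 6))
  expect_true(lyapunov_diagnostic(zero)$is_constant)

  # along a genuine epidemic V is recorded but is not constant
  traj <- sedpnr_integrate(f$params, f$init, 100)
  ly2 <- lyapunov_diagnostic(traj)
  expect_length(ly2$v_values, 101)
  expect_true(all(ly2$v_values >= 0))
  expect_false(ly2$is_constant)
})
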