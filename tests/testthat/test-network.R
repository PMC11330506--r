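test_that("preferential attachment produces the contracted edge count", {
  # m = 1 yields a tree
  net <- generate_scale_free(5, 1, seed = 1)
  expect_equal(nrow(net$edges), 4L)
  expect_equal(net$n_nodes, 5L)

  net2 <- generate_scale_free(500, 3, seed = 2)
  expect_equal(nrow(net2$edges), 3L * (500L - 3L) + 3L)
  # no self loops, no duplicate edges, indices in range
  e <- net2$edges
  expect_true(all(e[, 1] != e[, 2]))
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  expect_equal(anyDuplicated(key), 0L)
  expect_true(all(e >= 1 & e <= 500))

  # determinism: same seed, identical edge set
  expect_identical(generate_scale_free(300, 2, seed = 9)$edges,
                   generate_scale_free(300, 2, seed = 9)$edges)
  expect_false(identical(generate_scale_free(300, 2, seed = 9)$edges,
                         generate_scale_free(300, 2, seed = 10)$edges))

  expect_error(generate_scale_free(3, 3, seed = 1), "n > m")
})

test_that("generated graphs have a power-law degree tail", {
  net <- generate_scale_free(10000, 3, seed = 5)
  fit <- fit_power_law(node_degrees(net))
  expect_false(fit$degenerate)
  expect_gt(fit$exponent, 2)
  expect_lt(fit$exponent, 3.5)
})

test_that("power-law fit recovers a known exponent and flags degeneracy", {
  set.seed(31)
  x <- rzeta(10000, 2.5)
  fit <- fit_power_law(x)
  expect_equal(fit$exponent, 2.5, tolerance = 0.15 / 2.5)

  deg <- fit_power_law(rep(5L, 100))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$exponent))

  expect_error(fit_power_law(rep(2L, 10)), "at least 50")
})

test_that("superspreaders are the top-degree nodes", {
  # star graph: the hub wins
  star <- structure(list(n_nodes = 6L,
                         edges = cbind(from = rep(1L, 5), to = 2:6),
                         attachment_m = 1L, seed = 0L),
                    class = "sedpnr_network")
  expect_equal(identify_superspreaders(star, 1), 1L)

  net <- generate_scale_free(1000, 2, seed = 3)
  deg <- node_degrees(net)
  top <- identify_superspreaders(net, 10)
  brute <- order(-deg, seq_along(deg))[1:10]
  expect_equal(top, brute)
  # full ranking covers every node
  expect_setequal(identify_superspreaders(net, 1000), 1:1000)
  expect_error(identify_superspreaders(net, 0), "top_k")
})

test_that("network dynamics respect conservation, absorption, determinism", {
  net <- generate_scale_free(2000, 2, seed = 4)
  f <- fixtures("sensitivity_a01")
  init <- initial_node_states(net, c(S = 1980, P = 10, N = 10), seed = 5)

  r1 <- simulate_network(net, f$params, init, 50, seed = 6)
  r2 <- simulate_network(net, f$params, init, 50, seed = 6)
  expect_identical(r1, r2)

  counts <- r1$counts
  expect_equal(rowSums(counts[, -1]), rep(2000, 51))
  expect_true(all(diff(counts$R) >= 0))

  # all-Restrained start never moves
  rr <- simulate_network(net, f$params, rep("R", 2000), 20, seed = 1)
  expect_equal(rr$counts$R, rep(2000L, 21))

  # alpha = 0 with no exposed/doubtful: S frozen, P+N decays
  p0 <- sedpnr_params(lambda1 = 0.2, lambda2 = 0.2)
  r0 <- simulate_network(net, p0, init, 50, seed = 2)
  expect_equal(r0$counts$S, rep(1980L, 51))
  expect_true(all(diff(r0$counts$P + r0$counts$N) <= 0))

  expect_error(
    simulate_network(net, suppressWarnings(sedpnr_params(beta1 = 0.9,
                                                         gamma = 0.3)),
                     init, 5, seed = 1), "'e'")
})

test_that("neighbor hazard mode needs infectious contacts to spread", {
  net <- generate_scale_free(500, 2, seed = 11)
  p <- sedpnr_params(alpha = 0.9, beta1 = 0.2, beta2 = 0.2,
                     lambda1 = 0.1, lambda2 = 0.1)
  # no P/N anywhere: exposure hazard is zero in neighbor mode
  r <- simulate_network(net, p, rep("S", 500), 20, seed = 1,
                        hazard_mode = "neighbor")
  expect_equal(r$counts$S, rep(500L, 21))
  # with seeded spreaders the epidemic does move
  init <- initial_node_states(net, c(S = 490, P = 5, N = 5),
                              placement = "superspreader")
  r2 <- simulate_network(net, p, init, 20, seed = 1,
                         hazard_mode = "neighbor")
  expect_lt(r2$counts$S[21], 500)
  expect_equal(r2$hazard_mode, "neighbor")
})

test_that("ensemble mean tracks the Euler ODE trajectory (constant mode)", {
  # moderate size here; the full-scale agreement check runs in the
  # acceptance suite
  n <- 20000
  net <- generate_scale_free(n, 2, seed = 21)
  f <- fixtures("sensitivity_a01")
  init <- initial_node_states(net, c(S = n - 20, E = 5, D = 5, P = 5,
                                     N = 5), seed = 1)
  init_counts <- sedpnr_state(s = n - 20, e = 5, d = 5, p = 5, n = 5)
  ode <- sedpnr_integrate(f$params, init_counts, 50,
                          integration_scheme("euler"))
  sims <- lapply(1:5, function(sd)
    as.matrix(simulate_network(net, f$params, init, 50,
                               seed = sd)$counts[, -1]))
  arr <- simplify2array(sims)
  mn <- apply(arr, c(1, 2), mean)
  se <- apply(arr, c(1, 2), stats::sd) / sqrt(length(sims))
  ode_m <- as.matrix(ode[, c("s", "e", "d", "p", "n", "r")])
  # aggregate z-score check at this scale
  z <- abs(mn - ode_m) / pmax(se, 1)
  expect_lt(stats::median(z), 3)
  expect_lt(max(abs(mn - ode_m)) / n, 0.02)
})
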