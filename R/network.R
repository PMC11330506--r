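#' Generate a scale-free contact network by preferential attachment
#'
#' Barabási–Albert construction with a seeded clique start: the first `m`
#' nodes form a complete graph, and each subsequent node attaches `m` edges
#' to distinct existing nodes chosen with probability proportional to their
#' current degree (repeated-nodes sampling, O(N + E)). The edge count is
#' therefore exactly `m*(n - m) + choose(m, 2)`. The construction is
#' deterministic for a fixed seed.
#'
#' @param n number of nodes (`n > m`).
#' @param m edges attached per new node (`m >= 1`).
#' @param seed integer random seed.
#' @return An object of class `sedpnr_network`: list with `n_nodes`,
#'   `edges` (two-column integer matrix, 1-based node indices, each
#'   unordered pair once), `attachment_m`, `seed`.
#' @examples
#' net <- generate_scale_free(100, m = 2, seed = 1)
#' head(node_degrees(net))
#' @export
generate_scale_free <- function(n, m, seed = 0L) {
  if (!is.numeric(n) || !is.numeric(m) || m < 1 || n <= m)
    stop("generate_scale_free requires n > m >= 1")
  n <- as.integer(n); m <- as.integer(m)
  old_seed <- local_seed(seed)
  on.exit(restore_seed(old_seed), add = TRUE)

  n_edges <- m * (n - m) + m * (m - 1L) %/% 2L
  from <- integer(n_edges); to <- integer(n_edges)
  # repeated-nodes list: each edge endpoint appears once per incident edge
  targets <- integer(2L * n_edges)
  k <- 0L; tk <- 0L
  if (m > 1L) {
    for (i in 1:(m - 1L)) for (j in (i + 1L):m) {
      k <- k + 1L
      from[k] <- i; to[k] <- j
      targets[tk + 1L] <- i; targets[tk + 2L] <- j
      tk <- tk + 2L
    }
  }
  start <- m + 1L
  if (m == 1L && tk == 0L) {
    # single seed node has degree 0; first attachment is forced to node 1
    k <- k + 1L
    from[k] <- 1L; to[k] <- 2L
    targets[1:2] <- c(1L, 2L); tk <- 2L
    start <- 3L
  }
  if (start <= n) for (v in start:n) {
    chosen <- integer(0)
    while (length(chosen) < m) {
      cand <- targets[sample.int(tk, m - length(chosen), replace = TRUE)]
      chosen <- unique(c(chosen, cand))
    }
    for (u in chosen) {
      k <- k + 1L
      from[k] <- u; to[k] <- v
      targets[tk + 1L] <- u; targets[tk + 2L] <- v
      tk <- tk + 2L
    }
  }
  structure(list(n_nodes = n, edges = cbind(from = from, to = to),
                 attachment_m = m, seed = as.integer(seed)),
            class = "sedpnr_network")
}

#' @export
print.sedpnr_network <- function(x, ...) {
  cat("Scale-free network: ", x$n_nodes, " nodes, ", nrow(x$edges),
      " edges (m = ", x$attachment_m, ", seed = ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Node degrees of a network
#' @param net a `sedpnr_network`.
#' @return integer vector of degrees, one per node.
#' @export
node_degrees <- function(net) {
  tabulate(c(net$edges[, 1L], net$edges[, 2L]), nbins = net$n_nodes)
}

#' Stochastic SEDPNR dynamics on a network
#'
#' Synchronous discrete-time per-node transitions: at every integer step
#' each node draws one categorical transition with the model rates read as
#' per-step probabilities. S moves to E with probability `alpha`
#' (`hazard_mode = "constant"`) or `alpha` times the fraction of its
#' neighbors in P or N (`"neighbor"`); E moves to D/P/N/S with
#' probabilities `gamma`/`beta1`/`beta2`/`mu1`; D moves to P/N/S with
#' `beta3`/`beta4`/`mu2`; P and N move to R with `lambda1`/`lambda2`; R is
#' absorbing. One global RNG stream, node order ascending, so runs are
#' reproducible for a fixed seed. In constant mode the per-step expectation
#' of the counts obeys the forward-Euler recursion of the ODE system
#' exactly.
#'
#' @param net a `sedpnr_network`.
#' @param params a [sedpnr_params]; every compartment's total outflow must
#'   be a valid probability (<= 1).
#' @param init character vector of length `n_nodes` with values in
#'   `S,E,D,P,N,R`, or a named count vector (see [initial_node_states]).
#' @param t_end number of steps.
#' @param seed integer random seed.
#' @param hazard_mode `"constant"` (default; faithful to the linear ODE) or
#'   `"neighbor"` (contact-dependent exposure).
#' @return list with `counts` (data.frame `step,S,E,D,P,N,R`, one row per
#'   step 0..t_end), `final_states` (character vector per node),
#'   `hazard_mode` and `seed`.
#' @export
simulate_network <- function(net, params, init, t_end, seed = 0L,
                             hazard_mode = c("constant", "neighbor")) {
  hazard_mode <- match.arg(hazard_mode)
  ofl <- outflow_rates(params)
  if (any(ofl > 1 + 1e-12))
    stop("outflow probabilities exceed 1 for compartment '",
         names(ofl)[which(ofl > 1 + 1e-12)[1L]], "'")
  labels <- c("S", "E", "D", "P", "N", "R")
  if (is.character(init)) {
    if (length(init) != net$n_nodes)
      stop("init must have one state per node")
    if (!all(init %in% labels)) stop("invalid node state label in init")
    st <- match(init, labels)
  } else stop("init must be a character vector of node states")
  t_end <- as.integer(t_end)

  old_seed <- local_seed(seed)
  on.exit(restore_seed(old_seed), add = TRUE)
  pl <- unclass(params)

  nbr <- NULL
  deg <- NULL
  if (hazard_mode == "neighbor") {
    nbr <- net$edges
    deg <- node_degrees(net)
  }

  counts <- matrix(0L, nrow = t_end + 1L, ncol = 6L,
                   dimnames = list(NULL, labels))
  counts[1L, ] <- tabulate(st, 6L)
  n <- net$n_nodes

  for (step in seq_len(t_end)) {
    u <- stats::runif(n)
    new <- st
    isS <- st == 1L
    if (any(isS)) {
      if (hazard_mode == "constant") {
        p_inf <- pl$alpha
        new[isS & u < p_inf] <- 2L
      } else {
        inf <- st == 4L | st == 5L
        inf_deg <- tabulate(c(nbr[inf[nbr[, 2L]], 1L],
                              nbr[inf[nbr[, 1L]], 2L]), nbins = n)
        frac <- ifelse(deg > 0, inf_deg / deg, 0)
        new[isS & u < pl$alpha * frac] <- 2L
      }
    }
    isE <- st == 2L
    if (any(isE)) {
      uu <- u[isE]
      # ordered thresholds: D, P, N, S, stay
      c1 <- pl$gamma; c2 <- c1 + pl$beta1; c3 <- c2 + pl$beta2
      c4 <- c3 + pl$mu1
      dest <- ifelse(uu < c1, 3L,
              ifelse(uu < c2, 4L,
              ifelse(uu < c3, 5L,
              ifelse(uu < c4, 1L, 2L))))
      new[isE] <- dest
    }
    isD <- st == 3L
    if (any(isD)) {
      uu <- u[isD]
      c1 <- pl$beta3; c2 <- c1 + pl$beta4; c3 <- c2 + pl$mu2
      dest <- ifelse(uu < c1, 4L,
              ifelse(uu < c2, 5L,
              ifelse(uu < c3, 1L, 3L)))
      new[isD] <- dest
    }
    isP <- st == 4L
    new[isP & u < pl$lambda1] <- 6L
    isN <- st == 5L
    new[isN & u < pl$lambda2] <- 6L
    st <- new
    counts[step + 1L, ] <- tabulate(st, 6L)
  }
  list(counts = data.frame(step = 0:t_end, counts),
       final_states = labels[st],
       hazard_mode = hazard_mode, seed = as.integer(seed))
}

#' Build an initial node-state vector from compartment counts
#'
#' Places the requested number of nodes in each compartment. Non-susceptible
#' seeds are placed uniformly at random by default, or on the highest-degree
#' nodes (`placement = "superspreader"`), or at explicit indices.
#'
#' @param net a `sedpnr_network`.
#' @param counts named vector of per-compartment counts (names among
#'   `S,E,D,P,N,R`), summing to `n_nodes`.
#' @param seed seed for random placement.
#' @param placement `"random"`, `"superspreader"`, or an integer vector of
#'   node indices to receive the non-S states (in order E,D,P,N,R).
#' @return character vector of node states.
#' @export
initial_node_states <- function(net, counts, seed = 0L,
                                placement = "random") {
  labels <- c("S", "E", "D", "P", "N", "R")
  full <- stats::setNames(rep(0, 6L), labels)
  full[names(counts)] <- counts
  if (sum(full) != net$n_nodes)
    stop("counts must sum to n_nodes (", net$n_nodes, "), got ", sum(full))
  st <- rep("S", net$n_nodes)
  n_seed <- sum(full[-1L])
  if (n_seed == 0) return(st)
  if (is.numeric(placement)) {
    idx <- as.integer(placement)
    if (length(idx) != n_seed) stop("placement index length mismatch")
  } else if (identical(placement, "superspreader")) {
    idx <- identify_superspreaders(net, n_seed)
  } else {
    old_seed <- local_seed(seed)
    on.exit(restore_seed(old_seed), add = TRUE)
    idx <- sample.int(net$n_nodes, n_seed)
  }
  st[idx] <- rep(labels[-1L], times = full[-1L])
  st
}

#' Fit a discrete power law to a degree sequence
#'
#' Maximum-likelihood exponent with the lower cutoff `xmin` chosen by
#' Kolmogorov–Smirnov distance minimization (Clauset-style, via igraph's
#' plfit implementation).
#'
#' @param degrees integer vector of node degrees (at least 50 positive
#'   values).
#' @return list of class `sedpnr_powerlaw`: `exponent`, `xmin`,
#'   `ks_stat`, `method`, `degenerate` (TRUE when all degrees are equal,
#'   in which case the exponent is `NA`).
#' @export
fit_power_law <- function(degrees) {
  degrees <- degrees[degrees > 0]
  if (length(degrees) < 50L)
    stop("fit_power_law requires at least 50 positive degrees")
  if (length(unique(degrees)) == 1L)
    return(structure(list(exponent = NA_real_, xmin = degrees[1L],
                          ks_stat = NA_real_, method = "plfit",
                          degenerate = TRUE),
                     class = "sedpnr_powerlaw"))
  fit <- igraph::fit_power_law(degrees, implementation = "plfit")
  structure(list(exponent = fit$alpha, xmin = fit$xmin,
                 ks_stat = fit$KS.stat, method = "plfit",
                 degenerate = FALSE),
            class = "sedpnr_powerlaw")
}

#' @export
print.sedpnr_powerlaw <- function(x, ...) {
  if (x$degenerate) cat("Power-law fit: degenerate (all degrees equal)\n")
  else cat("Power-law fit: exponent ", format(x$exponent), ", xmin ",
           x$xmin, " (", x$method, ")\n", sep = "")
  invisible(x)
}

#' Identify super-spreader nodes
#'
#' The `top_k` nodes by degree; ties broken by lower node index.
#'
#' @param net a `sedpnr_network`.
#' @param top_k number of nodes to return (1..n_nodes).
#' @return integer vector of node indices, degree-descending.
#' @export
identify_superspreaders <- function(net, top_k) {
  if (top_k < 1 || top_k > net$n_nodes)
    stop("top_k must be in [1, n_nodes]")
  deg <- node_degrees(net)
  ord <- order(-deg, seq_along(deg))
  ord[seq_len(top_k)]
}

# seed helpers: set the RNG reproducibly, restoring prior state afterwards
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
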