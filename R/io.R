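#' Named parameter/initial-condition fixtures
#'
#' Immutable bundles of published parameter sets and initial conditions
#' used throughout the package's examples and tests:
#' \describe{
#'   \item{`sensitivity_a01` / `sensitivity_a02`}{sensitivity runs with
#'     `alpha` 0.1 / 0.2, `gamma` 0.025, all `beta` 0.05, `lambda` 0.035,
#'     `mu1` 0.01, `mu2` 0.1; init (299990, 0, 0, 5, 5, 0).}
#'   \item{`analysisR_200k`}{the same rates on a 200,000 population,
#'     init (199990, 10, 10, 5, 5, 0).}
#'   \item{`boundedness_low` / `boundedness_high`}{balanced vs elevated
#'     transmission (`beta1/beta3` 0.075 vs 0.75, `beta2/beta4` 0.06 vs
#'     0.6) on the 200,000 population.}
#'   \item{`intervention_fig8`}{high-transmission setting for intervention
#'     scenarios: `alpha` 0.1, `gamma` 0.1, `beta1` 0.5, `beta2` 0.4,
#'     `beta3` 0.5, `beta4` 0.6, `lambda` 0.01, `mu` 0.05; init
#'     (199990, 10, 10, 5, 5, 0).}
#'   \item{`table2_rates`}{baseline comparison rates: infection 0.1,
#'     recovery 0.035, population 300,000 with 10 initially infected.}
#' }
#'
#' @param name fixture name.
#' @return list with `params` (a [sedpnr_params], or for `table2_rates` a
#'   list with `beta`, `gamma`), `init` and where relevant `t_end`.
#' @export
fixtures <- function(name) {
  sens <- function(alpha) list(
    params = sedpnr_params(alpha = alpha, gamma = 0.025,
                           beta1 = 0.05, beta2 = 0.05, beta3 = 0.05,
                           beta4 = 0.05, lambda1 = 0.035, lambda2 = 0.035,
                           mu1 = 0.01, mu2 = 0.1),
    init = sedpnr_state(s = 299990, p = 5, n = 5), t_end = 100)
  # the high-transmission bundles exceed the per-step outflow bound and are
  # meant for adaptive integration; the validation warning is muted here
  # because the published values are fixed
  bound <- function(b13, b24) list(
    params = suppressWarnings(
      sedpnr_params(alpha = 0.1, gamma = 0.025,
                    beta1 = b13, beta2 = b24, beta3 = b13,
                    beta4 = b24, lambda1 = 0.035, lambda2 = 0.035,
                    mu1 = 0.01, mu2 = 0.1)),
    init = sedpnr_state(s = 199990, e = 10, d = 10, p = 5, n = 5),
    t_end = 100)
  all <- list(
    sensitivity_a01 = function() sens(0.1),
    sensitivity_a02 = function() sens(0.2),
    analysisR_200k = function() {
      f <- sens(0.1)
      f$init <- sedpnr_state(s = 199990, e = 10, d = 10, p = 5, n = 5)
      f
    },
    boundedness_low = function() bound(0.075, 0.06),
    boundedness_high = function() bound(0.75, 0.6),
    intervention_fig8 = function() list(
      params = suppressWarnings(
        sedpnr_params(alpha = 0.1, gamma = 0.1, beta1 = 0.5,
                      beta2 = 0.4, beta3 = 0.5, beta4 = 0.6,
                      lambda1 = 0.01, lambda2 = 0.01,
                      mu1 = 0.05, mu2 = 0.05)),
      init = sedpnr_state(s = 199990, e = 10, d = 10, p = 5, n = 5),
      t_end = 100),
    table2_rates = function() list(
      params = list(beta = 0.1, gamma = 0.035),
      init = c(S = 299990, I = 10), population = 3e5, t_end = 100)
  )
  if (!name %in% names(all))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(all), collapse = ", "))
  all[[name]]()
}

#' Write / read a trajectory as CSV
#'
#' Canonical trajectory format: header `time,s,e,d,p,n,r`, one row per
#' sampled step, full floating-point precision (round-trips exactly).
#'
#' @param traj a `sedpnr_trajectory` (or data.frame with those columns).
#' @param path file path.
#' @return `write_trajectory_csv` returns `path` invisibly;
#'   `read_trajectory_csv` returns the trajectory data.frame.
#' @export
write_trajectory_csv <- function(traj, path) {
  cols <- c("time", state_names)
  if (!all(cols %in% names(traj)))
    stop("trajectory must have columns ", paste(cols, collapse = ","))
  df <- as.data.frame(traj)[, cols]
  # format with full precision so the round-trip is exact
  out <- vapply(seq_len(nrow(df)), function(i)
    paste(vapply(df[i, ], function(v) format(v, digits = 17), ""),
          collapse = ","), "")
  writeLines(c(paste(cols, collapse = ","), out), path)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  cols <- c("time", state_names)
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  if (!identical(header, cols))
    stop("trajectory CSV header mismatch: expected '",
         paste(cols, collapse = ","), "', got '",
         paste(header, collapse = ","), "'")
  df <- utils::read.csv(path, colClasses = "numeric")
  if (anyNA(df)) stop("malformed trajectory CSV (ragged or non-numeric)")
  class(df) <- c("sedpnr_trajectory", "data.frame")
  df
}

#' Write / read a network edge list
#'
#' Two whitespace-separated integer columns, one edge per line (standard
#' edge-list dialect, 1-based node indices as stored).
#'
#' @param net a `sedpnr_network`.
#' @param path file path.
#' @param n_nodes node count when reading (inferred from the maximum index
#'   if omitted).
#' @return `write_edge_list` returns `path` invisibly; `read_edge_list`
#'   returns a `sedpnr_network`.
#' @export
write_edge_list <- function(net, path) {
  writeLines(paste(net$edges[, 1L], net$edges[, 2L]), path)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path, n_nodes = NULL) {
  m <- as.matrix(utils::read.table(path, col.names = c("from", "to"),
                                   colClasses = "integer"))
  if (is.null(n_nodes)) n_nodes <- max(m)
  structure(list(n_nodes = as.integer(n_nodes), edges = m,
                 attachment_m = NA_integer_, seed = NA_integer_),
            class = "sedpnr_network")
}

config_keys <- c("command", "alpha", "beta1", "beta2", "beta3", "beta4",
                 "gamma", "lambda1", "lambda2", "mu1", "mu2",
                 "init_s", "init_e", "init_d", "init_p", "init_n", "init_r",
                 "t_end", "scheme", "step_size", "seed")

#' Load and validate a run configuration
#'
#' Flat JSON object with the rate keys `alpha, beta1..beta4, gamma,
#' lambda1, lambda2, mu1, mu2`, initial counts `init_s..init_r`, and
#' `t_end`, `scheme` (`"adaptive"`/`"euler"`), `step_size`, `seed`.
#' Unknown keys are rejected by name; missing optional keys receive
#' defaults (rates and inits 0, `t_end` 100, scheme adaptive, seed 0).
#'
#' @param path path to a JSON config file.
#' @return list of class `sedpnr_config` with `params` ([sedpnr_params]),
#'   `init` ([sedpnr_state]), `t_end`, `scheme` ([integration_scheme]) and
#'   `seed`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("malformed JSON in ", path, ": ",
                                           conditionMessage(e)))
  unknown <- setdiff(names(cfg), config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  getd <- function(key, default) if (!is.null(cfg[[key]])) cfg[[key]]
                                 else default
  rate_names <- c("alpha", "beta1", "beta2", "beta3", "beta4", "gamma",
                  "lambda1", "lambda2", "mu1", "mu2")
  rates <- lapply(rate_names, getd, default = 0)
  names(rates) <- rate_names
  for (nm in rate_names)
    if (!is.numeric(rates[[nm]]) || rates[[nm]] < 0)
      stop("config rate '", nm, "' must be a non-negative number")
  params <- do.call(sedpnr_params, rates)
  init <- sedpnr_state(s = getd("init_s", 0), e = getd("init_e", 0),
                       d = getd("init_d", 0), p = getd("init_p", 0),
                       n = getd("init_n", 0), r = getd("init_r", 0))
  scheme <- integration_scheme(getd("scheme", "adaptive"),
                               getd("step_size", 1))
  structure(list(command = getd("command", "simulate"),
                 params = params, init = init,
                 t_end = getd("t_end", 100), scheme = scheme,
                 seed = as.integer(getd("seed", 0))),
            class = "sedpnr_config")
}

#' Write a run configuration as JSON
#'
#' Inverse of [load_config]; write-then-load round-trips exactly.
#'
#' @param config a `sedpnr_config` (or compatible list).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  init <- as_state_vector(config$init)
  flat <- c(list(command = config$command), unclass(config$params),
            as.list(stats::setNames(unname(init),
                                    paste0("init_", names(init)))),
            list(t_end = config$t_end, scheme = config$scheme$kind,
                 step_size = config$scheme$step_size, seed = config$seed))
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# metadata JSON accompanying every CLI run, sufficient for re-running
write_run_metadata <- function(path, command, seed, scheme = NULL,
                               extra = list()) {
  meta <- c(list(command = command, seed = seed,
                 package_version =
                   as.character(utils::packageVersion("sedpnr"))),
            if (!is.null(scheme)) list(scheme = scheme$kind,
                                       step_size = scheme$step_size),
            extra)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
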