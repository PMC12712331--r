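#' Model parameters for the covariant-tempo birth-death process
#'
#' Bundles the four rates of the model: baseline speciation rate
#' \eqn{\lambda} and extinction rate \eqn{\mu} (both per species per myr,
#' multiplied at any instant by the tempo \eqn{\tau = e^x} of the species),
#' the mean-reversion rate \eqn{\theta} of log-tempo (1/myr), and the
#' stationary standard-deviation scale \eqn{s} of log-tempo (dimensionless).
#' The derived net diversification rate \eqn{r = \lambda - \mu} is stored
#' alongside.
#'
#' The defaults are the package's reference parameter set: a near-critical
#' process (\eqn{\lambda = 0.51}, \eqn{\mu = 0.5}) in which a typical species
#' persists for about 1 myr, with slow mean reversion \eqn{\theta = 0.01}
#' chosen equal to \eqn{r} so that the equilibrium mean log-tempo is zero,
#' and \eqn{s = 1}.
#'
#' @param lambda_rate Baseline speciation rate, per species per myr. Must be
#'   positive.
#' @param mu_rate Baseline extinction rate, per species per myr. Must be
#'   non-negative.
#' @param theta Mean-reversion rate of log-tempo, 1/myr. Must be
#'   non-negative.
#' @param s Stationary standard-deviation scale of log-tempo. Must be
#'   non-negative.
#'
#' @return An object of class `cet_params`: a list with elements
#'   `lambda_rate`, `mu_rate`, `theta`, `s` and the derived `r`.
#' @examples
#' p <- cet_params()
#' p$r
#' cet_params(0.5, 0.5, 0.01, 1)$r # critical case
#' @export
cet_params <- function(lambda_rate = 0.51, mu_rate = 0.5, theta = 0.01,
                       s = 1) {
  check_scalar <- function(value, name) {
    if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
      stop(sprintf("%s must be a finite numeric scalar", name), call. = FALSE)
    }
  }
  check_scalar(lambda_rate, "lambda_rate")
  check_scalar(mu_rate, "mu_rate")
  check_scalar(theta, "theta")
  check_scalar(s, "s")
  if (lambda_rate <= 0) stop("lambda_rate must be > 0", call. = FALSE)
  if (mu_rate < 0) stop("mu_rate must be ≥ 0", call. = FALSE)
  if (theta < 0) stop("theta must be ≥ 0", call. = FALSE)
  if (s < 0) stop("s must be ≥ 0", call. = FALSE)
  structure(
    list(lambda_rate = lambda_rate, mu_rate = mu_rate, theta = theta, s = s,
         r = lambda_rate - mu_rate),
    class = "cet_params"
  )
}

#' @export
print.cet_params <- function(x, ...) {
  cat("Covariant-tempo birth-death parameters\n")
  cat(sprintf("  lambda = %g, mu = %g  (r = %g) per species per myr\n",
              x$lambda_rate, x$mu_rate, x$r))
  cat(sprintf("  theta  = %g /myr, s = %g\n", x$theta, x$s))
  invisible(x)
}

#' @export
tidy.cet_params <- function(x, ...) {
  tibble(
    term = c("lambda_rate", "mu_rate", "theta", "s", "r"),
    value = c(x$lambda_rate, x$mu_rate, x$theta, x$s, x$r)
  )
}

#' Uniform discretisation of log-tempo
#'
#' The log-tempo axis \eqn{x = \log\tau} is discretised on a uniform grid.
#' All solvers in the package share this grid; the boundary policy is
#' zero-flux (reflecting) at both ends, which conserves probability mass and
#' is innocuous when the boundaries are far outside the stationary bulk of
#' the process (the default range is \eqn{-10 < x < 10}, ten standard
#' deviations at `s = 1`).
#'
#' @param x_min,x_max Grid bounds; `x_min < 0 < x_max` required.
#' @param n_x Number of grid points, at least 51.
#' @return An object of class `cet_grid` with elements `x_min`, `x_max`,
#'   `n_x`, `dx`, `x` (the node coordinates) and `boundary`.
#' @examples
#' g <- log_tempo_grid()
#' g$dx
#' @export
log_tempo_grid <- function(x_min = -10, x_max = 10, n_x = 201L) {
  if (!is.numeric(x_min) || !is.numeric(x_max) || x_min >= 0 || x_max <= 0) {
    stop("grid must satisfy x_min < 0 < x_max", call. = FALSE)
  }
  n_x <- as.integer(n_x)
  if (is.na(n_x) || n_x < 51L) stop("n_x must be ≥ 51", call. = FALSE)
  dx <- (x_max - x_min) / (n_x - 1)
  structure(
    list(x_min = x_min, x_max = x_max, n_x = n_x, dx = dx,
         x = seq(x_min, x_max, length.out = n_x), boundary = "zero-flux"),
    class = "cet_grid"
  )
}

#' @export
print.cet_grid <- function(x, ...) {
  cat(sprintf("log-tempo grid: [%g, %g], %d points (dx = %g), %s boundaries\n",
              x$x_min, x$x_max, x$n_x, x$dx, x$boundary))
  invisible(x)
}

# Index of the grid node nearest to x0; errors if x0 does not lie (almost)
# exactly on a node, since point-mass initial conditions are node-aligned.
grid_index <- function(grid, x0, exact = TRUE) {
  i <- which.min(abs(grid$x - x0))
  if (exact && abs(grid$x[i] - x0) > 1e-9 * max(1, abs(x0)) + 1e-12) {
    stop(sprintf("x0 = %g is not a grid node (nearest: %g)", x0, grid$x[i]),
         call. = FALSE)
  }
  i
}

#' Run configuration
#'
#' Assembles parameters, grid and run settings into a single validated
#' object, as read from / written to flat YAML config files.
#'
#' @param params A [cet_params()] object.
#' @param grid A [log_tempo_grid()] object.
#' @param t_max Time horizon in myr; positive.
#' @param dt Time step in myr; positive, at most 1 by default use.
#' @param seed Integer RNG seed.
#' @param output_dir Output directory for table-writing commands.
#' @return An object of class `cet_config`.
#' @export
cet_config <- function(params = cet_params(), grid = log_tempo_grid(),
                       t_max = 500, dt = 0.25, seed = 0L,
                       output_dir = ".") {
  stopifnot(inherits(params, "cet_params"), inherits(grid, "cet_grid"))
  if (!is.numeric(t_max) || t_max <= 0) stop("t_max must be > 0", call. = FALSE)
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  structure(
    list(params = params, grid = grid, t_max = t_max, dt = dt,
         seed = as.integer(seed), output_dir = output_dir),
    class = "cet_config"
  )
}

config_keys <- c("lambda", "mu", "theta", "s", "x_min", "x_max", "n_x",
                 "t_max", "dt", "seed", "output_dir")

#' Read a run configuration from a flat YAML file
#'
#' The file is a flat key-value list; recognised keys are `lambda`, `mu`,
#' `theta`, `s`, `x_min`, `x_max`, `n_x`, `t_max`, `dt`, `seed`,
#' `output_dir`. Missing keys take the package defaults (the reference
#' parameter set, the \eqn{[-10, 10]} grid with 201 nodes, `t_max = 500`,
#' `dt = 0.25`, `seed = 0`); unknown keys produce a warning.
#'
#' @param path Path to a readable config file. An empty file yields the full
#'   default configuration.
#' @return A [cet_config()] object.
#' @seealso [write_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop(sprintf("could not parse config file %s: %s", path,
                 conditionMessage(e)), call. = FALSE)
  })
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config file must be a flat key-value mapping",
                          call. = FALSE)
  unknown <- setdiff(names(raw), config_keys)
  if (length(unknown) > 0) {
    warning(sprintf("ignoring unknown config keys: %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  }
  defaults <- list(lambda = 0.51, mu = 0.5, theta = 0.01, s = 1,
                   x_min = -10, x_max = 10, n_x = 201L, t_max = 500,
                   dt = 0.25, seed = 0L, output_dir = ".")
  conf <- modifyList(defaults, raw[intersect(names(raw), config_keys)])
  for (key in setdiff(config_keys, "output_dir")) {
    if (!is.numeric(conf[[key]]) || length(conf[[key]]) != 1L) {
      stop(sprintf("config key '%s' must be a single number", key),
           call. = FALSE)
    }
  }
  cet_config(
    params = cet_params(conf$lambda, conf$mu, conf$theta, conf$s),
    grid = log_tempo_grid(conf$x_min, conf$x_max, conf$n_x),
    t_max = conf$t_max, dt = conf$dt, seed = conf$seed,
    output_dir = conf$output_dir
  )
}

#' Write a run configuration to a flat YAML file
#'
#' @param config A [cet_config()] object.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @seealso [load_config()]
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "cet_config"))
  out <- list(
    lambda = config$params$lambda_rate, mu = config$params$mu_rate,
    theta = config$params$theta, s = config$params$s,
    x_min = config$grid$x_min, x_max = config$grid$x_max,
    n_x = config$grid$n_x, t_max = config$t_max, dt = config$dt,
    seed = config$seed, output_dir = config$output_dir
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
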