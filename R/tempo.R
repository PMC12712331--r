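#' Evolution of the tempo distribution across a clade
#'
#' The density \eqn{p(t, x)} of log-tempos among species alive at time
#' \eqn{t} obeys a replicator-mutation equation: faster-tempo species
#' over-produce descendants (selection-like term \eqn{r p (e^x - \langle
#' e^x\rangle)}) while anagenetic diffusion of tempo acts as mutation,
#' \deqn{\partial p/\partial t = r p\,(e^x - \langle e^x \rangle) +
#'   \theta\,\partial(x e^x p)/\partial x + s^2\theta\,\partial^2(e^x
#'   p)/\partial x^2.}
#' The solver marches the equivalent unnormalised linear equation (growth
#' term \eqn{r e^x u}) and renormalises every step; the \eqn{\langle
#' e^x\rangle} term of the nonlinear form is exactly the normalisation
#' drift. Point-mass initial conditions are realised as a single-cell spike
#' of unit mass.
#'
#' @param x0_or_density Either a single starting log-tempo (grid node) or a
#'   numeric vector of length `grid$n_x` giving an initial density.
#' @param t_grid Times (myr) at which to report the density; the first may
#'   be 0.
#' @param params,grid Model parameters and grid.
#' @param dt Time step (myr).
#' @return A tibble of class `cet_tempo_paths` with columns `t`, `x` and
#'   `density` (long format, normalised to unit integral at each time).
#' @examples
#' p <- evolve_tempo_density(0, c(0, 10), cet_params(), log_tempo_grid(n_x = 101))
#' @export
evolve_tempo_density <- function(x0_or_density, t_grid, params, grid,
                                 dt = 0.25) {
  stopifnot(inherits(params, "cet_params"), inherits(grid, "cet_grid"))
  t_grid <- sort(unique(t_grid))
  if (any(t_grid < 0)) stop("t_grid must be non-negative", call. = FALSE)
  u <- initial_density(x0_or_density, grid)
  fwd <- build_forward_operator(grid, params, growth_rate = params$r)
  out <- vector("list", length(t_grid))
  t_now <- 0
  first <- TRUE
  for (k in seq_along(t_grid)) {
    gap <- t_grid[k] - t_now
    if (gap > 1e-12) {
      if (params$theta == 0) {
        # no tempo diffusion: the equation is diagonal and solves exactly,
        # u(t) = u(0) exp(r e^x t) up to normalisation (done in log space)
        lg <- ifelse(u > 0, log(u), -Inf) + params$r * exp(grid$x) * gap
        u <- exp(lg - max(lg))
        u <- u / (sum(u) * grid$dx)
      } else {
        plan <- step_plan(gap, dt)
        res <- march_theta(u, fwd$matrix, plan$dt, plan$n,
                           n_implicit = if (first) 2L else 0L,
                           renorm = TRUE, dx = grid$dx)
        u <- res$field
      }
      first <- FALSE
      t_now <- t_grid[k]
    }
    if (min(u) < -1e-8) {
      stop(sprintf("tempo density went negative (min %.3g) at t = %g",
                   min(u), t_now), call. = FALSE)
    }
    out[[k]] <- tibble(t = t_grid[k], x = grid$x, density = pmax(u, 0))
  }
  structure(dplyr::bind_rows(out),
            class = c("cet_tempo_paths", class(tibble())),
            params = params)
}

initial_density <- function(x0_or_density, grid) {
  if (length(x0_or_density) == 1L) {
    u <- numeric(grid$n_x)
    u[grid_index(grid, x0_or_density)] <- 1 / grid$dx
    u
  } else if (length(x0_or_density) == grid$n_x) {
    u <- as.numeric(x0_or_density)
    if (any(u < 0)) stop("initial density must be non-negative",
                         call. = FALSE)
    m <- sum(u) * grid$dx
    if (m <= 0) stop("initial density has no mass", call. = FALSE)
    u / m
  } else {
    stop("x0_or_density must be a scalar or a density over the grid",
         call. = FALSE)
  }
}

#' Equilibrium distribution of log-tempo
#'
#' Time-marches the replicator-mutation equation until the per-myr L1
#' change of the normalised density falls below `tol`. The fixed point of
#' the normalised march is the principal eigenfunction of the linear
#' growth operator, so the converged density is independent of the time
#' step used to reach it. When the net diversification rate is zero the
#' equilibrium is exactly Gaussian with mean \eqn{-1} and variance
#' \eqn{s^2}; when \eqn{r = \theta} its mean is 0; larger \eqn{r} (at
#' fixed \eqn{\theta}) shifts the equilibrium upward.
#'
#' @param params,grid Model parameters and grid.
#' @param tol Stationarity tolerance on the per-myr L1 change.
#' @param dt Time step (myr); the equilibrium itself does not depend on it.
#' @param t_max Give up (with an error) beyond this horizon (myr).
#' @param x_init Starting point mass; default 0.
#' @return A tibble of class `cet_density` with columns `x` and `density`,
#'   and attributes `mean`, `sd`, `t_converged` and `residual`.
#' @examples
#' eq <- equilibrium_density(cet_params(0.5, 0.5, 0.05, 1),
#'                           log_tempo_grid(n_x = 101), tol = 1e-8)
#' attr(eq, "mean") # close to -1 for r = 0
#' @export
equilibrium_density <- function(params, grid = log_tempo_grid(),
                                tol = 1e-10, dt = 1, t_max = 50000,
                                x_init = 0) {
  stopifnot(tol > 0)
  u <- initial_density(x_init, grid)
  fwd <- build_forward_operator(grid, params, growth_rate = params$r)
  res <- march_theta(u, fwd$matrix, dt, n_steps = ceiling(t_max / dt),
                     theta = 1, n_implicit = 2L, renorm = TRUE,
                     dx = grid$dx, stop_tol = tol)
  if (!is.na(res$residual) && res$residual >= tol) {
    stop(sprintf(
      "equilibrium not reached by t = %g myr (residual %.3g, tol %.3g)",
      t_max, res$residual, tol), call. = FALSE)
  }
  dens <- tibble(x = grid$x, density = pmax(res$field, 0))
  mom <- density_moments(dens)
  structure(dens, class = c("cet_density", class(tibble())),
            mean = mom$mean, sd = mom$sd,
            t_converged = res$steps * dt, residual = res$residual,
            params = params)
}

#' Mean and standard deviation of a log-tempo density
#'
#' @param density A tibble with columns `x` and `density`, normalised to
#'   unit integral (e.g. from [equilibrium_density()] or one time slice of
#'   [evolve_tempo_density()]).
#' @return A one-row tibble with columns `mean` and `sd`.
#' @export
density_moments <- function(density) {
  stopifnot(all(c("x", "density") %in% names(density)))
  dx <- diff(density$x[1:2])
  m <- sum(density$x * density$density) * dx
  v <- sum(density$x^2 * density$density) * dx - m^2
  tibble(mean = m, sd = sqrt(max(v, 0)))
}

#' Summarise tempo-density paths as mean and sd through time
#'
#' @param x A `cet_tempo_paths` tibble from [evolve_tempo_density()].
#' @param ... Unused.
#' @return A tibble with one row per time: `t`, `mean`, `sd`.
#' @export
tidy.cet_tempo_paths <- function(x, ...) {
  dplyr::group_by(x, .data$t) |>
    dplyr::group_modify(~ density_moments(.x)) |>
    dplyr::ungroup()
}

#' @export
glance.cet_density <- function(x, ...) {
  tibble(mean = attr(x, "mean"), sd = attr(x, "sd"),
         t_converged = attr(x, "t_converged"),
         residual = attr(x, "residual"))
}

#' Average tempo of a density
#'
#' \eqn{\langle e^x \rangle = \int e^x p(x)\,dx}, the clade-average tempo
#' multiplier of a log-tempo density.
#'
#' @inheritParams density_moments
#' @return A single number.
#' @export
mean_tempo <- function(density) {
  dx <- diff(density$x[1:2])
  sum(exp(density$x) * density$density) * dx
}
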