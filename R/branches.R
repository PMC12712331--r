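#' Distribution of branch durations
#'
#' A branch (a species) starting with log-tempo \eqn{x} terminates — by
#' speciation or extinction — at instantaneous rate \eqn{e^x(\lambda +
#' \mu)} while its tempo keeps diffusing, so branch durations are not
#' exponential. The termination-time density \eqn{f_x(t)} obeys
#' \deqn{\partial f_x/\partial t = e^x\big(-(\lambda+\mu) f_x - \theta
#'   x\,\partial f_x/\partial x + \theta s^2\,\partial^2 f_x/\partial
#'   x^2\big).}
#' The solver works with the branch survival function \eqn{S_x(t)} (same
#' operator applied to \eqn{S(0) = 1}), which preserves positivity, and
#' reports \eqn{f = -\partial S/\partial t} by centred differencing with
#' \eqn{f_x(0) = e^x(\lambda + \mu)} at the origin.
#'
#' @param x0 Starting log-tempo(s), grid nodes.
#' @param t_grid Increasing times from 0 (myr) at which to report the
#'   density.
#' @param params,grid Model parameters and grid.
#' @param dt Time step of the march (myr).
#' @return A tibble of class `cet_branch_density` with columns `x0`, `t`,
#'   `density` and `survival`, and attribute `kind = "duration"`.
#' @export
branch_duration_density <- function(x0, t_grid, params,
                                    grid = log_tempo_grid(), dt = 0.05) {
  stopifnot(inherits(params, "cet_params"), inherits(grid, "cet_grid"))
  t_grid <- sort(unique(t_grid))
  if (t_grid[1] < 0) stop("t_grid must start at or above 0", call. = FALSE)
  idx <- vapply(x0, function(v) grid_index(grid, v), integer(1))
  rate <- params$lambda_rate + params$mu_rate
  op <- build_backward_operator(grid, params)
  L <- backward_full_matrix(op, reaction_rate = -rate)
  s_field <- rep(1, grid$n_x)
  surv <- matrix(NA_real_, length(t_grid), length(x0))
  t_now <- 0
  for (k in seq_along(t_grid)) {
    gap <- t_grid[k] - t_now
    if (gap > 1e-12) {
      plan <- step_plan(gap, dt)
      s_field <- march_theta(s_field, L, plan$dt, plan$n)$field
      t_now <- t_grid[k]
    }
    surv[k, ] <- s_field[idx]
  }
  out <- purrr::map_dfr(seq_along(x0), function(j) {
    s <- surv[, j]
    f <- -num_deriv(t_grid, s)
    if (t_grid[1] == 0) f[1] <- exp(x0[j]) * rate
    if (min(f) < -1e-8) {
      stop(sprintf("duration density went negative (min %.3g) for x0 = %g",
                   min(f), x0[j]), call. = FALSE)
    }
    tibble(x0 = x0[j], t = t_grid, density = pmax(f, 0), survival = s)
  })
  structure(out, class = c("cet_branch_density", class(tibble())),
            kind = "duration", params = params)
}

# centred first derivative on a possibly non-uniform grid
num_deriv <- function(t, y) {
  n <- length(t)
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (t[2] - t[1])
  d[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) {
    d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  }
  d
}

#' Distribution of molecular change along a branch
#'
#' Measuring branch length in molecular change \eqn{w} (myr-equivalents:
#' the expected change accumulated in 1 myr at tempo \eqn{\tau = 1})
#' removes the tempo dependence entirely: \eqn{dw = e^x dt} rescales the
#' termination rate to the constant \eqn{\lambda + \mu}, so
#' \deqn{f_x(w) = (\lambda + \mu)\, e^{-(\lambda+\mu) w}}
#' for every starting log-tempo. Slow branches are long in time, fast
#' branches short, but all carry the same distribution of molecular
#' change. This closed form is returned directly;
#' [molecular_change_pde()] provides the grid solution of the transformed
#' equation for cross-checking that the tempo derivatives really do drop
#' out.
#'
#' @param w_grid Non-negative molecular lengths (myr-equivalents).
#' @param params A [cet_params()].
#' @param x0 Starting log-tempos to tabulate (the density is identical for
#'   each; kept for plotting parity with the duration curves).
#' @return A tibble of class `cet_branch_density` with columns `x0`, `w`
#'   and `density`, attribute `kind = "molecular"`.
#' @export
molecular_change_density <- function(w_grid, params, x0 = 0) {
  if (any(w_grid < 0)) stop("w_grid must be non-negative", call. = FALSE)
  rate <- params$lambda_rate + params$mu_rate
  out <- purrr::map_dfr(x0, function(v) {
    tibble(x0 = v, w = w_grid, density = rate * exp(-rate * w_grid))
  })
  structure(out, class = c("cet_branch_density", class(tibble())),
            kind = "molecular", params = params)
}

#' Grid solution of the molecular-change equation
#'
#' Marches the change-of-variables form
#' \deqn{\partial f_x/\partial w = -(\lambda+\mu) f_x - \theta x\,
#'   \partial f_x/\partial x + \theta s^2\,\partial^2 f_x/\partial x^2,}
#' (no \eqn{e^x} factor) from the constant initial condition
#' \eqn{f_x(0) = \lambda + \mu}. Because the initial condition is flat in
#' \eqn{x}, the drift and diffusion terms vanish identically and the
#' solution should equal the exponential closed form for every \eqn{x};
#' this function exists to verify that numerically.
#'
#' @param w Molecular length at which to evaluate (myr-equivalents).
#' @param params,grid Model parameters and grid.
#' @param dw Step in molecular length.
#' @return A tibble with columns `x` and `density`.
#' @export
molecular_change_pde <- function(w, params, grid = log_tempo_grid(),
                                 dw = 0.01) {
  rate <- params$lambda_rate + params$mu_rate
  D <- backward_diffusion_matrix(grid, params)
  L <- D - rate * Matrix::Diagonal(grid$n_x)
  f <- rep(rate, grid$n_x)
  if (w > 0) {
    plan <- step_plan(w, dw)
    f <- march_theta(f, L, plan$dt, plan$n)$field
  }
  tibble(x = grid$x, density = f)
}

#' Expected branch duration by starting log-tempo
#'
#' \eqn{E[T_{\mathrm{branch}}] = \int_0^\infty S_{x_0}(t)\,dt}, computed by
#' trapezoidal quadrature of the survival function, marched until the
#' survival at `x0` falls below `s_floor` (the remainder is bounded by the
#' slowest-tempo exponential tail and added as a bound check, not to the
#' estimate). Durations grow roughly like \eqn{e^{-x_0}}: slow starters
#' persist far longer in real time.
#'
#' @param x0 Starting log-tempo (grid node).
#' @param params,grid Model parameters and grid.
#' @param dt March/quadrature step (myr).
#' @param t_max Hard horizon (myr).
#' @param s_floor Stop once survival drops below this.
#' @return Expected duration in myr (a single number).
#' @export
expected_duration <- function(x0, params, grid = log_tempo_grid(),
                              dt = 0.05, t_max = 5000, s_floor = 1e-10) {
  i0 <- grid_index(grid, x0)
  rate <- params$lambda_rate + params$mu_rate
  op <- build_backward_operator(grid, params)
  L <- backward_full_matrix(op, reaction_rate = -rate)
  s_field <- rep(1, grid$n_x)
  total <- 0
  t_now <- 0
  s_prev <- 1
  chunk <- 40L
  while (t_now < t_max) {
    res <- march_theta(s_field, L, dt, chunk)
    s_field <- res$field
    total <- total + chunk_integral(s_prev, s_field[i0], chunk * dt)
    s_prev <- s_field[i0]
    t_now <- t_now + chunk * dt
    if (s_prev < s_floor) break
  }
  # analytic tail bound: beyond t_now survival decays at least at the
  # slowest achievable rate exp(x_min) * (lambda + mu)
  tail_bound <- s_prev / (exp(grid$x_min) * rate)
  attr(total, "tail_bound") <- tail_bound
  total
}

# integral of the survival over one chunk of length tau, interpolating
# exponentially between the endpoint values (exact when the termination
# rate is constant over the chunk)
chunk_integral <- function(s0, s1, tau) {
  if (s1 <= 0 || s0 <= 0) return((s0 + s1) / 2 * tau)
  lr <- log(s1 / s0)
  if (abs(lr) < 1e-10) return((s0 + s1) / 2 * tau)
  (s1 - s0) * tau / lr
}
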