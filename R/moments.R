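#' Expected number of species by starting log-tempo
#'
#' The mean clade size \eqn{N_x(t) = E[n \mid t, x]} obeys the linear
#' backward equation
#' \deqn{\partial N_x/\partial t = e^x\,(r N_x - \theta x\,\partial
#'   N_x/\partial x + s^2 \theta\,\partial^2 N_x/\partial x^2),}
#' with \eqn{N_x(0) = 1}; one march yields the mean for every starting
#' log-tempo simultaneously.
#'
#' @param t Clade age (myr).
#' @param params A [cet_params()].
#' @param grid A [log_tempo_grid()].
#' @param dt Time step (myr).
#' @param theta_scheme Implicitness weight of the marcher.
#' @return A tibble with columns `x` and `n_expected`.
#' @examples
#' mean_species(0, cet_params(), log_tempo_grid(n_x = 51))
#' @export
mean_species <- function(t, params, grid, dt = 0.25, theta_scheme = 0.5) {
  stopifnot(inherits(params, "cet_params"), inherits(grid, "cet_grid"))
  n_field <- rep(1, grid$n_x)
  if (t > 0) {
    op <- build_backward_operator(grid, params)
    L <- backward_full_matrix(op, reaction_rate = params$r)
    plan <- step_plan(t, dt)
    n_field <- march_theta(n_field, L, plan$dt, plan$n,
                           theta = theta_scheme)$field
  }
  if (max(n_field) > 1e30) {
    warning("expected species counts exceed 1e30; values capped",
            call. = FALSE)
    n_field <- pmin(n_field, 1e30)
  }
  tibble(x = grid$x, n_expected = n_field)
}

#' Second factorial moment of clade size
#'
#' \eqn{M_2 = E[n(n-1)]} is obtained by differentiating the
#' generating-function equation twice at \eqn{z = 1}:
#' \deqn{\partial M_2/\partial t = e^x\,(2\lambda N_x^2 + r M_2 - \theta
#'   x\,\partial M_2/\partial x + s^2\theta\,\partial^2 M_2/\partial
#'   x^2),\qquad M_2(0) = 0.}
#' The source term is integrated with a trapezoidal rule while the mean
#' field \eqn{N_x} is marched alongside.
#'
#' @inheritParams mean_species
#' @return A tibble with columns `x`, `n_expected` and `m2` (so that
#'   \eqn{E[n^2] = m2 + n_expected}).
#' @export
second_moment <- function(t, params, grid, dt = 0.25, theta_scheme = 0.5) {
  stopifnot(inherits(params, "cet_params"), inherits(grid, "cet_grid"))
  n_x <- grid$n_x
  ex <- exp(grid$x)
  n_field <- rep(1, n_x)
  m2 <- rep(0, n_x)
  if (t > 0) {
    op <- build_backward_operator(grid, params)
    L <- backward_full_matrix(op, reaction_rate = params$r)
    plan <- step_plan(t, dt)
    h <- plan$dt
    th <- theta_scheme
    M1 <- Matrix::Diagonal(n_x) - th * h * L
    M0 <- Matrix::Diagonal(n_x) + (1 - th) * h * L
    lam2ex <- 2 * params$lambda_rate * ex
    for (step in seq_len(plan$n)) {
      src_old <- lam2ex * n_field^2
      n_new <- as.numeric(Matrix::solve(M1, M0 %*% n_field))
      src_new <- lam2ex * n_new^2
      rhs <- as.numeric(M0 %*% m2) + h * ((1 - th) * src_old + th * src_new)
      m2 <- as.numeric(Matrix::solve(M1, rhs))
      n_field <- n_new
      if (any(!is.finite(m2))) {
        stop(sprintf("second-moment march produced non-finite values at t = %g",
                     step * h), call. = FALSE)
      }
    }
  }
  tibble(x = grid$x, n_expected = n_field, m2 = m2)
}

#' Size-biased (experienced) clade size
#'
#' The expected size of the clade containing a randomly chosen modern
#' species, among clades of the same age: \eqn{E[n^2]/E[n] = (M_2 + N)/N}.
#' Size-biasing means the answer is identical whether or not the
#' distribution is conditioned on survival, since extinct clades contribute
#' no species.
#'
#' @inheritParams mean_species
#' @param x0 Starting log-tempo (a grid node).
#' @return A single number (expected experienced clade size).
#' @export
experienced_size <- function(t, x0, params, grid = log_tempo_grid(),
                             dt = 0.25, theta_scheme = 0.5) {
  mom <- second_moment(t, params, grid, dt = dt,
                       theta_scheme = theta_scheme)
  i <- grid_index(grid, x0)
  n_val <- mom$n_expected[i]
  if (n_val <= 0) stop("expected clade size is zero; size-biased mean undefined",
                       call. = FALSE)
  (mom$m2[i] + n_val) / n_val
}

#' Diversification and lineage curves through time
#'
#' For each starting log-tempo, computes the expected number of species
#' through time (the linear mean equation) and the expected number of
#' *lineages* — species at time \eqn{t} with at least one descendant at the
#' horizon \eqn{T} — via the survival weighting
#' \deqn{L(t) = \int u(t, x)\,\big(1 - G_x(T - t, 0)\big)\,dx,}
#' where \eqn{u} is the unnormalised forward density of species over
#' log-tempo started from a point mass at `x0`. With `conditional = TRUE`
#' the curves are instead estimated by Monte Carlo restricted to replicates
#' that survive to \eqn{T}, with standard errors across surviving
#' replicates.
#'
#' @param T Horizon (myr).
#' @param x0 Vector of starting log-tempos (grid nodes).
#' @param params,grid Model parameters and grid.
#' @param conditional Condition on clade survival to `T` (Monte Carlo).
#' @param n_reps Number of simulation replicates per starting tempo when
#'   `conditional = TRUE` (at least 100).
#' @param seed RNG seed for the conditional simulation.
#' @param t_eval Times at which to report the curves; default 51 points.
#' @param dt Time step for the deterministic solves.
#' @param sim_dt Time step for the simulator.
#' @param cap Species cap per simulated clade.
#' @return A tibble of class `cet_curves` with columns `t`, `x0`,
#'   `species`, `lineages`, `se_species` (NA for deterministic curves) and
#'   `conditional`.
#' @export
diversification_curves <- function(T, x0 = c(-2, 0, 2),
                                   params = cet_params(),
                                   grid = log_tempo_grid(),
                                   conditional = FALSE, n_reps = 1000L,
                                   seed = 1L, t_eval = NULL, dt = 0.25,
                                   sim_dt = 0.1, cap = 1e6) {
  if (is.null(t_eval)) t_eval <- seq(0, T, length.out = 51)
  t_eval <- sort(unique(pmin(pmax(t_eval, 0), T)))
  if (conditional) {
    if (n_reps < 100) {
      stop("conditional curves need n_reps >= 100", call. = FALSE)
    }
    out <- purrr::map_dfr(seq_along(x0), function(j) {
      ens <- simulate_ensemble(params, x0[j], T, n_reps = n_reps,
                               seed = seed + j - 1L, dt = sim_dt, cap = cap,
                               t_eval = t_eval)
      ltt <- ens$ltt[ens$survived, , drop = FALSE]
      lin <- ens$lineages[ens$survived, , drop = FALSE]
      n_surv <- nrow(ltt)
      if (n_surv == 0) {
        stop(sprintf("no surviving replicates at x0 = %g", x0[j]),
             call. = FALSE)
      }
      tibble(
        t = t_eval, x0 = x0[j],
        species = colMeans(ltt),
        lineages = colMeans(lin),
        se_species = apply(ltt, 2, stats::sd) / sqrt(n_surv),
        conditional = TRUE
      )
    })
  } else {
    op <- build_backward_operator(grid, params)
    L <- backward_full_matrix(op, reaction_rate = params$r)
    # survival weight 1 - G_x(T - t, 0) for each requested time
    wt <- lapply(t_eval, function(tt) {
      1 - extinction_prob(T - tt, params, grid, dt = dt)$p_extinct
    })
    fwd <- build_forward_operator(grid, params, growth_rate = params$r)
    out <- purrr::map_dfr(x0, function(x_start) {
      i0 <- grid_index(grid, x_start)
      n_field <- rep(1, grid$n_x)
      u <- numeric(grid$n_x)
      u[i0] <- 1 / grid$dx
      species <- lineages <- numeric(length(t_eval))
      t_now <- 0
      for (k in seq_along(t_eval)) {
        gap <- t_eval[k] - t_now
        if (gap > 1e-12) {
          plan <- step_plan(gap, dt)
          n_field <- march_theta(n_field, L, plan$dt, plan$n)$field
          u <- march_theta(u, fwd$matrix, plan$dt, plan$n,
                           n_implicit = if (t_now == 0) 2L else 0L)$field
          t_now <- t_eval[k]
        }
        species[k] <- n_field[i0]
        lineages[k] <- sum(u * wt[[k]]) * grid$dx
      }
      tibble(t = t_eval, x0 = x_start, species = species,
             lineages = lineages, se_species = NA_real_,
             conditional = FALSE)
    })
  }
  structure(out, class = c("cet_curves", class(tibble())),
            T = T, params = params)
}
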