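#' Posterior log-tempo of direct ancestors of a random modern species
#'
#' Pick a species alive at the horizon \eqn{T} uniformly at random and
#' follow its lineage back to an ancestor of age \eqn{a} (i.e. living at
#' time \eqn{T - a}). With the clade founder drawn from the equilibrium
#' tempo distribution \eqn{p(x)}, the prior for any species' log-tempo is
#' \eqn{p(x)}, and the likelihood that a species with log-tempo \eqn{x} is
#' ancestral to a random modern taxon is proportional to the expected
#' number of modern descendants it will generate, \eqn{N_x(a)}. Bayes'
#' rule gives
#' \deqn{p(x \mid \mathrm{ancestor}) = \frac{p(x) N_x(a)}{\int p(x')
#'   N_{x'}(a)\, dx'}.}
#' At age 0 the likelihood is flat and the posterior is the equilibrium
#' prior; at older ages the posterior concentrates on elevated tempos.
#'
#' @param age Ancestor age (myr before the horizon), in \eqn{[0, T]}.
#' @param T Clade age at the horizon (myr); only `age` enters the
#'   computation, `T` bounds it.
#' @param params,grid Model parameters and grid.
#' @param prior Optional equilibrium prior (a `cet_density`); computed if
#'   missing.
#' @param dt Time step for the mean-species solve.
#' @return A tibble of class `cet_density` (columns `x`, `density`) with
#'   attributes `mean`, `sd`, `age` and `mode = "ancestor"`.
#' @export
ancestor_posterior <- function(age, T = 500, params = cet_params(),
                               grid = log_tempo_grid(), prior = NULL,
                               dt = 0.25) {
  if (age < 0 || age > T) stop("age must lie in [0, T]", call. = FALSE)
  if (is.null(prior)) prior <- equilibrium_density(params, grid)
  n_field <- mean_species(age, params, grid, dt = dt)$n_expected
  posterior_from_weight(prior$density * n_field, grid,
                        age = age, mode = "ancestor")
}

posterior_from_weight <- function(w, grid, age, mode) {
  norm <- sum(w) * grid$dx
  if (!is.finite(norm) || norm <= 1e-300) {
    stop("posterior normaliser underflowed", call. = FALSE)
  }
  dens <- tibble(x = grid$x, density = pmax(w / norm, 0))
  mom <- density_moments(dens)
  structure(dens, class = c("cet_density", class(tibble())),
            mean = mom$mean, sd = mom$sd, age = age, mode = mode)
}

#' Probability that a founder tempo yields a given modern diversity
#'
#' For every starting log-tempo on the grid, computes \eqn{P(n_T \in
#' [n_T(1-w), n_T(1+w)] \mid x_0)} from one batched contour inversion of
#' the generating function at horizon `T`. The window (default \eqn{\pm
#' 10\%}) stabilises the conditioning on a single huge clade size. For
#' windows that reach sizes close to the truncation \eqn{M}, the default
#' contour damping is relaxed to \eqn{\rho = 10^{-2/M}} so that the
#' \eqn{\rho^{-n}} inversion factor does not amplify FFT round-off.
#'
#' @param T Horizon (myr).
#' @param n_T Conditioned modern clade size.
#' @param params,grid Model parameters and grid.
#' @param window Relative half-width of the diversity window.
#' @param M Contour size (power of two), at least the upper window edge;
#'   default the smallest power of two above it.
#' @param radius Contour radius; default \eqn{10^{-2/M}}.
#' @param dt PDE time step.
#' @param batch_size Passed to [solve_gf()].
#' @return A tibble with columns `x` and `weight`.
#' @export
historical_member_weights <- function(T, n_T, params = cet_params(),
                                      grid = log_tempo_grid(),
                                      window = 0.1, M = NULL,
                                      radius = NULL, dt = 0.25,
                                      batch_size = 16384L) {
  n_lo <- max(1, ceiling(n_T * (1 - window)))
  n_hi <- floor(n_T * (1 + window))
  if (is.null(M)) M <- 2^ceiling(log2(n_hi + 1))
  M <- as.integer(M)
  if (bitwAnd(M, M - 1L) != 0L) stop("M must be a power of two",
                                     call. = FALSE)
  if (n_hi >= M) stop(sprintf("M = %d too small for window up to n = %d",
                              M, n_hi), call. = FALSE)
  if (is.null(radius)) radius <- 10^(-2 / M)
  k <- 0:(M %/% 2)
  z <- radius * exp(2i * pi * k / M)
  gf <- solve_gf(z, T, params, grid, dt = dt, batch_size = batch_size)
  damp <- radius^(-(n_lo:n_hi))
  weight <- vapply(seq_len(grid$n_x), function(i) {
    g_half <- gf$values[i, ]
    g_full <- complex(length.out = M)
    g_full[k + 1] <- g_half
    if (M > 2) g_full[M:(M %/% 2 + 2)] <- Conj(g_half[2:(M %/% 2)])
    p <- Re(fft(g_full))[(n_lo:n_hi) + 1] / M * damp
    sum(pmax(p, 0))
  }, numeric(1))
  tibble(x = grid$x, weight = weight)
}

#' Posterior log-tempo of a random historical clade member given modern
#' diversity
#'
#' The tempo of a randomly chosen species alive at time \eqn{t} in a clade
#' known to contain \eqn{n_T} species at the horizon \eqn{T}, marginalised
#' over the unknown founder tempo:
#' \deqn{p(x_t \mid n_T) \approx \frac{\int p(x_t \mid x_0)\,P(n_T \mid
#'   x_0)\,p(x_0)\,dx_0}{P(n_T)},}
#' using the approximation that a single historical species contributes
#' negligibly to \eqn{n_T} (exact at \eqn{t = 0}, reasonable once the
#' clade is no longer small). \eqn{p(x_t \mid x_0)} is the
#' replicator-mutation density started from a point mass at \eqn{x_0},
#' solved on a coarse founder subgrid and linearly interpolated between
#' subgrid nodes.
#'
#' @param t Time since clade origin (myr), in \eqn{[0, T]}.
#' @param T Horizon (myr).
#' @param n_T Modern clade size conditioned on.
#' @param params,grid Model parameters and grid.
#' @param window Relative half-width of the diversity window.
#' @param M Contour size for the diversity weights (see
#'   [historical_member_weights()]).
#' @param dt PDE time step.
#' @param weights Optional precomputed tibble from
#'   [historical_member_weights()].
#' @param prior Optional equilibrium prior (a `cet_density`).
#' @param n_x0 Number of founder-subgrid nodes for the forward solves.
#' @return A tibble of class `cet_density` with attributes `mean`, `sd`,
#'   `age` (\eqn{T - t}) and `mode = "member"`.
#' @export
historical_member_posterior <- function(t, T = 500, n_T,
                                        params = cet_params(),
                                        grid = log_tempo_grid(),
                                        window = 0.1, M = NULL, dt = 0.25,
                                        weights = NULL, prior = NULL,
                                        n_x0 = 33L) {
  if (t < 0 || t > T) stop("t must lie in [0, T]", call. = FALSE)
  if (n_T < 1) stop("n_T must be at least 1", call. = FALSE)
  if (is.null(prior)) prior <- equilibrium_density(params, grid)
  if (is.null(weights)) {
    weights <- historical_member_weights(T, n_T, params, grid,
                                         window = window, M = M, dt = dt)
  }
  w_founder <- weights$weight * prior$density
  if (t == 0) {
    return(posterior_from_weight(w_founder, grid, age = T, mode = "member"))
  }
  mean_n_t <- sum(prior$density *
                    mean_species(t, params, grid, dt = dt)$n_expected) *
    grid$dx
  if (mean_n_t < 10) {
    warning(sprintf(
      "historical diversity is small at t = %g (E[n] = %.2f); the diversity-independence approximation may be inaccurate",
      t, mean_n_t), call. = FALSE)
  }
  sub_idx <- unique(round(seq(1, grid$n_x, length.out = n_x0)))
  spikes <- matrix(0, grid$n_x, length(sub_idx))
  spikes[cbind(sub_idx, seq_along(sub_idx))] <- 1 / grid$dx
  fwd <- build_forward_operator(grid, params, growth_rate = params$r)
  plan <- step_plan(t, dt)
  cond <- march_theta(spikes, fwd$matrix, plan$dt, plan$n, n_implicit = 2L,
                      renorm = TRUE, dx = grid$dx)$field
  # accumulate founder weights onto subgrid coefficients by linear
  # interpolation in x0
  coef <- numeric(length(sub_idx))
  xs <- grid$x[sub_idx]
  for (i in seq_len(grid$n_x)) {
    wi <- w_founder[i]
    if (wi <= 0) next
    j <- findInterval(grid$x[i], xs, all.inside = TRUE)
    a <- (grid$x[i] - xs[j]) / (xs[j + 1] - xs[j])
    a <- min(max(a, 0), 1)
    coef[j] <- coef[j] + wi * (1 - a)
    coef[j + 1] <- coef[j + 1] + wi * a
  }
  posterior_from_weight(as.numeric(cond %*% coef), grid, age = T - t,
                        mode = "member")
}

#' Expected historical tempo trajectories
#'
#' Assembles mean and standard-deviation curves of historical log-tempo
#' across ages, for either the direct ancestors of a random modern taxon
#' (`mode = "ancestor"`, [ancestor_posterior()]) or a random member of a
#' clade conditioned on its modern diversity (`mode = "member"`,
#' [historical_member_posterior()]).
#'
#' @param T Clade age (myr).
#' @param params,grid Model parameters and grid.
#' @param ages Ages (myr before present) at which to evaluate; within
#'   \eqn{[0, T]}.
#' @param mode `"ancestor"` or `"member"`.
#' @param n_T Modern clade size (member mode only).
#' @param window,M Diversity-window settings (member mode only).
#' @param dt PDE time step.
#' @param prior Optional precomputed equilibrium prior.
#' @return A tibble of class `cet_trajectory` with columns `age`, `mean`,
#'   `sd` and `mode`.
#' @export
tempo_trajectory <- function(T = 500, params = cet_params(),
                             grid = log_tempo_grid(),
                             ages = seq(0, T, by = 25),
                             mode = c("ancestor", "member"), n_T = NULL,
                             window = 0.1, M = NULL, dt = 0.25,
                             prior = NULL) {
  mode <- match.arg(mode)
  ages <- sort(unique(ages))
  if (any(ages < 0 | ages > T)) stop("ages must lie in [0, T]",
                                     call. = FALSE)
  if (is.null(prior)) prior <- equilibrium_density(params, grid)
  if (mode == "ancestor") {
    op <- build_backward_operator(grid, params)
    L <- backward_full_matrix(op, reaction_rate = params$r)
    n_field <- rep(1, grid$n_x)
    t_now <- 0
    rows <- purrr::map_dfr(ages, function(a) {
      gap <- a - t_now
      if (gap > 1e-12) {
        plan <- step_plan(gap, dt)
        n_field <<- march_theta(n_field, L, plan$dt, plan$n)$field
        t_now <<- a
      }
      post <- posterior_from_weight(prior$density * n_field, grid,
                                    age = a, mode = "ancestor")
      tibble(age = a, mean = attr(post, "mean"), sd = attr(post, "sd"))
    })
  } else {
    if (is.null(n_T)) stop("member mode needs n_T", call. = FALSE)
    weights <- historical_member_weights(T, n_T, params, grid,
                                         window = window, M = M, dt = dt)
    rows <- purrr::map_dfr(ages, function(a) {
      post <- historical_member_posterior(T - a, T, n_T, params, grid,
                                          window = window, dt = dt,
                                          weights = weights, prior = prior)
      tibble(age = a, mean = attr(post, "mean"), sd = attr(post, "sd"))
    })
  }
  structure(dplyr::mutate(rows, mode = mode),
            class = c("cet_trajectory", class(tibble())),
            T = T, params = params, n_T = n_T)
}
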