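test_that("tempo densities stay normalised and converge from any start", {
  g <- default_grid()
  p <- core_params()
  slices <- lapply(c(-2, 0, 2), function(x0) {
    d <- evolve_tempo_density(x0, c(100, 500), p, g, dt = 0.25)
    list(mid = d$density[d$t == 100], end = d$density[d$t == 500])
  })
  for (s in slices) {
    expect_lt(abs(sum(s$mid) * g$dx - 1), 1e-6)
    expect_lt(abs(sum(s$end) * g$dx - 1), 1e-6)
    expect_true(all(s$end >= 0))
  }
  # pairwise total variation at t = 500 below 0.05
  for (a in 1:2) for (b in (a + 1):3) {
    expect_lt(tv_dist(slices[[a]]$end, slices[[b]]$end) * g$dx, 0.05)
  }
})

test_that("delta initial conditions are honoured", {
  g <- default_grid()
  d0 <- evolve_tempo_density(2, 0, core_params(), g)
  mom <- density_moments(d0[d0$t == 0, ])
  expect_equal(mom$mean, 2)
  expect_lte(mom$sd, g$dx)
  expect_error(evolve_tempo_density(rep(-1, 10), 5, core_params(), g),
               "scalar or a density")
})

test_that("r = 0 equilibrium is the closed-form Gaussian with mean -1", {
  g <- default_grid()
  eq <- equilibrium_density(cet_params(0.5, 0.5, 0.01, 1), g)
  expect_lt(abs(attr(eq, "mean") + 1), 0.05)
  expect_lt(abs(attr(eq, "sd") - 1), 0.05)
  expect_lt(max(abs(eq$density - dnorm(g$x, -1, 1))), 0.01)
})

test_that("r = theta equilibrium has mean zero and sd of order s", {
  eq <- equilibrium_density(core_params(), default_grid())
  expect_lt(abs(attr(eq, "mean")), 0.05)
  expect_gt(attr(eq, "sd"), 0.5)
  expect_lt(attr(eq, "sd"), 2)
})

test_that("equilibrium mean increases with the diversification rate", {
  g <- default_grid()
  means <- sapply(c(0, 0.005, 0.01, 0.02), function(r) {
    attr(equilibrium_density(cet_params(0.5 + r, 0.5, 0.01, 1), g,
                             tol = 1e-9), "mean")
  })
  expect_true(all(diff(means) > 0))
})

test_that("the equilibrium is a fixed point of the dynamics", {
  g <- default_grid()
  p <- core_params()
  eq <- equilibrium_density(p, g)
  re <- evolve_tempo_density(eq$density, 100, p, g, dt = 0.5)
  expect_lt(max(abs(re$density[re$t == 100] - eq$density)), 1e-6)
})

test_that("the equilibrium matches the principal eigenvector of the flow", {
  g <- default_grid()
  p <- core_params()
  eq <- equilibrium_density(p, g)
  A <- as.matrix(build_forward_operator(g, p, growth_rate = p$r)$matrix)
  ev <- eigen(A)
  top <- which.max(Re(ev$values))
  v <- Re(ev$vectors[, top])
  v <- v * sign(sum(v))
  v <- v / (sum(v) * g$dx)
  expect_lt(tv_dist(v, eq$density) * g$dx, 1e-6)
})

test_that("without self-scaling and selection the OU stationary law appears", {
  g <- default_grid()
  op <- build_forward_operator(g, cet_params(0.5, 0.5, 0.05, 1),
                               growth_rate = 0, self_scaling = FALSE)
  u <- numeric(g$n_x)
  u[x_index(g, 0)] <- 1 / g$dx
  res <- march_theta(u, op$matrix, 1, 4000, theta = 1, n_implicit = 2L,
                     renorm = TRUE, dx = g$dx, stop_tol = 1e-12)
  expect_lt(max(abs(res$field - dnorm(g$x, 0, 1))), 0.01)
})

test_that("without mean reversion the average tempo runs away", {
  g <- default_grid()
  p0 <- cet_params(0.51, 0.5, 0, 1)
  u0 <- dnorm(g$x, 0, 1) * (abs(g$x) <= 3)
  tt <- c(0, 10, 20, 40, 80)
  d <- evolve_tempo_density(u0, tt, p0, g)
  met <- sapply(tt, function(t1) mean_tempo(d[d$t == t1, c("x", "density")]))
  expect_true(all(diff(met) > 0))
})

test_that("density moments handle symmetric and summary cases", {
  g <- default_grid()
  sym <- tibble::tibble(x = g$x, density = dnorm(g$x, 0, 1.3))
  expect_lt(abs(density_moments(sym)$mean), 1e-10)
  paths <- evolve_tempo_density(0, c(0, 50), core_params(), g, dt = 0.5)
  summ <- tidy(paths)
  expect_equal(names(summ), c("t", "mean", "sd"))
  expect_equal(nrow(summ), 2)
})
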