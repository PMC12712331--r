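test_that("backward operator differentiates as advertised", {
  g <- default_grid()
  p <- core_params()
  op <- build_backward_operator(g, p)
  # annihilates constants everywhere (reflecting closure included)
  expect_lt(max(abs(as.numeric(op$matrix %*% rep(1, g$n_x)))), 1e-12)
  # on f(x) = x the drift gives -theta * x exactly (interior)
  fx <- as.numeric(op$matrix %*% g$x)
  expect_lt(max(abs(fx + p$theta * g$x)[3:(g$n_x - 2)]), 1e-12)
  # theta = 0 switches the operator off entirely
  op0 <- build_backward_operator(g, cet_params(0.51, 0.5, 0, 1))
  expect_equal(max(abs(op0$matrix)), 0)
  op00 <- build_forward_operator(g, cet_params(0.51, 0.5, 0, 0))
  expect_equal(max(abs(op00$matrix)), 0)
})

test_that("forward operator conserves mass and is the discrete adjoint", {
  g <- default_grid()
  p <- core_params()
  fwd <- build_forward_operator(g, p)
  bwd <- build_backward_operator(g, p)
  set.seed(1)
  u <- abs(stats::rnorm(g$n_x)) + dnorm(g$x, 1, 0.7)
  expect_lt(abs(sum(as.numeric(fwd$matrix %*% u)) * g$dx), 1e-10)
  f <- sin(g$x) + 0.2 * g$x
  lhs <- sum(exp(g$x) * as.numeric(bwd$matrix %*% f) * u) * g$dx
  rhs <- sum(f * as.numeric(fwd$matrix %*% u)) * g$dx
  expect_lt(abs(lhs - rhs), 1e-8)
})

test_that("theta-stepper handles identity, decay and long conservation", {
  L0 <- Matrix::Matrix(0, 3, 3, sparse = TRUE)
  f <- c(1, 2, 3)
  expect_equal(step_imex(f, NULL, 0.1, L0), f)
  # pure decay reaction marched 1000 steps reaches e^{-1} within 1e-4
  fld <- c(1, 1, 1)
  for (i in 1:1000) fld <- step_imex(fld, function(v) -v, 0.001, L0)
  expect_lt(abs(fld[1] - exp(-1)), 1e-4)
  # a Gaussian density keeps unit mass for 500 myr under the forward flow
  g <- default_grid()
  A <- build_forward_operator(g, core_params())$matrix
  u0 <- dnorm(g$x, 0, 1)
  res <- march_theta(u0, A, 0.25, 2000)
  expect_lt(abs(sum(res$field) * g$dx - sum(u0) * g$dx), 1e-8)
  expect_error(step_imex(c(1, NaN, 1), NULL, 0.1, L0), "non-finite")
})

test_that("Crank-Nicolson marching is second order on a smooth problem", {
  g <- narrow_grid()
  p <- core_params()
  op <- build_backward_operator(g, p)
  L <- cetempo:::backward_full_matrix(op, reaction_rate = -1.01)
  f0 <- 1 + 0.3 * sin(g$x)
  ref <- march_theta(f0, L, 0.005, 4000)$field
  e1 <- max(abs(march_theta(f0, L, 0.16, 125)$field - ref))
  e2 <- max(abs(march_theta(f0, L, 0.08, 250)$field - ref))
  expect_gt(e1 / e2, 3)
  expect_lt(e1 / e2, 6)
})

test_that("homogeneous limit reduces to independent per-node ODEs", {
  # with s = 0, theta = 0 the full operator is diagonal, so each node
  # evolves as a scalar exponential decay at rate e^x (lambda + mu)
  g <- narrow_grid()
  op <- build_backward_operator(g, homog_params())
  L <- cetempo:::backward_full_matrix(op, reaction_rate = -1.01)
  res <- march_theta(rep(1, g$n_x), L, 0.001, 2000)$field
  expect_lt(max(abs(res - exp(-1.01 * exp(g$x) * 2))), 1e-5)
})

test_that("doubling the grid changes key outputs by far less than 0.5%", {
  p <- core_params()
  vals <- sapply(c(201, 401), function(nx) {
    g <- log_tempo_grid(n_x = nx)
    c(p0 = extinction_prob(500, p, g, dt = 0.5)$p_extinct[x_index(g, 0)],
      sd = attr(equilibrium_density(p, g, tol = 1e-9), "sd"))
  })
  expect_lt(abs(vals["p0", 2] / vals["p0", 1] - 1), 0.005)
  expect_lt(abs(vals["sd", 2] / vals["sd", 1] - 1), 0.005)
})
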