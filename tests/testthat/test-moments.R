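test_that("mean species starts at one and grows exponentially when homogeneous", {
  g <- narrow_grid()
  p <- homog_params()
  expect_equal(mean_species(0, p, g)$n_expected, rep(1, g$n_x))
  n50 <- mean_species(50, p, g, dt = 0.01)$n_expected[x_index(g, 0)]
  expect_lt(abs(n50 / exp(0.01 * 50) - 1), 1e-8)
})

test_that("second moment matches the classical law and its own inversion", {
  g <- narrow_grid()
  i0 <- x_index(g, 0)
  mom <- second_moment(200, homog_params(), g, dt = 0.05)
  expect_lt(abs(mom$m2[i0] / bdp_m2(200, 0.51, 0.5) - 1), 0.001)
  expect_equal(second_moment(0, core_params(), g)$m2, rep(0, g$n_x))
  # short-time expansion M2 ~ 2 lambda t e^x
  gd <- default_grid()
  mom2 <- second_moment(0.2, core_params(), gd, dt = 0.002)
  for (x0 in c(-2, 0, 2)) {
    i <- x_index(gd, x0)
    expect_lt(abs(mom2$m2[i] / (2 * 0.51 * 0.2 * exp(x0)) - 1), 0.05)
  }
  # cross-check against the full distribution at t = 50; the n(n-1)
  # weighting amplifies FFT round-off by rho^{-n} n^2 at the largest
  # resolved sizes, so the factorial-moment sum uses a milder contour
  # damping than probability queries need
  d <- invert_gf(50, 0, core_params(), gd, M = 4096L, dt = 0.1,
                 radius = 10^(-4 / 4096))
  m2_inv <- sum(d$n * (d$n - 1) * d$p)
  m2_pde <- second_moment(50, core_params(), gd, dt = 0.1)$m2[x_index(gd, 0)]
  expect_lt(abs(m2_inv / m2_pde - 1), 0.005)
})

test_that("experienced size is size-biased, bounded below by the mean", {
  g <- default_grid()
  p <- core_params()
  # at t = 0 every clade has exactly one species: the degenerate case
  expect_equal(experienced_size(0, 0, p, g), 1)
  for (tt in c(50, 200)) {
    mom <- second_moment(tt, p, g, dt = 0.25)
    i0 <- x_index(g, 0)
    exp_size <- experienced_size(tt, 0, p, g, dt = 0.25)
    expect_gte(exp_size, mom$n_expected[i0])
  }
  # homogeneous benchmark: experienced / conditional mean -> (lambda+mu)/lambda
  gn <- narrow_grid()
  momh <- second_moment(200, homog_params(), gn, dt = 0.05)
  ih <- x_index(gn, 0)
  nh <- momh$n_expected[ih]
  ratio <- ((momh$m2[ih] + nh) / nh) / (nh / (1 - bdp_p0(200, 0.51, 0.5)))
  expect_lt(abs(ratio - 1.01 / 0.51), 0.05)
})

test_that("forward density integral equals the backward mean", {
  g <- default_grid()
  p <- core_params()
  fwd <- build_forward_operator(g, p, growth_rate = p$r)
  for (x0 in c(-2, 0)) {
    u <- numeric(g$n_x)
    u[x_index(g, x0)] <- 1 / g$dx
    u <- march_theta(u, fwd$matrix, 0.25, 2000, n_implicit = 2L)$field
    n_val <- mean_species(500, p, g, dt = 0.25)$n_expected[x_index(g, x0)]
    expect_lt(abs(sum(u) * g$dx / n_val - 1), 0.005)
  }
})

test_that("diversification curves order by starting tempo and parallelise", {
  g <- default_grid()
  cur <- diversification_curves(500, c(-2, 0, 2), core_params(), g,
                                dt = 0.25, t_eval = seq(0, 500, by = 20))
  at100 <- cur[cur$t == 100, ]
  expect_true(all(diff(at100$species[order(at100$x0)]) > 0))
  # late-time log-slopes agree within 5% ("parallel lines")
  late <- cur[cur$t >= 400, ]
  slopes <- sapply(split(late, late$x0), function(df) {
    stats::coef(stats::lm(log(species) ~ t, df))[2]
  })
  expect_lt(max(slopes) / min(slopes) - 1, 0.05)
  # lineages never exceed species and the two curves meet at the horizon
  # (tolerance 1e-4: the forward density march opens with two damped
  # backward-Euler steps for the point mass, so it is not the exact
  # discrete adjoint of the mean march in those first steps)
  expect_true(all(cur$lineages <= cur$species * (1 + 1e-4)))
  at_end <- cur[cur$t == 500, ]
  expect_equal(at_end$lineages, at_end$species, tolerance = 1e-4)
})

test_that("surviving clades show the push of the past", {
  g <- default_grid()
  p <- core_params()
  cc <- diversification_curves(100, 0, p, g, conditional = TRUE,
                               n_reps = 400L, seed = 11,
                               t_eval = seq(0, 100, by = 25))
  expect_error(diversification_curves(100, 0, p, g, conditional = TRUE,
                                      n_reps = 50L), "n_reps")
  uncond <- mean_species(50, p, g, dt = 0.25)$n_expected[x_index(g, 0)]
  # conditional early growth far exceeds the unconditional mean
  expect_gt(cc$species[cc$t == 50], 2 * uncond)
  # lineage curve meets the species curve at the horizon
  expect_equal(cc$species[cc$t == 100], cc$lineages[cc$t == 100])
  expect_true(all(cc$lineages <= cc$species + 1e-9))
})
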