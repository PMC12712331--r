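test_that("ancestor posterior at age zero is the equilibrium prior", {
  g <- default_grid()
  p <- core_params()
  eq <- equilibrium_density(p, g)
  post <- ancestor_posterior(0, 500, p, g, prior = eq)
  expect_lt(tv_dist(post$density, eq$density) * g$dx, 1e-10)
  expect_error(ancestor_posterior(600, 500, p, g, prior = eq), "age")
})

test_that("a flat likelihood leaves the prior untouched", {
  g <- default_grid()
  eq <- equilibrium_density(core_params(), g)
  post <- cetempo:::posterior_from_weight(eq$density * 7.3, g, age = 10,
                                          mode = "ancestor")
  expect_equal(post$density, eq$density, tolerance = 1e-12)
})

test_that("ancestor posterior mean rises with age and then plateaus", {
  g <- default_grid()
  p <- core_params()
  eq <- equilibrium_density(p, g)
  tr <- tempo_trajectory(500, p, g, ages = seq(0, 400, by = 50),
                         mode = "ancestor", dt = 0.25, prior = eq)
  expect_true(all(diff(tr$mean) > -1e-9))
  expect_lt(abs(tr$mean[tr$age == 400] - tr$mean[tr$age == 300]), 0.02)
  # every posterior is a proper density
  post <- ancestor_posterior(300, 500, p, g, prior = eq)
  expect_true(all(post$density >= 0))
  expect_lt(abs(sum(post$density) * g$dx - 1), 1e-6)
})

test_that("member posterior at t = 0 reduces to the exact Bayes formula", {
  g <- default_grid()
  p <- core_params()
  eq <- equilibrium_density(p, g)
  w <- historical_member_weights(100, 50, p, g, M = 1024L, dt = 0.25)
  post <- historical_member_posterior(0, 100, 50, p, g, weights = w,
                                      prior = eq)
  manual <- w$weight * eq$density
  manual <- manual / (sum(manual) * g$dx)
  expect_equal(post$density, manual, tolerance = 1e-12)
  expect_error(historical_member_weights(100, 2000, p, g, M = 1024L),
               "too small")
})

test_that("clade-member tempo declines from the origin to the present", {
  g <- default_grid()
  p <- core_params()
  eq <- equilibrium_density(p, g)
  n_t <- round(experienced_size(100, 0, p, g, dt = 0.25))
  tr <- suppressWarnings(
    tempo_trajectory(100, p, g, ages = c(0, 25, 50, 75, 100),
                     mode = "member", n_T = n_t, dt = 0.25, prior = eq))
  expect_true(all(diff(tr$mean) > 0)) # mean grows with age
  # direct ancestors of modern taxa are tempo-elevated relative to the
  # clade as a whole away from the origin
  anc <- tempo_trajectory(100, p, g, ages = c(25, 50), mode = "ancestor",
                          dt = 0.25, prior = eq)
  for (a in c(25, 50)) {
    expect_gt(anc$mean[anc$age == a], tr$mean[tr$age == a])
  }
})

test_that("the diversity window width hardly moves the posterior mean", {
  g <- default_grid()
  p <- core_params()
  eq <- equilibrium_density(p, g)
  means <- sapply(c(0.1, 0.2), function(win) {
    w <- historical_member_weights(100, 400, p, g, window = win, M = 1024L,
                                   dt = 0.25)
    attr(historical_member_posterior(0, 100, 400, p, g, weights = w,
                                     prior = eq), "mean")
  })
  expect_lt(abs(means[2] - means[1]), 0.02)
})

test_that("simulated ancestor tempos reproduce the Bayes posterior", {
  # fast mean reversion keeps descendant counts light-tailed so that the
  # tip-weighted Monte Carlo average is an unbiased, low-variance estimate
  ps <- cet_params(0.55, 0.5, 0.2, 1)
  g <- default_grid()
  eq <- equilibrium_density(ps, g)
  cdf <- cumsum(eq$density) * g$dx
  set.seed(33)
  T_h <- 60
  snaps <- c(20, 45)
  trees <- list()
  tries <- 0
  while (length(trees) < 600 && tries < 40000) {
    tries <- tries + 1
    x0 <- g$x[findInterval(stats::runif(1), cdf) + 1]
    tr <- simulate_clade(ps, x0, T_h, dt = 0.25, cap = 5e4,
                         snapshot_times = snaps)
    if (attr(tr, "survived") && !attr(tr, "truncated")) {
      trees[[length(trees) + 1]] <- tr
    }
  }
  mc <- ancestral_tempo_mc(trees, snaps)
  for (tt in snaps) {
    ap <- ancestor_posterior(T_h - tt, T_h, ps, g, prior = eq)
    expect_lt(abs(attr(ap, "mean") - mc$mean_x[mc$time == tt]),
              2 * mc$se[mc$time == tt])
  }
})

test_that("the tip-weighted ancestor summary is exact on a known tree", {
  tr <- toy_tree()
  mc <- ancestral_tempo_mc(list(tr), c(1, 4, 8))
  # time 1: root branch carries all 3 tips
  expect_equal(mc$mean_x[mc$time == 1], 0.1)
  # time 4: branch 2 has 1 tip (x 0.6), branch 3 has 2 tips (x 0.2)
  expect_equal(mc$mean_x[mc$time == 4], (0.6 + 2 * 0.2) / 3)
  # time 8: the three tips themselves
  expect_equal(mc$mean_x[mc$time == 8], (0.9 + 0.0 - 0.5) / 3)
  expect_equal(mc$n_tips, rep(3, 3))
})
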