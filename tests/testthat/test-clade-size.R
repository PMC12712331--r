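test_that("inversion recovers the homogeneous clade-size law to 1e-6", {
  g <- default_grid()
  d <- invert_gf(50, 0, homog_params(), g, M = 256L)
  expected <- bdp_pn(50, 100, 0.51, 0.5)
  expect_lt(max(abs(d$p[1:101] - expected)), 1e-6)
  expect_lt(abs(sum(d$p) + attr(d, "tail_mass") - 1), 1e-6)
  expect_true(all(d$p >= 0))
})

test_that("inversion round-trips through a held-out z value", {
  g <- default_grid()
  p <- core_params()
  d <- invert_gf(50, 0, p, g, M = 1024L, dt = 0.25)
  z <- 0.37
  g_rec <- sum(d$p * z^d$n)
  g_direct <- Re(solve_gf(z, 50, p, g, dt = 0.25)$values[x_index(g, 0), 1])
  expect_lt(abs(g_rec - g_direct), 1e-6)
})

test_that("inversion validates its inputs", {
  g <- default_grid()
  expect_error(invert_gf(10, 0, core_params(), g, M = 1000L), "power of two")
  expect_error(invert_gf(10, 0, core_params(), g, M = 256L, radius = 1.5),
               "radius")
})

test_that("survival conditioning renormalises correctly", {
  d <- cetempo:::new_clade_dist(
    tibble::tibble(n = 0:2, p = c(0.5, 0.25, 0.25)), tail_mass = 0, M = 3L,
    radius = 1, t = 1, x0 = 0, conditional = FALSE, params = core_params())
  dc <- condition_on_survival(d)
  expect_equal(dc$p, c(0, 0.5, 0.5))
  # idempotent, and a no-op when P0 = 0
  expect_identical(condition_on_survival(dc)$p, dc$p)
  # conditional mean equals unconditional mean / (1 - P0)
  expect_equal(sum(dc$n * dc$p), sum(d$n * d$p) / (1 - d$p[1]))
  d1 <- cetempo:::new_clade_dist(
    tibble::tibble(n = 0:1, p = c(1, 0)), tail_mass = 0, M = 2L,
    radius = 1, t = 1, x0 = 0, conditional = FALSE, params = core_params())
  expect_error(condition_on_survival(d1), "P0")
})

test_that("homogeneous sister proportions are uniform with P(ratio>=20) = 2/21", {
  g <- default_grid()
  imb <- sister_imbalance(500, 0, homog_params(), g, M = 65536L,
                          k_thresholds = c(1, 20))
  ex20 <- imb$exceedance[imb$exceedance$k == 20, ]
  expect_lt(abs(ex20$p_mid - 2 / 21), 0.001)
  expect_equal(imb$exceedance$p_mid[imb$exceedance$k == 1], 1)
  d <- imb$density
  interior <- d$proportion > 0.02 & d$proportion < 0.98
  expect_lt(max(abs(d$density[interior] - 1)), 0.01)
  expect_lt(abs(sum(d$density) * diff(d$proportion[1:2]) - 1), 1e-4)
})

test_that("sister-proportion density is symmetric and integrates to one", {
  g <- default_grid()
  imb <- sister_imbalance(100, 0, core_params(), g, M = 4096L, dt = 0.5,
                          k_thresholds = c(2, 5, 20))
  d <- imb$density
  expect_lt(max(abs(d$density - rev(d$density))), 1e-10)
  expect_lt(abs(sum(d$density) * diff(d$proportion[1:2]) - 1), 1e-4)
  # exceedance decreasing in k, bounds ordered
  expect_true(all(diff(imb$exceedance$p_mid) < 0))
  expect_true(all(imb$exceedance$p_lower <= imb$exceedance$p_upper))
})

test_that("a degenerate size distribution gives a point mass at one half", {
  deg <- cetempo:::new_clade_dist(
    tibble::tibble(n = 0:7, p = c(0, 0, 0, 0, 0, 1, 0, 0)), tail_mass = 0,
    M = 8L, radius = 1, t = 1, x0 = 0, conditional = TRUE,
    params = core_params())
  imb <- sister_imbalance(dist = deg, k_thresholds = c(2, 20), n_bins = 100L)
  d <- imb$density
  expect_equal(d$density[d$proportion == 0.5], 100)
  expect_equal(sum(d$density > 0), 1)
  expect_equal(imb$exceedance$p_mid, c(0, 0))
})
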